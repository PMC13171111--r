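# Independent oracles and shared fixtures for the test suite.

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled sample to the first group (no ties assumed).
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Brute-force minimum Euclidean pixel distance between two masks,
# over ALL pixel pairs (not just boundaries).
brute_min_dist <- function(mask_a, mask_b) {
  pa <- which(mask_a, arr.ind = TRUE)
  pb <- which(mask_b, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Brute-force microglia-association category for each neuron id.
brute_mg_categories <- function(labels, cell_ids, classes, pixel_size_um) {
  neurons <- cell_ids[classes %in% c("IN", "PN")]
  mgs <- cell_ids[classes == "MG"]
  out <- setNames(rep(NA_character_, length(cell_ids)), cell_ids)
  for (nid in neurons) {
    if (length(mgs) == 0) { out[as.character(nid)] <- "FREE"; next }
    tied <- FALSE; near <- FALSE
    for (mid in mgs) {
      d <- brute_min_dist(labels == nid, labels == mid)
      if (d <= sqrt(2) + 1e-9) { tied <- TRUE; break }
      body_len <- 2 * sqrt(sum(labels == mid) / pi) * pixel_size_um
      if (d * pixel_size_um <= body_len) near <- TRUE
    }
    out[as.character(nid)] <- if (tied) "TIED" else if (near) "NEAR" else "FREE"
  }
  out
}

# Greedy matching of detected puncta to true spots within tol_px.
match_puncta <- function(pk, spots, tol_px = 3) {
  used <- rep(FALSE, nrow(spots))
  tp <- 0L
  for (i in seq_len(nrow(pk))) {
    d2 <- (spots$row - pk$centroid_row[i])^2 +
      (spots$col - pk$centroid_col[i])^2
    j <- which(!used & d2 <= tol_px^2)
    if (length(j)) { used[j[which.min(d2[j])]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, precision = tp / max(nrow(pk), 1),
       recall = tp / max(nrow(spots), 1), matched = used)
}

# Run the full imaging chain on a simulated field.
run_imaging_chain <- function(sim, marker_channels = character(0)) {
  st <- sim$stack
  cs <- detect_somata(st$channels$Nissl, st$pixel_size_um)
  cs <- classify_cells(cs, st)
  cs <- partition_nucleus_cytoplasm(
    cs, st$channels$Nissl,
    which_cells = cs$cells$cell_id[cs$cells$cell_class %in% c("IN", "PN")])
  cs <- score_mg_association(cs)
  pk <- quantify_cells(st, cs, marker_channels = marker_channels)
  list(cs = cs, pk = pk)
}

# Match detected cells to true cells by nearest centroid.
match_cells <- function(cs, truth) {
  vapply(seq_len(nrow(cs$cells)), function(i) {
    d <- (truth$cells$cr - cs$cells$centroid_row[i])^2 +
      (truth$cells$cc - cs$cells$centroid_col[i])^2
    truth$cells$cell_id[which.min(d)]
  }, integer(1))
}

# Shared medium-size simulated field, built once per test run.
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- force(expr)
  sim_cache[[key]]
}

medium_sim <- function() cached_sim("medium", simulate_image(sim_image_params(
  n_cells = c(IN = 3, PN = 5, NN = 3, MG = 3), field_px = 1280, seed = 101)))

medium_chain <- function() cached_sim("medium_chain",
                                      run_imaging_chain(medium_sim()))
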