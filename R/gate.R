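# Cell-class gating from marker positivity and microglia-association
# scoring from segmentation masks.

#' Classify cells from marker positivity
#'
#' Per-channel positivity: mean soma intensity above `background median +
#' k_mad * MAD`, the background being all pixels outside every soma.
#' Decision order per cell: Iba1+ is microglia (MG); else Nissl+, NeuN+
#' and GABA-marker+ is an inhibitory interneuron (IN); Nissl+ and NeuN+
#' without the GABA marker is a pyramidal neuron (PN); Nissl+ only is
#' non-neuronal (NN); anything else is UNCLASSIFIED. Gating is
#' deterministic and independent across cells. The GABA-marker role
#' accepts either a Gad67 antibody channel or a tdTomato reporter channel.
#'
#' @param cell_set A `cell_set` from [detect_somata()].
#' @param stack The [image_stack()] the cells were segmented from.
#' @param markers Named list mapping roles to channel names:
#'   `nissl`, `neun`, `gaba`, `iba1`.
#' @param k_mad Positivity threshold in background MAD units (default 3).
#' @return The `cell_set` with `cell_class` filled in.
#' @export
classify_cells <- function(cell_set, stack,
                           markers = list(nissl = "Nissl", neun = "NeuN",
                                          gaba = "Gad67", iba1 = "Iba1"),
                           k_mad = 3) {
  stopifnot(inherits(cell_set, "cell_set"), inherits(stack, "image_stack"))
  for (role in c("nissl", "neun", "gaba", "iba1")) {
    chn <- markers[[role]]
    if (is.null(chn) || !chn %in% names(stack$channels))
      stop("missing required channel for role '", role, "'")
  }
  labels <- cell_set$soma_labels
  bg <- labels == 0L
  cells <- cell_set$cells
  n <- nrow(cells)
  if (n == 0L) return(cell_set)
  # measure marker means on 2-px-eroded soma masks so that pixels bled
  # across a contact boundary by the watershed do not contaminate the gate
  core_idx <- lapply(cells$cell_id, function(id) {
    pos <- which(labels == id, arr.ind = TRUE)
    r0 <- min(pos[, 1]); r1 <- max(pos[, 1])
    c0 <- min(pos[, 2]); c1 <- max(pos[, 2])
    sub <- labels[r0:r1, c0:c1] == id
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(sub * 1),
                                            EBImage::makeBrush(5, "box"))) > 0
    use <- if (sum(er) >= 25) er else sub
    w <- which(use, arr.ind = TRUE)
    cbind(w[, 1] + r0 - 1L, w[, 2] + c0 - 1L)
  })
  roles <- c("nissl", "neun", "gaba", "iba1")
  positive <- matrix(FALSE, n, length(roles),
                     dimnames = list(NULL, roles))
  for (role in roles) {
    ch <- stack$channels[[markers[[role]]]]
    thr <- median(ch[bg]) + k_mad * mad(ch[bg])
    means <- vapply(core_idx, function(ix) mean(ch[ix]), numeric(1))
    positive[, role] <- means > thr
  }
  cls <- ifelse(positive[, "iba1"], "MG",
         ifelse(positive[, "nissl"] & positive[, "neun"] & positive[, "gaba"], "IN",
         ifelse(positive[, "nissl"] & positive[, "neun"], "PN",
         ifelse(positive[, "nissl"], "NN", "UNCLASSIFIED"))))
  cell_set$cells$cell_class <- cls
  cell_set
}

# boundary pixels of a logical mask (pixels with a 4-neighbour outside)
mask_boundary <- function(mask) {
  er <- EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                          EBImage::makeBrush(3, "diamond"))) > 0
  which(mask & !er, arr.ind = TRUE)
}

# minimum Euclidean distance (px) between two pixel sets given as
# (row, col) matrices
min_pixel_distance <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(best)
}

#' Score microglia association of neurons
#'
#' Each IN/PN neuron is scored against every microglial soma: `TIED` if
#' any MG mask overlaps or touches the neuron soma (adjacency after 1-px
#' dilation, i.e. minimum pixel distance <= sqrt(2)); otherwise `FREE` if
#' the minimum boundary-to-boundary distance to every MG exceeds that
#' MG's body length (its equivalent-circle diameter, evaluated per MG);
#' otherwise `NEAR` (an intermediate category usually excluded from
#' TIED/FREE contrasts). With no MG in the field all neurons are FREE.
#' MG cells themselves get `NA`.
#'
#' @param cell_set A classified `cell_set` (after [classify_cells()]).
#' @return The `cell_set` with an `mg_association` column added.
#' @export
score_mg_association <- function(cell_set) {
  stopifnot(inherits(cell_set, "cell_set"))
  cells <- cell_set$cells
  labels <- cell_set$soma_labels
  psz <- cell_set$pixel_size_um
  cells$mg_association <- NA_character_
  neurons <- cells$cell_id[cells$cell_class %in% c("IN", "PN")]
  mgs <- cells$cell_id[cells$cell_class == "MG"]
  if (length(neurons) == 0L) { cell_set$cells <- cells; return(cell_set) }
  if (length(mgs) == 0L) {
    cells$mg_association[cells$cell_id %in% neurons] <- "FREE"
    cell_set$cells <- cells
    return(cell_set)
  }
  mg_boundary <- lapply(mgs, function(id) mask_boundary(labels == id))
  mg_bodylen_um <- vapply(mgs, function(id)
    2 * sqrt(sum(labels == id) / pi) * psz, numeric(1))
  for (id in neurons) {
    nb <- mask_boundary(labels == id)
    tied <- FALSE; near <- FALSE
    for (k in seq_along(mgs)) {
      d_px <- min_pixel_distance(nb, mg_boundary[[k]])
      if (d_px <= sqrt(2) + 1e-9) { tied <- TRUE; break }
      if (d_px * psz <= mg_bodylen_um[k]) near <- TRUE
    }
    cells$mg_association[cells$cell_id == id] <-
      if (tied) "TIED" else if (near) "NEAR" else "FREE"
  }
  cell_set$cells <- cells
  cell_set
}
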