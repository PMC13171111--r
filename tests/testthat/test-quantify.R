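# synthetic single-cell fixture: nucleus and cytoplasm masks plus spots
# rendered at known centres
make_spot_field <- function(field = 160, n_spots = 12, amp = 400,
                            sigma = 2, noise_sd = 40, seed = 9) {
  set.seed(seed)
  nuc <- outer((1:field - field / 2)^2, (1:field - field / 2)^2, "+") <= 45^2
  soma <- outer((1:field - field / 2)^2, (1:field - field / 2)^2, "+") <= 70^2
  cyt <- soma & !nuc
  img <- matrix(200 + rnorm(field^2, 0, noise_sd), field, field)
  centers <- matrix(NA_real_, 0, 2)
  nuc_idx <- which(nuc, arr.ind = TRUE)
  while (nrow(centers) < n_spots) {
    cand <- nuc_idx[sample.int(nrow(nuc_idx), 1), ]
    if (nrow(centers) == 0 ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= 64)
      centers <- rbind(centers, cand)
  }
  for (s in seq_len(n_spots)) {
    rr <- pmax(1, centers[s, 1] - 6):pmin(field, centers[s, 1] + 6)
    cc <- pmax(1, centers[s, 2] - 6):pmin(field, centers[s, 2] + 6)
    d2 <- outer((rr - centers[s, 1])^2, (cc - centers[s, 2])^2, "+")
    img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
  }
  list(img = img, nuc = nuc, cyt = cyt, centers = centers)
}

test_that("a zero-intensity compartment yields no puncta", {
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  pk <- detect_puncta(matrix(0, 64, 64), list(NUCLEAR_SPECKLE = mask), 0.1)
  expect_equal(nrow(pk), 0)
  expect_error(detect_puncta(matrix(0, 64, 64),
                             list(NUCLEAR_SPECKLE = mask), 0.1,
                             min_area_um2 = 5, max_area_um2 = 2),
               "invalid size bounds")
})

test_that("well-separated bright spots are all recovered within 1 px", {
  f <- make_spot_field()
  pk <- detect_puncta(f$img, list(NUCLEAR_SPECKLE = f$nuc,
                                  CYTOPLASMIC_GRANULE = f$cyt), 0.1)
  expect_equal(nrow(pk), 12)
  expect_true(all(pk$compartment == "NUCLEAR_SPECKLE"))
  for (i in seq_len(nrow(pk))) {
    d <- sqrt(min((f$centers[, 1] - pk$centroid_row[i])^2 +
                    (f$centers[, 2] - pk$centroid_col[i])^2))
    expect_lte(d, 1)
  }
})

test_that("a boundary-straddling spot lands in exactly one compartment", {
  field <- 120
  nuc <- matrix(FALSE, field, field); nuc[, 1:60] <- TRUE
  cyt <- !nuc
  set.seed(4)
  img <- matrix(200 + rnorm(field^2, 0, 30), field, field)
  # spot centred 2 px on the cytoplasm side of the boundary
  ctr <- c(60, 62)
  rr <- (ctr[1] - 6):(ctr[1] + 6); cc <- (ctr[2] - 6):(ctr[2] + 6)
  img[rr, cc] <- img[rr, cc] +
    500 * exp(-outer((rr - ctr[1])^2, (cc - ctr[2])^2, "+") / (2 * 4))
  pk <- detect_puncta(img, list(NUCLEAR_SPECKLE = nuc,
                                CYTOPLASMIC_GRANULE = cyt), 0.1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$compartment, "CYTOPLASMIC_GRANULE")
})

test_that("marker measurement is exact for constant and proportional markers", {
  f <- make_spot_field(noise_sd = 20, seed = 10)
  pk <- detect_puncta(f$img, list(NUCLEAR_SPECKLE = f$nuc), 0.1)
  expect_gt(nrow(pk), 5)
  const <- matrix(731.5, nrow(f$img), ncol(f$img))
  pk1 <- measure_marker_in_puncta(pk, const, "c")
  expect_true(all(pk1$marker_c == 731.5))
  pk2 <- measure_marker_in_puncta(pk, 2 * f$img, "double")
  expect_equal(pk2$marker_double, 2 * pk2$polk_mean_intensity,
               tolerance = 1e-12)
  expect_error(measure_marker_in_puncta(pk, matrix(0, 2, 2), "x"),
               "dimension mismatch")
})

test_that("speckle-level marker coupling slope is recovered by regression", {
  sim <- cached_sim("marker_sim", simulate_image(sim_image_params(
    n_cells = c(IN = 3, PN = 5, NN = 0, MG = 0), field_px = 1280,
    marker_coupling = list(a = 100, b = 1.5, sigma = 20), seed = 55)))
  ch <- run_imaging_chain(sim, marker_channels = "gH2AX")
  pk <- ch$pk[ch$pk$compartment == "NUCLEAR_SPECKLE", ]
  expect_gt(nrow(pk), 150)
  sp <- sim$truth$spots
  amp <- vapply(seq_len(nrow(pk)), function(i) {
    d2 <- (sp$row - pk$centroid_row[i])^2 + (sp$col - pk$centroid_col[i])^2
    if (min(d2) <= 4) sp$amplitude[which.min(d2)] else NA_real_
  }, numeric(1))
  ok <- !is.na(amp)
  # marker mean carries the background offset; the slope against true
  # amplitude recovers the coupling
  fit <- lm(pk$marker_gH2AX[ok] ~ amp[ok])
  expect_lt(abs(coef(fit)[2] - 1.5), 0.1)
})

test_that("feature-table arithmetic, conservation and missing rules hold", {
  sim <- medium_sim()
  ch <- medium_chain()
  ft <- build_feature_table(ch$cs, ch$pk,
                            metadata = list(age_group = "1M"))
  expect_equal(nrow(ft),
               sum(ch$cs$cells$cell_class %in% c("IN", "PN", "NN")))
  expect_equal(ft$nuclear_count_per_area,
               ft$nuclear_count / ft$nucleus_area_um2)
  expect_true(all(ft$age_group == "1M"))
  # per-cell counts agree with the puncta table
  for (k in sample(seq_len(nrow(ft)), 5)) {
    expect_equal(ft$nuclear_count[k],
                 sum(ch$pk$parent_cell_id == ft$cell_id[k] &
                       ch$pk$compartment == "NUCLEAR_SPECKLE"))
  }
  # hand arithmetic on a constructed pair
  cs <- list(cells = data.frame(cell_id = 1L, cell_class = "IN",
                                soma_area_um2 = 120, nucleus_area_um2 = 50,
                                cytoplasm_area_um2 = 70, partitioned = TRUE,
                                mg_association = "FREE",
                                stringsAsFactors = FALSE),
             pixel_size_um = 0.1)
  class(cs) <- "cell_set"
  pk <- data.frame(punctum_id = 1:10, parent_cell_id = 1L,
                   compartment = "NUCLEAR_SPECKLE", area_um2 = 0.2,
                   polk_mean_intensity = 500,
                   polk_integrated_intensity = 1000,
                   centroid_row = 1, centroid_col = 1,
                   stringsAsFactors = FALSE)
  ft1 <- build_feature_table(cs, pk)
  expect_equal(ft1$nuclear_count_per_area, 0.2)
  expect_equal(ft1$cyto_count, 0)
  expect_true(is.na(ft1$cyto_median_intensity))
  pk_bad <- pk; pk_bad$parent_cell_id <- 99L
  expect_error(build_feature_table(cs, pk_bad), "orphan punctum")
})

test_that("doubling the pixel size quarters counts per area", {
  cs_of <- function(psz) {
    cs <- list(cells = data.frame(cell_id = 1L, cell_class = "IN",
                                  soma_area_um2 = 1200 * psz^2,
                                  nucleus_area_um2 = 500 * psz^2,
                                  cytoplasm_area_um2 = 700 * psz^2,
                                  partitioned = TRUE,
                                  mg_association = NA_character_,
                                  stringsAsFactors = FALSE),
               pixel_size_um = psz)
    class(cs) <- "cell_set"
    cs
  }
  pk <- data.frame(punctum_id = 1:6, parent_cell_id = 1L,
                   compartment = "NUCLEAR_SPECKLE", area_um2 = 0.2,
                   polk_mean_intensity = 500,
                   polk_integrated_intensity = 1000,
                   centroid_row = 1, centroid_col = 1,
                   stringsAsFactors = FALSE)
  f1 <- build_feature_table(cs_of(0.1), pk)
  f2 <- build_feature_table(cs_of(0.2), pk)
  expect_equal(f2$nuclear_count_per_area, f1$nuclear_count_per_area / 4)
})
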