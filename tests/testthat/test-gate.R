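test_that("marker gating recovers every simulated class", {
  sim <- medium_sim()
  ch <- medium_chain()
  cs <- ch$cs
  mt <- match_cells(cs, sim$truth)
  truth_class <- sim$truth$cells$cell_class[match(mt, sim$truth$cells$cell_id)]
  expect_equal(cs$cells$cell_class, truth_class)
})

test_that("cells with no marker signal are UNCLASSIFIED", {
  labels <- matrix(0L, 64, 64)
  labels[20:35, 20:35] <- 1L
  cs <- punctaging:::new_cell_set(labels, 0.1)
  set.seed(2)
  flat <- function() matrix(200 + rnorm(64 * 64, 0, 5), 64, 64)
  st <- image_stack(list(Nissl = flat(), NeuN = flat(), Gad67 = flat(),
                         Iba1 = flat()), 0.1)
  cs <- classify_cells(cs, st)
  expect_equal(cs$cells$cell_class, "UNCLASSIFIED")
  expect_error(classify_cells(cs, image_stack(list(Nissl = flat()), 0.1)),
               "missing required channel")
})

test_that("gating decision order prefers microglia over neuron markers", {
  labels <- matrix(0L, 64, 64)
  labels[10:25, 10:25] <- 1L
  cs <- punctaging:::new_cell_set(labels, 0.1)
  set.seed(3)
  base <- function() matrix(200 + rnorm(64 * 64, 0, 5), 64, 64)
  hot <- function() { m <- base(); m[10:25, 10:25] <- m[10:25, 10:25] + 500; m }
  st <- image_stack(list(Nissl = hot(), NeuN = hot(), Gad67 = hot(),
                         Iba1 = hot()), 0.1)
  expect_equal(classify_cells(cs, st)$cells$cell_class, "MG")
  st2 <- image_stack(list(Nissl = hot(), NeuN = hot(), Gad67 = base(),
                          Iba1 = base()), 0.1)
  expect_equal(classify_cells(cs, st2)$cells$cell_class, "PN")
  st3 <- image_stack(list(Nissl = hot(), NeuN = base(), Gad67 = base(),
                          Iba1 = base()), 0.1)
  expect_equal(classify_cells(cs, st3)$cells$cell_class, "NN")
})

# cell_set with prescribed labels/classes (no centroid relabelling, so
# label values stay aligned with the supplied class vector)
make_gate_set <- function(labels, classes, pixel_size_um = 0.5) {
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(soma_labels = labels, nucleus_labels = NULL,
                 cyto_labels = NULL,
                 cells = data.frame(cell_id = ids, cell_class = classes[ids],
                                    stringsAsFactors = FALSE),
                 pixel_size_um = pixel_size_um),
            class = "cell_set")
}

disc_mask <- function(field, ctr, r) {
  which(outer((1:field - ctr[1])^2, (1:field - ctr[2])^2, "+") <= r^2)
}

test_that("MG association distinguishes touching, near and free neurons", {
  field <- 160
  labels <- matrix(0L, field, field)
  labels[disc_mask(field, c(40, 40), 12)] <- 1L        # neuron
  mg <- disc_mask(field, c(40, 63), 10)                # gap ~1 px: touching?
  labels[mg[labels[mg] == 0L]] <- 2L
  cs <- make_gate_set(labels, c("PN", "MG"))
  cs <- score_mg_association(cs)
  d <- brute_min_dist(labels == 1L, labels == 2L)
  expected <- if (d <= sqrt(2) + 1e-9) "TIED" else {
    body <- 2 * sqrt(sum(labels == 2L) / pi) * 0.5
    if (d * 0.5 > body) "FREE" else "NEAR"
  }
  expect_equal(cs$cells$mg_association[1], expected)
  expect_true(is.na(cs$cells$mg_association[2]))

  # boundary-sharing MG is always TIED
  labels2 <- matrix(0L, field, field)
  labels2[disc_mask(field, c(40, 40), 12)] <- 1L
  mg2 <- disc_mask(field, c(40, 64), 12)
  labels2[mg2[labels2[mg2] == 0L]] <- 2L
  cs2 <- score_mg_association(make_gate_set(labels2, c("PN", "MG")))
  expect_equal(cs2$cells$mg_association[1], "TIED")

  # gap of 1.5 body lengths -> FREE; 0.5 body lengths -> NEAR
  r_mg <- 8; body_px <- 2 * sqrt(pi * r_mg^2 / pi) # ~ 2 r
  for (cfg in list(list(gap = 1.5, want = "FREE"),
                   list(gap = 0.5, want = "NEAR"))) {
    lab <- matrix(0L, field, field)
    lab[disc_mask(field, c(60, 30), 12)] <- 1L
    ctr_col <- 30 + 12 + r_mg + cfg$gap * body_px
    lab[disc_mask(field, c(60, round(ctr_col)), r_mg)] <- 2L
    cs3 <- score_mg_association(make_gate_set(lab, c("IN", "MG")))
    expect_equal(cs3$cells$mg_association[1], cfg$want)
  }
})

test_that("no microglia in the field means every neuron is FREE", {
  labels <- matrix(0L, 64, 64)
  labels[disc_mask(64, c(30, 30), 10)] <- 1L
  cs <- score_mg_association(make_gate_set(labels, "IN"))
  expect_equal(cs$cells$mg_association, "FREE")
})

test_that("MG scoring agrees exactly with the brute-force pixel oracle", {
  sim <- cached_sim("mg_field", simulate_image(sim_image_params(
    n_cells = c(IN = 2, PN = 2, NN = 1, MG = 3), field_px = 256,
    soma_radius_um = 2.2, pixel_size_um = 0.1, lambda_nuc = 3,
    lambda_cyt = 5, seed = 33)))
  labels <- sim$truth$soma_labels
  cls <- sim$truth$cells$cell_class
  cs <- make_gate_set(labels, cls, pixel_size_um = 0.1)
  cs <- score_mg_association(cs)
  oracle <- brute_mg_categories(labels, sim$truth$cells$cell_id, cls, 0.1)
  got <- setNames(cs$cells$mg_association, cs$cells$cell_id)
  expect_identical(got[!is.na(oracle)], oracle[!is.na(oracle)])
  expect_true(all(is.na(got[cls == "MG"])))
})
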