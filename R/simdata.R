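# Synthetic tissue images and per-cell feature tables with known ground
# truth, emulating the statistical structure of aged mouse cortex imaging:
# elliptical somata of four marker-defined classes, nuclear speckles whose
# count and size decline with age, cytoplasmic granules whose count
# declines while size grows, marker intensities affinely coupled to spot
# amplitude, and replicate-level intra-cluster correlation.

#' Default per-age feature effects
#'
#' Age trajectories for the feature-table generator. Mean *differences*
#' between age groups follow the reported contrast geometry (nuclear count
#' drops ~18 then ~21 from the young level; cytoplasmic count drops ~59
#' then ~66; speckle size shrinks ~20%; granule size grows ~60%); absolute
#' scales are simulator choices. Count noise SDs (20.6 nuclear, 45
#' cytoplasmic) are calibrated so that, with truncation of counts at zero
#' and the default replicate correlation, pooled Cohen's d is ~0.85-0.95
#' for nuclear-count contrasts of the young group and ~1.3-1.45 for
#' cytoplasmic-count contrasts. Cytoplasmic median intensity rises with
#' age (the main separator of the older brackets).
#'
#' @return Named list with `means` (list feature -> named vector by age)
#'   and `sds` (list feature -> scalar).
#' @export
age_effects_default <- function() {
  ages <- c("1M", "10M", "18M")
  mk <- function(v) setNames(v, ages)
  list(
    ages = ages,
    means = list(
      nuclear_count = mk(c(40.0, 21.6, 19.4)),
      cyto_count = mk(c(90.0, 30.9, 23.8)),
      nuclear_mean_area_um2 = mk(c(0.40, 0.36, 0.32)),
      cyto_mean_area_um2 = mk(c(0.55, 0.70, 0.88)),
      nuclear_median_intensity = mk(c(9000, 8200, 7600)),
      cyto_median_intensity = mk(c(4000, 5200, 6400)),
      nucleus_area_um2 = mk(c(35, 35, 35)),
      cytoplasm_area_um2 = mk(c(45, 45, 45))
    ),
    sds = list(
      nuclear_count = 20.6,
      cyto_count = 45,
      nuclear_mean_area_um2 = 0.10,
      cyto_mean_area_um2 = 0.18,
      nuclear_median_intensity = 1500,
      cyto_median_intensity = 1500,
      nucleus_area_um2 = 6,
      cytoplasm_area_um2 = 9
    ))
}

#' Default per-class offsets for the cell-class task
#'
#' Additive class offsets on nuclear counts reproduce the reported
#' class geometry (interneurons highest, then pyramidal, non-neuronal
#' lowest: IN-PN ~7.6, PN-NN ~21.8, pooled SD ~12.2, i.e. d ~0.6-2.4).
#' Somata sizes follow cortical cell-size dimorphism: pyramidal somata
#' are the largest, interneurons somewhat smaller, and non-neuronal cells
#' much smaller with no cytoplasmic compartment (their whole-soma signal
#' is treated as nuclear). The opposed count and size offsets make
#' nuclear count per unit area the leading class separator.
#'
#' @return List: `classes`, `offsets` (feature -> named vector by class),
#'   `count_sd` (class-task nuclear count SD).
#' @export
class_effects_default <- function() {
  classes <- c("IN", "PN", "NN")
  mk <- function(v) setNames(v, classes)
  list(
    classes = classes,
    offsets = list(
      nuclear_count = mk(c(7.6, 0, -21.8)),
      nucleus_area_um2 = mk(c(-6, 0, -15)),
      cytoplasm_area_um2 = mk(c(-10, 0, -35))
    ),
    count_sd = 12.2)
}

#' Simulate a per-cell feature table with known ground truth
#'
#' Draws per-cell features as `age mean + class offset + replicate effect
#' + residual`; counts are rounded and truncated at zero, areas truncated
#' at a small positive floor. The replicate effect SD is
#' `sd * sqrt(rho / (1 - rho))`, giving intra-replicate correlation `rho`
#' on the latent scale. Deterministic under `seed`.
#'
#' @param n_per_group Cells per age group (split over classes and
#'   replicates). May be a named vector by class.
#' @param ages Age-group labels (must name columns of `effects$means`).
#' @param classes Cell classes present (subset of IN/PN/NN).
#' @param n_replicates Biological replicates per age group.
#' @param rho Intra-replicate correlation on the latent feature scale,
#'   in `[0, 1)`.
#' @param effects Per-age effects, see [age_effects_default()].
#' @param class_effects Per-class offsets, see [class_effects_default()];
#'   set `NULL` for no class structure.
#' @param brain_areas Labels cycled over cells (default M1/S1).
#' @param seed Integer seed.
#' @return List with `table` (data frame, one row per cell) and `truth`
#'   (effect parameters actually used, including per-replicate effects).
#' @export
simulate_feature_table <- function(n_per_group = 500L,
                                   ages = NULL,
                                   classes = c("IN", "PN"),
                                   n_replicates = 3L,
                                   rho = 0.05,
                                   effects = age_effects_default(),
                                   class_effects = class_effects_default(),
                                   brain_areas = c("M1", "S1"),
                                   seed = 1L) {
  if (is.null(ages)) ages <- effects$ages
  stopifnot(rho >= 0, rho < 1, n_replicates >= 1L)
  for (f in names(effects$means))
    if (!all(ages %in% names(effects$means[[f]])))
      stop("inconsistent effect spec: ages missing for feature ", f)
  if (is.null(names(n_per_group))) {
    n_class <- setNames(rep(floor(n_per_group / length(classes)),
                            length(classes)), classes)
    n_class[1] <- n_class[1] + n_per_group - sum(n_class)
  } else {
    n_class <- n_per_group[classes]
  }
  rng <- local_rng(seed)
  feats <- names(effects$means)
  rep_effects <- list()
  rows <- list()
  for (age in ages) {
    # replicate effects per feature, shared by all cells of a replicate
    reff <- lapply(feats, function(f) {
      tau <- effects$sds[[f]] * sqrt(rho / (1 - rho))
      rnorm(n_replicates, 0, tau)
    })
    names(reff) <- feats
    rep_effects[[age]] <- reff
    for (cls in classes) {
      n <- n_class[[cls]]
      if (n == 0L) next
      rep_id <- rep(seq_len(n_replicates), length.out = n)
      vals <- lapply(feats, function(f) {
        mu <- effects$means[[f]][[age]]
        off <- 0
        sdv <- effects$sds[[f]]
        if (!is.null(class_effects) &&
            !is.null(class_effects$offsets[[f]]) &&
            cls %in% names(class_effects$offsets[[f]])) {
          off <- class_effects$offsets[[f]][[cls]]
        }
        if (!is.null(class_effects) && f == "nuclear_count" &&
            !is.null(class_effects$count_sd) && length(classes) > 2L) {
          sdv <- class_effects$count_sd
        }
        mu + off + reff[[f]][rep_id] + rnorm(n, 0, sdv)
      })
      names(vals) <- feats
      df <- as.data.frame(vals)
      df$cell_class <- cls
      df$age_group <- age
      df$replicate_id <- paste0(age, "_r", rep_id)
      df$brain_area <- rep(brain_areas, length.out = n)
      rows[[paste(age, cls)]] <- df
    }
  }
  rng()
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # domain constraints
  tab$nuclear_count <- pmax(round(tab$nuclear_count), 0)
  tab$cyto_count <- pmax(round(tab$cyto_count), 0)
  for (f in c("nucleus_area_um2", "cytoplasm_area_um2"))
    tab[[f]] <- pmax(tab[[f]], 1)
  for (f in c("nuclear_mean_area_um2", "cyto_mean_area_um2"))
    tab[[f]] <- pmax(tab[[f]], 0.05)
  if ("NN" %in% tab$cell_class) {
    nn <- tab$cell_class == "NN"
    tab$cyto_count[nn] <- 0L
    tab$cytoplasm_area_um2[nn] <- NA_real_
  }
  zn <- tab$nuclear_count == 0
  tab$nuclear_median_intensity[zn] <- NA_real_
  tab$nuclear_mean_area_um2[zn] <- NA_real_
  zc <- tab$cyto_count == 0
  tab$cyto_median_intensity[zc] <- NA_real_
  tab$cyto_mean_area_um2[zc] <- NA_real_
  tab$nuclear_count_per_area <- tab$nuclear_count / tab$nucleus_area_um2
  tab$cyto_count_per_area <- tab$cyto_count / tab$cytoplasm_area_um2
  tab$cell_id <- seq_len(nrow(tab))
  truth <- list(effects = effects, class_effects = class_effects,
                rho = rho, replicate_effects = rep_effects, seed = seed)
  list(table = tab, truth = truth)
}

# ---------------------------------------------------------------------------
# image simulation

#' Parameters for the tissue-image simulator
#'
#' @param n_cells Named integer vector: cells per class to place
#'   (IN, PN, NN, MG).
#' @param field_px Square field side in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param age_group One of the ages in `effects`; sets spot count means
#'   and radii.
#' @param soma_radius_um Mean equivalent radius of neuron somata (NN are
#'   drawn at 45%, MG at 60% of this).
#' @param nucleus_area_frac Nucleus area as a fraction of soma area for
#'   IN/PN (default 0.5, within the 45-60% range typical of neurons).
#' @param lambda_nuc,lambda_cyt Mean nuclear speckle / cytoplasmic granule
#'   count per cell; default follows the age trajectories 40/22/20 and
#'   90/31/24 for 1M/10M/18M.
#' @param r_nuc_px,r_cyt_px Gaussian spot radius (sigma, px); nuclear
#'   radius shrinks ~20% and cytoplasmic grows ~60% across the default
#'   ages.
#' @param spot_min_sep_px Minimum centre separation of spots within one
#'   compartment (length 1 or 2, nuclear/cytoplasmic); default 4 times the
#'   spot radius, keeping thresholded footprints resolvable.
#' @param amp_range Spot peak amplitude range, in multiples of the
#'   background noise SD.
#' @param noise_sd Gaussian background noise SD (0 = noise-free; amplitude
#'   multiples then use 1 as the unit).
#' @param bg_level Constant background offset for every channel.
#' @param marker_coupling `list(a=, b=, sigma=)`: inside each nuclear
#'   speckle the damage-marker channel takes value `a + b * amplitude +
#'   N(0, sigma)`.
#' @param marker_channels Names of coupled marker channels to render.
#' @param mg_fractions Fractions of MG placed touching a neuron, within
#'   one body length, and far (named `tied`, `near`, `free`).
#' @param class_lambda_scale Per-class multipliers on the spot count
#'   means, reflecting the class geometry of nuclear counts (interneurons
#'   highest, non-neuronal lowest).
#' @param max_attempts Rejection-sampling bound for placements.
#' @param seed Integer seed.
#' @return List of class `sim_image_params`.
#' @export
sim_image_params <- function(n_cells = c(IN = 10, PN = 25, NN = 10, MG = 5),
                             field_px = 2304L,
                             pixel_size_um = 0.1,
                             age_group = "1M",
                             soma_radius_um = 11,
                             nucleus_area_frac = 0.5,
                             lambda_nuc = NULL,
                             lambda_cyt = NULL,
                             r_nuc_px = NULL,
                             r_cyt_px = NULL,
                             spot_min_sep_px = NULL,
                             amp_range = c(8, 16),
                             noise_sd = 40,
                             bg_level = 200,
                             marker_coupling = list(a = 100, b = 1.5,
                                                    sigma = 40),
                             marker_channels = "gH2AX",
                             mg_fractions = c(tied = 0.3, near = 0.3,
                                              free = 0.4),
                             class_lambda_scale = c(IN = 1.2, PN = 1.0,
                                                    NN = 0.42),
                             max_attempts = 5000L,
                             seed = 1L) {
  traj <- list(`1M` = list(lnuc = 40, lcyt = 90, rnuc = 2.0, rcyt = 1.5),
               `10M` = list(lnuc = 22, lcyt = 31, rnuc = 1.8, rcyt = 2.0),
               `18M` = list(lnuc = 20, lcyt = 24, rnuc = 1.6, rcyt = 2.4))
  tr <- if (age_group %in% names(traj)) traj[[age_group]] else traj[["1M"]]
  if (is.null(lambda_nuc)) lambda_nuc <- tr$lnuc
  if (is.null(lambda_cyt)) lambda_cyt <- tr$lcyt
  if (is.null(r_nuc_px)) r_nuc_px <- tr$rnuc
  if (is.null(r_cyt_px)) r_cyt_px <- tr$rcyt
  if (is.null(spot_min_sep_px)) spot_min_sep_px <- 4 * c(r_nuc_px, r_cyt_px)
  spot_min_sep_px <- rep(spot_min_sep_px, length.out = 2L)
  names(spot_min_sep_px) <- c("NUCLEAR_SPECKLE", "CYTOPLASMIC_GRANULE")
  stopifnot(lambda_nuc >= 0, lambda_cyt >= 0, r_nuc_px > 0, r_cyt_px > 0,
            pixel_size_um > 0, field_px >= 64)
  structure(list(n_cells = n_cells, field_px = as.integer(field_px),
                 pixel_size_um = pixel_size_um, age_group = age_group,
                 soma_radius_um = soma_radius_um,
                 nucleus_area_frac = nucleus_area_frac,
                 lambda_nuc = lambda_nuc, lambda_cyt = lambda_cyt,
                 r_nuc_px = r_nuc_px, r_cyt_px = r_cyt_px,
                 spot_min_sep_px = spot_min_sep_px,
                 amp_range = amp_range, noise_sd = noise_sd,
                 bg_level = bg_level, marker_coupling = marker_coupling,
                 marker_channels = marker_channels,
                 mg_fractions = mg_fractions,
                 class_lambda_scale = class_lambda_scale,
                 max_attempts = as.integer(max_attempts), seed = seed),
            class = "sim_image_params")
}

# rasterise a filled ellipse; returns integer matrix indices (n x 2)
# rasterise a filled ellipse; returns n x 2 integer matrix of (row, col)
ellipse_pixels <- function(cr, cc, a, b, theta, field) {
  rmax <- ceiling(max(a, b))
  r0 <- max(1L, floor(cr - rmax)); r1 <- min(field, ceiling(cr + rmax))
  c0 <- max(1L, floor(cc - rmax)); c1 <- min(field, ceiling(cc + rmax))
  rr <- seq.int(r0, r1); cols <- seq.int(c0, c1)
  gr <- rep(rr, times = length(cols)) - cr
  gc <- rep(cols, each = length(rr)) - cc
  u <- gr * cos(theta) + gc * sin(theta)
  v <- -gr * sin(theta) + gc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(rep(rr, times = length(cols))[keep],
        rep(cols, each = length(rr))[keep])
}

# radius of an ellipse (semi-axes a >= along theta) in direction phi
ellipse_radius_along <- function(a, b, theta, phi) {
  psi <- phi - theta
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# pick spot centres inside a compartment with min separation; bounded
# rejection sampling, possibly returning fewer than requested
place_spots <- function(mask_idx, n, min_sep, max_attempts) {
  if (n == 0L || nrow(mask_idx) == 0L) return(matrix(0, 0, 2))
  centers <- matrix(0, 0, 2)
  attempts <- 0L
  while (nrow(centers) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- mask_idx[sample.int(nrow(mask_idx), 1L), ]
    if (nrow(centers) > 0) {
      d2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    centers <- rbind(centers, unname(cand))
  }
  centers
}

#' Simulate a multi-channel tissue image with ground truth
#'
#' Renders non-overlapping elliptical somata of four classes on a noisy
#' background: IN/PN carry an interior nuclear ellipse (dim in Nissl,
#' bright in NeuN), IN are additionally GABA-marker positive, NN are
#' small Nissl-only cells without a compartment split, and MG are
#' Iba1-positive irregular (lobed) somata placed either touching a
#' neuron, within one body length of one, or far from all neurons, per
#' `mg_fractions`. The POLK channel is background plus isotropic Gaussian
#' spots (truncated at 3 sigma) at ground-truth centres:
#' Poisson(`lambda_nuc`) per nucleus and Poisson(`lambda_cyt`) per
#' cytoplasm (whole soma for NN), with minimum centre separation enforced
#' by bounded rejection sampling; both the Poisson draw and the placed
#' count are recorded. Inside every nuclear speckle footprint each
#' coupled marker channel takes the value `a + b * amplitude +
#' N(0, sigma)` over a 2-sigma disc (discs of neighbouring speckles do
#' not overlap at the default separation). Identical parameters and seed give identical images.
#'
#' @param params A [sim_image_params()] object.
#' @return List with `stack` (an [image_stack()]) and `truth`: data frame
#'   `cells` (true class, centre, axes, MG placement category), data frame
#'   `spots` (per-object centre, sigma, amplitude, compartment, true
#'   marker means), data frame `draws` (drawn vs placed spot counts per
#'   cell), and the true label masks `soma_labels`, `nucleus_labels`,
#'   `cyto_labels`.
#' @export
simulate_image <- function(params = sim_image_params()) {
  stopifnot(inherits(params, "sim_image_params"))
  p <- params
  rng <- local_rng(p$seed)
  on.exit(rng(), add = TRUE)
  fp <- p$field_px
  r_soma <- p$soma_radius_um / p$pixel_size_um
  radius_of <- function(cls) switch(cls, IN = r_soma, PN = r_soma,
                                    NN = 0.45 * r_soma, MG = 0.6 * r_soma)
  margin <- 4
  classes <- rep(names(p$n_cells), times = p$n_cells)
  cells <- data.frame(cell_id = integer(0), cell_class = character(0),
                      cr = numeric(0), cc = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0), rmax = numeric(0),
                      mg_truth = character(0), stringsAsFactors = FALSE)

  # accept a candidate if it clears every placed cell by the required gap;
  # `gaps` is a vector of required boundary gaps per placed cell
  clears <- function(cr, cc, rad, gaps) {
    if (nrow(cells) == 0L) return(TRUE)
    dd <- sqrt((cells$cr - cr)^2 + (cells$cc - cc)^2)
    all(dd >= cells$rmax + rad + gaps)
  }

  # neurons and non-neuronal cells: uniform non-overlapping placement
  for (cls in classes[classes != "MG"]) {
    rad <- radius_of(cls) * runif(1, 0.9, 1.1)
    ecc <- runif(1, 0.75, 0.95)
    a <- rad / sqrt(ecc); b <- rad * sqrt(ecc)
    rmax <- max(a, b)
    ok <- FALSE
    for (att in seq_len(p$max_attempts)) {
      cr <- runif(1, rmax + margin, fp - rmax - margin)
      cc <- runif(1, rmax + margin, fp - rmax - margin)
      if (clears(cr, cc, rmax, rep(margin, nrow(cells)))) { ok <- TRUE; break }
    }
    if (!ok) stop("placement failure after max attempts")
    cells <- rbind(cells, data.frame(
      cell_id = nrow(cells) + 1L, cell_class = cls, cr = cr, cc = cc,
      a = a, b = b, theta = runif(1, 0, pi), rmax = rmax,
      mg_truth = NA_character_, stringsAsFactors = FALSE))
  }

  # microglia: placed relative to neurons to realise the three spatial
  # categories (touching / within one body length / beyond it)
  n_mg <- sum(classes == "MG")
  if (n_mg > 0) {
    fr <- p$mg_fractions[c("tied", "near", "free")]
    cats <- rep(c("TIED", "NEAR", "FREE"), ceiling(fr * n_mg) + 1L)
    cats <- cats[seq_len(n_mg)]
    neuron_rows <- which(cells$cell_class %in% c("IN", "PN"))
    for (k in seq_len(n_mg)) {
      rad <- radius_of("MG") * runif(1, 0.9, 1.1)
      body_len <- 2 * rad
      cat_k <- cats[k]
      ok <- FALSE
      for (att in seq_len(p$max_attempts)) {
        if (cat_k == "FREE") {
          cr <- runif(1, rad + margin, fp - rad - margin)
          cc <- runif(1, rad + margin, fp - rad - margin)
          ang <- runif(1, 0, 2 * pi)
          # must clear every neuron by well over one body length
          gaps <- ifelse(cells$cell_class %in% c("IN", "PN"),
                         1.7 * body_len, margin)
          if (clears(cr, cc, rad, gaps)) { ok <- TRUE; break }
        } else {
          host <- cells[sample(neuron_rows, 1L), ]
          ang <- runif(1, 0, 2 * pi)
          rh <- ellipse_radius_along(host$a, host$b, host$theta, ang)
          gap <- if (cat_k == "TIED") -3 else 0.5 * body_len
          dist <- rh + rad + gap
          cr <- host$cr + dist * cos(ang)
          cc <- host$cc + dist * sin(ang)
          if (cr < rad + 2 || cr > fp - rad - 2 ||
              cc < rad + 2 || cc > fp - rad - 2) next
          gaps <- rep(margin, nrow(cells))
          gaps[cells$cell_id == host$cell_id] <- gap - 1
          if (clears(cr, cc, rad, gaps)) { ok <- TRUE; break }
        }
      }
      if (!ok) stop("placement failure after max attempts")
      cells <- rbind(cells, data.frame(
        cell_id = nrow(cells) + 1L, cell_class = "MG", cr = cr, cc = cc,
        a = rad, b = 0.8 * rad, theta = ang, rmax = rad,
        mg_truth = cat_k, stringsAsFactors = FALSE))
    }
  }

  # rasterise true masks (MG pixels never overwrite other cells, so a
  # touching MG shares a boundary but not pixels)
  soma_labels <- matrix(0L, fp, fp)
  nucleus_labels <- matrix(0L, fp, fp)
  cyto_labels <- matrix(0L, fp, fp)
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    px <- ellipse_pixels(ci$cr, ci$cc, ci$a, ci$b, ci$theta, fp)
    if (ci$cell_class == "MG") {
      for (l in 1:3) {  # lobed, irregular outline
        lang <- ci$theta + l * 2.1
        lr <- 0.5 * ci$rmax
        px <- rbind(px, ellipse_pixels(ci$cr + 0.9 * ci$rmax * cos(lang),
                                       ci$cc + 0.9 * ci$rmax * sin(lang),
                                       lr, 0.7 * lr, lang, fp))
      }
      px <- px[!duplicated(px), , drop = FALSE]
      px <- px[soma_labels[px] == 0L, , drop = FALSE]
    }
    soma_labels[px] <- ci$cell_id
    if (ci$cell_class %in% c("IN", "PN")) {
      scale <- sqrt(p$nucleus_area_frac)
      npx <- ellipse_pixels(ci$cr, ci$cc, scale * ci$a, scale * ci$b,
                            ci$theta, fp)
      nucleus_labels[npx] <- ci$cell_id
      cpx <- px[nucleus_labels[px] != ci$cell_id, , drop = FALSE]
      cyto_labels[cpx] <- ci$cell_id
    }
  }

  # marker channels: class-specific levels in noise-SD units
  unit <- if (p$noise_sd > 0) p$noise_sd else 1
  nissl <- matrix(0, fp, fp); neun <- matrix(0, fp, fp)
  gad67 <- matrix(0, fp, fp); iba1 <- matrix(0, fp, fp)
  polk <- matrix(0, fp, fp)
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    own <- which(soma_labels == ci$cell_id)
    if (ci$cell_class %in% c("IN", "PN")) {
      nuc <- which(nucleus_labels == ci$cell_id)
      cyt <- which(cyto_labels == ci$cell_id)
      nissl[cyt] <- nissl[cyt] + 20 * unit
      nissl[nuc] <- nissl[nuc] + 5 * unit
      neun[nuc] <- neun[nuc] + 15 * unit
      if (ci$cell_class == "IN") gad67[own] <- gad67[own] + 12 * unit
    } else if (ci$cell_class == "NN") {
      nissl[own] <- nissl[own] + 14 * unit
    } else {
      nissl[own] <- nissl[own] + 12 * unit
      iba1[own] <- iba1[own] + 15 * unit
    }
  }

  # POLK spots; marker footprints collected and painted afterwards
  n_cells_total <- nrow(cells)
  draws <- data.frame(cell_id = cells$cell_id,
                      n_nuc_drawn = 0L, n_nuc_placed = 0L,
                      n_cyt_drawn = 0L, n_cyt_placed = 0L)
  sp_cell <- integer(0); sp_comp <- character(0)
  sp_row <- numeric(0); sp_col <- numeric(0)
  sp_sigma <- numeric(0); sp_amp <- numeric(0)
  marker_vals <- lapply(p$marker_channels, function(m) numeric(0))
  names(marker_vals) <- p$marker_channels
  marker_foot <- list()   # per nuclear speckle: pixel index matrix
  for (i in seq_len(n_cells_total)) {
    ci <- cells[i, ]
    if (ci$cell_class == "MG") next
    if (ci$cell_class %in% c("IN", "PN")) {
      nuc_idx <- which(nucleus_labels == ci$cell_id, arr.ind = TRUE)
      cyt_idx <- which(cyto_labels == ci$cell_id, arr.ind = TRUE)
    } else {
      nuc_idx <- which(soma_labels == ci$cell_id, arr.ind = TRUE)
      cyt_idx <- matrix(0L, 0, 2)
    }
    lscale <- p$class_lambda_scale[[ci$cell_class]]
    if (is.null(lscale) || is.na(lscale)) lscale <- 1
    comp <- list(NUCLEAR_SPECKLE = list(idx = nuc_idx,
                                        lambda = lscale * p$lambda_nuc,
                                        r = p$r_nuc_px),
                 CYTOPLASMIC_GRANULE = list(idx = cyt_idx,
                                            lambda = lscale * p$lambda_cyt,
                                            r = p$r_cyt_px))
    for (cname in names(comp)) {
      cmp <- comp[[cname]]
      if (nrow(cmp$idx) == 0L) next
      n_drawn <- rpois(1, cmp$lambda)
      centers <- place_spots(cmp$idx, n_drawn, p$spot_min_sep_px[[cname]],
                             p$max_attempts)
      n_placed <- nrow(centers)
      if (cname == "NUCLEAR_SPECKLE") {
        draws$n_nuc_drawn[i] <- n_drawn; draws$n_nuc_placed[i] <- n_placed
      } else {
        draws$n_cyt_drawn[i] <- n_drawn; draws$n_cyt_placed[i] <- n_placed
      }
      if (n_placed == 0L) next
      amps <- runif(n_placed, p$amp_range[1] * unit, p$amp_range[2] * unit)
      for (s in seq_len(n_placed)) {
        crs <- centers[s, 1]; ccs <- centers[s, 2]
        sig <- cmp$r
        rad3 <- ceiling(3 * sig)
        r0 <- max(1L, floor(crs - rad3)); r1 <- min(fp, ceiling(crs + rad3))
        c0 <- max(1L, floor(ccs - rad3)); c1 <- min(fp, ceiling(ccs + rad3))
        rr <- seq.int(r0, r1); cls2 <- seq.int(c0, c1)
        d2 <- outer((rr - crs)^2, (cls2 - ccs)^2, "+")
        g <- amps[s] * exp(-d2 / (2 * sig^2))
        g[d2 > (3 * sig)^2] <- 0
        polk[rr, cls2] <- polk[rr, cls2] + g
        sp_cell <- c(sp_cell, ci$cell_id); sp_comp <- c(sp_comp, cname)
        sp_row <- c(sp_row, crs); sp_col <- c(sp_col, ccs)
        sp_sigma <- c(sp_sigma, sig); sp_amp <- c(sp_amp, amps[s])
        if (cname == "NUCLEAR_SPECKLE" && length(p$marker_channels)) {
          foot <- ellipse_pixels(crs, ccs, 2 * sig, 2 * sig, 0, fp)
          marker_foot[[length(marker_foot) + 1L]] <- foot
          for (m in p$marker_channels) {
            v <- max(p$marker_coupling$a + p$marker_coupling$b * amps[s] +
                       rnorm(1, 0, p$marker_coupling$sigma), 0)
            marker_vals[[m]] <- c(marker_vals[[m]], v)
          }
        } else if (length(p$marker_channels)) {
          for (m in p$marker_channels)
            marker_vals[[m]] <- c(marker_vals[[m]], NA_real_)
        }
      }
    }
  }
  spots <- data.frame(spot_id = seq_along(sp_cell), cell_id = sp_cell,
                      compartment = sp_comp, row = sp_row, col = sp_col,
                      sigma_px = sp_sigma, amplitude = sp_amp,
                      stringsAsFactors = FALSE)
  for (m in p$marker_channels) spots[[paste0("true_", m)]] <- marker_vals[[m]]

  channels <- list(Nissl = nissl, NeuN = neun, Gad67 = gad67, Iba1 = iba1,
                   POLK = polk)
  for (m in p$marker_channels) {
    mm <- matrix(0, fp, fp)
    is_nuc <- spots$compartment == "NUCLEAR_SPECKLE"
    vals <- marker_vals[[m]][is_nuc]
    for (j in seq_along(marker_foot))
      mm[marker_foot[[j]]] <- mm[marker_foot[[j]]] + vals[j]
    channels[[m]] <- mm
  }
  for (nm in names(channels)) {
    channels[[nm]] <- channels[[nm]] + p$bg_level
    if (p$noise_sd > 0)
      channels[[nm]] <- channels[[nm]] +
        matrix(rnorm(fp * fp, 0, p$noise_sd), fp, fp)
    channels[[nm]] <- pmin(pmax(channels[[nm]], 0), 65535)
  }

  cells$rmax <- NULL
  truth <- list(cells = cells, spots = spots, draws = draws,
                soma_labels = soma_labels, nucleus_labels = nucleus_labels,
                cyto_labels = cyto_labels, params = p)
  list(stack = image_stack(channels, p$pixel_size_um), truth = truth)
}
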