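# Puncta detection per subcellular compartment, per-object intensity and
# co-marker measurement, and aggregation to the per-cell feature table.

#' Detect puncta within compartment masks of one cell
#'
#' White top-hat filtering (disc radius = the largest expected punctum
#' radius) flattens diffuse signal; a robust threshold (`median + k_sigma
#' * MAD` of the top-hat values inside each compartment) selects punctum
#' pixels, the MAD being estimated one-sidedly from the lower tail so
#' that the puncta themselves do not inflate it; connected components
#' are filtered by area and each object is
#' assigned to the compartment containing its centroid (boundary-
#' straddling objects therefore land in exactly one compartment).
#'
#' @param polk Numeric matrix: the puncta channel.
#' @param compartments Named list of logical masks (dimensions matching
#'   `polk`), e.g. `list(NUCLEAR_SPECKLE = ..., CYTOPLASMIC_GRANULE =
#'   ...)`. For non-compartmentalised cells pass a single whole-soma mask
#'   named `NUCLEAR_SPECKLE`.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_um2,max_area_um2 Punctum area bounds (um^2).
#' @param k_sigma Threshold in MAD units above the compartment median
#'   (default 5).
#' @param tophat_radius_px Structuring-element radius (px) for the white
#'   top-hat (default 10, about 3 times the largest expected punctum
#'   radius).
#' @return Data frame with one row per punctum: `compartment`,
#'   `area_um2`, `polk_mean_intensity`, `polk_integrated_intensity`,
#'   `centroid_row`, `centroid_col`, plus a `labels` attribute holding the
#'   punctum label matrix (for marker measurement).
#' @export
detect_puncta <- function(polk, compartments, pixel_size_um,
                          min_area_um2 = 0.04, max_area_um2 = 20,
                          k_sigma = 5, tophat_radius_px = 10) {
  stopifnot(is.matrix(polk), is.list(compartments), pixel_size_um > 0)
  if (!(min_area_um2 > 0) || !(max_area_um2 > min_area_um2))
    stop("invalid size bounds")
  empty <- data.frame(compartment = character(0), area_um2 = numeric(0),
                      polk_mean_intensity = numeric(0),
                      polk_integrated_intensity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      stringsAsFactors = FALSE)
  comp_names <- names(compartments)
  any_px <- Reduce(`|`, compartments)
  if (sum(any_px) == 0L) stop("compartment mask non-empty required")
  idx <- which(any_px, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - tophat_radius_px * 2L)
  r1 <- min(nrow(polk), max(idx[, 1]) + tophat_radius_px * 2L)
  c0 <- max(1L, min(idx[, 2]) - tophat_radius_px * 2L)
  c1 <- min(ncol(polk), max(idx[, 2]) + tophat_radius_px * 2L)
  sub <- polk[r0:r1, c0:c1]
  brush <- EBImage::makeBrush(2 * tophat_radius_px + 1, shape = "disc")
  th <- sub - EBImage::imageData(EBImage::opening(EBImage::Image(sub), brush))
  above <- matrix(FALSE, nrow(th), ncol(th))
  for (cn in comp_names) {
    cm <- compartments[[cn]][r0:r1, c0:c1]
    if (sum(cm) == 0L) next
    vals <- th[cm]
    med <- median(vals)
    # one-sided MAD from the lower tail: punctum signal only contaminates
    # the upper tail of the compartment's top-hat distribution
    sig <- (med - quantile(vals, 0.25, names = FALSE)) / 0.6744898
    thr <- med + k_sigma * sig
    above <- above | (cm & th > thr)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(above * 1)))
  storage.mode(lab) <- "integer"
  n_obj <- max(lab)
  attr_labels <- matrix(0L, nrow(polk), ncol(polk))
  if (n_obj == 0L) {
    attr(empty, "labels") <- attr_labels
    return(empty)
  }
  oidx <- which(lab > 0L)
  oval <- lab[oidx]
  rowi <- (oidx - 1L) %% nrow(lab) + 1L
  coli <- (oidx - 1L) %/% nrow(lab) + 1L
  area_px <- tabulate(oval, nbins = n_obj)
  cr <- rowsum(as.numeric(rowi), oval)[, 1] / area_px
  cc <- rowsum(as.numeric(coli), oval)[, 1] / area_px
  sub_raw <- sub
  tot <- rowsum(sub_raw[oidx], oval)[, 1]
  # area filter
  min_px <- min_area_um2 / pixel_size_um^2
  max_px <- max_area_um2 / pixel_size_um^2
  keep <- which(area_px >= min_px & area_px <= max_px)
  # compartment of the centroid; objects whose centroid falls outside all
  # compartments are assigned to the nearest (majority-pixel) one
  comp_of <- character(length(keep))
  for (j in seq_along(keep)) {
    o <- keep[j]
    ri <- round(cr[o]); cj <- round(cc[o])
    hit <- NA_character_
    for (cn in comp_names) {
      if (compartments[[cn]][r0 + ri - 1L, c0 + cj - 1L]) { hit <- cn; break }
    }
    if (is.na(hit)) {
      opx <- oidx[oval == o]
      votes <- vapply(comp_names, function(cn)
        sum(compartments[[cn]][r0:r1, c0:c1][opx]), numeric(1))
      hit <- comp_names[which.max(votes)]
    }
    comp_of[j] <- hit
  }
  out <- data.frame(compartment = comp_of,
                    area_um2 = area_px[keep] * pixel_size_um^2,
                    polk_mean_intensity = tot[keep] / area_px[keep],
                    polk_integrated_intensity = tot[keep],
                    centroid_row = r0 + cr[keep] - 1,
                    centroid_col = c0 + cc[keep] - 1,
                    stringsAsFactors = FALSE)
  # relabel kept objects 1..k in the full-size label matrix
  relab <- integer(n_obj)
  relab[keep] <- seq_along(keep)
  full <- attr_labels
  keep_mask <- relab[oval] > 0L
  full[cbind(rowi[keep_mask] + r0 - 1L, coli[keep_mask] + c0 - 1L)] <-
    relab[oval[keep_mask]]
  attr(out, "labels") <- full
  out
}

#' Measure a marker channel inside detected puncta
#'
#' Adds, for each punctum, the mean intensity of `marker` over the
#' punctum's pixel set. POLK intensities are untouched.
#'
#' @param puncta Data frame from [detect_puncta()] (with its `labels`
#'   attribute) or from [quantify_cells()].
#' @param marker Numeric matrix, same dimensions as the puncta channel.
#' @param name Column suffix; the new column is `marker_<name>`.
#' @return `puncta` with the added column (labels attribute preserved).
#' @export
measure_marker_in_puncta <- function(puncta, marker, name) {
  labels <- attr(puncta, "labels")
  if (is.null(labels)) stop("puncta carry no label matrix")
  if (!all(dim(marker) == dim(labels))) stop("dimension mismatch")
  col <- paste0("marker_", name)
  if (nrow(puncta) == 0L) {
    puncta[[col]] <- numeric(0)
    return(puncta)
  }
  idx <- which(labels > 0L)
  lv <- labels[idx]
  means <- rowsum(marker[idx], lv)[, 1] / tabulate(lv, nbins = max(lv))
  puncta[[col]] <- means[seq_len(nrow(puncta))]
  puncta
}

#' Detect puncta for every cell of a segmented, gated field
#'
#' Runs [detect_puncta()] per cell: IN/PN use their nucleus and cytoplasm
#' masks; NN cells use the whole soma with the signal treated as nuclear
#' (their nucleus occupies most of the soma); MG and unclassified cells
#' are skipped. Optionally measures marker channels inside nuclear
#' speckles.
#'
#' @param stack The [image_stack()].
#' @param cell_set A partitioned, classified `cell_set`.
#' @param polk_channel Name of the puncta channel (default "POLK").
#' @param marker_channels Channels to measure inside each punctum.
#' @param ... Passed to [detect_puncta()].
#' @return Data frame of puncta with `punctum_id` and `parent_cell_id`,
#'   with a combined `labels` attribute.
#' @export
quantify_cells <- function(stack, cell_set, polk_channel = "POLK",
                           marker_channels = character(0), ...) {
  stopifnot(inherits(stack, "image_stack"), inherits(cell_set, "cell_set"))
  polk <- stack$channels[[polk_channel]]
  if (is.null(polk)) stop("missing channel: ", polk_channel)
  cells <- cell_set$cells
  labels_all <- matrix(0L, nrow(polk), ncol(polk))
  out <- list()
  next_id <- 0L
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    cls <- ci$cell_class
    if (!cls %in% c("IN", "PN", "NN")) next
    if (cls %in% c("IN", "PN")) {
      if (is.null(cell_set$nucleus_labels) || !isTRUE(ci$partitioned)) next
      comps <- list(
        NUCLEAR_SPECKLE = cell_set$nucleus_labels == ci$cell_id,
        CYTOPLASMIC_GRANULE = cell_set$cyto_labels == ci$cell_id)
    } else {
      comps <- list(NUCLEAR_SPECKLE = cell_set$soma_labels == ci$cell_id)
    }
    pk <- detect_puncta(polk, comps, cell_set$pixel_size_um, ...)
    for (m in marker_channels)
      pk <- measure_marker_in_puncta(pk, stack$channels[[m]], m)
    if (nrow(pk) == 0L) next
    lab <- attr(pk, "labels")
    sel <- lab > 0L
    labels_all[sel] <- lab[sel] + next_id
    pk$punctum_id <- next_id + seq_len(nrow(pk))
    pk$parent_cell_id <- ci$cell_id
    next_id <- next_id + nrow(pk)
    out[[length(out) + 1L]] <- pk
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(compartment = character(0), area_um2 = numeric(0),
               polk_mean_intensity = numeric(0),
               polk_integrated_intensity = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               punctum_id = integer(0), parent_cell_id = integer(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "labels") <- labels_all
  res
}

#' Aggregate cells and puncta to the per-cell feature table
#'
#' One row per IN/PN/NN cell: nuclear and cytoplasmic puncta counts,
#' counts per compartment area (um^-2), median punctum mean intensity per
#' compartment (`NA` for zero-count cells, whose count stays 0), mean
#' punctum area, compartment areas and carried metadata. For NN cells the
#' whole-soma signal is booked as nuclear and the soma area is used as
#' the nuclear area.
#'
#' @param cell_set A partitioned, classified `cell_set`.
#' @param puncta Puncta data frame from [quantify_cells()].
#' @param metadata Optional named list (e.g. `age_group`, `replicate_id`,
#'   `brain_area`) recycled onto all rows.
#' @return Data frame, one row per cell entering quantification.
#' @export
build_feature_table <- function(cell_set, puncta, metadata = list()) {
  stopifnot(inherits(cell_set, "cell_set"))
  cells <- cell_set$cells
  keep <- cells$cell_class %in% c("IN", "PN", "NN")
  cells <- cells[keep, , drop = FALSE]
  if (nrow(puncta) > 0 &&
      !all(puncta$parent_cell_id %in% cell_set$cells$cell_id))
    stop("orphan punctum: parent cell not in cell set")
  agg <- function(ids, comp, fun, col) {
    vapply(ids, function(id) {
      v <- puncta[puncta$parent_cell_id == id & puncta$compartment == comp,
                  col]
      if (length(v) == 0L) NA_real_ else fun(v)
    }, numeric(1))
  }
  ids <- cells$cell_id
  nuc_n <- vapply(ids, function(id)
    sum(puncta$parent_cell_id == id &
          puncta$compartment == "NUCLEAR_SPECKLE"), numeric(1))
  cyt_n <- vapply(ids, function(id)
    sum(puncta$parent_cell_id == id &
          puncta$compartment == "CYTOPLASMIC_GRANULE"), numeric(1))
  nuc_area <- ifelse(cells$cell_class == "NN", cells$soma_area_um2,
                     cells$nucleus_area_um2 %||% NA_real_)
  cyt_area <- ifelse(cells$cell_class == "NN", NA_real_,
                     cells$cytoplasm_area_um2 %||% NA_real_)
  tab <- data.frame(
    cell_id = ids,
    cell_class = cells$cell_class,
    nuclear_count = nuc_n,
    cyto_count = cyt_n,
    nucleus_area_um2 = nuc_area,
    cytoplasm_area_um2 = cyt_area,
    nuclear_count_per_area = nuc_n / nuc_area,
    cyto_count_per_area = cyt_n / cyt_area,
    nuclear_median_intensity = agg(ids, "NUCLEAR_SPECKLE", median,
                                   "polk_mean_intensity"),
    cyto_median_intensity = agg(ids, "CYTOPLASMIC_GRANULE", median,
                                "polk_mean_intensity"),
    nuclear_mean_area_um2 = agg(ids, "NUCLEAR_SPECKLE", mean, "area_um2"),
    cyto_mean_area_um2 = agg(ids, "CYTOPLASMIC_GRANULE", mean, "area_um2"),
    mg_association = cells$mg_association %||% NA_character_,
    stringsAsFactors = FALSE)
  tab$cyto_count[cells$cell_class == "NN"] <- 0
  for (nm in names(metadata)) tab[[nm]] <- metadata[[nm]]
  rownames(tab) <- NULL
  tab
}
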