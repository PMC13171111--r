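# Soma detection and nucleus/cytoplasm partitioning from the fluorescent
# Nissl channel. The operator chain (smooth -> global Otsu threshold ->
# hole filling -> watershed split on the distance transform -> size
# filter) is fixed as the package's reference segmentation.

as_ebimage <- function(mat) EBImage::Image(mat)

#' Detect cell somata in a Nissl channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, watershed
#' split of touching objects on the distance transform, then an area
#' filter. Labels are assigned deterministically in (row, col) order of
#' object centroids. An image that is empty after thresholding yields
#' zero cells (not an error).
#'
#' @param nissl Numeric matrix (single channel).
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_um2,max_area_um2 Soma area bounds in um^2.
#' @param smooth_sigma Gaussian smoothing sigma in px.
#' @param watershed_tolerance Minimum distance-transform height separating
#'   two watershed peaks (px); default half the equivalent radius of
#'   `min_area_um2`.
#' @return List of class `cell_set`: `soma_labels` (integer label matrix),
#'   `cells` (data frame: `cell_id`, `centroid_row`, `centroid_col`,
#'   `soma_area_um2`, `cell_class` = "UNCLASSIFIED"), `pixel_size_um`.
#' @export
detect_somata <- function(nissl, pixel_size_um, min_area_um2 = 15,
                          max_area_um2 = 800, smooth_sigma = 2,
                          watershed_tolerance = NULL) {
  stopifnot(is.matrix(nissl), pixel_size_um > 0)
  if (!(min_area_um2 > 0) || !(max_area_um2 > min_area_um2))
    stop("invalid area bounds")
  min_px <- min_area_um2 / pixel_size_um^2
  max_px <- max_area_um2 / pixel_size_um^2
  if (is.null(watershed_tolerance))
    watershed_tolerance <- 0.5 * sqrt(min_px / pi)
  rng <- range(nissl)
  empty <- new_cell_set(matrix(0L, nrow(nissl), ncol(nissl)), pixel_size_um)
  if (diff(rng) == 0) return(empty)
  sm <- EBImage::gblur(as_ebimage((nissl - rng[1]) / diff(rng)),
                       sigma = smooth_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- EBImage::fillHull(sm > thr)
  if (sum(mask) == 0) return(empty)
  dm <- EBImage::distmap(mask)
  labels <- EBImage::imageData(EBImage::watershed(dm,
                                                  tolerance = watershed_tolerance))
  storage.mode(labels) <- "integer"
  # size filter
  sizes <- tabulate(labels, nbins = max(labels))
  keep <- which(sizes >= min_px & sizes <= max_px)
  if (length(keep) == 0L) return(empty)
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  new_cell_set(labels, pixel_size_um)
}

# build a cell_set from a label matrix; deterministic label order by
# centroid (row, col)
new_cell_set <- function(labels, pixel_size_um) {
  n <- max(labels)
  if (n == 0L) {
    cells <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                        centroid_col = numeric(0), soma_area_um2 = numeric(0),
                        cell_class = character(0), stringsAsFactors = FALSE)
    return(structure(list(soma_labels = labels,
                          nucleus_labels = NULL, cyto_labels = NULL,
                          cells = cells, pixel_size_um = pixel_size_um),
                     class = "cell_set"))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rowi <- (idx - 1L) %% nrow(labels) + 1L
  coli <- (idx - 1L) %/% nrow(labels) + 1L
  area_px <- tabulate(lab, nbins = n)
  cr <- rowsum(as.numeric(rowi), lab)[, 1] / area_px
  cc <- rowsum(as.numeric(coli), lab)[, 1] / area_px
  ord <- order(round(cr, 3), round(cc, 3))
  relab <- integer(n); relab[ord] <- seq_len(n)
  labels[idx] <- relab[lab]
  cells <- data.frame(cell_id = seq_len(n),
                      centroid_row = cr[ord], centroid_col = cc[ord],
                      soma_area_um2 = area_px[ord] * pixel_size_um^2,
                      cell_class = "UNCLASSIFIED",
                      stringsAsFactors = FALSE)
  structure(list(soma_labels = labels, nucleus_labels = NULL,
                 cyto_labels = NULL, cells = cells,
                 pixel_size_um = pixel_size_um),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cell(s), %.4g um/px\n",
              nrow(x$cells), x$pixel_size_um))
  if (nrow(x$cells)) print(table(x$cells$cell_class))
  invisible(x)
}

# erode a logical submatrix until its area is <= frac of the original;
# returns the eroded mask (never empty: stops before vanishing)
erode_to_fraction <- function(mask, frac) {
  target <- frac * sum(mask)
  cur <- mask
  brush <- EBImage::makeBrush(3, shape = "box")
  repeat {
    nxt <- EBImage::imageData(EBImage::erode(as_ebimage(cur * 1), brush)) > 0
    if (sum(nxt) < 1) return(cur)
    cur <- nxt
    if (sum(cur) <= target) return(cur)
  }
}

#' Partition somata into nucleus and cytoplasm
#'
#' For each selected cell the nucleus is the largest connected low-Nissl
#' region (below the per-cell median intensity, fluorescent Nissl being
#' cytoplasm-bright) wholly inside the soma, hole-filled. If that region
#' is smaller than `min_region_frac` of the soma, the cell falls back to
#' concentric erosion producing a nucleus of about `fallback_frac` times
#' the soma area. Cytoplasm is the soma minus the nucleus; the two masks
#' partition the soma exactly. Somata below `min_soma_px` pixels are
#' flagged `UNPARTITIONED` and excluded downstream.
#'
#' @param cell_set A `cell_set` from [detect_somata()].
#' @param nissl The Nissl channel matrix.
#' @param which_cells Cell ids to partition (default: all; gating
#'   typically restricts this to IN/PN).
#' @param fallback_frac Nucleus fraction of soma area for the erosion
#'   fallback (default 0.5).
#' @param min_region_frac Minimum low-Nissl region size (fraction of soma
#'   area) accepted before falling back (default 0.25).
#' @param min_soma_px Minimum soma size (px) to attempt a partition.
#' @param smooth_sigma Pre-smoothing sigma (px) for the intensity split.
#' @return The `cell_set` with `nucleus_labels`/`cyto_labels` matrices
#'   filled in, and `nucleus_area_um2`, `cytoplasm_area_um2`,
#'   `partitioned` columns added to `cells`.
#' @export
partition_nucleus_cytoplasm <- function(cell_set, nissl,
                                        which_cells = NULL,
                                        fallback_frac = 0.5,
                                        min_region_frac = 0.25,
                                        min_soma_px = 50L,
                                        smooth_sigma = 1) {
  stopifnot(inherits(cell_set, "cell_set"), is.matrix(nissl))
  cs <- cell_set
  labels <- cs$soma_labels
  stopifnot(all(dim(nissl) == dim(labels)))
  if (is.null(which_cells)) which_cells <- cs$cells$cell_id
  sm <- EBImage::imageData(EBImage::gblur(as_ebimage(nissl),
                                          sigma = smooth_sigma))
  nuc <- if (is.null(cs$nucleus_labels))
    matrix(0L, nrow(labels), ncol(labels)) else cs$nucleus_labels
  cyt <- if (is.null(cs$cyto_labels))
    matrix(0L, nrow(labels), ncol(labels)) else cs$cyto_labels
  cs$cells$nucleus_area_um2 <- cs$cells$nucleus_area_um2 %||% NA_real_
  cs$cells$cytoplasm_area_um2 <- cs$cells$cytoplasm_area_um2 %||% NA_real_
  cs$cells$partitioned <- cs$cells$partitioned %||% FALSE
  for (id in which_cells) {
    idx <- which(labels == id, arr.ind = TRUE)
    n_px <- nrow(idx)
    row_i <- which(cs$cells$cell_id == id)
    if (n_px < min_soma_px) {
      cs$cells$cell_class[row_i] <- "UNPARTITIONED"
      next
    }
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    soma_sub <- labels[r0:r1, c0:c1] == id
    vals_sub <- sm[r0:r1, c0:c1]
    med <- median(vals_sub[soma_sub])
    low <- soma_sub & (vals_sub < med)
    comp <- EBImage::bwlabel(as_ebimage(low * 1))
    comp <- EBImage::imageData(comp)
    nucleus_sub <- NULL
    if (max(comp) >= 1) {
      sizes <- tabulate(comp[comp > 0])
      big <- which.max(sizes)
      cand <- EBImage::imageData(
        EBImage::fillHull(as_ebimage((comp == big) * 1))) > 0
      cand <- cand & soma_sub
      # a plausible nucleus is an interior region, not a thin boundary rim
      # whose filled hull would swallow the soma
      if (sum(cand) >= min_region_frac * n_px &&
          sum(cand) <= 0.8 * n_px) nucleus_sub <- cand
    }
    if (is.null(nucleus_sub))
      nucleus_sub <- erode_to_fraction(soma_sub, fallback_frac)
    cyto_sub <- soma_sub & !nucleus_sub
    if (sum(cyto_sub) == 0L) {  # degenerate: keep a 1-px ring
      ring <- soma_sub &
        !(EBImage::imageData(EBImage::erode(as_ebimage(soma_sub * 1),
                                            EBImage::makeBrush(3, "box"))) > 0)
      nucleus_sub <- soma_sub & !ring
      cyto_sub <- ring
    }
    nb <- nuc[r0:r1, c0:c1]; nb[nucleus_sub] <- id; nuc[r0:r1, c0:c1] <- nb
    cb <- cyt[r0:r1, c0:c1]; cb[cyto_sub] <- id; cyt[r0:r1, c0:c1] <- cb
    psz <- cs$pixel_size_um
    cs$cells$nucleus_area_um2[row_i] <- sum(nucleus_sub) * psz^2
    cs$cells$cytoplasm_area_um2[row_i] <- sum(cyto_sub) * psz^2
    cs$cells$partitioned[row_i] <- TRUE
  }
  cs$nucleus_labels <- nuc
  cs$cyto_labels <- cyt
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
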