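#' punctaging: quantification of nucleo-cytoplasmic puncta redistribution
#'
#' Pipeline for quantitative fluorescence microscopy of subcellular protein
#' puncta in brain tissue: synthetic image generation with ground truth,
#' soma segmentation and nucleus/cytoplasm partitioning, marker-based
#' cell-class gating, puncta detection and per-object intensity
#' measurement, clustered statistics, and ensemble age / cell-class
#' classifiers.
#'
#' @keywords internal
#' @importFrom stats coef complete.cases cor.test df.residual lm mad median
#'   pnorm predict pt quantile rbinom rnorm rpois runif sd setNames sigma
#'   wilcox.test p.adjust rnbinom
#' @importFrom utils read.csv write.csv head modifyList
"_PACKAGE"

# Cell classes recognised by the gating stage.
CELL_CLASSES <- c("IN", "PN", "NN", "MG", "UNCLASSIFIED")

# Microglia-association categories for neurons (MG cells themselves get NA).
MG_CATEGORIES <- c("TIED", "NEAR", "FREE")

#' Construct a multi-channel image stack
#'
#' An image stack is the unit of segmentation input: a set of named 2-D
#' intensity rasters sharing identical dimensions, plus square pixel size in
#' micrometres. Matrices are stored row-major with 0-based pixel-centre
#' coordinates reported downstream as (row, col).
#'
#' @param channels Named list of numeric matrices (16-bit intensity range,
#'   values >= 0). All matrices must share dimensions.
#' @param pixel_size_um Scalar micrometres per pixel (square pixels), > 0.
#' @return An object of class `image_stack` with elements `channels`,
#'   `pixel_size_um`, `height_px`, `width_px`.
#' @export
image_stack <- function(channels, pixel_size_um) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of matrices")
  nms <- names(channels)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("channel-name collision or missing channel names")
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("all channels must be 2-D matrices (non-2D planes are rejected)")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share identical dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("intensities must be >= 0")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         height_px = unname(dims[1, 1]), width_px = unname(dims[2, 1])),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d px, %.4g um/px, %d channel(s): %s\n",
              x$height_px, x$width_px, x$pixel_size_um,
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a TIFF image into an image stack
#'
#' Reads a plain or OME multi-plane TIFF (one grey-scale plane per channel).
#' Channel names are taken from `channel_names`; the pixel size falls back
#' to `default_pixel_size_um` (0.078 um, a typical 40x confocal scaling)
#' when the file carries no resolution metadata and no explicit value is
#' given. RGB-interleaved files are rejected as ambiguous.
#'
#' @param path Path to a TIFF file.
#' @param channel_names Character vector naming the planes in order. If
#'   `NULL`, planes are named `ch1`, `ch2`, ...
#' @param pixel_size_um Explicit pixel size, overriding file metadata.
#' @param default_pixel_size_um Fallback pixel size when neither
#'   `pixel_size_um` nor usable file metadata is available.
#' @return An [image_stack()].
#' @export
read_image <- function(path, channel_names = NULL, pixel_size_um = NULL,
                       default_pixel_size_um = 0.078) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (any(vapply(planes, function(p) length(dim(p)) != 2L, logical(1))))
    stop("ambiguous channel layout: interleaved (e.g. RGB) planes are not supported; ",
         "supply one grey-scale plane per channel")
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_along(planes))
  }
  if (length(channel_names) != length(planes))
    stop(sprintf("file has %d plane(s) but %d channel name(s) were supplied",
                 length(planes), length(channel_names)))
  if (anyDuplicated(channel_names)) stop("channel-name collision")
  if (is.null(pixel_size_um)) {
    info <- attributes(planes[[1]])
    # TIFF x.resolution is pixels per unit; unit "cm" gives um = 1e4 / res.
    if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
        info$x.resolution > 0 && identical(info$resolution.unit, "cm")) {
      pixel_size_um <- 1e4 / info$x.resolution
    } else {
      pixel_size_um <- default_pixel_size_um
    }
  }
  channels <- lapply(planes, function(p) {
    attributes(p) <- list(dim = dim(p))
    storage.mode(p) <- "double"
    p
  })
  names(channels) <- channel_names
  image_stack(channels, pixel_size_um)
}

#' Write an image stack to a multi-plane 16-bit TIFF
#'
#' Planes are written in channel order. Pixel size is not stored in the
#' file (plain TIFF carries no reliable calibration); supply it on read
#' via `pixel_size_um` or the config default, as for any externally
#' produced TIFF.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  planes <- lapply(stack$channels, function(ch) {
    ch <- pmin(pmax(ch, 0), 65535)
    ch / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

# Stable column orders for the on-disk tables (documented contract; the
# round-trip tests rely on these).
CELL_COLUMNS <- c("cell_id", "cell_class", "centroid_row", "centroid_col",
                  "soma_area_um2", "nucleus_area_um2", "cytoplasm_area_um2",
                  "mg_association", "age_group", "replicate_id", "brain_area")

PUNCTUM_COLUMNS <- c("punctum_id", "parent_cell_id", "compartment",
                     "area_um2", "polk_mean_intensity",
                     "polk_integrated_intensity",
                     "centroid_row", "centroid_col")

#' Normalise a per-cell table to the documented column order
#' @noRd
normalize_cell_table <- function(cells) {
  for (col in CELL_COLUMNS)
    if (is.null(cells[[col]])) cells[[col]] <- rep(NA, nrow(cells))
  extra <- setdiff(names(cells), CELL_COLUMNS)
  cells[, c(CELL_COLUMNS, extra), drop = FALSE]
}

#' @noRd
normalize_punctum_table <- function(puncta) {
  for (col in PUNCTUM_COLUMNS)
    if (is.null(puncta[[col]])) puncta[[col]] <- rep(NA, nrow(puncta))
  extra <- setdiff(names(puncta), PUNCTUM_COLUMNS)
  # marker_* columns sorted for stability
  extra <- extra[order(extra)]
  puncta[, c(PUNCTUM_COLUMNS, extra), drop = FALSE]
}

#' Write per-cell and per-punctum tables as CSV
#'
#' Writes two CSV files with a documented, stable column order (cells:
#' `cell_id`, `cell_class`, `centroid_row`, `centroid_col`,
#' `soma_area_um2`, `nucleus_area_um2`, `cytoplasm_area_um2`,
#' `mg_association`, `age_group`, `replicate_id`, `brain_area`; puncta:
#' `punctum_id`, `parent_cell_id`, `compartment`, `area_um2`,
#' `polk_mean_intensity`, `polk_integrated_intensity`, `centroid_row`,
#' `centroid_col`, then `marker_*` columns in alphabetical order). Tables
#' round-trip losslessly through [read_tables()].
#'
#' @param cells Per-cell data frame (may have zero rows).
#' @param puncta Per-punctum data frame (may have zero rows).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; files are `<prefix>_cells.csv` and
#'   `<prefix>_puncta.csv`.
#' @return Named character vector with the two file paths.
#' @export
write_tables <- function(cells, puncta, dir, prefix = "punctaging") {
  stopifnot(is.data.frame(cells), is.data.frame(puncta))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cell_path <- file.path(dir, paste0(prefix, "_cells.csv"))
  punc_path <- file.path(dir, paste0(prefix, "_puncta.csv"))
  write.csv(normalize_cell_table(cells), cell_path, row.names = FALSE)
  write.csv(normalize_punctum_table(puncta), punc_path, row.names = FALSE)
  c(cells = cell_path, puncta = punc_path)
}

#' Read tables written by [write_tables()]
#'
#' @param dir Directory holding the CSV files.
#' @param prefix File-name prefix used at write time.
#' @return List with data frames `cells` and `puncta`.
#' @export
read_tables <- function(dir, prefix = "punctaging") {
  cell_path <- file.path(dir, paste0(prefix, "_cells.csv"))
  punc_path <- file.path(dir, paste0(prefix, "_puncta.csv"))
  if (!file.exists(cell_path) || !file.exists(punc_path))
    stop("table files not found under ", dir)
  list(cells = read.csv(cell_path, stringsAsFactors = FALSE),
       puncta = read.csv(punc_path, stringsAsFactors = FALSE))
}

#' Area of a pixel count in square micrometres
#' @param n_px Number of pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @return Area in um^2.
#' @export
px_area_um2 <- function(n_px, pixel_size_um) n_px * pixel_size_um^2
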