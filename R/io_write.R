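# output: field TIFFs, segmentation overlays, metrics tables

#' Write an ImageField as a two-page 16-bit grayscale TIFF
#'
#' Page 1 is the nuclei channel, page 2 the cell channel. Intensities are
#' rounded and clipped to the 16-bit range; integer-valued fields round-trip
#' bit-exactly through [read_field()].
#'
#' @param field an [image_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  clip <- function(ch) pmin(pmax(round(ch), 0), 65535) / 65535
  tiff::writeTIFF(list(clip(field$nuclei_channel), clip(field$cell_channel)),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Render a segmentation overlay (neurites white, nuclei cyan)
#'
#' The cell channel is rendered in grayscale, nucleus pixels in cyan and
#' skeleton pixels in white; where a skeleton pixel falls on a nucleus, white
#' takes precedence. Output is a PNG or TIFF depending on the file
#' extension; rendering is a pure function of its inputs so reruns are
#' byte-identical.
#'
#' @param field an [image_field()].
#' @param nuclei a [segment_nuclei()] result (or `NULL` for no nuclei).
#' @param skeleton a [segment_neurites()] result (or `NULL`).
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(field, nuclei = NULL, skeleton = NULL, path) {
  dims <- dim(field$cell_channel)
  nmask <- if (is.null(nuclei)) matrix(FALSE, dims[1], dims[2]) else
    nuclei$label_mask > 0
  smask <- if (is.null(skeleton)) matrix(FALSE, dims[1], dims[2]) else
    skeleton$skeleton_mask
  if (!identical(dim(nmask), dims) || !identical(dim(smask), dims))
    stop_input("input error: mask dimensions do not match the field")
  rng <- max(field$cell_channel)
  g <- if (rng > 0) field$cell_channel / rng else field$cell_channel
  r <- g; gg <- g; b <- g
  r[nmask] <- 0; gg[nmask] <- 1; b[nmask] <- 1         # cyan
  r[smask] <- 1; gg[smask] <- 1; b[smask] <- 1         # white wins
  rgb <- array(c(r, gg, b), dim = c(dims, 3L))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(rgb, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(rgb, path,
                                                      bits.per.sample = 8L)
  else stop_input("overlay path must end in .png, .tif or .tiff")
  invisible(path)
}

.metrics_cols <- c("field_id", "condition", "nuclei_count",
                   "total_neurite_length_um", "neurite_length_per_cell_um",
                   "neurite_component_count", "branch_point_count",
                   "neurite_positive_cell_fraction", "excluded",
                   "min_neurite_length_um", "pixel_size_um")

#' Write per-field metrics to CSV
#'
#' One row per field in a fixed, documented column order (`field_id`,
#' `condition`, `nuclei_count`, `total_neurite_length_um`,
#' `neurite_length_per_cell_um`, `neurite_component_count`,
#' `branch_point_count`, `neurite_positive_cell_fraction`, `excluded`,
#' `min_neurite_length_um`, `pixel_size_um`). Doubles are written with 17
#' significant digits so [read_metrics()] reproduces them exactly.
#'
#' @param metrics a list of [quantify_field()] results or the data.frame
#'   returned by [metrics_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- metrics_table(metrics)
  if (nrow(df) == 0L) stop_input("input error: empty metrics list")
  out <- df
  for (cn in names(out)) {
    if (is.double(out[[cn]]))
      out[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                          sprintf("%.17g", out[[cn]]))
  }
  tryCatch(write.csv(out, path, row.names = FALSE, quote = which(
    names(out) %in% c("field_id", "condition"))),
    error = function(e) stop_input("I/O error writing '", path, "': ",
                                   conditionMessage(e)))
  invisible(path)
}

#' Read back a metrics CSV written by [write_metrics()]
#' @param path CSV path.
#' @return data.frame of per-field metrics.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop_input("input error: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$excluded <- as.logical(df$excluded)
  df
}

#' Collect FieldMetrics records into a data.frame
#'
#' @param metrics a single [quantify_field()] result, a list of them, or an
#'   already-collected data.frame (returned unchanged, column order fixed).
#' @return data.frame with the documented metrics column order.
#' @export
metrics_table <- function(metrics) {
  if (is.data.frame(metrics)) {
    miss <- setdiff(.metrics_cols, names(metrics))
    if (length(miss))
      stop_input("metrics data.frame missing column(s): ",
                 paste(miss, collapse = ", "))
    return(metrics[, .metrics_cols])
  }
  if (inherits(metrics, "field_metrics")) metrics <- list(metrics)
  if (!length(metrics)) stop_input("input error: empty metrics list")
  rows <- lapply(metrics, function(m) {
    as.data.frame(m[.metrics_cols], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
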