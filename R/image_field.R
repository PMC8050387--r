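# ImageField container and TIFF/manifest input

#' Construct an ImageField
#'
#' An `image_field` holds one microscopy field: two co-registered intensity
#' channels (nuclei and cell/neurite) with a physical pixel size and
#' condition metadata. Intensities are kept as read; downstream operations
#' normalize internally. Coordinates are (row, col), 1-based in R.
#'
#' @param nuclei_channel,cell_channel numeric matrices of identical
#'   dimensions, finite and non-negative.
#' @param field_id character scalar identifying the field.
#' @param condition character scalar, experimental condition label.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @return object of class `image_field`.
#' @export
image_field <- function(nuclei_channel, cell_channel, field_id = "field",
                        condition = "unknown", pixel_size_um = 0.65) {
  if (!is.matrix(nuclei_channel) || !is.matrix(cell_channel))
    stop_input("channels must be matrices")
  if (!identical(dim(nuclei_channel), dim(cell_channel)))
    stop_input("format error: channel dimension mismatch (",
               paste(dim(nuclei_channel), collapse = "x"), " vs ",
               paste(dim(cell_channel), collapse = "x"), ")")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_input("pixel_size_um must be a positive scalar")
  for (ch in list(nuclei_channel, cell_channel)) {
    if (anyNA(ch) || !all(is.finite(ch)))
      stop_input("channel intensities must be finite")
    if (min(ch) < 0) stop_input("channel intensities must be >= 0")
  }
  structure(list(field_id = as.character(field_id),
                 condition = as.character(condition),
                 nuclei_channel = nuclei_channel,
                 cell_channel = cell_channel,
                 pixel_size_um = pixel_size_um),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat("<image_field> ", x$field_id, " [", x$condition, "] ",
      nrow(x$nuclei_channel), "x", ncol(x$nuclei_channel),
      " px @ ", x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path))
    stop_input("input error: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop_input("format error reading '", path, "': ",
                                 conditionMessage(e)))
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample of multi-sample
    storage.mode(p) <- "double"
    p
  })
}

#' Read a two-channel field from TIFF file(s)
#'
#' Accepts either a single multi-page grayscale TIFF (pages selected by
#' `channel_map`) or two single-channel files (one per channel). 8- and
#' 16-bit images are read as their raw integer values without rescaling.
#'
#' @param paths one or two TIFF paths.
#' @param channel_map named integer vector with entries `nuclei` and `cell`.
#'   For a single multi-page file these are page numbers; for two files they
#'   index into `paths`.
#' @param pixel_size_um physical pixel size (µm per pixel).
#' @param field_id,condition metadata attached to the field.
#' @return an [image_field()].
#' @export
read_field <- function(paths, channel_map = c(nuclei = 1L, cell = 2L),
                       pixel_size_um = 0.65, field_id = NULL,
                       condition = "unknown") {
  if (!all(c("nuclei", "cell") %in% names(channel_map)))
    stop_input("channel_map must name a 'nuclei' and a 'cell' channel")
  if (is.null(field_id))
    field_id <- tools::file_path_sans_ext(basename(paths[1]))
  if (length(paths) == 1L) {
    pages <- read_tiff_pages(paths)
    want <- channel_map[c("nuclei", "cell")]
    if (any(want < 1L) || any(want > length(pages)))
      stop_input("format error: '", paths, "' has ", length(pages),
                 " page(s); channel_map requests ",
                 paste(want, collapse = ", "))
    nuc <- pages[[want[["nuclei"]]]]
    cel <- pages[[want[["cell"]]]]
  } else if (length(paths) == 2L) {
    nuc <- read_tiff_pages(paths[channel_map[["nuclei"]]])[[1]]
    cel <- read_tiff_pages(paths[channel_map[["cell"]]])[[1]]
  } else {
    stop_input("paths must reference one multi-page or two single-page TIFFs")
  }
  if (!identical(dim(nuc), dim(cel)))
    stop_input("format error: channel dimension mismatch (",
               paste(dim(nuc), collapse = "x"), " vs ",
               paste(dim(cel), collapse = "x"), ")")
  image_field(nuc, cel, field_id = field_id, condition = condition,
              pixel_size_um = pixel_size_um)
}

#' Read a plate/condition manifest CSV
#'
#' Required columns: `file`, `field_id`, `condition`. Optional:
#' `pixel_size_um` (defaults to `default_pixel_size_um`, echoed in outputs),
#' `nuclei_page`, `cell_page` (default 1 and 2). Relative file paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param default_pixel_size_um used where the manifest has no
#'   `pixel_size_um` column (0.65 µm/px, a typical 10x sCMOS scale).
#' @return data.frame with one row per field, class `neuritor_manifest`.
#' @export
read_manifest <- function(path, default_pixel_size_um = 0.65) {
  if (!file.exists(path)) stop_input("input error: manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "field_id", "condition")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_input("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$field_id))
    stop_input("manifest field_id values must be unique")
  if (is.null(m$pixel_size_um)) m$pixel_size_um <- default_pixel_size_um
  if (is.null(m$nuclei_page)) m$nuclei_page <- 1L
  if (is.null(m$cell_page)) m$cell_page <- 2L
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$file), m$file,
                file.path(base, m$file))
  missing_files <- abs[!file.exists(abs)]
  if (length(missing_files))
    stop_input("input error: manifest references missing file(s): ",
               paste(missing_files, collapse = ", "))
  m$file <- abs
  class(m) <- c("neuritor_manifest", "data.frame")
  m
}
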