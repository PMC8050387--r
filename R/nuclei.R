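# nuclei segmentation: the per-field cell-count denominator

#' Parameters for nuclei segmentation
#'
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma (px). Default 1.5
#'   (heavier smoothing flattens the distance-transform saddle between
#'   touching nuclei and defeats watershed splitting).
#' @param threshold_method `"otsu"` (default) or `"fixed"` (threshold taken
#'   directly from `threshold_offset` on the normalized channel).
#' @param threshold_offset additive offset to the Otsu threshold, expressed
#'   in multiples of the normalized channel's median absolute deviation so
#'   it transfers across bit depths. Default 0.
#' @param min_area_um2,max_area_um2 area gate for accepted nuclei, in µm².
#'   Defaults 30 and 500 (plausible for SH-SY5Y nuclei at 10x).
#' @param split_touching split fused nuclei by watershed on the distance
#'   transform. Default `TRUE`.
#' @param exclude_border drop nuclei touching the field border (partial
#'   nuclei bias counts and areas). Default `TRUE`.
#' @param background_radius_px disc radius for the illumination-correction
#'   opening; must exceed the nucleus radius. Default 25.
#' @param watershed_tolerance_px minimum distance-transform height (px) a
#'   basin must rise above its saddle to count as a separate nucleus;
#'   controls the splitting granularity; applied to a lightly smoothed
#'   distance map. Default 0.25.
#' @return named list of class `nuclei_params`.
#' @export
nuclei_params <- function(smoothing_sigma_px = 1.5,
                          threshold_method = c("otsu", "fixed"),
                          threshold_offset = 0,
                          min_area_um2 = 30, max_area_um2 = 500,
                          split_touching = TRUE, exclude_border = TRUE,
                          background_radius_px = 25,
                          watershed_tolerance_px = 0.25) {
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 threshold_method = match.arg(threshold_method),
                 threshold_offset = threshold_offset,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 split_touching = isTRUE(split_touching),
                 exclude_border = isTRUE(exclude_border),
                 background_radius_px = background_radius_px,
                 watershed_tolerance_px = watershed_tolerance_px),
            class = "nuclei_params")
}

#' Subtract a morphological-opening background estimate
#'
#' Estimates slowly varying background as the grayscale opening of the
#' channel with a disc whose radius exceeds the object radius, subtracts it
#' and clips at zero. Objects smaller than the disc survive essentially
#' unchanged; background structure larger than the disc is removed.
#'
#' @param channel numeric intensity matrix.
#' @param background_radius_px disc radius in pixels (> 0, larger than the
#'   nucleus radius).
#' @return corrected intensity matrix (same dimensions, >= 0).
#' @export
correct_illumination <- function(channel, background_radius_px) {
  if (!is.numeric(background_radius_px) || length(background_radius_px) != 1 ||
      !is.finite(background_radius_px) || background_radius_px <= 0)
    stop_input("parameter error: background_radius_px must be > 0")
  # EBImage grayscale morphology assumes intensities in [0, 1]; opening is
  # positively homogeneous, so normalize, open, and scale back (exact)
  scale <- max(channel)
  if (scale <= 0) return(channel * 0)
  bg <- as.matrix(EBImage::opening(channel / scale,
                                   disc_brush(background_radius_px))) * scale
  out <- pmax(channel - bg, 0)
  dim(out) <- dim(channel)
  out
}

relabel_sequential <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- map[lab[nz]]
  out
}

label_stats <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx))
    return(list(areas_px = integer(0), centroids = matrix(NA_real_, 0, 2)))
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  areas <- tabulate(l)
  cr <- tapply(rows, l, mean)
  cc <- tapply(cols, l, mean)
  list(areas_px = as.integer(areas),
       centroids = cbind(row = as.numeric(cr), col = as.numeric(cc)))
}

#' Segment Hoechst-stained nuclei
#'
#' Pipeline: Gaussian smoothing, illumination correction (opening-based
#' background subtraction), global Otsu threshold with a robust additive
#' offset, hole filling, small-object removal (`min_area_um2`), optional
#' watershed splitting of touching nuclei on the distance transform,
#' large-object removal (`max_area_um2`), optional removal of
#' border-touching labels, and sequential relabeling. Labeling is
#' 8-connected.
#'
#' @param channel nuclei-channel intensity matrix (finite, non-negative).
#' @param params a [nuclei_params()] list.
#' @param pixel_size_um µm per pixel, used to convert the area gates.
#' @return object of class `nuclei_result` with elements `label_mask`
#'   (integer matrix, labels `1..N`), `count`, `centroids` (N x 2 matrix of
#'   (row, col)), `areas_um2`, and `pixel_size_um`.
#' @export
segment_nuclei <- function(channel, params = nuclei_params(),
                           pixel_size_um = 0.65) {
  if (anyNA(channel)) stop_input("input error: NaN/NA in nuclei channel")
  if (!all(is.finite(channel)) || min(channel) < 0)
    stop_input("input error: nuclei channel must be finite and >= 0")
  p <- params
  px_area <- pixel_size_um^2

  sm <- if (p$smoothing_sigma_px > 0)
    as.matrix(EBImage::gblur(channel, sigma = p$smoothing_sigma_px))
  else channel
  corr <- correct_illumination(sm, p$background_radius_px)
  rng <- max(corr)
  if (rng <= 0) return(empty_nuclei_result(dim(channel), pixel_size_um))
  v <- corr / rng
  thr <- if (p$threshold_method == "otsu") {
    # the noise floor guards against Otsu bisecting pure noise on fields
    # without any real foreground
    max(as.numeric(EBImage::otsu(EBImage::Image(v), range = c(0, 1))) +
          p$threshold_offset * stats::mad(as.numeric(v)),
        median(v) + 3 * stats::mad(as.numeric(v)))
  } else {
    p$threshold_offset
  }
  mask <- v > thr
  mask <- as.matrix(EBImage::fillHull(mask * 1)) > 0

  lab <- label_components(mask)
  st <- label_stats(lab)
  drop <- which(st$areas_px * px_area < p$min_area_um2)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    lab <- relabel_sequential(lab)
  }
  if (max(lab) == 0L) return(empty_nuclei_result(dim(channel), pixel_size_um))

  if (p$split_touching) {
    dm <- as.matrix(EBImage::distmap(lab > 0))
    # lightly smooth the distance map so boundary roughness does not seed
    # spurious basins, then zero it outside the mask again
    dm <- as.matrix(EBImage::gblur(dm, sigma = 0.7))
    dm[lab == 0L] <- 0
    ws <- EBImage::watershed(EBImage::Image(dm),
                             tolerance = p$watershed_tolerance_px, ext = 1)
    lab <- relabel_sequential(as.matrix(ws))
  }

  st <- label_stats(lab)
  drop <- which(st$areas_px * px_area < p$min_area_um2 |
                  st$areas_px * px_area > p$max_area_um2)
  if (p$exclude_border) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border_labels[border_labels > 0])
  }
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    lab <- relabel_sequential(lab)
  }
  st <- label_stats(lab)
  structure(list(label_mask = lab,
                 count = max(lab),
                 centroids = st$centroids,
                 areas_um2 = st$areas_px * px_area,
                 pixel_size_um = pixel_size_um),
            class = "nuclei_result")
}

empty_nuclei_result <- function(dims, pixel_size_um) {
  structure(list(label_mask = matrix(0L, dims[1], dims[2]),
                 count = 0L,
                 centroids = matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("row", "col"))),
                 areas_um2 = numeric(0),
                 pixel_size_um = pixel_size_um),
            class = "nuclei_result")
}

#' @export
print.nuclei_result <- function(x, ...) {
  cat("<nuclei_result> ", x$count, " nuclei, ",
      nrow(x$label_mask), "x", ncol(x$label_mask), " px\n", sep = "")
  invisible(x)
}
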