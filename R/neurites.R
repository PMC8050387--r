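# neurite detection: ridge enhancement -> threshold -> soma exclusion ->
# skeleton -> pruning -> component lengths and topology

#' Parameters for neurite segmentation
#'
#' @param scales_px ridge-filter scales (px), see [enhance_ridges()];
#'   defaults `c(1.5, 2.5)`, matched to neurites a few pixels wide.
#' @param response_threshold robust threshold on the ridge response,
#'   expressed in multiples of the response's median absolute deviation
#'   above its median, so it transfers across intensity scales and bit
#'   depths. Default 8.
#' @param polarity ridge polarity, see [enhance_ridges()].
#' @param soma_dilation_um nuclei labels are dilated by this margin (µm) and
#'   the dilated region excluded, so only projections outside cell bodies
#'   are measured. The margin is measured from the nucleus boundary and
#'   must reach past the soma edge and the ridge-response spread around
#'   it; with ~7 µm somata the default is 8.
#' @param prune_spur_length_um terminal spurs shorter than this are removed
#'   from the skeleton. Default 5.
#' @param min_component_length_um skeleton components shorter than this are
#'   discarded. Default 10.
#' @return named list of class `neurite_params`.
#' @export
neurite_params <- function(scales_px = c(1.5, 2.5),
                           response_threshold = 8,
                           polarity = "bright_on_dark",
                           soma_dilation_um = 8,
                           prune_spur_length_um = 5,
                           min_component_length_um = 10) {
  structure(list(scales_px = scales_px,
                 response_threshold = response_threshold,
                 polarity = polarity,
                 soma_dilation_um = soma_dilation_um,
                 prune_spur_length_um = prune_spur_length_um,
                 min_component_length_um = min_component_length_um),
            class = "neurite_params")
}

fill_small_holes <- function(mask, max_hole_px = 64L) {
  filled <- as.matrix(EBImage::fillHull(mask * 1)) > 0
  added <- filled & !mask
  if (!any(added)) return(mask)
  lab <- label_components(added)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas <= max_hole_px)
  mask | (added & matrix(lab %in% small, nrow(lab), ncol(lab)))
}

neurite_skeleton <- function(mask, pixel_size_um) {
  labels <- label_components(mask)
  n <- max(labels)
  if (n == 0L) {
    comps <- data.frame(component = integer(0), length_um = numeric(0),
                        n_px = integer(0))
    topo <- skeleton_topology(mask)
    return(structure(list(skeleton_mask = mask, label_mask = labels,
                          components = comps, total_length_um = 0,
                          branch_points = topo$branch_points,
                          endpoints = topo$endpoints,
                          pixel_size_um = pixel_size_um),
                     class = "neurite_skeleton"))
  }
  len <- skeleton_length(mask, pixel_size_um, labels = labels)
  topo <- skeleton_topology(mask)
  comps <- data.frame(component = seq_len(n),
                      length_um = len$per_component_um,
                      n_px = tabulate(labels[labels > 0], nbins = n))
  structure(list(skeleton_mask = mask, label_mask = labels,
                 components = comps,
                 total_length_um = sum(len$per_component_um),
                 branch_points = topo$branch_points,
                 endpoints = topo$endpoints,
                 pixel_size_um = pixel_size_um),
            class = "neurite_skeleton")
}

#' @export
print.neurite_skeleton <- function(x, ...) {
  cat("<neurite_skeleton> ", nrow(x$components), " component(s), total ",
      round(x$total_length_um, 2), " um, ",
      nrow(x$branch_points), " branch point(s)\n", sep = "")
  invisible(x)
}

#' Segment neurites and reduce them to a measured skeleton
#'
#' Pipeline: multi-scale Hessian ridge enhancement of the cell channel,
#' relative thresholding of the response, morphological closing, exclusion
#' of soma regions (nuclei labels dilated by `soma_dilation_um`),
#' skeletonization to unit width, iterative pruning of short terminal
#' spurs, removal of components below `min_component_length_um`, and
#' topology extraction.
#'
#' @param field an [image_field()].
#' @param nuclei matching [segment_nuclei()] result (defines the soma
#'   exclusion zone).
#' @param params a [neurite_params()] list.
#' @return object of class `neurite_skeleton`: `skeleton_mask`,
#'   `label_mask` (8-connected component labels), `components` (data.frame
#'   with `length_um` per component), `total_length_um`, `branch_points`,
#'   `endpoints`, `pixel_size_um`.
#' @export
segment_neurites <- function(field, nuclei, params = neurite_params()) {
  if (!identical(dim(field$cell_channel), dim(nuclei$label_mask)))
    stop_input("input error: field and nuclei dimensions differ")
  p <- params
  px <- field$pixel_size_um
  rf <- ridge_filter(field$cell_channel, scales_px = p$scales_px,
                     polarity = p$polarity)
  resp <- rf$response
  if (max(resp) <= 0)
    return(neurite_skeleton(matrix(FALSE, nrow(resp), ncol(resp)), px))
  # centerline extraction: across-ridge non-maximum suppression keeps the
  # 1-2 px ridge crest; the robust floor (response median + k MADs)
  # rejects noise crests
  thr <- max(median(resp) + p$response_threshold * stats::mad(as.numeric(resp)),
             0.25 * max(resp))
  mask <- ridge_nms(rf) & resp > thr
  # bridge 1 px gaps along the crest, then re-thin
  mask <- as.matrix(EBImage::closing(mask * 1, disc_brush(1))) > 0
  mask <- fill_small_holes(mask, max_hole_px = 16L)

  if (nuclei$count > 0) {
    soma_r_px <- p$soma_dilation_um / px
    soma <- as.matrix(EBImage::dilate(nuclei$label_mask > 0,
                                      disc_brush(soma_r_px))) > 0
    mask[soma] <- FALSE
  }

  skel <- skeletonize(mask)
  skel <- prune_spurs(skel, p$prune_spur_length_um / px)
  # drop components shorter than the minimum physical length
  labels <- label_components(skel)
  if (max(labels) > 0L) {
    len <- skeleton_length(skel, px, labels = labels)
    keep <- which(len$per_component_um >= p$min_component_length_um)
    skel <- skel & matrix(labels %in% keep, nrow(labels), ncol(labels))
  }
  neurite_skeleton(skel, px)
}
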