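# per-field morphometrics: combine nuclei and skeleton into FieldMetrics

#' Quantification parameters
#'
#' @param min_neurite_length_um a cell counts as neurite-positive when the
#'   total skeleton length assigned to it reaches this threshold (µm).
#'   Default 20 (about one to two SH-SY5Y soma diameters).
#' @return named list of class `quant_params`.
#' @export
quant_params <- function(min_neurite_length_um = 20) {
  structure(list(min_neurite_length_um = min_neurite_length_um),
            class = "quant_params")
}

#' Assign each skeleton component to its nearest nucleus
#'
#' A component is assigned to the nucleus whose centroid is nearest to the
#' component's closest pixel; exact distance ties go to the lower nucleus
#' label. Deterministic.
#'
#' @param skeleton a [segment_neurites()] result.
#' @param nuclei a [segment_nuclei()] result with `count >= 1`.
#' @return integer vector, one nucleus label per skeleton component
#'   (named by component label). Empty when the skeleton has no components.
#' @export
assign_components_to_cells <- function(skeleton, nuclei) {
  if (nuclei$count < 1L)
    stop_input("assignment error: no nuclei to assign components to")
  ncomp <- nrow(skeleton$components)
  if (ncomp == 0L) return(setNames(integer(0), character(0)))
  cents <- nuclei$centroids
  lab <- skeleton$label_mask
  out <- integer(ncomp)
  for (k in seq_len(ncomp)) {
    pix <- which(lab == k, arr.ind = TRUE)
    # min over component pixels of distance to each centroid
    d <- vapply(seq_len(nrow(cents)), function(j) {
      min(sqrt((pix[, 1] - cents[j, 1])^2 + (pix[, 2] - cents[j, 2])^2))
    }, numeric(1))
    out[k] <- which(d <= min(d) + 1e-9)[1]
  }
  setNames(out, as.character(seq_len(ncomp)))
}

#' Compute per-field neurite-outgrowth morphometrics
#'
#' Fills the per-field metric record: nuclei count, total neurite length,
#' length per cell, component and branch-point counts, and the fraction of
#' cells whose assigned neurite length reaches `min_neurite_length_um`.
#' Fields with zero nuclei get `NA` for the per-cell quantities and are
#' flagged `excluded = TRUE` (excluded from downstream statistics rather
#' than imputed).
#'
#' @param nuclei a [segment_nuclei()] result.
#' @param skeleton the matching [segment_neurites()] result.
#' @param params a [quant_params()] list.
#' @param field_id,condition metadata copied into the record.
#' @return object of class `field_metrics` (a named list; see
#'   [metrics_table()] for the column order).
#' @export
quantify_field <- function(nuclei, skeleton, params = quant_params(),
                           field_id = "field", condition = "unknown") {
  total <- skeleton$total_length_um
  ncomp <- nrow(skeleton$components)
  nbp <- nrow(skeleton$branch_points)
  if (nuclei$count == 0L) {
    m <- list(field_id = field_id, condition = condition,
              nuclei_count = 0L,
              total_neurite_length_um = total,
              neurite_length_per_cell_um = NA_real_,
              neurite_component_count = ncomp,
              branch_point_count = nbp,
              neurite_positive_cell_fraction = NA_real_,
              excluded = TRUE,
              min_neurite_length_um = params$min_neurite_length_um,
              pixel_size_um = nuclei$pixel_size_um)
    return(structure(m, class = "field_metrics"))
  }
  per_cell <- numeric(nuclei$count)
  if (ncomp > 0L) {
    owner <- assign_components_to_cells(skeleton, nuclei)
    sums <- tapply(skeleton$components$length_um, owner, sum)
    per_cell[as.integer(names(sums))] <- as.numeric(sums)
  }
  frac <- mean(per_cell >= params$min_neurite_length_um)
  structure(list(field_id = field_id, condition = condition,
                 nuclei_count = nuclei$count,
                 total_neurite_length_um = total,
                 neurite_length_per_cell_um = total / nuclei$count,
                 neurite_component_count = ncomp,
                 branch_point_count = nbp,
                 neurite_positive_cell_fraction = frac,
                 excluded = FALSE,
                 min_neurite_length_um = params$min_neurite_length_um,
                 pixel_size_um = nuclei$pixel_size_um),
            class = "field_metrics")
}

#' @export
print.field_metrics <- function(x, ...) {
  cat("<field_metrics> ", x$field_id, " [", x$condition, "]: ",
      x$nuclei_count, " nuclei, ",
      round(x$total_neurite_length_um, 1), " um neurite (",
      if (is.na(x$neurite_length_per_cell_um)) "NA" else
        round(x$neurite_length_per_cell_um, 1), " um/cell)\n", sep = "")
  invisible(x)
}
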