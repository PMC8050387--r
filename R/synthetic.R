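# synthetic two-channel fields with analytic ground truth
#
# Nuclei are Gaussian-blurred ellipses in the nuclei channel; each cell has
# a soma blob in the cell channel and neurites leave the soma boundary along
# smooth chains of circular arcs whose arc length is known exactly. Noise is
# Poisson shot noise on the signal plus Gaussian read noise, with the
# amplitude calibrated so (peak - background) / noise SD equals the
# requested SNR.

#' Specification for a synthetic field
#'
#' Defaults describe a 10x-like live-cell field of SH-SY5Y-like cells:
#' 512x512 px at 0.65 µm/px, nuclei of 4-7 µm radius, somata of 7 µm
#' radius, and neurites of 40-120 µm arc length, 3 px wide, with bounded
#' curvature (minimum bending radius 20 µm).
#'
#' @param field_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um µm per pixel.
#' @param n_nuclei nuclei per field.
#' @param nucleus_radius_um `c(min, max)` semi-major axis range (µm).
#' @param allowed_overlap_fraction maximum allowed pairwise nucleus overlap,
#'   as `1 - d / (r1 + r2)`; 0 keeps nuclei disjoint. Must be in `[0, 0.5)`.
#' @param nucleus_axis_ratio `c(min, max)` minor/major axis ratio of
#'   nucleus ellipses; `c(1, 1)` gives circles.
#' @param n_neurites neurites per field (anchored to random somata).
#' @param neurite_length_um `c(min, max)` of the uniform arc-length
#'   distribution (µm).
#' @param neurite_width_px stroke width of rendered neurites (px).
#' @param curvature_max maximum unsigned path curvature (rad/µm).
#' @param soma_radius_um soma blob radius (µm).
#' @param soma_exclusion_margin_um margin beyond the soma radius within
#'   which neurite pixels are excluded from the ground-truth neurite mask
#'   and length-outside bookkeeping (mirrors the segmentation soma-exclusion
#'   rule). Default 5.
#' @param background_level background intensity (counts).
#' @param snr target signal-to-noise ratio: (peak - background) divided by
#'   the noise SD at peak signal.
#' @param read_noise_sd Gaussian read-noise SD (counts).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(field_shape = c(512L, 512L), pixel_size_um = 0.65,
                           n_nuclei = 25, nucleus_radius_um = c(4, 7),
                           allowed_overlap_fraction = 0,
                           nucleus_axis_ratio = c(0.75, 1),
                           n_neurites = 12, neurite_length_um = c(40, 120),
                           neurite_width_px = 3, curvature_max = 0.05,
                           soma_radius_um = 7, soma_exclusion_margin_um = 5,
                           background_level = 100, snr = 10,
                           read_noise_sd = 2, seed = 1) {
  spec <- list(field_shape = as.integer(field_shape),
               pixel_size_um = pixel_size_um, n_nuclei = n_nuclei,
               nucleus_radius_um = nucleus_radius_um,
               allowed_overlap_fraction = allowed_overlap_fraction,
               nucleus_axis_ratio = nucleus_axis_ratio,
               n_neurites = n_neurites, neurite_length_um = neurite_length_um,
               neurite_width_px = neurite_width_px,
               curvature_max = curvature_max, soma_radius_um = soma_radius_um,
               soma_exclusion_margin_um = soma_exclusion_margin_um,
               background_level = background_level, snr = snr,
               read_noise_sd = read_noise_sd, seed = seed)
  stopifnot(length(spec$field_shape) == 2L, all(spec$field_shape > 16L))
  pos <- c("pixel_size_um", "neurite_width_px", "soma_radius_um", "snr")
  for (nm in pos) if (spec[[nm]] <= 0)
    stop_input("parameter error: ", nm, " must be > 0")
  if (spec$allowed_overlap_fraction < 0 || spec$allowed_overlap_fraction >= 0.5)
    stop_input("parameter error: allowed_overlap_fraction must be in [0, 0.5)")
  class(spec) <- "synthetic_spec"
  spec
}

# ---- arc-chain paths -------------------------------------------------------

#' Evaluate a circular-arc chain at given arc lengths
#'
#' A chain is a data.frame with signed `kappa` (curvature, rad/µm; 0 for a
#' straight segment) and `length_um` per segment. Positions are exact:
#' within a segment of curvature k, advancing s from heading h moves by the
#' chord of a circle of radius 1/k. Used both to build ground truth and as
#' the dense-polyline cross-check of the analytic arc length.
#'
#' @param chain data.frame with columns `kappa`, `length_um`.
#' @param start numeric `c(row, col)` in µm.
#' @param heading initial heading (rad; 0 points along +col).
#' @param s arc-length positions (µm) at which to evaluate, in `[0, total]`.
#' @return matrix with columns `row`, `col` (µm) for each `s`.
#' @export
arc_chain_points <- function(chain, start, heading, s) {
  ends <- cumsum(chain$length_um)
  starts <- c(0, ends[-length(ends)])
  # precompute segment start poses
  pose <- matrix(0, nrow(chain) + 1L, 3L)  # row, col, heading
  pose[1, ] <- c(start[1], start[2], heading)
  for (i in seq_len(nrow(chain))) {
    pose[i + 1L, ] <- advance_pose(pose[i, ], chain$kappa[i],
                                   chain$length_um[i])
  }
  out <- matrix(0, length(s), 2L, dimnames = list(NULL, c("row", "col")))
  seg <- findInterval(s, starts, rightmost.closed = FALSE)
  seg[seg > nrow(chain)] <- nrow(chain)
  seg[seg < 1L] <- 1L
  for (i in seq_along(s)) {
    p <- advance_pose(pose[seg[i], ], chain$kappa[seg[i]],
                      s[i] - starts[seg[i]])
    out[i, ] <- p[1:2]
  }
  out
}

advance_pose <- function(pose, kappa, s) {
  h <- pose[3]
  if (abs(kappa) < 1e-12) {
    c(pose[1] + s * sin(h), pose[2] + s * cos(h), h)
  } else {
    # heading convention: col ~ cos, row ~ sin; turning at rate kappa
    c(pose[1] + (cos(h) - cos(h + kappa * s)) / kappa,
      pose[2] + (sin(h + kappa * s) - sin(h)) / kappa,
      h + kappa * s)
  }
}

sample_arc_chain <- function(total_um, curvature_max,
                             seg_len_range = c(15, 40)) {
  lens <- numeric(0)
  remaining <- total_um
  while (remaining > 1e-9) {
    l <- min(remaining, runif(1, seg_len_range[1], seg_len_range[2]))
    lens <- c(lens, l)
    remaining <- remaining - l
  }
  data.frame(kappa = runif(length(lens), -curvature_max, curvature_max),
             length_um = lens)
}

# arc-length parameter at which the path first leaves the disc of radius r
# around center (row, col) in µm; exact to tol by bisection
first_exit_s <- function(chain, start, heading, center, r, tol = 1e-9) {
  total <- sum(chain$length_um)
  sgrid <- seq(0, total, length.out = max(64L, ceiling(total * 4)))
  pts <- arc_chain_points(chain, start, heading, sgrid)
  d <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  k <- which(d >= r)[1]
  if (is.na(k)) return(total)
  if (k == 1L) return(0)
  lo <- sgrid[k - 1L]; hi <- sgrid[k]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    p <- arc_chain_points(chain, start, heading, mid)
    if (sqrt((p[1] - center[1])^2 + (p[2] - center[2])^2) >= r) hi <- mid
    else lo <- mid
  }
  (lo + hi) / 2
}

# ---- rendering -------------------------------------------------------------

fill_ellipse <- function(mask, center_px, a_px, b_px, theta) {
  r0 <- max(1L, floor(center_px[1] - a_px - 1))
  r1 <- min(nrow(mask), ceiling(center_px[1] + a_px + 1))
  c0 <- max(1L, floor(center_px[2] - a_px - 1))
  c1 <- min(ncol(mask), ceiling(center_px[2] + a_px + 1))
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - center_px[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center_px[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  mask[rr, cc] <- mask[rr, cc] | inside
  mask
}

stamp_polyline <- function(dims, pts_px, radius_px) {
  mask <- matrix(FALSE, dims[1], dims[2])
  offs <- disc_offsets(radius_px)
  rows <- as.integer(round(rep(pts_px[, 1], each = nrow(offs)) + offs[, 1]))
  cols <- as.integer(round(rep(pts_px[, 2], each = nrow(offs)) + offs[, 2]))
  ok <- rows >= 1 & cols >= 1 & rows <= dims[1] & cols <= dims[2]
  mask[cbind(rows[ok], cols[ok])] <- TRUE
  mask
}

# amplitude x solving x^2 = snr^2 * (background + x + read_sd^2): the
# amplitude at which (peak - bg) / sqrt(peak + read_sd^2) equals snr under
# Poisson + Gaussian noise
calibrate_amplitude <- function(snr, background, read_sd) {
  (snr^2 + sqrt(snr^4 + 4 * snr^2 * (background + read_sd^2))) / 2
}

add_noise <- function(clean, read_sd) {
  n <- length(clean)
  noisy <- rpois(n, lambda = as.numeric(clean)) + rnorm(n, 0, read_sd)
  out <- pmax(noisy, 0)
  dim(out) <- dim(clean)
  out
}

scale_to_snr <- function(clean, background, snr, read_sd) {
  peak <- max(clean)
  if (peak <= background) return(clean)
  x <- calibrate_amplitude(snr, background, read_sd)
  background + (clean - background) * (x / (peak - background))
}

# ---- generation ------------------------------------------------------------

#' Generate one synthetic two-channel field with ground truth
#'
#' Renders nuclei (Gaussian-blurred ellipses), somata (blurred discs) and
#' neurites (constant-width strokes along bounded-curvature arc chains whose
#' analytic arc length is recorded exactly), then adds Poisson shot noise
#' plus Gaussian read noise calibrated to the spec's SNR. Fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param field_id,condition metadata for the returned field.
#' @param nucleus_centers_px optional n x 2 matrix of (row, col) nucleus
#'   centres (px), overriding random placement (used to construct
#'   deliberately touching or known-position nuclei).
#' @param nucleus_radii_um optional vector of semi-major radii paired with
#'   `nucleus_centers_px`.
#' @return list with elements `field` (an [image_field()]) and `truth`, a
#'   `ground_truth` list: `nuclei` (centres px, radii), `neurites`
#'   (per-neurite `length_um` and `length_outside_um`, anchor),
#'   `total_length_um`, `total_length_outside_um`, and clean masks
#'   `nuclei_mask`, `soma_mask` (exclusion zone) and `neurite_mask`
#'   (outside the exclusion zone).
#' @export
generate_field <- function(spec, field_id = "synthetic", condition = "synthetic",
                           nucleus_centers_px = NULL, nucleus_radii_um = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_field_impl(spec, field_id, condition,
                                           nucleus_centers_px,
                                           nucleus_radii_um))
}

generate_field_impl <- function(spec, field_id, condition,
                                nucleus_centers_px, nucleus_radii_um) {
  dims <- spec$field_shape
  px <- spec$pixel_size_um
  rmax_px <- spec$nucleus_radius_um[2] / px
  margin <- rmax_px + 3

  # nucleus placement
  if (!is.null(nucleus_centers_px)) {
    centers <- nucleus_centers_px
    a_um <- if (!is.null(nucleus_radii_um)) nucleus_radii_um else
      rep(mean(spec$nucleus_radius_um), nrow(centers))
    n_nuc <- nrow(centers)
  } else {
    n_nuc <- spec$n_nuclei
    centers <- matrix(NA_real_, n_nuc, 2L)
    a_um <- runif(n_nuc, spec$nucleus_radius_um[1], spec$nucleus_radius_um[2])
    for (i in seq_len(n_nuc)) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        cand <- c(runif(1, margin, dims[1] - margin),
                  runif(1, margin, dims[2] - margin))
        if (i == 1L) { centers[i, ] <- cand; placed <- TRUE; break }
        d <- sqrt((centers[seq_len(i - 1L), 1] - cand[1])^2 +
                    (centers[seq_len(i - 1L), 2] - cand[2])^2)
        min_d <- (a_um[seq_len(i - 1L)] + a_um[i]) / px *
          (1 - spec$allowed_overlap_fraction)
        if (all(d >= min_d)) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop_input("generation error: cannot place nucleus ", i,
                   " under the overlap constraint")
    }
  }
  b_um <- a_um * runif(n_nuc, spec$nucleus_axis_ratio[1],
                       spec$nucleus_axis_ratio[2])
  theta <- runif(n_nuc, 0, pi)

  nuclei_mask <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(n_nuc))
    nuclei_mask <- fill_ellipse(nuclei_mask, centers[i, ],
                                a_um[i] / px, b_um[i] / px, theta[i])

  soma_r_px <- spec$soma_radius_um / px
  soma_render <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(n_nuc))
    soma_render <- fill_ellipse(soma_render, centers[i, ],
                                soma_r_px, soma_r_px, 0)
  excl_r_um <- spec$soma_radius_um + spec$soma_exclusion_margin_um
  soma_excl <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(n_nuc))
    soma_excl <- fill_ellipse(soma_excl, centers[i, ],
                              excl_r_um / px, excl_r_um / px, 0)

  # neurites
  n_neur <- spec$n_neurites
  neur_mask <- matrix(FALSE, dims[1], dims[2])
  neur_stroke <- matrix(FALSE, dims[1], dims[2])
  neur_df <- data.frame(neurite = integer(0), anchor = integer(0),
                        length_um = numeric(0), length_outside_um = numeric(0))
  if (n_neur > 0 && n_nuc > 0) {
    anchors <- sample.int(n_nuc, n_neur, replace = n_neur > n_nuc)
    for (j in seq_len(n_neur)) {
      anc <- anchors[j]
      c_um <- centers[anc, ] * px
      accepted <- FALSE
      for (try in seq_len(200L)) {
        phi <- runif(1, 0, 2 * pi)
        start <- c_um + spec$soma_radius_um * c(sin(phi), cos(phi))
        heading <- phi + runif(1, -0.3, 0.3)
        L <- runif(1, spec$neurite_length_um[1], spec$neurite_length_um[2])
        chain <- sample_arc_chain(L, spec$curvature_max)
        sgrid <- seq(0, L, length.out = max(64L, ceiling(L * 4)))
        dense <- arc_chain_points(chain, start, heading, sgrid)
        dense_px <- dense / px
        if (any(dense_px[, 1] < 4 | dense_px[, 2] < 4 |
                  dense_px[, 1] > dims[1] - 3 | dense_px[, 2] > dims[2] - 3))
          next
        # must leave its anchor exclusion disc and never re-enter any
        s_exit <- first_exit_s(chain, start, heading, c_um, excl_r_um)
        if (s_exit >= L - 2) next
        after <- dense[sgrid > s_exit + 2, , drop = FALSE]
        bad <- FALSE
        for (i in seq_len(n_nuc)) {
          di <- sqrt((after[, 1] - centers[i, 1] * px)^2 +
                       (after[, 2] - centers[i, 2] * px)^2)
          if (any(di < excl_r_um)) { bad <- TRUE; break }
        }
        if (bad) next
        accepted <- TRUE
        break
      }
      if (!accepted)
        stop_input("generation error: cannot place neurite ", j,
                   " inside the field under the soma-avoidance constraint")
      step_px <- 0.25
      s_draw <- seq(0, L, by = step_px * px)
      pts_px <- arc_chain_points(chain, start, heading, s_draw) / px
      stroke <- stamp_polyline(dims, pts_px, spec$neurite_width_px / 2)
      neur_stroke <- neur_stroke | stroke
      neur_df <- rbind(neur_df,
                       data.frame(neurite = j, anchor = anc, length_um = L,
                                  length_outside_um = L - s_exit))
    }
    neur_mask <- neur_stroke & !soma_excl
  }

  bg <- spec$background_level
  amp <- 1000  # nominal, rescaled by SNR calibration
  nuc_clean <- bg + amp * (nuclei_mask * 1)
  nuc_clean <- as.matrix(EBImage::gblur(nuc_clean, sigma = 1.2))
  nuc_clean <- scale_to_snr(nuc_clean, bg, spec$snr, spec$read_noise_sd)

  cell_sig <- pmax(soma_render * 1, neur_stroke * 0.85)
  cell_clean <- bg + amp * cell_sig
  cell_clean <- as.matrix(EBImage::gblur(cell_clean, sigma = 0.8))
  cell_clean <- scale_to_snr(cell_clean, bg, spec$snr, spec$read_noise_sd)

  field <- image_field(add_noise(nuc_clean, spec$read_noise_sd),
                       add_noise(cell_clean, spec$read_noise_sd),
                       field_id = field_id, condition = condition,
                       pixel_size_um = px)
  truth <- structure(list(
    nuclei = data.frame(nucleus = seq_len(n_nuc),
                        row_px = centers[, 1], col_px = centers[, 2],
                        radius_a_um = a_um, radius_b_um = b_um),
    neurites = neur_df,
    total_length_um = sum(neur_df$length_um),
    total_length_outside_um = sum(neur_df$length_outside_um),
    nuclei_mask = nuclei_mask, soma_mask = soma_excl,
    neurite_mask = neur_mask,
    clean_nuclei_channel = nuc_clean, clean_cell_channel = cell_clean),
    class = "ground_truth")
  list(field = field, truth = truth)
}

#' Generate a multi-condition synthetic experiment on disk
#'
#' Writes per-field two-page 16-bit TIFFs, a manifest CSV readable by
#' [read_manifest()], and a ground-truth CSV aligned by `field_id`.
#' Per-field seeds are derived deterministically from the master seed, so
#' fields are independent yet the whole experiment reproduces exactly.
#'
#' @param condition_specs named list; each element is a list with elements
#'   `spec` (a [synthetic_spec()]) and `n_fields`.
#' @param out_dir output directory (created; must be empty unless
#'   `overwrite`).
#' @param master_seed seed from which per-field seeds are derived.
#' @param overwrite allow writing into a non-empty directory.
#' @return list with `manifest` (data.frame), `truth` (data.frame) and the
#'   paths written.
#' @export
generate_experiment <- function(condition_specs, out_dir, master_seed = 1,
                                overwrite = FALSE) {
  if (length(condition_specs) < 1L)
    stop_input("need at least one condition")
  if (is.null(names(condition_specs)))
    stop_input("condition_specs must be a named list")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop_input("I/O error: output directory '", out_dir,
               "' is not empty (use overwrite = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  man <- list(); tru <- list()
  fi <- 0L
  for (cond in names(condition_specs)) {
    cs <- condition_specs[[cond]]
    for (k in seq_len(cs$n_fields)) {
      fi <- fi + 1L
      fid <- sprintf("%s_f%03d", cond, k)
      spec <- cs$spec
      spec$seed <- derive_seed(master_seed, fi)
      g <- generate_field(spec, field_id = fid, condition = cond)
      rel <- file.path("images", paste0(fid, ".tif"))
      write_field_tiff(g$field, file.path(out_dir, rel))
      man[[fi]] <- data.frame(file = rel, field_id = fid, condition = cond,
                              pixel_size_um = spec$pixel_size_um,
                              nuclei_page = 1L, cell_page = 2L)
      tru[[fi]] <- data.frame(field_id = fid, condition = cond,
                              n_nuclei = nrow(g$truth$nuclei),
                              total_length_um = g$truth$total_length_um,
                              total_length_outside_um =
                                g$truth$total_length_outside_um)
    }
  }
  manifest <- do.call(rbind, man)
  truth <- do.call(rbind, tru)
  man_path <- file.path(out_dir, "manifest.csv")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write.csv(manifest, man_path, row.names = FALSE)
  write.csv(truth, truth_path, row.names = FALSE)
  list(manifest = manifest, truth = truth,
       manifest_path = man_path, truth_path = truth_path)
}
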