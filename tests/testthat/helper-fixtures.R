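# shared fixtures: all synthetic, built in code at test time

# a tiny deterministic two-channel field with integer intensities
tiny_field <- function(dims = c(48L, 64L), seed = 1) {
  withr::with_seed(seed, {
    nuc <- matrix(sample.int(4096L, prod(dims), replace = TRUE) - 1L,
                  dims[1], dims[2])
    cel <- matrix(sample.int(4096L, prod(dims), replace = TRUE) - 1L,
                  dims[1], dims[2])
    image_field(nuc, cel, field_id = "tiny", condition = "ctrl",
                pixel_size_um = 0.5)
  })
}

# field with touching nucleus pairs at a known overlap fraction:
# 4 pairs (overlap ~ U(0.1, 0.3)) + 4 singles = 12 nuclei, circular
touching_pairs_field <- function(rep) {
  set.seed(9000 + rep)
  centers <- NULL; radii <- NULL
  grid <- expand.grid(r = c(70, 170, 270, 340), c = c(70, 190, 310))
  pick <- grid[sample(nrow(grid), 8), ]
  px <- 0.65
  for (i in 1:8) {
    r1 <- runif(1, 4.5, 6.5)
    if (i <= 4) {
      r2 <- runif(1, 4.5, 6.5)
      f <- runif(1, 0.1, 0.3)
      d <- (r1 + r2) * (1 - f) / px
      ang <- runif(1, 0, 2 * pi)
      centers <- rbind(centers, c(pick$r[i], pick$c[i]),
                       c(pick$r[i] + d * sin(ang), pick$c[i] + d * cos(ang)))
      radii <- c(radii, r1, r2)
    } else {
      centers <- rbind(centers, c(pick$r[i], pick$c[i]))
      radii <- c(radii, r1)
    }
  }
  sp <- synthetic_spec(field_shape = c(400L, 380L), n_neurites = 0, snr = 6,
                       allowed_overlap_fraction = 0.4,
                       nucleus_axis_ratio = c(1, 1), seed = rep)
  generate_field(sp, nucleus_centers_px = centers, nucleus_radii_um = radii)
}

# brute-force skeleton length: enumerate every unique 8-adjacent pixel pair
brute_force_length <- function(mask, pixel_size_um) {
  pix <- which(mask, arr.ind = TRUE)
  n <- nrow(pix)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dr <- abs(pix[i, 1] - pix[j, 1])
      dc <- abs(pix[i, 2] - pix[j, 2])
      if (max(dr, dc) == 1)
        total <- total + if (dr + dc == 2) sqrt(2) else 1
    }
  }
  total * pixel_size_um
}

# random small unit-width skeletons: random walks thinned to unit width
random_small_skeleton <- function(seed, max_px = 40L) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, 24L, 24L)
    pos <- c(12L, 12L)
    m[pos[1], pos[2]] <- TRUE
    for (i in seq_len(max_px)) {
      step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      pos <- pmin(pmax(pos + step, 2L), 23L)
      m[pos[1], pos[2]] <- TRUE
    }
    skeletonize(m)
  })
}

# naive grayscale opening with the same structuring element, written as
# plain min/max loops (independent of EBImage's C implementation);
# border handling differs from EBImage so compare interiors only
naive_opening <- function(img, brush) {
  stopifnot(nrow(brush) == ncol(brush))
  half <- (nrow(brush) - 1L) %/% 2L
  offs <- which(brush > 0, arr.ind = TRUE) - half - 1L
  nr <- nrow(img); nc <- ncol(img)
  at <- function(src, r, c)
    vapply(seq_len(nrow(offs)), function(k)
      src[pmin(pmax(r + offs[k, 1], 1L), nr),
          pmin(pmax(c + offs[k, 2], 1L), nc)], numeric(1))
  mmin <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) mmin[r, c] <- min(at(img, r, c))
  mmax <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) mmax[r, c] <- max(at(mmin, r, c))
  mmax
}
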