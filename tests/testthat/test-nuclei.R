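# nuclei segmentation and illumination correction

test_that("illumination correction removes background, keeps small objects", {
  # uniform image -> all zero
  flat <- matrix(7, 40, 40)
  expect_true(all(correct_illumination(flat, 10) == 0))
  expect_error(correct_illumination(flat, 0), "background_radius_px")

  # disk (radius 8, amplitude 100) on a linear ramp, opening radius 25
  nr <- 120; nc <- 120
  ramp <- outer(seq(0, 50, length.out = nr), rep(1, nc))
  img <- ramp
  ctr <- c(60, 60)
  for (r in 1:nr) for (c in 1:nc)
    if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 64) img[r, c] <- img[r, c] + 100
  out <- correct_illumination(img, 25)
  off_disk <- sqrt(outer((1:nr) - ctr[1], rep(1, nc))^2 +
                     outer(rep(1, nr), (1:nc) - ctr[2])^2) > 12
  interior <- matrix(FALSE, nr, nc); interior[30:90, 30:90] <- TRUE
  expect_lt(max(out[off_disk & interior]), 0.02 * 50)  # ramp suppressed
  expect_gte(out[ctr[1], ctr[2]], 95)                  # peak retained
})

test_that("correct_illumination matches a naive opening oracle", {
  withr::with_seed(11, {
    img <- matrix(runif(28 * 28, 0, 10), 28, 28)
    img[10:14, 10:14] <- img[10:14, 10:14] + 20
  })
  brush <- EBImage::makeBrush(9, "disc")
  expected <- pmax(img - naive_opening(img, brush), 0)
  got <- correct_illumination(img, 4)
  # border handling differs and opening propagates it 2 x radius inward;
  # compare the deep interior
  inner <- 10:19
  expect_equal(got[inner, inner], expected[inner, inner], tolerance = 1e-10)
})

test_that("disjoint blurred nuclei are counted exactly with tight centroids", {
  sp <- synthetic_spec(field_shape = c(320L, 320L), n_nuclei = 10,
                       n_neurites = 0, snr = 10, seed = 5)
  g <- generate_field(sp)
  nuc <- segment_nuclei(g$field$nuclei_channel, pixel_size_um = 0.65)
  expect_equal(nuc$count, 10L)
  truth <- g$truth$nuclei
  derr <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((nuc$centroids[, 1] - truth$row_px[i])^2 +
               (nuc$centroids[, 2] - truth$col_px[i])^2)), numeric(1))
  expect_lt(max(derr), 1)
  # labels contiguous and areas consistent with the mask
  expect_setequal(unique(as.vector(nuc$label_mask[nuc$label_mask > 0])),
                  seq_len(nuc$count))
  expect_equal(sum(nuc$areas_um2) / 0.65^2, sum(nuc$label_mask > 0))
})

test_that("pure-noise and degenerate inputs are handled", {
  withr::with_seed(2, {
    noise <- matrix(rpois(160 * 160, 100) + rnorm(160 * 160, 0, 2), 160, 160)
  })
  noise <- pmax(noise, 0)
  expect_equal(segment_nuclei(noise)$count, 0L)
  expect_equal(segment_nuclei(matrix(0, 64, 64))$count, 0L)
  bad <- matrix(1, 32, 32); bad[3, 3] <- NaN
  expect_error(segment_nuclei(bad), "NaN")
})

test_that("touching nuclei are split by the watershed", {
  # two equal circles fused at center distance 1.2 x radius (a 40%
  # overlap of the radius sum)
  px <- 0.65
  r_um <- 5.5
  centers <- rbind(c(100, 90), c(100, 90 + 1.2 * r_um / px))
  sp <- synthetic_spec(field_shape = c(200L, 220L), n_neurites = 0, snr = 8,
                       allowed_overlap_fraction = 0.45,
                       nucleus_axis_ratio = c(1, 1), seed = 21)
  g <- generate_field(sp, nucleus_centers_px = centers,
                      nucleus_radii_um = c(r_um, r_um))
  split <- segment_nuclei(g$field$nuclei_channel, pixel_size_um = px)
  expect_equal(split$count, 2L)
  fused <- segment_nuclei(g$field$nuclei_channel,
                          nuclei_params(split_touching = FALSE),
                          pixel_size_um = px)
  expect_equal(fused$count, 1L)
})

test_that("count is invariant to rotation, mirroring and affine rescaling", {
  sp <- synthetic_spec(field_shape = c(256L, 256L), n_nuclei = 8,
                       n_neurites = 0, snr = 8, seed = 9)
  ch <- generate_field(sp)$field$nuclei_channel
  n0 <- segment_nuclei(ch)$count
  expect_equal(n0, 8L)
  rot90 <- t(ch)[ncol(ch):1, ]
  expect_equal(segment_nuclei(rot90)$count, n0)
  expect_equal(segment_nuclei(ch[nrow(ch):1, ])$count, n0)
  expect_equal(segment_nuclei(3.7 * ch + 55)$count, n0)
})

test_that("raising the minimum area never increases the count", {
  sp <- synthetic_spec(field_shape = c(256L, 256L), n_nuclei = 12,
                       n_neurites = 0, nucleus_radius_um = c(3, 7),
                       snr = 8, seed = 4)
  ch <- generate_field(sp)$field$nuclei_channel
  counts <- vapply(c(10, 30, 60, 90, 120), function(a)
    segment_nuclei(ch, nuclei_params(min_area_um2 = a))$count, integer(1))
  expect_true(all(diff(counts) <= 0))
})
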