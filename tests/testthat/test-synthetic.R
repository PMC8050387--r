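# synthetic generator: determinism, exact ground truth, SNR calibration

test_that("generation is fully deterministic given the spec", {
  sp <- synthetic_spec(field_shape = c(192L, 192L), n_nuclei = 6,
                       n_neurites = 3, neurite_length_um = c(30, 60),
                       seed = 17)
  g1 <- generate_field(sp)
  g2 <- generate_field(sp)
  expect_identical(g1$field$nuclei_channel, g2$field$nuclei_channel)
  expect_identical(g1$field$cell_channel, g2$field$cell_channel)
  expect_identical(g1$truth$neurites, g2$truth$neurites)
})

test_that("no neurites means somata only and zero true length", {
  sp <- synthetic_spec(field_shape = c(192L, 192L), n_nuclei = 5,
                       n_neurites = 0, seed = 2)
  g <- generate_field(sp)
  expect_equal(g$truth$total_length_um, 0)
  expect_equal(nrow(g$truth$neurites), 0L)
  expect_false(any(g$truth$neurite_mask))
})

test_that("arc-chain lengths are analytic: two-arc example and polyline", {
  # radii 50 and 30 um sweeping 0.8 and 1.0 rad -> 50*0.8 + 30*1.0 = 70 um
  chain <- data.frame(kappa = c(1 / 50, 1 / 30),
                      length_um = c(50 * 0.8, 30 * 1.0))
  expect_equal(sum(chain$length_um), 70)
  s <- seq(0, 70, length.out = 14001)
  pts <- arc_chain_points(chain, start = c(10, 20), heading = 0.6, s = s)
  poly <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
  expect_equal(poly, 70, tolerance = 1e-3)  # dense polyline, within 0.1%
  # ground-truth lengths in generated fields agree with dense integration
  sp <- synthetic_spec(field_shape = c(256L, 256L), n_nuclei = 3,
                       n_neurites = 2, neurite_length_um = c(40, 70),
                       seed = 23)
  g <- generate_field(sp)
  expect_equal(g$truth$total_length_um, sum(g$truth$neurites$length_um))
  expect_true(all(g$truth$neurites$length_outside_um <=
                    g$truth$neurites$length_um))
})

test_that("realized SNR matches the requested SNR within 10%", {
  for (snr in c(5, 10)) {
    sp <- synthetic_spec(field_shape = c(256L, 256L), n_nuclei = 12,
                         n_neurites = 6, neurite_length_um = c(30, 70),
                         snr = snr, seed = 3)
    g <- generate_field(sp)
    cc <- g$truth$clean_cell_channel
    bgl <- sp$background_level
    peak <- max(cc)
    hi <- cc > bgl + 0.95 * (peak - bgl)
    est <- (peak - bgl) / sd((g$field$cell_channel - cc)[hi])
    expect_lt(abs(est / snr - 1), 0.1)
  }
})

test_that("invalid specs and infeasible placement raise errors", {
  expect_error(synthetic_spec(allowed_overlap_fraction = 0.6),
               "allowed_overlap_fraction")
  expect_error(synthetic_spec(snr = -1), "snr")
  # far too many non-overlapping nuclei for a small field
  sp <- synthetic_spec(field_shape = c(96L, 96L), n_nuclei = 200,
                       n_neurites = 0, seed = 1)
  expect_error(generate_field(sp), "generation error")
})

test_that("generate_experiment writes a readable, reproducible experiment", {
  sp <- synthetic_spec(field_shape = c(160L, 160L), n_nuclei = 4,
                       n_neurites = 2, neurite_length_um = c(25, 40))
  specs <- list(ctrl = list(spec = sp, n_fields = 2),
                treat = list(spec = sp, n_fields = 3))
  dir1 <- withr::local_tempdir()
  res <- generate_experiment(specs, file.path(dir1, "exp"), master_seed = 5)
  expect_equal(nrow(res$manifest), 5L)
  expect_equal(nrow(res$truth), 5L)
  man <- read_manifest(res$manifest_path)
  expect_equal(nrow(man), 5L)
  fld <- read_field(man$file[1], pixel_size_um = man$pixel_size_um[1])
  expect_equal(dim(fld$nuclei_channel), c(160L, 160L))
  # refusing to overwrite
  expect_error(generate_experiment(specs, file.path(dir1, "exp"),
                                   master_seed = 5), "not empty")
  # same master seed -> identical files
  res2 <- generate_experiment(specs, file.path(dir1, "exp2"), master_seed = 5)
  h1 <- tools::md5sum(sort(list.files(file.path(dir1, "exp"),
                                      recursive = TRUE, full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(file.path(dir1, "exp2"),
                                      recursive = TRUE, full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))
})

test_that("a 2x longer neurite condition doubles the mean true length", {
  short <- synthetic_spec(field_shape = c(160L, 160L), n_nuclei = 4,
                          n_neurites = 2, neurite_length_um = c(20, 30),
                          soma_radius_um = 5)
  long <- short; long$neurite_length_um <- c(40, 60)
  means <- sapply(list(short, long), function(sp) {
    lens <- vapply(1:60, function(i) {
      sp$seed <- 1000 + i
      generate_field(sp)$truth$total_length_um
    }, numeric(1))
    mean(lens)
  })
  expect_equal(means[2] / means[1], 2, tolerance = 0.1)
})
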