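# TIFF/manifest input, overlay and metrics output

test_that("two-page 16-bit TIFF round-trips bit-exactly", {
  f <- tiny_field()
  path <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(f, path)
  back <- read_field(path, pixel_size_um = f$pixel_size_um,
                     field_id = f$field_id, condition = f$condition)
  expect_identical(back$nuclei_channel, f$nuclei_channel + 0)
  expect_identical(back$cell_channel, f$cell_channel + 0)
  expect_equal(back$pixel_size_um, 0.5)
})

test_that("read_field rejects missing files, bad pages and mixed sizes", {
  expect_error(read_field("/nonexistent/field.tif"), "nonexistent")
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 16, 16), path)
  expect_error(read_field(path), "page")         # needs 2 pages
  # container with differently sized pages
  path2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.2, 16, 16), matrix(0.2, 8, 8)), path2)
  expect_error(read_field(path2), "dimension mismatch")
})

test_that("image_field enforces its invariants", {
  m <- matrix(1, 4, 4)
  expect_error(image_field(m, matrix(1, 4, 5)), "dimension mismatch")
  expect_error(image_field(m, m, pixel_size_um = 0), "pixel_size_um")
  expect_error(image_field(m - 2, m), ">= 0")
  bad <- m; bad[2, 2] <- NA
  expect_error(image_field(bad, m), "finite")
})

test_that("overlay renders neurites white over cyan nuclei", {
  f <- tiny_field(dims = c(20L, 20L))
  nmask <- matrix(0L, 20, 20); nmask[5:8, 5:8] <- 1L
  smask <- matrix(FALSE, 20, 20); smask[7, 3:12] <- TRUE  # crosses nucleus
  nuclei <- list(label_mask = nmask, count = 1L)
  skel <- list(skeleton_mask = smask)
  path <- withr::local_tempfile(fileext = ".png")
  write_overlay(f, nuclei, skel, path)
  rgb <- png::readPNG(path)
  # skeleton pixels pure white, including where they cross the nucleus
  for (ch in 1:3) expect_true(all(rgb[, , ch][smask] == 1))
  # nucleus-only pixels cyan
  nonly <- nmask > 0 & !smask
  expect_true(all(rgb[, , 1][nonly] == 0))
  expect_true(all(rgb[, , 2][nonly] == 1))
  expect_true(all(rgb[, , 3][nonly] == 1))
  # empty masks reproduce the grayscale cell channel
  path2 <- withr::local_tempfile(fileext = ".png")
  write_overlay(f, NULL, NULL, path2)
  rgb2 <- png::readPNG(path2)
  g <- f$cell_channel / max(f$cell_channel)
  expect_equal(max(abs(rgb2[, , 1] - g)), 0, tolerance = 1 / 255)
  expect_identical(rgb2[, , 1], rgb2[, , 2])
  # overlays are pure functions of their inputs
  path3 <- withr::local_tempfile(fileext = ".png")
  write_overlay(f, nuclei, skel, path3)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path3, "raw", file.size(path3)))
})

test_that("metrics CSV round-trips exactly, with fixed column order", {
  m1 <- structure(list(field_id = "a", condition = "ctrl", nuclei_count = 5L,
                       total_neurite_length_um = 100.123456789,
                       neurite_length_per_cell_um = 20.0246913578,
                       neurite_component_count = 3L, branch_point_count = 1L,
                       neurite_positive_cell_fraction = 0.4, excluded = FALSE,
                       min_neurite_length_um = 20, pixel_size_um = 0.65),
                  class = "field_metrics")
  m2 <- m1; m2$field_id <- "b"; m2$nuclei_count <- 0L
  m2$neurite_length_per_cell_um <- NA_real_
  m2$neurite_positive_cell_fraction <- NA_real_; m2$excluded <- TRUE
  class(m2) <- "field_metrics"
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(list(m1, m2), path)
  lines <- readLines(path)
  expect_length(lines, 3L)  # header + 2 rows
  expect_match(lines[1], "^\"field_id\",\"condition\",\"nuclei_count\"")
  back <- read_metrics(path)
  expect_identical(back$total_neurite_length_um[1], m1$total_neurite_length_um)
  expect_identical(back$neurite_length_per_cell_um[1],
                   m1$neurite_length_per_cell_um)
  expect_true(is.na(back$neurite_length_per_cell_um[2]))
  expect_identical(back$excluded, c(FALSE, TRUE))
  expect_error(write_metrics(list(), path), "empty")
  suppressWarnings(
    expect_error(write_metrics(list(m1), "/nonexistent/dir/x.csv"),
                 "I/O error"))
})

test_that("manifest validation catches duplicates and missing files", {
  dir <- withr::local_tempdir()
  f <- tiny_field()
  write_field_tiff(f, file.path(dir, "f1.tif"))
  man <- data.frame(file = "f1.tif", field_id = "f1", condition = "ctrl")
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$pixel_size_um, 0.65)  # default echoed
  man2 <- rbind(man, man)
  write.csv(man2, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "dup.csv")), "unique")
  man3 <- data.frame(file = "ghost.tif", field_id = "g", condition = "x")
  write.csv(man3, file.path(dir, "ghost.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "ghost.csv")), "missing file")
})
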