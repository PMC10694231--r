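# Dataset assembly, joining, splitting and image I/O.

ref_row <- function(mp, date, dm = 5, lai = 3, nc = 2) {
  r <- data.frame(microplot_id = mp, date = date, dm_total = dm, lai = lai,
                  n_conc = nc, n_upt = dm * nc * 10)
  r[paste0("dm_", organs())] <- as.list(rep(0.25, 4))
  r[paste0("nupt_", organs())] <- as.list(rep(0.25, 4))
  r[paste0("nconc_", organs())] <- as.list(rep(nc, 4))
  r
}

write_fixture <- function(dir, md, rf) {
  dir.create(dir, showWarnings = FALSE)
  mp <- file.path(dir, "metadata.csv"); rp <- file.path(dir, "reference.csv")
  write.csv(md, mp, row.names = FALSE)
  write.csv(rf, rp, row.names = FALSE)
  c(metadata = mp, reference = rp)
}

md3 <- data.frame(
  microplot_id = "A_R1", treatment_id = "A",
  date = c("2022-03-01", "2022-04-01", "2022-05-01"),
  thermal_time = c(100, 400, 800), camera = "ms", image_path = "")

test_that("load_dataset joins on exact (microplot, date) only", {
  d <- tempfile("core")
  p <- write_fixture(d, md3, ref_row("A_R1", "2022-04-01"))
  ds <- load_dataset(p["metadata"], p["reference"])
  expect_equal(nrow(ds$acquisitions), 3)
  expect_equal(nrow(ds$references), 1)
  expect_equal(ds$references$thermal_time, 400)

  # a reference dated between acquisitions is reported, not snapped
  p2 <- write_fixture(tempfile("core"), md3,
                      rbind(ref_row("A_R1", "2022-04-01"),
                            ref_row("A_R1", "2022-04-15")))
  expect_warning(ds2 <- load_dataset(p2["metadata"], p2["reference"]),
                 "no matching acquisition")
  expect_equal(nrow(ds2$references), 1)
})

test_that("load_dataset validates schema and thermal-time monotonicity", {
  p <- write_fixture(tempfile("core"), md3[, -4], ref_row("A_R1",
                                                          "2022-04-01"))
  expect_error(load_dataset(p["metadata"], p["reference"]), "thermal_time")
  bad <- md3; bad$thermal_time <- c(100, 90, 800)
  p <- write_fixture(tempfile("core"), bad, ref_row("A_R1", "2022-04-01"))
  expect_error(load_dataset(p["metadata"], p["reference"]),
               "strictly increasing")
})

test_that("synthetic trial written then reloaded is identical on metadata", {
  ds <- generate_trial(3, 2, 8, 4, render_config("feature"), seed = 7)
  dir <- tempfile("rt")
  paths <- save_dataset(ds, dir)
  ds2 <- load_dataset(paths["metadata"], paths["reference"])
  expect_equal(nrow(ds2$acquisitions), nrow(ds$acquisitions))
  for (col in c("microplot_id", "treatment_id", "thermal_time", "camera"))
    expect_equal(ds2$acquisitions[[col]], ds$acquisitions[[col]])
  expect_equal(as.character(ds2$acquisitions$date),
               as.character(ds$acquisitions$date))
  expect_equal(ds2$references[trait_columns()], ds$references[trait_columns()],
               tolerance = 1e-12)
})

test_that("split_by_treatment holds out whole treatments", {
  ds <- generate_trial(5, 3, 6, 3, render_config("feature"), seed = 1)
  ds1 <- split_by_treatment(ds, "T03")
  expect_setequal(split_microplots(ds1, "val"),
                  paste0("T03_R", 1:3))
  expect_length(intersect(names(ds1$split)[ds1$split == "train"],
                          names(ds1$split)[ds1$split == "val"]), 0)

  ds0 <- split_by_treatment(ds, character(0))
  expect_true(all(ds0$split == "train"))
  expect_error(split_by_treatment(ds, "T99"), "unknown treatment")

  ds7 <- generate_trial(7, 2, 6, 3, render_config("feature"), seed = 2)
  ds7 <- split_by_treatment(ds7, c("T02", "T06"))
  expect_equal(attr(ds7, "val_fraction"), 2 / 7, tolerance = 0.01)
})

test_that("trait identity holds on every synthetic reference", {
  ds <- generate_trial(4, 2, 8, 5, render_config("feature"), seed = 3)
  r <- ds$references
  expect_true(all(abs(r$n_upt - r$dm_total * r$n_conc * 10) <=
                    0.01 * r$n_upt))
  expect_silent(validate_traits(r))
})

test_that("read_image enforces kinds, clips BRF and round-trips", {
  f6 <- tempfile(fileext = ".tif")
  write_tiff(array(0.5, c(8, 10, 6)), f6, "float32")
  ms <- read_image(f6, "ms")
  expect_equal(dim(ms), c(8, 10, 6))
  expect_true(all(ms == 0.5))

  fc <- tempfile(fileext = ".tif")
  write_tiff(array(1.2, c(4, 4, 6)), fc, "float32")
  expect_message(msc <- read_image(fc, "ms"), "clipped")
  expect_true(all(msc == 1))
  expect_equal(attr(msc, "clipped"), 4 * 4 * 6)

  f4 <- tempfile(fileext = ".tif")
  write_tiff(array(0.5, c(4, 4, 4)), f4, "float32")
  expect_error(read_image(f4, "ms"), "6 band")

  fr <- tempfile(fileext = ".tif")
  rgb <- array(sample(0:255, 5 * 7 * 3, TRUE), c(5, 7, 3))
  write_tiff(rgb, fr, "uint8")
  expect_equal(read_image(fr, "rgb")[, , ], rgb, ignore_attr = TRUE)

  fh <- tempfile(fileext = ".tif")
  h <- matrix(runif(30), 5, 6)
  write_tiff(h, fh, "float32")
  expect_equal(read_image(fh, "height"), h, tolerance = 1e-6)
})

test_that("disk-backed trials are readable through read_image", {
  root <- tempfile("imgs")
  ds <- generate_trial(2, 1, 6, 3,
                       render_config("image", image_size = 24), seed = 4,
                       image_backend = "disk", image_root = root)
  expect_true(all(file.exists(ds$acquisitions$image_path)))
  ms <- read_image(ds$acquisitions$image_path[1], "ms")
  expect_equal(dim(ms), c(24, 24, 6))
  expect_true(all(ms >= 0 & ms <= 1))
})
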