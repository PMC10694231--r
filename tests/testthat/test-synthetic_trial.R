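# Synthetic trial generator: trajectories, organ schedule, rendering and
# the feature-mode response.

test_that("trajectories honor the growth model and organ schedule", {
  p <- trajectory_params()
  sch <- organ_schedule()
  tr <- simulate_trajectories(p, sch, seq(0, 2000, 100))

  # pre-appearance zeros and the logistic start
  expect_equal(tr$dm_ear[tr$thermal_time < sch$t_ear_appear],
               rep(0, sum(tr$thermal_time < sch$t_ear_appear)))
  expect_equal(tr$dm_l1[tr$thermal_time < sch$t_l1_appear],
               rep(0, sum(tr$thermal_time < sch$t_l1_appear)))
  expect_lt(tr$dm_total[1], 0.2)

  # logistic asymptote
  far <- simulate_trajectories(p, sch, c(0, 1e5))
  expect_equal(far$dm_total[2], p$dm_max * p$treatment_factor,
               tolerance = 1e-6)

  # all trait invariants on the grid; dilution monotone where dm > 1
  expect_silent(validate_traits(tr))
  big <- tr$dm_total > 1
  expect_true(all(diff(tr$n_conc[big]) <= 1e-12))

  # LAI unimodal, senesced below 10% of peak at season end
  expect_lt(tr$lai[nrow(tr)], 0.1 * max(tr$lai))
  peak <- which.max(tr$lai)
  expect_true(all(diff(tr$lai[1:peak]) >= 0))
  expect_true(all(diff(tr$lai[peak:nrow(tr)]) <= 0))

  expect_error(simulate_trajectories(p, sch, numeric(0)), "non-empty")
})

test_that("generate_trial produces the designed counts deterministically", {
  ds <- generate_trial(5, 3, 15, 6, render_config("feature"), seed = 1)
  expect_equal(nrow(ds$acquisitions), 5 * 3 * 15)
  expect_equal(nrow(ds$references), 5 * 3 * 6)
  expect_equal(nrow(ds$features), 225)

  d1 <- tempfile(); d2 <- tempfile()
  save_dataset(ds, d1)
  save_dataset(generate_trial(5, 3, 15, 6, render_config("feature"),
                              seed = 1), d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "reference.csv"))),
                   unname(tools::md5sum(file.path(d2, "reference.csv"))))
  # a different seed changes the references
  d3 <- tempfile()
  save_dataset(generate_trial(5, 3, 15, 6, render_config("feature"),
                              seed = 2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1,
                                                        "reference.csv"))),
                         unname(tools::md5sum(file.path(d3,
                                                        "reference.csv")))))
})

test_that("treatment factors scale final dry matter as the trajectory says", {
  lo <- trajectory_params(treatment_factor = 0.4)
  hi <- trajectory_params(treatment_factor = 1.2)
  t_end <- 1950
  dm_lo <- simulate_trajectories(lo, organ_schedule(), t_end)$dm_total
  dm_hi <- simulate_trajectories(hi, organ_schedule(), t_end)$dm_total
  expect_equal(dm_lo / dm_hi, 1 / 3, tolerance = 1e-9)
})

test_that("rendered scenes map traits to appearance monotonically", {
  cfg <- render_config("image", image_size = 64)
  # bare soil: plant ratio near zero (guarded segmentation)
  t0 <- trait_vector(0, 0, 0, 0)
  sc0 <- render_canopy(t0, cfg, seed = 3)
  expect_lt(suppressMessages(plant_ratio(sc0$ms[, , 5])), 0.05)

  # plant cover strictly increasing in LAI at fixed seed
  ratios <- vapply(c(0, 1, 2, 3, 4, 5, 6), function(l) {
    sc <- render_canopy(make_traits(dm = 5, lai = l), cfg, seed = 7)
    mean(sc$ms[, , 5] > 0.35)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))

  # constant-height canopy: p95 equals the canopy height exactly when the
  # scene is noise-free and fully covered
  dense <- render_config("image", image_size = 64, noise_sd = 0,
                         leaf_density_scale = 200)
  tv <- make_traits(dm = 20, lai = 6)
  sch <- render_canopy(tv, dense, seed = 1)
  h <- 0.95 * (20 / 25)^(1 / 3)
  expect_equal(height_p95(sch$height), h, tolerance = 1e-9)

  # nitrogen brightens red-edge/NIR leaf reflectance
  lo_n <- render_canopy(make_traits(nc = 1), dense, seed = 2)
  hi_n <- render_canopy(make_traits(nc = 4), dense, seed = 2)
  expect_gt(mean(hi_n$ms[, , 5]), mean(lo_n$ms[, , 5]))

  expect_error(render_canopy(tv, render_config("image", image_size = 8)),
               "image_size")
})

test_that("feature response has the documented functional dependences", {
  # zero canopy at zero noise sits at the soil baselines
  zero <- trait_vector(0, 0, 0, 0)
  f0 <- feature_response(zero, noise_sd = 0)
  expect_equal(unname(f0["ndvi"]), 0.15)
  expect_equal(unname(f0["plant_ratio"]), 0)
  expect_equal(unname(f0["height_p95"]), 0)
  expect_equal(unname(f0[1:6]), c(0.10, 0.14, 0.18, 0.20, 0.22, 0.24))

  # only the height feature responds to dry matter (plain lists bypass the
  # constructor so n_upt can be held fixed while dm varies)
  a <- feature_response(list(dm_total = 5, lai = 3, n_conc = 2,
                             n_upt = 100), 0)
  b <- feature_response(list(dm_total = 15, lai = 3, n_conc = 2,
                             n_upt = 100), 0)
  diffs <- names(a)[abs(a - b) > 1e-12]
  expect_identical(diffs, "height_p95")

  # band means are invertible-in-expectation through the documented
  # saturating cover link lai / (lai + 2)
  lai <- seq(0, 6, by = 0.25)
  f1 <- vapply(lai, function(l)
    feature_response(make_traits(dm = 5, lai = l, nc = 2), 0)[["brf_490"]],
    numeric(1))
  expect_gt(cor(f1, lai / (lai + 2))^2, 0.99)
})
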