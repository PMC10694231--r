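# Synthetic winter-wheat trials: parametric trait trajectories over thermal
# time, organ partitioning schedules, sparse reference sampling against dense
# acquisition, and procedural canopy rendering (image mode) or an engineered
# feature response (feature mode). The generator is the package's stated
# world: every downstream stage is tested against it.

#' Trajectory parameters for one microplot
#'
#' Dry matter follows a logistic in thermal time with asymptote
#' `dm_max * treatment_factor`; LAI is unimodal (logistic rise times
#' exponential senescence after `lai_peak_time`); whole-plant %N follows the
#' critical-dilution form `min(n_max, a * DM^-b)` with
#' `a = ndil_a * treatment_factor`, so fertilization shifts both biomass and
#' nitrogen status, as field treatments do.
#'
#' @param dm_max Dry-matter asymptote, t/ha (before the treatment factor).
#' @param dm_rate Logistic rate, per degree-day.
#' @param dm_mid Logistic inflection, degree-days.
#' @param lai_peak Peak LAI (dimensionless).
#' @param lai_rise_time,lai_rise_scale Midpoint and scale of the LAI rise.
#' @param lai_peak_time Onset of senescence, degree-days.
#' @param lai_senescence_rate Senescence decay rate, per degree-day.
#' @param ndil_a,ndil_b Nitrogen dilution coefficients (% and exponent); the
#'   defaults are the conventional winter-wheat values.
#' @param n_max Cap on %N at very low biomass.
#' @param treatment_factor Fertility multiplier applied to `dm_max` and
#'   `ndil_a` (>= 0).
#' @return A classed parameter list.
#' @export
trajectory_params <- function(dm_max = 23, dm_rate = 0.005, dm_mid = 1100,
                              lai_peak = 6.5, lai_rise_time = 500,
                              lai_rise_scale = 140, lai_peak_time = 950,
                              lai_senescence_rate = 0.004,
                              ndil_a = 5.35, ndil_b = 0.442, n_max = 4.8,
                              treatment_factor = 1) {
  p <- list(dm_max = dm_max, dm_rate = dm_rate, dm_mid = dm_mid,
            lai_peak = lai_peak, lai_rise_time = lai_rise_time,
            lai_rise_scale = lai_rise_scale, lai_peak_time = lai_peak_time,
            lai_senescence_rate = lai_senescence_rate,
            ndil_a = ndil_a, ndil_b = ndil_b, n_max = n_max,
            treatment_factor = treatment_factor)
  if (any(unlist(p) <= 0) && treatment_factor > 0)
    stop("trajectory parameters must be positive")
  if (treatment_factor < 0) stop("treatment_factor must be >= 0")
  class(p) <- "trajectory_params"
  p
}

#' Organ appearance schedule and partitioning basis
#'
#' Stem and inferior leaves are present from emergence; the flag leaf (L1)
#' and ear appear at fixed thermal times. Each organ has a positive basis
#' function of thermal time; proportions are the bases zeroed before
#' appearance and renormalized to sum to one, so an organ's share is exactly
#' zero before it exists.
#'
#' @param t_l1_appear,t_ear_appear Appearance thermal times, degree-days.
#' @param share_basis Optional named list of functions of thermal time (one
#'   per organ, positive); a default set reproducing the usual seasonal
#'   pattern (ear share growing to ~60% at maturity) is built from the
#'   appearance times.
#' @param n_factor Relative organ %N multipliers (leaves richer than stems).
#' @return A classed schedule list.
#' @export
organ_schedule <- function(t_l1_appear = 600, t_ear_appear = 1000,
                           share_basis = NULL,
                           n_factor = c(stem = 0.6, linf = 1.3,
                                        l1 = 1.6, ear = 1.1)) {
  if (t_l1_appear < 0 || t_ear_appear < 0)
    stop("appearance times must be non-negative")
  if (is.null(share_basis)) {
    t_ear <- t_ear_appear
    share_basis <- list(
      stem = function(t) rep(0.5, length(t)),
      linf = function(t) 0.9 * exp(-t / 900) + 0.1,
      l1   = function(t) rep(0.15, length(t)),
      ear  = function(t) 1.4 * stats::plogis((t - (t_ear + 150)) / 120))
  }
  stopifnot(identical(sort(names(share_basis)), sort(organs())),
            identical(sort(names(n_factor)), sort(organs())))
  s <- list(t_l1_appear = t_l1_appear, t_ear_appear = t_ear_appear,
            share_basis = share_basis[organs()], n_factor = n_factor[organs()])
  class(s) <- "organ_schedule"
  s
}

#' Rendering configuration for synthetic acquisitions
#'
#' @param mode `"image"` (procedural 6-band + RGB + height rendering) or
#'   `"feature"` (direct engineered-feature response, no pixels).
#' @param image_size Square image side in pixels (image mode, >= 16).
#' @param noise_sd Per-channel reflectance noise standard deviation.
#' @param leaf_density_scale Pseudo-leaf ellipses drawn per unit LAI.
#' @param seed Optional default seed.
#' @return A classed configuration list.
#' @export
render_config <- function(mode = c("feature", "image"), image_size = 64,
                          noise_sd = 0.02, leaf_density_scale = 30,
                          seed = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, image_size = as.integer(image_size),
              noise_sd = noise_sd, leaf_density_scale = leaf_density_scale,
              seed = seed)
  class(cfg) <- "render_config"
  cfg
}

#' Simulate trait trajectories over thermal time
#'
#' Evaluates the parametric growth model at the given thermal times and
#' returns one trait row per time: logistic dry matter, unimodal LAI,
#' dilution-curve %N (declining with biomass), the exact uptake identity
#' `Nupt = DM x %N x 10`, and organ partitioning following the schedule
#' (zero before appearance, renormalized to sum to one). Organ %N is the
#' plant %N scaled by relative organ factors normalized so that organ
#' uptake shares are consistent with the dry-matter shares.
#'
#' @param params A [trajectory_params()] object.
#' @param schedule An [organ_schedule()] object.
#' @param times Sorted ascending thermal times, degree-days.
#' @return Data frame with `thermal_time` plus the [trait_columns()].
#' @export
simulate_trajectories <- function(params = trajectory_params(),
                                  schedule = organ_schedule(),
                                  times) {
  if (length(times) == 0) stop("times must be non-empty")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  tf <- params$treatment_factor
  dm <- tf * params$dm_max /
    (1 + exp(-params$dm_rate * (times - params$dm_mid)))
  rise <- stats::plogis((times - params$lai_rise_time) / params$lai_rise_scale)
  sen <- exp(-params$lai_senescence_rate *
               pmax(0, times - params$lai_peak_time))
  lai <- params$lai_peak * rise * sen
  a <- params$ndil_a * tf
  nc <- ifelse(dm > 1e-6, pmin(params$n_max, a * dm^(-params$ndil_b)),
               params$n_max * min(tf, 1))
  nupt <- dm * nc * 10

  appear <- c(stem = 0, linf = 0, l1 = schedule$t_l1_appear,
              ear = schedule$t_ear_appear)
  basis <- vapply(organs(),
                  function(o) schedule$share_basis[[o]](times),
                  numeric(length(times)))
  basis <- matrix(basis, nrow = length(times))
  colnames(basis) <- organs()
  for (o in organs()) basis[times < appear[[o]], o] <- 0
  dm_prop <- basis / rowSums(basis)

  nf <- schedule$n_factor
  fmat <- matrix(rep(unlist(nf), each = length(times)),
                 nrow = length(times), dimnames = list(NULL, organs()))
  fmat[dm_prop == 0] <- 0
  s <- rowSums(dm_prop * fmat)
  nconc_organ <- fmat / s * nc
  nupt_prop <- dm_prop * fmat / s

  out <- data.frame(thermal_time = times, dm_total = dm, lai = lai,
                    n_conc = nc, n_upt = nupt)
  out[paste0("dm_", organs())] <- dm_prop
  out[paste0("nupt_", organs())] <- nupt_prop
  out[paste0("nconc_", organs())] <- nconc_organ
  validate_traits(out)
  out
}

# Two-class reflectance tables (bands 490/550/680/720/800/900 nm).
.soil_brf <- c(0.10, 0.14, 0.18, 0.20, 0.22, 0.24)
.leaf_brf_base <- c(0.05, 0.12, 0.04, 0.30, 0.48, 0.46)
.ear_brf <- c(0.12, 0.20, 0.22, 0.30, 0.38, 0.36)

# Leaf reflectance modulated by nitrogen status: green, red-edge and NIR
# bands brighten with %N (greener, denser mesophyll).
leaf_brf <- function(n_conc) {
  b <- .leaf_brf_base
  b[c(2, 4, 5, 6)] <- b[c(2, 4, 5, 6)] * (0.8 + 0.1 * n_conc)
  pmin(b, 0.95)
}

#' Render a procedural canopy scene
#'
#' Deliberately low-fidelity procedural art whose only contract is a
#' monotone, noisy trait-to-appearance mapping: a soil background is overlaid
#' with `leaf_density_scale * lai` pseudo-leaf ellipses (leaf reflectance
#' brightening in green/red-edge/NIR with %N) and with ear ellipses whose
#' count scales with the ear dry-matter pool; the height map places the
#' canopy surface at `0.95 * (DM/25)^(1/3)` m on plant pixels. Ellipse
#' parameters are drawn sequentially so that, at a fixed seed, a larger LAI
#' reuses the smaller LAI's ellipses and adds more (plant cover is monotone
#' in LAI); the noise field has its own derived seed and is independent of
#' the ellipse count.
#'
#' @param traits One trait row (data frame row, list or named vector).
#' @param cfg A [render_config()] in image mode.
#' @param seed Integer seed.
#' @return List with `rgb` (`S x S x 3`, 0-255), `ms` (`S x S x 6` BRF) and
#'   `height` (`S x S` matrix, meters).
#' @export
render_canopy <- function(traits, cfg = render_config(mode = "image"),
                          seed = 1) {
  if (cfg$image_size < 16) stop("image_size must be >= 16")
  tr <- as.list(traits)
  s <- cfg$image_size
  n_leaf <- max(0, round(cfg$leaf_density_scale * tr$lai))
  n_ear <- max(0, round(cfg$leaf_density_scale *
                          tr$dm_total * tr$dm_ear / 8))
  xs <- matrix(seq_len(s), s, s)
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  draw <- function(n, a_rng, b_rng) {
    mask <- matrix(FALSE, s, s)
    for (i in seq_len(n)) {
      cx <- stats::runif(1, 1, s); cy <- stats::runif(1, 1, s)
      a <- stats::runif(1, a_rng[1], a_rng[2])
      b <- stats::runif(1, b_rng[1], b_rng[2])
      th <- stats::runif(1, 0, pi)
      u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      mask <- mask | (u / a)^2 + (v / b)^2 <= 1
    }
    mask
  }
  set.seed(seed)
  leaf_mask <- draw(n_leaf, c(s / 16, s / 9), c(s / 32, s / 18))
  ear_mask <- draw(n_ear, c(s / 24, s / 16), c(s / 30, s / 20))

  set.seed(seed + 104729L)  # noise independent of ellipse count
  noise <- array(stats::rnorm(s * s * 6, 0, cfg$noise_sd), c(s, s, 6))
  hnoise <- matrix(stats::rnorm(s * s, 0, cfg$noise_sd), s, s)

  leaf <- leaf_brf(tr$n_conc)
  ms <- array(0, c(s, s, 6))
  for (b in 1:6) {
    plane <- matrix(.soil_brf[b], s, s)
    plane[leaf_mask] <- leaf[b]
    plane[ear_mask] <- .ear_brf[b]
    ms[, , b] <- plane
  }
  ms <- pmin(pmax(ms + noise, 0), 1)

  rgb <- array(0, c(s, s, 3))
  rgb[, , 1] <- ms[, , 3]; rgb[, , 2] <- ms[, , 2]; rgb[, , 3] <- ms[, , 1]
  rgb <- round(rgb * 255)

  h <- 0.95 * (tr$dm_total / 25)^(1 / 3)
  height <- matrix(0, s, s)
  plant <- leaf_mask | ear_mask
  height[plant] <- h * (1 + hnoise[plant])
  list(rgb = rgb, ms = ms, height = height)
}

#' Engineered-feature response of a canopy (feature mode)
#'
#' A documented, invertible-in-expectation stand-in for extracting the 20
#' features from pixels: band means mix soil and leaf reflectance through a
#' saturating cover term `lai / (lai + 2)`; structural vegetation indices
#' saturate in LAI (`lai / (lai + k)`); chlorophyll/nitrogen indices respond
#' to %N (MCARI, mNDB, GR, linear in %N) or to canopy nitrogen mass (MTCI and
#' CI-red-edge, linear in Nupt, as red-edge indices do in the field); the
#' height feature is `0.95 (DM/25)^(1/3)` and the plant ratio is
#' `1 - exp(-0.6 lai)`. Gaussian noise of sd `noise_sd` is added to every
#' entry. Only the height feature depends on dry matter, which the functional
#' dependence tests rely on.
#'
#' @param traits One trait row (data frame row, list or named vector).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Named numeric vector of length 20 in [feature_names()] order.
#' @export
feature_response <- function(traits, noise_sd = 0.02, seed = 1) {
  tr <- as.list(traits)
  lai <- tr$lai; nc <- tr$n_conc; nupt <- tr$n_upt; dm <- tr$dm_total
  cov2 <- lai / (lai + 2)
  leaf <- leaf_brf(nc)
  brf <- .soil_brf + (leaf - .soil_brf) * cov2
  vi <- c(
    ndvi       = 0.15 + 0.75 * lai / (lai + 1.5),
    gndvi      = 0.10 + 0.60 * lai / (lai + 2.0),
    ndre       = 0.05 + 0.50 * lai / (lai + 2.5),
    savi       = 0.10 + 0.60 * lai / (lai + 1.8),
    osavi      = 0.10 + 0.65 * lai / (lai + 2.2),
    evi2       = 0.10 + 1.10 * lai / (lai + 3.0),
    mcari      = 0.10 + 0.25 * nc + 0.05 * cov2,
    mtci       = 0.40 + 0.012 * nupt,
    ci_green   = 0.20 + 0.90 * cov2 * (0.7 + 0.1 * nc),
    ci_rededge = 0.10 + 0.008 * nupt,
    mndb       = 0.10 + 0.15 * nc,
    gr         = 1.00 + 0.45 * nc)
  x <- c(stats::setNames(brf, paste0("brf_", .ms_bands)), vi,
         height_p95 = 0.95 * (dm / 25)^(1 / 3),
         plant_ratio = 1 - exp(-0.6 * lai))
  x <- x[feature_names()]
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(length(x), 0, noise_sd)
  }
  x
}

#' Generate a complete synthetic trial
#'
#' One microplot per treatment x replicate; treatment fertility factors are
#' spread evenly over \[0.4, 1.2\]; every microplot is imaged (or
#' feature-measured) at all `n_acq_dates` thermal times but destructively
#' sampled only at `n_ref_dates` of them, emulating sparse reference sampling
#' against dense acquisition. Reference measurements carry multiplicative
#' lognormal noise (default CV 5%) on DM, LAI and %N (uptake is recomputed so
#' the unit identity holds exactly) and jittered, renormalized organ
#' proportions. Per-microplot trajectory parameters receive small lognormal
#' replicate jitter. All output is a pure function of the arguments and
#' `seed`.
#'
#' @param n_treatments,n_replicates Trial design (microplots = product).
#' @param n_acq_dates,n_ref_dates Acquisition and reference date counts
#'   (`n_ref_dates <= n_acq_dates`).
#' @param render A [render_config()]; feature mode attaches a per-acquisition
#'   feature table, image mode renders scenes.
#' @param seed Integer seed.
#' @param params,schedule Baseline [trajectory_params()] / [organ_schedule()].
#' @param measurement_cv Reference measurement coefficient of variation.
#' @param image_backend `"memory"` (arrays stored in the dataset) or
#'   `"disk"` (TIFFs written under `image_root`).
#' @param image_root Directory for disk-backed images.
#' @return A `trial_dataset`; `$organ_appearance` carries the schedule's
#'   appearance times, `$features` the feature table (feature mode),
#'   `$images` the array store (memory image mode).
#' @export
generate_trial <- function(n_treatments = 5, n_replicates = 3,
                           n_acq_dates = 15, n_ref_dates = 6,
                           render = render_config(), seed = 1,
                           params = trajectory_params(),
                           schedule = organ_schedule(),
                           measurement_cv = 0.05,
                           image_backend = c("memory", "disk"),
                           image_root = tempfile("trial_")) {
  image_backend <- match.arg(image_backend)
  if (n_ref_dates > n_acq_dates) stop("n_ref_dates must be <= n_acq_dates")
  set.seed(seed)
  factors <- if (n_treatments == 1) 0.8 else
    seq(0.4, 1.2, length.out = n_treatments)
  acq_tt <- round(seq(150, 1950, length.out = n_acq_dates))
  ref_idx <- unique(round(seq(1, n_acq_dates, length.out = n_ref_dates)))
  dates <- as.Date("2022-03-01") + round((acq_tt - min(acq_tt)) / 10)
  sdlog <- sqrt(log(1 + measurement_cv^2))

  acq <- list(); refs <- list(); feats <- list(); imgs <- list()
  if (render$mode == "image" && image_backend == "disk")
    dir.create(image_root, showWarnings = FALSE, recursive = TRUE)

  k <- 0L
  for (ti in seq_len(n_treatments)) {
    trt <- sprintf("T%02d", ti)
    for (ri in seq_len(n_replicates)) {
      k <- k + 1L
      mp <- sprintf("%s_R%d", trt, ri)
      p <- params
      p$treatment_factor <- factors[ti]
      p$dm_max <- p$dm_max * stats::rlnorm(1, 0, 0.04)
      p$lai_peak <- p$lai_peak * stats::rlnorm(1, 0, 0.05)
      p$dm_mid <- p$dm_mid + stats::rnorm(1, 0, 30)
      traj <- simulate_trajectories(p, schedule, acq_tt)

      for (di in seq_len(n_acq_dates)) {
        aid <- sprintf("%s_%s_ms_1", mp, dates[di])
        path <- NA_character_
        row_seed <- (seed * 7919L + k * 131L + di) %% 2147483647L
        if (render$mode == "image") {
          scene <- render_canopy(traj[di, ], render, seed = row_seed)
          if (image_backend == "memory") {
            imgs[[aid]] <- scene
          } else {
            path <- file.path(image_root, paste0(aid, ".tif"))
            write_tiff(scene$ms, path, "float32")
            write_tiff(scene$rgb, sub("\\.tif$", "_rgb.tif", path), "uint8")
            write_tiff(scene$height, sub("\\.tif$", "_h.tif", path),
                       "float32")
          }
        } else {
          feats[[aid]] <- feature_response(traj[di, ], render$noise_sd,
                                           seed = row_seed)
        }
        acq[[length(acq) + 1L]] <- data.frame(
          microplot_id = mp, treatment_id = trt, date = dates[di],
          thermal_time = acq_tt[di], camera = "ms",
          image_path = path, acq_id = aid)
      }

      for (di in ref_idx) {
        tv <- traj[di, ]
        dm <- tv$dm_total * stats::rlnorm(1, 0, sdlog)
        lai <- tv$lai * stats::rlnorm(1, 0, sdlog)
        nc <- tv$n_conc * stats::rlnorm(1, 0, sdlog)
        dmp <- unlist(tv[paste0("dm_", organs())]) *
          stats::rlnorm(4, 0, sdlog / 2)
        dmp <- dmp / sum(dmp)
        nco <- unlist(tv[paste0("nconc_", organs())]) *
          stats::rlnorm(4, 0, sdlog)
        nup <- dmp * nco
        nup <- if (sum(nup) > 0) nup / sum(nup) else dmp
        rr <- data.frame(microplot_id = mp, date = dates[di],
                         thermal_time = acq_tt[di],
                         dm_total = dm, lai = lai, n_conc = nc,
                         n_upt = dm * nc * 10)
        rr[paste0("dm_", organs())] <- as.list(dmp)
        rr[paste0("nupt_", organs())] <- as.list(nup)
        rr[paste0("nconc_", organs())] <- as.list(nco)
        refs[[length(refs) + 1L]] <- rr
      }
    }
  }

  acq <- do.call(rbind, acq)
  refs <- do.call(rbind, refs)
  validate_traits(refs)
  features <- if (length(feats)) {
    fm <- do.call(rbind, feats)
    data.frame(acq_id = rownames(fm), fm, row.names = NULL,
               check.names = FALSE)
  } else NULL
  ds <- new_trial_dataset(
    acq, refs,
    images = if (length(imgs)) imgs else NULL,
    features = features,
    organ_appearance = c(stem = 0, linf = 0,
                         l1 = schedule$t_l1_appear,
                         ear = schedule$t_ear_appear))
  ds
}
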