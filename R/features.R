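# Engineered canopy features: Otsu segmentation, plant ratio from the 800 nm
# band, per-band reflectance means over plant pixels, twelve vegetation
# indices, 95th-percentile height, and the scan-based LAI calibration.

.ms_bands <- c(490L, 550L, 680L, 720L, 800L, 900L)

#' Otsu threshold of a single-channel image
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning the
#' data range; ties are broken towards the lowest threshold. The returned
#' value is the upper edge of the winning bin, so "foreground" is
#' `pixels > threshold`.
#'
#' @param gray Numeric matrix or vector with at least two distinct values.
#' @param n_bins Histogram resolution (default 256).
#' @return Threshold value on the data scale.
#' @export
otsu_threshold <- function(gray, n_bins = 256) {
  x <- as.numeric(gray)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) < 2 || diff(rng) == 0)
    stop("otsu_threshold requires at least two distinct values")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE), 1), n_bins)
  cnt <- tabulate(bin, n_bins)
  p <- cnt / sum(cnt)
  mids <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  valid <- w0 > 0 & w0 < 1
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb2)  # which.max takes the first (lowest) maximizer
  brk[k + 1]
}

# Guarded NIR segmentation: Otsu when the two classes are genuinely
# separated, else a fixed reflectance threshold (soil stays well below,
# vegetation well above 0.35 in the 800 nm band). Without the guard, Otsu on
# a single-class frame splits its noise in half.
segment_nir <- function(nir, min_contrast = 0.10, fallback_threshold = 0.35) {
  thr <- otsu_threshold(nir)
  lo <- nir <= thr
  contrast <- mean(nir[!lo]) - mean(nir[lo])
  if (!is.finite(contrast) || contrast < min_contrast) {
    message("low NIR class contrast (", round(contrast, 3),
            "); using fixed threshold ", fallback_threshold)
    thr <- fallback_threshold
  }
  nir > thr
}

#' Plant ratio from the 800 nm band
#'
#' Fraction of pixels classified as vegetation by thresholding the near
#' infrared band: the Otsu threshold when the resulting class means are at
#' least `min_contrast` apart, otherwise (single-class frame, e.g. bare soil
#' or closed canopy) a fixed BRF threshold of `fallback_threshold`.
#'
#' @param nir 800 nm BRF band, values in \[0,1\].
#' @param min_contrast Minimum between-class mean separation for Otsu to be
#'   trusted.
#' @param fallback_threshold Fixed BRF cutoff used below that contrast.
#' @return Fraction in \[0,1\].
#' @export
plant_ratio <- function(nir, min_contrast = 0.10, fallback_threshold = 0.35) {
  mean(segment_nir(nir, min_contrast, fallback_threshold))
}

#' 95th percentile of a height map
#'
#' Linear-interpolation convention (R quantile type 7); NaN/NA pixels are
#' ignored.
#'
#' @param height_map Numeric matrix of heights in meters.
#' @return Height in meters.
#' @export
height_p95 <- function(height_map) {
  x <- as.numeric(height_map)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("height map has no valid pixels")
  unname(stats::quantile(x, 0.95, type = 7))
}

.safe_div_count <- new.env(parent = emptyenv())

safe_div <- function(num, den, eps = 1e-9) {
  if (abs(den) < eps) {
    n <- get0("n", envir = .safe_div_count, ifnotfound = 0)
    assign("n", n + 1, envir = .safe_div_count)
    message("vegetation-index denominator ~0; index set to 0 (count ",
            n + 1, ")")
    return(0)
  }
  num / den
}

#' Default vegetation-index registry
#'
#' Twelve standard six-band indices computed from the scene-level plant-pixel
#' mean BRFs `b490 ... b900`. The set (NDVI, GNDVI, NDRE, SAVI, OSAVI, EVI2,
#' MCARI, MTCI, CI-green, CI-red-edge, mND-blue, GR) is user-overridable:
#' pass any named list of functions of the band vector to
#' [compute_features()] to change it.
#'
#' @return Named list of 12 functions taking a named band vector.
#' @export
vi_registry <- function() {
  list(
    ndvi = function(b) safe_div(b["b800"] - b["b680"], b["b800"] + b["b680"]),
    gndvi = function(b) safe_div(b["b800"] - b["b550"], b["b800"] + b["b550"]),
    ndre = function(b) safe_div(b["b800"] - b["b720"], b["b800"] + b["b720"]),
    savi = function(b) 1.5 * safe_div(b["b800"] - b["b680"],
                                      b["b800"] + b["b680"] + 0.5),
    osavi = function(b) 1.16 * safe_div(b["b800"] - b["b680"],
                                        b["b800"] + b["b680"] + 0.16),
    evi2 = function(b) 2.5 * safe_div(b["b800"] - b["b680"],
                                      b["b800"] + 2.4 * b["b680"] + 1),
    mcari = function(b) ((b["b720"] - b["b680"]) -
                           0.2 * (b["b720"] - b["b550"])) *
      safe_div(b["b720"], b["b680"]),
    mtci = function(b) safe_div(b["b800"] - b["b720"], b["b720"] - b["b680"]),
    ci_green = function(b) safe_div(b["b800"], b["b550"]) - 1,
    ci_rededge = function(b) safe_div(b["b800"], b["b720"]) - 1,
    mndb = function(b) safe_div(b["b800"] - b["b720"],
                                b["b800"] + b["b720"] - 2 * b["b490"]),
    gr = function(b) safe_div(b["b550"], b["b680"]))
}

#' Canonical feature names
#'
#' Fixed order of the 20 engineered features: six band means, twelve
#' vegetation indices (registry order), the 95th-percentile height and the
#' plant ratio. Selection indices and feature CSV columns rely on this order
#' being stable.
#'
#' @param registry Vegetation-index registry (for its names).
#' @return Character vector of length 20.
#' @export
feature_names <- function(registry = vi_registry()) {
  c(paste0("brf_", .ms_bands), names(registry), "height_p95", "plant_ratio")
}

#' Compute the 20-feature vector of one acquisition
#'
#' Plant pixels are segmented on the 800 nm band (guarded Otsu, see
#' [plant_ratio()]); band means are taken over plant pixels (over all pixels,
#' with a warning, if none are found) and the vegetation indices are
#' evaluated on those scene-level means rather than per pixel.
#'
#' @param ms `H x W x 6` BRF array (bands 490/550/680/720/800/900 nm).
#' @param height_map `H x W` height matrix in meters (optional; `NULL` sets
#'   the height feature to 0).
#' @param registry Named list of vegetation-index functions.
#' @return Named numeric vector of length `6 + length(registry) + 2`.
#' @export
compute_features <- function(ms, height_map = NULL,
                             registry = vi_registry()) {
  stopifnot(length(dim(ms)) == 3, dim(ms)[3] == 6)
  nir <- ms[, , 5]
  constant <- diff(range(nir)) == 0
  mask <- if (constant) matrix(TRUE, nrow(nir), ncol(nir)) else
    segment_nir(nir)
  ratio <- if (constant) 0 else mean(mask)
  if (!any(mask)) {
    warning("no plant pixels; band means computed over all pixels")
    mask <- matrix(TRUE, nrow(nir), ncol(nir))
  }
  brf <- vapply(1:6, function(b) mean(ms[, , b][mask]), numeric(1))
  names(brf) <- paste0("b", .ms_bands)
  vi <- vapply(registry, function(f) as.numeric(f(brf)), numeric(1))
  hp <- if (is.null(height_map)) 0 else height_p95(height_map)
  out <- c(stats::setNames(brf, paste0("brf_", .ms_bands)), vi,
           height_p95 = hp, plant_ratio = ratio)
  names(out) <- feature_names(registry)
  out
}

#' Calibrate the fresh-mass to LAI regression
#'
#' The scan-based LAI protocol is run on a handful of microplots only; their
#' LAI values are regressed on the sampled fresh masses and the fit predicts
#' LAI for the remaining plots. A Pearson correlation below 0.9 triggers a
#' warning (the protocol's acceptability bar).
#'
#' @param scan_lai LAI values from the scanned-leaf protocol.
#' @param fresh_masses Corresponding fresh masses, kg.
#' @return List with `slope`, `intercept`, `r` and the fitted `lm` object,
#'   class `"lai_calibration"`.
#' @export
calibrate_lai <- function(scan_lai, fresh_masses) {
  if (length(scan_lai) != length(fresh_masses))
    stop("scan_lai and fresh_masses must have equal length")
  if (length(scan_lai) < 3)
    stop("at least 3 calibration points required")
  fit <- stats::lm(scan_lai ~ fresh_masses)
  r <- stats::cor(scan_lai, fresh_masses)
  if (is.finite(r) && abs(r) < 0.9)
    warning(sprintf("LAI calibration correlation %.3f below 0.9", r))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, fit = fit),
            class = "lai_calibration")
}

#' Predict LAI from fresh mass with a calibration
#' @param cal A [calibrate_lai()] object.
#' @param fresh_masses Fresh masses, kg.
#' @return Predicted LAI values.
#' @export
predict_lai <- function(cal, fresh_masses) {
  cal$intercept + cal$slope * fresh_masses
}
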