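# Metrics, nitrogen nutrition index, organ reconstruction and reporting.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; unbounded below (worse-than-mean predictions give
#' negative values, which do occur for hard organ targets).
#'
#' @param y_true Observed values (length >= 2, non-constant).
#' @param y_pred Predicted values.
#' @return Dimensionless scalar, at most 1.
#' @export
r2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2) stop("r2 requires at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("r2 undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return RMSE in the trait's units.
#' @export
rmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) stop("rmse of empty vectors")
  sqrt(mean((y_true - y_pred)^2))
}

#' Critical nitrogen dilution curve
#'
#' `Nc(DM) = a * DM^-b` for `DM >= dm_min`, constant at `a * dm_min^-b`
#' below, the conventional winter-wheat critical curve; coefficients are
#' configurable.
#'
#' @param a Coefficient, percent (default 5.35).
#' @param b Dilution exponent (default 0.442).
#' @param dm_min Biomass floor, t/ha (default 1.55).
#' @return A `critical_n_curve`.
#' @export
critical_n_curve <- function(a = 5.35, b = 0.442, dm_min = 1.55) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  structure(list(a = a, b = b, dm_min = dm_min),
            class = "critical_n_curve")
}

#' Nitrogen nutrition index
#'
#' Measured %N divided by the critical %N at the measured biomass:
#' `NNI = %N / Nc(DM)`. NNI = 1 on the critical curve, < 1 under nitrogen
#' deficiency.
#'
#' @param dm_total Dry matter, t/ha (> 0).
#' @param n_conc Nitrogen concentration, percent.
#' @param curve A [critical_n_curve()].
#' @return Dimensionless NNI (vectorized).
#' @export
nni <- function(dm_total, n_conc, curve = critical_n_curve()) {
  if (any(dm_total <= 0)) stop("nni requires positive dry matter")
  nc <- curve$a * pmax(dm_total, curve$dm_min)^(-curve$b)
  n_conc / nc
}

#' Reconstruct absolute organ values from a total and proportions
#'
#' Elementwise `total x proportion`; proportions whose sum deviates from 1
#' by more than `tol` are renormalized with a warning, so the outputs always
#' sum to the total to machine precision.
#'
#' @param total Whole-plant trait value (scalar) or vector of length T.
#' @param proportions Length-4 vector or `T x 4` matrix over [organs()].
#' @param tol Tolerated deviation of the proportion sum from 1.
#' @return Vector or matrix of absolute organ values.
#' @export
reconstruct_organs <- function(total, proportions, tol = 1e-3) {
  p <- if (is.matrix(proportions)) proportions else
    matrix(proportions, nrow = 1)
  stopifnot(ncol(p) == 4)
  s <- rowSums(p)
  off <- abs(s - 1) > tol
  if (any(off)) {
    warning(sum(off), " proportion row(s) deviate from sum 1 beyond ", tol,
            "; renormalized")
  }
  p <- p / s
  out <- p * total
  colnames(out) <- organs()
  if (!is.matrix(proportions)) out[1, ] else out
}

#' Partitioning series for stacked plots
#'
#' Multiplies a total-trait curve by a proportion series, giving absolute
#' per-organ values whose row sums reproduce the total exactly.
#'
#' @param thermal_time Time axis.
#' @param total Total-trait values.
#' @param proportions `T x 4` proportion matrix over [organs()].
#' @return Data frame `thermal_time, stem, linf, l1, ear, total`.
#' @export
stackplot_series <- function(thermal_time, total, proportions) {
  abs_vals <- reconstruct_organs(total, proportions)
  out <- data.frame(thermal_time = thermal_time, abs_vals)
  out$total <- total
  out
}

#' Metric and plot-data report
#'
#' Builds the model x label-source x split metric grid and 1:1 scatter data
#' (with season-stage coloring by thermal-time tercile) from per-reference
#' prediction tables such as `run_pipeline()$predictions`. An empty
#' validation split is flagged and its rows omitted.
#'
#' @param predictions Data frame with columns `split`, `label_source`,
#'   `thermal_time` and `true_<trait>` / `pred_<trait>` pairs, optionally
#'   `model`.
#' @param partition Optional list with `thermal_time`, `total` and
#'   `proportions` forwarded to [stackplot_series()].
#' @return List with `metrics`, `scatter`, optional `partition`, and
#'   `flags`.
#' @export
report <- function(predictions, partition = NULL) {
  p <- predictions
  if (is.null(p$model)) p$model <- "model"
  traits <- sub("^true_", "", grep("^true_", names(p), value = TRUE))
  flags <- character()
  if (!"val" %in% p$split) flags <- c(flags, "validation split empty")
  rows <- list()
  for (m in unique(p$model)) for (src in unique(p$label_source))
    for (side in intersect(c("train", "val"), unique(p$split))) {
      q <- p[p$model == m & p$label_source == src & p$split == side, ]
      if (!nrow(q)) next
      for (tr in traits) {
        yt <- q[[paste0("true_", tr)]]; yp <- q[[paste0("pred_", tr)]]
        ok <- is.finite(yt) & is.finite(yp)
        rows[[length(rows) + 1]] <- data.frame(
          model = m, label_source = src, split = side, trait = tr,
          rmse = if (any(ok)) rmse(yt[ok], yp[ok]) else NA_real_,
          r2 = if (sum(ok) >= 2 && stats::sd(yt[ok]) > 0)
            r2(yt[ok], yp[ok]) else NA_real_,
          n = sum(ok))
      }
    }
  stage <- cut(rank(p$thermal_time, ties.method = "first"),
               breaks = 3, labels = c("early", "mid", "late"))
  scatter <- cbind(p, stage = stage)
  out <- list(metrics = do.call(rbind, rows), scatter = scatter,
              flags = flags)
  if (!is.null(partition))
    out$partition <- stackplot_series(partition$thermal_time,
                                      partition$total,
                                      partition$proportions)
  out
}
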