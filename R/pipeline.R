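# The pseudo-labeling pipeline with temporal growth-curve correction:
# Model 1 (trained on the sparse reference labels) predicts every
# acquisition; per-microplot growth curves over thermal time smooth those
# predictions; corrected pseudo-labels retrain Model 2 from fresh
# initialization on the full acquisition set.

#' Correction rules for pseudo-labels
#'
#' @param clip_nonnegative Clip negative curve values to 0.
#' @param organ_presence Named vector of appearance thermal times per organ;
#'   an organ's value is forced to exactly 0 before its appearance.
#' @param renormalize_proportions Renormalize proportion 4-vectors to sum to
#'   one over present organs.
#' @return A `correction_rules` list.
#' @export
correction_rules <- function(clip_nonnegative = TRUE,
                             organ_presence = c(stem = 0, linf = 0,
                                                l1 = 0, ear = 0),
                             renormalize_proportions = TRUE) {
  if (any(organ_presence < 0)) stop("appearance times must be non-negative")
  structure(list(clip_nonnegative = clip_nonnegative,
                 organ_presence = organ_presence,
                 renormalize_proportions = renormalize_proportions),
            class = "correction_rules")
}

#' Fit a growth curve to a per-microplot prediction series
#'
#' A cubic polynomial (plain least squares; a cubic is already stiff) or a
#' cubic smoothing spline whose generalized cross-validation penalty is
#' multiplied by a stiffness factor, the package's reading of fitting "with
#' a high smoothing condition".
#'
#' @param thermal_time,values Series points (>= 5 for cubic families).
#' @param family `"cubic_polynomial"` or `"cubic_bspline"`.
#' @param smoothing Stiffness multiplier on the GCV-chosen spline penalty.
#' @param microplot Identifier used in error messages.
#' @return A `growth_curve` (family, fit, support, residual summary).
#' @export
fit_curve <- function(thermal_time, values,
                      family = c("cubic_polynomial", "cubic_bspline"),
                      smoothing = 10, microplot = "?") {
  family <- match.arg(family)
  ok <- is.finite(values)
  t <- thermal_time[ok]; v <- values[ok]
  if (length(t) < 5)
    stop("too few points (", length(t), ") to fit a cubic curve for ",
         "microplot ", microplot)
  if (family == "cubic_polynomial") {
    fit <- stats::lm(v ~ stats::poly(t, 3, raw = TRUE))
    fitted_vals <- stats::fitted(fit)
  } else {
    base <- stats::smooth.spline(t, v, cv = FALSE)
    fit <- stats::smooth.spline(t, v, lambda = base$lambda * smoothing)
    fitted_vals <- stats::predict(fit, t)$y
  }
  structure(list(family = family, fit = fit,
                 support = range(t),
                 residual_sd = stats::sd(v - fitted_vals)),
            class = "growth_curve")
}

#' Evaluate a growth curve
#'
#' @param curve A `growth_curve`.
#' @param times Thermal times; values outside the fitted support raise a
#'   warning (the pipeline never extrapolates: pseudo-labels exist only at
#'   observed acquisition times).
#' @return Numeric curve values.
#' @export
predict_curve <- function(curve, times) {
  if (any(times < curve$support[1] - 1e-9 |
            times > curve$support[2] + 1e-9))
    warning("evaluating growth curve outside its support")
  if (curve$family == "cubic_polynomial") {
    co <- stats::coef(curve$fit)
    co[!is.finite(co)] <- 0
    drop(cbind(1, times, times^2, times^3) %*% co)
  } else {
    stats::predict(curve$fit, times)$y
  }
}

#' Apply correction rules to curve values
#'
#' @param curve A `growth_curve`.
#' @param times Evaluation thermal times.
#' @param rules A [correction_rules()] object.
#' @param organ Organ name when the series is an organ value (enables the
#'   presence correction); `NULL` for whole-plant traits.
#' @return Corrected values.
#' @export
correct <- function(curve, times, rules = correction_rules(),
                    organ = NULL) {
  v <- predict_curve(curve, times)
  if (rules$clip_nonnegative) v <- pmax(v, 0)
  if (!is.null(organ)) {
    if (!organ %in% names(rules$organ_presence))
      stop("no appearance time for organ ", organ)
    v[times < rules$organ_presence[[organ]]] <- 0
  }
  v
}

# Renormalize a T x 4 proportion matrix after per-organ correction; rows
# with no present organ fall back to uniform over organs present per rules.
renormalize_props <- function(mat, times, rules) {
  present <- vapply(organs(), function(o)
    times >= rules$organ_presence[[o]], logical(length(times)))
  present <- matrix(present, nrow = length(times))
  mat[!present] <- 0
  s <- rowSums(mat)
  zero <- s <= 0
  if (any(zero)) {
    np <- rowSums(present)
    mat[zero, ] <- present[zero, , drop = FALSE] / pmax(np[zero], 1)
    s[zero] <- rowSums(mat[zero, , drop = FALSE])
  }
  mat / s
}

.group_cols <- list(dm_prop = paste0("dm_", c("stem", "linf", "l1", "ear")),
                    nupt_prop = paste0("nupt_", c("stem", "linf", "l1",
                                                  "ear")),
                    nconc_organ = paste0("nconc_", c("stem", "linf", "l1",
                                                     "ear")))

trait_family <- function(trait) {
  if (trait == "lai") "cubic_bspline" else "cubic_polynomial"
}

# Reference labels joined to acquisitions (one row per matching acquisition).
reference_labels <- function(ds, cols) {
  key_acq <- paste(ds$acquisitions$microplot_id, ds$acquisitions$date)
  key_ref <- paste(ds$references$microplot_id, ds$references$date)
  hit <- match(key_acq, key_ref)
  keep <- !is.na(hit)
  out <- data.frame(acq_id = ds$acquisitions$acq_id[keep])
  out[cols] <- ds$references[hit[keep], cols]
  out
}

#' Predict every acquisition and assemble per-microplot series
#'
#' Runs the trainer's predict over all acquisitions of the requested
#' microplots and averages multiple images of one microplot and date into a
#' single point, yielding one series per microplot (columns per output).
#'
#' @param trainer A `wc_trainer`.
#' @param bundle Its fitted `model_bundle`.
#' @param ds The `trial_dataset`.
#' @param microplots Microplots to cover (default: training split).
#' @return Data frame `microplot_id, thermal_time, <outputs...>` sorted by
#'   microplot and time.
#' @export
predict_all <- function(trainer, bundle, ds,
                        microplots = split_microplots(ds, "train")) {
  acq <- ds$acquisitions[ds$acquisitions$microplot_id %in% microplots, ]
  pred <- trainer$predict(bundle, ds, acq$acq_id)
  k <- ncol(pred)
  agg <- stats::aggregate(pred,
                          by = list(microplot_id = acq$microplot_id,
                                    thermal_time = acq$thermal_time),
                          FUN = mean)
  names(agg)[-(1:2)] <- if (k == 1) "value" else organs()
  agg[order(agg$microplot_id, agg$thermal_time), ]
}

#' Run the two-stage pseudo-labeling pipeline
#'
#' Trains Model 1 on the matched reference labels of the training split,
#' predicts the full training acquisition series, fits a per-microplot,
#' per-output growth curve against thermal time (cubic smoothing spline for
#' LAI, cubic polynomial otherwise), applies the correction rules
#' (non-negativity, organ presence, proportion renormalization) to extract
#' pseudo-labels at every acquisition time, and retrains Model 2 from fresh
#' initialization on the pseudo-labels. Both models are evaluated on the
#' training and held-out validation references.
#'
#' @param trainer A `wc_trainer` ([cnn_trainer()] or [plsr_trainer()]).
#' @param ds A split `trial_dataset`.
#' @param trait One of `dm_total`, `lai`, `n_conc`, `n_upt` or a group
#'   `dm_prop`, `nupt_prop`, `nconc_organ`.
#' @param seed Integer seed (Model 2 uses `seed + 1`).
#' @param smoothing Spline stiffness multiplier.
#' @param rules [correction_rules()]; defaults to the dataset's recorded
#'   organ appearance times if present.
#' @param include_ytrue Include the reference measurements themselves as
#'   additional points (equal weight) when fitting each growth curve. On by
#'   default: the references are the most trusted points on the trajectory,
#'   and anchoring the curve at them keeps prediction bias at unlabeled
#'   dates from propagating into the pseudo-labels.
#' @param overwrite_with_ytrue Replace pseudo-labels by reference values at
#'   reference-matched acquisitions (off by default: Model 2 sees the m
#'   corrected pseudo-labels).
#' @return List with `model1`, `model2`, `pseudo_labels` (per-acquisition
#'   y_pred and y_pseu), `curves`, `metrics` (model x label source x split
#'   grid) and `predictions` (per-reference predictions for reporting).
#' @export
run_pipeline <- function(trainer, ds, trait = "dm_total", seed = 1,
                         smoothing = 10, rules = NULL,
                         include_ytrue = TRUE,
                         overwrite_with_ytrue = FALSE) {
  if (!length(ds$split)) stop("pipeline stage split: dataset has no split")
  if (is.null(rules)) {
    rules <- if (!is.null(ds$organ_appearance))
      correction_rules(organ_presence = ds$organ_appearance) else
      correction_rules()
  }
  is_group <- trait %in% names(.group_cols)
  cols <- if (is_group) .group_cols[[trait]] else trait

  labels_true <- reference_labels(ds, cols)
  train_acq <- ds$acquisitions[
    ds$acquisitions$microplot_id %in% split_microplots(ds, "train"), ]
  labels_train <- labels_true[labels_true$acq_id %in% train_acq$acq_id, ]
  if (!nrow(labels_train)) stop("pipeline stage model1: no labeled ",
                                "training acquisitions")

  model1 <- trainer$fit(ds, labels_train, "ytrue", seed)
  series <- predict_all(trainer, model1, ds)

  vcols <- if (is_group) organs() else "value"
  curves <- list(); pseu <- list()
  for (mp in unique(series$microplot_id)) {
    s <- series[series$microplot_id == mp, ]
    tt <- s$thermal_time
    refs_mp <- ds$references[ds$references$microplot_id == mp, ]
    vals <- matrix(NA_real_, length(tt), length(vcols))
    curves[[mp]] <- list()
    for (j in seq_along(vcols)) {
      fit_t <- tt; fit_v <- s[[vcols[j]]]
      if (include_ytrue && nrow(refs_mp)) {
        fit_t <- c(fit_t, refs_mp$thermal_time)
        fit_v <- c(fit_v, refs_mp[[cols[j]]])
      }
      cv <- fit_curve(fit_t, fit_v,
                      family = trait_family(trait),
                      smoothing = smoothing, microplot = mp)
      curves[[mp]][[vcols[j]]] <- cv
      vals[, j] <- correct(cv, tt, rules,
                           organ = if (is_group) organs()[j] else NULL)
    }
    if (is_group && rules$renormalize_proportions &&
          trait %in% c("dm_prop", "nupt_prop"))
      vals <- renormalize_props(vals, tt, rules)
    out <- data.frame(microplot_id = mp, thermal_time = tt)
    out[cols] <- as.data.frame(vals)
    pseu[[mp]] <- out
  }
  pseu <- do.call(rbind, pseu)

  key_acq <- paste(train_acq$microplot_id, train_acq$thermal_time)
  key_pseu <- paste(pseu$microplot_id, pseu$thermal_time)
  labels_pseu <- data.frame(acq_id = train_acq$acq_id)
  labels_pseu[cols] <- pseu[match(key_acq, key_pseu), cols]
  if (overwrite_with_ytrue) {
    hit <- match(labels_pseu$acq_id, labels_train$acq_id)
    labels_pseu[!is.na(hit), cols] <-
      labels_train[hit[!is.na(hit)], cols]
  }

  model2 <- trainer$fit(ds, labels_pseu, "ypseu", seed + 1)

  preds_series <- predict_all(trainer, model1, ds,
                              microplots = unique(
                                ds$acquisitions$microplot_id))
  pred_of <- function(bundle) {
    sp <- predict_all(trainer, bundle, ds,
                      microplots = unique(ds$acquisitions$microplot_id))
    key <- paste(sp$microplot_id, sp$thermal_time)
    keyr <- paste(ds$references$microplot_id, ds$references$thermal_time)
    hit <- match(keyr, key)
    out <- ds$references[c("microplot_id", "thermal_time")]
    trt <- ds$acquisitions$treatment_id[
      match(out$microplot_id, ds$acquisitions$microplot_id)]
    out$split <- unname(ds$split[trt])
    for (cc in cols) {
      out[[paste0("true_", cc)]] <- ds$references[[cc]]
      out[[paste0("pred_", cc)]] <- sp[[if (length(cols) == 1) "value" else
        organs()[match(cc, cols)]]][hit]
    }
    out
  }
  p1 <- pred_of(model1); p2 <- pred_of(model2)

  metric_rows <- list()
  for (src in c("ytrue", "ypseu")) {
    p <- if (src == "ytrue") p1 else p2
    for (side in intersect(c("train", "val"), unique(p$split))) {
      q <- p[p$split == side, ]
      for (cc in cols) {
        yt <- q[[paste0("true_", cc)]]; yp <- q[[paste0("pred_", cc)]]
        metric_rows[[length(metric_rows) + 1]] <- data.frame(
          model = trainer$kind, label_source = src, split = side,
          trait = cc, rmse = rmse(yt, yp),
          r2 = if (stats::sd(yt) > 0) r2(yt, yp) else NA_real_,
          n = length(yt))
      }
    }
  }

  pl <- data.frame(pseu[c("microplot_id", "thermal_time")])
  key_s <- paste(series$microplot_id, series$thermal_time)
  for (j in seq_along(cols)) {
    pl[[paste0("y_pred_", cols[j])]] <-
      series[[vcols[j]]][match(key_pseu, key_s)]
    pl[[paste0("y_pseu_", cols[j])]] <- pseu[[cols[j]]]
  }

  list(model1 = model1, model2 = model2, trait = trait,
       pseudo_labels = pl, curves = curves,
       metrics = do.call(rbind, metric_rows),
       predictions = rbind(cbind(p1, label_source = "ytrue"),
                           cbind(p2, label_source = "ypseu")))
}
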