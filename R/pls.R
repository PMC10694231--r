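# Partial least squares baseline (NIPALS, single response) and sequential
# backward feature selection under grouped k-fold cross-validation.

#' Fit a PLS regression model
#'
#' NIPALS PLS1: predictors are standardized (mean 0, sd 1 on the training
#' data), the response centered, and `n_components` latent scores extracted.
#' With `n_components` equal to the predictor rank the fit reproduces
#' ordinary least squares. Constant columns are dropped with a warning.
#'
#' @param X Numeric matrix or data frame of predictors (named columns).
#' @param y Numeric response.
#' @param n_components Number of latent components (default 2, the usual
#'   off-the-shelf setting), capped at the number of surviving columns.
#' @param label_source Provenance tag, `"ytrue"` or `"ypseu"`.
#' @return A `pls_model`: standardization constants, regression coefficients
#'   on the standardized scale, intercept and metadata.
#' @export
fit_pls <- function(X, y, n_components = 2,
                    label_source = c("ytrue", "ypseu")) {
  label_source <- match.arg(label_source)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0) stop("no non-constant predictors")
  rank_x <- qr(scale(X))$rank
  if (n_components > rank_x)
    stop("n_components (", n_components, ") exceeds predictor rank (",
         rank_x, ")")
  if (nrow(X) < n_components + 1)
    stop("need at least n_components + 1 rows")
  mus <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mus), 2, sds, "/")
  my <- mean(y)
  yr <- y - my

  p <- ncol(Xs)
  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  E <- Xs
  f <- yr
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(k - 1), drop = FALSE]
                      P <- P[, seq_len(k - 1), drop = FALSE]
                      q <- q[seq_len(k - 1)]; break }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pk <- drop(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, pk)
    f <- f - qk * t
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
  }
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(features = colnames(X), mus = mus, sds = sds,
                 coefficients = drop(B), intercept = my,
                 n_components = ncol(W), label_source = label_source),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' Columns are aligned by name, so predictor order is irrelevant; the
#' training standardization is applied.
#'
#' @param model A `pls_model`.
#' @param X Matrix or data frame containing the model's features.
#' @return Numeric predictions.
#' @export
predict_pls <- function(model, X) {
  X <- as.data.frame(X)
  miss <- setdiff(model$features, names(X))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  Xm <- as.matrix(X[model$features])
  Xs <- sweep(sweep(Xm, 2, model$mus), 2, model$sds, "/")
  drop(Xs %*% model$coefficients) + model$intercept
}

#' @export
predict.pls_model <- function(object, newdata, ...) predict_pls(object, newdata)

# Deterministic fold assignment over groups (e.g. microplots), so replicate
# rows of one group never straddle a fold boundary.
make_folds <- function(groups, folds, seed) {
  ug <- unique(groups)
  if (length(ug) < folds)
    stop("fewer groups/samples (", length(ug), ") than folds (", folds, ")")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep_len(seq_len(folds), length(ug))), ug)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  unname(fold_of[as.character(groups)])
}

# Pooled k-fold cross-validated R^2 of a PLS fit on a fixed fold assignment.
cv_r2_pls <- function(X, y, fold_id, n_components = 2) {
  X <- as.matrix(X)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    nc <- min(n_components, ncol(X), sum(tr) - 1)
    m <- suppressWarnings(tryCatch(fit_pls(X[tr, , drop = FALSE], y[tr], nc),
                                   error = function(e) NULL))
    pred[!tr] <- if (is.null(m)) mean(y[tr]) else
      predict_pls(m, X[!tr, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Sequential backward feature selection for PLS
#'
#' Starting from the full feature set, every subset of size k-1 is scored by
#' k-fold cross-validated R-squared (folds fixed once by `seed` for the whole
#' run and partitioned by `groups`, so replicate images of one microplot
#' never leak across folds); the feature whose removal maximizes the score is
#' eliminated. The descent continues to a single feature and the reported
#' best set is the global argmax over all visited sets, which dominates the
#' "stop at the first maximum" reading of the procedure.
#'
#' @param X Feature matrix or data frame (>= 2 columns).
#' @param y Response.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed fixing the fold assignment.
#' @param groups Optional grouping vector (e.g. microplot ids); defaults to
#'   one group per row.
#' @param n_components PLS components used throughout (capped per subset).
#' @return A `selection_trace`: data frame `steps` (step, removed feature,
#'   surviving size, cv_r2), list `surviving` of the surviving sets,
#'   `best_set` and `best_cv_r2`.
#' @export
backward_select <- function(X, y, folds = 5, seed = 1, groups = NULL,
                            n_components = 2) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("backward selection needs at least 2 features")
  if (is.null(groups)) groups <- seq_len(nrow(X))
  fold_id <- make_folds(groups, folds, seed)

  current <- names(X)
  visited_sets <- list(current)
  visited_r2 <- cv_r2_pls(X[current], y, fold_id, n_components)
  steps <- list()
  step <- 0L
  while (length(current) > 1) {
    scores <- vapply(current, function(feat) {
      keep <- setdiff(current, feat)
      cv_r2_pls(X[keep], y, fold_id, n_components)
    }, numeric(1))
    drop_feat <- names(scores)[which.max(scores)]
    current <- setdiff(current, drop_feat)
    step <- step + 1L
    steps[[step]] <- data.frame(step = step, removed = drop_feat,
                                n_features = length(current),
                                cv_r2 = unname(max(scores)))
    visited_sets[[step + 1L]] <- current
    visited_r2[step + 1L] <- max(scores)
  }
  best <- which.max(visited_r2)
  structure(list(steps = do.call(rbind, steps),
                 surviving = visited_sets,
                 best_set = visited_sets[[best]],
                 best_cv_r2 = visited_r2[best],
                 fold_id = fold_id,
                 n_components = n_components),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("backward selection:", nrow(x$steps), "eliminations; best CV R2 =",
      round(x$best_cv_r2, 4), "with", length(x$best_set), "features\n")
  cat("  best set:", paste(x$best_set, collapse = ", "), "\n")
  invisible(x)
}
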