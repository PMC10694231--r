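# Model-agnostic trainer contract used by the pseudo-labeling pipeline: a
# trainer exposes fit(ds, labels, label_source, seed) -> model_bundle and
# predict(bundle, ds, acq_ids) -> prediction matrix. Both the CNN and the
# PLS baseline ride the same pipeline through this interface.

#' CNN trainer for the pipeline
#'
#' @param backbone A [backbone_spec()] (default `tiny_test_cnn`).
#' @param head A [head_spec()].
#' @param fit_phases Phases for training on reference labels
#'   (default [default_phases()] for the backbone).
#' @param pseudo_phases Phases for retraining on pseudo-labels.
#' @param batch_size Mini-batch size.
#' @param augment_flips Random flip augmentation during training.
#' @return A `wc_trainer` list with `fit` and `predict` closures.
#' @export
cnn_trainer <- function(backbone = backbone_spec("tiny_test_cnn"),
                        head = head_spec("single_linear"),
                        fit_phases = NULL, pseudo_phases = NULL,
                        batch_size = 16, augment_flips = TRUE) {
  if (is.null(fit_phases)) fit_phases <- default_phases(backbone, "fit")
  if (is.null(pseudo_phases))
    pseudo_phases <- default_phases(backbone, "pseudo")

  load_tensor <- function(ds, acq_ids, stats) {
    arrs <- lapply(acq_ids, function(a)
      preprocess(acquisition_image(ds, a, "ms"), "ms", backbone, stats))
    s <- backbone$input_size
    x <- array(0, c(s, s, dim(arrs[[1]])[3], length(arrs)))
    for (i in seq_along(arrs)) x[, , , i] <- arrs[[i]]
    x
  }

  fit <- function(ds, labels, label_source = "ytrue", seed = 1) {
    train_acq <- ds$acquisitions[
      ds$acquisitions$microplot_id %in% split_microplots(ds, "train"), ]
    stats <- ms_train_stats(lapply(train_acq$acq_id, function(a)
      acquisition_image(ds, a, "ms")), source = "train")
    x <- load_tensor(ds, labels$acq_id, stats)
    y <- as.matrix(labels[setdiff(names(labels), "acq_id")])
    phases <- if (label_source == "ytrue") fit_phases else pseudo_phases
    model <- build_model(backbone, head, in_channels = dim(x)[3],
                         seed = seed)
    model <- train_model(model, x, y, phases, seed = seed,
                         batch_size = batch_size,
                         augment_flips = augment_flips)
    model_bundle(model, stats = stats, label_source = label_source,
                 phases = phases, seed = seed,
                 trait = setdiff(names(labels), "acq_id"))
  }

  predict_fn <- function(bundle, ds, acq_ids) {
    x <- load_tensor(ds, acq_ids, bundle$stats)
    out <- nn_forward(bundle$model, x)
    rownames(out) <- acq_ids
    out
  }

  structure(list(kind = "cnn", fit = fit, predict = predict_fn,
                 head = head, backbone = backbone),
            class = "wc_trainer")
}

#' PLS trainer for the pipeline
#'
#' Rides the pseudo-labeling pipeline on feature-mode datasets
#' (`ds$features`); single-output only, as the baseline is.
#'
#' @param n_components PLS components.
#' @param features Feature columns to use (default all 20).
#' @return A `wc_trainer`.
#' @export
plsr_trainer <- function(n_components = 2, features = NULL) {
  get_X <- function(ds, acq_ids) {
    if (is.null(ds$features)) stop("dataset has no feature table")
    rows <- match(acq_ids, ds$features$acq_id)
    if (anyNA(rows)) stop("acquisitions missing from feature table")
    X <- ds$features[rows, setdiff(names(ds$features), "acq_id"),
                     drop = FALSE]
    if (!is.null(features)) X <- X[features]
    X
  }
  fit <- function(ds, labels, label_source = "ytrue", seed = 1) {
    X <- get_X(ds, labels$acq_id)
    y <- labels[[setdiff(names(labels), "acq_id")[1]]]
    m <- fit_pls(X, y, n_components, label_source = label_source)
    model_bundle(m, stats = NULL, label_source = label_source, seed = seed,
                 trait = setdiff(names(labels), "acq_id"))
  }
  predict_fn <- function(bundle, ds, acq_ids) {
    out <- matrix(predict_pls(bundle$model, get_X(ds, acq_ids)), ncol = 1)
    rownames(out) <- acq_ids
    out
  }
  structure(list(kind = "plsr", fit = fit, predict = predict_fn),
            class = "wc_trainer")
}
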