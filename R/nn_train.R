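# Preprocessing, augmentation and the Adam training loop with freezing
# scopes for the compact regression CNN.

# Bilinear resize of an H x W x C array to size x size.
resize_bilinear <- function(img, size) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; ch <- dim(img)[3]
  if (h == size && w == size) return(img)
  ry <- if (size == 1) 1 else (h - 1) / (size - 1)
  rx <- if (size == 1) 1 else (w - 1) / (size - 1)
  y <- (seq_len(size) - 1) * ry + 1
  x <- (seq_len(size) - 1) * rx + 1
  y0 <- pmin(floor(y), h - 1); x0 <- pmin(floor(x), w - 1)
  fy <- y - y0; fx <- x - x0
  out <- array(0, c(size, size, ch))
  for (c in seq_len(ch)) {
    m <- img[, , c]
    a <- m[y0, x0, drop = FALSE]; b <- m[y0 + 1, x0, drop = FALSE]
    cc <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
    out[, , c] <- a * outer(1 - fy, 1 - fx) + b * outer(fy, 1 - fx) +
      cc * outer(1 - fy, fx) + d * outer(fy, fx)
  }
  out
}

#' Per-channel multispectral training statistics
#'
#' Computes channel means and standard deviations over the given BRF arrays.
#' The provenance tag records which split they came from; [preprocess()]
#' refuses statistics not computed on the training split, which closes the
#' validation-leakage path.
#'
#' @param ms_list List of `H x W x 6` BRF arrays.
#' @param source `"train"` or `"val"` (provenance of the arrays).
#' @return An `ms_stats` object with `mean`, `sd`, `source`.
#' @export
ms_train_stats <- function(ms_list, source = "train") {
  stacked <- vapply(ms_list, function(a) apply(a, 3, mean), numeric(6))
  sq <- vapply(ms_list, function(a) apply(a, 3, function(m) mean(m^2)),
               numeric(6))
  mu <- rowMeans(stacked)
  sd <- sqrt(pmax(rowMeans(sq) - mu^2, 1e-12))
  structure(list(mean = mu, sd = sd, source = source), class = "ms_stats")
}

#' Preprocess an image for the network
#'
#' Center-crops to a square (avoiding distortion), resizes bilinearly to the
#' backbone's input size, then applies the pixel scaling: the backbone's RGB
#' convention for `kind = "rgb"`, or channelwise standardization
#' `(x - mean) / sd` with training-split statistics for `kind = "ms"`.
#' Multispectral preprocessing without training statistics, or with
#' statistics whose provenance is not the training split, is an error.
#'
#' @param image `H x W x C` array (0-255 RGB or \[0,1\] BRF).
#' @param kind `"rgb"` or `"ms"`.
#' @param spec A [backbone_spec()].
#' @param train_stats An [ms_train_stats()] object (required for `ms`).
#' @return Array `input_size x input_size x C`.
#' @export
preprocess <- function(image, kind = c("rgb", "ms"),
                       spec = backbone_spec("tiny_test_cnn"),
                       train_stats = NULL) {
  kind <- match.arg(kind)
  h <- dim(image)[1]; w <- dim(image)[2]
  side <- min(h, w)
  r0 <- floor((h - side) / 2); c0 <- floor((w - side) / 2)
  img <- image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), , drop = FALSE]
  img <- resize_bilinear(img, spec$input_size)
  if (kind == "rgb") return(spec$scaling(img))
  if (is.null(train_stats))
    stop("multispectral preprocessing requires training-split statistics")
  if (!identical(train_stats$source, "train"))
    stop("train_stats were not computed on the training split (source: ",
         train_stats$source, "); refusing to leak validation statistics")
  for (c in seq_len(dim(img)[3]))
    img[, , c] <- (img[, , c] - train_stats$mean[c]) / train_stats$sd[c]
  img
}

#' Random flip augmentation
#'
#' Independent vertical and horizontal flips, each with probability 0.5,
#' deterministic for a given seed. Both flips together equal a 180-degree
#' rotation; applying the same seeded augmentation twice is the identity.
#'
#' @param tensor `H x W x C` array.
#' @param seed Integer seed.
#' @return Flipped array.
#' @export
augment <- function(tensor, seed) {
  set.seed(seed)
  flips <- stats::runif(2) < 0.5
  if (flips[1]) tensor <- tensor[rev(seq_len(dim(tensor)[1])), , ,
                                 drop = FALSE]
  if (flips[2]) tensor <- tensor[, rev(seq_len(dim(tensor)[2])), ,
                                 drop = FALSE]
  tensor
}

adam_init <- function(params, names) {
  st <- list()
  for (nm in names)
    st[[nm]] <- list(m = params[[nm]] * 0, v = params[[nm]] * 0, t = 0)
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(state)) {
    s <- state[[nm]]
    g <- grads[[nm]]
    s$t <- s$t + 1
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^s$t)
    vh <- s$v / (1 - beta2^s$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train a model through a sequence of phases
#'
#' Runs Adam over mini-batches with the masked/weighted squared-error loss,
#' honoring each phase's trainable scope (parameters outside the scope are
#' bit-identical before and after), random flip augmentation on training
#' batches, and per-epoch train (and optional validation) loss logging.
#' Fully deterministic for a given seed.
#'
#' @param model A `wc_model` from [build_model()].
#' @param x Preprocessed input array `H x W x C x N`.
#' @param y Target matrix `N x n_outputs` (vector accepted for single
#'   output).
#' @param phases List of [train_phase()] objects, executed in order.
#' @param seed Integer seed (shuffling and augmentation).
#' @param batch_size Mini-batch size (default 16; unspecified upstream).
#' @param x_val,y_val Optional held-out tensors for loss logging only.
#' @param augment_flips Apply random flips to training batches.
#' @return The trained `wc_model` with a `history` data frame attached
#'   (phase, epoch, train_loss, val_loss).
#' @export
train_model <- function(model, x, y, phases, seed = 1, batch_size = 16,
                        x_val = NULL, y_val = NULL, augment_flips = TRUE) {
  y <- as.matrix(y)
  n <- dim(x)[4]
  if (n == 0) stop("empty training set")
  stopifnot(nrow(y) == n)
  set.seed(seed)
  history <- list()
  for (phase in phases) {
    trainable <- scope_params(model, phase$trainable_scope)
    state <- adam_init(model$params, trainable)
    for (ep in seq_len(phase$epochs)) {
      idx <- sample(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1, n)]
        xb <- x[, , , bi, drop = FALSE]
        if (augment_flips) {
          for (k in seq_along(bi)) {
            fl <- stats::runif(2) < 0.5
            if (fl[1]) xb[, , , k] <- xb[rev(seq_len(dim(xb)[1])), , , k,
                                         drop = FALSE]
            if (fl[2]) xb[, , , k] <- xb[, rev(seq_len(dim(xb)[2])), , k,
                                         drop = FALSE]
          }
        }
        out <- nn_forward(model, xb, keep_cache = TRUE)
        cache <- attr(out, "cache")
        lg <- masked_weighted_mse(y[bi, , drop = FALSE],
                                  unclass(out)[, , drop = FALSE],
                                  model$head, return_grad = TRUE)
        losses <- c(losses, lg$loss)
        if (phase$learning_rate > 0) {
          grads <- nn_backward(model, cache, lg$grad)
          upd <- adam_step(model$params, grads, state, phase$learning_rate)
          model$params <- upd$params
          state <- upd$state
        }
      }
      val_loss <- NA_real_
      if (!is.null(x_val)) {
        pv <- nn_forward(model, x_val)
        val_loss <- masked_weighted_mse(as.matrix(y_val), pv, model$head)
      }
      history[[length(history) + 1]] <-
        data.frame(phase = phase$name, epoch = ep,
                   train_loss = mean(losses), val_loss = val_loss)
    }
  }
  model$history <- do.call(rbind, history)
  model
}

#' Bundle a trained model with its preprocessing contract
#'
#' @param model Trained `wc_model` (or `pls_model`).
#' @param stats Preprocessing statistics ([ms_train_stats()]) if any.
#' @param label_source `"ytrue"` or `"ypseu"`.
#' @param phases Phases used.
#' @param seed Training seed.
#' @param trait Trait name(s) predicted.
#' @return A `model_bundle`.
#' @export
model_bundle <- function(model, stats = NULL,
                         label_source = c("ytrue", "ypseu"),
                         phases = NULL, seed = NA_integer_,
                         trait = "dm_total") {
  label_source <- match.arg(label_source)
  structure(list(model = model, stats = stats, label_source = label_source,
                 phases = phases, seed = seed, trait = trait),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("model bundle:", class(x$model)[1], "| trait:",
      paste(x$trait, collapse = ","),
      "| labels:", x$label_source, "\n")
  invisible(x)
}
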