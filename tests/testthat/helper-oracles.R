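# Independent oracles used across the suite. These deliberately do not share
# code paths with the package implementation they check.

# PLS1 with k components via the Krylov-subspace formulation: the PLS
# regression vector lies in span{s, Cs, C^2 s, ...} with s = X'y, C = X'X
# (on standardized predictors / centered response), and the coefficient is
# the least-squares solution restricted to that subspace.
krylov_pls_predict <- function(X_train, y_train, X_new, k) {
  X_train <- as.matrix(X_train); X_new <- as.matrix(X_new)
  mu <- colMeans(X_train)
  sd_ <- apply(X_train, 2, sd)
  keep <- sd_ > 0
  Xs <- sweep(sweep(X_train[, keep, drop = FALSE], 2, mu[keep]), 2,
              sd_[keep], "/")
  my <- mean(y_train)
  yc <- y_train - my
  s <- drop(crossprod(Xs, yc))
  C <- crossprod(Xs)
  K <- matrix(0, length(s), k)
  v <- s
  for (j in seq_len(k)) { K[, j] <- v; v <- drop(C %*% v) }
  beta <- K %*% solve(t(K) %*% C %*% K, drop(t(K) %*% s))
  Xn <- sweep(sweep(X_new[, keep, drop = FALSE], 2, mu[keep]), 2,
              sd_[keep], "/")
  drop(Xn %*% beta) + my
}

# Pooled k-fold CV R^2 computed with the Krylov oracle on a fixed fold
# assignment (mirrors the package's fold contract, not its code).
oracle_cv_r2 <- function(X, y, fold_id, k = 2) {
  X <- as.matrix(X)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    kk <- min(k, ncol(X), sum(tr) - 1)
    pred[!tr] <- tryCatch(
      krylov_pls_predict(X[tr, , drop = FALSE], y[tr],
                         X[!tr, , drop = FALSE], kk),
      error = function(e) mean(y[tr]))
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

# Direct, loop-based masked weighted squared-error (element by element).
loop_masked_mse <- function(y_true, y_pred, weights, mask_zero) {
  total <- 0; n_inc <- 0L
  for (i in seq_len(nrow(y_true))) for (j in seq_len(ncol(y_true))) {
    if (mask_zero && y_true[i, j] <= 0) next
    total <- total + weights[j] * (y_true[i, j] - y_pred[i, j])^2
    n_inc <- n_inc + 1L
  }
  if (n_inc == 0) 0 else total / n_inc
}

# A trait row with sensible defaults for rendering / feature tests.
make_traits <- function(dm = 10, lai = 4, nc = 2,
                        dm_prop = c(0.4, 0.25, 0.1, 0.25)) {
  trait_vector(dm_total = dm, lai = lai, n_conc = nc, dm_prop = dm_prop)
}

# Stack H x W x C arrays into the network's H x W x C x N tensor.
stack_tensor <- function(lst) {
  d <- dim(lst[[1]])
  x <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) x[, , , i] <- lst[[i]]
  x
}
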