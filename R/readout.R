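#' Linear readout probe trained by cosine-distance minimization
#'
#' Fits a linear map (with bias) from frozen features to target vectors by
#' minimizing the mean cosine distance between predictions and targets with
#' gradient descent (backtracking line search; the training loss decreases
#' monotonically until the relative change falls below `tol`). Weights are
#' initialized at the ridge least-squares solution. The test metric is the
#' mean cosine similarity between predicted and target vectors on the
#' held-out split; the floor is the same metric for the constant predictor
#' equal to the mean training target.
#'
#' Target rows with zero norm have no defined cosine and are excluded with a
#' warning.
#'
#' @param features Matrix `n x q` of frozen features (or a
#'   `feature_matrix`).
#' @param targets Matrix `n x d_t` of target vectors (embeddings or
#'   multi-hot labels; or a `feature_matrix`).
#' @param test_fraction Fraction of rows held out for testing (default 0.2),
#'   drawn by a seeded shuffle; train and test are disjoint.
#' @param seed Integer seed.
#' @param max_iter Maximum gradient steps.
#' @param tol Relative-loss-change convergence tolerance (default 1e-6).
#' @return A `readout_result`: list with `test_cosine`, `floor`, `n_train`,
#'   `n_test`, `loss_trace`, `converged`.
#' @export
readout_probe <- function(features, targets, test_fraction = 0.2, seed = 1L,
                          max_iter = 500L, tol = 1e-6) {
  if (inherits(features, "feature_matrix")) features <- features$values
  if (inherits(targets, "feature_matrix")) targets <- targets$values
  X <- as.matrix(features)
  T_ <- as.matrix(targets)
  if (nrow(X) != nrow(T_)) abort("Features and targets must align by row.")

  norms <- sqrt(rowSums(T_^2))
  if (any(norms == 0)) {
    warn(sprintf("%d zero-norm target row(s) excluded.", sum(norms == 0)))
    keep <- norms > 0
    X <- X[keep, , drop = FALSE]
    T_ <- T_[keep, , drop = FALSE]
  }
  n <- nrow(X)
  if (n < 4L) abort("Too few usable rows for a train/test split.")

  test_idx <- with_seed(derive_seed(seed, "readout_split"), {
    sample.int(n, size = max(1L, round(test_fraction * n)))
  })
  tr <- setdiff(seq_len(n), test_idx)
  Xtr <- cbind(1, X[tr, , drop = FALSE])
  Ttr <- T_[tr, , drop = FALSE]
  Xte <- cbind(1, X[test_idx, , drop = FALSE])
  Tte <- T_[test_idx, , drop = FALSE]

  # ridge least-squares initialization
  lambda <- 1e-6 * sum(diag(crossprod(Xtr))) / ncol(Xtr)
  W <- solve(crossprod(Xtr) + lambda * diag(ncol(Xtr)), crossprod(Xtr, Ttr))

  cosine_rows <- function(P, T2) {
    num <- rowSums(P * T2)
    den <- sqrt(rowSums(P^2)) * sqrt(rowSums(T2^2))
    den[den == 0] <- .Machine$double.eps
    num / den
  }
  loss_fn <- function(W) mean(1 - cosine_rows(Xtr %*% W, Ttr))
  grad_fn <- function(W) {
    P <- Xtr %*% W
    pn <- sqrt(rowSums(P^2))
    pn[pn == 0] <- .Machine$double.eps
    tn <- sqrt(rowSums(Ttr^2))
    cosv <- rowSums(P * Ttr) / (pn * tn)
    G <- -(Ttr / (pn * tn) - (cosv / pn^2) * P) / nrow(Xtr)
    crossprod(Xtr, G)
  }

  loss <- loss_fn(W)
  trace <- loss
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- grad_fn(W)
    repeat {
      W_new <- W - step * G
      loss_new <- loss_fn(W_new)
      if (loss_new <= loss || step < 1e-12) break
      step <- step / 2
    }
    if (loss_new > loss) break  # no descent direction at machine precision
    rel <- (loss - loss_new) / max(loss, .Machine$double.eps)
    W <- W_new
    loss <- loss_new
    trace <- c(trace, loss)
    step <- step * 1.5
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }

  mean_target <- colMeans(Ttr)
  floor_pred <- matrix(mean_target, nrow(Xte), ncol(T_), byrow = TRUE)
  structure(
    list(test_cosine = mean(cosine_rows(Xte %*% W, Tte)),
         floor = mean(cosine_rows(floor_pred, Tte)),
         n_train = length(tr), n_test = length(test_idx),
         loss_trace = trace, converged = converged),
    class = "readout_result"
  )
}

#' @export
print.readout_result <- function(x, ...) {
  cat(sprintf("<readout_result> test cosine %.3f (floor %.3f), %d train / %d test, %s\n",
              x$test_cosine, x$floor, x$n_train, x$n_test,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}
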