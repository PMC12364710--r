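#' Default regularization-fraction grid
#'
#' Twenty fractions from 0.05 to 1.00 in steps of 0.05.
#'
#' @return Numeric vector of length 20.
#' @export
fraction_grid <- function() seq(0.05, 1, by = 0.05)

#' Fractional ridge regression coefficients along a fraction path
#'
#' Ridge regression reparameterized by the ratio of the regularized to the
#' unregularized (OLS) coefficient L2-norm: for each requested fraction `f`
#' and each target column of `Y`, the ridge penalty `gamma` is solved (along
#' the SVD of `X`) so that the coefficient norm equals `f` times the OLS
#' norm. Fraction 1 returns the OLS solution; on rank-deficient designs the
#' minimum-norm OLS solution is used with a warning.
#'
#' `X` is expected column-centred and `Y` centred; the intercept is handled
#' by the caller (see [fit_encoding_model()]).
#'
#' @param X Design matrix `n x q` (column-centred).
#' @param Y Target matrix `n x T` (centred) or a vector.
#' @param fractions Vector of norm fractions in (0, 1].
#' @return A `frac_ridge_path`: list with `coefficients` (array
#'   `q x T x length(fractions)`), `gamma` (`T x length(fractions)`),
#'   and `fractions`.
#' @export
#' @examples
#' X <- scale(matrix(rnorm(200), 40, 5), scale = FALSE)
#' y <- X %*% rnorm(5) + rnorm(40)
#' y <- y - mean(y)
#' fit <- fractional_ridge_path(X, y, c(0.5, 1))
#' # norm of the f = 0.5 solution is half the OLS norm
#' sqrt(sum(fit$coefficients[, 1, 1]^2)) / sqrt(sum(fit$coefficients[, 1, 2]^2))
fractional_ridge_path <- function(X, Y, fractions = fraction_grid()) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("`X` and `Y` must have the same rows.")
  if (any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must lie in (0, 1].")
  }
  q <- ncol(X)
  n_t <- ncol(Y)
  n_f <- length(fractions)

  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < q && any(fractions == 1)) {
    warn("Rank-deficient design; fraction 1 returns the minimum-norm OLS solution.")
  }
  d1 <- sv$d[seq_len(rank)]
  d2 <- d1^2
  U <- sv$u[, seq_len(rank), drop = FALSE]
  V <- sv$v[, seq_len(rank), drop = FALSE]

  # rotated OLS coefficients, one column per target
  alpha <- (crossprod(U, Y)) / d1

  coefs <- array(0, dim = c(q, n_t, n_f))
  gammas <- matrix(0, n_t, n_f)
  for (t_i in seq_len(n_t)) {
    a <- alpha[, t_i]
    norm_ols <- sqrt(sum(a^2))
    if (norm_ols == 0) {
      gammas[t_i, ] <- Inf
      next
    }
    for (f_i in seq_len(n_f)) {
      f <- fractions[f_i]
      g <- frac_solve_gamma(a, d2, f, norm_ols)
      gammas[t_i, f_i] <- g
      shrink <- d2 / (d2 + g)
      coefs[, t_i, f_i] <- V %*% (a * shrink)
    }
  }
  structure(list(coefficients = coefs, gamma = gammas, fractions = fractions),
            class = "frac_ridge_path")
}

# solve ||a * d2/(d2+g)|| = f * norm_ols for g >= 0; the norm fraction is
# strictly decreasing in g, from 1 at g = 0 toward 0
frac_solve_gamma <- function(a, d2, f, norm_ols) {
  if (f == 1) return(0)
  fn <- function(g) sqrt(sum((a * d2 / (d2 + g))^2)) / norm_ols - f
  hi <- max(d2)
  while (fn(hi) > 0) hi <- hi * 10
  stats::uniroot(fn, c(0, hi), tol = .Machine$double.eps^0.5)$root
}
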