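#' Group-level inference across participants with BH-FDR correction
#'
#' One-sample two-tailed t-test of the participant values against a null
#' value at every location (voxel, sphere center or ROI), followed by the
#' Benjamini-Hochberg step-up adjustment across locations and a significance
#' mask at level `alpha`.
#'
#' Locations where every participant is missing are dropped from the family
#' (`NA` throughout). A location with zero variance across participants has
#' an undefined t statistic unless the mean equals the null exactly, in which
#' case `t = 0, p = 1`; otherwise the location is flagged and excluded from
#' the FDR family with a warning. Missing participants are excluded pairwise
#' per location.
#'
#' @param values Numeric matrix, participants in rows, locations in columns
#'   (column names become location labels).
#' @param alpha FDR level (default 0.05).
#' @param null Null value tested against (default 0).
#' @return A `group_result` tibble with columns `location`, `n`, `estimate`,
#'   `t`, `p`, `q`, `sig`.
#' @export
group_inference <- function(values, alpha = 0.05, null = 0) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) abort("At least 2 participants are required.")
  alpha <- check_number(alpha, "alpha", min = 0)
  loc <- colnames(values)
  if (is.null(loc)) loc <- as.character(seq_len(ncol(values)))

  n <- colSums(!is.na(values))
  est <- colMeans(values, na.rm = TRUE)
  sds <- apply(values, 2, sd, na.rm = TRUE)

  tstat <- (est - null) / (sds / sqrt(n))
  pval <- 2 * pt(-abs(tstat), df = n - 1)

  degen <- !is.na(sds) & sds == 0 & n >= 2
  zero_mean <- degen & abs(est - null) < .Machine$double.eps^0.5
  tstat[zero_mean] <- 0
  pval[zero_mean] <- 1
  bad <- degen & !zero_mean
  tstat[bad] <- NA_real_
  pval[bad] <- NA_real_
  too_few <- n < 2
  tstat[too_few] <- NA_real_
  pval[too_few] <- NA_real_
  if (any(bad)) {
    warn(sprintf(
      "%d location(s) with zero variance and nonzero effect; excluded from the FDR family.",
      sum(bad)))
  }

  q <- rep(NA_real_, length(pval))
  ok <- !is.na(pval)
  q[ok] <- p.adjust(pval[ok], method = "BH")

  structure(
    tibble(location = loc, n = as.integer(n), estimate = est,
           t = tstat, p = pval, q = q, sig = !is.na(q) & q <= alpha),
    class = c("group_result", class(tibble())),
    alpha = alpha, null = null
  )
}
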