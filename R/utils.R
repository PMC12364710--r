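#' @importFrom stats cor sd rnorm runif pt setNames p.adjust quantile
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# argument checks ------------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  as.numeric(x)
}

#' Derive a reproducible child seed from a global seed
#'
#' One global seed is expanded into independent per-component seeds so that
#' changing, say, the number of distractors in a dictionary does not perturb
#' the random stream used to simulate trial responses. The scheme is a
#' splitmix-style integer hash of the seed and a component key, reduced
#' modulo 2^31 - 1 so the result is always a valid R seed.
#'
#' @param seed Single integer global seed.
#' @param key Character scalar naming the component (e.g. `"trials"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "scenes")
derive_seed <- function(seed, key) {
  seed <- check_count(seed, "seed", min = 0L)
  stopifnot(is.character(key), length(key) == 1L)
  h <- as.double(seed) + 1
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  # extra mixing round so nearby seeds map far apart
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# fast column-wise Pearson between paired columns of two matrices
paired_col_cor <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

upper_tri_vec <- function(m) m[upper.tri(m)]
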