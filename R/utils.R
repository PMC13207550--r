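# internal numerical helpers shared across modules

# Cholesky with a diagnostic error; optional jitter for matrices that are
# PSD only up to rounding (e.g. lambda = 0 transforms of near-singular C).
.chol_safe <- function(M, jitter = 0, what = "covariance matrix") {
  if (jitter > 0) M <- M + diag(jitter, nrow(M))
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(L)) {
    stop(what, " is not positive definite; consider adding a small ",
         "diagonal jitter", call. = FALSE)
  }
  L
}

# log-determinant from an upper Cholesky factor
.logdet_chol <- function(U) 2 * sum(log(diag(U)))

# numerically stable log(1 + exp(x))
.log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x < 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

.bernoulli_loglik <- function(y, eta) sum(y * eta) - sum(.log1pexp(eta))

# modal value with lexicographic tie-break; returns NA_character_ on empty
.lex_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(value = NA_character_, tie = FALSE))
  tab <- table(as.character(x))
  top <- names(tab)[tab == max(tab)]
  list(value = sort(top)[1L], tie = length(top) > 1L)
}

.stopifnot_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be TRUE or FALSE", call. = FALSE)
}
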