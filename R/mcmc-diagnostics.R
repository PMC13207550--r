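# Rank-normalized split-Rhat and bulk/tail effective sample size
# (Vehtari, Gelman, Simpson, Carpenter & Buerkner 2021 conventions).

# split each chain in half; x is iterations x chains
.split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# rank-normalize jointly across all chains
.rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

.rhat_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) return(if (B > 0) Inf else 1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat convergence diagnostic
#'
#' Rank-normalized split-R-hat: chains are split in half, draws are
#' rank-normalized jointly, and the classic potential-scale-reduction factor
#' is computed on both the rank-normalized draws and their folded version
#' (absolute deviation from the median); the larger of the two is returned.
#' Values at or very near 1 indicate between-chain agreement.
#'
#' @param x matrix of posterior draws, iterations x chains.
#' @return the split R-hat value.
#' @export
split_rhat <- function(x) {
  s <- .split_chains(x)
  z <- .rank_normalize(s)
  folded <- .rank_normalize(abs(s - stats::median(s)))
  max(1, .rhat_basic(z), .rhat_basic(folded))
}

# combined-chain ESS with Geyer initial monotone sequence; x split already
.ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  if (all(apply(x, 2, stats::var) == 0)) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) {
    ch <- x[, j] - mean(x[, j])
    drop(stats::acf(ch, lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = FALSE)$acf)
  }, numeric(n))
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- W * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: pair sums, truncate at first negative, enforce monotone decrease
  maxpair <- floor((n - 1) / 2)
  P <- rho[2 * seq_len(maxpair)] + rho[2 * seq_len(maxpair) + 1]
  if (anyNA(P)) P <- P[!is.na(P)]
  neg <- which(P < 0)
  if (length(neg)) P <- P[seq_len(neg[1] - 1)]
  if (length(P) > 1) P <- cummin(P)
  tau <- -rho[1] + 2 * (rho[1] + if (length(P)) sum(P) else 0)
  tau <- max(tau, 1 / (n * m)) # guard
  min(n * m / tau, n * m * log10(n * m)) # cap for antithetic chains
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains, reflecting sampling efficiency in
#' the bulk of the distribution.
#'
#' @inheritParams split_rhat
#' @return estimated effective sample size.
#' @export
ess_bulk <- function(x) {
  s <- .split_chains(x)
  .ess_basic(.rank_normalize(s))
}

#' Tail effective sample size
#'
#' Minimum of the ESS of the 5% and 95% quantile-indicator variables,
#' reflecting sampling efficiency in the distribution tails.
#'
#' @inheritParams split_rhat
#' @return estimated effective sample size.
#' @export
ess_tail <- function(x) {
  s <- .split_chains(x)
  q <- stats::quantile(as.vector(s), c(0.05, 0.95), names = FALSE)
  lo <- .ess_basic((s <= q[1]) + 0)
  hi <- .ess_basic((s >= q[2]) + 0)
  if (is.na(lo) && is.na(hi)) return(NA_real_)
  min(lo, hi, na.rm = TRUE)
}
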