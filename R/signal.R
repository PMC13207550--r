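#' Generalized least-squares phylogenetic mean and mean squared errors
#'
#' Shared kernel for the signal statistics: the GLS estimate of the
#' phylogenetic (ancestral) mean \eqn{\hat a = (1'C^{-1}1)^{-1} 1'C^{-1}x},
#' the ordinary mean squared error
#' \eqn{MSE_0 = (x-\hat a)'(x-\hat a)/(n-1)} and the phylogenetically
#' corrected \eqn{MSE = (x-\hat a)'C^{-1}(x-\hat a)/(n-1)}.
#'
#' @param C positive-definite phylogenetic covariance (see [phylo_vcv()]).
#' @param x complete numeric trait vector ordered as the rows of `C`.
#' @return list with `ahat`, `MSE`, `MSE0`.
#' @export
phylo_gls_mean <- function(C, x) {
  n <- length(x)
  if (!is.matrix(C) || nrow(C) != n || ncol(C) != n)
    stop("'C' must be an n x n matrix matching x", call. = FALSE)
  if (anyNA(x)) stop("'x' must be complete", call. = FALSE)
  U <- tryCatch(chol(C), error = function(e)
    stop("'C' is singular or not positive definite; add a small jitter ",
         "(e.g. 1e-10 on the diagonal)", call. = FALSE))
  Ci1 <- backsolve(U, backsolve(U, rep(1, n), transpose = TRUE))
  Cix <- backsolve(U, backsolve(U, x, transpose = TRUE))
  ahat <- sum(Cix) / sum(Ci1)
  r <- x - ahat
  list(ahat = ahat,
       MSE = drop(crossprod(r, backsolve(U, backsolve(U, r, transpose = TRUE)))) / (n - 1),
       MSE0 = sum(r^2) / (n - 1))
}

# precompute quantities reused across permutations of the same tree
.k_kernel <- function(C) {
  n <- nrow(C)
  U <- .chol_safe(C, what = "phylogenetic covariance")
  Cinv <- chol2inv(U)
  one <- rep(1, n)
  list(Cinv = Cinv, s1 = sum(Cinv), trC = sum(diag(C)), n = n,
       denom = (sum(diag(C)) - n / sum(Cinv)) / (n - 1))
}

.k_stat <- function(kern, X) {
  # X: n x m matrix of trait vectors (columns); returns K per column
  X <- as.matrix(X)
  a <- colSums(kern$Cinv %*% X) / kern$s1
  Xc <- sweep(X, 2, a)
  mse0 <- colSums(Xc^2) / (kern$n - 1)
  mse <- colSums(Xc * (kern$Cinv %*% Xc)) / (kern$n - 1)
  (mse0 / mse) / kern$denom
}

#' Blomberg's K with a randomization test
#'
#' \eqn{K = (MSE_0/MSE) / [(tr(C) - n/(1'C^{-1}1))/(n-1)]}: the ratio of
#' observed to Brownian-expected variance structure. K = 1 matches the
#' Brownian expectation (and holds exactly on a star phylogeny); K > 1
#' indicates stronger phylogenetic conservatism than Brownian motion, K < 1
#' weaker signal. Significance is assessed by recomputing K on `n_perm`
#' shuffles of the tip values; the reported p-value uses the add-one
#' correction, so it is never zero.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param x complete, non-constant trait vector; if named, reordered to the
#'   tip labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed for the permutations.
#' @return list with `K` and `p_random`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = 1) {
  .check_phylo(tree)
  x <- .align_vector(x, tree$tip.label)
  if (stats::var(x) == 0)
    stop("trait is constant; K is undefined", call. = FALSE)
  if (n_perm < 99) stop("'n_perm' must be at least 99", call. = FALSE)
  kern <- .k_kernel(phylo_vcv(tree))
  K_obs <- .k_stat(kern, x)
  set.seed(seed)
  perms <- replicate(n_perm, sample(x))
  K_perm <- .k_stat(kern, perms)
  list(K = unname(K_obs),
       p_random = (1 + sum(K_perm >= K_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

# profile log-likelihood of x under N(a1, sigma2 * C(lambda))
.lambda_profile_loglik <- function(C, Clam, x) {
  n <- length(x)
  U <- tryCatch(chol(Clam), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  Ci1 <- backsolve(U, backsolve(U, rep(1, n), transpose = TRUE))
  Cix <- backsolve(U, backsolve(U, x, transpose = TRUE))
  a <- sum(Cix) / sum(Ci1)
  r <- x - a
  q <- drop(crossprod(r, backsolve(U, backsolve(U, r, transpose = TRUE))))
  s2 <- q / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + .logdet_chol(U) + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the Gaussian likelihood of `x` with mean \eqn{a 1} and covariance
#' \eqn{\sigma^2 C(\lambda)} over \eqn{\lambda \in [0, \lambda_{max}]}, with
#' the mean and rate profiled analytically. The search bound starts at 1.1 --
#' estimates slightly above 1 are representable -- and is shrunk if
#' \eqn{C(\lambda)} loses positive definiteness. The reported p-value is the
#' upper chi-squared(1 df) tail of the likelihood-ratio statistic against
#' \eqn{\lambda = 0} (conservative, given the boundary at zero).
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param x complete trait vector; if named, reordered to the tip labels.
#' @param lambda_max upper search bound before positive-definiteness shrinkage.
#' @return list with `lambda`, `logL_lambda`, `logL_zero`, `p_random`.
#' @export
pagel_lambda_ml <- function(tree, x, lambda_max = 1.1) {
  .check_phylo(tree)
  x <- .align_vector(x, tree$tip.label)
  C <- phylo_vcv(tree)
  # the PD region in lambda is an interval [0, l*]; locate l* by bisection
  pd <- function(l) {
    V <- C * l; diag(V) <- diag(C)
    !inherits(tryCatch(chol(V), error = function(e) e), "error")
  }
  if (!pd(lambda_max)) {
    lo <- if (pd(1)) 1 else 0
    if (lo == 0)
      warning("C(lambda) not positive definite even at lambda = 1; ",
              "search bound reduced below 1", call. = FALSE)
    hi <- if (lo == 1) lambda_max else 1
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (pd(mid)) lo <- mid else hi <- mid
    }
    lambda_max <- 0.999 * lo
  }
  f <- function(l) .lambda_profile_loglik(C, transform_covariance(C, "lambda", l), x)
  opt <- stats::optimize(f, c(0, lambda_max), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1, lambda_max)
  ll <- vapply(cand, f, numeric(1))
  best <- which.max(ll)
  logL0 <- ll[2]
  list(lambda = cand[best], logL_lambda = ll[best], logL_zero = logL0,
       p_random = stats::pchisq(2 * (ll[best] - logL0), df = 1,
                                lower.tail = FALSE))
}

#' Phylogenetic signal of a continuous trait (K and lambda)
#'
#' Convenience wrapper combining [blomberg_k()] and [pagel_lambda_ml()] into
#' one record, with a plain-language interpretation of K relative to the
#' Brownian expectation.
#'
#' @inheritParams blomberg_k
#' @return object of class `"signal_continuous"`.
#' @export
signal_continuous <- function(tree, x, n_perm = 999, seed = 1) {
  k <- blomberg_k(tree, x, n_perm = n_perm, seed = seed)
  l <- pagel_lambda_ml(tree, x)
  structure(list(K = k$K, p_random_K = k$p_random,
                 lambda = l$lambda, logL_lambda = l$logL_lambda,
                 logL_zero = l$logL_zero, p_random_lambda = l$p_random,
                 interpretation = if (k$K > 1)
                   "stronger phylogenetic conservatism than expected under Brownian motion"
                 else "phylogenetic signal at or below the Brownian expectation"),
            class = "signal_continuous")
}

#' @export
print.signal_continuous <- function(x, ...) {
  cat(sprintf("K = %.3f (pRandom = %.4g), lambda = %.3f (pRandom = %.4g)\n",
              x$K, x$p_random_K, x$lambda, x$p_random_lambda))
  invisible(x)
}

# data-independent adjusted branch lengths and traversal order for the
# contrast-style nodal averaging (binary tree required)
.nodal_prep <- function(tree) {
  n <- length(tree$tip.label)
  kids <- .children_list(tree)
  b <- numeric(n + tree$Nnode)
  b[tree$edge[, 2]] <- tree$edge.length
  # reversed preorder: every internal node is visited after its descendants,
  # robust to zero-length edges (where depth ties would be ambiguous)
  pre <- integer(0)
  stack <- n + 1L
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x > n) {
      pre <- c(pre, x)
      stack <- c(stack, kids[[x]])
    }
  }
  ord <- rev(pre)
  w1 <- w2 <- numeric(length(ord))
  c1 <- c2 <- integer(length(ord))
  for (i in seq_along(ord)) {
    ch <- kids[[ord[i]]]
    if (length(ch) != 2L)
      stop("tree must be strictly bifurcating; resolve polytomies first",
           call. = FALSE)
    b1 <- b[ch[1]]; b2 <- b[ch[2]]
    if (b1 + b2 == 0) { w1[i] <- w2[i] <- 0.5 } else if (b1 == 0) {
      w1[i] <- 1; w2[i] <- 0
    } else if (b2 == 0) {
      w1[i] <- 0; w2[i] <- 1
    } else {
      w1[i] <- (1 / b1) / (1 / b1 + 1 / b2)
      w2[i] <- 1 - w1[i]
    }
    c1[i] <- ch[1]; c2[i] <- ch[2]
    if (b1 + b2 > 0) b[ord[i]] <- b[ord[i]] + b1 * b2 / (b1 + b2)
  }
  list(order = ord, c1 = c1, c2 = c2, w1 = w1, w2 = w2, n = n,
       edge = tree$edge)
}

# vectorized nodal sum of changes: Y is n x m (tip rows in tip-label order)
.nodal_d <- function(prep, Y) {
  Y <- as.matrix(Y)
  V <- matrix(0, prep$n + length(prep$order), ncol(Y))
  V[seq_len(prep$n), ] <- Y
  for (i in seq_along(prep$order))
    V[prep$order[i], ] <- prep$w1[i] * V[prep$c1[i], ] +
      prep$w2[i] * V[prep$c2[i], ]
  colSums(abs(V[prep$edge[, 1], , drop = FALSE] -
                V[prep$edge[, 2], , drop = FALSE]))
}

#' Sum of nodal changes of a binary trait
#'
#' Estimates internal node values tipward-to-rootward by contrast-style
#' weighted averages \eqn{v = (v_1/b_1 + v_2/b_2)/(1/b_1 + 1/b_2)}, extending
#' each merged pair's parent branch by \eqn{b_1 b_2/(b_1+b_2)} (zero-length
#' pairs use equal weights), and returns the sum over all edges of the
#' absolute parent-child change. This is the raw statistic behind
#' [fritz_purvis_d()].
#'
#' @param tree a strictly bifurcating `"phylo"` object.
#' @param y 0/1 vector with both states present; if named, reordered to tips.
#' @return the observed sum of changes `d`.
#' @export
nodal_sum_of_changes <- function(tree, y) {
  .check_phylo(tree)
  y <- .align_vector(y, tree$tip.label)
  .check_binary_states(y)
  .nodal_d(.nodal_prep(tree), matrix(y, ncol = 1))
}

#' Fritz-Purvis D for a binary trait
#'
#' Scales the observed sum of changes between two prevalence-matched nulls:
#' `n_sim` tip-label permutations (`d_r`) and `n_sim` Brownian liability
#' simulations thresholded to the observed number of 1s (`d_b`):
#' \deqn{D = (d_{obs} - \bar d_b) / (\bar d_r - \bar d_b).}
#' D = 0 matches a Brownian threshold pattern, D = 1 a phylogenetically
#' random one; D < 0 indicates stronger-than-Brownian conservatism and D > 1
#' overdispersion. `p_random` is the fraction of permutation nulls with
#' `d <= d_obs` (small when the trait is clumped, i.e. non-random);
#' `p_brownian` is the fraction of Brownian nulls with `d >= d_obs` (large
#' when the trait is at least as conserved as Brownian). Both use the add-one
#' correction. Trees with polytomies are resolved internally via
#' [resolve_polytomies()], which leaves patristic distances unchanged.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param y 0/1 vector with both states present; if named, reordered to tips.
#' @param n_sim simulations per null (>= 500; default 1000).
#' @param seed integer RNG seed.
#' @return object of class `"signal_binary"` with fields `d_obs`, `D`,
#'   `p_brownian`, `p_random`, `n_sim`.
#' @export
fritz_purvis_d <- function(tree, y, n_sim = 1000, seed = 1) {
  .check_phylo(tree)
  y <- .align_vector(y, tree$tip.label)
  .check_binary_states(y)
  if (n_sim < 500) stop("'n_sim' must be at least 500", call. = FALSE)
  if (!is_binary_tree(tree)) tree <- resolve_polytomies(tree)
  prep <- .nodal_prep(tree)
  n <- length(y)
  k <- sum(y)
  d_obs <- .nodal_d(prep, matrix(y, ncol = 1))
  set.seed(seed)
  perms <- replicate(n_sim, sample(y))
  d_r <- .nodal_d(prep, perms)
  L <- t(.chol_safe(phylo_vcv(tree), jitter = 1e-10,
                    what = "phylogenetic covariance"))
  lia <- L %*% matrix(stats::rnorm(n * n_sim), n, n_sim)
  thr <- apply(lia, 2, function(z)
    as.numeric(rank(-z, ties.method = "first") <= k))
  d_b <- .nodal_d(prep, thr)
  if (abs(mean(d_r) - mean(d_b)) < 1e-8 * (1 + mean(d_r)))
    stop("random and Brownian nulls coincide; tree or prevalence is ",
         "uninformative for D", call. = FALSE)
  structure(list(d_obs = d_obs,
                 D = (d_obs - mean(d_b)) / (mean(d_r) - mean(d_b)),
                 p_random = (1 + sum(d_r <= d_obs)) / (n_sim + 1),
                 p_brownian = (1 + sum(d_b >= d_obs)) / (n_sim + 1),
                 n_sim = n_sim),
            class = "signal_binary")
}

#' @export
print.signal_binary <- function(x, ...) {
  cat(sprintf("D = %.3f (pBrownian = %.4g, pRandom = %.4g; %d sims per null)\n",
              x$D, x$p_brownian, x$p_random, x$n_sim))
  invisible(x)
}

#' Binarize a multi-level categorical trait against its modal level
#'
#' Signal statistics for binary traits are applied to categorical traits with
#' more than two levels by coding the modal level as 1 and all others as 0;
#' the chosen level is recorded so downstream reports can flag the coding.
#'
#' @param x character or factor vector.
#' @return 0/1 numeric vector with attribute `"modal_level"`.
#' @export
binarize_vs_modal <- function(x) {
  m <- .lex_mode(x)
  if (is.na(m$value)) stop("no observed values", call. = FALSE)
  out <- as.numeric(as.character(x) == m$value)
  names(out) <- names(x)
  attr(out, "modal_level") <- m$value
  out
}

.align_vector <- function(x, labels) {
  if (!is.null(names(x))) {
    if (!all(labels %in% names(x)))
      stop("vector names do not cover the tip labels", call. = FALSE)
    x <- x[labels]
  } else if (length(x) != length(labels)) {
    stop("trait vector length does not match the number of tips", call. = FALSE)
  }
  if (anyNA(x)) stop("trait vector must be complete", call. = FALSE)
  as.numeric(x)
}

.check_binary_states <- function(y) {
  if (!all(y %in% c(0, 1)))
    stop("'y' must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("'y' has a single state; the statistic is undefined (degenerate ",
         "prevalence)", call. = FALSE)
  invisible(y)
}
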