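#' Maximum-likelihood logistic GLMM with a guild random intercept
#'
#' Laplace-approximation fit of `y ~ X + (1 | group)` with a Bernoulli
#' response (via [lme4::glmer()]); with fewer than two groups the model
#' reduces to plain logistic regression (via [stats::glm()]). Marginal
#' R-squared follows the same decomposition as [variance_decomposition()],
#' using the point estimates: `var(X beta) / (var(X beta) + sigma_guild^2 +
#' pi^2/3)`. Coefficients beyond 15 in absolute value on the standardized
#' scale indicate quasi-separation; they are clamped with a warning.
#'
#' @param X numeric design matrix (no intercept column).
#' @param y 0/1 response.
#' @param group grouping factor (feeding guild).
#' @return list with `coefficients` (intercept first), `sigma_guild`,
#'   `logL`, `R2_marginal`, `fit`.
#' @export
glmm_laplace_fit <- function(X, y, group) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  group <- factor(group)
  df <- data.frame(.y = y, X, check.names = FALSE)
  if (nlevels(group) < 2L) {
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    coefs <- stats::coef(fit)
    sigma_g <- 0
    ll <- as.numeric(stats::logLik(fit))
  } else {
    df$.g <- group
    form <- stats::as.formula(paste(".y ~",
                                    if (ncol(X)) paste(sprintf("`%s`", colnames(X)),
                                                       collapse = " + ") else "1",
                                    "+ (1 | .g)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(form, data = df, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.grad = "ignore",
                                               check.conv.singular = "ignore",
                                               check.conv.hess = "ignore"))))
    coefs <- lme4::fixef(fit)
    sigma_g <- sqrt(as.numeric(lme4::VarCorr(fit)$.g[1]))
    ll <- as.numeric(stats::logLik(fit))
  }
  if (any(abs(coefs) > 15)) {
    warning("possible separation: coefficient(s) clamped at |15|: ",
            paste(names(coefs)[abs(coefs) > 15], collapse = ", "),
            call. = FALSE)
    coefs <- pmin(pmax(coefs, -15), 15)
  }
  vf <- if (ncol(X)) stats::var(drop(X %*% coefs[-1])) else 0
  list(coefficients = coefs, sigma_guild = sigma_g, logL = ll,
       R2_marginal = vf / (vf + sigma_g^2 + pi^2 / 3), fit = fit)
}

#' Hierarchical partitioning of predictor blocks
#'
#' Chevan-Sutherland averaging of goodness-of-fit gains: for every subset S
#' of the other blocks, the gain of block j is `g(S + j) - g(S)`, weighted by
#' `|S|! (b - |S| - 1)! / b!`; the weighted sum is block j's independent
#' contribution `I_j`. Goodness is the marginal R-squared of the
#' Laplace-approximation GLMM of [glmm_laplace_fit()] on the subset's
#' columns, with the empty model's goodness fixed at 0, so the `I_j` sum
#' exactly to the full-model R-squared. Categorical traits enter as single
#' blocks (all dummy columns together).
#'
#' @param blocks named list; each element is the column indices (or names)
#'   of one predictor block in `X`.
#' @param X numeric design matrix.
#' @param y 0/1 response.
#' @param group grouping factor passed to [glmm_laplace_fit()].
#' @return object of class `"hpart_result"`: `table` (block, independent
#'   contribution `I`, `percent`), `full_model_R2`, and all subset fits for
#'   audit (`subsets`).
#' @export
hierarchical_partition <- function(blocks, X, y, group) {
  X <- as.matrix(X)
  b <- length(blocks)
  if (b < 1) stop("need at least one block", call. = FALSE)
  if (b > 12) stop("more than 12 blocks (2^b model fits) is not supported",
                   call. = FALSE)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("'blocks' must be a fully named list", call. = FALSE)
  cols <- lapply(blocks, function(ix) {
    if (is.character(ix)) match(ix, colnames(X)) else as.integer(ix)
  })
  if (anyNA(unlist(cols))) stop("block columns not found in X", call. = FALSE)
  nsub <- 2^b
  g <- numeric(nsub) # goodness per subset, indexed by bitmask + 1
  for (s in seq_len(nsub - 1)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(b) - 1L)) != 0L)
    ix <- unlist(cols[members])
    fit <- tryCatch(
      glmm_laplace_fit(X[, ix, drop = FALSE], y, group),
      error = function(e)
        stop("subset fit failed for blocks {",
             paste(names(blocks)[members], collapse = ", "), "}: ",
             conditionMessage(e), call. = FALSE))
    g[s + 1] <- fit$R2_marginal
  }
  lf <- lfactorial(0:b)
  I <- setNames(numeric(b), names(blocks))
  for (j in seq_len(b)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (s in 0:(nsub - 1)) {
      if (bitwAnd(s, bit_j) != 0L) next
      sz <- sum(bitwAnd(s, bitwShiftL(1L, seq_len(b) - 1L)) != 0L)
      w <- exp(lf[sz + 1] + lf[b - sz] - lf[b + 1])
      I[j] <- I[j] + w * (g[bitwOr(s, bit_j) + 1] - g[s + 1])
    }
  }
  full <- g[nsub]
  structure(list(table = data.frame(block = names(blocks), I = unname(I),
                                    percent = 100 * unname(I) / sum(I)),
                 full_model_R2 = full,
                 subsets = data.frame(mask = 0:(nsub - 1), R2_marginal = g)),
            class = "hpart_result")
}

#' @export
print.hpart_result <- function(x, ...) {
  cat(sprintf("hierarchical partitioning: full-model marginal R2 = %.4f\n",
              x$full_model_R2))
  tab <- x$table[order(-x$table$I), ]
  rownames(tab) <- NULL
  print(tab, digits = 3)
  invisible(x)
}
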