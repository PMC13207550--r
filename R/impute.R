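#' Log-likelihood of a partially observed trait matrix under a
#' multivariate phylogenetic Gaussian model
#'
#' The model places `vec(Y)` (species within trait columns) under
#' `Normal(mu replicated over species, R %x% C_model)`: `R` is the p x p
#' across-trait covariance and `C_model` the (possibly transformed)
#' phylogenetic covariance across species. Missing cells are marginalized by
#' restricting to the observed rows/columns of the joint covariance.
#'
#' @param C_model positive-definite species covariance (n x n), e.g. from
#'   [transform_covariance()].
#' @param Y species x traits matrix with `NA` for missing cells.
#' @param R trait covariance (p x p, positive definite).
#' @param mu per-trait root means (length p).
#' @return the log-likelihood of the observed cells.
#' @export
mvbm_loglik <- function(C_model, Y, R, mu) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  stopifnot(nrow(C_model) == n, length(mu) == p, nrow(R) == p)
  .chol_safe(R, what = "trait covariance R")
  obs <- which(!is.na(as.vector(Y)))
  if (!length(obs)) stop("no observed cells", call. = FALSE)
  if (any(colSums(!is.na(Y)) == 0))
    stop("every trait needs at least one observed cell", call. = FALSE)
  Sigma <- kronecker(R, C_model)
  m <- rep(mu, each = n)
  U <- .chol_safe(Sigma[obs, obs, drop = FALSE], jitter = 0,
                  what = "observed-cell covariance")
  r <- as.vector(Y)[obs] - m[obs]
  z <- backsolve(U, r, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + .logdet_chol(U) + sum(z^2))
}

# one EM pass structure shared by fitting and imputation --------------------

# conditional moments of missing cells given observed, under (mu, R, C)
.cond_moments <- function(C, Y, R, mu) {
  n <- nrow(Y)
  v <- as.vector(Y)
  obs <- which(!is.na(v)); mis <- which(is.na(v))
  Sigma <- kronecker(R, C)
  m <- rep(mu, each = n)
  U <- .chol_safe(Sigma[obs, obs, drop = FALSE],
                  what = "observed-cell covariance")
  Som <- Sigma[obs, mis, drop = FALSE]
  w <- backsolve(U, backsolve(U, v[obs] - m[obs], transpose = TRUE))
  cmean <- m[mis] + drop(crossprod(Som, w))
  B <- backsolve(U, Som, transpose = TRUE)
  V <- Sigma[mis, mis, drop = FALSE] - crossprod(B)
  list(obs = obs, mis = mis, mean = cmean, V = V)
}

# EM for (mu, R) given the species covariance C; returns the ML fit
.em_fit <- function(C, Y, R0, mu0, max_iter = 200, tol = 1e-8) {
  n <- nrow(Y); p <- ncol(Y)
  W <- chol2inv(.chol_safe(C, what = "species covariance"))
  sW <- sum(W)
  has_missing <- anyNA(Y)
  mis <- which(is.na(as.vector(Y)))
  mis_sp <- ((mis - 1) %% n) + 1L
  mis_tr <- ((mis - 1) %/% n) + 1L
  Mtr <- matrix(0, length(mis), p)
  if (length(mis)) Mtr[cbind(seq_along(mis), mis_tr)] <- 1
  mu <- mu0; R <- R0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    if (has_missing) {
      cm <- .cond_moments(C, Y, R, mu)
      Yhat <- Y
      Yhat[cbind(mis_sp, mis_tr)] <- cm$mean
      Lam <- t(Mtr) %*% ((W[mis_sp, mis_sp, drop = FALSE] * cm$V) %*% Mtr)
    } else {
      Yhat <- Y
      Lam <- matrix(0, p, p)
    }
    WY <- W %*% Yhat
    mu <- colSums(WY) / sW
    Xc <- sweep(Yhat, 2, mu)
    S <- crossprod(Xc, W %*% Xc) + Lam
    R <- (S + t(S)) / (2 * n)
    if (inherits(tryCatch(chol(R), error = function(e) e), "error"))
      R <- R + diag(1e-10 * mean(diag(R)), p)
    ll <- mvbm_loglik(C, Y, R, mu)
    if (!has_missing) return(list(mu = mu, R = R, logL = ll, converged = TRUE))
    if (abs(ll - ll_old) < tol * (1 + abs(ll)))
      return(list(mu = mu, R = R, logL = ll, converged = TRUE))
    ll_old <- ll
  }
  list(mu = mu, R = R, logL = ll_old, converged = FALSE)
}

# best-of-three-starts EM (diagonal R at empirical variances x {0.5, 1, 2})
.em_beststart <- function(C, Y, max_iter = 200, tol = 1e-8) {
  v <- apply(Y, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  mu0 <- colMeans(Y, na.rm = TRUE)
  fits <- lapply(c(0.5, 1, 2), function(f)
    tryCatch(.em_fit(C, Y, diag(f * v, length(v)), mu0, max_iter, tol),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && is.finite(f$logL), fits)
  if (!length(fits))
    stop("trait-evolution model fit failed from all starts; check for ",
         "degenerate traits or a singular tree covariance", call. = FALSE)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "logL"))]]
  if (!best$converged && !any(vapply(fits, `[[`, logical(1), "converged")))
    stop("EM did not converge from any start (", max_iter,
         " iterations); logL path ended at ", format(best$logL), call. = FALSE)
  best
}

#' Fit a multivariate trait-evolution model to a partially observed
#' trait matrix
#'
#' Maximum-likelihood fit of the joint Gaussian model of [mvbm_loglik()]
#' under one of four species-covariance transforms (see
#' [transform_covariance()]). Trait means and the trait covariance `R` are
#' estimated by an EM algorithm (closed-form updates; three deterministic
#' starts with diagonal `R` at empirical variances times 0.5, 1 and 2), and
#' the single shared transform parameter by a bounded one-dimensional profile
#' search: lambda in [0, 1.1], OU alpha in (0, 50/T], EB rate in [-10/T, 0]
#' with T the tree height. The parameter count for AIC is
#' `p + p(p+1)/2 + 1` (the transform; 0 for BM).
#'
#' @param tree a rooted `"phylo"` object.
#' @param Y species x traits matrix (log-scale continuous traits) with `NA`
#'   for missing cells; rownames must match the tip labels.
#' @param model one of `"BM"`, `"lambda"`, `"OU"`, `"EB"`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return object of class `"evomodel_fit"`: `model`, `R`, `mu`,
#'   `transform_param`, `logL`, `n_par`, `AIC`.
#' @export
fit_evomodel <- function(tree, Y, model = c("BM", "lambda", "OU", "EB"),
                         max_iter = 200, tol = 1e-8) {
  model <- match.arg(model)
  .check_phylo(tree)
  Y <- .align_matrix(Y, tree$tip.label)
  if (any(colSums(!is.na(Y)) < 5))
    stop("each trait needs at least 5 observed species", call. = FALSE)
  C0 <- phylo_vcv(tree)
  Tht <- max(diag(C0))
  p <- ncol(Y)
  if (model == "BM") {
    fit <- .em_beststart(C0, Y, max_iter, tol)
    par <- NULL
  } else {
    bounds <- switch(model,
                     lambda = c(0, 1.1),
                     OU = c(1e-6 / Tht, 50 / Tht),
                     EB = c(-10 / Tht, 0))
    g <- function(par) {
      Cm <- tryCatch(transform_covariance(C0, model, par),
                     error = function(e) NULL)
      if (is.null(Cm)) return(-1e10) # outside the PD region
      out <- tryCatch(.em_beststart(Cm, Y, max_iter = 100, tol = 1e-6),
                      error = function(e) NULL)
      if (is.null(out) || !is.finite(out$logL)) -1e10 else out$logL
    }
    opt <- stats::optimize(g, bounds, maximum = TRUE, tol = 1e-4)
    cand <- c(opt$maximum, bounds)
    ll <- vapply(cand, g, numeric(1))
    par <- cand[which.max(ll)]
    fit <- .em_beststart(transform_covariance(C0, model, par), Y,
                         max_iter, tol)
  }
  n_par <- p + p * (p + 1) / 2 + as.integer(model != "BM")
  structure(list(model = model, R = fit$R, mu = fit$mu,
                 transform_param = par, logL = fit$logL, n_par = n_par,
                 AIC = 2 * n_par - 2 * fit$logL,
                 traits = colnames(Y), species = rownames(Y),
                 tree_height = Tht),
            class = "evomodel_fit")
}

#' @export
print.evomodel_fit <- function(x, ...) {
  cat(sprintf("%s model: logL = %.3f, n_par = %d, AIC = %.2f", x$model,
              x$logL, x$n_par, x$AIC))
  if (!is.null(x$transform_param))
    cat(sprintf(", parameter = %.4f", x$transform_param))
  cat("\n")
  invisible(x)
}

#' Compare trait-evolution models by AIC
#'
#' Fits each requested model with [fit_evomodel()] and tabulates
#' log-likelihood, parameter count, AIC and delta-AIC.
#'
#' @inheritParams fit_evomodel
#' @param models models to fit.
#' @return list with `fits` (named list), `table` (data frame ordered by
#'   AIC), and `best` (the winning fit).
#' @export
compare_evomodels <- function(tree, Y,
                              models = c("BM", "lambda", "OU", "EB"), ...) {
  fits <- lapply(models, function(m) fit_evomodel(tree, Y, m, ...))
  names(fits) <- models
  tab <- data.frame(model = models,
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(fits = fits, table = tab, best = fits[[tab$model[1]]])
}

#' Impute missing continuous traits from a fitted evolution model
#'
#' Fills each missing cell with the conditional mean of the joint Gaussian
#' model given all observed cells, and reports the conditional variance of
#' each filled cell. Observed cells are never altered. On a star phylogeny
#' with a single trait this reduces to mean imputation.
#'
#' @param fit an `"evomodel_fit"` from [fit_evomodel()].
#' @param tree the tree the fit was produced on.
#' @param Y the trait matrix the fit was produced on.
#' @return object of class `"imputed_traits"`: `completed` (matrix),
#'   `imputed_mask` (logical matrix), `imputation_variance` (matrix, `NA`
#'   for observed cells).
#' @export
impute_missing <- function(fit, tree, Y) {
  stopifnot(inherits(fit, "evomodel_fit"))
  .check_phylo(tree)
  Y <- .align_matrix(Y, tree$tip.label)
  if (!identical(colnames(Y), fit$traits) ||
      !identical(rownames(Y), fit$species))
    stop("'fit' was not produced on this (tree, Y) pair", call. = FALSE)
  n <- nrow(Y)
  mask <- is.na(Y)
  vari <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  completed <- Y
  if (any(mask)) {
    Cm <- transform_covariance(phylo_vcv(tree), fit$model,
                               fit$transform_param)
    cm <- .cond_moments(Cm, Y, fit$R, fit$mu)
    mis <- cm$mis
    mis_sp <- ((mis - 1) %% n) + 1L
    mis_tr <- ((mis - 1) %/% n) + 1L
    completed[cbind(mis_sp, mis_tr)] <- cm$mean
    vari[cbind(mis_sp, mis_tr)] <- pmax(diag(cm$V), 0)
  }
  structure(list(completed = completed, imputed_mask = mask,
                 imputation_variance = vari, model = fit$model),
            class = "imputed_traits")
}

#' @export
print.imputed_traits <- function(x, ...) {
  cat("imputed_traits:", sum(x$imputed_mask), "cell(s) filled under the",
      x$model, "model\n")
  invisible(x)
}

.align_matrix <- function(Y, labels) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) {
    if (nrow(Y) != length(labels))
      stop("trait matrix rows do not match the number of tips", call. = FALSE)
    rownames(Y) <- labels
  } else {
    if (!all(labels %in% rownames(Y)))
      stop("trait matrix rownames do not cover the tip labels", call. = FALSE)
    Y <- Y[labels, , drop = FALSE]
  }
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  storage.mode(Y) <- "double"
  Y
}
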