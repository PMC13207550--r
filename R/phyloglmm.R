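#' Build the design for the phylogenetic Bernoulli mixed model
#'
#' Assembles a model specification from completed traits: continuous
#' predictors are z-standardized (so the weakly informative Normal(0, 0.5)
#' coefficient priors act on a common scale), categorical traits are
#' dummy-coded against the lexicographically first level, and column order is
#' deterministic (continuous traits in input order, then dummies).
#'
#' @param continuous complete numeric matrix of continuous traits, or an
#'   `"imputed_traits"` object (its `completed` matrix is used).
#' @param categorical data frame of complete categorical traits, or `NULL`.
#' @param guild factor (or character) assigning each species to a feeding
#'   guild.
#' @param invasion 0/1 invasion status vector.
#' @param A phylogenetic covariance across the same species; standardized to
#'   unit diagonal internally if it is not already.
#' @param priors list with elements `beta_sd` (default 0.5), `alpha_sd`
#'   (default 1.5) and `sigma_sd` (default 1, half-Normal scale of the
#'   random-effect SDs).
#' @param mcmc list with elements `chains` (4), `iter` (6000), `warmup`
#'   (4000), `seed` (1).
#' @return object of class `"pglmm_spec"`.
#' @export
build_design <- function(continuous, categorical = NULL, guild, invasion, A,
                         priors = list(), mcmc = list()) {
  if (inherits(continuous, "imputed_traits")) continuous <- continuous$completed
  X <- as.matrix(continuous)
  if (anyNA(X)) stop("continuous predictors must be complete", call. = FALSE)
  Xs <- scale(X)
  if (any(!is.finite(Xs)))
    stop("constant continuous predictor cannot be standardized", call. = FALSE)
  Xs <- Xs[, , drop = FALSE]
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  if (!is.null(categorical)) {
    categorical <- as.data.frame(categorical, stringsAsFactors = FALSE)
    if (anyNA(categorical))
      stop("categorical predictors must be complete", call. = FALSE)
    D <- .dummy_code(categorical)
    if (!is.null(D)) Xs <- cbind(Xs, D)
  }
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1) {
    aliased <- colnames(Xs)[setdiff(seq_len(ncol(Xs) + 1),
                                    qrX$pivot[seq_len(qrX$rank)]) - 1L]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(invasion)
  if (!all(y %in% c(0, 1))) stop("'invasion' must be 0/1", call. = FALSE)
  g <- factor(guild)
  if (length(g) != nrow(Xs) || length(y) != nrow(Xs))
    stop("'guild' and 'invasion' must match the number of species",
         call. = FALSE)
  A <- as.matrix(A)
  if (nrow(A) != nrow(Xs))
    stop("'A' must match the number of species", call. = FALSE)
  if (abs(max(diag(A)) - 1) > 1e-8) A <- A / max(diag(A))
  pri <- utils::modifyList(list(beta_sd = 0.5, alpha_sd = 1.5, sigma_sd = 1),
                           priors)
  mc <- utils::modifyList(list(chains = 4L, iter = 6000L, warmup = 4000L,
                               seed = 1L), mcmc)
  if (mc$warmup >= mc$iter) stop("warmup must be < iter", call. = FALSE)
  structure(list(X = Xs, y = y, guild = as.integer(g),
                 guild_levels = levels(g), A = A, priors = pri, mcmc = mc),
            class = "pglmm_spec")
}

# univariate slice sampler on [0, Inf) with stepping out and shrinkage
.slice_pos <- function(x0, logf, w = 0.5, max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  L <- max(0, x0 - w * stats::runif(1))
  R <- L + w
  s <- 0
  while (L > 0 && logf(L) > y && s < max_steps) { L <- max(0, L - w); s <- s + 1 }
  s <- 0
  while (logf(R) > y && s < max_steps) { R <- R + w; s <- s + 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# elliptical slice sampler (Murray, Adams & MacKay 2010): theta has a
# zero-mean Gaussian prior sampled by prior_draw(); loglik takes theta
.ess_step <- function(theta, prior_draw, loglik) {
  nu <- prior_draw()
  logy <- loglik(theta) - stats::rexp(1)
  a <- stats::runif(1, 0, 2 * pi)
  amin <- a - 2 * pi; amax <- a
  repeat {
    prop <- theta * cos(a) + nu * sin(a)
    if (loglik(prop) >= logy) return(prop)
    if (a < 0) amin <- a else amax <- a
    a <- stats::runif(1, amin, amax)
    if (amax - amin < 1e-12) return(theta)
  }
}

#' Fit the Bayesian phylogenetic Bernoulli mixed model
#'
#' Posterior sampling for the logit model
#' \deqn{\mathrm{logit}\,P_j = \alpha + \sum_i \beta_i X_{ij} +
#'   u_{phylo(j)} + u_{guild(j)}}
#' with \eqn{u_{phylo} \sim N(0, \sigma^2_{phylo} A)} (omitted when
#' `include_phylo = FALSE`) and \eqn{u_{guild} \sim N(0, \sigma^2_{guild} I)}.
#' The phylogenetic effect uses a non-centered (whitened) parameterization
#' \eqn{u = \sigma L z} with `L` the Cholesky factor of `A`. Gaussian-prior
#' blocks (intercept and coefficients jointly; each whitened latent vector)
#' are updated by elliptical slice sampling, and the random-effect SDs by a
#' univariate slice sampler under their half-Normal priors, so no proposal
#' tuning is required. Chains are run sequentially with seeds derived from
#' the spec seed.
#'
#' @param spec a `"pglmm_spec"` from [build_design()].
#' @param include_phylo include the phylogenetic random effect?
#' @param sigma_phylo_fixed optionally fix the phylogenetic SD (e.g. 0 for a
#'   nested-model check) instead of sampling it.
#' @param chains,iter,warmup,seed override the spec's MCMC settings.
#' @param check_convergence raise an error if any monitored parameter has
#'   split R-hat > 1.01 or bulk/tail ESS < 400. Disable for deliberately
#'   short exploratory runs.
#' @return object of class `"pglmm_fit"` with per-chain draw matrices
#'   (`draws`), monitored-parameter diagnostics (`diagnostics`), and the
#'   model kind (`"PGLMM"` or `"GLMM"`).
#' @export
fit_bernoulli_mixed <- function(spec, include_phylo = TRUE,
                                sigma_phylo_fixed = NULL,
                                chains = NULL, iter = NULL, warmup = NULL,
                                seed = NULL, check_convergence = FALSE) {
  stopifnot(inherits(spec, "pglmm_spec"))
  mc <- spec$mcmc
  chains <- chains %||% mc$chains
  iter <- iter %||% mc$iter
  warmup <- warmup %||% mc$warmup
  seed <- seed %||% mc$seed
  if (warmup >= iter) stop("warmup must be < iter", call. = FALSE)
  X <- spec$X; y <- spec$y
  n <- length(y); k <- ncol(X); G <- length(spec$guild_levels)
  gidx <- spec$guild
  L <- t(.chol_safe(spec$A, jitter = 1e-10, what = "phylogenetic covariance A"))
  w1 <- forwardsolve(L, rep(1, n)) # L^{-1} 1, for the recentering move
  wss <- sum(w1^2)
  pri <- spec$priors
  bsd <- c(pri$alpha_sd, rep(pri$beta_sd, k))
  par_names <- c("alpha", paste0("b_", colnames(X)),
                 if (include_phylo) "sigma_phylo", "sigma_guild")
  extra_names <- c(paste0("u_phylo.", seq_len(n)),
                   paste0("u_guild.", spec$guild_levels))
  keep <- iter - warmup
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    ab <- stats::rnorm(k + 1, 0, 0.3)
    zp <- stats::rnorm(n, 0, 0.1)
    zg <- stats::rnorm(G, 0, 0.1)
    sp <- if (!include_phylo) 0 else
      if (!is.null(sigma_phylo_fixed)) sigma_phylo_fixed else
        abs(stats::rnorm(1, 0, 0.5)) + 0.05
    sg <- abs(stats::rnorm(1, 0, 0.5)) + 0.05
    vp <- drop(L %*% zp)
    out <- matrix(NA_real_, keep,
                  length(par_names) + length(extra_names))
    colnames(out) <- c(par_names, extra_names)
    fix <- drop(X %*% ab[-1]) + ab[1]
    for (it in seq_len(iter)) {
      for (scan in 1:2) { # two full update scans per stored iteration
      # (alpha, beta) block: several elliptical-slice sweeps per scan, since
      # this block carries the strongest posterior correlations
      rest <- sp * vp + sg * zg[gidx]
      for (r in 1:8)
        ab <- .ess_step(ab,
                        function() stats::rnorm(k + 1, 0, bsd),
                        function(th) .bernoulli_loglik(y, th[1] + X %*% th[-1] + rest))
      fix <- drop(X %*% ab[-1]) + ab[1]
      # whitened phylogenetic latents
      if (include_phylo && sp != 0) {
        base <- fix + sg * zg[gidx]
        for (r in 1:8)
          zp <- .ess_step(zp, function() stats::rnorm(n),
                          function(z) .bernoulli_loglik(y, base + sp * (L %*% z)))
        vp <- drop(L %*% zp)
      }
      # guild latents
      base <- fix + sp * vp
      zg <- .ess_step(zg, function() stats::rnorm(G),
                      function(z) .bernoulli_loglik(y, base + sg * z[gidx]))
      # random-effect SDs (half-Normal priors): likelihood-based slice in the
      # non-centered parameterization, then an interweaving step drawing the
      # SD from its centered-parameterization conditional (which depends only
      # on u = sigma * z, not on the data) and rescaling z -- this breaks the
      # strong sigma-z coupling that otherwise stalls mixing near sigma = 0
      if (include_phylo && is.null(sigma_phylo_fixed)) {
        base <- fix + sg * zg[gidx]
        for (r in 1:4) { # the phylogenetic SD is the slowest direction
          sp <- .slice_pos(sp, function(s)
            -0.5 * (s / pri$sigma_sd)^2 + .bernoulli_loglik(y, base + s * vp))
          qf <- sp^2 * sum(zp^2)
          if (qf > 0) {
            sp_new <- .slice_pos(sp, function(s)
              if (s <= 0) -Inf else
                -n * log(s) - qf / (2 * s^2) - 0.5 * (s / pri$sigma_sd)^2,
              w = 0.3 * max(sp, 0.1))
            ratio <- sp / sp_new # keep u = sp * (L zp) fixed: rescale both
            zp <- zp * ratio
            vp <- vp * ratio
            sp <- sp_new
          }
          # partially centered scaling move: sigma -> sigma e^t,
          # z -> z e^(-t/2), so u scales by e^(t/2); Metropolis with the
          # exact Jacobian bridges the sigma-u funnel
          ll_old <- .bernoulli_loglik(y, base + sp * vp)
          for (rr in 1:3) {
            tstep <- stats::rnorm(1, 0, 0.4)
            sp_p <- sp * exp(tstep)
            scl <- exp(-tstep / 2)
            ll_new <- .bernoulli_loglik(y, base + sp_p * vp * scl)
            logr <- ll_new - ll_old +
              0.5 * sum(zp^2) * (1 - scl^2) +
              0.5 * ((sp / pri$sigma_sd)^2 - (sp_p / pri$sigma_sd)^2) +
              tstep * (1 - n / 2)
            if (is.finite(logr) && log(stats::runif(1)) < logr) {
              sp <- sp_p
              zp <- zp * scl
              vp <- vp * scl
              ll_old <- ll_new
            }
          }
        }
      }
      base <- fix + sp * vp
      vg <- zg[gidx]
      sg <- .slice_pos(sg, function(s)
        -0.5 * (s / pri$sigma_sd)^2 + .bernoulli_loglik(y, base + s * vg))
      qf <- sg^2 * sum(zg^2)
      if (qf > 0) {
        sg_new <- .slice_pos(sg, function(s)
          if (s <= 0) -Inf else
            -G * log(s) - qf / (2 * s^2) - 0.5 * (s / pri$sigma_sd)^2,
          w = 0.3 * max(sg, 0.1))
        zg <- zg * (sg / sg_new)
        sg <- sg_new
      }
      # exact recentering (Gibbs) between the intercept and each latent mean:
      # shifting alpha by delta and the latent effects by -delta leaves the
      # likelihood unchanged, so delta has a Gaussian full conditional under
      # the priors; this decorrelates alpha from the random-effect means
      if (include_phylo && sp > 0) {
        prec <- 1 / pri$alpha_sd^2 + wss / sp^2
        del <- stats::rnorm(1, (-ab[1] / pri$alpha_sd^2 + sum(w1 * zp) / sp) / prec,
                            1 / sqrt(prec))
        ab[1] <- ab[1] + del
        zp <- zp - (del / sp) * w1
        vp <- vp - del / sp
      }
      prec <- 1 / pri$alpha_sd^2 + G / sg^2
      del <- stats::rnorm(1, (-ab[1] / pri$alpha_sd^2 + sum(zg) / sg) / prec,
                          1 / sqrt(prec))
      ab[1] <- ab[1] + del
      zg <- zg - del / sg
      } # end scans
      if (it > warmup) {
        out[it - warmup, ] <- c(ab[1], ab[-1],
                                if (include_phylo) sp, sg,
                                sp * vp, sg * zg)
      }
    }
    draws[[ch]] <- out
  }
  fit <- structure(list(draws = draws, par_names = par_names,
                        model_kind = if (include_phylo) "PGLMM" else "GLMM",
                        chains = chains, iter = iter, warmup = warmup,
                        seed = seed, spec = spec),
                   class = "pglmm_fit")
  fit$diagnostics <- .fit_diagnostics(fit)
  if (check_convergence) {
    d <- fit$diagnostics
    if (any(d$rhat > 1.01, na.rm = TRUE) ||
        any(pmin(d$ess_bulk, d$ess_tail) < 400, na.rm = TRUE))
      stop("MCMC convergence contract not met (split R-hat > 1.01 or ",
           "ESS < 400); increase the budget or inspect the traces",
           call. = FALSE)
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_diagnostics <- function(fit) {
  mon <- fit$par_names
  d <- data.frame(parameter = mon,
                  rhat = NA_real_, ess_bulk = NA_real_, ess_tail = NA_real_)
  if (fit$chains >= 2) {
    for (i in seq_along(mon)) {
      m <- sapply(fit$draws, function(dd) dd[, mon[i]])
      d$rhat[i] <- split_rhat(m)
      d$ess_bulk[i] <- ess_bulk(m)
      d$ess_tail[i] <- ess_tail(m)
    }
  }
  d
}

#' Combined posterior draws of a fitted model
#' @param fit a `"pglmm_fit"`.
#' @param pars parameter names (defaults to all stored columns).
#' @return matrix of draws (all chains stacked) x parameters.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "pglmm_fit"))
  out <- do.call(rbind, fit$draws)
  if (!is.null(pars)) out <- out[, pars, drop = FALSE]
  out
}

#' Posterior summary table
#'
#' Mean, SD and central 80% and 95% intervals for the intercept, trait
#' coefficients and random-effect SDs.
#'
#' @param fit a `"pglmm_fit"`.
#' @return data frame, one row per monitored parameter.
#' @export
posterior_summary <- function(fit) {
  dr <- posterior_draws(fit, fit$par_names)
  data.frame(parameter = colnames(dr),
             mean = colMeans(dr),
             sd = apply(dr, 2, stats::sd),
             q10 = apply(dr, 2, stats::quantile, 0.10),
             q90 = apply(dr, 2, stats::quantile, 0.90),
             q2.5 = apply(dr, 2, stats::quantile, 0.025),
             q97.5 = apply(dr, 2, stats::quantile, 0.975),
             row.names = NULL)
}

#' @export
print.pglmm_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d chains x %d iterations (%d warmup)\n",
              x$model_kind, x$chains, x$iter, x$warmup))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Convergence report for a fitted model
#'
#' Rank-normalized split R-hat and bulk/tail effective sample sizes for every
#' monitored parameter, and an overall pass/fail against the contract
#' R-hat <= 1.01 and ESS >= 400.
#'
#' @param fit a `"pglmm_fit"` with at least two chains.
#' @return object of class `"convergence_report"`: `table`, `pass`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "pglmm_fit"))
  if (fit$chains < 2)
    stop("convergence diagnostics require at least two chains", call. = FALSE)
  d <- fit$diagnostics
  pass <- all(d$rhat <= 1.01, na.rm = TRUE) &&
    all(pmin(d$ess_bulk, d$ess_tail) >= 400, na.rm = TRUE)
  structure(list(table = d, pass = pass), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  print(x$table, digits = 4)
  cat(if (x$pass) "PASS" else "FAIL",
      ": contract is split R-hat <= 1.01 and bulk/tail ESS >= 400\n")
  invisible(x)
}

#' Variance decomposition and Nakagawa R-squared
#'
#' Per posterior draw, the fixed-effect variance is the variance over species
#' of the linear predictor \eqn{X\beta}; the phylogenetic and guild variances
#' are the squared random-effect SDs; the residual variance of the logit link
#' is the constant \eqn{\pi^2/3}. Marginal R-squared is the fixed-effect
#' share of the total, conditional R-squared adds the random-effect
#' variances, and per-component shares (which sum to 1 with the residual
#' share, per draw) quantify the relative contributions.
#'
#' @param fit a `"pglmm_fit"`.
#' @param spec the `"pglmm_spec"` used for the fit (defaults to the one
#'   stored in the fit).
#' @return object of class `"variance_decomposition"`: posterior mean and
#'   central 95% intervals of `R2_marginal`, `R2_conditional` and the
#'   component shares, plus the per-draw matrix.
#' @export
variance_decomposition <- function(fit, spec = fit$spec) {
  stopifnot(inherits(fit, "pglmm_fit"))
  X <- spec$X
  dr <- posterior_draws(fit)
  betas <- dr[, paste0("b_", colnames(X)), drop = FALSE]
  lin <- X %*% t(betas)
  var_fixed <- apply(lin, 2, stats::var)
  var_phylo <- if (fit$model_kind == "PGLMM") dr[, "sigma_phylo"]^2 else
    rep(0, nrow(dr))
  var_guild <- dr[, "sigma_guild"]^2
  var_resid <- pi^2 / 3
  denom <- var_fixed + var_phylo + var_guild + var_resid
  per_draw <- cbind(R2_marginal = var_fixed / denom,
                    R2_conditional = (var_fixed + var_phylo + var_guild) / denom,
                    share_fixed = var_fixed / denom,
                    share_phylo = var_phylo / denom,
                    share_guild = var_guild / denom,
                    share_resid = var_resid / denom)
  summ <- t(apply(per_draw, 2, function(v)
    c(mean = mean(v), lower = unname(stats::quantile(v, 0.025)),
      upper = unname(stats::quantile(v, 0.975)))))
  structure(list(summary = as.data.frame(summ), per_draw = per_draw,
                 var_resid = var_resid, model_kind = fit$model_kind),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("variance decomposition (", x$model_kind, "; logit residual variance ",
      sprintf("%.4f", x$var_resid), ")\n", sep = "")
  print(round(x$summary, 3))
  invisible(x)
}
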