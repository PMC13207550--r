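#' Simulate a pure-birth (Yule) tree scaled to unit height
#'
#' Stand-in for a dated molecular phylogeny: a pure-birth tree with `n_tips`
#' tips, rescaled so the root-to-tip depth is exactly 1, with tips labeled
#' `sp0001`, `sp0002`, ... in the tree's cladewise order. Deterministic given
#' the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return an ultrametric `"phylo"` object of height 1.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("'n_tips' must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / tree_height(tree)
  tree$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tree
}

# split 1..n into k contiguous blocks with random sizes >= 1
.contiguous_blocks <- function(n, k) {
  if (k > n) stop("more blocks than items", call. = FALSE)
  sizes <- as.vector(stats::rmultinom(1, n - k, rep(1 / k, k))) + 1L
  rep(seq_len(k), sizes)
}

# tips in cladewise order so contiguous blocks approximate clades
.cladewise_tips <- function(tree) {
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  e[e[, 2] <= length(tree$tip.label), 2]
}

#' Simulate a nested taxonomy over the tips of a tree
#'
#' Orders, families and genera are assigned as contiguous blocks of tips in
#' cladewise order, so taxonomic groups correspond to clades, mimicking real
#' classifications.
#'
#' @param tree a `"phylo"` object.
#' @param n_orders number of orders.
#' @param families_per_order,genera_per_family average nesting factors.
#' @param seed integer RNG seed.
#' @return taxonomy data frame (species, genus, family, order).
#' @export
simulate_taxonomy <- function(tree, n_orders = 7, families_per_order = 3,
                              genera_per_family = 3, seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  ord_tips <- .cladewise_tips(tree)
  ords <- .contiguous_blocks(n, n_orders)
  fam <- gen <- integer(n)
  nf <- 0L; ng <- 0L
  for (o in seq_len(n_orders)) {
    ix <- which(ords == o)
    kf <- max(1L, min(length(ix), stats::rpois(1, families_per_order - 1) + 1L))
    fb <- .contiguous_blocks(length(ix), kf)
    fam[ix] <- nf + fb
    for (f in seq_len(kf)) {
      jx <- ix[fb == f]
      kg <- max(1L, min(length(jx), stats::rpois(1, genera_per_family - 1) + 1L))
      gen[jx] <- ng + .contiguous_blocks(length(jx), kg)
      ng <- ng + kg
    }
    nf <- nf + kf
  }
  out <- data.frame(species = tree$tip.label[ord_tips],
                    genus = sprintf("gen%03d", gen),
                    family = sprintf("fam%03d", fam),
                    order = sprintf("ord%02d", ords),
                    stringsAsFactors = FALSE)
  out[match(tree$tip.label, out$species), , drop = FALSE]
}

#' Assign feeding guilds as clade blocks
#'
#' Guilds are contiguous blocks of tips in cladewise order, reflecting the
#' taxonomic clustering of feeding strategies in real assemblages.
#'
#' @param tree a `"phylo"` object.
#' @param n_guilds number of guilds.
#' @param seed integer RNG seed.
#' @return named factor of guild labels, one per tip.
#' @export
assign_guilds <- function(tree, n_guilds = 7, seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  blocks <- .contiguous_blocks(n, n_guilds)
  g <- character(n)
  g[.cladewise_tips(tree)] <- sprintf("guild%d", blocks)
  stats::setNames(factor(g), tree$tip.label)
}

#' Simulate correlated continuous traits on a tree
#'
#' Draws `vec(Y)` from `Normal(mu, R %x% C_model)` where `R` is the
#' across-trait covariance and `C_model` the transformed phylogenetic
#' covariance, via the Kronecker-factored Cholesky `Y = L_C Z L_R'`.
#' Returned traits are on the (log) scale of the model.
#'
#' @param tree a `"phylo"` object.
#' @param R trait covariance matrix (p x p).
#' @param model,transform_param passed to [transform_covariance()].
#' @param mu per-trait means (recycled).
#' @param seed integer RNG seed.
#' @return species x traits matrix with tip labels as rownames.
#' @export
simulate_traits <- function(tree, R, model = "BM", transform_param = NULL,
                            mu = 0, seed = 1) {
  set.seed(seed)
  R <- as.matrix(R)
  p <- ncol(R)
  C <- transform_covariance(phylo_vcv(tree), model, transform_param)
  n <- nrow(C)
  Lc <- t(.chol_safe(C, jitter = 1e-12, what = "species covariance"))
  Lr <- t(.chol_safe(R, what = "trait covariance"))
  Y <- Lc %*% matrix(stats::rnorm(n * p), n, p) %*% t(Lr)
  Y <- sweep(Y, 2, rep_len(mu, p), "+")
  rownames(Y) <- tree$tip.label
  colnames(Y) <- colnames(R) %||% paste0("trait", seq_len(p))
  Y
}

#' Simulate a binary trait under the Brownian threshold model
#'
#' A Brownian liability evolves on the tree; the species with the top
#' `round(prevalence * n)` liabilities are coded 1 (so a 29.5% target on 129
#' species gives exactly 38 ones). This is the generating model under which
#' Fritz-Purvis D is calibrated to 0.
#'
#' @param tree a `"phylo"` object.
#' @param prevalence fraction of species coded 1, in (0, 1).
#' @param seed integer RNG seed.
#' @return named 0/1 vector over the tips.
#' @export
simulate_binary_threshold <- function(tree, prevalence, seed = 1) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must be in (0, 1)", call. = FALSE)
  lia <- simulate_traits(tree, matrix(1), "BM", seed = seed)[, 1]
  k <- max(1L, round(prevalence * length(lia)))
  y <- as.numeric(rank(-lia, ties.method = "first") <= k)
  stats::setNames(y, tree$tip.label)
}

#' Simulate invasion outcomes from the phylogenetic Bernoulli mixed model
#'
#' Samples `u_phylo ~ Normal(0, sigma_phylo^2 A)` (with `A` the standardized
#' phylogenetic covariance of `tree`), guild intercepts
#' `u_guild ~ Normal(0, sigma_guild^2)`, and
#' `y_j ~ Bernoulli(plogis(alpha + X_j beta + u_phylo_j + u_guild_g(j)))`.
#' When `alpha` is `NULL` and `target_prevalence` is given, the intercept is
#' calibrated by bisection so the mean success probability over the realized
#' linear predictors matches the target.
#'
#' @param X design matrix (standardized predictors).
#' @param guild factor of guild membership.
#' @param beta coefficient vector (length `ncol(X)`).
#' @param sigma_phylo,sigma_guild random-effect SDs.
#' @param tree the phylogeny (for `A`).
#' @param seed integer RNG seed.
#' @param alpha intercept; if `NULL`, calibrated to `target_prevalence`.
#' @param target_prevalence desired mean success probability.
#' @return list with `y`, `alpha`, `prob`, `u_phylo`, `u_guild`.
#' @export
simulate_invasion <- function(X, guild, beta, sigma_phylo, sigma_guild, tree,
                              seed = 1, alpha = NULL,
                              target_prevalence = NULL) {
  X <- as.matrix(X)
  stopifnot(length(beta) == ncol(X))
  set.seed(seed)
  A <- phylo_vcv(tree, standardize = TRUE)
  n <- nrow(A)
  if (nrow(X) != n) stop("X rows must match tree tips", call. = FALSE)
  guild <- factor(guild)
  L <- t(.chol_safe(A, jitter = 1e-10))
  u_p <- sigma_phylo * drop(L %*% stats::rnorm(n))
  u_g <- stats::setNames(stats::rnorm(nlevels(guild), 0, sigma_guild),
                         levels(guild))
  lp <- drop(X %*% beta) + u_p + u_g[as.integer(guild)]
  if (is.null(alpha)) {
    if (is.null(target_prevalence))
      stop("give 'alpha' or 'target_prevalence'", call. = FALSE)
    f <- function(a) mean(stats::plogis(a + lp)) - target_prevalence
    alpha <- stats::uniroot(f, c(-20, 20), tol = 1e-8)$root
  }
  prob <- stats::plogis(alpha + lp)
  y <- stats::setNames(stats::rbinom(n, 1, prob), rownames(X) %||% tree$tip.label)
  list(y = y, alpha = alpha, prob = prob, u_phylo = u_p, u_guild = u_g)
}

#' Mask trait cells completely at random
#'
#' Applies an MCAR mask at the given rate over the cells of `Y`, guaranteeing
#' at least 5 observed species per trait (cells are unmasked at random, with
#' the same seed stream, if a trait would fall below).
#'
#' @param Y numeric matrix.
#' @param rate masking rate in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @return `Y` with masked cells set to `NA`.
#' @export
apply_missingness <- function(Y, rate, seed = 1) {
  Y <- as.matrix(Y)
  if (rate < 0 || rate > 0.5)
    stop("'rate' must be in [0, 0.5]", call. = FALSE)
  if (nrow(Y) < 5)
    stop("fewer than 5 species; cannot guarantee 5 observed per trait",
         call. = FALSE)
  if (rate == 0) return(Y)
  set.seed(seed)
  mask <- matrix(stats::runif(length(Y)) < rate, nrow(Y), ncol(Y))
  for (j in seq_len(ncol(Y))) {
    excess <- sum(!mask[, j]) - 5L
    if (excess < 0) {
      fix <- sample(which(mask[, j]), -excess)
      mask[fix, j] <- FALSE
    }
  }
  Y[mask] <- NA_real_
  Y
}

#' Default across-trait covariance of the synthetic assemblage
#'
#' Log-scale covariance for the seven continuous life-history traits: unit
#' variances scaled to 0.5, a mild exchangeable correlation of 0.2, and a
#' strong 0.8 correlation between age at maturity and lifespan (two traits
#' that are tightly linked in real life histories).
#'
#' @return a 7 x 7 positive-definite matrix with trait names.
#' @export
default_trait_covariance <- function() {
  traits <- c("body_length", "fecundity", "host_number", "voltinism",
              "age_maturity", "lifespan", "migration_distance")
  R <- matrix(0.2, 7, 7, dimnames = list(traits, traits))
  diag(R) <- 1
  R["age_maturity", "lifespan"] <- R["lifespan", "age_maturity"] <- 0.8
  0.5 * R
}

#' Simulate a complete synthetic study bundle
#'
#' One-stop generator reproducing the statistical structure the pipeline
#' assumes: a unit-height Yule tree, a nested taxonomy, clade-structured
#' feeding guilds, seven correlated log-scale continuous traits with strong
#' phylogenetic signal (Pagel's lambda transform), three categorical traits
#' obtained by thresholding Brownian liabilities, invasion outcomes drawn
#' from the phylogenetic Bernoulli mixed model with the intercept calibrated
#' to the target prevalence, and MCAR missingness in the continuous traits.
#'
#' @param n_species,n_orders,n_guilds assemblage dimensions.
#' @param prevalence target invasive fraction.
#' @param missing_rate MCAR rate over continuous trait cells.
#' @param categorical_missing_rate MCAR rate over categorical cells (default
#'   0; the taxonomic backfill stage is exercised when positive).
#' @param trait_lambda Pagel's lambda of the generating trait model.
#' @param beta named coefficients on the standardized continuous traits
#'   (names must match the trait columns; omitted traits get 0).
#' @param sigma_phylo,sigma_guild generative random-effect SDs.
#' @param seed integer RNG seed; all internal seeds derive from it.
#' @return list with `tree`, `taxonomy`, `guild`, `traits` (a
#'   [trait_table()] with missing cells), `invasion`, and `truth` (complete
#'   traits, generative parameters and latent effects).
#' @export
simulate_study <- function(n_species = 129, n_orders = 7, n_guilds = 7,
                           prevalence = 0.295, missing_rate = 0.0908,
                           categorical_missing_rate = 0,
                           trait_lambda = 0.9,
                           beta = c(fecundity = 1, host_number = 0.3,
                                    body_length = -0.3,
                                    migration_distance = -0.2),
                           sigma_phylo = 1.5, sigma_guild = 0.5, seed = 1) {
  tree <- simulate_yule_tree(n_species, seed)
  taxonomy <- simulate_taxonomy(tree, n_orders, seed = seed + 1)
  guild <- assign_guilds(tree, n_guilds, seed = seed + 2)
  R <- default_trait_covariance()
  Y <- simulate_traits(tree, R, "lambda", trait_lambda,
                       mu = c(1.5, 4, 1, 0.5, 3, 3.5, 1), seed = seed + 3)
  # categorical traits: thresholded Brownian liabilities, conserved on the tree
  set.seed(seed + 4)
  lia <- simulate_traits(tree, diag(3), "BM", seed = seed + 4)
  cut3 <- stats::quantile(lia[, 1], c(0.45, 0.8))
  categorical <- data.frame(
    oviposition_substrate = c("leaf", "stem", "soil")[
      1 + (lia[, 1] > cut3[1]) + (lia[, 1] > cut3[2])],
    reproductive_mode = ifelse(lia[, 2] > stats::quantile(lia[, 2], 0.6),
                               "asexual", "sexual"),
    habitat_type = ifelse(lia[, 3] > stats::median(lia[, 3]),
                          "aquatic", "terrestrial"),
    stringsAsFactors = FALSE)
  rownames(categorical) <- tree$tip.label
  b <- stats::setNames(numeric(ncol(Y)), colnames(Y))
  bad <- setdiff(names(beta), names(b))
  if (length(bad)) stop("unknown traits in 'beta': ",
                        paste(bad, collapse = ", "), call. = FALSE)
  b[names(beta)] <- beta
  inv <- simulate_invasion(scale(Y), guild, b, sigma_phylo, sigma_guild,
                           tree, seed = seed + 5,
                           target_prevalence = prevalence)
  Ymiss <- apply_missingness(Y, missing_rate, seed = seed + 6)
  cat_miss <- categorical
  if (categorical_missing_rate > 0) {
    set.seed(seed + 7)
    for (j in seq_len(ncol(cat_miss))) {
      drop_ix <- which(stats::runif(n_species) < categorical_missing_rate)
      drop_ix <- drop_ix[seq_len(min(length(drop_ix), n_species - 5L))]
      cat_miss[drop_ix, j] <- NA_character_
    }
  }
  traits <- trait_table(tree$tip.label, Ymiss, cat_miss, log_scale = TRUE)
  list(tree = tree, taxonomy = taxonomy, guild = guild, traits = traits,
       invasion = inv$y,
       truth = list(continuous = Y, categorical = categorical, beta = b,
                    alpha = inv$alpha, sigma_phylo = sigma_phylo,
                    sigma_guild = sigma_guild, trait_lambda = trait_lambda,
                    u_phylo = inv$u_phylo, u_guild = inv$u_guild,
                    prob = inv$prob))
}
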