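#' Composition summary by family, order and guild
#'
#' Species counts, invasive counts, within-group invasion proportions and
#' each group's share of all invasive species, at the family, order and
#' feeding-guild levels, plus the overall prevalence. Groups with no species
#' (unused factor levels) are retained with `NaN` proportions.
#'
#' @param metadata data frame with columns `species`, `guild`, `invasive`
#'   (0/1).
#' @param taxonomy taxonomy data frame (see [read_taxonomy()]).
#' @return object of class `"composition_summary"`: data frames `family`,
#'   `order`, `guild`, and `overall` (n, n_invasive, prevalence).
#' @export
summarize_composition <- function(metadata, taxonomy) {
  need <- c("species", "guild", "invasive")
  if (!all(need %in% names(metadata)))
    stop("'metadata' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  taxonomy <- .check_taxonomy(taxonomy)
  ix <- match(metadata$species, taxonomy$species)
  if (anyNA(ix)) stop("taxonomy does not cover all species", call. = FALSE)
  inv <- as.numeric(metadata$invasive)
  if (!all(inv %in% c(0, 1))) stop("'invasive' must be 0/1", call. = FALSE)
  n_inv_total <- sum(inv)
  one_level <- function(g) {
    g <- if (is.factor(g)) g else factor(g)
    n <- as.vector(table(g))
    ni <- as.vector(tapply(inv, g, sum, default = 0))
    data.frame(group = levels(g), n = n, n_invasive = ni,
               prop_invasive = ni / n,
               share_of_invasive = if (n_inv_total > 0) ni / n_inv_total
               else rep(NaN, length(n)))
  }
  structure(list(family = one_level(taxonomy$family[ix]),
                 order = one_level(taxonomy$order[ix]),
                 guild = one_level(metadata$guild),
                 overall = data.frame(n = length(inv), n_invasive = n_inv_total,
                                      prevalence = mean(inv))),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("%d species, %d invasive (prevalence %.1f%%)\n",
              x$overall$n, x$overall$n_invasive, 100 * x$overall$prevalence))
  cat("\nby order:\n"); print(x$order, digits = 3)
  cat("\nby guild:\n"); print(x$guild, digits = 3)
  invisible(x)
}

.log_stage <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [pestphylo] ", ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full comparative pipeline
#'
#' Orchestrates the analysis end to end: load (or accept in-memory) data,
#' graft species without phylogenetic data, backfill categorical traits,
#' log-transform if needed, compute phylogenetic signal for every trait and
#' for invasion status, compare trait-evolution models and impute missing
#' continuous traits, screen collinearity, fit the Bayesian PGLMM and its
#' non-phylogenetic GLMM counterpart with convergence checks and variance
#' decomposition, run the Laplace GLMM with hierarchical partitioning, and
#' summarize assemblage composition. Each stage can be toggled; all outputs
#' are returned and, when `outdir` is set, also written as delimited text and
#' JSON.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{data}{either a bundle as returned by [simulate_study()] (fields
#'       `tree`, `traits`, `taxonomy`, `guild`, `invasion`), or a `paths`
#'       list with files `tree` (Newick), `traits` (TSV; requires
#'       `continuous` and `categorical` name vectors), `taxonomy` (TSV) and
#'       `metadata` (TSV with species, guild, invasive).}
#'     \item{stages}{logical toggles `graft`, `backfill`, `signal`,
#'       `impute`, `screen`, `fit`, `hpart`, `composition` (all default
#'       TRUE except `hpart`).}
#'     \item{signal}{`n_perm` (999), `n_sim` (1000), `seed` (1).}
#'     \item{impute}{`models` (default all four).}
#'     \item{mcmc}{`chains`, `iter`, `warmup`, `seed`; `include_phylogeny`
#'       toggle (TRUE).}
#'     \item{vif_threshold}{default 5.}
#'     \item{outdir}{optional output directory.}
#'   }
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- utils::modifyList(list(graft = TRUE, backfill = TRUE,
                                   signal = TRUE, impute = TRUE,
                                   screen = TRUE, fit = TRUE, hpart = FALSE,
                                   composition = TRUE),
                              config$stages %||% list())
  sigcfg <- utils::modifyList(list(n_perm = 999, n_sim = 1000, seed = 1),
                              config$signal %||% list())
  impcfg <- utils::modifyList(list(models = c("BM", "lambda", "OU", "EB")),
                              config$impute %||% list())
  mccfg <- utils::modifyList(list(chains = 4, iter = 6000, warmup = 4000,
                                  seed = 1, include_phylogeny = TRUE,
                                  check_convergence = FALSE),
                             config$mcmc %||% list())
  outdir <- config$outdir
  logfile <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(outdir, "pipeline.log")
  }
  res <- list(config = config)
  stage <- function(name, expr) {
    .log_stage(logfile, "stage: ", name)
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) .write_outputs(res, outdir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- load ----------------------------------------------------------------
  dat <- stage("load", {
    d <- config$data
    if (!is.null(d$paths)) {
      p <- d$paths
      md <- utils::read.table(p$metadata, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      list(tree = read_newick(file = p$tree),
           traits = read_trait_table(p$traits, d$continuous,
                                     d$categorical %||% character(0),
                                     log_scale = isTRUE(d$log_scale)),
           taxonomy = read_taxonomy(p$taxonomy),
           guild = stats::setNames(factor(md$guild), md$species),
           invasion = stats::setNames(md$invasive, md$species))
    } else {
      list(tree = d$tree, traits = d$traits, taxonomy = d$taxonomy,
           guild = d$guild, invasion = d$invasion)
    }
  })
  tree <- dat$tree; traits <- dat$traits

  if (stages$graft) {
    res$grafted <- stage("graft", {
      missing <- setdiff(traits$species, tree$tip.label)
      if (length(missing))
        tree <- graft_missing_species(tree, dat$taxonomy, missing)
      missing
    })
  }
  ord <- match(tree$tip.label, traits$species)
  if (anyNA(ord)) stop("tree tips without trait rows", call. = FALSE)

  if (stages$backfill && !is.null(traits$categorical)) {
    traits <- stage("backfill", backfill_categorical(traits, dat$taxonomy))
    res$backfill_provenance <- traits$provenance
    # cells with no observed genus- or family-level relative fall back to the
    # assemblage-wide modal level so the modeling stages see complete data
    if (anyNA(traits$categorical)) {
      for (j in names(traits$categorical)) {
        nas <- is.na(traits$categorical[[j]])
        if (any(nas))
          traits$categorical[nas, j] <- .lex_mode(traits$categorical[[j]])$value
      }
      res$backfill_global <- attr(res$backfill_provenance, "unfilled")
    }
  }
  if (!any(traits$log_scale))
    traits <- stage("log-transform", log_transform_traits(traits))

  y <- as.numeric(dat$invasion[tree$tip.label])
  guild <- dat$guild[tree$tip.label]

  if (stages$signal) {
    res$signal <- stage("signal", {
      rows <- list()
      for (j in colnames(traits$continuous)) {
        x <- traits$continuous[tree$tip.label, j]
        sub <- ape::keep.tip(tree, names(x)[!is.na(x)])
        s <- signal_continuous(sub, x[!is.na(x)], n_perm = sigcfg$n_perm,
                               seed = sigcfg$seed)
        rows[[length(rows) + 1]] <- data.frame(
          trait = j, statistic = c("K", "lambda"),
          value = c(s$K, s$lambda), pBrownian = NA,
          pRandom = c(s$p_random_K, s$p_random_lambda))
      }
      cats <- if (!is.null(traits$categorical))
        c(as.list(traits$categorical), list(invasion_status = y)) else
          list(invasion_status = y)
      for (j in names(cats)) {
        v <- cats[[j]]
        yy <- if (is.numeric(v)) stats::setNames(v, traits$species) else
          binarize_vs_modal(stats::setNames(v, traits$species))
        yy <- yy[tree$tip.label]
        yy <- yy[!is.na(yy)] # cells that stayed unfilled are dropped
        d <- fritz_purvis_d(ape::keep.tip(tree, names(yy)), yy,
                            n_sim = sigcfg$n_sim, seed = sigcfg$seed)
        rows[[length(rows) + 1]] <- data.frame(
          trait = j, statistic = "D", value = d$D,
          pBrownian = d$p_brownian, pRandom = d$p_random)
      }
      do.call(rbind, rows)
    })
  }

  completed <- traits$continuous[tree$tip.label, , drop = FALSE]
  if (stages$impute && anyNA(completed)) {
    res$model_comparison <- stage("impute", {
      cmp <- compare_evomodels(tree, completed, impcfg$models)
      res$imputed <- impute_missing(cmp$best, tree, completed)
      cmp$table
    })
    completed <- res$imputed$completed
  }

  if (stages$screen) {
    res$screen <- stage("screen", {
      tt <- trait_table(tree$tip.label, completed,
                        traits$categorical[tree$tip.label, , drop = FALSE],
                        log_scale = TRUE)
      collinearity_screen(tt, threshold = config$vif_threshold %||% 5)
    })
  }

  spec <- build_design(completed,
                       traits$categorical[tree$tip.label, , drop = FALSE],
                       guild, y, phylo_vcv(tree, standardize = TRUE),
                       mcmc = mccfg[c("chains", "iter", "warmup", "seed")])
  res$design <- spec
  if (stages$fit) {
    stage("fit", {
      if (isTRUE(mccfg$include_phylogeny)) {
        res$pglmm <- fit_bernoulli_mixed(
          spec, include_phylo = TRUE,
          check_convergence = isTRUE(mccfg$check_convergence))
      }
      res$glmm <- fit_bernoulli_mixed(
        spec, include_phylo = FALSE,
        check_convergence = isTRUE(mccfg$check_convergence))
    })
    res$convergence <- stage("convergence", {
      lapply(Filter(Negate(is.null), res[c("pglmm", "glmm")]),
             convergence_report)
    })
    res$variance <- stage("variance-decomposition", {
      lapply(Filter(Negate(is.null), res[c("pglmm", "glmm")]),
             variance_decomposition)
    })
  }

  if (stages$hpart) {
    res$hpart <- stage("hierarchical-partitioning", {
      blocks <- .trait_blocks(spec$X, colnames(traits$continuous),
                              names(traits$categorical))
      hierarchical_partition(blocks, spec$X, y, guild)
    })
  }

  if (stages$composition) {
    res$composition <- stage("composition", {
      summarize_composition(
        data.frame(species = tree$tip.label, guild = guild, invasive = y),
        dat$taxonomy)
    })
  }

  if (!is.null(outdir)) .write_outputs(res, outdir)
  .log_stage(logfile, "done")
  invisible(res)
}

# group design-matrix columns into per-trait blocks (dummies together)
.trait_blocks <- function(X, continuous, categorical) {
  blocks <- lapply(continuous, function(j) which(colnames(X) == j))
  names(blocks) <- continuous
  for (j in categorical %||% character(0))
    blocks[[j]] <- grep(paste0("^", j, "\\."), colnames(X))
  Filter(length, blocks)
}

.write_outputs <- function(res, outdir) {
  w <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$signal)) w(res$signal, "signal_table.tsv")
  if (!is.null(res$model_comparison)) {
    w(res$model_comparison, "model_comparison.tsv")
    jsonlite::write_json(res$model_comparison,
                         file.path(outdir, "model_comparison.json"),
                         dataframe = "rows", digits = NA)
  }
  if (!is.null(res$pglmm)) w(posterior_summary(res$pglmm), "pglmm_coefficients.tsv")
  if (!is.null(res$glmm)) w(posterior_summary(res$glmm), "glmm_coefficients.tsv")
  if (!is.null(res$variance)) {
    for (m in names(res$variance)) {
      v <- res$variance[[m]]$summary
      w(cbind(component = rownames(v), v), paste0(m, "_variance.tsv"))
    }
  }
  if (!is.null(res$hpart)) w(res$hpart$table, "hierarchical_partitioning.tsv")
  if (!is.null(res$composition)) {
    for (lev in c("family", "order", "guild"))
      w(res$composition[[lev]], paste0("composition_", lev, ".tsv"))
  }
  invisible(outdir)
}
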