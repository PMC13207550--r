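#' Construct a species-by-trait table
#'
#' Container for the trait data consumed by the pipeline: a matrix of
#' continuous traits (missing cells as `NA`), a data frame of categorical
#' traits, and per-trait flags recording whether the continuous traits are on
#' the natural-log scale.
#'
#' @param species character vector of unique species identifiers.
#' @param continuous numeric matrix (species x traits) with `NA` for missing
#'   cells; column names are trait names.
#' @param categorical data frame of categorical traits (character or factor
#'   columns, `NA` for missing), or `NULL`.
#' @param log_scale logical vector, one per continuous trait: is the column
#'   already natural-log transformed?
#' @return an object of class `"trait_table"`.
#' @export
trait_table <- function(species, continuous, categorical = NULL,
                        log_scale = FALSE) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicated species", call. = FALSE)
  continuous <- as.matrix(continuous)
  storage.mode(continuous) <- "double"
  if (nrow(continuous) != length(species))
    stop("'continuous' must have one row per species", call. = FALSE)
  if (is.null(colnames(continuous)))
    colnames(continuous) <- paste0("trait", seq_len(ncol(continuous)))
  rownames(continuous) <- species
  if (any(is.infinite(continuous)))
    stop("continuous traits must be finite where observed", call. = FALSE)
  if (!is.null(categorical)) {
    categorical <- as.data.frame(categorical, stringsAsFactors = FALSE)
    if (nrow(categorical) != length(species))
      stop("'categorical' must have one row per species", call. = FALSE)
    categorical[] <- lapply(categorical, as.character)
    rownames(categorical) <- species
  }
  log_scale <- rep_len(log_scale, ncol(continuous))
  names(log_scale) <- colnames(continuous)
  structure(list(species = species, continuous = continuous,
                 categorical = categorical, log_scale = log_scale,
                 provenance = NULL),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", length(x$species), "species,",
      ncol(x$continuous), "continuous trait(s)",
      if (!is.null(x$categorical)) paste0(", ", ncol(x$categorical),
                                          " categorical trait(s)"), "\n")
  ms <- missingness_summary(x)
  cat(sprintf("overall missingness: %.1f%%\n", 100 * ms$overall))
  invisible(x)
}

#' Read a trait table from delimited text
#'
#' Expects a header row with a `species` column; remaining columns are split
#' into continuous and categorical traits by name. Missing cells may be empty
#' or `NA`.
#'
#' @param file path to a delimited file.
#' @param continuous character vector of continuous trait column names.
#' @param categorical character vector of categorical trait column names.
#' @param sep field separator.
#' @param log_scale are the continuous columns already log-transformed?
#' @return a [trait_table()].
#' @export
read_trait_table <- function(file, continuous, categorical = character(0),
                             sep = "\t", log_scale = FALSE) {
  df <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          fileEncoding = "UTF-8")
  miss <- setdiff(c("species", continuous, categorical), names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  trait_table(df$species, as.matrix(df[continuous]),
              if (length(categorical)) df[categorical] else NULL,
              log_scale = log_scale)
}

#' Write a trait table as delimited text
#' @param table a [trait_table()].
#' @param file output path.
#' @param sep field separator.
#' @export
write_trait_table <- function(table, file, sep = "\t") {
  df <- data.frame(species = table$species, table$continuous,
                   check.names = FALSE)
  if (!is.null(table$categorical)) df <- cbind(df, table$categorical)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(file)
}

#' Natural-log transform the continuous traits
#'
#' Observed values must be non-negative; zeros (possible for semi-quantitative
#' traits such as migration distance) are shifted as `log(x + delta)` with a
#' per-trait offset defaulting to half the smallest positive observed value of
#' that trait. Missing cells are untouched.
#'
#' @param table a [trait_table()].
#' @param delta optional named numeric vector of per-trait offsets; traits
#'   without zeros ignore the offset.
#' @return the table with log-scale continuous traits and `log_scale` flags set.
#' @export
log_transform_traits <- function(table, delta = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (any(table$log_scale))
    stop("continuous traits are already log-transformed", call. = FALSE)
  Y <- table$continuous
  for (j in colnames(Y)) {
    x <- Y[, j]
    obs <- !is.na(x)
    if (any(x[obs] < 0)) {
      bad <- table$species[obs & x < 0][1]
      stop("negative value of trait '", j, "' for species '", bad,
           "'; cannot log-transform", call. = FALSE)
    }
    if (any(x[obs] == 0)) {
      d <- if (!is.null(delta) && j %in% names(delta)) delta[[j]] else {
        pos <- x[obs & x > 0]
        if (!length(pos)) stop("trait '", j, "' is all zero", call. = FALSE)
        min(pos) / 2
      }
      x[obs] <- x[obs] + d
    }
    Y[obs, j] <- log(x[obs])
  }
  table$continuous <- Y
  table$log_scale[] <- TRUE
  table
}

#' Backfill missing categorical traits from taxonomic relatives
#'
#' Each missing categorical cell is filled with the modal value among observed
#' congeners; if no congener is observed, with the modal value among
#' confamilials; otherwise it stays missing and is reported. Ties are broken
#' by taking the lexicographically first level and flagged. Observed cells are
#' never altered. A provenance label per cell (`observed`, `genus`, `family`,
#' `unfilled`) is stored in the returned table's `provenance` field.
#'
#' @param table a [trait_table()] with categorical traits.
#' @param taxonomy taxonomy data frame covering all species (see
#'   [read_taxonomy()]).
#' @return the table with filled categorical cells; attributes `"ties"` and
#'   `"unfilled"` on the `provenance` matrix list flagged cells.
#' @export
backfill_categorical <- function(table, taxonomy) {
  stopifnot(inherits(table, "trait_table"))
  if (is.null(table$categorical))
    stop("table has no categorical traits", call. = FALSE)
  taxonomy <- .check_taxonomy(taxonomy)
  idx <- match(table$species, taxonomy$species)
  if (anyNA(idx))
    stop("taxonomy does not cover all species", call. = FALSE)
  gen <- taxonomy$genus[idx]
  fam <- taxonomy$family[idx]
  cat_df <- table$categorical
  prov <- matrix("observed", nrow(cat_df), ncol(cat_df),
                 dimnames = list(table$species, names(cat_df)))
  ties <- character(0); unfilled <- character(0)
  for (j in names(cat_df)) {
    x <- cat_df[[j]]
    for (i in which(is.na(x))) {
      filled <- FALSE
      for (lev in c("genus", "family")) {
        grp <- if (lev == "genus") gen == gen[i] else fam == fam[i]
        m <- .lex_mode(x[grp & seq_along(x) != i])
        if (!is.na(m$value)) {
          cat_df[i, j] <- m$value
          prov[i, j] <- lev
          if (m$tie) ties <- c(ties, paste0(table$species[i], ":", j))
          filled <- TRUE
          break
        }
      }
      if (!filled) {
        prov[i, j] <- "unfilled"
        unfilled <- c(unfilled, paste0(table$species[i], ":", j))
      }
    }
  }
  attr(prov, "ties") <- ties
  attr(prov, "unfilled") <- unfilled
  table$categorical <- cat_df
  table$provenance <- prov
  table
}

#' Per-trait and overall missingness fractions
#'
#' The overall fraction counts missing cells over all traits, continuous and
#' categorical alike, so it equals the cell-count-weighted mean of the
#' per-trait fractions.
#'
#' @param table a [trait_table()].
#' @return list with `per_trait` (named fractions) and `overall`.
#' @export
missingness_summary <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  cells <- cbind(is.na(table$continuous),
                 if (!is.null(table$categorical))
                   vapply(table$categorical, is.na,
                          logical(length(table$species))))
  per <- colMeans(cells)
  list(per_trait = per, overall = mean(cells),
       n_missing = colSums(cells), n_species = length(table$species))
}

#' Collinearity screen: Spearman correlations and variance inflation factors
#'
#' Computes the pairwise Spearman rank-correlation matrix (average ranks for
#' ties) among predictors and, for each predictor, the variance inflation
#' factor \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} comes from an
#' ordinary least-squares regression of predictor j on all others. Predictors
#' with VIF below the threshold are retained.
#'
#' @param table a [trait_table()] with complete continuous traits
#'   (post-imputation), or a numeric design matrix.
#' @param dummy_code include categorical traits, dummy-coded against the
#'   lexicographically first level? Only used when `table` is a trait table.
#' @param threshold VIF retention threshold (default 5).
#' @return list of class `"screen_report"`: `spearman`, `vif`, `retained`,
#'   `threshold`.
#' @export
collinearity_screen <- function(table, dummy_code = TRUE, threshold = 5) {
  if (inherits(table, "trait_table")) {
    X <- table$continuous
    if (anyNA(X))
      stop("continuous traits must be complete (impute first)", call. = FALSE)
    if (dummy_code && !is.null(table$categorical)) {
      if (anyNA(table$categorical))
        stop("categorical traits must be complete (backfill first)",
             call. = FALSE)
      X <- cbind(X, .dummy_code(table$categorical))
    }
  } else {
    X <- as.matrix(table)
    if (anyNA(X)) stop("design matrix must be complete", call. = FALSE)
  }
  k <- ncol(X)
  sp <- suppressWarnings(stats::cor(X, method = "spearman")) # constant
  # columns yield NA correlations and are reported through the VIF warning
  vif <- setNames(numeric(k), colnames(X))
  for (j in seq_len(k)) {
    xj <- X[, j]
    if (stats::var(xj) == 0) {
      warning("constant predictor '", colnames(X)[j], "': VIF is infinite",
              call. = FALSE)
      vif[j] <- Inf
      next
    }
    if (k == 1L) { vif[j] <- 1; next }
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), xj)
    r2 <- 1 - sum(fit$residuals^2) / sum((xj - mean(xj))^2)
    vif[j] <- 1 / max(1 - r2, .Machine$double.eps)
  }
  structure(list(spearman = sp, vif = vif,
                 retained = colnames(X)[vif < threshold],
                 threshold = threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("collinearity screen (VIF threshold", x$threshold, ")\n")
  print(round(x$vif, 2))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

# dummy-code a data frame of categorical traits against the lexicographically
# first level of each; column names <trait>.<level>
.dummy_code <- function(categorical) {
  cols <- lapply(names(categorical), function(j) {
    levs <- sort(unique(categorical[[j]]))
    if (length(levs) < 2L) return(NULL)
    m <- vapply(levs[-1], function(l) as.numeric(categorical[[j]] == l),
                numeric(nrow(categorical)))
    colnames(m) <- paste0(j, ".", levs[-1])
    m
  })
  do.call(cbind, cols)
}
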