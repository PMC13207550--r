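#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ordinary `"phylo"` object; polytomies are retained (see
#' [resolve_polytomies()]) and every non-root edge must carry a branch length.
#'
#' @param text Newick string (terminated by `;`). Exactly one of `text` and
#'   `file` must be given.
#' @param file path to a Newick file.
#' @return an object of class `"phylo"` with branch lengths.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  # locate unbalanced parentheses before handing off, so the error names a position
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                       ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(bal < 0))
    stop("malformed Newick: unmatched ')' at position ", which(bal < 0)[1],
         call. = FALSE)
  if (utils::tail(bal, 1) != 0)
    stop("malformed Newick: ", utils::tail(bal, 1), " unclosed '(' by position ",
         nchar(text), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick: parse failed near position ", nchar(text),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("Newick string has no branch lengths; lengths are required on all ",
         "non-root edges", call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("missing branch length on ", sum(is.na(tree$edge.length)),
         " edge(s); lengths are required on all non-root edges", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  tree
}

#' Write a phylogeny as a Newick string
#'
#' Serializes with 17 significant digits so that branch lengths survive a
#' write/read round trip exactly (used internally by [resolve_polytomies()],
#' whose contract is exact preservation of patristic distances).
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param file optional path; if `NULL` the string is returned.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  .check_phylo(tree)
  n <- length(tree$tip.label)
  kids <- .children_list(tree)
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    parts <- vapply(kids[[node]], function(k)
      sprintf("%s:%.17g", rec(k), blen[k]), character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(rec(n + 1L), ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

# children of each node as a list indexed by node id (edge-matrix order)
.children_list <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

.check_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be a \"phylo\" object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("'tree' must have branch lengths", call. = FALSE)
  invisible(tree)
}

#' Tree height (maximum root-to-tip depth)
#' @param tree a `"phylo"` object.
#' @return maximum root-to-tip path length, in the tree's time units.
#' @export
tree_height <- function(tree) {
  .check_phylo(tree)
  max(ape::node.depth.edgelength(tree))
}

#' Is the tree strictly bifurcating?
#' @param tree a `"phylo"` object.
#' @return `TRUE` if every internal node has exactly two children.
#' @export
is_binary_tree <- function(tree) {
  .check_phylo(tree)
  tab <- tabulate(tree$edge[, 1])
  all(tab[tab > 0] == 2L)
}

#' Check ultrametricity within a relative tolerance
#' @param tree a `"phylo"` object.
#' @param tol maximum allowed spread of root-to-tip depths, relative to the
#'   tree height.
#' @return `TRUE` if all tips are equidistant from the root within `tol`.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-6) {
  .check_phylo(tree)
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Resolve polytomies deterministically with zero-length edges
#'
#' Multifurcations are broken into a left-accumulating ladder of zero-length
#' edges, with children ordered by the lexicographically smallest tip label in
#' each child subtree, so that the resolution is reproducible and the
#' patristic distance matrix is unchanged exactly. Binary trees are returned
#' structurally identical. Contrast-based statistics
#' ([nodal_sum_of_changes()], [fritz_purvis_d()]) require the resolved tree.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @return a strictly bifurcating `"phylo"` object.
#' @examples
#' tr <- read_newick("((A:1,B:1,C:1):1,D:2);")
#' is_binary_tree(tr)
#' is_binary_tree(resolve_polytomies(tr))
#' @export
resolve_polytomies <- function(tree) {
  .check_phylo(tree)
  if (is_binary_tree(tree)) return(tree)
  n <- length(tree$tip.label)
  kids <- .children_list(tree)
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  # rec() returns list(str = subtree Newick without trailing length, min = min tip label)
  rec <- function(node) {
    if (node <= n)
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    ch <- lapply(kids[[node]], rec)
    items <- Map(function(x, k) list(str = x$str, len = blen[k], min = x$min),
                 ch, kids[[node]])
    if (length(items) > 2L) {
      items <- items[order(vapply(items, `[[`, character(1), "min"))]
      while (length(items) > 2L) {
        merged <- list(
          str = sprintf("(%s:%.17g,%s:%.17g)", items[[1]]$str, items[[1]]$len,
                        items[[2]]$str, items[[2]]$len),
          len = 0, min = items[[1]]$min)
        items <- c(list(merged), items[-(1:2)])
      }
    }
    parts <- vapply(items, function(it) sprintf("%s:%.17g", it$str, it$len),
                    character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"),
         min = min(vapply(items, `[[`, character(1), "min")))
  }
  out <- ape::read.tree(text = paste0(rec(n + 1L)$str, ";"))
  out
}

#' Phylogenetic covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`
#' (computed by [ape::vcv.phylo()]); the diagonal holds root-to-tip depths.
#' With `standardize = TRUE` the matrix is divided by its largest diagonal
#' entry (the tree height for an ultrametric tree) so that the phylogenetic
#' random effect of the mixed model has a unit-diagonal correlation-like
#' covariance and its standard deviation is directly interpretable.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @param standardize scale so that the maximum diagonal entry is 1.
#' @return a symmetric positive semi-definite matrix with tip labels as
#'   dimnames and attribute `"standardized"`.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree, standardize = FALSE) {
  .check_phylo(tree)
  .stopifnot_scalar_flag(standardize, "standardize")
  C <- ape::vcv.phylo(tree)
  if (standardize) C <- C / max(diag(C))
  attr(C, "standardized") <- standardize
  C
}

#' Transform a phylogenetic covariance under a trait-evolution model
#'
#' Applies the covariance transform implied by one of four models of
#' continuous trait evolution, up to the rate scale \eqn{\sigma^2} which is
#' handled by callers:
#' \describe{
#'   \item{BM}{Brownian motion; `C` is returned unchanged.}
#'   \item{lambda}{Pagel's lambda; off-diagonal entries are multiplied by
#'     `param`, the diagonal is unchanged.}
#'   \item{OU}{Ornstein-Uhlenbeck with attraction `param` = alpha > 0:
#'     \eqn{V_{ij} = \exp(-2\alpha(T - s_{ij}))(1 - \exp(-2\alpha s_{ij}))/(2\alpha)}
#'     where \eqn{s_{ij} = C_{ij}} and T is the tree height.}
#'   \item{EB}{Early burst with rate `param` = r <= 0:
#'     \eqn{V_{ij} = (\exp(r s_{ij}) - 1)/r}, with the r = 0 limit
#'     \eqn{s_{ij}}.}
#' }
#' OU and EB assume an ultrametric tree; for non-ultrametric input a warning
#' is issued and per-pair depths \eqn{T_{ij} = (C_{ii} + C_{jj})/2} are used.
#'
#' @param C phylogenetic covariance from [phylo_vcv()].
#' @param model one of `"BM"`, `"lambda"`, `"OU"`, `"EB"`.
#' @param param transform parameter (ignored for BM).
#' @return transformed covariance matrix with the dimnames of `C`.
#' @export
transform_covariance <- function(C, model = c("BM", "lambda", "OU", "EB"),
                                 param = NULL) {
  model <- match.arg(model)
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("'C' must be a square matrix", call. = FALSE)
  if (model == "BM") return(C)
  if (is.null(param) || !is.finite(param))
    stop("'param' is required for model ", model, call. = FALSE)
  if (model == "lambda") {
    if (param < 0) stop("lambda must be >= 0", call. = FALSE)
    V <- C * param
    diag(V) <- diag(C)
    ok <- tryCatch({chol(V); TRUE}, error = function(e) FALSE)
    if (!ok)
      stop("lambda = ", format(param),
           " produces a non-positive-definite covariance", call. = FALSE)
    return(V)
  }
  d <- diag(C)
  Tmax <- max(d)
  if ((max(d) - min(d)) > 1e-6 * Tmax) {
    warning("covariance is not from an ultrametric tree; using per-pair depths",
            call. = FALSE)
    Tm <- (outer(d, d, "+")) / 2
  } else {
    Tm <- matrix(Tmax, nrow(C), ncol(C))
  }
  if (model == "OU") {
    if (param <= 0) stop("OU alpha must be > 0", call. = FALSE)
    a <- param
    V <- exp(-2 * a * (Tm - C)) * (1 - exp(-2 * a * C)) / (2 * a)
  } else { # EB
    if (param > 0) stop("EB rate must be <= 0", call. = FALSE)
    V <- if (param == 0) C else (exp(param * C) - 1) / param
  }
  dimnames(V) <- dimnames(C)
  V
}
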