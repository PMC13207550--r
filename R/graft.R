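#' Graft sequence-less species into a dated tree by taxonomic affinity
#'
#' Species without molecular data are inserted next to their nearest available
#' relatives: each is attached as sister to the subtree spanned by its
#' congeners if any are present in the tree, otherwise by its confamilials,
#' otherwise by members of its order. The attachment node is placed on the
#' target clade's stem branch at an age (time before present) equal to the
#' mean crown age of same-rank clades with two or more tips elsewhere in the
#' tree; when that age does not fall strictly inside the stem branch, the stem
#' midpoint is used. The new terminal branch is then set so the grafted tip is
#' exactly as deep as the original tips, keeping the tree ultrametric. Grafting
#' is fully deterministic and sequential in sorted species order, so earlier
#' grafts can serve as relatives for later ones; the pairwise distances among
#' original tips are never altered.
#'
#' @param tree a rooted, ultrametric (within relative tolerance `tol`)
#'   `"phylo"` object.
#' @param taxonomy data frame with columns `species`, `genus`, `family`,
#'   `order` covering both the tree tips and the species to graft.
#' @param missing character vector of species to insert.
#' @param tol relative ultrametricity tolerance.
#' @return a `"phylo"` object with `length(missing)` additional tips.
#' @examples
#' tr <- read_newick("((A_gen1:1,B_gen1:1):1,C_gen2:2);")
#' tax <- data.frame(species = c("A_gen1", "B_gen1", "C_gen2", "D_gen1"),
#'                   genus = c("gen1", "gen1", "gen2", "gen1"),
#'                   family = "fam1", order = "ord1")
#' graft_missing_species(tr, tax, "D_gen1")
#' @export
graft_missing_species <- function(tree, taxonomy, missing, tol = 1e-3) {
  .check_phylo(tree)
  taxonomy <- .check_taxonomy(taxonomy)
  if (!length(missing)) return(tree)
  missing <- as.character(missing)
  if (!is_ultrametric_tol(tree, tol))
    stop("tree must be ultrametric within relative tolerance ", tol,
         call. = FALSE)
  already <- intersect(missing, tree$tip.label)
  if (length(already))
    stop("species already in tree: ", paste(already, collapse = ", "),
         call. = FALSE)
  no_tax <- setdiff(missing, taxonomy$species)
  if (length(no_tax))
    stop("no taxonomy for: ", paste(no_tax, collapse = ", "), call. = FALSE)

  H <- tree_height(tree)
  for (sp in sort(missing)) {
    tax_sp <- taxonomy[match(sp, taxonomy$species), ]
    tip_tax <- taxonomy[match(tree$tip.label, taxonomy$species), ]
    target <- which(tip_tax$genus == tax_sp$genus)
    rank <- "genus"
    if (!length(target)) {
      target <- which(tip_tax$family == tax_sp$family)
      rank <- "family"
    }
    if (!length(target)) {
      target <- which(tip_tax$order == tax_sp$order)
      rank <- "order"
    }
    if (!length(target))
      stop("order '", tax_sp$order, "' of species '", sp,
           "' is absent from the tree; cannot graft", call. = FALSE)
    target <- target[!is.na(target)]
    tree <- .graft_one(tree, sp, target, rank, tip_tax, H)
  }
  tree
}

# attach one tip as sister to the clade spanned by tip indices `target`
.graft_one <- function(tree, sp, target, rank, tip_tax, H) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  root <- n + 1L
  node <- if (length(target) == 1L) target else ape::getMRCA(tree, target)
  if (node == root) {
    # sister-to-everything would raise the root; instead descend into the
    # root child holding the most target tips (ties: first child)
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    counts <- vapply(kids, function(k) {
      tips <- if (k <= n) k else .tips_below(tree, k)
      length(intersect(tips, target))
    }, integer(1))
    k <- kids[which.max(counts)]
    sub <- intersect(if (k <= n) k else .tips_below(tree, k), target)
    node <- if (length(sub) <= 1L) k else ape::getMRCA(tree, sub)
  }
  # target age: mean crown age of same-rank clades with >= 2 tips
  groups <- split(seq_len(n), tip_tax[[rank]])
  crown <- vapply(groups[lengths(groups) >= 2L], function(ix)
    H - depth[ape::getMRCA(tree, ix)], numeric(1))
  t_node <- depth[node]
  t_par <- depth[tree$edge[tree$edge[, 2] == node, 1]]
  t_attach <- if (length(crown)) H - mean(crown) else (t_par + t_node) / 2
  eps <- 1e-9 * max(H, 1)
  if (!(t_attach > t_par + eps && t_attach < t_node - eps))
    t_attach <- (t_par + t_node) / 2
  phytools::bind.tip(tree, sp, edge.length = H - t_attach,
                     where = node, position = t_node - t_attach)
}

.tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  kids <- .children_list(tree)
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    if (x <= n) out <- c(out, x) else stack <- c(stack, kids[[x]])
  }
  out
}

.check_taxonomy <- function(taxonomy) {
  need <- c("species", "genus", "family", "order")
  if (!is.data.frame(taxonomy) || !all(need %in% names(taxonomy)))
    stop("'taxonomy' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  taxonomy[need] <- lapply(taxonomy[need], as.character)
  if (anyDuplicated(taxonomy$species))
    stop("duplicated species in taxonomy", call. = FALSE)
  bad <- !stats::complete.cases(taxonomy[need]) |
    apply(taxonomy[need] == "", 1, any)
  if (any(bad))
    stop("taxonomy rows with empty fields: ",
         paste(taxonomy$species[bad], collapse = ", "), call. = FALSE)
  taxonomy
}

#' Read a taxonomy table
#'
#' @param file delimited text file (tab- or comma-separated, with header)
#'   holding columns `species`, `genus`, `family`, `order`.
#' @param sep field separator.
#' @return a validated data frame.
#' @export
read_taxonomy <- function(file, sep = "\t") {
  .check_taxonomy(utils::read.table(file, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE, quote = "\"",
                                    fileEncoding = "UTF-8"))
}
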