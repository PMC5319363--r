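# Tree data model and tree-derived statistics.
#
# A `dated_tree` is an ape "phylo" object validated to be rooted, binary and
# ultrametric (after snapping near-present tips to age 0), with node ages in
# My before present cached in `$node_age` (ape node numbering: tips 1..n,
# internals n+1..n+Nnode). Recently extinct species are expected to enter as
# tips whose small nonzero age falls below the ultrametricity tolerance.

#' Validate a phylogeny as a dated (ultrametric, binary) tree
#'
#' Checks that the tree is rooted and binary, has non-negative branch lengths,
#' and is ultrametric up to a relative tolerance. Tips whose age deviates from
#' zero by at most `tol_rel * crown_age` are snapped to age 0 by adjusting
#' their terminal branch; larger deviations are an error, not silently
#' repaired.
#'
#' @param phy an object of class "phylo" with branch lengths in My.
#' @param tol_rel relative ultrametricity tolerance (default 1e-6 of the
#'   crown age).
#' @return the tree with class `c("dated_tree", "phylo")`, node ages in
#'   `$node_age` and the crown age in `$crown_age`.
#' @export
as_dated_tree <- function(phy, tol_rel = 1e-6) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a \"phylo\" object")
  # always revalidate: subsetting a validated tree (extract.clade, keep.tip)
  # carries stale cached ages, so the class alone cannot be trusted
  phy$node_age <- NULL
  phy$crown_age <- NULL
  class(phy) <- "phylo"
  if (is.null(phy$edge.length)) stop("tree has no branch lengths (required, in My)")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  n <- ape::Ntip(phy)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (!ape::is.binary(phy))
    stop("tree contains polytomies; resolve them upstream (e.g. ape::multi2di) ",
         "before analysis -- the likelihoods assume a binary tree")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(phy)   # root-to-node path lengths
  age <- max(depth[seq_len(n)]) - depth      # ages before present
  crown <- age[n + 1L]
  tol <- tol_rel * crown
  tip_age <- age[seq_len(n)]
  if (any(tip_age > tol))
    stop("tree is not ultrametric: ", sum(tip_age > tol), " tip(s) deviate from ",
         "the present by more than ", signif(tol, 3), " My; truly extinct tips ",
         "must be pruned before analysis")
  if (any(tip_age > 0)) {
    # snap near-present tips (e.g. recently extinct species) to age 0
    term <- match(seq_len(n), phy$edge[, 2L])
    phy$edge.length[term] <- phy$edge.length[term] + tip_age
    age[seq_len(n)] <- 0
  }
  phy$node_age <- unname(age)
  phy$crown_age <- unname(crown)
  class(phy) <- c("dated_tree", "phylo")
  phy
}

#' Read a dated tree from a Newick or NEXUS file
#'
#' @param path file path.
#' @param format "newick" or "nexus"; guessed from the file extension when
#'   missing.
#' @param tol_rel ultrametricity tolerance passed to [as_dated_tree()].
#' @return a `dated_tree`.
#' @export
read_tree <- function(path, format = c("guess", "newick", "nexus"), tol_rel = 1e-6) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.(nex|nexus|trees?)$", tolower(path))) "nexus" else "newick"
  }
  phy <- switch(format, newick = ape::read.tree(path), nexus = ape::read.nexus(path))
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("file contains ", length(phy), " trees; expected one")
    phy <- phy[[1L]]
  }
  if (is.null(phy)) stop("could not parse a tree from ", path)
  as_dated_tree(phy, tol_rel = tol_rel)
}

#' Write a dated tree as Newick
#'
#' @param tree a `dated_tree` (or any phylo).
#' @param path output file path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated ultrametric tree:", ape::Ntip(x), "tips, crown age",
      format(x$crown_age, digits = 5), "My\n")
  invisible(x)
}

#' Crown age of a dated tree
#' @param tree a `dated_tree`.
#' @return crown age in My.
#' @export
crown_age <- function(tree) as_dated_tree(tree)$crown_age

#' Branching times, oldest first
#'
#' The ages of the n-1 internal nodes of an n-tip ultrametric tree, sorted
#' from the crown (oldest) toward the present. Input to all birth--death
#' likelihoods.
#'
#' @param tree a `dated_tree`.
#' @return numeric vector of length `Ntip(tree) - 1`, decreasing; the first
#'   element is the crown age.
#' @export
branching_times <- function(tree) {
  tree <- as_dated_tree(tree)
  sort(unname(ape::branching.times(tree)), decreasing = TRUE)
}

#' Lineage-through-time curve
#'
#' @param tree a `dated_tree`.
#' @return data frame with columns `age` (My, decreasing from the crown age
#'   to 0) and `lineages`; the count is 2 at the crown age and `Ntip(tree)`
#'   at the present.
#' @export
ltt_curve <- function(tree) {
  tree <- as_dated_tree(tree)
  bt <- branching_times(tree)
  data.frame(age = c(bt, 0), lineages = c(seq_along(bt) + 1L, ape::Ntip(tree)))
}

#' Pybus--Harvey gamma statistic
#'
#' Standardized measure of the temporal distribution of internal nodes;
#' asymptotically standard normal under a constant-rate pure-birth process.
#' Positive values indicate nodes concentrated toward the tips (as expected
#' when diversification rates increase toward the present).
#'
#' @param tree a `dated_tree` with at least 3 tips.
#' @return the gamma statistic (scalar).
#' @export
gamma_statistic <- function(tree) {
  tree <- as_dated_tree(tree)
  if (ape::Ntip(tree) < 3L) stop("gamma statistic requires at least 3 tips")
  ape::gammaStat(tree)
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree a tree with branch lengths.
#' @return symmetric matrix of path-length distances, zero diagonal, in the
#'   tree's tip-label order.
#' @export
patristic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Extract the crown clade spanned by a set of tips
#'
#' @param tree a `dated_tree`.
#' @param tips character vector of tip labels; the subtree rooted at their
#'   most recent common ancestor is returned.
#' @return a `dated_tree` for the crown clade.
#' @export
extract_clade <- function(tree, tips) {
  tree <- as_dated_tree(tree)
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad)) stop("unknown tip label(s): ", paste(head(bad, 5L), collapse = ", "))
  if (!length(tips)) stop("`tips` must be non-empty")
  if (setequal(tips, tree$tip.label)) return(tree)
  if (length(tips) == 1L) stop("need at least 2 tips to define a crown clade")
  node <- ape::getMRCA(tree, tips)
  as_dated_tree(ape::extract.clade(tree, node))
}

#' Read a species-richness table
#'
#' Two-column CSV `tip_label,n_species` assigning to each tip the total number
#' of known species it stands for (its own species plus unsampled ones).
#'
#' @param path CSV file path.
#' @return data frame with columns `tip_label` (character) and `n_species`
#'   (positive integer).
#' @export
read_richness <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tip_label", "n_species") %in% names(x)))
    stop("richness table must have columns tip_label,n_species")
  validate_richness(x)
}

validate_richness <- function(x) {
  if (any(is.na(x$n_species)) || any(x$n_species < 1) ||
      any(x$n_species != round(x$n_species)))
    stop("n_species must be positive integers")
  x$n_species <- as.integer(x$n_species)
  x
}

#' Clade sampling fraction from a richness table
#'
#' @param tree a `dated_tree`.
#' @param richness richness table as from [read_richness()]; tips missing from
#'   the table count as 1 species each.
#' @return sampling fraction rho = Ntip / total assigned richness, in (0, 1].
#' @export
sampling_fraction <- function(tree, richness = NULL) {
  tree <- as_dated_tree(tree)
  n <- ape::Ntip(tree)
  if (is.null(richness)) return(1)
  richness <- validate_richness(richness)
  m <- setNames(rep(1L, n), tree$tip.label)
  keep <- richness$tip_label %in% tree$tip.label
  m[richness$tip_label[keep]] <- richness$n_species[keep]
  rho <- n / sum(m)
  if (rho > 1) stop("total richness is below the number of tips")
  rho
}

# Richness per tip, in tip order, defaulting to 1.
tip_richness <- function(tree, richness = NULL) {
  n <- ape::Ntip(tree)
  m <- setNames(rep(1L, n), tree$tip.label)
  if (!is.null(richness)) {
    richness <- validate_richness(richness)
    bad <- setdiff(richness$tip_label, tree$tip.label)
    if (length(bad)) stop("richness table names tips not in the tree: ",
                          paste(head(bad, 5L), collapse = ", "))
    m[richness$tip_label] <- richness$n_species
  }
  m
}
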