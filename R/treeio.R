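#' Read and validate a rooted phylogeny from Newick
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object and enforces the structural contract the downstream statistics
#' rely on: a single rooted tree with at least two uniquely labelled tips,
#' finite non-negative branch lengths, and strictly positive terminal
#' branches (a zero-length terminal branch would make contrast
#' standardization divide by zero). Polytomies are preserved as written;
#' zero-length internal branches are allowed but flagged with a warning,
#' since collapsing short internal branches is the standard way polytomies
#' arise.
#'
#' @param x A Newick string, or the path to a file whose contents are one.
#' @return A rooted `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("\\(", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "")
  }
  check_newick_syntax(x)
  tree <- tryCatch(
    ape::read.tree(text = x),
    error = function(e) abort(sprintf("Newick parse failed: %s", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse failed: no tree found in input.")
  validate_phylo(tree)
}

# Cheap pre-parse scan so malformed strings fail with a character position.
check_newick_syntax <- function(x) {
  chars <- strsplit(x, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Newick parse failed: unbalanced ')' at character %d.", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "Newick parse failed: %d unclosed '(' at end of string (length %d).",
      depth, length(chars)
    ))
  }
  if (!grepl(";", x)) {
    abort(sprintf(
      "Newick parse failed: missing terminating ';' by character %d.",
      length(chars)
    ))
  }
  invisible(x)
}

#' Validate the structural invariants of a phylogeny
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  n <- ape::Ntip(tree)
  if (n < 2L) abort("Tree must have at least 2 tips.")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate tip labels: %s.", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(tree$tip.label))) abort("Empty tip labels are not allowed.")
  if (is.null(tree$edge.length)) {
    abort("Tree must carry branch lengths.")
  }
  if (any(!is.finite(tree$edge.length))) abort("All branch lengths must be finite.")
  if (any(tree$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  tip_edges <- tree$edge[, 2] <= n
  if (any(tree$edge.length[tip_edges] <= 0)) {
    bad <- tree$tip.label[tree$edge[tip_edges, 2][tree$edge.length[tip_edges] <= 0]]
    abort(sprintf(
      "Zero-length terminal branches (tips: %s) are not allowed; they break contrast standardization.",
      paste(bad, collapse = ", ")
    ))
  }
  if (any(tree$edge.length[!tip_edges] == 0)) {
    warn("Tree has zero-length internal branches; they are retained (treated as soft polytomies).")
  }
  invisible(tree)
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written to disk.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Reconcile a trait table with a phylogeny
#'
#' Intersects the species of a trait table with the tip labels of a tree
#' (exact, case-sensitive string match on species codes), prunes unmatched
#' tips (suppressing unary nodes and summing their branch lengths), drops
#' unmatched trait rows, and reorders the trait table to tip order.
#'
#' @param traits A data frame with a `species` column, one row per species.
#' @param tree A `phylo` object.
#' @return A list with elements `traits` (aligned tibble, in tip order),
#'   `tree` (pruned), and `report` (a list with `dropped_tips` and
#'   `dropped_species`).
#' @export
match_taxa <- function(traits, tree) {
  stopifnot(is.data.frame(traits))
  if (!"species" %in% names(traits)) abort("`traits` must have a `species` column.")
  if (anyDuplicated(traits$species)) {
    abort("`traits` must have at most one row per species.")
  }
  validate_phylo(tree)
  shared <- intersect(tree$tip.label, traits$species)
  if (length(shared) < 2L) {
    abort(sprintf(
      "Fewer than 2 species shared between tree (%d tips) and traits (%d rows); cannot proceed.",
      ape::Ntip(tree), nrow(traits)
    ))
  }
  dropped_tips <- setdiff(tree$tip.label, shared)
  dropped_species <- setdiff(traits$species, shared)
  pruned <- if (length(dropped_tips) > 0L) ape::keep.tip(tree, shared) else tree
  aligned <- as_tibble(traits)[match(pruned$tip.label, traits$species), ]
  list(
    traits = aligned,
    tree = pruned,
    report = list(dropped_tips = dropped_tips, dropped_species = dropped_species)
  )
}

#' Brownian-motion tip covariance matrix of a phylogeny
#'
#' Returns the n-by-n matrix V whose entry (i, j) is the total branch
#' length shared by the root-to-tip paths of tips i and j; the diagonal
#' holds root-to-tip distances. V is the trait covariance (up to the
#' Brownian rate) implied by the tree and is the workhorse of Blomberg's K.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  ape::vcv(tree)
}
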