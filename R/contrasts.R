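# Core contrast engine. Traits are linear in tip values only on strictly
# bifurcating trees; the polytomy split rule depends on trait ranks, so the
# engine is re-run per permutation rather than cached as a matrix.

# Align a trait column with the tips of a tree; errors name missing tips.
tip_trait_vector <- function(traits, tree, trait) {
  stopifnot(is.data.frame(traits))
  if (!"species" %in% names(traits)) abort("`traits` must have a `species` column.")
  if (!trait %in% names(traits)) {
    abort(sprintf("Trait `%s` not found in trait table.", trait))
  }
  idx <- match(tree$tip.label, traits$species)
  if (anyNA(idx)) {
    abort(sprintf(
      "Tips without trait rows: %s.",
      paste(tree$tip.label[is.na(idx)], collapse = ", ")
    ))
  }
  x <- traits[[trait]][idx]
  if (any(!is.finite(x))) {
    abort(sprintf(
      "Non-finite `%s` value for tip(s): %s.",
      trait, paste(tree$tip.label[!is.finite(x)], collapse = ", ")
    ))
  }
  x
}

# Branch-length-weighted (1/b) mean of child values; children on
# zero-length branches carry infinite weight, so the limit is their mean.
wcombine <- function(v, b) {
  if (any(b == 0)) {
    list(value = mean(v[b == 0]), branch = 0)
  } else {
    w <- 1 / b
    list(value = sum(v * w) / sum(w), branch = 1 / sum(w))
  }
}

# One pass of Felsenstein-style contrasts over a (possibly polytomous)
# rooted tree; x is aligned with tree$tip.label. Returns parallel vectors
# over internal nodes in postorder.
ic_engine <- function(tree, x) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  val <- numeric(n + m)
  val[seq_len(n)] <- x
  bl <- numeric(n + m)
  bl[tr$edge[, 2]] <- tr$edge.length
  nodes <- unique(tr$edge[, 1])
  contrast <- numeric(m)
  node_value <- numeric(m)
  adj_bl <- numeric(m)
  polytomy <- logical(m)
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    kids <- sort(tr$edge[tr$edge[, 1] == nd, 2])
    v <- val[kids]
    b <- bl[kids]
    if (length(kids) == 2L) {
      lo <- list(value = v[1], branch = b[1])
      hi <- list(value = v[2], branch = b[2])
      this_contrast <- (v[1] - v[2])
    } else {
      polytomy[k] <- TRUE
      # Rank split at the median of child values: the lower half (ties
      # broken by node id, the larger half when odd) forms one group.
      ord <- order(v, kids)
      g <- ceiling(length(kids) / 2)
      lo <- wcombine(v[ord[seq_len(g)]], b[ord[seq_len(g)]])
      hi <- wcombine(v[ord[-seq_len(g)]], b[ord[-seq_len(g)]])
      this_contrast <- (hi$value - lo$value)
    }
    denom <- lo$branch + hi$branch
    if (denom <= 0) {
      abort(sprintf(
        "Zero combined branch length at internal node %d; cannot standardize contrast.",
        nd
      ))
    }
    contrast[k] <- this_contrast / sqrt(denom)
    cmb <- wcombine(c(lo$value, hi$value), c(lo$branch, hi$branch))
    node_value[k] <- cmb$value
    val[nd] <- cmb$value
    bl[nd] <- bl[nd] + lo$branch * hi$branch / denom
    adj_bl[k] <- bl[nd]
  }
  list(
    node = nodes, contrast = contrast, node_value = node_value,
    adj_branch = adj_bl, polytomy = polytomy
  )
}

#' Standardized independent contrasts
#'
#' Computes one branch-length-standardized contrast per internal node by
#' post-order traversal. At a bifurcation with child values \eqn{x_1, x_2}
#' on adjusted branches \eqn{b_1, b_2}: the contrast is
#' \eqn{(x_1 - x_2)/\sqrt{b_1 + b_2}}, the node's trait estimate is the
#' \eqn{1/b}-weighted mean, and the node's own branch is lengthened by
#' \eqn{b_1 b_2/(b_1+b_2)}. A polytomy yields a single contrast between two
#' groups of children split at the median of their trait values (ranks,
#' ties broken by node id); group values and branches are the weighted
#' combinations of their members, and the node is flagged. Contrasts are
#' i.i.d. with variance equal to the Brownian rate when the trait evolves
#' by Brownian motion on the tree.
#'
#' @param traits A trait table with a `species` column covering every tip.
#' @param tree A rooted `phylo` with branch lengths (terminal branches
#'   strictly positive).
#' @param trait Name of the trait column.
#' @return A tibble of class `phylosoil_contrasts`: one row per internal
#'   node with columns `node` (ape node id), `contrast` (trait units per
#'   square-root branch-length unit), `node_value` (trait units),
#'   `adj_branch`, `polytomy`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tab <- tibble::tibble(species = c("A", "B", "C", "D"), z = c(0, 0, 10, 10))
#' independent_contrasts(tab, tr, "z")
independent_contrasts <- function(traits, tree, trait) {
  validate_phylo(tree)
  x <- tip_trait_vector(traits, tree, trait)
  res <- ic_engine(tree, x)
  out <- tibble(
    node = res$node,
    contrast = res$contrast,
    node_value = res$node_value,
    adj_branch = res$adj_branch,
    polytomy = res$polytomy
  )
  class(out) <- c("phylosoil_contrasts", class(out))
  attr(out, "trait") <- trait
  out
}

#' Phylogeny-wide signal from mean absolute contrasts
#'
#' The observed statistic is the mean of |contrast| over all internal
#' nodes. Its null distribution comes from `R` random reassignments of the
#' trait values across the tips; a significantly *low* tail (observed mean
#' contrast smaller than expected under shuffling) is the signature of
#' phylogenetic conservatism. Tail p values use the add-one rule
#' \eqn{(r+1)/(R+1)} with ties counted as extreme.
#'
#' @inheritParams independent_contrasts
#' @param R Number of permutations (default 999).
#' @param seed Optional integer seed; recorded in the result.
#' @return A `phylosoil_signal` object: list with `observed`, `null`
#'   (length `R`), `p_low`, `p_high`, `R`, `seed`, `trait`.
#' @export
phylogeny_wide_signal <- function(traits, tree, trait, R = 999, seed = NULL) {
  assert_scalar_number(R, "R", lower = 1)
  validate_phylo(tree)
  x <- tip_trait_vector(traits, tree, trait)
  observed <- mean(abs(ic_engine(tree, x)$contrast))
  null <- with_seed_opt(seed, {
    vapply(
      seq_len(R),
      function(r) mean(abs(ic_engine(tree, sample(x))$contrast)),
      numeric(1)
    )
  })
  structure(
    list(
      observed = observed, null = null,
      p_low = perm_p(null, observed, "low"),
      p_high = perm_p(null, observed, "high"),
      R = as.integer(R), seed = seed, trait = trait
    ),
    class = "phylosoil_signal"
  )
}

#' @export
print.phylosoil_signal <- function(x, ...) {
  cat(sprintf(
    "<phylosoil_signal> trait %s: mean |contrast| = %.5g (R = %d)\n  p_low = %.4g, p_high = %.4g\n",
    x$trait %||% "?", x$observed, x$R, x$p_low, x$p_high
  ))
  invisible(x)
}

#' Blomberg's K statistic
#'
#' K compares the observed partitioning of trait variance on the tree with
#' its Brownian-motion expectation. With tip covariance matrix `V` (from
#' [phylo_vcv()]), phylogenetic mean
#' \eqn{\hat a = (1'V^{-1}1)^{-1} 1'V^{-1}X}, and
#' \eqn{MSE_0 = (X-\hat a)'(X-\hat a)/(n-1)},
#' \eqn{MSE = (X-\hat a)'V^{-1}(X-\hat a)/(n-1)}, the statistic is the
#' observed ratio \eqn{MSE_0/MSE} divided by its Brownian expectation
#' \eqn{[\mathrm{tr}(V) - n/(1'V^{-1}1)]/(n-1)}. K = 1 under Brownian
#' evolution; K > 1 means closer relatives are more similar than Brownian
#' motion predicts, K < 1 less. K is invariant to affine trait changes and
#' to global rescaling of branch lengths.
#'
#' @inheritParams independent_contrasts
#' @return A `phylosoil_k` object: list with `K`, `MSE0`, `MSE`,
#'   `observed_ratio`, `expected_ratio`, `n`, `ridge` (TRUE when a tiny
#'   ridge was added to a singular V), `trait`; `p_two_tailed`, `null`,
#'   `R`, `seed` are filled by [k_significance()].
#' @export
blomberg_k <- function(traits, tree, trait) {
  validate_phylo(tree)
  x <- tip_trait_vector(traits, tree, trait)
  if (sd(x) == 0) {
    abort(sprintf("Trait `%s` is constant across tips; K is undefined (MSE0 = 0).", trait))
  }
  V <- phylo_vcv(tree)
  n <- length(x)
  ridge <- FALSE
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) {
    V <- V + diag(1e-8 * mean(diag(V)), n)
    Vinv <- tryCatch(solve(V), error = function(e) {
      abort("Phylogenetic covariance matrix is singular even after ridging.")
    })
    ridge <- TRUE
  }
  stat <- k_stat(matrix(x, ncol = 1), Vinv, diag_V = diag(V))
  structure(
    list(
      K = stat$K, MSE0 = stat$MSE0, MSE = stat$MSE,
      observed_ratio = stat$MSE0 / stat$MSE,
      expected_ratio = stat$expected_ratio,
      n = n, ridge = ridge, trait = trait,
      p_two_tailed = NA_real_, null = NULL, R = NA_integer_, seed = NULL
    ),
    class = "phylosoil_k"
  )
}

# Vectorized K over the columns of X given a fixed tree (via Vinv).
k_stat <- function(X, Vinv, diag_V) {
  n <- nrow(X)
  one <- rep(1, n)
  Vi1 <- Vinv %*% one
  s <- sum(Vi1)
  a_hat <- as.numeric(crossprod(Vi1, X)) / s
  D <- sweep(X, 2, a_hat)
  MSE0 <- colSums(D^2) / (n - 1)
  MSE <- colSums(D * (Vinv %*% D)) / (n - 1)
  expected_ratio <- (sum(diag_V) - n / s) / (n - 1)
  list(
    K = (MSE0 / MSE) / expected_ratio,
    MSE0 = MSE0, MSE = MSE, expected_ratio = expected_ratio
  )
}

#' Permutation significance for Blomberg's K
#'
#' Builds the null distribution of K from `R` random reassignments of the
#' trait values across tips and reports a two-tailed p value: twice the
#' smaller of the two add-one tail probabilities, capped at 1.
#'
#' @inheritParams phylogeny_wide_signal
#' @return A `phylosoil_k` object with `p_two_tailed`, `null`, `R` and
#'   `seed` filled in.
#' @export
k_significance <- function(traits, tree, trait, R = 999, seed = NULL) {
  assert_scalar_number(R, "R", lower = 1)
  obs <- blomberg_k(traits, tree, trait)
  x <- tip_trait_vector(traits, tree, trait)
  n <- length(x)
  V <- phylo_vcv(tree)
  if (obs$ridge) V <- V + diag(1e-8 * mean(diag(V)), n)
  Vinv <- solve(V)
  perms <- with_seed_opt(seed, {
    matrix(replicate(R, sample.int(n)), nrow = n)
  })
  Xp <- matrix(x[perms], nrow = n)
  null <- k_stat(Xp, Vinv, diag_V = diag(V))$K
  p_hi <- perm_p(null, obs$K, "high")
  p_lo <- perm_p(null, obs$K, "low")
  obs$p_two_tailed <- min(1, 2 * min(p_hi, p_lo))
  obs$null <- null
  obs$R <- as.integer(R)
  obs$seed <- seed
  obs
}

#' @export
print.phylosoil_k <- function(x, ...) {
  cat(sprintf("<phylosoil_k> trait %s: K = %.4g (n = %d)\n", x$trait %||% "?", x$K, x$n))
  if (!is.na(x$p_two_tailed)) {
    cat(sprintf("  two-tailed p = %.4g (R = %d)\n", x$p_two_tailed, x$R))
  }
  if (isTRUE(x$ridge)) cat("  note: ridge added to a singular covariance matrix\n")
  invisible(x)
}

#' Write a table of K statistics for several traits
#'
#' One row per trait with columns `trait`, `K`, `p_value`, mirroring the
#' conventional published layout.
#'
#' @param k_results A list of `phylosoil_k` objects.
#' @param file Output TSV path.
#' @return The assembled tibble, invisibly.
#' @export
write_k_table <- function(k_results, file) {
  tab <- purrr::map(k_results, function(k) {
    tibble(trait = k$trait, K = round(k$K, 4), p_value = round(k$p_two_tailed, 4))
  }) |> bind_rows()
  readr::write_tsv(tab, file, progress = FALSE)
  invisible(tab)
}
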