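# Node-specific evolutionary signal: per-node trait means under two
# averaging schemes against a tip-shuffle null. Both node statistics are
# linear in the tip values, so each is represented as a weight matrix over
# tips and the whole permutation null is a single matrix product.

# Weight matrices over tips for every internal node.
#  - tip averaging: each subtended tip weighted 1/(number of subtended tips)
#  - ancestral averaging: recursive equal weight over immediate daughters
#    (each daughter counts once regardless of subtree size); branch lengths
#    are ignored by construction.
node_weight_matrices <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  W_tip <- matrix(0, n + m, n)
  W_anc <- matrix(0, n + m, n)
  W_tip[cbind(seq_len(n), seq_len(n))] <- 1
  W_anc[cbind(seq_len(n), seq_len(n))] <- 1
  nodes <- unique(tr$edge[, 1])
  for (nd in nodes) {
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    W_tip[nd, ] <- colSums(W_tip[kids, , drop = FALSE])
    W_anc[nd, ] <- colMeans(W_anc[kids, , drop = FALSE])
  }
  sizes <- rowSums(W_tip[nodes, , drop = FALSE])
  W_tip[nodes, ] <- W_tip[nodes, , drop = FALSE] / sizes
  list(
    nodes = nodes,
    tip = W_tip[nodes, , drop = FALSE],
    anc = W_anc[nodes, , drop = FALSE],
    n_tips = rowSums(W_tip[nodes, , drop = FALSE] > 0)
  )
}

#' Per-node trait means (tip averaging)
#'
#' For every internal node, the unweighted arithmetic mean of the trait
#' values of all tips it subtends. The root's value is the grand mean of
#' all species values.
#'
#' @inheritParams independent_contrasts
#' @return A tibble with columns `node` and `mean`.
#' @export
tip_means <- function(traits, tree, trait) {
  validate_phylo(tree)
  x <- tip_trait_vector(traits, tree, trait)
  W <- node_weight_matrices(tree)
  tibble(node = W$nodes, mean = as.numeric(W$tip %*% x))
}

#' Per-node trait means (ancestral averaging)
#'
#' The recursive nodes-as-units average: a tip's value is its trait value,
#' an internal node's value is the unweighted mean of its immediate
#' daughters' values, so large subclades do not dominate deep node means.
#' Branch lengths play no role.
#'
#' @inheritParams independent_contrasts
#' @return A tibble with columns `node` and `mean`.
#' @export
ancestral_means <- function(traits, tree, trait) {
  validate_phylo(tree)
  x <- tip_trait_vector(traits, tree, trait)
  W <- node_weight_matrices(tree)
  tibble(node = W$nodes, mean = as.numeric(W$anc %*% x))
}

#' Node-specific permutation tests of trait means
#'
#' Compares each internal node's observed trait mean, under both tip and
#' ancestral averaging, to a null distribution built from `R` random
#' reassignments of trait values across tips. One shared stream of
#' permutations serves every node and both averaging methods, so results
#' are comparable within a run. Tail p values use the add-one rule
#' \eqn{(r+1)/(R+1)} with ties counted as extreme; the root's tip-average
#' is permutation invariant, so its p values are 1 by construction. A node
#' is flagged significant in a tail when its p value is at most `alpha`
#' (inclusive) under *both* averaging methods.
#'
#' @inheritParams phylogeny_wide_signal
#' @param alpha Per-tail significance level in (0, 0.5], default 0.05.
#' @return A tibble of class `phylosoil_nodes`: one row per internal node
#'   with `node`, `species` (list of subtended tip labels), `n_species`,
#'   `counts` (list of `n_individuals`, in `species` order; all `NA` when
#'   the trait table has no counts), `tip_mean`, `anc_mean`,
#'   `p_low_tip`, `p_high_tip`, `p_low_anc`, `p_high_anc`,
#'   `significant_both_low`, `significant_both_high`. Attributes: `trait`,
#'   `R`, `seed`, `alpha`.
#' @export
node_permutation_test <- function(traits, tree, trait, R = 999, seed = NULL,
                                  alpha = 0.05) {
  assert_scalar_number(R, "R", lower = 1)
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 0.5)
  validate_phylo(tree)
  if (ape::Ntip(tree) < 3L) abort("Node tests need at least 3 tips.")
  x <- tip_trait_vector(traits, tree, trait)
  n <- length(x)
  W <- node_weight_matrices(tree)
  obs_tip <- as.numeric(W$tip %*% x)
  obs_anc <- as.numeric(W$anc %*% x)
  perms <- with_seed_opt(seed, matrix(replicate(R, sample.int(n)), nrow = n))
  Xp <- matrix(x[perms], nrow = n)
  null_tip <- W$tip %*% Xp
  null_anc <- W$anc %*% Xp
  # Tie detection needs a tolerance: a permuted mean equal in exact
  # arithmetic can differ in the last float bits under summation reorder.
  tie_tol <- 1e-9 * (max(abs(x)) + 1)
  p_of <- function(null, obs, ge) {
    cmp <- if (ge) null >= obs - tie_tol else null <= obs + tie_tol
    (rowSums(cmp) + 1) / (R + 1)
  }
  p_high_tip <- p_of(null_tip, obs_tip, TRUE)
  p_low_tip <- p_of(null_tip, obs_tip, FALSE)
  p_high_anc <- p_of(null_anc, obs_anc, TRUE)
  p_low_anc <- p_of(null_anc, obs_anc, FALSE)
  tips_of <- apply(W$tip > 0, 1, function(row) tree$tip.label[row], simplify = FALSE)
  counts_all <- if ("n_individuals" %in% names(traits)) {
    setNames(traits$n_individuals, traits$species)
  } else {
    setNames(rep(NA_integer_, n), tree$tip.label)
  }
  out <- tibble(
    node = W$nodes,
    species = tips_of,
    n_species = as.integer(W$n_tips),
    counts = purrr::map(tips_of, ~ unname(counts_all[.x])),
    tip_mean = obs_tip,
    anc_mean = obs_anc,
    p_low_tip = p_low_tip,
    p_high_tip = p_high_tip,
    p_low_anc = p_low_anc,
    p_high_anc = p_high_anc,
    significant_both_low = p_low_tip <= alpha & p_low_anc <= alpha,
    significant_both_high = p_high_tip <= alpha & p_high_anc <= alpha
  )
  class(out) <- c("phylosoil_nodes", class(out))
  attr(out, "trait") <- trait
  attr(out, "R") <- as.integer(R)
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  out
}

#' Apply the reporting filters to node test results
#'
#' Three filters shape which node associations are reported:
#' \enumerate{
#'   \item `require_both`: keep only nodes significant (in at least one
#'     tail) under *both* tip and ancestral averaging — never less
#'     conservative than a single-method rule.
#'   \item Rare-species dependence: a node containing any species with
#'     fewer than `min_individuals` stems gets `min_count_flag`; for each
#'     such species a leave-one-out re-test (drop the species, re-prune,
#'     re-run with the same permutation count) checks whether significance
#'     survives. A node whose significance disappears in any re-test is
#'     marked `loo_dependent` and excluded — its association hinges on a
#'     poorly sampled species. Nodes that keep significance are retained
#'     with the flag, since rare species inside an otherwise robust clade
#'     are not by themselves disqualifying.
#'   \item `pca_high_only`: for traits flagged as PCA axes, low-tail
#'     significance is suppressed from the report (a low composite
#'     fertility score has no direct interpretation), though low-tail p
#'     values remain in the full results.
#' }
#'
#' @param results A `phylosoil_nodes` tibble from [node_permutation_test()].
#' @param traits The trait table used for the test (needed for the
#'   leave-one-out re-tests; must carry `n_individuals`).
#' @param tree The tree used for the test.
#' @param min_individuals Minimum stem count per species (default 5).
#' @param require_both Require significance under both averaging methods
#'   (default TRUE).
#' @param pca_high_only Suppress low-tail records for PCA-axis traits
#'   (default TRUE).
#' @param is_pca Whether the tested trait is a PCA axis; default detects
#'   names matching `^PCA`.
#' @return The filtered tibble (only reportable nodes, with `min_count_flag`
#'   and `loo_dependent` columns and `sig_low`/`sig_high` report flags);
#'   the unfiltered input is attached as attribute `full`.
#' @export
filter_and_flag <- function(results, traits, tree, min_individuals = 5,
                            require_both = TRUE, pca_high_only = TRUE,
                            is_pca = NULL) {
  stopifnot(inherits(results, "phylosoil_nodes"))
  trait <- attr(results, "trait")
  alpha <- attr(results, "alpha")
  R <- attr(results, "R")
  seed <- attr(results, "seed")
  is_pca <- is_pca %||% grepl("^PCA", trait)
  full <- results
  out <- as_tibble(results)
  if (require_both) {
    out$sig_low <- out$significant_both_low
    out$sig_high <- out$significant_both_high
  } else {
    out$sig_low <- out$p_low_tip <= alpha
    out$sig_high <- out$p_high_tip <= alpha
  }
  if (is_pca && pca_high_only) out$sig_low <- FALSE
  out$min_count_flag <- purrr::map_lgl(out$counts, ~ any(!is.na(.x) & .x < min_individuals))
  out <- out[out$sig_low | out$sig_high, , drop = FALSE]
  out$loo_dependent <- FALSE
  if (nrow(out) > 0L && any(out$min_count_flag)) {
    for (i in which(out$min_count_flag)) {
      sp <- out$species[[i]]
      cnt <- out$counts[[i]]
      rare <- sp[!is.na(cnt) & cnt < min_individuals]
      for (r in rare) {
        rest <- setdiff(sp, r)
        if (length(rest) < 2L) {
          # Dropping the rare species leaves no testable clade: treat the
          # original significance as dependent on it.
          out$loo_dependent[i] <- TRUE
          break
        }
        traits2 <- traits[traits$species != r, , drop = FALSE]
        mt <- match_taxa(traits2, tree)
        res2 <- node_permutation_test(mt$traits, mt$tree, trait,
          R = R, seed = seed, alpha = alpha
        )
        j <- which(purrr::map_lgl(res2$species, ~ setequal(.x, rest)))
        surviving <- if (length(j) == 1L) {
          (out$sig_high[i] && (if (require_both) {
            res2$significant_both_high[j]
          } else {
            res2$p_high_tip[j] <= alpha
          })) ||
            (out$sig_low[i] && (if (require_both) {
              res2$significant_both_low[j]
            } else {
              res2$p_low_tip[j] <= alpha
            }))
        } else {
          FALSE
        }
        if (!surviving) {
          out$loo_dependent[i] <- TRUE
          break
        }
      }
    }
    out <- out[!out$loo_dependent, , drop = FALSE]
  }
  class(out) <- c("phylosoil_nodes", class(tibble()))
  attr(out, "trait") <- trait
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  attr(out, "full") <- full
  out
}

#' Write node test report rows as TSV
#'
#' One row per reportable node with columns `trait`, `node`, `species`
#' (comma-joined tip labels), `n_individuals` (comma-joined counts, same
#' order), `t_mean` (tip-average mean) and `t_p` (tip-average tail p),
#' sorted by trait then p. An empty result yields a header-only file.
#'
#' @param results A `phylosoil_nodes` tibble (or a list of them, one per
#'   trait) as returned by [filter_and_flag()].
#' @param file Output path.
#' @param tail Which tail to report: `"high"` or `"low"`.
#' @return The report tibble, invisibly.
#' @export
write_node_tables <- function(results, file, tail = c("high", "low")) {
  tail <- match.arg(tail)
  if (inherits(results, "phylosoil_nodes")) results <- list(results)
  rows <- purrr::map(results, function(res) {
    keep_col <- if (tail == "high") "sig_high" else "sig_low"
    p_col <- if (tail == "high") "p_high_tip" else "p_low_tip"
    trait <- attr(res, "trait") %||% NA_character_
    res <- as_tibble(res)
    if (!keep_col %in% names(res)) {
      abort("`results` must come from filter_and_flag() (missing report flags).")
    }
    res <- res[res[[keep_col]], , drop = FALSE]
    tibble(
      trait = rep(trait, nrow(res)),
      node = res$node,
      species = purrr::map_chr(res$species, paste, collapse = ", "),
      n_individuals = purrr::map_chr(res$counts, paste, collapse = ", "),
      t_mean = res$tip_mean,
      t_p = res[[p_col]]
    )
  })
  out <- bind_rows(rows)
  out <- arrange(out, .data$trait, .data$t_p)
  readr::write_tsv(out, file, progress = FALSE)
  invisible(out)
}

#' Long-format export of every node test p value
#'
#' Machine-readable companion to the report tables: every node x tail x
#' averaging-method p value for one or more traits.
#'
#' @param results A `phylosoil_nodes` tibble or list of them (pre- or
#'   post-filter).
#' @param file Optional output TSV path.
#' @return A long tibble with columns `trait`, `node`, `n_species`,
#'   `method`, `tail`, `mean`, `p`.
#' @export
node_tests_long <- function(results, file = NULL) {
  if (inherits(results, "phylosoil_nodes")) results <- list(results)
  out <- purrr::map(results, function(res) {
    full <- attr(res, "full") %||% res
    full <- as_tibble(full)
    base <- full[c("node", "n_species")]
    bind_rows(
      bind_cols(base, tibble(
        method = "tip", tail = "low",
        mean = full$tip_mean, p = full$p_low_tip
      )),
      bind_cols(base, tibble(
        method = "tip", tail = "high",
        mean = full$tip_mean, p = full$p_high_tip
      )),
      bind_cols(base, tibble(
        method = "ancestral", tail = "low",
        mean = full$anc_mean, p = full$p_low_anc
      )),
      bind_cols(base, tibble(
        method = "ancestral", tail = "high",
        mean = full$anc_mean, p = full$p_high_anc
      ))
    ) |>
      mutate(trait = attr(res, "trait") %||% NA_character_, .before = 1)
  }) |> bind_rows()
  if (!is.null(file)) readr::write_tsv(out, file, progress = FALSE)
  out
}
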