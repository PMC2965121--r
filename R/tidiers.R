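# broom-style tidiers for the fitted objects.

#' Tidy a soil PCA
#'
#' @param x A `soil_pca`.
#' @param matrix Which component to return: `"loadings"` (long tibble of
#'   variable x axis loadings), `"eigenvalues"` (per-axis eigenvalue and
#'   variance fraction) or `"scores"` (per-cell axis scores, long).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.soil_pca <- function(x, matrix = c("loadings", "eigenvalues", "scores"), ...) {
  matrix <- match.arg(matrix)
  p <- length(x$variables)
  if (matrix == "loadings") {
    as_tibble(x$loadings, rownames = "variable") |>
      tidyr::pivot_longer(-"variable", names_to = "axis", values_to = "loading")
  } else if (matrix == "eigenvalues") {
    tibble(
      axis = paste0("PCA", seq_len(p)),
      eigenvalue = x$eigenvalues,
      variance_fraction = x$variance_fraction,
      cumulative = cumsum(x$variance_fraction)
    )
  } else {
    tidyr::pivot_longer(x$scores, -c("cell_i", "cell_j"),
      names_to = "axis", values_to = "score"
    )
  }
}

#' One-row summary of a soil PCA
#' @param x A `soil_pca`.
#' @param ... Unused.
#' @return A one-row tibble with the number of variables and cells and the
#'   cumulative variance of the first three axes.
#' @export
glance.soil_pca <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  tibble(
    n_variables = length(x$variables),
    n_cells = x$n_cells,
    var_top3 = sum(x$variance_fraction[seq_len(k)])
  )
}

#' Tidy a Blomberg's K result
#' @param x A `phylosoil_k`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, its components and the
#'   two-tailed permutation p value (NA before [k_significance()]).
#' @export
tidy.phylosoil_k <- function(x, ...) {
  tibble(
    trait = x$trait %||% NA_character_,
    K = x$K, MSE0 = x$MSE0, MSE = x$MSE,
    observed_ratio = x$observed_ratio, expected_ratio = x$expected_ratio,
    p_value = x$p_two_tailed, n = x$n, R = x$R
  )
}

#' @rdname tidy.phylosoil_k
#' @export
glance.phylosoil_k <- function(x, ...) tidy.phylosoil_k(x, ...)

#' Tidy a phylogeny-wide signal result
#' @param x A `phylosoil_signal`.
#' @param ... Unused.
#' @return A one-row tibble with the observed mean |contrast|, the two
#'   tail p values and the null sample size.
#' @export
tidy.phylosoil_signal <- function(x, ...) {
  tibble(
    trait = x$trait %||% NA_character_,
    observed = x$observed,
    null_mean = mean(x$null),
    p_low = x$p_low, p_high = x$p_high, R = x$R
  )
}

#' @rdname tidy.phylosoil_signal
#' @export
glance.phylosoil_signal <- function(x, ...) tidy.phylosoil_signal(x, ...)

#' Flat tidy view of node test results
#' @param x A `phylosoil_nodes` tibble.
#' @param ... Unused.
#' @return A tibble with list columns rendered as comma-joined strings.
#' @export
tidy.phylosoil_nodes <- function(x, ...) {
  out <- as_tibble(x)
  out$species <- purrr::map_chr(out$species, paste, collapse = ", ")
  out$counts <- purrr::map_chr(out$counts, paste, collapse = ", ")
  mutate(out, trait = attr(x, "trait") %||% NA_character_, .before = 1)
}

#' One-row summary of node test results
#' @param x A `phylosoil_nodes` tibble.
#' @param ... Unused.
#' @return A one-row tibble counting tested nodes and significant nodes
#'   per tail (both-methods rule), plus R and alpha.
#' @export
glance.phylosoil_nodes <- function(x, ...) {
  tibble(
    trait = attr(x, "trait") %||% NA_character_,
    n_nodes = nrow(attr(x, "full") %||% x),
    n_sig_high = sum(x$significant_both_high),
    n_sig_low = sum(x$significant_both_low),
    R = attr(x, "R"),
    alpha = attr(x, "alpha")
  )
}
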