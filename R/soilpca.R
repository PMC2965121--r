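#' Log-transform and standardize soil grid variables
#'
#' Replaces the listed variables by their natural logarithm (errors on any
#' non-positive value, naming the variable and cell: variables whose range
#' crosses zero, like net nitrogen mineralization, must never be logged),
#' then standardizes every variable to mean 0 and variance 1 across its
#' non-missing cells. Natural log is the fixed convention; after
#' standardization the base only rescales, but fixing it keeps runs
#' reproducible.
#'
#' @param grid A `soil_grid`.
#' @param log_vars Character vector of variables to log before scaling.
#'   Use [default_log_vars()] for the conventional extractable-element set.
#' @return A `soil_grid` with the same cells, transformed values.
#' @export
transform_variables <- function(grid, log_vars = character()) {
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  vars <- grid_variables(grid)
  unknown <- setdiff(log_vars, vars)
  if (length(unknown) > 0L) {
    abort(sprintf("log_vars not in grid: %s.", paste(unknown, collapse = ", ")))
  }
  out <- as_tibble(grid)
  for (v in log_vars) {
    bad <- which(!is.na(out[[v]]) & out[[v]] <= 0)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Cannot log-transform `%s`: non-positive value %g at cell (%d, %d).",
        v, out[[v]][bad[1]], out$cell_i[bad[1]], out$cell_j[bad[1]]
      ))
    }
    out[[v]] <- log(out[[v]])
  }
  for (v in vars) {
    x <- out[[v]]
    m <- mean(x, na.rm = TRUE)
    # Population (1/n) standard deviation: the cells are the full lattice,
    # not a sample from it.
    s <- sqrt(mean((x - m)^2, na.rm = TRUE))
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Cannot standardize `%s`: zero variance across cells.", v))
    }
    out[[v]] <- (x - m) / s
  }
  soil_grid(out,
    cell_size = attr(grid, "cell_size"),
    nx = attr(grid, "nx"), ny = attr(grid, "ny")
  )
}

#' Default set of log-transformed soil variables
#'
#' Extractable boron, calcium, copper, iron, potassium, magnesium,
#' phosphorus and zinc, plus elevation: the right-skewed positive variables
#' conventionally logged before a correlation-matrix PCA of soil fertility.
#'
#' @return A character vector of variable names.
#' @export
default_log_vars <- function() {
  c("B", "Ca", "Cu", "Fe", "K", "Mg", "P", "Zn", "elev")
}

#' Principal component analysis of soil grid variables
#'
#' Correlation-matrix PCA of the grid cells (cells are the observations,
#' soil variables the columns): each variable is centred and scaled to unit
#' variance, so the eigenvalues sum to the number of variables and each
#' axis' variance fraction is `eigenvalue / p`. Cells with any missing
#' variable are dropped listwise. Each axis is oriented so that its
#' largest-|loading| variable has a positive loading; axis orientation is
#' arbitrary in PCA, so published loading tables may differ axis by axis in
#' sign.
#'
#' @param grid A `soil_grid` (typically the output of
#'   [transform_variables()]; variables are re-standardized internally, so
#'   raw grids give identical axes up to the log transform).
#' @param variables Variables to include (default: all layers).
#' @return A `soil_pca` object: list with `variables`, `loadings` (p x p,
#'   orthonormal columns), `eigenvalues`, `variance_fraction`, `scores` (a
#'   tibble `cell_i`, `cell_j`, `PCA1..PCAp` for complete cells), and
#'   `n_cells`.
#' @export
run_pca <- function(grid, variables = NULL) {
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  variables <- variables %||% grid_variables(grid)
  if (length(variables) < 2L) abort("PCA needs at least 2 variables.")
  missing_vars <- setdiff(variables, grid_variables(grid))
  if (length(missing_vars) > 0L) {
    abort(sprintf("Unknown variable(s): %s.", paste(missing_vars, collapse = ", ")))
  }
  cells <- as_tibble(grid)[c("cell_i", "cell_j", variables)]
  complete <- complete.cases(cells[variables])
  if (sum(complete) < 3L) abort("PCA needs at least 3 complete cells.")
  if (sum(complete) < length(variables)) {
    warn(sprintf(
      "Fewer complete cells (%d) than variables (%d): PCA is rank deficient.",
      sum(complete), length(variables)
    ))
  }
  X <- as.matrix(cells[complete, variables])
  fit <- prcomp(X, center = TRUE, scale. = TRUE)
  p <- length(variables)
  eig <- fit$sdev^2
  # prcomp returns min(n-1, p) components; pad structural zeros.
  if (length(eig) < p) eig <- c(eig, rep(0, p - length(eig)))
  load <- matrix(0, p, p, dimnames = list(variables, paste0("PCA", seq_len(p))))
  load[, seq_len(ncol(fit$rotation))] <- fit$rotation
  scores <- matrix(0, nrow(X), p)
  scores[, seq_len(ncol(fit$x))] <- fit$x
  # Sign convention: dominant variable of each axis loads positively.
  for (k in seq_len(p)) {
    i_star <- which.max(abs(load[, k]))
    if (load[i_star, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- paste0("PCA", seq_len(p))
  score_tbl <- bind_cols(cells[complete, c("cell_i", "cell_j")], as_tibble(scores))
  structure(
    list(
      variables = variables,
      loadings = load,
      eigenvalues = eig,
      variance_fraction = eig / p,
      scores = score_tbl,
      n_cells = sum(complete),
      grid_attrs = list(
        nx = attr(grid, "nx"), ny = attr(grid, "ny"),
        cell_size = attr(grid, "cell_size")
      )
    ),
    class = "soil_pca"
  )
}

#' @export
print.soil_pca <- function(x, ...) {
  cat(sprintf(
    "<soil_pca> %d variables, %d cells\n", length(x$variables), x$n_cells
  ))
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf(
    "  first %d axes: %s of variance\n", k,
    paste(sprintf("%.0f%%", 100 * x$variance_fraction[seq_len(k)]), collapse = " + ")
  ))
  invisible(x)
}

#' Append PCA axis scores to a soil grid as new layers
#'
#' Per-cell scores of the first `k` axes become layers `PCA1..PCAk`; cells
#' that were incomplete (and so excluded from the PCA) get missing scores.
#'
#' @param grid The `soil_grid` the PCA was run on (or any grid on the same
#'   lattice).
#' @param pca A `soil_pca` object.
#' @param k Number of axes to append (default 3, the conventional number
#'   of interpretable soil-fertility axes).
#' @return `grid` with `k` additional layers.
#' @export
scores_to_grid <- function(grid, pca, k = 3) {
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  if (!inherits(pca, "soil_pca")) abort("`pca` must be a `soil_pca`.")
  p <- length(pca$variables)
  if (k < 1L || k > p) {
    abort(sprintf("`k` must be between 1 and %d (number of variables).", p))
  }
  axes <- paste0("PCA", seq_len(k))
  out <- left_join(
    as_tibble(grid),
    pca$scores[c("cell_i", "cell_j", axes)],
    by = c("cell_i", "cell_j")
  )
  soil_grid(out,
    cell_size = attr(grid, "cell_size"),
    nx = attr(grid, "nx"), ny = attr(grid, "ny")
  )
}

#' Write PCA loadings as a TSV table
#'
#' Rows are variables, columns the first `k` axes, with a final
#' `% variance` row, mirroring the conventional published layout of soil
#' PCA loading tables.
#'
#' @param pca A `soil_pca`.
#' @param file Output path.
#' @param k Number of axes to print.
#' @return `file`, invisibly.
#' @export
write_pca_loadings <- function(pca, file, k = 3) {
  k <- min(k, length(pca$variables))
  axes <- paste0("PCA", seq_len(k))
  tab <- tibble(variable = pca$variables)
  for (j in seq_len(k)) {
    tab[[axes[j]]] <- sprintf("%.3f", pca$loadings[, j])
  }
  footer <- tibble(variable = "% variance")
  for (j in seq_len(k)) {
    footer[[axes[j]]] <- sprintf("%.0f%%", 100 * pca$variance_fraction[j])
  }
  readr::write_tsv(bind_rows(tab, footer), file, progress = FALSE)
  invisible(file)
}
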