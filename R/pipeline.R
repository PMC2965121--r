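#' Build and validate a pipeline run configuration
#'
#' Collects every parameter of the end-to-end analysis, fills defaults and
#' checks invariants. Inputs may be given as paths (Newick / TSV / CSV) or
#' as in-memory objects (`phylo`, census tibble, `soil_grid`).
#'
#' @param tree Tree: path to a Newick file or a `phylo`.
#' @param census Stem census: path to a TSV or a data frame.
#' @param grid Soil grid: path to a CSV or a `soil_grid`.
#' @param out_dir Output directory (created if absent).
#' @param variables Soil variables to test (default `Al`, `Mn`, `P`, `pH`,
#'   `slope`; PCA axes are appended automatically).
#' @param log_vars Variables to log-transform before the PCA (default
#'   [default_log_vars()] intersected with the grid's layers).
#' @param n_axes Number of PCA axes carried forward as traits (default 3).
#' @param min_dbh Stem diameter filter in cm, inclusive (default 1).
#' @param cell_size Grid cell size in metres (used when reading a grid
#'   from CSV; default 20).
#' @param R Permutation count (default 999).
#' @param alpha Per-tail significance level (default 0.05).
#' @param min_individuals Rare-species threshold for the node-report
#'   filter (default 5).
#' @param require_both Require node significance under both averaging
#'   methods (default TRUE).
#' @param pca_high_only Report only high-tail associations for PCA axes
#'   (default TRUE).
#' @param seed Integer seed (default 1).
#' @return A validated `phylosoil_config` list.
#' @export
run_config <- function(tree, census, grid, out_dir,
                       variables = c("Al", "Mn", "P", "pH", "slope"),
                       log_vars = NULL, n_axes = 3, min_dbh = 1,
                       cell_size = 20, R = 999, alpha = 0.05,
                       min_individuals = 5, require_both = TRUE,
                       pca_high_only = TRUE, seed = 1) {
  validate_config(list(
    tree = tree, census = census, grid = grid, out_dir = out_dir,
    variables = variables, log_vars = log_vars, n_axes = n_axes,
    min_dbh = min_dbh, cell_size = cell_size, R = R, alpha = alpha,
    min_individuals = min_individuals, require_both = require_both,
    pca_high_only = pca_high_only, seed = seed
  ))
}

#' Validate a raw configuration list
#'
#' Fills defaults, rejects unknown keys by name, and checks every
#' invariant (`R >= 1`, `alpha` in (0, 0.5], positive sizes, referenced
#' paths exist).
#'
#' @param config A named list of configuration entries.
#' @return A normalized `phylosoil_config` list.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(
    tree = NULL, census = NULL, grid = NULL, out_dir = NULL,
    variables = c("Al", "Mn", "P", "pH", "slope"),
    log_vars = NULL, n_axes = 3, min_dbh = 1, cell_size = 20,
    R = 999, alpha = 0.05, min_individuals = 5,
    require_both = TRUE, pca_high_only = TRUE, seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
  for (key in c("tree", "census", "grid", "out_dir")) {
    if (is.null(cfg[[key]])) abort(sprintf("Configuration key `%s` is required.", key))
  }
  for (key in c("tree", "census", "grid")) {
    if (is.character(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(sprintf("Configuration key `%s`: file not found: %s.", key, cfg[[key]]))
    }
  }
  assert_scalar_number(cfg$R, "R", lower = 1)
  assert_scalar_number(cfg$alpha, "alpha", lower = 1e-12, upper = 0.5)
  assert_scalar_number(cfg$n_axes, "n_axes", lower = 0)
  assert_scalar_number(cfg$min_dbh, "min_dbh", lower = 0)
  assert_scalar_number(cfg$cell_size, "cell_size", lower = .Machine$double.eps)
  assert_scalar_number(cfg$min_individuals, "min_individuals", lower = 0)
  assert_scalar_number(cfg$seed, "seed")
  if (!is.character(cfg$variables) || length(cfg$variables) < 1L) {
    abort("`variables` must name at least one soil variable.")
  }
  structure(cfg, class = "phylosoil_config")
}

pipeline_log <- function(stage, fmt, ...) {
  inform(sprintf("[phylosoil] %s: %s", stage, sprintf(fmt, ...)))
}

#' Run the whole plant-soil signal analysis
#'
#' Orchestrates every stage: read inputs, log-transform and standardize
#' the soil layers, PCA, append axis-score layers, overlay the census to
#' build per-species medians (PCA axes treated exactly like soil
#' variables), reconcile species with the tree, then per trait compute
#' Blomberg's K with permutation significance and node-specific
#' permutation tests with the reporting filters. All tables are written
#' under `config$out_dir` together with a JSON metadata sidecar; outputs
#' are byte-identical across runs with the same config and seed.
#'
#' @param config A `phylosoil_config` from [run_config()] /
#'   [validate_config()].
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a list with `traits`, `pca`, `k_results`,
#'   `node_results` (full, per trait), `node_reports` (filtered, per
#'   trait), `match_report` and `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "phylosoil_config")) config <- validate_config(config)
  log_fn <- if (quiet) function(...) NULL else pipeline_log

  tree <- if (is.character(config$tree)) read_newick(config$tree) else validate_phylo(config$tree)
  census <- if (is.character(config$census)) read_census(config$census) else {
    validate_census(config$census)
    as_tibble(config$census)
  }
  grid <- if (is.character(config$grid)) {
    read_soil_grid(config$grid, cell_size = config$cell_size)
  } else {
    config$grid
  }
  if (!inherits(grid, "soil_grid")) abort("`grid` must resolve to a `soil_grid`.")
  log_fn("input", "%d stems, %d tips, %d grid cells, %d layers",
    nrow(census), ape::Ntip(tree), nrow(grid), length(grid_variables(grid)))

  missing_vars <- setdiff(config$variables, grid_variables(grid))
  if (length(missing_vars) > 0L) {
    abort(sprintf(
      "Configured variable(s) absent from grid: %s.",
      paste(missing_vars, collapse = ", ")
    ))
  }

  axes <- character(0)
  pca <- NULL
  grid_full <- grid
  if (config$n_axes >= 1) {
    log_vars <- config$log_vars %||% intersect(default_log_vars(), grid_variables(grid))
    tgrid <- transform_variables(grid, log_vars = log_vars)
    pca <- run_pca(tgrid)
    grid_full <- scores_to_grid(grid, pca, k = config$n_axes)
    axes <- paste0("PCA", seq_len(config$n_axes))
    log_fn("pca", "%d variables; first %d axes carry %.0f%% of variance",
      length(pca$variables), config$n_axes,
      100 * sum(pca$variance_fraction[seq_len(config$n_axes)]))
  }
  test_vars <- c(config$variables, axes)

  traits <- species_medians(census, grid_full,
    variables = test_vars, min_dbh = config$min_dbh
  )
  log_fn("extract", "%d species with medians over %d trait(s)", nrow(traits), length(test_vars))

  mt <- match_taxa(traits, tree)
  log_fn("match", "%d species retained; dropped %d tips, %d trait rows",
    nrow(mt$traits), length(mt$report$dropped_tips), length(mt$report$dropped_species))

  complete <- complete.cases(mt$traits[test_vars])
  if (!all(complete)) {
    log_fn("match", "dropping %d species with missing trait medians", sum(!complete))
    mt <- match_taxa(mt$traits[complete, , drop = FALSE], mt$tree)
  }

  k_results <- purrr::imap(setNames(test_vars, test_vars), function(v, i) {
    k_significance(mt$traits, mt$tree, v,
      R = config$R,
      seed = derive_seed(config$seed, 10L + match(v, test_vars))
    )
  })
  log_fn("signal", "K computed for %d trait(s)", length(k_results))

  node_results <- purrr::map(setNames(test_vars, test_vars), function(v) {
    node_permutation_test(mt$traits, mt$tree, v,
      R = config$R,
      seed = derive_seed(config$seed, 50L + match(v, test_vars)),
      alpha = config$alpha
    )
  })
  node_reports <- purrr::map(node_results, function(res) {
    filter_and_flag(res, mt$traits, mt$tree,
      min_individuals = config$min_individuals,
      require_both = config$require_both,
      pca_high_only = config$pca_high_only
    )
  })
  n_sig <- sum(purrr::map_int(node_reports, nrow))
  log_fn("node-tests", "%d node(s) pass the reporting filters across %d trait(s)",
    n_sig, length(test_vars))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    traits = file.path(config$out_dir, "traits.tsv"),
    k_table = file.path(config$out_dir, "k_table.tsv"),
    node_low = file.path(config$out_dir, "node_tests_low.tsv"),
    node_high = file.path(config$out_dir, "node_tests_high.tsv"),
    node_long = file.path(config$out_dir, "node_tests_full.tsv"),
    metadata = file.path(config$out_dir, "run_metadata.json")
  )
  write_traits(mt$traits, files[["traits"]])
  if (!is.null(pca)) {
    files[["pca_loadings"]] <- file.path(config$out_dir, "pca_loadings.tsv")
    files[["pca_scores"]] <- file.path(config$out_dir, "pca_scores.csv")
    write_pca_loadings(pca, files[["pca_loadings"]], k = config$n_axes)
    write_soil_grid(
      scores_to_grid(grid, pca, k = config$n_axes)[
        , c("cell_i", "cell_j", axes)
      ] |> soil_grid(cell_size = attr(grid, "cell_size")),
      files[["pca_scores"]]
    )
  }
  write_k_table(k_results, files[["k_table"]])
  write_node_tables(node_reports, files[["node_low"]], tail = "low")
  write_node_tables(node_reports, files[["node_high"]], tail = "high")
  node_tests_long(node_results, files[["node_long"]])

  metadata <- list(
    package_version = as.character(utils::packageVersion("phylosoil")),
    parameters = config[c(
      "variables", "log_vars", "n_axes", "min_dbh", "cell_size", "R",
      "alpha", "min_individuals", "require_both", "pca_high_only", "seed"
    )],
    counts = list(
      stems = nrow(census),
      species_tested = nrow(mt$traits),
      internal_nodes = mt$tree$Nnode,
      traits_tested = length(test_vars),
      significant_nodes = n_sig
    ),
    dropped = mt$report
  )
  jsonlite::write_json(metadata, files[["metadata"]],
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  log_fn("done", "outputs in %s", config$out_dir)

  invisible(list(
    traits = mt$traits, tree = mt$tree, pca = pca, k_results = k_results,
    node_results = node_results, node_reports = node_reports,
    match_report = mt$report, files = files
  ))
}
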