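#' Construct a soil grid
#'
#' A soil grid is a tibble of raster cells on a regular lattice: integer
#' 0-based cell indices `cell_i` (x direction) and `cell_j` (y direction)
#' plus one numeric column per environmental variable (units vary by
#' variable: mg element per kg dry soil for Mehlich-3 extractions, pH
#' units, degrees slope, metres elevation, unitless PCA scores). Missing
#' cells are encoded as `NA`. The physical cell size and lattice extent
#' travel as attributes.
#'
#' @param cells A data frame with columns `cell_i`, `cell_j` and at least
#'   one variable column; one row per cell, no duplicated cells.
#' @param cell_size Cell edge length in metres (default 20, the standard
#'   census quadrat).
#' @param nx,ny Lattice extent in cells; inferred from the indices when
#'   omitted.
#' @return A `soil_grid` tibble.
#' @export
soil_grid <- function(cells, cell_size = 20, nx = NULL, ny = NULL) {
  stopifnot(is.data.frame(cells))
  if (!all(c("cell_i", "cell_j") %in% names(cells))) {
    abort("`cells` must have `cell_i` and `cell_j` columns.")
  }
  assert_scalar_number(cell_size, "cell_size", lower = .Machine$double.eps)
  cells <- as_tibble(cells)
  cells$cell_i <- as.integer(cells$cell_i)
  cells$cell_j <- as.integer(cells$cell_j)
  if (any(cells$cell_i < 0L) || any(cells$cell_j < 0L)) {
    abort("Cell indices must be non-negative (0-based).")
  }
  if (anyDuplicated(cells[c("cell_i", "cell_j")])) {
    abort("Duplicated cells in `cells`.")
  }
  vars <- setdiff(names(cells), c("cell_i", "cell_j"))
  if (length(vars) == 0L) abort("`cells` must contain at least one variable column.")
  for (v in vars) {
    if (!is.numeric(cells[[v]])) abort(sprintf("Variable `%s` must be numeric.", v))
    if (any(is.infinite(cells[[v]]))) {
      abort(sprintf("Variable `%s` has non-finite (infinite) values.", v))
    }
  }
  nx <- nx %||% (max(cells$cell_i) + 1L)
  ny <- ny %||% (max(cells$cell_j) + 1L)
  if (nx < 1L || ny < 1L) abort("`nx` and `ny` must be at least 1.")
  structure(
    cells,
    class = c("soil_grid", class(tibble())),
    nx = as.integer(nx), ny = as.integer(ny), cell_size = cell_size
  )
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf(
    "<soil_grid> %d x %d cells of %g m, %d variable(s)\n",
    attr(x, "nx"), attr(x, "ny"), attr(x, "cell_size"),
    length(grid_variables(x))
  ))
  NextMethod()
}

#' Variable names of a soil grid
#' @param grid A `soil_grid`.
#' @return Character vector of layer names.
#' @export
grid_variables <- function(grid) {
  setdiff(names(grid), c("cell_i", "cell_j"))
}

#' Read / write soil grids as CSV
#'
#' The wide format has columns `cell_i`, `cell_j`, then one column per
#' variable; the long format has columns `cell_i`, `cell_j`, `variable`,
#' `value`. The format is detected from the header on read.
#'
#' @param file Path to a CSV file.
#' @param cell_size Cell edge length in metres.
#' @param grid A `soil_grid`.
#' @param format `"wide"` (default) or `"long"`.
#' @return `read_soil_grid()` returns a `soil_grid`; `write_soil_grid()`
#'   returns `file` invisibly.
#' @export
read_soil_grid <- function(file, cell_size = 20) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  if (all(c("variable", "value") %in% names(df))) {
    df <- tidyr::pivot_wider(df, names_from = "variable", values_from = "value")
  }
  soil_grid(df, cell_size = cell_size)
}

#' @rdname read_soil_grid
#' @export
write_soil_grid <- function(grid, file, format = c("wide", "long")) {
  format <- match.arg(format)
  out <- as_tibble(grid)
  if (format == "long") {
    out <- tidyr::pivot_longer(out, -c("cell_i", "cell_j"),
      names_to = "variable", values_to = "value"
    )
  }
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}

#' Read / write a stem census
#'
#' A stem census is a tibble with columns `species` (species code), `x`,
#' `y` (metres from the plot corner) and `dbh` (stem diameter in cm).
#'
#' @param file Path to a TSV file with header `species, x, y, dbh`.
#' @param census A census data frame.
#' @return `read_census()` returns a tibble; `write_census()` returns
#'   `file` invisibly.
#' @export
read_census <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  validate_census(df)
  df
}

#' @rdname read_census
#' @export
write_census <- function(census, file) {
  validate_census(census)
  readr::write_tsv(as_tibble(census), file, progress = FALSE)
  invisible(file)
}

validate_census <- function(census) {
  stopifnot(is.data.frame(census))
  need <- c("species", "x", "y", "dbh")
  miss <- setdiff(need, names(census))
  if (length(miss) > 0L) {
    abort(sprintf("Census is missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(census$x)) || any(!is.finite(census$y))) {
    abort("Census coordinates must be finite.")
  }
  if (any(!is.finite(census$dbh)) || any(census$dbh <= 0)) {
    abort("Census dbh values must be positive and finite.")
  }
  invisible(census)
}

#' Read / write a species trait table
#'
#' Columns: `species`, one column per trait, and `n_individuals` (the
#' number of stems behind each species' medians).
#'
#' @param file Path to a TSV file.
#' @param traits A trait data frame.
#' @return `read_traits()` returns a tibble; `write_traits()` returns
#'   `file` invisibly.
#' @export
read_traits <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, file) {
  readr::write_tsv(as_tibble(traits), file, progress = FALSE)
  invisible(file)
}

#' Map plot coordinates to grid cell indices
#'
#' Cells are half-open intervals `[i*s, (i+1)*s)` starting at the plot
#' corner, so `i = floor(x / s)`; points exactly on the far plot boundary
#' are clamped into the last cell so every in-bounds stem lands in exactly
#' one cell. Indices are 0-based.
#'
#' @param x,y Coordinates in metres (vectors of equal length).
#' @param cell_size Cell edge length in metres.
#' @param nx,ny Lattice extent in cells.
#' @return A tibble with integer columns `cell_i`, `cell_j`.
#' @export
#' @examples
#' assign_quadrat(c(0, 25.3, 1000), c(0, 47.9, 500), 20, 50, 25)
assign_quadrat <- function(x, y, cell_size = 20, nx, ny) {
  stopifnot(length(x) == length(y))
  assert_scalar_number(cell_size, "cell_size", lower = .Machine$double.eps)
  xmax <- nx * cell_size
  ymax <- ny * cell_size
  bad <- which(x < 0 | x > xmax | y < 0 | y > ymax | !is.finite(x) | !is.finite(y))
  if (length(bad) > 0L) {
    abort(sprintf(
      "%d record(s) out of plot bounds [0, %g] x [0, %g]; first offending record index: %d (x=%g, y=%g).",
      length(bad), xmax, ymax, bad[1], x[bad[1]], y[bad[1]]
    ))
  }
  tibble(
    cell_i = pmin(as.integer(floor(x / cell_size)), nx - 1L),
    cell_j = pmin(as.integer(floor(y / cell_size)), ny - 1L)
  )
}

#' Extract a soil value for every stem
#'
#' Looks up, for each census stem, the value of one grid variable in the
#' stem's cell. Stems falling in missing-value cells are excluded from the
#' output; their count is attached as the `n_excluded` attribute so the
#' overlay stays auditable (values kept + excluded = stems in).
#'
#' @param census A stem census data frame.
#' @param grid A `soil_grid`.
#' @param variable Name of the grid layer to extract.
#' @return The census tibble restricted to stems with a value, with added
#'   columns `cell_i`, `cell_j` and `value`; attribute `n_excluded` counts
#'   stems dropped for missing cells.
#' @export
stem_values <- function(census, grid, variable) {
  validate_census(census)
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  if (!variable %in% grid_variables(grid)) {
    abort(sprintf(
      "Unknown variable `%s`; available layers: %s.",
      variable, paste(grid_variables(grid), collapse = ", ")
    ))
  }
  cells <- assign_quadrat(
    census$x, census$y,
    cell_size = attr(grid, "cell_size"),
    nx = attr(grid, "nx"), ny = attr(grid, "ny")
  )
  out <- bind_cols(as_tibble(census), cells)
  lut <- as_tibble(grid)[c("cell_i", "cell_j", variable)]
  names(lut)[3] <- "value"
  out <- left_join(out, lut, by = c("cell_i", "cell_j"))
  n_excluded <- sum(is.na(out$value))
  out <- out[!is.na(out$value), ]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-species median soil associations
#'
#' The trait-file construction: filter the census to stems at least
#' `min_dbh` cm in diameter (inclusive), extract each stem's cell value for
#' every requested variable, and take the per-species median (mean of the
#' two middle order statistics at even counts). Species with no included
#' stems for a variable get `NA` there; species with no included stems at
#' all are omitted. `n_individuals` is the number of stems passing the
#' diameter filter (stems in missing cells still count as individuals;
#' they just contribute no value).
#'
#' @param census A stem census data frame.
#' @param grid A `soil_grid`.
#' @param variables Layer names to summarise (default: all layers).
#' @param min_dbh Minimum stem diameter in cm, inclusive (default 1).
#' @return A trait tibble: `species`, one column per variable,
#'   `n_individuals`; sorted by species code.
#' @export
species_medians <- function(census, grid, variables = NULL, min_dbh = 1) {
  validate_census(census)
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  variables <- variables %||% grid_variables(grid)
  missing_vars <- setdiff(variables, grid_variables(grid))
  if (length(missing_vars) > 0L) {
    abort(sprintf(
      "Unknown variable(s): %s; available layers: %s.",
      paste(missing_vars, collapse = ", "),
      paste(grid_variables(grid), collapse = ", ")
    ))
  }
  kept <- census[census$dbh >= min_dbh, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort(sprintf("No stems left after the dbh >= %g cm filter.", min_dbh))
  }
  counts <- kept |>
    as_tibble() |>
    dplyr::count(.data$species, name = "n_individuals")
  med <- purrr::map(variables, function(v) {
    vals <- stem_values(kept, grid, v)
    vals |>
      group_by(.data$species) |>
      summarise("{v}" := median(.data$value), .groups = "drop")
  })
  out <- Reduce(function(a, b) dplyr::full_join(a, b, by = "species"), med, counts)
  out <- out[, c("species", variables, "n_individuals")]
  arrange(out, .data$species)
}
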