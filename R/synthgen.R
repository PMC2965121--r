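# Synthetic study systems: a pure-birth phylogeny, Brownian species soil
# optima, a spatially autocorrelated multivariate soil landscape, and
# clustered habitat-filtered stem placement. The generator gives every
# pipeline stage a testbed with known truth.

#' Default per-variable calibration targets for synthetic soil landscapes
#'
#' Fifteen soil/topography variables with target means and ranges typical
#' of a lowland moist tropical forest plot on 20 m cells: Mehlich-3
#' extractable elements (mg element per kg dry soil), KCl-extractable
#' inorganic nitrogen and net N mineralization (mg N per kg soil per 28
#' days), pH, elevation (m) and slope (degrees). Generated layers are
#' affinely rescaled so each variable matches its target mean and stays
#' inside its target range.
#'
#' @return A tibble with columns `variable`, `mean`, `min`, `max`, `log`.
#' @export
default_soil_targets <- function() {
  tibble::tribble(
    ~variable, ~mean, ~min, ~max,
    "Al",   1012.1, 283.2, 1563.8,
    "B",    0.93,   0.04,  3.33,
    "Ca",   1697.3, 343.5, 4416.5,
    "Cu",   7.1,    1.3,   15.1,
    "Fe",   178.0,  51.1,  350.0,
    "K",    167.4,  58.2,  391.1,
    "Mg",   296.3,  43.9,  861.3,
    "Mn",   368.2,  9.4,   781.5,
    "P",    2.87,   0.30,  8.30,
    "Zn",   5.1,    0.9,   17.9,
    "N",    25.9,   12.5,  47.1,
    "Nmin", 17.9,  -11.7,  47.6,
    "pH",   4.67,   3.64,  5.35,
    "elev", 144.4,  121.3, 159.3,
    "slope", 4.33,  0.02,  16.66
  ) |>
    mutate(log = .data$variable %in% default_log_vars())
}

#' Define a synthetic scenario
#'
#' Bundles every knob of the synthetic study system. The defaults emulate
#' the sampling frame of a 50-ha (1000 m x 500 m) mapped forest plot
#' gridded at 20 m, with a pure-birth phylogeny scaled to unit root depth,
#' unit-rate Brownian evolution of species soil optima, a smooth
#' cross-correlated 15-variable soil landscape, and aggregated stems
#' placed by a parent-offspring (Thomas-type) cluster process filtered on
#' one designated driver variable.
#'
#' @param n_species Number of species (default 64).
#' @param total_stems Total stems to place (default 10000).
#' @param nx,ny,cell_size Landscape lattice: cells in x and y and cell
#'   edge in metres (defaults 50, 25, 20).
#' @param n_latent Latent spatial factors mixed into the variables
#'   (default 3).
#' @param bandwidth Gaussian smoothing bandwidth of the latent fields, in
#'   cells (default 3; 0 gives spatially white layers).
#' @param noise_sd Independent per-variable noise, in latent-field SD
#'   units (default 0.6).
#' @param targets Per-variable calibration table
#'   (default [default_soil_targets()]).
#' @param sigma2 Brownian rate of optimum evolution per unit branch length
#'   (default 1, matching the unit-depth tree so optima have roughly unit
#'   variance).
#' @param root_value Root optimum (default 0, on the standardized driver
#'   scale).
#' @param driver Variable whose standardized layer filters stem placement
#'   (default `"P"`).
#' @param tau Habitat-filter width in landscape SD units (default 0.5;
#'   small tau = strict filtering).
#' @param parents_per_species,scatter_sd Thomas-process clustering: parent
#'   points per species and offspring scatter SD in metres (defaults 5 and
#'   30).
#' @param abund_sdlog SD of log relative abundances (default 1).
#' @param min_abund Minimum stems guaranteed per species (default 5).
#' @param collapse_epsilon Internal branches shorter than this are
#'   collapsed into polytomies (default 0: keep the tree binary).
#' @param planted_clade Optional list `list(size =, shift =)`: after the
#'   Brownian simulation, shift the optima of one internal clade with
#'   `size` tips by `shift` landscape SD units, planting a known-positive
#'   node for power studies.
#' @param seed Integer seed driving every stochastic stage.
#' @return A `phylosoil_scenario` list.
#' @export
scenario <- function(n_species = 64, total_stems = 10000,
                     nx = 50, ny = 25, cell_size = 20,
                     n_latent = 3, bandwidth = 3, noise_sd = 0.6,
                     targets = default_soil_targets(),
                     sigma2 = 1, root_value = 0,
                     driver = "P", tau = 0.5,
                     parents_per_species = 5, scatter_sd = 30,
                     abund_sdlog = 1, min_abund = 5,
                     collapse_epsilon = 0,
                     planted_clade = NULL, seed = 1) {
  assert_scalar_number(n_species, "n_species", lower = 2)
  assert_scalar_number(total_stems, "total_stems", lower = 1)
  assert_scalar_number(tau, "tau", lower = 1e-12)
  assert_scalar_number(sigma2, "sigma2", lower = 0)
  assert_scalar_number(bandwidth, "bandwidth", lower = 0)
  stopifnot(is.data.frame(targets), all(c("variable", "mean", "min", "max") %in% names(targets)))
  if (any(targets$min >= targets$max)) abort("Every target range needs min < max.")
  if (!driver %in% targets$variable) {
    abort(sprintf("Driver `%s` is not among the target variables.", driver))
  }
  structure(
    list(
      n_species = as.integer(n_species), total_stems = as.integer(total_stems),
      nx = as.integer(nx), ny = as.integer(ny), cell_size = cell_size,
      n_latent = as.integer(n_latent), bandwidth = bandwidth, noise_sd = noise_sd,
      targets = as_tibble(targets),
      sigma2 = sigma2, root_value = root_value,
      driver = driver, tau = tau,
      parents_per_species = as.integer(parents_per_species),
      scatter_sd = scatter_sd,
      abund_sdlog = abund_sdlog, min_abund = as.integer(min_abund),
      collapse_epsilon = collapse_epsilon,
      planted_clade = planted_clade,
      seed = as.integer(seed)
    ),
    class = "phylosoil_scenario"
  )
}

#' Simulate a pure-birth phylogeny
#'
#' Constant-rate (Yule) speciation down to `n_species` tips; branch lengths
#' are rescaled so the root-to-tip depth is exactly 1, making the Brownian
#' rate directly interpretable as the expected tip variance.
#'
#' @param n_species Number of tips (at least 2).
#' @param seed Optional integer seed.
#' @return A rooted ultrametric `phylo`.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  assert_scalar_number(n_species, "n_species", lower = 2)
  tree <- with_seed_opt(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Collapse short internal branches into polytomies
#'
#' Internal branches strictly shorter than `epsilon` are removed and their
#' length absorbed into each child branch, so the tip set and every
#' root-to-tip distance are preserved exactly while the node becomes a
#' multifurcation. Useful for exercising the polytomy path of the contrast
#' engine with realistic soft polytomies.
#'
#' @param tree A rooted `phylo`.
#' @param epsilon Collapse threshold (same units as branch lengths).
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_short_branches <- function(tree, epsilon) {
  assert_scalar_number(epsilon, "epsilon", lower = 0)
  validate_phylo(tree)
  if (epsilon == 0) return(tree)
  n <- ape::Ntip(tree)
  root <- n + 1L
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  # items(): the child subtrees to attach at `node`, each as "str:length",
  # with `extra` length inherited from collapsed ancestors above them.
  items <- function(node, extra) {
    unlist(lapply(kids_of[[as.character(node)]], function(ch) {
      l <- blen[ch] + extra
      if (ch <= n) {
        paste0(tree$tip.label[ch], ":", fmt(l))
      } else if (blen[ch] < epsilon) {
        items(ch, extra = l)
      } else {
        paste0("(", paste(items(ch, 0), collapse = ","), "):", fmt(l))
      }
    }))
  }
  txt <- paste0("(", paste(items(root, 0), collapse = ","), ");")
  ape::read.tree(text = txt)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Each branch contributes an independent normal increment with variance
#' `sigma2` times its length; a tip's value is the root value plus the sum
#' of increments on its root path, so across replicates the tip covariance
#' equals `sigma2` times the tree covariance [phylo_vcv()].
#'
#' @param tree A rooted `phylo`.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root_value Value at the root.
#' @param seed Optional integer seed.
#' @return A named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  assert_scalar_number(sigma2, "sigma2", lower = 0)
  validate_phylo(tree)
  if (sigma2 == 0) {
    return(setNames(rep(root_value, ape::Ntip(tree)), tree$tip.label))
  }
  with_seed_opt(seed, {
    ape::rTraitCont(tree,
      model = "BM", sigma = sqrt(sigma2),
      root.value = root_value
    )
  })
}

# Gaussian kernel smoothing of an nx-by-ny matrix with reflective edges;
# bandwidth in cells, 0 = identity.
smooth_field <- function(mat, bandwidth) {
  if (bandwidth <= 0) return(mat)
  half <- max(1L, ceiling(3 * bandwidth))
  ker <- exp(-((-half:half)^2) / (2 * bandwidth^2))
  ker <- ker / sum(ker)
  pad_apply <- function(m) {
    # smooth along rows with reflective padding
    top <- m[rev(seq_len(min(half, nrow(m)))), , drop = FALSE]
    bot <- m[rev(nrow(m) + 1 - seq_len(min(half, nrow(m)))), , drop = FALSE]
    while (nrow(top) < half) top <- rbind(top[1, , drop = FALSE], top)
    while (nrow(bot) < half) bot <- rbind(bot, bot[nrow(bot), , drop = FALSE])
    mp <- rbind(top, m, bot)
    out <- apply(mp, 2, function(col) stats::filter(col, ker, sides = 2))
    out[(half + 1):(half + nrow(m)), , drop = FALSE]
  }
  sm <- pad_apply(mat)
  t(pad_apply(t(sm)))
}

#' Simulate a spatially autocorrelated, cross-correlated soil landscape
#'
#' Draws `n_latent` latent fields as Gaussian-kernel-smoothed white noise,
#' mixes them into one layer per target variable with random weights plus
#' independent noise, and affinely rescales each layer so its mean matches
#' the target mean and its values stay inside the target range. Variables
#' sharing latent factors are cross-correlated; the smoothing bandwidth
#' sets the spatial autocorrelation length.
#'
#' @param scn A `phylosoil_scenario` (or arguments accepted by
#'   [scenario()]).
#' @param seed Optional seed overriding the scenario's.
#' @return A complete (no missing cells) `soil_grid`.
#' @export
simulate_landscape <- function(scn = scenario(), seed = NULL) {
  stopifnot(inherits(scn, "phylosoil_scenario"))
  seed <- seed %||% derive_seed(scn$seed, 1L)
  nx <- scn$nx
  ny <- scn$ny
  with_seed_opt(seed, {
    latent <- lapply(seq_len(scn$n_latent), function(k) {
      f <- smooth_field(matrix(rnorm(nx * ny), nx, ny), scn$bandwidth)
      (f - mean(f)) / sd(f)
    })
    cells <- tidyr::expand_grid(cell_i = 0:(nx - 1), cell_j = 0:(ny - 1))
    for (r in seq_len(nrow(scn$targets))) {
      tg <- scn$targets[r, ]
      w <- rnorm(scn$n_latent)
      field <- Reduce(`+`, Map(`*`, latent, as.list(w)))
      field <- field + scn$noise_sd * matrix(rnorm(nx * ny), nx, ny)
      v <- field[cbind(cells$cell_i + 1L, cells$cell_j + 1L)]
      # Affine rescale: exact target mean, values inside the target range.
      vbar <- mean(v)
      spread_hi <- (tg$max - tg$mean) / max(v - vbar)
      spread_lo <- (tg$mean - tg$min) / max(vbar - v)
      out <- tg$mean + (v - vbar) * min(spread_hi, spread_lo)
      # guard the range contract against last-bit float overshoot
      cells[[tg$variable]] <- pmin(pmax(out, tg$min), tg$max)
    }
    soil_grid(cells, cell_size = scn$cell_size, nx = nx, ny = ny)
  })
}

#' Place clustered, habitat-filtered stems on a landscape
#'
#' A Thomas-type cluster process per species: parent points fall in cells
#' with probability proportional to
#' \eqn{\exp(-(z - o_s)^2 / (2\tau^2))}, where `z` is the standardized
#' driver layer and \eqn{o_s} the species optimum; stems scatter around a
#' random parent with isotropic Gaussian SD `scatter_sd` metres (redrawn
#' until inside the plot). Diameters are 1 cm plus an exponential deviate
#' calibrated so about 90% of stems are below 10 cm.
#'
#' @param grid A `soil_grid` containing the driver layer.
#' @param optima Named numeric vector of species optima on the
#'   standardized driver scale.
#' @param abundances Named integer vector of stem counts per species
#'   (names matching `optima`); the census contains exactly
#'   `sum(abundances)` stems.
#' @param driver Driver layer name.
#' @param tau Habitat-filter width (landscape SD units).
#' @param parents_per_species,scatter_sd Clustering parameters.
#' @param seed Optional integer seed.
#' @return A stem census tibble (`species`, `x`, `y`, `dbh`).
#' @export
place_stems <- function(grid, optima, abundances, driver, tau = 0.5,
                        parents_per_species = 5, scatter_sd = 30,
                        seed = NULL) {
  if (!inherits(grid, "soil_grid")) abort("`grid` must be a `soil_grid`.")
  if (!driver %in% grid_variables(grid)) {
    abort(sprintf("Driver `%s` is not a grid layer.", driver))
  }
  stopifnot(length(optima) == length(abundances))
  if (!setequal(names(optima), names(abundances))) {
    abort("`optima` and `abundances` must be named for the same species.")
  }
  z_raw <- grid[[driver]]
  if (all(is.na(z_raw))) abort("Driver layer is entirely missing; cannot place stems.")
  z <- (z_raw - mean(z_raw, na.rm = TRUE)) / sd(z_raw, na.rm = TRUE)
  ok <- which(!is.na(z))
  s <- attr(grid, "cell_size")
  xmax <- attr(grid, "nx") * s
  ymax <- attr(grid, "ny") * s
  with_seed_opt(seed, {
    out <- purrr::map(names(optima), function(sp) {
      m <- abundances[[sp]]
      if (m == 0L) return(NULL)
      logw <- -(z[ok] - optima[[sp]])^2 / (2 * tau^2)
      w <- exp(logw - max(logw))
      pcell <- sample(ok, parents_per_species, replace = TRUE, prob = w)
      px <- (grid$cell_i[pcell] + runif(parents_per_species)) * s
      py <- (grid$cell_j[pcell] + runif(parents_per_species)) * s
      pick <- sample.int(parents_per_species, m, replace = TRUE)
      x <- px[pick] + rnorm(m, 0, scatter_sd)
      y <- py[pick] + rnorm(m, 0, scatter_sd)
      bad <- which(x < 0 | x > xmax | y < 0 | y > ymax)
      while (length(bad) > 0L) {
        x[bad] <- px[pick[bad]] + rnorm(length(bad), 0, scatter_sd)
        y[bad] <- py[pick[bad]] + rnorm(length(bad), 0, scatter_sd)
        bad <- bad[x[bad] < 0 | x[bad] > xmax | y[bad] < 0 | y[bad] > ymax]
      }
      tibble(species = sp, x = x, y = y, dbh = 1 + rexp(m, rate = log(10) / 9))
    })
    bind_rows(out)
  })
}

# Stem counts per species: a lognormal abundance profile with a guaranteed
# floor, summing exactly to total_stems.
draw_abundances <- function(n_species, total_stems, sdlog, min_abund, labels) {
  floor_total <- min_abund * n_species
  if (floor_total > total_stems) {
    abort(sprintf(
      "total_stems (%d) cannot cover the per-species floor of %d x %d.",
      total_stems, min_abund, n_species
    ))
  }
  w <- exp(rnorm(n_species, 0, sdlog))
  extra <- as.vector(rmultinom(1, total_stems - floor_total, prob = w))
  setNames(as.integer(min_abund + extra), labels)
}

# Pick an internal node with exactly `size` descendant tips, or NULL.
find_clade_of_size <- function(tree, size) {
  n <- ape::Ntip(tree)
  W <- node_weight_matrices(tree)
  hit <- which(W$n_tips == size & W$nodes != n + 1L)
  if (length(hit) == 0L) return(NULL)
  nd <- W$nodes[hit[1]]
  list(node = nd, tips = tree$tip.label[W$tip[hit[1], ] > 0])
}

#' Generate a full synthetic study system
#'
#' Runs every generator stage of a scenario end to end: tree (optionally
#' collapsed to polytomies), Brownian species optima (optionally with a
#' planted shifted clade), landscape, abundances, and clustered
#' habitat-filtered stem placement. Also places a *null* census from
#' optima shuffled across species: the optimum multiset (and hence every
#' marginal) is preserved while phylogenetic conservatism is destroyed,
#' giving a matched negative control.
#'
#' @param scn A `phylosoil_scenario`.
#' @return A list of class `phylosoil_bundle`: `tree`, `grid`, `census`,
#'   `null_census`, and `truth` (optima, shuffled optima, abundances,
#'   driver, sigma2, tau, seed, and — when planted — `planted_node` and
#'   `planted_tips`).
#' @export
make_scenario_bundle <- function(scn = scenario()) {
  stopifnot(inherits(scn, "phylosoil_scenario"))
  tree <- simulate_tree(scn$n_species, seed = derive_seed(scn$seed, 2L))
  if (scn$collapse_epsilon > 0) {
    tree <- collapse_short_branches(tree, scn$collapse_epsilon)
  }
  planted <- NULL
  if (!is.null(scn$planted_clade)) {
    size <- scn$planted_clade$size
    # Redraw the tree (bounded retries) until a clade of the exact size
    # exists; pure-birth trees of moderate size usually contain one.
    for (try in 0:49) {
      planted <- find_clade_of_size(tree, size)
      if (!is.null(planted)) break
      tree <- simulate_tree(scn$n_species, seed = derive_seed(scn$seed, 100L + try))
      if (scn$collapse_epsilon > 0) {
        tree <- collapse_short_branches(tree, scn$collapse_epsilon)
      }
    }
    if (is.null(planted)) {
      abort(sprintf("Could not find a clade of exactly %d tips in 50 tree draws.", size))
    }
  }
  optima <- simulate_bm(tree,
    sigma2 = scn$sigma2, root_value = scn$root_value,
    seed = derive_seed(scn$seed, 3L)
  )
  if (!is.null(planted)) {
    optima[planted$tips] <- optima[planted$tips] + scn$planted_clade$shift
  }
  grid <- simulate_landscape(scn)
  abund <- with_seed_opt(derive_seed(scn$seed, 4L), {
    draw_abundances(
      scn$n_species, scn$total_stems, scn$abund_sdlog,
      scn$min_abund, tree$tip.label
    )
  })
  census <- place_stems(grid, optima, abund,
    driver = scn$driver, tau = scn$tau,
    parents_per_species = scn$parents_per_species,
    scatter_sd = scn$scatter_sd,
    seed = derive_seed(scn$seed, 5L)
  )
  shuffled <- with_seed_opt(derive_seed(scn$seed, 6L), {
    setNames(sample(unname(optima)), names(optima))
  })
  null_census <- place_stems(grid, shuffled, abund,
    driver = scn$driver, tau = scn$tau,
    parents_per_species = scn$parents_per_species,
    scatter_sd = scn$scatter_sd,
    seed = derive_seed(scn$seed, 7L)
  )
  structure(
    list(
      tree = tree, grid = grid, census = census, null_census = null_census,
      truth = list(
        optima = optima, shuffled_optima = shuffled, abundances = abund,
        driver = scn$driver, sigma2 = scn$sigma2, tau = scn$tau,
        seed = scn$seed,
        planted_node = if (!is.null(planted)) planted$node else NULL,
        planted_tips = if (!is.null(planted)) planted$tips else NULL
      )
    ),
    class = "phylosoil_bundle"
  )
}

#' @export
print.phylosoil_bundle <- function(x, ...) {
  cat(sprintf(
    "<phylosoil_bundle> %d species, %d stems on a %d x %d grid\n",
    ape::Ntip(x$tree), nrow(x$census), attr(x$grid, "nx"), attr(x$grid, "ny")
  ))
  if (!is.null(x$truth$planted_node)) {
    cat(sprintf(
      "  planted clade: node %d (%d tips)\n",
      x$truth$planted_node, length(x$truth$planted_tips)
    ))
  }
  invisible(x)
}
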