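test_that("contrasts reproduce the hand-worked small cases", {
  two <- read_newick("(A:1,B:1);")
  ic2 <- independent_contrasts(
    tibble::tibble(species = c("A", "B"), z = c(3, 1)), two, "z"
  )
  expect_equal(abs(ic2$contrast), 2 / sqrt(2), tolerance = 1e-9)

  case <- four_tip_case()
  ic <- independent_contrasts(case$traits, case$tree, "z")
  expect_equal(sort(abs(ic$contrast)), c(0, 0, 10 / sqrt(3)), tolerance = 1e-9)
  # root child branches adjusted to 1 + 1*1/(1+1) = 1.5
  root <- ape::Ntip(case$tree) + 1L
  expect_equal(ic$adj_branch[ic$node != root], c(1.5, 1.5), tolerance = 1e-9)
  expect_equal(mean(abs(ic$contrast)), 1.92450, tolerance = 1e-5)

  # constant traits give identically zero contrasts
  const <- tibble::tibble(species = c("A", "B", "C", "D"), z = rep(4.2, 4))
  expect_equal(independent_contrasts(const, case$tree, "z")$contrast, rep(0, 3))
})

test_that("contrast engine matches ape::pic on bifurcating trees", {
  set.seed(71)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:15, 1))
    x <- rnorm(ape::Ntip(tr))
    mine <- independent_contrasts(
      tibble::tibble(species = tr$tip.label, z = x), tr, "z"
    )
    ref <- ape::pic(stats::setNames(x, tr$tip.label), tr)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref))), tolerance = 1e-9)
  }
})

test_that("contrast engine matches the brute-force recursion, polytomies included", {
  set.seed(81)
  n_poly <- 0L
  for (i in 1:200) {
    tr <- random_test_tree(sample(4:8, 1))
    if (any(tabulate(tr$edge[, 1]) > 2)) n_poly <- n_poly + 1L
    x <- rnorm(ape::Ntip(tr))
    mine <- independent_contrasts(
      tibble::tibble(species = tr$tip.label, z = x), tr, "z"
    )
    ref <- oracle_contrasts(tr, x)
    mine <- mine[order(mine$node), ]
    ref <- ref[order(ref$node), ]
    expect_equal(mine$contrast, ref$contrast, tolerance = 1e-9)
    expect_equal(mine$node_value, ref$node_value, tolerance = 1e-9)
  }
  expect_gt(n_poly, 20L) # the sample genuinely exercises the polytomy path
})

test_that("errors name the offending tip or node", {
  case <- four_tip_case()
  miss <- tibble::tibble(species = c("A", "B", "C"), z = 1:3)
  expect_error(independent_contrasts(miss, case$tree, "z"), "Tips without trait rows: D")
  na_tab <- tibble::tibble(species = c("A", "B", "C", "D"), z = c(1, NA, 3, 4))
  expect_error(independent_contrasts(na_tab, case$tree, "z"), "Non-finite `z`.*B")
})

test_that("standardized contrasts under Brownian motion are i.i.d. with the simulation rate", {
  set.seed(91)
  tr <- simulate_tree(24)
  sigma2 <- 2.5
  cons <- unlist(lapply(1:150, function(i) {
    x <- simulate_bm(tr, sigma2 = sigma2)
    independent_contrasts(
      tibble::tibble(species = names(x), z = unname(x)), tr, "z"
    )$contrast
  }))
  # variance ratio within sampling error of 1
  expect_equal(var(cons) / sigma2, 1, tolerance = 0.12)
  expect_equal(mean(cons), 0, tolerance = 0.05)
})

test_that("phylogeny-wide signal matches exact enumeration on the worked example", {
  case <- four_tip_case()
  obs <- mean(abs(independent_contrasts(case$traits, case$tree, "z")$contrast))
  expect_equal(obs, 1.92450, tolerance = 1e-5)
  vals <- case$traits$z
  stats_all <- vapply(all_perms(4), function(p) {
    tab <- tibble::tibble(species = case$traits$species, z = vals[p])
    mean(abs(independent_contrasts(tab, case$tree, "z")$contrast))
  }, numeric(1))
  p_low_exact <- mean(stats_all <= obs + 1e-12)
  expect_equal(p_low_exact, 2 / 6, tolerance = 1e-12)

  mc <- phylogeny_wide_signal(case$traits, case$tree, "z", R = 999, seed = 17)
  se3 <- 3 * sqrt(p_low_exact * (1 - p_low_exact) / 999)
  expect_lt(abs(mc$p_low - p_low_exact), se3)
})

test_that("signal p values use the add-one rule with ties extreme", {
  case <- four_tip_case()
  const <- tibble::tibble(species = case$traits$species, z = rep(1, 4))
  s <- phylogeny_wide_signal(const, case$tree, "z", R = 99, seed = 1)
  expect_equal(s$observed, 0)
  expect_equal(s$p_low, 1) # every null draw ties the observed zero
  expect_equal(s$p_high, 1)
  expect_error(phylogeny_wide_signal(case$traits, case$tree, "z", R = 0), "R")
})

test_that("phylogeny-wide p is uniform under tip-exchangeable traits", {
  set.seed(101)
  tr <- simulate_tree(12)
  ps <- vapply(1:500, function(i) {
    tab <- tibble::tibble(species = tr$tip.label, z = rnorm(12))
    phylogeny_wide_signal(tab, tr, "z", R = 99)$p_low
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Blomberg's K is exactly 1 on equal-depth star trees", {
  set.seed(111)
  for (n in c(5, 20)) {
    star <- ape::stree(n, type = "star")
    star$edge.length <- rep(runif(1, 0.5, 3), n)
    star$tip.label <- paste0("t", seq_len(n))
    for (i in 1:5) {
      tab <- tibble::tibble(species = star$tip.label, z = rnorm(n))
      expect_equal(blomberg_k(tab, star, "z")$K, 1, tolerance = 1e-9)
    }
  }
})

test_that("K agrees with picante and is invariant to affine traits and branch rescaling", {
  set.seed(121)
  for (i in 1:10) {
    tr <- ape::rtree(sample(6:20, 1))
    x <- rnorm(ape::Ntip(tr))
    tab <- tibble::tibble(species = tr$tip.label, z = x)
    k1 <- blomberg_k(tab, tr, "z")$K
    expect_equal(k1, as.numeric(picante::Kcalc(setNames(x, tr$tip.label), tr)),
      tolerance = 1e-9
    )
    # affine trait invariance
    tab2 <- tibble::tibble(species = tr$tip.label, z = -3.7 * x + 11)
    expect_equal(blomberg_k(tab2, tr, "z")$K, k1, tolerance = 1e-9)
    # global branch-length rescaling invariance
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * 42
    expect_equal(blomberg_k(tab, tr2, "z")$K, k1, tolerance = 1e-9)
  }
})

test_that("K errors on constant traits", {
  case <- four_tip_case()
  const <- tibble::tibble(species = case$traits$species, z = rep(2, 4))
  expect_error(blomberg_k(const, case$tree, "z"), "constant across tips")
})

test_that("k_significance applies the doubled-tail rule and records the seed", {
  set.seed(131)
  tr <- simulate_tree(16)
  x <- simulate_bm(tr)
  tab <- tibble::tibble(species = names(x), z = unname(x))
  k <- k_significance(tab, tr, "z", R = 199, seed = 23)
  expect_equal(length(k$null), 199L)
  expect_equal(k$seed, 23)
  p_hi <- (sum(k$null >= k$K) + 1) / 200
  p_lo <- (sum(k$null <= k$K) + 1) / 200
  expect_equal(k$p_two_tailed, min(1, 2 * min(p_hi, p_lo)))
  # determinism
  k2 <- k_significance(tab, tr, "z", R = 199, seed = 23)
  expect_identical(k$null, k2$null)
})

test_that("K detects strong conservatism on deep trees", {
  set.seed(141)
  tr <- simulate_tree(40)
  # amplify conservatism: traits follow deep clade structure
  deep <- ifelse(seq_len(40) <= 20, 0, 5)
  ord <- order(match(tr$tip.label, tr$tip.label))
  # use clade membership of the two root daughters
  root_kids <- tr$edge[tr$edge[, 1] == 41, 2]
  grp <- as.integer(tr$tip.label %in% ape::extract.clade(tr, root_kids[1])$tip.label)
  tab <- tibble::tibble(species = tr$tip.label, z = 5 * grp + rnorm(40, 0, 0.3))
  k <- k_significance(tab, tr, "z", R = 199, seed = 5)
  expect_lt(k$p_two_tailed, 0.05)
})
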