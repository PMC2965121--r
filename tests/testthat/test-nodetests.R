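test_that("tip and ancestral means follow their definitions", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  tab <- tibble::tibble(species = c("A", "B", "C"), z = c(0, 0, 6))
  root <- 4L
  tm <- tip_means(tab, tr, "z")
  am <- ancestral_means(tab, tr, "z")
  expect_equal(tm$mean[tm$node == root], 2) # grand mean
  expect_equal(tm$mean[tm$node != root], 0) # cherry (A,B)
  expect_equal(am$mean[am$node != root], 0)
  expect_equal(am$mean[am$node == root], 3) # mean(cherry value 0, C 6)

  # cherries agree under both methods; balanced trees agree everywhere
  case <- four_tip_case()
  tmb <- tip_means(case$traits, case$tree, "z")
  amb <- ancestral_means(case$traits, case$tree, "z")
  expect_equal(tmb$mean, amb$mean)
})

test_that("node permutation test matches exact enumeration on the worked example", {
  case <- four_tip_case()
  nt <- node_permutation_test(case$traits, case$tree, "z", R = 999, seed = 31)
  cd <- which(purrr::map_lgl(nt$species, ~ setequal(.x, c("C", "D"))))
  expect_equal(nt$tip_mean[cd], 10)
  # enumeration: node means over all 24 assignments = {10,5,...,0}
  means_all <- vapply(all_perms(4), function(p) {
    tab <- tibble::tibble(species = case$traits$species, z = case$traits$z[p])
    tm <- tip_means(tab, case$tree, "z")
    tm$mean[tm$node == nt$node[cd]]
  }, numeric(1))
  p_high_exact <- mean(means_all >= 10 - 1e-12)
  expect_equal(p_high_exact, 1 / 6, tolerance = 1e-12)
  se3 <- 3 * sqrt(p_high_exact * (1 - p_high_exact) / 999)
  expect_lt(abs(nt$p_high_tip[cd] - p_high_exact), se3)
})

test_that("Monte-Carlo p agrees with exact enumeration on a 5-tip tree", {
  set.seed(41)
  tr <- random_test_tree(5, p_poly = 0)
  x <- c(2.3, -1.1, 0.4, 5.0, 1.7)
  tab <- tibble::tibble(species = tr$tip.label, z = x)
  nt <- node_permutation_test(tab, tr, "z", R = 999, seed = 42)
  perms <- all_perms(5)
  for (row in seq_len(nrow(nt))) {
    means_all <- vapply(perms, function(p) {
      tm <- tip_means(tibble::tibble(species = tr$tip.label, z = x[p]), tr, "z")
      tm$mean[tm$node == nt$node[row]]
    }, numeric(1))
    p_exact <- mean(means_all >= nt$tip_mean[row] - 1e-12)
    se3 <- 3 * sqrt(max(p_exact * (1 - p_exact), 1 / 999) / 999)
    expect_lt(abs(nt$p_high_tip[row] - p_exact), se3 + 1 / 999)
  }
})

test_that("the root's tip-average is permutation invariant (p = 1)", {
  set.seed(51)
  tr <- simulate_tree(10)
  tab <- tibble::tibble(species = tr$tip.label, z = rnorm(10))
  nt <- node_permutation_test(tab, tr, "z", R = 99, seed = 1)
  root <- ape::Ntip(tr) + 1L
  expect_equal(nt$p_low_tip[nt$node == root], 1)
  expect_equal(nt$p_high_tip[nt$node == root], 1)
  expect_false(nt$significant_both_low[nt$node == root])
  expect_false(nt$significant_both_high[nt$node == root])
})

test_that("subtended species lists partition consistently with the tree", {
  set.seed(61)
  tr <- random_test_tree(12)
  tab <- tibble::tibble(species = tr$tip.label, z = rnorm(ape::Ntip(tr)))
  nt <- node_permutation_test(tab, tr, "z", R = 19, seed = 1)
  root <- ape::Ntip(tr) + 1L
  expect_setequal(nt$species[[which(nt$node == root)]], tr$tip.label)
  expect_equal(
    nt$tip_mean[nt$node == root],
    mean(tab$z),
    tolerance = 1e-12
  )
  for (row in seq_len(nrow(nt))) {
    kids <- tr$edge[tr$edge[, 1] == nt$node[row], 2]
    kid_rows <- match(kids[kids > ape::Ntip(tr)], nt$node)
    kid_tips <- c(
      tr$tip.label[kids[kids <= ape::Ntip(tr)]],
      unlist(nt$species[kid_rows])
    )
    expect_setequal(nt$species[[row]], kid_tips)
    expect_equal(anyDuplicated(kid_tips), 0L)
  }
})

test_that("identical seeds give identical results; parameters are checked", {
  set.seed(71)
  tr <- simulate_tree(8)
  tab <- tibble::tibble(species = tr$tip.label, z = rnorm(8))
  a <- node_permutation_test(tab, tr, "z", R = 199, seed = 9)
  b <- node_permutation_test(tab, tr, "z", R = 199, seed = 9)
  expect_identical(a, b)
  expect_error(node_permutation_test(tab, tr, "z", R = 0), "R")
  expect_error(node_permutation_test(tab, tr, "z", alpha = 0.6), "alpha")
})

test_that("marginal type-I rate is nominal under exchangeable traits", {
  set.seed(81)
  tr <- simulate_tree(16)
  root <- ape::Ntip(tr) + 1L
  hits <- unlist(lapply(1:300, function(i) {
    tab <- tibble::tibble(species = tr$tip.label, z = rnorm(16))
    nt <- node_permutation_test(tab, tr, "z", R = 99)
    nr <- nt$node != root
    c(nt$p_low_tip[nr] <= 0.05, nt$p_high_tip[nr] <= 0.05)
  }))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("the both-methods rule is never less conservative than tip-only", {
  set.seed(91)
  for (i in 1:25) {
    tr <- random_test_tree(sample(6:14, 1))
    tab <- tibble::tibble(species = tr$tip.label, z = rnorm(ape::Ntip(tr)))
    nt <- node_permutation_test(tab, tr, "z", R = 99)
    both <- sum(nt$significant_both_high) + sum(nt$significant_both_low)
    tip_only <- sum(nt$p_high_tip <= 0.05) + sum(nt$p_low_tip <= 0.05)
    expect_lte(both, tip_only)
  }
})

# A fixture with a strongly shifted clade {E,F,G} in which G is rare
# (2 individuals): the clade's signal survives dropping G, so the node is
# retained with a flag.
loo_fixture <- function() {
  tree <- read_newick(
    "((((A:1,B:1):1,(C:1,D:1):1):1,H:3):1,((E:1,F:1):1,G:2):1);"
  )
  traits <- tibble::tibble(
    species = LETTERS[1:8],
    z = c(0, 0.2, -0.1, 0.1, 10, 10.4, 9.8, 0.3),
    n_individuals = c(50L, 40L, 30L, 60L, 80L, 90L, 2L, 70L)
  )
  list(tree = tree, traits = traits)
}

test_that("rare-species filter keeps nodes whose signal survives leave-one-out", {
  fx <- loo_fixture()
  nt <- node_permutation_test(fx$traits, fx$tree, "z", R = 999, seed = 3)
  efg <- which(purrr::map_lgl(nt$species, ~ setequal(.x, c("E", "F", "G"))))
  expect_true(nt$significant_both_high[efg])
  kept <- filter_and_flag(nt, fx$traits, fx$tree, min_individuals = 5)
  krow <- which(purrr::map_lgl(kept$species, ~ setequal(.x, c("E", "F", "G"))))
  expect_length(krow, 1L) # retained: {E,F} alone is still extreme
  expect_true(kept$min_count_flag[krow])
  expect_false(kept$loo_dependent[krow])
  # every reported node flags rare membership where present
  for (row in seq_len(nrow(kept))) {
    expect_equal(kept$min_count_flag[row], any(kept$counts[[row]] < 5))
  }
})

test_that("nodes whose significance hinges on a rare species are excluded", {
  # 12 tips; G carries an extreme value but only 2 individuals. The node
  # {E,F,G,H} is significant only because of G: with G removed, {E,F,H}
  # sits mid-distribution and the signal vanishes.
  tree <- read_newick(paste0(
    "((((A:1,B:1):1,(C:1,D:1):1):1,(I:1,(J:1,(K:1,L:1):1):1):1):1,",
    "((E:1,F:1):1,(G:1,H:1):1):1);"
  ))
  traits <- tibble::tibble(
    species = LETTERS[1:12],
    z = c(
      0.6, 0.3, 0.55, 0.35, 0.62, 0.58, 100, 0.66,
      0.65, 0.25, 0.7, 0.2
    ),
    n_individuals = c(rep(50L, 6), 2L, rep(50L, 5))
  )
  nt <- node_permutation_test(traits, tree, "z", R = 999, seed = 11)
  efgh <- which(purrr::map_lgl(nt$species, ~ setequal(.x, c("E", "F", "G", "H"))))
  expect_true(nt$significant_both_high[efgh])
  kept <- filter_and_flag(nt, traits, tree, min_individuals = 5)
  expect_false(any(purrr::map_lgl(kept$species, ~ setequal(.x, c("E", "F", "G", "H")))))
})

test_that("require_both drops nodes significant under a single method only", {
  set.seed(101)
  found <- FALSE
  for (i in 1:40) {
    tr <- random_test_tree(sample(8:14, 1))
    tab <- tibble::tibble(
      species = tr$tip.label, z = rnorm(ape::Ntip(tr)),
      n_individuals = rep(50L, ape::Ntip(tr))
    )
    nt <- node_permutation_test(tab, tr, "z", R = 199, seed = i)
    one_method <- (nt$p_high_tip <= 0.05 & !nt$significant_both_high)
    if (any(one_method)) {
      found <- TRUE
      kept <- filter_and_flag(nt, tab, tr, require_both = TRUE)
      bad <- nt$node[one_method & !(nt$p_low_tip <= 0.05 & nt$p_low_anc <= 0.05)]
      kept_high <- kept$node[kept$sig_high]
      expect_false(any(bad %in% kept_high))
      break
    }
  }
  expect_true(found)
})

test_that("PCA traits report only the high tail when pca_high_only", {
  fx <- loo_fixture()
  names(fx$traits)[2] <- "PCA1"
  nt <- node_permutation_test(fx$traits, fx$tree, "PCA1", R = 999, seed = 3)
  expect_true(any(nt$significant_both_low)) # the low {A..D} side exists
  kept <- filter_and_flag(nt, fx$traits, fx$tree, pca_high_only = TRUE)
  expect_false(any(kept$sig_low))
  kept2 <- filter_and_flag(nt, fx$traits, fx$tree, pca_high_only = FALSE)
  expect_true(any(kept2$sig_low))
  # full results retained either way
  expect_true(any(attr(kept, "full")$significant_both_low))
})

test_that("node tables render counts in species order and sort by trait then p", {
  fx <- loo_fixture()
  nt <- node_permutation_test(fx$traits, fx$tree, "z", R = 999, seed = 3)
  kept <- filter_and_flag(nt, fx$traits, fx$tree)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_node_tables(kept, f, tail = "high")
  expect_true(file.exists(f))
  expect_false(is.unsorted(tab$t_p))
  for (row in seq_len(nrow(tab))) {
    sp <- strsplit(tab$species[row], ", ")[[1]]
    cnt <- as.integer(strsplit(tab$n_individuals[row], ", ")[[1]])
    expect_equal(
      cnt,
      fx$traits$n_individuals[match(sp, fx$traits$species)]
    )
  }
  # no significant nodes -> header-only file (values arranged so every
  # clade mean sits at the centre of the null)
  flat <- tibble::tibble(
    species = LETTERS[1:8],
    z = c(0.7, 0, 0.6, 0.1, 0.5, 0.2, 0.35, 0.35),
    n_individuals = rep(50L, 8)
  )
  nt0 <- node_permutation_test(flat, fx$tree, "z", R = 999, seed = 4)
  kept0 <- filter_and_flag(nt0, flat, fx$tree)
  f0 <- withr::local_tempfile(fileext = ".tsv")
  tab0 <- write_node_tables(kept0, f0, tail = "high")
  expect_equal(nrow(tab0), 0L)
  expect_equal(length(readLines(f0)), 1L)
})
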