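# Independent oracles, coded from first principles (recursive, no shared
# code with the package's iterative engines).

# Brute-force recursive contrast computation. Same definitions as the
# package documents (including the rank-split polytomy rule), derived
# independently as a direct recursion over the tree.
oracle_contrasts <- function(tree, x) {
  n <- ape::Ntip(tree)
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  rows <- list()
  combine <- function(v, b) {
    if (any(b == 0)) {
      c(mean(v[b == 0]), 0)
    } else {
      c(sum(v / b) / sum(1 / b), 1 / sum(1 / b))
    }
  }
  recurse <- function(nd) {
    if (nd <= n) {
      return(c(x[nd], blen[nd]))
    }
    kids <- sort(kids_of[[as.character(nd)]])
    sub <- vapply(kids, recurse, numeric(2))
    v <- sub[1, ]
    b <- sub[2, ]
    if (length(kids) == 2L) {
      raw <- v[1] - v[2]
      grp_lo <- c(v[1], b[1])
      grp_hi <- c(v[2], b[2])
    } else {
      ord <- order(v, kids)
      g <- ceiling(length(kids) / 2)
      grp_lo <- combine(v[ord[seq_len(g)]], b[ord[seq_len(g)]])
      grp_hi <- combine(v[ord[-seq_len(g)]], b[ord[-seq_len(g)]])
      raw <- grp_hi[1] - grp_lo[1]
    }
    bsum <- grp_lo[2] + grp_hi[2]
    est <- combine(c(grp_lo[1], grp_hi[1]), c(grp_lo[2], grp_hi[2]))
    rows[[length(rows) + 1L]] <<- data.frame(
      node = nd, contrast = raw / sqrt(bsum), node_value = est[1]
    )
    c(est[1], blen[nd] + grp_lo[2] * grp_hi[2] / bsum)
  }
  recurse(n + 1L)
  do.call(rbind, rows)
}

# Root-to-node distance by explicit parent walking.
oracle_node_depth <- function(tree, nd) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  d <- 0
  while (nd != n + 1L) {
    d <- d + blen[nd]
    nd <- parent[nd]
  }
  d
}

# Shared root-path length of two tips = depth of their MRCA.
oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  mrcas <- ape::mrca(tree)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- if (i == j) oracle_node_depth(tree, i) else oracle_node_depth(tree, mrcas[i, j])
    }
  }
  V
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Random tree with random branch lengths; with probability p_poly, short
# internal branches are collapsed by ape (independent of package code),
# yielding polytomies.
random_test_tree <- function(n, p_poly = 0.5) {
  tree <- ape::rtree(n)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 2)
  if (runif(1) < p_poly && n > 3) {
    tree <- ape::di2multi(tree, tol = 0.45)
  }
  tree
}

# Lag-1 spatial autocorrelation of a grid layer: correlation between each
# cell and its east/north neighbour.
lag1_autocor <- function(grid, variable) {
  df <- as.data.frame(grid)[c("cell_i", "cell_j", variable)]
  names(df)[3] <- "v"
  east <- merge(df, transform(df, cell_i = cell_i - 1L), by = c("cell_i", "cell_j"))
  north <- merge(df, transform(df, cell_j = cell_j - 1L), by = c("cell_i", "cell_j"))
  stats::cor(c(east$v.x, north$v.x), c(east$v.y, north$v.y))
}

# A small hand-checkable trait table on four species.
four_tip_case <- function() {
  list(
    tree = read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
    traits = tibble::tibble(species = c("A", "B", "C", "D"), z = c(0, 0, 10, 10))
  )
}
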