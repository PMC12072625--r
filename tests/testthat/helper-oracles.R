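# Independent oracles used across test files.

# Connected components under 26-connectivity by a route independent of the
# package's union-find: pairwise Chebyshev adjacency fed to igraph.
oracle_components26 <- function(mask) {
  idx <- which(mask != 0)
  n <- length(idx)
  if (n == 0) return(integer(0))
  coords <- arrayInd(idx, dim(mask))
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      cheb <- pmax(abs(coords[js, 1] - coords[i, 1]),
                   pmax(abs(coords[js, 2] - coords[i, 2]),
                        abs(coords[js, 3] - coords[i, 3])))
      hit <- js[cheb == 1]
      if (length(hit)) edges <- rbind(edges, cbind(i, hit))
    }
  }
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_len(n), seq_len(n))),
                                   directed = FALSE)
  igraph::components(g)$membership
}

# Exact two-sided Mann-Whitney p-value by full enumeration over all
# C(n1 + n2, n1) group assignments (tie-free data only).
oracle_mw_exact_p <- function(low, high) {
  n1 <- length(low)
  vals <- c(low, high)
  stopifnot(!any(duplicated(vals)))
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(length(vals), n1)
  u_all <- apply(assignments, 2, function(ix) {
    sum(rank(vals)[ix]) - n1 * (n1 + 1) / 2
  })
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Spearman rho by hand: average ranks, then the Pearson formula on ranks.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random sparse small mask in a small grid.
random_small_mask <- function(dims = c(8, 8, 5), density = 0.15) {
  array(stats::runif(prod(dims)) < density, dims)
}

# A cohort spec with all effects off: symptomatic and asymptomatic groups
# identical in law.
null_cohort_spec <- function(seed) {
  cohort_spec(sex_effect = 0, effects = NULL, seed = seed)
}
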