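# Independent brute-force oracles used across the suite. They recompute
# quantities from raw edge lists / full enumeration, never through the
# package's own code paths.

# Degree-based layer classifier working directly on the raw edge list.
brute_layers <- function(net, scheme = c("simple", "stringent")) {
  scheme <- match.arg(scheme)
  nodes <- net$nodes
  e <- net$edges
  out <- vapply(nodes, function(v) sum(e$source == v), numeric(1))
  inn <- vapply(nodes, function(v) sum(e$target == v), numeric(1))
  lab <- character(length(nodes))
  for (i in seq_along(nodes)) {
    o <- out[i]
    k <- inn[i]
    lab[i] <- if (scheme == "simple") {
      if (o > 0 && k == 0) "TOP"
      else if (o > 0 && k > 0) "MID"
      else if (k > 0) "BOT"
      else "OUTGROUP"
    } else {
      if (o >= 2 && k <= 1) "TOP"
      else if (o >= 2 && k >= 2) "MID"
      else if (o <= 1 && k >= 2) "BOT"
      else "OUTGROUP"
    }
  }
  setNames(lab, nodes)
}

# Random directed graph (possibly with isolated nodes) for property tests.
random_graph <- function(n_nodes, p_edge) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  grid <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  e <- grid[runif(nrow(grid)) < p_edge, , drop = FALSE]
  build_network(e, node_universe = nodes)
}

# Exact rank-sum p-value by full enumeration of all C(n, nx) group labelings.
enum_ranksum_p <- function(x, y, tail) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  ws <- apply(utils::combn(n, nx), 2, function(idx) sum(r[idx]))
  pg <- mean(ws >= w_obs - 1e-9)
  pl <- mean(ws <= w_obs + 1e-9)
  switch(tail,
    `one-tailed-greater` = pg,
    `one-tailed-less` = pl,
    `two-tailed` = min(1, 2 * min(pg, pl))
  )
}

# Two-tailed Fisher p-value by direct enumeration over the table support,
# using binomial coefficients only.
enum_fisher_two_tailed <- function(a, b, c, d) {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  n <- row1 + row2
  supp <- max(0, col1 - row2):min(col1, row1)
  pr <- choose(row1, supp) * choose(row2, col1 - supp) / choose(n, col1)
  p_obs <- choose(row1, a) * choose(row2, c) / choose(n, col1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Small planted spec used by several tests.
dense_planted_spec <- function(seed, n_spurious = 0, min_out = 1, min_in = 1) {
  planted_network_spec(
    5, 5, 5, 3,
    p_top_mid = 0.6, p_top_bot = 0.5, p_mid_bot = 0.6, p_mid_mid = 0.2,
    min_out = min_out, min_in = min_in, n_spurious = n_spurious, seed = seed
  )
}
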