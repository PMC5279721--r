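test_that("enzyme table generation is deterministic and honors class sizes and rates", {
  spec <- yeast_enzyme_spec(seed = 7)
  tab <- generate_enzyme_table(spec)
  expect_equal(nrow(tab), 187)
  expect_equal(sum(tab$enzyme_class == "kinase"), 137)
  expect_equal(sum(tab$enzyme_class == "phosphatase"), 50)
  expect_identical(tab, generate_enzyme_table(yeast_enzyme_spec(seed = 7)))
  expect_false(identical(tab, generate_enzyme_table(yeast_enzyme_spec(seed = 8))))

  # degenerate rate: zero essentiality means zero essential flags
  cl <- list(enzyme_class_spec("kinase", 40, essential_rate = 0))
  t0 <- generate_enzyme_table(enzyme_table_spec(cl, seed = 5))
  expect_equal(sum(t0$essential), 0)

  expect_error(enzyme_class_spec("kinase", 10, essential_rate = 1.2), "essential_rate")
  expect_error(enzyme_class_spec("kinase", 0), "n_genes")
  expect_error(enzyme_class_spec("kinase", 10, abundance_median = -1), "abundance_median")
})

test_that("empirical distributions converge to the specified class parameters", {
  cl <- list(
    enzyme_class_spec("kinase", 2000, abundance_median = 30, abundance_sdlog = 0.5,
                      essential_rate = 0.23),
    enzyme_class_spec("phosphatase", 2000, abundance_median = 60, abundance_sdlog = 0.5,
                      essential_rate = 0.10)
  )
  tab <- generate_enzyme_table(enzyme_table_spec(cl, seed = 1))
  med <- with(tab, tapply(abundance, enzyme_class, median))
  expect_gte(med[["phosphatase"]] / med[["kinase"]], 1.8)
  expect_lte(med[["phosphatase"]] / med[["kinase"]], 2.2)
  expect_lt(abs(med[["kinase"]] - 30) / 30, 0.10)
  expect_lt(abs(med[["phosphatase"]] - 60) / 60, 0.10)
  ess <- with(tab, tapply(essential, enzyme_class, mean))
  expect_lt(abs(ess[["kinase"]] - 0.23), 0.03)
  expect_lt(abs(ess[["phosphatase"]] - 0.10), 0.03)
})

test_that("missingness is applied at the requested rate and only to numeric metrics", {
  cl <- list(enzyme_class_spec("kinase", 3000))
  tab <- generate_enzyme_table(enzyme_table_spec(cl, seed = 3, missing_rate = 0.2))
  expect_lt(abs(mean(is.na(tab$abundance)) - 0.2), 0.04)
  expect_lt(abs(mean(is.na(tab$half_life)) - 0.2), 0.04)
  expect_equal(sum(is.na(tab$essential)), 0)
})

test_that("planted networks carry ground truth recovered exactly by the simple scheme", {
  g <- generate_planted_network(dense_planted_spec(seed = 3))
  expect_equal(unname(layer_counts(g$truth)), c(5L, 5L, 5L, 3L))
  expect_equal(layer_recovery(g$truth, assign_layers_simple(g$network)), 1)

  # no middle layer: bipartite top -> bot network
  g2 <- generate_planted_network(planted_network_spec(4, 0, 4, 2, p_top_bot = 0.6, seed = 5))
  expect_false(any(g2$truth$labels == "MID"))
  expect_equal(layer_recovery(g2$truth, assign_layers_simple(g2$network)), 1)

  # one spurious edge adds exactly one edge relative to the same-seed clean network
  g0 <- generate_planted_network(dense_planted_spec(seed = 9))
  g1 <- generate_planted_network(dense_planted_spec(seed = 9, n_spurious = 1))
  expect_equal(nrow(g1$network$edges), nrow(g0$network$edges) + 1)
  shared <- paste(g0$network$edges$source, g0$network$edges$target)
  expect_true(all(shared %in% paste(g1$network$edges$source, g1$network$edges$target)))

  # infeasible degree minima are rejected
  expect_error(planted_network_spec(3, 0, 1, 0, min_out = 2, seed = 1),
               "min_out")
})

test_that("noiseless planted recovery holds across randomized specifications", {
  set.seed(31)
  for (i in 1:25) {
    spec <- planted_network_spec(
      n_top = sample(2:8, 1), n_mid = sample(2:8, 1), n_bot = sample(2:8, 1),
      n_out = sample(0:4, 1),
      p_top_mid = runif(1, 0.1, 0.9), p_top_bot = runif(1, 0.1, 0.9),
      p_mid_bot = runif(1, 0.1, 0.9), p_mid_mid = runif(1, 0, 0.4),
      min_out = sample(1:2, 1), min_in = sample(1:2, 1),
      seed = sample.int(1e6, 1)
    )
    g <- generate_planted_network(spec)
    expect_equal(layer_recovery(g$truth, assign_layers_simple(g$network)), 1)
  }
})

test_that("perturbation adds exactly the requested non-duplicate edges", {
  g <- generate_planted_network(dense_planted_spec(seed = 4))
  net <- g$network
  expect_identical(perturb_network(net, 0, seed = 1), net)

  p2 <- perturb_network(net, 2, seed = 11)
  expect_equal(nrow(p2$edges), nrow(net$edges) + 2)
  expect_identical(p2, perturb_network(net, 2, seed = 11))
  expect_false(any(duplicated(p2$edges[, c("source", "target")])))
  expect_false(any(p2$edges$source == p2$edges$target))

  tiny <- build_network(data.frame(source = "A", target = "B"))
  expect_error(perturb_network(tiny, 5, seed = 1), "too small")
})

test_that("one spurious incoming edge flips a simple TOP label but not a stringent one", {
  g <- generate_planted_network(dense_planted_spec(seed = 6, min_out = 2))
  truth <- g$truth$labels
  top_nodes <- names(truth)[truth == "TOP"]
  bot_nodes <- names(truth)[truth == "BOT"]
  for (v in top_nodes) {
    noisy <- build_network(
      rbind(g$network$edges[, c("source", "target")],
            data.frame(source = bot_nodes[1], target = v)),
      node_universe = g$network$nodes
    )
    expect_equal(unname(assign_layers_simple(noisy)$labels[v]), "MID")
    expect_equal(unname(assign_layers_stringent(noisy)$labels[v]), "TOP")
  }
})
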