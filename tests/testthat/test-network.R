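test_that("network construction deduplicates, drops self-loops and keeps declared nodes", {
  net <- build_network(data.frame(source = c("A", "A"), target = c("B", "B")))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$n_duplicates_dropped, 1)

  net <- build_network(data.frame(source = c("A", "A"), target = c("A", "B")))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$n_self_loops_dropped, 1)

  net <- build_network(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "A")),
    node_universe = c("A", "B", "C", "D")
  )
  expect_equal(length(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)

  expect_error(build_network(data.frame(source = "A", target = "")), "malformed edge")
  expect_error(build_network(), "nonempty edge list")
})

test_that("class subnetwork equals a brute-force filter of the edge list", {
  records <- data.frame(
    id = c("K1", "K2", "K3", "P1", "S1"),
    enzyme_class = c("kinase", "kinase", "kinase", "phosphatase", "substrate"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    source = c("K1", "K2", "K1", "K2", "P1"),
    target = c("K2", "K3", "S1", "S1", "K3"),
    stringsAsFactors = FALSE
  )
  net <- build_network(edges, node_universe = records$id)
  kk <- subnetwork_by_class(net, records, "kinase")
  expect_equal(nrow(kk$edges), 2)
  kin <- records$id[records$enzyme_class == "kinase"]
  brute <- edges[edges$source %in% kin & edges$target %in% kin, ]
  expect_equal(kk$edges[, c("source", "target")], brute,
               ignore_attr = TRUE)
  expect_setequal(kk$nodes, kin)
  expect_error(subnetwork_by_class(net, records, "ligase"), "unknown class")

  # no within-class edges: all members isolated
  only_sub <- build_network(data.frame(source = c("K1", "K2"), target = c("S1", "S1")),
                            node_universe = records$id)
  kk0 <- subnetwork_by_class(only_sub, records, "kinase")
  expect_equal(nrow(kk0$edges), 0)
  expect_setequal(kk0$nodes, intersect(only_sub$nodes, kin))
})

test_that("simple scheme follows the degree definitions", {
  chain <- build_network(data.frame(source = c("A", "B"), target = c("B", "C")))
  lab <- assign_layers_simple(chain)$labels
  expect_equal(unname(lab[c("A", "B", "C")]), c("TOP", "MID", "BOT"))

  iso <- build_network(node_universe = c("X", "Y"))
  expect_true(all(assign_layers_simple(iso)$labels == "OUTGROUP"))
})

test_that("stringent scheme requires two supporting relationships", {
  chain <- build_network(data.frame(source = c("A", "B"), target = c("B", "C")))
  expect_true(all(assign_layers_stringent(chain)$labels == "OUTGROUP"))

  # out-degree 2 with a single (possibly noisy) incoming edge stays TOP
  net <- build_network(data.frame(source = c("A", "A", "D"), target = c("B", "C", "A")))
  expect_equal(unname(assign_layers_stringent(net)$labels["A"]), "TOP")
  expect_equal(unname(assign_layers_simple(net)$labels["A"]), "MID")
})

test_that("both schemes agree with the brute-force classifier and partition the nodes", {
  set.seed(21)
  for (i in 1:40) {
    net <- random_graph(sample(3:25, 1), runif(1, 0.02, 0.35))
    simple <- assign_layers_simple(net)
    stringent <- assign_layers_stringent(net)
    expect_equal(simple$labels[net$nodes], brute_layers(net, "simple"))
    expect_equal(stringent$labels[net$nodes], brute_layers(net, "stringent"))
    expect_equal(sum(layer_counts(simple)), length(net$nodes))
    expect_equal(sum(layer_counts(stringent)), length(net$nodes))
    # scheme nesting: stringent TOP within simple TOP/MID, stringent BOT within simple BOT/MID
    st <- stringent$labels
    si <- simple$labels[names(st)]
    expect_true(all(si[st == "TOP"] %in% c("TOP", "MID")))
    expect_true(all(si[st == "BOT"] %in% c("BOT", "MID")))
  }
})

test_that("restriction to measured identifiers behaves like set intersection", {
  net <- build_network(data.frame(source = c("A", "B"), target = c("B", "C")),
                       node_universe = c("A", "B", "C", "D"))
  expect_equal(suppressMessages(restrict_to_measured(net, net$nodes))$nodes, net$nodes)

  r <- suppressMessages(restrict_to_measured(net, c("B", "C", "D")))
  expect_false("A" %in% r$nodes)
  expect_equal(nrow(r$edges), 1)
  expect_setequal(r$nodes, intersect(net$nodes, c("B", "C", "D")))

  asg <- assign_layers_simple(net)
  ra <- suppressMessages(restrict_to_measured(asg, c("B", "C")))
  expect_setequal(names(ra$labels), c("B", "C"))

  expect_error(restrict_to_measured(net, "Z"), "measured")
  expect_error(restrict_to_measured(net, character(0)), "empty measured")
})

test_that("phosphatase placement tallies impacted kinases per layer", {
  records <- data.frame(
    id = c("K1", "K2", "K3", "K4", "P1", "P2", "P3"),
    enzyme_class = c(rep("kinase", 4), rep("phosphatase", 3)),
    stringsAsFactors = FALSE
  )
  # kinase hierarchy: K1 -> K2 -> K3; K4 isolated
  edges <- data.frame(
    source = c("K1", "K2", "P1", "P1", "P1", "K2", "P2"),
    target = c("K2", "K3", "K3", "K2", "P2", "P1", "K3"),
    stringsAsFactors = FALSE
  )
  net <- build_network(edges, node_universe = records$id)
  kk <- subnetwork_by_class(net, records, "kinase")
  layers <- assign_layers_simple(kk)
  placement <- phosphatase_placement(net, layers, records)
  p1 <- placement[placement$id == "P1", ]
  expect_equal(p1$MID, 1) # K2
  expect_equal(p1$BOT, 1) # K3
  expect_equal(p1$pp_edges, 1) # P1 -> P2
  expect_equal(p1$from_kinases, 1) # K2 -> P1
  expect_false(p1$outgroup)
  p3 <- placement[placement$id == "P3", ]
  expect_true(p3$outgroup)
  expect_equal(p3$TOP + p3$MID + p3$BOT + p3$OUTGROUP, 0)

  # brute-force tally for an eraser impacting only lower layers
  p2 <- placement[placement$id == "P2", ]
  expect_equal(p2$BOT, sum(edges$source == "P2" & edges$target %in%
                             names(layers$labels)[layers$labels == "BOT"]))

  bad <- records
  bad$enzyme_class[bad$id == "K1"] <- "phosphatase"
  bad <- rbind(bad, data.frame(id = "K1", enzyme_class = "kinase"))
  expect_error(phosphatase_placement(net, layers, bad), "both classes")
})

test_that("layer recovery measures label agreement", {
  a <- assign_layers_simple(build_network(data.frame(source = c("A", "B"), target = c("B", "C"))))
  expect_equal(layer_recovery(a, a), 1)
  flipped <- a
  flipped$labels[] <- c("BOT", "TOP", "MID")
  expect_equal(layer_recovery(a, flipped), 0)
  smaller <- a
  smaller$labels <- a$labels[1:2]
  expect_error(layer_recovery(a, smaller), "node sets differ")
})

test_that("attributed export round-trips through the readers", {
  net <- build_network(data.frame(source = c("A", "B"), target = c("B", "C")),
                       node_universe = c("A", "B", "C", "D"))
  layers <- assign_layers_simple(net)
  breadth <- impact_breadth(net)
  prefix <- file.path(tempdir(), "export_test")
  export_attributed_network(net, layers, breadth, prefix)
  back <- read_attributed_network(prefix)
  expect_equal(back$network$edges[, c("source", "target")],
               net$edges[, c("source", "target")])
  expect_setequal(back$network$nodes, net$nodes)
  expect_equal(setNames(back$nodes$layer, back$nodes$node),
               layers$labels[back$nodes$node])
  expect_equal(setNames(back$nodes$breadth, back$nodes$node),
               breadth[back$nodes$node], ignore_attr = TRUE)

  empty <- build_network(node_universe = c("X", "Y"))
  prefix2 <- file.path(tempdir(), "export_empty")
  export_attributed_network(empty, prefix = prefix2)
  lines <- readLines(paste0(prefix2, "_edges.tsv"))
  expect_equal(length(lines), 1) # header only
  back2 <- read_attributed_network(prefix2)
  expect_setequal(back2$network$nodes, c("X", "Y"))
})
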