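#' Build a directed impact network from an edge list
#'
#' An impact edge points from an inactivated enzyme to a protein whose
#' phosphorylation changed in the inactivated strain. Duplicate edges are
#' collapsed to a single relationship and self-loops are dropped (both
#' counted on the returned object); isolated identifiers supplied through
#' `node_universe` are retained so they can become OUTGROUP downstream.
#'
#' @param edges a data frame with columns `source` and `target` (an optional
#'   `provenance` column is kept), or a two-column matrix.
#' @param node_universe optional character vector of node identifiers to
#'   retain even when they touch no edge.
#' @return an object of class `impact_network` with elements `nodes`,
#'   `edges`, `n_self_loops_dropped`, `n_duplicates_dropped`.
#' @export
build_network <- function(edges = NULL, node_universe = NULL) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    if (is.null(node_universe)) {
      stop("build_network: need a nonempty edge list or a node universe")
    }
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) {
    edges <- data.frame(source = edges[, 1], target = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  if (!all(c("source", "target") %in% names(edges))) {
    stop("build_network: edge list must have 'source' and 'target' columns")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  bad <- which(is.na(edges$source) | is.na(edges$target) |
                 edges$source == "" | edges$target == "")
  if (length(bad)) {
    stop(sprintf("build_network: malformed edge (missing endpoint) at row %s",
                 paste(bad, collapse = ", ")))
  }
  keep_prov <- "provenance" %in% names(edges)
  self <- edges$source == edges$target
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  dup <- duplicated(edges[, c("source", "target")])
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  cols <- c("source", "target", if (keep_prov) "provenance")
  edges <- edges[, cols, drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(c(edges$source, edges$target, as.character(node_universe %||% character())))
  structure(
    list(nodes = nodes, edges = edges,
         n_self_loops_dropped = n_self, n_duplicates_dropped = n_dup),
    class = "impact_network"
  )
}

#' @export
print.impact_network <- function(x, ...) {
  cat(sprintf("impact network: %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (x$n_self_loops_dropped || x$n_duplicates_dropped) {
    cat(sprintf(" (dropped %d self-loops, %d duplicates)",
                x$n_self_loops_dropped, x$n_duplicates_dropped))
  }
  cat("\n")
  invisible(x)
}

#' Convert an impact network to an igraph graph
#'
#' @param net an `impact_network`.
#' @return a directed `igraph` graph with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "impact_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

network_degrees <- function(net) {
  g <- as_igraph(net)
  list(
    out = igraph::degree(g, mode = "out"),
    `in` = igraph::degree(g, mode = "in")
  )
}

#' Restrict a network to edges within one enzyme class
#'
#' The hierarchy is built on impact relationships *within* a class (e.g.
#' kinase-kinase edges); the full edge set also contains writer-to-substrate
#' and eraser edges. Keeps only edges whose both endpoints belong to the
#' class; the node set becomes the class members present in the network.
#'
#' @param net an `impact_network`.
#' @param records enzyme annotation data frame with columns `id` and
#'   `enzyme_class`.
#' @param class class label to keep.
#' @return an `impact_network` over the class members.
#' @export
subnetwork_by_class <- function(net, records, class) {
  stopifnot(inherits(net, "impact_network"))
  if (!class %in% records$enzyme_class) {
    stop(sprintf("subnetwork_by_class: unknown class '%s'", class))
  }
  ids <- records$id[records$enzyme_class == class]
  e <- net$edges
  e <- e[e$source %in% ids & e$target %in% ids, , drop = FALSE]
  build_network(e, node_universe = intersect(net$nodes, ids))
}

new_layer_assignment <- function(labels, scheme) {
  structure(list(labels = labels, scheme = scheme), class = "layer_assignment")
}

#' @export
print.layer_assignment <- function(x, ...) {
  cat(sprintf("layer assignment (%s scheme), %d nodes:\n", x$scheme, length(x$labels)))
  print(table(factor(x$labels, levels = c("TOP", "MID", "BOT", "OUTGROUP"))))
  invisible(x)
}

#' @export
as.data.frame.layer_assignment <- function(x, ...) {
  data.frame(node = names(x$labels), layer = unname(x$labels),
             scheme = x$scheme, stringsAsFactors = FALSE)
}

#' Count nodes per layer
#'
#' @param assignment a `layer_assignment`.
#' @return named integer vector over TOP, MID, BOT, OUTGROUP.
#' @export
layer_counts <- function(assignment) {
  stopifnot(inherits(assignment, "layer_assignment"))
  tab <- table(factor(assignment$labels, levels = c("TOP", "MID", "BOT", "OUTGROUP")))
  setNames(as.integer(tab), names(tab))
}

#' Simple layering scheme
#'
#' Partitions every node of a within-class impact network by its in/out
#' degrees: TOP impacts peers and is not targeted by any (out > 0, in = 0);
#' MID both impacts and is targeted (out > 0, in > 0); BOT is targeted only
#' (out = 0, in > 0); OUTGROUP has no impact or target relationships.
#'
#' @param net an `impact_network` (typically the kinase-kinase subnetwork).
#' @return a `layer_assignment` with scheme `"simple"`.
#' @export
assign_layers_simple <- function(net) {
  stopifnot(inherits(net, "impact_network"))
  deg <- network_degrees(net)
  out <- deg$out
  inn <- deg$`in`
  labels <- ifelse(out > 0 & inn == 0, "TOP",
            ifelse(out > 0 & inn > 0, "MID",
            ifelse(out == 0 & inn > 0, "BOT", "OUTGROUP")))
  new_layer_assignment(setNames(labels, names(out)), "simple")
}

#' Stringent layering scheme
#'
#' A more robust layering in which no assignment rests on a single impact
#' relationship: TOP requires impacting two or more peers while being the
#' target of at most one (out >= 2, in <= 1); MID requires out >= 2 and
#' in >= 2; BOT requires out <= 1 and in >= 2. Nodes matching none of the
#' rules (out <= 1 and in <= 1) are OUTGROUP.
#'
#' @inheritParams assign_layers_simple
#' @return a `layer_assignment` with scheme `"stringent"`.
#' @export
assign_layers_stringent <- function(net) {
  stopifnot(inherits(net, "impact_network"))
  deg <- network_degrees(net)
  out <- deg$out
  inn <- deg$`in`
  labels <- ifelse(out >= 2 & inn <= 1, "TOP",
            ifelse(out >= 2 & inn >= 2, "MID",
            ifelse(out <= 1 & inn >= 2, "BOT", "OUTGROUP")))
  new_layer_assignment(setNames(labels, names(out)), "stringent")
}

#' Restrict a network or layer assignment to measured identifiers
#'
#' Analyses consider only genes/proteins that were actually measured;
#' unmeasured nodes are removed before layering or profiling. Removal counts
#' are reported via `message()`.
#'
#' @param x an `impact_network` or `layer_assignment`.
#' @param measured_ids nonempty character vector of measured identifiers.
#' @return object of the same class restricted to `measured_ids`.
#' @export
restrict_to_measured <- function(x, measured_ids) {
  UseMethod("restrict_to_measured")
}

#' @export
restrict_to_measured.impact_network <- function(x, measured_ids) {
  if (length(measured_ids) == 0) stop("restrict_to_measured: empty measured set")
  keep <- intersect(x$nodes, measured_ids)
  if (length(keep) == 0) {
    stop("restrict_to_measured: no network node is in the measured set")
  }
  e <- x$edges[x$edges$source %in% keep & x$edges$target %in% keep, , drop = FALSE]
  message(sprintf("restrict_to_measured: kept %d/%d nodes, %d/%d edges",
                  length(keep), length(x$nodes), nrow(e), nrow(x$edges)))
  build_network(e, node_universe = keep)
}

#' @export
restrict_to_measured.layer_assignment <- function(x, measured_ids) {
  if (length(measured_ids) == 0) stop("restrict_to_measured: empty measured set")
  keep <- names(x$labels) %in% measured_ids
  if (!any(keep)) {
    stop("restrict_to_measured: no assigned node is in the measured set")
  }
  message(sprintf("restrict_to_measured: kept %d/%d nodes",
                  sum(keep), length(x$labels)))
  new_layer_assignment(x$labels[keep], x$scheme)
}

#' Place phosphatases relative to the kinase hierarchy
#'
#' Erasers (phosphatases) are incorporated into the hierarchy by their impact
#' relationships among themselves and with kinases. For each phosphatase the
#' function tallies how many kinases it impacts in each layer, how many
#' phosphatase-phosphatase edges it participates in (either direction), and
#' how many incoming edges it receives from kinases. Phosphatases with no
#' relationship to any kinase or phosphatase are flagged as outgroup-grid
#' members.
#'
#' @param full_net the full `impact_network` (all enzyme and substrate edges).
#' @param kinase_layers `layer_assignment` built from the kinase-kinase
#'   subnetwork of `full_net`.
#' @param records annotation data frame with `id` and `enzyme_class`.
#' @param writer_class,eraser_class class labels of writers and erasers.
#' @return a data frame with one row per eraser: per-layer impacted-kinase
#'   counts, `pp_edges`, `from_kinases` and the `outgroup` flag.
#' @export
phosphatase_placement <- function(full_net, kinase_layers, records,
                                  writer_class = "kinase",
                                  eraser_class = "phosphatase") {
  stopifnot(inherits(full_net, "impact_network"),
            inherits(kinase_layers, "layer_assignment"))
  kin <- records$id[records$enzyme_class == writer_class]
  pho <- records$id[records$enzyme_class == eraser_class]
  both <- intersect(kin, pho)
  if (length(both)) {
    stop(sprintf("phosphatase_placement: ids annotated as both classes: %s",
                 paste(both, collapse = ", ")))
  }
  if (length(pho) == 0) stop("phosphatase_placement: no erasers in records")
  e <- full_net$edges
  layers <- c("TOP", "MID", "BOT", "OUTGROUP")
  rows <- lapply(pho, function(p) {
    targets <- e$target[e$source == p]
    sources <- e$source[e$target == p]
    hit_kin <- intersect(targets, kin)
    lab <- kinase_layers$labels[hit_kin]
    per_layer <- sapply(layers, function(l) sum(lab == l, na.rm = TRUE))
    pp <- sum(targets %in% pho) + sum(sources %in% pho)
    from_kin <- sum(sources %in% kin)
    outgroup <- (length(hit_kin) == 0 && pp == 0 && from_kin == 0)
    data.frame(id = p, t(per_layer), pp_edges = pp, from_kinases = from_kin,
               outgroup = outgroup, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of nodes whose inferred layer matches the ground truth
#'
#' @param truth,inferred two `layer_assignment`s over the same node set.
#' @return fraction in `[0, 1]` of nodes with matching labels.
#' @export
layer_recovery <- function(truth, inferred) {
  stopifnot(inherits(truth, "layer_assignment"),
            inherits(inferred, "layer_assignment"))
  if (!setequal(names(truth$labels), names(inferred$labels))) {
    stop("layer_recovery: node sets differ between assignments")
  }
  ids <- names(truth$labels)
  mean(truth$labels[ids] == inferred$labels[ids])
}

#' Export an attributed network as edge and node-attribute tables
#'
#' Writes `<prefix>_edges.tsv` (source, target, provenance when present) and
#' `<prefix>_nodes.tsv` (node, layer, impact breadth) for external rendering
#' tools. The pair round-trips through [read_attributed_network()].
#'
#' @param net an `impact_network`.
#' @param layers optional `layer_assignment` supplying the `layer` column.
#' @param breadth optional named vector of impact breadths (distinct-target
#'   counts) supplying the `breadth` column.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
export_attributed_network <- function(net, layers = NULL, breadth = NULL, prefix) {
  stopifnot(inherits(net, "impact_network"))
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(node = net$nodes, stringsAsFactors = FALSE)
  nodes$layer <- if (!is.null(layers)) unname(layers$labels[nodes$node]) else NA_character_
  nodes$breadth <- if (!is.null(breadth)) unname(breadth[nodes$node]) else NA_real_
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Read back an attributed network export
#'
#' @param prefix the path prefix given to [export_attributed_network()].
#' @return list with `network` (an `impact_network`) and `nodes` (the node
#'   attribute data frame).
#' @export
read_attributed_network <- function(prefix) {
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"), stringsAsFactors = FALSE)
  edge_path <- paste0(prefix, "_edges.tsv")
  edges <- read.delim(edge_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  net <- if (nrow(edges) == 0) {
    build_network(node_universe = nodes$node)
  } else {
    build_network(edges, node_universe = nodes$node)
  }
  list(network = net, nodes = nodes)
}
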