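check_rate <- function(x, field, allow_na = FALSE) {
  if (allow_na && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("invalid specification: '%s' must be a rate in [0, 1]", field))
  }
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || is.na(x) || x <= 0) {
    stop(sprintf("invalid specification: '%s' must be > 0", field))
  }
  invisible(x)
}

#' Specification of one enzyme class for the table generator
#'
#' Distributional parameters for the per-class annotation metrics emulated by
#' the generator: protein abundance (log-normal parameterized by its median,
#' as ppm abundances are positive and right-skewed), essentiality and disease
#' flags (Bernoulli), PPI degree (negative binomial, overdispersed as typical
#' of interaction data), transcriptional responsiveness (zero-inflated: a
#' Bernoulli "differentially expressed in at least one perturbation" flag
#' with a shifted-geometric perturbation count given responsiveness), protein
#' half-life (log-normal), three phospho-capacity evidence flags (curated
#' events, phospho-peptide evidence, conserved sites), conserved-site counts
#' and negative genetic interaction (NGI) counts.
#'
#' @param class class label, e.g. `"kinase"` or `"phosphatase"`.
#' @param n_genes number of genes in the class (>= 1).
#' @param abundance_median,abundance_sdlog log-normal abundance parameters
#'   (median in ppm; dispersion on the log scale).
#' @param essential_rate probability that a gene is essential.
#' @param disease_rate probability of disease association (NA to omit).
#' @param ppi_mu,ppi_size negative-binomial mean and size of the PPI degree.
#' @param responsive_rate probability of differential expression in at least
#'   one perturbation.
#' @param de_count_q geometric parameter of the perturbation count given
#'   responsiveness (count = 1 + geometric(q)).
#' @param half_life_median,half_life_sdlog log-normal half-life parameters
#'   (minutes).
#' @param phospho_rates named rates of the three phospho-capacity evidence
#'   flags: `curated`, `peptide`, `conserved`.
#' @param conserved_lambda Poisson mean of extra conserved sites given the
#'   conserved-site flag (count = 1 + Poisson).
#' @param ngi_rate probability of having at least one NGI.
#' @param ngi_q geometric parameter of the NGI count given at least one.
#' @param subclass optional subclass annotation applied to all genes.
#' @return a list of class `enzyme_class_spec`.
#' @export
enzyme_class_spec <- function(class, n_genes,
                              abundance_median = 30, abundance_sdlog = 1,
                              essential_rate = 0.2, disease_rate = NA,
                              ppi_mu = 8, ppi_size = 1,
                              responsive_rate = 0.35, de_count_q = 0.25,
                              half_life_median = 40, half_life_sdlog = 0.6,
                              phospho_rates = c(curated = 0.3, peptide = 0.3, conserved = 0.3),
                              conserved_lambda = 1.5,
                              ngi_rate = 0.7, ngi_q = 0.25,
                              subclass = NA_character_) {
  if (!is.numeric(n_genes) || n_genes < 1 || n_genes != round(n_genes)) {
    stop("invalid specification: 'n_genes' must be an integer >= 1")
  }
  check_pos(abundance_median, "abundance_median")
  check_pos(abundance_sdlog, "abundance_sdlog")
  check_rate(essential_rate, "essential_rate")
  check_rate(disease_rate, "disease_rate", allow_na = TRUE)
  check_pos(ppi_mu, "ppi_mu")
  check_pos(ppi_size, "ppi_size")
  check_rate(responsive_rate, "responsive_rate")
  check_rate(de_count_q, "de_count_q")
  check_pos(half_life_median, "half_life_median")
  check_pos(half_life_sdlog, "half_life_sdlog")
  if (!all(c("curated", "peptide", "conserved") %in% names(phospho_rates))) {
    stop("invalid specification: 'phospho_rates' needs curated, peptide, conserved")
  }
  for (nm in names(phospho_rates)) {
    check_rate(phospho_rates[[nm]], paste0("phospho_rates$", nm))
  }
  check_pos(conserved_lambda, "conserved_lambda")
  check_rate(ngi_rate, "ngi_rate")
  check_rate(ngi_q, "ngi_q")
  structure(
    list(class = class, n_genes = as.integer(n_genes),
         abundance_median = abundance_median, abundance_sdlog = abundance_sdlog,
         essential_rate = essential_rate, disease_rate = disease_rate,
         ppi_mu = ppi_mu, ppi_size = ppi_size,
         responsive_rate = responsive_rate, de_count_q = de_count_q,
         half_life_median = half_life_median, half_life_sdlog = half_life_sdlog,
         phospho_rates = phospho_rates, conserved_lambda = conserved_lambda,
         ngi_rate = ngi_rate, ngi_q = ngi_q, subclass = subclass),
    class = "enzyme_class_spec"
  )
}

#' Specification of a synthetic enzyme annotation table
#'
#' @param classes list of [enzyme_class_spec()] objects.
#' @param seed integer global seed; each class/metric pair draws from its own
#'   substream derived from it.
#' @param missing_rate missing-at-random probability applied to the numeric
#'   metrics (abundance, PPI degree, half-life), emulating incomplete
#'   measurement coverage.
#' @param organism organism tag stored on every record.
#' @return a list of class `enzyme_table_spec`.
#' @export
enzyme_table_spec <- function(classes, seed, missing_rate = 0, organism = "yeast") {
  stopifnot(is.list(classes), length(classes) >= 1)
  for (cl in classes) stopifnot(inherits(cl, "enzyme_class_spec"))
  check_rate(missing_rate, "missing_rate")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("invalid specification: 'seed' must be a single integer")
  }
  structure(list(classes = classes, seed = as.integer(seed),
                 missing_rate = missing_rate, organism = organism),
            class = "enzyme_table_spec")
}

#' Default study conditions: the yeast kinome/phosphatome
#'
#' Class specifications mirroring the budding-yeast kinase/phosphatase
#' statistics the analyses assume: 137 kinases with median abundance 30.4
#' ppm versus 50 phosphatases with median 63 ppm; essentiality rates 23%
#' versus 10%; kinases with more PPI partners, shorter half-lives (medians
#' 33 versus 42 minutes), higher responsiveness counts, higher
#' phospho-capacity rates; phosphatases with more NGIs (median 4 versus 2
#' per gene given at least one, rates 74% versus 67%). A genome-wide
#' `protein` background class (4,925 genes) is included for
#' versus-background comparisons.
#'
#' @param seed integer global seed.
#' @param missing_rate missing-at-random rate for numeric metrics.
#' @param include_background include the genome-wide background class.
#' @return an `enzyme_table_spec`.
#' @export
yeast_enzyme_spec <- function(seed, missing_rate = 0, include_background = FALSE) {
  classes <- list(
    enzyme_class_spec(
      "kinase", n_genes = 137,
      abundance_median = 30.4, abundance_sdlog = 1,
      essential_rate = 0.23,
      ppi_mu = 12, ppi_size = 1,
      responsive_rate = 0.34, de_count_q = 0.2,
      half_life_median = 33, half_life_sdlog = 0.6,
      phospho_rates = c(curated = 0.42, peptide = 0.45, conserved = 0.44),
      conserved_lambda = 2,
      ngi_rate = 0.67, ngi_q = 1 - sqrt(0.5)
    ),
    enzyme_class_spec(
      "phosphatase", n_genes = 50,
      abundance_median = 63, abundance_sdlog = 1,
      essential_rate = 0.10,
      ppi_mu = 6, ppi_size = 1,
      responsive_rate = 0.34, de_count_q = 0.35,
      half_life_median = 42, half_life_sdlog = 0.6,
      phospho_rates = c(curated = 0.12, peptide = 0.10, conserved = 0.08),
      conserved_lambda = 1,
      ngi_rate = 0.74, ngi_q = 1 - 0.5^(1 / 3)
    )
  )
  if (include_background) {
    classes <- c(classes, list(enzyme_class_spec(
      "protein", n_genes = 4925,
      abundance_median = 20, abundance_sdlog = 1.2,
      essential_rate = 0.189,
      ppi_mu = 5, ppi_size = 1,
      responsive_rate = 0.44, de_count_q = 0.25,
      half_life_median = 44, half_life_sdlog = 0.6,
      phospho_rates = c(curated = 0.2, peptide = 0.25, conserved = 0.2),
      conserved_lambda = 1.5,
      ngi_rate = 0.3, ngi_q = 0.3
    )))
  }
  enzyme_table_spec(classes, seed = seed, missing_rate = missing_rate)
}

class_prefix <- function(class) toupper(substr(gsub("[^A-Za-z]", "", class), 1, 3))

generate_class_records <- function(cl, seed, missing_rate, organism) {
  n <- cl$n_genes
  draw <- function(metric, expr) {
    with_seed(substream_seed(seed, paste(cl$class, metric, sep = ":")), expr)
  }
  abundance <- draw("abundance", rlnorm(n, log(cl$abundance_median), cl$abundance_sdlog))
  essential <- draw("essential", rbinom(n, 1, cl$essential_rate) == 1)
  disease <- if (is.na(cl$disease_rate)) rep(NA, n) else {
    draw("disease", rbinom(n, 1, cl$disease_rate) == 1)
  }
  ppi <- draw("ppi", rnbinom(n, mu = cl$ppi_mu, size = cl$ppi_size))
  responsive <- draw("responsive", rbinom(n, 1, cl$responsive_rate) == 1)
  de_count <- draw("de_count", ifelse(responsive, 1 + rgeom(n, cl$de_count_q), NA_integer_))
  half_life <- draw("half_life", rlnorm(n, log(cl$half_life_median), cl$half_life_sdlog))
  ph_cur <- draw("phospho_curated", rbinom(n, 1, cl$phospho_rates[["curated"]]) == 1)
  ph_pep <- draw("phospho_peptide", rbinom(n, 1, cl$phospho_rates[["peptide"]]) == 1)
  ph_con <- draw("phospho_conserved", rbinom(n, 1, cl$phospho_rates[["conserved"]]) == 1)
  cons_sites <- draw("conserved_sites", ifelse(ph_con, 1 + rpois(n, cl$conserved_lambda), 0L))
  has_ngi <- draw("ngi_flag", rbinom(n, 1, cl$ngi_rate) == 1)
  ngi <- draw("ngi_count", ifelse(has_ngi, 1 + rgeom(n, cl$ngi_q), 0L))
  df <- data.frame(
    id = sprintf("%s_%04d", class_prefix(cl$class), seq_len(n)),
    organism = organism,
    enzyme_class = cl$class,
    subclass = cl$subclass,
    abundance = abundance,
    essential = essential,
    disease_associated = disease,
    ppi_degree = as.integer(ppi),
    de_responsive = responsive,
    de_perturbation_count = as.integer(de_count),
    half_life = half_life,
    phospho_curated = ph_cur,
    phospho_peptide = ph_pep,
    phospho_conserved = ph_con,
    conserved_sites = as.integer(cons_sites),
    ngi_count = as.integer(ngi),
    stringsAsFactors = FALSE
  )
  if (missing_rate > 0) {
    for (metric in c("abundance", "ppi_degree", "half_life")) {
      miss <- draw(paste0("missing:", metric),
                   rbinom(n, 1, missing_rate) == 1)
      df[[metric]][miss] <- NA
    }
  }
  df
}

#' Generate a synthetic enzyme annotation table
#'
#' Draws one record per gene for every class in the specification, with each
#' class/metric pair on its own random substream so the output is
#' deterministic given the seed and stable under adding metrics.
#' `de_perturbation_count` is `NA` for non-responsive genes, matching
#' analyses that compare perturbation counts among genes that were
#' differentially expressed at least once.
#'
#' @param spec an [enzyme_table_spec()].
#' @return data frame of enzyme records (one row per gene).
#' @export
generate_enzyme_table <- function(spec) {
  stopifnot(inherits(spec, "enzyme_table_spec"))
  out <- do.call(rbind, lapply(spec$classes, generate_class_records,
                               seed = spec$seed,
                               missing_rate = spec$missing_rate,
                               organism = spec$organism))
  rownames(out) <- NULL
  out
}

#' Specification of a planted-hierarchy impact network
#'
#' Defines a ground-truth layered network: `n_top` source-only nodes,
#' `n_mid` intermediate nodes, `n_bot` sink-only nodes and `n_out` isolated
#' nodes. Edges are drawn independently within four strata (top-to-mid,
#' top-to-bot, mid-to-bot, mid-to-mid) and then repaired so that, before
#' noise, every TOP node has out-degree >= `min_out` and in-degree 0, every
#' MID node satisfies both minima, every BOT node has in-degree >= `min_in`
#' and out-degree 0, and OUT nodes stay isolated. With `n_spurious = 0` the
#' simple layering scheme recovers the planted labels exactly.
#'
#' @param n_top,n_mid,n_bot,n_out layer sizes (nonnegative integers).
#' @param p_top_mid,p_top_bot,p_mid_bot,p_mid_mid per-stratum edge
#'   probabilities in `[0, 1]`.
#' @param min_out minimum out-degree of TOP and MID nodes (>= 1).
#' @param min_in minimum in-degree of MID and BOT nodes (>= 1).
#' @param n_spurious number of uniformly random extra edges added after the
#'   planted structure (may break the planted labels).
#' @param seed integer seed.
#' @return a list of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_top, n_mid, n_bot, n_out = 0,
                                 p_top_mid = 0.4, p_top_bot = 0.3,
                                 p_mid_bot = 0.4, p_mid_mid = 0.1,
                                 min_out = 1, min_in = 1,
                                 n_spurious = 0, seed) {
  sizes <- c(n_top = n_top, n_mid = n_mid, n_bot = n_bot, n_out = n_out)
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    stop("invalid specification: layer sizes must be nonnegative integers")
  }
  if (sum(sizes) == 0) stop("invalid specification: network has no nodes")
  for (nm in c("p_top_mid", "p_top_bot", "p_mid_bot", "p_mid_mid")) {
    check_rate(get(nm), nm)
  }
  if (min_out < 1 || min_in < 1) {
    stop("invalid specification: min_out and min_in must be >= 1")
  }
  if (n_spurious < 0 || n_spurious != round(n_spurious)) {
    stop("invalid specification: n_spurious must be a nonnegative integer")
  }
  # feasibility of the degree minima given the layer sizes
  if (n_top > 0 && n_mid + n_bot < min_out) {
    stop("planted network generation failed: TOP nodes cannot reach min_out targets")
  }
  if (n_mid > 0 && (n_bot + n_mid - 1 < min_out || n_top + n_mid - 1 < min_in)) {
    stop("planted network generation failed: MID degree minima are unsatisfiable")
  }
  if (n_bot > 0 && n_top + n_mid < min_in) {
    stop("planted network generation failed: BOT nodes cannot receive min_in edges")
  }
  structure(
    list(n_top = as.integer(n_top), n_mid = as.integer(n_mid),
         n_bot = as.integer(n_bot), n_out = as.integer(n_out),
         p_top_mid = p_top_mid, p_top_bot = p_top_bot,
         p_mid_bot = p_mid_bot, p_mid_mid = p_mid_mid,
         min_out = as.integer(min_out), min_in = as.integer(min_in),
         n_spurious = as.integer(n_spurious), seed = as.integer(seed)),
    class = "planted_network_spec"
  )
}

sample_stratum <- function(sources, targets, p) {
  if (length(sources) == 0 || length(targets) == 0 || p == 0) {
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(source = sources, target = targets,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  grid[runif(nrow(grid)) < p, , drop = FALSE]
}

#' Generate a planted-hierarchy impact network with ground-truth labels
#'
#' @param spec a [planted_network_spec()].
#' @return list with `network` (an `impact_network`) and `truth` (a
#'   `layer_assignment` with scheme `"planted"`).
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  ids <- sprintf("n%03d", seq_len(spec$n_top + spec$n_mid + spec$n_bot + spec$n_out))
  top <- ids[seq_len(spec$n_top)]
  mid <- ids[spec$n_top + seq_len(spec$n_mid)]
  bot <- ids[spec$n_top + spec$n_mid + seq_len(spec$n_bot)]
  out <- ids[spec$n_top + spec$n_mid + spec$n_bot + seq_len(spec$n_out)]

  edges <- with_seed(substream_seed(spec$seed, "edges"), {
    e <- rbind(
      sample_stratum(top, mid, spec$p_top_mid),
      sample_stratum(top, bot, spec$p_top_bot),
      sample_stratum(mid, bot, spec$p_mid_bot),
      sample_stratum(mid, mid, spec$p_mid_mid)
    )
    e <- e[!duplicated(e), , drop = FALSE]
    add_edge <- function(e, from, to) rbind(e, data.frame(source = from, target = to,
                                                          stringsAsFactors = FALSE))
    # repair pass: top up degrees that fall short of the planted minima
    for (v in top) {
      have <- e$target[e$source == v]
      need <- spec$min_out - length(have)
      if (need > 0) {
        pool <- setdiff(c(mid, bot), have)
        e <- add_edge(e, v, sample(pool, need))
      }
    }
    for (v in mid) {
      have <- e$target[e$source == v]
      need <- spec$min_out - length(have)
      if (need > 0) {
        pool <- setdiff(c(bot, setdiff(mid, v)), have)
        if (length(pool) < need) stop("planted network generation failed: MID out-degree")
        e <- add_edge(e, v, sample(pool, need))
      }
    }
    for (v in mid) {
      have <- e$source[e$target == v]
      need <- spec$min_in - length(have)
      if (need > 0) {
        pool <- setdiff(c(top, setdiff(mid, v)), have)
        if (length(pool) < need) stop("planted network generation failed: MID in-degree")
        e <- add_edge(e, sample(pool, need), v)
      }
    }
    for (v in bot) {
      have <- e$source[e$target == v]
      need <- spec$min_in - length(have)
      if (need > 0) {
        pool <- setdiff(c(top, mid), have)
        e <- add_edge(e, sample(pool, need), v)
      }
    }
    e
  })

  net <- build_network(edges, node_universe = ids)
  if (spec$n_spurious > 0) {
    net <- perturb_network(net, spec$n_spurious,
                           seed = substream_seed(spec$seed, "spurious"))
  }
  labels <- setNames(
    rep(c("TOP", "MID", "BOT", "OUTGROUP"),
        times = c(spec$n_top, spec$n_mid, spec$n_bot, spec$n_out)),
    ids
  )
  list(network = net, truth = new_layer_assignment(labels, "planted"))
}

#' Add spurious random edges to a network
#'
#' Adds `n_spurious` uniformly random edges not already present, excluding
#' self-loops; all original edges are preserved. Used to probe the
#' robustness of layer assignments to single noisy impact relationships.
#'
#' @param net an `impact_network`.
#' @param n_spurious nonnegative number of edges to add.
#' @param seed integer seed.
#' @return the perturbed `impact_network`.
#' @export
perturb_network <- function(net, n_spurious, seed) {
  stopifnot(inherits(net, "impact_network"))
  if (n_spurious < 0 || n_spurious != round(n_spurious)) {
    stop("perturb_network: n_spurious must be a nonnegative integer")
  }
  if (n_spurious == 0) return(net)
  nodes <- net$nodes
  grid <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  key <- paste(grid$source, grid$target, sep = "\r")
  existing <- paste(net$edges$source, net$edges$target, sep = "\r")
  grid <- grid[!key %in% existing, , drop = FALSE]
  if (nrow(grid) < n_spurious) {
    stop("perturb_network: graph too small to host the requested spurious edges")
  }
  new_rows <- with_seed(substream_seed(seed, "perturb"), {
    grid[sample(nrow(grid), n_spurious), , drop = FALSE]
  })
  e <- net$edges
  if ("provenance" %in% names(e)) new_rows$provenance <- "spurious"
  build_network(rbind(e[, names(new_rows), drop = FALSE], new_rows),
                node_universe = nodes)
}
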