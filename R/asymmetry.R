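records_of_class <- function(records, class) {
  if (!class %in% records$enzyme_class) {
    stop(sprintf("unknown enzyme class '%s'", class))
  }
  records[records$enzyme_class == class, , drop = FALSE]
}

metric_values <- function(records, metric) {
  if (!metric %in% names(records)) {
    stop(sprintf("metric '%s' absent from records", metric))
  }
  records[[metric]]
}

#' Ratio of gene counts between two enzyme classes
#'
#' The most basic asymmetry: genomes carry several times more writer genes
#' than eraser genes (e.g. 137 yeast kinases versus 50 phosphatases,
#' a ratio of ~2.7:1).
#'
#' @param records annotation data frame.
#' @param class_a,class_b class labels (numerator, denominator).
#' @return `countA / countB`.
#' @export
gene_count_ratio <- function(records, class_a, class_b) {
  na <- nrow(records_of_class(records, class_a))
  nb <- nrow(records_of_class(records, class_b))
  na / nb
}

#' Compare a numeric metric between two enzyme classes
#'
#' Drops missing values (only measured genes/proteins are considered),
#' reports per-class medians, and tests the difference with the rank-sum
#' test. `tail = "auto"` tests in the direction of the observed median
#' difference; fix the tail explicitly to test a stated directional claim.
#'
#' @param records annotation data frame.
#' @param metric numeric metric column name.
#' @param class_a,class_b class labels.
#' @param tail `"auto"`, `"two-tailed"`, `"one-tailed-greater"` or
#'   `"one-tailed-less"` (direction refers to `class_a`).
#' @param exact passed to [rank_sum_test()].
#' @return a [comparison_result].
#' @export
compare_numeric_metric <- function(records, metric, class_a, class_b,
                                   tail = "auto", exact = NULL) {
  x <- metric_values(records_of_class(records, class_a), metric)
  y <- metric_values(records_of_class(records, class_b), metric)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop(sprintf("no measured '%s' values in one of the classes", metric))
  }
  tail <- resolve_tail(tail, median(x), median(y))
  rank_sum_test(x, y, tail = tail, exact = exact,
                metric = metric, groups = c(class_a, class_b))
}

#' Compare a flag metric between two enzyme classes
#'
#' Builds the 2x2 flag-by-class table on measured flags and applies Fisher's
#' exact test (two-tailed by default, as used for overlap comparisons).
#'
#' @inheritParams compare_numeric_metric
#' @param flag_metric logical metric column name.
#' @param tail Fisher tail.
#' @return a [comparison_result] with per-class fractions.
#' @export
compare_fraction_metric <- function(records, flag_metric, class_a, class_b,
                                    tail = "two-tailed") {
  fa <- metric_values(records_of_class(records, class_a), flag_metric)
  fb <- metric_values(records_of_class(records, class_b), flag_metric)
  fa <- fa[!is.na(fa)]
  fb <- fb[!is.na(fb)]
  if (!length(fa) || !length(fb)) {
    stop(sprintf("no measured '%s' flags in one of the classes", flag_metric))
  }
  res <- fisher_2x2(sum(fa), sum(!fa), sum(fb), sum(!fb), tail = tail,
                    metric = flag_metric, groups = c(class_a, class_b))
  res
}

#' Compare a class against the genome-wide background
#'
#' As [compare_numeric_metric()] with all protein-coding records as group B.
#' By default the focal class stays inside its own background, matching
#' genome-wide denominators; set `exclude_class = TRUE` to remove it.
#'
#' @inheritParams compare_numeric_metric
#' @param class focal class label (looked up in `records`).
#' @param background_records data frame of background records (all proteins).
#' @param exclude_class drop the focal class ids from the background.
#' @return a [comparison_result].
#' @export
compare_vs_background <- function(records, metric, class, background_records,
                                  tail = "auto", exclude_class = FALSE,
                                  exact = NULL) {
  x <- metric_values(records_of_class(records, class), metric)
  bg <- background_records
  if (exclude_class) {
    focal_ids <- records$id[records$enzyme_class == class]
    bg <- bg[!bg$id %in% focal_ids, , drop = FALSE]
  }
  y <- metric_values(bg, metric)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop(sprintf("no measured '%s' values in class or background", metric))
  }
  tail <- resolve_tail(tail, median(x), median(y))
  res <- rank_sum_test(x, y, tail = tail, exact = exact,
                       metric = metric, groups = c(class, "background"))
  res$stars <- significance_stars(res$p_value, "+")
  res
}

#' Correlation between responsiveness and protein abundance
#'
#' Spearman correlation between the number of perturbations in which a gene
#' was differentially expressed and its protein expression level, over all
#' records or a subset of classes. A near-zero correlation shows that the
#' lower responsiveness of erasers is not a trivial consequence of their
#' higher abundance.
#'
#' @param records annotation data frame.
#' @param scope `"all"` or a character vector of class labels.
#' @return list with `rho`, `p`, `n` (see [spearman_corr()]).
#' @export
responsiveness_abundance_correlation <- function(records, scope = "all") {
  if (!identical(scope, "all")) {
    records <- records[records$enzyme_class %in% scope, , drop = FALSE]
  }
  spearman_corr(records$de_perturbation_count, records$abundance)
}

#' Filter records by subclass annotation rules
#'
#' Set algebra over the `subclass` annotation: keep records whose subclass
#' matches `include` and does not match `exclude` (regular expressions;
#' `NULL` disables a rule). Used e.g. to build an exclusively-tyrosine
#' enzyme set by including tyrosine-activity annotations and excluding
#' serine/threonine ones.
#'
#' @param records annotation data frame with a `subclass` column.
#' @param include,exclude regular expressions on `subclass`.
#' @return filtered records; a `message()` logs the counts.
#' @export
filter_by_subclass <- function(records, include = NULL, exclude = NULL) {
  if (!"subclass" %in% names(records)) {
    stop("filter_by_subclass: records have no 'subclass' column")
  }
  sub <- as.character(records$subclass)
  sub[is.na(sub)] <- ""
  keep <- rep(TRUE, nrow(records))
  if (!is.null(include)) keep <- keep & grepl(include, sub)
  if (!is.null(exclude)) keep <- keep & !grepl(exclude, sub)
  message(sprintf("filter_by_subclass: kept %d/%d records", sum(keep), nrow(records)))
  records[keep, , drop = FALSE]
}

#' Default configuration of the class-asymmetry battery
#'
#' One row per comparison: the numeric metrics (abundance, half-life, PPI
#' degree, perturbation count, NGI count) tested by rank-sum and the flag
#' metrics (essentiality, responsiveness, the three phospho-capacity
#' evidence sources) tested by Fisher's exact test.
#'
#' @param class_a,class_b classes compared (writer first).
#' @return data frame with columns `metric`, `type`, `class_a`, `class_b`,
#'   `tail`.
#' @export
default_battery_config <- function(class_a = "kinase", class_b = "phosphatase") {
  data.frame(
    metric = c("abundance", "half_life", "ppi_degree", "de_perturbation_count",
               "ngi_count", "essential", "de_responsive", "phospho_curated",
               "phospho_peptide", "phospho_conserved"),
    type = c(rep("numeric", 5), rep("fraction", 5)),
    class_a = class_a,
    class_b = class_b,
    tail = c(rep("auto", 5), rep("two-tailed", 5)),
    stringsAsFactors = FALSE
  )
}

#' Run the class-asymmetry statistical battery
#'
#' Executes every configured comparison between the two opposing enzyme
#' classes (plus optional versus-background rows when `background_records`
#' is given and a row's `class_b` is `"background"`). Per-comparison errors
#' are recorded in the report and do not stop the battery. Output ordering
#' follows the configuration, so identical inputs give identical reports.
#'
#' @param records annotation data frame.
#' @param background_records optional genome-wide background records.
#' @param config comparison table, see [default_battery_config()].
#' @return an object of class `battery_report`: list with `results` (the
#'   [comparison_result] objects or error strings) and `table` (one row per
#'   comparison).
#' @export
run_battery <- function(records, background_records = NULL,
                        config = default_battery_config()) {
  stopifnot(all(c("metric", "type", "class_a", "class_b", "tail") %in% names(config)))
  results <- vector("list", nrow(config))
  rows <- vector("list", nrow(config))
  for (i in seq_len(nrow(config))) {
    cfg <- config[i, ]
    res <- tryCatch({
      if (identical(cfg$class_b, "background")) {
        if (is.null(background_records)) stop("no background records supplied")
        compare_vs_background(records, cfg$metric, cfg$class_a,
                              background_records, tail = cfg$tail)
      } else if (cfg$type == "numeric") {
        compare_numeric_metric(records, cfg$metric, cfg$class_a, cfg$class_b,
                               tail = cfg$tail)
      } else {
        compare_fraction_metric(records, cfg$metric, cfg$class_a, cfg$class_b,
                                tail = if (cfg$tail == "auto") "two-tailed" else cfg$tail)
      }
    }, error = function(e) conditionMessage(e))
    results[[i]] <- res
    rows[[i]] <- if (inherits(res, "comparison_result")) {
      cbind(as.data.frame(res), error = NA_character_)
    } else {
      data.frame(metric = cfg$metric, group_a = cfg$class_a, group_b = cfg$class_b,
                 n_a = NA_integer_, n_b = NA_integer_,
                 summary_type = NA_character_,
                 summary_a = NA_real_, summary_b = NA_real_,
                 test = NA_character_, tail = NA_character_,
                 statistic = NA_real_, p_value = NA_real_, stars = NA_character_,
                 error = res, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    rows <- list(data.frame(
      metric = character(), group_a = character(), group_b = character(),
      n_a = integer(), n_b = integer(), summary_type = character(),
      summary_a = numeric(), summary_b = numeric(), test = character(),
      tail = character(), statistic = numeric(), p_value = numeric(),
      stars = character(), error = character(), stringsAsFactors = FALSE
    ))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(results = results, table = tab), class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("class-asymmetry battery: %d comparisons\n", nrow(x$table)))
  print(x$table[, c("metric", "group_a", "group_b", "summary_a", "summary_b",
                    "p_value", "stars", "error")])
  invisible(x)
}
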