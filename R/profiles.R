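#' Impact breadth: number of distinct targets of an enzyme
#'
#' The out-degree of an enzyme in the full impact network (all targets, not
#' only within-class ones); a proxy for the breadth of its downstream
#' impact.
#'
#' @param net the full `impact_network`.
#' @param enzymes enzyme identifiers; `NULL` for all network nodes.
#' @return named integer vector of distinct-target counts.
#' @export
impact_breadth <- function(net, enzymes = NULL) {
  stopifnot(inherits(net, "impact_network"))
  deg <- network_degrees(net)$out
  if (is.null(enzymes)) return(deg)
  missing <- setdiff(enzymes, names(deg))
  if (length(missing)) {
    stop(sprintf("impact_breadth: unknown enzyme(s): %s",
                 paste(missing, collapse = ", ")))
  }
  deg[enzymes]
}

kinase_layer_groups <- function(layers, focal_layer, include_outgroup) {
  labs <- layers$labels
  valid <- c("TOP", "MID", "BOT", if (include_outgroup) "OUTGROUP")
  if (!focal_layer %in% valid) {
    stop(sprintf("unknown or excluded focal layer '%s'", focal_layer))
  }
  list(
    focal = names(labs)[labs == focal_layer],
    rest = names(labs)[labs %in% setdiff(valid, focal_layer)]
  )
}

new_layer_profile <- function(metric, focal_layer, summaries, comparison, type) {
  structure(
    list(metric = metric, focal_layer = focal_layer,
         layer_summaries = summaries, comparison = comparison,
         summary_type = type),
    class = "layer_profile"
  )
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("layer profile of '%s' (%s per layer):\n", x$metric, x$summary_type))
  print(x$layer_summaries)
  cat(sprintf("%s vs rest: ", x$focal_layer))
  print(x$comparison)
  invisible(x)
}

#' Profile a numeric metric across hierarchy layers
#'
#' Reports per-layer medians of a per-enzyme metric and tests the focal
#' layer against the pooled remaining kinase layers with the rank-sum test.
#' OUTGROUP enzymes are excluded by default (they are omitted from layer
#' analyses); missing values are dropped.
#'
#' @param layers a `layer_assignment` over kinases.
#' @param values named numeric vector of per-enzyme metric values.
#' @param focal_layer layer tested against the rest.
#' @param tail `"auto"` or an explicit rank-sum tail (direction refers to the
#'   focal layer).
#' @param include_outgroup include OUTGROUP enzymes in the comparison pool.
#' @return a `layer_profile` containing per-layer medians and the one-vs-rest
#'   [comparison_result].
#' @export
profile_numeric_by_layer <- function(layers, values, focal_layer,
                                     tail = "auto", include_outgroup = FALSE) {
  stopifnot(inherits(layers, "layer_assignment"))
  grp <- kinase_layer_groups(layers, focal_layer, include_outgroup)
  x <- values[grp$focal]
  y <- values[grp$rest]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x)) stop("profile_numeric_by_layer: focal layer has no measured values")
  if (!length(y)) stop("profile_numeric_by_layer: no measured values outside the focal layer")
  meds <- sapply(c("TOP", "MID", "BOT", "OUTGROUP"), function(l) {
    v <- values[names(layers$labels)[layers$labels == l]]
    median(v, na.rm = TRUE)
  })
  tail <- resolve_tail(tail, median(x), median(y))
  cmp <- rank_sum_test(x, y, tail = tail, metric = "layer_metric",
                       groups = c(focal_layer, "rest"))
  cmp$metric <- attr(values, "metric") %||% "value"
  new_layer_profile(cmp$metric, focal_layer, meds, cmp, "median")
}

#' Profile a flag metric across hierarchy layers
#'
#' Per-layer fractions of a logical flag with a one-vs-rest Fisher exact
#' test.
#'
#' @inheritParams profile_numeric_by_layer
#' @param flags named logical vector of per-enzyme flags.
#' @param tail Fisher tail.
#' @return a `layer_profile`.
#' @export
profile_fraction_by_layer <- function(layers, flags, focal_layer,
                                      tail = "two-tailed", include_outgroup = FALSE) {
  stopifnot(inherits(layers, "layer_assignment"))
  grp <- kinase_layer_groups(layers, focal_layer, include_outgroup)
  x <- flags[grp$focal]
  y <- flags[grp$rest]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x)) stop("profile_fraction_by_layer: focal layer has no measured flags")
  if (!length(y)) stop("profile_fraction_by_layer: no measured flags outside the focal layer")
  fracs <- sapply(c("TOP", "MID", "BOT", "OUTGROUP"), function(l) {
    v <- flags[names(layers$labels)[layers$labels == l]]
    mean(v, na.rm = TRUE)
  })
  cmp <- fisher_2x2(sum(x), sum(!x), sum(y), sum(!y), tail = tail,
                    metric = attr(flags, "metric") %||% "flag",
                    groups = c(focal_layer, "rest"))
  new_layer_profile(cmp$metric, focal_layer, fracs, cmp, "fraction")
}

#' Profile phosphatases as a group against kinase layers
#'
#' Erasers do not form their own hierarchy; they are treated as a fifth
#' group and compared against the chosen kinase layers (rank-sum for numeric
#' metrics, Fisher for flags).
#'
#' @param phosphatase_values named numeric or logical vector over
#'   phosphatases.
#' @param layers kinase `layer_assignment`.
#' @param kinase_values named vector of the same metric over kinases.
#' @param compare_layers kinase layers pooled as the comparison group.
#' @param type `"numeric"` or `"fraction"`.
#' @param tail test tail (`"auto"` allowed for numeric; direction refers to
#'   the phosphatases).
#' @return a `layer_profile` with focal group `"PHO"`.
#' @export
phosphatase_group_profile <- function(phosphatase_values, layers, kinase_values,
                                      compare_layers = c("TOP", "MID", "BOT"),
                                      type = c("numeric", "fraction"),
                                      tail = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(layers, "layer_assignment"))
  pool <- names(layers$labels)[layers$labels %in% compare_layers]
  x <- phosphatase_values[!is.na(phosphatase_values)]
  y <- kinase_values[intersect(names(kinase_values), pool)]
  y <- y[!is.na(y)]
  if (!length(x)) stop("phosphatase_group_profile: no measured phosphatase values")
  if (!length(y)) stop("phosphatase_group_profile: no measured kinase values in the chosen layers")
  if (type == "numeric") {
    tail <- resolve_tail(tail %||% "auto", median(as.numeric(x)), median(as.numeric(y)))
    cmp <- rank_sum_test(as.numeric(x), as.numeric(y), tail = tail,
                         metric = "phosphatase_vs_layers",
                         groups = c("PHO", paste(compare_layers, collapse = "+")))
    summaries <- c(PHO = median(as.numeric(x)), layers = median(as.numeric(y)))
    new_layer_profile(cmp$metric, "PHO", summaries, cmp, "median")
  } else {
    x <- as.logical(x)
    y <- as.logical(y)
    cmp <- fisher_2x2(sum(x), sum(!x), sum(y), sum(!y),
                      tail = tail %||% "two-tailed",
                      metric = "phosphatase_vs_layers",
                      groups = c("PHO", paste(compare_layers, collapse = "+")))
    summaries <- c(PHO = mean(x), layers = mean(y))
    new_layer_profile(cmp$metric, "PHO", summaries, cmp, "fraction")
  }
}
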