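# Canonical typed columns of the annotation table. "NA" is the missing
# sentinel; unknown columns are preserved untouched.
annotation_numeric_cols <- c("abundance", "ppi_degree", "de_perturbation_count",
                             "half_life", "conserved_sites", "ngi_count")
annotation_logical_cols <- c("essential", "disease_associated", "de_responsive",
                             "phospho_curated", "phospho_peptide", "phospho_conserved")

coerce_numeric_col <- function(x, col) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "NA" & is.na(out))
  if (length(bad)) {
    stop(sprintf("read_annotation_table: non-numeric value in column '%s' at data row %s",
                 col, paste(bad, collapse = ", ")))
  }
  out
}

coerce_logical_col <- function(x, col) {
  if (is.logical(x)) return(x)
  up <- toupper(as.character(x))
  out <- ifelse(up %in% c("TRUE", "T", "1"), TRUE,
         ifelse(up %in% c("FALSE", "F", "0"), FALSE, NA))
  bad <- which(!is.na(x) & up != "NA" & is.na(out))
  if (length(bad)) {
    stop(sprintf("read_annotation_table: non-logical value in column '%s' at data row %s",
                 col, paste(bad, collapse = ", ")))
  }
  out
}

#' Read an enzyme annotation table
#'
#' Reads a UTF-8 TSV with a mandatory header; `"NA"` marks missing values.
#' Columns `id` and `enzyme_class` are mandatory; the canonical numeric and
#' flag columns are typed and validated with row-numbered errors, and any
#' other column is preserved as an opaque annotation.
#'
#' @param path path to the TSV file.
#' @return annotation data frame.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                   check.names = FALSE, colClasses = "character")
  need <- setdiff(c("id", "enzyme_class"), names(df))
  if (length(need)) {
    stop(sprintf("read_annotation_table: missing mandatory column(s): %s",
                 paste(need, collapse = ", ")))
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop(sprintf("read_annotation_table: duplicate id(s): %s",
                 paste(dup, collapse = ", ")))
  }
  for (col in intersect(annotation_numeric_cols, names(df))) {
    df[[col]] <- coerce_numeric_col(df[[col]], col)
  }
  for (col in intersect(annotation_logical_cols, names(df))) {
    df[[col]] <- coerce_logical_col(df[[col]], col)
  }
  message(sprintf("read_annotation_table: %d records, %d columns", nrow(df), ncol(df)))
  df
}

#' Write an enzyme annotation table
#'
#' @param records annotation data frame.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_annotation_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an impact edge list
#'
#' TSV with header columns `source`, `target` and optional `provenance`.
#' Trailing newlines and CRLF line endings are tolerated; a blank endpoint
#' raises a parse error naming the offending line.
#'
#' @param path path to the TSV file.
#' @return data frame of edges in file order, ready for [build_network()].
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- setdiff(c("source", "target"), names(df))
  if (length(need)) {
    stop(sprintf("read_edge_list: missing mandatory column(s): %s",
                 paste(need, collapse = ", ")))
  }
  bad <- which(is.na(df$source) | df$source == "" | is.na(df$target) | df$target == "")
  if (length(bad)) {
    stop(sprintf("read_edge_list: blank endpoint at line %s",
                 paste(bad + 1L, collapse = ", ")))
  }
  df
}

#' Write an impact edge list
#'
#' @param edges edge data frame or `impact_network`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "impact_network")) edges <- edges$edges
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a battery configuration from YAML or JSON
#'
#' The file holds a list of comparison rows with fields `metric`, `type`
#' (`numeric`/`fraction`), `class_a`, `class_b` and optional `tail`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return configuration data frame for [run_battery()].
#' @export
read_battery_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- lapply(cfg, function(row) {
    data.frame(
      metric = row$metric, type = row$type,
      class_a = row$class_a, class_b = row$class_b,
      tail = row$tail %||% (if (identical(row$type, "numeric")) "auto" else "two-tailed"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write the analysis report
#'
#' Writes a deterministic set of outputs into `dir`: `report.tsv` (one row
#' per comparison, fixed column order), `report.json` (the same rows at full
#' numeric precision plus run metadata: package version, seed and a hash of
#' the configuration), and `layers.tsv` / `profiles.tsv` when layer
#' assignments or profiles are supplied. Rerunning with identical inputs
#' reproduces the files byte for byte.
#'
#' @param report a `battery_report` (or its `table` data frame).
#' @param layers optional `layer_assignment` or list of them.
#' @param profiles optional list of `layer_profile` objects.
#' @param dir output directory (created if absent).
#' @param seed optional seed recorded in the metadata.
#' @param config optional configuration object; hashed into the metadata.
#' @return invisibly, named vector of written paths.
#' @export
write_report <- function(report, layers = NULL, profiles = NULL, dir,
                         seed = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (inherits(report, "battery_report")) report$table else report
  paths <- c(report_tsv = file.path(dir, "report.tsv"),
             report_json = file.path(dir, "report.json"))
  write.table(tab, paths[["report_tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  meta <- list(
    package = "phosym",
    version = as.character(utils::packageVersion("phosym")),
    seed = seed,
    config_hash = if (!is.null(config)) {
      sprintf("%08x", str_hash31(paste(deparse(config), collapse = "\n")))
    }
  )
  jsonlite::write_json(list(metadata = meta, results = tab),
                       paths[["report_json"]],
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (!is.null(layers)) {
    if (inherits(layers, "layer_assignment")) layers <- list(layers)
    ltab <- do.call(rbind, lapply(layers, as.data.frame))
    paths <- c(paths, layers_tsv = file.path(dir, "layers.tsv"))
    write.table(ltab, paths[["layers_tsv"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(profiles)) {
    ptab <- do.call(rbind, lapply(profiles, function(p) {
      cbind(focal = p$focal_layer, as.data.frame(p$comparison))
    }))
    paths <- c(paths, profiles_tsv = file.path(dir, "profiles.tsv"))
    write.table(ptab, paths[["profiles_tsv"]], sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  invisible(paths)
}
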