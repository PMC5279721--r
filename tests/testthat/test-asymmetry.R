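make_two_class_records <- function(values_a, values_b, metric = "abundance",
                                   class_a = "kinase", class_b = "phosphatase") {
  df <- data.frame(
    id = sprintf("g%03d", seq_len(length(values_a) + length(values_b))),
    enzyme_class = rep(c(class_a, class_b), c(length(values_a), length(values_b))),
    stringsAsFactors = FALSE
  )
  df[[metric]] <- c(values_a, values_b)
  df
}

test_that("gene-count ratio reflects the writer excess", {
  tab <- generate_enzyme_table(yeast_enzyme_spec(seed = 2))
  expect_equal(gene_count_ratio(tab, "kinase", "phosphatase"), 137 / 50)
  eq <- make_two_class_records(1:5, 1:5)
  expect_equal(gene_count_ratio(eq, "kinase", "phosphatase"), 1)
  expect_error(gene_count_ratio(eq, "kinase", "ligase"), "unknown")
})

test_that("numeric metric comparison reports medians and respects missing values", {
  rec <- make_two_class_records(c(1, 2, 3), c(1, 2, 3))
  res <- compare_numeric_metric(rec, "abundance", "kinase", "phosphatase",
                                tail = "two-tailed")
  expect_equal(res$p_value, 1)
  expect_equal(res$summaries, c(2, 2))

  # group sizes count measured values, never raw class sizes
  rec2 <- make_two_class_records(c(1, 2, NA, NA), c(3, 4, 5))
  res2 <- compare_numeric_metric(rec2, "abundance", "kinase", "phosphatase")
  expect_equal(res2$n, c(2L, 3L))

  expect_error(compare_numeric_metric(rec, "half_life", "kinase", "phosphatase"),
               "absent")

  # generator with a genuine two-fold abundance difference is detected
  cl <- list(
    enzyme_class_spec("kinase", 100, abundance_median = 30, abundance_sdlog = 0.5),
    enzyme_class_spec("phosphatase", 100, abundance_median = 60, abundance_sdlog = 0.5)
  )
  tab <- generate_enzyme_table(enzyme_table_spec(cl, seed = 5))
  res3 <- compare_numeric_metric(tab, "abundance", "kinase", "phosphatase")
  expect_equal(res3$tail, "one-tailed-less")
  expect_lt(res3$p_value, 0.01)
})

test_that("rank-based comparisons are invariant to monotone transforms", {
  cl <- list(
    enzyme_class_spec("kinase", 60, abundance_median = 30),
    enzyme_class_spec("phosphatase", 40, abundance_median = 60)
  )
  tab <- generate_enzyme_table(enzyme_table_spec(cl, seed = 8))
  raw <- compare_numeric_metric(tab, "abundance", "kinase", "phosphatase")
  tab$abundance <- log(tab$abundance)
  logd <- compare_numeric_metric(tab, "abundance", "kinase", "phosphatase")
  expect_equal(raw$p_value, logd$p_value)
  expect_equal(raw$statistic, logd$statistic)
})

test_that("fraction metric comparison builds the flag-by-class table", {
  rec <- make_two_class_records(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5),
                                metric = "essential")
  expect_equal(compare_fraction_metric(rec, "essential", "kinase", "phosphatase")$p_value, 1)

  rec2 <- make_two_class_records(rep(c(TRUE, FALSE), c(8, 2)),
                                 rep(c(TRUE, FALSE), c(2, 8)),
                                 metric = "essential")
  res <- compare_fraction_metric(rec2, "essential", "kinase", "phosphatase")
  expect_equal(res$p_value, enum_fisher_two_tailed(8, 2, 2, 8))
  expect_equal(res$summaries, c(0.8, 0.2))
})

test_that("versus-background comparisons use plus markers and detect shifted classes", {
  set.seed(41)
  bg_values <- rlnorm(400, log(10), 1)
  bg <- data.frame(id = sprintf("b%03d", 1:400), enzyme_class = "protein",
                   abundance = bg_values, stringsAsFactors = FALSE)
  same <- data.frame(id = sprintf("k%03d", 1:400), enzyme_class = "kinase",
                     abundance = bg_values, stringsAsFactors = FALSE)
  res <- compare_vs_background(same, "abundance", "kinase", bg)
  expect_equal(res$p_value, 1)

  shifted <- same[1:100, ]
  shifted$abundance <- rlnorm(100, log(30), 1)
  res2 <- compare_vs_background(shifted, "abundance", "kinase", bg)
  expect_lt(res2$p_value, 0.05)
  expect_true(res2$stars %in% c("+", "++", "+++"))

  # excluding the focal class removes its ids from the background
  bg2 <- rbind(bg, same)
  res3 <- compare_vs_background(same, "abundance", "kinase", bg2, exclude_class = TRUE)
  expect_equal(res3$n[2], 400L)
})

test_that("responsiveness-abundance correlation is near zero for independent metrics", {
  cl <- list(enzyme_class_spec("kinase", 1000, responsive_rate = 0.9))
  tab <- generate_enzyme_table(enzyme_table_spec(cl, seed = 2))
  res <- responsiveness_abundance_correlation(tab)
  expect_lt(abs(res$rho), 0.1)

  coupled <- data.frame(id = sprintf("g%02d", 1:20), enzyme_class = "kinase",
                        abundance = 1:20, de_perturbation_count = (1:20)^2,
                        stringsAsFactors = FALSE)
  expect_equal(responsiveness_abundance_correlation(coupled, scope = "kinase")$rho, 1)
})

test_that("subclass filtering is plain set algebra on annotations", {
  rec <- data.frame(
    id = sprintf("g%02d", 1:6),
    enzyme_class = "kinase",
    subclass = c("tyrosine", "tyrosine;ser_thr", "ser_thr", "tyrosine", NA, "other"),
    stringsAsFactors = FALSE
  )
  expect_equal(suppressMessages(filter_by_subclass(rec)), rec)
  expect_equal(nrow(suppressMessages(filter_by_subclass(rec, include = "nomatch"))), 0)
  got <- suppressMessages(filter_by_subclass(rec, include = "tyrosine", exclude = "ser_thr"))
  brute <- rec[grepl("tyrosine", rec$subclass) & !grepl("ser_thr", rec$subclass) &
                 !is.na(rec$subclass), ]
  expect_equal(got$id, brute$id)
})

test_that("the battery runs every configured comparison deterministically", {
  tab <- generate_enzyme_table(yeast_enzyme_spec(seed = 5))
  rep1 <- run_battery(tab)
  expect_equal(nrow(rep1$table), nrow(default_battery_config()))
  expect_identical(rep1$table, run_battery(tab)$table)

  # the planted two-fold abundance asymmetry is flagged, eraser above writer
  ab <- rep1$table[rep1$table$metric == "abundance", ]
  expect_gt(ab$summary_b, ab$summary_a)
  expect_lt(ab$p_value, 0.05)

  # a failing row is recorded without stopping the battery
  cfg <- default_battery_config()
  cfg$metric[1] <- "no_such_metric"
  rep2 <- run_battery(tab, config = cfg)
  expect_match(rep2$table$error[1], "absent")
  expect_true(all(is.na(rep2$table$error[-1])))
})
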