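test_that("spearman handles monotone, reversed and tied inputs", {
  expect_equal(spearman_test(1:5, c(2, 4, 6, 8, 10))$rho, 1.0)
  expect_equal(spearman_test(1:5, c(2, 4, 6, 8, 10))$p, 0)
  expect_equal(spearman_test(c(1, 2, 3), c(3, 2, 1))$rho, -1.0)
  res <- spearman_test(c(1, 1, 0, 0), c(4, 3, 2, 1))
  expect_equal(res$rho, 4 / sqrt(20), tolerance = 1e-12)
  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_test(c(1, 2), c(1, 2)), "at least 3")
})

test_that("spearman matches the explicit midrank oracle with ties", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE) + round(stats::rnorm(n), 1)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- spearman_test(x, y)
    expect_equal(res$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    # cross-check against the library implementation
    expect_equal(res$rho,
                 unname(suppressWarnings(
                   stats::cor.test(x, y, method = "spearman")$estimate)),
                 tolerance = 1e-12)
    # p equals the t test on midranks
    pt_ref <- stats::cor.test(rank(x), rank(y), method = "pearson")$p.value
    expect_equal(res$p, pt_ref, tolerance = 1e-10)
  }
})

test_that("spearman is symmetric and invariant to monotone transforms", {
  set.seed(5)
  x <- sample(1:5, 20, replace = TRUE)
  y <- stats::rnorm(20)
  expect_equal(spearman_test(x, y)$rho, spearman_test(y, x)$rho)
  expect_equal(spearman_test(exp(x), y)$rho, spearman_test(x, y)$rho)
  expect_equal(spearman_test(x, 3 * y - 10)$rho, spearman_test(x, y)$rho)
})

test_that("exact permutation p matches the exact null for untied data", {
  set.seed(9)
  x <- c(3, 1, 4, 5, 2, 6)
  y <- c(2, 1, 5, 3, 6, 4)
  ex <- spearman_test(x, y, exact = TRUE)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  expect_equal(ex$p, ref, tolerance = 1e-12)
  expect_error(spearman_test(1:9, 9:1, exact = TRUE), "n <= 8")
})

test_that("significance flags follow the 0.05 / 0.01 thresholds", {
  expect_equal(herdnet:::significance_label(0.004), "p<0.01")
  expect_equal(herdnet:::significance_label(0.03), "p<0.05")
  expect_equal(herdnet:::significance_label(0.2), "ns")
})

test_that("the three data sets have the documented shapes", {
  res <- run_pipeline(small_config(n_periods = 4), verbose = FALSE)
  ds <- res$datasets
  expect_equal(nrow(ds$global_vs_activity), 7L * 4L)
  expect_equal(nrow(ds$local_vs_activity), 7L * 4L * 91L)
  expect_equal(nrow(ds$attribute_vs_centrality), 7L * 4L * 91L)
  # exactly one activity indicator is 1 per row
  ind <- as.matrix(ds$global_vs_activity[, activities()])
  expect_true(all(rowSums(ind) == 1L))
  # attributes joined from the roster
  i <- sample(nrow(ds$attribute_vs_centrality), 1)
  row <- ds$attribute_vs_centrality[i, ]
  m <- match(row$animal_id, res$roster$animal_id)
  expect_equal(row$age, res$roster$age[m])
  expect_equal(row$gender, res$roster$gender[m])

  assoc <- res$associations
  expect_equal(nrow(assoc$global), 21L)
  expect_equal(nrow(assoc$local), 28L)
  expect_equal(nrow(assoc$attribute), 56L)
})

test_that("constant vectors propagate as missing results with a reason", {
  prev <- c(grazing = 0.6, moving = 0.4, standing = 0, ruminating = 0,
            wallowing = 0, lying = 0, drinking = 0)
  res <- run_pipeline(small_config(n_periods = 4,
                                   activity_prevalence = prev),
                      verbose = FALSE)
  # drinking never occurs: its networks exist but every centrality is 0
  # there, so the attribute correlations are undefined and reported missing
  at <- res$associations$attribute
  drank <- at[at$activity_context == "drinking", ]
  expect_true(all(is.na(drank$rho)))
  expect_true(all(grepl("constant", drank$note)))
  # its activity indicator still varies across networks, so data set 1
  # correlations stay defined (the empty networks are genuine cases)
  g <- res$associations$global
  expect_true(all(!is.na(g$rho[g$variable %in% c("grazing", "drinking")])))
})

test_that("a single-animal herd yields edgeless networks and missing associations", {
  ros <- herd_roster("B1", 5, 1)
  cfg <- generator_config(seed = 2, n_female = 1, n_male = 0, n_periods = 5)
  rec <- generate_records(cfg, ros)
  res <- run_pipeline(roster = ros, records = rec, verbose = FALSE)
  expect_true(all(res$index_table$local$degree == 0L))
  expect_true(all(is.na(res$associations$local$rho)))
  expect_true(all(nzchar(res$associations$local$note)))
})

test_that("correlogram cells format rho with significance stars", {
  expect_equal(herdnet:::format_cell(0.5, 0.004), "0.50**")
  expect_equal(herdnet:::format_cell(-0.123, 0.03), "-0.12*")
  expect_equal(herdnet:::format_cell(0.02, 0.5), "0.02")
  expect_equal(herdnet:::format_cell(NA_real_, NA_real_), "NA")

  res <- run_pipeline(small_config(n_periods = 4), verbose = FALSE)
  tabs <- res$correlograms
  expect_equal(dim(tabs$global), c(7L, 1L + 3L))
  expect_equal(dim(tabs$local), c(7L, 1L + 4L))
  expect_equal(dim(tabs$attribute), c(14L, 2L + 4L))
  expect_true(all(grepl("^(NA|-?\\d+\\.\\d{2}\\**)$",
                        unlist(tabs$global[, -1]))))
})
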