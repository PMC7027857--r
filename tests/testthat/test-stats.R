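test_that("aggregation attaches design labels and is order-invariant", {
  d <- experiment_design(replicates_per_cell = 10, seed = 2)
  res <- data.frame(column_id = d$column_id, n_interactions = 2,
                    n_colonize = 1, n_cross = 1, n_changed = 1,
                    n_unchanged = 1, n_indeterminate = 0)
  agg <- aggregate_columns(res, d)
  expect_equal(mean(agg$n_interactions), 2)
  expect_true(all(c("genotype", "treatment", "block") %in% names(agg)))

  agg2 <- aggregate_columns(res[sample(nrow(res)), ], d)
  expect_equal(agg2, agg)

  expect_error(aggregate_columns(res, d[, c("column_id", "genotype")]),
               "manifest must provide")
  expect_error(aggregate_columns(rbind(res, data.frame(
    column_id = "C999", n_interactions = 0, n_colonize = 0, n_cross = 0,
    n_changed = 0, n_unchanged = 0, n_indeterminate = 0)), d),
    "missing design labels")
})

test_that("aggregated means match hand computation on truth-known data", {
  sc <- default_scene()
  d <- experiment_design(replicates_per_cell = 2, seed = 12)
  ex <- simulate_experiment(d, sc$spec, pores = sc$pores, n_filler = 0)
  res <- do.call(rbind, lapply(ex$columns, function(cl)
    analyze_column(cl, sc$pores)))
  agg <- aggregate_columns(res, d)
  hand <- nrow(ex$truth) / nrow(d)
  expect_equal(mean(agg$n_interactions), hand)
  expect_equal(sum(agg$n_colonize), sum(ex$truth$outcome_colonize))
})

test_that("Shapiro-Wilk behaves as a normality test should", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  set.seed(1)
  p_norm <- replicate(100, shapiro_wilk(rnorm(50))$p)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- replicate(100, shapiro_wilk(rexp(50))$p)
  expect_gte(mean(p_exp < 0.05), 0.9)
  W <- replicate(50, shapiro_wilk(rnorm(20))$W)
  expect_true(all(W <= 1 & W > 0))
})

test_that("randomized-block ANOVA detects large effects and partitions SS", {
  d <- experiment_design(seed = 3)
  set.seed(31)
  d$y <- rnorm(40) + ifelse(d$treatment == "compact_1.6", 3, 0)
  d$genotype <- factor(d$genotype); d$treatment <- factor(d$treatment)
  d$block <- factor(d$block)
  tab <- rbd_anova(d, "y")
  expect_setequal(tab$term, c("block", "genotype", "treatment",
                              "genotype:treatment", "Residuals"))
  expect_lt(tab$p[tab$term == "treatment"], 0.01)
  ## SS identity: components sum to the total SS
  expect_equal(sum(tab$ss), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  ## df consistent with the design: 5 + 1 + 1 + 1 + 31 = 39
  expect_equal(sum(tab$df), 39)
})

test_that("ANOVA p-values are calibrated under the null", {
  d <- experiment_design(seed = 6)
  d$genotype <- factor(d$genotype); d$treatment <- factor(d$treatment)
  d$block <- factor(d$block)
  set.seed(60)
  ps <- t(replicate(200, {
    d$y <- rnorm(40)
    tab <- rbd_anova(d, "y")
    c(g = tab$p[tab$term == "genotype"],
      t = tab$p[tab$term == "treatment"],
      gt = tab$p[tab$term == "genotype:treatment"])
  }))
  for (j in 1:3) {
    expect_gt(suppressWarnings(stats::ks.test(ps[, j], "punif")$p.value), 0.01)
  }
})

test_that("LSD follows its closed form and limits", {
  expect_equal(lsd(1, 27, 10), qt(0.975, 27) * sqrt(2 / 10), tolerance = 1e-12)
  ns <- c(4, 8, 16, 32)
  vals <- sapply(ns, function(n) lsd(2.5, 30, n))
  expect_true(all(diff(vals) < 0))
  expect_lt(lsd(1, 27, 10, alpha = 1 - 1e-9), 1e-4)
  expect_error(lsd(-1, 27, 10))
})

test_that("combined percentages follow counting arithmetic", {
  ev <- data.frame(
    classification = c(rep("colonize", 11), rep("cross", 5)),
    trajectory = c(rep("changed", 11), rep("unchanged", 4), "indeterminate"),
    treatment = "compact_1.6")
  pct <- combined_percentages(ev)
  expect_equal(pct$pct_colonize, 100 * 11 / 16)   # 68.75
  expect_equal(pct$pct_colonize + pct$pct_cross, 100)
  ## changed over determinate events only (15 of 16)
  expect_equal(pct$pct_changed, 100 * 11 / 15)
  expect_equal(pct$n_determinate, 15)

  none <- data.frame(classification = rep("cross", 4),
                     trajectory = rep("unchanged", 4), treatment = "loose_1.2")
  expect_equal(combined_percentages(none)$pct_colonize, 0)
  expect_error(combined_percentages(ev[0, ]), "no events")
})

test_that("treatment effects on colonization reach significance in full experiments", {
  sc <- default_scene()
  reject <- logical(5)
  for (i in seq_len(5)) {
    d <- experiment_design(seed = 100 + i)
    ex <- simulate_experiment(d, sc$spec, pores = sc$pores, n_filler = 0)
    tr <- ex$truth
    counts <- table(factor(tr$column_id, levels = d$column_id),
                    tr$outcome_colonize)
    res <- data.frame(column_id = d$column_id,
                      n_colonize = as.vector(counts[, "TRUE"]))
    agg <- aggregate_columns(res, d)
    tab <- rbd_anova(agg, "n_colonize")
    reject[i] <- tab$p[tab$term == "treatment"] < 0.05
  }
  expect_gte(mean(reject), 0.8)
})

test_that("stats_report assembles a coherent summary", {
  sc <- default_scene()
  d <- experiment_design(replicates_per_cell = 3, seed = 9)
  ex <- simulate_experiment(d, sc$spec, pores = sc$pores, n_filler = 0)
  res <- do.call(rbind, lapply(ex$columns, function(cl)
    analyze_column(cl, sc$pores)))
  agg <- aggregate_columns(res, d)
  ev <- do.call(rbind, lapply(ex$columns, classify_events, sc$pores))
  ev <- merge(ev, d[, c("column_id", "treatment")], by = "column_id")
  rep <- suppressMessages(stats_report(agg, ev))
  expect_s3_class(rep, "stats_report")
  expect_equal(nrow(rep$cell_means), 4)
  expect_true(all(rep$lsd > 0 | is.na(rep$lsd)))
  if (!is.null(rep$percentages)) {
    expect_equal(rep$percentages$pct_colonize + rep$percentages$pct_cross,
                 rep(100, nrow(rep$percentages)))
  }
  dir <- tempfile()
  write_stats_report(rep, dir)
  expect_true(file.exists(file.path(dir, "stats_report.json")))
  expect_true(file.exists(file.path(dir, "cell_means.csv")))
  unlink(dir, recursive = TRUE)
})
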