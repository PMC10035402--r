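test_that("mutation rates are per targeted megabase", {
  panel <- list(target_mbp = 3.75)
  r <- mutation_rate_per_biopsy(30, 15, panel)
  expect_equal(r$total, 12)
  expect_equal(r$nonsilent, 8)
  expect_equal(mutation_rate_per_biopsy(0, 0, panel)$total, 0)
  expect_error(mutation_rate_per_biopsy(-1, 0, panel), "negative")
})

test_that("two-sample t matches the textbook pooled formula", {
  a <- c(1, 2, 3)
  b <- c(1, 2, 3, 100)
  tt <- two_sample_t(a, b)
  # independent closed-form oracle
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df_oracle <- length(a) + length(b) - 2
  p_oracle <- 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE)
  expect_equal(tt$t, t_oracle, tolerance = 1e-10)
  expect_equal(tt$df, df_oracle)
  expect_equal(tt$p, p_oracle, tolerance = 1e-10)
  # identical nondegenerate groups
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(c(1), c(1, 2)), ">= 2")
})

test_that("t statistic is invariant under common affine transforms", {
  set.seed(3)
  a <- rnorm(10)
  b <- rnorm(12, 1)
  t0 <- two_sample_t(a, b)$t
  t1 <- two_sample_t(3 * a + 7, 3 * b + 7)$t
  expect_equal(t0, t1, tolerance = 1e-12)
})

test_that("age comparison reproduces the printed group means", {
  p <- read_cohort_table(table1_path())
  col <- p$age[p$country == "Colombia"]
  other <- p$age[p$country %in% c("Mexico", "USA")]
  tt <- two_sample_t(col, other)
  expect_equal(round(tt$mean_a, 1), 54.6)
  expect_equal(round(tt$mean_b, 1), 66.9)
  expect_equal(tt$n_missing, 1)   # the NA-age patient
  expect_lt(tt$p, 0.05)
})

test_that("Freeman-Halton enumeration matches hand-computed hypergeometrics", {
  # 2x2 [[2,0],[0,2]]: three tables with these margins, p = 1/6 + 1/6
  p <- fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(as.numeric(p), 1 / 3, tolerance = 1e-12)
  # identical rows: observed table has maximal probability
  expect_equal(as.numeric(fisher_exact(matrix(c(5, 5, 5, 5), 2))), 1)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("2x2 enumeration agrees with the classical two-sided Fisher test", {
  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0 || sum(tab) > 40) next
    mine <- as.numeric(fisher_exact(tab))
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-8, info = paste(tab, collapse = ","))
  }
})

test_that("r x c enumeration agrees with fisher.test and with Monte Carlo", {
  tab <- matrix(c(1, 2, 8, 8,
                  1, 0, 3, 5), ncol = 2)
  p_enum <- as.numeric(fisher_exact(tab, "enumerate"))
  expect_equal(p_enum, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  n_draws <- 2e4
  p_mc <- as.numeric(fisher_exact(tab, "monte_carlo", n_draws = n_draws,
                                  seed = 4))
  se <- sqrt(p_enum * (1 - p_enum) / n_draws)
  expect_lt(abs(p_mc - p_enum), 3 * se)
  # a second table with different shape
  tab2 <- matrix(c(6, 1, 2, 5, 3, 3), nrow = 2)
  p2 <- as.numeric(fisher_exact(tab2, "enumerate"))
  p2mc <- as.numeric(fisher_exact(tab2, "monte_carlo", n_draws = n_draws,
                                  seed = 5))
  expect_lt(abs(p2mc - p2), 3 * sqrt(p2 * (1 - p2) / n_draws) + 1e-6)
})

test_that("the Latino subtype-by-country table gives the printed Fisher p", {
  p <- read_cohort_table(table1_path())
  tab <- subtype_country_table(p, countries = c("Colombia", "Mexico"),
                               ethnicity = "Latino")
  expect_equal(unname(tab[, "Colombia"]), c(1, 2, 8, 8))
  expect_equal(unname(tab[, "Mexico"]), c(1, 0, 3, 5))
  pv <- as.numeric(fisher_exact(tab, "enumerate"))
  expect_equal(round(pv, 1), 0.8)
})

test_that("cohort summary reproduces the printed clinical statistics", {
  p <- read_cohort_table(table1_path())
  s <- summarize_cohort(p)
  expect_equal(s$percent_male, 59)
  expect_equal(s$percent_advanced_stage, 76)
  expect_equal(s$mean_age_rounded, 60)
  expect_equal(as.vector(s$subtype_percent_latino), c(7, 7, 38, 48))
  # invariance under patient reordering
  s2 <- summarize_cohort(p[rev(seq_len(nrow(p))), ])
  expect_equal(s2$percent_male, s$percent_male)
  expect_equal(s2$percent_advanced_stage, s$percent_advanced_stage)
  expect_equal(s2$subtype_percent, s$subtype_percent)
  # denominator variant over all 32 patients
  s3 <- summarize_cohort(p, advanced_denominator = "all")
  expect_equal(s3$percent_advanced_stage, round_half_up(100 * 22 / 32))
})
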