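test_that("Clopper-Pearson interval matches the binomial-tail root oracle", {
  grid <- expand.grid(k = c(0, 1, 5, 9, 13, 15, 18, 35), n = c(11, 18, 24, 35, 50))
  grid <- grid[grid$k <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]
    n <- grid$n[i]
    ci <- clopper_pearson_interval(k, n, 0.90)
    expect_equal(ci$lower, cp_lower_oracle(k, n, 0.05), tolerance = 1e-8)
    expect_equal(ci$upper, cp_upper_oracle(k, n, 0.05), tolerance = 1e-8)
    # cross-check against stats::binom.test at the same level
    bt <- binom.test(k, n, conf.level = 0.90)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-12)
  }
})

test_that("interval endpoints honour the boundary clamps and contain k/n", {
  expect_equal(clopper_pearson_interval(0, 10, 0.90)$lower, 0)
  expect_equal(clopper_pearson_interval(10, 10, 0.90)$upper, 1)
  set.seed(1)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson_interval(k, n, runif(1, 0.5, 0.99))
    expect_true(ci$lower <= k / n + 1e-12 && k / n <= ci$upper + 1e-12)
  }
  # width shrinks as n grows at fixed k/n
  w <- sapply(c(10, 40, 160), function(n) {
    ci <- clopper_pearson_interval(0.6 * n, n, 0.90)
    ci$upper - ci$lower
  })
  expect_true(all(diff(w) < 0))
  expect_error(clopper_pearson_interval(3, 0), "n must be")
})

test_that("exact interval is conservative: true coverage >= nominal", {
  # exact coverage: sum binomial probabilities of the k whose interval covers p
  for (n in c(10, 30, 80)) {
    ci <- clopper_pearson_interval(0:n, n, 0.90)
    for (p in seq(0.1, 0.9, by = 0.1)) {
      coverage <- sum(dbinom(0:n, n, p)[ci$lower <= p & p <= ci$upper])
      expect_gte(coverage, 0.90)
    }
  }
})

test_that("exact binomial test agrees with enumeration and binom.test", {
  # lower tail by direct enumeration
  p_lower <- sum(dbinom(0:16, 50, 0.45))
  expect_equal(
    exact_binomial_test(16, 50, 0.45, "less")$p_value, p_lower,
    tolerance = 1e-12
  )
  cases <- list(c(16, 50, 0.45), c(10, 45, 0.20), c(9, 11, 0.5), c(0, 10, 0.3))
  for (cs in cases) {
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(
        exact_binomial_test(cs[1], cs[2], cs[3], alt)$p_value,
        binom.test(cs[1], cs[2], cs[3], alternative = alt)$p.value,
        tolerance = 1e-9,
        label = paste(cs, collapse = "/")
      )
    }
  }
  # at the mode the two-sided p-value is ~1 and never rejects
  expect_gt(exact_binomial_test(20, 100, 0.2)$p_value, 0.95)
  expect_error(exact_binomial_test(5, 10, 1.2), "p0")
})

test_that("concordance table splits evaluable patients by criterion", {
  calls <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:40),
    status = c(rep("mR", 9), rep("mPD", 2), rep("mR", 6), rep("mPD", 18),
      rep("undetectable", 3), rep("not_evaluable", 2)),
    baseline_max_maf = c(runif(35, 0.01, 0.2), rep(0, 3), NA, NA)
  )
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:40),
    recist_bor = c(rep("PR", 11), rep("PD", 24), rep("SD", 3), "NE", "NE"),
    irecist_bor = c(rep("iPR", 11), rep("iPD", 24), rep("iSD", 3), "NE", "NE")
  )
  tab <- build_concordance_table(calls, patients, "RECIST")
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(9L, 2L, 6L, 18L))
  # undetectable / not-evaluable / NE all excluded
  expect_identical(tab$a + tab$b + tab$c + tab$d, 35L)
  g <- glance(tab)
  expect_identical(g$n, 35L)

  perf <- concordance_performance(tab, level = 0.90)
  sens <- perf[perf$statistic == "sensitivity", ]
  spec <- perf[perf$statistic == "specificity", ]
  expect_equal(sens$estimate, 9 / 11)
  expect_equal(spec$estimate, 18 / 24)
  expect_equal(sens$lower, qbeta(0.05, 9, 3))

  # performance is invariant to patient ordering
  idx <- sample(nrow(calls))
  tab2 <- build_concordance_table(calls[idx, ], patients[sample(40), ], "RECIST")
  expect_identical(
    c(tab2$a, tab2$b, tab2$c, tab2$d), c(tab$a, tab$b, tab$c, tab$d)
  )

  # empty margin reports absent statistic
  tab3 <- concordance_table(5, 0, 0, 7)
  perf3 <- concordance_performance(tab3)
  expect_equal(perf3$estimate, c(1, 1))
  tab4 <- concordance_table(0, 0, 3, 7)
  perf4 <- concordance_performance(tab4)
  expect_true(is.na(perf4$estimate[perf4$statistic == "sensitivity"]))
  expect_error(build_concordance_table(calls, patients, "WHO"))
})

test_that("baseline maxMAF subgroups reproduce generator-known tables", {
  # two strata with known 2x2 tables: low stratum (8 resp: 6 mR; 12 nonresp:
  # 3 mR) high stratum (6 resp: 5 mR; 10 nonresp: 1 mR)
  calls <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:36),
    status = c(
      rep("mR", 6), rep("mPD", 2), rep("mR", 3), rep("mPD", 9),
      rep("mR", 5), rep("mPD", 1), rep("mR", 1), rep("mPD", 9)
    ),
    baseline_max_maf = c(rep(0.01, 20), rep(0.08, 16))
  )
  patients <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:36),
    recist_bor = c(rep("PR", 8), rep("PD", 12), rep("PR", 6), rep("PD", 10)),
    irecist_bor = NA_character_
  )
  sub <- subgroup_concordance_by_baseline_maf(
    calls, patients,
    thresholds = 0.03, criterion = "RECIST"
  )
  lo_sens <- sub[sub$stratum == "<0.03" & sub$statistic == "sensitivity", ]
  lo_spec <- sub[sub$stratum == "<0.03" & sub$statistic == "specificity", ]
  hi_sens <- sub[sub$stratum == ">=0.03" & sub$statistic == "sensitivity", ]
  hi_spec <- sub[sub$stratum == ">=0.03" & sub$statistic == "specificity", ]
  expect_equal(lo_sens$estimate, 6 / 8)
  expect_equal(lo_spec$estimate, 9 / 12)
  expect_equal(hi_sens$estimate, 5 / 6)
  expect_equal(hi_spec$estimate, 9 / 10)

  # a threshold below every baseline load reproduces the unstratified result
  all_in_one <- subgroup_concordance_by_baseline_maf(
    calls, patients,
    thresholds = 0.001, criterion = "RECIST"
  )
  pooled <- concordance_performance(
    build_concordance_table(calls, patients, "RECIST")
  )
  up <- all_in_one[all_in_one$stratum == ">=0.001", ]
  expect_equal(up$estimate, pooled$estimate)

  # two thresholds -> four performance rows per statistic pair
  sub2 <- subgroup_concordance_by_baseline_maf(
    calls, patients,
    thresholds = c(0.03, 0.04), criterion = "RECIST"
  )
  expect_identical(nrow(sub2), 8L)
})

test_that("design bound: 18 responders ensure a 90% CI lower bound above 50%", {
  res <- min_responders_for_bound(0.70, 0.90, 0.50)
  # the bound is non-monotone in n; the smallest passing n is 13 (k = 10),
  # and the trial-style sufficient count 18 (k = 13) passes it too
  expect_identical(res$n, 13L)
  expect_identical(res$k, 10L)
  expect_gt(res$lower, 0.50)
  expect_gt(clopper_pearson_interval(13, 18, 0.90)$lower, 0.50)
  # oracle: tail probability at the reported lower bound equals alpha
  expect_equal(
    pbinom(res$k - 1, res$n, res$lower, lower.tail = FALSE), 0.05,
    tolerance = 1e-8
  )
  # small n fails the bound
  k5 <- ceiling(0.70 * 5)
  expect_lt(clopper_pearson_interval(k5, 5, 0.90)$lower, 0.50)
  # trivial bound
  expect_identical(min_responders_for_bound(0.70, 0.90, 0)$n, 1L)
  expect_error(min_responders_for_bound(0.4, 0.9, 0.5), "assumed_rate")
})
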