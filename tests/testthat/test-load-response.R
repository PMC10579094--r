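test_that("load trajectory computes metrics over tracked tumor variants", {
  cohort <- make_test_cohort()
  ann <- annotate_cohort_origins(cohort)
  traj <- compute_load_trajectory(cohort, ann)

  # P1 tracks two tumor variants (hotspot 0.0019, TP53 0.04) at baseline
  p1c1 <- traj[traj$patient_id == "P1" & traj$timepoint == "C1D1", ]
  expect_identical(p1c1$n_tracked, 2L)
  expect_equal(p1c1$max_maf, 0.04)
  expect_equal(p1c1$mean_maf, mean(c(0.04, 0.0019)))
  # both cleared from C2D1 on: zero-filled, not dropped
  p1c2 <- traj[traj$patient_id == "P1" & traj$timepoint == "C2D1", ]
  expect_identical(p1c2$n_tracked, 2L)
  expect_identical(p1c2$n_detected, 0L)
  expect_equal(p1c2$max_maf, 0)

  # germline/CHIP excluded everywhere
  expect_true(all(traj$max_maf[traj$patient_id == "P1"] <= 0.04, na.rm = TRUE))

  # max >= mean >= 0 and max >= median at every available timepoint
  av <- traj[traj$sample_available, ]
  expect_true(all(av$max_maf >= av$mean_maf - 1e-12))
  expect_true(all(av$max_maf >= av$median_maf - 1e-12))
})

test_that("trajectory arithmetic matches direct computation", {
  mafs <- c(0.012, 0.005, 0.002)
  ov <- purrr::imap_dfr(mafs, function(m, i) {
    tibble::tibble(
      patient_id = "P2", sample_id = "P2_C1_P", timepoint = "C1D1",
      compartment = "plasma", chrom = "chrZ", pos = as.integer(i), ref = "A",
      alt = "T", gene = NA_character_, protein_change = NA_character_,
      maf = m, mutant_reads = 30L, distinct_coverage = 3000L
    )
  })
  base <- make_test_cohort()
  cohort <- cohort_dataset(ov, base$samples, base$patients)
  traj <- compute_load_trajectory(cohort, annotate_cohort_origins(cohort))
  row <- traj[traj$patient_id == "P2" & traj$timepoint == "C1D1", ]
  expect_equal(row$max_maf, 0.012)
  expect_equal(row$mean_maf, mean(mafs))
  expect_equal(row$median_maf, 0.005)
})

test_that("response calling covers the canonical trajectory cases", {
  cases <- list(
    list(maf = c(0.04, 0, 0), status = "mR", clr = "C2D1", pat = "clearance_C2"),
    list(maf = c(0.03, 0.01, 0), status = "mR", clr = "C3D1", pat = "clearance_C3"),
    list(maf = c(0.02, 0.002, 0.0025), status = "mPD", clr = NA, pat = "deep_reduction"),
    list(maf = c(0.04, 0, NA), status = "mR", clr = "C2D1", pat = "clearance_C2"),
    list(maf = c(0, 0, 0), status = "undetectable", clr = NA, pat = "none"),
    # cleared at C2 but detectable again at C3: maxMAF persists -> mPD; the
    # transient 100% reduction still counts as a deep (>85%) reduction
    list(maf = c(0.02, 0, 0.004), status = "mPD", clr = NA, pat = "deep_reduction"),
    # baseline zero with later detectable ctDNA -> mPD
    list(maf = c(0, 0.01, 0.02), status = "mPD", clr = NA, pat = "persistence"),
    # no on-therapy draws -> not evaluable
    list(maf = c(0.02, NA, NA), status = "not_evaluable", clr = NA, pat = "none"),
    # baseline missing -> not evaluable
    list(maf = c(NA, 0.01, 0), status = "not_evaluable", clr = NA, pat = "none")
  )
  for (cs in cases) {
    call <- call_molecular_response(make_trajectory(cs$maf))
    expect_identical(call$status, cs$status, label = paste(cs$maf, collapse = "/"))
    if (is.na(cs$clr)) {
      expect_true(is.na(call$clearance_timepoint))
    } else {
      expect_identical(call$clearance_timepoint, cs$clr)
    }
    expect_identical(call$kinetic_pattern, cs$pat,
      label = paste(cs$maf, collapse = "/")
    )
  }
})

test_that("deep reduction needs >85% best on-therapy reduction without clearance", {
  # 86% reduction at C2
  call <- call_molecular_response(make_trajectory(c(0.01, 0.0014, 0.002)))
  expect_identical(call$kinetic_pattern, "deep_reduction")
  expect_equal(call$best_on_therapy_reduction, 1 - 0.0014 / 0.01)
  # 10% reduction: persistence
  call2 <- call_molecular_response(make_trajectory(c(0.01, 0.009, 0.012)))
  expect_identical(call2$kinetic_pattern, "persistence")
  # raising the threshold can only demote deep_reduction to persistence
  call3 <- call_molecular_response(make_trajectory(c(0.01, 0.0014, 0.002)),
    reduction_threshold = 0.9
  )
  expect_identical(call3$kinetic_pattern, "persistence")
})

test_that("calling depends only on maxMAF and is scale-invariant at threshold 0", {
  set.seed(11)
  for (i in 1:20) {
    maf <- c(runif(1, 0.001, 0.3), sample(c(0, runif(1, 0.001, 0.3)), 2, TRUE))
    tr <- make_trajectory(maf)
    call <- call_molecular_response(tr)
    # mean/median perturbation does not change the call
    tr2 <- tr
    tr2$mean_maf <- tr2$mean_maf / 2
    tr2$median_maf <- tr2$median_maf / 3
    expect_identical(call_molecular_response(tr2)$status, call$status)
    # uniform rescaling of all MAFs
    c_scale <- runif(1, 0.1, 5)
    tr3 <- make_trajectory(maf * c_scale)
    expect_identical(call_molecular_response(tr3)$status, call$status)
  }
})

test_that("every patient gets exactly one status and counts sum to cohort size", {
  sim <- generate_cohort(simulation_config(n_patients = 120), seed = 5)
  ann <- annotate_cohort_origins(sim$cohort)
  calls <- call_molecular_response(compute_load_trajectory(sim$cohort, ann))
  expect_identical(nrow(calls), 120L)
  expect_identical(anyDuplicated(calls$patient_id), 0L)
  expect_true(all(calls$status %in% c("mR", "mPD", "undetectable", "not_evaluable")))
  expect_identical(sum(table(calls$status)), 120L)
})

test_that("molecular response rate uses the evaluable denominator with exact CI", {
  calls <- tibble::tibble(status = c(
    rep("mR", 15), rep("mPD", 20), rep("undetectable", 10), rep("not_evaluable", 5)
  ))
  r <- molecular_response_rate(calls, level = 0.90)
  expect_identical(r$k, 15L)
  expect_identical(r$n, 35L)
  expect_equal(round(r$rate, 2), 0.43)
  expect_equal(r$lower, qbeta(0.05, 15, 21))
  expect_equal(r$upper, qbeta(0.95, 16, 20))

  r0 <- molecular_response_rate(tibble::tibble(status = rep("mPD", 10)))
  expect_equal(r0$rate, 0)
  expect_equal(r0$lower, 0)
  r1 <- molecular_response_rate(tibble::tibble(status = rep("mR", 10)))
  expect_equal(r1$rate, 1)
  expect_equal(r1$upper, 1)
  rn <- molecular_response_rate(tibble::tibble(status = rep("undetectable", 4)))
  expect_true(is.na(rn$rate))
})
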