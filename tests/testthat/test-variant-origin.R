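test_that("single-variant rule engine follows the four-rule precedence", {
  # hotspot stays tumor even when shared with WBC at low MAF
  expect_identical(
    classify_variant_origin(0.0014, wbc_detected = TRUE, wbc_maf = 0.001,
      is_hotspot = TRUE),
    "tumor"
  )
  # high-MAF WBC-shared variant everywhere -> germline
  expect_identical(
    classify_variant_origin(c(0.48, 0.5), wbc_detected = TRUE, wbc_maf = 0.49,
      is_hotspot = FALSE),
    "germline"
  )
  # low-MAF WBC-shared -> clonal hematopoiesis
  expect_identical(
    classify_variant_origin(0.02, wbc_detected = TRUE, wbc_maf = 0.015,
      is_hotspot = FALSE),
    "hematopoietic"
  )
  # plasma-only -> tumor
  expect_identical(
    classify_variant_origin(0.003, wbc_detected = FALSE, wbc_maf = NA,
      is_hotspot = FALSE),
    "tumor"
  )
  # one plasma draw below 25% vetoes germline, still hematopoietic
  expect_identical(
    classify_variant_origin(c(0.48, 0.10), wbc_detected = TRUE, wbc_maf = 0.49,
      is_hotspot = FALSE),
    "hematopoietic"
  )
  # no WBC sample: WBC rules inapplicable, defaults to tumor
  expect_identical(
    classify_variant_origin(0.48, wbc_detected = FALSE, wbc_maf = NA,
      is_hotspot = FALSE, wbc_available = FALSE),
    "tumor"
  )
})

test_that("hotspot override is invariant to WBC detection", {
  for (wd in c(TRUE, FALSE)) {
    expect_identical(
      classify_variant_origin(c(0.3, 0.4), wbc_detected = wd,
        wbc_maf = if (wd) 0.45 else NA, is_hotspot = TRUE),
      "tumor"
    )
  }
})

test_that("lowering the germline threshold only moves labels toward germline", {
  set.seed(42)
  for (i in 1:50) {
    mafs <- runif(sample(1:3, 1), 0, 0.6)
    wmaf <- runif(1, 0, 0.6)
    hi <- classify_variant_origin(mafs, TRUE, wmaf, FALSE,
      germline_maf_threshold = 0.25
    )
    lo <- classify_variant_origin(mafs, TRUE, wmaf, FALSE,
      germline_maf_threshold = 0.10
    )
    if (hi == "germline") expect_identical(lo, "germline")
    if (lo != "germline") expect_identical(hi, lo)
  }
})

test_that("cohort annotation reproduces hand-derived counts on the fixture", {
  cohort <- make_test_cohort()
  ann <- annotate_cohort_origins(cohort)
  # P1: germline-like, CHIP-like, hotspot (tumor), plasma-only (tumor);
  # P2: plasma-only (tumor)
  expect_identical(nrow(ann), 5L)
  counts <- table(ann$origin)
  expect_identical(unname(counts[["germline"]]), 1L)
  expect_identical(unname(counts[["hematopoietic"]]), 1L)
  expect_identical(unname(counts[["tumor"]]), 3L)
  hs <- ann[ann$gene == "KRAS", ]
  expect_true(hs$is_hotspot && hs$wbc_detected && hs$origin == "tumor")
  expect_true(all(ann$excluded_from_load == (ann$origin != "tumor")))
})

test_that("a 10-variant mixed fixture yields counts {germline 1, CHIP 2, tumor 7}", {
  base <- make_test_cohort()
  ov <- function(pid, sid, tp, comp, chrom, pos, ref, alt, maf) {
    tibble::tibble(
      patient_id = pid, sample_id = sid, timepoint = tp, compartment = comp,
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      gene = NA_character_, protein_change = NA_character_, maf = maf,
      mutant_reads = as.integer(max(1, round(maf * 3000))),
      distinct_coverage = 3000L
    )
  }
  v <- dplyr::bind_rows(
    # germline-like
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chrA", 1, "A", "G", 0.5),
    ov("P1", "P1_W", "C1D1", "wbc", "chrA", 1, "A", "G", 0.5),
    # two WBC-shared low-MAF
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chrA", 2, "A", "G", 0.02),
    ov("P1", "P1_W", "C1D1", "wbc", "chrA", 2, "A", "G", 0.01),
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chrA", 3, "A", "G", 0.04),
    ov("P1", "P1_W", "C1D1", "wbc", "chrA", 3, "A", "G", 0.03),
    # hotspot present in WBC (KRAS G12C genomic key)
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chr12", 25245351, "C", "A", 0.0014),
    ov("P1", "P1_W", "C1D1", "wbc", "chr12", 25245351, "C", "A", 0.001),
    # six plasma-only
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chrB", 10, "C", "T", 0.01),
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chrB", 11, "C", "T", 0.02),
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chrB", 12, "C", "T", 0.03),
    ov("P2", "P2_C1_P", "C1D1", "plasma", "chrB", 13, "C", "T", 0.001),
    ov("P2", "P2_C1_P", "C1D1", "plasma", "chrB", 14, "C", "T", 0.15),
    ov("P2", "P2_C1_P", "C1D1", "plasma", "chrB", 15, "C", "T", 0.3)
  )
  cohort <- cohort_dataset(v, base$samples, base$patients)
  ann <- annotate_cohort_origins(cohort)
  expect_identical(nrow(ann), 10L)
  counts <- table(ann$origin)
  expect_identical(unname(counts[["germline"]]), 1L)
  expect_identical(unname(counts[["hematopoietic"]]), 2L)
  expect_identical(unname(counts[["tumor"]]), 7L)
})

test_that("patients without plasma variants yield no annotated records", {
  cohort <- make_test_cohort()
  v <- cohort$variants[cohort$variants$patient_id == "P1", ]
  cohort2 <- cohort_dataset(v, cohort$samples, cohort$patients)
  ann <- annotate_cohort_origins(cohort2)
  expect_false("P2" %in% ann$patient_id)
})

test_that("origin summary renders the trial-style proportions", {
  ann <- tibble::tibble(origin = c(
    rep("germline", 4), rep("hematopoietic", 14), rep("tumor", 64)
  ))
  s <- origin_summary(ann)
  expect_equal(sum(s$proportion), 1)
  expect_identical(s$label, c("5%", "17%", "78%"))

  s1 <- origin_summary(tibble::tibble(origin = "tumor"))
  expect_identical(s1$n, c(0L, 0L, 1L))
  expect_identical(s1$label[3], "100%")

  s0 <- origin_summary(tibble::tibble(origin = character(0)))
  expect_identical(sum(s0$n), 0L)
  expect_true(all(is.na(s0$proportion)))
})

test_that("tumor-tissue concordance counts confirmed plasma tumor calls", {
  ann <- tibble::tibble(
    patient_id = rep("P1", 5),
    chrom = paste0("chr", 1:5), pos = 1:5 * 100L,
    ref = "A", alt = "G", gene = NA_character_,
    protein_change = NA_character_,
    origin = c("tumor", "tumor", "tumor", "tumor", "hematopoietic"),
    is_hotspot = FALSE, wbc_detected = FALSE, wbc_maf = NA_real_,
    wbc_missing = FALSE, n_plasma_obs = 1L, max_plasma_maf = 0.02,
    excluded_from_load = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  # tissue confirms 3 of the 4 plasma tumor calls
  tumor_obs <- tibble::tibble(
    patient_id = "P1", chrom = paste0("chr", 1:3), pos = 1:3 * 100L,
    ref = "A", alt = "G"
  )
  res <- tumor_plasma_origin_concordance(ann, tumor_obs)
  expect_identical(res$n_evaluated, 4L)
  expect_identical(res$n_confirmed, 3L)
  expect_equal(res$concordance, 0.75)
  # CHIP variant never enters the comparison
  expect_false(any(res$per_variant$chrom == "chr5"))

  res_all <- tumor_plasma_origin_concordance(
    ann,
    tibble::tibble(
      patient_id = "P1", chrom = paste0("chr", 1:4), pos = 1:4 * 100L,
      ref = "A", alt = "G"
    )
  )
  expect_equal(res_all$concordance, 1)

  res_none <- tumor_plasma_origin_concordance(ann, tumor_obs[0, ])
  expect_true(is.na(res_none$concordance))
})
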