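#' Seeded synthetic cohort generator
#'
#' Generates cohorts with the statistical structure of a molecular
#' response-adaptive immunotherapy trial: ~20% of patients with undetectable
#' ctDNA, clonal-hematopoiesis and germline contamination among plasma
#' variants (~17% / ~5% of unique variants), baseline tumor-variant MAFs
#' spanning roughly 0.1%-35% (truncated log-normal), response-conditional
#' clearance probabilities matched to target sensitivity/specificity,
#' missing-draw patterns, and response-dependent exponential PFS/OS. The
#' latent assignments are all recorded in a ground-truth table so every
#' pipeline stage can be checked end to end; generated MAFs respect the
#' classification-rule margins (germline >= 40%, CHIP <= 20%) so rule outcomes
#' are unambiguous.
#'
#' @name synthetic_cohort
NULL

#' Simulation configuration
#'
#' Defaults reproduce the headline composition of a 50-patient molecular
#' response-adaptive cohort (the "br36" preset): 32% radiographic responders,
#' 20% undetectable ctDNA, sensitivity/specificity targets 0.82/0.75,
#' 13/15 of molecular responders clearing at the first on-therapy draw, and
#' stratum-specific survival medians (PFS 5.03 vs 2.6 months, OS not-reached
#' vs 7.23 months for mR vs mPD). The "design" preset swaps in the protocol
#' design assumption of a 45% objective response rate.
#'
#' @param preset "br36" (default) or "design".
#' @param n_patients Cohort size.
#' @param ... Overrides for any configuration field (see Details in the
#'   package vignette).
#' @return A list of class `mr_sim_config`.
#' @export
simulation_config <- function(preset = c("br36", "design"), n_patients = 50,
                              ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_patients = n_patients,
    timepoints = .default_timepoints,
    p_undetectable = 0.20,
    p_responder = if (preset == "br36") 0.32 else 0.45,
    p_cr_given_responder = 0.12,
    p_sd_given_nonresponder = 10 / 24,
    sens_target = 0.82,
    spec_target = 0.75,
    p_clear_at_C2_given_mR = 13 / 15,
    deep_reduction_probability = 0.10,
    deep_reduction_range = c(0.86, 0.98),
    persistence_multiplier_sdlog = 0.35,
    persistence_multiplier_clamp = c(0.3, 2.5),
    chip_fraction = 0.17,
    germline_fraction = 0.05,
    hotspot_probability = 0.10,
    p_hotspot_wbc_leak = 0.25,
    n_extra_variants_lambda = 0.8,
    baseline_maf_meanlog = log(0.02),
    baseline_maf_sdlog = 1.0,
    maf_range = c(0.001, 0.35),
    chip_maf_range = c(0.005, 0.08),
    germline_maf_range = c(0.40, 0.60),
    coverage_mean = 3000,
    coverage_sd = 300,
    min_mutant_reads = 3,
    p_missed_run_in = 0.06,
    p_ne_radiology = 0.04,
    p_missed_c3 = 0.13,
    collection_day_means = c(C1D1 = 0, C2D1 = 23, C3D1 = 64),
    collection_day_sd = 4,
    median_pfs_mr = 5.03,
    median_pfs_mpd = 2.6,
    median_os_mr = 30,
    median_os_mpd = 7.23,
    median_pfs_undetectable = 8.31,
    median_os_undetectable = 16.89,
    censor_range_months = c(2.5, 23),
    p_tumor_sequenced = 0.38,
    p_tumor_missed_variant = 0.09
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  probs <- c(
    cfg$p_undetectable, cfg$p_responder, cfg$sens_target, cfg$spec_target,
    cfg$p_clear_at_C2_given_mR, cfg$deep_reduction_probability,
    cfg$chip_fraction, cfg$germline_fraction, cfg$hotspot_probability,
    cfg$p_missed_run_in, cfg$p_ne_radiology, cfg$p_missed_c3
  )
  if (any(probs < 0 | probs > 1)) {
    abort("Configured probabilities must lie in [0, 1]", class = "ctdnamr_config_error")
  }
  if (cfg$chip_fraction + cfg$germline_fraction >= 1) {
    abort("chip_fraction + germline_fraction must be < 1",
      class = "ctdnamr_config_error"
    )
  }
  structure(cfg, class = "mr_sim_config")
}

.sim_genes <- c(
  "TP53", "ARID1A", "ATM", "PDGFRA", "STK11", "KEAP1", "MET", "ERBB2",
  "FGFR1", "CDKN2A", "SMAD4", "NF1"
)
.sim_chip_genes <- c("TET2", "ASXL1", "JAK2", "SF3B1", "PPM1D", "CBL")
.sim_germline_genes <- c("TP53", "ATM", "APC", "BRCA2")
.bases <- c("A", "C", "G", "T")

.random_variant_keys <- function(n, genes) {
  ref <- sample(.bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1), "")
  tibble(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n, replace = TRUE) + 1e6,
    ref = ref, alt = unname(alt),
    gene = sample(genes, n, replace = TRUE),
    protein_change = NA_character_
  )
}

.rcoverage <- function(n, cfg) {
  pmax(100L, as.integer(round(rnorm(n, cfg$coverage_mean, cfg$coverage_sd))))
}

.sim_reads <- function(maf, coverage, min_reads) {
  # condition on the variant having been called: at least min_reads families
  raw <- rbinom(length(maf), coverage, maf)
  as.integer(pmin(coverage, pmax(min_reads, raw)))
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config An `mr_sim_config` from [simulation_config()].
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return An `mr_sim_cohort`: list with `cohort` (a `ctdna_cohort`) and
#'   `truth` (list of tibbles `patients` and `variants` recording every latent
#'   assignment).
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "mr_sim_config"))
  cfg <- config
  set.seed(seed)
  n <- cfg$n_patients
  tps <- cfg$timepoints

  pts <- tibble(
    patient_id = sprintf("SIM%04d", seq_len(n)),
    responder = runif(n) < cfg$p_responder,
    undetectable = runif(n) < cfg$p_undetectable,
    missed_run_in = runif(n) < cfg$p_missed_run_in,
    ne_radiology = runif(n) < cfg$p_ne_radiology,
    missed_c3 = runif(n) < cfg$p_missed_c3,
    tumor_sequenced = runif(n) < cfg$p_tumor_sequenced
  ) %>%
    mutate(
      recist_bor = case_when(
        .data$ne_radiology ~ "NE",
        .data$responder & runif(n) < cfg$p_cr_given_responder ~ "CR",
        .data$responder ~ "PR",
        runif(n) < cfg$p_sd_given_nonresponder ~ "SD",
        TRUE ~ "PD"
      ),
      irecist_bor = c(
        CR = "iCR", PR = "iPR", SD = "iSD", PD = "iPD", NE = "NE"
      )[.data$recist_bor],
      mr_latent = !.data$undetectable &
        if_else(.data$responder,
          runif(n) < cfg$sens_target,
          runif(n) < 1 - cfg$spec_target
        ),
      clear_at_c2 = .data$mr_latent & runif(n) < cfg$p_clear_at_C2_given_mR,
      deep_reduction = !.data$undetectable & !.data$mr_latent &
        runif(n) < cfg$deep_reduction_probability,
      # a C3 clearance is only observable with a C3 draw, so the missing-C3
      # pattern never hits a C3-clearer (the conditional clearance
      # probabilities are for observed statuses)
      missed_c3 = .data$missed_c3 & !(.data$mr_latent & !.data$clear_at_c2)
    )

  # true molecular status accounting for the missing-draw pattern
  pts <- pts %>%
    mutate(
      true_status = case_when(
        .data$missed_run_in ~ "not_evaluable",
        .data$undetectable ~ "undetectable",
        .data$mr_latent ~ "mR",
        TRUE ~ "mPD"
      ),
      clearance_timepoint = case_when(
        .data$true_status != "mR" ~ NA_character_,
        .data$clear_at_c2 ~ tps[2],
        TRUE ~ tps[3]
      )
    )

  # ---- samples ------------------------------------------------------------
  day_mean <- cfg$collection_day_means
  plasma <- tidyr::expand_grid(
    patient_id = pts$patient_id, timepoint = tps
  ) %>%
    left_join(
      pts %>% select("patient_id", "missed_run_in", "missed_c3"),
      by = "patient_id"
    ) %>%
    filter(
      .data$timepoint == tps[1] |
        (!.data$missed_run_in &
          (.data$timepoint != tps[3] | !.data$missed_c3))
    ) %>%
    mutate(
      compartment = "plasma",
      collection_day = as.integer(round(pmax(
        0, rnorm(dplyr::n(), day_mean[.data$timepoint], cfg$collection_day_sd)
      ))),
      collection_day = if_else(.data$timepoint == tps[1], 0L, .data$collection_day),
      sample_id = paste0(.data$patient_id, "_", .data$timepoint, "_P")
    ) %>%
    select("sample_id", "patient_id", "timepoint", "compartment", "collection_day")

  wbc <- tibble(
    sample_id = paste0(pts$patient_id, "_", tps[1], "_W"),
    patient_id = pts$patient_id, timepoint = tps[1], compartment = "wbc",
    collection_day = 0L
  )
  tumor_samples <- pts %>%
    filter(.data$tumor_sequenced) %>%
    mutate(
      sample_id = paste0(.data$patient_id, "_T"),
      timepoint = tps[1], compartment = "tumor", collection_day = NA_integer_
    ) %>%
    select("sample_id", "patient_id", "timepoint", "compartment", "collection_day")
  samples <- bind_rows(plasma, wbc, tumor_samples) %>%
    mutate(available = TRUE)

  # ---- tumor-derived variants --------------------------------------------
  hs_table <- default_hotspots()
  det <- pts %>% filter(!.data$undetectable)
  n_var <- 1L + rpois(nrow(det), cfg$n_extra_variants_lambda)
  tv <- det %>%
    select("patient_id") %>%
    mutate(n_var = n_var) %>%
    tidyr::uncount(.data$n_var)
  m <- nrow(tv)
  is_hs <- runif(m) < cfg$hotspot_probability & nrow(hs_table) > 0
  keys <- .random_variant_keys(m, .sim_genes)
  if (any(is_hs)) {
    hs_pick <- hs_table[sample.int(nrow(hs_table), sum(is_hs), replace = TRUE), ]
    keys[is_hs, c("chrom", "pos", "ref", "alt", "gene", "protein_change")] <-
      hs_pick[, c("chrom", "pos", "ref", "alt", "gene", "protein_change")]
  }
  tv <- bind_cols(tv, keys) %>%
    mutate(
      is_hotspot = is_hs,
      true_origin = "tumor",
      wbc_leak = .data$is_hotspot & runif(m) < cfg$p_hotspot_wbc_leak,
      baseline_maf = pmin(
        cfg$maf_range[2],
        pmax(
          cfg$maf_range[1],
          rlnorm(m, cfg$baseline_maf_meanlog, cfg$baseline_maf_sdlog)
        )
      )
    ) %>%
    distinct(.data$patient_id, .data$chrom, .data$pos, .data$ref, .data$alt,
      .keep_all = TRUE
    )

  # patient-level on-therapy multipliers (applied to all tumor variants so the
  # identity of the maximal variant is preserved)
  mult <- pts %>%
    filter(!.data$undetectable) %>%
    mutate(
      m2 = case_when(
        .data$mr_latent & .data$clear_at_c2 ~ 0,
        .data$mr_latent ~ runif(dplyr::n(), 0.2, 0.8),
        .data$deep_reduction ~
          1 - runif(dplyr::n(), cfg$deep_reduction_range[1], cfg$deep_reduction_range[2]),
        TRUE ~ pmin(
          cfg$persistence_multiplier_clamp[2],
          pmax(
            cfg$persistence_multiplier_clamp[1],
            exp(rnorm(dplyr::n(), 0, cfg$persistence_multiplier_sdlog))
          )
        )
      ),
      m3 = case_when(
        .data$mr_latent ~ 0,
        .data$deep_reduction ~
          1 - runif(dplyr::n(), cfg$deep_reduction_range[1], cfg$deep_reduction_range[2]),
        TRUE ~ pmin(
          cfg$persistence_multiplier_clamp[2],
          pmax(
            cfg$persistence_multiplier_clamp[1],
            exp(rnorm(dplyr::n(), 0, cfg$persistence_multiplier_sdlog))
          )
        )
      )
    ) %>%
    select("patient_id", "m2", "m3")

  tumor_long <- tv %>%
    left_join(mult, by = "patient_id") %>%
    tidyr::expand_grid(timepoint = tps) %>%
    mutate(
      maf = case_when(
        .data$timepoint == tps[1] ~ .data$baseline_maf,
        .data$timepoint == tps[2] ~ .data$baseline_maf * .data$m2,
        TRUE ~ .data$baseline_maf * .data$m3
      ),
      maf = pmin(0.95, .data$maf)
    ) %>%
    select(
      "patient_id", "timepoint", "chrom", "pos", "ref", "alt", "gene",
      "protein_change", "maf", "wbc_leak"
    )

  # ---- CHIP and germline contamination ------------------------------------
  e_tumor <- (1 - cfg$p_undetectable) * (1 + cfg$n_extra_variants_lambda)
  denom <- 1 - cfg$chip_fraction - cfg$germline_fraction
  r_chip <- e_tumor * cfg$chip_fraction / denom
  r_germ <- e_tumor * cfg$germline_fraction / denom

  n_chip <- rpois(n, r_chip)
  chip <- pts %>%
    select("patient_id") %>%
    mutate(nv = n_chip) %>%
    tidyr::uncount(.data$nv)
  if (nrow(chip) > 0) {
    chip <- bind_cols(chip, .random_variant_keys(nrow(chip), .sim_chip_genes)) %>%
      mutate(
        true_origin = "hematopoietic", is_hotspot = FALSE, wbc_leak = TRUE,
        base_maf = runif(dplyr::n(), cfg$chip_maf_range[1], cfg$chip_maf_range[2])
      )
  }
  n_germ <- rpois(n, r_germ)
  germ <- pts %>%
    select("patient_id") %>%
    mutate(nv = n_germ) %>%
    tidyr::uncount(.data$nv)
  if (nrow(germ) > 0) {
    germ <- bind_cols(germ, .random_variant_keys(nrow(germ), .sim_germline_genes)) %>%
      mutate(
        true_origin = "germline", is_hotspot = FALSE, wbc_leak = TRUE,
        base_maf = runif(dplyr::n(), cfg$germline_maf_range[1], cfg$germline_maf_range[2])
      )
  }
  contam <- bind_rows(
    if (nrow(chip) > 0) chip else NULL,
    if (nrow(germ) > 0) germ else NULL
  )
  contam_long <- NULL
  if (!is.null(contam) && nrow(contam) > 0) {
    contam_long <- contam %>%
      tidyr::expand_grid(timepoint = tps) %>%
      mutate(
        maf = if_else(
          .data$true_origin == "hematopoietic",
          pmin(0.20, .data$base_maf * runif(dplyr::n(), 0.8, 1.25)),
          pmin(0.60, pmax(0.40, .data$base_maf * runif(dplyr::n(), 0.95, 1.05)))
        )
      ) %>%
      select(
        "patient_id", "timepoint", "chrom", "pos", "ref", "alt", "gene",
        "protein_change", "maf", "wbc_leak"
      )
  }

  plasma_long <- bind_rows(tumor_long, contam_long) %>%
    # only draws that exist and variants actually present
    inner_join(
      plasma %>% select("sample_id", "patient_id", "timepoint"),
      by = c("patient_id", "timepoint")
    ) %>%
    filter(.data$maf > 0)

  cov <- .rcoverage(nrow(plasma_long), cfg)
  plasma_obs <- plasma_long %>%
    mutate(
      compartment = "plasma",
      distinct_coverage = cov,
      mutant_reads = .sim_reads(.data$maf, cov, cfg$min_mutant_reads)
    ) %>%
    select(
      "patient_id", "sample_id", "timepoint", "compartment", "chrom", "pos",
      "ref", "alt", "gene", "protein_change", "maf", "mutant_reads",
      "distinct_coverage"
    )

  # WBC observations: all CHIP/germline plus leaked hotspots
  truth_variants <- bind_rows(
    tv %>% select(
      "patient_id", "chrom", "pos", "ref", "alt", "gene", "protein_change",
      "true_origin", "is_hotspot", "wbc_leak"
    ),
    if (!is.null(contam) && nrow(contam) > 0) {
      contam %>% select(
        "patient_id", "chrom", "pos", "ref", "alt", "gene", "protein_change",
        "true_origin", "is_hotspot", "wbc_leak"
      )
    } else {
      NULL
    }
  )
  wbc_vars <- truth_variants %>% filter(.data$wbc_leak)
  wbc_obs <- NULL
  if (nrow(wbc_vars) > 0) {
    wbc_maf <- dplyr::case_when(
      wbc_vars$true_origin == "germline" ~ runif(nrow(wbc_vars), 0.45, 0.55),
      wbc_vars$true_origin == "hematopoietic" ~ runif(nrow(wbc_vars), 0.01, 0.15),
      TRUE ~ runif(nrow(wbc_vars), 0.001, 0.01) # buffy-coat tumor leak
    )
    wcov <- .rcoverage(nrow(wbc_vars), cfg)
    wbc_obs <- wbc_vars %>%
      mutate(
        sample_id = paste0(.data$patient_id, "_", tps[1], "_W"),
        timepoint = tps[1], compartment = "wbc",
        maf = wbc_maf, distinct_coverage = wcov,
        mutant_reads = .sim_reads(wbc_maf, wcov, cfg$min_mutant_reads)
      ) %>%
      select(
        "patient_id", "sample_id", "timepoint", "compartment", "chrom", "pos",
        "ref", "alt", "gene", "protein_change", "maf", "mutant_reads",
        "distinct_coverage"
      )
  }

  # tumor-tissue observations for sequenced patients
  tumor_obs <- NULL
  seq_pts <- pts %>% filter(.data$tumor_sequenced)
  if (nrow(seq_pts) > 0) {
    tt <- tv %>%
      filter(.data$patient_id %in% seq_pts$patient_id) %>%
      mutate(confirmed = runif(dplyr::n()) >= cfg$p_tumor_missed_variant) %>%
      filter(.data$confirmed)
    if (nrow(tt) > 0) {
      tcov <- pmax(100L, as.integer(round(rnorm(nrow(tt), 1100, 150))))
      tmaf <- runif(nrow(tt), 0.05, 0.40)
      tumor_obs <- tt %>%
        mutate(
          sample_id = paste0(.data$patient_id, "_T"),
          timepoint = tps[1], compartment = "tumor",
          maf = tmaf, distinct_coverage = tcov,
          mutant_reads = .sim_reads(tmaf, tcov, cfg$min_mutant_reads)
        ) %>%
        select(
          "patient_id", "sample_id", "timepoint", "compartment", "chrom",
          "pos", "ref", "alt", "gene", "protein_change", "maf",
          "mutant_reads", "distinct_coverage"
        )
    }
  }

  variants <- bind_rows(plasma_obs, wbc_obs, tumor_obs)

  # ---- survival ------------------------------------------------------------
  rate <- function(median) log(2) / median
  pfs_med <- case_when(
    pts$undetectable ~ cfg$median_pfs_undetectable,
    pts$mr_latent ~ cfg$median_pfs_mr,
    TRUE ~ cfg$median_pfs_mpd
  )
  os_med <- case_when(
    pts$undetectable ~ cfg$median_os_undetectable,
    pts$mr_latent ~ cfg$median_os_mr,
    TRUE ~ cfg$median_os_mpd
  )
  pfs_lat <- rexp(n, rate = rate(pfs_med))
  os_lat <- pmax(rexp(n, rate = rate(os_med)), pfs_lat)
  cens <- runif(n, cfg$censor_range_months[1], cfg$censor_range_months[2])
  pts <- pts %>%
    mutate(
      pfs_latent = pfs_lat, os_latent = os_lat, censor_months = cens,
      pfs_months = pmin(.data$pfs_latent, .data$censor_months),
      pfs_event = .data$pfs_latent <= .data$censor_months,
      os_months = pmin(.data$os_latent, .data$censor_months),
      os_event = .data$os_latent <= .data$censor_months,
      first_response_day = if_else(.data$responder, 84L, NA_integer_)
    )

  baseline_max <- tv %>%
    group_by(.data$patient_id) %>%
    summarise(baseline_max_maf = max(.data$baseline_maf), .groups = "drop")
  truth_patients <- pts %>%
    left_join(baseline_max, by = "patient_id") %>%
    mutate(baseline_max_maf = dplyr::coalesce(.data$baseline_max_maf, 0))

  patients_tbl <- pts %>%
    select(
      "patient_id", "recist_bor", "irecist_bor", "pfs_months", "pfs_event",
      "os_months", "os_event", "first_response_day"
    )

  cohort <- cohort_dataset(
    variants = variants, samples = samples, patients = patients_tbl,
    hotspots = hs_table, timepoints = tps
  )
  structure(
    list(
      cohort = cohort,
      truth = list(patients = truth_patients, variants = truth_variants),
      config = cfg, seed = seed
    ),
    class = "mr_sim_cohort"
  )
}

#' @export
#' @method print mr_sim_cohort
print.mr_sim_cohort <- function(x, ...) {
  cat("<mr_sim_cohort> seed", x$seed, "preset", x$config$preset, "\n")
  print(x$cohort)
  invisible(x)
}

#' Expected summaries from simulation ground truth
#'
#' Oracle values for end-to-end assertions: the true origin counts, the true
#' molecular-vs-radiographic 2x2 table (over patients with definitive status
#' and non-NE radiology), true kinetic-pattern counts, and the undetectable
#' fraction among patients evaluable for molecular response.
#'
#' @param sim An `mr_sim_cohort`.
#' @return List: origin_counts, concordance (a, b, c, d), pattern_counts,
#'   status_counts, undetectable_fraction.
#' @export
generate_expected_summaries <- function(sim) {
  stopifnot(inherits(sim, "mr_sim_cohort"))
  tp <- sim$truth$patients
  tv <- sim$truth$variants
  origin_counts <- tv %>% count(.data$true_origin)
  concord <- tp %>%
    filter(.data$true_status %in% c("mR", "mPD"), .data$recist_bor != "NE")
  a <- sum(concord$responder & concord$true_status == "mR")
  b <- sum(concord$responder & concord$true_status == "mPD")
  cc <- sum(!concord$responder & concord$true_status == "mR")
  d <- sum(!concord$responder & concord$true_status == "mPD")
  tps <- sim$config$timepoints
  pattern <- tp %>%
    mutate(pattern = case_when(
      .data$true_status == "mR" & .data$clearance_timepoint == tps[2] ~
        paste0("clearance_", .cycle_label(tps[2])),
      .data$true_status == "mR" ~ paste0("clearance_", .cycle_label(tps[3])),
      .data$true_status == "mPD" & .data$deep_reduction ~ "deep_reduction",
      .data$true_status == "mPD" ~ "persistence",
      TRUE ~ "none"
    )) %>%
    count(.data$pattern)
  evaluable <- tp %>% filter(.data$true_status != "not_evaluable")
  list(
    origin_counts = origin_counts,
    concordance = list(a = a, b = b, c = cc, d = d),
    pattern_counts = pattern,
    status_counts = tp %>% count(.data$true_status),
    undetectable_fraction = mean(evaluable$true_status == "undetectable")
  )
}
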