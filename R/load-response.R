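#' Circulating tumor load and molecular response calling
#'
#' Circulating tumor load at a timepoint is summarised over a patient's
#' tumor-derived plasma variants by the maximal mutant allele fraction
#' (maxMAF); mean and median MAF are carried alongside. A tumor-derived
#' variant that was called at any timepoint is *tracked* at every timepoint:
#' where it was not called it contributes MAF 0. Molecular response (mR) is
#' maxMAF clearance to undetectable (<= `clearance_threshold`, default exactly
#' 0) at the last on-therapy draw; persistence is molecular progression (mPD).
#'
#' @name tumor_load_response
NULL

#' Per-patient, per-timepoint circulating tumor load
#'
#' Computes max/mean/median MAF over the tracked tumor-derived variant set for
#' every patient at every timepoint, on the full timepoint grid. Metrics are 0
#' when an available plasma sample contains no tumor-derived variant and NA
#' when no plasma sample is available at that timepoint.
#'
#' @param cohort A `ctdna_cohort`.
#' @param annotated Output of [annotate_cohort_origins()]; germline and
#'   hematopoietic variants are excluded from load.
#' @return Tibble: patient_id, timepoint (ordered factor), sample_available,
#'   n_tracked (variants tracked for the patient), n_detected (with MAF > 0 at
#'   the timepoint), max_maf, mean_maf, median_maf.
#' @export
compute_load_trajectory <- function(cohort, annotated) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  tps <- cohort$timepoints
  plasma_samples <- cohort$samples %>%
    filter(.data$compartment == "plasma", .data$available)

  grid <- tidyr::expand_grid(
    patient_id = unique(cohort$patients$patient_id),
    timepoint = as_timepoint(tps, tps)
  ) %>%
    left_join(
      plasma_samples %>%
        distinct(.data$patient_id, .data$timepoint) %>%
        mutate(sample_available = TRUE),
      by = c("patient_id", "timepoint")
    ) %>%
    mutate(sample_available = !is.na(.data$sample_available))

  tumor_variants <- annotated %>%
    filter(!.data$excluded_from_load) %>%
    select("patient_id", "chrom", "pos", "ref", "alt")

  obs <- cohort$variants %>%
    filter(.data$compartment == "plasma", .data$mutant_reads >= 1) %>%
    semi_join(tumor_variants, by = c("patient_id", "chrom", "pos", "ref", "alt")) %>%
    select("patient_id", "timepoint", "chrom", "pos", "ref", "alt", "maf")

  # tracked set x available timepoints, zero-filled where not called
  tracked <- tumor_variants %>%
    inner_join(
      grid %>% filter(.data$sample_available),
      by = "patient_id", relationship = "many-to-many"
    ) %>%
    left_join(obs,
      by = c("patient_id", "timepoint", "chrom", "pos", "ref", "alt")
    ) %>%
    mutate(maf = dplyr::coalesce(.data$maf, 0))

  if (nrow(tracked) == 0) {
    return(grid %>%
      mutate(
        n_tracked = if_else(.data$sample_available, 0L, NA_integer_),
        n_detected = if_else(.data$sample_available, 0L, NA_integer_),
        max_maf = if_else(.data$sample_available, 0, NA_real_),
        mean_maf = if_else(.data$sample_available, 0, NA_real_),
        median_maf = if_else(.data$sample_available, 0, NA_real_)
      ) %>%
      arrange(.data$patient_id, .data$timepoint))
  }

  metrics <- tracked %>%
    group_by(.data$patient_id, .data$timepoint) %>%
    summarise(
      n_tracked = dplyr::n(),
      n_detected = sum(.data$maf > 0),
      max_maf = max(.data$maf),
      mean_maf = mean(.data$maf),
      median_maf = median(.data$maf),
      .groups = "drop"
    )

  grid %>%
    left_join(metrics, by = c("patient_id", "timepoint")) %>%
    mutate(
      n_tracked = if_else(.data$sample_available,
        dplyr::coalesce(.data$n_tracked, 0L), NA_integer_
      ),
      n_detected = if_else(.data$sample_available,
        dplyr::coalesce(.data$n_detected, 0L), NA_integer_
      ),
      max_maf = if_else(.data$sample_available,
        dplyr::coalesce(.data$max_maf, 0), NA_real_
      ),
      mean_maf = if_else(.data$sample_available,
        dplyr::coalesce(.data$mean_maf, 0), NA_real_
      ),
      median_maf = if_else(.data$sample_available,
        dplyr::coalesce(.data$median_maf, 0), NA_real_
      )
    ) %>%
    arrange(.data$patient_id, .data$timepoint)
}

#' Call molecular response per patient
#'
#' Status rules, applied to the maxMAF trajectory only:
#' * `not_evaluable` - no baseline plasma sample, or no on-therapy sample in
#'   addition to baseline (reason recorded);
#' * `undetectable` - maxMAF is 0 at every available timepoint;
#' * `mR` - maxMAF <= `clearance_threshold` at the last available on-therapy
#'   timepoint (clearance at an earlier draw followed by detectable ctDNA at a
#'   later one is *not* a response);
#' * `mPD` - otherwise.
#'
#' The clearance timepoint is the earliest on-therapy draw from which maxMAF
#' stays cleared through all later available draws.
#'
#' @param trajectory Output of [compute_load_trajectory()].
#' @param clearance_threshold MAF at or below which ctDNA counts as cleared
#'   (default exactly 0, i.e. assay-undetected).
#' @param reduction_threshold Fractional reduction defining the
#'   "deep reduction" kinetic pattern (default 0.85).
#' @return Tibble, one row per patient: status, clearance_timepoint,
#'   kinetic_pattern, baseline_max_maf, best_on_therapy_reduction,
#'   not_evaluable_reason.
#' @export
call_molecular_response <- function(trajectory, clearance_threshold = 0,
                                    reduction_threshold = 0.85) {
  tps <- levels(trajectory$timepoint)
  baseline_tp <- tps[1]
  thr <- clearance_threshold

  per <- trajectory %>%
    arrange(.data$patient_id, .data$timepoint) %>%
    group_by(.data$patient_id) %>%
    summarise(
      base_avail = any(.data$sample_available[.data$timepoint == baseline_tp]),
      baseline_max_maf = if (base_avail) {
        .data$max_maf[.data$timepoint == baseline_tp & .data$sample_available][1]
      } else {
        NA_real_
      },
      n_avail = sum(.data$sample_available),
      n_ontx = sum(.data$sample_available & .data$timepoint != baseline_tp),
      all_zero = n_avail > 0 &&
        all(.data$max_maf[.data$sample_available] == 0),
      min_ontx = if (n_ontx > 0) {
        min(.data$max_maf[.data$sample_available & .data$timepoint != baseline_tp])
      } else {
        NA_real_
      },
      ontx_clear = list(
        .data$max_maf[.data$sample_available & .data$timepoint != baseline_tp] <= thr
      ),
      ontx_tps = list(as.character(
        .data$timepoint[.data$sample_available & .data$timepoint != baseline_tp]
      )),
      .groups = "drop"
    )

  # earliest on-therapy draw from which clearance persists through the last
  # available draw (position after the last non-cleared draw)
  clr_tp <- purrr::map2_chr(per$ontx_clear, per$ontx_tps, function(cl, tp) {
    if (length(cl) == 0 || !cl[length(cl)]) {
      return(NA_character_)
    }
    not_cl <- which(!cl)
    tp[if (length(not_cl) > 0) max(not_cl) + 1L else 1L]
  })

  per %>%
    mutate(
      clearance_timepoint = clr_tp,
      best_on_therapy_reduction = if_else(
        !is.na(.data$baseline_max_maf) & .data$baseline_max_maf > 0 &
          .data$n_ontx > 0,
        1 - .data$min_ontx / .data$baseline_max_maf,
        NA_real_
      ),
      status = case_when(
        .data$n_avail == 0 ~ "not_evaluable",
        !.data$base_avail ~ "not_evaluable",
        .data$n_ontx == 0 ~ "not_evaluable",
        .data$all_zero ~ "undetectable",
        !is.na(.data$clearance_timepoint) ~ "mR",
        TRUE ~ "mPD"
      ),
      not_evaluable_reason = case_when(
        .data$n_avail == 0 ~ "no_plasma_samples",
        !.data$base_avail ~ "missing_baseline",
        .data$n_ontx == 0 ~ "no_on_therapy_sample",
        TRUE ~ NA_character_
      ),
      clearance_timepoint = if_else(.data$status == "mR",
        .data$clearance_timepoint, NA_character_
      ),
      kinetic_pattern = case_when(
        .data$status == "mR" ~
          paste0("clearance_", .cycle_label(.data$clearance_timepoint)),
        .data$status == "mPD" & !is.na(.data$best_on_therapy_reduction) &
          .data$best_on_therapy_reduction > reduction_threshold ~ "deep_reduction",
        .data$status == "mPD" ~ "persistence",
        TRUE ~ "none"
      ),
      baseline_max_maf = if_else(.data$base_avail, .data$baseline_max_maf, NA_real_)
    ) %>%
    select(
      "patient_id", "status", "clearance_timepoint", "kinetic_pattern",
      "baseline_max_maf", "best_on_therapy_reduction", "not_evaluable_reason"
    )
}

#' Classify the ctDNA kinetic pattern
#'
#' Four patterns over detectable, evaluable patients: clearance at the first
#' on-therapy cycle, clearance at the second, deep reduction (best on-therapy
#' maxMAF reduction strictly above `reduction_threshold` without clearance),
#' and persistence. Undetectable or not-evaluable patients get "none".
#' [call_molecular_response()] already emits this label; this accessor
#' recomputes it from a trajectory for a single patient.
#'
#' @param trajectory Trajectory rows for one patient.
#' @inheritParams call_molecular_response
#' @return Character scalar pattern label.
#' @export
classify_kinetic_pattern <- function(trajectory, clearance_threshold = 0,
                                     reduction_threshold = 0.85) {
  stopifnot(length(unique(trajectory$patient_id)) <= 1)
  call <- call_molecular_response(
    trajectory,
    clearance_threshold = clearance_threshold,
    reduction_threshold = reduction_threshold
  )
  call$kinetic_pattern[1]
}

#' Molecular response rate with exact confidence interval
#'
#' Number of mR patients divided by the number evaluable for molecular
#' response (mR + mPD; undetectable and not-evaluable patients are excluded
#' from the denominator), with a Clopper-Pearson interval.
#'
#' @param calls Output of [call_molecular_response()].
#' @param level Two-sided confidence level (default 0.90).
#' @return Tibble: k, n, rate, lower, upper, level. Zero evaluable patients
#'   yield NA rate and bounds.
#' @export
molecular_response_rate <- function(calls, level = 0.90) {
  k <- sum(calls$status == "mR", na.rm = TRUE)
  n <- sum(calls$status %in% c("mR", "mPD"), na.rm = TRUE)
  if (n == 0) {
    return(tibble(
      k = 0L, n = 0L, rate = NA_real_, lower = NA_real_, upper = NA_real_,
      level = level
    ))
  }
  ci <- clopper_pearson_interval(k, n, level)
  tibble(
    k = as.integer(k), n = as.integer(n), rate = k / n,
    lower = ci$lower, upper = ci$upper, level = level
  )
}
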