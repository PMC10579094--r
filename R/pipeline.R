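#' One-command pipeline orchestration
#'
#' Runs the full analysis in fixed stage order - validate, classify origins,
#' compute load trajectories, call molecular response, concordance, depth of
#' response / ROC, limit of detection, survival - writes every stage output
#' under `out_dir`, and returns a run manifest. Stages whose prerequisites
#' are absent (no tumor samples, no evaluable patients, no survival columns)
#' are skipped with a notice in the manifest rather than failing, so the
#' pipeline degrades gracefully on partial cohorts.
#'
#' @param cohort A `ctdna_cohort`.
#' @param out_dir Output directory.
#' @param germline_maf_threshold,wbc_min_reads Origin-rule parameters.
#' @param clearance_threshold,reduction_threshold Response-calling parameters.
#' @param ci_level Two-sided confidence level for concordance and response
#'   rate (default 0.90).
#' @param maf_subgroup_thresholds Baseline maxMAF strata (default 3% and 4%).
#' @param lod_maf_grid MAF grid for the limit-of-detection profile.
#' @param lod_min_reads Minimum mutant read families for the LOD model.
#' @param error_on_validation Abort when validation reports violations
#'   (default TRUE).
#' @return A `mr_run_manifest`: list with `files` (tibble), `stages` (tibble
#'   of stage, status, rows, note), `results` (the in-memory stage outputs)
#'   and the parameter snapshot.
#' @export
run_pipeline <- function(cohort, out_dir,
                         germline_maf_threshold = 0.25, wbc_min_reads = 1,
                         clearance_threshold = 0, reduction_threshold = 0.85,
                         ci_level = 0.90,
                         maf_subgroup_thresholds = c(0.03, 0.04),
                         lod_maf_grid = c(0.001, 0.002, 0.003, 0.005, 0.01),
                         lod_min_reads = 3,
                         error_on_validation = TRUE) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  stages <- list()
  note_stage <- function(stage, status, rows = NA_integer_, note = NA_character_) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, status = status, rows = as.integer(rows), note = note
    )
  }
  results <- list()

  report <- validate_cohort(cohort)
  results$validation <- report
  if (nrow(report) > 0 && error_on_validation) {
    abort(
      paste0("Validation failed with ", nrow(report), " violation(s); ",
             "first: ", report$rule[1], " (", report$message[1], ")"),
      class = "ctdnamr_validation_error"
    )
  }
  note_stage("validate", "completed", nrow(report),
    if (nrow(report) > 0) "violations reported" else "clean"
  )

  annotated <- annotate_cohort_origins(
    cohort,
    germline_maf_threshold = germline_maf_threshold,
    wbc_min_reads = wbc_min_reads
  )
  results$annotated <- annotated
  note_stage("classify_origins", "completed", nrow(annotated))

  trajectories <- compute_load_trajectory(cohort, annotated)
  results$trajectories <- trajectories
  note_stage("load_trajectories", "completed", nrow(trajectories))

  calls <- call_molecular_response(
    trajectories,
    clearance_threshold = clearance_threshold,
    reduction_threshold = reduction_threshold
  )
  results$calls <- calls
  note_stage("call_response", "completed", nrow(calls))

  # concordance ---------------------------------------------------------
  has_bor <- any(!is.na(cohort$patients$recist_bor))
  n_definitive <- sum(calls$status %in% c("mR", "mPD"))
  if (has_bor && n_definitive > 0) {
    conc <- list()
    for (crit in c("RECIST", "iRECIST")) {
      bor_col <- if (crit == "RECIST") "recist_bor" else "irecist_bor"
      if (all(is.na(cohort$patients[[bor_col]]))) next
      tab <- build_concordance_table(calls, cohort$patients, crit)
      conc[[crit]] <- list(
        counts = list(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
        performance = concordance_performance(tab, level = ci_level),
        subgroups = subgroup_concordance_by_baseline_maf(
          calls, cohort$patients,
          thresholds = maf_subgroup_thresholds,
          criterion = crit, level = ci_level
        )
      )
    }
    conc$response_rate <- molecular_response_rate(calls, level = ci_level)
    results$concordance <- conc
    note_stage("concordance", "completed", n_definitive)
  } else {
    note_stage(
      "concordance", "skipped", 0,
      "no evaluable patients with radiographic response"
    )
  }

  # depth of response / ROC ---------------------------------------------
  tps <- cohort$timepoints
  roc_results <- list()
  if (has_bor && n_definitive > 0) {
    resp_tbl <- cohort$patients %>%
      filter(.data$recist_bor %in% c("CR", "PR", "SD", "PD")) %>%
      mutate(responder = .data$recist_bor %in% c("CR", "PR"))
    depth_all <- list()
    for (tp in tps[-1]) {
      dt <- tryCatch(
        cohort_depth_table(
          trajectories %>%
            semi_join(
              calls %>% filter(.data$status %in% c("mR", "mPD")),
              by = "patient_id"
            ),
          tp,
          metric = "max"
        ),
        error = function(e) NULL
      )
      if (is.null(dt)) next
      depth_all[[tp]] <- dt
      scored <- dt %>% inner_join(resp_tbl, by = "patient_id")
      if (length(unique(scored$responder)) == 2) {
        roc_results[[paste0("maxMAF_", tp)]] <-
          roc_auc(scored, d, responder)
      }
    }
    results$depth <- bind_rows(depth_all)
    if (length(roc_results) > 0) results$roc <- roc_results
    note_stage("depth_roc", "completed", length(roc_results))
  } else {
    note_stage("depth_roc", "skipped", 0, "no radiographic labels")
  }

  # limit of detection ---------------------------------------------------
  baseline_positions <- cohort$variants %>%
    semi_join(
      results$annotated %>% filter(!.data$excluded_from_load),
      by = c("patient_id", "chrom", "pos", "ref", "alt")
    ) %>%
    filter(.data$compartment == "plasma", .data$timepoint == tps[1])
  if (nrow(baseline_positions) > 0) {
    results$lod <- assay_sensitivity_profile(
      baseline_positions,
      maf_grid = lod_maf_grid, min_reads = lod_min_reads
    )
    note_stage("lod", "completed", nrow(baseline_positions))
  } else {
    note_stage("lod", "skipped", 0, "no baseline tumor-derived positions")
  }

  # survival -------------------------------------------------------------
  surv_ok <- all(c("pfs_months", "pfs_event", "os_months", "os_event") %in%
    names(cohort$patients)) &&
    any(!is.na(cohort$patients$pfs_months))
  if (surv_ok) {
    sdf <- cohort$patients %>%
      inner_join(calls %>% select("patient_id", "status"), by = "patient_id") %>%
      filter(.data$status %in% c("mR", "mPD"))
    surv <- list()
    if (nrow(sdf) > 0 && sum(sdf$pfs_event) > 0) {
      for (endpoint in c("pfs", "os")) {
        sdf2 <- sdf
        sdf2$.time <- sdf[[paste0(endpoint, "_months")]]
        sdf2$.event <- sdf[[paste0(endpoint, "_event")]]
        km <- kaplan_meier(sdf2, .time, .event, group = status, level = ci_level)
        surv[[endpoint]] <- list(
          medians = median_survival(km),
          log_rank = if (length(unique(sdf2$status)) == 2 &&
            sum(sdf2$.event) > 0) {
            log_rank_test(sdf2, .time, .event, status)
          } else {
            NULL
          }
        )
      }
      ttm <- build_time_to_molecular_response(calls, cohort$samples)
      if (nrow(ttm) > 0 && sum(ttm$event) > 0) {
        surv$time_to_molecular_response <- median_survival(
          kaplan_meier(ttm, months, event, level = ci_level)
        )
      }
      results$survival <- surv
      note_stage("survival", "completed", nrow(sdf))
    } else {
      note_stage("survival", "skipped", 0, "no definitive statuses with events")
    }
  } else {
    note_stage("survival", "skipped", 0, "no survival columns")
  }

  files <- write_analysis_outputs(results, out_dir)
  note_stage("write_outputs", "completed", nrow(files))

  structure(
    list(
      files = files,
      stages = bind_rows(stages),
      results = results,
      parameters = list(
        germline_maf_threshold = germline_maf_threshold,
        wbc_min_reads = wbc_min_reads,
        clearance_threshold = clearance_threshold,
        reduction_threshold = reduction_threshold,
        ci_level = ci_level,
        maf_subgroup_thresholds = maf_subgroup_thresholds,
        lod_maf_grid = lod_maf_grid,
        lod_min_reads = lod_min_reads
      ),
      out_dir = out_dir
    ),
    class = "mr_run_manifest"
  )
}

#' @export
#' @method print mr_run_manifest
print.mr_run_manifest <- function(x, ...) {
  cat("<mr_run_manifest>", x$out_dir, "\n")
  print(x$stages)
  invisible(x)
}
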