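#' Depth of ctDNA response and ROC/AUC
#'
#' The depth of response at an on-therapy timepoint is the fractional change
#' in circulating tumor load from baseline,
#' `d = (m_baseline - m_timepoint) / m_baseline`, where m is the max (or mean
#' or median) MAF over tumor-derived variants. d = 1 means clearance and
#' negative d an increase. When the baseline load is 0 the ratio is undefined;
#' such patients receive the smallest d observed among the remaining patients
#' at that timepoint (the largest increase in the cohort), flagged as imputed.
#'
#' @name depth_response_roc
NULL

#' Depth of response for each patient at one timepoint
#'
#' No imputation is applied here; entries with zero baseline load are returned
#' undefined (NA) for [cohort_depth_table()] to resolve cohort-wide.
#'
#' @param trajectory Output of [compute_load_trajectory()].
#' @param timepoint On-therapy timepoint label (e.g. "C2D1").
#' @param metric One of "max", "mean", "median".
#' @return Tibble: patient_id, timepoint, metric, baseline, on_therapy, d,
#'   defined. Patients missing the baseline or the requested on-therapy sample
#'   are excluded, with the exclusion reason in the `dropped` attribute.
#' @export
depth_of_response <- function(trajectory, timepoint,
                              metric = c("max", "mean", "median")) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_maf")
  tps <- levels(trajectory$timepoint)
  if (!timepoint %in% tps[-1]) {
    abort(paste0("timepoint must be an on-therapy draw: ",
                 paste(tps[-1], collapse = ", ")))
  }
  tp_sel <- timepoint
  wide <- trajectory %>%
    filter(.data$timepoint %in% c(tps[1], tp_sel)) %>%
    mutate(role = if_else(.data$timepoint == tps[1], "baseline", "on_therapy")) %>%
    select("patient_id", "role",
      value = dplyr::all_of(col), "sample_available"
    ) %>%
    tidyr::pivot_wider(
      names_from = "role", values_from = c("value", "sample_available")
    )
  dropped <- wide %>%
    filter(!.data$sample_available_baseline | !.data$sample_available_on_therapy) %>%
    mutate(reason = case_when(
      !.data$sample_available_baseline ~ "missing_baseline",
      TRUE ~ "missing_on_therapy_sample"
    )) %>%
    select("patient_id", "reason")
  res <- wide %>%
    filter(.data$sample_available_baseline, .data$sample_available_on_therapy) %>%
    mutate(
      timepoint = tp_sel, metric = !!metric,
      d = if_else(.data$value_baseline > 0,
        (.data$value_baseline - .data$value_on_therapy) / .data$value_baseline,
        NA_real_
      ),
      defined = .data$value_baseline > 0
    ) %>%
    select("patient_id", "timepoint", "metric",
      baseline = "value_baseline", on_therapy = "value_on_therapy",
      "d", "defined"
    )
  attr(res, "dropped") <- dropped
  res
}

#' Cohort depth-of-response table with undefined-baseline imputation
#'
#' Applies the cohort-minimum imputation: every patient whose baseline load is
#' 0 gets the smallest defined d at that timepoint, flagged `imputed`.
#'
#' @inheritParams depth_of_response
#' @return Tibble as [depth_of_response()] plus an `imputed` flag.
#' @export
cohort_depth_table <- function(trajectory, timepoint,
                               metric = c("max", "mean", "median")) {
  d_tbl <- depth_of_response(trajectory, timepoint, metric)
  if (nrow(d_tbl) == 0) {
    return(d_tbl %>% mutate(imputed = logical(0)))
  }
  if (!any(d_tbl$defined)) {
    abort("All baseline loads are zero: depth of response cannot be imputed")
  }
  fill <- min(d_tbl$d[d_tbl$defined])
  d_tbl %>%
    mutate(
      imputed = !.data$defined,
      d = if_else(.data$defined, .data$d, fill)
    )
}

#' ROC curve and AUC with DeLong-style confidence interval
#'
#' The curve sweeps all score thresholds (predicting the positive class for
#' scores >= threshold); the AUC is the trapezoidal area, which equals the
#' normalized Mann-Whitney pairwise statistic with ties counted 1/2. The
#' default CI uses the asymptotic DeLong placement variance, truncated to
#' \[0, 1\]; a seeded bootstrap is available as an alternative.
#'
#' @param data Data frame holding scores and binary labels.
#' @param score Column (tidy-eval) with the continuous score; higher scores
#'   predict the positive class.
#' @param label Column (tidy-eval) with the class label: logical, or coercible
#'   to logical via comparison with `positive`.
#' @param positive Value of `label` counting as positive when `label` is not
#'   logical.
#' @param ci_method "delong" (default) or "bootstrap".
#' @param level Confidence level (default 0.95).
#' @param boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An `mr_roc`: list with `points` (threshold, fpr, tpr), `auc`,
#'   `ci_lower`, `ci_upper`, `n_pos`, `n_neg`, `ci_method`, `level`.
#' @export
roc_auc <- function(data, score, label, positive = TRUE,
                    ci_method = c("delong", "bootstrap"), level = 0.95,
                    boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  s <- dplyr::pull(data, {{ score }})
  lab <- dplyr::pull(data, {{ label }})
  if (!is.logical(lab)) lab <- lab == positive
  keep <- !is.na(s) & !is.na(lab)
  s <- s[keep]
  lab <- lab[keep]
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute a ROC curve")
  }

  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s[lab] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(s[!lab] >= t) / n0, 0)
  points <- tibble(
    threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
    utils::tail(points$tpr, -1)) / 2)

  if (ci_method == "delong") {
    pos <- s[lab]
    neg <- s[!lab]
    v10 <- vapply(pos, function(x) (sum(neg < x) + 0.5 * sum(neg == x)) / n0, 0)
    v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / n1, 0)
    se <- sqrt(var(v10) / n1 + var(v01) / n0)
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(auc - z * se, auc + z * se)
  } else {
    set.seed(seed)
    reps <- vapply(seq_len(boot), function(i) {
      bi <- c(
        sample(which(lab), n1, replace = TRUE),
        sample(which(!lab), n0, replace = TRUE)
      )
      .auc_rank(s[bi], lab[bi])
    }, 0)
    ci <- unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  structure(
    list(
      points = points, auc = auc,
      ci_lower = max(0, ci[1]), ci_upper = min(1, ci[2]),
      n_pos = n1, n_neg = n0, ci_method = ci_method, level = level
    ),
    class = "mr_roc"
  )
}

# Rank-based AUC (Mann-Whitney with midranks); used by the bootstrap.
.auc_rank <- function(s, lab) {
  n1 <- sum(lab)
  n0 <- sum(!lab)
  r <- rank(s)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
#' @method print mr_roc
print.mr_roc <- function(x, ...) {
  cat(
    "<mr_roc> AUC ", round(x$auc, 3), " (", round(100 * x$level), "% CI ",
    round(x$ci_lower, 3), "-", round(x$ci_upper, 3), ", ", x$ci_method,
    "), ", x$n_pos, " positives / ", x$n_neg, " negatives\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.mr_roc <- function(x, ...) x$points

#' @export
glance.mr_roc <- function(x, ...) {
  tibble(
    auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    level = x$level, ci_method = x$ci_method, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
autoplot.mr_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf(
        "AUC %.2f (%d%% CI %.2f-%.2f)", object$auc,
        round(100 * object$level), object$ci_lower, object$ci_upper
      )
    ) +
    ggplot2::theme_minimal()
}
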