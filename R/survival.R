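#' Survival analysis for molecular-response strata
#'
#' Thin tidyverse-facing layer over the survival package: Kaplan-Meier
#' product-limit curves (Greenwood variance, log-log median CIs), log-rank
#' group comparison, and Cox proportional-hazards regression with Efron tie
#' handling. Trial convention: medians reported with 90% CIs, hazard ratios
#' with 95% CIs; both levels are arguments. Time unit is months throughout
#' (1 month = 30.4375 days).
#'
#' @name survival_analysis
NULL

DAYS_PER_MONTH <- 30.4375

#' Time to molecular response from draw days
#'
#' Event time is the clearance sample's collection day (converted to months)
#' for mR patients; others are censored at their last liquid-biopsy draw.
#' Patients with missing collection days are excluded (reported in the
#' `excluded` attribute).
#'
#' @param calls Output of [call_molecular_response()].
#' @param samples Sample table with collection_day for plasma draws.
#' @return Tibble: patient_id, months, event (TRUE at molecular response).
#' @export
build_time_to_molecular_response <- function(calls, samples) {
  plasma <- samples %>%
    filter(.data$compartment == "plasma", .data$available)
  df <- calls %>%
    filter(.data$status %in% c("mR", "mPD")) %>%
    left_join(
      plasma %>%
        group_by(.data$patient_id) %>%
        summarise(
          last_draw_day = max(.data$collection_day),
          .groups = "drop"
        ),
      by = "patient_id"
    ) %>%
    left_join(
      plasma %>% select("patient_id",
        clearance_tp = "timepoint", clearance_day = "collection_day"
      ) %>% mutate(clearance_tp = as.character(.data$clearance_tp)),
      by = c("patient_id", clearance_timepoint = "clearance_tp")
    ) %>%
    mutate(
      event = .data$status == "mR",
      day = if_else(.data$event, .data$clearance_day, .data$last_draw_day),
      months = .data$day / DAYS_PER_MONTH
    )
  excluded <- df %>% filter(is.na(.data$day)) %>% pull(.data$patient_id)
  if (length(excluded) > 0) {
    inform(paste0(
      length(excluded),
      " patient(s) excluded from time-to-response: missing collection days"
    ))
  }
  out <- df %>%
    filter(!is.na(.data$day)) %>%
    select("patient_id", "months", "event")
  attr(out, "excluded") <- excluded
  out
}

#' Kaplan-Meier survival curve
#'
#' @param data Data frame with one row per subject.
#' @param time,event Columns (tidy-eval) holding follow-up time (months) and
#'   the event indicator (TRUE/1 = event, FALSE/0 = censored).
#' @param group Optional grouping column (tidy-eval) for stratified curves.
#' @param level Confidence level for survival and median CIs (default 0.90).
#' @return An `mr_survcurve`: the `survfit` object plus a tidy step table.
#' @export
kaplan_meier <- function(data, time, event, group = NULL, level = 0.90) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  if (length(t) == 0) abort("Empty input")
  if (any(t < 0, na.rm = TRUE)) abort("Times must be non-negative")
  g <- rlang::enquo(group)
  df <- data.frame(.time = t, .event = e)
  if (!rlang::quo_is_null(g)) {
    df$.group <- as.character(dplyr::pull(data, {{ group }}))
    fit <- survival::survfit(
      survival::Surv(.time, .event) ~ .group,
      data = df, conf.int = level, conf.type = "log-log"
    )
  } else {
    df$.group <- "all"
    fit <- survival::survfit(
      survival::Surv(.time, .event) ~ 1,
      data = df, conf.int = level, conf.type = "log-log"
    )
  }
  smry <- summary(fit, censored = TRUE)
  strata <- if (is.null(smry$strata)) {
    rep("all", length(smry$time))
  } else {
    sub("^\\.group=", "", as.character(smry$strata))
  }
  steps <- tibble(
    group = strata, time = smry$time, n_risk = smry$n.risk,
    n_event = smry$n.event, n_censor = smry$n.censor,
    survival = smry$surv, std_err = smry$std.err,
    lower = smry$lower, upper = smry$upper
  )
  structure(
    list(fit = fit, steps = steps, level = level, data = df),
    class = "mr_survcurve"
  )
}

#' @export
#' @method print mr_survcurve
print.mr_survcurve <- function(x, ...) {
  cat("<mr_survcurve>\n")
  print(median_survival(x))
  invisible(x)
}

#' @export
tidy.mr_survcurve <- function(x, ...) x$steps

#' Median survival with confidence interval
#'
#' The median is the smallest time at which the survival estimate drops to
#' 0.5 or below; when the curve never reaches 0.5 the median is "not reached"
#' (reported as NA with `reached = FALSE`, never as a number).
#'
#' @param curve An `mr_survcurve`.
#' @return Tibble per group: n, events, median, lower, upper, reached.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "mr_survcurve"))
  tab <- summary(curve$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  lcl_col <- grep("LCL$", colnames(tab), value = TRUE)[1]
  ucl_col <- grep("UCL$", colnames(tab), value = TRUE)[1]
  tibble(
    group = sub("^\\.group=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median = tab[, "median"],
    lower = tab[, lcl_col], upper = tab[, ucl_col],
    reached = !is.na(tab[, "median"]),
    level = curve$level
  )
}

#' @export
glance.mr_survcurve <- function(x, ...) median_survival(x)

#' @export
autoplot.mr_survcurve <- function(object, ...) {
  steps0 <- object$steps %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ bind_rows(
      tibble(
        time = 0, survival = 1, lower = 1, upper = 1,
        n_risk = max(.x$n_risk), n_event = 0, n_censor = 0, std_err = 0
      ),
      .x
    )) %>%
    ungroup()
  ggplot2::ggplot(
    steps0,
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(steps0, .data$n_censor > 0), shape = 3
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Months", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Log-rank test between survival groups
#'
#' @param data Data frame with one row per subject.
#' @param time,event,group Columns (tidy-eval): follow-up time, event
#'   indicator, and group.
#' @return Tibble: statistic (chi-square), df, p_value, n, n_events.
#' @export
log_rank_test <- function(data, time, event, group) {
  df <- data.frame(
    .time = dplyr::pull(data, {{ time }}),
    .event = as.integer(dplyr::pull(data, {{ event }})),
    .group = as.character(dplyr::pull(data, {{ group }}))
  )
  if (length(unique(df$.group)) < 2) abort("Need at least two groups")
  if (sum(df$.event) < 1) abort("Need at least one event")
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  df_free <- length(sd$n) - 1
  tibble(
    statistic = sd$chisq, df = df_free,
    p_value = stats::pchisq(sd$chisq, df_free, lower.tail = FALSE),
    n = sum(sd$n), n_events = sum(sd$obs)
  )
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood maximisation via `survival::coxph` with Efron tie
#' handling by default and Wald confidence intervals. Monotone-likelihood
#' (complete separation) fits are flagged rather than silently reported.
#'
#' @param data Data frame with one row per subject.
#' @param time,event Columns (tidy-eval) with follow-up time and event flag.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie-handling rule, "efron" (default) or "breslow".
#' @param level Confidence level for hazard-ratio CIs (default 0.95).
#' @return An `mr_cox`: the `coxph` fit plus the call parameters; `tidy()`
#'   gives term-level hazard ratios with CIs, `glance()` model-level fit
#'   statistics.
#' @export
cox_ph <- function(data, time, event, covariates, ties = c("efron", "breslow"),
                   level = 0.95) {
  ties <- match.arg(ties)
  if (length(covariates) < 1) abort("Need at least one covariate")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("Covariate(s) not in data: ", paste(missing_cov, collapse = ", ")))
  }
  df <- as.data.frame(data)
  df$.time <- dplyr::pull(data, {{ time }})
  df$.event <- as.integer(dplyr::pull(data, {{ event }}))
  if (sum(df$.event) < 1) abort("Need at least one event")
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = ties)
  flagged <- any(is.na(stats::coef(fit))) ||
    any(abs(stats::coef(fit)) > 15) ||
    any(sqrt(diag(fit$var)) > 100)
  if (flagged) {
    warn("Cox fit may be degenerate (possible monotone likelihood / separation)")
  }
  structure(
    list(fit = fit, level = level, ties = ties, flagged = flagged),
    class = "mr_cox"
  )
}

#' @export
#' @method print mr_cox
print.mr_cox <- function(x, ...) {
  cat("<mr_cox> ties:", x$ties, if (x$flagged) "(flagged)" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.mr_cox <- function(x, ...) {
  co <- stats::coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  z <- stats::qnorm(1 - (1 - x$level) / 2)
  tibble(
    term = names(co), estimate = unname(co),
    hazard_ratio = exp(unname(co)),
    std_error = unname(se),
    conf_low = exp(unname(co) - z * se),
    conf_high = exp(unname(co) + z * se),
    statistic = unname(co / se),
    p_value = 2 * stats::pnorm(-abs(unname(co / se))),
    level = x$level
  )
}

#' @export
glance.mr_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$fit$n, n_events = x$fit$nevent,
    loglik = x$fit$loglik[2],
    lr_statistic = unname(s$logtest["test"]),
    lr_p_value = unname(s$logtest["pvalue"]),
    concordance = unname(s$concordance["C"]),
    flagged = x$flagged
  )
}
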