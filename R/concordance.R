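#' Exact binomial machinery and molecular/radiographic concordance
#'
#' Sensitivity here is P(mR | radiographic responder) and specificity is
#' P(mPD | radiographic non-responder), each with an exact (Clopper-Pearson)
#' confidence interval. The two-sided interval at level `1 - 2a` doubles as a
#' pair of one-sided bounds at level `1 - a`; the trial-style success
#' criterion is that the one-sided lower bound exceeds 0.50.
#'
#' @name concordance_stats
NULL

#' Clopper-Pearson exact binomial confidence interval
#'
#' Endpoints via the beta-quantile identity: the lower endpoint is the p at
#' which the upper binomial tail P(X >= k) equals (1-level)/2, i.e.
#' `qbeta(a, k, n-k+1)`, and symmetrically for the upper endpoint. k = 0
#' forces lower = 0 and k = n forces upper = 1.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Two-sided confidence level (default 0.90).
#' @return Tibble: k, n, level, estimate, lower, upper.
#' @export
clopper_pearson_interval <- function(k, n, level = 0.90) {
  if (any(n < 1)) abort("n must be >= 1")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  a <- (1 - level) / 2
  lower <- ifelse(k == 0, 0, qbeta(a, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  tibble(
    k = as.integer(k), n = as.integer(n), level = level,
    estimate = k / n, lower = lower, upper = upper
  )
}

#' Exact binomial test
#'
#' Direct tail computation from binomial probabilities. One-sided p-values are
#' tail sums; the two-sided p-value follows the minimum-likelihood rule (sum
#' of the probabilities of all outcomes no more probable than the observed
#' one, with a small relative tolerance for ties).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return Tibble: k, n, p0, alternative, p_value.
#' @export
exact_binomial_test <- function(k, n, p0,
                                alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (p0 <= 0 || p0 >= 1) abort("p0 must be in (0, 1)")
  if (k < 0 || k > n) abort("k must satisfy 0 <= k <= n")
  probs <- dbinom(0:n, n, p0)
  p <- switch(alternative,
    less = sum(probs[seq_len(k + 1)]),
    greater = sum(probs[(k + 1):(n + 1)]),
    two.sided = {
      obs <- probs[k + 1]
      sum(probs[probs <= obs * (1 + 1e-7)])
    }
  )
  tibble(
    k = as.integer(k), n = as.integer(n), p0 = p0,
    alternative = alternative, p_value = min(1, p)
  )
}

#' Build the 2x2 molecular-vs-radiographic concordance table
#'
#' Includes only patients with a definitive molecular status (mR or mPD) and
#' a non-missing, non-NE best overall response under the chosen criterion.
#' Responder means CR/PR (RECIST) or iCR/iPR (iRECIST).
#'
#' @param calls Output of [call_molecular_response()].
#' @param patients Patient table with recist_bor / irecist_bor.
#' @param criterion "RECIST" (default) or "iRECIST".
#' @return An object of class `mr_concordance`: list with counts `a`
#'   (mR & responder), `b` (mPD & responder), `c` (mR & non-responder),
#'   `d` (mPD & non-responder), the criterion, and the patient-level table.
#' @export
build_concordance_table <- function(calls, patients,
                                    criterion = c("RECIST", "iRECIST")) {
  criterion <- match.arg(criterion)
  bor_col <- if (criterion == "RECIST") "recist_bor" else "irecist_bor"
  resp_lv <- if (criterion == "RECIST") c("CR", "PR") else c("iCR", "iPR")
  nonresp_lv <- if (criterion == "RECIST") c("SD", "PD") else c("iSD", "iPD")

  df <- calls %>%
    inner_join(patients, by = "patient_id") %>%
    filter(
      .data$status %in% c("mR", "mPD"),
      !is.na(.data[[bor_col]]),
      .data[[bor_col]] %in% c(resp_lv, nonresp_lv)
    ) %>%
    mutate(
      responder = .data[[bor_col]] %in% resp_lv,
      molecular_response = .data$status == "mR"
    )
  structure(
    list(
      a = sum(df$responder & df$molecular_response),
      b = sum(df$responder & !df$molecular_response),
      c = sum(!df$responder & df$molecular_response),
      d = sum(!df$responder & !df$molecular_response),
      criterion = criterion,
      patients = df %>% select(
        "patient_id", "status", dplyr::all_of(bor_col), "responder",
        "molecular_response"
      )
    ),
    class = "mr_concordance"
  )
}

#' Construct a concordance table directly from counts
#'
#' @param a,b,c,d Counts: mR & responder, mPD & responder, mR & non-responder,
#'   mPD & non-responder.
#' @param criterion Label, default "RECIST".
#' @return An `mr_concordance`.
#' @export
concordance_table <- function(a, b, c, d, criterion = "RECIST") {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  structure(
    list(
      a = a, b = b, c = c, d = d, criterion = criterion,
      patients = NULL
    ),
    class = "mr_concordance"
  )
}

#' @export
#' @method print mr_concordance
print.mr_concordance <- function(x, ...) {
  cat("<mr_concordance> criterion:", x$criterion, "\n")
  m <- matrix(c(x$a, x$c, x$b, x$d),
    nrow = 2,
    dimnames = list(
      c("responder", "non-responder"), c("mR", "mPD")
    )
  )
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of molecular response, with exact CIs
#'
#' @param table An `mr_concordance`.
#' @param level Two-sided confidence level (default 0.90); the reported
#'   `one_sided_lower` is the same lower endpoint read as a one-sided bound at
#'   level `1 - (1-level)/2` (0.95 by default), the trial success criterion
#'   being that it exceeds 0.50.
#' @return Tibble with rows sensitivity and specificity: k, n, estimate,
#'   lower, upper, one_sided_lower, level. A statistic whose margin is empty
#'   is reported absent (NA row).
#' @export
concordance_performance <- function(table, level = 0.90) {
  stopifnot(inherits(table, "mr_concordance"))
  one_row <- function(statistic, k, n) {
    if (n == 0) {
      return(tibble(
        statistic = statistic, k = NA_integer_, n = 0L, estimate = NA_real_,
        lower = NA_real_, upper = NA_real_, one_sided_lower = NA_real_,
        level = level
      ))
    }
    ci <- clopper_pearson_interval(k, n, level)
    tibble(
      statistic = statistic, k = as.integer(k), n = as.integer(n),
      estimate = k / n, lower = ci$lower, upper = ci$upper,
      one_sided_lower = ci$lower, level = level
    )
  }
  bind_rows(
    one_row("sensitivity", table$a, table$a + table$b),
    one_row("specificity", table$d, table$c + table$d)
  )
}

#' @export
tidy.mr_concordance <- function(x, level = 0.90, ...) {
  concordance_performance(x, level = level)
}

#' @export
glance.mr_concordance <- function(x, ...) {
  tibble(
    criterion = x$criterion, a = x$a, b = x$b, c = x$c, d = x$d,
    n = x$a + x$b + x$c + x$d,
    accuracy = if (x$a + x$b + x$c + x$d > 0) {
      (x$a + x$d) / (x$a + x$b + x$c + x$d)
    } else {
      NA_real_
    }
  )
}

#' Concordance stratified by baseline circulating tumor load
#'
#' Splits the evaluable patients at each baseline maxMAF threshold and reports
#' sensitivity/specificity per stratum. Strata with an empty margin get NA
#' for the affected statistic.
#'
#' @param calls Output of [call_molecular_response()] (needs
#'   `baseline_max_maf`).
#' @param patients Patient table.
#' @param thresholds Baseline maxMAF thresholds as fractions
#'   (default c(0.03, 0.04)).
#' @param criterion "RECIST" or "iRECIST".
#' @param level Confidence level.
#' @return Tibble: threshold, stratum ("<t" / ">=t"), statistic, k, n,
#'   estimate, lower, upper.
#' @export
subgroup_concordance_by_baseline_maf <- function(calls, patients,
                                                 thresholds = c(0.03, 0.04),
                                                 criterion = c("RECIST", "iRECIST"),
                                                 level = 0.90) {
  criterion <- match.arg(criterion)
  purrr::map_dfr(thresholds, function(th) {
    purrr::map_dfr(c(FALSE, TRUE), function(upper_stratum) {
      sub <- calls %>%
        filter(
          !is.na(.data$baseline_max_maf),
          if (upper_stratum) {
            .data$baseline_max_maf >= th
          } else {
            .data$baseline_max_maf < th
          }
        )
      tab <- build_concordance_table(sub, patients, criterion)
      concordance_performance(tab, level) %>%
        mutate(
          threshold = th,
          stratum = if (upper_stratum) paste0(">=", th) else paste0("<", th),
          .before = 1
        )
    })
  })
}

#' Smallest responder count guaranteeing an exact lower confidence bound
#'
#' Design-stage bound: the smallest n such that, observing the smallest k with
#' k/n at least `assumed_rate`, the two-sided exact interval's lower endpoint
#' exceeds `bound`. With an assumed sensitivity of 70%, 18 responders suffice
#' for a 90% two-sided (95% one-sided) lower bound above 50%.
#'
#' @param assumed_rate Assumed true proportion (must exceed `bound`).
#' @param level Two-sided confidence level (default 0.90).
#' @param bound Lower bound to exceed (default 0.50).
#' @param max_n Search limit (default 10000).
#' @return Tibble: n, k, lower (achieved lower endpoint).
#' @export
min_responders_for_bound <- function(assumed_rate, level = 0.90, bound = 0.50,
                                     max_n = 10000) {
  if (assumed_rate <= bound || assumed_rate > 1) {
    abort("assumed_rate must lie in (bound, 1]")
  }
  if (bound <= 0) {
    k <- as.integer(ceiling(assumed_rate * 1))
    return(tibble(n = 1L, k = k, lower = clopper_pearson_interval(k, 1, level)$lower))
  }
  for (n in seq_len(max_n)) {
    k <- ceiling(assumed_rate * n)
    lo <- clopper_pearson_interval(k, n, level)$lower
    if (lo > bound) {
      return(tibble(n = as.integer(n), k = as.integer(k), lower = lo))
    }
  }
  abort(paste0("No n <= ", max_n, " attains a lower bound above ", bound),
    class = "ctdnamr_search_limit_error"
  )
}
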