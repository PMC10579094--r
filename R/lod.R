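#' Binomial limit-of-detection model
#'
#' With error-corrected distinct coverage n at a genomic position and a true
#' mutant allele fraction p, the number of mutant read families is
#' Binomial(n, p); the assay calls a variant when at least `min_reads`
#' (default 3) mutant families are observed. Detection probability is the
#' upper binomial tail P(X >= min_reads), evaluated through the distribution's
#' survival function rather than naive summation so small p / large n do not
#' lose precision to cancellation. Assay-level sensitivity at a MAF is the
#' median detection probability across the profiled positions.
#'
#' @name lod_model
NULL

#' Probability of detecting a variant at given coverage and MAF
#'
#' @param coverage Error-corrected distinct coverage (non-negative integer;
#'   vectorised).
#' @param maf True mutant allele fraction in \[0, 1\] (vectorised).
#' @param min_reads Minimum mutant read families required for a call
#'   (default 3).
#' @return Numeric vector of probabilities P(X >= min_reads),
#'   X ~ Binomial(coverage, maf).
#' @export
detection_probability <- function(coverage, maf, min_reads = 3) {
  if (any(coverage < 0)) abort("coverage must be non-negative")
  if (any(maf < 0 | maf > 1)) abort("maf must lie in [0, 1]")
  if (any(min_reads < 1)) abort("min_reads must be >= 1")
  pbinom(min_reads - 1, size = coverage, prob = maf, lower.tail = FALSE)
}

#' Assay sensitivity profile across profiled positions
#'
#' @param positions Data frame with one row per genomic position carrying a
#'   `distinct_coverage` column (any identifier columns are carried through).
#' @param maf_grid MAF levels to evaluate (default 0.1%-1%).
#' @param min_reads Minimum mutant read families (default 3).
#' @return An `mr_lod`: list with `per_position` (long tibble of detection
#'   probabilities), `summary` (per MAF: median/min/max probability), and the
#'   call parameters.
#' @export
assay_sensitivity_profile <- function(positions,
                                      maf_grid = c(0.001, 0.002, 0.003, 0.005, 0.01),
                                      min_reads = 3) {
  positions <- as_tibble(positions)
  if (nrow(positions) == 0) abort("positions must contain at least one row")
  if (!"distinct_coverage" %in% names(positions)) {
    abort("positions must have a distinct_coverage column")
  }
  per_position <- tidyr::expand_grid(
    position = seq_len(nrow(positions)), maf = maf_grid
  ) %>%
    mutate(
      distinct_coverage = positions$distinct_coverage[.data$position],
      detection_probability = detection_probability(
        .data$distinct_coverage, .data$maf, min_reads
      )
    )
  summary <- per_position %>%
    group_by(.data$maf) %>%
    summarise(
      median_sensitivity = median(.data$detection_probability),
      min_sensitivity = min(.data$detection_probability),
      max_sensitivity = max(.data$detection_probability),
      n_positions = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      per_position = per_position, summary = summary,
      min_reads = min_reads, maf_grid = maf_grid,
      n_positions = nrow(positions)
    ),
    class = "mr_lod"
  )
}

#' @export
#' @method print mr_lod
print.mr_lod <- function(x, ...) {
  cat(
    "<mr_lod> ", x$n_positions, " positions, min_reads = ", x$min_reads, "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' @export
tidy.mr_lod <- function(x, ...) x$summary

#' @export
glance.mr_lod <- function(x, ...) {
  tibble(
    n_positions = x$n_positions, min_reads = x$min_reads,
    maf_grid = paste(x$maf_grid, collapse = ",")
  )
}

#' @export
autoplot.mr_lod <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = 100 * .data$maf, y = 100 * .data$median_sensitivity)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = 100 * .data$min_sensitivity, ymax = 100 * .data$max_sensitivity
      ),
      fill = "grey85"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Mutant allele fraction (%)", y = "Detection probability (%)",
      title = sprintf(
        "Assay sensitivity (median over %d positions, >=%d mutant reads)",
        object$n_positions, object$min_reads
      )
    ) +
    ggplot2::theme_minimal()
}
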