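#' Plasma variant cellular-origin classification
#'
#' The tumor-agnostic, WBC-informed rules assign each unique plasma variant of
#' a patient one of three origins, in strict precedence:
#'
#' 1. cancer hotspot -> `tumor` (independent of WBC detection; WBC reads for a
#'    hotspot more likely reflect circulating tumor cells in the buffy coat
#'    than clonal hematopoiesis);
#' 2. non-hotspot detected in the matched WBC DNA with MAF at or above the
#'    germline threshold (default 25%) there and in every plasma sample in
#'    which it was called -> `germline`;
#' 3. any other non-hotspot detected in the matched WBC DNA -> `hematopoietic`
#'    (clonal hematopoiesis, CHIP);
#' 4. otherwise -> `tumor`.
#'
#' Germline and hematopoietic variants are excluded from circulating tumor
#' load downstream. Timepoints at which a variant was not called do not veto
#' the germline rule. Patients without a WBC sample get tumor labels with a
#' `wbc_missing` provenance flag rather than being dropped.
#'
#' @name variant_origin
NULL

.origin_levels <- c("germline", "hematopoietic", "tumor")

#' Classify a single variant's cellular origin
#'
#' Rule engine for one unique (patient, variant) pair; see
#' [annotate_cohort_origins()] for the cohort-level driver.
#'
#' @param plasma_mafs Numeric vector of MAFs from the plasma samples in which
#'   the variant was called (at least one).
#' @param wbc_detected Was the variant called in the matched WBC DNA (with at
#'   least `wbc_min_reads` mutant reads)?
#' @param wbc_maf MAF in the WBC sample (NA when not detected).
#' @param is_hotspot Is the variant on the cancer-hotspot list?
#' @param wbc_available Does the patient have a WBC sample at all? When FALSE,
#'   rules 2-3 are inapplicable and the label is `tumor`.
#' @param germline_maf_threshold Fraction above which a WBC-shared variant in
#'   all plasma samples is deemed germline (default 0.25).
#' @return One of "germline", "hematopoietic", "tumor".
#' @export
classify_variant_origin <- function(plasma_mafs, wbc_detected, wbc_maf,
                                    is_hotspot, wbc_available = TRUE,
                                    germline_maf_threshold = 0.25) {
  if (length(plasma_mafs) < 1) {
    abort("classify_variant_origin() needs at least one plasma observation")
  }
  if (isTRUE(is_hotspot)) {
    return("tumor")
  }
  if (!isTRUE(wbc_available) || !isTRUE(wbc_detected)) {
    return("tumor")
  }
  germ <- all(plasma_mafs >= germline_maf_threshold) &&
    !is.na(wbc_maf) && wbc_maf >= germline_maf_threshold
  if (germ) "germline" else "hematopoietic"
}

.hotspot_flags <- function(keys, hotspots) {
  if (is.null(hotspots) || nrow(hotspots) == 0) {
    return(rep(FALSE, nrow(keys)))
  }
  hs <- as_tibble(hotspots)
  by_genomic <- hs %>% filter(!is.na(.data$chrom) & !is.na(.data$pos))
  by_protein <- hs %>% filter(!is.na(.data$gene) & !is.na(.data$protein_change))
  flag <- rep(FALSE, nrow(keys))
  if (nrow(by_genomic) > 0) {
    gk <- paste(by_genomic$chrom, by_genomic$pos, by_genomic$ref, by_genomic$alt)
    flag <- flag | paste(keys$chrom, keys$pos, keys$ref, keys$alt) %in% gk
  }
  if (nrow(by_protein) > 0 && all(c("gene", "protein_change") %in% names(keys))) {
    pk <- paste(by_protein$gene, by_protein$protein_change)
    flag <- flag |
      (!is.na(keys$gene) & !is.na(keys$protein_change) &
        paste(keys$gene, keys$protein_change) %in% pk)
  }
  flag
}

#' Annotate every unique plasma variant with its cellular origin
#'
#' Applies [classify_variant_origin()] to each unique (patient, chrom, pos,
#' ref, alt) with at least one plasma observation. Only observations with at
#' least `min_reads` mutant reads count as detections (both in plasma and, via
#' `wbc_min_reads`, in WBC).
#'
#' @param cohort A `ctdna_cohort`.
#' @param germline_maf_threshold Fraction for the germline rule (default 0.25).
#' @param wbc_min_reads Minimum WBC mutant reads for "detected in WBC"
#'   (default 1; no WBC read floor is imposed by the classification scheme).
#' @return Tibble of annotated variants: one row per unique patient-level
#'   plasma variant with columns origin, is_hotspot, wbc_detected, wbc_maf,
#'   wbc_missing, n_plasma_obs, max_plasma_maf and excluded_from_load
#'   (TRUE for germline/hematopoietic).
#' @export
annotate_cohort_origins <- function(cohort, germline_maf_threshold = 0.25,
                                    wbc_min_reads = 1) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  v <- cohort$variants
  plasma <- v %>% filter(.data$compartment == "plasma", .data$mutant_reads >= 1)
  if (nrow(plasma) == 0) {
    return(tibble(
      patient_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), gene = character(0),
      protein_change = character(0), origin = character(0),
      is_hotspot = logical(0), wbc_detected = logical(0), wbc_maf = double(0),
      wbc_missing = logical(0), n_plasma_obs = integer(0),
      max_plasma_maf = double(0), excluded_from_load = logical(0)
    ))
  }
  wbc_raw <- v %>%
    filter(.data$compartment == "wbc", .data$mutant_reads >= wbc_min_reads)
  wbc <- if (nrow(wbc_raw) > 0) {
    wbc_raw %>%
      group_by(.data$patient_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
      summarise(wbc_maf = max(.data$maf), .groups = "drop") %>%
      mutate(wbc_detected = TRUE)
  } else {
    tibble(
      patient_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), wbc_maf = double(0),
      wbc_detected = logical(0)
    )
  }
  wbc_patients <- cohort$samples %>%
    filter(.data$compartment == "wbc") %>%
    pull(.data$patient_id) %>%
    unique()

  ann <- plasma %>%
    group_by(.data$patient_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      gene = first(.data$gene[!is.na(.data$gene)], default = NA_character_),
      protein_change = first(.data$protein_change[!is.na(.data$protein_change)],
        default = NA_character_
      ),
      n_plasma_obs = dplyr::n(),
      max_plasma_maf = max(.data$maf),
      min_plasma_maf = min(.data$maf),
      .groups = "drop"
    ) %>%
    left_join(wbc, by = c("patient_id", "chrom", "pos", "ref", "alt")) %>%
    mutate(
      wbc_detected = !is.na(.data$wbc_detected),
      wbc_missing = !(.data$patient_id %in% wbc_patients),
      is_hotspot = .hotspot_flags(
        dplyr::pick("chrom", "pos", "ref", "alt", "gene", "protein_change"),
        cohort$hotspots
      ),
      origin = case_when(
        is_hotspot ~ "tumor",
        wbc_missing | !wbc_detected ~ "tumor",
        .data$min_plasma_maf >= germline_maf_threshold &
          .data$wbc_maf >= germline_maf_threshold ~ "germline",
        TRUE ~ "hematopoietic"
      ),
      excluded_from_load = .data$origin %in% c("germline", "hematopoietic")
    ) %>%
    select(
      "patient_id", "chrom", "pos", "ref", "alt", "gene", "protein_change",
      "origin", "is_hotspot", "wbc_detected", "wbc_maf", "wbc_missing",
      "n_plasma_obs", "max_plasma_maf", "excluded_from_load"
    )
  ann
}

#' Counts and proportions of variant origins
#'
#' Denominator is the number of unique plasma variants. With an empty input
#' the counts are zero and proportions are reported absent (NA).
#'
#' @param annotated Output of [annotate_cohort_origins()].
#' @return Tibble: origin, n, proportion (fractions summing to 1), label
#'   (integer-percent rendering).
#' @export
origin_summary <- function(annotated) {
  base <- tibble(origin = .origin_levels)
  counts <- annotated %>%
    count(.data$origin) %>%
    dplyr::right_join(base, by = "origin") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  total <- sum(counts$n)
  counts %>%
    mutate(
      origin = factor(.data$origin, levels = .origin_levels),
      proportion = if (total > 0) .data$n / total else NA_real_,
      label = if (total > 0) percent(.data$n / total) else NA_character_
    ) %>%
    arrange(.data$origin)
}

#' Concordance of WBC-informed origin calls with tumor tissue sequencing
#'
#' For patients with tumor-compartment sequencing and at least one
#' plasma-called tumor-derived variant, reports the fraction of those variants
#' confirmed present in the tumor tissue call set. Discordant variants (called
#' tumor-derived from plasma but absent from tissue) are reported, never
#' reclassified: single-region archival tissue can genuinely miss true ctDNA
#' variants.
#'
#' @param annotated Output of [annotate_cohort_origins()].
#' @param tumor_observations Variant observations from the tumor compartment
#'   (e.g. `cohort$variants` filtered to `compartment == "tumor"`); only the
#'   variant key columns are used.
#' @return List with `concordance` (fraction), `n_confirmed`, `n_evaluated`,
#'   `per_variant` tibble, and `n_patients` evaluated. When no tumor
#'   observations exist, returns zero-row results with a message attribute.
#' @export
tumor_plasma_origin_concordance <- function(annotated, tumor_observations) {
  tumor_obs <- as_tibble(tumor_observations)
  if (nrow(tumor_obs) == 0) {
    res <- list(
      concordance = NA_real_, n_confirmed = 0L, n_evaluated = 0L,
      n_patients = 0L,
      per_variant = tibble(
        patient_id = character(0), chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0), confirmed_in_tumor = logical(0)
      )
    )
    attr(res, "notice") <- "no tumor-compartment observations available"
    return(res)
  }
  tkey <- tumor_obs %>%
    distinct(.data$patient_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    mutate(confirmed_in_tumor = TRUE)
  seq_patients <- unique(tumor_obs$patient_id)
  eval_tbl <- annotated %>%
    filter(.data$origin == "tumor", .data$patient_id %in% seq_patients) %>%
    left_join(tkey, by = c("patient_id", "chrom", "pos", "ref", "alt")) %>%
    mutate(confirmed_in_tumor = !is.na(.data$confirmed_in_tumor)) %>%
    select(
      "patient_id", "chrom", "pos", "ref", "alt", "gene", "protein_change",
      "confirmed_in_tumor"
    )
  list(
    concordance = if (nrow(eval_tbl) > 0) {
      mean(eval_tbl$confirmed_in_tumor)
    } else {
      NA_real_
    },
    n_confirmed = sum(eval_tbl$confirmed_in_tumor),
    n_evaluated = nrow(eval_tbl),
    n_patients = length(unique(eval_tbl$patient_id)),
    per_variant = eval_tbl
  )
}
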