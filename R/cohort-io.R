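#' Cohort data model and table I/O
#'
#' A cohort dataset bundles the four long-format tables the pipeline consumes:
#' per-sample variant observations, a sample inventory, patient-level clinical
#' records and a cancer-hotspot list. All tables are plain tibbles so every
#' downstream verb composes with dplyr.
#'
#' @name cohort_io
NULL

.variant_cols <- c(
  patient_id = "character", sample_id = "character", timepoint = "character",
  compartment = "character", chrom = "character", pos = "integer",
  ref = "character", alt = "character", maf = "double",
  mutant_reads = "integer", distinct_coverage = "integer"
)
.variant_opt_cols <- c(gene = "character", protein_change = "character")
.sample_cols <- c(
  sample_id = "character", patient_id = "character", timepoint = "character",
  compartment = "character"
)
.sample_opt_cols <- c(collection_day = "integer", available = "logical")
.patient_cols <- c(patient_id = "character")
.patient_opt_cols <- c(
  recist_bor = "character", irecist_bor = "character",
  pfs_months = "double", pfs_event = "logical",
  os_months = "double", os_event = "logical", first_response_day = "integer"
)
.hotspot_opt_cols <- c(
  gene = "character", protein_change = "character", chrom = "character",
  pos = "integer", ref = "character", alt = "character"
)

.compartments <- c("plasma", "wbc", "tumor")
.recist_levels <- c("CR", "PR", "SD", "PD", "NE")
.irecist_levels <- c("iCR", "iPR", "iSD", "iPD", "NE")

.coerce_cols <- function(df, spec, table, required = TRUE) {
  missing <- setdiff(names(spec), names(df))
  if (required && length(missing) > 0) {
    abort(paste0(
      "Table '", table, "' is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "ctdnamr_schema_error")
  }
  for (col in intersect(names(spec), names(df))) {
    df[[col]] <- switch(spec[[col]],
      character = as.character(df[[col]]),
      integer   = as.integer(df[[col]]),
      double    = as.double(df[[col]]),
      logical   = as.logical(df[[col]])
    )
  }
  for (col in setdiff(names(spec), names(df))) {
    df[[col]] <- switch(spec[[col]],
      character = NA_character_, integer = NA_integer_,
      double = NA_real_, logical = NA
    )
  }
  df
}

#' Assemble a cohort dataset from in-memory tables
#'
#' Validates schemas, coerces column types, and checks referential integrity
#' (every variant observation must cite an existing sample; every sample an
#' existing patient). Structural rule violations beyond referential integrity
#' are left to [validate_cohort()] so a dataset with, say, a duplicated plasma
#' draw can still be constructed and inspected.
#'
#' @param variants Data frame of per-sample variant observations. Required
#'   columns: patient_id, sample_id, timepoint, compartment, chrom, pos, ref,
#'   alt, maf, mutant_reads, distinct_coverage. Optional: gene, protein_change.
#' @param samples Data frame of samples: sample_id, patient_id, timepoint,
#'   compartment; optional collection_day, available.
#' @param patients Data frame keyed by patient_id with optional clinical
#'   columns (recist_bor, irecist_bor, pfs/os times and event flags,
#'   first_response_day).
#' @param hotspots Optional data frame of cancer hotspots; matching is by
#'   (chrom, pos, ref, alt) when present, else by (gene, protein_change).
#' @param timepoints Chronologically ordered timepoint labels.
#' @return An object of class `ctdna_cohort`: a list of tibbles `variants`,
#'   `samples`, `patients`, `hotspots` plus the timepoint order.
#' @seealso [read_cohort_tables()], [validate_cohort()]
#' @export
cohort_dataset <- function(variants, samples, patients,
                           hotspots = default_hotspots(),
                           timepoints = .default_timepoints) {
  variants <- .coerce_cols(as_tibble(variants), .variant_cols, "variants")
  variants <- .coerce_cols(variants, .variant_opt_cols, "variants", required = FALSE)
  samples <- .coerce_cols(as_tibble(samples), .sample_cols, "samples")
  samples <- .coerce_cols(samples, .sample_opt_cols, "samples", required = FALSE)
  patients <- .coerce_cols(as_tibble(patients), .patient_cols, "patients")
  patients <- .coerce_cols(patients, .patient_opt_cols, "patients", required = FALSE)
  hotspots <- .coerce_cols(as_tibble(hotspots), .hotspot_opt_cols, "hotspots",
    required = FALSE
  )
  if (anyNA(samples$available)) {
    samples$available[is.na(samples$available)] <- TRUE
  }

  samples$timepoint <- as_timepoint(samples$timepoint, timepoints)
  variants$timepoint <- as_timepoint(variants$timepoint, timepoints)

  bad_maf <- which(!is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1))
  if (length(bad_maf) > 0) {
    abort(paste0(
      "variants: maf outside [0, 1] at row(s) ",
      paste(utils::head(bad_maf, 5), collapse = ", "),
      " - if MAFs are percentages, read with maf_dialect = \"percent\""
    ), class = "ctdnamr_value_error")
  }
  orphan <- setdiff(variants$sample_id, samples$sample_id)
  if (length(orphan) > 0) {
    abort(paste0(
      "variants cite unknown sample_id(s): ",
      paste(utils::head(orphan, 5), collapse = ", ")
    ), class = "ctdnamr_integrity_error")
  }
  orphan_p <- setdiff(samples$patient_id, patients$patient_id)
  if (length(orphan_p) > 0) {
    abort(paste0(
      "samples cite unknown patient_id(s): ",
      paste(utils::head(orphan_p, 5), collapse = ", ")
    ), class = "ctdnamr_integrity_error")
  }

  structure(
    list(
      variants = variants, samples = samples, patients = patients,
      hotspots = hotspots, timepoints = timepoints
    ),
    class = "ctdna_cohort"
  )
}

#' @export
#' @method print ctdna_cohort
print.ctdna_cohort <- function(x, ...) {
  cat(
    "<ctdna_cohort> ", nrow(x$patients), " patients, ", nrow(x$samples),
    " samples, ", nrow(x$variants), " variant observations\n",
    sep = ""
  )
  cat("timepoints:", paste(x$timepoints, collapse = " < "), "\n")
  invisible(x)
}

#' Read a cohort from TSV tables
#'
#' Reads the four tab-separated tables of the documented dialect (header row;
#' columns as in [cohort_dataset()]) and returns a validated dataset. MAFs may
#' be stored as fractions (default) or percentages; percentages are converted
#' to fractions on read (x -> x/100).
#'
#' @param dir Directory containing `variants.tsv`, `samples.tsv`,
#'   `patients.tsv` and optionally `hotspots.tsv`; ignored when explicit paths
#'   are given.
#' @param variants,samples,patients,hotspots Optional explicit file paths.
#' @param maf_dialect Either "fraction" or "percent".
#' @param timepoints Chronologically ordered timepoint labels.
#' @return A `ctdna_cohort`.
#' @export
read_cohort_tables <- function(dir = NULL, variants = NULL, samples = NULL,
                               patients = NULL, hotspots = NULL,
                               maf_dialect = c("fraction", "percent"),
                               timepoints = .default_timepoints) {
  maf_dialect <- match.arg(maf_dialect)
  path_of <- function(given, name) {
    p <- given %||% file.path(dir %||% ".", paste0(name, ".tsv"))
    p
  }
  read1 <- function(p, required = TRUE) {
    if (!file.exists(p)) {
      if (required) abort(paste0("File not found: ", p))
      return(NULL)
    }
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  v <- read1(path_of(variants, "variants"))
  s <- read1(path_of(samples, "samples"))
  p <- read1(path_of(patients, "patients"))
  h <- read1(path_of(hotspots, "hotspots"), required = FALSE)
  if (maf_dialect == "percent" && "maf" %in% names(v)) v$maf <- v$maf / 100
  cohort_dataset(v, s, p, h %||% default_hotspots(), timepoints = timepoints)
}

#' Write a cohort to TSV tables
#'
#' Inverse of [read_cohort_tables()] under the fraction MAF dialect:
#' `read_cohort_tables(dir)` on the output reproduces all field values.
#'
#' @param cohort A `ctdna_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("variants", "samples", "patients", "hotspots")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    tab <- cohort[[nm]]
    if ("timepoint" %in% names(tab)) tab$timepoint <- as.character(tab$timepoint)
    readr::write_tsv(tab, p, progress = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Built-in cancer hotspot list
#'
#' A small editable table of canonical activating codons (KRAS/NRAS codons 12,
#' 13 and 61, BRAF V600, EGFR L858R/T790M, PIK3CA E542K/E545K/H1047R) used to
#' force tumor-derived origin regardless of white-blood-cell detection.
#' Shipped as `inst/extdata/hotspots.tsv`; replace with an assay-specific list
#' via the `hotspots` argument of [cohort_dataset()].
#'
#' @return Tibble with columns gene, protein_change (genomic key columns empty).
#' @export
default_hotspots <- function() {
  p <- system.file("extdata", "hotspots.tsv", package = "ctdnamr")
  if (nzchar(p)) {
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  } else {
    # during development before installation
    tibble(gene = character(0), protein_change = character(0))
  }
}

#' Validate a cohort dataset
#'
#' Reports every structural rule violation rather than stopping at the first:
#' MAF range, read support not exceeding distinct coverage, duplicate variant
#' keys within a sample, at most one plasma sample per patient-timepoint, a
#' unique baseline WBC sample per patient, and PFS not exceeding OS. An empty
#' report means the dataset is clean.
#'
#' @param cohort A `ctdna_cohort`.
#' @return Tibble with columns rule, table, id, message (zero rows if clean).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ctdna_cohort"))
  v <- cohort$variants
  s <- cohort$samples
  p <- cohort$patients
  out <- list()
  add <- function(rule, table, id, message) {
    out[[length(out) + 1]] <<- tibble(
      rule = rule, table = table, id = as.character(id), message = message
    )
  }

  bad <- which(!is.na(v$maf) & (v$maf < 0 | v$maf > 1))
  for (i in bad) add("maf_range", "variants", i, paste0("maf = ", v$maf[i]))
  bad <- which(v$mutant_reads > v$distinct_coverage)
  for (i in bad) {
    add(
      "read_support", "variants", i,
      paste0(v$mutant_reads[i], " mutant reads > coverage ", v$distinct_coverage[i])
    )
  }
  bad <- which(v$distinct_coverage < 1 | v$mutant_reads < 0)
  for (i in bad) add("coverage_positive", "variants", i, "nonpositive coverage or negative reads")

  dup <- v %>%
    count(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    filter(n > 1)
  for (i in seq_len(nrow(dup))) {
    add(
      "duplicate_variant_key", "variants", dup$sample_id[i],
      paste0(dup$chrom[i], ":", dup$pos[i], " ", dup$ref[i], ">", dup$alt[i])
    )
  }

  dupp <- s %>%
    filter(.data$compartment == "plasma") %>%
    count(.data$patient_id, .data$timepoint) %>%
    filter(n > 1)
  for (i in seq_len(nrow(dupp))) {
    add(
      "duplicate_plasma_timepoint", "samples", dupp$patient_id[i],
      paste0("multiple plasma samples at ", dupp$timepoint[i])
    )
  }
  dupw <- s %>%
    filter(.data$compartment == "wbc") %>%
    count(.data$patient_id) %>%
    filter(n > 1)
  for (i in seq_len(nrow(dupw))) {
    add("duplicate_wbc", "samples", dupw$patient_id[i], "more than one WBC sample")
  }
  badc <- which(!s$compartment %in% .compartments)
  for (i in badc) add("compartment", "samples", s$sample_id[i], s$compartment[i])

  both <- !is.na(p$pfs_months) & !is.na(p$os_months)
  bad <- which(both & p$pfs_months > p$os_months + 1e-9)
  for (i in bad) {
    add(
      "pfs_le_os", "patients", p$patient_id[i],
      paste0("pfs ", p$pfs_months[i], " > os ", p$os_months[i])
    )
  }
  badb <- which(!is.na(p$recist_bor) & !p$recist_bor %in% .recist_levels)
  for (i in badb) add("recist_bor", "patients", p$patient_id[i], p$recist_bor[i])
  badb <- which(!is.na(p$irecist_bor) & !p$irecist_bor %in% .irecist_levels)
  for (i in badb) add("irecist_bor", "patients", p$patient_id[i], p$irecist_bor[i])

  if (length(out) == 0) {
    tibble(
      rule = character(0), table = character(0), id = character(0),
      message = character(0)
    )
  } else {
    bind_rows(out)
  }
}

#' Ingest variant observations from a single-sample VCF
#'
#' Extracts one observation per alternate allele from a standard VCF.
#' Multiallelic records are decomposed into one observation per alt. The
#' allele-fraction and depth fields are named in `mapping`; each may refer to
#' an INFO field or a per-sample FORMAT field (searched in that order).
#' Records with allele fraction 0 are retained - filtering is the caller's
#' decision.
#'
#' @param vcf_path Path to a VCF (4.x, plain or bgzipped).
#' @param sample_id Sample identifier to stamp on the observations.
#' @param patient_id,timepoint,compartment Metadata for the observations.
#' @param mapping Named list with elements `af` and `dp` giving the field names
#'   holding the allele fraction and the distinct (error-corrected) depth.
#'   Default `list(af = "AF", dp = "DP")`.
#' @return Tibble of variant observations in the [cohort_dataset()] dialect.
#' @export
ingest_sample_vcf <- function(vcf_path, sample_id, patient_id,
                              timepoint = "C1D1", compartment = "plasma",
                              mapping = list(af = "AF", dp = "DP")) {
  if (!file.exists(vcf_path)) abort(paste0("File not found: ", vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      patient_id = character(0), sample_id = character(0),
      timepoint = character(0), compartment = character(0),
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), gene = character(0), protein_change = character(0),
      maf = double(0), mutant_reads = integer(0), distinct_coverage = integer(0)
    ))
  }

  get_field <- function(name) {
    info <- tryCatch(
      vcfR::extract.info(vcf, element = name, as.numeric = FALSE),
      error = function(e) NULL
    )
    if (!is.null(info) && !all(is.na(info))) {
      return(info)
    }
    gt <- tryCatch(
      vcfR::extract.gt(vcf, element = name, as.numeric = FALSE),
      error = function(e) NULL
    )
    if (!is.null(gt) && ncol(gt) >= 1 && !all(is.na(gt[, 1]))) {
      return(gt[, 1])
    }
    abort(
      paste0("VCF field '", name, "' not found in INFO or FORMAT of ", vcf_path),
      class = "ctdnamr_extraction_error"
    )
  }
  af_raw <- get_field(mapping$af)
  dp_raw <- get_field(mapping$dp)

  recs <- purrr::pmap(
    list(
      seq_len(nrow(fix)), fix$CHROM, fix$POS, fix$REF, fix$ALT,
      af_raw, dp_raw
    ),
    function(i, chrom, pos, ref, alt, af, dp) {
      alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
      afs <- suppressWarnings(as.numeric(strsplit(af, ",", fixed = TRUE)[[1]]))
      if (anyNA(afs)) {
        abort(
          paste0("Cannot parse allele fraction at record ", i, " (", af, ")"),
          class = "ctdnamr_extraction_error"
        )
      }
      if (length(afs) == 1 && length(alts) > 1) afs <- rep(afs, length(alts))
      if (length(afs) != length(alts)) {
        abort(
          paste0("Record ", i, ": ", length(alts), " alt allele(s) but ",
                 length(afs), " AF value(s)"),
          class = "ctdnamr_extraction_error"
        )
      }
      dpv <- suppressWarnings(as.integer(dp))
      if (is.na(dpv)) {
        abort(paste0("Cannot parse depth at record ", i),
          class = "ctdnamr_extraction_error"
        )
      }
      tibble(
        chrom = chrom, pos = as.integer(pos), ref = ref, alt = alts,
        maf = afs, distinct_coverage = dpv,
        mutant_reads = as.integer(round(afs * dpv))
      )
    }
  )
  bind_rows(recs) %>%
    mutate(
      patient_id = patient_id, sample_id = sample_id,
      timepoint = timepoint, compartment = compartment,
      gene = NA_character_, protein_change = NA_character_
    ) %>%
    select(
      "patient_id", "sample_id", "timepoint", "compartment", "chrom", "pos",
      "ref", "alt", "gene", "protein_change", "maf", "mutant_reads",
      "distinct_coverage"
    )
}

#' Write the analysis output file set
#'
#' Writes a deterministic set of result files (annotated variants, response
#' calls, concordance, ROC, LOD and survival summaries) and returns a manifest.
#' Re-running on identical inputs yields byte-identical files.
#'
#' @param results Named list as produced by [run_pipeline()]; recognised names:
#'   `annotated`, `calls`, `trajectories`, `concordance`, `depth`, `roc`,
#'   `lod`, `survival`, `validation`.
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest: file, rows, md5.
#' @export
write_analysis_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir))
  }
  manifest <- list()
  emit_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    df <- as_tibble(df)
    df[] <- lapply(df, function(col) if (is.factor(col)) as.character(col) else col)
    readr::write_tsv(df, p, progress = FALSE)
    manifest[[length(manifest) + 1]] <<- tibble(
      file = name, rows = nrow(df), md5 = unname(tools::md5sum(p))
    )
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    manifest[[length(manifest) + 1]] <<- tibble(
      file = name, rows = NA_integer_, md5 = unname(tools::md5sum(p))
    )
  }

  if (!is.null(results$validation)) emit_tsv(results$validation, "validation.tsv")
  if (!is.null(results$annotated)) emit_tsv(results$annotated, "annotated_variants.tsv")
  if (!is.null(results$trajectories)) emit_tsv(results$trajectories, "load_trajectories.tsv")
  if (!is.null(results$calls)) emit_tsv(results$calls, "response_calls.tsv")
  if (!is.null(results$depth)) emit_tsv(results$depth, "depth_of_response.tsv")
  if (!is.null(results$concordance)) emit_json(results$concordance, "concordance.json")
  if (!is.null(results$roc)) {
    emit_tsv(
      bind_rows(lapply(results$roc, function(r) tidy(r)), .id = "analysis"),
      "roc_curves.tsv"
    )
    emit_json(
      lapply(results$roc, function(r) as.list(glance(r))),
      "roc_summary.json"
    )
  }
  if (!is.null(results$lod)) {
    emit_tsv(tidy(results$lod), "lod.tsv")
    emit_json(as.list(glance(results$lod)), "lod_summary.json")
  }
  if (!is.null(results$survival)) emit_json(results$survival, "survival.json")
  bind_rows(manifest)
}
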