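# Hand-built miniature cohort used across the unit tests.
#
# Two patients:
#   P1 - WBC sample; a germline-like variant (>=40% everywhere incl. WBC), a
#        CHIP-like variant (low MAF, shared with WBC), a KRAS G12A hotspot
#        (present in WBC too: must stay tumor), and a plasma-only tumor
#        variant that clears at C2D1 and stays cleared. RECIST PR.
#   P2 - WBC sample; one plasma-only tumor variant persisting at all
#        timepoints. RECIST PD.
make_test_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2"),
    recist_bor = c("PR", "PD"),
    irecist_bor = c("iPR", "iPD"),
    pfs_months = c(8.0, 2.0), pfs_event = c(FALSE, TRUE),
    os_months = c(14.0, 6.0), os_event = c(FALSE, TRUE),
    first_response_day = c(84L, NA_integer_)
  )
  samples <- tibble::tibble(
    sample_id = c(
      "P1_C1_P", "P1_C2_P", "P1_C3_P", "P1_W",
      "P2_C1_P", "P2_C2_P", "P2_C3_P", "P2_W"
    ),
    patient_id = rep(c("P1", "P2"), each = 4),
    timepoint = rep(c("C1D1", "C2D1", "C3D1", "C1D1"), 2),
    compartment = rep(c("plasma", "plasma", "plasma", "wbc"), 2),
    collection_day = rep(c(0L, 21L, 42L, 0L), 2),
    available = TRUE
  )
  ov <- function(pid, sid, tp, comp, chrom, pos, ref, alt, gene, pc, maf) {
    cov <- 3000L
    tibble::tibble(
      patient_id = pid, sample_id = sid, timepoint = tp, compartment = comp,
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      gene = gene, protein_change = pc, maf = maf,
      mutant_reads = as.integer(max(1, round(maf * cov))),
      distinct_coverage = cov
    )
  }
  variants <- dplyr::bind_rows(
    # P1 germline-like: chr2:111 A>G, ~48-49% everywhere
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chr2", 111, "A", "G", "XRCC1", NA, 0.48),
    ov("P1", "P1_C2_P", "C2D1", "plasma", "chr2", 111, "A", "G", "XRCC1", NA, 0.50),
    ov("P1", "P1_C3_P", "C3D1", "plasma", "chr2", 111, "A", "G", "XRCC1", NA, 0.47),
    ov("P1", "P1_W", "C1D1", "wbc", "chr2", 111, "A", "G", "XRCC1", NA, 0.49),
    # P1 CHIP-like: chr4:222 C>T, ~2% plasma, 1.5% WBC
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chr4", 222, "C", "T", "TET2", NA, 0.02),
    ov("P1", "P1_C2_P", "C2D1", "plasma", "chr4", 222, "C", "T", "TET2", NA, 0.021),
    ov("P1", "P1_W", "C1D1", "wbc", "chr4", 222, "C", "T", "TET2", NA, 0.015),
    # P1 hotspot KRAS G12A, also in WBC (buffy-coat leak); clears at C2
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chr12", 25245350, "C", "G", "KRAS", "G12A", 0.0019),
    ov("P1", "P1_W", "C1D1", "wbc", "chr12", 25245350, "C", "G", "KRAS", "G12A", 0.001),
    # P1 plasma-only tumor variant: baseline 4%, cleared from C2 onward
    ov("P1", "P1_C1_P", "C1D1", "plasma", "chr17", 7578406, "C", "T", "TP53", "R175H", 0.04),
    # P2 plasma-only tumor variant persisting
    ov("P2", "P2_C1_P", "C1D1", "plasma", "chr9", 5073770, "G", "T", "JAK2", NA, 0.03),
    ov("P2", "P2_C2_P", "C2D1", "plasma", "chr9", 5073770, "G", "T", "JAK2", NA, 0.025),
    ov("P2", "P2_C3_P", "C3D1", "plasma", "chr9", 5073770, "G", "T", "JAK2", NA, 0.035)
  )
  ctdnamr::cohort_dataset(variants, samples, patients)
}

# Trajectory grid for a single synthetic patient given per-timepoint maxMAF
# values (NA = sample unavailable); mean/median set to maxMAF (single-variant
# patient), which response calling ignores anyway.
make_trajectory <- function(max_mafs, patient_id = "PX",
                            tps = c("C1D1", "C2D1", "C3D1")) {
  avail <- !is.na(max_mafs)
  tibble::tibble(
    patient_id = patient_id,
    timepoint = ctdnamr::as_timepoint(tps, tps),
    sample_available = avail,
    n_tracked = ifelse(avail, 1L, NA_integer_),
    n_detected = ifelse(avail & max_mafs > 0, 1L, ifelse(avail, 0L, NA_integer_)),
    max_maf = ifelse(avail, max_mafs, NA_real_),
    mean_maf = ifelse(avail, max_mafs, NA_real_),
    median_maf = ifelse(avail, max_mafs, NA_real_)
  )
}

# Clopper-Pearson lower bound by direct binomial-tail root finding:
# the largest p with P(Bin(n, p) >= k) <= alpha.
cp_lower_oracle <- function(k, n, alpha) {
  if (k == 0) return(0)
  f <- function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}
cp_upper_oracle <- function(k, n, alpha) {
  if (k == n) return(1)
  f <- function(p) pbinom(k, n, p) - alpha
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# Brute-force pairwise AUC: concordant pairs + half ties over all pos x neg.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
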