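#' Size-classification rule for peptide ions
#'
#' Di/tripeptides are separated from oligopeptides by neutral (uncharged)
#' mass, with an inclusive cutoff. The default 425 Da sits at the upper range
#' of common tripeptides; absolute size-fraction values depend on this choice
#' while comparisons between digests are stable under it.
#'
#' @param ditri_max_neutral_mass inclusive upper neutral-mass bound (Da) for
#'   the di/tripeptide class (default 425).
#' @param proton_mass proton mass in Da used to de-charge m/z.
#' @return object of class `size_class_rule`.
#' @export
size_class_rule <- function(ditri_max_neutral_mass = 425,
                            proton_mass = 1.007276) {
  stopifnot(ditri_max_neutral_mass > 0, proton_mass > 0)
  structure(list(ditri_max_neutral_mass = ditri_max_neutral_mass,
                 proton_mass = proton_mass),
            class = "size_class_rule")
}

#' Neutral mass of a peptide ion
#'
#' Standard de-charging relation for protonated positive-mode ions:
#' `(mz - proton_mass) * charge`, in Dalton.
#'
#' @param mz mass-to-charge ratio (Th). Vectorised.
#' @param charge charge state (>= 1).
#' @param rule a [size_class_rule()] (supplies the proton mass).
#' @return neutral mass(es) in Da.
#' @export
neutral_mass <- function(mz, charge, rule = size_class_rule()) {
  (mz - rule$proton_mass) * charge
}

#' Classify peptide ions into di/tri vs oligopeptide size classes
#'
#' @param mz,charge ion coordinates (vectorised).
#' @param rule a [size_class_rule()].
#' @return character vector, `"ditri"` (neutral mass <= cutoff, inclusive) or
#'   `"oligo"`.
#' @export
classify_size <- function(mz, charge, rule = size_class_rule()) {
  ifelse(neutral_mass(mz, charge, rule) <= rule$ditri_max_neutral_mass,
         "ditri", "oligo")
}

#' Per-digest characteristics from a benchmark match
#'
#' Derives the five digest characteristics used for proteomic clustering:
#' (a) abundance fractions of di/tri- vs oligopeptide ions (complementary,
#' abundance-weighted), (b) total retained abundance, (c) number of unique
#' (non-benchmark-overlapping) ions, (d) overlapping-ion count as a percentage
#' of retained ions, and (e) overlapping-ion abundance as a percentage of
#' total retained abundance.
#'
#' @param digest the retained (filtered, blank-corrected) `ion_table` the
#'   match was computed from.
#' @param match the `match_result` of `digest` against the benchmark.
#' @param rule a [size_class_rule()].
#' @return one-row data frame with columns `source_id`, `replicate_id`,
#'   `frac_ditri`, `frac_oligo`, `total_abundance`, `n_unique`,
#'   `pct_overlap`, `pct_abundance_overlap`, `n_retained`, `n_overlapping`.
#' @export
compute_features <- function(digest, match, rule = size_class_rule()) {
  if (match$audit$n_query_in != nrow(digest)) {
    stop("match result was not produced from this digest table (",
         match$audit$n_query_in, " query ions vs ", nrow(digest), " rows)")
  }
  n_ret <- nrow(digest)
  total_ab <- sum(digest$abundance)
  n_over <- match$audit$n_matched
  n_unique <- match$audit$n_unmatched
  if (n_ret == 0L) {
    warning("empty digest [", source_id(digest), "/", replicate_id(digest),
            "]: percentages and fractions defined as 0")
    frac_ditri <- frac_oligo <- pct_overlap <- pct_ab_overlap <- 0
  } else {
    cls <- classify_size(digest$mz, digest$charge, rule)
    if (total_ab > 0) {
      frac_ditri <- sum(digest$abundance[cls == "ditri"]) / total_ab
      frac_oligo <- 1 - frac_ditri
      pct_ab_overlap <- 100 * sum(match$pairs$query_abundance) / total_ab
    } else {
      frac_ditri <- frac_oligo <- pct_ab_overlap <- 0
    }
    pct_overlap <- 100 * n_over / n_ret
  }
  data.frame(source_id = source_id(digest), replicate_id = replicate_id(digest),
             frac_ditri = frac_ditri, frac_oligo = frac_oligo,
             total_abundance = total_ab, n_unique = n_unique,
             pct_overlap = pct_overlap,
             pct_abundance_overlap = pct_ab_overlap,
             n_retained = n_ret, n_overlapping = n_over,
             stringsAsFactors = FALSE)
}

#' Overlap export tables for tile and abundance-comparison plots
#'
#' The tile table has one row per benchmark ion with an overlap indicator and
#' size class; the comparison table has, per overlapping benchmark ion, the
#' benchmark abundance next to the summed abundance of the digest ions
#' assigned to it.
#'
#' @param match a `match_result` of the digest against the benchmark.
#' @param digest the digest `ion_table` the match was computed from.
#' @param benchmark the reference `ion_table` used in the match.
#' @param rule a [size_class_rule()].
#' @return list with data frames `tile` (`ref_id`, `mz`, `charge`, `rt`,
#'   `size_class`, `overlapping`) and `comparison` (`ref_id`,
#'   `benchmark_abundance`, `digest_abundance`).
#' @export
export_overlap_tables <- function(match, digest, benchmark,
                                  rule = size_class_rule()) {
  tile <- data.frame(
    ref_id = benchmark$ion_id,
    mz = benchmark$mz,
    charge = benchmark$charge,
    rt = benchmark$rt,
    size_class = classify_size(benchmark$mz, benchmark$charge, rule),
    overlapping = benchmark$ion_id %in% match$pairs$ref_id,
    stringsAsFactors = FALSE)
  comparison <- merge(
    data.frame(ref_id = benchmark$ion_id,
               benchmark_abundance = benchmark$abundance),
    stats::setNames(match$ref_abundance, c("ref_id", "digest_abundance")),
    by = "ref_id")
  comparison <- comparison[order(comparison$ref_id), , drop = FALSE]
  rownames(comparison) <- NULL
  list(tile = tile, comparison = comparison)
}
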