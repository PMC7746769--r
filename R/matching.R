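#' Matching tolerances for ion-peak comparison
#'
#' Ion peaks from separate samples are considered candidate matches when their
#' charges are equal and their absolute m/z and retention-time differences are
#' within tolerance (inclusive bounds). The two dimensions are weighed equally
#' by scaling m/z differences with `weight = rt_tol / mz_tol`, so that one m/z
#' tolerance equals one retention-time tolerance (0.003 Th = 0.5 min at the
#' defaults).
#'
#' @param mz_tol m/z tolerance in Thomson (default 0.003).
#' @param rt_tol retention-time tolerance in minutes (default 0.5).
#' @return object of class `match_tolerances` with fields `mz_tol`, `rt_tol`
#'   and the derived `weight` (rt-equivalent minutes per Thomson).
#' @export
match_tolerances <- function(mz_tol = 0.003, rt_tol = 0.5) {
  stopifnot(is.numeric(mz_tol), mz_tol > 0, is.numeric(rt_tol), rt_tol > 0)
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol, weight = rt_tol / mz_tol),
            class = "match_tolerances")
}

#' Weighted two-dimensional match distance
#'
#' The Pythagorean distance between two ion peaks in (m/z, retention time)
#' space, with the m/z axis rescaled by `rt_tol / mz_tol` so both matching
#' criteria carry equal weight:
#' `sqrt((delta_mz * weight)^2 + delta_rt^2)`, in retention-time-equivalent
#' minutes. Used to pick the nearest reference peak among tolerance
#' candidates.
#'
#' @param delta_mz m/z difference in Thomson (sign irrelevant). Vectorised.
#' @param delta_rt retention-time difference in minutes (sign irrelevant).
#' @param tol a [match_tolerances()].
#' @return non-negative distance(s) in rt-equivalent minutes.
#' @examples
#' eq1_distance(0.003, 0)    # 0.5: one mz tolerance equals one rt tolerance
#' eq1_distance(0.003, 0.5)  # sqrt(0.25 + 0.25)
#' @export
eq1_distance <- function(delta_mz, delta_rt, tol = match_tolerances()) {
  sqrt((delta_mz * tol$weight)^2 + delta_rt^2)
}

#' Tolerance predicate for a candidate ion-peak match
#'
#' `TRUE` iff the charges are equal, `|delta mz| <= mz_tol` and
#' `|delta rt| <= rt_tol` (inclusive bounds).
#'
#' @param q,r single-row data frames or lists with `mz`, `charge`, `rt`.
#' @param tol a [match_tolerances()].
#' @return logical.
#' @export
tolerance_match_predicate <- function(q, r, tol = match_tolerances()) {
  q$charge == r$charge &&
    abs(q$mz - r$mz) <= tol$mz_tol &&
    abs(q$rt - r$rt) <= tol$rt_tol
}

#' Exclude low-abundance ion peaks
#'
#' Removes ions whose raw abundance is strictly below `threshold` (the study
#' regime excludes raw abundance < 1e5); ions at exactly the threshold are
#' retained. Row order is preserved.
#'
#' @param table an `ion_table`.
#' @param threshold abundance threshold (default 1e5).
#' @return list with `table` (retained ions) and `n_excluded`.
#' @export
filter_low_abundance <- function(table, threshold = 1e5) {
  stopifnot(threshold >= 0)
  keep <- table$abundance >= threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_id") <- attr(table, "source_id")
  attr(out, "replicate_id") <- attr(table, "replicate_id")
  class(out) <- class(table)
  list(table = out, n_excluded = sum(!keep))
}

# Nearest reference candidate per query ion. Returns, per query row, the row
# index of the matched reference (NA if no tolerance candidate) and the match
# distance. Uses per-charge mz-sorted windows; ties on distance are broken by
# smaller |delta mz|, then smaller reference ion_id.
.nearest_reference <- function(query, reference, tol) {
  n_q <- nrow(query)
  ref_row <- rep(NA_integer_, n_q)
  dist <- rep(NA_real_, n_q)
  if (n_q == 0L || nrow(reference) == 0L) {
    return(list(ref_row = ref_row, distance = dist))
  }
  for (z in intersect(unique(query$charge), unique(reference$charge))) {
    qi <- which(query$charge == z)
    ri <- which(reference$charge == z)
    ord <- ri[order(reference$mz[ri])]
    smz <- reference$mz[ord]
    lo <- findInterval(query$mz[qi] - tol$mz_tol, smz, left.open = TRUE) + 1L
    hi <- findInterval(query$mz[qi] + tol$mz_tol, smz)
    for (j in seq_along(qi)) {
      if (lo[j] > hi[j]) next
      cand <- ord[lo[j]:hi[j]]
      dmz <- reference$mz[cand] - query$mz[qi[j]]
      drt <- reference$rt[cand] - query$rt[qi[j]]
      ok <- abs(dmz) <= tol$mz_tol & abs(drt) <= tol$rt_tol
      if (!any(ok)) next
      cand <- cand[ok]; dmz <- dmz[ok]; drt <- drt[ok]
      d <- sqrt((dmz * tol$weight)^2 + drt^2)
      best <- which(d == min(d))
      if (length(best) > 1L) {
        best <- best[abs(dmz[best]) == min(abs(dmz[best]))]
        if (length(best) > 1L) {
          ids <- reference$ion_id[cand[best]]
          best <- best[order(ids)[1L]]
        }
      }
      best <- best[1L]
      ref_row[qi[j]] <- cand[best]
      dist[qi[j]] <- d[best]
    }
  }
  list(ref_row = ref_row, distance = dist)
}

#' Match a query ion table to a reference (benchmark) table
#'
#' Each query ion is assigned to the nearest reference ion among those passing
#' the tolerance predicate, nearness measured with [eq1_distance()]. Ties are
#' broken deterministically: smaller absolute m/z difference, then smaller
#' reference `ion_id`. A query ion is assigned to at most one reference ion;
#' a reference ion may collect several query ions, whose abundances are summed
#' in the per-reference aggregate.
#'
#' @param query,reference validated `ion_table`s (typically already
#'   abundance-filtered and blank-corrected).
#' @param tol a [match_tolerances()].
#' @return object of class `match_result`: list with
#'   `pairs` (data frame: `query_id`, `ref_id`, `distance`,
#'   `query_abundance`), `unmatched_query` (ion ids),
#'   `ref_abundance` (data frame: `ref_id`, `total_abundance`), and
#'   `audit` (`n_query_in`, `n_matched`, `n_unmatched`).
#' @export
match_to_reference <- function(query, reference, tol = match_tolerances()) {
  validate_ion_table(query)
  validate_ion_table(reference)
  nn <- .nearest_reference(query, reference, tol)
  matched <- !is.na(nn$ref_row)
  pairs <- data.frame(
    query_id = query$ion_id[matched],
    ref_id = reference$ion_id[nn$ref_row[matched]],
    distance = nn$distance[matched],
    query_abundance = query$abundance[matched],
    stringsAsFactors = FALSE)
  ref_abundance <- if (nrow(pairs) > 0L) {
    agg <- stats::aggregate(query_abundance ~ ref_id, pairs, sum)
    names(agg) <- c("ref_id", "total_abundance")
    agg
  } else {
    data.frame(ref_id = reference$ion_id[0], total_abundance = numeric(0))
  }
  structure(list(
    pairs = pairs,
    unmatched_query = query$ion_id[!matched],
    ref_abundance = ref_abundance,
    audit = list(n_query_in = nrow(query), n_matched = sum(matched),
                 n_unmatched = sum(!matched))),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d/%d query ions matched (%d unmatched)\n",
              x$audit$n_matched, x$audit$n_query_in, x$audit$n_unmatched))
  invisible(x)
}

#' Subtract enzyme-blank ion peaks from a table
#'
#' Removes every ion for which at least one blank ion passes the tolerance
#' predicate (same charge, m/z and retention time within tolerance). Exclusion
#' needs no nearest-match ranking, so only the predicate is applied.
#' Idempotent: subtracting the same blank twice removes nothing new.
#'
#' @param table,blank `ion_table`s (typically abundance-filtered).
#' @param tol a [match_tolerances()].
#' @return list with `table` (remainder) and `n_excluded`.
#' @export
subtract_blank <- function(table, blank, tol = match_tolerances()) {
  nn <- .nearest_reference(table, blank, tol)
  keep <- is.na(nn$ref_row)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_id") <- attr(table, "source_id")
  attr(out, "replicate_id") <- attr(table, "replicate_id")
  class(out) <- class(table)
  list(table = out, n_excluded = sum(!keep))
}

#' Per-table filtering audit
#'
#' Book-keeping for the noise-correction steps: every observed ion is either
#' excluded by the abundance filter, excluded by blank overlap, or retained.
#' The constructor enforces the conservation identity
#' `n_observed = n_abundance_excluded + n_blank_excluded + n_retained`.
#'
#' @param n_observed,n_abundance_excluded,n_blank_excluded,n_retained
#'   non-negative integer counts.
#' @return object of class `filter_audit`.
#' @export
filter_audit <- function(n_observed, n_abundance_excluded, n_blank_excluded,
                         n_retained) {
  counts <- c(n_observed = n_observed,
              n_abundance_excluded = n_abundance_excluded,
              n_blank_excluded = n_blank_excluded,
              n_retained = n_retained)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("filter_audit counts must be non-negative integers")
  }
  if (n_observed != n_abundance_excluded + n_blank_excluded + n_retained) {
    stop(sprintf(paste0("filter_audit conservation violated: %d observed != ",
                        "%d abundance-excluded + %d blank-excluded + %d retained"),
                 n_observed, n_abundance_excluded, n_blank_excluded, n_retained))
  }
  structure(as.list(counts), class = "filter_audit")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat(sprintf(paste0("filter_audit: %d observed = %d abundance-excluded + ",
                     "%d blank-excluded + %d retained\n"),
              x$n_observed, x$n_abundance_excluded, x$n_blank_excluded,
              x$n_retained))
  invisible(x)
}

#' Run the full noise-correction and benchmark-matching pipeline
#'
#' Applies, in study order: the raw-abundance filter to every table (digests,
#' blank, benchmark), blank subtraction to the digests (and, by default, to
#' the benchmark itself), then nearest-match assignment of every digest to the
#' blank-corrected benchmark.
#'
#' @param digests list of `ion_table`s (one per source x replicate).
#' @param blank the enzyme-only `ion_table`.
#' @param benchmark the benchmark-protein `ion_table` (e.g. WPC).
#' @param tol a [match_tolerances()].
#' @param threshold abundance filter threshold (default 1e5).
#' @param blank_subtract_benchmark also blank-correct the benchmark before it
#'   serves as matching reference (default `TRUE`).
#' @return list with per-digest results (`match` a `match_result`, `audit` a
#'   [filter_audit()], `table` the retained digest ions) under
#'   `$digests` (named by `source_id/replicate_id`), plus `$benchmark` (the
#'   corrected benchmark table) and `$blank` (the filtered blank).
#' @export
run_matching_pipeline <- function(digests, blank, benchmark,
                                  tol = match_tolerances(), threshold = 1e5,
                                  blank_subtract_benchmark = TRUE) {
  if (is.null(benchmark) || nrow(benchmark) == 0L) {
    stop("configuration error: benchmark ion table is absent or empty")
  }
  if (inherits(digests, "ion_table")) digests <- list(digests)
  blank_f <- filter_low_abundance(blank, threshold)$table
  bench_f <- filter_low_abundance(benchmark, threshold)$table
  if (blank_subtract_benchmark) {
    bench_f <- subtract_blank(bench_f, blank_f, tol)$table
  }
  out <- lapply(digests, function(dg) {
    n_obs <- nrow(dg)
    ab <- filter_low_abundance(dg, threshold)
    bl <- subtract_blank(ab$table, blank_f, tol)
    audit <- filter_audit(n_obs, ab$n_excluded, bl$n_excluded, nrow(bl$table))
    match <- match_to_reference(bl$table, bench_f, tol)
    list(match = match, audit = audit, table = bl$table)
  })
  names(out) <- vapply(digests, function(dg) {
    paste(source_id(dg), replicate_id(dg), sep = "/")
  }, character(1))
  list(digests = out, benchmark = bench_f, blank = blank_f)
}

#' Serialize a match result to JSON
#' @param match a `match_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_match_result_json <- function(match, path) {
  jsonlite::write_json(
    list(pairs = match$pairs, unmatched_query = match$unmatched_query,
         ref_abundance = match$ref_abundance, audit = match$audit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
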