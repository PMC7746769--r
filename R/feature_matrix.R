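#' Assemble a sources x features matrix from per-replicate records
#'
#' Replicate means are computed for each (source, feature) cell; the result is
#' one row per source, one column per requested feature, unstandardized.
#'
#' @param records data frame with `source_id`, `replicate_id` and one column
#'   per feature (e.g. the output of [compute_features()] row-bound across
#'   digests), or a long table with columns `variable` and `value` (e.g. a
#'   `bio_readout_table`).
#' @param feature_list character vector of feature (or variable) names to
#'   keep, in column order. Defaults to every feature present.
#' @return a `feature_matrix`: numeric matrix with source row names, feature
#'   column names and attribute `standardized = FALSE`.
#' @export
build_feature_matrix <- function(records, feature_list = NULL) {
  stopifnot(is.data.frame(records), "source_id" %in% names(records))
  long <- all(c("variable", "value") %in% names(records))
  if (long) {
    feats <- if (is.null(feature_list)) unique(records$variable) else feature_list
    sources <- unique(records$source_id)
    m <- matrix(NA_real_, length(sources), length(feats),
                dimnames = list(sources, feats))
    agg <- stats::aggregate(value ~ source_id + variable, records, mean)
    agg <- agg[agg$variable %in% feats, , drop = FALSE]
    m[cbind(match(agg$source_id, sources), match(agg$variable, feats))] <-
      agg$value
  } else {
    all_feats <- setdiff(names(records),
                         c("source_id", "replicate_id"))
    feats <- if (is.null(feature_list)) all_feats else feature_list
    missing_feats <- setdiff(feats, names(records))
    if (length(missing_feats) > 0L) {
      stop("feature(s) absent from records: ",
           paste(missing_feats, collapse = ", "))
    }
    sources <- unique(records$source_id)
    m <- matrix(NA_real_, length(sources), length(feats),
                dimnames = list(sources, feats))
    for (f in feats) {
      agg <- stats::aggregate(records[[f]],
                              by = list(source_id = records$source_id), mean)
      m[match(agg$source_id, sources), f] <- agg$x
    }
  }
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("missing (source, feature) cell(s): ",
         paste(sprintf("%s/%s", rownames(m)[idx[, 1]], colnames(m)[idx[, 2]]),
               collapse = ", "))
  }
  attr(m, "standardized") <- FALSE
  class(m) <- c("feature_matrix", class(m))
  m
}

#' Column-wise z-standardization of a feature matrix
#'
#' Centers each column to mean zero and scales to sample standard deviation
#' one (n-1 convention). Idempotent up to floating tolerance.
#'
#' @param m a `feature_matrix` or plain numeric matrix.
#' @return the standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize <- function(m) {
  cls <- class(m)
  m <- unclass(m)
  sds <- apply(m, 2, stats::sd)
  zero_var <- which(!is.finite(sds) | sds == 0)
  if (length(zero_var) > 0L) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[zero_var], collapse = ", "))
  }
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  class(out) <- unique(c("feature_matrix", setdiff(cls, "feature_matrix")))
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d sources x %d features (%s)\n", nrow(x),
              ncol(x),
              if (isTRUE(attr(x, "standardized"))) "standardized" else "raw"))
  print(unclass(x), ...)
  invisible(x)
}
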