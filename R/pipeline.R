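#' Feature presets for the three clustering analyses
#'
#' `"proteomic"`: five digest characteristics. The two size fractions are
#' complementary (`frac_oligo = 1 - frac_ditri`), so after standardization
#' they are exactly collinear and would make every full-covariance family
#' singular; the preset therefore keeps `frac_ditri` only, while both
#' fractions remain exported and the feature list stays configurable.
#' `"proteomic_combined"`: the four proteomic columns entering the combined
#' analysis (total abundance, unique ions, and the two overlap percentages).
#' `"biological"`: the seven assay read-outs.
#'
#' @param preset one of `"proteomic"`, `"proteomic_combined"`,
#'   `"biological"`.
#' @return character vector of feature names.
#' @export
feature_preset <- function(preset = c("proteomic", "proteomic_combined",
                                      "biological")) {
  preset <- match.arg(preset)
  switch(preset,
    proteomic = c("frac_ditri", "total_abundance", "n_unique",
                  "pct_overlap", "pct_abundance_overlap"),
    proteomic_combined = c("total_abundance", "n_unique", "pct_overlap",
                           "pct_abundance_overlap"),
    biological = c("inulin_fitc_leakage", "zo1_intersections",
                   "cell_viability", "alp_activity", "il6", "tgfb", "no"))
}

#' Proteomic analysis: filtering, matching, characteristics and clustering
#'
#' Executes the proteomic arm end to end: abundance filter, blank
#' subtraction, benchmark matching, per-replicate digest characteristics,
#' replicate-mean feature matrix, z-standardization, and the BIC model sweep.
#' The blank serves as subtraction reference only and is not a clustered row.
#'
#' @param digests list of per-replicate digest `ion_table`s.
#' @param blank enzyme-blank `ion_table`.
#' @param benchmark benchmark `ion_table` (e.g. WPC).
#' @param tol a [match_tolerances()].
#' @param threshold abundance filter threshold (default 1e5).
#' @param rule a [size_class_rule()].
#' @param feature_list features to cluster on (default
#'   `feature_preset("proteomic")`).
#' @param families,k_range,n_restarts,seed model sweep settings, see
#'   [select_model()].
#' @return list with `pipeline` (per-digest match/audit/table), `features`
#'   (per-replicate records), `matrix` (standardized `feature_matrix`),
#'   `selection` (`model_selection`) and `assignments` (data frame).
#' @export
run_proteomic_analysis <- function(digests, blank, benchmark,
                                   tol = match_tolerances(), threshold = 1e5,
                                   rule = size_class_rule(),
                                   feature_list = feature_preset("proteomic"),
                                   families = MIXTURE_FAMILIES,
                                   k_range = 1:6, n_restarts = 10L,
                                   seed = 1L) {
  pipe <- run_matching_pipeline(digests, blank, benchmark, tol = tol,
                                threshold = threshold)
  features <- do.call(rbind, lapply(pipe$digests, function(res) {
    compute_features(res$table, res$match, rule)
  }))
  rownames(features) <- NULL
  m <- build_feature_matrix(features, feature_list)
  ms <- standardize(m)
  selection <- select_model(ms, families = families, k_range = k_range,
                            n_restarts = n_restarts, seed = seed)
  list(pipeline = pipe, features = features, matrix = ms,
       selection = selection,
       assignments = data.frame(source_id = rownames(ms),
                                cluster = selection$best$assignments,
                                stringsAsFactors = FALSE))
}

#' Biological analysis: outlier screening, benchmark tests and clustering
#'
#' Grubbs-screens every (source, variable) replicate group, compares each
#' source to the benchmark (t-tests and one-way ANOVA), computes replicate
#' means, z-standardizes, and runs the BIC model sweep. The blank sample, if
#' present, participates as an ordinary data row.
#'
#' @param bio a `bio_readout_table`.
#' @param benchmark benchmark source label (default `"WPC"`).
#' @param alpha significance level for screening and tests (default 0.05).
#' @param variables variables to cluster on (default: all present).
#' @param families,k_range,n_restarts,seed model sweep settings.
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @return list with `cleaned` (screened table), `outliers`, `tests`
#'   (from [compare_to_benchmark()]), `matrix` (standardized), `selection`
#'   and `assignments`.
#' @export
run_biological_analysis <- function(bio, benchmark = "WPC", alpha = 0.05,
                                    variables = NULL,
                                    families = MIXTURE_FAMILIES,
                                    k_range = 1:6, n_restarts = 10L,
                                    seed = 1L, var_equal = FALSE) {
  scr <- screen_outliers(bio, alpha = alpha)
  tests <- compare_to_benchmark(scr$cleaned, benchmark = benchmark,
                                alpha = alpha, var_equal = var_equal)
  m <- build_feature_matrix(scr$cleaned, variables)
  ms <- standardize(m)
  selection <- select_model(ms, families = families, k_range = k_range,
                            n_restarts = n_restarts, seed = seed)
  list(cleaned = scr$cleaned, outliers = scr$outliers, tests = tests,
       matrix = ms, selection = selection,
       assignments = data.frame(source_id = rownames(ms),
                                cluster = selection$best$assignments,
                                stringsAsFactors = FALSE))
}

#' Combined analysis: joined proteomic + biological clustering
#'
#' Joins the proteomic and biological replicate-mean feature matrices by
#' source (sources missing from either side are dropped with a warning),
#' standardizes the joined columns jointly, and runs the BIC model sweep.
#' With the default presets the joined matrix has 11 columns, the biological
#' variables outnumbering the proteomic ones 7:4.
#'
#' @param proteomic_matrix unstandardized proteomic `feature_matrix` (or the
#'   per-replicate `features` records, which are averaged here).
#' @param bio_matrix unstandardized biological `feature_matrix` (or a
#'   `bio_readout_table`).
#' @param proteomic_features proteomic columns to keep (default
#'   `feature_preset("proteomic_combined")`).
#' @param bio_features biological columns to keep (default: all).
#' @param families,k_range,n_restarts,seed model sweep settings.
#' @return list with `matrix` (standardized joined matrix), `selection` and
#'   `assignments`.
#' @export
run_combined_analysis <- function(proteomic_matrix, bio_matrix,
                                  proteomic_features =
                                    feature_preset("proteomic_combined"),
                                  bio_features = NULL,
                                  families = MIXTURE_FAMILIES,
                                  k_range = 1:4, n_restarts = 10L,
                                  seed = 1L) {
  if (is.data.frame(proteomic_matrix)) {
    proteomic_matrix <- build_feature_matrix(proteomic_matrix,
                                             proteomic_features)
  }
  if (is.data.frame(bio_matrix)) {
    bio_matrix <- build_feature_matrix(bio_matrix, bio_features)
  }
  pm <- unclass(proteomic_matrix)[, intersect(proteomic_features,
                                              colnames(proteomic_matrix)),
                                  drop = FALSE]
  bm <- unclass(bio_matrix)
  if (!is.null(bio_features)) bm <- bm[, bio_features, drop = FALSE]
  shared <- intersect(rownames(pm), rownames(bm))
  if (length(shared) == 0L) {
    stop("no sources shared between proteomic and biological matrices")
  }
  dropped <- setdiff(union(rownames(pm), rownames(bm)), shared)
  if (length(dropped) > 0L) {
    warning("sources present on one side only, dropped from combined ",
            "analysis: ", paste(dropped, collapse = ", "))
  }
  joined <- cbind(pm[shared, , drop = FALSE], bm[shared, , drop = FALSE])
  attr(joined, "standardized") <- FALSE
  class(joined) <- c("feature_matrix", class(joined))
  ms <- standardize(joined)
  selection <- select_model(ms, families = families, k_range = k_range,
                            n_restarts = n_restarts, seed = seed)
  list(matrix = ms, selection = selection,
       assignments = data.frame(source_id = rownames(ms),
                                cluster = selection$best$assignments,
                                stringsAsFactors = FALSE))
}
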