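#' Two-sided single-outlier Grubbs test
#'
#' Tests the most extreme value of a small replicate group:
#' `G = max |x_i - mean(x)| / sd(x)`, compared against the t-based critical
#' value `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the upper
#' `alpha/(2n)` quantile of the t-distribution on `n-2` degrees of freedom.
#' At most one outlier is flagged per call; a constant vector has `G = 0` and
#' no outlier.
#'
#' @param values numeric vector of replicate measurements (n >= 3, finite).
#' @param alpha significance level (default 0.05).
#' @return object of class `grubbs_result`: list with `g_statistic`,
#'   `critical_value`, `outlier_index` (`NA` if none), `alpha`, `n`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("Grubbs test requires at least 3 values, got ", n)
  if (any(!is.finite(values))) stop("Grubbs test requires finite values")
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  s <- stats::sd(values)
  if (s == 0) {
    return(structure(list(g_statistic = 0, critical_value = crit,
                          outlier_index = NA_integer_, alpha = alpha, n = n),
                     class = "grubbs_result"))
  }
  dev <- abs(values - mean(values)) / s
  g <- max(dev)
  idx <- if (g > crit) which.max(dev) else NA_integer_
  structure(list(g_statistic = g, critical_value = crit, outlier_index = idx,
                 alpha = alpha, n = n), class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("grubbs_result: G = %.4f vs %.4f (alpha %.3g, n %d): %s\n",
              x$g_statistic, x$critical_value, x$alpha, x$n,
              if (is.na(x$outlier_index)) "no outlier"
              else paste("outlier at index", x$outlier_index)))
  invisible(x)
}

#' Grubbs outlier screening of a biological read-out table
#'
#' Applies [grubbs_test()] to every (source, variable) replicate group and
#' removes flagged values. By default a single pass is made (at most one
#' outlier removed per group); `iterative = TRUE` repeats until no group
#' flags, still one value per pass per group.
#'
#' @param bio a `bio_readout_table` (long).
#' @param alpha significance level (default 0.05).
#' @param iterative repeat screening until clean (default `FALSE`).
#' @return list with `cleaned` (the table minus flagged rows) and `outliers`
#'   (data frame: `source_id`, `replicate_id`, `variable`, `value`,
#'   `g_statistic`).
#' @export
screen_outliers <- function(bio, alpha = 0.05, iterative = FALSE) {
  df <- as.data.frame(bio)
  removed <- df[0, , drop = FALSE]
  removed$g_statistic <- numeric(0)
  repeat {
    key <- interaction(df$source_id, df$variable, drop = TRUE)
    drop_rows <- integer(0)
    gstats <- numeric(0)
    for (grp in levels(key)) {
      rows <- which(key == grp)
      if (length(rows) < 3L) next
      res <- grubbs_test(df$value[rows], alpha = alpha)
      if (!is.na(res$outlier_index)) {
        drop_rows <- c(drop_rows, rows[res$outlier_index])
        gstats <- c(gstats, res$g_statistic)
      }
    }
    if (length(drop_rows) == 0L) break
    rem <- df[drop_rows, , drop = FALSE]
    rem$g_statistic <- gstats
    removed <- rbind(removed, rem)
    df <- df[-drop_rows, , drop = FALSE]
    if (!iterative) break
  }
  rownames(df) <- NULL
  rownames(removed) <- NULL
  class(df) <- c("bio_readout_table", "data.frame")
  list(cleaned = df, outliers = removed)
}

#' Normalize assay values to a run control
#'
#' Divides each value by the mean of the paired run's control measurements;
#' `scale = 100` expresses the result as percent of control (the convention
#' for viability, where the unexposed control is set to 100%).
#'
#' @param values numeric vector of per-source replicate values.
#' @param control numeric vector of the run's control values.
#' @param scale multiplier applied after division (default 1).
#' @return numeric vector of relative values.
#' @export
normalize_to_control <- function(values, control, scale = 1) {
  m <- mean(control)
  if (!is.finite(m) || m <= 0) {
    stop("control mean must be positive, got ", m)
  }
  values / m * scale
}

#' Compare every source to the benchmark per assay variable
#'
#' For each variable, a two-sample t-test of each non-benchmark source against
#' the benchmark (Welch by default) plus a one-way ANOVA across all sources.
#' No multiple-testing correction is applied by default; an optional
#' Benjamini-Hochberg adjustment of the t-test p-values is available.
#'
#' @param bio a `bio_readout_table`, ideally after [screen_outliers()].
#' @param benchmark source label of the reference protein (default `"WPC"`).
#' @param alpha significance level (default 0.05).
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return list with `t_tests` (data frame: `source_id`, `variable`, `n1`,
#'   `n2`, `statistic`, `p`, `significant`, `testable`) and `anova`
#'   (data frame: `variable`, `f_statistic`, `p`, `significant`).
#' @export
compare_to_benchmark <- function(bio, benchmark = "WPC", alpha = 0.05,
                                 var_equal = FALSE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  df <- as.data.frame(bio)
  if (!benchmark %in% df$source_id) {
    stop("benchmark source '", benchmark, "' absent from bio table")
  }
  vars <- unique(df$variable)
  sources <- setdiff(unique(df$source_id), benchmark)
  rows <- list()
  arows <- list()
  for (v in vars) {
    sub <- df[df$variable == v, , drop = FALSE]
    ref <- sub$value[sub$source_id == benchmark]
    for (s in sources) {
      x <- sub$value[sub$source_id == s]
      testable <- length(x) >= 2L && length(ref) >= 2L &&
        (stats::sd(x) > 0 || stats::sd(ref) > 0)
      if (testable) {
        tt <- stats::t.test(x, ref, var.equal = var_equal)
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = s, variable = v, n1 = length(x), n2 = length(ref),
          statistic = unname(tt$statistic), p = tt$p.value,
          testable = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = s, variable = v, n1 = length(x), n2 = length(ref),
          statistic = NA_real_, p = NA_real_, testable = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    if (length(unique(sub$source_id)) >= 2L) {
      fit <- stats::aov(value ~ source_id, data = sub)
      an <- summary(fit)[[1]]
      arows[[length(arows) + 1L]] <- data.frame(
        variable = v, f_statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
        stringsAsFactors = FALSE)
    }
  }
  t_tests <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    t_tests$p <- stats::p.adjust(t_tests$p, method = "BH")
  }
  t_tests$significant <- !is.na(t_tests$p) & t_tests$p < alpha
  anova <- do.call(rbind, arows)
  anova$significant <- anova$p < alpha
  list(t_tests = t_tests, anova = anova)
}
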