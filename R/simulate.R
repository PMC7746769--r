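#' Configuration for synthetic ion-table generation
#'
#' The generator emulates the acquisition regime of a 40-minute LC-MS run
#' over a 70-1200 Th window: uniform (m/z, retention time) positions, charges
#' 1-3, and log-normal raw abundances placed so that roughly a quarter of the
#' mass falls below the 1e5 abundance filter threshold (so the filter is
#' always exercised). Digest tables are built from a benchmark table by
#' copying a controlled fraction of benchmark ions with sub-tolerance jitter,
#' adding unique ions placed outside tolerance of every benchmark ion, and
#' contaminating with jittered copies of blank (enzyme-only) ions. The
#' default jitter standard deviations (0.0008 Th, 0.1 min) keep more than 99%
#' of planted overlaps inside the 0.003 Th / 0.5 min tolerance box (3.75 and
#' 5 sigma respectively).
#'
#' @param seed integer seed; all generators are bitwise reproducible given
#'   the configuration.
#' @param n_benchmark_ions ions in the benchmark table (default 500).
#' @param n_digest_ions ions per digest table before blank contamination
#'   (default 1000); the overlap count is `round(overlap_fraction *
#'   n_digest_ions)` and the remainder are unique ions.
#' @param n_blank_ions ions in the enzyme-blank table (default 150).
#' @param mz_range m/z window in Thomson (default `c(70, 1200)`).
#' @param rt_range retention-time window in minutes (default `c(0, 40)`).
#' @param charge_probs sampling weights over charges 1, 2, 3.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters
#'   (defaults put ~25% of mass below 1e5).
#' @param overlap_fraction fraction of digest ions copied from benchmark ions
#'   in `[0, 1]`.
#' @param mz_jitter_sd,rt_jitter_sd jitter SDs applied to planted copies.
#' @param blank_contamination_fraction extra digest ions that are jittered
#'   blank copies, as a fraction of `n_digest_ions`.
#' @param tol the [match_tolerances()] the separation constraint is relative
#'   to.
#' @return object of class `ion_sim_config`.
#' @export
ion_sim_config <- function(seed = 1L, n_benchmark_ions = 500L,
                           n_digest_ions = 1000L, n_blank_ions = 150L,
                           mz_range = c(70, 1200), rt_range = c(0, 40),
                           charge_probs = c(0.4, 0.45, 0.15),
                           abundance_meanlog = log(1e5) + 0.6745 * 1.2,
                           abundance_sdlog = 1.2,
                           overlap_fraction = 0.5,
                           mz_jitter_sd = 0.0008, rt_jitter_sd = 0.1,
                           blank_contamination_fraction = 0.05,
                           tol = match_tolerances()) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            length(rt_range) == 2L, rt_range[1] <= rt_range[2],
            length(charge_probs) == 3L, all(charge_probs >= 0),
            mz_jitter_sd >= 0, rt_jitter_sd >= 0,
            blank_contamination_fraction >= 0)
  structure(list(seed = as.integer(seed),
                 n_benchmark_ions = as.integer(n_benchmark_ions),
                 n_digest_ions = as.integer(n_digest_ions),
                 n_blank_ions = as.integer(n_blank_ions),
                 mz_range = mz_range, rt_range = rt_range,
                 charge_probs = charge_probs / sum(charge_probs),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 overlap_fraction = overlap_fraction,
                 mz_jitter_sd = mz_jitter_sd, rt_jitter_sd = rt_jitter_sd,
                 blank_contamination_fraction = blank_contamination_fraction,
                 tol = tol), class = "ion_sim_config")
}

# TRUE for each row of `pts` (mz, charge, rt) that lies within `mult` times
# the tolerance radius (in the weighted metric) of any same-charge row of
# `ref`.
.near_any <- function(pts, ref, tol, mult = 1) {
  n <- nrow(pts)
  hit <- logical(n)
  if (n == 0L || nrow(ref) == 0L) return(hit)
  radius <- mult * sqrt((tol$mz_tol * tol$weight)^2 + tol$rt_tol^2)
  mz_win <- radius / tol$weight
  for (z in intersect(unique(pts$charge), unique(ref$charge))) {
    pi_ <- which(pts$charge == z)
    ri <- which(ref$charge == z)
    ord <- ri[order(ref$mz[ri])]
    smz <- ref$mz[ord]
    lo <- findInterval(pts$mz[pi_] - mz_win, smz, left.open = TRUE) + 1L
    hi <- findInterval(pts$mz[pi_] + mz_win, smz)
    for (j in seq_along(pi_)) {
      if (lo[j] > hi[j]) next
      cand <- ord[lo[j]:hi[j]]
      d <- sqrt(((ref$mz[cand] - pts$mz[pi_[j]]) * tol$weight)^2 +
                  (ref$rt[cand] - pts$rt[pi_[j]])^2)
      if (any(d <= radius)) hit[pi_[j]] <- TRUE
    }
  }
  hit
}

# Sample n (mz, charge, rt) positions, all separated from every same-charge
# row of `avoid` by more than `mult` tolerance radii, and mutually separated
# likewise.
.sample_positions <- function(n, cfg, avoid = NULL, mult = 2,
                              max_rounds = 200L) {
  draw <- function(m) data.frame(
    mz = stats::runif(m, cfg$mz_range[1], cfg$mz_range[2]),
    charge = sample(1:3, m, replace = TRUE, prob = cfg$charge_probs),
    rt = stats::runif(m, cfg$rt_range[1], cfg$rt_range[2]))
  pts <- draw(n)
  for (round in seq_len(max_rounds)) {
    bad <- logical(n)
    if (!is.null(avoid)) bad <- .near_any(pts, avoid, cfg$tol, mult)
    # mutual separation: a point is bad if another accepted point is close
    ord <- order(pts$charge, pts$mz)
    for (idx in seq_len(n - 1L)) {
      a <- ord[idx]
      b <- ord[idx + 1L]
      if (pts$charge[a] == pts$charge[b]) {
        d <- sqrt(((pts$mz[a] - pts$mz[b]) * cfg$tol$weight)^2 +
                    (pts$rt[a] - pts$rt[b])^2)
        lim <- mult * sqrt((cfg$tol$mz_tol * cfg$tol$weight)^2 +
                             cfg$tol$rt_tol^2)
        if (d <= lim) bad[b] <- TRUE
      }
    }
    if (!any(bad)) return(pts)
    pts[bad, ] <- draw(sum(bad))
  }
  stop("could not place ", n, " ions at the requested density under the ",
       "separation constraint")
}

.sample_abundance <- function(n, cfg) {
  stats::rlnorm(n, meanlog = cfg$abundance_meanlog, sdlog = cfg$abundance_sdlog)
}

#' Simulate a benchmark ion table
#'
#' All same-charge ion pairs are separated by more than twice the tolerance
#' radius in the weighted (m/z, rt) metric, so a sub-tolerance jittered copy
#' of a benchmark ion is unambiguously nearest to its parent and matches no
#' other benchmark ion.
#'
#' @param cfg an [ion_sim_config()].
#' @param source_id,replicate_id labels (defaults `"WPC"`, `"R1"`).
#' @return an `ion_table` with `cfg$n_benchmark_ions` ions.
#' @export
simulate_benchmark <- function(cfg, source_id = "WPC", replicate_id = "R1") {
  set.seed(cfg$seed)
  n <- cfg$n_benchmark_ions
  if (n == 0L) {
    return(ion_table(source_id = source_id, replicate_id = replicate_id))
  }
  pts <- .sample_positions(n, cfg)
  ion_table(mz = pts$mz, charge = pts$charge, rt = pts$rt,
            abundance = .sample_abundance(n, cfg),
            source_id = source_id, replicate_id = replicate_id)
}

#' Simulate an enzyme-blank ion table
#'
#' Blank ions are separated from every benchmark ion (and from one another)
#' by more than twice the tolerance radius, keeping blank-contamination
#' ground truth unambiguous.
#'
#' @param benchmark the benchmark `ion_table` to avoid.
#' @param cfg an [ion_sim_config()].
#' @return an `ion_table` with `cfg$n_blank_ions` ions labelled `"Blank"`.
#' @export
simulate_blank <- function(benchmark, cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_blank_ions
  if (n == 0L) {
    return(ion_table(source_id = "Blank", replicate_id = "R1"))
  }
  pts <- .sample_positions(n, cfg, avoid = benchmark)
  ion_table(mz = pts$mz, charge = pts$charge, rt = pts$rt,
            abundance = .sample_abundance(n, cfg),
            source_id = "Blank", replicate_id = "R1")
}

#' Simulate a digest ion table with planted ground truth
#'
#' Builds a digest of `round(overlap_fraction * n_digest_ions)` jittered
#' copies of distinct benchmark ions, `n_digest_ions` minus that many unique
#' ions placed outside tolerance of every benchmark and blank ion, plus
#' `round(blank_contamination_fraction * n_digest_ions)` jittered copies of
#' blank ions. Abundances are drawn independently from the configured
#' log-normal.
#'
#' @param benchmark `ion_table` from [simulate_benchmark()].
#' @param cfg an [ion_sim_config()]; `seed` is combined with the digest
#'   labels so replicates differ.
#' @param source_id,replicate_id digest labels.
#' @param blank optional `ion_table` from [simulate_blank()]; when supplied,
#'   blank-contamination ions are planted and unique ions also avoid the
#'   blank.
#' @param seed optional integer overriding the config seed.
#' @return list with `table` (the digest `ion_table`) and `truth`, a list
#'   holding `origin` (data frame: `ion_id`, `origin` in
#'   `{"benchmark","unique","blank"}`, `parent_id`), and the planted counts
#'   `n_overlap`, `n_unique`, `n_blank_contam`.
#' @export
simulate_digest <- function(benchmark, cfg, source_id = "digest",
                            replicate_id = "R1", blank = NULL, seed = NULL) {
  if (is.null(seed)) {
    seed <- (cfg$seed + 7L * sum(utf8ToInt(paste(source_id, replicate_id)))) %%
      .Machine$integer.max
  }
  set.seed(seed)
  n <- cfg$n_digest_ions
  n_over <- round(cfg$overlap_fraction * n)
  if (n_over > nrow(benchmark)) {
    stop("overlap_fraction * n_digest_ions (", n_over,
         ") exceeds benchmark size (", nrow(benchmark), ")")
  }
  n_unique <- n - n_over
  n_contam <- if (is.null(blank)) 0L else {
    min(round(cfg$blank_contamination_fraction * n), nrow(blank))
  }

  over <- if (n_over > 0L) {
    parents <- sample(seq_len(nrow(benchmark)), n_over)
    data.frame(
      mz = benchmark$mz[parents] + stats::rnorm(n_over, 0, cfg$mz_jitter_sd),
      charge = benchmark$charge[parents],
      rt = pmax(0, benchmark$rt[parents] +
                  stats::rnorm(n_over, 0, cfg$rt_jitter_sd)),
      parent = benchmark$ion_id[parents], origin = "benchmark")
  }

  avoid <- benchmark
  if (!is.null(blank)) {
    avoid <- rbind(as.data.frame(benchmark)[c("mz", "charge", "rt")],
                   as.data.frame(blank)[c("mz", "charge", "rt")])
  }
  uniq <- if (n_unique > 0L) {
    pts <- .sample_positions(n_unique, cfg, avoid = avoid, mult = 1.0001)
    data.frame(mz = pts$mz, charge = pts$charge, rt = pts$rt,
               parent = NA, origin = "unique")
  }
  contam <- if (n_contam > 0L) {
    bp <- sample(seq_len(nrow(blank)), n_contam)
    data.frame(
      mz = blank$mz[bp] + stats::rnorm(n_contam, 0, cfg$mz_jitter_sd),
      charge = blank$charge[bp],
      rt = pmax(0, blank$rt[bp] + stats::rnorm(n_contam, 0, cfg$rt_jitter_sd)),
      parent = blank$ion_id[bp], origin = "blank")
  }
  if (!is.null(uniq)) uniq$parent <- NA_integer_
  all_ions <- rbind(over, uniq, contam)
  if (is.null(all_ions) || nrow(all_ions) == 0L) {
    tab <- ion_table(source_id = source_id, replicate_id = replicate_id)
    return(list(table = tab,
                truth = list(origin = data.frame(ion_id = integer(0),
                                                 origin = character(0),
                                                 parent_id = integer(0)),
                             n_overlap = 0L, n_unique = 0L,
                             n_blank_contam = 0L)))
  }
  perm <- sample.int(nrow(all_ions))
  all_ions <- all_ions[perm, , drop = FALSE]
  tab <- ion_table(mz = all_ions$mz, charge = all_ions$charge,
                   rt = all_ions$rt,
                   abundance = .sample_abundance(nrow(all_ions), cfg),
                   source_id = source_id, replicate_id = replicate_id)
  truth <- data.frame(ion_id = tab$ion_id, origin = all_ions$origin,
                      parent_id = all_ions$parent, stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(origin = truth, n_overlap = n_over, n_unique = n_unique,
                    n_blank_contam = n_contam))
}

#' Configuration for synthetic biological read-outs
#'
#' Emulates the seven-variable intestinal read-out table with planted
#' multivariate-Gaussian cluster structure over sources. Replicate values are
#' drawn around each source's cluster mean with spherical within-group noise;
#' optional outliers are injected with magnitude at least five within-group
#' SDs.
#'
#' @param seed integer seed.
#' @param source_ids character vector of sources (default the benchmark, a
#'   blank and 17 numbered digests: 19 rows).
#' @param variables assay variable names (default the seven-read-out panel).
#' @param n_clusters planted cluster count (default 6, matching the
#'   biological analysis scale).
#' @param assignment integer cluster per source (default: round-robin).
#' @param cluster_means `n_clusters x d` matrix of planted means (default:
#'   seeded Gaussian draws with 5-SD spread around 100).
#' @param noise_sd within-cluster replicate SD (default 1).
#' @param n_replicates replicates per source (default 3).
#' @param outlier_rate probability a (source, variable) group receives one
#'   injected outlier (default 0).
#' @param outlier_magnitude outlier shift in within-group SDs (default 8,
#'   contract minimum 5).
#' @return object of class `bio_sim_config`.
#' @export
bio_sim_config <- function(seed = 1L,
                           source_ids = c("WPC", "Blank",
                                          sprintf("S%02d", 1:17)),
                           variables = c("inulin_fitc_leakage",
                                         "zo1_intersections",
                                         "cell_viability", "alp_activity",
                                         "il6", "tgfb", "no"),
                           n_clusters = 6L, assignment = NULL,
                           cluster_means = NULL, noise_sd = 1,
                           n_replicates = 3L, outlier_rate = 0,
                           outlier_magnitude = 8) {
  d <- length(variables)
  n_s <- length(source_ids)
  if (is.null(assignment)) {
    assignment <- rep_len(seq_len(n_clusters), n_s)
  }
  stopifnot(length(assignment) == n_s, all(assignment >= 1),
            all(assignment <= n_clusters), noise_sd > 0,
            n_replicates >= 1, outlier_rate >= 0, outlier_rate <= 1,
            outlier_magnitude >= 5)
  if (is.null(cluster_means)) {
    set.seed(seed + 211L)
    cluster_means <- matrix(100 + stats::rnorm(n_clusters * d,
                                               sd = 5 * noise_sd),
                            n_clusters, d)
  }
  stopifnot(nrow(cluster_means) == n_clusters, ncol(cluster_means) == d)
  structure(list(seed = as.integer(seed), source_ids = source_ids,
                 variables = variables, n_clusters = as.integer(n_clusters),
                 assignment = as.integer(assignment),
                 cluster_means = cluster_means, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude),
            class = "bio_sim_config")
}

#' Simulate a biological read-out table with planted clusters
#'
#' @param cfg a [bio_sim_config()].
#' @return list with `table` (a `bio_readout_table`), `assignment` (named
#'   integer vector: planted cluster per source) and `outliers` (data frame
#'   of injected outlier cells).
#' @export
simulate_bio_readouts <- function(cfg) {
  set.seed(cfg$seed)
  rows <- list()
  outliers <- list()
  for (si in seq_along(cfg$source_ids)) {
    mu <- cfg$cluster_means[cfg$assignment[si], ]
    for (r in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = cfg$source_ids[si],
        replicate_id = sprintf("R%d", r),
        variable = cfg$variables,
        value = mu + stats::rnorm(length(mu), sd = cfg$noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (cfg$outlier_rate > 0) {
    for (si in seq_along(cfg$source_ids)) {
      for (v in cfg$variables) {
        if (stats::runif(1) < cfg$outlier_rate) {
          rep_hit <- sample.int(cfg$n_replicates, 1L)
          sel <- df$source_id == cfg$source_ids[si] & df$variable == v &
            df$replicate_id == sprintf("R%d", rep_hit)
          shift <- sample(c(-1, 1), 1L) * cfg$outlier_magnitude * cfg$noise_sd
          df$value[sel] <- df$value[sel] + shift
          outliers[[length(outliers) + 1L]] <- data.frame(
            source_id = cfg$source_ids[si],
            replicate_id = sprintf("R%d", rep_hit), variable = v,
            shift = shift, stringsAsFactors = FALSE)
        }
      }
    }
  }
  rownames(df) <- NULL
  assignment <- stats::setNames(cfg$assignment, cfg$source_ids)
  list(table = bio_readout_table(df), assignment = assignment,
       outliers = if (length(outliers)) do.call(rbind, outliers) else
         data.frame(source_id = character(0), replicate_id = character(0),
                    variable = character(0), shift = numeric(0)))
}

#' Draw a sample from a finite Gaussian mixture
#'
#' Generic mixture sampler used for clustering-recovery checks: component
#' membership is multinomial in the weights, observations are multivariate
#' normal with the given component means and covariances.
#'
#' @param n sample size.
#' @param weights k mixing proportions (need not be normalized).
#' @param means d x k matrix of component means.
#' @param sigmas d x d x k array of component covariances.
#' @param seed integer seed.
#' @return list with `x` (n x d matrix) and `z` (integer component labels).
#' @export
simulate_mixture <- function(n, weights, means, sigmas, seed = 1L) {
  set.seed(seed)
  means <- as.matrix(means)
  d <- nrow(means)
  k <- ncol(means)
  stopifnot(length(weights) == k, all(dim(sigmas) == c(d, d, k)))
  weights <- weights / sum(weights)
  z <- sample.int(k, n, replace = TRUE, prob = weights)
  x <- matrix(0, n, d)
  for (g in seq_len(k)) {
    idx <- which(z == g)
    if (length(idx) == 0L) next
    R <- chol(sigmas[, , g])
    x[idx, ] <- matrix(stats::rnorm(length(idx) * d), length(idx), d) %*% R +
      matrix(means[, g], length(idx), d, byrow = TRUE)
  }
  list(x = x, z = z)
}

#' Random orthonormal matrix
#'
#' QR-based draw from the orthogonal group, sign-normalized so the
#' decomposition is unique; used to build randomly oriented covariance
#' structures for simulation.
#'
#' @param d dimension.
#' @param seed optional integer seed.
#' @return d x d orthonormal matrix.
#' @export
random_orthonormal <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), d)
}
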