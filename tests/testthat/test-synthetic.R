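test_that("generators are bitwise reproducible given the configuration", {
  cfg <- ion_sim_config(seed = 9, n_benchmark_ions = 200, n_digest_ions = 150)
  b1 <- simulate_benchmark(cfg)
  b2 <- simulate_benchmark(cfg)
  expect_identical(b1, b2)
  d1 <- simulate_digest(b1, cfg, source_id = "Pea")
  d2 <- simulate_digest(b2, cfg, source_id = "Pea")
  expect_identical(d1, d2)
  s1 <- simulate_bio_readouts(bio_sim_config(seed = 9))
  s2 <- simulate_bio_readouts(bio_sim_config(seed = 9))
  expect_identical(s1, s2)
})

test_that("benchmark ions respect the separation postcondition", {
  cfg <- ion_sim_config(seed = 2, n_benchmark_ions = 400)
  bm <- simulate_benchmark(cfg)
  tol <- cfg$tol
  radius <- sqrt((tol$mz_tol * tol$weight)^2 + tol$rt_tol^2)
  for (z in unique(bm$charge)) {
    sub <- bm[bm$charge == z, ]
    ord <- order(sub$mz)
    # exhaustive pairwise check within each charge stratum
    d <- as.matrix(dist(cbind(sub$mz * tol$weight, sub$rt)))
    diag(d) <- Inf
    expect_gt(min(d), 2 * radius)
  }
  expect_equal(nrow(simulate_benchmark(
    ion_sim_config(seed = 1, n_benchmark_ions = 0))), 0L)
})

test_that("zero-jitter digests are recovered exactly end to end", {
  cfg <- ion_sim_config(seed = 4, n_benchmark_ions = 400, n_digest_ions = 300,
                        n_blank_ions = 80, overlap_fraction = 0.5,
                        mz_jitter_sd = 0, rt_jitter_sd = 0,
                        blank_contamination_fraction = 0.1)
  bm <- simulate_benchmark(cfg)
  bl <- simulate_blank(bm, cfg)
  dg <- simulate_digest(bm, cfg, source_id = "QM", blank = bl)
  # threshold 0 keeps every ion so the counts are exact
  out <- run_matching_pipeline(list(dg$table), bl, bm, threshold = 0)
  res <- out$digests[[1]]
  expect_equal(res$audit$n_blank_excluded, dg$truth$n_blank_contam)
  expect_equal(res$match$audit$n_matched, dg$truth$n_overlap)
  expect_equal(res$match$audit$n_unmatched, dg$truth$n_unique)
  # every planted pair is identified with its true parent
  truth <- dg$truth$origin
  planted <- truth[truth$origin == "benchmark", ]
  got <- res$match$pairs[match(planted$ion_id, res$match$pairs$query_id), ]
  expect_equal(got$ref_id, planted$parent_id)
  expect_true(all(got$distance == 0))
})

test_that("extreme overlap fractions behave as planted", {
  cfg1 <- ion_sim_config(seed = 6, n_benchmark_ions = 150,
                         n_digest_ions = 100, overlap_fraction = 1,
                         mz_jitter_sd = 0, rt_jitter_sd = 0)
  bm <- simulate_benchmark(cfg1)
  dg <- simulate_digest(bm, cfg1, source_id = "full")
  m <- match_to_reference(dg$table, bm)
  expect_equal(m$audit$n_unmatched, 0L)

  cfg0 <- ion_sim_config(seed = 6, n_benchmark_ions = 150,
                         n_digest_ions = 100, overlap_fraction = 0)
  dg0 <- simulate_digest(bm, cfg0, source_id = "none")
  m0 <- match_to_reference(dg0$table, bm)
  expect_equal(nrow(m0$pairs), 0L)

  cfg_bad <- ion_sim_config(seed = 6, n_benchmark_ions = 50,
                            n_digest_ions = 100, overlap_fraction = 1)
  expect_error(simulate_digest(bm[1:50, ], cfg_bad), "exceeds benchmark")
})

test_that("abundance model straddles the filter threshold", {
  cfg <- ion_sim_config(seed = 12, n_benchmark_ions = 2000)
  bm <- simulate_benchmark(cfg)
  frac_below <- mean(bm$abundance < 1e5)
  expect_gt(frac_below, 0.15)
  expect_lt(frac_below, 0.35)
})

test_that("zero-noise bio read-outs reproduce the planted means", {
  cfg <- bio_sim_config(seed = 3, noise_sd = 1e-12)
  sim <- simulate_bio_readouts(cfg)
  m <- build_feature_matrix(sim$table)
  for (si in seq_along(cfg$source_ids)) {
    expect_equal(unname(m[cfg$source_ids[si], ]),
                 cfg$cluster_means[cfg$assignment[si], ], tolerance = 1e-9)
  }
})

test_that("injected bio outliers are detected by the Grubbs screen", {
  # the single-outlier statistic is bounded by (n-1)/sqrt(n), so detection
  # power is only adequate for groups of >= 5 replicates
  hits <- 0; total <- 0
  for (seed in c(1, 2, 3)) {
    cfg <- bio_sim_config(seed = seed, n_replicates = 6, outlier_rate = 0.25,
                          outlier_magnitude = 8)
    sim <- simulate_bio_readouts(cfg)
    scr <- screen_outliers(sim$table, alpha = 0.05)
    planted <- paste(sim$outliers$source_id, sim$outliers$replicate_id,
                     sim$outliers$variable)
    found <- paste(scr$outliers$source_id, scr$outliers$replicate_id,
                   scr$outliers$variable)
    hits <- hits + sum(planted %in% found)
    total <- total + length(planted)
  }
  expect_gt(total, 20)
  expect_gte(hits / total, 0.9)
})
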