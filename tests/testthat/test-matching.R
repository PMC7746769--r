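test_that("abundance filter excludes strictly below threshold, keeps order", {
  tab <- make_ions(mz = c(100, 101, 102), abundance = c(5e4, 1e5, 2e5))
  res <- filter_low_abundance(tab)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$table$abundance, c(1e5, 2e5))  # 1e5 boundary retained
  expect_equal(res$table$mz, c(101, 102))

  empty <- filter_low_abundance(make_ions(numeric(0), integer(0),
                                          numeric(0), numeric(0)))
  expect_equal(nrow(empty$table), 0L)
  expect_equal(empty$n_excluded, 0L)

  expect_equal(filter_low_abundance(tab, threshold = 0)$table$abundance,
               tab$abundance)
})

test_that("tolerance predicate uses inclusive bounds and exact charge equality", {
  tol <- match_tolerances()
  a <- list(mz = 500, charge = 2L, rt = 10)
  expect_true(tolerance_match_predicate(a, a, tol))
  expect_true(tolerance_match_predicate(
    a, list(mz = 500.003, charge = 2L, rt = 10), tol))
  expect_true(tolerance_match_predicate(
    a, list(mz = 500, charge = 2L, rt = 10.5), tol))
  expect_false(tolerance_match_predicate(
    a, list(mz = 500.0031, charge = 2L, rt = 10), tol))
  expect_false(tolerance_match_predicate(
    a, list(mz = 500, charge = 3L, rt = 10), tol))
})

test_that("weighted match distance honours the stated equivalence and identities", {
  tol <- match_tolerances()
  expect_equal(eq1_distance(0.003, 0, tol), 0.5, tolerance = 1e-12)
  expect_identical(eq1_distance(0, 0, tol), 0)
  expect_equal(eq1_distance(0.003, 0.5, tol), sqrt(0.5), tolerance = 1e-12)
  # sign symmetry and axis restrictions
  for (seed in 1:20) {
    set.seed(seed)
    dmz <- rnorm(1, 0, 0.002); drt <- rnorm(1, 0, 0.3)
    expect_identical(eq1_distance(dmz, drt, tol),
                     eq1_distance(-dmz, -drt, tol))
    expect_equal(eq1_distance(dmz, 0, tol), abs(dmz) * tol$weight)
    expect_equal(eq1_distance(0, drt, tol), abs(drt))
  }
})

test_that("nearest-match assignment picks the minimal weighted distance", {
  query <- make_ions(mz = 500.000, charge = 2L, rt = 10.0)
  refs <- make_ions(mz = c(500.001, 500.002), charge = c(2L, 2L),
                    rt = c(10.0, 10.1))
  m <- match_to_reference(query, refs)
  expect_equal(m$pairs$ref_id, 1L)
  expect_equal(m$pairs$distance, 0.001 * (0.5 / 0.003), tolerance = 1e-9)

  # self-match at distance zero
  tab <- random_ions(50, seed = 11)
  self <- match_to_reference(tab, tab)
  expect_equal(self$audit$n_matched, 50L)
  expect_equal(self$pairs$query_id, self$pairs$ref_id)
  expect_true(all(self$pairs$distance == 0))
})

test_that("distance ties break by smaller |dmz| then smaller reference id", {
  # two references exactly equidistant, one closer in mz
  q <- make_ions(mz = 500.000, charge = 2L, rt = 10.0)
  refs <- make_ions(mz = c(500.000, 500.0024), charge = c(2L, 2L),
                    rt = c(10.4, 10.0), ion_id = c(5L, 9L))
  # distances: |drt| = 0.4 vs |dmz|*w = 0.0024*166.67 = 0.4
  expect_equal(eq1_distance(0, 0.4), eq1_distance(0.0024, 0))
  m <- match_to_reference(q, refs)
  expect_equal(m$pairs$ref_id, 5L)

  # fully symmetric: equal distance and equal |dmz| -> smaller ion_id
  refs2 <- make_ions(mz = c(500.001, 499.999), charge = c(2L, 2L),
                     rt = c(10, 10), ion_id = c(9L, 5L))
  m2 <- match_to_reference(q, refs2)
  expect_equal(m2$pairs$ref_id, 5L)
})

test_that("matching agrees with the exhaustive brute-force oracle", {
  for (seed in 1:8) {
    query <- random_ions(120, seed = seed, mz_range = c(100, 100.6),
                         rt_range = c(0, 6))
    refs <- random_ions(120, seed = seed + 1000, mz_range = c(100, 100.6),
                        rt_range = c(0, 6))
    got <- match_to_reference(query, refs)
    want <- oracle_match(query, refs)
    expect_equal(got$pairs$query_id, want$pairs$query_id)
    expect_equal(got$pairs$ref_id, want$pairs$ref_id)
    expect_equal(got$pairs$distance, want$pairs$distance)
    expect_equal(sort(got$unmatched_query), sort(want$unmatched))
  }
})

test_that("multiple query ions on one reference sum in the aggregate", {
  q <- make_ions(mz = c(500.001, 499.999), charge = c(2L, 2L),
                 rt = c(10, 10), abundance = c(3e5, 4e5))
  ref <- make_ions(mz = 500.000, charge = 2L, rt = 10)
  m <- match_to_reference(q, ref)
  expect_equal(nrow(m$pairs), 2L)
  expect_equal(m$ref_abundance$total_abundance, 7e5)
  expect_equal(m$audit$n_matched + m$audit$n_unmatched, m$audit$n_query_in)
})

test_that("blank subtraction removes overlap, is idempotent, respects charge", {
  tab <- random_ions(60, seed = 3)
  same <- subtract_blank(tab, tab)
  expect_equal(nrow(same$table), 0L)
  expect_equal(same$n_excluded, 60L)

  blank <- tab
  blank$charge <- tab$charge + 3L  # disjoint charge sets
  untouched <- subtract_blank(tab, blank)
  expect_equal(nrow(untouched$table), nrow(tab))

  half_blank <- tab[1:30, ]
  class(half_blank) <- class(tab)
  once <- subtract_blank(tab, half_blank)
  twice <- subtract_blank(once$table, half_blank)
  expect_equal(twice$n_excluded, 0L)
  expect_identical(twice$table$ion_id, once$table$ion_id)
})

test_that("planted blank-derived ions are exactly the ones removed", {
  cfg <- ion_sim_config(seed = 21, n_benchmark_ions = 300,
                        n_digest_ions = 600, n_blank_ions = 100,
                        blank_contamination_fraction = 0.05)
  bm <- simulate_benchmark(cfg)
  bl <- simulate_blank(bm, cfg)
  dg <- simulate_digest(bm, cfg, source_id = "Soy", blank = bl)
  expect_equal(dg$truth$n_blank_contam, 30L)
  res <- subtract_blank(dg$table, bl)
  planted <- dg$truth$origin$ion_id[dg$truth$origin$origin == "blank"]
  removed <- setdiff(dg$table$ion_id, res$table$ion_id)
  expect_setequal(removed, planted)
})

test_that("filter audit enforces the conservation identity", {
  a <- filter_audit(100, 60, 10, 30)
  expect_s3_class(a, "filter_audit")
  expect_error(filter_audit(100, 60, 10, 31), "conservation")
  expect_error(filter_audit(-1, 0, 0, -1), "non-negative")
})

test_that("pipeline audits conserve ions and a self-benchmark fully matches", {
  cfg <- ion_sim_config(seed = 5, n_benchmark_ions = 250, n_digest_ions = 300,
                        overlap_fraction = 0.4)
  bm <- simulate_benchmark(cfg)
  bl <- simulate_blank(bm, cfg)
  digests <- lapply(1:3, function(i) {
    simulate_digest(bm, cfg, source_id = paste0("S", i), blank = bl)$table
  })
  out <- run_matching_pipeline(digests, bl, bm)
  for (res in out$digests) {
    a <- res$audit
    expect_equal(a$n_observed,
                 a$n_abundance_excluded + a$n_blank_excluded + a$n_retained)
    expect_equal(res$match$audit$n_query_in, a$n_retained)
  }

  # digest identical to benchmark with an empty blank: everything matches
  empty_blank <- make_ions(numeric(0), integer(0), numeric(0), numeric(0),
                           source_id = "Blank")
  ident <- run_matching_pipeline(list(bm), empty_blank, bm)
  res <- ident$digests[[1]]
  expect_equal(res$match$audit$n_unmatched, 0L)
  expect_error(run_matching_pipeline(list(bm), empty_blank,
                                     empty_blank), "benchmark")
})
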