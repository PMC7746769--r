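test_that("Grubbs test flags a gross outlier and matches the t-based formula", {
  res <- grubbs_test(c(1.0, 1.1, 0.9, 5.0), alpha = 0.05)
  expect_equal(res$outlier_index, 4L)
  # recompute G and G_crit independently from the stated formulas
  x <- c(1.0, 1.1, 0.9, 5.0)
  n <- 4
  g_hand <- max(abs(x - mean(x))) / sd(x)
  t_hand <- qt(1 - 0.05 / (2 * n), n - 2)
  crit_hand <- ((n - 1) / sqrt(n)) * sqrt(t_hand^2 / (n - 2 + t_hand^2))
  expect_equal(res$g_statistic, g_hand)
  expect_equal(res$critical_value, crit_hand)
  expect_gt(g_hand, crit_hand)
})

test_that("Grubbs handles symmetric, constant and short inputs", {
  expect_true(is.na(grubbs_test(c(1, 2, 3))$outlier_index))
  const <- grubbs_test(c(2, 2, 2, 2))
  expect_equal(const$g_statistic, 0)
  expect_true(is.na(const$outlier_index))
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  expect_error(grubbs_test(c(1, 2, NA)), "finite")
})

test_that("null flag rate stays near the nominal level (mini calibration)", {
  set.seed(5)
  n_sim <- 2000
  for (n in c(3, 6)) {
    x <- matrix(rnorm(n_sim * n), n_sim, n)
    flags <- vapply(seq_len(n_sim), function(i) {
      !is.na(grubbs_test(x[i, ])$outlier_index)
    }, logical(1))
    expect_lte(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
  }
})

test_that("outlier screening removes at most one value per group per pass", {
  sim <- simulate_bio_readouts(bio_sim_config(seed = 13, n_replicates = 5,
                                              outlier_rate = 0.3))
  scr <- screen_outliers(sim$table)
  # every removed row corresponds to a distinct (source, variable) group
  key <- paste(scr$outliers$source_id, scr$outliers$variable)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(scr$cleaned) + nrow(scr$outliers), nrow(sim$table))
  # cleaned table differs from raw exactly at the flagged cells
  raw_key <- paste(sim$table$source_id, sim$table$replicate_id,
                   sim$table$variable)
  clean_key <- paste(scr$cleaned$source_id, scr$cleaned$replicate_id,
                     scr$cleaned$variable)
  rem_key <- paste(scr$outliers$source_id, scr$outliers$replicate_id,
                   scr$outliers$variable)
  expect_setequal(setdiff(raw_key, clean_key), rem_key)
})

test_that("control normalization scales correctly and is scale-equivariant", {
  expect_equal(normalize_to_control(c(2, 4), c(1, 3)), c(1, 2))
  expect_equal(normalize_to_control(c(2, 2), c(2, 2)), c(1, 1))
  expect_equal(normalize_to_control(c(2, 4), c(2, 2), scale = 100),
               c(100, 200))
  v <- c(3, 5, 7); ctrl <- c(4, 4)
  expect_equal(normalize_to_control(v * 13, ctrl * 13),
               normalize_to_control(v, ctrl))
  expect_error(normalize_to_control(1, c(-2, 0)), "positive")
})

test_that("benchmark comparison tests behave like their closed forms", {
  df <- expand.grid(source_id = c("WPC", "A", "B"),
                    replicate_id = c("R1", "R2", "R3"),
                    variable = "il6", stringsAsFactors = FALSE)
  set.seed(2)
  df$value <- rnorm(nrow(df), 100, 1)
  # push B far away: 10 within-group SDs
  df$value[df$source_id == "B"] <- df$value[df$source_id == "B"] + 10
  res <- compare_to_benchmark(bio_readout_table(df), benchmark = "WPC")
  tb <- res$t_tests
  expect_false(tb$significant[tb$source_id == "A"])
  expect_true(tb$significant[tb$source_id == "B"])

  # ANOVA with exactly two groups reproduces F = t^2 (pooled t)
  df2 <- df[df$source_id %in% c("WPC", "B"), ]
  res2 <- compare_to_benchmark(bio_readout_table(df2), benchmark = "WPC",
                               var_equal = TRUE)
  expect_equal(res2$anova$f_statistic, res2$t_tests$statistic^2,
               tolerance = 1e-10)

  # identical groups: p far from significance
  df3 <- df
  df3$value <- rep(c(1, 2, 3), each = 3)
  res3 <- compare_to_benchmark(bio_readout_table(df3), benchmark = "WPC")
  expect_false(any(res3$t_tests$significant))
})

test_that("untestable cells are flagged instead of failing", {
  df <- data.frame(source_id = c("WPC", "WPC", "WPC", "A"),
                   replicate_id = c("R1", "R2", "R3", "R1"),
                   variable = "no", value = c(1, 2, 3, 4))
  res <- suppressWarnings(
    compare_to_benchmark(suppressWarnings(bio_readout_table(df))))
  expect_false(res$t_tests$testable[res$t_tests$source_id == "A"])
  expect_true(is.na(res$t_tests$p[res$t_tests$source_id == "A"]))
})
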