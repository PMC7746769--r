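test_that("free-parameter counts match hand computation for small d, k", {
  # means k*d + weights (k-1) + covariance count per family
  expect_equal(n_mixture_params("EII", d = 2, k = 2), 4 + 1 + 1)
  expect_equal(n_mixture_params("VII", d = 3, k = 3), 9 + 2 + 3)
  expect_equal(n_mixture_params("EEI", d = 3, k = 2), 6 + 1 + 3)
  expect_equal(n_mixture_params("VEI", d = 2, k = 3), 6 + 2 + (3 + 1))
  expect_equal(n_mixture_params("EVI", d = 3, k = 2), 6 + 1 + (1 + 2 * 2))
  expect_equal(n_mixture_params("VVI", d = 2, k = 3), 6 + 2 + 6)
  expect_equal(n_mixture_params("EEE", d = 3, k = 2), 6 + 1 + 6)
  expect_equal(n_mixture_params("VEE", d = 3, k = 2), 6 + 1 + (2 + 2 + 3))
  expect_equal(n_mixture_params("EVE", d = 3, k = 2), 6 + 1 + (1 + 4 + 3))
  expect_equal(n_mixture_params("VVE", d = 3, k = 3), 9 + 2 + (3 + 6 + 3))
  expect_equal(n_mixture_params("EEV", d = 3, k = 3), 9 + 2 + (1 + 2 + 9))
  expect_equal(n_mixture_params("VEV", d = 2, k = 2), 4 + 1 + (2 + 1 + 2))
  expect_equal(n_mixture_params("EVV", d = 3, k = 2), 6 + 1 + (1 + 4 + 6))
  expect_equal(n_mixture_params("VVV", d = 3, k = 2), 6 + 1 + 12)
  # one dimension: only the volume letter remains
  expect_equal(n_mixture_params("EII", d = 1, k = 3), 3 + 2 + 1)
  expect_equal(n_mixture_params("VVV", d = 1, k = 2), 2 + 1 + 2)
})

test_that("k = 1 fits reduce to the closed-form single Gaussian", {
  set.seed(42)
  x <- matrix(rnorm(60), 20, 3)
  n <- nrow(x); d <- ncol(x)
  ctr <- sweep(x, 2, colMeans(x), "-")
  S <- crossprod(ctr) / n
  # full covariance: loglik = -n/2 (d log 2pi + log|S| + d)
  ll_full <- -n / 2 * (d * log(2 * pi) +
                         as.numeric(determinant(S)$modulus) + d)
  fit_eee <- fit_mixture(x, "EEE", k = 1)
  expect_equal(fit_eee$loglik, ll_full, tolerance = 1e-9)
  expect_equal(c(fit_eee$means), colMeans(x), tolerance = 1e-12)
  # spherical: lambda = tr(S)/d
  lam <- sum(diag(S)) / d
  ll_sph <- -n / 2 * (d * log(2 * pi) + d * log(lam) + d)
  fit_eii <- fit_mixture(x, "EII", k = 1)
  expect_equal(fit_eii$loglik, ll_sph, tolerance = 1e-9)
  # bic identity on the spherical fit: hand value
  m <- n_mixture_params("EII", d, 1)
  expect_equal(fit_eii$bic, 2 * ll_sph - m * log(n), tolerance = 1e-9)
})

test_that("BIC is monotone in parameter count at fixed log-likelihood", {
  f1 <- fit_mixture(matrix(rnorm(30), 30, 1), "EII", k = 1)
  # doubling the penalty at fixed loglik lowers bic by delta * log(n)
  expect_equal((2 * f1$loglik - f1$n_params * log(f1$n)) -
                 (2 * f1$loglik - 2 * f1$n_params * log(f1$n)),
               f1$n_params * log(f1$n))
  expect_equal(bic(f1), f1$bic)
})

test_that("EM log-likelihood is non-decreasing and constraints hold", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(120 * 3), 120, 3) +
      (sample(0:1, 120, TRUE)) * matrix(rep(c(2, 0, 1), each = 120), 120, 3)
    for (fam in MIXTURE_FAMILIES) {
      fit <- fit_mixture(x, fam, k = 2, seed = seed)
      tr <- fit$loglik_trace
      expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-1]))),
                  label = sprintf("monotone loglik (%s, seed %d)", fam, seed))
      if (isTRUE(fit$converged)) expect_family_constraints(fit)
    }
  }
})

test_that("EII agrees with an independent spherical-mixture implementation", {
  sim <- sep3_mixture(300, seed = 10)
  z0 <- matrix(0, 300, 2)
  set.seed(99)
  cl <- sample(1:2, 300, replace = TRUE)
  z0[cbind(1:300, cl)] <- 1
  z0 <- (z0 + 1e-10) / (1 + 2e-10)
  ref <- spherical_em(sim$x, k = 2, z0 = z0)
  fit <- fit_mixture(sim$x, "EII", k = 2, z_init = z0, tol = 1e-12,
                     max_iter = 2000)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("reported log-likelihood matches an independent evaluation", {
  sim <- sep3_mixture(250, seed = 3)
  for (fam in MIXTURE_FAMILIES) {
    fit <- fit_mixture(sim$x, fam, k = 3, seed = 1)
    if (!isTRUE(fit$converged)) next
    expect_equal(fit$loglik,
                 loglik_at(sim$x, fit$weights, fit$means, fit$sigma),
                 tolerance = 1e-8, label = paste("loglik", fam))
  }
})

test_that("parameters of a known variable-orientation mixture are recovered", {
  sim <- sep3_mixture(500, seed = 8, separation = 4)
  # reference: per-component sample means under the true labels
  ref_means <- sapply(1:3, function(g) colMeans(sim$x[sim$z == g, ]))
  fit <- fit_mixture(sim$x, "EEV", k = 3, seed = 1)
  expect_true(fit$converged)
  perm <- apply(fit$means, 2, function(m) {
    which.min(colSums((ref_means - m)^2))
  })
  expect_setequal(perm, 1:3)
  for (g in 1:3) {
    expect_lt(sqrt(sum((fit$means[, g] - ref_means[, perm[g]])^2)), 0.1)
  }
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 500),
               tolerance = 1e-10)
})

test_that("more general families dominate nested ones at the optimum", {
  sim <- sep3_mixture(300, seed = 15)
  z0 <- matrix(1e-10, 300, 3)
  z0[cbind(1:300, sim$z)] <- 1
  z0 <- z0 / rowSums(z0)
  ll <- sapply(MIXTURE_FAMILIES, function(fam) {
    fit_mixture(sim$x, fam, k = 3, z_init = z0, tol = 1e-10)$loglik
  })
  chains <- list(c("EII", "EEI", "EEE", "VVV"),
                 c("EII", "VII", "VVI", "VVV"),
                 c("EEI", "EEV", "VEV", "VVV"),
                 c("EEE", "VEE", "VVV"))
  for (ch in chains) {
    expect_true(all(diff(ll[ch]) >= -1e-6 * abs(ll[ch][-1])),
                label = paste("dominance", paste(ch, collapse = "<=")))
  }
})

test_that("model selection is deterministic and finds planted structure", {
  sim <- sep3_mixture(400, seed = 23)
  s1 <- select_model(sim$x, k_range = 1:4, n_restarts = 2, seed = 7)
  s2 <- select_model(sim$x, k_range = 1:4, n_restarts = 2, seed = 7)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$best$loglik, s2$best$loglik)
  expect_equal(s1$best$spec$k, 3)
  # single-k sweep returns the best family at that k
  s3 <- select_model(sim$x, k_range = 1, n_restarts = 1, seed = 1)
  expect_equal(s3$best$spec$k, 1)
  expect_equal(s3$best$bic, max(s3$table$bic))
})

test_that("selection agrees with an independent mixture package on easy data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust() needs the namespace attached
  sim <- sep3_mixture(400, seed = 31)
  ours <- select_model(sim$x, k_range = 1:5, n_restarts = 2, seed = 1)
  theirs <- mclust::Mclust(sim$x, G = 1:5, verbose = FALSE)
  expect_equal(ours$best$spec$k, 3)
  expect_equal(theirs$G, 3)
  # cross-implementation EM check: same start, same family, same optimum
  z0 <- mclust::unmap(sim$z)
  for (fam in c("EEE", "EEV", "VVV")) {
    ref <- mclust::me(data = sim$x, modelName = fam, z = z0)
    fit <- fit_mixture(sim$x, fam, k = 3, z_init = z0, tol = 1e-10)
    expect_equal(fit$loglik, ref$loglik, tolerance = 1e-5,
                 label = paste("me cross-check", fam))
  }
})

test_that("shared-covariance data favour equal over variable orientation", {
  wins <- vapply(1:7, function(seed) {
    set.seed(seed * 17)
    S <- diag(c(2, 1, 0.5))
    R <- random_orthonormal(3)
    sig <- array(rep(R %*% S %*% t(R), 3), c(3, 3, 3))
    sim <- simulate_mixture(300, rep(1, 3),
                            cbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0)), sig,
                            seed = seed * 17)
    fe <- fit_mixture(sim$x, "EEE", k = 3, seed = 1)
    fv <- fit_mixture(sim$x, "EEV", k = 3, seed = 1)
    fe$bic - fv$bic
  }, numeric(1))
  expect_gt(median(wins), 0)
})

test_that("pairwise plot tables enumerate feature pairs with shared labels", {
  sim <- sep3_mixture(60, seed = 40)
  colnames(sim$x) <- c("a", "b", "c")
  rownames(sim$x) <- paste0("s", 1:60)
  sel <- select_model(sim$x, families = "EEI", k_range = 2:3,
                      n_restarts = 1, seed = 1)
  tabs <- two_component_plot_data(sim$x, sel)
  expect_length(tabs, 3)  # d(d-1)/2
  expect_named(tabs, c("a.vs.b", "a.vs.c", "b.vs.c"))
  labs <- lapply(tabs, function(t) t$cluster)
  expect_identical(labs[[1]], labs[[2]])
  expect_identical(labs[[1]], labs[[3]])
  # round trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tabs[[1]], path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$cluster, tabs[[1]]$cluster)
})

test_that("degenerate requests are flagged, not thrown", {
  set.seed(1)
  x <- matrix(rnorm(12), 6, 2)
  fit <- fit_mixture(x, "VVV", k = 5, seed = 1)  # far too many components
  if (fit$degenerate) {
    # degenerate fits are excluded from selection via converged = FALSE
    expect_false(fit$converged)
  } else {
    expect_true(is.finite(fit$bic))
  }
  expect_error(select_model(x, families = "VVV", k_range = 1:6), "k_range")
  expect_error(fit_mixture(x, "VVV", k = 6), "components")
})
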