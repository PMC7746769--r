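# Independent oracles and small builders shared across the suite.
# These deliberately avoid the package's internal code paths.

make_ions <- function(mz, charge = rep(2L, length(mz)),
                      rt = rep(10, length(mz)),
                      abundance = rep(2e5, length(mz)),
                      source_id = "S", replicate_id = "R1", ion_id = NULL) {
  ion_table(mz = mz, charge = charge, rt = rt, abundance = abundance,
            ion_id = ion_id, source_id = source_id,
            replicate_id = replicate_id)
}

random_ions <- function(n, seed, source_id = "S", mz_range = c(100, 110),
                        rt_range = c(0, 20)) {
  set.seed(seed)
  make_ions(mz = runif(n, mz_range[1], mz_range[2]),
            charge = sample(1:3, n, replace = TRUE),
            rt = runif(n, rt_range[1], rt_range[2]),
            abundance = rlnorm(n, log(1e6), 1),
            source_id = source_id)
}

# Exhaustive O(n^2) nearest-match oracle: plain double loop, same matching
# rules as the spec states them (inclusive tolerance, minimal weighted
# distance, ties by |dmz| then reference ion_id).
oracle_match <- function(query, reference, tol = match_tolerances()) {
  pairs <- list()
  unmatched <- c()
  for (i in seq_len(nrow(query))) {
    best_j <- NA
    best_d <- Inf
    best_dmz <- Inf
    for (j in seq_len(nrow(reference))) {
      if (query$charge[i] != reference$charge[j]) next
      dmz <- abs(query$mz[i] - reference$mz[j])
      drt <- abs(query$rt[i] - reference$rt[j])
      if (dmz > tol$mz_tol || drt > tol$rt_tol) next
      d <- sqrt((dmz * tol$rt_tol / tol$mz_tol)^2 + drt^2)
      better <- d < best_d ||
        (d == best_d && (dmz < best_dmz ||
                           (dmz == best_dmz &&
                              reference$ion_id[j] < reference$ion_id[best_j])))
      if (better) {
        best_j <- j; best_d <- d; best_dmz <- dmz
      }
    }
    if (is.na(best_j)) {
      unmatched <- c(unmatched, query$ion_id[i])
    } else {
      pairs[[length(pairs) + 1L]] <- data.frame(
        query_id = query$ion_id[i], ref_id = reference$ion_id[best_j],
        distance = best_d)
    }
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
    data.frame(query_id = integer(0), ref_id = integer(0),
               distance = numeric(0)),
    unmatched = unmatched)
}

# Independent spherical equal-variance mixture EM (the unconstrained
# reference for the EII family), written from the textbook update equations.
spherical_em <- function(x, k, z0, max_iter = 2000, tol = 1e-12) {
  n <- nrow(x); d <- ncol(x)
  z <- z0
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- colSums(z)
    w <- nk / n
    mu <- lapply(seq_len(k), function(g) colSums(x * z[, g]) / nk[g])
    s2 <- sum(vapply(seq_len(k), function(g) {
      sum(z[, g] * rowSums(sweep(x, 2, mu[[g]], "-")^2))
    }, numeric(1))) / (n * d)
    logd <- vapply(seq_len(k), function(g) {
      -0.5 * (d * log(2 * pi * s2) +
                rowSums(sweep(x, 2, mu[[g]], "-")^2) / s2) + log(w[g])
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    z <- exp(logd - lse)
    if (abs(ll - prev) < tol * (1 + abs(ll))) return(list(loglik = ll, z = z))
    prev <- ll
  }
  list(loglik = prev, z = z)
}

# Mixture log-likelihood evaluated with plain solve()/determinant(),
# independent of the package's Cholesky-based path.
loglik_at <- function(x, w, mu, sigma) {
  n <- nrow(x); d <- ncol(x); k <- length(w)
  dens <- vapply(seq_len(k), function(g) {
    Sinv <- solve(sigma[, , g])
    ld <- as.numeric(determinant(sigma[, , g], logarithm = TRUE)$modulus)
    xc <- sweep(x, 2, mu[, g], "-")
    q <- rowSums((xc %*% Sinv) * xc)
    w[g] * exp(-0.5 * (d * log(2 * pi) + ld + q))
  }, numeric(n))
  sum(log(rowSums(dens)))
}

# Covariances for a k-component mixture with shared shape/volume and random
# per-component orientations (the variable-orientation regime).
eev_sigmas <- function(d, k, lambda = 1, shape = NULL, seed = 1) {
  if (is.null(shape)) {
    shape <- exp(seq(log(2), log(0.5), length.out = d))
    shape <- shape / exp(mean(log(shape)))
  }
  sig <- array(0, c(d, d, k))
  for (g in seq_len(k)) {
    D <- random_orthonormal(d, seed = seed * 100 + g)
    sig[, , g] <- lambda * D %*% (shape * t(D))
  }
  sig
}

# Well-separated 3-component test mixture in 3 dimensions; separation is the
# nearest-pair mean distance in units of the largest marginal SD.
sep3_mixture <- function(n, seed, separation = 4, lambda = 1) {
  sig <- eev_sigmas(3, 3, lambda = lambda, seed = seed)
  sdmax <- sqrt(max(apply(sig, 3, function(s) max(eigen(s)$values))))
  delta <- separation * sdmax
  means <- cbind(c(0, 0, 0), c(delta, 0, 0), c(0, delta, 0))
  simulate_mixture(n, rep(1, 3), means, sig, seed = seed)
}

# Verify that the realized component covariances satisfy a family's equality
# constraints (volume/shape/orientation equal, variable, or identity).
expect_family_constraints <- function(fit, tol = 1e-8) {
  sig <- fit$sigma
  d <- dim(sig)[1]; k <- dim(sig)[3]
  fam <- fit$spec$family
  if (d == 1L) {
    if (substr(fam, 1, 1) == "E" && k > 1) {
      expect_equal(max(sig) - min(sig), 0, tolerance = tol)
    }
    return(invisible(fit))
  }
  lt <- strsplit(fam, "")[[1]]
  offdiag <- function(s) max(abs(s - diag(diag(s), d)))
  dets <- apply(sig, 3, det)^(1 / d)
  evs <- apply(sig, 3, function(s) {
    sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  })
  scale_ref <- max(abs(sig))
  if (lt[3] == "I") {
    for (g in seq_len(k)) expect_lt(offdiag(sig[, , g]), tol * scale_ref)
  }
  if (lt[2] == "I") {
    # spherical: all eigenvalues equal within a component
    for (g in seq_len(k)) {
      expect_lt(max(evs[, g]) - min(evs[, g]), tol * scale_ref)
    }
  }
  if (lt[1] == "E" && k > 1) {
    expect_lt(max(dets) - min(dets), tol * scale_ref)  # equal volume
  }
  if (lt[2] == "E" && k > 1) {
    # equal shape: volume-normalized eigenvalue profiles identical
    shp <- sweep(evs, 2, dets, "/")
    expect_lt(max(apply(shp, 1, function(r) max(r) - min(r))), tol)
  }
  if (lt[3] == "E" && k > 1) {
    # shared orientation: the fitted D simultaneously diagonalizes all
    D <- fit$orient
    for (g in seq_len(k)) {
      expect_lt(offdiag(t(D) %*% sig[, , g] %*% D), tol * scale_ref)
    }
  }
  if (fam == "EEE" && k > 1) {
    for (g in 2:k) {
      expect_lt(max(abs(sig[, , g] - sig[, , 1])), tol * scale_ref)
    }
  }
  invisible(fit)
}
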