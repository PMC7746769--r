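#' The fourteen eigen-decomposed covariance families
#'
#' Component covariances are parameterized as
#' `Sigma_k = lambda_k * D_k %*% A_k %*% t(D_k)` with volume `lambda_k > 0`,
#' diagonal shape `A_k` (determinant 1) and orthonormal orientation `D_k`.
#' Each of the three letters of a family code states whether volume, shape and
#' orientation are Equal across components, Variable, or (for shape and
#' orientation) the Identity. `"EEV"` for instance shares volume and shape but
#' lets each component rotate freely.
#'
#' @format character vector of the 14 three-letter codes.
#' @export
MIXTURE_FAMILIES <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI",
                      "EEE", "EVE", "VEE", "VVE", "EEV", "VEV", "EVV", "VVV")

#' Specify a constrained Gaussian mixture model
#'
#' @param family one of [MIXTURE_FAMILIES].
#' @param k number of mixture components (>= 1).
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(family, k) {
  family <- match.arg(family, MIXTURE_FAMILIES)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  structure(list(family = family, k = k), class = "mixture_spec")
}

#' Free-parameter count of a constrained mixture
#'
#' Means contribute `k*d`, mixing weights `k-1`, and the covariance the
#' standard eigen-decomposition count: volume 1 (E) or `k` (V); shape 0 (I),
#' `d-1` (E) or `k*(d-1)` (V); orientation 0 (I), `d*(d-1)/2` (E) or
#' `k*d*(d-1)/2` (V). In one dimension only the volume letter is meaningful.
#'
#' @param family family code.
#' @param d data dimension.
#' @param k number of components.
#' @return integer number of free parameters.
#' @export
n_mixture_params <- function(family, d, k) {
  family <- match.arg(family, MIXTURE_FAMILIES)
  lt <- strsplit(family, "")[[1]]
  if (d == 1L) {
    ncov <- if (lt[1] == "E") 1 else k
  } else {
    vol <- if (lt[1] == "E") 1 else k
    shape <- switch(lt[2], I = 0, E = d - 1, V = k * (d - 1))
    orient <- switch(lt[3], I = 0, E = d * (d - 1) / 2, V = k * d * (d - 1) / 2)
    ncov <- vol + shape + orient
  }
  as.integer(k * d + (k - 1) + ncov)
}

# ---- covariance M-steps -----------------------------------------------------
# W: d x d x k array of responsibility-weighted scatter matrices
# nk: effective component sizes. Returns list(sigma = d x d x k array,
# lambda, shape, orient) or NULL when the estimate degenerates.

.geomean <- function(x) exp(mean(log(x)))

# The eigenvalues of Sigma_k are exactly lambda_k * A_k, so degeneracy
# (non-positive or numerically singular covariance) is read off the
# structured parameters without any decomposition.
.cov_degenerate_params <- function(lambda, shape, k) {
  vals <- if (is.matrix(shape)) {
    shape * rep(if (length(lambda) == 1L) rep(lambda, k) else lambda,
                each = nrow(shape))
  } else {
    outer(shape, if (length(lambda) == 1L) rep(lambda, k) else lambda)
  }
  any(!is.finite(vals)) || min(vals) <= 0 || min(vals) < max(vals) * 1e-12
}

.sigma_from <- function(lambda, shape, orient, k, d) {
  # lambda: scalar or k-vector; shape: d-vector or d x k; orient: d x d or
  # d x d x k
  sigma <- array(0, dim = c(d, d, k))
  for (g in seq_len(k)) {
    lam <- if (length(lambda) == 1L) lambda else lambda[g]
    A <- if (is.matrix(shape)) shape[, g] else shape
    D <- if (length(dim(orient)) == 3L) orient[, , g] else orient
    sigma[, , g] <- lam * D %*% (A * t(D))
  }
  sigma
}

# Sorted eigen-decomposition of each scatter matrix (values descending).
.eig_each <- function(W, k) {
  lapply(seq_len(k), function(g) eigen(W[, , g], symmetric = TRUE))
}

# MM update for a shared orientation D minimizing sum_k tr(D' W_k D B_k)
# over orthogonal D, with B_k diagonal positive weights (Browne-McNicholas
# style majorization). omega_k is the largest eigenvalue of W_k.
.orient_mm <- function(W, Binv, D, k, d, n_iter = 5L) {
  omega <- vapply(seq_len(k), function(g) {
    max(eigen(W[, , g], symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  for (it in seq_len(n_iter)) {
    FF <- matrix(0, d, d)
    for (g in seq_len(k)) {
      FF <- FF + (omega[g] * D - W[, , g] %*% D) *
        rep(Binv[, g], each = d)   # right-multiply by diag(Binv)
    }
    sv <- svd(FF)
    D_new <- sv$u %*% t(sv$v)
    if (max(abs(D_new - D)) < 1e-10) { D <- D_new; break }
    D <- D_new
  }
  D
}

.cov_mstep <- function(family, W, nk, n, d, prev = NULL) {
  k <- length(nk)
  if (any(!is.finite(W)) || any(nk < d * 1e-8)) return(NULL)
  if (d == 1L) {
    wk <- W[1, 1, ]
    if (substr(family, 1, 1) == "E") {
      lambda <- sum(wk) / n
      sig <- rep(lambda, k)
    } else {
      sig <- wk / nk
      lambda <- sig
    }
    if (any(!is.finite(sig)) || any(sig <= 0)) return(NULL)
    return(list(sigma = array(sig, dim = c(1, 1, k)), lambda = lambda,
                shape = rep(1, k), orient = diag(1)))
  }
  res <- switch(family,
    EII = {
      lambda <- sum(vapply(seq_len(k), function(g) sum(diag(W[, , g])),
                           numeric(1))) / (n * d)
      list(lambda = lambda, shape = rep(1, d), orient = diag(d))
    },
    VII = {
      lambda <- vapply(seq_len(k), function(g) sum(diag(W[, , g])),
                       numeric(1)) / (nk * d)
      list(lambda = lambda, shape = rep(1, d), orient = diag(d))
    },
    EEI = {
      S <- rowSums(vapply(seq_len(k), function(g) diag(W[, , g]),
                          numeric(d))) / n
      if (any(S <= 0)) return(NULL)
      lambda <- .geomean(S)
      list(lambda = lambda, shape = S / lambda, orient = diag(d))
    },
    VEI = {
      B <- vapply(seq_len(k), function(g) diag(W[, , g]), numeric(d))
      if (any(B <= 0)) return(NULL)
      A <- if (!is.null(prev)) prev$shape else rep(1, d)
      lambda <- rep(1, k)
      for (it in 1:20) {
        lambda <- colSums(B / A) / (nk * d)
        if (any(lambda <= 0)) return(NULL)
        Araw <- rowSums(sweep(B, 2, lambda, "/"))
        A_new <- Araw / .geomean(Araw)
        if (max(abs(A_new - A)) < 1e-10) { A <- A_new; break }
        A <- A_new
      }
      list(lambda = lambda, shape = A, orient = diag(d))
    },
    EVI = {
      B <- vapply(seq_len(k), function(g) diag(W[, , g]), numeric(d))
      if (any(B <= 0)) return(NULL)
      ck <- apply(B, 2, .geomean)
      lambda <- sum(ck) / n
      list(lambda = lambda, shape = sweep(B, 2, ck, "/"), orient = diag(d))
    },
    VVI = {
      B <- vapply(seq_len(k), function(g) diag(W[, , g]), numeric(d)) /
        rep(nk, each = d)
      if (any(B <= 0)) return(NULL)
      lambda <- apply(B, 2, .geomean)
      list(lambda = lambda, shape = sweep(B, 2, lambda, "/"),
           orient = diag(d))
    },
    EEE = {
      S <- rowSums(W, dims = 2) / n
      ev <- eigen(S, symmetric = TRUE)
      if (any(ev$values <= 0)) return(NULL)
      lambda <- .geomean(ev$values)
      list(lambda = lambda, shape = ev$values / lambda, orient = ev$vectors)
    },
    VVV = {
      lambda <- numeric(k); shape <- matrix(0, d, k)
      orient <- array(0, dim = c(d, d, k))
      for (g in seq_len(k)) {
        ev <- eigen(W[, , g] / nk[g], symmetric = TRUE)
        if (any(ev$values <= 0)) return(NULL)
        lambda[g] <- .geomean(ev$values)
        shape[, g] <- ev$values / lambda[g]
        orient[, , g] <- ev$vectors
      }
      list(lambda = lambda, shape = shape, orient = orient)
    },
    EEV = {
      eig <- .eig_each(W, k)
      Om <- vapply(eig, function(e) e$values, numeric(d))
      if (any(Om <= 0)) return(NULL)
      Lam <- rowSums(Om) / n
      lambda <- .geomean(Lam)
      orient <- array(0, dim = c(d, d, k))
      for (g in seq_len(k)) orient[, , g] <- eig[[g]]$vectors
      list(lambda = lambda, shape = Lam / lambda, orient = orient)
    },
    VEV = {
      eig <- .eig_each(W, k)
      Om <- vapply(eig, function(e) e$values, numeric(d))
      if (any(Om <= 0)) return(NULL)
      A <- if (!is.null(prev)) prev$shape else rep(1, d)
      lambda <- rep(1, k)
      for (it in 1:20) {
        lambda <- colSums(Om / A) / (nk * d)
        if (any(lambda <= 0)) return(NULL)
        Araw <- rowSums(sweep(Om, 2, lambda, "/"))
        A_new <- Araw / .geomean(Araw)
        if (max(abs(A_new - A)) < 1e-10) { A <- A_new; break }
        A <- A_new
      }
      orient <- array(0, dim = c(d, d, k))
      for (g in seq_len(k)) orient[, , g] <- eig[[g]]$vectors
      list(lambda = lambda, shape = A, orient = orient)
    },
    EVV = {
      lambda_ck <- numeric(k); shape <- matrix(0, d, k)
      orient <- array(0, dim = c(d, d, k))
      for (g in seq_len(k)) {
        ev <- eigen(W[, , g], symmetric = TRUE)
        if (any(ev$values <= 0)) return(NULL)
        c_g <- .geomean(ev$values)
        lambda_ck[g] <- c_g
        shape[, g] <- ev$values / c_g
        orient[, , g] <- ev$vectors
      }
      list(lambda = sum(lambda_ck) / n, shape = shape, orient = orient)
    },
    VEE = {
      lambda <- rep(1, k)
      C <- if (!is.null(prev)) {
        prev$orient %*% (prev$shape * t(prev$orient))
      } else {
        C0 <- rowSums(W, dims = 2)
        C0 / det(C0)^(1 / d)
      }
      for (it in 1:20) {
        Cinv <- tryCatch(solve(C), error = function(e) NULL)
        if (is.null(Cinv)) return(NULL)
        lambda <- vapply(seq_len(k), function(g) {
          sum(diag(Cinv %*% W[, , g]))
        }, numeric(1)) / (nk * d)
        if (any(lambda <= 0) || any(!is.finite(lambda))) return(NULL)
        Craw <- matrix(0, d, d)
        for (g in seq_len(k)) Craw <- Craw + W[, , g] / lambda[g]
        dt <- det(Craw)
        if (!is.finite(dt) || dt <= 0) return(NULL)
        C_new <- Craw / dt^(1 / d)
        if (max(abs(C_new - C)) < 1e-10) { C <- C_new; break }
        C <- C_new
      }
      ev <- eigen(C, symmetric = TRUE)
      if (any(ev$values <= 0)) return(NULL)
      list(lambda = lambda, shape = ev$values, orient = ev$vectors)
    },
    EVE = {
      D <- if (!is.null(prev)) prev$orient else {
        eigen(rowSums(W, dims = 2), symmetric = TRUE)$vectors
      }
      shape <- matrix(1, d, k); lambda <- 1
      for (it in 1:4) {
        B <- vapply(seq_len(k), function(g) diag(t(D) %*% W[, , g] %*% D),
                    numeric(d))
        if (any(B <= 0)) return(NULL)
        ck <- apply(B, 2, .geomean)
        shape_new <- sweep(B, 2, ck, "/")
        lambda <- sum(ck) / n
        conv <- max(abs(shape_new - shape)) < 1e-10
        shape <- shape_new
        D <- .orient_mm(W, 1 / shape, D, k, d)
        if (conv && it > 1) break
      }
      list(lambda = lambda, shape = shape, orient = D)
    },
    VVE = {
      D <- if (!is.null(prev)) prev$orient else {
        eigen(rowSums(W, dims = 2), symmetric = TRUE)$vectors
      }
      shape <- matrix(1, d, k); lambda <- rep(1, k)
      for (it in 1:4) {
        B <- vapply(seq_len(k), function(g) diag(t(D) %*% W[, , g] %*% D),
                    numeric(d)) / rep(nk, each = d)
        if (any(B <= 0)) return(NULL)
        lambda <- apply(B, 2, .geomean)
        shape_new <- sweep(B, 2, lambda, "/")
        conv <- max(abs(shape_new - shape)) < 1e-10
        shape <- shape_new
        D <- .orient_mm(W, 1 / (shape * rep(lambda, each = d)), D, k, d)
        if (conv && it > 1) break
      }
      list(lambda = lambda, shape = shape, orient = D)
    },
    stop("unknown family: ", family))
  if (.cov_degenerate_params(res$lambda, res$shape, k)) return(NULL)
  sigma <- .sigma_from(res$lambda, res$shape, res$orient, k, d)
  c(list(sigma = sigma), res)
}

# ---- E/M steps --------------------------------------------------------------

.mstep <- function(x, z, family, prev_cov = NULL) {
  n <- nrow(x); d <- ncol(x); k <- ncol(z)
  nk <- colSums(z)
  if (any(nk < .Machine$double.eps * n)) return(NULL)
  w <- nk / n
  mu <- crossprod(x, z)          # d x k, unnormalized
  mu <- sweep(mu, 2, nk, "/")
  W <- array(0, dim = c(d, d, k))
  for (g in seq_len(k)) {
    xc <- x - matrix(mu[, g], n, d, byrow = TRUE)
    W[, , g] <- crossprod(xc * z[, g], xc)
  }
  cov <- .cov_mstep(family, W, nk, n, d, prev = prev_cov)
  if (is.null(cov)) return(NULL)
  list(w = w, mu = mu, cov = cov)
}

.estep <- function(x, w, mu, sigma) {
  n <- nrow(x); d <- ncol(x); k <- length(w)
  logdens <- matrix(0, n, k)
  for (g in seq_len(k)) {
    R <- tryCatch(chol(sigma[, , g]), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    xc <- x - matrix(mu[, g], n, d, byrow = TRUE)
    zq <- backsolve(R, t(xc), transpose = TRUE)
    quad <- colSums(zq^2)
    logdet <- 2 * sum(log(diag(R)))
    logdens[, g] <- -0.5 * (d * log(2 * pi) + logdet + quad) + log(w[g])
  }
  m <- logdens[, 1]
  if (k > 1L) for (g in 2:k) m <- pmax(m, logdens[, g])
  lse <- m + log(rowSums(exp(logdens - m)))
  z <- exp(logdens - lse)
  list(loglik = sum(lse), z = z)
}

# k-means++ seeded hard assignment converted to responsibilities.
.init_responsibilities <- function(x, k, seed) {
  n <- nrow(x)
  if (k == 1L) return(matrix(1, n, 1))
  set.seed(seed)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ], "-")^2)
  for (g in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[g, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[g, ], "-")^2))
  }
  cl <- tryCatch(
    stats::kmeans(x, centers = centers, iter.max = 20L)$cluster,
    error = function(e) {
      max.col(-vapply(seq_len(k), function(g) {
        rowSums(sweep(x, 2, centers[g, ], "-")^2)
      }, numeric(n)), ties.method = "first")
    })
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), cl)] <- 1
  # soften slightly so no component starts empty after the first M-step
  (z + 1e-10) / (1 + k * 1e-10)
}

#' Fit a constrained Gaussian mixture by EM
#'
#' Expectation-maximization with family-constrained covariance M-steps under
#' the eigen-decomposition `Sigma_k = lambda_k D_k A_k t(D_k)`. The
#' log-likelihood is non-decreasing across iterations; iteration stops when
#' the relative change falls below `tol` or after `max_iter` iterations.
#' Covariance degeneracy (singular within machine tolerance, or an emptied
#' component) marks the fit non-converged rather than raising an error.
#'
#' @param x numeric matrix (rows = observations) or `feature_matrix`.
#' @param spec a [mixture_spec()], or a family code combined with `k`.
#' @param k number of components when `spec` is a family code.
#' @param seed integer seed controlling the k-means++ initialization.
#' @param z_init optional n x k responsibility matrix overriding the seeded
#'   initialization (used for shared-initialization comparisons).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return object of class `fitted_mixture`: list with `spec`, `weights`,
#'   `means` (d x k), `sigma` (d x d x k), structured covariance parameters
#'   (`lambda`, `shape`, `orient`), `responsibilities`, `assignments`
#'   (argmax responsibility, ties toward the lower component index), `loglik`,
#'   `loglik_trace`, `n_params`, `bic`, `n`, `d`, `converged`, `degenerate`,
#'   `n_iter`.
#' @export
fit_mixture <- function(x, spec, k = NULL, seed = 1L, z_init = NULL,
                        max_iter = 500L, tol = 1e-8) {
  if (is.character(spec)) spec <- mixture_spec(spec, k)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x); k <- spec$k
  if (n <= k) stop("need more observations (", n, ") than components (", k, ")")
  z <- if (is.null(z_init)) .init_responsibilities(x, k, seed) else z_init
  stopifnot(nrow(z) == n, ncol(z) == k)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  ms <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ms_new <- .mstep(x, z, spec$family,
                     prev_cov = if (is.null(ms)) NULL else ms$cov)
    if (is.null(ms_new)) { degenerate <- TRUE; break }
    es <- .estep(x, ms_new$w, ms_new$mu, ms_new$cov$sigma)
    if (is.null(es) || !is.finite(es$loglik)) { degenerate <- TRUE; break }
    ms <- ms_new
    trace[it] <- es$loglik
    z <- es$z
    if (it > 1L && abs(es$loglik - prev) < tol * (1 + abs(es$loglik))) {
      converged <- TRUE
      prev <- es$loglik
      break
    }
    prev <- es$loglik
  }
  if (is.null(ms)) {
    return(structure(list(spec = spec, converged = FALSE, degenerate = TRUE,
                          loglik = NA_real_, bic = NA_real_,
                          n_params = n_mixture_params(spec$family, d, k),
                          loglik_trace = trace, n = n, d = d, n_iter = it),
                     class = "fitted_mixture"))
  }
  loglik <- prev
  m <- n_mixture_params(spec$family, d, k)
  structure(list(
    spec = spec, weights = ms$w, means = ms$mu, sigma = ms$cov$sigma,
    lambda = ms$cov$lambda, shape = ms$cov$shape, orient = ms$cov$orient,
    responsibilities = z,
    assignments = max.col(z, ties.method = "first"),
    loglik = loglik, loglik_trace = trace, n_params = m,
    bic = 2 * loglik - m * log(n), n = n, d = d,
    converged = converged && !degenerate, degenerate = degenerate,
    n_iter = it), class = "fitted_mixture")
}

#' @export
print.fitted_mixture <- function(x, ...) {
  cat(sprintf("fitted_mixture %s k=%d: loglik %.4f, BIC %.4f, %s in %d iter\n",
              x$spec$family, x$spec$k,
              ifelse(is.na(x$loglik), NaN, x$loglik),
              ifelse(is.na(x$bic), NaN, x$bic),
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' `2*loglik - n_params*log(n)` under the maximize convention, so the best
#' model is the one with the largest BIC.
#'
#' @param fit a `fitted_mixture`.
#' @return numeric BIC (NA for degenerate fits).
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "fitted_mixture"))
  fit$bic
}

#' Sweep covariance families and component counts, selecting by BIC
#'
#' Fits every requested (family, k) combination with `n_restarts` seeded
#' k-means++ initializations, keeping the best final log-likelihood per
#' combination, and selects the converged fit with maximal BIC. Degenerate
#' fits are recorded as non-converged with NA BIC and excluded from
#' selection. Deterministic given `(x, seed, n_restarts)`.
#'
#' @param x numeric matrix or `feature_matrix` (rows = entities to cluster).
#' @param families subset of [MIXTURE_FAMILIES] (default all 14).
#' @param k_range integer vector of component counts (default `1:6`), each
#'   `< nrow(x)`.
#' @param n_restarts seeded initializations per combination (default 10).
#' @param seed base seed.
#' @param max_iter,tol passed to [fit_mixture()].
#' @return object of class `model_selection`: list with `table` (data frame:
#'   `family`, `k`, `loglik`, `bic`, `n_params`, `converged`) and `best`
#'   (the winning `fitted_mixture`).
#' @export
select_model <- function(x, families = MIXTURE_FAMILIES, k_range = 1:6,
                         n_restarts = 10L, seed = 1L, max_iter = 500L,
                         tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (any(k_range < 1L) || any(k_range >= n)) {
    stop("k_range must lie within [1, n-1] for n = ", n, " rows")
  }
  families <- match.arg(families, MIXTURE_FAMILIES, several.ok = TRUE)
  rows <- list()
  best <- NULL
  for (fi in seq_along(families)) {
    for (k in k_range) {
      fit_best <- NULL
      for (r in seq_len(n_restarts)) {
        s <- (as.integer(seed) + 7919L * fi + 611953L * as.integer(k) +
                15485863L * r) %% .Machine$integer.max
        fit <- fit_mixture(x, families[fi], k = k, seed = s,
                           max_iter = max_iter, tol = tol)
        if (isTRUE(fit$converged) &&
            (is.null(fit_best) || fit$loglik > fit_best$loglik)) {
          fit_best <- fit
        }
        if (k == 1L) break  # deterministic: no initialization dependence
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = families[fi], k = k,
        loglik = if (is.null(fit_best)) NA_real_ else fit_best$loglik,
        bic = if (is.null(fit_best)) NA_real_ else fit_best$bic,
        n_params = n_mixture_params(families[fi], ncol(x), k),
        converged = !is.null(fit_best), stringsAsFactors = FALSE)
      if (!is.null(fit_best) &&
          (is.null(best) || fit_best$bic > best$bic)) {
        best <- fit_best
      }
    }
  }
  table <- do.call(rbind, rows)
  if (is.null(best)) {
    stop("all fits degenerate; sweep table:\n",
         paste(utils::capture.output(print(table)), collapse = "\n"))
  }
  structure(list(table = table, best = best), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model_selection: best %s with k=%d (BIC %.3f) over %d fits\n",
              x$best$spec$family, x$best$spec$k, x$best$bic, nrow(x$table)))
  invisible(x)
}

#' Two-component scatter tables for all feature pairs
#'
#' For each unordered pair of features, a table of the two feature columns
#' with the cluster label from the full d-dimensional best fit (labels are
#' identical across pair tables).
#'
#' @param x the (standardized) matrix the selection was computed on, with row
#'   names identifying the sources.
#' @param selection a `model_selection` computed on `x`.
#' @return named list of data frames (`source_id`, `<feature i>`,
#'   `<feature j>`, `cluster`), one per feature pair, named `"fi.vs.fj"`.
#' @export
two_component_plot_data <- function(x, selection) {
  x <- as.matrix(x)
  stopifnot(inherits(selection, "model_selection"),
            nrow(x) == selection$best$n)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(x)))
  src <- rownames(x)
  if (is.null(src)) src <- paste0("row", seq_len(nrow(x)))
  cl <- selection$best$assignments
  out <- list()
  if (ncol(x) >= 2L) {
    for (i in seq_len(ncol(x) - 1L)) {
      for (j in seq((i + 1L), ncol(x))) {
        df <- data.frame(source_id = src, x[, i], x[, j], cluster = cl,
                         stringsAsFactors = FALSE)
        names(df)[2:3] <- feats[c(i, j)]
        rownames(df) <- NULL
        out[[paste(feats[i], feats[j], sep = ".vs.")]] <- df
      }
    }
  }
  out
}

#' Serialize a model selection to JSON
#' @param selection a `model_selection`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_model_selection_json <- function(selection, path) {
  best <- selection$best
  jsonlite::write_json(list(
    table = selection$table,
    best = list(family = best$spec$family, k = best$spec$k,
                loglik = best$loglik, bic = best$bic,
                n_params = best$n_params, weights = best$weights,
                means = best$means, assignments = best$assignments)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
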