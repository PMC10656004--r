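# Comparator resampling methods: naive residual permutation, MVNpermute,
# a PQL-fitted logistic mixed model sampler, and binarized variants.

#' Fit the Gaussian linear mixed model null
#'
#' REML fit of `Y = X beta + e`, `e ~ MVN(0, sigma1^2 Phi + sigma2^2 I)`,
#' by profiling the likelihood in the mixing proportion
#' `xi = sigma1^2 / (sigma1^2 + sigma2^2)` over a single eigendecomposition
#' of `Phi`.
#'
#' @param y numeric response vector (for the comparators this is the binary
#'   trait treated as quantitative).
#' @param x covariate matrix including an intercept.
#' @param phi kinship / GRM matrix; ignored when `eigen_phi` is given.
#' @param eigen_phi optional precomputed `eigen(phi, symmetric = TRUE)`.
#' @return an object of class `brass_lmm_fit` with `beta_hat`, `sigma1_sq`,
#'   `sigma2_sq`, `residuals`, the cached eigendecomposition, and
#'   `converged`.
#' @export
fit_lmm_null <- function(y, x, phi = NULL, eigen_phi = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  x <- validate_covariates(x, n)
  k <- ncol(x)
  if (is.null(eigen_phi)) {
    phi <- validate_kinship(phi, n)
    eigen_phi <- eigen(phi, symmetric = TRUE)
  }
  u <- eigen_phi$vectors
  d <- pmax(eigen_phi$values, 0)
  identity_phi <- max(abs(d - 1)) < 1e-8 # xi unidentifiable; fix xi = 0
  yt <- drop(crossprod(u, y))
  xt <- crossprod(u, x)

  # Negative REML criterion profiled over sigma^2 at fixed xi.
  neg_reml <- function(xi) {
    w <- xi * d + (1 - xi)
    xw <- xt / w
    xtwx <- crossprod(xt, xw)
    beta <- solve(xtwx, crossprod(xw, yt))
    r <- yt - drop(xt %*% beta)
    rss <- sum(r^2 / w)
    s2 <- rss / (n - k)
    0.5 * ((n - k) * log(s2) + sum(log(w)) +
             determinant(xtwx, logarithm = TRUE)$modulus)
  }
  if (identity_phi) {
    xi <- 0
  } else {
    opt <- stats::optimize(neg_reml, interval = c(0, 1 - 1e-9))
    xi <- opt$minimum
    # Guard against an interior optimum reported next to a flat boundary.
    for (cand in c(0, 1 - 1e-9)) {
      if (neg_reml(cand) < neg_reml(xi)) xi <- cand
    }
  }
  w <- xi * d + (1 - xi)
  xw <- xt / w
  beta <- drop(solve(crossprod(xt, xw), crossprod(xw, yt)))
  r <- yt - drop(xt %*% beta)
  s2 <- sum(r^2 / w) / (n - k)
  structure(
    list(beta_hat = beta, sigma1_sq = s2 * xi, sigma2_sq = s2 * (1 - xi),
         residuals = y - drop(x %*% beta), fitted = drop(x %*% beta),
         eigvecs = u, eigvals = d, omega_eigvals = s2 * w,
         x = x, y = y, converged = TRUE),
    class = "brass_lmm_fit"
  )
}

#' Naive residual-permutation replicates
#'
#' `Y_pi = X beta_hat + Pi (Y - X beta_hat)`: LMM residuals are permuted
#' without any decorrelation.
#'
#' @param lmm a [fit_lmm_null()] result.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param permutations optional list of explicit permutations of length n.
#' @return a `brass_replicates` object (real-valued).
#' @export
naive_replicates <- function(lmm, n_reps, seed = NULL, permutations = NULL) {
  stopifnot(inherits(lmm, "brass_lmm_fit"))
  reps <- permute_backtransform(lmm$fitted, diag(length(lmm$y)),
                                lmm$residuals, n_reps, seed, permutations)
  new_replicate_set(reps, seed, binary = FALSE, method = "naive")
}

#' MVNpermute replicates
#'
#' The Gaussian analog of the binary-trait transform: with
#' `Omega_L = sigma1^2 Phi + sigma2^2 I`, a factorization `C_L` with
#' `C_L^T C_L = Omega_L` decorrelates the LMM residuals, the component along
#' `W_L = C_L^-T X` is projected out, the remainder is permuted and
#' back-transformed:
#' `Y_pi = X beta_hat + C_L^T V_L Pi V_L^T C_L^-T (Y - X beta_hat)`.
#'
#' @inheritParams naive_replicates
#' @param permutations optional list of explicit permutations of length
#'   `n - k`.
#' @return a `brass_replicates` object (real-valued).
#' @export
mvnpermute_replicates <- function(lmm, n_reps, seed = NULL,
                                  permutations = NULL) {
  stopifnot(inherits(lmm, "brass_lmm_fit"))
  n <- length(lmm$y)
  k <- ncol(lmm$x)
  sql <- sqrt(pmax(lmm$omega_eigvals, 1e-12))
  ut <- t(lmm$eigvecs)
  c_factor <- sql * ut
  c_inv_t <- ut / sql
  w <- c_inv_t %*% lmm$x
  qrw <- qr(w)
  if (qrw$rank < k) stop("W = C^-T X is rank deficient")
  v <- qr.Q(qrw, complete = TRUE)[, (k + 1):n, drop = FALSE]
  zeta <- drop(crossprod(v, c_inv_t %*% lmm$residuals))
  reps <- permute_backtransform(lmm$fitted, crossprod(c_factor, v), zeta,
                                n_reps, seed, permutations)
  new_replicate_set(reps, seed, binary = FALSE, method = "mvnpermute")
}

#' Fit a logistic mixed model by penalized quasi-likelihood
#'
#' Model: given `u ~ MVN(0, sigma^2 Phi)`, `Y_i ~ Bernoulli(m_i)`
#' independently with `logit(m) = X beta + u`. Fitting alternates (i) a
#' working-response linear mixed model step
#' `z = X beta + u + Gamma(m)^-1 (Y - m)` with weight matrix
#' `Gamma(m) = diag(m_i (1 - m_i))`, solved through an eigendecomposition of
#' `Gamma^1/2 Phi Gamma^1/2`, and (ii) a one-dimensional REML update of
#' `sigma^2` on the working model, iterated to joint convergence. PQL is
#' fast but known to bias `sigma^2` downward for binary data; the sampler
#' built on it inherits that bias.
#'
#' @inheritParams fit_lmm_null
#' @param tol_inner tolerance for the working-model coefficient updates.
#' @param tol_outer tolerance for the outer (beta, sigma^2) iteration.
#' @param max_iter maximum outer iterations.
#' @return an object of class `brass_pql_fit` with `beta_hat`, `sigma_sq`,
#'   `u_hat`, `m_hat` and `working_converged`.
#' @export
fit_pql_logmm <- function(y, x, phi = NULL, eigen_phi = NULL,
                          tol_inner = 1e-6, tol_outer = 1e-4,
                          max_iter = 50L) {
  y <- validate_phenotype(y)
  n <- length(y)
  x <- validate_covariates(x, n)
  if (is.null(eigen_phi)) {
    phi <- validate_kinship(phi, n)
    eigen_phi <- eigen(phi, symmetric = TRUE)
  }
  u_phi <- eigen_phi$vectors
  d_phi <- pmax(eigen_phi$values, 0)
  eps <- 1e-10

  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(x, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, ncol(x))
  )
  if (anyNA(beta)) beta <- rep(0, ncol(x))
  uvec <- rep(0, n)
  s2 <- 0.5
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta) + uvec
    m <- clamp(inv_logit(eta), eps, 1 - eps)
    gam <- m * (1 - m)
    z <- eta + (y - m) / gam
    # Working model: z = X beta + e*, Var(e*) = s2 Phi + diag(1/gam).
    # Whitening by Gamma^1/2: zt = Q^T Gamma^1/2 z has variance
    # s2 diag(kappa) + I with K = Gamma^1/2 Phi Gamma^1/2 = Q diag(kappa) Q^T.
    sg <- sqrt(gam)
    kmat <- sg * t(sg * u_phi %*% (d_phi * t(u_phi)))
    ek <- eigen((kmat + t(kmat)) / 2, symmetric = TRUE)
    q <- ek$vectors
    kap <- pmax(ek$values, 0)
    zt <- drop(crossprod(q, sg * z))
    xt <- crossprod(q, sg * x)
    # Fixed unit dispersion (Bernoulli): V = s2 K + I in the whitened basis,
    # with no free multiplier to profile out.
    neg_reml <- function(ls2) {
      w <- exp(ls2) * kap + 1
      xw <- xt / w
      xtwx <- crossprod(xt, xw)
      bb <- solve(xtwx, crossprod(xw, zt))
      r <- zt - drop(xt %*% bb)
      0.5 * (sum(r^2 / w) + sum(log(w)) +
               determinant(xtwx, logarithm = TRUE)$modulus)
    }
    opt <- stats::optimize(neg_reml, interval = c(log(1e-8), log(100)))
    s2_new <- exp(opt$minimum)
    if (neg_reml(log(1e-12)) <= opt$objective) s2_new <- 0
    # Dispersion of the working model is fixed at 1 (Bernoulli); only the
    # ratio matters for (beta, u), so rescale the REML profile estimate.
    w <- s2_new * kap + 1
    xw <- xt / w
    beta_new <- drop(solve(crossprod(xt, xw), crossprod(xw, zt)))
    resid_t <- zt - drop(xt %*% beta_new)
    # u = s2 Phi V^-1 (z - X beta); in the whitened basis V^-1 acts as 1/w.
    uvec_new <- drop(u_phi %*% (d_phi * t(u_phi) %*% (sg * (q %*% (resid_t / w))))) * s2_new
    delta <- max(abs(beta_new - beta), abs(s2_new - s2))
    beta <- beta_new
    uvec <- uvec_new
    s2 <- s2_new
    if (delta < tol_outer) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("PQL fit did not converge in ", max_iter, " iterations")
  m <- clamp(inv_logit(drop(x %*% beta) + uvec), eps, 1 - eps)
  structure(
    list(beta_hat = beta, sigma_sq = max(s2, 0), u_hat = uvec, m_hat = m,
         working_converged = converged, x = x, y = y,
         eigvecs = u_phi, eigvals = d_phi),
    class = "brass_pql_fit"
  )
}

#' Binary replicates sampled from a fitted logistic mixed model
#'
#' Per replicate, draws `u ~ MVN(0, sigma_hat^2 Phi)` through the cached
#' factorization of `Phi` and then `Y_i ~ Bernoulli(logit^-1(x_i beta_hat +
#' u_i))` independently given `u`.
#'
#' @param fit a [fit_pql_logmm()] result.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return a `brass_replicates` object with binary entries.
#' @export
logmm_sample_replicates <- function(fit, n_reps, seed = NULL) {
  stopifnot(inherits(fit, "brass_pql_fit"))
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps <= 0) {
    stop("n_reps must be a positive count")
  }
  n_reps <- as.integer(n_reps)
  n <- length(fit$y)
  xb <- drop(fit$x %*% fit$beta_hat)
  half <- scale_cols(fit$eigvecs, sqrt(pmax(fit$eigvals, 0) * fit$sigma_sq))
  reps <- with_seed(seed, {
    umat <- half %*% matrix(stats::rnorm(n * n_reps), n, n_reps)
    pmat <- inv_logit(xb + umat)
    matrix(stats::rbinom(n * n_reps, 1L, pmat), n, n_reps)
  })
  new_replicate_set(t(reps), seed, binary = TRUE, method = "logmm_pql")
}

#' Binarize real-valued replicates to match the observed case count
#'
#' For each replicate, the entries with the largest values are set to 1 so
#' that the replicate has exactly as many cases as the observed trait; ties
#' at the threshold are broken by stable sample-index order.
#'
#' @param reps a real-valued `brass_replicates` object.
#' @param y the observed binary phenotype.
#' @return a binary `brass_replicates` object; the method name gains a
#'   `_mod` suffix.
#' @export
binarize_replicates <- function(reps, y) {
  stopifnot(inherits(reps, "brass_replicates"))
  if (reps$binary) stop("replicates are already binary")
  y <- validate_phenotype(y)
  n <- ncol(reps$replicates)
  if (length(y) != n) stop("phenotype length does not match replicates")
  n_case <- as.integer(ceiling(sum(y)))
  out <- t(apply(reps$replicates, 1, function(r) {
    z <- numeric(n)
    # order() with the radix method is stable, so ties at the threshold
    # resolve to the smaller sample index.
    z[order(-r, method = "radix")[seq_len(n_case)]] <- 1
    z
  }))
  new_replicate_set(out, reps$permutation_seed, binary = TRUE,
                    method = paste0(reps$method, "_mod"))
}

#' Unified resampling front-end
#'
#' Dispatches to one of the seven resampling methods; model fits may be
#' passed in to share work across methods, otherwise they are computed.
#'
#' @param y binary phenotype vector.
#' @param x covariate matrix including an intercept.
#' @param phi kinship / GRM; ignored when `eigen_phi` is given.
#' @param method one of `"brass"`, `"brass_mod"`, `"mvnpermute"`,
#'   `"mvnpermute_mod"`, `"naive"`, `"naive_mod"`, `"logmm_pql"`.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param eigen_phi optional precomputed eigendecomposition of `phi`.
#' @param fit optional prefit [fit_null_model()] (brass variants).
#' @param lmm optional prefit [fit_lmm_null()] (naive / mvnpermute variants).
#' @param pql optional prefit [fit_pql_logmm()] (logmm_pql).
#' @return a `brass_replicates` object.
#' @export
resample_traits <- function(y, x, phi = NULL,
                            method = c("brass", "brass_mod", "mvnpermute",
                                       "mvnpermute_mod", "naive", "naive_mod",
                                       "logmm_pql"),
                            n_reps = 1000L, seed = NULL, eigen_phi = NULL,
                            fit = NULL, lmm = NULL, pql = NULL) {
  method <- match.arg(method)
  base <- sub("_mod$", "", method)
  reps <- switch(
    base,
    brass = {
      if (is.null(fit)) fit <- fit_null_model(y, x, phi, eigen_phi = eigen_phi)
      generate_replicates(y, fit, build_transform(fit), n_reps, seed)
    },
    naive = {
      if (is.null(lmm)) lmm <- fit_lmm_null(y, x, phi, eigen_phi = eigen_phi)
      naive_replicates(lmm, n_reps, seed)
    },
    mvnpermute = {
      if (is.null(lmm)) lmm <- fit_lmm_null(y, x, phi, eigen_phi = eigen_phi)
      mvnpermute_replicates(lmm, n_reps, seed)
    },
    logmm_pql = {
      if (is.null(pql)) pql <- fit_pql_logmm(y, x, phi, eigen_phi = eigen_phi)
      logmm_sample_replicates(pql, n_reps, seed)
    }
  )
  if (grepl("_mod$", method)) reps <- binarize_replicates(reps, y) else reps
}
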