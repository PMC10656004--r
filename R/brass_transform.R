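# Decorrelating transform of the phenotypic residuals and replicate
# generation.
#
# After the null fit, the residual vector Y - mu_hat carries correlation
# from two sources: the polygenic covariance through Omega, and the use of
# an estimated mean. A factorization C with C^T C = Omega_hat removes the
# first; projecting onto the orthogonal complement of W = C^-T Gamma_hat X
# removes the second. The resulting vector zeta = V^T C^-T (Y - mu_hat)
# has approximately unit-variance, uncorrelated entries (second-order
# exchangeability), so permuting it and back-transforming
#   Y_pi = mu_hat + C^T V Pi V^T C^-T (Y - mu_hat)
# yields trait replicates that preserve the fitted mean and covariance
# structure. Replicates are real-valued; see [binarize_replicates()] for the
# thresholded variants.

#' First-order approximation to the residual covariance
#'
#' Evaluates `Omega - Gamma X (X^T Gamma Omega^-1 Gamma X)^-1 X^T Gamma` at
#' the fitted null parameters: the covariance of `Y - mu_hat` accounting for
#' the estimation of `beta`.
#'
#' @param fit a converged [fit_null_model()] result.
#' @return n x n symmetric matrix.
#' @export
residual_covariance <- function(fit) {
  stopifnot(inherits(fit, "brass_null_fit"))
  if (!fit$converged) stop("null model fit did not converge")
  gx <- fit$gamma_diag * fit$x
  # X^T Gamma Omega^-1 Gamma X = W^T W with W = C^-T Gamma X
  wtw <- crossprod(gx, omega_inverse_multiply(fit, gx))
  middle <- tryCatch(solve(wtw), error = function(e) {
    stop("X^T Gamma Omega^-1 Gamma X is singular; collinear covariates")
  })
  m <- omega_matrix(fit) - gx %*% middle %*% t(gx)
  (m + t(m)) / 2
}

#' Build the decorrelating transform from a fitted null model
#'
#' Constructs `C = Sigma_factor %*% Gamma^1/2` with `C^T C = Omega_hat`,
#' `W = C^-T Gamma_hat X`, and an orthonormal basis `V` of the orthogonal
#' complement of the column space of `W` (the eigenvalue-1 eigenspace of the
#' projector `I - W (W^T W)^-1 W^T`), computed from the full QR
#' decomposition of `W` without materializing the projector.
#'
#' @param fit a converged [fit_null_model()] result.
#' @return an object of class `brass_transform` with elements `c_factor`
#'   (C), `c_inv_t` (C^-T), `w`, `v`, `zeta_hat`, `mu_hat`, `back` (the
#'   back-map `C^T V`), and `k`.
#' @export
build_transform <- function(fit) {
  stopifnot(inherits(fit, "brass_null_fit"))
  if (!fit$converged) stop("null model fit did not converge")
  n <- length(fit$y)
  k <- ncol(fit$x)
  if (k >= n) stop("need k < n covariates to build the transform")
  sg <- sqrt(fit$gamma_diag)
  sql <- sqrt(fit$sigma_eigvals)
  ut <- t(fit$eigvecs)
  c_factor <- scale_cols(sql * ut, sg)      # diag(sqrt(lam)) U^T diag(sg)
  c_inv_t <- scale_cols(ut / sql, 1 / sg)   # diag(1/sqrt(lam)) U^T diag(1/sg)
  w <- c_inv_t %*% (fit$gamma_diag * fit$x)
  qrw <- qr(w)
  if (qrw$rank < k) stop("W = C^-T Gamma X is rank deficient")
  q <- qr.Q(qrw, complete = TRUE)
  v <- q[, (k + 1):n, drop = FALSE]
  zeta <- drop(crossprod(v, c_inv_t %*% (fit$y - fit$mu_hat)))
  structure(
    list(c_factor = c_factor, c_inv_t = c_inv_t, w = w, v = v,
         zeta_hat = zeta, mu_hat = fit$mu_hat,
         back = crossprod(c_factor, v), k = k),
    class = "brass_transform"
  )
}

# Shared permute-and-backtransform engine: replicate r is
#   base + back %*% zeta[perm_r].
# `permutations` (a list of index vectors) overrides random draws, which is
# how the exhaustive small-n oracles enumerate the full replicate set.
permute_backtransform <- function(base, back, zeta, n_reps, seed,
                                  permutations = NULL) {
  m <- length(zeta)
  if (is.null(permutations)) {
    if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps <= 0) {
      stop("n_reps must be a positive count")
    }
    n_reps <- as.integer(n_reps)
    zmat <- with_seed(seed, {
      vapply(seq_len(n_reps), function(r) zeta[sample.int(m)], numeric(m))
    })
  } else {
    stopifnot(all(vapply(permutations, length, 1L) == m))
    zmat <- vapply(permutations, function(p) zeta[p], numeric(m))
  }
  t(base + back %*% zmat) # replicates in rows
}

new_replicate_set <- function(replicates, seed, binary, method) {
  structure(list(replicates = replicates, permutation_seed = seed,
                 binary = binary, method = method),
            class = "brass_replicates")
}

#' @export
print.brass_replicates <- function(x, ...) {
  cat("Trait replicate set:", nrow(x$replicates), "replicates x",
      ncol(x$replicates), "samples (method:", x$method,
      if (x$binary) ", binary)\n" else ", real-valued)\n")
  invisible(x)
}

#' Generate trait replicates by permuting the exchangeable residuals
#'
#' Draws `n_reps` independent uniform-random permutations of `zeta_hat` and
#' back-transforms each to the trait scale. The identity permutation
#' reproduces `y` exactly; replicates are real-valued.
#'
#' @param y the observed binary phenotype the transform was fitted to.
#' @param fit the [fit_null_model()] result.
#' @param transform the [build_transform()] result built from `fit`.
#' @param n_reps number of replicates.
#' @param seed integer seed controlling the permutations.
#' @param permutations optional list of explicit permutations (index
#'   vectors of length `n - k`) overriding the random draws.
#' @return a `brass_replicates` object whose `replicates` element is an
#'   `n_reps x n` matrix with one replicate per row.
#' @export
generate_replicates <- function(y, fit, transform, n_reps, seed = NULL,
                                permutations = NULL) {
  stopifnot(inherits(fit, "brass_null_fit"),
            inherits(transform, "brass_transform"))
  y <- validate_phenotype(y)
  if (!isTRUE(all.equal(y, fit$y, tolerance = 1e-12))) {
    stop("transform must be built from the same phenotype vector")
  }
  reps <- permute_backtransform(transform$mu_hat, transform$back,
                                transform$zeta_hat, n_reps, seed,
                                permutations)
  new_replicate_set(reps, seed, binary = FALSE, method = "brass")
}
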