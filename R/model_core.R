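# Quasi-likelihood null model for a correlated binary trait.
#
# The model specifies only the first two conditional moments of the trait:
#   E(Y | X)   = mu = logit^-1(X beta)
#   Var(Y | X) = Omega = Gamma^1/2 Sigma Gamma^1/2,
# with Gamma = diag(mu_i (1 - mu_i)) and Sigma = xi Phi + (1 - xi) I, where
# Phi is a kinship/genetic relatedness matrix and xi in [0, 1] acts as a
# heritability parameter. (beta, xi) are estimated under the null of no
# marker effect by solving the quasi-score equation for beta jointly with a
# method-of-moments equation for xi.

#' Inverse-logit mean under the null model
#'
#' Computes `mu = logit^-1(X beta)`, clamped away from 0 and 1 so that the
#' variance function `mu (1 - mu)` stays invertible.
#'
#' @param x numeric covariate matrix (n x k), including an intercept column.
#' @param beta numeric coefficient vector of length k.
#' @param eps clamping bound; fitted means are restricted to
#'   `[eps, 1 - eps]`.
#' @return numeric vector of length n of fitted means.
#' @examples
#' x <- cbind(1, rnorm(5))
#' inverse_logit_mean(x, c(0, 0)) # all 0.5
#' @export
inverse_logit_mean <- function(x, beta, eps = 1e-10) {
  x <- as.matrix(x)
  beta <- as.numeric(beta)
  if (ncol(x) != length(beta)) {
    stop("dimension mismatch: x has ", ncol(x), " columns but beta has length ",
         length(beta))
  }
  clamp(inv_logit(drop(x %*% beta)), eps, 1 - eps)
}

#' Trait covariance profile Sigma = xi Phi + (1 - xi) I
#'
#' @param phi kinship / GRM matrix (n x n, symmetric PSD).
#' @param xi heritability-like mixing parameter in `[0, 1]`.
#' @return n x n matrix `xi * phi + (1 - xi) * I`.
#' @export
build_sigma <- function(phi, xi) {
  phi <- validate_kinship(phi)
  if (length(xi) != 1L || is.na(xi) || xi < 0 || xi > 1) {
    stop("xi must be a scalar in [0, 1]")
  }
  sigma <- xi * phi
  diag(sigma) <- diag(sigma) + (1 - xi)
  sigma
}

#' Trait variance matrix Omega = Gamma^1/2 Sigma Gamma^1/2
#'
#' Most callers should work with a factorization instead of the dense matrix
#' (see [build_transform()]); this constructor exists for small problems and
#' for checking.
#'
#' @param mu vector of means, each strictly inside (0, 1).
#' @param sigma covariance profile from [build_sigma()].
#' @return n x n symmetric matrix.
#' @export
build_omega <- function(mu, sigma) {
  mu <- as.numeric(mu)
  if (any(mu <= 0 | mu >= 1)) {
    stop("mu touches {0,1}; clamp the fitted means before forming Omega ",
         "(offending indices: ",
         paste(utils::head(which(mu <= 0 | mu >= 1), 5), collapse = ", "), ")")
  }
  sg <- sqrt(mu * (1 - mu))
  sg * t(sg * sigma) # Gamma^1/2 Sigma Gamma^1/2 via row and column scaling
}

# Left-hand side minus right-hand side of the xi estimating equation,
# written in the eigenbasis of Phi: with Phi = U diag(d) U^T,
# Sigma(xi) has eigenvalues lam = xi d + (1 - xi), and for
# t = U^T Gamma^-1/2 (y - mu),
#   h(xi) = sum t_i^2 (d_i - 1) / lam_i^2 - sum (d_i - 1) / lam_i.
xi_moment_residual <- function(xi, tvec, d) {
  lam <- pmax(xi * d + (1 - xi), 1e-12)
  sum(tvec^2 * (d - 1) / lam^2) - sum((d - 1) / lam)
}

#' Fit the quasi-likelihood null model
#'
#' Estimates `(beta, xi)` by alternating Fisher-scoring updates for `beta`
#' (holding `xi`) with a one-dimensional root-find for `xi` on `[0, 1]`
#' (holding `beta`). All `Sigma(xi)` factorizations are obtained from a single
#' eigendecomposition of `phi`, so each `xi` evaluation costs O(n^2).
#'
#' When `phi` is (numerically) the identity, the moment equation for `xi` is
#' degenerate; `xi` is then set to 0 by convention and `beta` coincides with
#' the ordinary logistic-regression MLE.
#'
#' @param y binary phenotype vector (0/1), at least one case and one control.
#' @param x covariate matrix including an intercept column.
#' @param phi kinship / GRM matrix. May be omitted when `eigen_phi` is given.
#' @param eigen_phi optional precomputed `eigen(phi, symmetric = TRUE)`; used
#'   to share one decomposition across many fits with the same `phi`.
#' @param eps clamping bound for fitted means.
#' @param tol convergence tolerance on `max(|delta beta|)` and `|delta xi|`.
#' @param max_iter maximum number of outer iterations.
#' @return an object of class `brass_null_fit` with elements `beta_hat`,
#'   `xi_hat`, `mu_hat`, `gamma_diag`, `eigvecs`, `eigvals` (of `phi`),
#'   `sigma_eigvals` (of `Sigma(xi_hat)`), `converged`, `n_iter`,
#'   `xi_boundary` (TRUE when the moment equation had no interior root), and
#'   the data `y`, `x`.
#' @export
fit_null_model <- function(y, x, phi = NULL, eigen_phi = NULL, eps = 1e-10,
                           tol = 1e-6, max_iter = 100L) {
  y <- validate_phenotype(y)
  n <- length(y)
  x <- validate_covariates(x, n)
  k <- ncol(x)
  if (is.null(eigen_phi)) {
    if (is.null(phi)) stop("either phi or eigen_phi must be supplied")
    phi <- validate_kinship(phi, n)
    eigen_phi <- eigen(phi, symmetric = TRUE)
  }
  u <- eigen_phi$vectors
  d <- eigen_phi$values
  if (length(d) != n) stop("eigendecomposition does not match sample size")
  # tolerance accommodates single-precision GRM files (GCTA .grm.bin)
  if (min(d) < -1e-6) {
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         format(min(d)), ")")
  }
  d <- pmax(d, 0)
  identity_phi <- max(abs(d - 1)) < 1e-8

  # Initialize beta from plain logistic regression ignoring Phi.
  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(x, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, k)
  )
  if (anyNA(beta)) beta <- rep(0, k)
  xi <- if (identity_phi) 0 else 0.5
  xi_boundary <- FALSE

  fisher_beta <- function(beta, xi, step_tol = tol) {
    lam <- pmax(xi * d + (1 - xi), 1e-12)
    for (it in seq_len(50L)) {
      mu <- clamp(inv_logit(drop(x %*% beta)), eps, 1 - eps)
      sg <- sqrt(mu * (1 - mu))
      a <- crossprod(u, x * sg)             # U^T Gamma^1/2 X
      s <- crossprod(u, (y - mu) / sg)      # U^T Gamma^-1/2 (y - mu)
      score <- crossprod(a, s / lam)
      info <- crossprod(a, a / lam)
      delta <- tryCatch(solve(info, score), error = function(e) {
        stop("singular information matrix; covariates may be collinear")
      })
      beta <- beta + drop(delta)
      if (max(abs(delta)) < step_tol) break
    }
    beta
  }

  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    beta_new <- fisher_beta(beta, xi)
    if (identity_phi) {
      xi_new <- 0
    } else {
      mu <- clamp(inv_logit(drop(x %*% beta_new)), eps, 1 - eps)
      tvec <- drop(crossprod(u, (y - mu) / sqrt(mu * (1 - mu))))
      h0 <- xi_moment_residual(0, tvec, d)
      h1 <- xi_moment_residual(1, tvec, d)
      if (is.finite(h0) && is.finite(h1) && h0 * h1 < 0) {
        xi_new <- stats::uniroot(xi_moment_residual, c(0, 1), tvec = tvec,
                                 d = d, tol = 1e-9)$root
        xi_boundary <- FALSE
      } else {
        xi_new <- if (abs(h0) <= abs(h1)) 0 else 1
        xi_boundary <- TRUE
      }
    }
    done <- max(abs(beta_new - beta)) < tol && abs(xi_new - xi) < tol
    beta <- beta_new
    xi <- xi_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("null model did not converge in ", max_iter, " iterations")
  }
  # polish beta at the final xi so the quasi-score is zero to near machine
  # precision; downstream identity-permutation exactness depends on it
  beta <- fisher_beta(beta, xi, step_tol = 1e-12)
  if (xi_boundary && !identity_phi) {
    message("xi estimate hit the boundary of [0, 1]: xi_hat = ", xi)
  }

  mu <- clamp(inv_logit(drop(x %*% beta)), eps, 1 - eps)
  if (any(mu <= eps | mu >= 1 - eps)) {
    warning("fitted means pinned at the clamping bounds; ",
            "possible separation in the covariates")
  }
  structure(
    list(beta_hat = beta, xi_hat = xi, mu_hat = mu,
         gamma_diag = mu * (1 - mu),
         eigvecs = u, eigvals = d,
         sigma_eigvals = pmax(xi * d + (1 - xi), 1e-12),
         converged = converged, n_iter = n_iter, xi_boundary = xi_boundary,
         eps = eps, y = y, x = x),
    class = "brass_null_fit"
  )
}

#' @export
print.brass_null_fit <- function(x, ...) {
  cat("Quasi-likelihood null model fit\n")
  cat("  n =", length(x$y), " covariates k =", ncol(x$x), "\n")
  cat("  xi_hat =", format(x$xi_hat, digits = 4),
      if (x$xi_boundary) "(boundary)" else "", "\n")
  cat("  beta_hat =", paste(format(x$beta_hat, digits = 4), collapse = ", "), "\n")
  cat("  converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

# Action of Omega^-1 = Gamma^-1/2 Sigma^-1 Gamma^-1/2 on a vector/matrix,
# through the cached eigendecomposition.
omega_inverse_multiply <- function(fit, v) {
  v <- as.matrix(v)
  sg <- sqrt(fit$gamma_diag)
  w <- crossprod(fit$eigvecs, v / sg)
  (fit$eigvecs %*% (w / fit$sigma_eigvals)) / sg
}

# Dense Omega^-1 for vectorized replicate scans (one O(n^2) build per fit).
omega_inverse_matrix <- function(fit) {
  sg <- sqrt(fit$gamma_diag)
  a <- scale_cols(t(fit$eigvecs) / sqrt(fit$sigma_eigvals), 1 / sg)
  # Omega^-1 = (diag(1/sqrt(lam)) U^T diag(1/sg))^T (same) = a^T a
  crossprod(a)
}

# Dense Omega for checking and for the residual-covariance approximation.
omega_matrix <- function(fit) {
  sg <- sqrt(fit$gamma_diag)
  b <- scale_cols(sqrt(fit$sigma_eigvals) * t(fit$eigvecs), sg)
  crossprod(b)
}

#' Quasi-score residual of a fitted null model
#'
#' Returns `X^T Gamma Omega^-1 (Y - mu)` evaluated at the fit; its max-norm
#' is the convergence criterion for the mean model.
#'
#' @param fit a `brass_null_fit`.
#' @return numeric vector of length k.
#' @export
quasi_score <- function(fit) {
  stopifnot(inherits(fit, "brass_null_fit"))
  drop(crossprod(fit$gamma_diag * fit$x,
                 omega_inverse_multiply(fit, fit$y - fit$mu_hat)))
}
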