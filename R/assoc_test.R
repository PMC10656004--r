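# Retrospective quasi-score association test for single markers, usable on
# both the observed binary trait and real-valued trait replicates.
#
# The score for the genotype effect is the quasi-score with Jacobian
# Gamma G, i.e. S = G^T R with the weighted residual
# R = Gamma_hat Omega_hat^-1 (Y - mu_hat); the statistic is
# T = S^2 / (sigma_g^2 * R^T Phi_adj R), referred to chi-square with 1 df
# (the retrospective variance of S given the trait treats the genotype as
# random with covariance sigma_g^2 Phi_adj). The quasi-score equation for
# beta makes R orthogonal to X, so genotype components aligned with the
# covariates (including the removed PCs and the intercept) cancel from the
# numerator. The
# genotype-variance scale sigma_g^2 is estimated either from the allele
# frequency (original form) or from the quadratic form G^T P G / (n - D - 1)
# with P the Phi_adj^-1-based projection complement (modified form), which
# accounts for the relatedness of the individuals contributing to the
# variance estimate.

#' Allele-frequency genotype-variance estimate
#'
#' `sigma_g^2 = 2 f (1 - f)` with `f = mean(G) / 2`.
#'
#' @param g genotype dosage vector in `[0, 2]`.
#' @return scalar variance estimate (0 for a monomorphic marker).
#' @export
genotype_variance_original <- function(g) {
  g <- validate_genotype(g)
  f <- mean(g) / 2
  2 * f * (1 - f)
}

#' Structure-adjusted genotype-variance estimate
#'
#' `sigma_g^2 = G^T P G / (n - D - 1)` with
#' `P = A^-1 - A^-1 Z (Z^T A^-1 Z)^-1 Z^T A^-1`, `A` the PC-adjusted GRM and
#' `Z = [removed PCs | 1]`. `P` annihilates the span of `Z`, so constant
#' markers (and markers fully explained by the removed PCs) get variance 0
#' and are reported untestable.
#'
#' @param g genotype dosage vector.
#' @param structure a [remove_top_pcs()] result.
#' @return scalar variance estimate.
#' @export
genotype_variance_modified <- function(g, structure) {
  stopifnot(inherits(structure, "brass_structure"))
  g <- validate_genotype(g, nrow(structure$phi))
  drop(crossprod(g, project_complement(structure, g))) /
    (length(g) - structure$d - 1)
}

# P %*% v for the modified estimator, via cached pieces.
project_complement <- function(structure, v) {
  v <- as.matrix(v)
  ainv_v <- phi_adj_inverse_multiply(structure, v)
  ainv_v - structure$ainv_z %*%
    (structure$ztainvz_inv %*% crossprod(structure$z, ainv_v))
}

#' Quasi-score association test of one marker
#'
#' @param y_or_replicate trait vector: the observed 0/1 phenotype or a
#'   real-valued replicate with matching first and second moments.
#' @param g genotype dosage vector.
#' @param structure a [remove_top_pcs()] result (provides the adjusted GRM).
#' @param fit the [fit_null_model()] result for the observed data; replicate
#'   scans reuse it, which for the permutation replicates preserves the
#'   score orthogonality exactly.
#' @param estimator `"modified"` (default) or `"original"` genotype-variance
#'   estimator.
#' @return an object of class `brass_score_test`: a list with `statistic`,
#'   `p_value`, `sigma_g_sq`, `estimator_kind`, and `untestable`.
#' @export
carat_test <- function(y_or_replicate, g, structure, fit,
                       estimator = c("modified", "original")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(fit, "brass_null_fit"),
            inherits(structure, "brass_structure"))
  yv <- as.numeric(y_or_replicate)
  n <- length(fit$y)
  if (length(yv) != n) stop("trait vector has wrong length")
  g <- validate_genotype(g, n)
  sg2 <- switch(estimator,
                modified = genotype_variance_modified(g, structure),
                original = genotype_variance_original(g))
  r <- fit$gamma_diag * drop(omega_inverse_multiply(fit, yv - fit$mu_hat))
  quad <- drop(crossprod(r, structure$phi_adj %*% r))
  if (sg2 <= 1e-8 || quad <= 0) {
    out <- list(statistic = 0, p_value = 1, sigma_g_sq = sg2,
                estimator_kind = estimator, untestable = TRUE)
  } else {
    stat <- drop(crossprod(r, g))^2 / (sg2 * quad)
    out <- list(statistic = stat,
                p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                sigma_g_sq = sg2, estimator_kind = estimator,
                untestable = FALSE)
  }
  class(out) <- "brass_score_test"
  out
}

#' @export
print.brass_score_test <- function(x, ...) {
  cat("Quasi-score test:", "statistic =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4),
      if (x$untestable) " (untestable marker)" else "", "\n")
  invisible(x)
}

#' Minimum p-value over a marker panel
#'
#' Runs [carat_test()] on each marker and returns the smallest p-value;
#' untestable markers are excluded.
#'
#' @inheritParams carat_test
#' @param panel n x m genotype dosage matrix.
#' @return scalar minimum p-value.
#' @export
min_p_scan <- function(y_or_replicate, panel, structure, fit,
                       estimator = c("modified", "original")) {
  estimator <- match.arg(estimator)
  panel <- as.matrix(panel)
  if (ncol(panel) < 1) stop("panel must contain at least one marker")
  p <- vapply(seq_len(ncol(panel)), function(j) {
    res <- carat_test(y_or_replicate, panel[, j], structure, fit, estimator)
    if (res$untestable) NA_real_ else res$p_value
  }, numeric(1))
  if (all(is.na(p))) stop("all markers untestable")
  min(p, na.rm = TRUE)
}

#' Vectorized minimum-p scan of a replicate set
#'
#' Computes the per-replicate minimum quasi-score p-value over a marker
#' panel in a handful of matrix products, reusing the observed-data null
#' fit. For the real-valued permutation replicates this reuse is exact: the
#' back-transformed residual satisfies the quasi-score equation of the
#' observed fit identically. Binary resampled replicates (logistic mixed
#' model draws, binarized variants) carry their own realized structure and
#' must be analyzed like the observed data, with their own null fit; pass
#' `refit = TRUE` for those (done automatically for a `brass_replicates`
#' input flagged binary).
#'
#' @param traits n x L matrix of trait vectors in columns (e.g.
#'   `t(reps$replicates)`), or a `brass_replicates` object.
#' @param refit refit the null model per replicate instead of reusing
#'   `fit`; defaults to the replicate set's binary flag.
#' @inheritParams min_p_scan
#' @return numeric vector of L minimum p-values (NA for replicates whose
#'   null fit failed, with a warning).
#' @export
scan_min_p <- function(traits, panel, structure, fit,
                       estimator = c("modified", "original"),
                       refit = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(traits, "brass_replicates")) {
    if (is.null(refit)) refit <- traits$binary
    traits <- t(traits$replicates)
  }
  if (isTRUE(refit)) {
    return(scan_min_p_refit(traits, panel, structure, fit, estimator))
  }
  traits <- as.matrix(traits)
  panel <- as.matrix(panel)
  n <- length(fit$y)
  stopifnot(nrow(traits) == n, nrow(panel) == n)
  sg2 <- switch(
    estimator,
    modified = colSums(panel * project_complement(structure, panel)) /
      (n - structure$d - 1),
    original = apply(panel, 2, genotype_variance_original)
  )
  testable <- sg2 > 1e-8
  if (!any(testable)) stop("all markers untestable")
  rmat <- fit$gamma_diag * (omega_inverse_matrix(fit) %*% (traits - fit$mu_hat))
  quad <- colSums(rmat * (structure$phi_adj %*% rmat)) # length L
  numer <- crossprod(panel[, testable, drop = FALSE], rmat)^2 # m* x L
  stat <- numer / (sg2[testable] * rep(quad, each = sum(testable)))
  pmat <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pmat[!is.finite(pmat)] <- 1 # degenerate replicate (zero residual)
  apply(pmat, 2, min)
}

# Per-replicate refit scan for binary replicates: each replicate gets its
# own quasi-likelihood null fit (sharing the cached eigendecomposition of
# the GRM), then the quasi-score scan with per-marker variances precomputed
# once across replicates.
scan_min_p_refit <- function(traits, panel, structure, fit, estimator) {
  eig <- list(vectors = fit$eigvecs, values = fit$eigvals)
  n <- nrow(traits)
  sg2 <- switch(
    estimator,
    modified = colSums(panel * project_complement(structure, panel)) /
      (n - structure$d - 1),
    original = apply(panel, 2, genotype_variance_original)
  )
  testable <- sg2 > 1e-8
  if (!any(testable)) stop("all markers untestable")
  panel_t <- panel[, testable, drop = FALSE]
  out <- vapply(seq_len(ncol(traits)), function(l) {
    yl <- traits[, l]
    fl <- tryCatch(
      suppressWarnings(suppressMessages(
        fit_null_model(yl, fit$x, eigen_phi = eig, eps = fit$eps,
                       max_iter = 50L))),
      error = function(e) NULL)
    if (is.null(fl)) return(NA_real_)
    r <- fl$gamma_diag * drop(omega_inverse_multiply(fl, yl - fl$mu_hat))
    quad <- drop(crossprod(r, structure$phi_adj %*% r))
    if (quad <= 0) return(NA_real_)
    stat <- drop(crossprod(panel_t, r))^2 / (sg2[testable] * quad)
    min(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }, numeric(1))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " replicate(s) dropped: null fit failed")
    out <- out[!is.na(out)]
  }
  out
}
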