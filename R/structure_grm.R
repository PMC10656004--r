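# Genetic relatedness matrices, principal-component adjustment, and
# leave-one-chromosome-out (LOCO) construction.

#' Compute a GRM from a genotype dosage matrix
#'
#' Standard centered-and-scaled estimator
#' `Phi = (1/M) sum_m (g_m - 2 f_m)(g_m - 2 f_m)^T / (2 f_m (1 - f_m))`
#' over the `M` polymorphic markers, with `f_m` the sample allele frequency.
#' Monomorphic markers are skipped and counted in the `n_skipped` attribute.
#'
#' @param genotypes n x M numeric matrix of dosages in `[0, 2]` (samples in
#'   rows).
#' @param min_maf optional minor-allele-frequency filter; markers below it
#'   are excluded (default 0 = keep all polymorphic markers).
#' @return n x n symmetric matrix with attributes `n_markers_used` and
#'   `n_skipped`.
#' @export
compute_grm <- function(genotypes, min_maf = 0) {
  g <- as.matrix(genotypes)
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    warning("missing dosages mean-imputed")
    for (j in which(colSums(is.na(g)) > 0)) {
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
    }
  }
  if (ncol(g) < 2) stop("need at least 2 markers")
  f <- colMeans(g) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf > 0 & maf >= min_maf
  n_skipped <- sum(!keep)
  if (sum(keep) < 2) stop("fewer than 2 usable polymorphic markers")
  g <- g[, keep, drop = FALSE]
  f <- f[keep]
  s <- scale_cols(sweep(g, 2, 2 * f, "-"), 1 / sqrt(2 * f * (1 - f)))
  phi <- tcrossprod(s) / ncol(s)
  phi <- (phi + t(phi)) / 2
  attr(phi, "n_markers_used") <- ncol(s)
  attr(phi, "n_skipped") <- n_skipped
  phi
}

#' Remove top principal components from a GRM
#'
#' Takes the top `d` eigenvectors `U` of `phi`, forms the projected GRM
#' `(I - U U^T) phi (I - U U^T) + ridge * I` (a small ridge restores
#' positive definiteness in the removed directions), and returns the PCs for
#' use as fixed-effect covariates. Because the projector is built from
#' `phi`'s own eigenvectors, the adjusted GRM shares `phi`'s eigenvectors,
#' with the top `d` eigenvalues replaced by `ridge`; the cached
#' eigendecomposition is exposed for reuse by downstream fits.
#'
#' @param phi kinship / GRM matrix.
#' @param d number of PCs to remove (`d = 0` leaves `phi` unchanged, no
#'   ridge).
#' @param ridge ridge added after projection (default 1e-6).
#' @param eigen_phi optional precomputed `eigen(phi, symmetric = TRUE)`.
#' @return an object of class `brass_structure` with elements `phi`,
#'   `phi_adj`, `pcs` (n x d), `d`, `z` (`[pcs | 1]`), `eigvecs`,
#'   `adj_eigvals`, and `ridge`.
#' @export
remove_top_pcs <- function(phi, d, ridge = 1e-6, eigen_phi = NULL) {
  phi <- validate_kinship(phi)
  n <- nrow(phi)
  d <- as.integer(d)
  if (d < 0 || d >= n) stop("d must satisfy 0 <= d < n")
  if (is.null(eigen_phi)) eigen_phi <- eigen(phi, symmetric = TRUE)
  u <- eigen_phi$vectors
  vals <- eigen_phi$values
  if (min(vals) < -1e-6) stop("GRM is not positive semi-definite")
  vals <- pmax(vals, 0)
  if (d == 0) {
    adj_vals <- vals
    phi_adj <- phi
    pcs <- matrix(numeric(0), n, 0)
  } else {
    adj_vals <- c(rep(ridge, d), vals[(d + 1):n] + ridge)
    phi_adj <- u %*% (adj_vals * t(u))
    phi_adj <- (phi_adj + t(phi_adj)) / 2
    pcs <- u[, seq_len(d), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(d))
  }
  z <- cbind(pcs, rep(1, n))
  # Cache the pieces of P = A^-1 - A^-1 Z (Z^T A^-1 Z)^-1 Z^T A^-1 with
  # A = phi_adj, used by the modified genotype-variance estimator.
  ainv_z <- u %*% (crossprod(u, z) / adj_vals)
  ztainvz_inv <- solve(crossprod(z, ainv_z))
  structure(
    list(phi = phi, phi_adj = phi_adj, pcs = pcs, d = d, z = z,
         eigvecs = u, eigvals = vals, adj_eigvals = adj_vals, ridge = ridge,
         ainv_z = ainv_z, ztainvz_inv = ztainvz_inv, loco = NULL),
    class = "brass_structure"
  )
}

#' @export
print.brass_structure <- function(x, ...) {
  cat("Sample-structure model: n =", nrow(x$phi), ",", x$d,
      "PC(s) removed (ridge", x$ridge, ")\n")
  if (!is.null(x$loco)) cat("  LOCO GRMs for:", paste(names(x$loco), collapse = ", "), "\n")
  invisible(x)
}

# Action of phi_adj^-1 on a vector/matrix via the cached eigendecomposition.
phi_adj_inverse_multiply <- function(structure, v) {
  structure$eigvecs %*% (crossprod(structure$eigvecs, as.matrix(v)) /
                           structure$adj_eigvals)
}

#' Leave-one-chromosome-out GRMs
#'
#' For each chromosome, computes a GRM from all markers **not** on that
#' chromosome, so that replicates generated for a chromosome's markers are
#' not informed by those markers.
#'
#' @param genotypes n x M dosage matrix.
#' @param chrom_labels length-M vector of chromosome labels.
#' @param min_maf passed to [compute_grm()].
#' @return named list mapping each chromosome to its GRM.
#' @export
loco_grms <- function(genotypes, chrom_labels, min_maf = 0) {
  g <- as.matrix(genotypes)
  chrom_labels <- as.character(chrom_labels)
  if (length(chrom_labels) != ncol(g)) {
    stop("chrom_labels must have one entry per marker")
  }
  chroms <- unique(chrom_labels)
  if (length(chroms) < 2) stop("need markers on at least 2 chromosomes")
  out <- lapply(chroms, function(ch) {
    keep <- chrom_labels != ch
    if (!any(keep)) stop("chromosome ", ch, " contains all markers")
    compute_grm(g[, keep, drop = FALSE], min_maf = min_maf)
  })
  names(out) <- chroms
  out
}
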