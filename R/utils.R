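# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded operations
#' (replicate generation, simulation) do not disturb the caller's RNG stream.
#' A `NULL` seed runs the code against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

inv_logit <- function(eta) 1 / (1 + exp(-eta))

# Scale columns of a matrix: A %*% diag(s) without forming diag(s).
scale_cols <- function(a, s) a * rep(s, each = nrow(a))

#' Validate a binary phenotype vector
#' @noRd
validate_phenotype <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotype contains missing values")
  if (!all(y %in% c(0, 1))) stop("phenotype must be coded 0/1")
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("phenotype must contain at least one case and one control")
  }
  y
}

#' Validate a covariate matrix (with intercept) against a sample size
#' @noRd
validate_covariates <- function(x, n) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("covariate matrix contains missing values")
  if (nrow(x) != n) stop("covariate matrix has ", nrow(x), " rows; expected ", n)
  if (ncol(x) >= n) stop("more covariates than samples")
  if (!any(apply(x, 2, function(col) all(col == col[1]) && col[1] != 0))) {
    stop("covariate matrix must include an intercept column")
  }
  if (qr(x)$rank < ncol(x)) stop("covariate matrix is rank deficient")
  x
}

#' Validate a kinship / GRM matrix
#'
#' Checks symmetry to 1e-10. Positive semi-definiteness is checked where the
#' eigendecomposition is taken (fitting), to avoid an extra O(n^3) pass.
#' @noRd
validate_kinship <- function(phi, n = NULL) {
  phi <- as.matrix(phi)
  if (!is.null(n) && nrow(phi) != n) {
    stop("kinship matrix has ", nrow(phi), " rows; expected ", n)
  }
  if (nrow(phi) != ncol(phi)) stop("kinship matrix must be square")
  if (max(abs(phi - t(phi))) > 1e-10) stop("kinship matrix is not symmetric")
  phi
}

validate_genotype <- function(g, n = NULL) {
  g <- as.numeric(g)
  if (anyNA(g)) stop("genotype vector contains missing values")
  if (!is.null(n) && length(g) != n) stop("genotype vector has wrong length")
  if (any(g < 0 | g > 2)) stop("genotype dosages must lie in [0, 2]")
  g
}
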