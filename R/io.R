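# File I/O for the standard plain-text and GCTA formats.

#' Read a phenotype/covariate table
#'
#' Tab-separated file with a header row; the first column (or `id_col`)
#' holds sample identifiers. Missing values are rejected, not imputed.
#'
#' @param path file path.
#' @param id_col name or index of the sample-ID column (default 1).
#' @return data frame with sample IDs as row names.
#' @export
read_pheno_table <- function(path, id_col = 1L) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(tab)) stop("missing values in ", path, "; imputation is not supported")
  ids <- tab[[id_col]]
  if (anyDuplicated(ids)) stop("duplicated sample IDs in ", path)
  tab <- tab[, -match(if (is.numeric(id_col)) id_col else
    which(names(tab) == id_col), seq_along(tab)), drop = FALSE]
  rownames(tab) <- as.character(ids)
  tab
}

#' Write / read a GRM as a square plain-text matrix
#'
#' The header row and first column carry sample IDs.
#'
#' @param phi GRM matrix (row/col names used as IDs when present).
#' @param path file path.
#' @return `read_grm_text` returns the GRM with dimnames set.
#' @export
write_grm_text <- function(phi, path) {
  phi <- validate_kinship(phi)
  ids <- rownames(phi)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(phi)))
  df <- data.frame(id = ids, phi, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_text
#' @export
read_grm_text <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  phi <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(phi) <- list(ids, ids)
  validate_kinship(phi)
}

#' Write / read a GRM in GCTA binary format
#'
#' Writes the `.grm.bin` (single-precision lower triangle including the
#' diagonal), `.grm.id` (family/individual ID pairs) and `.grm.N.bin`
#' (marker counts) files understood by GCTA.
#'
#' @param phi GRM matrix.
#' @param prefix path prefix (files `prefix.grm.bin`, `prefix.grm.id`,
#'   `prefix.grm.N.bin`).
#' @param n_markers marker count recorded in `.grm.N.bin` (defaults to the
#'   `n_markers_used` attribute, or 1).
#' @return `read_grm_gcta` returns a list with `grm` (dimnamed matrix) and
#'   `n_markers`.
#' @export
write_grm_gcta <- function(phi, prefix, n_markers = NULL) {
  phi <- validate_kinship(phi)
  n <- nrow(phi)
  ids <- rownames(phi)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  if (is.null(n_markers)) {
    n_markers <- attr(phi, "n_markers_used")
    if (is.null(n_markers)) n_markers <- 1L
  }
  lower <- phi[upper.tri(phi, diag = TRUE)] # column-major upper = row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_markers), length(lower)), con, size = 4)
  close(con)
  utils::write.table(data.frame(fid = ids, iid = ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  m <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, numeric(), n = m, size = 4)
  close(con)
  phi <- matrix(0, n, n)
  phi[upper.tri(phi, diag = TRUE)] <- vals
  phi <- phi + t(phi) - diag(diag(phi))
  dimnames(phi) <- list(ids, ids)
  n_file <- paste0(prefix, ".grm.N.bin")
  n_markers <- if (file.exists(n_file)) {
    con <- file(n_file, "rb")
    on.exit(close(con))
    readBin(con, numeric(), n = 1, size = 4)
  } else NA_real_
  list(grm = phi, n_markers = n_markers)
}

#' Read a genotype dosage table
#'
#' Accepts a PLINK `.raw`-style export (header `FID IID PAT MAT SEX
#' PHENOTYPE SNP1 ...`, additive dosages) or a plain matrix TSV with marker
#' columns and an ID first column.
#'
#' @param path file path.
#' @return numeric dosage matrix with sample IDs as row names.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  plink_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_cols %in% names(tab))) {
    ids <- tab$IID
    g <- as.matrix(tab[, setdiff(names(tab), plink_cols), drop = FALSE])
  } else {
    ids <- tab[[1]]
    g <- as.matrix(tab[, -1, drop = FALSE])
  }
  storage.mode(g) <- "double"
  rownames(g) <- as.character(ids)
  if (anyNA(g)) warning("missing dosages present; compute_grm will mean-impute")
  g
}

#' Write a replicate set as TSV
#'
#' Samples in rows, replicates in columns; a `#`-prefixed metadata header
#' records the method, seed and binary flag.
#'
#' @param reps a `brass_replicates` object.
#' @param path file path.
#' @param ids optional sample IDs.
#' @return the path, invisibly.
#' @export
write_replicates_tsv <- function(reps, path, ids = NULL) {
  stopifnot(inherits(reps, "brass_replicates"))
  n <- ncol(reps$replicates)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  con <- file(path, "w")
  writeLines(sprintf("# method=%s seed=%s binary=%s", reps$method,
                     if (is.null(reps$permutation_seed)) "NA"
                     else reps$permutation_seed, reps$binary), con)
  df <- data.frame(id = ids, t(reps$replicates), check.names = FALSE)
  colnames(df) <- c("id", paste0("rep", seq_len(nrow(reps$replicates))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
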