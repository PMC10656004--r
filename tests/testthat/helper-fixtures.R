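# Shared fixtures: block kinship matrices, an exact-moment correlated
# binary generator, and exhaustive permutation enumeration.

# Block-diagonal exchangeable kinship: n_blocks blocks of size block_size
# with within-block off-diagonal rho and unit diagonal.
block_kinship <- function(n_blocks, block_size, rho) {
  blk <- matrix(rho, block_size, block_size)
  diag(blk) <- 1
  phi <- matrix(0, n_blocks * block_size, n_blocks * block_size)
  for (b in seq_len(n_blocks)) {
    idx <- (b - 1) * block_size + seq_len(block_size)
    phi[idx, idx] <- blk
  }
  phi
}

# Correlated binary traits with EXACT first and second moments matching the
# quasi-likelihood null model with constant mean mu, Sigma = xi Phi +
# (1 - xi) I, and Phi = block_kinship(n_blocks, block_size, rho):
# each block shares a latent success probability q = mu +/- a with
# a^2 = mu (1 - mu) xi rho, giving Var(Y_i) = mu (1 - mu) and within-block
# Cov(Y_i, Y_j) = mu (1 - mu) xi rho exactly.
sim_exchangeable_binary <- function(n_reps, n_blocks, block_size, mu, xi, rho) {
  a <- sqrt(mu * (1 - mu) * xi * rho)
  stopifnot(mu + a < 1, mu - a > 0)
  n <- n_blocks * block_size
  vapply(seq_len(n_reps), function(r) {
    q <- mu + a * (2 * stats::rbinom(n_blocks, 1, 0.5) - 1)
    stats::rbinom(n, 1, rep(q, each = block_size))
  }, numeric(n))
}

# All permutations of 1..n as a list (n <= 7).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# A small simulated dataset plus fitted structure/model, reused by several
# tests.
quick_fitted_dataset <- function(seed = 101, n_pedigrees = 6, m_causal = 200,
                                 m_null = 20, cv = 0.4, error_share = NULL) {
  spec <- calibrate_trait_model(covariate_fraction = cv, scenario = "a",
                                error_share_target = error_share,
                                n_mc = 2e4, seed = 3)
  sim <- simulate_dataset(spec, n_pedigrees = n_pedigrees,
                          m_causal = m_causal, m_null = m_null, seed = seed)
  grm <- compute_grm(sim$causal)
  struct <- remove_top_pcs(grm, 1)
  xcov <- cbind(intercept = 1, struct$pcs, age = sim$covariates$age,
                sex = sim$covariates$sex, norm = sim$covariates$norm)
  eig <- list(vectors = struct$eigvecs, values = struct$adj_eigvals)
  fit <- fit_null_model(sim$y, xcov, eigen_phi = eig)
  list(spec = spec, sim = sim, struct = struct, x = xcov, fit = fit)
}
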