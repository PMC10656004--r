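test_that("subpopulation frequencies follow the Balding-Nichols moments", {
  # tiny F: subpopulation frequencies hug the ancestral values
  fr0 <- simulate_subpop_frequencies(2000, f_st = 1e-6, seed = 3)
  expect_lt(max(abs(t(fr0$freq) - fr0$ancestral)), 1e-2)
  # mean and variance at F = .01
  fr <- simulate_subpop_frequencies(50000, f_st = 0.01, seed = 5)
  dev <- t(fr$freq) - fr$ancestral
  expect_lt(abs(mean(dev)), 1e-3)
  pq <- fr$ancestral * (1 - fr$ancestral)
  expect_lt(abs(mean(dev^2 / pq) - 0.01), 0.001)
  expect_error(simulate_subpop_frequencies(10, f_st = 0), "f_st")
})

test_that("Wright's F_ST between the two subpopulations is close to F", {
  fr <- simulate_subpop_frequencies(30000, f_st = 0.01, seed = 7)
  p1 <- fr$freq[1, ]; p2 <- fr$freq[2, ]
  pbar <- (p1 + p2) / 2
  fst_hat <- mean((p1 - p2)^2) / mean(2 * pbar * (1 - pbar))
  expect_lt(abs(fst_hat - 0.01), 0.002)
})

test_that("allele transmission is Mendelian", {
  set.seed(11)
  g2 <- matrix(2, 5, 100)
  expect_true(all(brass:::transmit_allele(g2) == 1))
  g0 <- matrix(0, 5, 100)
  expect_true(all(brass:::transmit_allele(g0) == 0))
  g1 <- matrix(1, 1, 20000)
  expect_lt(abs(mean(brass:::transmit_allele(g1)) - 0.5), 0.02)
})

test_that("gene-dropped genotypes are Mendelian-consistent at every marker", {
  freqs <- simulate_subpop_frequencies(150, f_st = 0.01, seed = 13)
  ped <- three_generation_pedigree()
  drop <- gene_drop_pedigrees(freqs, ped, 10, seed = 17)
  g <- drop$genotypes
  for (i in which(!is.na(ped$father))) {
    for (pd in 1:10) {
      rows <- (pd - 1) * nrow(ped)
      gc <- g[rows + i, ]
      gf <- g[rows + ped$father[i], ]
      gm <- g[rows + ped$mother[i], ]
      lo <- (gf == 2) + (gm == 2)
      hi <- (gf > 0) + (gm > 0)
      expect_true(all(gc >= lo & gc <= hi))
    }
  }
  expect_error(gene_drop_pedigrees(freqs, ped, 5), "divisible")
})

test_that("full siblings show the expected genotype correlation", {
  freqs <- simulate_subpop_frequencies(300, f_st = 0.01, seed = 19)
  ped <- three_generation_pedigree()
  drop <- gene_drop_pedigrees(freqs, ped, 200, seed = 23)
  # members 13 and 14 are full sibs in every pedigree
  i13 <- which(drop$member == 13)
  i14 <- which(drop$member == 14)
  g13 <- scale(drop$genotypes[i13, ])
  g14 <- scale(drop$genotypes[i14, ])
  corr <- mean(colSums(g13 * g14) / (length(i13) - 1), na.rm = TRUE)
  expect_lt(abs(corr - 0.5), 0.03)
})

test_that("covariates have the documented moments", {
  cov <- simulate_covariates(1e5, seed = 29)
  expect_lt(abs(mean(cov$sex) - 0.5), 0.01)
  expect_lt(abs(var(cov$norm) - 1), 0.02)
  expect_lt(abs(mean(cov$age)), 0.01)
  expect_lt(abs(var(cov$age) - 1), 0.02)
})

test_that("scenario-b calibration hits prevalence 5% and error share 55%", {
  spec <- calibrate_trait_model(covariate_fraction = 0.6, scenario = "b",
                                n_mc = 5e4, seed = 31)
  expect_lt(abs(spec$achieved$prevalence - 0.05), 0.005)
  expect_lt(abs(spec$achieved$error_share - 0.55), 0.02)
  # covariate fraction of the linear-predictor variance
  b <- spec$beta
  v_cov <- b[["age"]]^2 + 0.25 * b[["sex"]]^2 + b[["norm"]]^2
  expect_equal(v_cov / (v_cov + spec$sigma_a_sq), 0.6, tolerance = 1e-6)
})

test_that("liability calibration also meets its targets", {
  spec <- calibrate_trait_model(model = "liability", covariate_fraction = 0.4,
                                scenario = "a", n_mc = 5e4, seed = 37)
  expect_lt(abs(spec$achieved$prevalence - 0.30), 0.005)
  expect_lt(abs(spec$achieved$error_share - 0.20), 0.02)
})

test_that("trait generation honours degenerate parameter limits", {
  base <- calibrate_trait_model(covariate_fraction = 0.4, scenario = "a",
                                n_mc = 2e4, seed = 3)
  n <- 5e4
  cov0 <- simulate_covariates(n, seed = 41)
  g <- matrix(rbinom(n * 3, 2, 0.5), n, 3)
  # sigma_a = 0, only an intercept: prevalence = inverse logit of it
  spec0 <- base
  spec0$beta[] <- c(-0.6, 0, 0, 0)
  spec0$sigma_a_sq <- 0
  tr <- simulate_trait(spec0, g, cov0, seed = 43)
  expect_lt(abs(mean(tr$y) - plogis(-0.6)), 0.01)
  expect_equal(unique(tr$prob), plogis(-0.6))
  # symmetric liability threshold: prevalence one half
  specl <- base
  specl$model <- "liability"
  specl$sigma_e_sq <- 1
  specl$beta[] <- c(0, 0, 0, 0)
  specl$sigma_a_sq <- 0
  trl <- simulate_trait(specl, g, cov0, seed = 47)
  expect_lt(abs(mean(trl$y) - 0.5), 0.01)
})

test_that("sibling trait correlation rises with the polygenic variance", {
  base <- calibrate_trait_model(covariate_fraction = 0.4, scenario = "a",
                                n_mc = 2e4, seed = 3)
  freqs <- simulate_subpop_frequencies(150, f_st = 0.01, seed = 53)
  ped <- three_generation_pedigree()
  drop <- gene_drop_pedigrees(freqs, ped, 4000, seed = 59)
  n <- nrow(drop$genotypes)
  cov0 <- simulate_covariates(n, seed = 61)
  i13 <- which(drop$member == 13)
  i14 <- which(drop$member == 14)
  cors <- vapply(c(0, 2, 8, 32), function(s2a) {
    spec <- base
    spec$beta[] <- c(-0.85, 0, 0, 0)
    spec$sigma_a_sq <- s2a
    tr <- simulate_trait(spec, drop$genotypes, cov0, seed = 67)
    cor(tr$y[i13], tr$y[i14])
  }, numeric(1))
  expect_true(all(diff(cors) > -0.02))
  expect_gt(cors[4], cors[1] + 0.1)
})

test_that("ascertainment retains exact case/control counts or errors", {
  set.seed(71)
  trait <- rbinom(5000, 1, 0.35)
  keep_bal <- ascertain_sample(trait, 1000, 0.5, seed = 73)
  expect_equal(sum(trait[keep_bal]), 500)
  expect_equal(sum(1 - trait[keep_bal]), 500)
  keep_37 <- ascertain_sample(trait, 1000, 0.3, seed = 79)
  expect_equal(sum(trait[keep_37]), 300)
  expect_equal(sum(1 - trait[keep_37]), 700)
  small <- rbinom(1000, 1, 0.4) # ~400 cases
  expect_error(ascertain_sample(small, 1000, 0.5), "enlarge")
})

test_that("null markers are independent of the trait by construction", {
  fx <- quick_fitted_dataset(seed = 307)
  corrs <- abs(cor(fx$sim$y, fx$sim$null_markers))
  # weak structure-induced correlation only; average near zero
  expect_lt(mean(corrs), 0.15)
})

test_that("datasets are reproducible from their seed", {
  spec <- calibrate_trait_model(covariate_fraction = 0.4, scenario = "a",
                                n_mc = 2e4, seed = 3)
  s1 <- simulate_dataset(spec, n_pedigrees = 4, m_causal = 50, m_null = 5,
                         seed = 83)
  s2 <- simulate_dataset(spec, n_pedigrees = 4, m_causal = 50, m_null = 5,
                         seed = 83)
  expect_identical(s1$causal, s2$causal)
  expect_identical(s1$y, s2$y)
})
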