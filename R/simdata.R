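# Synthetic-data generator: two-subpopulation Balding-Nichols allele
# frequencies, gene-dropped pedigree genotypes, covariates, and binary
# traits from calibrated logistic or liability-threshold models, with
# optional case/control ascertainment.

#' Subpopulation allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are drawn uniformly on (.2, .8); each
#' subpopulation's frequency is then Beta(p (1 - F) / F, (1 - p)(1 - F) / F),
#' independently across subpopulations, so that
#' `Var(freq) = F p (1 - p)` and the expected Wright's F_ST between
#' subpopulations equals `F`.
#'
#' @param n_snps number of markers.
#' @param f_st divergence parameter `F` in (0, 1); default .01.
#' @param n_subpops number of subpopulations (default 2).
#' @param seed integer seed.
#' @return list with `ancestral` (length `n_snps`) and `freq`
#'   (`n_subpops` x `n_snps` matrix).
#' @export
simulate_subpop_frequencies <- function(n_snps, f_st = 0.01, n_subpops = 2L,
                                        seed = NULL) {
  if (f_st <= 0 || f_st >= 1) stop("f_st must lie in (0, 1)")
  with_seed(seed, {
    p <- stats::runif(n_snps, 0.2, 0.8)
    a <- p * (1 - f_st) / f_st
    b <- (1 - p) * (1 - f_st) / f_st
    freq <- matrix(stats::rbeta(n_subpops * n_snps,
                                rep(a, each = n_subpops),
                                rep(b, each = n_subpops)),
                   n_subpops, n_snps)
    list(ancestral = p, freq = freq)
  })
}

#' Default three-generation pedigree configuration
#'
#' Generation 1: two founder couples. Generation 2: each couple has two
#' children, and each child marries a spouse drawn from the same
#' subpopulation (founder-like). Generation 3: each of the four resulting
#' couples has `n_grandchildren` children. With the default of 2
#' grandchildren per couple the pedigree has 20 members (4 founders, 4
#' offspring, 4 married-in spouses, 8 grandchildren).
#'
#' @param n_grandchildren grandchildren per generation-2 couple.
#' @return data frame with columns `id`, `father`, `mother` (NA for
#'   founders), `generation`.
#' @export
three_generation_pedigree <- function(n_grandchildren = 2L) {
  stopifnot(n_grandchildren >= 1)
  ped <- data.frame(id = 1:12,
                    father = c(rep(NA, 4), 1, 1, 3, 3, rep(NA, 4)),
                    mother = c(rep(NA, 4), 2, 2, 4, 4, rep(NA, 4)),
                    generation = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2))
  couples <- cbind(c(5, 6, 7, 8), c(9, 10, 11, 12))
  next_id <- 13L
  for (i in seq_len(nrow(couples))) {
    for (j in seq_len(n_grandchildren)) {
      ped <- rbind(ped, data.frame(id = next_id, father = couples[i, 1],
                                   mother = couples[i, 2], generation = 3))
      next_id <- next_id + 1L
    }
  }
  ped
}

# Transmit one allele from a parent with genotype count g (per marker):
# the transmitted allele is Bernoulli(g / 2), vectorized over a matrix of
# parental genotypes.
transmit_allele <- function(g) {
  matrix(stats::rbinom(length(g), 1L, g / 2), nrow(g), ncol(g))
}

#' Gene-drop genotypes through replicated pedigrees
#'
#' Equal numbers of pedigrees (all with the same configuration) are
#' assigned to each subpopulation. Founders receive two alleles i.i.d.
#' Bernoulli(subpopulation frequency); each non-founder receives one allele
#' from each parent, chosen uniformly and independently per marker (no
#' linkage; markers independent).
#'
#' @param freqs result of [simulate_subpop_frequencies()] (or a matrix of
#'   subpopulation frequencies with subpopulations in rows).
#' @param ped pedigree configuration data frame (see
#'   [three_generation_pedigree()]).
#' @param n_pedigrees total number of pedigrees; must be divisible by the
#'   number of subpopulations.
#' @param seed integer seed.
#' @return list with `genotypes` (n x M), `pedigree` (pedigree index per
#'   sample), `subpop` (subpopulation per sample), `member` (pedigree member
#'   id per sample).
#' @export
gene_drop_pedigrees <- function(freqs, ped, n_pedigrees, seed = NULL) {
  freq <- if (is.list(freqs)) freqs$freq else as.matrix(freqs)
  n_sub <- nrow(freq)
  m <- ncol(freq)
  if (n_pedigrees %% n_sub != 0) {
    stop("n_pedigrees must be divisible by the number of subpopulations")
  }
  n_mem <- nrow(ped)
  founder <- is.na(ped$father)
  ord <- order(ped$generation, ped$id)
  subpop_of_ped <- rep(seq_len(n_sub), each = n_pedigrees / n_sub)
  fmat <- freq[subpop_of_ped, , drop = FALSE] # n_pedigrees x m

  with_seed(seed, {
    # geno[[member id]] is an n_pedigrees x m matrix: the same member slot
    # across all pedigrees is simulated in one vectorized draw.
    geno <- vector("list", n_mem)
    for (i in ord) {
      if (founder[i]) {
        geno[[ped$id[i]]] <- matrix(stats::rbinom(n_pedigrees * m, 2L, fmat),
                                    n_pedigrees, m)
      } else {
        geno[[ped$id[i]]] <- transmit_allele(geno[[ped$father[i]]]) +
          transmit_allele(geno[[ped$mother[i]]])
      }
    }
    g <- matrix(0L, n_pedigrees * n_mem, m)
    for (j in seq_len(n_mem)) { # pedigree-major layout, members in ped order
      g[(seq_len(n_pedigrees) - 1L) * n_mem + j, ] <- geno[[ped$id[j]]]
    }
    list(genotypes = g,
         pedigree = rep(seq_len(n_pedigrees), each = n_mem),
         subpop = rep(subpop_of_ped, each = n_mem),
         member = rep(ped$id, n_pedigrees))
  })
}

#' Simulate covariates: standardized age, sex, and a standard normal
#'
#' Age is uniform on (20, 80) and standardized to mean 0, variance 1; sex is
#' Bernoulli(.5) coded 0/1; the third covariate is i.i.d. standard normal.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return data frame with columns `age`, `sex`, `norm`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  with_seed(seed, {
    age_raw <- stats::runif(n, 20, 80)
    data.frame(age = (age_raw - 50) / sqrt(60^2 / 12),
               sex = stats::rbinom(n, 1L, 0.5),
               norm = stats::rnorm(n))
  })
}

#' Calibrate the generative trait model
#'
#' Chooses the intercept, covariate effects and additive polygenic variance
#' so that, on the linear (logit or liability) scale, the covariate share of
#' `Var(X beta + W alpha)` equals `covariate_fraction`, and so that the
#' Bernoulli-error share of the total phenotypic variance
#' `E[p(1-p)] / Var(Y)` and the prevalence `E[Y]` hit their targets.
#' Scenario "a" targets an error share of 20% with prevalence 30%;
#' scenario "b" targets 55% with prevalence 5%. The two free scales
#' (intercept and total linear-predictor variance) are solved by nested
#' one-dimensional root-finding over a fixed Monte-Carlo sample of the
#' covariates and an i.i.d.-normal stand-in for the (marginally normal)
#' polygenic term. The normal covariate's effect is set so that its Wald
#' test in a mixed-model analysis of `n_ref` individuals averages p = .05,
#' via the first-order rule `beta_norm = z_.975 sd(Y) / (E[mu(1-mu)]
#' sqrt(n_ref))`; the remaining covariate variance is split equally between
#' age and sex.
#'
#' @param model `"logistic"` or `"liability"`.
#' @param covariate_fraction fraction of linear-scale variance due to
#'   covariates: one of .2, .4, .6, .8 in the study settings (any value in
#'   (0, 1) is accepted).
#' @param scenario `"a"` (error share 20%, prevalence 30%) or `"b"` (error
#'   share 55%, prevalence 5%); ignored when explicit targets are given.
#' @param prevalence_target,error_share_target explicit targets overriding
#'   `scenario`.
#' @param n_ref reference sample size for the normal-covariate effect rule.
#' @param n_mc Monte-Carlo sample size used inside the calibration.
#' @param sigma_e_sq liability-model residual variance (fixed scale).
#' @param seed seed for the internal Monte-Carlo draws.
#' @return an object of class `brass_trait_spec`: list with `model`, `beta`
#'   (named: intercept, age, sex, norm), `sigma_a_sq`, `sigma_e_sq`,
#'   `covariate_fraction`, targets, and the achieved Monte-Carlo values.
#' @export
calibrate_trait_model <- function(model = c("logistic", "liability"),
                                  covariate_fraction = 0.4,
                                  scenario = c("a", "b"),
                                  prevalence_target = NULL,
                                  error_share_target = NULL,
                                  n_ref = 1000L, n_mc = 1e5, seed = 1L,
                                  sigma_e_sq = 1) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  if (is.null(prevalence_target)) {
    prevalence_target <- if (scenario == "a") 0.30 else 0.05
  }
  if (is.null(error_share_target)) {
    error_share_target <- if (scenario == "a") 0.20 else 0.55
  }
  cv <- covariate_fraction
  if (cv <= 0 || cv >= 1) stop("covariate_fraction must lie in (0, 1)")

  draws <- with_seed(seed, {
    cov <- simulate_covariates(n_mc)
    list(cov = cov, e = stats::rnorm(n_mc))
  })
  cov <- draws$cov
  sex_c <- cov$sex - 0.5
  prob_given <- function(lin, b0) {
    if (model == "logistic") inv_logit(b0 + lin)
    else stats::pnorm((b0 + lin) / sqrt(sigma_e_sq))
  }

  solve_scales <- function(beta_norm) {
    # Linear predictor at total variance v, split cv / (1 - cv); the
    # normal covariate keeps its externally fixed effect inside the
    # covariate share.
    lin_at <- function(v) {
      v_cov <- v * cv
      resid_cov <- v_cov - beta_norm^2
      if (resid_cov < 0) {
        stop("infeasible constraints: the normal-covariate effect alone ",
             "exceeds the covariate variance share")
      }
      b_age <- sqrt(resid_cov / 2)
      b_sex <- sqrt(resid_cov / 2) / 0.5 # sex has variance .25
      b_age * cov$age + b_sex * sex_c + beta_norm * cov$norm +
        sqrt(v * (1 - cv)) * draws$e
    }
    err_share_at <- function(v) {
      lin <- lin_at(v)
      b0 <- stats::uniroot(function(b) mean(prob_given(lin, b)) - prevalence_target,
                           c(-200, 200), tol = 1e-10)$root
      p <- prob_given(lin, b0)
      list(share = mean(p * (1 - p)) / (stats::var(p) + mean(p * (1 - p))),
           b0 = b0)
    }
    v_lo <- max(1e-6, beta_norm^2 / cv + 1e-9) # covariate share must hold beta_norm
    v <- tryCatch(
      stats::uniroot(function(v) err_share_at(v)$share - error_share_target,
                     c(v_lo, 400), tol = 1e-8)$root,
      error = function(e) {
        stop("infeasible constraint combination (prevalence ",
             prevalence_target, ", error share ", error_share_target,
             ", covariate fraction ", cv, "): ", conditionMessage(e))
      })
    res <- err_share_at(v)
    v_cov <- v * cv
    resid_cov <- v_cov - beta_norm^2
    list(v = v, b0 = res$b0,
         beta = c(intercept = res$b0, age = sqrt(resid_cov / 2),
                  sex = sqrt(resid_cov / 2) / 0.5, norm = beta_norm),
         sigma_a_sq = v * (1 - cv))
  }

  # First pass without the normal covariate; then fix its effect from the
  # Wald rule and re-solve (its variance share is small, one refinement
  # suffices).
  sol <- solve_scales(0)
  beta_norm <- 0
  for (pass in 1:2) {
    lin <- {
      resid_cov <- sol$v * cv - beta_norm^2
      sqrt(resid_cov / 2) * cov$age + (sqrt(resid_cov / 2) / 0.5) * sex_c +
        beta_norm * cov$norm + sqrt(sol$sigma_a_sq) * draws$e
    }
    p <- prob_given(lin, sol$b0)
    var_y <- stats::var(p) + mean(p * (1 - p))
    beta_norm <- stats::qnorm(0.975) * sqrt(var_y) /
      (mean(p * (1 - p)) * sqrt(n_ref))
    sol <- solve_scales(beta_norm)
  }

  lin <- {
    resid_cov <- sol$v * cv - beta_norm^2
    sqrt(resid_cov / 2) * cov$age + (sqrt(resid_cov / 2) / 0.5) * sex_c +
      beta_norm * cov$norm + sqrt(sol$sigma_a_sq) * draws$e
  }
  p <- prob_given(lin, sol$b0)
  achieved <- list(prevalence = mean(p),
                   error_share = mean(p * (1 - p)) /
                     (stats::var(p) + mean(p * (1 - p))),
                   covariate_share = (sol$v * cv) / sol$v)
  structure(
    list(model = model, beta = sol$beta, sigma_a_sq = sol$sigma_a_sq,
         sigma_e_sq = if (model == "liability") sigma_e_sq else NA_real_,
         covariate_fraction = cv,
         prevalence_target = prevalence_target,
         error_share_target = error_share_target,
         n_ref = n_ref, achieved = achieved),
    class = "brass_trait_spec"
  )
}

#' @export
print.brass_trait_spec <- function(x, ...) {
  cat("Calibrated", x$model, "trait model\n")
  cat("  covariate fraction:", x$covariate_fraction,
      " sigma_a^2:", format(x$sigma_a_sq, digits = 4), "\n")
  cat("  beta:", paste(names(x$beta), format(x$beta, digits = 3),
                       sep = "=", collapse = ", "), "\n")
  cat("  achieved prevalence:", format(x$achieved$prevalence, digits = 3),
      " error share:", format(x$achieved$error_share, digits = 3), "\n")
  invisible(x)
}

#' Simulate a binary trait from a calibrated model
#'
#' Draws the causal-marker random effects `alpha ~ MVN(0, sigma^2 I)` with
#' `sigma^2 = sigma_a_sq / M_c` once, standardizes the causal genotypes to
#' mean 0 and variance 1 (monomorphic markers are dropped and `sigma^2`
#' rescaled to preserve `sigma_a_sq`), and generates `Y` from the logistic
#' model `Y_i ~ Bernoulli(logit^-1(X_i beta + W_i alpha))` or the liability
#' model `Y_i = 1{X_i beta + W_i alpha + eps_i > 0}`.
#'
#' @param spec a [calibrate_trait_model()] result.
#' @param genotypes n x M_c causal genotype dosage matrix.
#' @param covariates data frame from [simulate_covariates()] (columns
#'   `age`, `sex`, `norm`).
#' @param seed integer seed.
#' @return list with `y` (0/1 vector), `prob` (Bernoulli success
#'   probabilities; for the liability model, the conditional probability
#'   given the linear predictor), `linear` (X beta + W alpha, without
#'   intercept removed), and `alpha`.
#' @export
simulate_trait <- function(spec, genotypes, covariates, seed = NULL) {
  stopifnot(inherits(spec, "brass_trait_spec"))
  g <- as.matrix(genotypes)
  n <- nrow(g)
  f <- colMeans(g) / 2
  poly <- f > 0 & f < 1
  if (!all(poly)) {
    g <- g[, poly, drop = FALSE]
  }
  mc <- ncol(g)
  if (mc < 1) stop("no polymorphic causal markers")
  w <- scale(g) # mean 0, variance 1 columns
  sigma2 <- spec$sigma_a_sq / mc # rescaled to the markers actually used
  xb <- spec$beta[["intercept"]] +
    spec$beta[["age"]] * covariates$age +
    spec$beta[["sex"]] * (covariates$sex - 0.5) +
    spec$beta[["norm"]] * covariates$norm
  with_seed(seed, {
    alpha <- stats::rnorm(mc, 0, sqrt(sigma2))
    lin <- xb + drop(w %*% alpha)
    if (spec$model == "logistic") {
      prob <- inv_logit(lin)
      y <- stats::rbinom(n, 1L, prob)
    } else {
      prob <- stats::pnorm(lin / sqrt(spec$sigma_e_sq))
      y <- as.integer(lin + stats::rnorm(n, 0, sqrt(spec$sigma_e_sq)) > 0)
    }
    list(y = y, prob = prob, linear = lin, alpha = alpha)
  })
}

#' Ascertain a case/control subsample with exact counts
#'
#' @param trait 0/1 vector for the source population.
#' @param n_keep total number of individuals to retain.
#' @param case_frac fraction of cases among the retained individuals (e.g.
#'   0.5 for a balanced 1:1 design, 0.3 for 3:7).
#' @param seed integer seed.
#' @return integer vector of retained indices (cases first).
#' @export
ascertain_sample <- function(trait, n_keep, case_frac, seed = NULL) {
  trait <- as.numeric(trait)
  n_case <- round(n_keep * case_frac)
  n_ctrl <- n_keep - n_case
  cases <- which(trait == 1)
  ctrls <- which(trait == 0)
  if (length(cases) < n_case) {
    stop("requested ", n_case, " cases but only ", length(cases),
         " available; enlarge the source population")
  }
  if (length(ctrls) < n_ctrl) {
    stop("requested ", n_ctrl, " controls but only ", length(ctrls),
         " available; enlarge the source population")
  }
  with_seed(seed, {
    c(sample(cases, n_case), sample(ctrls, n_ctrl))
  })
}

#' Simulate one complete dataset
#'
#' Stage-(1) generator: Balding-Nichols frequencies, gene-dropped pedigree
#' genotypes for `m_causal` causal and `m_null` null markers, covariates,
#' and a trait from the calibrated model. Null markers are generated by the
#' same process but never enter the trait model. Optional ascertainment
#' retains an exact case/control split.
#'
#' @param spec a [calibrate_trait_model()] result.
#' @param n_pedigrees number of pedigrees (split equally across the two
#'   subpopulations).
#' @param m_causal,m_null numbers of causal and null markers.
#' @param f_st Balding-Nichols divergence parameter.
#' @param ped pedigree configuration (default
#'   [three_generation_pedigree()]).
#' @param ascertainment `NULL`, or a list `list(n_keep =, case_frac =)`.
#' @param seed integer seed.
#' @return list with `causal`, `null_markers` (genotype matrices), `y`,
#'   `prob`, `covariates`, `subpop`, `pedigree`, and `seed`.
#' @export
simulate_dataset <- function(spec, n_pedigrees = 10L, m_causal = 500L,
                             m_null = 20L, f_st = 0.01,
                             ped = three_generation_pedigree(),
                             ascertainment = NULL, seed = NULL) {
  if (!is.null(ascertainment)) {
    # Auto-size the source population so the requested exact case/control
    # counts exist with high probability (20% margin over the calibrated
    # prevalence); one doubling retry covers the remaining tail.
    prev <- spec$achieved$prevalence
    n_case <- round(ascertainment$n_keep * ascertainment$case_frac)
    n_min <- 1.2 * max(n_case / prev,
                       (ascertainment$n_keep - n_case) / (1 - prev))
    ped_min <- 2L * ceiling(n_min / nrow(ped) / 2)
    n_pedigrees <- max(n_pedigrees, ped_min)
  }
  with_seed(seed, {
    freqs <- simulate_subpop_frequencies(m_causal + m_null, f_st = f_st)
    drop_res <- gene_drop_pedigrees(freqs, ped, n_pedigrees)
    n <- nrow(drop_res$genotypes)
    covariates <- simulate_covariates(n)
    causal <- drop_res$genotypes[, seq_len(m_causal), drop = FALSE]
    nulls <- drop_res$genotypes[, m_causal + seq_len(m_null), drop = FALSE]
    tr <- simulate_trait(spec, causal, covariates)
    keep <- seq_len(n)
    if (!is.null(ascertainment)) {
      keep <- tryCatch(
        sort(ascertain_sample(tr$y, ascertainment$n_keep,
                              ascertainment$case_frac)),
        error = function(e) NULL)
      if (is.null(keep)) { # tail event: regrow the pool once
        drop_res <- gene_drop_pedigrees(freqs, ped, 2L * n_pedigrees)
        n <- nrow(drop_res$genotypes)
        covariates <- simulate_covariates(n)
        causal <- drop_res$genotypes[, seq_len(m_causal), drop = FALSE]
        nulls <- drop_res$genotypes[, m_causal + seq_len(m_null), drop = FALSE]
        tr <- simulate_trait(spec, causal, covariates)
        keep <- sort(ascertain_sample(tr$y, ascertainment$n_keep,
                                      ascertainment$case_frac))
      }
    }
    list(causal = causal[keep, , drop = FALSE],
         null_markers = nulls[keep, , drop = FALSE],
         y = tr$y[keep], prob = tr$prob[keep],
         covariates = covariates[keep, , drop = FALSE],
         subpop = drop_res$subpop[keep], pedigree = drop_res$pedigree[keep],
         seed = seed)
  })
}
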