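# Stages (2)-(4) of the simulation study: per-dataset replicate generation,
# empirical genome-wide threshold estimation, and evaluation of the type 1
# error of the threshold procedure per resampling method.

#' Empirical significance threshold from replicate minimum p-values
#'
#' The 100*alpha-th percentile of the per-replicate minimum p-values,
#' defined as the order statistic of rank `ceiling(alpha * L)`.
#'
#' @param min_p_values numeric vector of per-replicate minimum p-values.
#' @param alpha significance level in (0, 1).
#' @return scalar threshold.
#' @export
estimate_threshold <- function(min_p_values, alpha) {
  if (length(min_p_values) == 0) stop("empty minimum p-value vector")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  l <- length(min_p_values)
  if (l < 1 / alpha) {
    warning("fewer than 1/alpha replicates; threshold estimate is coarse")
  }
  sort(min_p_values)[max(1L, ceiling(alpha * l))]
}

#' Evaluate empirical type 1 error against Monte-Carlo rejection bounds
#'
#' The rate is the proportion of datasets whose observed minimum p-value
#' falls at or below the dataset's estimated threshold. The bounds are
#' `alpha +/- z_.975 sqrt(alpha (1 - alpha) / n_datasets)`, outside of which
#' the z-test comparing the rate to the nominal level rejects at level .05.
#'
#' @param observed_min_p per-dataset observed minimum p-values.
#' @param thresholds per-dataset estimated thresholds (same length).
#' @param alpha nominal level.
#' @param n_datasets number of datasets (defaults to the vector length;
#'   supplied explicitly when some datasets failed upstream).
#' @return list with `rate`, `lower`, `upper`, `mc_variance`
#'   (`alpha (1 - alpha) / n_datasets`), `n_rejections`, `n_datasets`, and
#'   `verdict` (one of `"inflated"`, `"well-controlled"`,
#'   `"conservative"`).
#' @export
evaluate_type1 <- function(observed_min_p, thresholds, alpha,
                           n_datasets = length(observed_min_p)) {
  if (length(observed_min_p) != length(thresholds)) {
    stop("observed_min_p and thresholds must have matching lengths")
  }
  n_rej <- sum(observed_min_p <= thresholds)
  rate <- n_rej / n_datasets
  half <- stats::qnorm(0.975) * sqrt(alpha * (1 - alpha) / n_datasets)
  verdict <- if (rate > alpha + half) "inflated"
             else if (rate < alpha - half) "conservative"
             else "well-controlled"
  list(rate = rate, lower = alpha - half, upper = alpha + half,
       mc_variance = alpha * (1 - alpha) / n_datasets,
       n_rejections = n_rej, n_datasets = n_datasets, verdict = verdict)
}

#' Adaptive early-stopping decision for one dataset
#'
#' After each batch of permutation replicates, the dataset's permutation
#' p-value (the proportion of replicate minimum p-values at or below the
#' observed minimum p-value) is bracketed by a two-sided binomial
#' confidence interval at level `conf`; when the interval excludes the
#' nominal level `alpha`, the rejection decision can no longer change and
#' replication stops.
#'
#' @param perm_min_p replicate minimum p-values accumulated so far.
#' @param observed_min_p the dataset's observed minimum p-value.
#' @param alpha nominal level of the threshold procedure.
#' @param conf confidence level of the interval (default 0.9999).
#' @return list with `stop` (logical), `perm_p`, `ci` (length 2).
#' @export
adaptive_stop <- function(perm_min_p, observed_min_p, alpha, conf = 0.9999) {
  l <- length(perm_min_p)
  if (l < 1) stop("need at least one completed batch")
  x <- sum(perm_min_p <= observed_min_p)
  ci <- stats::binom.test(x, l, conf.level = conf)$conf.int
  list(stop = alpha < ci[1] || alpha > ci[2], perm_p = x / l, ci = ci)
}

#' Configuration for a type-1-error experiment
#'
#' @param methods character vector of resampling methods (see
#'   [resample_traits()]).
#' @param n_datasets number of simulated datasets.
#' @param n_replicates replicates per dataset and method.
#' @param alpha nominal level of the threshold procedure.
#' @param n_pedigrees,m_causal,m_null,f_st passed to [simulate_dataset()].
#' @param model,covariate_fraction,scenario passed to
#'   [calibrate_trait_model()].
#' @param ascertainment `NULL` or `list(n_keep =, case_frac =)`.
#' @param missing_covariate drop the normal covariate from the analysis and
#'   replicate models (never from generation).
#' @param d_pcs number of top PCs removed from the GRM and added as
#'   covariates.
#' @param adaptive enable [adaptive_stop()]-based early stopping (default
#'   off); `adaptive_batch` is the batch size.
#' @param seed master seed; per-dataset seeds are drawn from it.
#' @return list of class `brass_experiment_config`.
#' @export
experiment_config <- function(methods = "brass", n_datasets = 100L,
                              n_replicates = 500L, alpha = 0.01,
                              n_pedigrees = 10L, m_causal = 500L,
                              m_null = 20L, f_st = 0.01,
                              model = "logistic", covariate_fraction = 0.4,
                              scenario = "a", ascertainment = NULL,
                              missing_covariate = FALSE, d_pcs = 1L,
                              adaptive = FALSE, adaptive_batch = 100L,
                              seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_replicates < 1 / alpha) {
    warning("n_replicates < 1/alpha; threshold estimates will be coarse")
  }
  structure(
    list(methods = methods, n_datasets = as.integer(n_datasets),
         n_replicates = as.integer(n_replicates), alpha = alpha,
         n_pedigrees = as.integer(n_pedigrees),
         m_causal = as.integer(m_causal), m_null = as.integer(m_null),
         f_st = f_st, model = model,
         covariate_fraction = covariate_fraction, scenario = scenario,
         ascertainment = ascertainment,
         missing_covariate = missing_covariate, d_pcs = as.integer(d_pcs),
         adaptive = adaptive, adaptive_batch = as.integer(adaptive_batch),
         seed = as.integer(seed)),
    class = "brass_experiment_config"
  )
}

# Stages (2)-(3) for a single simulated dataset: structure building, null
# fit, observed scan, and per-method replicate scans and thresholds.
run_one_dataset <- function(config, spec, ds_seed) {
  sim <- simulate_dataset(spec, n_pedigrees = config$n_pedigrees,
                          m_causal = config$m_causal, m_null = config$m_null,
                          f_st = config$f_st,
                          ascertainment = config$ascertainment,
                          seed = ds_seed)
  grm <- compute_grm(sim$causal)
  struct <- remove_top_pcs(grm, d = config$d_pcs)
  xcov <- cbind(intercept = 1, struct$pcs,
                age = sim$covariates$age, sex = sim$covariates$sex)
  if (!config$missing_covariate) {
    xcov <- cbind(xcov, norm = sim$covariates$norm)
  }
  eig_adj <- list(vectors = struct$eigvecs, values = struct$adj_eigvals)
  fit <- fit_null_model(sim$y, xcov, eigen_phi = eig_adj)
  obs_minp <- min_p_scan(sim$y, sim$null_markers, struct, fit)

  method_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, length(config$methods)),
    config$methods)
  lmm <- NULL
  pql <- NULL
  thresholds <- numeric(0)
  for (method in config$methods) {
    base <- sub("_mod$", "", method)
    if (base %in% c("naive", "mvnpermute") && is.null(lmm)) {
      lmm <- fit_lmm_null(sim$y, xcov, eigen_phi = eig_adj)
    }
    if (base == "logmm_pql" && is.null(pql)) {
      pql <- fit_pql_logmm(sim$y, xcov, eigen_phi = eig_adj)
    }
    scan_batch <- function(n_reps, seed) {
      reps <- resample_traits(sim$y, xcov, method = method, n_reps = n_reps,
                              seed = seed, eigen_phi = eig_adj,
                              fit = fit, lmm = lmm, pql = pql)
      scan_min_p(reps, sim$null_markers, struct, fit)
    }
    if (config$adaptive) {
      minp <- numeric(0)
      batch_seed <- method_seeds[[method]]
      while (length(minp) < config$n_replicates) {
        todo <- min(config$adaptive_batch,
                    config$n_replicates - length(minp))
        minp <- c(minp, scan_batch(todo, batch_seed))
        batch_seed <- batch_seed + 1L
        if (adaptive_stop(minp, obs_minp, config$alpha)$stop) break
      }
    } else {
      minp <- scan_batch(config$n_replicates, method_seeds[[method]])
    }
    thresholds[method] <- estimate_threshold(minp, config$alpha)
  }
  list(obs_minp = obs_minp, thresholds = thresholds,
       xi_hat = fit$xi_hat, converged = fit$converged)
}

#' Run a type-1-error simulation experiment
#'
#' For each dataset: simulate genotypes, covariates and trait; build the
#' GRM from the causal markers and remove the top PC(s) into fixed-effect
#' covariates; fit the quasi-likelihood null model; scan the null markers
#' for the observed minimum p-value; generate replicates with each
#' configured method, scan them, and estimate the empirical threshold at
#' level alpha; finally compare observed minimum p-values to thresholds
#' across datasets. Failures in individual datasets are recorded and
#' skipped. Fully reproducible from `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param spec optional precomputed [calibrate_trait_model()] result
#'   matching the config (calibrated internally when omitted).
#' @param progress print a progress line every 100 datasets.
#' @return an object of class `brass_experiment_result`: list with `summary`
#'   (data frame: method, rate, lower, upper, verdict), `obs_minp`,
#'   `thresholds` (matrix datasets x methods), `n_failed`, and `config`.
#' @export
run_type1_experiment <- function(config, spec = NULL, progress = FALSE) {
  stopifnot(inherits(config, "brass_experiment_config"))
  out <- with_seed(config$seed, {
    if (is.null(spec)) {
      spec <- calibrate_trait_model(
        model = config$model,
        covariate_fraction = config$covariate_fraction,
        scenario = config$scenario,
        seed = sample.int(.Machine$integer.max - 1L, 1))
    }
    ds_seeds <- sample.int(.Machine$integer.max - 1L, config$n_datasets)
    run_seeds <- sample.int(.Machine$integer.max - 1L, config$n_datasets)
    obs <- rep(NA_real_, config$n_datasets)
    thr <- matrix(NA_real_, config$n_datasets, length(config$methods),
                  dimnames = list(NULL, config$methods))
    failures <- character(0)
    for (i in seq_len(config$n_datasets)) {
      res <- tryCatch(
        with_seed(run_seeds[i],
                  run_one_dataset(config, spec, ds_seeds[i])),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, paste0("dataset ", i, ": ",
                                       conditionMessage(res)))
        next
      }
      obs[i] <- res$obs_minp
      thr[i, ] <- res$thresholds[config$methods]
      if (progress && i %% 100 == 0) {
        message("  dataset ", i, "/", config$n_datasets)
      }
    }
    ok <- !is.na(obs)
    summary <- do.call(rbind, lapply(config$methods, function(m) {
      ev <- evaluate_type1(obs[ok], thr[ok, m], config$alpha,
                           n_datasets = sum(ok))
      data.frame(method = m, rate = ev$rate, lower = ev$lower,
                 upper = ev$upper, n_rejections = ev$n_rejections,
                 n_datasets = ev$n_datasets, verdict = ev$verdict)
    }))
    list(summary = summary, obs_minp = obs, thresholds = thr,
         n_failed = length(failures), failures = failures, config = config)
  })
  class(out) <- "brass_experiment_result"
  out
}

#' @export
print.brass_experiment_result <- function(x, ...) {
  cat("Type-1-error experiment:", x$config$n_datasets, "datasets x",
      x$config$n_replicates, "replicates, alpha =", x$config$alpha, "\n")
  if (x$n_failed > 0) cat(" ", x$n_failed, "dataset(s) failed\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
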