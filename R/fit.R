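#' MCMC configuration
#'
#' @param n_chains Number of independent chains (>= 2 for convergence
#'   diagnostics). Default 4.
#' @param n_burnin Burn-in iterations per chain. Default 2000.
#' @param n_samples Retained post-burn-in draws per chain. Default 5000.
#' @param thin Thinning interval. Default 1.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param psrf_threshold Potential-scale-reduction flag threshold.
#'   Default 1.1.
#' @param mh_step Log-scale random-walk step for the residual-variance
#'   Metropolis updates. Default 0.5.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_burnin = 2000, n_samples = 5000,
                        thin = 1, seed = 1, psrf_threshold = 1.1,
                        mh_step = 0.5) {
  stopifnot(n_chains >= 1, n_samples >= 1, thin >= 1, n_burnin >= 0)
  structure(list(n_chains = n_chains, n_burnin = n_burnin,
                 n_samples = n_samples, thin = thin, seed = seed,
                 psrf_threshold = psrf_threshold, mh_step = mh_step),
            class = "mcmc_config")
}

scalar_names <- function() {
  c("alpha0", "beta0", "gamma",
    "sigma2_alpha_super", "sigma2_alpha_region", "sigma2_alpha_country",
    "sigma2_beta_super", "sigma2_beta_region", "sigma2_beta_country",
    "rw2_var_world", "rw2_var_super", "rw2_var_region", "rw2_var_country",
    "tau2_subnational", "tau2_community",
    "nu2_subnational", "nu2_community", "omega2")
}

# Assemble the sampler's data list from a filtered, single-sex observation
# table.
prepare_fit_data <- function(observations, hierarchy, config) {
  obs <- tibble::as_tibble(observations)
  if (nrow(obs) == 0) stop("no observations to fit")
  if (!"birth_cohort" %in% names(obs)) {
    obs$mid_age <- mid_age(obs$age_group)
    obs$birth_cohort <- obs$survey_year - obs$mid_age
  }
  if (length(unique(obs$sex)) != 1) {
    stop("fit one sex at a time (all analyses are sex-stratified)")
  }
  h <- validate_hierarchy(hierarchy)
  if (!all(obs$country %in% h$countries)) {
    stop("observation countries missing from hierarchy")
  }
  idx <- hierarchy_indices(h)
  pos <- grid_position(obs$birth_cohort, config)
  k <- length(config$grid)
  i0 <- pmin(floor(pos), k - 1)

  use_off <- isTRUE(config$use_study_offsets)
  off_tab <- if (use_off) {
    unique(obs[obs$coverage != "national", c("study_id", "coverage")])
  } else {
    obs[0, c("study_id", "coverage")]
  }
  study_idx <- match(obs$study_id, off_tab$study_id)
  study_idx[is.na(study_idx) | obs$coverage == "national"] <- 0L

  list(
    K = k, nC = idx$nC, nR = idx$nR, nS = idx$nS, nB = nrow(off_tab),
    use_rw2 = isTRUE(config$use_rw2), use_offsets = use_off,
    y = obs$mean_cm, se2 = obs$se_cm^2,
    dt = obs$birth_cohort - config$t0,
    a18 = obs$mid_age - 18, w = pos - i0, i0 = as.integer(i0 - 1),
    country = match(obs$country, h$countries) - 1L,
    cov = match(obs$coverage,
                c("national", "subnational", "community")) - 1L,
    study = as.integer(study_idx - 1L),
    region_of_country = idx$region_of_country - 1L,
    super_of_region = idx$super_of_region - 1L,
    super_of_country = idx$super_of_country - 1L,
    b_level = match(off_tab$coverage, c("subnational", "community")),
    dtgrid = config$grid - config$t0,
    offset_studies = off_tab, obs = obs, sex = obs$sex[1]
  )
}

ig_median <- function(p) p[["scale"]] / stats::qgamma(0.5, p[["shape"]])

#' Fit the hierarchical height model by MCMC
#'
#' Runs independent blocked-Gibbs chains from dispersed starting points:
#' effects start at zero (the world intercept at the precision-weighted data
#' mean) and variance parameters at their prior medians scaled by
#' chain-specific factors 0.25, 1, 4, 16, ... Within each iteration all
#' Gaussian effect blocks are drawn from their exact multivariate-normal
#' full conditionals; deviation, RW2 and study-offset variances from
#' conjugate inverse-gamma conditionals; and residual variances by
#' log-scale Metropolis. Fully reproducible given the config seed.
#'
#' @param observations Filtered single-sex observation tibble (see
#'   [filter_analysis_set()]; `birth_cohort`/`mid_age` are computed if
#'   absent).
#' @param hierarchy A `country_index` (countries without data are retained
#'   and borrow strength from their region).
#' @param config A `height_model_config`.
#' @param mcmc An `mcmc_config`.
#' @param fix_hyper Named list of variance families to hold fixed instead of
#'   sampling, e.g. `list(omega2 = 0.01, nu2 = c(subnational = 0.25,
#'   community = 1))`. Families: `sigma2_alpha`, `sigma2_beta`, `rw2_var`,
#'   `tau2`, `nu2`, `omega2`.
#' @param monitor_state Also retain the full effect-vector draws (memory
#'   heavy; intended for small instances and tests). Default FALSE.
#' @return A `heightfit` object: per-chain posterior draws of country
#'   height-at-18 curves on the grid and of scalar parameters, plus model
#'   metadata. Use [check_convergence()] and [summarize_fit()] on it.
#' @export
fit <- function(observations, hierarchy, config = model_config(),
                mcmc = mcmc_config(), fix_hyper = NULL,
                monitor_state = FALSE) {
  dat <- prepare_fit_data(observations, hierarchy, config)

  fam_sizes <- list(sigma2_alpha = 3, sigma2_beta = 3, rw2_var = 4,
                    tau2 = 2, nu2 = 2, omega2 = 1)
  fixed <- vapply(names(fam_sizes), function(f) {
    !is.null(fix_hyper[[f]])
  }, logical(1))
  if (!is.null(fix_hyper)) {
    unknown <- setdiff(names(fix_hyper), names(fam_sizes))
    if (length(unknown) > 0) {
      stop("unknown fix_hyper families: ", paste(unknown, collapse = ", "))
    }
  }

  prior <- list(alpha0_mean = config$alpha0_mean,
                alpha0_var = config$alpha0_var,
                beta0_var = config$beta0_var, gamma_var = config$gamma_var,
                sigma2_alpha_prior = unname(config$sigma2_alpha_prior),
                sigma2_beta_prior = unname(config$sigma2_beta_prior),
                rw2_var_prior = unname(config$rw2_var_prior),
                tau2_prior = unname(config$tau2_prior),
                nu2_prior = unname(config$nu2_prior),
                omega2_prior = unname(config$omega2_prior))

  wmean <- sum(dat$y / dat$se2) / sum(1 / dat$se2)
  base_init <- list(
    sigma2_alpha = ig_median(config$sigma2_alpha_prior),
    sigma2_beta = ig_median(config$sigma2_beta_prior),
    rw2_var = ig_median(config$rw2_var_prior),
    tau2 = ig_median(config$tau2_prior),
    nu2 = ig_median(config$nu2_prior),
    omega2 = ig_median(config$omega2_prior))

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    fac <- 4^(ch - 2) # 0.25, 1, 4, 16, ...
    init_fam <- function(f, len) {
      if (fixed[[f]]) rep_len(unname(fix_hyper[[f]]), len)
      else rep(base_init[[f]] * fac, len)
    }
    init <- list(alpha0 = wmean,
                 sigma2_alpha = init_fam("sigma2_alpha", 3),
                 sigma2_beta = init_fam("sigma2_beta", 3),
                 rw2_var = init_fam("rw2_var", 4),
                 tau2 = init_fam("tau2", 2),
                 nu2 = init_fam("nu2", 2),
                 omega2 = init_fam("omega2", 1))
    control <- list(n_burnin = mcmc$n_burnin, n_samples = mcmc$n_samples,
                    thin = mcmc$thin, monitor_state = monitor_state,
                    mh_step = mcmc$mh_step,
                    fixed = stats::setNames(as.logical(fixed),
                                            names(fam_sizes)))
    res <- with_seed(mcmc$seed + ch - 1,
                     run_chain_cpp(dat, init, prior, control))
    curves <- array(res$curves, dim = c(dat$nC, dat$K, mcmc$n_samples),
                    dimnames = list(hierarchy$countries, NULL, NULL))
    scalars <- res$scalars
    rownames(scalars) <- scalar_names()
    chains[[ch]] <- list(curves = curves, scalars = scalars,
                         mh_accept_rate = res$mh_accept_rate,
                         state = res$state)
  }

  structure(list(chains = chains, hierarchy = hierarchy, config = config,
                 mcmc = mcmc, sex = dat$sex, grid = config$grid,
                 offset_studies = dat$offset_studies,
                 n_obs = length(dat$y), fixed = fixed,
                 data = dat$obs),
            class = "heightfit")
}

#' @export
print.heightfit <- function(x, ...) {
  cat(sprintf("heightfit (%s): %d countries, %d observations\n", x$sex,
              length(x$hierarchy$countries), x$n_obs))
  cat(sprintf("  %d chain(s) x %d retained draws (burn-in %d, thin %d)\n",
              x$mcmc$n_chains, x$mcmc$n_samples, x$mcmc$n_burnin,
              x$mcmc$thin))
  invisible(x)
}

# Pooled draws across chains: curves as nC x K x (chains * draws),
# scalars as parameter x draws.
pooled_draws <- function(fit) {
  curves <- do.call(abind3, lapply(fit$chains, function(ch) ch$curves))
  scalars <- do.call(cbind, lapply(fit$chains, function(ch) ch$scalars))
  list(curves = curves, scalars = scalars)
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(unlist(arrs, use.names = FALSE),
               dim = c(d[1], d[2], sum(vapply(arrs, function(a) dim(a)[3],
                                              numeric(1)))),
               dimnames = list(dimnames(arrs[[1]])[[1]], NULL, NULL))
  out
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from parallel chains: with within-chain variance W and
#' between-chain variance B, the pooled variance estimate is
#' `(n-1)/n * W + B/n` and the PSRF its ratio to W, square-rooted.
#' Degenerate chains with zero total variance report 1.
#'
#' @param x Iterations-by-chains matrix of one scalar summary.
#' @return Scalar PSRF.
#' @export
psrf <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("PSRF needs at least 2 chains")
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b_over_n <- stats::var(colMeans(x))
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes the Brooks-Gelman-Rubin PSRF for every scalar monitor (world
#' intercept/slope, age drift, variances) and for country height at
#' selected cohorts, and flags any summary exceeding the threshold. Also
#' returns tidy trace-plot data.
#'
#' @param fit A `heightfit` with at least 2 chains.
#' @param cohorts Cohorts at which country heights are monitored; default
#'   the grid ends and midpoint.
#' @param threshold Flag threshold; default the fit's
#'   `psrf_threshold`.
#' @return List with `psrf` (tibble: parameter, psrf, flagged), `converged`
#'   (logical), `threshold`, and `traces` (tibble: chain, iteration,
#'   parameter, value).
#' @export
check_convergence <- function(fit, cohorts = NULL, threshold = NULL) {
  if (fit$mcmc$n_chains < 2) stop("convergence check needs >= 2 chains")
  if (is.null(threshold)) threshold <- fit$mcmc$psrf_threshold
  grid <- fit$grid
  if (is.null(cohorts)) {
    cohorts <- unique(grid[c(1, ceiling(length(grid) / 2), length(grid))])
  }
  ki <- match(cohorts, grid)
  if (anyNA(ki)) stop("monitored cohort not on grid")

  per_chain <- lapply(fit$chains, function(ch) {
    hs <- ch$curves[, ki, , drop = FALSE]
    hm <- matrix(hs, nrow = dim(hs)[1] * length(ki))
    rownames(hm) <- paste0("height18_",
                           rep(dimnames(ch$curves)[[1]], times = length(ki)),
                           "_", rep(cohorts, each = dim(hs)[1]))
    rbind(ch$scalars, hm)
  })
  params <- rownames(per_chain[[1]])
  psrfs <- vapply(seq_along(params), function(i) {
    psrf(vapply(per_chain, function(m) m[i, ], numeric(ncol(per_chain[[1]]))))
  }, numeric(1))
  tab <- tibble::tibble(parameter = params, psrf = psrfs,
                        flagged = psrfs > threshold)
  tab <- tab[!vapply(params, function(p) {
    # fixed variance families have zero variance by construction; skip
    any(startsWith(p, names(fit$fixed)[fit$fixed]))
  }, logical(1)), ]

  traces <- dplyr::bind_rows(lapply(seq_along(fit$chains), function(ci) {
    sc <- fit$chains[[ci]]$scalars
    tibble::tibble(chain = ci,
                   iteration = rep(seq_len(ncol(sc)), each = nrow(sc)),
                   parameter = rep(rownames(sc), times = ncol(sc)),
                   value = as.vector(sc))
  }))
  list(psrf = tab, converged = !any(tab$flagged), threshold = threshold,
       traces = traces)
}

#' Posterior summaries of height at age 18
#'
#' Pools draws across chains and returns, for each country and requested
#' grid cohort, the posterior mean and the 2.5th--97.5th percentile credible
#' interval of population mean height at age 18 (study offsets zero).
#'
#' @param fit A `heightfit`.
#' @param countries Countries to report; default all.
#' @param cohorts Grid cohorts to report; default the whole grid. Cohorts
#'   off the grid are rejected.
#' @return An estimate table: tibble with `country`, `sex`, `birth_cohort`,
#'   `mean_cm`, `lo_cm`, `hi_cm`.
#' @export
summarize_fit <- function(fit, countries = NULL, cohorts = NULL) {
  if (is.null(countries)) countries <- fit$hierarchy$countries
  if (is.null(cohorts)) cohorts <- fit$grid
  ki <- match(cohorts, fit$grid)
  if (anyNA(ki)) stop("requested cohort not on the model grid")
  ci <- match(countries, fit$hierarchy$countries)
  if (anyNA(ci)) stop("unknown country requested")
  draws <- pooled_draws(fit)$curves

  rows <- lapply(seq_along(ci), function(a) {
    m <- draws[ci[a], ki, , drop = TRUE]
    m <- matrix(m, nrow = length(ki))
    tibble::tibble(country = countries[a], sex = fit$sex,
                   birth_cohort = cohorts,
                   mean_cm = rowMeans(m),
                   lo_cm = apply(m, 1, qtl, p = 0.025),
                   hi_cm = apply(m, 1, qtl, p = 0.975))
  })
  dplyr::bind_rows(rows)
}
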