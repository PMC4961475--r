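#' Model configuration
#'
#' Collects the cohort grid, prior scales and hyperprior shapes of the
#' hierarchical height model. Mean height at age 18 for a country is the sum
#' of a world line, super-region/region/country deviations in intercept and
#' slope, and constrained second-order random-walk (RW2) components at each
#' of the four levels; measured means additionally carry a linear age-drift
#' term and, for non-national sources, a study offset.
#'
#' Variance hyperpriors are inverse-gamma (conjugate for Gibbs); RW2
#' innovation variances are shared across units within a level.
#'
#' @param grid_start,grid_end,grid_step Cohort grid (birth years); default
#'   1896--1996 in steps of 1.
#' @param t0 Centering cohort for the linear terms (numerical conditioning).
#' @param use_rw2 Include the RW2 non-linear components. Default TRUE.
#' @param use_study_offsets Include random offsets for subnational and
#'   community studies. Default TRUE.
#' @param alpha0_mean,alpha0_var Normal prior for the world intercept (cm).
#' @param beta0_var Normal prior variance for the world slope (cm/yr).
#' @param gamma_var Normal prior variance for the age-drift slope
#'   (cm per year of age beyond 18).
#' @param sigma2_alpha_prior,sigma2_beta_prior Inverse-gamma (shape, scale)
#'   for intercept / slope deviation variances (all levels).
#' @param rw2_var_prior Inverse-gamma (shape, scale) for RW2 innovation
#'   variances (all levels).
#' @param tau2_prior Inverse-gamma (shape, scale) for study-offset variances.
#' @param nu2_prior Inverse-gamma (shape, scale) for non-national extra
#'   residual variances.
#' @param omega2_prior Inverse-gamma (shape, scale) for the global residual
#'   variance.
#' @return A `height_model_config` list.
#' @export
model_config <- function(grid_start = 1896, grid_end = 1996, grid_step = 1,
                         t0 = 1946,
                         use_rw2 = TRUE, use_study_offsets = TRUE,
                         alpha0_mean = 160, alpha0_var = 400,
                         beta0_var = 1, gamma_var = 0.25,
                         sigma2_alpha_prior = c(shape = 2, scale = 4),
                         sigma2_beta_prior = c(shape = 2, scale = 2e-3),
                         rw2_var_prior = c(shape = 2, scale = 1e-2),
                         tau2_prior = c(shape = 2, scale = 1),
                         nu2_prior = c(shape = 2, scale = 0.5),
                         omega2_prior = c(shape = 2, scale = 0.1)) {
  grid <- seq(grid_start, grid_end, by = grid_step)
  if (length(grid) < 3) stop("cohort grid must have at least 3 points")
  if (grid[length(grid)] != grid_end) {
    stop("grid_step must divide the grid span")
  }
  structure(list(grid_start = grid_start, grid_end = grid_end,
                 grid_step = grid_step, t0 = t0, grid = grid,
                 use_rw2 = use_rw2, use_study_offsets = use_study_offsets,
                 alpha0_mean = alpha0_mean, alpha0_var = alpha0_var,
                 beta0_var = beta0_var, gamma_var = gamma_var,
                 sigma2_alpha_prior = sigma2_alpha_prior,
                 sigma2_beta_prior = sigma2_beta_prior,
                 rw2_var_prior = rw2_var_prior,
                 tau2_prior = tau2_prior, nu2_prior = nu2_prior,
                 omega2_prior = omega2_prior),
            class = "height_model_config")
}

#' @export
print.height_model_config <- function(x, ...) {
  cat("hierarchical height model configuration\n")
  cat(sprintf("  cohort grid: %d..%d step %g (%d points), centred at %g\n",
              x$grid_start, x$grid_end, x$grid_step, length(x$grid), x$t0))
  cat(sprintf("  RW2 components: %s; study offsets: %s\n",
              ifelse(x$use_rw2, "on", "off"),
              ifelse(x$use_study_offsets, "on", "off")))
  cat(sprintf("  world priors: alpha0 ~ N(%g, %g), beta0 ~ N(0, %g), gamma ~ N(0, %g)\n",
              x$alpha0_mean, x$alpha0_var, x$beta0_var, x$gamma_var))
  pr <- function(p) sprintf("IG(%g, %g)", p[["shape"]], p[["scale"]])
  cat(sprintf("  hyperpriors: sigma2_alpha %s, sigma2_beta %s, rw2 %s,\n",
              pr(x$sigma2_alpha_prior), pr(x$sigma2_beta_prior),
              pr(x$rw2_var_prior)))
  cat(sprintf("               tau2 %s, nu2 %s, omega2 %s\n",
              pr(x$tau2_prior), pr(x$nu2_prior), pr(x$omega2_prior)))
  invisible(x)
}

# Fractional grid position (index scale 1..K) of a cohort value.
grid_position <- function(cohort, config) {
  pos <- (cohort - config$grid_start) / config$grid_step + 1
  k <- length(config$grid)
  if (any(pos < 1 - 1e-9 | pos > k + 1e-9)) {
    stop("cohort outside the model grid [", config$grid_start, ", ",
         config$grid_end, "]")
  }
  pmin(pmax(pos, 1), k)
}

#' Zero-initialised model parameters
#'
#' Container for all model parameters: world intercept/slope/age-drift,
#' per-level intercept and slope deviations, per-level constrained RW2
#' vectors (columns of a grid-by-units matrix), and study offsets.
#'
#' @param hierarchy A `country_index`.
#' @param config A `height_model_config`.
#' @param study_ids Character ids of offset-carrying (non-national) studies.
#' @param study_coverage Coverage level (`"subnational"`/`"community"`) for
#'   each element of `study_ids`.
#' @return A `height_params` list.
#' @export
zero_params <- function(hierarchy, config, study_ids = character(),
                        study_coverage = character()) {
  k <- length(config$grid)
  h <- validate_hierarchy(hierarchy)
  zv <- function(codes) stats::setNames(numeric(length(codes)), codes)
  zm <- function(codes) matrix(0, k, length(codes),
                               dimnames = list(NULL, codes))
  structure(list(
    alpha0 = 0, beta0 = 0, gamma = 0,
    alpha_g = zv(h$super_regions), alpha_r = zv(h$regions),
    alpha_c = zv(h$countries),
    beta_g = zv(h$super_regions), beta_r = zv(h$regions),
    beta_c = zv(h$countries),
    u_glob = numeric(k), u_g = zm(h$super_regions), u_r = zm(h$regions),
    u_c = zm(h$countries),
    b = stats::setNames(numeric(length(study_ids)), study_ids),
    b_level = stats::setNames(as.character(study_coverage), study_ids)
  ), class = "height_params")
}

#' Default hyperparameter values
#'
#' @param config A `height_model_config`; values default to the hyperprior
#'   means (scale / (shape - 1)).
#' @return A `height_hyper` list of variance parameters.
#' @export
default_hyper <- function(config) {
  m <- function(p) p[["scale"]] / (p[["shape"]] - 1)
  structure(list(
    sigma2_alpha = c(super = m(config$sigma2_alpha_prior),
                     region = m(config$sigma2_alpha_prior),
                     country = m(config$sigma2_alpha_prior)),
    sigma2_beta = c(super = m(config$sigma2_beta_prior),
                    region = m(config$sigma2_beta_prior),
                    country = m(config$sigma2_beta_prior)),
    rw2_var = c(world = m(config$rw2_var_prior),
                super = m(config$rw2_var_prior),
                region = m(config$rw2_var_prior),
                country = m(config$rw2_var_prior)),
    tau2 = c(subnational = m(config$tau2_prior),
             community = m(config$tau2_prior)),
    nu2 = c(subnational = m(config$nu2_prior),
            community = m(config$nu2_prior)),
    omega2 = m(config$omega2_prior)
  ), class = "height_hyper")
}

#' Model mean height
#'
#' Evaluates the model mean for given parameters: hierarchical line
#' (world + super-region + region + country, in intercept and slope about
#' the centring cohort), the four RW2 components (linearly interpolated at
#' half-integer cohorts), the age-drift term, and the study offset for
#' non-national sources. Population-level prediction uses `study_id = NA`
#' (offset zero), as do national studies.
#'
#' @param params A `height_params`.
#' @param hierarchy A `country_index`.
#' @param config A `height_model_config`.
#' @param country Country code(s).
#' @param cohort Birth-cohort value(s), within the grid range.
#' @param age Age(s) at measurement in years (>= 18). Default 18.
#' @param study_id Study id(s) or NA; offsets apply only to ids present in
#'   `params$b`.
#' @return Numeric vector of mean heights (cm).
#' @export
mean_height <- function(params, hierarchy, config, country, cohort,
                        age = 18, study_id = NA_character_) {
  h <- validate_hierarchy(hierarchy)
  n <- max(length(country), length(cohort), length(age), length(study_id))
  country <- rep_len(country, n); cohort <- rep_len(cohort, n)
  age <- rep_len(age, n); study_id <- rep_len(study_id, n)
  if (any(age < 18)) stop("age must be >= 18")
  if (!all(country %in% h$countries)) stop("unknown country code")
  reg <- h$region_of[country]
  sup <- h$super_region_of[reg]
  dt <- cohort - config$t0
  pos <- grid_position(cohort, config)

  level <- params$alpha0 + params$alpha_g[sup] + params$alpha_r[reg] +
    params$alpha_c[country]
  slope <- params$beta0 + params$beta_g[sup] + params$beta_r[reg] +
    params$beta_c[country]
  out <- level + slope * dt + params$gamma * (age - 18)

  if (config$use_rw2) {
    out <- out + interp_grid(params$u_glob, pos)
    k <- length(config$grid)
    i0 <- pmin(floor(pos), k - 1); w <- pos - i0
    pick <- function(m, codes) {
      j <- match(codes, colnames(m))
      m[cbind(i0, j)] * (1 - w) + m[cbind(i0 + 1, j)] * w
    }
    out <- out + pick(params$u_g, sup) + pick(params$u_r, reg) +
      pick(params$u_c, country)
  }
  if (config$use_study_offsets && length(params$b) > 0) {
    j <- match(study_id, names(params$b))
    out <- out + ifelse(is.na(j), 0, params$b[ifelse(is.na(j), 1, j)])
  }
  unname(out)
}

# Observation-level total residual variance: sampling + global + study-type.
obs_variance <- function(hyper, se_cm, coverage) {
  nu2 <- c(national = 0, hyper$nu2)[coverage]
  v <- se_cm^2 + hyper$omega2 + unname(nu2)
  if (any(v <= 0)) stop("non-positive total observation variance")
  v
}

#' Model log-likelihood
#'
#' Independent normal likelihood for study-summary means: each observed mean
#' is normal around the model mean with variance se^2 + omega^2 + nu^2 for
#' its coverage level (nu^2 is zero for national sources).
#'
#' @param params A `height_params`.
#' @param hyper A `height_hyper`.
#' @param observations Filtered observation tibble (needs `mean_cm`,
#'   `se_cm`, `country`, `birth_cohort`, `mid_age`, `coverage`, `study_id`).
#' @param hierarchy A `country_index`.
#' @param config A `height_model_config`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, hyper, observations, hierarchy, config) {
  obs <- observations
  mu <- mean_height(params, hierarchy, config, obs$country, obs$birth_cohort,
                    age = obs$mid_age, study_id = obs$study_id)
  v <- obs_variance(hyper, obs$se_cm, obs$coverage)
  sum(stats::dnorm(obs$mean_cm, mu, sqrt(v), log = TRUE))
}

# log inverse-gamma density (shape a, scale b), up to nothing — exact.
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Model log-prior
#'
#' Sum of: normal priors for the world intercept, slope and age drift;
#' zero-mean normal priors for intercept/slope deviations at each level with
#' level-specific variances; improper RW2 kernels
#' `(k-2)/2 * log(1/v) - Q(u)/(2v)` for each constrained RW2 vector;
#' zero-mean normal study offsets; and inverse-gamma hyperprior terms for
#' all variance parameters. RW2 vectors violating their identifiability
#' constraints (beyond 1e-8) are rejected.
#'
#' @inheritParams log_likelihood
#' @return Scalar log-prior (improper: finite but unnormalised over RW2
#'   blocks).
#' @export
log_prior <- function(params, hyper, config) {
  lp <- stats::dnorm(params$alpha0, config$alpha0_mean,
                     sqrt(config$alpha0_var), log = TRUE) +
    stats::dnorm(params$beta0, 0, sqrt(config$beta0_var), log = TRUE) +
    stats::dnorm(params$gamma, 0, sqrt(config$gamma_var), log = TRUE)

  dev_block <- function(x, s2) sum(stats::dnorm(x, 0, sqrt(s2), log = TRUE))
  lp <- lp +
    dev_block(params$alpha_g, hyper$sigma2_alpha[["super"]]) +
    dev_block(params$alpha_r, hyper$sigma2_alpha[["region"]]) +
    dev_block(params$alpha_c, hyper$sigma2_alpha[["country"]]) +
    dev_block(params$beta_g, hyper$sigma2_beta[["super"]]) +
    dev_block(params$beta_r, hyper$sigma2_beta[["region"]]) +
    dev_block(params$beta_c, hyper$sigma2_beta[["country"]])

  if (config$use_rw2) {
    k <- length(config$grid)
    rw2_block <- function(u, v) {
      viol <- max(abs(sum(u)), abs(sum((seq_len(k) - (k + 1) / 2) * u)))
      if (viol > 1e-8) stop("RW2 vector violates identifiability constraints")
      (k - 2) / 2 * log(1 / v) - rw2_quadratic_form(u) / (2 * v)
    }
    lp <- lp + rw2_block(params$u_glob, hyper$rw2_var[["world"]])
    for (level in list(list(m = params$u_g, v = hyper$rw2_var[["super"]]),
                       list(m = params$u_r, v = hyper$rw2_var[["region"]]),
                       list(m = params$u_c, v = hyper$rw2_var[["country"]]))) {
      for (j in seq_len(ncol(level$m))) {
        lp <- lp + rw2_block(level$m[, j], level$v)
      }
    }
  }
  if (config$use_study_offsets && length(params$b) > 0) {
    tau2 <- hyper$tau2[params$b_level]
    lp <- lp + sum(stats::dnorm(params$b, 0, sqrt(tau2), log = TRUE))
  }

  ig <- function(x, p) sum(dinvgamma_log(x, p[["shape"]], p[["scale"]]))
  lp + ig(hyper$sigma2_alpha, config$sigma2_alpha_prior) +
    ig(hyper$sigma2_beta, config$sigma2_beta_prior) +
    (if (config$use_rw2) ig(hyper$rw2_var, config$rw2_var_prior) else 0) +
    (if (config$use_study_offsets) ig(hyper$tau2, config$tau2_prior) else 0) +
    ig(hyper$nu2, config$nu2_prior) +
    ig(hyper$omega2, config$omega2_prior)
}
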