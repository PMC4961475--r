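# Shared fixtures and independent oracles, built in code at test time.

# Tiny two-country instance used for the closed-form Gibbs oracle: grid
# length 5 (1990..1994), six observations, one subnational and one
# community study.
tiny_hierarchy <- function() make_hierarchy(2, 1, 1, seed = 3)

tiny_config <- function() {
  model_config(grid_start = 1990, grid_end = 1994, grid_step = 1, t0 = 1992)
}

tiny_obs <- function() {
  set.seed(11)
  obs <- tibble::tibble(
    study_id = c("S1", "S1", "S2", "S3", "S3", "S4"),
    country = c("C001", "C001", "C001", "C002", "C002", "C002"),
    sex = "male",
    coverage = c("national", "national", "subnational", "national",
                 "national", "community"),
    scope = "mixed",
    survey_year = c(2010, 2010, 2012, 2011, 2011, 2012),
    age_group = c("18", "19", "18", "18", "19", "18"),
    mean_cm = round(170 + rnorm(6, 0, 2), 1),
    se_cm = c(0.5, 0.6, 0.8, 0.4, 0.5, 1.0),
    n = 100, measured = TRUE)
  obs$mid_age <- mid_age(obs$age_group)
  obs$birth_cohort <- obs$survey_year - obs$mid_age
  obs
}

tiny_fixed_hyper <- function() {
  list(sigma2_alpha = 2, sigma2_beta = 0.01, rw2_var = 0.05,
       tau2 = 1, nu2 = 0.5, omega2 = 0.1)
}

# Dense closed-form posterior of the full Gaussian effect vector for the
# tiny instance at fixed variances: build the complete design and prior
# precision, restrict to the RW2 constraint subspace via an orthonormal
# null-space basis, and solve the normal equations. Entirely independent
# of the sampler's update scheme.
tiny_dense_oracle <- function(obs = tiny_obs(), h = tiny_hierarchy(),
                              cfg = tiny_config(),
                              fixh = tiny_fixed_hyper()) {
  K <- length(cfg$grid)
  off_ids <- unique(obs$study_id[obs$coverage != "national"])
  p_scal <- 11
  p_u <- 5 * K
  p <- p_scal + p_u + length(off_ids)

  xrow <- function(r) {
    x <- numeric(p)
    dt <- obs$birth_cohort[r] - cfg$t0
    cidx <- match(obs$country[r], h$countries)
    x[1] <- 1; x[2] <- dt; x[3] <- obs$mid_age[r] - 18
    x[4] <- 1; x[5] <- 1; x[5 + cidx] <- 1
    x[8] <- dt; x[9] <- dt; x[9 + cidx] <- dt
    pos <- (obs$birth_cohort[r] - cfg$grid_start) / cfg$grid_step + 1
    i0 <- min(floor(pos), K - 1); wgt <- pos - i0
    for (blk in c(1, 2, 3, 3 + cidx)) {
      iv <- p_scal + (blk - 1) * K + c(i0, i0 + 1)
      x[iv] <- x[iv] + c(1 - wgt, wgt)
    }
    j <- match(obs$study_id[r], off_ids)
    if (!is.na(j) && obs$coverage[r] != "national") x[p_scal + p_u + j] <- 1
    x
  }
  X <- t(vapply(seq_len(nrow(obs)), xrow, numeric(p)))
  vtot <- obs$se_cm^2 + fixh$omega2 +
    c(national = 0, subnational = fixh$nu2,
      community = fixh$nu2)[obs$coverage]
  W <- diag(1 / vtot)

  Krw <- rw2_structure_matrix(K)
  P0 <- matrix(0, p, p)
  P0[1, 1] <- 1 / cfg$alpha0_var; P0[2, 2] <- 1 / cfg$beta0_var
  P0[3, 3] <- 1 / cfg$gamma_var
  for (i in 4:7) P0[i, i] <- 1 / fixh$sigma2_alpha
  for (i in 8:11) P0[i, i] <- 1 / fixh$sigma2_beta
  for (blk in 1:5) {
    idx <- p_scal + (blk - 1) * K + 1:K
    P0[idx, idx] <- Krw / fixh$rw2_var
  }
  for (j in seq_along(off_ids)) {
    P0[p_scal + p_u + j, p_scal + p_u + j] <- 1 / fixh$tau2
  }
  mu0 <- numeric(p); mu0[1] <- cfg$alpha0_mean

  Cc <- rbind(rep(1, K), seq_len(K) - (K + 1) / 2)
  Call <- matrix(0, 10, p)
  for (blk in 1:5) {
    Call[(blk - 1) * 2 + 1:2, p_scal + (blk - 1) * K + 1:K] <- Cc
  }
  Z <- svd(Call, nv = p)$v[, (nrow(Call) + 1):p]

  Pfull <- P0 + t(X) %*% W %*% X
  bfull <- P0 %*% mu0 + t(X) %*% W %*% obs$mean_cm
  Pz <- t(Z) %*% Pfull %*% Z
  mean_x <- as.vector(Z %*% solve(Pz, t(Z) %*% bfull))
  cov_x <- Z %*% solve(Pz) %*% t(Z)
  list(mean = mean_x, cov = cov_x, p = p)
}

# Batch-means Monte-Carlo standard error (accounts for autocorrelation).
mcse_batch <- function(x, n_batches = 40) {
  bs <- floor(length(x) / n_batches)
  bm <- colMeans(matrix(x[seq_len(n_batches * bs)], bs))
  stats::sd(bm) / sqrt(n_batches)
}

# Fabricated heightfit with given curve draws, for summary/report tests.
# curves: nC x K x ndraws array with country dimnames.
fake_fit <- function(curves, grid, sex = "male", scalars = NULL,
                     hierarchy = NULL) {
  nC <- dim(curves)[1]
  if (is.null(hierarchy)) {
    hierarchy <- make_hierarchy(nC, 1, 1, seed = 1)
    dimnames(curves)[[1]] <- hierarchy$countries
  }
  nd <- dim(curves)[3]
  if (is.null(scalars)) {
    scalars <- matrix(0, length(scalar_names_for_tests()), nd,
                      dimnames = list(scalar_names_for_tests(), NULL))
  }
  structure(list(
    chains = list(list(curves = curves, scalars = scalars,
                       mh_accept_rate = NA_real_)),
    hierarchy = hierarchy,
    config = model_config(grid_start = grid[1],
                          grid_end = grid[length(grid)],
                          grid_step = grid[2] - grid[1]),
    mcmc = mcmc_config(n_chains = 1, n_burnin = 0, n_samples = nd, seed = 1),
    sex = sex, grid = grid, n_obs = 0,
    fixed = stats::setNames(rep(FALSE, 6),
                            c("sigma2_alpha", "sigma2_beta", "rw2_var",
                              "tau2", "nu2", "omega2")),
    offset_studies = NULL, data = NULL), class = "heightfit")
}

scalar_names_for_tests <- function() {
  c("alpha0", "beta0", "gamma",
    "sigma2_alpha_super", "sigma2_alpha_region", "sigma2_alpha_country",
    "sigma2_beta_super", "sigma2_beta_region", "sigma2_beta_country",
    "rw2_var_world", "rw2_var_super", "rw2_var_region", "rw2_var_country",
    "tau2_subnational", "tau2_community",
    "nu2_subnational", "nu2_community", "omega2")
}

# Small synthetic world reused across tests (moderate size for speed).
small_world <- function(seed = 42) {
  simulate_world(n_countries = 12, n_regions = 4, n_super_regions = 2,
                 design = survey_design(studies_per_country =
                                          c(min = 3, max = 8)),
                 seed = seed)
}
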