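test_that("Gibbs draws match the dense constrained-MVN posterior", {
  # 2 countries, 6 observations, grid length 5, fixed variances: the
  # sampler's marginal mean and SD of the full Gaussian effect vector are
  # compared with the closed-form dense-matrix posterior.
  oracle <- tiny_dense_oracle()
  mc <- mcmc_config(n_chains = 2, n_burnin = 500, n_samples = 2500,
                    seed = 5)
  f <- fit(tiny_obs(), tiny_hierarchy(), tiny_config(), mc,
           fix_hyper = tiny_fixed_hyper(), monitor_state = TRUE)
  S <- do.call(cbind, lapply(f$chains, function(ch) ch$state))
  expect_equal(nrow(S), oracle$p)

  m_hat <- rowMeans(S)
  mcse <- apply(S, 1, mcse_batch)
  z <- (m_hat - oracle$mean) / pmax(mcse, 1e-12)
  expect_lt(max(abs(z)), 4) # within Monte-Carlo error

  sd_hat <- apply(S, 1, stats::sd)
  sd_or <- sqrt(pmax(diag(oracle$cov), 0))
  live <- sd_or > 1e-3
  expect_lt(max(abs(sd_hat[live] - sd_or[live]) / sd_or[live]), 0.1)
})

test_that("posterior collapses to weighted least squares without RW2", {
  # single country and hierarchy level, national data, RW2 and offsets
  # disabled, deviation variances pinned: the posterior mean line must
  # match the closed-form generalised-least-squares solution.
  h <- make_hierarchy(1, 1, 1, seed = 1)
  cfg <- model_config(grid_step = 4, use_rw2 = FALSE,
                      use_study_offsets = FALSE)
  set.seed(31)
  years <- sample(1960:2014, 40, replace = TRUE)
  obs <- tibble::tibble(
    study_id = sprintf("s%02d", seq_along(years)), country = "C001",
    sex = "male", coverage = "national", scope = "mixed",
    survey_year = years, age_group = "18",
    se_cm = runif(40, 0.3, 0.8), n = 200, measured = TRUE)
  obs$mid_age <- 18
  obs$birth_cohort <- obs$survey_year - 18
  obs$mean_cm <- 165 + 0.08 * (obs$birth_cohort - cfg$t0) +
    rnorm(40, 0, obs$se_cm)

  fixh <- list(sigma2_alpha = 1e-10, sigma2_beta = 1e-12,
               rw2_var = 1e-8, tau2 = 1e-8, nu2 = 1e-12, omega2 = 1e-12)
  mc <- mcmc_config(n_chains = 2, n_burnin = 200, n_samples = 1500,
                    seed = 17)
  f <- fit(obs, h, cfg, mc, fix_hyper = fixh)

  # GLS oracle with the (diffuse, proper) world-line prior included
  X <- cbind(1, obs$birth_cohort - cfg$t0)
  W <- diag(1 / obs$se_cm^2)
  P <- diag(c(1 / cfg$alpha0_var, 1 / cfg$beta0_var)) + t(X) %*% W %*% X
  bvec <- c(cfg$alpha0_mean / cfg$alpha0_var, 0) +
    drop(t(X) %*% W %*% obs$mean_cm)
  coef_or <- solve(P, bvec)

  draws <- do.call(cbind, lapply(f$chains, function(ch) ch$scalars))
  for (nm in c("alpha0", "beta0")) {
    est <- draws[nm, ]
    target <- coef_or[match(nm, c("alpha0", "beta0"))]
    expect_lt(abs(mean(est) - target), 3 * mcse_batch(est) + 1e-8)
  }
})

test_that("identical seeds give identical draw streams", {
  w <- small_world(seed = 77)
  fa <- filter_analysis_set(w$observations)
  obs <- fa$retained[fa$retained$sex == "female", ]
  cfg <- model_config(grid_step = 4)
  mc <- mcmc_config(n_chains = 2, n_burnin = 50, n_samples = 100, seed = 3)
  f1 <- fit(obs, w$hierarchy, cfg, mc)
  f2 <- fit(obs, w$hierarchy, cfg, mc)
  expect_identical(f1$chains[[1]]$scalars, f2$chains[[1]]$scalars)
  expect_identical(f1$chains[[2]]$curves, f2$chains[[2]]$curves)
  mc2 <- mc; mc2$seed <- 4
  f3 <- fit(obs, w$hierarchy, cfg, mc2)
  expect_false(identical(f1$chains[[1]]$scalars, f3$chains[[1]]$scalars))
})

test_that("PSRF behaves on degenerate, well-mixed and separated chains", {
  n <- 10000
  set.seed(8)
  x <- rnorm(n)
  # exact copies: between-chain variance zero, value at its small-n limit
  expect_lt(psrf(cbind(x, x)), 1 + 1e-3)
  # same distribution: near 1
  r <- psrf(matrix(rnorm(2 * n), ncol = 2))
  expect_gte(r, 1 - 1e-6)
  expect_lt(r, 1.05)
  # separated chains must flag clearly
  expect_gt(psrf(cbind(rnorm(n, 0), rnorm(n, 10))), 1.1)
  expect_error(psrf(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("convergence report flags separated chains and passes mixed ones", {
  w <- small_world(seed = 5)
  fa <- filter_analysis_set(w$observations)
  obs <- fa$retained[fa$retained$sex == "male", ]
  cfg <- model_config(grid_step = 4)
  mc <- mcmc_config(n_chains = 2, n_burnin = 300, n_samples = 400, seed = 2)
  f <- fit(obs, w$hierarchy, cfg, mc)
  cc <- check_convergence(f)
  expect_true(all(c("parameter", "psrf", "flagged") %in% names(cc$psrf)))
  expect_true(is.logical(cc$converged))
  expect_lt(max(cc$psrf$psrf), 1.3)
  # doctored fit: shift one chain far away
  f2 <- f
  f2$chains[[2]]$curves <- f2$chains[[2]]$curves + 50
  cc2 <- check_convergence(f2)
  expect_false(cc2$converged)
  expect_true(any(cc2$psrf$flagged))
  f$mcmc$n_chains <- 1
  expect_error(check_convergence(f), "2 chains")
})

test_that("posterior summaries follow the 2.5-97.5 percentile convention", {
  grid <- c(1990, 1992, 1994)
  # constant draws: interval collapses to the value
  cur <- array(170, dim = c(2, 3, 50))
  f <- fake_fit(cur, grid)
  est <- summarize_fit(f)
  expect_true(all(est$mean_cm == 170 & est$lo_cm == 170 & est$hi_cm == 170))

  # normal draws: bounds at the normal quantiles within MC tolerance
  set.seed(12)
  nd <- 5000
  cur2 <- array(rep(170 + rnorm(nd), each = 6), dim = c(2, 3, nd))
  f2 <- fake_fit(cur2, grid)
  est2 <- summarize_fit(f2, countries = "C001", cohorts = 1992)
  expect_equal(est2$lo_cm, 170 + qnorm(0.025), tolerance = 0.1)
  expect_equal(est2$hi_cm, 170 + qnorm(0.975), tolerance = 0.1)

  # ordering invariant on a real fit
  w <- small_world(seed = 9)
  fa <- filter_analysis_set(w$observations)
  cfg <- model_config(grid_step = 4)
  mc <- mcmc_config(n_chains = 2, n_burnin = 100, n_samples = 200, seed = 6)
  fr <- fit(fa$retained[fa$retained$sex == "male", ], w$hierarchy, cfg, mc)
  tab <- summarize_fit(fr)
  expect_true(all(tab$lo_cm <= tab$mean_cm & tab$mean_cm <= tab$hi_cm))
  expect_error(summarize_fit(fr, cohorts = 1991), "grid")
})

test_that("countries without data shrink to their region (prior recovery)", {
  # country C002 has no data: its deviations must be sampled from their
  # prior (mean 0, the fixed SD), i.e. its curve borrows the region's
  obs <- tiny_obs()[1:3, ] # C001 only
  fixh <- tiny_fixed_hyper()
  mc <- mcmc_config(n_chains = 2, n_burnin = 300, n_samples = 2000,
                    seed = 19)
  f <- fit(obs, tiny_hierarchy(), tiny_config(), mc, fix_hyper = fixh,
           monitor_state = TRUE)
  S <- do.call(cbind, lapply(f$chains, function(ch) ch$state))
  ac2 <- S[7, ]  # layout: alpha0 beta0 gamma ag ar ac1 ac2 ...
  bc2 <- S[11, ]
  expect_lt(abs(mean(ac2)), 3 * mcse_batch(ac2))
  expect_lt(abs(mean(bc2)), 3 * mcse_batch(bc2))
  nd <- length(ac2)
  expect_gt(stats::sd(ac2), sqrt(fixh$sigma2_alpha) * 0.9)
  expect_lt(stats::sd(ac2), sqrt(fixh$sigma2_alpha) * 1.1)
  expect_gt(stats::sd(bc2), sqrt(fixh$sigma2_beta) * 0.9)
  expect_lt(stats::sd(bc2), sqrt(fixh$sigma2_beta) * 1.1)
})

test_that("a high-precision observation does not widen the interval", {
  w <- small_world(seed = 30)
  fa <- filter_analysis_set(w$observations)
  obs <- fa$retained[fa$retained$sex == "male", ]
  cfg <- model_config(grid_step = 4)
  mc <- mcmc_config(n_chains = 2, n_burnin = 200, n_samples = 600, seed = 4)
  f0 <- fit(obs, w$hierarchy, cfg, mc)
  est0 <- summarize_fit(f0, countries = "C001", cohorts = 1976)

  extra <- obs[1, ]
  extra$study_id <- "precise"; extra$country <- "C001"
  extra$coverage <- "national"; extra$survey_year <- 1994
  extra$age_group <- "18"; extra$mid_age <- 18; extra$birth_cohort <- 1976
  extra$se_cm <- 0.05; extra$n <- 5000
  extra$mean_cm <- est0$mean_cm
  f1 <- fit(dplyr::bind_rows(obs, extra), w$hierarchy, cfg, mc)
  est1 <- summarize_fit(f1, countries = "C001", cohorts = 1976)
  width0 <- est0$hi_cm - est0$lo_cm
  width1 <- est1$hi_cm - est1$lo_cm
  expect_lt(width1, width0 + 0.05) # no widening beyond MC jitter
})

test_that("empty data are rejected", {
  expect_error(fit(tiny_obs()[0, ], tiny_hierarchy(), tiny_config(),
                   mcmc_config(n_chains = 2, n_samples = 10)),
               "no observations")
  both <- tiny_obs(); both$sex[1] <- "female"
  expect_error(fit(both, tiny_hierarchy(), tiny_config(),
                   mcmc_config()), "one sex")
})
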