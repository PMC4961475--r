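test_that("RW2 quadratic form penalises curvature only", {
  expect_equal(rw2_quadratic_form(c(0, 0, 0, 0)), 0)
  expect_equal(rw2_quadratic_form(c(1, 2, 3, 4)), 0)
  expect_equal(rw2_quadratic_form(c(0, 1, 4, 9)), 8)
  expect_error(rw2_quadratic_form(c(1, 2)), "length")
  # structure matrix reproduces the quadratic form for random vectors
  set.seed(1)
  for (k in c(3, 5, 12)) {
    u <- rnorm(k)
    Krw <- rw2_structure_matrix(k)
    expect_equal(drop(t(u) %*% Krw %*% u), rw2_quadratic_form(u))
  }
})

test_that("RW2 constraint projection removes constant and linear parts", {
  k <- 9
  tc <- seq_len(k) - (k + 1) / 2
  expect_equal(constrain_rw2(rep(3, k)), numeric(k))
  expect_equal(constrain_rw2(2 * seq_len(k)), numeric(k), tolerance = 1e-12)
  set.seed(2)
  u <- rnorm(k)
  v <- constrain_rw2(u)
  expect_lt(abs(sum(v)), 1e-10)
  expect_lt(abs(sum(tc * v)), 1e-10)
  expect_equal(constrain_rw2(v), v, tolerance = 1e-12) # idempotent
})

test_that("mean height assembles line, RW2, age drift and offsets", {
  h <- tiny_hierarchy()
  cfg <- tiny_config()
  p <- zero_params(h, cfg, study_ids = "S9", study_coverage = "community")

  p$alpha0 <- 160; p$beta0 <- 0.05
  expect_equal(mean_height(p, h, cfg, "C001", cfg$t0 + 2, age = 18), 160.1)

  p$gamma <- -0.02
  d <- mean_height(p, h, cfg, "C001", cfg$t0, age = 28) -
    mean_height(p, h, cfg, "C001", cfg$t0, age = 18)
  expect_equal(d, -0.2) # one decade of ageing

  # interpolation: u = (…,1,2,…) at the half-integer cohort gives 1.5
  p2 <- zero_params(h, cfg)
  p2$u_c[, "C001"] <- constrain_rw2(c(0, 1, 2, 3, 4)) # linear -> 0; set raw:
  p2$u_c[, "C001"] <- c(0, 1, 2, 0, -3) # not constrained; fine for mean eval
  v <- mean_height(p2, h, cfg, "C001", 1991.5)
  expect_equal(v, 1.5)
  k_int <- mean_height(p2, h, cfg, "C001", 1992)
  expect_equal(k_int, 2) # integer cohorts hit the grid exactly

  # study offsets apply only to their study
  p$b[] <- 1.5
  expect_equal(mean_height(p, h, cfg, "C001", cfg$t0, study_id = "S9") -
                 mean_height(p, h, cfg, "C001", cfg$t0), 1.5)
  expect_error(mean_height(p, h, cfg, "C001", 1800), "grid")
  expect_error(mean_height(p, h, cfg, "C001", cfg$t0, age = 17), "age")
})

test_that("log-likelihood is the sum of closed-form normal densities", {
  h <- tiny_hierarchy(); cfg <- tiny_config()
  hyp <- default_hyper(cfg)
  hyp$omega2 <- 0.1; hyp$nu2 <- c(subnational = 0.5, community = 0.75)
  p <- zero_params(h, cfg); p$alpha0 <- 170

  one <- tibble::tibble(study_id = "s", country = "C001", sex = "male",
                        coverage = "national", survey_year = 2010,
                        age_group = "18", mean_cm = 170, se_cm = 0.5,
                        n = 100, measured = TRUE, mid_age = 18,
                        birth_cohort = 1992)
  v <- 0.5^2 + 0.1
  expect_equal(log_likelihood(p, hyp, one, h, cfg), -0.5 * log(2 * pi * v))

  obs <- tiny_obs()
  ll1 <- log_likelihood(p, hyp, obs, h, cfg)
  ll2 <- log_likelihood(p, hyp, dplyr::bind_rows(obs, obs), h, cfg)
  expect_equal(ll2, 2 * ll1)

  # a community row with nu2 > 0 penalises the same residual less than a
  # national row, matching direct density evaluation
  row_n <- one
  row_c <- one; row_c$coverage <- "community"; row_c$mean_cm <- 172
  row_n$mean_cm <- 172
  lln <- log_likelihood(p, hyp, row_n, h, cfg)
  llc <- log_likelihood(p, hyp, row_c, h, cfg)
  expect_equal(lln, dnorm(172, 170, sqrt(0.5^2 + 0.1), log = TRUE))
  expect_equal(llc, dnorm(172, 170, sqrt(0.5^2 + 0.1 + 0.75), log = TRUE))
  expect_gt(llc, lln)

  hyp_bad <- hyp; hyp_bad$omega2 <- -1
  expect_error(log_likelihood(p, hyp_bad, obs, h, cfg), "variance")
})

test_that("log-prior blocks follow their stated kernels", {
  h <- tiny_hierarchy(); cfg <- tiny_config()
  hyp <- default_hyper(cfg)
  base <- zero_params(h, cfg)

  # scaling one country deviation d -> 2d changes the block by -3d^2/(2s2)
  d <- 0.8
  p1 <- base; p1$alpha_c["C001"] <- d
  p2 <- base; p2$alpha_c["C001"] <- 2 * d
  expect_equal(log_prior(p2, hyp, cfg) - log_prior(p1, hyp, cfg),
               -3 * d^2 / (2 * hyp$sigma2_alpha[["country"]]))

  # RW2 block equals -Q(u)/(2v) against the dense structure matrix
  set.seed(4)
  u <- constrain_rw2(rnorm(5))
  p3 <- base; p3$u_glob <- u
  Krw <- rw2_structure_matrix(5)
  expect_equal(log_prior(p3, hyp, cfg) - log_prior(base, hyp, cfg),
               -drop(t(u) %*% Krw %*% u) / (2 * hyp$rw2_var[["world"]]))

  # unconstrained RW2 vectors are rejected
  p4 <- base; p4$u_glob <- c(1, 0, 0, 0, 0)
  expect_error(log_prior(p4, hyp, cfg), "constraint")
})

test_that("balanced level shifts leave the likelihood but not the prior invariant", {
  h <- tiny_hierarchy(); cfg <- tiny_config()
  hyp <- default_hyper(cfg)
  obs <- tiny_obs()
  p <- zero_params(h, cfg)
  p$alpha0 <- 168; p$alpha_c[] <- c(0.5, -0.5); p$alpha_r[] <- 0.3

  delta <- 1.23
  p_shift <- p
  p_shift$alpha_c <- p$alpha_c + delta
  p_shift$alpha_r <- p$alpha_r - delta
  expect_equal(log_likelihood(p_shift, hyp, obs, h, cfg),
               log_likelihood(p, hyp, obs, h, cfg))
  expect_false(isTRUE(all.equal(log_prior(p_shift, hyp, cfg),
                                log_prior(p, hyp, cfg))))
})
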