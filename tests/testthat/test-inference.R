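test_that("temperature schedule is the quartic power-posterior ladder", {
  s <- temperature_schedule(40)
  expect_length(s, 41)
  expect_identical(s[1], 0)
  expect_identical(s[41], 1)
  expect_equal(s[21], 0.5^4)
  expect_true(all(diff(s) > 0))
  expect_error(temperature_schedule(1))
})

test_that("analytic posterior reduces to the prior without data", {
  m <- lbf_model(basis_poly(0), name = "const", xi = 2, sigma = 1)
  p <- analytic_posterior(m, NULL, 1, 2)
  expect_equal(p$mean, 0)
  expect_equal(p$cov, diag(4, 1))

  # effectively uninformative data
  d <- oed_dataset("y", "1", c(0, 1), c(1, 1), c(1, 3), sigma = 1)
  p2 <- analytic_posterior(m, d, sigma = 1e12, xi = 2)
  expect_equal(p2$mean, 0, tolerance = 1e-6)
  expect_equal(p2$cov[1, 1], 4, tolerance = 1e-6)
})

test_that("conjugate update recovers the sample mean in the flat limit", {
  m <- lbf_model(basis_poly(0), name = "const", xi = 1e3, sigma = 1)
  d <- oed_dataset("y", "1", c(0, 1), c(1, 1), c(1, 3), sigma = 1)
  p <- analytic_posterior(m, d, 1, 1e3)
  expect_equal(p$mean, 2, tolerance = 1e-4)
  expect_equal(p$cov[1, 1], 0.5, tolerance = 1e-4)
})

test_that("population MCMC reproduces the analytic posterior", {
  bm <- conjugate_benchmark()
  ch <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = 12,
                        n_samples = 4000, burnin = 1500, seed = 11,
                        sigma = bm$sigma)
  ps <- thin(ch, 4000)
  ana <- analytic_posterior(bm$model, bm$data, bm$sigma, bm$xi)
  mcse <- apply(ps$draws, 2, sd) / sqrt(ps$ess)
  z <- (colMeans(ps$draws) - ana$mean) / mcse
  expect_true(all(abs(z) < 3))
  # covariance entries within 10%
  expect_equal(unname(cov(ps$draws)), ana$cov, tolerance = 0.1)
})

test_that("the T = 0 chain samples the prior", {
  bm <- conjugate_benchmark()
  ch <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = 8,
                        n_samples = 4000, burnin = 1000, seed = 3,
                        sigma = bm$sigma)
  prior_chain <- ch$draws[[1]]
  # N(0, 1) prior marginals: mean and sd within generous MC error for
  # an autocorrelated chain
  expect_equal(unname(colMeans(prior_chain)), c(0, 0), tolerance = 0.15)
  expect_equal(unname(apply(prior_chain, 2, sd)), c(1, 1),
               tolerance = 0.15)
})

test_that("population MCMC is reproducible given the seed", {
  bm <- conjugate_benchmark()
  a <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = 4,
                       n_samples = 300, burnin = 200, seed = 9,
                       sigma = bm$sigma)
  b <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = 4,
                       n_samples = 300, burnin = 200, seed = 9,
                       sigma = bm$sigma)
  expect_identical(a$draws, b$draws)
  expect_identical(a$loglik, b$loglik)
})

test_that("thinning strides evenly to the exact target", {
  bm <- conjugate_benchmark()
  ch <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = 3,
                        n_samples = 400, burnin = 100, seed = 2,
                        sigma = bm$sigma)
  th <- thin(ch, 200)
  expect_equal(nrow(th$draws), 200)
  expect_equal(th$thin_stride, 2)
  full <- ch$draws[[length(ch$draws)]]
  expect_equal(th$draws, full[seq(2, 400, by = 2), ])
  expect_identical(thin(ch, 400)$draws, full)
  expect_error(thin(ch, 401), "at least")
})

test_that("propriety profiling flags proper and improper posteriors", {
  m <- lbf_model(basis_poly(1), name = "line", xi = 1, sigma = 0.1)
  d <- generate_data(m, 1.2,
                     data.frame(observable = "y", condition = "1",
                                time = seq(0, 1, 0.2), replicates = 1L),
                     0.1, seed = 1, sigma_attr = 0.1)
  pr <- prior_spec(theta1 = prior_gaussian(1))
  prof <- check_propriety(m, d, pr, "theta1",
                          seq(-3, 3, length.out = 25), sigma = 0.1)
  expect_true(prof$proper)
  expect_equal(which.max(prof$profile),
               which.min(abs(prof$grid - 1.2)), tolerance = 1)

  # likelihood independent of the parameter, near-flat prior
  null <- lbf_model(function(t) 0 * t, name = "null", xi = 1, sigma = 1)
  d0 <- oed_dataset("y", "1", 0, 1, 0, sigma = 1)
  flat <- prior_spec(theta1 = prior_gaussian(1e6))
  prof2 <- check_propriety(null, d0, flat, "theta1",
                           seq(-50, 50, length.out = 21), sigma = 1)
  expect_false(prof2$proper)
})

test_that("profile of a gamma prior alone follows the prior density", {
  null <- lbf_model(function(t) 0 * t, name = "null", xi = 1, sigma = 1)
  d0 <- oed_dataset("y", "1", 0, 1, 0, sigma = 1)
  pg <- prior_spec(theta1 = prior_gamma(1, 3))
  g <- seq(0.05, 12, length.out = 20)
  prof <- check_propriety(null, d0, pg, "theta1", g, sigma = 1)
  expect_equal(prof$profile - max(prof$profile),
               dgamma(g, 1, scale = 3, log = TRUE) -
                 max(dgamma(g, 1, scale = 3, log = TRUE)),
               tolerance = 1e-8)
})

test_that("fitted motif posterior covers most true parameters", {
  q <- motif_quartet()
  dat <- motif_dataset(q, seed = 1)
  fit <- fit_posterior(q$M1, dat, method = "mcmc", prior = motif_prior(),
                       n_temps = 8, n_samples = 2000, burnin = 1000,
                       thin_to = 1000, seed = 2)
  th <- c(motif_true_params(), sigma = 0.03)
  qs <- apply(fit$posterior$draws, 2, quantile, c(0.025, 0.975))
  covered <- vapply(names(th), function(nm)
    th[[nm]] >= qs[1, nm] && th[[nm]] <= qs[2, nm], logical(1))
  # short-chain coverage is imperfect; most parameters must be inside
  expect_gte(mean(covered), 0.7)
  # premise: the fit describes the data to an acceptable degree
  expect_lt(sd(residuals(fit)), 3 * 0.03)
})
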