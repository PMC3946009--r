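test_that("analytic evidence matches hand-computed marginals", {
  m <- lbf_model(basis_poly(0), name = "const", xi = 2, sigma = 1)
  expect_equal(analytic_log_evidence(m, NULL, 1, 2)$logz, 0)

  d <- oed_dataset("y", "1", 0, 1, 0.7, sigma = 1)
  e <- analytic_log_evidence(m, d, sigma = 1, xi = 2)
  expect_equal(e$logz, dnorm(0.7, 0, sqrt(2^2 + 1), log = TRUE))
  expect_equal(e$se, 0)
})

test_that("evidence penalizes superfluous model complexity", {
  q <- linear_quartet(sigma = 0.05)
  dsg <- data.frame(observable = "y", condition = "1",
                    time = seq(0, 1, length.out = 12), replicates = 1L)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    th <- rnorm(1)
    d <- generate_data(q$M1, th, dsg, 0.05, seed = s, sigma_attr = 0.05)
    analytic_log_evidence(q$M1, d)$logz > analytic_log_evidence(q$M4, d)$logz
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("thermodynamic integration handles the degenerate flat case", {
  fake <- structure(list(schedule = temperature_schedule(4),
                         loglik = matrix(0, 100, 5)),
                    class = "tempered_chains")
  e <- thermodynamic_log_evidence(fake)
  expect_equal(e$logz, 0)

  truncated <- structure(list(schedule = temperature_schedule(4)[-1],
                              loglik = matrix(0, 100, 4)),
                         class = "tempered_chains")
  expect_error(thermodynamic_log_evidence(truncated), "schedule")
})

test_that("thermodynamic evidence agrees with the analytic value", {
  bm <- conjugate_benchmark()
  ana <- analytic_log_evidence(bm$model, bm$data, bm$sigma, bm$xi)
  ch <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = 20,
                        n_samples = 2500, burnin = 1000, seed = 11,
                        sigma = bm$sigma)
  ti <- thermodynamic_log_evidence(ch)
  expect_lt(abs(ti$logz - ana$logz) / ti$se, 3)
})

test_that("ladder refinement shrinks the quadrature bias", {
  bm <- conjugate_benchmark()
  ana <- analytic_log_evidence(bm$model, bm$data, bm$sigma, bm$xi)$logz
  err <- vapply(c(2, 8), function(nt) {
    ch <- population_mcmc(bm$model, bm$data, bm$prior, n_temps = nt,
                          n_samples = 1500, burnin = 600, seed = 1,
                          sigma = bm$sigma)
    abs(thermodynamic_log_evidence(ch)$logz - ana)
  }, numeric(1))
  expect_gt(err[1], err[2])
})

test_that("Bayes factors are antisymmetric with the 100:1 decisive rule", {
  a <- analytic_log_evidence(lbf_model(basis_poly(0), name = "c"), NULL)
  expect_equal(bayes_factor(a, a)$log10_bf, 0)

  z2 <- structure(list(logz = 2 * log(10), se = 0, method = "analytic"),
                  class = "log_evidence")
  z0 <- structure(list(logz = 0, se = 0, method = "analytic"),
                  class = "log_evidence")
  bf <- bayes_factor(z2, z0)
  expect_equal(bf$log10_bf, 2)
  expect_equal(bf$label, "decisive")
  expect_equal(bayes_factor(z0, z2)$log10_bf, -bf$log10_bf)
})

test_that("expected update vanishes for an indistinguishable experiment", {
  fx <- quartet_fixture()
  # same model on both sides: evidences cancel exactly on every replicate
  up <- expected_bf_update(fx$fits$M3, fx$fits$M3,
                           candidate_experiment(design_point("y", 1.5)),
                           n_rep = 20, seed = 1)
  expect_equal(up$mean, 0)
  expect_equal(up$sd, 0)
  expect_error(expected_bf_update(fx$fits$M3, fx$fits$M1,
                                  candidate_experiment(
                                    design_point("y", 1.5)),
                                  n_rep = 1), "n_rep")
})

test_that("informative experiments push the Bayes factor toward truth", {
  fx <- quartet_fixture()
  far <- candidate_experiment(design_point("y", 2))
  up <- expected_bf_update(fx$fits$M3, fx$fits$M1, far, n_rep = 60,
                           seed = 2)
  expect_gt(up$mean, 0.5)

  # noise-free data from the truth cannot favour the wrong model
  up0 <- expected_bf_update(fx$fits$M3, fx$fits$M1, far, n_rep = 30,
                            seed = 3, generator = "truth",
                            truth = list(theta = fx$theta, sigma = 0))
  expect_gt(up0$mean, 0)
})

test_that("consistent repeated observations do not erode a lead", {
  fx <- quartet_fixture()
  d <- fx$data
  base <- bayes_factor(
    analytic_log_evidence(fx$quartet$M3, d),
    analytic_log_evidence(fx$quartet$M1, d))$log10_bf
  # duplicate an existing, perfectly consistent observation
  mu <- model_predict(fx$quartet$M3, fx$theta, d[1, ])
  extra <- oed_dataset("y", "1", d$time[1], max(d$replicate) + 1L, mu,
                       sigma = fx$sigma)
  aug <- rbind(as.data.frame(d), as.data.frame(extra))
  aug <- oed_dataset(aug$observable, aug$condition, aug$time,
                     aug$replicate, aug$value, sigma = fx$sigma)
  after <- bayes_factor(
    analytic_log_evidence(fx$quartet$M3, aug),
    analytic_log_evidence(fx$quartet$M1, aug))$log10_bf
  expect_gt(after, base - 0.2)
})
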