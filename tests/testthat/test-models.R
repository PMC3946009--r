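test_that("linear basis simulation evaluates sum of weighted bases", {
  m <- lbf_model(basis_poly(1), name = "line")
  expect_equal(simulate_linear(m, 2, c(0, 1, 3)), c(0, 2, 6))

  q3 <- linear_quartet()$M3
  expect_equal(simulate_linear(q3, c(0, 0, 0), c(-1, 0, 2)), c(0, 0, 0))
  expect_equal(simulate_linear(q3, c(1, 1, 1), 0), 0)
  # direct evaluation of the three terms
  t <- 0.37
  expect_equal(simulate_linear(q3, c(1, 1, 1), t),
               t + t^2 + sin(15 * t) / 3)
})

test_that("non-finite basis values raise an informative error", {
  m <- lbf_model(basis_poly(1), function(t) 1 / t, name = "bad")
  expect_error(simulate_linear(m, c(1, 1), c(0, 1)), "basis 2")
  expect_error(simulate_linear(m, c(1, 1), c(0, 1)), "t = 0")
})

test_that("Gaussian log likelihood sums per-point densities", {
  d1 <- oed_dataset("y", "1", 0, 1, 0.5, sigma = 1)
  expect_equal(log_likelihood(d1, 0.5, 1), dnorm(0, log = TRUE))

  d2 <- oed_dataset("y", "1", c(0, 1), c(1, 1), c(0.5, 0.5), sigma = 1)
  expect_equal(log_likelihood(d2, c(0.5, 0.5), 1),
               2 * log_likelihood(d1, 0.5, 1))

  # brute-force per-point oracle on stated residuals
  res <- c(0.3, -1.2, 0.05, 2.4, -0.7)
  d5 <- oed_dataset("y", "1", 1:5, rep(1, 5), res, sigma = 0.4)
  oracle <- sum(vapply(res, function(r) dnorm(r, 0, 0.4, log = TRUE),
                       numeric(1)))
  expect_equal(log_likelihood(d5, rep(0, 5), 0.4), oracle,
               tolerance = 1e-12)

  expect_error(log_likelihood(d1, 0.5, 0), "sigma")
  expect_error(log_likelihood(d1, 0.5, -1), "sigma")
})

test_that("likelihood factorizes over disjoint dataset parts", {
  m <- linear_quartet()$M2
  dsg <- function(t) data.frame(observable = "y", condition = "1",
                                time = t, replicates = 2L)
  a <- generate_data(m, c(1, -0.5), dsg(c(0, 0.5)), 0.2, seed = 1,
                     sigma_attr = 0.2)
  b <- generate_data(m, c(1, -0.5), dsg(c(1, 1.5)), 0.2, seed = 2,
                     sigma_attr = 0.2)
  b$replicate <- b$replicate + 2L
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  ab <- oed_dataset(ab$observable, ab$condition, ab$time, ab$replicate,
                    ab$value, sigma = 0.2)
  pred <- function(d) model_predict(m, c(1, -0.5), d)
  expect_equal(log_likelihood(ab, pred(ab), 0.2),
               log_likelihood(a, pred(a), 0.2) +
                 log_likelihood(b, pred(b), 0.2),
               tolerance = 1e-12)
})

test_that("log prior matches known densities and support", {
  pr <- prior_spec(k = prior_gamma(1, 3))
  expect_equal(log_prior(c(k = 1e-12), pr), log(1 / 3), tolerance = 1e-9)
  expect_identical(log_prior(c(k = -0.1), pr), -Inf)

  pg <- prior_spec(b = prior_gaussian(1))
  expect_equal(log_prior(c(b = 0), pg), -0.5 * log(2 * pi))

  # shape-rate switch
  pr2 <- prior_spec(k = prior_gamma(1, rate = 3))
  expect_equal(log_prior(c(k = 1e-12), pr2), log(3), tolerance = 1e-9)
})

test_that("synthetic data generation is seeded and honest about noise", {
  m <- linear_quartet()$M2
  dsg <- data.frame(observable = "y", condition = "1",
                    time = seq(0, 1, 0.25), replicates = 3L)
  a <- generate_data(m, c(1, 1), dsg, 0.1, seed = 7)
  b <- generate_data(m, c(1, 1), dsg, 0.1, seed = 7)
  expect_identical(a, b)
  c2 <- generate_data(m, c(1, 1), dsg, 0.1, seed = 8)
  expect_false(identical(a$value, c2$value))

  noiseless <- generate_data(m, c(1, 1), dsg, 0)
  expect_equal(noiseless$value,
               model_predict(m, c(1, 1), noiseless))
})

test_that("generated residuals are Gaussian with the requested sd", {
  m <- lbf_model(basis_poly(1), name = "line")
  dsg <- data.frame(observable = "y", condition = "1", time = 0.5,
                    replicates = 12000L)
  d <- generate_data(m, 2, dsg, 0.03, seed = 42)
  res <- d$value - 1
  expect_equal(sd(res), 0.03, tolerance = 0.03)
  expect_gt(stats::shapiro.test(sample(res, 5000))$p.value, 1e-3)
})

test_that("ODE simulation matches fixed points and closed forms", {
  const <- ode_model(name = "const", states = c("a", "b"),
                     rhs = function(t, x, p, u) c(0, 0),
                     x0 = c(a = 2, b = 0.5), conditions = list("1" = 1))
  out <- simulate_ode(const, c(p = 1), "1", c(0, 5, 50))
  expect_true(all(out[, "a"] == 2) && all(out[, "b"] == 0.5))

  dec <- decay_model()
  tms <- c(0, 0.5, 1, 5, 20, 100)
  out <- simulate_ode(dec, c(p = 1), "1", tms)
  expect_equal(unname(out[, "x"]), exp(-tms), tolerance = 1e-7)
})

test_that("steady-state sentinel integrates to a settled state", {
  dec <- decay_model()
  out <- simulate_ode(dec, c(p = 0.5), "1", Inf)
  expect_lt(abs(out[1, "x"]), 1e-6)

  # all four motif variants settle under both stimuli
  q <- motif_quartet()
  th <- motif_true_params()
  for (m in q) for (cond in c("1", "2")) {
    ss <- simulate_ode(m, th, cond, Inf)
    expect_true(all(is.finite(ss)) && all(ss >= 0))
  }
})

test_that("motif truth shows a visible Bp overshoot at the design times", {
  q <- motif_quartet()
  th <- motif_true_params()
  tms <- c(0, 2, 5, 10, 20, 40, 60, 100)
  tr <- simulate_ode(q$M1, th, "1", tms)
  expect_true(all(is.finite(tr)))
  # transient peak above the late-time level by well over the noise sd
  expect_gt(max(tr[, "Bp"]) - tr[length(tms), "Bp"], 3 * 0.03)
})

test_that("motif dataset follows the benchmark design", {
  d <- motif_dataset(seed = 1)
  expect_equal(nrow(d), 8 * 3 + 8 * 2)
  expect_setequal(unique(d$observable), c("Bp", "Dp"))
  expect_equal(max(d$replicate[d$observable == "Bp"]), 3)
  expect_equal(max(d$replicate[d$observable == "Dp"]), 2)
  expect_true(all(is.na(attr(d, "sigma"))))  # noise sd is inferred
  expect_identical(motif_dataset(seed = 1), d)
})

test_that("datasets round-trip through CSV including steady state", {
  d <- motif_dataset(seed = 2)
  ss <- oed_dataset(c("Cp", "Cp"), "1", c(Inf, 3), c(1, 1), c(0.5, 0.2))
  path <- tempfile(fileext = ".csv")
  write_dataset(ss, path)
  back <- read_dataset(path)
  expect_equal(back$time, c(Inf, 3))
  path2 <- tempfile(fileext = ".csv")
  write_dataset(d, path2)
  expect_equal(as.data.frame(read_dataset(path2)), as.data.frame(d))
})

test_that("duplicate measurement records are rejected", {
  expect_error(oed_dataset(c("y", "y"), "1", c(0, 0), c(1, 1), c(1, 2)),
               "unique")
})

test_that("models and priors can be declared in YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("type: linear", "name: M3", "xi: 1", "sigma: 0.2",
               "bases:",
               "  - {type: poly, degree: 1}",
               "  - {type: poly, degree: 2}",
               "  - {type: sinmod, freq: 15, scale: 3}"), cfg)
  m <- model_from_config(cfg)
  expect_equal(simulate_linear(m, c(1, 1, 1), c(0.3, 0.7)),
               simulate_linear(linear_quartet()$M3, c(1, 1, 1),
                               c(0.3, 0.7)))
  pcfg <- tempfile(fileext = ".yaml")
  writeLines(c("prior:",
               "  k1: {dist: gamma, shape: 1, scale: 3}",
               "  sigma: {dist: halfnormal, scale: 1}"), pcfg)
  pr <- prior_from_config(pcfg)
  expect_s3_class(pr, "prior_spec")
  expect_equal(log_prior(c(k1 = 1e-12, sigma = 0), pr),
               log(1 / 3) + log(2) - 0.5 * log(2 * pi), tolerance = 1e-9)
})
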