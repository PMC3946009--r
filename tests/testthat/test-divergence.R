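test_that("unit ball volumes match the closed form", {
  expect_equal(unit_ball_volume(1), 2)
  expect_equal(unit_ball_volume(2), pi)
  expect_equal(unit_ball_volume(3), 4 * pi / 3)
  expect_error(unit_ball_volume(0))
})

test_that("tree and brute-force neighbour searches agree exactly", {
  set.seed(42)
  for (d in 1:3) {
    A <- matrix(rnorm(800 * d), ncol = d)
    B <- matrix(rnorm(600 * d), ncol = d)
    expect_identical(kth_nn_dist(A, B, 7),
                     kth_nn_dist(A, B, 7, method = "brute"))
    expect_identical(kth_nn_dist(A, A, 5, self = TRUE),
                     kth_nn_dist(A, A, 5, self = TRUE, method = "brute"))
  }
  expect_error(kth_nn_dist(A, B, 601), "k must be")
})

test_that("kNN density reproduces hand computations and scaling", {
  # sample {0, 1}, leave-one-out at each point: rho_1 = 1, v_1 = 2
  expect_equal(knn_density(c(0, 1), c(0, 1), k = 1, exclude_self = TRUE),
               c(0.5, 0.5))
  set.seed(1)
  x <- matrix(runif(40000), ncol = 1)
  q <- matrix(seq(0.2, 0.8, length.out = 40), ncol = 1)
  expect_equal(mean(knn_density(q, x, k = 50)), 1, tolerance = 0.05)
  # 1-D change of variables: scaling by c divides the density by c
  c0 <- 3.7
  expect_equal(knn_density(c0 * q, c0 * x, k = 50),
               knn_density(q, x, k = 50) / c0)
})

test_that("JSD estimator is exactly symmetric in its arguments", {
  set.seed(2)
  a <- cbind(rnorm(800), rnorm(800))
  b <- cbind(rnorm(800, 1), rnorm(800))
  expect_identical(knn_jsd(a, b, k = 10)$jsd, knn_jsd(b, a, k = 10)$jsd)
})

test_that("JSD saturates for disjoint supports and vanishes for copies", {
  set.seed(3)
  a <- gauss_sample(4000)
  b <- gauss_sample(4000, mean = 100)
  expect_equal(knn_jsd(a, b, k = 10)$jsd, 1, tolerance = 0.02)

  one <- gauss_sample(8000)
  halves <- knn_jsd(one[seq(1, 8000, 2), , drop = FALSE],
                    one[seq(2, 8000, 2), , drop = FALSE], k = 10)
  expect_lt(abs(halves$jsd), 0.05)

  # degenerate all-identical samples: floored distances, value ~ 0
  const <- matrix(1, 500, 1)
  est <- knn_jsd(const, const, k = 10)
  expect_lt(abs(est$jsd), 0.01)
  expect_gt(est$degeneracies, 0)

  expect_error(knn_jsd(gauss_sample(20), gauss_sample(20), k = 19), "k")
})

test_that("JSD stays within its documented bounds", {
  set.seed(4)
  for (rep in 1:10) {
    mu <- runif(1, 0, 5)
    sdv <- runif(1, 0.3, 3)
    d <- sample(1:3, 1)
    a <- matrix(rnorm(1000 * d), ncol = d)
    b <- matrix(rnorm(1000 * d, mu, sdv), ncol = d)
    v <- knn_jsd(a, b, k = 10)$jsd
    expect_gte(v, -0.05)
    expect_lte(v, 1.05)
  }
})

test_that("JSD is invariant under rigid motions of both samples", {
  set.seed(5)
  a <- cbind(rnorm(1500), rnorm(1500, 0, 2))
  b <- cbind(rnorm(1500, 1), rnorm(1500, -0.5, 2))
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(5, -3)
  move <- function(x) sweep(x %*% R, 2, shift, "+")
  expect_equal(knn_jsd(move(a), move(b), k = 10)$jsd,
               knn_jsd(a, b, k = 10)$jsd, tolerance = 1e-10)
})

test_that("quadrature oracle matches known identities", {
  same <- jsd_oracle(function(x) dnorm(x), function(x) dnorm(x),
                     lower = -10, upper = 10)
  expect_equal(same$jsd, 0, tolerance = 1e-8)

  disjoint <- jsd_oracle(function(x) dunif(x, 0, 1),
                         function(x) dunif(x, 2, 3),
                         lower = -0.5, upper = 3.5)
  expect_equal(disjoint$jsd, 1, tolerance = 1e-8)

  # self-convergence across refinements
  f <- function(x) dnorm(x)
  g <- function(x) dnorm(x, 0, 2)
  v1 <- jsd_oracle(f, g, lower = -25, upper = 25, tol = 1e-6)$jsd
  v2 <- jsd_oracle(f, g, lower = -25, upper = 25, tol = 1e-9)$jsd
  expect_equal(v1, v2, tolerance = 1e-6)

  expect_error(jsd_oracle(function(x) 2 * dnorm(x), f,
                          lower = -10, upper = 10), "integrate")
})

test_that("Monte-Carlo oracle agrees with quadrature in higher d", {
  o1 <- jsd_oracle(function(x) dnorm(x), function(x) dnorm(x, 1),
                   lower = -12, upper = 13)$jsd
  set.seed(6)
  o3 <- jsd_oracle(
    function(x) dnorm(x[, 1]) * dnorm(x[, 2]),
    function(x) dnorm(x[, 1], 1) * dnorm(x[, 2]),
    d = 2, method = "mc",
    sampler_a = function(n) cbind(rnorm(n), rnorm(n)),
    sampler_b = function(n) cbind(rnorm(n, 1), rnorm(n)),
    n_mc = 2e5)
  expect_lt(abs(o3$jsd - o1), 5 * o3$error)
})

test_that("oracle equals the mutual information with a model label", {
  # JSD = I(Y; C) for an equal-weight two-component mixture; compute the
  # mutual information independently as H(Y) - H(Y | C)
  f <- function(x) dnorm(x)
  g <- function(x) dnorm(x, 1.3, 0.7)
  mix <- function(x) 0.5 * f(x) + 0.5 * g(x)
  ent <- function(p) integrate(function(x) {
    v <- p(x)
    out <- numeric(length(x))
    pos <- v > 0
    out[pos] <- -v[pos] * log2(v[pos])
    out
  }, -15, 15, rel.tol = 1e-10)$value
  mi <- ent(mix) - (0.5 * ent(f) + 0.5 * ent(g))
  o <- jsd_oracle(f, g, lower = -15, upper = 15, tol = 1e-9)
  expect_equal(o$jsd, mi, tolerance = 1e-6)
})

test_that("estimate converges to the oracle as samples and k grow", {
  o <- jsd_oracle(function(x) dnorm(x), function(x) dnorm(x, 1),
                  lower = -12, upper = 13)$jsd
  meds <- vapply(c(500, 2000, 10000), function(N) {
    k <- round(sqrt(N))
    errs1 <- vapply(1:10, function(s) {
      set.seed(s)
      abs(knn_jsd(gauss_sample(N), gauss_sample(N, 1), k = k)$jsd - o)
    }, numeric(1))
    errs2 <- vapply(1:10, function(s) {
      set.seed(100 + s)
      abs(knn_jsd(cbind(rnorm(N), rnorm(N)),
                  cbind(rnorm(N, 1), rnorm(N)), k = k)$jsd - o)
    }, numeric(1))
    median(c(errs1, errs2))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("k-sweep reports a stable plateau around the default", {
  set.seed(7)
  a <- gauss_sample(4000)
  b <- gauss_sample(4000, 1)
  sw <- jsd_k_sweep(a, b, ks = c(1, 5, 10, 20, 50))
  expect_equal(sw$k, c(1, 5, 10, 20, 50))
  # k = 10..50 estimates vary far less than the k = 1 outlier
  expect_lt(max(diff(sw$jsd[3:5])), abs(sw$jsd[2] - sw$jsd[1]))
})
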