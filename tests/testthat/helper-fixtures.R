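# shared fixtures, all generated in code

# conjugate linear-Gaussian benchmark: quadratic model, 8 points
conjugate_benchmark <- function(seed = 5) {
  model <- lbf_model(basis_poly(1), basis_poly(2), name = "quad",
                     xi = 1, sigma = 0.2)
  design <- data.frame(observable = "y", condition = "1",
                       time = seq(0, 1, length.out = 8), replicates = 1L)
  data <- generate_data(model, c(0.7, -0.4), design, 0.2, seed = seed,
                        sigma_attr = 0.2)
  prior <- prior_spec(theta1 = prior_gaussian(1),
                      theta2 = prior_gaussian(1))
  list(model = model, data = data, prior = prior, sigma = 0.2, xi = 1)
}

# regression quartet fitted to data from the third (true) model
quartet_fixture <- function(theta = c(1, 1, 1), window = c(0, 1),
                            n_data = 10, sigma = 0.2, seed = 4) {
  quartet <- linear_quartet(sigma = sigma)
  design <- data.frame(observable = "y", condition = "1",
                       time = seq(window[1], window[2],
                                  length.out = n_data),
                       replicates = 1L)
  data <- generate_data(quartet$M3, theta, design, sigma, seed = seed,
                        sigma_attr = sigma)
  fits <- lapply(quartet, fit_posterior, data = data,
                 method = "analytic")
  list(quartet = quartet, data = data, fits = fits, window = window,
       theta = theta, sigma = sigma)
}

# first-order decay ODE with analytic solution exp(-p t)
decay_model <- function() {
  ode_model(
    name = "decay", states = "x",
    rhs = function(t, x, p, u) -p[["p"]] * x[["x"]],
    x0 = c(x = 1), conditions = list("1" = 1))
}

gauss_sample <- function(n, mean = 0, sd = 1) matrix(rnorm(n, mean, sd),
                                                    ncol = 1)
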