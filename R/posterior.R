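#' Analytic posterior of a linear-Gaussian model
#'
#' Conjugate update for a linear basis-function model with known noise sd
#' `sigma` and independent zero-mean Gaussian coefficient priors of sd
#' `xi`: the posterior is Gaussian with covariance
#' `(B'B / sigma^2 + I / xi^2)^{-1}` and mean `Cov B'y / sigma^2`, where B
#' is the design matrix of basis evaluations at the data times. With no
#' data the posterior equals the prior.
#'
#' @param model an [lbf_model()].
#' @param data an [oed_dataset()] (only `time` and `value` are used).
#' @param sigma,xi noise and prior standard deviations (default: model's).
#' @return a `gaussian_posterior`: list with `mean` and `cov`.
#' @export
analytic_posterior <- function(model, data, sigma = model$sigma,
                               xi = model$xi) {
  stopifnot(inherits(model, "lbf_model"), sigma > 0, xi > 0)
  L <- model$L
  if (is.null(data) || nrow(data) == 0) {
    return(structure(list(mean = rep(0, L), cov = diag(xi^2, L)),
                     class = "gaussian_posterior"))
  }
  B <- design_matrix_basis(model, data$time)
  prec <- crossprod(B) / sigma^2 + diag(1 / xi^2, L)
  cov <- chol2inv(chol(prec))
  cov <- (cov + t(cov)) / 2
  mean <- drop(cov %*% crossprod(B, data$value)) / sigma^2
  structure(list(mean = mean, cov = cov), class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat("Gaussian posterior over", length(x$mean), "parameters\n")
  cat("  mean:", paste(signif(x$mean, 4), collapse = ", "), "\n")
  cat("  sd:  ", paste(signif(sqrt(diag(x$cov)), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a model's Bayesian posterior
#'
#' The central fitting function. Linear basis-function models with known
#' noise sd are fitted analytically (conjugate Gaussian posterior); ODE
#' models (or linear models with `method = "mcmc"`) are fitted by
#' population MCMC on a power-posterior temperature ladder, which also
#' yields the thermodynamic-integration marginal likelihood.
#'
#' @param model an [lbf_model()] or [ode_model()].
#' @param data an [oed_dataset()].
#' @param method `"auto"` (analytic where available), `"analytic"` or
#'   `"mcmc"`.
#' @param prior a [prior_spec()]; required for MCMC. When the dataset's
#'   noise sd is flagged as inferred and the prior lacks a `"sigma"` entry,
#'   a broad half-normal (scale 1) is added.
#' @param sigma,xi known noise / prior sd for the analytic route.
#' @param n_temps highest ladder index N_T; the quartic schedule
#'   `T_n = (n / N_T)^4`, n = 0..N_T, is used (default N_T = 40).
#' @param n_samples post-burn-in sweeps to retain per temperature.
#' @param burnin adaptation sweeps discarded before sampling.
#' @param thin_to size of the thinned temperature-1 sample (default
#'   10000, capped at `n_samples`).
#' @param seed RNG seed.
#' @param ... passed to [population_mcmc()].
#' @return a `bayes_fit` object with the posterior (a
#'   `gaussian_posterior` or thinned `posterior_sample`), the tempered
#'   chains when MCMC was used, and the fitting settings.
#' @seealso [predict.bayes_fit()] for posterior predictive samples,
#'   [log_evidence()] for the marginal likelihood.
#' @export
fit_posterior <- function(model, data, method = c("auto", "analytic", "mcmc"),
                          prior = NULL, sigma = NULL, xi = NULL,
                          n_temps = 40, n_samples = 10000, burnin = 2000,
                          thin_to = 10000, seed = 1, ...) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (inherits(model, "lbf_model") &&
                  !all(is.na(attr(data, "sigma") %||% model$sigma)))
      "analytic" else "mcmc"

  if (method == "analytic") {
    if (!inherits(model, "lbf_model"))
      stop("analytic fitting requires a linear basis-function model")
    sigma <- sigma %||% first_finite(attr(data, "sigma")) %||% model$sigma
    xi <- xi %||% model$xi
    post <- analytic_posterior(model, data, sigma, xi)
    fit <- list(model = model, data = data, method = "analytic",
                posterior = post, chains = NULL, sigma = sigma, xi = xi,
                prior = NULL, seed = seed)
  } else {
    if (is.null(prior)) stop("MCMC fitting requires a prior_spec")
    sig_attr <- attr(data, "sigma")
    infer_sigma <- is.null(sig_attr) || all(is.na(sig_attr))
    if (infer_sigma && !"sigma" %in% names(prior))
      prior <- prior_spec(c(unclass(prior),
                            list(sigma = prior_halfnormal(1))))
    chains <- population_mcmc(model, data, prior, n_temps = n_temps,
                              n_samples = n_samples, burnin = burnin,
                              seed = seed,
                              sigma = if (infer_sigma) NULL else sig_attr,
                              ...)
    post <- thin(chains, target = min(thin_to, n_samples))
    fit <- list(model = model, data = data, method = "mcmc",
                posterior = post, chains = chains,
                sigma = if (infer_sigma) NA else sig_attr, xi = NULL,
                prior = prior, seed = seed)
  }
  structure(fit, class = "bayes_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

first_finite <- function(x) {
  if (is.null(x) || all(is.na(x))) NULL else x
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("Bayesian fit of model ", model_name(x$model), " (", x$method,
      ")\n", sep = "")
  cat("  data: ", nrow(x$data), " observations\n", sep = "")
  cm <- coef(x)
  cat("  posterior mean:\n")
  print(signif(cm, 4))
  invisible(x)
}

model_name <- function(model) model$name %||% "model"

#' @export
coef.bayes_fit <- function(object, ...) {
  if (object$method == "analytic") {
    setNames(object$posterior$mean,
             paste0("theta", seq_along(object$posterior$mean)))
  } else {
    colMeans(object$posterior$draws)
  }
}

#' @export
summary.bayes_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  if (object$method == "analytic") {
    m <- object$posterior$mean
    s <- sqrt(diag(object$posterior$cov))
    q <- t(vapply(seq_along(m),
                  function(i) qnorm(probs, m[i], s[i]),
                  numeric(length(probs))))
    tab <- cbind(mean = m, sd = s, q)
    rownames(tab) <- paste0("theta", seq_along(m))
  } else {
    d <- object$posterior$draws
    tab <- cbind(mean = colMeans(d), sd = apply(d, 2, sd),
                 t(apply(d, 2, quantile, probs = probs)))
  }
  colnames(tab)[-(1:2)] <- paste0(format(100 * probs, trim = TRUE), "%")
  structure(list(model = model_name(object$model), method = object$method,
                 table = tab, n_obs = nrow(object$data)),
            class = "summary.bayes_fit")
}

#' @export
print.summary.bayes_fit <- function(x, ...) {
  cat("Posterior summary for ", x$model, " (", x$method, ", n = ",
      x$n_obs, ")\n", sep = "")
  print(signif(x$table, 4))
  invisible(x)
}

posterior_mean_theta <- function(fit) {
  if (fit$method == "analytic") fit$posterior$mean else
    strip_sigma(colMeans(fit$posterior$draws))
}

#' @export
residuals.bayes_fit <- function(object, ...) {
  mu <- model_predict(object$model, posterior_mean_theta(object),
                      object$data)
  object$data$value - mu
}

#' Simulate replicate datasets from a fitted model's posterior predictive
#'
#' Each simulation redraws parameters from the posterior and measurement
#' noise from the error model at the original design points.
#'
#' @param object a `bayes_fit`.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return a list of [oed_dataset()]s.
#' @export
simulate.bayes_fit <- function(object, nsim = 1, seed = 1, ...) {
  d <- object$data
  cand <- candidate_experiment(lapply(seq_len(nrow(d)), function(i)
    design_point(d$observable[i], d$time[i], d$condition[i])))
  ps <- sample_ppd(object, cand, n = nsim, noise = TRUE, seed = seed)
  lapply(seq_len(nsim), function(j)
    oed_dataset(d$observable, d$condition, d$time, d$replicate, ps[j, ],
                sigma = attr(d, "sigma")))
}

#' Plot data and posterior predictive band for one observable
#'
#' @param x a `bayes_fit`.
#' @param observable observable to plot (default: first in the data).
#' @param condition condition identifier.
#' @param times time grid for the band.
#' @param n posterior predictive sample size per time.
#' @param level credible level of the band.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bayes_fit <- function(x, observable = NULL, condition = NULL,
                           times = NULL, n = 500, level = 0.95, ...) {
  d <- x$data
  observable <- observable %||% d$observable[1]
  condition <- condition %||% d$condition[1]
  sub <- d[d$observable == observable & d$condition == condition &
             is.finite(d$time), ]
  times <- times %||% seq(min(sub$time), max(sub$time), length.out = 40)
  cand <- candidate_experiment(lapply(times, function(t)
    design_point(observable, t, condition)))
  ps <- sample_ppd(x, cand, n = n, noise = TRUE, seed = x$seed)
  a <- (1 - level) / 2
  qs <- apply(ps, 2, quantile, probs = c(a, 0.5, 1 - a))
  graphics::plot(sub$time, sub$value, xlab = "time", ylab = observable,
                 ylim = range(qs, sub$value), ...)
  graphics::lines(times, qs[2, ], lty = 1)
  graphics::lines(times, qs[1, ], lty = 2)
  graphics::lines(times, qs[3, ], lty = 2)
  invisible(x)
}
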