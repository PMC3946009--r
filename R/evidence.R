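#' Marginal likelihood of a linear-Gaussian model, in closed form
#'
#' For the linear basis-function model with coefficient prior
#' `N(0, xi^2 I)` and known noise sd `sigma`, the marginal distribution of
#' the data vector is Gaussian with mean 0 and covariance
#' `xi^2 B B' + sigma^2 I`, so the log evidence is a multivariate normal
#' log density. An empty dataset has log evidence 0 (empty product).
#'
#' @param model an [lbf_model()].
#' @param data an [oed_dataset()].
#' @param sigma,xi noise / prior standard deviations.
#' @return a `log_evidence` object (natural-log value, SE = 0, method
#'   `"analytic"`).
#' @export
analytic_log_evidence <- function(model, data, sigma = model$sigma,
                                  xi = model$xi) {
  stopifnot(inherits(model, "lbf_model"), sigma > 0, xi > 0)
  if (is.null(data) || nrow(data) == 0)
    return(new_log_evidence(0, 0, "analytic"))
  B <- design_matrix_basis(model, data$time)
  C <- xi^2 * tcrossprod(B) + diag(sigma^2, nrow(B))
  R <- chol(C)
  z <- backsolve(R, data$value, transpose = TRUE)
  logz <- -0.5 * (nrow(B) * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
  new_log_evidence(logz, 0, "analytic")
}

new_log_evidence <- function(logz, se, method) {
  stopifnot(is.finite(logz), se >= 0)
  structure(list(logz = logz, se = se, method = method),
            class = "log_evidence")
}

#' @export
print.log_evidence <- function(x, ...) {
  cat("log evidence = ", signif(x$logz, 6),
      if (x$se > 0) paste0(" (MC SE ", signif(x$se, 3), ")"),
      " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Thermodynamic-integration marginal likelihood
#'
#' The log evidence equals the integral over T in \[0, 1\] of the
#' power-posterior expectation of the log likelihood; the integral is
#' evaluated by the trapezoidal rule over the chain's temperature ladder,
#' with a Monte-Carlo standard error propagated through the quadrature
#' weights (per-temperature variances scaled by the effective sample
#' size).
#'
#' @param chains a `tempered_chains` object from [population_mcmc()]
#'   covering the schedule from 0 to 1.
#' @return a `log_evidence` object (method `"thermodynamic"`).
#' @export
thermodynamic_log_evidence <- function(chains) {
  stopifnot(inherits(chains, "tempered_chains"))
  sched <- chains$schedule
  if (abs(sched[1]) > 0 || abs(sched[length(sched)] - 1) > 0)
    stop("temperature schedule must run from 0 to 1; missing endpoints: ",
         paste(setdiff(c(0, 1), range(sched)), collapse = ", "))
  m <- colMeans(chains$loglik)
  nT <- length(sched)
  dt <- diff(sched)
  w <- c(dt / 2, 0) + c(0, dt / 2)  # trapezoid weights
  logz <- sum(w * m)
  v <- vapply(seq_len(nT), function(i) {
    x <- chains$loglik[, i]
    var(x) / max(ess(x), 1)
  }, numeric(1))
  new_log_evidence(logz, sqrt(sum(w^2 * v)), "thermodynamic")
}

#' Marginal likelihood of a fitted model
#'
#' Dispatches on the fitting route: analytic for conjugate linear-Gaussian
#' fits, thermodynamic integration over the tempered chains otherwise.
#'
#' @param fit a `bayes_fit`.
#' @return a `log_evidence` object.
#' @export
log_evidence <- function(fit) {
  stopifnot(inherits(fit, "bayes_fit"))
  if (fit$method == "analytic")
    analytic_log_evidence(fit$model, fit$data, fit$sigma, fit$xi)
  else
    thermodynamic_log_evidence(fit$chains)
}

#' Bayes factor from two log evidences
#'
#' `log10 B_ab = (log Z_a - log Z_b) / ln 10`, with the conventional
#' qualitative label: a ratio of at least 100:1 (|log10 B| >= 2) is
#' "decisive".
#'
#' @param a,b `log_evidence` objects (or `bayes_fit`s, whose evidences are
#'   computed first), ordered so that positive values favour `a`.
#' @param labels model-pair labels.
#' @return a `bayes_factor` object with `log10_bf`, `se` and label.
#' @export
bayes_factor <- function(a, b, labels = c("a", "b")) {
  if (inherits(a, "bayes_fit")) {
    labels <- c(model_name(a$model), model_name(b$model))
    a <- log_evidence(a)
    b <- log_evidence(b)
  }
  stopifnot(inherits(a, "log_evidence"), inherits(b, "log_evidence"))
  l10 <- (a$logz - b$logz) / log(10)
  se <- sqrt(a$se^2 + b$se^2) / log(10)
  jeffreys <- if (abs(l10) >= 2) "decisive"
    else if (abs(l10) >= 1) "strong"
    else if (abs(l10) >= 0.5) "substantial"
    else "not worth more than a bare mention"
  structure(list(log10_bf = l10, se = se, pair = labels, label = jeffreys),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat("log10 B(", x$pair[1], " vs ", x$pair[2], ") = ",
      signif(x$log10_bf, 4),
      if (x$se > 0) paste0(" +/- ", signif(x$se, 2)),
      "  [", x$label, "]\n", sep = "")
  invisible(x)
}

#' Expected Bayes-factor update for a candidate experiment
#'
#' Monte-Carlo estimate of how the log10 Bayes factor between two fitted
#' models would change after performing a candidate experiment: new
#' observations are drawn from the designated generating distribution (by
#' default the posterior predictive distribution of `fit_a`'s model, the
#' presumed truth; optionally from fixed true parameters plus noise), both
#' evidences are recomputed with the augmented dataset, and the change in
#' log10 B_ab is summarized over replicates.
#'
#' For MCMC-fitted models each replicate requires a full
#' thermodynamic-integration run per model; that path is deliberately
#' gated behind `expensive = TRUE`.
#'
#' @param fit_a,fit_b fitted models (`bayes_fit`); the Bayes factor is
#'   B_ab, positive changes favour `fit_a`'s model.
#' @param candidate a [candidate_experiment()].
#' @param n_rep number of simulated replicate experiments (>= 2).
#' @param seed RNG seed.
#' @param generator `"ppd"` (sample new data from `fit_a`'s posterior
#'   predictive) or `"truth"` (simulate from `truth$theta` plus noise).
#' @param truth list with `theta` (and optionally `sigma`) when
#'   `generator = "truth"`.
#' @param expensive allow the thermodynamic route for MCMC fits.
#' @param ... passed to the refit for MCMC models.
#' @return a `bf_update`: mean, sd, central credible interval and the
#'   replicate draws of the change in log10 B_ab.
#' @export
expected_bf_update <- function(fit_a, fit_b, candidate, n_rep = 100,
                               seed = 1, generator = c("ppd", "truth"),
                               truth = NULL, expensive = FALSE, ...) {
  generator <- match.arg(generator)
  stopifnot(inherits(fit_a, "bayes_fit"), inherits(fit_b, "bayes_fit"))
  if (n_rep < 2) stop("n_rep must be at least 2")
  if ((fit_a$method != "analytic" || fit_b$method != "analytic") &&
      !expensive)
    stop("expected Bayes-factor updates for MCMC-fitted models require ",
         "a thermodynamic-integration run per replicate; pass ",
         "expensive = TRUE to confirm")
  pts <- candidate$points
  d <- length(pts)

  # new-measurement draws: n_rep x d
  if (generator == "ppd") {
    ynew <- sample_ppd(fit_a, candidate, n = n_rep, noise = TRUE,
                       seed = seed)
  } else {
    if (is.null(truth$theta)) stop("generator = 'truth' needs truth$theta")
    sig <- truth$sigma %||% fit_a$sigma
    records <- candidate_records(candidate)
    mu <- model_predict(fit_a$model, truth$theta, records)
    set.seed(seed)
    ynew <- matrix(rep(mu, each = n_rep), n_rep, d) +
      matrix(rnorm(n_rep * d, 0, sig), n_rep, d)
  }

  base <- bayes_factor(fit_a, fit_b)$log10_bf
  records <- candidate_records(candidate)
  rep_base <- max(fit_a$data$replicate) + 1L
  delta <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    newdata <- oed_dataset(records$observable, records$condition,
                           records$time, rep_base + seq_len(d) - 1L,
                           ynew[r, ], sigma = attr(fit_a$data, "sigma"))
    aug <- rbind_dataset(fit_a$data, newdata)
    lz <- tryCatch({
      za <- refit_evidence(fit_a, aug, seed = seed + r, ...)
      zb <- refit_evidence(fit_b, aug, seed = seed + r, ...)
      (za$logz - zb$logz) / log(10)
    }, error = function(e) NA_real_)
    delta[r] <- lz - base
  }
  dropped <- sum(is.na(delta))
  if (dropped > 0) delta <- delta[!is.na(delta)]
  structure(list(mean = mean(delta), sd = sd(delta),
                 ci = quantile(delta, c(0.025, 0.975)), draws = delta,
                 n_rep = n_rep, dropped = dropped,
                 pair = c(model_name(fit_a$model),
                          model_name(fit_b$model)),
                 candidate = candidate$label),
            class = "bf_update")
}

refit_evidence <- function(fit, data, seed = 1, ...) {
  if (fit$method == "analytic") {
    analytic_log_evidence(fit$model, data, fit$sigma, fit$xi)
  } else {
    chains <- population_mcmc(fit$model, data, fit$prior,
                              n_temps = length(fit$chains$schedule) - 1,
                              n_samples = fit$chains$n_samples,
                              burnin = fit$chains$burnin, seed = seed, ...)
    thermodynamic_log_evidence(chains)
  }
}

#' @export
print.bf_update <- function(x, ...) {
  cat("Expected change in log10 B(", x$pair[1], " vs ", x$pair[2],
      ") for candidate ", x$candidate, "\n", sep = "")
  cat("  mean ", signif(x$mean, 4), ", sd ", signif(x$sd, 3),
      ", 95% CI [", signif(x$ci[1], 3), ", ", signif(x$ci[2], 3),
      "], reps ", length(x$draws),
      if (x$dropped > 0) paste0(" (", x$dropped, " dropped)"),
      "\n", sep = "")
  invisible(x)
}
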