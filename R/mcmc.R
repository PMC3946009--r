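#' Power-posterior temperature schedule
#'
#' The quartic ladder `T_n = (n / N_T)^4` for `n = 0 ... N_T`, running from
#' the prior (T = 0) to the full posterior (T = 1). The quartic spacing
#' concentrates temperatures near the prior end, where the integrand of the
#' thermodynamic-integration identity changes fastest.
#'
#' @param n_temps highest ladder index N_T (>= 2).
#' @param exponent ladder exponent (default 4).
#' @return numeric vector of length `n_temps + 1`, strictly increasing,
#'   ending at exactly 1.
#' @examples
#' temperature_schedule(40)[c(1, 21, 41)]  # 0, 0.5^4, 1
#' @export
temperature_schedule <- function(n_temps, exponent = 4) {
  stopifnot(n_temps >= 2)
  (0:n_temps / n_temps)^exponent
}

# Build log-likelihood / log-prior closures on the (partially
# log-transformed) sampling scale. Positivity-constrained parameters are
# sampled as eta = log(theta) with the Jacobian term added to the prior.
make_target <- function(model, data, prior, sigma_known = NULL) {
  nm <- names(prior)
  pos <- prior_is_positive(prior)
  infer_sigma <- "sigma" %in% nm && is.null(sigma_known)

  # fast path for linear models: cache the design matrix
  B <- if (inherits(model, "lbf_model"))
    design_matrix_basis(model, data$time) else NULL
  y <- data$value

  to_theta <- function(eta) {
    th <- eta
    th[pos] <- exp(eta[pos])
    names(th) <- nm
    th
  }
  loglik <- function(eta) {
    th <- to_theta(eta)
    s <- if (infer_sigma) th[["sigma"]] else sigma_known
    mu <- if (!is.null(B)) drop(B %*% strip_sigma(th)) else
      tryCatch(model_predict(model, th, data), error = function(e) NULL)
    if (is.null(mu)) return(-Inf)
    sum(dnorm(y - mu, 0, s, log = TRUE))
  }
  logprior <- function(eta) {
    th <- to_theta(eta)
    lp <- log_prior(th, prior)
    # Jacobian of the log transform
    lp + sum(eta[pos])
  }
  list(nm = nm, pos = pos, to_theta = to_theta, loglik = loglik,
       logprior = logprior, infer_sigma = infer_sigma,
       sigma_known = sigma_known, B = B, y = y)
}

# finite-difference Jacobian of the data predictions w.r.t. eta,
# used to build the Hessian-based proposal covariance
proposal_covariance <- function(model, data, tgt, eta0, prior_sds,
                                h = 1e-4) {
  p <- length(eta0)
  sig <- if (tgt$infer_sigma) exp(eta0[which(tgt$nm == "sigma")]) else
    tgt$sigma_known
  pred <- function(eta) {
    th <- tgt$to_theta(eta)
    if (!is.null(tgt$B)) drop(tgt$B %*% strip_sigma(th)) else
      model_predict(model, th, data)
  }
  # on the log scale a unit sd spans about a decade, a sensible default
  # dispersion for rate constants; unconstrained axes keep their prior sd
  prior_sd_eta <- ifelse(tgt$pos, 1, prior_sds)
  fallback <- diag(prior_sd_eta^2, p)
  J <- tryCatch({
    mu0 <- pred(eta0)
    vapply(seq_len(p), function(j) {
      e <- eta0
      e[j] <- e[j] + h
      (pred(e) - mu0) / h
    }, numeric(length(mu0)))
  }, error = function(e) NULL)
  if (is.null(J) || any(!is.finite(J))) return(fallback)
  H <- crossprod(J) / sig[1]^2 + diag(1 / prior_sd_eta^2, p)
  S <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(S)) fallback else (S + t(S)) / 2
}

#' Population MCMC on a power-posterior temperature ladder
#'
#' Runs coupled Metropolis chains targeting `p(y|theta)^T p(theta)` at the
#' temperatures of the quartic ladder, with one adjacent-pair exchange
#' (swap) attempt per sweep. Positivity-constrained parameters are sampled
#' on the log scale with the Jacobian correction. The Gaussian proposal
#' covariance is initialized from an approximate Hessian built from a
#' finite-difference Jacobian of the model predictions (falling back to the
#' prior covariance when that approximation is not positive definite), and
#' the per-temperature proposal scale adapts toward 23% acceptance during
#' burn-in only, so the retained chains are Markovian.
#'
#' @param model an [lbf_model()] or [ode_model()].
#' @param data an [oed_dataset()].
#' @param prior a [prior_spec()] covering every sampled parameter
#'   (including `"sigma"` when the noise sd is inferred).
#' @param n_temps highest ladder index N_T (default 40 per the standard
#'   configuration); the ladder has `n_temps + 1` chains including the
#'   prior chain at T = 0.
#' @param n_samples post-burn-in sweeps retained per temperature.
#' @param burnin adaptation sweeps discarded.
#' @param seed RNG seed (the run is reproducible given the seed).
#' @param sigma known noise sd, or `NULL` when sigma is sampled.
#' @param exponent ladder exponent.
#' @param init optional named initial parameter vector (natural scale).
#' @param optimize_init refine the initial point by a short posterior-mode
#'   search before sampling.
#' @return a `tempered_chains` object: per-temperature draw matrices
#'   (natural scale), log-likelihood traces, the schedule, acceptance
#'   statistics and the seed.
#' @export
population_mcmc <- function(model, data, prior, n_temps = 40,
                            n_samples = 1000, burnin = 1000, seed = 1,
                            sigma = NULL, exponent = 4, init = NULL,
                            optimize_init = TRUE) {
  stopifnot(inherits(prior, "prior_spec"), n_temps >= 2, n_samples >= 1)
  set.seed(seed)
  schedule <- temperature_schedule(n_temps, exponent)
  nT <- length(schedule)
  tgt <- make_target(model, data, prior, sigma_known = sigma)
  p <- length(tgt$nm)
  prior_sds <- prior_sd_vector(prior)

  # initial point: supplied, or prior draw refined toward the mode
  from_theta <- function(th) {
    e <- th[tgt$nm]
    e[tgt$pos] <- log(e[tgt$pos])
    unname(e)
  }
  eta0 <- if (!is.null(init)) from_theta(init) else {
    draws <- prior_draw(prior, 25)
    lls <- apply(draws, 1, function(th) tgt$loglik(from_theta(th)))
    from_theta(draws[which.max(lls), ])
  }
  if (!is.finite(tgt$loglik(eta0) + tgt$logprior(eta0)))
    stop("non-finite posterior at the initial point")
  if (optimize_init) {
    opt <- tryCatch(
      optim(eta0, function(e) -(tgt$loglik(e) + tgt$logprior(e)),
            method = "Nelder-Mead",
            control = list(maxit = 200 * p, warn.1d.NelderMead = FALSE)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) eta0 <- opt$par
  }

  S <- proposal_covariance(model, data, tgt, eta0, prior_sds)
  # replace the generic unit prior sd on the unconstrained axes
  Lp <- t(chol(S))
  scales <- rep(2.38 / sqrt(p), nT)

  eta <- matrix(rep(eta0, each = nT), nT, p) +
    0.01 * matrix(rnorm(nT * p), nT, p)
  ll <- apply(eta, 1, tgt$loglik)
  lp <- apply(eta, 1, tgt$logprior)
  bad <- !is.finite(ll + lp)
  if (any(bad)) {
    eta[bad, ] <- matrix(rep(eta0, each = sum(bad)), sum(bad), p)
    ll[bad] <- tgt$loglik(eta0)
    lp[bad] <- tgt$logprior(eta0)
  }

  total <- burnin + n_samples
  draws <- array(NA_real_, c(n_samples, p, nT))
  ll_trace <- matrix(NA_real_, n_samples, nT)
  acc <- integer(nT)
  prop <- integer(nT)
  swap_acc <- 0L
  swap_prop <- 0L
  stall <- 0L

  for (sweep in seq_len(total)) {
    adapting <- sweep <= burnin
    z <- matrix(rnorm(nT * p), p, nT)
    logu <- log(runif(nT))
    for (i in seq_len(nT)) {
      cand <- eta[i, ] + scales[i] * drop(Lp %*% z[, i])
      lpc <- tgt$logprior(cand)
      if (is.finite(lpc)) {
        llc <- tgt$loglik(cand)
        la <- schedule[i] * (llc - ll[i]) + (lpc - lp[i])
      } else la <- -Inf
      prop[i] <- prop[i] + 1L
      accept <- is.finite(la) && logu[i] < la
      if (accept) {
        eta[i, ] <- cand
        ll[i] <- llc
        lp[i] <- lpc
        acc[i] <- acc[i] + 1L
      }
      if (adapting)
        scales[i] <- scales[i] *
          exp(min(0.1, 2 / sqrt(sweep)) * ((if (accept) 1 else 0) - 0.23))
    }
    # one adjacent-pair exchange attempt per sweep
    j <- sample.int(nT - 1L, 1L)
    swap_prop <- swap_prop + 1L
    la <- (schedule[j] - schedule[j + 1]) * (ll[j + 1] - ll[j])
    if (is.finite(la) && log(runif(1)) < la) {
      swap_acc <- swap_acc + 1L
      tmp <- eta[j, ]; eta[j, ] <- eta[j + 1, ]; eta[j + 1, ] <- tmp
      tmp <- ll[j]; ll[j] <- ll[j + 1]; ll[j + 1] <- tmp
      tmp <- lp[j]; lp[j] <- lp[j + 1]; lp[j + 1] <- tmp
    }
    if (sweep > burnin) {
      s <- sweep - burnin
      for (i in seq_len(nT)) draws[s, , i] <- eta[i, ]
      ll_trace[s, ] <- ll
    }
  }
  if (all(acc == 0))
    stop("population MCMC stalled: no proposal accepted; last state: ",
         paste(signif(tgt$to_theta(eta[nT, ]), 4), collapse = ", "))

  theta_draws <- lapply(seq_len(nT), function(i) {
    m <- draws[, , i, drop = FALSE]
    dim(m) <- c(n_samples, p)
    m[, tgt$pos] <- exp(m[, tgt$pos, drop = FALSE])
    colnames(m) <- tgt$nm
    m
  })
  structure(list(schedule = schedule, draws = theta_draws,
                 loglik = ll_trace, acceptance = acc / pmax(prop, 1),
                 swap_rate = swap_acc / max(swap_prop, 1),
                 scales = scales, seed = seed, burnin = burnin,
                 n_samples = n_samples, parameters = tgt$nm,
                 model = model_name(model)),
            class = "tempered_chains")
}

#' @export
print.tempered_chains <- function(x, ...) {
  cat("Population MCMC chains for ", x$model, "\n", sep = "")
  cat("  ", length(x$schedule), " temperatures (quartic ladder), ",
      x$n_samples, " retained sweeps after ", x$burnin, " burn-in\n",
      sep = "")
  cat("  acceptance: ", paste(sprintf("%.2f", range(x$acceptance)),
                              collapse = " - "),
      "; swap rate ", sprintf("%.2f", x$swap_rate), "\n", sep = "")
  invisible(x)
}

#' Thin the temperature-1 chain to a fixed sample size
#'
#' Evenly-strided subsample of the posterior (T = 1) chain, of exactly
#' `target` draws (default 10000).
#'
#' @param chains a `tempered_chains` object.
#' @param target number of retained draws.
#' @return a `posterior_sample`: draw matrix with ESS diagnostics.
#' @export
thin <- function(chains, target = 10000) {
  stopifnot(inherits(chains, "tempered_chains"))
  d <- chains$draws[[length(chains$draws)]]
  n <- nrow(d)
  if (n < target)
    stop("chain has ", n, " post-burn-in draws; at least ", target,
         " are required (increase n_samples)")
  stride <- floor(n / target)
  idx <- n - stride * (target - seq_len(target))
  out <- d[idx, , drop = FALSE]
  structure(list(draws = out, model = chains$model,
                 ess = apply(out, 2, ess), thin_stride = stride,
                 seed = chains$seed),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample for ", x$model, ": ", nrow(x$draws), " draws of ",
      ncol(x$draws), " parameters\n", sep = "")
  cat("  min ESS: ", signif(min(x$ess), 3), "\n", sep = "")
  invisible(x)
}

# effective sample size by the initial positive sequence estimator
ess <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  lag_max <- min(n - 1, 400)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  for (i in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[i] + ac[i + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' Profile the posterior along one parameter to check propriety
#'
#' For each grid value of the named parameter, maximizes
#' `log likelihood + log prior` over the remaining parameters and reports
#' the profile. The posterior is flagged proper when the profile has
#' dropped from its maximum by at least `drop_threshold` at both grid ends
#' (i.e. the likelihood times the prior does not flatten out in the tails).
#'
#' @param model,data,prior as in [population_mcmc()].
#' @param parameter name of the profiled parameter.
#' @param grid grid of values spanning the prior's bulk.
#' @param sigma known noise sd (`NULL` when sigma is in the prior).
#' @param drop_threshold required log-density drop (default log 100).
#' @return a `propriety_profile`: grid, profile values, and flag.
#' @export
check_propriety <- function(model, data, prior, parameter, grid,
                            sigma = NULL, drop_threshold = log(100)) {
  stopifnot(parameter %in% names(prior))
  tgt <- make_target(model, data, prior, sigma_known = sigma)
  j <- which(tgt$nm == parameter)
  free <- setdiff(seq_along(tgt$nm), j)
  eta_from <- function(v) if (tgt$pos[j]) log(v) else v

  start <- prior_draw(prior, 1)[1, ]
  eta_start <- start
  eta_start[tgt$pos] <- log(eta_start[tgt$pos])
  eta_free <- unname(eta_start[free])

  profile <- vapply(grid, function(v) {
    ev <- eta_from(v)
    if (!is.finite(ev)) return(-Inf)
    # the profile is of likelihood x prior on the natural scale (no
    # log-transform Jacobian); the transform only eases the optimizer
    obj <- function(ef) {
      e <- numeric(length(tgt$nm))
      e[j] <- ev
      e[free] <- ef
      -(tgt$loglik(e) + log_prior(tgt$to_theta(e), prior))
    }
    if (length(free) == 0) return(-obj(numeric(0)))
    res <- tryCatch(
      optim(eta_free, obj, method = "Nelder-Mead",
            control = list(maxit = 200 * length(free),
                           warn.1d.NelderMead = FALSE)),
      error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    eta_free <<- res$par
    -res$value
  }, numeric(1))

  ok <- is.finite(profile)
  pk <- max(profile[ok])
  ends <- profile[c(which(ok)[1], tail(which(ok), 1))]
  proper <- all(pk - ends >= drop_threshold)
  structure(list(parameter = parameter, grid = grid, profile = profile,
                 proper = proper, drop_threshold = drop_threshold),
            class = "propriety_profile")
}

#' @export
print.propriety_profile <- function(x, ...) {
  cat("Propriety profile for '", x$parameter, "': ",
      if (x$proper) "proper" else "improper (profile flattens out)",
      "\n", sep = "")
  invisible(x)
}
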