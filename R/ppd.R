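#' Candidate observations and candidate experiments
#'
#' A design point is one candidate observation: an observable, a time
#' (`Inf` = steady state) and a stimulus condition. A candidate experiment
#' is an ordered list of `d >= 1` design points measured jointly;
#' duplicated points represent replicate measurements.
#'
#' @param observable observable name.
#' @param time observation time, or `Inf` for steady state (ODE models
#'   require t >= 0; regression models admit any real time).
#' @param condition condition identifier.
#' @return `design_point`: a `design_point` object.
#' @export
design_point <- function(observable, time, condition = "1") {
  stopifnot(is.character(observable), length(observable) == 1,
            !is.na(time))
  structure(list(observable = observable, time = as.numeric(time),
                 condition = as.character(condition)),
            class = "design_point")
}

point_label <- function(p) {
  tm <- if (is.finite(p$time)) paste0("t=", format(p$time)) else "ss"
  paste0(p$observable, "@", tm, "|u", p$condition)
}

#' @rdname design_point
#' @param points list of `design_point`s (or a single one).
#' @param label experiment label (auto-generated by default).
#' @export
candidate_experiment <- function(points, label = NULL) {
  if (inherits(points, "design_point")) points <- list(points)
  stopifnot(length(points) >= 1,
            all(vapply(points, inherits, logical(1), "design_point")))
  label <- label %||%
    paste(vapply(points, point_label, character(1)), collapse = " + ")
  structure(list(points = points, d = length(points), label = label),
            class = "candidate_experiment")
}

#' @export
print.candidate_experiment <- function(x, ...) {
  cat("Candidate experiment (d = ", x$d, "): ", x$label, "\n", sep = "")
  invisible(x)
}

candidate_records <- function(candidate) {
  data.frame(
    observable = vapply(candidate$points, `[[`, character(1), "observable"),
    condition = vapply(candidate$points, `[[`, character(1), "condition"),
    time = vapply(candidate$points, `[[`, numeric(1), "time"),
    stringsAsFactors = FALSE)
}

#' Sample the posterior predictive distribution of a candidate experiment
#'
#' Simulates the fitted model at the candidate's design points for each
#' posterior parameter draw and adds measurement noise from the error
#' model (noise is on by default: future observations are noisy). When the
#' noise sd was inferred, each draw uses its own sigma, propagating the
#' full posterior uncertainty. For analytic linear-Gaussian fits the PPD
#' is sampled from its closed form
#' `N(B* mu, B* Sigma B*' + sigma^2 I)`.
#'
#' @param fit a `bayes_fit`.
#' @param candidate a [candidate_experiment()] (or single
#'   [design_point()]).
#' @param n number of predictive draws (default: the posterior sample
#'   size for MCMC fits, 5000 for analytic fits).
#' @param noise include measurement noise.
#' @param seed RNG seed.
#' @return a `predictive_sample`: an `n` x d matrix (columns follow the
#'   candidate's design-point order) with attributes `model`, `candidate`,
#'   `noise` and `seed`.
#' @export
sample_ppd <- function(fit, candidate, n = NULL, noise = TRUE, seed = 1) {
  stopifnot(inherits(fit, "bayes_fit"))
  if (inherits(candidate, "design_point"))
    candidate <- candidate_experiment(candidate)
  d <- candidate$d
  records <- candidate_records(candidate)
  set.seed(seed)

  if (fit$method == "analytic") {
    n <- n %||% 5000
    Bs <- design_matrix_basis(fit$model, records$time)
    # draw coefficient vectors once; the draw does not depend on the
    # candidate, so permuting the design points permutes columns exactly
    Rch <- chol(fit$posterior$cov)
    Theta <- matrix(rnorm(n * length(fit$posterior$mean)), n) %*% Rch
    Theta <- sweep(Theta, 2, fit$posterior$mean, "+")
    Y <- Theta %*% t(Bs)
    sig <- rep(fit$sigma, n)
  } else {
    draws <- fit$posterior$draws
    if (!is.null(n) && n < nrow(draws)) {
      idx <- nrow(draws) - floor(nrow(draws) / n) * (n - seq_len(n))
      draws <- draws[idx, , drop = FALSE]
    } else if (!is.null(n) && n > nrow(draws)) {
      stop("requested ", n, " predictive draws but the posterior sample ",
           "has only ", nrow(draws))
    }
    n <- nrow(draws)
    sig <- if ("sigma" %in% colnames(draws)) draws[, "sigma"] else
      rep(fit$sigma, n)
    Y <- matrix(NA_real_, n, d)
    failed <- 0L
    for (i in seq_len(n)) {
      mu <- tryCatch(
        model_predict(fit$model, draws[i, ], records),
        error = function(e) NULL)
      if (is.null(mu)) { failed <- failed + 1L; next }
      Y[i, ] <- mu
    }
    if (failed > 0.01 * n)
      stop(failed, " of ", n, " posterior draws failed to simulate")
    if (failed > 0) {
      keep <- complete.cases(Y)
      Y <- Y[keep, , drop = FALSE]
      sig <- sig[keep]
      n <- nrow(Y)
    }
  }
  if (noise) {
    # measurement noise is keyed to the design point (not the column
    # position), so reordering the candidate reorders columns exactly;
    # duplicated points (replicates) get independent draws per occurrence
    labs <- vapply(candidate$points, point_label, character(1))
    occ <- stats::ave(seq_len(d), labs, FUN = seq_along)
    for (j in seq_len(d)) {
      set.seed(point_noise_seed(seed, labs[j], occ[j]))
      Y[, j] <- Y[, j] + rnorm(n, 0, sig)
    }
  }
  colnames(Y) <- vapply(candidate$points, point_label, character(1))
  structure(Y, class = c("predictive_sample", "matrix", "array"),
            model = model_name(fit$model), candidate = candidate$label,
            noise = noise, seed = seed)
}

# deterministic noise stream per (seed, design point, occurrence)
point_noise_seed <- function(seed, label, occurrence) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, "#", occurrence)))
    h <- (h * 31 + ch) %% 1977654321
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

#' @export
print.predictive_sample <- function(x, ...) {
  cat("Predictive sample for ", attr(x, "model"), ": ", nrow(x),
      " draws x ", ncol(x), " prediction(s)",
      if (isTRUE(attr(x, "noise"))) " (noise included)", "\n", sep = "")
  cat("  candidate: ", attr(x, "candidate"), "\n", sep = "")
  s <- rbind(mean = colMeans(x), sd = apply(x, 2, sd))
  print(signif(s, 4))
  invisible(x)
}

#' Predictive samples via the predict method
#'
#' @param object a `bayes_fit`.
#' @param candidate a [candidate_experiment()] or [design_point()].
#' @param n,noise,seed see [sample_ppd()].
#' @param ... unused.
#' @return a `predictive_sample` matrix.
#' @export
predict.bayes_fit <- function(object, candidate, n = NULL, noise = TRUE,
                              seed = 1, ...) {
  sample_ppd(object, candidate, n = n, noise = noise, seed = seed)
}

#' Enumerate candidate experiments over a measurement grid
#'
#' All unordered size-`d` combinations, with repetition (an exact
#' duplicate represents a replicate measurement), over the
#' observable x time x condition grid.
#'
#' @param observables character vector of observable names.
#' @param times numeric times (may include `Inf` for steady state).
#' @param conditions condition identifiers.
#' @param d experiment dimension (number of joint measurements).
#' @param cap refuse to enumerate more than this many candidates.
#' @return list of [candidate_experiment()]s.
#' @examples
#' length(enumerate_candidates("y", c(0, 1, 2), "1", d = 1))  # 3
#' @export
enumerate_candidates <- function(observables, times, conditions = "1",
                                 d = 1, cap = 1e5) {
  grid <- expand.grid(observable = observables, time = times,
                      condition = conditions, stringsAsFactors = FALSE)
  n <- nrow(grid)
  count <- choose(n + d - 1, d)
  if (count > cap)
    stop("grid yields ", count, " candidates (cap ", cap,
         "); coarsen the grid or lower d")
  pts <- lapply(seq_len(n), function(i)
    design_point(grid$observable[i], grid$time[i], grid$condition[i]))
  combos <- combn_with_repetition(n, d)
  lapply(seq_len(ncol(combos)), function(j)
    candidate_experiment(pts[combos[, j]]))
}

# unordered combinations with repetition as an d x count index matrix
combn_with_repetition <- function(n, d) {
  if (d == 1) return(matrix(seq_len(n), 1))
  sub <- combn(n + d - 1, d)
  sub - (seq_len(d) - 1L)
}
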