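#' Experimental datasets
#'
#' A dataset is a data frame with one row per measured value and columns
#' `observable`, `condition`, `time`, `replicate`, `value`. Steady-state
#' observations are represented by `time = Inf` in memory (and encoded as
#' `time = -1` plus a `steady_state` flag column on disk). The noise
#' standard deviation is carried as the `"sigma"` attribute: a positive
#' number (or named per-observable vector) when known, `NA` when it is to
#' be inferred.
#'
#' @param observable character vector of observable names.
#' @param condition condition identifiers (coerced to character).
#' @param time numeric times (>= 0, or `Inf` for steady state).
#' @param replicate integer replicate indices.
#' @param value measured values.
#' @param sigma known noise sd, or `NA` to flag it as inferred.
#' @return an `oed_dataset` (a data.frame subclass).
#' @export
oed_dataset <- function(observable, condition, time, replicate, value,
                        sigma = NA) {
  d <- data.frame(observable = as.character(observable),
                  condition = as.character(condition),
                  time = as.numeric(time),
                  replicate = as.integer(replicate),
                  value = as.numeric(value),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$value))) stop("values must be finite")
  # negative times are legal for regression models; ODE simulation
  # enforces t >= 0 itself
  if (any(is.na(d$time))) stop("times must not be NA")
  key <- do.call(paste, c(d[c("observable", "condition", "time",
                              "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop("(observable, condition, time, replicate) tuples must be unique")
  if (!all(is.na(sigma)) && any(sigma <= 0)) stop("sigma must be positive")
  attr(d, "sigma") <- sigma
  class(d) <- c("oed_dataset", "data.frame")
  d
}

#' @export
print.oed_dataset <- function(x, ...) {
  s <- attr(x, "sigma")
  cat("Dataset: ", nrow(x), " observations of ",
      length(unique(x$observable)), " observable(s), noise sd ",
      if (all(is.na(s))) "inferred" else paste(format(s), collapse = ", "),
      "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

rbind_dataset <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  oed_dataset(out$observable, out$condition, out$time, out$replicate,
              out$value, sigma = attr(a, "sigma"))
}

#' Read / write datasets as CSV
#'
#' On disk, steady-state rows carry `time = -1` and `steady_state = TRUE`.
#'
#' @param path file path.
#' @param data an [oed_dataset()].
#' @param sigma noise sd to attach on read (`NA` = inferred).
#' @return `read_dataset` returns an [oed_dataset()].
#' @export
read_dataset <- function(path, sigma = NA) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable", "condition", "time", "replicate", "value")
  if (!all(need %in% names(d)))
    stop("dataset file must have columns: ", paste(need, collapse = ", "))
  tm <- as.numeric(d$time)
  if ("steady_state" %in% names(d)) tm[as.logical(d$steady_state)] <- Inf
  oed_dataset(d$observable, d$condition, tm, d$replicate, d$value,
              sigma = sigma)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "oed_dataset"))
  out <- as.data.frame(data)
  out$steady_state <- !is.finite(out$time)
  out$time[out$steady_state] <- -1
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Gaussian log likelihood of a dataset given predictions
#'
#' Independent Gaussian errors: the log likelihood is the sum over series
#' and time points of the per-point log densities of the residuals, so the
#' likelihood of a concatenated dataset factorizes over its parts.
#'
#' @param data an [oed_dataset()].
#' @param predictions numeric vector of model predictions, aligned with the
#'   rows of `data`.
#' @param sigma noise sd: scalar, or named vector with one entry per
#'   observable.
#' @return scalar log likelihood (natural log).
#' @export
log_likelihood <- function(data, predictions, sigma) {
  if (length(predictions) != nrow(data))
    stop("predictions must align with the dataset rows")
  if (any(sigma <= 0) || any(!is.finite(sigma))) stop("sigma must be > 0")
  s <- if (length(sigma) > 1L) {
    if (is.null(names(sigma))) stop("per-observable sigma must be named")
    unname(sigma[data$observable])
  } else rep(sigma, nrow(data))
  if (any(is.na(s))) stop("missing sigma for some observable")
  sum(dnorm(data$value - predictions, 0, s, log = TRUE))
}

#' Model predictions aligned to dataset rows
#'
#' Evaluates the model's noise-free predictions for every record of a
#' dataset (grouping ODE solves by condition).
#'
#' @param model an [lbf_model()] or [ode_model()].
#' @param theta parameter vector (coefficients for linear models; named
#'   kinetic parameters for ODE models, an entry named `"sigma"` is
#'   ignored here).
#' @param data an [oed_dataset()] or data.frame with `observable`,
#'   `condition`, `time` columns.
#' @return numeric vector, one prediction per row of `data`.
#' @export
model_predict <- function(model, theta, data) UseMethod("model_predict")

#' @export
model_predict.lbf_model <- function(model, theta, data) {
  theta <- strip_sigma(theta)
  simulate_linear(model, theta, data$time)
}

#' @export
model_predict.ode_model <- function(model, theta, data) {
  theta <- strip_sigma(theta)
  out <- numeric(nrow(data))
  for (cond in unique(data$condition)) {
    rows <- which(data$condition == cond)
    tms <- sort(unique(data$time[rows]))
    sim <- simulate_ode(model, theta, condition = cond, times = tms)
    ti <- match(data$time[rows], tms)
    oi <- match(data$observable[rows], colnames(sim))
    if (anyNA(oi))
      stop("unknown observable: ",
           paste(unique(data$observable[rows][is.na(oi)]), collapse = ", "))
    out[rows] <- sim[cbind(ti, oi)]
  }
  out
}

strip_sigma <- function(theta) {
  if (!is.null(names(theta)) && "sigma" %in% names(theta))
    theta <- theta[names(theta) != "sigma"]
  theta
}

#' Simulate a synthetic dataset from known parameters
#'
#' Simulates the model at the requested design and adds i.i.d. Gaussian
#' measurement noise; reproducible given `seed`.
#'
#' @param model an [lbf_model()] or [ode_model()].
#' @param theta_true generating parameter vector.
#' @param design data.frame with columns `observable`, `condition`, `time`
#'   and `replicates` (number of replicate measurements per point).
#' @param sigma noise sd (scalar or named per-observable); `sigma = 0`
#'   returns the noise-free simulation.
#' @param seed RNG seed.
#' @param sigma_attr value stored as the dataset's `"sigma"` attribute
#'   (defaults to `sigma`; pass `NA` to flag the noise as to-be-inferred).
#' @return an [oed_dataset()].
#' @export
generate_data <- function(model, theta_true, design, sigma, seed = 1,
                          sigma_attr = if (all(sigma == 0)) NA else
                            sigma) {
  stopifnot(all(c("observable", "condition", "time") %in% names(design)))
  if (is.null(design$replicates)) design$replicates <- 1L
  rows <- design[rep(seq_len(nrow(design)), design$replicates), , drop = FALSE]
  rep_idx <- unlist(lapply(design$replicates, seq_len))
  records <- data.frame(observable = as.character(rows$observable),
                        condition = as.character(rows$condition),
                        time = as.numeric(rows$time),
                        stringsAsFactors = FALSE)
  mu <- model_predict(model, theta_true, records)
  s <- if (length(sigma) > 1L) unname(sigma[records$observable]) else sigma
  set.seed(seed)
  noise <- if (all(s == 0)) 0 else rnorm(nrow(records), 0, s)
  oed_dataset(records$observable, records$condition, records$time,
              rep_idx, mu + noise, sigma = sigma_attr)
}
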