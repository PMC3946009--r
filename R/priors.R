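#' Prior distribution specifications
#'
#' Per-parameter prior building blocks. Kinetic rate constants get a gamma
#' prior (default shape 1, scale 3: relatively non-informative, mean 3,
#' while avoiding the Lindley-paradox regime of arbitrarily vague priors);
#' linear-model coefficients get a zero-mean Gaussian with standard
#' deviation `xi`; the noise scale sigma gets a broad half-normal.
#'
#' The gamma parameterization is shape-scale by default; pass `rate` instead
#' of `scale` to use the shape-rate convention.
#'
#' @param shape,scale,rate gamma hyperparameters (strictly positive); give
#'   either `scale` or `rate`.
#' @param sd standard deviation of the zero-mean Gaussian.
#' @return a `prior_dist` object.
#' @examples
#' prior_gamma(1, 3)          # mean-3 exponential
#' prior_gaussian(1)
#' prior_halfnormal(1)
#' @export
prior_gamma <- function(shape = 1, scale = 3, rate = NULL) {
  if (!is.null(rate)) {
    stopifnot(rate > 0)
    scale <- 1 / rate
  }
  stopifnot(shape > 0, scale > 0)
  structure(list(dist = "gamma", shape = shape, scale = scale,
                 positive = TRUE),
            class = "prior_dist")
}

#' @rdname prior_gamma
#' @export
prior_gaussian <- function(sd = 1) {
  stopifnot(sd > 0)
  structure(list(dist = "gaussian", sd = sd, positive = FALSE),
            class = "prior_dist")
}

#' @rdname prior_gamma
#' @export
prior_halfnormal <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(dist = "halfnormal", scale = scale, positive = TRUE),
            class = "prior_dist")
}

#' Bundle per-parameter priors into a prior specification
#'
#' @param ... named `prior_dist` objects, one per model parameter.
#' @return a `prior_spec` object (named list).
#' @examples
#' prior_spec(k1 = prior_gamma(1, 3), sigma = prior_halfnormal(1))
#' @export
prior_spec <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "prior_dist"))
    ps <- ps[[1]]
  if (is.null(names(ps)) || any(names(ps) == ""))
    stop("every prior entry must be named")
  ok <- vapply(ps, inherits, logical(1), "prior_dist")
  if (!all(ok)) stop("entries must be prior_dist objects")
  structure(ps, class = "prior_spec")
}

log_prior_one <- function(x, p) {
  switch(p$dist,
    gamma = dgamma(x, shape = p$shape, scale = p$scale, log = TRUE),
    gaussian = dnorm(x, 0, p$sd, log = TRUE),
    halfnormal = ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, p$scale, log = TRUE)),
    stop("unknown prior distribution: ", p$dist)
  )
}

#' Log prior density of a parameter vector
#'
#' Sum of the per-parameter log densities; returns `-Inf` outside the
#' support (e.g. a negative value under a gamma prior).
#'
#' @param theta named numeric vector; names must match the prior spec.
#' @param prior a [prior_spec()].
#' @return scalar log density (natural log).
#' @export
log_prior <- function(theta, prior) {
  stopifnot(inherits(prior, "prior_spec"))
  nm <- names(prior)
  if (!all(nm %in% names(theta)))
    stop("theta is missing parameters: ",
         paste(setdiff(nm, names(theta)), collapse = ", "))
  sum(vapply(nm, function(n) log_prior_one(theta[[n]], prior[[n]]),
             numeric(1)))
}

#' Draw a parameter vector from a prior specification
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @return an `n` x p matrix of draws with parameter names as columns.
#' @export
prior_draw <- function(prior, n = 1) {
  stopifnot(inherits(prior, "prior_spec"))
  draws <- vapply(prior, function(p) {
    switch(p$dist,
      gamma = rgamma(n, shape = p$shape, scale = p$scale),
      gaussian = rnorm(n, 0, p$sd),
      halfnormal = abs(rnorm(n, 0, p$scale)))
  }, numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1,
                               dimnames = list(NULL, names(prior)))
  draws
}

prior_is_positive <- function(prior) {
  vapply(prior, function(p) isTRUE(p$positive), logical(1))
}

prior_sd_vector <- function(prior) {
  vapply(prior, function(p) {
    switch(p$dist,
      gamma = sqrt(p$shape) * p$scale,
      gaussian = p$sd,
      halfnormal = p$scale * sqrt(1 - 2 / pi))
  }, numeric(1))
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification (", length(x), " parameters)\n", sep = "")
  for (nm in names(x)) {
    p <- x[[nm]]
    desc <- switch(p$dist,
      gamma = sprintf("gamma(shape=%g, scale=%g)", p$shape, p$scale),
      gaussian = sprintf("gaussian(sd=%g)", p$sd),
      halfnormal = sprintf("half-normal(scale=%g)", p$scale))
    cat("  ", format(nm, width = 10), desc, "\n")
  }
  invisible(x)
}
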