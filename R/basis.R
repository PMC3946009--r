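#' Basis functions for linear regression models
#'
#' A small registry of time basis functions used by the linear
#' basis-function models: monomials `t^a` and modulated sinusoids
#' `sin(freq * t) * t^power / scale`.
#'
#' @param degree polynomial degree (>= 0).
#' @param freq,power,scale sinusoid frequency, polynomial modulation power
#'   and amplitude divisor.
#' @return a `basis_fn` object: a function of time with a `label` attribute.
#' @examples
#' b <- basis_sinmod(15, scale = 3)   # sin(15 t) / 3
#' b(0)
#' @export
basis_poly <- function(degree) {
  stopifnot(degree >= 0)
  force(degree)
  structure(function(t) t^degree,
            label = if (degree == 1) "t" else sprintf("t^%g", degree),
            class = "basis_fn")
}

#' @rdname basis_poly
#' @export
basis_sinmod <- function(freq, power = 0, scale = 1) {
  stopifnot(is.finite(freq), power >= 0, scale > 0)
  force(freq); force(power); force(scale)
  lab <- sprintf("sin(%gt)", freq)
  if (power > 0) lab <- paste0(lab, if (power == 1) "*t" else
                                 sprintf("*t^%g", power))
  if (scale != 1) lab <- paste0(lab, sprintf("/%g", scale))
  structure(function(t) sin(freq * t) * t^power / scale,
            label = lab, class = "basis_fn")
}

basis_label <- function(b) {
  lb <- attr(b, "label")
  if (is.null(lb)) "B(t)" else lb
}

#' Linear basis-function model
#'
#' A regression model `y(t) = sum_i theta_i B_i(t) + eps` with Gaussian
#' observation noise of known standard deviation `sigma` and independent
#' zero-mean Gaussian priors of standard deviation `xi` on the
#' coefficients. The conjugate structure makes the posterior and the
#' marginal likelihood available in closed form, which is what makes these
#' models the workhorse for validating the divergence-based design
#' criterion against exact Bayes factors.
#'
#' @param ... basis functions (`basis_fn` objects or plain functions of t).
#' @param name model identifier.
#' @param xi prior standard deviation of the coefficients.
#' @param sigma known observation noise standard deviation.
#' @return an `lbf_model` object.
#' @examples
#' m <- lbf_model(basis_poly(1), basis_poly(2), name = "M2")
#' simulate_linear(m, c(1, 1), times = c(0, 1, 2))
#' @export
lbf_model <- function(..., name = "M", xi = 1, sigma = 0.2) {
  bases <- list(...)
  if (length(bases) == 1L && is.list(bases[[1]]) &&
      !is.function(bases[[1]]))
    bases <- bases[[1]]
  stopifnot(length(bases) >= 1, xi > 0, sigma > 0)
  ok <- vapply(bases, is.function, logical(1))
  if (!all(ok)) stop("all basis entries must be functions of time")
  structure(list(bases = bases, L = length(bases), name = name,
                 xi = xi, sigma = sigma),
            class = "lbf_model")
}

#' @export
print.lbf_model <- function(x, ...) {
  labs <- vapply(x$bases, basis_label, character(1))
  terms <- paste(sprintf("theta%d*%s", seq_along(labs), labs),
                 collapse = " + ")
  cat("Linear basis-function model ", x$name, ": y(t) = ", terms,
      " + eps\n", sep = "")
  cat("  coefficients: ", x$L, ", prior sd xi = ", x$xi,
      ", noise sd sigma = ", x$sigma, "\n", sep = "")
  invisible(x)
}

#' Evaluate the design matrix of a linear basis-function model
#'
#' @param model an [lbf_model()].
#' @param times numeric vector of time points.
#' @return a `length(times)` x L matrix of basis evaluations.
#' @export
design_matrix_basis <- function(model, times) {
  stopifnot(inherits(model, "lbf_model"))
  B <- vapply(model$bases, function(b) b(times), numeric(length(times)))
  B <- matrix(B, nrow = length(times), ncol = model$L)
  bad <- which(!is.finite(B), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("basis %d is not finite at t = %g",
                 bad[1, 2], times[bad[1, 1]]))
  B
}

#' Noise-free simulation of a linear basis-function model
#'
#' Returns `sum_i theta_i B_i(t)` for each requested time.
#'
#' @param model an [lbf_model()].
#' @param theta coefficient vector of length `model$L`.
#' @param times numeric vector of time points.
#' @return numeric vector of predicted means.
#' @export
simulate_linear <- function(model, theta, times) {
  stopifnot(inherits(model, "lbf_model"))
  theta <- as.numeric(theta)
  if (length(theta) != model$L)
    stop("theta must have length ", model$L)
  drop(design_matrix_basis(model, times) %*% theta)
}
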