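#' Declare models and priors from a YAML/JSON config
#'
#' A light declarative interface. Linear models list basis functions from
#' the registry (`poly` with `degree`; `sinmod` with `freq`, `power`,
#' `scale`); ODE models name a registered system (currently the
#' `motif` quartet with a `variant`). Example:
#'
#' ```yaml
#' type: linear
#' name: M3
#' xi: 1
#' sigma: 0.2
#' bases:
#'   - {type: poly, degree: 1}
#'   - {type: poly, degree: 2}
#'   - {type: sinmod, freq: 15, scale: 3}
#' ```
#'
#' @param path YAML file path.
#' @return an [lbf_model()] or [ode_model()].
#' @export
model_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- cfg$type %||% stop("config needs a 'type' field")
  if (type == "linear") {
    bases <- lapply(cfg$bases, function(b) {
      switch(b$type,
        poly = basis_poly(b$degree %||% 1),
        sinmod = basis_sinmod(b$freq, b$power %||% 0, b$scale %||% 1),
        stop("unknown basis type: ", b$type))
    })
    lbf_model(bases, name = cfg$name %||% "M", xi = cfg$xi %||% 1,
              sigma = cfg$sigma %||% 0.2)
  } else if (type == "ode") {
    if ((cfg$system %||% "motif") != "motif")
      stop("unknown ODE system: ", cfg$system)
    v <- cfg$variant %||% 1
    motif_quartet()[[paste0("M", v)]]
  } else stop("unknown model type: ", type)
}

#' @rdname model_from_config
#' @export
prior_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$prior %||% cfg
  ps <- lapply(entries, function(e) {
    switch(e$dist,
      gamma = prior_gamma(e$shape %||% 1, e$scale %||% 3,
                          rate = e$rate),
      gaussian = prior_gaussian(e$sd %||% 1),
      halfnormal = prior_halfnormal(e$scale %||% 1),
      stop("unknown prior distribution: ", e$dist))
  })
  names(ps) <- names(entries)
  prior_spec(ps)
}
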