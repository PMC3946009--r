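#' Feedback-motif model quartet
#'
#' Four ODE models of a phosphorylation cascade with complex formation
#' (stimulus u drives B phosphorylation; Bp phosphorylates C; Bp and Cp
#' form the complex BpCp, which phosphorylates D; all phosphoforms decay
#' first-order). The four variants differ only in the origin and point of
#' action of a negative feedback, applied as a `1 / (1 + kf X)`
#' multiplier:
#'
#' * `M1`: Dp inhibits the stimulus-driven B phosphorylation (the
#'   conventional data-generating truth),
#' * `M2`: Dp inhibits the Bp + Cp complex formation,
#' * `M3`: BpCp inhibits the B phosphorylation,
#' * `M4`: Cp inhibits the B phosphorylation.
#'
#' All four variants can describe data generated by `M1` to an acceptable
#' degree, which is what makes discriminating them a design problem. The
#' right-hand sides are compiled (see the package sources) and integrated
#' with tight tolerances. Observables are the five species
#' Bp, Cp, BpCp, Dp and B; the stimulus conditions map to u = 1 and
#' u = 2.
#'
#' @param x0 named initial conditions (defaults: B = C = D = 1,
#'   phosphoforms and complex 0).
#' @return named list of four [ode_model()]s `M1` to `M4`.
#' @export
motif_quartet <- function(x0 = NULL) {
  states <- c("B", "Bp", "C", "Cp", "BpCp", "D", "Dp")
  x0 <- x0 %||% c(B = 1, Bp = 0, C = 1, Cp = 0, BpCp = 0, D = 1, Dp = 0)
  obs <- function(x) x[, c("Bp", "Cp", "BpCp", "Dp", "B"), drop = FALSE]
  mk <- function(variant) {
    ode_model(
      name = paste0("M", variant), states = states,
      compiled = list(
        func = "motif_derivs", initfunc = "motif_init",
        dllname = "jsdesign",
        parms_fn = function(p, u)
          c(u, variant, unname(p[c("k1", "k2", "k3", "k4", "k5", "k6",
                                   "k7", "k8")]),
            unname(p["kf"]))),
      x0 = x0, observables = obs,
      conditions = list("1" = 1, "2" = 2), t_horizon = 100)
  }
  out <- lapply(1:4, mk)
  names(out) <- paste0("M", 1:4)
  out
}

#' True parameters of the motif benchmark
#'
#' Rate constants of the data-generating model (`M1`), chosen so that the
#' Bp trajectory under stimulus shows a visible overshoot above the noise
#' level (the transient peak characteristic of negative-feedback motifs)
#' within the measured time window.
#'
#' @return named numeric vector `k1` to `k8` plus the feedback strength
#'   `kf`.
#' @export
motif_true_params <- function() {
  c(k1 = 0.5, k2 = 0.3, k3 = 1, k4 = 0.3, k5 = 4, k6 = 0.2,
    k7 = 2, k8 = 0.15, kf = 15)
}

#' Default gamma-prior specification for the motif parameters
#'
#' Gamma(shape 1, scale 3) on every rate constant and the feedback
#' strength; the noise sd gets a broad half-normal when inferred.
#'
#' @param include_sigma add a `sigma` entry.
#' @return a [prior_spec()].
#' @export
motif_prior <- function(include_sigma = TRUE) {
  ps <- lapply(names(motif_true_params()), function(n) prior_gamma(1, 3))
  names(ps) <- names(motif_true_params())
  if (include_sigma) ps$sigma <- prior_halfnormal(1)
  prior_spec(ps)
}

#' Default inference dataset of the motif benchmark
#'
#' Data simulated from `M1` under stimulus 1: Bp with three replicates and
#' Dp with two, measured at t = 0, 2, 5, 10, 20, 40, 60, 100, with
#' additive Gaussian white noise of sd 0.03. The noise sd is flagged as
#' inferred (the fits sample sigma).
#'
#' @param quartet a [motif_quartet()].
#' @param theta_true generating parameters.
#' @param times measurement times.
#' @param sigma generating noise sd.
#' @param seed RNG seed.
#' @return an [oed_dataset()].
#' @export
motif_dataset <- function(quartet = motif_quartet(),
                          theta_true = motif_true_params(),
                          times = c(0, 2, 5, 10, 20, 40, 60, 100),
                          sigma = 0.03, seed = 1) {
  design <- rbind(
    data.frame(observable = "Bp", condition = "1", time = times,
               replicates = 3L),
    data.frame(observable = "Dp", condition = "1", time = times,
               replicates = 2L))
  generate_data(quartet$M1, theta_true, design, sigma, seed = seed,
                sigma_attr = NA)
}

#' Run the nonlinear feedback-motif design study
#'
#' End-to-end validation on the motif quartet: fits all four models to the
#' shared dataset by population MCMC, samples predictive sources over the
#' single-measurement axis (five observables x time grid plus steady
#' state x two stimulus conditions), fills pairwise d = 2 design
#' matrices, and evaluates three named validation experiments:
#'
#' 1. steady-state Cp and BpCp (condition 1) -- expected to separate
#'    M1 from M3;
#' 2. Bp and Dp during the peak under the second condition (u = 2), the
#'    peak being the time of maximum posterior-median Bp;
#' 3. steady-state Cp alone -- expected to add no discriminatory power.
#'
#' Expected Bayes-factor updates for the experiments require a
#' thermodynamic-integration run per replicate and are gated behind
#' `expensive_bf = TRUE`.
#'
#' @param quartet a [motif_quartet()].
#' @param data the shared inference dataset (default [motif_dataset()]).
#' @param prior parameter priors.
#' @param pairs list of model-name pairs for the design matrices.
#' @param times time grid of the candidate axis.
#' @param n_temps,n_samples,burnin population-MCMC settings.
#' @param n_ppd predictive sample size.
#' @param k neighbour rank.
#' @param seed RNG seed (the study is deterministic given the seed).
#' @param expensive_bf also compute expected Bayes-factor updates.
#' @param n_rep_bf replicates for the (expensive) update estimates.
#' @return a `motif_study` list: fits, design matrices, validation
#'   experiment JSDs (and updates when requested), the peak time, and
#'   settings.
#' @export
run_motif_study <- function(quartet = motif_quartet(),
                            data = NULL,
                            prior = motif_prior(),
                            pairs = list(c("M1", "M2"), c("M1", "M3"),
                                         c("M1", "M4")),
                            times = c(2, 5, 10, 20, 40, 100),
                            n_temps = 8, n_samples = 2000, burnin = 1000,
                            n_ppd = 500, k = 10, seed = 1,
                            expensive_bf = FALSE, n_rep_bf = 10) {
  data <- data %||% motif_dataset(quartet, seed = seed)
  models <- names(quartet)

  fits <- lapply(seq_along(quartet), function(i)
    fit_posterior(quartet[[i]], data, method = "mcmc", prior = prior,
                  n_temps = n_temps, n_samples = n_samples,
                  burnin = burnin, thin_to = min(n_samples, 10000),
                  seed = seed + i))
  names(fits) <- models

  # candidate axis: observables x (times + steady state) x conditions
  axis <- list()
  for (cond in c("1", "2"))
    for (obs in c("Bp", "Cp", "BpCp", "Dp", "B"))
      for (tm in c(times, Inf))
        axis[[length(axis) + 1L]] <- design_point(obs, tm, cond)

  sources <- lapply(seq_along(fits), function(i)
    ppd_source(fits[[i]], axis, n = n_ppd, seed = seed + 100 + i))
  names(sources) <- models

  matrices <- lapply(pairs, function(pr)
    compute_design_matrix(sources[[pr[1]]], sources[[pr[2]]], k = k,
                          d = 2, seed = seed + 200))
  names(matrices) <- vapply(pairs, paste, character(1), collapse = "_")

  # peak of the posterior-median Bp trajectory under u = 2 (true model)
  grid <- seq(0, max(times), length.out = 41)
  med <- apply(sample_ppd(fits$M1,
                          candidate_experiment(lapply(grid, function(t)
                            design_point("Bp", t, "2"))),
                          n = min(n_ppd, 200), noise = FALSE,
                          seed = seed + 300),
               2, median)
  peak_time <- grid[which.max(med)]

  experiments <- list(
    ss_Cp_BpCp = candidate_experiment(list(
      design_point("Cp", Inf, "1"), design_point("BpCp", Inf, "1")),
      label = "steady-state Cp + BpCp"),
    peak_Bp_Dp = candidate_experiment(list(
      design_point("Bp", peak_time, "2"),
      design_point("Dp", peak_time, "2")),
      label = "Bp + Dp at the u=2 peak"),
    ss_Cp = candidate_experiment(design_point("Cp", Inf, "1"),
                                 label = "steady-state Cp"))

  exp_jsd <- lapply(experiments, function(cand) {
    vapply(pairs, function(pr) {
      pa <- sample_ppd(fits[[pr[1]]], cand, n = n_ppd, seed = seed + 400)
      pb <- sample_ppd(fits[[pr[2]]], cand, n = n_ppd, seed = seed + 401)
      knn_jsd(pa, pb, k = k)$jsd
    }, numeric(1)) |> setNames(vapply(pairs, paste, character(1),
                                      collapse = "_"))
  })

  exp_dbf <- NULL
  if (expensive_bf) {
    exp_dbf <- lapply(experiments, function(cand)
      lapply(pairs, function(pr)
        expected_bf_update(fits[[pr[1]]], fits[[pr[2]]], cand,
                           n_rep = n_rep_bf, seed = seed + 500,
                           expensive = TRUE)))
  }

  structure(list(fits = fits, sources = sources, matrices = matrices,
                 experiments = experiments, exp_jsd = exp_jsd,
                 exp_dbf = exp_dbf, peak_time = peak_time, data = data,
                 settings = list(n_temps = n_temps, n_samples = n_samples,
                                 burnin = burnin, n_ppd = n_ppd, k = k,
                                 times = times, seed = seed)),
            class = "motif_study")
}

#' @export
print.motif_study <- function(x, ...) {
  cat("Feedback-motif design study (", length(x$fits), " models, ",
      length(x$matrices), " design matrices)\n", sep = "")
  cat("  u=2 Bp peak at t = ", x$peak_time, "\n", sep = "")
  for (nm in names(x$exp_jsd)) {
    cat("  ", format(nm, width = 12), " JSD: ",
        paste(names(x$exp_jsd[[nm]]),
              signif(x$exp_jsd[[nm]], 2), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Diagonal-darkness statistic of a d = 2 design matrix
#'
#' Within each tile of a design matrix that compares an observable with
#' itself (same observable and condition, different times), measuring the
#' same point twice (the tile diagonal) typically adds less information
#' than combining two different time points. The statistic is the
#' fraction of such tiles in which the mean diagonal JSD is below the
#' mean off-diagonal JSD.
#'
#' @param dm a d = 2 `design_matrix`.
#' @return fraction in \[0, 1\] (NA when no tile has >= 2 times).
#' @export
tile_diagonal_stat <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"), dm$d == 2)
  key <- vapply(dm$axis, function(p)
    paste(p$observable, p$condition), character(1))
  darker <- logical(0)
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) < 2) next
    block <- dm$values[idx, idx, drop = FALSE]
    dg <- mean(diag(block))
    off <- mean(block[upper.tri(block)])
    darker <- c(darker, dg < off)
  }
  if (length(darker) == 0) return(NA_real_)
  mean(darker)
}
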