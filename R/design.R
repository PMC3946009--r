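#' Posterior predictive source over a single-measurement axis
#'
#' Precomputes, for one fitted model, the noise-free posterior predictive
#' draws at every single-measurement candidate of an axis (the
#' observable x time x condition grid flattened to a list of design
#' points), together with each draw's noise sd. Design matrices are then
#' filled from column pairs with fresh measurement noise, so that a
#' candidate combining the same point twice correctly has independent
#' replicate noise on the two coordinates.
#'
#' @param fit a `bayes_fit`.
#' @param axis list of [design_point()]s.
#' @param n predictive sample size.
#' @param seed RNG seed.
#' @return a `ppd_source`: noiseless draw matrix `S` (n x axis), sigma
#'   draws, axis metadata.
#' @export
ppd_source <- function(fit, axis, n = 1000, seed = 1) {
  stopifnot(all(vapply(axis, inherits, logical(1), "design_point")))
  cand <- candidate_experiment(axis, label = "axis")
  S <- sample_ppd(fit, cand, n = n, noise = FALSE, seed = seed)
  n_eff <- nrow(S)
  sig <- ppd_sigma_draws(fit, n_eff)
  structure(list(S = as_point_matrix(S), sigma = sig, axis = axis,
                 labels = vapply(axis, point_label, character(1)),
                 model = model_name(fit$model), n = n_eff, seed = seed),
            class = "ppd_source")
}

ppd_sigma_draws <- function(fit, n) {
  if (fit$method == "analytic") return(rep(fit$sigma, n))
  draws <- fit$posterior$draws
  if ("sigma" %in% colnames(draws)) {
    idx <- nrow(draws) - floor(nrow(draws) / n) * (n - seq_len(n))
    draws[idx, "sigma"]
  } else rep(fit$sigma, n)
}

#' @export
print.ppd_source <- function(x, ...) {
  cat("PPD source for ", x$model, ": ", x$n, " draws over ",
      length(x$axis), " axis points\n", sep = "")
  invisible(x)
}

#' Pairwise design matrix of JSD values
#'
#' For one model pair, fills the symmetric matrix of kNN-JSD values over
#' all two-measurement candidates formed from a single-measurement axis
#' (d = 2; diagonal cells are replicate measurements of one point). With
#' `d = 1` a vector of single-measurement JSDs is returned instead.
#'
#' @param source_a,source_b [ppd_source()]s of the two models, built on
#'   the same axis with equal sample sizes.
#' @param k neighbour rank.
#' @param d candidate dimension: 2 (matrix) or 1 (vector).
#' @param seed RNG seed for the measurement-noise draws.
#' @return a `design_matrix` object; `$values` is the symmetric matrix
#'   (or vector), labelled by axis point.
#' @export
compute_design_matrix <- function(source_a, source_b, k = 10, d = 2,
                                  seed = 1) {
  stopifnot(inherits(source_a, "ppd_source"),
            inherits(source_b, "ppd_source"),
            d %in% c(1, 2))
  if (!identical(source_a$labels, source_b$labels))
    stop("sources must share the candidate axis; mismatch at: ",
         paste(head(setdiff(source_a$labels, source_b$labels)),
               collapse = ", "))
  if (source_a$n != source_b$n)
    stop("PPD sample sizes must be equal")
  P <- length(source_a$labels)
  set.seed(seed)
  noisy <- function(src) {
    n <- src$n
    # two independent noise realizations per axis point (replicates)
    list(Y1 = src$S + matrix(rnorm(n * P, 0, rep(src$sigma, P)), n, P),
         Y2 = src$S + matrix(rnorm(n * P, 0, rep(src$sigma, P)), n, P))
  }
  A <- noisy(source_a)
  B <- noisy(source_b)

  if (d == 1) {
    vals <- vapply(seq_len(P), function(i)
      knn_jsd(A$Y1[, i, drop = FALSE], B$Y1[, i, drop = FALSE],
              k = k)$jsd, numeric(1))
    names(vals) <- source_a$labels
  } else {
    vals <- matrix(NA_real_, P, P,
                   dimnames = list(source_a$labels, source_a$labels))
    for (i in seq_len(P)) {
      for (j in i:P) {
        v <- knn_jsd(cbind(A$Y1[, i], A$Y2[, j]),
                     cbind(B$Y1[, i], B$Y2[, j]), k = k)$jsd
        vals[i, j] <- v
        vals[j, i] <- v
      }
    }
  }
  structure(list(values = vals, axis = source_a$axis,
                 labels = source_a$labels,
                 pair = c(source_a$model, source_b$model),
                 k = k, d = d, n = source_a$n, seed = seed),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("JSD design matrix (", x$pair[1], " vs ", x$pair[2], "), d = ",
      x$d, ", k = ", x$k, ", N = ", x$n, "\n", sep = "")
  if (x$d == 1) print(signif(x$values, 3)) else {
    cat("  ", length(x$labels), " axis points; value range ",
        signif(min(x$values), 3), " - ", signif(max(x$values), 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a design matrix to long-format CSV
#'
#' Columns: `candidate_i`, `candidate_j`, `pair`, `jsd`.
#'
#' @param dm a `design_matrix`.
#' @param path output file.
#' @export
write_design_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "design_matrix"))
  pair <- paste(dm$pair, collapse = "_vs_")
  if (dm$d == 1) {
    out <- data.frame(candidate_i = dm$labels, candidate_j = NA,
                      pair = pair, jsd = unname(dm$values))
  } else {
    idx <- which(upper.tri(dm$values, diag = TRUE), arr.ind = TRUE)
    out <- data.frame(candidate_i = dm$labels[idx[, 1]],
                      candidate_j = dm$labels[idx[, 2]],
                      pair = pair, jsd = dm$values[idx])
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Rank candidate experiments across model pairs
#'
#' Aggregates each candidate's JSD over a set of pairwise design matrices
#' (default: the minimum across pairs, the conservative worst-case
#' discriminability; models are weighted equally a priori) and returns the
#' candidates sorted by decreasing aggregate score, ties broken by
#' candidate label.
#'
#' @param matrices list of `design_matrix` objects on a common axis.
#' @param aggregate `"min"` or `"mean"`, or a function of a numeric
#'   vector.
#' @return a `ranked_design` data.frame: candidate label(s), per-pair JSD
#'   columns and the aggregate `score`, sorted descending.
#' @export
rank_candidates <- function(matrices, aggregate = c("min", "mean")) {
  if (inherits(matrices, "design_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  agg <- if (is.function(aggregate)) aggregate else
    switch(match.arg(aggregate), min = min, mean = mean)
  d <- matrices[[1]]$d
  labs <- matrices[[1]]$labels
  per_pair <- lapply(matrices, function(m) {
    stopifnot(identical(m$labels, labs), m$d == d)
    if (d == 1) unname(m$values) else m$values[upper.tri(m$values,
                                                         diag = TRUE)]
  })
  if (d == 1) {
    cand <- data.frame(candidate = labs, stringsAsFactors = FALSE)
  } else {
    idx <- which(upper.tri(matrices[[1]]$values, diag = TRUE),
                 arr.ind = TRUE)
    cand <- data.frame(candidate = paste(labs[idx[, 1]], labs[idx[, 2]],
                                         sep = " + "),
                       stringsAsFactors = FALSE)
  }
  pm <- do.call(cbind, per_pair)
  colnames(pm) <- vapply(matrices, function(m)
    paste(m$pair, collapse = "|"), character(1))
  score <- apply(pm, 1, agg)
  out <- cbind(cand, pm, score = score)
  out <- out[order(-out$score, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_design", "data.frame")
  out
}

#' Greedy augmentation of a candidate experiment
#'
#' Evaluates the JSD of `current + p` for every design point `p` of a
#' pool and returns the ranked extensions. Since adding a coordinate can
#' only add information, the true JSD of an extension is at least that of
#' the base; the kNN estimate respects this up to estimator tolerance.
#' The candidate dimension is capped (default 3) because the kNN density
#' estimates degrade as the dimension grows.
#'
#' @param current a [candidate_experiment()].
#' @param pool list of [design_point()]s.
#' @param fit_a,fit_b the fitted model pair.
#' @param k neighbour rank.
#' @param n predictive sample size.
#' @param seed RNG seed.
#' @param max_d dimension cap.
#' @return data.frame of extensions sorted by decreasing JSD, with the
#'   base JSD as an attribute.
#' @export
augment_design <- function(current, pool, fit_a, fit_b, k = 10, n = 5000,
                           seed = 1, max_d = 3) {
  stopifnot(inherits(current, "candidate_experiment"))
  if (inherits(pool, "design_point")) pool <- list(pool)
  if (current$d + 1 > max_d)
    stop("dimension cap (", max_d, ") exceeded: kNN density estimates ",
         "degrade as the number of jointly designed experiments grows")
  base <- knn_jsd(sample_ppd(fit_a, current, n = n, seed = seed),
                  sample_ppd(fit_b, current, n = n, seed = seed + 1),
                  k = k)$jsd
  ext <- vapply(seq_along(pool), function(i) {
    cand <- candidate_experiment(c(current$points, list(pool[[i]])))
    knn_jsd(sample_ppd(fit_a, cand, n = n, seed = seed),
            sample_ppd(fit_b, cand, n = n, seed = seed + 1),
            k = k)$jsd
  }, numeric(1))
  out <- data.frame(
    extension = vapply(pool, point_label, character(1)),
    jsd = ext, gain = ext - base, stringsAsFactors = FALSE)
  out <- out[order(-out$jsd, out$extension), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_jsd") <- base
  out
}
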