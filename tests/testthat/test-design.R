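make_sources <- function(fx, times = seq(-1, 2, length.out = 7),
                         n = 1500, seed = 21) {
  axis <- lapply(times, function(t) design_point("y", t))
  list(M3 = ppd_source(fx$fits$M3, axis, n = n, seed = seed),
       M1 = ppd_source(fx$fits$M1, axis, n = n, seed = seed + 1),
       M2 = ppd_source(fx$fits$M2, axis, n = n, seed = seed + 2),
       times = times)
}

test_that("design matrix is symmetric and near zero for identical models", {
  fx <- quartet_fixture()
  src <- make_sources(fx)
  # the same model against itself (independent predictive draws)
  axis <- lapply(src$times, function(t) design_point("y", t))
  twin <- ppd_source(fx$fits$M3, axis, n = 1500, seed = 99)
  dm0 <- compute_design_matrix(src$M3, twin, k = 10, d = 2, seed = 3)
  expect_identical(dm0$values, t(dm0$values))
  expect_lt(max(abs(dm0$values)), 0.06)

  dm <- compute_design_matrix(src$M3, src$M1, k = 10, d = 2, seed = 3)
  expect_identical(dm$values, t(dm$values))
  expect_true(all(is.finite(dm$values)))
})

test_that("d = 1 design vectors reproduce the extrapolation pattern", {
  fx <- quartet_fixture()
  src <- make_sources(fx)
  dm <- compute_design_matrix(src$M3, src$M1, k = 10, d = 1, seed = 3)
  expect_length(dm$values, length(src$times))
  inside <- src$times >= 0 & src$times <= 1
  expect_gt(mean(dm$values[!inside]), mean(dm$values[inside]))
})

test_that("design matrices are deterministic given seeds", {
  fx <- quartet_fixture()
  src <- make_sources(fx)
  a <- compute_design_matrix(src$M3, src$M1, k = 10, d = 2, seed = 5)
  b <- compute_design_matrix(src$M3, src$M1, k = 10, d = 2, seed = 5)
  expect_identical(a$values, b$values)
})

test_that("ranking aggregates across pairs with the min rule", {
  fx <- quartet_fixture()
  src <- make_sources(fx)
  dm31 <- compute_design_matrix(src$M3, src$M1, k = 10, d = 1, seed = 3)
  dm32 <- compute_design_matrix(src$M3, src$M2, k = 10, d = 1, seed = 3)

  single <- rank_candidates(dm31)
  expect_true(!is.unsorted(rev(single$score)))
  expect_equal(single$score, unname(sort(dm31$values, decreasing = TRUE)))

  both <- rank_candidates(list(dm31, dm32), aggregate = "min")
  expect_equal(both$score,
               pmin(both[[2]], both[[3]]))

  # a candidate with zero JSD against one pair sinks under min-aggregation
  zeroed <- dm32
  top_lab <- single$candidate[1]
  zeroed$values[top_lab] <- 0
  ranked <- rank_candidates(list(dm31, zeroed), aggregate = "min")
  pos <- which(ranked$candidate == top_lab)
  all_pos <- ranked[ranked$score > 0, ]
  expect_gt(pos, nrow(all_pos))
})

test_that("long-format serialization covers every unordered cell", {
  fx <- quartet_fixture()
  src <- make_sources(fx, times = c(0, 0.5, 1))
  dm <- compute_design_matrix(src$M3, src$M1, k = 10, d = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_design_matrix(dm, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 3 * 4 / 2)
  expect_named(out, c("candidate_i", "candidate_j", "pair", "jsd"))
})

test_that("greedy augmentation ranks informative extensions first", {
  fx <- quartet_fixture()
  # far-extrapolation base: the predictive spread dominates the noise,
  # so a replicate of the same point cannot add much
  base <- candidate_experiment(design_point("y", 1.8))
  pool <- lapply(c(-0.8, 0.5, 1.8), function(t) design_point("y", t))
  ext <- augment_design(base, pool, fx$fits$M3, fx$fits$M1, n = 4000,
                        seed = 9)
  b0 <- attr(ext, "base_jsd")
  dup <- ext$jsd[ext$extension == "y@t=1.8|u1"]
  expect_lt(abs(dup - b0), 0.05)
  # extrapolation extensions dominate and respect near-monotonicity
  expect_gt(max(ext$jsd), b0)
  expect_true(all(ext$jsd >= b0 - 0.05))

  expect_error(
    augment_design(candidate_experiment(rep(list(design_point("y", 1)),
                                            3)),
                   pool, fx$fits$M3, fx$fits$M1),
    "cap")
})

test_that("a separating coordinate saturates an uninformative candidate", {
  fx <- quartet_fixture()
  # the same model twice: no information anywhere
  base <- candidate_experiment(design_point("y", 0.5))
  j0 <- knn_jsd(sample_ppd(fx$fits$M3, base, n = 3000, seed = 1),
                sample_ppd(fx$fits$M3, base, n = 3000, seed = 2), k = 10)
  expect_lt(abs(j0$jsd), 0.05)
  # append a coordinate with disjoint supports by construction
  a <- cbind(sample_ppd(fx$fits$M3, base, n = 3000, seed = 3),
             rnorm(3000, 0, 0.1))
  b <- cbind(sample_ppd(fx$fits$M3, base, n = 3000, seed = 4),
             rnorm(3000, 50, 0.1))
  expect_gt(knn_jsd(a, b, k = 10)$jsd, 0.95)
})
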