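test_that("fill_missing_replicates interpolates in replicate-index space", {
  # interior: rep1=2, rep2 missing, rep3=6 -> midpoint 4
  v <- rbind(c(2, 1), c(NA, 1), c(6, 1))
  f <- fill_missing_replicates(curve_matrix("A", c(0, 30), v))
  expect_equal(f$curve$values[2, 1], 4)
  expect_equal(f$n_interpolated, 1L)

  # boundary bug-fix semantics: rep1 missing, rep2=4, rep3=8 ->
  # cyclic mean of last present (8) and next present (4) = 6
  v <- rbind(c(NA, 1), c(4, 1), c(8, 1))
  f <- fill_missing_replicates(curve_matrix("A", c(0, 30), v))
  expect_equal(f$curve$values[1, 1], 6)

  # symmetric case: last replicate missing
  v <- rbind(c(4, 1), c(8, 1), c(NA, 1))
  f <- fill_missing_replicates(curve_matrix("A", c(0, 30), v))
  expect_equal(f$curve$values[3, 1], 6)

  # non-adjacent interior gap uses index distances as weights
  v <- rbind(c(0, 1), c(NA, 1), c(NA, 1), c(9, 1))
  f <- fill_missing_replicates(curve_matrix("A", c(0, 30), v))
  expect_equal(f$curve$values[2:3, 1], c(3, 6))
  expect_equal(f$n_interpolated, 2L)

  # complete matrix untouched
  v <- matrix(1:6, 3, 2)
  f <- fill_missing_replicates(curve_matrix("A", c(0, 30), v))
  expect_equal(unname(f$curve$values), unname(v * 1.0))
  expect_equal(f$n_interpolated, 0L)
})

test_that("count_crossings matches frozen examples and strict-sign rule", {
  expect_equal(count_crossings(cm2x2(c(4, 6), c(6, 4))), 1L)
  expect_equal(count_crossings(cm2x2(c(4, 6), c(5, 7))), 0L)  # parallel
  # touching (zero difference at an endpoint) is not a crossing
  expect_equal(count_crossings(cm2x2(c(4, 5), c(5, 5))), 0L)
  # 3 replicates x 3 timepoints: all three pairs cross in both intervals
  cm <- curve_matrix("A", c(0, 15, 30),
                     rbind(c(1, 5, 1), c(3, 3, 3), c(5, 1, 5)))
  expect_equal(count_crossings(cm), 6L)
})

test_that("count_crossings agrees with exhaustive enumeration oracle", {
  set.seed(11)
  for (i in 1:25) {
    R <- sample(2:5, 1); T <- sample(2:5, 1)
    vals <- matrix(sample(0:4, R * T, replace = TRUE), R, T)  # ties likely
    # perturb rows so no column is fully tied (curve_matrix allows ties fine)
    cm <- curve_matrix("A", seq(0, by = 10, length.out = T), vals)
    expect_equal(count_crossings(cm), crossings_oracle(vals))
  }
})

test_that("profile repeatability reproduces hand-computed dispersion", {
  # parallel pair: G = 5, v_t = 0.08 each, S = 0.16, PR = 1/1.16
  res <- profile_repeatability(cm2x2(c(4, 4), c(6, 6)))
  expect_equal(res$score, 1 / 1.16, tolerance = 1e-12)
  expect_equal(res$detail$per_time_variance, c(0.08, 0.08))
  expect_equal(res$detail$crossings, 0L)
  expect_equal(res$detail$raw_dispersion, 0.16)

  # same values crossed: C = 1 of C_max = 1 doubles S
  res2 <- profile_repeatability(cm2x2(c(4, 6), c(6, 4)))
  expect_equal(res2$score, 1 / 1.32, tolerance = 1e-12)
  expect_lt(res2$score, res$score)

  # identical replicates: S = 0, PR = 1
  res3 <- profile_repeatability(cm2x2(c(5, 20), c(5, 20)))
  expect_equal(res3$score, 1)
  expect_equal(res3$detail$raw_dispersion, 0)

  # interpolation penalty: m = 1 in a 3x2 matrix multiplies S by 1 + 1/6
  v_complete <- rbind(c(2, 1), c(4, 1), c(6, 1))
  v_missing <- rbind(c(2, 1), c(NA, 1), c(6, 1))
  s_complete <- profile_repeatability(
    curve_matrix("A", c(0, 30), v_complete))$detail$raw_dispersion
  det <- profile_repeatability(curve_matrix("A", c(0, 30), v_missing))$detail
  expect_equal(det$n_interpolated, 1L)
  expect_equal(det$raw_dispersion, s_complete * (1 + 1 / 6),
               tolerance = 1e-12)

  # zero grand mean is an error
  expect_error(profile_repeatability(cm2x2(c(-1, 1), c(1, -1))),
               "grand mean")
})

test_that("PR is bounded, maximal iff identical, and scale invariant", {
  set.seed(23)
  for (i in 1:20) {
    cm <- random_curve(sample(2:6, 1), sample(2:5, 1))
    pr <- profile_repeatability(cm)$score
    expect_gte(pr, 0); expect_lte(pr, 1)
    # scale invariance under c > 0
    scaled <- curve_matrix("A", cm$times, cm$values * 37.5)
    expect_equal(profile_repeatability(scaled)$score, pr, tolerance = 1e-10)
    # non-identical replicates never reach 1
    if (any(apply(cm$values, 2, stats::var) > 1e-12)) expect_lt(pr, 1)
  }
  ident <- curve_matrix("A", c(0, 15, 30),
                        matrix(c(3, 10, 7), 4, 3, byrow = TRUE))
  expect_equal(profile_repeatability(ident)$score, 1)
})

test_that("PR decreases monotonically (in trend) with noise amplitude", {
  base <- matrix(rep(c(5, 25, 30, 15), each = 4), 4, 4)
  sds <- c(0.1, 0.5, 1, 2, 4, 8)
  set.seed(99)
  mean_pr <- vapply(sds, function(s) {
    mean(vapply(1:15, function(i) {
      v <- pmax(base + matrix(rnorm(16, sd = s), 4, 4), 0.1)
      profile_repeatability(curve_matrix("A", c(0, 15, 30, 60), v))$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pr) < 0))
})

test_that("generalized KL divergence matches direct evaluation and is ordered", {
  # identical curves -> 0
  cm <- curve_matrix("A", c(0, 30), rbind(c(2, 3), c(2, 3), c(2, 3)))
  expect_equal(kl_divergence_score(cm)$score, 0)

  # p=(1,2), q=(2,1) -> ln 2
  expect_equal(kl_divergence_score(cm2x2(c(1, 2), c(2, 1)))$score, log(2),
               tolerance = 1e-12)

  # asymmetry: reversing replicate order changes the score
  fwd <- kl_divergence_score(cm2x2(c(1, 3), c(2, 2)))$score
  rev <- kl_divergence_score(cm2x2(c(2, 2), c(1, 3)))$score
  expect_equal(fwd, 1 * log(1 / 2) + 3 * log(3 / 2), tolerance = 1e-12)
  expect_equal(rev, 2 * log(2) + 2 * log(2 / 3), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fwd, rev)))

  # three replicates: mean of the two successive divergences
  cm3 <- curve_matrix("A", c(0, 30), rbind(c(1, 2), c(2, 1), c(1, 2)))
  d <- kl_divergence_score(cm3)
  expect_equal(length(d$detail$pairwise_divergences), 2L)
  expect_equal(d$score, mean(d$detail$pairwise_divergences))
})

test_that("KL divergence is nonnegative on random positive curves", {
  set.seed(31)
  for (i in 1:20) {
    cm <- random_curve(sample(2:6, 1), sample(2:5, 1))
    expect_gte(kl_divergence_score(cm)$score, 0)
  }
})

test_that("KL divergence refuses missing and nonpositive values, naming the cell", {
  v <- rbind(c(1, NA), c(2, 3), c(4, 5))
  expect_error(kl_divergence_score(curve_matrix("A", c(0, 30), v)),
               "missing datapoints")
  v <- rbind(c(1, 2), c(0, 3))
  expect_error(kl_divergence_score(curve_matrix("A", c(0, 30), v)),
               "replicate 2, time 0")
})

test_that("HPA flexibility equals the RMSSD of per-curve means", {
  # means (1, 2, 4) -> sqrt(2.5)
  cm <- curve_matrix("A", c(0, 30), rbind(c(1, 1), c(2, 2), c(4, 4)))
  res <- hpa_flexibility_score(cm)
  expect_equal(res$score, sqrt(2.5), tolerance = 1e-12)
  expect_equal(unname(res$detail$replicate_means), c(1, 2, 4))

  # order sensitivity: means (1, 4, 2) -> sqrt(6.5)
  cm2 <- curve_matrix("A", c(0, 30), rbind(c(1, 1), c(4, 4), c(2, 2)))
  expect_equal(hpa_flexibility_score(cm2)$score, sqrt(6.5),
               tolerance = 1e-12)

  # equal means (different shapes) -> 0
  cm3 <- curve_matrix("A", c(0, 30), rbind(c(1, 3), c(3, 1)))
  expect_equal(hpa_flexibility_score(cm3)$score, 0)

  expect_error(hpa_flexibility_score(
    curve_matrix("A", c(0, 30), rbind(c(1, NA), c(2, 3), c(4, 5)))),
    "missing")
})

test_that("RMSSD matches brute-force oracle on random curves", {
  set.seed(41)
  for (i in 1:20) {
    cm <- random_curve(sample(2:8, 1), sample(2:5, 1))
    expect_equal(hpa_flexibility_score(cm)$score,
                 rmssd_oracle(rowMeans(cm$values)), tolerance = 1e-12)
  }
})

test_that("score_dataset batches metrics and annotates errors", {
  set.seed(5)
  ds <- stress_curve_dataset(lapply(LETTERS[1:3], function(id)
    random_curve(4, 3, id = id)), name = "batch")
  tab <- score_dataset(ds)
  expect_equal(nrow(tab), 9L)
  expect_equal(attr(tab, "directions"),
               c(PR = "higher", KL = "lower", RMSSD = "lower"))
  # per-row consistency with direct calls
  expect_equal(tab$score[tab$metric == "KL" & tab$individual == "B"],
               kl_divergence_score(ds$curves[["B"]])$score)

  # a missing cell: PR-only succeeds, KL errors naming the individual
  v <- ds$curves[["B"]]$values; v[1, 2] <- NA
  dsm <- stress_curve_dataset(list(ds$curves[["A"]],
           curve_matrix("B", ds$times, v), ds$curves[["C"]]), name = "m")
  expect_silent(score_dataset(dsm, metrics = "PR"))
  expect_error(score_dataset(dsm, metrics = c("PR", "KL")), "individual B")
})
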