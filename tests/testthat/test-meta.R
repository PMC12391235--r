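test_that("two identical studies pool to their common value with no heterogeneity", {
  recs <- study_records(c("a", "b"), estimate = c(26.41, 26.41),
                        variance = c(1, 1), n = c(100, 100))
  pool <- pool_random_effects(recs)
  expect_equal(pool$estimate, 26.41)
  expect_equal(pool$tau2, 0)
})

test_that("homogeneous pooling equals the hand-computed inverse-variance mean", {
  # w = 1000 each, ybar = 0.11, Q = 0.2 <= k - 1 so tau2 truncates to 0 and
  # the pool is the plain inverse-variance mean
  recs <- study_records(letters[1:3], estimate = c(0.10, 0.11, 0.12),
                        variance = rep(0.001, 3), n = rep(100, 3),
                        type = "proportion")
  pool <- pool_random_effects(recs)
  expect_equal(pool$tau2, 0)
  expect_equal(pool$estimate, 0.11)
  expect_equal(pool$Q, 0.2)
  expect_equal(pool$se, sqrt(1 / 3000))
})

test_that("with tau2 truncated at zero the pool is the fixed-effect mean (brute force)", {
  set.seed(11)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    est <- rnorm(k, 10, 0.01)        # near-identical: Q stays below k - 1
    v <- runif(k, 0.5, 2)
    recs <- study_records(paste0("s", seq_len(k)), est, v, rep(50L, k))
    pool <- pool_random_effects(recs)
    expect_equal(pool$tau2, 0)
    expect_equal(pool$estimate, sum(est / v) / sum(1 / v))
  }
})

test_that("DerSimonian-Laird agrees with metafor on heterogeneous studies", {
  skip_if_not_installed("metafor")
  set.seed(7)
  est <- rnorm(8, 26.41, 1.2)
  v <- runif(8, 0.2, 1.5)
  recs <- study_records(paste0("s", 1:8), est, v, rep(100L, 8))
  pool <- pool_random_effects(recs)
  ref <- metafor::rma(yi = est, vi = v, method = "DL")
  expect_equal(pool$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(pool$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(pool$se, ref$se, tolerance = 1e-10)
})

test_that("pooling a large simulated meta-analysis recovers the generating mean", {
  recs <- generate_study_summaries(60, true_mean = 26.41, tau2 = 0.5,
                                   within_var = 1, seed = 42)
  pool <- pool_random_effects(recs)
  expect_lt(abs(pool$estimate - 26.41), 3 * pool$se)
  expect_gt(pool$tau2, 0)
})

test_that("proportion records default to binomial variance and validate their range", {
  recs <- study_records(c("a", "b"), estimate = c(0.2, 0.3), n = c(50, 40),
                        type = "proportion")
  expect_equal(recs$variance, c(0.2 * 0.8 / 50, 0.3 * 0.7 / 40))
  expect_error(study_records("a", 1.2, n = 10, type = "proportion"),
               "\\[0, 1\\]")
})

test_that("pooling rejects degenerate inputs but tolerates one zero variance", {
  one <- study_records("a", 0.5, 0.1, 10)
  expect_error(pool_random_effects(one), "at least 2")
  zeros <- study_records(c("a", "b"), c(0.4, 0.6), c(0, 0), c(10, 10))
  expect_error(pool_random_effects(zeros), "all-zero")
  mixed <- pool_random_effects(
    study_records(c("a", "b"), c(0.4, 0.6), c(0, 0.01), c(10, 10)))
  # the zero-variance study carries the larger random-effects weight (total
  # dominance holds only when tau2 truncates to zero)
  expect_gt(mixed$weights[1], mixed$weights[2])
  expect_lt(mixed$estimate, 0.5)
})

test_that("study records round-trip through CSV", {
  recs <- study_records(c("a", "b", "c"), c(0.10, 0.11, 0.12),
                        rep(0.001, 3), c(100L, 120L, 90L), type = "proportion")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(recs), path, row.names = FALSE)
  back <- read_study_records(path, type = "proportion")
  expect_equal(back$estimate, recs$estimate)
  expect_equal(back$variance, recs$variance)
  expect_equal(pool_random_effects(back)$estimate,
               pool_random_effects(recs)$estimate)
})
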