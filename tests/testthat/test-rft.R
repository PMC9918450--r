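# family-wise thresholds: RFT solution properties and permutation checks

test_that("a zero-resel field reduces to the uncorrected quantile", {
  for (nu in c(5, 18, 40)) for (al in c(0.01, 0.05, 0.1)) {
    expect_equal(rft_threshold("t", nu, resels = 0, alpha = al,
                               two_sided = FALSE), qt(1 - al, nu))
    expect_equal(rft_threshold("t", nu, resels = 0, alpha = al),
                 qt(1 - al / 2, nu))
  }
})

test_that("thresholds rise with resels and fall with alpha", {
  z0 <- rft_threshold("t", 18, resels = 0)
  z5 <- rft_threshold("t", 18, resels = 5)
  z10 <- rft_threshold("t", 18, resels = 10)
  expect_true(z0 < z5 && z5 < z10)
  expect_gt(rft_threshold("t", 18, resels = 5, alpha = 0.01), z5)
  expect_gt(z5, qt(0.95, 18))  # never below the pointwise quantile
  f5 <- rft_threshold("T2", 18, p = 3, resels = 5)
  expect_gt(rft_threshold("T2", 18, p = 3, resels = 10), f5)
  expect_gt(f5, rft_threshold("T2", 18, p = 3, resels = 0))
})

test_that("the T2 threshold with one component is the squared |t| threshold", {
  for (R in c(0, 3, 8))
    expect_equal(rft_threshold("T2", 18, p = 1, resels = R),
                 rft_threshold("t", 18, resels = R)^2, tolerance = 1e-8)
})

test_that("the RFT threshold sits in the Monte-Carlo band of the max-|t| quantile", {
  # nu = 18 (10 vs 10), true FWHM 20 known, Q = 101, alpha = 0.05
  set.seed(30)
  nsim <- 4000
  maxima <- numeric(nsim)
  for (s in seq_len(nsim)) {
    A <- smooth_gaussian_field(10, fwhm = 20)
    B <- smooth_gaussian_field(10, fwhm = 20)
    maxima[s] <- max(abs(t_field_two_sample_for_test(A, B)))
  }
  srt <- sort(maxima)
  lo <- srt[qbinom(0.025, nsim, 0.95)]
  hi <- srt[qbinom(0.975, nsim, 0.95)]
  zstar <- rft_threshold("t", 18, resels = 100 / 20, alpha = 0.05)
  expect_gt(zstar, lo)
  expect_lt(zstar, hi)
})

test_that("tiny two-sample designs are enumerated exactly", {
  set.seed(31)
  A <- matrix(rnorm(3 * 21), 3); B <- matrix(rnorm(3 * 21), 3) + 0.5
  # 3 vs 3: 20 distinct label splits, exactly 1/alpha at 5%
  thr <- permutation_threshold(A, B, "t_twosample", alpha = 0.05,
                               n_perm = 1000)
  expect_true(attr(thr, "exact"))
  expect_equal(attr(thr, "n_perm"), 20L)
  # brute-force oracle: enumerate all splits with the textbook t field
  Z <- rbind(A, B)
  maxima <- apply(combn(6, 3), 2, function(idx)
    max(abs(oracle_t_two_sample(Z[idx, ], Z[-idx, ]))))
  expect_equal(as.numeric(thr),
               unname(quantile(maxima, 0.95, type = 7)), tolerance = 1e-12)
  # below 1/alpha the requested alpha is unresolvable: warn
  expect_warning(
    permutation_threshold(A, B, "t_twosample", alpha = 0.01, n_perm = 1000),
    "alpha cannot be resolved")
})

test_that("permutation thresholds are deterministic in the seed", {
  set.seed(32)
  A <- smooth_gaussian_field(10, fwhm = 15)
  B <- smooth_gaussian_field(10, fwhm = 15)
  t1 <- permutation_threshold(A, B, "t_twosample", n_perm = 300, seed = 9)
  t2 <- permutation_threshold(A, B, "t_twosample", n_perm = 300, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
})

test_that("permutation inference is calibrated on null fields", {
  set.seed(33)
  nrep <- 300
  rej <- 0L
  for (r in seq_len(nrep)) {
    A <- smooth_gaussian_field(8, fwhm = 20)
    B <- smooth_gaussian_field(8, fwhm = 20)
    res <- spm_t_two_sample(A, B, inference = "permutation", n_perm = 300,
                            seed = r)
    if (nrow(res$clusters) > 0L) rej <- rej + 1L
  }
  ci <- qbinom(c(0.005, 0.995), nrep, 0.05) / nrep
  expect_gte(rej / nrep, ci[1])
  expect_lte(rej / nrep, ci[2])
})

test_that("RFT and permutation thresholds agree on smooth fields", {
  set.seed(34)
  rft <- perm <- numeric(10)
  for (i in seq_len(10)) {
    A <- smooth_gaussian_field(10, fwhm = 20)
    B <- smooth_gaussian_field(10, fwhm = 20)
    rft[i] <- spm_t_two_sample(A, B)$z_star
    perm[i] <- permutation_threshold(A, B, "t_twosample", n_perm = 2000,
                                     seed = i)
  }
  expect_lt(abs(mean(rft) - mean(perm)) / mean(perm), 0.05)
})
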