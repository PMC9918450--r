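# statistic-field correctness against independent textbook oracles

test_that("the two-node worked example reproduces the pooled t value", {
  a <- matrix(c(1, 2, 2, 3, 3, 4), 3, 2, byrow = TRUE)
  b <- matrix(c(5, 6, 6, 7, 7, 8), 3, 2, byrow = TRUE)
  # (residuals of these affine rows are perfectly smooth, hence the
  # degenerate-smoothness warning; the statistic field is what is checked)
  res <- suppressWarnings(spm_t_two_sample(a, b))
  # diff -4, pooled s^2 = 1, se = sqrt(2/3): frozen from the closed form
  expect_equal(res$z, rep(-4.898979485566356, 2), tolerance = 1e-12)
  expect_equal(res$df, 4)
})

test_that("identical groups give a zero field and no clusters", {
  set.seed(20)
  a <- matrix(rnorm(404), 4)
  res <- spm_t_two_sample(a, a)
  expect_true(all(abs(res$z) < 1e-12))
  expect_equal(nrow(res$clusters), 0L)
})

test_that("t fields match per-node textbook computations", {
  set.seed(21)
  for (rep in 1:3) {
    na <- sample(2:12, 1); nb <- sample(2:12, 1)
    A <- matrix(rnorm(na * 101), na); B <- matrix(rnorm(nb * 101), nb)
    expect_equal(spm_t_two_sample(A, B)$z, oracle_t_two_sample(A, B),
                 tolerance = 1e-12)
  }
  A <- matrix(rnorm(8 * 101), 8); B <- matrix(rnorm(8 * 101), 8)
  expect_equal(spm_t_paired(A, B)$z, oracle_t_paired(A, B),
               tolerance = 1e-12)
})

test_that("Hotelling fields match a brute-force oracle with explicit inverses", {
  set.seed(22)
  for (p in 1:3) {
    A <- make_vector_array(10, p, fwhm = 10)
    B <- make_vector_array(10, p, fwhm = 10)
    expect_equal(spm_hotelling_two_sample(A, B)$z, oracle_T2_two_sample(A, B),
                 tolerance = 1e-10)
    expect_equal(spm_hotelling_paired(A, B)$z, oracle_T2_paired(A, B),
                 tolerance = 1e-10)
  }
})

test_that("Hotelling with one component equals the squared t field", {
  set.seed(23)
  A <- smooth_gaussian_field(9, fwhm = 15); B <- smooth_gaussian_field(11, fwhm = 15)
  t2s <- spm_hotelling_two_sample(array(A, c(9, 101, 1)),
                                  array(B, c(11, 101, 1)))
  expect_equal(t2s$z, spm_t_two_sample(A, B)$z^2, tolerance = 1e-10)
  Ap <- smooth_gaussian_field(8, fwhm = 15); Bp <- smooth_gaussian_field(8, fwhm = 15)
  t2p <- spm_hotelling_paired(array(Ap, c(8, 101, 1)),
                              array(Bp, c(8, 101, 1)))
  expect_equal(t2p$z, spm_t_paired(Ap, Bp)$z^2, tolerance = 1e-10)
})

test_that("degenerate zero-variance inputs warn and mask instead of crashing", {
  set.seed(24)
  a <- matrix(rnorm(606), 6)
  # paired test of a set against itself: all differences zero
  expect_warning(expect_warning(res <- spm_t_paired(a, a), "zero"),
                 "degenerate")
  expect_false(any(res$valid_mask))
  expect_true(is.na(res$z_star))
  # paired with a constant shift: still zero difference variance
  expect_warning(expect_warning(res2 <- spm_t_paired(a, a + 3), "zero"),
                 "degenerate")
  expect_false(any(res2$valid_mask))
  # one shared constant node in a two-sample test: only that node masked
  b <- matrix(rnorm(606), 6)
  a2 <- a; b2 <- b
  a2[, 40] <- 1; b2[, 40] <- 1
  expect_warning(res3 <- spm_t_two_sample(a2, b2), "zero pooled variance")
  expect_false(res3$valid_mask[40])
  expect_true(all(res3$valid_mask[-40]))
})

test_that("trial-count preconditions are enforced", {
  a <- matrix(rnorm(202), 2)
  expect_error(spm_t_two_sample(a[1, , drop = FALSE], a), "at least 2")
  expect_error(spm_t_paired(matrix(rnorm(303), 3), a), "equal trial counts")
  expect_error(
    spm_hotelling_two_sample(make_vector_array(2, 3),
                             make_vector_array(2, 3)),
    "n_a \\+ n_b - 2 > p")
})

test_that("statistic fields are invariant to common affine/linear maps", {
  set.seed(25)
  A <- smooth_gaussian_field(8, fwhm = 12); B <- smooth_gaussian_field(9, fwhm = 12)
  z0 <- spm_t_two_sample(A, B)$z
  expect_equal(spm_t_two_sample(5.3 * A - 2, 5.3 * B - 2)$z, z0,
               tolerance = 1e-10)
  Av <- make_vector_array(10, 3); Bv <- make_vector_array(10, 3)
  M <- matrix(c(2, 0.5, 0, -1, 1.5, 0.3, 0.2, 0, 1), 3, 3)  # invertible
  tr <- function(X) {
    Y <- X
    for (q in seq_len(dim(X)[2])) Y[, q, ] <- X[, q, ] %*% t(M)
    Y
  }
  expect_equal(spm_hotelling_two_sample(tr(Av), tr(Bv))$z,
               spm_hotelling_two_sample(Av, Bv)$z, tolerance = 1e-8)
})

test_that("smoothness estimation recovers known field roughness", {
  set.seed(26)
  # white noise: E[(du)^2] = 2 -> FWHM floor sqrt(2 log 2) ~ 1.177
  wn <- matrix(rnorm(500 * 101), 500)
  expect_equal(estimate_fwhm(wn - rep(colMeans(wn), each = 500)),
               sqrt(2 * log(2)), tolerance = 0.03)
  # parameter recovery at FWHM 20 within 10%
  f <- smooth_gaussian_field(50, fwhm = 20)
  est <- estimate_fwhm(f - rep(colMeans(f), each = 50))
  expect_gt(est, 18); expect_lt(est, 22)
  # monotone recovery
  f10 <- smooth_gaussian_field(50, fwhm = 10)
  f40 <- smooth_gaussian_field(50, fwhm = 40)
  expect_lt(estimate_fwhm(f10 - rep(colMeans(f10), each = 50)),
            estimate_fwhm(f40 - rep(colMeans(f40), each = 50)))
})

test_that("constant residuals degrade to the upper clip with a warning", {
  expect_warning(fw <- estimate_fwhm(matrix(1, 5, 101)), "degenerate")
  expect_equal(fw, 100)
})

test_that("cluster extraction returns maximal runs split at invalid nodes", {
  z <- rep(0, 101)
  expect_equal(nrow(extract_clusters(z, 2)), 0L)
  z[11:21] <- 3; z[51:56] <- 4
  cl <- extract_clusters(z, 2)
  expect_equal(cl, data.frame(start = c(10L, 50L), end = c(20L, 55L)))
  valid <- rep(TRUE, 101); valid[15] <- FALSE
  cl2 <- extract_clusters(z, 2, valid)
  expect_equal(cl2$start, c(10L, 15L, 50L))
  expect_equal(cl2$end, c(13L, 20L, 55L))
  # boundary equality is not exceedance
  expect_equal(nrow(extract_clusters(rep(2, 101), 2)), 0L)
})
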