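test_that("very smooth fields approach a constant", {
  set.seed(60)
  f <- smooth_gaussian_field(5, Q = 101, fwhm = 1010)
  # pointwise SD is 1; variation along the field collapses
  expect_lt(max(apply(f, 1, sd)), 0.15)
})

test_that("generated fields have the requested pointwise mean and SD", {
  set.seed(61)
  for (fwhm in c(5, 20)) {
    f <- smooth_gaussian_field(4000, fwhm = fwhm, sd = 0.7)
    expect_equal(mean(colMeans(f)), 0, tolerance = 0.01)
    expect_equal(unname(apply(f, 2, sd)), rep(0.7, 101), tolerance = 0.05)
  }
})

test_that("field smoothness closes the loop with the estimator", {
  set.seed(62)
  f <- smooth_gaussian_field(50, fwhm = 20)
  est <- estimate_fwhm(f - rep(colMeans(f), each = 50))
  expect_gt(est, 18); expect_lt(est, 22)
})

test_that("generation is byte-identical for identical seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sp <- synth_spec(measures = "moments", limbs = "right", joints = "knee",
                   n_pre = 5, n_post = 0, seed = 63)
  simulate_gait_dataset(sp, d1)
  simulate_gait_dataset(sp, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  expect_gt(length(f1), 0L)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("reference rows share the trial rows' pointwise SD", {
  # subject averages are emulated with inflated trial noise so delivered
  # rows are equal in distribution across conditions under the null
  set.seed(64)
  sp <- synth_spec(measures = "moments", limbs = "right", joints = "knee",
                   dimensions = "X", n_reference = 400, n_pre = 400,
                   seed = 64)
  ds <- simulate_gait_dataset(sp)
  ref <- get_component(ds, component_key("moments", "right", "knee", "X",
                                         "reference"))
  pre <- get_component(ds, component_key("moments", "right", "knee", "X",
                                         "pre"))
  sd_ref <- mean(apply(ref$values, 2, sd))
  sd_pre <- mean(apply(pre$values, 2, sd))
  expect_equal(sd_ref / sd_pre, 1, tolerance = 0.1)
  expect_equal(sd_pre, sp$noise_sd, tolerance = 0.05)
})

test_that("an injected bump is detected and localised by the pipeline", {
  bump <- list(target = component_key("moments", "right", "knee", "X",
                                      "pre"),
               center = 50, width = 5, amplitude = 10 * 0.5)
  hits <- 0L; centers <- numeric(0)
  for (s in 1:20) {
    ds <- simulate_gait_dataset(
      synth_spec(measures = "moments", limbs = "right", joints = "knee",
                 dimensions = "X", effects = list(bump), seed = 100 + s))
    rep <- suppressWarnings(
      run_analysis(ds, analysis_config("pre_vs_ref", measures = "moments")))
    cl <- rep[["moments_right_knee"]]$comparisons$pre_vs_ref$per_component$X$spm$clusters
    covered <- any(cl$start <= 50 & cl$end >= 50)
    if (covered) {
      hits <- hits + 1L
      centers <- c(centers, (cl$start + cl$end)[cl$start <= 50 &
                                                  cl$end >= 50][1] / 2)
    }
  }
  expect_gte(hits, 19L)
  expect_lte(abs(median(centers) - 50), bump$width)
})

test_that("power is monotone in effect amplitude", {
  set.seed(65)
  peak_t <- function(amp, s) {
    bump <- list(target = component_key("moments", "right", "knee", "X",
                                        "pre"),
                 center = 50, width = 5, amplitude = amp)
    ds <- simulate_gait_dataset(
      synth_spec(measures = "moments", limbs = "right", joints = "knee",
                 dimensions = "X", effects = list(bump), seed = s))
    pre <- get_component(ds, component_key("moments", "right", "knee", "X",
                                           "pre"))
    ref <- get_component(ds, component_key("moments", "right", "knee", "X",
                                           "reference"))
    max(abs(spm_t_two_sample(pre, ref)$z))
  }
  small <- vapply(1:8, function(s) peak_t(0.25, 200 + s), numeric(1))
  large <- vapply(1:8, function(s) peak_t(2.5, 200 + s), numeric(1))
  expect_gt(mean(large), mean(small))
})
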