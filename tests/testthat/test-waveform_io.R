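test_that("a well-formed file reads into a full trajectory set", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  rows <- lapply(1:3, function(i) sprintf("%.6f", rnorm(101)))
  write_raw_csv(path, rows)
  ts <- read_trajectory_csv(path)
  expect_s3_class(ts, "trajectory_set")
  expect_equal(ts$n_trials, 3L)
  expect_equal(ts$node_count, 101L)
  expect_false(any(ts$missing_mask))
})

test_that("empty and non-numeric cells become NaN and set the missing mask", {
  path <- withr::local_tempfile(fileext = ".csv")
  # recording stops at 60% of the cycle: cells 62..101 empty in every row
  rows <- lapply(1:4, function(i) {
    r <- sprintf("%.4f", rnorm(101))
    r[62:101] <- ""
    r
  })
  write_raw_csv(path, rows)
  ts <- read_trajectory_csv(path)
  expect_equal(ts$node_count, 101L)
  expect_true(all(is.nan(ts$values[, 62:101])))
  expect_identical(unname(which(ts$missing_mask)), 62:101)
  expect_false(any(ts$missing_mask[1:61]))
})

test_that("the missing mask marks exactly the non-numeric cells", {
  set.seed(42)
  for (rep in 1:5) {
    path <- withr::local_tempfile(fileext = ".csv")
    vals <- matrix(sprintf("%.4f", rnorm(5 * 40)), 5, 40)
    holes <- matrix(runif(200) < 0.15, 5, 40)
    vals[holes] <- sample(c("", "n/a", "?"), sum(holes), replace = TRUE)
    write_raw_csv(path, lapply(1:5, function(i) vals[i, ]))
    ts <- read_trajectory_csv(path)
    expect_identical(is.nan(ts$values), unname(holes))
    expect_identical(ts$missing_mask, unname(apply(holes, 2, any)))
  }
})

test_that("row length is accepted as-is at read time", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(path, lapply(1:2, function(i) sprintf("%.4f", rnorm(97))))
  expect_equal(read_trajectory_csv(path)$node_count, 97L)
})

test_that("ragged rows raise a format error naming the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(path, list(rep("1.0", 10), rep("2.0", 9), rep("3.0", 10)))
  expect_error(read_trajectory_csv(path), "ragged rows.*line 2")
})

test_that("trajectory write/read is an identity on finite values", {
  set.seed(3)
  ts <- trajectory_set(matrix(rnorm(4 * 101) * 10^sample(-3:3, 404, TRUE), 4),
                       meta = component_key("moments", "right", "knee", "X",
                                            "pre"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(ts, path)
  back <- read_trajectory_csv(path)
  expect_identical(back$values, ts$values)
  # and byte-identical on a second write (idempotent formatting)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("dataset loading mirrors exactly the files present", {
  root <- withr::local_tempdir()
  keys <- list(
    component_key("moments", "right", "knee", "X", "pre"),
    component_key("moments", "right", "hip", "X", "pre"),
    component_key("moments", "right", "ankle", "X", "pre"))
  set.seed(4)
  for (k in keys)
    write_trajectory_csv(trajectory_set(matrix(rnorm(303), 3), k),
                         file.path(root, default_naming()$filename(k)))
  ds <- load_gait_dataset(root)
  expect_length(ds$components, 3L)
  expect_identical(ds$conditions_present, "pre")
  # ankle Y/Z absent: queryable, not an error
  expect_false(has_component(
    ds, component_key("moments", "right", "ankle", "Y", "pre")))
  expect_null(get_component(
    ds, component_key("moments", "right", "ankle", "Z", "pre")))
  expect_identical(joint_dimensions(ds, "pre", "moments", "right", "ankle"),
                   "X")
})

test_that("all three condition subtrees are discovered", {
  root <- withr::local_tempdir()
  set.seed(5)
  for (cond in c("reference", "pre", "post")) {
    k <- component_key("kinematics", "left", "hip", "Y", cond)
    write_trajectory_csv(trajectory_set(matrix(rnorm(202), 2), k),
                         file.path(root, default_naming()$filename(k)))
  }
  ds <- load_gait_dataset(root)
  expect_identical(ds$conditions_present, c("reference", "pre", "post"))
})

test_that("an empty directory warns and yields an empty dataset", {
  root <- withr::local_tempdir()
  expect_warning(ds <- load_gait_dataset(root), "empty")
  expect_length(ds$components, 0L)
})

test_that("severity maps round-trip through CSV bit-identically", {
  set.seed(6)
  z <- c(runif(90, 0, 10), rep(NaN, 11))
  res <- fake_spm(z, z_star = 2, valid = is.finite(z))
  map <- severity_from_spm(res, severity_scale())
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_severity_csv(map, p1)
  back <- read_severity_csv(p1)
  expect_identical(back$values, map$values)
  expect_identical(back$masked, map$masked)
  write_severity_csv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an all-zero severity map serialises as a row of zeros", {
  map <- severity_from_spm(fake_spm(rep(0, 101), z_star = 2),
                           severity_scale())
  path <- withr::local_tempfile(fileext = ".csv")
  write_severity_csv(map, path)
  row <- strsplit(readLines(path)[2], ",")[[1]]
  expect_identical(row, rep("0", 101))
})
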