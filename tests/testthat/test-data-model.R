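test_that("standardization statistics match their definition", {
  # two features x two samples, one of them constant
  s <- standardize_fit(matrix(c(1, 2, 3, 2), 2, 2))
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(1, 0))
  expect_equal(s$zero_var, c(FALSE, TRUE))

  expect_equal(standardize_apply(matrix(4), structure(
    list(mean = 2, sd = 1, zero_var = FALSE), class = "mv_standardization")),
    matrix(2))
  # constant feature at its own mean maps to 0
  expect_equal(standardize_apply(matrix(7), s2 <- structure(
    list(mean = 7, sd = 0, zero_var = TRUE), class = "mv_standardization")),
    matrix(0))

  set.seed(42)
  x <- matrix(rnorm(5 * 100), 5, 100)
  st <- standardize_fit(x)
  expect_true(all(abs(st$mean) < 3 / sqrt(100)))
  z <- standardize_apply(x, st)
  expect_equal(rowMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 5), tolerance = 1e-12)
  # idempotence: re-fitting on standardized data changes nothing
  z2 <- standardize_apply(z, standardize_fit(z))
  expect_equal(z2, z, tolerance = 1e-10)
  # affine inverse
  expect_equal(standardize_invert(z, st), x, tolerance = 1e-12)

  expect_error(standardize_fit(matrix(numeric(0), 0, 0)), class = "mvg_invalid_input")
  expect_error(standardize_apply(matrix(1, 3, 1), st), class = "mvg_invalid_input")
})

test_that("dataset constructors validate shapes, labels and finiteness", {
  d <- tiny_dataset(m = 4)
  expect_s3_class(d, "mv_dataset")
  expect_error(multiview_dataset(matrix(0, 2, 3), matrix(0, 2, 2), matrix(0, 2, 3),
                                 rep("a", 3)), class = "mvg_shape_error")
  expect_error(multiview_dataset(matrix(NA_real_, 2, 2), matrix(0, 2, 2),
                                 matrix(0, 2, 2), rep("a", 2)),
               class = "mvg_invalid_input")
  # zero-shot split refuses shared categories
  expect_error(multiview_dataset(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
                                 c("cat", "dog"), matrix(0, 2, 1), matrix(0, 2, 1),
                                 "dog"), class = "mvg_invalid_input")
  expect_error(candidate_set(c("a", "a"), matrix(0, 2, 2), matrix(0, 2, 2)),
               class = "mvg_invalid_input")
  expect_error(test_set(matrix(0, 2, 1), "zebra",
                        candidate_set(c("a", "b"), matrix(0, 2, 2), matrix(0, 2, 2))),
               class = "mvg_invalid_input")
})

test_that("manifest write/load roundtrips all dataset objects exactly", {
  dir <- withr::local_tempdir()
  d <- tiny_dataset(m = 4, seed = 7)
  d2 <- load_dataset(write_dataset(d, dir))
  expect_identical(d2$brain, d$brain)
  expect_identical(d2$add_semantic, d$add_semantic)
  expect_identical(d2$paired_labels, d$paired_labels)
  expect_identical(d2$zero_shot, d$zero_shot)

  cand <- candidate_set(c("ostrich", "kangaroo", "mailbox"),
                        matrix(rnorm(9), 3), matrix(rnorm(6), 2))
  c2 <- load_dataset(write_dataset(cand, dir))
  expect_identical(c2$names, cand$names)    # file order preserved
  expect_identical(c2$visual, cand$visual)

  ts <- test_set(matrix(rnorm(8), 4), c("a", "b"))
  t2 <- load_dataset(write_dataset(ts, dir))
  expect_identical(t2$brain, ts$brain)

  expect_error(load_dataset(file.path(dir, "nope.json")), class = "mvg_load_error")
})

test_that("corrupt manifests raise distinct load errors", {
  dir <- withr::local_tempdir()
  d <- tiny_dataset(m = 2, seed = 3)
  manifest <- write_dataset(d, dir)
  # shape mismatch: drop a column of the visual block on disk
  vis <- d$visual[, -1]
  utils::write.csv(as.data.frame(t(vis)), file.path(dir, "dataset_visual.csv"),
                   row.names = FALSE)
  expect_error(load_dataset(manifest), class = "mvg_shape_error")
  # non-finite entries
  bad <- as.data.frame(t(d$visual)); bad[1, 1] <- NaN
  utils::write.csv(bad, file.path(dir, "dataset_visual.csv"), row.names = FALSE)
  expect_error(load_dataset(manifest), class = "mvg_load_error")
  # duplicate candidate names
  cand <- candidate_set(c("a", "b"), matrix(0, 2, 2), matrix(0, 2, 2))
  cpath <- write_dataset(cand, dir)
  spec <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  spec$labels$names <- c("a", "a")
  jsonlite::write_json(spec, cpath, auto_unbox = TRUE)
  expect_error(load_dataset(cpath), class = "mvg_load_error")
})

test_that("standardize_bundle fits on the paired block only", {
  bench <- sample_dataset(sample_ground_truth(seed = 5), seed = 6)
  std <- standardize_bundle(bench$dataset, bench$test, bench$candidates)
  # paired blocks are exactly z-scored
  expect_equal(rowMeans(std$dataset$brain), rep(0, nrow(std$dataset$brain)),
               tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(std$dataset$visual^2)),
               rep(1, nrow(std$dataset$visual)), tolerance = 1e-12)
  # additional block uses the paired statistics, so it is not centred at 0
  expect_gt(max(abs(rowMeans(std$dataset$add_visual))), 0.05)
  # candidates transformed with the same statistics
  expect_equal(std$candidates$visual,
               standardize_apply(bench$candidates$visual, std$stats$visual))
})

test_that("write_results refuses non-finite output and echoes config", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "metrics.json")
  write_results(list(accuracy = 0.5), p, config = list(run = "x"), seed = 7L)
  parsed <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(parsed$metrics$accuracy, 0.5)
  expect_equal(parsed$seed, 7L)
  expect_equal(parsed$config$run, "x")

  m <- matrix(rnorm(6) * 1e-7, 2, 3)
  f <- file.path(dir, "pred.csv")
  write_results(m, f)
  expect_equal(unname(t(as.matrix(utils::read.csv(f)))), m, tolerance = 1e-12)
  m[1] <- NaN
  expect_error(write_results(m, f), class = "mvg_invalid_input")
})
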