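test_that("gesture CSV round trip is lossless with a verbatim header", {
  ds <- small_synth()[1:100, ]
  ds <- gesture_dataset(as.data.frame(ds, check.names = FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gesture_csv(ds, path)

  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header, gesture_columns())

  back <- read_gesture_csv(path)
  expect_identical(back$letter, ds$letter)
  for (cn in gesture_columns()[-1]) {
    expect_equal(back[[cn]], ds[[cn]], tolerance = 1e-10)
  }
})

test_that("malformed CSV inputs raise format errors naming the defect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(gesture_columns()[1:57], collapse = ","), path)
  expect_error(read_gesture_csv(path), "59-column",
               class = "fs_format_error")

  writeLines(character(0), path)
  expect_error(read_gesture_csv(path), class = "fs_format_error")

  writeLines(c(paste(gesture_columns(), collapse = ","),
               paste(c("A", "oops", rep("0", 57)), collapse = ",")), path)
  expect_error(read_gesture_csv(path), "row 1.*unit-0",
               class = "fs_format_error")

  expect_error(read_gesture_csv(file.path(tempdir(), "missing.csv")),
               class = "fs_format_error")
})

test_that("drop_empty removes only no-hand records", {
  set.seed(61)
  units <- matrix(runif(10 * 56, 0.1, 2), 10, 56)
  units[, 29:56][3, ] <- 0              # single-hand record: keep
  ds <- make_ds(units, labels = rep("B", 10))
  blank <- make_ds(matrix(0, 3, 56), labels = rep("B", 3))
  both <- gesture_dataset(rbind(as.data.frame(ds, check.names = FALSE),
                                as.data.frame(blank, check.names = FALSE)))

  cleaned <- drop_empty(both)
  expect_equal(nrow(cleaned), 10)
  expect_equal(sum(rowSums(as.matrix(
    as.data.frame(cleaned, check.names = FALSE)[paste0("unit-", 28:55)])) == 0), 1)
  expect_equal(nrow(drop_empty(cleaned)), 10)   # idempotent / no-op case
})

test_that("drop_duplicates keeps first occurrences of exact matches", {
  set.seed(62)
  units <- matrix(runif(4 * 56), 4, 56)
  df <- as.data.frame(make_ds(units, labels = c("A", "B", "C", "D")),
                      check.names = FALSE)
  repeated <- gesture_dataset(df[c(1, 1, 1, 1, 1, 2, 3, 4), ])
  out <- drop_duplicates(repeated)
  expect_equal(nrow(out), 4)
  expect_identical(out$letter, c("A", "B", "C", "D"))

  near <- df
  near[2, "unit-10"] <- near[1, "unit-10"] + 1e-10   # 10th-decimal difference
  near$letter[2] <- "A"
  expect_equal(nrow(drop_duplicates(gesture_dataset(near))), 4)
  expect_equal(nrow(drop_duplicates(out)), 4)        # idempotent
})

test_that("the standardised-score filter drops any-column violations", {
  units <- matrix(0.5, 51, 56)
  units[, 6] <- c(rep(0, 50), 1000)
  ds <- make_ds(units, labels = rep("A", 51))
  out <- zscore_filter(ds)
  expect_equal(nrow(out), 50)                  # |Z| of the 1000 is ~7.07 > 3

  constant <- make_ds(matrix(0.7, 20, 56), labels = rep("A", 20))
  expect_equal(nrow(zscore_filter(constant)), 20)   # sigma = 0 columns skip

  # single-hand records: structural zero blocks must not read as outliers
  set.seed(63)
  mixed <- matrix(runif(40 * 56, 0.9, 1.1), 40, 56)
  mixed[1:5, 29:56] <- 0
  kept <- zscore_filter(make_ds(mixed, labels = rep("C", 40)))
  expect_equal(nrow(kept), 40)
})

test_that("normal-tail removal fraction matches the cutoff's tail mass", {
  set.seed(64)
  units <- matrix(0.5, 10000, 56)
  units[, 10] <- rnorm(10000)
  out <- zscore_filter(make_ds(units, labels = rep("A", 10000)))
  frac <- 1 - nrow(out) / 10000
  expect_equal(frac, 2 * (1 - pnorm(3)), tolerance = 0.0015 / (2 * (1 - pnorm(3))))
})

test_that("min-max normalisation maps fitted columns onto [0, 1] without clipping", {
  units <- matrix(0.5, 3, 56)
  units[, 1] <- c(2, 4, 6)
  units[, 2] <- 7          # constant column
  ds <- make_ds(units, labels = c("A", "B", "A"))
  params <- minmax_fit(ds, "self")
  out <- minmax_apply(ds, params)
  expect_equal(out[["unit-0"]], c(0, 0.5, 1))
  expect_equal(out[["unit-1"]], c(0, 0, 0))
  u <- as.matrix(as.data.frame(out, check.names = FALSE)[paste0("unit-", 0:55)])
  expect_true(all(u >= 0 & u <= 1))
  expect_identical(out$letter, ds$letter)

  # params fitted on [0, 10] applied to 12 extrapolate linearly
  fit_units <- matrix(0.5, 2, 56); fit_units[, 1] <- c(0, 10)
  p <- minmax_fit(make_ds(fit_units, labels = c("A", "B")))
  apply_units <- matrix(0.5, 1, 56); apply_units[, 1] <- 12
  shifted <- minmax_apply(make_ds(apply_units, labels = "A"), p)
  expect_equal(shifted[["unit-0"]], 1.2)

  bad <- p; bad$min <- bad$min[1:10]
  expect_error(minmax_apply(ds, bad), class = "fs_schema_error")
})

test_that("hand-swap augmentation doubles the data and is an involution", {
  set.seed(65)
  units <- matrix(runif(5 * 56), 5, 56)
  units[5, 29:56] <- 0                       # single-hand record
  ds <- make_ds(units, labels = c("A", "B", "C", "D", "C"),
                tip1 = c(1L, 0L, 3L, 0L, 0L), tip2 = 0L)
  out <- swap_hands(ds)
  expect_equal(nrow(out), 10)
  expect_identical(out$letter, rep(ds$letter, 2))
  copy <- out[6:10, ]
  expect_equal(unname(as.matrix(copy[paste0("unit-", 0:27)])),
               units[, 29:56])
  expect_equal(copy[["tip-2"]], c(1, 0, 3, 0, 0))
  expect_equal(unname(as.matrix(copy[paste0("unit-", 0:27)]))[5, ],
               rep(0, 28))                   # blocks transpose

  # swapping the swapped copies recovers the originals exactly
  back <- swap_hands(gesture_dataset(as.data.frame(out[6:10, ],
                                                   check.names = FALSE)))
  restored <- gesture_dataset(as.data.frame(back[6:10, ], check.names = FALSE))
  expect_identical(restored$letter, ds$letter)
  expect_equal(unname(as.matrix(as.data.frame(restored,
                                check.names = FALSE)[-1])),
               unname(as.matrix(as.data.frame(ds, check.names = FALSE)[-1])))
})

test_that("the stratified split holds out the target fraction per class", {
  set.seed(66)
  units <- matrix(runif(1000 * 56), 1000, 56)
  ds <- make_ds(units, labels = rep(LETTERS[1:10], each = 100))
  parts <- split_gestures(ds, split_config(seed = 9))
  expect_equal(nrow(parts$test), 200)
  expect_equal(nrow(parts$train) + nrow(parts$test), 1000)
  expect_true(all(table(parts$test$letter) == 20))

  again <- split_gestures(ds, split_config(seed = 9))
  expect_identical(as.data.frame(again$test, check.names = FALSE),
                   as.data.frame(parts$test, check.names = FALSE))

  balanced <- make_ds(matrix(runif(36 * 50 * 56), 36 * 50, 56),
                      labels = rep(gesture_classes(), each = 50))
  bp <- split_gestures(balanced, split_config(seed = 1))
  expect_true(all(table(bp$test$letter) == 10))

  singleton <- make_ds(matrix(runif(3 * 56), 3, 56),
                       labels = c("A", "A", "Q"))
  expect_error(split_gestures(singleton), "Q", class = "fs_split_error")
})
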