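#' The 59-column gesture dataset
#'
#' A gesture dataset is a data frame with a fixed header: `letter`, the 56
#' unit columns `unit-0` .. `unit-55`, and two touch-code columns `tip-1`,
#' `tip-2`. All transforms (cleaning, normalisation, augmentation,
#' splitting) operate on this container and append to its provenance log.
#' The intended order of operations is: drop empties, drop duplicates,
#' standardised-score outlier filter, optional hand-swap augmentation,
#' stratified split, then min-max fit on the training split applied to both
#' splits.
#'
#' @name dataset
NULL

#' Column names of the gesture CSV
#' @return Character vector of the 59 column names in fixed order.
#' @export
gesture_columns <- function() {
  c("letter", paste0("unit-", 0:55), "tip-1", "tip-2")
}

unit_columns <- function() paste0("unit-", 0:55)

#' Valid gesture class labels
#' @return The 36 labels: letters `A`-`Z` then numbers `1`-`10`.
#' @export
gesture_classes <- function() c(LETTERS, as.character(1:10))

#' Construct a gesture dataset
#'
#' @param df A data frame with the 59 columns of [gesture_columns()] (label
#'   column character, the rest numeric), or a list of `gesture_record`
#'   objects from [assemble_record()].
#' @param provenance Character vector of transform log lines.
#' @return An object of class `gesture_dataset` (a data frame).
#' @export
gesture_dataset <- function(df, provenance = character()) {
  if (is.list(df) && !is.data.frame(df) &&
      all(vapply(df, inherits, logical(1), "gesture_record"))) {
    mat <- t(vapply(df, function(r) c(r$units, r$tips), numeric(58)))
    out <- data.frame(letter = vapply(df, function(r) r$label, character(1)),
                      mat, check.names = FALSE, stringsAsFactors = FALSE)
    names(out) <- gesture_columns()
    df <- out
  }
  df <- as.data.frame(df, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df), gesture_columns())) {
    fs_abort(sprintf(
      "gesture dataset requires the fixed 59-column header; got %d column(s)",
      ncol(df)), "fs_format_error")
  }
  df$letter <- as.character(df$letter)
  for (cn in names(df)[-1]) {
    if (!is.numeric(df[[cn]])) {
      fs_abort(sprintf("column '%s' must be numeric", cn), "fs_format_error")
    }
  }
  rownames(df) <- NULL
  structure(df, provenance = as.character(provenance),
            class = c("gesture_dataset", "data.frame"))
}

#' Provenance log of a dataset
#' @param ds A `gesture_dataset`.
#' @return Character vector of applied-transform descriptions.
#' @export
provenance <- function(ds) attr(ds, "provenance")

log_step <- function(ds, line) {
  attr(ds, "provenance") <- c(attr(ds, "provenance"), line)
  ds
}

# rebuild class/attrs after a row subset (data.frame methods strip them)
rewrap <- function(df, template) {
  rownames(df) <- NULL
  structure(df, provenance = attr(template, "provenance"),
            class = c("gesture_dataset", "data.frame"))
}

unit_matrix <- function(ds) {
  as.matrix(as.data.frame(ds, check.names = FALSE)[unit_columns()])
}

#' @export
print.gesture_dataset <- function(x, ...) {
  cat(sprintf("<gesture_dataset: %d records, %d classes>\n",
              nrow(x), length(unique(x$letter))))
  if (length(provenance(x))) {
    cat("provenance:\n")
    cat(paste0("  - ", provenance(x)), sep = "\n")
  }
  invisible(x)
}

#' Write / read the gesture CSV
#'
#' Comma-separated, UTF-8, `.` decimal, header row exactly
#' `letter,unit-0,...,unit-55,tip-1,tip-2`. Numeric fields are written with
#' 15 significant digits so a round trip preserves them well past 10
#' significant digits.
#'
#' @param ds A `gesture_dataset`.
#' @param path File path.
#' @return `write_gesture_csv` returns `path` invisibly; `read_gesture_csv`
#'   returns a `gesture_dataset`.
#' @export
write_gesture_csv <- function(ds, path) {
  stopifnot(inherits(ds, "gesture_dataset"))
  df <- as.data.frame(ds, check.names = FALSE)
  for (cn in names(df)[-1]) {
    df[[cn]] <- formatC(df[[cn]], digits = 15, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gesture_csv
#' @export
read_gesture_csv <- function(path) {
  if (!file.exists(path)) {
    fs_abort(sprintf("no such file: %s", path), "fs_format_error")
  }
  header <- tryCatch(
    utils::read.csv(path, nrows = 1, header = FALSE, check.names = FALSE,
                    stringsAsFactors = FALSE),
    error = function(e) fs_abort(sprintf("cannot parse '%s': no header", path),
                                 "fs_format_error"))
  if (ncol(header) != 59L ||
      !identical(as.character(unlist(header[1, ])), gesture_columns())) {
    fs_abort(sprintf(
      "'%s': header must be the fixed 59-column gesture layout (found %d columns)",
      path, ncol(header)), "fs_format_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (cn in names(df)[-1]) {
    vals <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(vals) | !nzchar(df[[cn]]))
    if (length(bad)) {
      fs_abort(sprintf("'%s': non-numeric value at data row %d, column '%s'",
                       path, bad[1], cn), "fs_format_error")
    }
    df[[cn]] <- vals
  }
  gesture_dataset(df, provenance = sprintf("read from %s", path))
}

#' Remove records with no hand at all
#'
#' Records whose 56 unit fields are all zero carry no gesture (the capture
#' saw no hand) and are dropped. Single-hand records (one 28-unit block
#' zero, the other not) are legitimate and kept.
#'
#' @param ds A `gesture_dataset`.
#' @return The filtered dataset, with the removal count logged.
#' @export
drop_empty <- function(ds) {
  empty <- rowSums(abs(unit_matrix(ds))) == 0
  out <- rewrap(ds[!empty, , drop = FALSE], ds)
  log_step(out, sprintf("drop_empty: removed %d record(s)", sum(empty)))
}

#' Remove exact duplicate records
#'
#' A duplicate matches another record on the label and all 58 numeric
#' fields exactly; the first occurrence is kept and order is stable.
#'
#' @inheritParams drop_empty
#' @export
drop_duplicates <- function(ds) {
  dup <- duplicated(as.data.frame(ds, check.names = FALSE))
  out <- rewrap(ds[!dup, , drop = FALSE], ds)
  log_step(out, sprintf("drop_duplicates: removed %d record(s)", sum(dup)))
}

#' Outlier filter configuration
#'
#' @param z_cutoff Standardised-score magnitude above which a value flags
#'   its record as an outlier. Default 3.
#' @return A list with element `z_cutoff`.
#' @export
outlier_config <- function(z_cutoff = 3) {
  if (!is.finite(z_cutoff) || z_cutoff <= 0) {
    fs_abort("z_cutoff must be positive", "fs_schema_error")
  }
  list(z_cutoff = as.numeric(z_cutoff))
}

#' Standardised-score outlier filter
#'
#' Per unit column, values are standardised against the column mean and
#' population standard deviation; a record is removed when any of its
#' columns exceeds the cutoff in magnitude. Zero-variance columns are
#' skipped. Structural zeros from an absent hand (a record whose whole
#' 28-unit block is zero) are excluded from both the column statistics and
#' the violation test, so legitimate single-hand records survive.
#'
#' @param ds A `gesture_dataset` with at least 2 records.
#' @param cfg [outlier_config()].
#' @return The filtered dataset, with removal counts logged.
#' @export
zscore_filter <- function(ds, cfg = outlier_config()) {
  if (nrow(ds) < 2L) {
    fs_abort("outlier filtering needs at least 2 records", "fs_format_error")
  }
  u <- unit_matrix(ds)
  h1_absent <- rowSums(abs(u[, 1:28, drop = FALSE])) == 0
  h2_absent <- rowSums(abs(u[, 29:56, drop = FALSE])) == 0
  present <- cbind(matrix(!h1_absent, nrow(u), 28),
                   matrix(!h2_absent, nrow(u), 28))
  bad <- logical(nrow(u))
  for (j in seq_len(56)) {
    sel <- present[, j]
    vals <- u[sel, j]
    if (length(vals) < 2L) next
    mu <- mean(vals)
    sigma <- sqrt(mean((vals - mu)^2))
    if (sigma < 1e-12) next
    z <- (u[, j] - mu) / sigma
    bad <- bad | (sel & abs(z) > cfg$z_cutoff)
  }
  out <- rewrap(ds[!bad, , drop = FALSE], ds)
  log_step(out, sprintf("zscore_filter(cutoff=%g): removed %d record(s)",
                        cfg$z_cutoff, sum(bad)))
}

#' Fit / apply min-max normalisation
#'
#' `minmax_fit` records each unit column's min and max; `minmax_apply`
#' rescales by `(x - min) / (max - min)`. On the fitted data every unit
#' column maps into [0, 1]; params fitted on a training split may send
#' unseen values outside [0, 1] and they are deliberately not clipped.
#' Zero-range columns map to 0. Tip-code columns are categorical and are
#' never rescaled.
#'
#' @param ds A `gesture_dataset`.
#' @param fitted_on Provenance tag for the fit.
#' @return `minmax_fit`: a `minmax_params` list with `min`, `max`,
#'   `fitted_on`. `minmax_apply`: the rescaled dataset.
#' @export
minmax_fit <- function(ds, fitted_on = "unnamed") {
  if (nrow(ds) < 1L) fs_abort("cannot fit on an empty dataset",
                              "fs_format_error")
  u <- unit_matrix(ds)
  structure(list(min = apply(u, 2, min), max = apply(u, 2, max),
                 fitted_on = fitted_on),
            class = "minmax_params")
}

#' @rdname minmax_fit
#' @param params A `minmax_params` object from `minmax_fit`.
#' @export
minmax_apply <- function(ds, params) {
  stopifnot(inherits(params, "minmax_params"))
  if (!all(unit_columns() %in% names(ds)) || length(params$min) != 56L) {
    fs_abort("normalisation params do not match the dataset columns",
             "fs_schema_error")
  }
  u <- unit_matrix(ds)
  rng <- params$max - params$min
  scaled <- sweep(u, 2, params$min, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng <= 0] <- 0
  out <- as.data.frame(ds, check.names = FALSE)
  out[unit_columns()] <- scaled
  out <- rewrap(out, ds)
  log_step(out, sprintf("minmax_apply: params fitted on '%s'",
                        params$fitted_on))
}

#' Hand-swap augmentation
#'
#' Appends, for every record, a copy with the hand-1 and hand-2 feature
#' blocks exchanged (`unit-i` with `unit-(i+28)`, `tip-1` with `tip-2`),
#' covering left- and right-dominant signers. Labels are unchanged and the
#' dataset doubles in size. Swapping the swapped copies recovers the
#' originals exactly.
#'
#' @inheritParams drop_empty
#' @export
swap_hands <- function(ds) {
  df <- as.data.frame(ds, check.names = FALSE)
  swapped <- df
  swapped[paste0("unit-", 0:27)] <- df[paste0("unit-", 28:55)]
  swapped[paste0("unit-", 28:55)] <- df[paste0("unit-", 0:27)]
  swapped[["tip-1"]] <- df[["tip-2"]]
  swapped[["tip-2"]] <- df[["tip-1"]]
  out <- rewrap(rbind(df, swapped), ds)
  log_step(out, sprintf("swap_hands: %d -> %d records", nrow(df),
                        2L * nrow(df)))
}

#' Split configuration
#'
#' @param test_fraction Held-out proportion, strictly between 0 and 1
#'   (default 0.20).
#' @param stratified Stratify by class label (default TRUE).
#' @param seed RNG seed making the split reproducible.
#' @return A list of the three settings.
#' @export
split_config <- function(test_fraction = 0.20, stratified = TRUE, seed = 42L) {
  if (!is.finite(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    fs_abort("test_fraction must lie strictly between 0 and 1",
             "fs_schema_error")
  }
  list(test_fraction = test_fraction, stratified = isTRUE(stratified),
       seed = as.integer(seed))
}

#' Stratified train/test split
#'
#' Holds out `test_fraction` of the records (per class when stratified,
#' each class within one record of the target proportion), disjoint and
#' exhaustive, reproducible under the same seed.
#'
#' @param ds A `gesture_dataset`.
#' @param cfg [split_config()].
#' @return A list with elements `train` and `test`, both `gesture_dataset`s.
#' @export
split_gestures <- function(ds, cfg = split_config()) {
  n <- nrow(ds)
  test_idx <- with_local_seed(cfg$seed, {
    if (cfg$stratified) {
      counts <- table(ds$letter)
      if (any(counts < 2L)) {
        fs_abort(sprintf(
          "stratified split impossible: class '%s' has a single record",
          names(counts)[counts < 2L][1]), "fs_split_error")
      }
      unlist(lapply(split(seq_len(n), ds$letter), function(idx) {
        k <- round(cfg$test_fraction * length(idx))
        if (k == 0L || k == length(idx)) k <- max(1L, min(length(idx) - 1L, k))
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      sample(n, round(cfg$test_fraction * n))
    }
  })
  is_test <- seq_len(n) %in% test_idx
  tag <- sprintf("split(test_fraction=%g, stratified=%s, seed=%d)",
                 cfg$test_fraction, cfg$stratified, cfg$seed)
  list(
    train = log_step(rewrap(ds[!is_test, , drop = FALSE], ds),
                     paste0(tag, ": train part")),
    test = log_step(rewrap(ds[is_test, , drop = FALSE], ds),
                    paste0(tag, ": test part"))
  )
}
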