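#' Landmark stream input/output
#'
#' The on-disk stand-in for live capture: one JSON object per line with
#' fields `label` (optional), `image_width`, `image_height`, and `hands`, a
#' list of at most two objects each holding `handedness` and `points` (21
#' `[x, y]` pairs in topology order).
#'
#' @name landmark_stream
NULL

#' Read a landmark stream file
#'
#' @param path Path to a line-delimited JSON landmark file.
#' @return A list of [frame_observation()] objects. Lines that fail frame
#'   validation are returned as `fs_error` condition objects in place, so a
#'   caller can keep good frames and report bad ones per line.
#' @export
read_landmark_stream <- function(path) {
  if (!file.exists(path)) {
    fs_abort(sprintf("no such file: %s", path), "fs_format_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    tryCatch({
      rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
      dims <- image_dims(rec$image_width, rec$image_height)
      hands <- rec$hands
      if (is.data.frame(hands)) {
        hands <- lapply(seq_len(nrow(hands)), function(k) hands[k, ])
      }
      hands <- lapply(hands, function(h) {
        pts <- h$points
        if (is.list(pts)) pts <- do.call(rbind, pts)
        hand_landmarks(matrix(as.numeric(pts), ncol = 2),
                       handedness = as.character(h$handedness))
      })
      frame_observation(hands, dims, label = rec$label)
    }, error = function(e) {
      structure(class = c("fs_frame_error", "fs_error", "condition"),
                list(message = sprintf("line %d: %s", i, conditionMessage(e)),
                     call = NULL))
    })
  })
}

#' Write frames as a landmark stream
#'
#' @param frames A list of [frame_observation()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_stream <- function(frames, path) {
  lines <- vapply(frames, function(fr) {
    jsonlite::toJSON(list(
      label = if (is.null(fr$label)) NULL else jsonlite::unbox(fr$label),
      image_width = jsonlite::unbox(as.integer(fr$dims[["width"]])),
      image_height = jsonlite::unbox(as.integer(fr$dims[["height"]])),
      hands = lapply(fr$hands, function(h) list(
        handedness = jsonlite::unbox(h$handedness),
        points = unname(h$points)
      ))
    ), digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Featurise a landmark stream into a gesture dataset
#'
#' @param path Landmark stream file.
#' @param cfg [touch_config()].
#' @param on_error `"drop"` silently skips invalid frames; `"stop"` aborts
#'   on the first one.
#' @return A `gesture_dataset`; skipped frame counts are logged in its
#'   provenance.
#' @export
ingest_landmarks <- function(path, cfg = touch_config(),
                             on_error = c("drop", "stop")) {
  on_error <- match.arg(on_error)
  frames <- read_landmark_stream(path)
  records <- list()
  skipped <- 0L
  for (fr in frames) {
    res <- if (inherits(fr, "condition")) fr else
      tryCatch(assemble_record(fr, cfg = cfg), fs_error = function(e) e)
    if (inherits(res, "condition")) {
      if (on_error == "stop") stop(res)
      skipped <- skipped + 1L
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  if (length(records) == 0L) {
    fs_abort("no valid frames in stream", "fs_format_error")
  }
  gesture_dataset(records,
                  provenance = sprintf("ingested %d frame(s) from %s (%d skipped)",
                                       length(records), path, skipped))
}
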