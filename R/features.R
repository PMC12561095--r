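#' Relative-distance features and fingertip touch codes
#'
#' Each hand contributes 28 pairwise distances between named anatomical
#' points, each divided by the hand's standard length (wrist to thumb
#' base), making the block invariant to translation, rotation and uniform
#' scale. Hand 1 fills unit-0..unit-27, hand 2 fills unit-28..unit-55.
#' Two integer tip codes record which fingertip of each hand is touched by
#' the opposite hand's index tip; this is the only cue separating the five
#' vowels, whose handshapes are identical.
#'
#' @name features
NULL

# The 28 named pairs, in fixed column order. Row i defines unit-(i-1) for
# hand 1 and unit-(i+27) for hand 2.
.schema_pairs <- matrix(c(
  "WRIST",       "THUMB_BASE",
  "THUMB_BASE",  "THUMB_MIDDLE",
  "THUMB_MIDDLE","THUMB_TIP",
  "THUMB_TIP",   "INDEX_TIP",
  "INDEX_TIP",   "MIDDLE_TIP",
  "MIDDLE_TIP",  "RING_TIP",
  "RING_TIP",    "LITTLE_TIP",
  "LITTLE_TIP",  "PALM_BASE",
  "THUMB_BASE",  "INDEX_BASE",
  "INDEX_BASE",  "MIDDLE_BASE",
  "MIDDLE_BASE", "RING_BASE",
  "RING_BASE",   "LITTLE_BASE",
  "THUMB_BASE",  "INDEX_TIP",
  "INDEX_BASE",  "MIDDLE_TIP",
  "MIDDLE_BASE", "RING_TIP",
  "RING_BASE",   "LITTLE_TIP",
  "THUMB_BASE",  "MIDDLE_TIP",
  "THUMB_BASE",  "RING_TIP",
  "THUMB_BASE",  "LITTLE_TIP",
  "INDEX_BASE",  "RING_TIP",
  "INDEX_BASE",  "LITTLE_TIP",
  "MIDDLE_BASE", "LITTLE_TIP",
  "WRIST",       "INDEX_TIP",
  "WRIST",       "MIDDLE_TIP",
  "WRIST",       "RING_TIP",
  "WRIST",       "LITTLE_TIP",
  "PALM_BASE",   "THUMB_LITTLE_MIDPOINT",
  "PALM_BASE",   "INDEX_LITTLE_MIDPOINT"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("a", "b")))

#' The per-hand distance schema
#'
#' @return A data frame with columns `unit` (0-27), `a` and `b` (named
#'   point of each endpoint). Position `i` defines `unit-i` for hand 1 and
#'   `unit-(i+28)` for hand 2.
#' @export
distance_schema <- function() {
  data.frame(unit = 0:27, a = .schema_pairs[, "a"], b = .schema_pairs[, "b"],
             stringsAsFactors = FALSE)
}

#' Fingertip-touch configuration
#'
#' @param threshold_px Pixel distance below which (strictly) two fingertips
#'   count as touching. Default 30 px.
#' @return A list with element `threshold_px`.
#' @export
touch_config <- function(threshold_px = 30) {
  if (!is.finite(threshold_px) || threshold_px <= 0) {
    fs_abort("touch threshold must be a positive pixel distance",
             "fs_schema_error")
  }
  list(threshold_px = as.numeric(threshold_px))
}

#' 28 relative distances for one hand
#'
#' Each schema pair's Euclidean distance divided by the hand's standard
#' length. Element 1 (unit-0) is the reference pair itself and is exactly 1
#' for any non-degenerate hand.
#'
#' @param hand A [hand_landmarks()] object.
#' @param schema The [distance_schema()] (exposed for inspection; the pair
#'   order is fixed).
#' @return Numeric vector of 28 non-negative dimensionless distances.
#' @export
hand_distance_vector <- function(hand, schema = distance_schema()) {
  pts <- resolve_all_points(hand)
  ia <- match(schema$a, rownames(pts))
  ib <- match(schema$b, rownames(pts))
  d <- sqrt(rowSums((pts[ia, , drop = FALSE] - pts[ib, , drop = FALSE])^2))
  if (d[1] < 1e-9) {
    fs_abort("degenerate hand: wrist and thumb base coincide",
             "fs_degenerate_hand")
  }
  unname(d / d[1])
}

#' Are two fingertips touching?
#'
#' TRUE iff the pixel distance between the tips is strictly less than the
#' configured threshold.
#'
#' @param tip_a,tip_b Points as returned by [norm_point()].
#' @param dims [image_dims()] of the frame.
#' @param cfg [touch_config()].
#' @return Logical scalar.
#' @export
detect_touch <- function(tip_a, tip_b, dims, cfg = touch_config()) {
  pixel_distance(tip_a, tip_b, dims) < cfg$threshold_px
}

#' Touch code of one hand
#'
#' Which of this hand's five fingertips (1 thumb .. 5 little) the *other*
#' hand's index tip is touching; 0 when none is within threshold or when the
#' other hand is absent. When several tips are within threshold the nearest
#' wins, ties going to the lowest digit. In dual-handed fingerspelling the
#' dominant hand's index finger acts as the pointer, so the opposite index
#' tip is the probe.
#'
#' @param hand The hand whose fingertips are probed.
#' @param other The probing hand, or `NULL` when absent.
#' @inheritParams detect_touch
#' @return Integer in 0..5.
#' @export
tip_code <- function(hand, other, dims, cfg = touch_config()) {
  if (is.null(other)) return(0L)
  probe <- resolve_named_point("INDEX_TIP", other)
  tips <- hand$points[c(5L, 9L, 13L, 17L, 21L), , drop = FALSE]
  dist_px <- sqrt(((tips[, 1] - probe[1]) * dims[[1]])^2 +
                  ((tips[, 2] - probe[2]) * dims[[2]])^2)
  hit <- which(dist_px < cfg$threshold_px)
  if (length(hit) == 0L) return(0L)
  # nearest tip; which.min already breaks exact ties by lowest index
  as.integer(hit[which.min(dist_px[hit])])
}

#' Assemble one gesture record from a frame
#'
#' Hands are assigned to slot 1 / slot 2 by handedness (left is hand 1,
#' right is hand 2; unknown hands fill free slots in input order). Each
#' present hand contributes its 28 relative distances and its touch code;
#' an absent hand contributes 28 zeros and code 0.
#'
#' @param frame A [frame_observation()].
#' @param schema The [distance_schema()].
#' @param cfg [touch_config()].
#' @return An object of class `gesture_record`: list with `label` (may be
#'   `NA`), `units` (numeric 56) and `tips` (integer 2).
#' @export
assemble_record <- function(frame, schema = distance_schema(),
                            cfg = touch_config()) {
  hands <- frame$hands
  if (length(hands) == 0L) {
    fs_abort("empty frame: no hands to featurise", "fs_empty_frame")
  }
  slot <- list(NULL, NULL)
  for (h in hands) {
    i <- switch(h$handedness, left = 1L, right = 2L,
                if (is.null(slot[[1]])) 1L else 2L)
    if (!is.null(slot[[i]])) i <- if (i == 1L) 2L else 1L
    slot[[i]] <- h
  }
  units <- numeric(56)
  tips <- integer(2)
  for (i in 1:2) {
    if (is.null(slot[[i]])) next
    units[(i - 1L) * 28L + 1:28] <- hand_distance_vector(slot[[i]], schema)
    other <- slot[[if (i == 1L) 2L else 1L]]
    tips[i] <- tip_code(slot[[i]], other, frame$dims, cfg)
  }
  structure(list(label = if (is.null(frame$label)) NA_character_ else
                   frame$label,
                 units = units, tips = tips),
            class = "gesture_record")
}
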