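#' Hand-landmark geometry
#'
#' The landmark data model follows the 21-point hand topology used by
#' real-time hand trackers: index 0 is the wrist, 1-4 the thumb
#' (CMC/MCP/IP/TIP), 5-8 the index finger (MCP/PIP/DIP/TIP), 9-12 the
#' middle, 13-16 the ring and 17-20 the little finger. Coordinates are
#' normalised image fractions (x over width, y over height); values
#' slightly outside [0, 1] are legal off-frame landmarks.
#'
#' @name geometry
NULL

#' Construct a normalised 2-D point
#'
#' @param x,y Finite normalised coordinates (fractions of the image side).
#' @return A length-2 numeric vector `c(x, y)`.
#' @export
norm_point <- function(x, y) {
  p <- c(as.numeric(x), as.numeric(y))
  if (!all(is.finite(p))) {
    fs_abort("landmark coordinates must be finite", "fs_invalid_landmark")
  }
  p
}

#' Image dimensions in pixels
#'
#' @param width,height Positive integer pixel dimensions.
#' @return A named numeric vector with elements `width` and `height`.
#' @export
image_dims <- function(width, height) {
  w <- as.numeric(width)
  h <- as.numeric(height)
  if (!all(is.finite(c(w, h))) || w < 1 || h < 1) {
    fs_abort("image dimensions must be positive (>= 1 pixel per side)",
             "fs_invalid_dims")
  }
  c(width = w, height = h)
}

#' A single hand as 21 ordered landmarks
#'
#' @param points A 21 x 2 numeric matrix (or coercible) of normalised
#'   coordinates in topology order 0-20 (row `i` holds landmark `i - 1`).
#' @param handedness One of `"left"`, `"right"`, `"unknown"`.
#' @return An object of class `hand_landmarks`.
#' @export
hand_landmarks <- function(points, handedness = "unknown") {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 21L || ncol(points) != 2L) {
    fs_abort("a hand requires exactly 21 landmarks with 2 coordinates each",
             "fs_invalid_landmark")
  }
  if (!all(is.finite(points))) {
    fs_abort("all landmark coordinates must be finite", "fs_invalid_landmark")
  }
  handedness <- match.arg(handedness, c("left", "right", "unknown"))
  if (any(points < 0 | points > 1)) {
    warning("landmarks outside [0, 1]: off-frame points accepted",
            call. = FALSE)
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, handedness = handedness),
            class = "hand_landmarks")
}

#' A single frame: up to two hands plus the pixel frame that scales them
#'
#' @param hands List of 0-2 [hand_landmarks()] objects.
#' @param dims [image_dims()] of the frame.
#' @param label Optional gesture label (`"A"`-`"Z"` or `"1"`-`"10"`).
#' @return An object of class `frame_observation`.
#' @export
frame_observation <- function(hands, dims, label = NULL) {
  if (inherits(hands, "hand_landmarks")) hands <- list(hands)
  if (length(hands) > 2L) {
    fs_abort("a frame holds at most two hands", "fs_invalid_landmark")
  }
  lapply(hands, function(h) {
    if (!inherits(h, "hand_landmarks")) {
      fs_abort("frame hands must be hand_landmarks objects",
               "fs_invalid_landmark")
    }
  })
  if (length(hands) == 2L) {
    hd <- vapply(hands, function(h) h$handedness, character(1))
    if (all(hd != "unknown") && hd[1] == hd[2]) {
      fs_abort("two hands in one frame cannot share a handedness label",
               "fs_invalid_landmark")
    }
  }
  structure(list(hands = hands, dims = dims,
                 label = if (is.null(label)) NULL else as.character(label)),
            class = "frame_observation")
}

#' Euclidean distance between two normalised points
#'
#' `sqrt((x1 - x2)^2 + (y1 - y2)^2)` in normalised-coordinate units.
#'
#' @param p1,p2 Points as returned by [norm_point()].
#' @return Non-negative distance (dimensionless).
#' @export
euclidean_distance <- function(p1, p2) {
  if (!all(is.finite(c(p1, p2)))) {
    fs_abort("points must be finite", "fs_invalid_landmark")
  }
  unname(sqrt((p1[1] - p2[1])^2 + (p1[2] - p2[2])^2))
}

#' Pixel distance between two normalised points
#'
#' Scales each coordinate by the image side it is a fraction of, then takes
#' the Euclidean distance, giving a length in pixels. This is the metric the
#' fingertip-touch rule thresholds against.
#'
#' @inheritParams euclidean_distance
#' @param dims [image_dims()] of the frame.
#' @return Distance in pixels.
#' @export
pixel_distance <- function(p1, p2, dims) {
  if (!is.numeric(dims) || length(dims) != 2L || !all(is.finite(dims)) ||
      any(dims < 1)) {
    fs_abort("invalid image dimensions", "fs_invalid_dims")
  }
  unname(sqrt(((p1[1] - p2[1]) * dims[[1]])^2 +
              ((p1[2] - p2[2]) * dims[[2]])^2))
}

# Named anatomical points. "Base" means the MCP knuckle for every finger
# including the thumb (the thumb CMC, landmark 1, is unused); the three
# derived points are constructed from landmark combinations.
.named_points <- c(
  "WRIST", "THUMB_BASE", "THUMB_MIDDLE", "THUMB_TIP",
  "INDEX_BASE", "INDEX_TIP", "MIDDLE_BASE", "MIDDLE_TIP",
  "RING_BASE", "RING_TIP", "LITTLE_BASE", "LITTLE_TIP",
  "PALM_BASE", "THUMB_LITTLE_MIDPOINT", "INDEX_LITTLE_MIDPOINT"
)

# direct landmark indices (0-based) for the non-derived names
.named_point_index <- c(
  WRIST = 0L, THUMB_BASE = 2L, THUMB_MIDDLE = 3L, THUMB_TIP = 4L,
  INDEX_BASE = 5L, INDEX_TIP = 8L, MIDDLE_BASE = 9L, MIDDLE_TIP = 12L,
  RING_BASE = 13L, RING_TIP = 16L, LITTLE_BASE = 17L, LITTLE_TIP = 20L
)

#' Names of the anatomical points used by the distance schema
#' @return Character vector of the 15 named points.
#' @export
named_points <- function() .named_points

#' Resolve a named anatomical point on a hand
#'
#' Direct names map to single landmarks; `PALM_BASE` is the centroid of the
#' wrist and the index/little MCP knuckles (a palm-interior point distinct
#' from the wrist), and the two midpoint names bisect the thumb-little and
#' index-little tip segments.
#'
#' @param name One of [named_points()].
#' @param hand A [hand_landmarks()] object.
#' @return A length-2 numeric point.
#' @export
resolve_named_point <- function(name, hand) {
  pts <- unname(hand$points)
  if (name %in% names(.named_point_index)) {
    return(pts[.named_point_index[[name]] + 1L, ])
  }
  switch(name,
    PALM_BASE = (pts[1L, ] + pts[6L, ] + pts[18L, ]) / 3,
    THUMB_LITTLE_MIDPOINT = (pts[5L, ] + pts[21L, ]) / 2,
    INDEX_LITTLE_MIDPOINT = (pts[9L, ] + pts[21L, ]) / 2,
    fs_abort(sprintf("unknown named point '%s'", name), "fs_schema_error")
  )
}

# Resolve every named point at once: a 15 x 2 matrix in named_points() order.
resolve_all_points <- function(hand) {
  pts <- hand$points
  direct <- pts[.named_point_index + 1L, , drop = FALSE]
  derived <- rbind(
    (pts[1L, ] + pts[6L, ] + pts[18L, ]) / 3,
    (pts[5L, ] + pts[21L, ]) / 2,
    (pts[9L, ] + pts[21L, ]) / 2
  )
  out <- rbind(direct, derived)
  rownames(out) <- .named_points
  out
}

#' Standard reference length of a hand
#'
#' The wrist to thumb-base distance, used as the denominator of every
#' relative distance so that the feature vector is invariant to hand size
#' and camera distance.
#'
#' @param hand A [hand_landmarks()] object.
#' @param epsilon Degeneracy floor; a reference below this aborts, since all
#'   downstream ratios would blow up.
#' @return Positive dimensionless length.
#' @export
standard_length <- function(hand, epsilon = 1e-9) {
  len <- euclidean_distance(resolve_named_point("WRIST", hand),
                            resolve_named_point("THUMB_BASE", hand))
  if (len < epsilon) {
    fs_abort("degenerate hand: wrist and thumb base coincide",
             "fs_degenerate_hand")
  }
  len
}
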