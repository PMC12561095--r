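#' Synthetic hand-pose and dataset generation
#'
#' A seeded simulator that emulates the statistical structure of a
#' dual-handed fingerspelling capture: 36 gesture classes (letters A-Z,
#' numbers 1-10), per-class handshapes drawn from a planar kinematic hand
#' skeleton, intra-class variation as landmark jitter plus a random
#' similarity transform (rotation / scale / translation), a single-hand
#' class (letter C), and the five vowels sharing one handshape and
#' differing only in which digit of hand 1 the pointing hand touches.
#'
#' @name synthesis
NULL

# --- canonical planar hand skeleton -----------------------------------------
# Wrist at the origin, fingers pointing "up" (+y, flipped to image
# coordinates at placement time). Segment lengths are a fixed canonical
# hand model in normalised units; per-finger curl in [0, 1] folds the
# finger chain joint by joint toward the palm.

.fingers <- list(
  index  = list(base = c(-0.075, 0.165), len = c(0.085, 0.055, 0.040), splay = -12),
  middle = list(base = c(-0.025, 0.175), len = c(0.095, 0.060, 0.045), splay = -4),
  ring   = list(base = c( 0.025, 0.170), len = c(0.085, 0.055, 0.040), splay = 4),
  little = list(base = c( 0.075, 0.155), len = c(0.065, 0.045, 0.035), splay = 12)
)

.deg <- pi / 180

# direction unit vector at angle `a` degrees clockwise from +y
.dir <- function(a) c(sin(a * .deg), cos(a * .deg))

#' Render a hand pose from kinematic parameters
#'
#' @param flexion Numeric length 5 in [0, 1] (thumb, index, middle, ring,
#'   little); 0 extended, 1 fully curled.
#' @param abduction_deg Thumb abduction angle offset in degrees.
#' @return A 21 x 2 landmark matrix in canonical coordinates (wrist at the
#'   origin, y up).
#' @export
render_hand_pose <- function(flexion, abduction_deg = 0) {
  stopifnot(length(flexion) == 5L, all(flexion >= 0 & flexion <= 1))
  pts <- matrix(0, 21, 2)
  # thumb chain: CMC (landmark 1) then MCP/IP/TIP
  cmc <- c(-0.050, 0.040)
  pts[2, ] <- cmc
  a <- -55 + abduction_deg
  lens <- c(0.060, 0.050, 0.040)
  curl <- flexion[1] * c(0, 35, 45)
  p <- cmc
  for (k in 1:3) {
    a <- a + curl[k]
    p <- p + lens[k] * .dir(a)
    pts[2 + k, ] <- p
  }
  # four fingers: MCP/PIP/DIP/TIP at rows 6-9, 10-13, 14-17, 18-21
  for (f in seq_along(.fingers)) {
    fg <- .fingers[[f]]
    row0 <- 2 + 4 * f  # MCP row index
    pts[row0, ] <- fg$base
    a <- fg$splay
    bend <- flexion[f + 1] * c(80, 90, 60)
    p <- fg$base
    for (k in 1:3) {
      a <- a + bend[k]
      p <- p + fg$len[k] * .dir(a)
      pts[row0 + k, ] <- p
    }
  }
  pts
}

#' Noise model for synthetic capture
#'
#' Defaults emulate a cooperative signer in front of a webcam: small
#' per-landmark tracking jitter, moderate in-plane wrist rotation, modest
#' distance-to-camera (scale) and framing (translation) changes.
#'
#' @param jitter_sd Per-landmark Gaussian jitter, normalised units.
#' @param rotation_range Half-range of in-plane rotation, degrees.
#' @param scale_range Multiplicative scale interval.
#' @param translation_range Half-range of frame translation, normalised.
#' @param seed Integer seed; together with the draw index it fully
#'   determines every sampled pose.
#' @return A `noise_model` list.
#' @export
noise_model <- function(jitter_sd = 0.008, rotation_range = 15,
                        scale_range = c(0.85, 1.15),
                        translation_range = 0.04, seed = 42L) {
  stopifnot(all(is.finite(c(jitter_sd, rotation_range, scale_range,
                            translation_range))),
            length(scale_range) == 2L, scale_range[1] <= scale_range[2])
  structure(list(jitter_sd = jitter_sd, rotation_range = rotation_range,
                 scale_range = scale_range,
                 translation_range = translation_range,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# signature vector used to enforce a minimum between-class handshape margin
.tpl_signature <- function(flexion, abduction, hands_present) {
  h2 <- if (hands_present == "both") c(flexion[2, ], abduction[2] / 60) else
    rep(-1, 6)
  c(flexion[1, ], abduction[1] / 60, h2)
}

#' Pose template library for the 36 gesture classes
#'
#' One template per class: letters A-Z then numbers 1-10. The five vowels
#' share a single handshape (open hand 1, pointing hand 2) and differ only
#' in `touch_spec` (thumb through little, in vowel order A, E, I, O, U).
#' Letter C is a single-hand class. Every other class gets a procedurally
#' drawn handshape at least `margin` away (max absolute flexion
#' difference) from every other template.
#'
#' @param seed Integer seed making the library deterministic.
#' @param margin Minimum between-class handshape separation in flexion
#'   units (default 0.25).
#' @return Named list of 36 `pose_template` objects.
#' @export
class_library <- function(seed = 42L, margin = 0.25) {
  vowels <- c(A = 1L, E = 2L, I = 3L, O = 4L, U = 5L)
  vowel_flex <- rbind(rep(0, 5),            # hand 1: open palm, digits exposed
                      c(0.5, 0, 1, 1, 1))   # hand 2: index pointer
  vowel_abd <- c(0, 0)
  c_flex <- rbind(c(0.35, 0.45, 0.45, 0.45, 0.45), rep(0, 5))
  c_abd <- c(10, 0)

  taken <- list(.tpl_signature(vowel_flex, vowel_abd, "both"),
                .tpl_signature(c_flex, c_abd, "hand1-only"))
  grid <- seq(0, 1, by = 0.25)
  abds <- c(-15, 0, 15)

  with_local_seed(mix_seed(seed, 7), {
    templates <- lapply(gesture_classes(), function(lab) {
      if (lab %in% names(vowels)) {
        return(structure(list(class_label = lab, flexion = vowel_flex,
                              abduction = vowel_abd, hands_present = "both",
                              touch_spec = list(hand = 1L,
                                                digit = vowels[[lab]])),
                         class = "pose_template"))
      }
      if (lab == "C") {
        return(structure(list(class_label = lab, flexion = c_flex,
                              abduction = c_abd,
                              hands_present = "hand1-only",
                              touch_spec = NULL),
                         class = "pose_template"))
      }
      for (try in 1:10000) {
        fl <- matrix(sample(grid, 10, replace = TRUE), 2, 5, byrow = TRUE)
        ab <- sample(abds, 2, replace = TRUE)
        sig <- .tpl_signature(fl, ab, "both")
        ok <- all(vapply(taken, function(s) max(abs(s - sig)) >= margin,
                         logical(1)))
        if (ok) {
          taken[[length(taken) + 1L]] <<- sig
          return(structure(list(class_label = lab, flexion = fl,
                                abduction = ab, hands_present = "both",
                                touch_spec = NULL),
                           class = "pose_template"))
        }
      }
      fs_abort("could not place a template at the requested margin",
               "fs_schema_error")
    })
    names(templates) <- gesture_classes()
    templates
  })
}

# rigid placement of a canonical hand into image coordinates
.place_hand <- function(canon, center, rot_deg, scale) {
  m <- canon
  m[, 2] <- -m[, 2]  # image y grows downward
  a <- rot_deg * .deg
  rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  m <- scale * (m %*% t(rot))
  sweep(m, 2, center, "+")
}

.hand_tips <- function(pts) pts[c(5L, 9L, 13L, 17L, 21L), , drop = FALSE]

#' Sample one noisy frame from a pose template
#'
#' Renders each present hand from the planar skeleton, applies per-landmark
#' jitter then an independent random similarity transform per hand within
#' the noise ranges, places the hands side by side in the frame, and
#' finally translates hand 2 rigidly so its index tip lands within the
#' touch threshold of the digit named by `touch_spec` (rigid translation
#' leaves every relative distance unchanged). Templates without a touch
#' spec get the hands pushed apart until no accidental touch can register.
#' Fully deterministic given `(template, noise$seed, draw_index)`.
#'
#' @param tpl A `pose_template` from [class_library()].
#' @param noise A [noise_model()].
#' @param draw_index Positive integer identifying the draw.
#' @param dims Frame [image_dims()].
#' @param touch_px Touch threshold in pixels used to place or avoid
#'   contacts (default 30, matching [touch_config()]).
#' @return A [frame_observation()] labelled with the template's class.
#' @export
sample_pose <- function(tpl, noise = noise_model(), draw_index = 1L,
                        dims = image_dims(640, 480), touch_px = 30) {
  seed_i <- mix_seed(noise$seed, draw_index,
                     sum(utf8ToInt(tpl$class_label)))
  with_local_seed(seed_i, {
    centers <- list(c(0.34, 0.72), c(0.66, 0.72))
    hands <- list()
    n_hands <- if (tpl$hands_present == "both") 2L else 1L
    placed <- vector("list", n_hands)
    for (i in seq_len(n_hands)) {
      canon <- render_hand_pose(tpl$flexion[i, ], tpl$abduction[i])
      canon <- canon + matrix(stats::rnorm(42, sd = noise$jitter_sd), 21, 2)
      rot <- stats::runif(1, -noise$rotation_range, noise$rotation_range)
      sc <- stats::runif(1, noise$scale_range[1], noise$scale_range[2])
      tr <- stats::runif(2, -noise$translation_range, noise$translation_range)
      placed[[i]] <- .place_hand(canon, centers[[i]] + tr, rot, sc)
    }
    wpx <- dims[["width"]]; hpx <- dims[["height"]]
    if (n_hands == 2L) {
      if (!is.null(tpl$touch_spec)) {
        target <- .hand_tips(placed[[1]])[tpl$touch_spec$digit, ]
        probe <- placed[[2]][9L, ]  # hand 2 index tip
        # fixed sub-threshold offset; direction varies with the digit
        ang <- (45 + 70 * tpl$touch_spec$digit) * .deg
        delta <- 0.3 * touch_px * c(cos(ang) / wpx, sin(ang) / hpx)
        shift <- target + delta - probe
        placed[[2]] <- sweep(placed[[2]], 2, shift, "+")
      } else {
        clearance <- 1.5 * touch_px
        for (iter in 1:30) {
          gaps <- c(
            sqrt(colSums(((t(.hand_tips(placed[[1]])) -
                             placed[[2]][9L, ]) * c(wpx, hpx))^2)),
            sqrt(colSums(((t(.hand_tips(placed[[2]])) -
                             placed[[1]][9L, ]) * c(wpx, hpx))^2)))
          if (min(gaps) >= clearance) break
          placed[[2]][, 1] <- placed[[2]][, 1] + 0.02
        }
      }
    }
    hands <- lapply(seq_len(n_hands), function(i) {
      suppressWarnings(hand_landmarks(placed[[i]],
                                      handedness = c("left", "right")[i]))
    })
    degenerate <- any(vapply(hands, function(h) {
      tryCatch({standard_length(h); FALSE},
               fs_degenerate_hand = function(e) TRUE)
    }, logical(1)))
    if (degenerate) {
      fs_abort("noise ranges collapsed the hand's standard length",
               "fs_degenerate_hand")
    }
    frame_observation(hands, dims, label = tpl$class_label)
  })
}

#' Generate a synthetic gesture dataset
#'
#' Draws `n_per_class` frames from every template in the class library and
#' featurises them, giving a class-balanced 59-column dataset. The
#' defaults (36 classes, noise model defaults, seed 42) are the package's
#' reference simulation conditions.
#'
#' @param n_per_class Frames per gesture class (>= 1).
#' @param noise A [noise_model()]; its seed drives both the template
#'   library and the draws unless `seed` overrides it.
#' @param seed Optional integer overriding `noise$seed`.
#' @param cfg [touch_config()] used during featurisation.
#' @param dims Frame [image_dims()].
#' @return A `gesture_dataset` with full provenance.
#' @export
generate_dataset <- function(n_per_class = 200L, noise = noise_model(),
                             seed = NULL, cfg = touch_config(),
                             dims = image_dims(640, 480)) {
  stopifnot(n_per_class >= 1L)
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  lib <- class_library(seed = noise$seed)
  records <- vector("list", length(lib) * n_per_class)
  k <- 0L
  for (ci in seq_along(lib)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      frame <- sample_pose(lib[[ci]], noise,
                           draw_index = (ci - 1L) * n_per_class + j,
                           dims = dims, touch_px = cfg$threshold_px)
      records[[k]] <- assemble_record(frame, cfg = cfg)
    }
  }
  gesture_dataset(records, provenance = sprintf(
    paste0("synthetic: %d classes x %d, jitter_sd=%g, rotation=%g, ",
           "scale=[%g,%g], translation=%g, seed=%d"),
    length(lib), n_per_class, noise$jitter_sd, noise$rotation_range,
    noise$scale_range[1], noise$scale_range[2], noise$translation_range,
    noise$seed))
}
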