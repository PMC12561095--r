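# Fixtures are built in code from the kinematic skeleton; nothing is read
# from disk.

# a valid in-frame hand derived from the canonical skeleton
make_hand <- function(flexion = rep(0.2, 5), handedness = "left",
                      shift = c(0.45, 0.65)) {
  pts <- render_hand_pose(flexion)
  pts[, 2] <- -pts[, 2]
  suppressWarnings(hand_landmarks(sweep(pts, 2, shift, "+"), handedness))
}

# apply a similarity transform (rotation degrees, uniform scale, shift)
apply_similarity <- function(hand, angle = 0, scale = 1, shift = c(0, 0),
                             center = c(0, 0)) {
  a <- angle * pi / 180
  rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  pts <- sweep(hand$points, 2, center, "-") %*% t(rot) * scale
  pts <- sweep(pts, 2, center + shift, "+")
  suppressWarnings(hand_landmarks(pts, hand$handedness))
}

# a hand whose landmark matrix is set verbatim (no off-frame warnings)
raw_hand <- function(pts, handedness = "unknown") {
  suppressWarnings(hand_landmarks(pts, handedness))
}

# gesture dataset built directly from a unit matrix (n x 56)
make_ds <- function(units, labels, tip1 = 0L, tip2 = 0L) {
  df <- data.frame(letter = labels, units, tip1, tip2, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- gesture_columns()
  gesture_dataset(df)
}

# small cleaned synthetic dataset shared across tests
small_synth <- local({
  cache <- NULL
  function(n_per_class = 12, seed = 7) {
    if (is.null(cache)) {
      ds <- generate_dataset(n_per_class, noise_model(seed = seed))
      cache <<- zscore_filter(drop_duplicates(drop_empty(ds)))
    }
    cache
  }
})

zero_noise <- function(seed = 3L) {
  noise_model(jitter_sd = 0, rotation_range = 0, scale_range = c(1, 1),
              translation_range = 0, seed = seed)
}
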