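Package: fingerspell
Title: Dual-Handed Fingerspelling Recognition from Hand Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for recognising dual-handed sign-language
    fingerspelling (letters A-Z and numbers 1-10, as used in New Zealand
    Sign Language) from 21-point hand-landmark frames. Computes a
    56-unit scale-invariant relative-distance feature vector from named
    anatomical landmark pairs, detects which fingertip of one hand is
    touched by the other hand's index tip (the cue that disambiguates
    the vowels, whose handshapes are otherwise identical), manages the
    59-column gesture CSV format with cleaning, min-max normalisation,
    hand-swap augmentation and stratified splitting, trains and compares
    seven classifier families, and ships a seeded kinematic hand-pose
    simulator so the whole pipeline can be exercised without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    rpart,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
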