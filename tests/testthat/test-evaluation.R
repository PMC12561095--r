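test_that("confusion matrices count actual-by-predicted pairs", {
  cm <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(cm == diag(3)))

  cm2 <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(cm2["A", "A"], 1L)
  expect_equal(cm2["A", "B"], 1L)
  expect_equal(cm2["B", "B"], 1L)
  expect_equal(sum(cm2), 3L)

  set.seed(71)
  act <- sample(LETTERS[1:5], 40, replace = TRUE)
  prd <- sample(LETTERS[1:5], 40, replace = TRUE)
  expect_equal(sum(confusion_matrix(act, prd)), 40L)
  expect_error(confusion_matrix(c("A", "B"), "A"), class = "fs_eval_error")
})

test_that("metrics reproduce the closed-form binary case", {
  # TP = 9, FN = 2, FP = 1, TN = 8 for the positive class
  cm <- confusion_matrix(
    c(rep("pos", 11), rep("neg", 9)),
    c(rep("pos", 9), rep("neg", 2), "pos", rep("neg", 8)))
  rep <- metrics(cm)
  expect_equal(rep$accuracy, 0.85)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.9)
  expect_equal(pos$recall, 9 / 11, tolerance = 1e-12)
  expect_equal(pos$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11), tolerance = 1e-12)

  perfect <- metrics(confusion_matrix(LETTERS[1:4], LETTERS[1:4]))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$macro_f1, 1)
})

test_that("metrics agree with a brute-force recount and the recall identity", {
  set.seed(72)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    n <- sample(20:80, 1)
    classes <- LETTERS[1:k]
    act <- sample(classes, n, replace = TRUE)
    prd <- sample(classes, n, replace = TRUE)
    rep <- suppressWarnings(metrics(confusion_matrix(act, prd, classes)))

    # independent oracle: recount TP/FP/FN from the raw label pairs
    oracle <- vapply(classes, function(cl) {
      tp <- sum(act == cl & prd == cl)
      fp <- sum(act != cl & prd == cl)
      fn <- sum(act == cl & prd != cl)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(sum(act == cl) / n * prec, sum(act == cl) / n * rec,
        sum(act == cl) / n * f1)
    }, numeric(3))
    expect_equal(rep$precision, sum(oracle[1, ]), tolerance = 1e-12)
    expect_equal(rep$recall, sum(oracle[2, ]), tolerance = 1e-12)
    expect_equal(rep$f1, sum(oracle[3, ]), tolerance = 1e-12)
    expect_equal(rep$accuracy, mean(act == prd), tolerance = 1e-12)
    # weighted recall is identically the accuracy in multiclass scoring
    expect_equal(rep$recall, rep$accuracy, tolerance = 1e-12)
    # per class, F1 lies between precision and recall
    pc <- rep$per_class
    expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12 &
                    pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
  }
})

test_that("the suite trains all seven families deterministically", {
  ds <- small_synth()
  parts <- split_gestures(ds, split_config(seed = 3))
  p <- minmax_fit(parts$train)
  tr <- minmax_apply(parts$train, p)
  te <- minmax_apply(parts$test, p)

  models <- train_suite(tr, seed = 13, norm_params = p)
  expect_length(models, 7)
  expect_setequal(names(models),
                  c("random_forest", "knn", "naive_bayes", "decision_tree",
                    "logistic_regression", "svm", "adaboost"))

  r1 <- suppressWarnings(evaluate_model(models$random_forest, te))
  models2 <- train_suite(tr, seed = 13, norm_params = p)
  r2 <- suppressWarnings(evaluate_model(models2$random_forest, te))
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$recall, r1$accuracy, tolerance = 1e-12)

  single <- gesture_dataset(as.data.frame(tr[tr$letter == "A", ],
                                          check.names = FALSE))
  expect_error(train_model(single, classifier_spec("random_forest")),
               class = "fs_eval_error")
})

test_that("shuffled labels drive accuracy to chance", {
  ds <- small_synth()
  shuffled <- gesture_dataset(as.data.frame(ds, check.names = FALSE))
  set.seed(14)
  shuffled$letter <- sample(shuffled$letter)
  parts <- split_gestures(shuffled, split_config(seed = 14))
  p <- minmax_fit(parts$train)
  m <- train_model(minmax_apply(parts$train, p),
                   classifier_spec("random_forest", ntree = 100), seed = 14)
  acc <- suppressWarnings(
    evaluate_model(m, minmax_apply(parts$test, p)))$accuracy
  n_test <- nrow(parts$test)
  chance <- 1 / 36
  expect_lt(acc, chance + 3 * sqrt(chance * (1 - chance) / n_test))
})

test_that("models memorise clean zero-noise data and persist bit-identically", {
  # >= k duplicates per class so the k-nearest tie set is the own class
  ds <- generate_dataset(6, zero_noise(seed = 9))
  p <- minmax_fit(ds)
  tr <- minmax_apply(ds, p)
  for (fam in c("random_forest", "decision_tree", "knn")) {
    m <- train_model(tr, classifier_spec(fam), seed = 9, norm_params = p)
    expect_equal(evaluate_model(m, tr)$accuracy, 1,
                 info = fam)                 # training-set recall of a
  }                                          # memorisable noiseless set

  m <- train_model(tr, classifier_spec("random_forest"), seed = 9,
                   norm_params = p)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  r1 <- evaluate_model(m, tr)
  r2 <- evaluate_model(m2, tr)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$per_class, r2$per_class)
})

test_that("predict_letter closes the loop from frame to label", {
  ds <- generate_dataset(6, zero_noise(seed = 4))
  p <- minmax_fit(ds)
  model <- train_model(minmax_apply(ds, p), classifier_spec("random_forest"),
                       seed = 4, norm_params = p)

  lib <- class_library(seed = 4)
  frame <- sample_pose(lib$B, zero_noise(seed = 4), draw_index = 99)
  expect_identical(predict_letter(model, frame), "B")
  expect_identical(predict_letter(model, frame),
                   predict_letter(model, frame))     # deterministic

  rec <- assemble_record(frame)
  expect_identical(predict_letter(model, rec), "B")
  expect_error(predict_letter(model, rec$units[1:55]),
               class = "fs_schema_error")
})

test_that("the forest is no worse than a single tree on average", {
  deltas <- vapply(1:5, function(s) {
    ds <- generate_dataset(10, noise_model(jitter_sd = 0.02, seed = s))
    parts <- split_gestures(ds, split_config(seed = s))
    p <- minmax_fit(parts$train)
    tr <- minmax_apply(parts$train, p)
    te <- minmax_apply(parts$test, p)
    rf <- suppressWarnings(evaluate_model(
      train_model(tr, classifier_spec("random_forest", ntree = 100),
                  seed = s), te))$accuracy
    dt <- suppressWarnings(evaluate_model(
      train_model(tr, classifier_spec("decision_tree"), seed = s),
      te))$accuracy
    rf - dt
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})
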