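#' Classifier suite
#'
#' Seven classical families are benchmarked on the 58 feature columns (56
#' relative distances plus the two tip codes): random forest, k-nearest
#' neighbours, Gaussian naive Bayes, decision tree, multinomial logistic
#' regression, radial-kernel SVM, and multiclass (SAMME) AdaBoost on
#' depth-1 trees. Standard fits go through randomForest, class, e1071,
#' rpart and nnet; the SAMME booster is implemented here since no
#' installed package provides multiclass AdaBoost.
#'
#' @name classifiers
NULL

.families <- c("random_forest", "knn", "naive_bayes", "decision_tree",
               "logistic_regression", "svm", "adaboost")

#' Specify a classifier
#'
#' @param family One of `random_forest`, `knn`, `naive_bayes`,
#'   `decision_tree`, `logistic_regression`, `svm`, `adaboost`.
#' @param ... Hyperparameter overrides. Defaults: forest `ntree = 200`;
#'   knn `k = 5` (Euclidean); tree `cp = 0`, `minsplit = 5` (effectively
#'   unlimited depth); logistic `maxit = 1000`; svm radial with
#'   `cost = 1`; adaboost `rounds = 50` depth-1 trees.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family, ...) {
  family <- match.arg(family, .families)
  defaults <- switch(family,
    random_forest = list(ntree = 200L),
    knn = list(k = 5L),
    naive_bayes = list(),
    decision_tree = list(cp = 0, minsplit = 5L, maxdepth = 30L),
    logistic_regression = list(maxit = 1000L),
    svm = list(cost = 1, kernel = "radial"),
    adaboost = list(rounds = 50L, maxdepth = 1L)
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(family = family, hyperparameters = hp),
            class = "classifier_spec")
}

#' The default seven-family suite
#' @return Named list of seven [classifier_spec()]s.
#' @export
default_suite <- function() {
  specs <- lapply(.families, classifier_spec)
  names(specs) <- .families
  specs
}

# feature frame with syntactic column names (unit.0 ... tip.2)
feature_frame <- function(ds) {
  df <- as.data.frame(ds, check.names = FALSE)[gesture_columns()[-1]]
  names(df) <- make.names(names(df))
  df
}

.fit_adaboost <- function(df, y, rounds, maxdepth) {
  n <- nrow(df)
  k <- nlevels(y)
  w <- rep(1 / n, n)
  data <- df
  data$.y <- y
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 2L,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                               usesurrogate = 0L)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., data = data, weights = w, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, data, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / k) break          # weaker than chance: stop boosting
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas[length(alphas) + 1L] <- alpha
    if (err <= 1e-10) break
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

.predict_adaboost <- function(fit, df) {
  votes <- matrix(0, nrow(df), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$stumps)) {
    pred <- stats::predict(fit$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  factor(fit$levels[max.col(votes, ties.method = "first")],
         levels = fit$levels)
}

#' Train one classifier on a gesture dataset
#'
#' @param train A `gesture_dataset` already on the training feature scale
#'   (see [minmax_apply()]).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for stochastic fits.
#' @param norm_params Optional [minmax_fit()] params the model will apply
#'   to raw records at prediction time ([predict_letter()]); stored so the
#'   live path cannot skew scaling.
#' @return A `gesture_model`.
#' @export
train_model <- function(train, spec, seed = 42L, norm_params = NULL) {
  stopifnot(inherits(train, "gesture_dataset"),
            inherits(spec, "classifier_spec"))
  if (nrow(train) == 0L) fs_abort("empty training data", "fs_eval_error")
  y <- factor(train$letter, levels = sort(unique(train$letter)))
  if (nlevels(y) < 2L) {
    fs_abort("training requires at least two classes", "fs_eval_error")
  }
  df <- feature_frame(train)
  hp <- spec$hyperparameters
  data <- df
  data$.y <- y
  fit <- with_local_seed(mix_seed(seed, match(spec$family, .families)), {
    switch(spec$family,
      random_forest = randomForest::randomForest(
        x = as.matrix(df), y = y, ntree = hp$ntree),
      knn = list(x = as.matrix(df), y = y, k = hp$k),
      naive_bayes = e1071::naiveBayes(x = df, y = y),
      decision_tree = rpart::rpart(
        .y ~ ., data = data, method = "class",
        control = rpart::rpart.control(cp = hp$cp, minsplit = hp$minsplit,
                                       maxdepth = hp$maxdepth, xval = 0L)),
      logistic_regression = nnet::multinom(
        .y ~ ., data = data, maxit = hp$maxit,
        MaxNWts = 1e5, trace = FALSE),
      svm = e1071::svm(x = as.matrix(df), y = y, kernel = hp$kernel,
                       cost = hp$cost, scale = FALSE),
      adaboost = .fit_adaboost(df, y, hp$rounds, hp$maxdepth)
    )
  })
  structure(list(
    family = spec$family, hyperparameters = hp, fit = fit,
    classes = levels(y), feature_names = gesture_columns()[-1],
    norm_params = norm_params, seed = as.integer(seed),
    provenance = list(n_train = nrow(train),
                      fingerprint = sprintf("%d:%0.10e", nrow(train),
                                            sum(as.matrix(df))))
  ), class = "gesture_model")
}

# predicted labels (character) for a syntactic-name feature frame
.predict_frame <- function(model, df) {
  pred <- switch(model$family,
    random_forest = stats::predict(model$fit, as.matrix(df)),
    knn = with_local_seed(mix_seed(model$seed, 99), {
      class::knn(model$fit$x, as.matrix(df), model$fit$y, k = model$fit$k)
    }),
    naive_bayes = stats::predict(model$fit, df),
    decision_tree = stats::predict(model$fit, df, type = "class"),
    logistic_regression = stats::predict(model$fit, df),
    svm = stats::predict(model$fit, as.matrix(df)),
    adaboost = .predict_adaboost(model$fit, df)
  )
  as.character(pred)
}

#' Train the full suite
#'
#' @param train A `gesture_dataset` on the training scale.
#' @param specs List of [classifier_spec()]s (default: all seven families).
#' @param seed Integer seed; per-family sub-seeds are derived from it, so
#'   the whole suite is reproducible.
#' @param norm_params Optional params stored in every model (see
#'   [train_model()]).
#' @return Named list of `gesture_model`s.
#' @export
train_suite <- function(train, specs = default_suite(), seed = 42L,
                        norm_params = NULL) {
  models <- lapply(specs, train_model, train = train, seed = seed,
                   norm_params = norm_params)
  names(models) <- vapply(specs, function(s) s$family, character(1))
  models
}

#' Evaluate a model on a held-out dataset
#'
#' @param model A `gesture_model`.
#' @param test A `gesture_dataset` on the same feature scale the model was
#'   trained on.
#' @return An `eval_report` (see [metrics()]), including the per-class F1
#'   table and the confusion matrix.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "gesture_model"))
  if (!inherits(test, "gesture_dataset") || nrow(test) == 0L) {
    fs_abort("evaluation requires a non-empty gesture dataset",
             "fs_eval_error")
  }
  if (!all(test$letter %in% model$classes)) {
    fs_abort("test labels outside the model's class inventory",
             "fs_eval_error")
  }
  pred <- .predict_frame(model, feature_frame(test))
  metrics(confusion_matrix(test$letter, pred, classes = model$classes))
}

#' Predict the gesture of a single frame or record
#'
#' Accepts a [frame_observation()] (featurised via [assemble_record()]), a
#' `gesture_record`, or a bare numeric vector of the 58 feature values.
#' The normalisation parameters stored in the model are applied before
#' prediction, so raw records from live capture land on the training
#' scale.
#'
#' @param model A `gesture_model`.
#' @param x The frame, record or feature vector.
#' @param cfg [touch_config()] used when featurising a frame.
#' @return A single predicted label from the model's class inventory.
#' @export
predict_letter <- function(model, x, cfg = touch_config()) {
  stopifnot(inherits(model, "gesture_model"))
  if (inherits(x, "frame_observation")) x <- assemble_record(x, cfg = cfg)
  feats <- if (inherits(x, "gesture_record")) {
    c(x$units, x$tips)
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    fs_abort("predict_letter expects a frame, gesture record or numeric vector",
             "fs_schema_error")
  }
  if (length(feats) != 58L) {
    fs_abort(sprintf("expected 58 feature values, got %d", length(feats)),
             "fs_schema_error")
  }
  units <- feats[1:56]
  if (!is.null(model$norm_params)) {
    p <- model$norm_params
    rng <- p$max - p$min
    units <- (units - p$min) / ifelse(rng > 0, rng, 1)
    units[rng <= 0] <- 0
  }
  df <- as.data.frame(as.list(c(units, feats[57:58])))
  names(df) <- make.names(model$feature_names)
  .predict_frame(model, df)
}

#' Save / load a trained model
#'
#' The artifact is a single RDS file bundling the fitted state with its
#' metadata: family, hyperparameters, class inventory, feature column
#' names, normalisation parameters and training provenance.
#'
#' @param model A `gesture_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gesture_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    fs_abort(sprintf("no such file: %s", path), "fs_format_error")
  }
  model <- readRDS(path)
  if (!inherits(model, "gesture_model")) {
    fs_abort("file does not contain a gesture model", "fs_format_error")
  }
  model
}

#' Compare the full suite on a train/test pair
#'
#' Trains every spec and evaluates it, returning the model-by-metric
#' comparison table; the full `eval_report`s (with per-class F1 and
#' confusion matrices) are attached as attribute `reports`.
#'
#' @inheritParams train_suite
#' @param test Held-out `gesture_dataset` on the training scale.
#' @return A data frame with columns model, accuracy, precision, recall,
#'   f1 (weighted averages, proportions in [0, 1]).
#' @export
compare_classifiers <- function(train, test, specs = default_suite(),
                                seed = 42L, norm_params = NULL) {
  models <- train_suite(train, specs, seed = seed, norm_params = norm_params)
  reports <- lapply(models, evaluate_model, test = test)
  out <- data.frame(
    model = names(reports),
    accuracy = vapply(reports, function(r) r$accuracy, numeric(1)),
    precision = vapply(reports, function(r) r$precision, numeric(1)),
    recall = vapply(reports, function(r) r$recall, numeric(1)),
    f1 = vapply(reports, function(r) r$f1, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reports") <- reports
  out
}
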