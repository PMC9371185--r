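test_that("the stratified split preserves the 80:20 ratio and class balance", {
  set.seed(1)
  data <- tibble::tibble(
    x = rnorm(100),
    label = rep(c("a", "b"), times = c(60, 40))
  )
  sp <- split_dataset(data, "label", ratio = 0.8, seed = 5)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)
  # stratification: per-class train counts within 1 of the exact 80%
  tr <- table(sp$train$label)
  expect_lte(abs(tr[["a"]] - 48), 1)
  expect_lte(abs(tr[["b"]] - 32), 1)
  # determinism
  sp2 <- split_dataset(data, "label", ratio = 0.8, seed = 5)
  expect_identical(sp$train, sp2$train)

  rare <- tibble::tibble(x = rnorm(12), label = c(rep("a", 11), "b"))
  expect_error(split_dataset(rare, "label"),
    class = "sensoryrisk_stratification_error"
  )
})

test_that("grouped splitting keeps whole children on one side", {
  data <- tibble::tibble(
    x = rnorm(60),
    child = rep(sprintf("c%02d", 1:10), each = 6),
    label = rep(c("a", "b"), 30)
  )
  sp <- split_dataset(data, "label", seed = 2, group_col = "child")
  expect_length(intersect(sp$train$child, sp$test$child), 0)
})

test_that("a single-point grid is returned as the best setting", {
  ds <- tiny_models()$data$dataset
  grids <- list(KNN = tibble::tibble(k = 7))
  set <- train_models(ds, "attention",
    grids = grids, families = "KNN",
    seed = 1
  )
  expect_equal(set$best$KNN$k, 7)
  expect_error(
    train_models(ds, "attention",
      grids = list(KNN = tibble::tibble()),
      families = "KNN", seed = 1
    ),
    class = "sensoryrisk_config_error"
  )
})

test_that("CV model selection is deterministic under a fixed seed", {
  ds <- tiny_models()$data$dataset
  sub <- ds[seq(1, nrow(ds), by = 8), ]
  grids <- list(RF = tidyr::expand_grid(
    num_trees = c(50, 100), max_depth = c(0, 3)
  ))
  s1 <- train_models(sub, "stress", grids = grids, families = "RF", seed = 3)
  s2 <- train_models(sub, "stress", grids = grids, families = "RF", seed = 3)
  expect_identical(s1$best, s2$best)
  expect_identical(s1$cv, s2$cv)
})

test_that("metrics reproduce hand-computed confusion examples", {
  # perfect predictor
  perfect <- classification_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  # TP=4, FP=1, FN=1, TN=4 -> precision = recall = f1 = accuracy = 0.8
  truth <- c(rep("pos", 5), rep("neg", 5))
  pred <- c(rep("pos", 4), "neg", "pos", rep("neg", 4))
  m <- classification_metrics(truth, pred, "weighted")
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$by_class$precision[m$by_class$class == "pos"], 0.8)
  expect_equal(m$by_class$recall[m$by_class$class == "pos"], 0.8)
  expect_equal(m$f1, 0.8)
  # all-one-class predictor on a 50/50 set: macro F1 = 1/3
  lazy <- classification_metrics(
    truth = rep(c("a", "b"), each = 5), predicted = rep("a", 10),
    averaging = "macro"
  )
  expect_equal(lazy$accuracy, 0.5)
  expect_equal(lazy$f1, 1 / 3)
})

test_that("weighted F1 equals macro F1 on a balanced binary test set", {
  set.seed(8)
  truth <- rep(c("a", "b"), each = 20)
  pred <- sample(c("a", "b"), 40, replace = TRUE)
  w <- classification_metrics(truth, pred, "weighted")
  m <- classification_metrics(truth, pred, "macro")
  expect_equal(w$f1, m$f1)
})

test_that("accuracy equals one minus the independent wrong-prediction rate", {
  fit <- tiny_models()
  ds <- fit$data$dataset
  sp <- split_dataset(ds, "stress", seed = 4)
  rep <- evaluate_model(fit$stress, sp$test, "stress", averaging = "macro")
  x <- as.matrix(sp$test[feature_names()])
  pred <- as.character(sensoryrisk:::.predict_model(fit$stress, x))
  wrong <- sum(pred != sp$test$stress)
  expect_equal(rep$accuracy, 1 - wrong / nrow(sp$test))
  expect_gte(rep$inference_time_ms, 0)
})

test_that("select_model picks by accuracy with documented tie-breaks", {
  attention <- tibble::tibble(
    family = c("LR", "KNN", "RF", "ANN", "GBDT"),
    accuracy = c(65.71, 81.90, 79.05, 80.95, 86.67),
    inference_time_ms = c(0.0052, 0.0291, 0.0958, 0.0040, 0.0046)
  )
  expect_equal(select_model(attention), "GBDT")
  stress <- tibble::tibble(
    family = c("LR", "KNN", "RF", "ANN", "GBDT"),
    accuracy = c(65.30, 93.92, 98.82, 96.89, 98.50),
    inference_time_ms = c(0.0013, 0.1041, 0.0182, 0.0021, 0.0366)
  )
  expect_equal(select_model(stress), "RF")
  tie <- tibble::tibble(
    family = c("RF", "GBDT"),
    accuracy = c(0.9, 0.9),
    inference_time_ms = c(0.5, 0.1)
  )
  expect_equal(select_model(tie), "GBDT")
})

test_that("caregiver corrections append rows and count wrong predictions", {
  ds <- tiny_models()$data$dataset
  sid <- ds$session_id[1]
  n0 <- nrow(ds)
  ev <- function(t, pred, corr) {
    correction_event(sid, t, pred, corr, target = "stress")
  }
  upd <- ingest_correction(ds, ev(0, "low", "high"))
  upd <- ingest_correction(upd, ev(1, "low", "moderate"))
  upd <- ingest_correction(upd, ev(2, "low", "high"))
  expect_equal(nrow(upd), n0 + 3)
  counts <- wrong_prediction_counts(upd)
  expect_equal(counts$wrong_predictions[counts$session_id == sid], 3)
  expect_equal(sum(upd$source == "caregiver"), 3)
  # invariant: a correction must change the label
  expect_error(correction_event(sid, 0, "low", "low", "stress"),
    class = "sensoryrisk_validation_error"
  )
  expect_error(
    ingest_correction(ds, correction_event("nope", 0, "a", "b", "stress")),
    class = "sensoryrisk_lookup_error"
  )
})

test_that("every family separates high-contrast simulated data", {
  ds <- tiny_models()$data$dataset
  # thin to keep the grid search quick; classes stay balanced
  sub <- ds[seq(1, nrow(ds), by = 6), ]
  sp <- split_dataset(sub, "attention", seed = 6)
  set <- train_models(sp$train, "attention", seed = 6)
  reps <- evaluate_models(set, sp$test, averaging = "weighted")
  accs <- vapply(reps, function(r) r$accuracy, numeric(1))
  expect_true(all(accs >= 0.9))
})
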