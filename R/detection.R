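# fixed family order; also the final tie-break in select_model
.model_families <- c("LR", "KNN", "RF", "ANN", "GBDT")

#' Default hyperparameter grids for the model comparison
#'
#' One tibble of candidate settings per family. The protocol tunes LR, KNN,
#' RF and GBDT by grid-searched five-fold cross-validation; the ANN is not
#' grid-searched but fit with a single hidden layer and L2 weight decay.
#'
#' @return Named list of tibbles keyed by family.
#' @export
default_grids <- function() {
  list(
    LR = tibble::tibble(lambda = c(0.1, 0.01, 0.001, 0.0001)),
    KNN = tibble::tibble(k = c(3, 5, 7, 11)),
    RF = tidyr::expand_grid(
      num_trees = c(100, 300), max_depth = c(0, 5, 10)
    ),
    ANN = tibble::tibble(size = 16, decay = 1e-3),
    GBDT = tidyr::expand_grid(
      nrounds = c(100, 300), eta = c(0.05, 0.1), max_depth = c(2, 3)
    )
  )
}

# ---- family fit/predict wrappers ------------------------------------------
# x: numeric matrix; y: factor. Every fit is seeded for reproducibility.

# training-set standardisation for the scale-sensitive learners (KNN, ANN);
# constant columns get unit scale so they pass through unchanged
.fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

.apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

.fit_family <- function(family, x, y, params, seed) {
  set.seed(seed)
  lev <- levels(y)
  scaler <- NULL
  fit <- switch(family,
    LR = {
      fam <- if (length(lev) == 2) "binomial" else "multinomial"
      glmnet::glmnet(x, y,
        family = fam, alpha = 0,
        lambda = params$lambda, standardize = TRUE
      )
    },
    KNN = {
      scaler <- .fit_scaler(x)
      list(x = .apply_scaler(scaler, x), y = y, k = params$k) # lazy learner
    },
    RF = ranger::ranger(
      x = x, y = y,
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      seed = seed, num.threads = 1
    ),
    ANN = {
      scaler <- .fit_scaler(x)
      nnet::nnet(.apply_scaler(scaler, x), nnet::class.ind(y),
        size = params$size, decay = params$decay,
        softmax = TRUE, maxit = 300, trace = FALSE
      )
    },
    GBDT = {
      obj <- if (length(lev) == 2) "binary:logistic" else "multi:softmax"
      extra <- if (length(lev) > 2) list(num_class = length(lev)) else list()
      dtrain <- xgboost::xgb.DMatrix(x,
        label = as.integer(y) - 1L,
        nthread = 1
      )
      xgboost::xgb.train(
        params = c(list(
          objective = obj, eta = params$eta,
          max_depth = params$max_depth, nthread = 1,
          seed = seed
        ), extra),
        data = dtrain, nrounds = params$nrounds, verbose = 0
      )
    },
    abort(paste0("unknown model family: ", family),
      class = "sensoryrisk_config_error"
    )
  )
  structure(
    list(
      family = family, fit = fit, levels = lev, params = params,
      scaler = scaler
    ),
    class = "sensoryrisk_model"
  )
}

.predict_model <- function(model, x) {
  lev <- model$levels
  out <- switch(model$family,
    LR = {
      p <- predict(model$fit, newx = x, type = "class")
      as.character(p[, 1])
    },
    KNN = as.character(class::knn(
      train = model$fit$x, test = .apply_scaler(model$scaler, x),
      cl = model$fit$y, k = model$fit$k
    )),
    RF = as.character(predict(model$fit,
      data = x,
      num.threads = 1
    )$predictions),
    ANN = {
      p <- predict(model$fit, .apply_scaler(model$scaler, x))
      colnames(p) <- lev
      lev[max.col(p, ties.method = "first")]
    },
    GBDT = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1))
      if (length(lev) == 2) {
        lev[as.integer(p > 0.5) + 1L]
      } else {
        lev[as.integer(p) + 1L]
      }
    }
  )
  factor(out, levels = lev)
}

# ---- dataset splitting -----------------------------------------------------

#' Stratified train/test split
#'
#' Splits labelled rows into disjoint train and test sets, stratified by the
#' label column so class proportions carry over, reproducibly under a seed.
#'
#' @param data Data frame of labelled rows.
#' @param label_col Name of the label column.
#' @param ratio Training fraction, default 0.8.
#' @param seed Integer seed.
#' @param group_col Optional grouping column (e.g. `child_id`): when given,
#'   whole groups are assigned to one side to avoid per-child leakage.
#' @return List with `train` and `test` tibbles.
#' @export
split_dataset <- function(data, label_col, ratio = 0.8, seed = 1,
                          group_col = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 10) {
    abort("need at least 10 labelled rows to split",
      class = "sensoryrisk_validation_error"
    )
  }
  y <- data[[label_col]]
  if (anyNA(y)) {
    abort("label column contains NA; filter unlabelled rows first",
      class = "sensoryrisk_validation_error"
    )
  }
  set.seed(seed)
  if (!is.null(group_col)) {
    groups <- unique(data[[group_col]])
    n_tr <- max(1, round(ratio * length(groups)))
    tr_groups <- sample(groups, n_tr)
    tr_idx <- which(data[[group_col]] %in% tr_groups)
  } else {
    counts <- table(y)
    if (any(counts < 2)) {
      abort(paste0(
        "class '", names(counts)[which.min(counts)],
        "' has fewer than 2 members; cannot stratify"
      ), class = "sensoryrisk_stratification_error")
    }
    tr_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(ratio * length(idx)))
    }), use.names = FALSE)
  }
  list(
    train = data[sort(tr_idx), ],
    test = data[-sort(tr_idx), ]
  )
}

# stratified fold assignment for CV
.make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (idx in split(seq_along(y), y)) {
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# ---- training --------------------------------------------------------------

#' Train and tune the candidate model families
#'
#' For each family with a multi-point grid, runs stratified k-fold
#' cross-validation over the grid on the training rows, picks the setting
#' with the best mean CV accuracy (first maximum on ties), and refits on
#' the full training split. The ANN is fit directly with its fixed L2
#' decay. Fully seeded.
#'
#' @param train Training tibble containing the feature columns and the
#'   label column.
#' @param label_col Name of the label column.
#' @param features Feature column names, default [feature_names()].
#' @param grids Named list of grids, see [default_grids()].
#' @param families Families to train (subset of LR, KNN, RF, ANN, GBDT).
#' @param folds Number of CV folds, default 5.
#' @param seed Integer seed.
#' @return A `detector_set`: list with fitted `models`, a `cv` tibble of
#'   per-setting mean CV accuracies, and `best` hyperparameters per family.
#' @export
train_models <- function(train, label_col, features = feature_names(),
                         grids = default_grids(),
                         families = .model_families,
                         folds = 5, seed = 1) {
  train <- tibble::as_tibble(train)
  families <- match.arg(families, .model_families, several.ok = TRUE)
  x <- as.matrix(train[features])
  y <- factor(train[[label_col]])
  models <- list()
  best <- list()
  cv_rows <- list()
  fold <- .make_folds(y, folds, seed)
  for (family in families) {
    grid <- grids[[family]]
    if (is.null(grid) || nrow(grid) == 0) {
      abort(paste0("empty hyperparameter grid for ", family),
        class = "sensoryrisk_config_error"
      )
    }
    grid <- tibble::as_tibble(grid)
    if (nrow(grid) > 1) {
      cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
        params <- as.list(grid[i, ])
        accs <- vapply(seq_len(folds), function(f) {
          tr <- fold != f
          m <- .fit_family(family, x[tr, , drop = FALSE], y[tr],
            params,
            seed = seed + f
          )
          mean(.predict_model(m, x[!tr, , drop = FALSE]) == y[!tr])
        }, numeric(1))
        mean(accs)
      }, numeric(1))
      pick <- which.max(cv_acc)
      cv_rows[[family]] <- dplyr::mutate(grid,
        family = family,
        cv_accuracy = cv_acc, .before = 1
      )
    } else {
      pick <- 1L
      cv_rows[[family]] <- dplyr::mutate(grid,
        family = family,
        cv_accuracy = NA_real_, .before = 1
      )
    }
    params <- as.list(grid[pick, ])
    best[[family]] <- params
    models[[family]] <- .fit_family(family, x, y, params, seed = seed)
  }
  structure(
    list(
      models = models, best = best,
      cv = dplyr::bind_rows(cv_rows),
      label_col = label_col, features = features, seed = seed
    ),
    class = "detector_set"
  )
}

#' @export
print.detector_set <- function(x, ...) {
  cat(sprintf(
    "<detector_set> %d model(s) for '%s': %s\n",
    length(x$models), x$label_col, paste(names(x$models), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy detector_set
#' @export
tidy.detector_set <- function(x, ...) {
  x$cv
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics from truth and prediction
#'
#' Accuracy (correct / total), per-class precision, recall and F1
#' (`F1 = 2 * precision * recall / (precision + recall)`), and the averaged
#' F1: weighted by class support, or unweighted macro. A class absent from
#' the truth contributes an F1 of 0 under macro averaging and is flagged.
#'
#' @param truth,predicted Vectors of labels (coerced to a common factor).
#' @param averaging `"weighted"` or `"macro"`.
#' @return List with `accuracy`, `f1`, `averaging`, per-class tibble
#'   `by_class`, and `flagged_classes`.
#' @export
#' @examples
#' classification_metrics(
#'   truth = c(rep("a", 5), rep("b", 5)),
#'   predicted = c(rep("a", 4), "b", "a", rep("b", 4))
#' )
classification_metrics <- function(truth, predicted,
                                   averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  if (length(truth) == 0) {
    abort("empty test set", class = "sensoryrisk_validation_error")
  }
  cm <- table(truth = truth, predicted = predicted)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
  support <- rowSums(cm)
  by_class <- tibble::tibble(
    class = lev, support = as.integer(support),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1)
  )
  flagged <- lev[support == 0]
  avg_f1 <- if (averaging == "weighted") {
    sum(f1 * support) / sum(support)
  } else {
    mean(f1)
  }
  list(
    accuracy = sum(tp) / length(truth),
    f1 = avg_f1,
    averaging = averaging,
    by_class = by_class,
    flagged_classes = flagged
  )
}

#' Evaluate a fitted model on held-out data
#'
#' Computes accuracy and the averaged F1 on the test rows (weighted
#' averaging for the binary attention target, macro for the 3-class stress
#' target), plus the per-sample inference time in milliseconds, measured
#' over enough repeated scoring passes to total at least `min_passes`
#' scored samples.
#'
#' @param model A fitted model from a `detector_set` (`set$models$RF`, ...).
#' @param test Test tibble with feature and label columns.
#' @param label_col Name of the label column.
#' @param features Feature column names.
#' @param averaging `"weighted"` or `"macro"`.
#' @param min_passes Minimum total number of scored samples for timing.
#' @return A `model_report`: list with `family`, `params`, `accuracy`,
#'   `f1`, `averaging`, `inference_time_ms`, `n_test`, `by_class`.
#' @export
evaluate_model <- function(model, test, label_col,
                           features = feature_names(),
                           averaging = c("weighted", "macro"),
                           min_passes = 1000) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(model, "sensoryrisk_model"))
  test <- tibble::as_tibble(test)
  if (nrow(test) == 0) {
    abort("empty test set", class = "sensoryrisk_validation_error")
  }
  x <- as.matrix(test[features])
  truth <- factor(test[[label_col]], levels = model$levels)
  pred <- .predict_model(model, x)
  metrics <- classification_metrics(truth, pred, averaging)
  reps <- max(1L, ceiling(min_passes / nrow(x)))
  t0 <- Sys.time()
  for (i in seq_len(reps)) .predict_model(model, x)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(
    list(
      family = model$family,
      params = model$params,
      accuracy = metrics$accuracy,
      f1 = metrics$f1,
      averaging = averaging,
      inference_time_ms = 1000 * elapsed / (reps * nrow(x)),
      n_test = nrow(x),
      by_class = metrics$by_class,
      flagged_classes = metrics$flagged_classes
    ),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %s: accuracy %.4f, %s F1 %.4f, %.4g ms/sample (n = %d)\n",
    x$family, x$accuracy, x$averaging, x$f1, x$inference_time_ms, x$n_test
  ))
  invisible(x)
}

#' @method tidy model_report
#' @export
tidy.model_report <- function(x, ...) {
  x$by_class
}

#' @method glance model_report
#' @export
glance.model_report <- function(x, ...) {
  tibble::tibble(
    family = x$family, accuracy = x$accuracy, f1 = x$f1,
    averaging = x$averaging, inference_time_ms = x$inference_time_ms,
    n_test = x$n_test
  )
}

#' Compare every family on held-out data
#'
#' @param set A `detector_set` from [train_models()].
#' @param test Test tibble.
#' @param averaging `"weighted"` or `"macro"`.
#' @return Named list of `model_report`s.
#' @export
evaluate_models <- function(set, test, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  purrr::map(set$models, evaluate_model,
    test = test, label_col = set$label_col,
    features = set$features, averaging = averaging
  )
}

#' Select the deployed model family from a set of reports
#'
#' Highest accuracy wins; ties break toward the smaller inference time and
#' then toward the fixed family order LR, KNN, RF, ANN, GBDT.
#'
#' @param reports List of `model_report`s, or a data frame with columns
#'   `family`, `accuracy` and optionally `inference_time_ms`.
#' @return The chosen family name.
#' @export
#' @examples
#' select_model(tibble::tibble(
#'   family = c("LR", "KNN", "RF", "ANN", "GBDT"),
#'   accuracy = c(65.71, 81.90, 79.05, 80.95, 86.67)
#' ))
select_model <- function(reports) {
  if (is.data.frame(reports)) {
    df <- tibble::as_tibble(reports)
    if (!"inference_time_ms" %in% names(df)) {
      df$inference_time_ms <- 0
    }
  } else {
    stopifnot(length(reports) >= 1)
    df <- dplyr::bind_rows(purrr::map(reports, glance))
  }
  df$family_rank <- match(df$family, .model_families)
  df <- dplyr::arrange(
    df, dplyr::desc(.data$accuracy),
    .data$inference_time_ms, .data$family_rank
  )
  df$family[1]
}

# ---- caregiver corrections -------------------------------------------------

#' A caregiver correction event
#'
#' Records that a real-time prediction at one timestamp of a session was
#' corrected to a different label.
#'
#' @param session_id Session identifier.
#' @param t Timestamp (seconds since session start).
#' @param predicted The model's label.
#' @param corrected The caregiver's label; must differ from `predicted`.
#' @param target `"attention"` or `"stress"`.
#' @return A `correction_event` list.
#' @export
correction_event <- function(session_id, t, predicted, corrected,
                             target = c("attention", "stress")) {
  target <- match.arg(target)
  if (identical(predicted, corrected)) {
    abort("a correction must change the label (predicted == corrected)",
      class = "sensoryrisk_validation_error"
    )
  }
  structure(
    list(
      session_id = session_id, t = t, predicted = predicted,
      corrected = corrected, target = target
    ),
    class = "correction_event"
  )
}

#' Ingest a caregiver correction into a labelled dataset
#'
#' Appends the corrected row (the matching (session, timestamp) feature row
#' with the corrected label) flagged `source = "caregiver"`, and increments
#' the session's wrong-prediction counter. Append-only: the training set
#' never shrinks.
#'
#' @param dataset Labelled per-sample tibble (as from [generate_dataset()]).
#' @param event A [correction_event()].
#' @return The updated dataset; the running correction log is kept in
#'   `attr(dataset, "corrections")`.
#' @export
ingest_correction <- function(dataset, event) {
  stopifnot(inherits(event, "correction_event"))
  dataset <- tibble::as_tibble(dataset)
  if (!"source" %in% names(dataset)) dataset$source <- "sensor"
  hit <- which(dataset$session_id == event$session_id &
    dataset$t == event$t & dataset$source == "sensor")
  if (length(hit) == 0) {
    abort(paste0(
      "no row for session '", event$session_id, "' at t = ", event$t
    ), class = "sensoryrisk_lookup_error")
  }
  row <- dataset[hit[1], ]
  row[[event$target]] <- event$corrected
  row$source <- "caregiver"
  log <- attr(dataset, "corrections")
  if (is.null(log)) {
    log <- tibble::tibble(
      session_id = character(), t = numeric(),
      target = character(), predicted = character(),
      corrected = character()
    )
  }
  log <- dplyr::bind_rows(log, tibble::tibble(
    session_id = event$session_id, t = event$t, target = event$target,
    predicted = event$predicted, corrected = event$corrected
  ))
  out <- dplyr::bind_rows(dataset, row)
  attr(out, "corrections") <- log
  out
}

#' Wrong-prediction counts per session
#'
#' @param dataset A dataset that has been through [ingest_correction()].
#' @return Tibble with `session_id`, `target`, `wrong_predictions`.
#' @export
wrong_prediction_counts <- function(dataset) {
  log <- attr(dataset, "corrections")
  if (is.null(log) || nrow(log) == 0) {
    return(tibble::tibble(
      session_id = character(), target = character(),
      wrong_predictions = integer()
    ))
  }
  dplyr::count(log, .data$session_id, .data$target,
    name = "wrong_predictions"
  )
}

#' Plot a model comparison
#'
#' @param reports List of `model_report`s or their [glance()] rows.
#' @return A ggplot bar chart of accuracy and F1 by family.
#' @export
plot_model_comparison <- function(reports) {
  df <- if (is.data.frame(reports)) {
    tibble::as_tibble(reports)
  } else {
    dplyr::bind_rows(purrr::map(reports, glance))
  }
  long <- tidyr::pivot_longer(df[c("family", "accuracy", "f1")],
    -"family",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    factor(.data$family, levels = .model_families),
    .data$value,
    fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, title = "Model comparison") +
    ggplot2::ylim(0, 1)
}
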