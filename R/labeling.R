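#' Shannon entropy of a label sequence, in bits
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the observed classes.
#'
#' @param labels Non-empty vector of class labels.
#' @return Entropy in bits (>= 0).
#' @export
#' @examples
#' entropy(c("low", "low", "normal", "normal")) # 1 bit
entropy <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) {
    abort("entropy of an empty label sequence is undefined",
      class = "sensoryrisk_validation_error"
    )
  }
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a threshold split
#'
#' Gain of splitting `labels` by `scores <= threshold` versus
#' `scores > threshold`:
#' \eqn{IG = H(labels) - \sum_s (n_s/n) H(labels_s)}. A threshold that puts
#' all scores on one side has zero gain (not an error).
#'
#' @param scores Numeric scores aligned with `labels`.
#' @param labels Class labels.
#' @param threshold Finite split point.
#' @return Information gain in bits (>= 0 up to floating-point error).
#' @export
information_gain <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), is.finite(threshold))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n <- length(scores)
  if (n == 0) {
    abort("no complete (score, label) pairs",
      class = "sensoryrisk_validation_error"
    )
  }
  left <- scores <= threshold
  h <- entropy(labels)
  h_split <- 0
  for (side in list(left, !left)) {
    if (any(side)) {
      h_split <- h_split + sum(side) / n * entropy(labels[side])
    }
  }
  max(0, h - h_split)
}

#' Best threshold split by information gain
#'
#' Evaluates candidate thresholds at midpoints between consecutive distinct
#' sorted scores and returns the gain-maximising one; ties break toward the
#' smaller threshold. If all labels are identical the gain is zero and the
#' result carries a `degenerate` flag.
#'
#' @param scores Numeric scores (>= 2 distinct values).
#' @param labels Aligned class labels.
#' @return A `split_result`: list with `threshold`, `information_gain`,
#'   `parent_entropy`, `degenerate` flag and the full `candidates` tibble
#'   (threshold, gain).
#' @export
#' @examples
#' best_split(c(0.2, 0.4, 0.7, 0.9), c("low", "low", "normal", "normal"))
best_split <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  distinct <- sort(unique(scores))
  if (length(distinct) < 2) {
    abort("best_split needs at least two distinct scores",
      class = "sensoryrisk_validation_error"
    )
  }
  degenerate <- length(unique(labels)) < 2
  if (degenerate) {
    warn("all labels identical; information gain is zero everywhere")
  }
  candidates <- (distinct[-length(distinct)] + distinct[-1]) / 2
  gains <- vapply(
    candidates,
    function(th) information_gain(scores, labels, th),
    numeric(1)
  )
  best <- which.max(gains) # which.max returns the first (smallest) maximum
  structure(
    list(
      threshold = candidates[best],
      information_gain = gains[best],
      parent_entropy = entropy(labels),
      degenerate = degenerate,
      candidates = tibble::tibble(threshold = candidates, gain = gains)
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> threshold = %.4g, gain = %.4g bits (parent %.4g)%s\n",
    x$threshold, x$information_gain, x$parent_entropy,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @method tidy split_result
#' @export
tidy.split_result <- function(x, ...) {
  x$candidates
}

#' @method glance split_result
#' @export
glance.split_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    information_gain = x$information_gain,
    parent_entropy = x$parent_entropy,
    degenerate = x$degenerate
  )
}

#' Attention label from task accuracy
#'
#' Accuracy strictly above the threshold is a normal level of attention;
#' accuracy at or below it is low attention. The default cut of 0.6 is the
#' split the information-gain analysis selects on protocol-style data.
#'
#' @param task_accuracy Accuracy fraction in `[0, 1]` (vectorised).
#' @param threshold Cut point, default 0.6.
#' @return Character vector, `"normal"` or `"low"`.
#' @export
#' @examples
#' assign_attention_label(c(0.61, 0.6, 0)) # normal, low, low
assign_attention_label <- function(task_accuracy, threshold = 0.6) {
  if (any(is.na(task_accuracy)) ||
    any(task_accuracy < 0 | task_accuracy > 1)) {
    abort("task_accuracy must lie in [0, 1]",
      class = "sensoryrisk_validation_error"
    )
  }
  ifelse(task_accuracy > threshold, "normal", "low")
}

#' Stress label from activity and regime class
#'
#' The protocol's scheme: relaxing in moderate conditions is low stress;
#' performing tasks in moderate and extreme conditions is moderate and high
#' stress respectively. The scheme does not define the (relaxing, extreme)
#' cell, which is refused rather than guessed.
#'
#' @param activity `"relaxing"` or `"task"`.
#' @param regime_class `"moderate"` or `"extreme"` (overall regime class,
#'   see [regime_class()]).
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
assign_stress_label <- function(activity, regime_class) {
  stopifnot(length(activity) == 1, length(regime_class) == 1)
  if (!activity %in% c("relaxing", "task")) {
    abort("activity must be 'relaxing' or 'task'",
      class = "sensoryrisk_validation_error"
    )
  }
  if (!regime_class %in% c("moderate", "extreme")) {
    abort("regime_class must be 'moderate' or 'extreme'",
      class = "sensoryrisk_validation_error"
    )
  }
  if (activity == "relaxing" && regime_class == "extreme") {
    abort("the (relaxing, extreme) combination has no defined stress label",
      class = "sensoryrisk_undefined_combination"
    )
  }
  switch(activity,
    relaxing = "low",
    task = if (regime_class == "moderate") "moderate" else "high"
  )
}
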