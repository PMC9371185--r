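#' Score an adapted caregiver-teacher report form
#'
#' Items on the problem section are scored 0 ("Not True"), 1 ("Somewhat or
#' Sometimes True") or 2 ("Very True or Often True") and summed per
#' subscale; the adapted form covers the Anxious/Depressed ("stress") and
#' Attention Problem subscales. Higher scores mean more problems. The real
#' instrument's item list is configurable; a synthetic 10+10-item form is
#' the default for testing.
#'
#' @param responses Named numeric vector/list, item id -> score in
#'   `{0, 1, 2}`.
#' @param items Named character vector mapping item id to subscale
#'   (`"attention"` or `"stress"`); default [ctrf_synthetic_items()].
#' @return Tibble with columns `subscale` and `score`.
#' @export
#' @examples
#' items <- ctrf_synthetic_items()
#' score_ctrf(stats::setNames(rep(1, length(items)), names(items)), items)
score_ctrf <- function(responses, items = ctrf_synthetic_items()) {
  responses <- unlist(responses)
  missing <- setdiff(names(items), names(responses))
  if (length(missing) > 0) {
    abort(paste0(
      "missing response(s) for item(s): ",
      paste(missing, collapse = ", ")
    ), class = "sensoryrisk_validation_error")
  }
  vals <- responses[names(items)]
  if (any(!vals %in% c(0, 1, 2))) {
    bad <- names(items)[!vals %in% c(0, 1, 2)]
    abort(paste0(
      "responses must be 0, 1 or 2; offending item(s): ",
      paste(bad, collapse = ", ")
    ), class = "sensoryrisk_validation_error")
  }
  tibble::tibble(subscale = unname(items), score = unname(vals)) |>
    dplyr::group_by(.data$subscale) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop")
}

#' Synthetic adapted report-form item map
#'
#' Ten attention-problem and ten anxious/depressed items; a stand-in for
#' the adapted instrument, whose item list is not public.
#'
#' @return Named character vector, item id -> subscale.
#' @export
ctrf_synthetic_items <- function() {
  stats::setNames(
    rep(c("attention", "stress"), each = 10),
    c(sprintf("att_%02d", 1:10), sprintf("anx_%02d", 1:10))
  )
}

#' System Usability Scale score
#'
#' Standard SUS scoring: each of the 10 item scores (1-5 Likert; item means
#' across respondents are permitted, hence non-integer values) is mapped to
#' a 0-4 contribution — odd-numbered (positively worded) items contribute
#' `score - 1`, even-numbered (negatively worded) items `5 - score` — then
#' summed and multiplied by 2.5 onto the 0-100 scale.
#'
#' @param scores Numeric vector of exactly 10 item scores in `[1, 5]`,
#'   in statement order.
#' @return SUS score in `[0, 100]`.
#' @export
#' @examples
#' score_sus(rep(3, 10)) # 50
score_sus <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) != 10) {
    abort("a SUS response has exactly 10 item scores",
      class = "sensoryrisk_validation_error"
    )
  }
  if (any(is.na(scores)) || any(scores < 1 | scores > 5)) {
    abort("SUS item scores must lie in [1, 5]",
      class = "sensoryrisk_validation_error"
    )
  }
  odd <- seq(1, 9, by = 2)
  even <- seq(2, 10, by = 2)
  2.5 * (sum(scores[odd] - 1) + sum(5 - scores[even]))
}

#' Cohen's d from group summaries with magnitude label
#'
#' Standardised mean difference using the pooled SD of the two sessions,
#' `d = (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)`, labelled by the
#' conventional bands: small if `|d|` in [0.2, 0.5), moderate in
#' [0.5, 0.8), large at 0.8 or above, negligible below 0.2.
#'
#' @param mean_a,sd_a Mean and SD of the first session.
#' @param mean_b,sd_b Mean and SD of the second session.
#' @return An `effect_size`: list with `d` and `magnitude`.
#' @export
#' @examples
#' cohens_d(8.1, 3.5, 6.5, 2.8) # d = 0.505, moderate
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (sd_a < 0 || sd_b < 0) {
    abort("standard deviations must be non-negative",
      class = "sensoryrisk_validation_error"
    )
  }
  if (sd_a == 0 && sd_b == 0) {
    abort("effect size undefined when both SDs are zero",
      class = "sensoryrisk_validation_error"
    )
  }
  d <- (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
  magnitude <- if (abs(d) >= 0.8) {
    "large"
  } else if (abs(d) >= 0.5) {
    "moderate"
  } else if (abs(d) >= 0.2) {
    "small"
  } else {
    "negligible"
  }
  structure(list(d = d, magnitude = magnitude), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.3f (%s)\n", x$d, x$magnitude))
  invisible(x)
}

#' @method glance effect_size
#' @export
glance.effect_size <- function(x, ...) {
  tibble::tibble(d = x$d, magnitude = x$magnitude)
}

#' Paired t-test on per-participant differences
#'
#' `t = mean(diff) / (sd(diff) / sqrt(n))` with a two-tailed p-value from
#' the Student t distribution on `n - 1` degrees of freedom.
#'
#' @param differences Numeric vector of paired differences (`n >= 2`).
#' @return Tibble with `t`, `df`, `p_two_tailed`, `mean_diff`, `sd_diff`,
#'   `n`.
#' @export
#' @examples
#' paired_t(c(1, 1, 1, 3)) # t = 3
paired_t <- function(differences) {
  differences <- differences[!is.na(differences)]
  n <- length(differences)
  if (n < 2) {
    abort("paired t-test needs at least 2 differences",
      class = "sensoryrisk_validation_error"
    )
  }
  s <- stats::sd(differences)
  if (s == 0) {
    if (all(differences == 0)) {
      return(tibble::tibble(
        t = 0, df = n - 1, p_two_tailed = 1,
        mean_diff = 0, sd_diff = 0, n = n
      ))
    }
    abort("zero variance of non-zero differences: degenerate test",
      class = "sensoryrisk_validation_error"
    )
  }
  tval <- mean(differences) / (s / sqrt(n))
  tibble::tibble(
    t = tval, df = n - 1,
    p_two_tailed = 2 * stats::pt(-abs(tval), df = n - 1),
    mean_diff = mean(differences), sd_diff = s, n = n
  )
}

#' Summarise per-session measures for a participant group
#'
#' Mean and SD per session type of wrong-prediction counts (attention,
#' stress) and of the report-form subscale scores by rater, mirroring the
#' evaluation study's summary layout (no-SMRS, SMRS #1, SMRS #2 sessions).
#'
#' @param data Tibble with one row per participant x session, columns
#'   `participant`, `session` (`"no-SMRS"`, `"SMRS#1"`, `"SMRS#2"`) and any
#'   of `wrong_attention`, `wrong_stress`, `ctrf_attention_caregiver`,
#'   `ctrf_attention_teacher`, `ctrf_stress_caregiver`,
#'   `ctrf_stress_teacher`.
#' @param group Group label attached to the output (e.g. `"ASD"`, `"TD"`).
#' @return Tibble with `group`, `session`, `measure`, `mean`, `sd`, `n`,
#'   and a `small_n` flag (SD reported as 0 with a flag when n = 1).
#' @export
summarize_sessions <- function(data, group = "ASD") {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    abort("empty participant group", class = "sensoryrisk_validation_error")
  }
  measures <- intersect(
    c(
      "wrong_attention", "wrong_stress",
      "ctrf_attention_caregiver", "ctrf_attention_teacher",
      "ctrf_stress_caregiver", "ctrf_stress_teacher"
    ),
    names(data)
  )
  data |>
    tidyr::pivot_longer(dplyr::all_of(measures),
      names_to = "measure", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$session, .data$measure) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      small_n = dplyr::n() < 2,
      .groups = "drop"
    ) |>
    dplyr::mutate(group = group, .before = 1)
}

#' Full effect-size table from a session summary
#'
#' Computes, per measure, the pooled-SD Cohen's d between two session types
#' from their summary means and SDs.
#'
#' @param summary A tibble from [summarize_sessions()].
#' @param session_a,session_b Session types to contrast (defaults: the
#'   baseline session versus the second assisted session).
#' @return Tibble with `group`, `measure`, `d`, `magnitude`.
#' @export
effect_size_table <- function(summary, session_a = "no-SMRS",
                              session_b = "SMRS#2") {
  a <- dplyr::filter(summary, .data$session == session_a)
  b <- dplyr::filter(summary, .data$session == session_b)
  joined <- dplyr::inner_join(a, b,
    by = c("group", "measure"),
    suffix = c("_a", "_b")
  )
  purrr::pmap_dfr(joined, function(group, measure, mean_a, sd_a,
                                   mean_b, sd_b, ...) {
    es <- cohens_d(mean_a, sd_a, mean_b, sd_b)
    tibble::tibble(
      group = group, measure = measure,
      d = es$d, magnitude = es$magnitude
    )
  })
}
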