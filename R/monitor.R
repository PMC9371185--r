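#' Majority-vote smoothing of per-second labels
#'
#' Optional post-processing for per-sample predictions: each second is
#' replaced by the majority label over the trailing window (ties keep the
#' current label). Off by default everywhere.
#'
#' @param labels Character vector of per-second labels.
#' @param window Window length in seconds, default 10.
#' @return Smoothed label vector.
#' @export
smooth_predictions <- function(labels, window = 10) {
  n <- length(labels)
  out <- labels
  for (i in seq_len(n)) {
    win <- labels[max(1, i - window + 1):i]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    if (!labels[i] %in% top) out[i] <- top[1]
  }
  out
}

#' Monitor a session: detect, assess risk, recommend, alert
#'
#' The full working flow on one recorded (or simulated) session: extract
#' the per-second feature table, predict attention and stress with the
#' deployed models, track the duration of atypical responses per modality,
#' run the three fuzzy controllers in parallel each second, pick the
#' maximum-risk modality as the recommendation, and emit an alert payload
#' for each High Risk second when a subscription is active.
#'
#' @param session A [sensor_session()].
#' @param profile The child's `sensory_profile`.
#' @param attention_model,stress_model Fitted models (from a
#'   `detector_set`'s `models` list).
#' @param controllers Controllers from [load_fuzzy_controllers()].
#' @param catalog Strategy catalogue.
#' @param subscription Phone-number string or `NULL`.
#' @param smooth Apply the 10 s majority-vote smoother to predictions.
#' @return A `monitor_log`: list with `assessments` (per-second tibble:
#'   `t`, predictions, per-modality categories, chosen `modality`,
#'   `category`, `crisp`, `strategy`, `alert`), and `alerts` (list of
#'   payloads).
#' @export
monitor <- function(session, profile, attention_model, stress_model,
                    controllers = load_fuzzy_controllers(),
                    catalog = load_strategy_catalog(),
                    subscription = NULL, smooth = FALSE) {
  if (is.null(attention_model) || is.null(stress_model)) {
    abort("both a trained attention and stress model are required",
      class = "sensoryrisk_startup_error"
    )
  }
  feat <- extract_features(session, profile)
  x <- as.matrix(feat[feature_names()])
  attention <- as.character(.predict_model(attention_model, x))
  stress <- as.character(.predict_model(stress_model, x))
  if (smooth) {
    attention <- smooth_predictions(attention)
    stress <- smooth_predictions(stress)
  }
  stim_values <- list(
    brightness = session$records$brightness_lx,
    temperature = session$records$temp_c,
    noise = session$records$noise_db
  )
  n <- nrow(feat)
  per_modality <- purrr::imap(controllers, function(ctrl, modality) {
    vals <- stim_values[[modality]]
    terms <- vapply(vals, function(v) {
      deg <- fuzzify(ctrl$variables$stimulus, v)
      names(deg)[which.max(deg)]
    }, character(1))
    dur <- track_duration(attention, stress, terms)
    assess <- purrr::map(seq_len(n), function(i) {
      infer(ctrl, vals[i], dur[i], attention[i], stress[i],
        catalog = catalog
      )
    })
    list(terms = terms, duration = dur, assess = assess)
  })
  cat_rank <- stats::setNames(seq_along(.risk_terms), .risk_terms)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    cats <- vapply(
      per_modality, function(m) m$assess[[i]]$category,
      character(1)
    )
    crisps <- vapply(
      per_modality, function(m) m$assess[[i]]$crisp,
      numeric(1)
    )
    # max risk category wins; ties toward the higher crisp value
    ord <- order(-cat_rank[cats], -crisps)
    pick <- names(per_modality)[ord[1]]
    a <- per_modality[[pick]]$assess[[i]]
    tibble::tibble(
      t = feat$t[i],
      attention = attention[i], stress = stress[i],
      brightness_category = cats[["brightness"]],
      temperature_category = cats[["temperature"]],
      noise_category = cats[["noise"]],
      modality = pick, stimulus_term = a$stimulus_term,
      crisp = a$crisp, category = a$category, strategy = a$strategy,
      alert = a$category == "High Risk" && !is.null(subscription)
    )
  })
  alerts <- purrr::compact(purrr::map(seq_len(n), function(i) {
    if (!rows$alert[i]) {
      return(NULL)
    }
    idx <- rows$modality[i]
    build_alert(per_modality[[idx]]$assess[[i]], subscription,
      timestamp = rows$t[i]
    )
  }))
  structure(
    list(assessments = rows, alerts = alerts,
         session_id = session$meta$child_id),
    class = "monitor_log"
  )
}

#' @export
print.monitor_log <- function(x, ...) {
  tab <- table(x$assessments$category)
  cat(sprintf(
    "<monitor_log> %d seconds: %s; %d alert(s)\n",
    nrow(x$assessments),
    paste(names(tab), tab, sep = " = ", collapse = ", "),
    length(x$alerts)
  ))
  invisible(x)
}

#' Write a monitor log as JSON lines
#'
#' One event object per second, suitable for downstream ingestion.
#'
#' @param log A `monitor_log` from [monitor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monitor_log <- function(log, path) {
  stopifnot(inherits(log, "monitor_log"))
  rows <- log$assessments
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    as.character(jsonlite::toJSON(as.list(rows[i, ]),
      auto_unbox = TRUE, digits = NA
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Plot a monitored session's risk timeline
#'
#' @param object A `monitor_log`.
#' @param ... Unused.
#' @return A ggplot of crisp risk over time, coloured by category.
#' @method autoplot monitor_log
#' @export
autoplot.monitor_log <- function(object, ...) {
  df <- object$assessments
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$crisp)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "Low Risk" = "forestgreen", "Medium Risk" = "orange",
      "High Risk" = "firebrick"
    )) +
    ggplot2::labs(
      x = "time since session start (s)", y = "crisp risk (0-10)",
      title = "Risk assessment timeline"
    )
}
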