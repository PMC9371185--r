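#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
#' @importFrom nnet nnet
#' @importFrom xgboost xgb.train
#' @importFrom class knn
NULL

# canonical record columns, fixed order; `t` is seconds since session start
.record_cols <- c(
  "t", "temp_c", "humidity_pct", "noise_db", "brightness_lx",
  "pressure_kpa", "gsr", "hr_bpm", "ax", "ay", "az"
)

#' Construct a sensor session
#'
#' A session is an ordered run of 1 Hz multi-channel samples plus child
#' metadata. Records sit on an integer 0-based time grid; channels may be
#' individually missing (`NA`), never silently zero-filled. Gaps in the time
#' grid are detected and kept as a flag table rather than being filled.
#'
#' @param records Data frame with columns `t`, `temp_c`, `humidity_pct`,
#'   `noise_db`, `brightness_lx`, `pressure_kpa`, `gsr`, `hr_bpm`,
#'   `ax`, `ay`, `az`. `t` must be non-negative integers, strictly
#'   increasing.
#' @param child_id Character scalar identifying the child.
#' @param gender `"male"` or `"female"` (encoded 0/1 downstream), or `NA`.
#' @param age Age in years, or `NA`.
#' @param task_accuracy Fraction of task items correct in `[0, 1]`, or `NA`.
#' @param attention_label Assessor attention label, `"low"`/`"normal"`, or
#'   `NA` for unlabelled sessions.
#' @param stress_label Assessor stress label, `"low"`/`"moderate"`/`"high"`,
#'   or `NA`.
#' @param start_time Optional wall-clock start time (metadata only; all
#'   computation is offset-based).
#'
#' @return An object of class `sensor_session`: a list with a `records`
#'   tibble, a `meta` list, and a `gaps` tibble flagging missing seconds.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   t = 0:9, temp_c = 26, humidity_pct = 55, noise_db = 60,
#'   brightness_lx = 400, pressure_kpa = 101, gsr = 200, hr_bpm = 95,
#'   ax = 0, ay = 0, az = 0
#' )
#' s <- sensor_session(rec, child_id = "c01", gender = "male", age = 5)
#' s
sensor_session <- function(records, child_id, gender = NA_character_,
                           age = NA_real_, task_accuracy = NA_real_,
                           attention_label = NA_character_,
                           stress_label = NA_character_,
                           start_time = NULL) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.record_cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "records is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "sensoryrisk_schema_error")
  }
  records <- records[.record_cols]
  records <- dplyr::mutate(records, dplyr::across(
    dplyr::everything(),
    as.numeric
  ))
  if (nrow(records) == 0) {
    abort("session has no records", class = "sensoryrisk_empty_session")
  }
  t <- records$t
  if (anyNA(t) || any(t < 0) || any(t != floor(t))) {
    abort("timestamps must be non-negative integers on a 1 Hz grid",
      class = "sensoryrisk_validation_error"
    )
  }
  if (anyDuplicated(t)) {
    abort(paste0(
      "duplicate timestamp(s): ",
      paste(unique(t[duplicated(t)]), collapse = ", ")
    ), class = "sensoryrisk_validation_error")
  }
  if (is.unsorted(t)) {
    records <- records[order(t), ]
    t <- records$t
  }
  bad_hum <- which(!is.na(records$humidity_pct) &
    (records$humidity_pct < 0 | records$humidity_pct > 100))
  if (length(bad_hum) > 0) {
    abort(paste0("humidity out of [0, 100] at t = ", t[bad_hum[1]]),
      class = "sensoryrisk_validation_error"
    )
  }
  bad_hr <- which(!is.na(records$hr_bpm) & records$hr_bpm <= 0)
  if (length(bad_hr) > 0) {
    abort(paste0("non-positive heart rate at t = ", t[bad_hr[1]]),
      class = "sensoryrisk_validation_error"
    )
  }
  if (!is.na(task_accuracy) &&
    (task_accuracy < 0 || task_accuracy > 1)) {
    abort("task_accuracy must lie in [0, 1]",
      class = "sensoryrisk_validation_error"
    )
  }
  if (!is.na(attention_label) &&
    !attention_label %in% c("low", "normal")) {
    abort("attention_label must be 'low' or 'normal'",
      class = "sensoryrisk_validation_error"
    )
  }
  if (!is.na(stress_label) &&
    !stress_label %in% c("low", "moderate", "high")) {
    abort("stress_label must be 'low', 'moderate' or 'high'",
      class = "sensoryrisk_validation_error"
    )
  }
  gaps <- .find_gaps(t)
  structure(
    list(
      records = records,
      meta = list(
        child_id = as.character(child_id),
        gender = gender,
        age = age,
        task_accuracy = task_accuracy,
        attention_label = attention_label,
        stress_label = stress_label,
        start_time = start_time
      ),
      gaps = gaps
    ),
    class = "sensor_session"
  )
}

# gap table: runs of missing seconds between min(t) and max(t)
.find_gaps <- function(t) {
  missing_t <- setdiff(seq(min(t), max(t)), t)
  if (length(missing_t) == 0) {
    return(tibble::tibble(
      from = integer(), to = integer(),
      n_missing = integer()
    ))
  }
  runs <- split(missing_t, cumsum(c(1, diff(missing_t) != 1)))
  tibble::tibble(
    from = unname(vapply(runs, min, numeric(1))),
    to = unname(vapply(runs, max, numeric(1))),
    n_missing = unname(vapply(runs, length, integer(1)))
  )
}

#' @export
print.sensor_session <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<sensor_session> child %s: %d records (t = %d..%d), %d gap(s)\n",
    m$child_id, nrow(x$records), min(x$records$t), max(x$records$t),
    nrow(x$gaps)
  ))
  lab <- c(
    if (!is.na(m$task_accuracy)) {
      sprintf("task_accuracy = %.2f", m$task_accuracy)
    },
    if (!is.na(m$attention_label)) {
      sprintf("attention = %s", m$attention_label)
    },
    if (!is.na(m$stress_label)) sprintf("stress = %s", m$stress_label)
  )
  if (length(lab) > 0) cat("  ", paste(lab, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Write a session to disk
#'
#' CSV format: one header row with the canonical column names plus a JSON
#' metadata sidecar `<stem>.meta.json`. JSON-lines format: one record object
#' per line with the same sidecar. Numeric values roundtrip exactly.
#'
#' @param session A [sensor_session()].
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "sensor_session"))
  rec <- session$records
  if (format == "csv") {
    out <- vapply(rec, function(col) {
      ifelse(is.na(col), "", format(col, digits = 17, trim = TRUE,
        scientific = FALSE
      ))
    }, character(nrow(rec)))
    out <- matrix(out, nrow = nrow(rec))
    lines <- c(
      paste(.record_cols, collapse = ","),
      apply(out, 1, paste, collapse = ",")
    )
    writeLines(lines, path)
  } else {
    lines <- vapply(seq_len(nrow(rec)), function(i) {
      as.character(jsonlite::toJSON(as.list(rec[i, ]),
        auto_unbox = TRUE, digits = NA, na = "null"
      ))
    }, character(1))
    writeLines(lines, path)
  }
  meta <- session$meta
  meta$start_time <- if (is.null(meta$start_time)) {
    NULL
  } else {
    format(meta$start_time)
  }
  jsonlite::write_json(meta, .meta_path(path),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read a session from disk
#'
#' Reads the CSV or JSON-lines session dialect written by [write_session()],
#' restoring metadata from the `<stem>.meta.json` sidecar when present.
#' Malformed rows raise a parse error naming the offending line; duplicate
#' timestamps are rejected; gaps on the 1 Hz grid are flagged in the
#' returned object's `gaps` table (records are retained, never filled).
#'
#' @param path Session file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return A [sensor_session()].
#' @export
read_session <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("no such session file: ", path),
      class = "sensoryrisk_io_error"
    )
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "csv") {
    if (length(lines) < 2) {
      abort(paste0("empty session file: ", path),
        class = "sensoryrisk_empty_session"
      )
    }
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (!setequal(header, .record_cols)) {
      abort(paste0(
        "header does not match the session schema; expected: ",
        paste(.record_cols, collapse = ",")
      ), class = "sensoryrisk_schema_error")
    }
    body <- strsplit(lines[-1], ",", fixed = TRUE)
    n_field <- lengths(body)
    if (any(n_field != length(header))) {
      bad <- which(n_field != length(header))[1]
      abort(sprintf("malformed row at line %d of %s", bad + 1L, path),
        class = "sensoryrisk_parse_error"
      )
    }
    mat <- do.call(rbind, body)
    colnames(mat) <- header
    rec <- tibble::as_tibble(mat)[.record_cols]
    for (col in .record_cols) {
      raw <- rec[[col]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & nzchar(raw))
      if (length(bad) > 0) {
        abort(sprintf(
          "non-numeric value '%s' in column %s at line %d of %s",
          raw[bad[1]], col, bad[1] + 1L, path
        ), class = "sensoryrisk_parse_error")
      }
      rec[[col]] <- val
    }
  } else {
    if (length(lines) == 0) {
      abort(paste0("empty session file: ", path),
        class = "sensoryrisk_empty_session"
      )
    }
    parsed <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(
        jsonlite::fromJSON(lines[i]),
        error = function(e) {
          abort(sprintf("malformed JSON at line %d of %s", i, path),
            class = "sensoryrisk_parse_error"
          )
        }
      )
      obj[vapply(obj, is.null, logical(1))] <- NA_real_
      obj
    })
    rec <- dplyr::bind_rows(lapply(parsed, function(x) {
      tibble::as_tibble(x[intersect(.record_cols, names(x))])
    }))
    missing_cols <- setdiff(.record_cols, names(rec))
    for (col in missing_cols) rec[[col]] <- NA_real_
    rec <- rec[.record_cols]
  }
  meta <- list()
  mp <- .meta_path(path)
  if (file.exists(mp)) meta <- jsonlite::fromJSON(mp)
  sensor_session(
    rec,
    child_id = meta$child_id %||% tools::file_path_sans_ext(basename(path)),
    gender = meta$gender %||% NA_character_,
    age = meta$age %||% NA_real_,
    task_accuracy = meta$task_accuracy %||% NA_real_,
    attention_label = meta$attention_label %||% NA_character_,
    stress_label = meta$stress_label %||% NA_character_,
    start_time = meta$start_time
  )
}

#' Carry missing channel values forward within a session
#'
#' Optional last-observation-carried-forward imputation, applied within a
#' single session only; leading `NA`s stay `NA`. Off by default everywhere:
#' downstream feature extraction refuses missing channels unless records
#' have been imputed explicitly.
#'
#' @param session A [sensor_session()].
#' @param channels Channels to impute (default: all data channels).
#' @return The session with imputed records.
#' @export
impute_locf <- function(session, channels = setdiff(.record_cols, "t")) {
  stopifnot(inherits(session, "sensor_session"))
  rec <- session$records
  for (col in channels) {
    x <- rec[[col]]
    ok <- !is.na(x)
    if (any(ok) && anyNA(x)) {
      idx <- cumsum(ok)
      fill <- c(NA_real_, x[ok])[idx + 1L]
      rec[[col]] <- fill
    }
  }
  session$records <- rec
  session
}

#' Plot the channels of a session
#'
#' @param object A [sensor_session()].
#' @param channels Channels to show.
#' @param ... Unused.
#' @return A ggplot object, channels faceted on free y scales.
#' @method autoplot sensor_session
#' @export
autoplot.sensor_session <- function(object,
                                    channels = c(
                                      "temp_c", "noise_db",
                                      "brightness_lx", "gsr", "hr_bpm"
                                    ),
                                    ...) {
  long <- tidyr::pivot_longer(
    object$records[c("t", channels)],
    -"t",
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "time since session start (s)", y = NULL,
      title = paste("Session", object$meta$child_id)
    )
}
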