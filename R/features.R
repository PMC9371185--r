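#' Canonical feature names
#'
#' The 14 predictors used by the attention and stress detectors, in fixed
#' order: five environmental channels, four sensory-profile quadrant scores,
#' three physiological measures (GSR, heart rate, and the mean absolute
#' value of the three accelerometer axes), and two personal characteristics.
#'
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c(
    "temperature", "noise", "humidity", "brightness", "air_pressure",
    .quadrants,
    "gsr", "heart_rate", "accel_mav",
    "gender", "age"
  )
}

#' Extract the per-sample feature table from a session
#'
#' One row per 1 Hz record with the 14 canonical predictors.
#' `accel_mav = (|ax| + |ay| + |az|) / 3`; gender is encoded
#' `male = 0, female = 1`. Missing channels raise an error naming the
#' channel unless the session has been imputed first (see [impute_locf()]).
#'
#' @param session A [sensor_session()].
#' @param profile A `sensory_profile` from [score_sensory_profile()].
#' @return A tibble with columns `t` plus [feature_names()].
#' @export
#' @examples
#' map <- load_profile_map()
#' prof <- score_sensory_profile(
#'   stats::setNames(rep(3, nrow(map)), map$item_id), map
#' )
#' rec <- tibble::tibble(
#'   t = 0:4, temp_c = 26, humidity_pct = 55, noise_db = 60,
#'   brightness_lx = 400, pressure_kpa = 101, gsr = 200, hr_bpm = 95,
#'   ax = 0.1, ay = -0.1, az = 0.1
#' )
#' s <- sensor_session(rec, "c01", gender = "male", age = 5)
#' extract_features(s, prof)
extract_features <- function(session, profile) {
  stopifnot(
    inherits(session, "sensor_session"),
    inherits(profile, "sensory_profile")
  )
  rec <- session$records
  data_cols <- setdiff(.record_cols, "t")
  na_counts <- vapply(rec[data_cols], function(x) sum(is.na(x)), integer(1))
  if (any(na_counts > 0)) {
    ch <- names(na_counts)[na_counts > 0][1]
    abort(paste0(
      "channel '", ch, "' has ", na_counts[[ch]],
      " missing value(s); impute explicitly (impute_locf) or drop the session"
    ), class = "sensoryrisk_missing_data_error")
  }
  meta <- session$meta
  if (is.na(meta$gender) || !meta$gender %in% c("male", "female")) {
    abort("session gender must be 'male' or 'female' for feature extraction",
      class = "sensoryrisk_validation_error"
    )
  }
  if (is.na(meta$age)) {
    abort("session age is required for feature extraction",
      class = "sensoryrisk_validation_error"
    )
  }
  q <- .profile_scores(profile)
  tibble::tibble(
    t = rec$t,
    temperature = rec$temp_c,
    noise = rec$noise_db,
    humidity = rec$humidity_pct,
    brightness = rec$brightness_lx,
    air_pressure = rec$pressure_kpa,
    low_registration = q[["low_registration"]],
    sensory_seeking = q[["sensory_seeking"]],
    sensory_sensitivity = q[["sensory_sensitivity"]],
    sensory_avoiding = q[["sensory_avoiding"]],
    gsr = rec$gsr,
    heart_rate = rec$hr_bpm,
    accel_mav = (abs(rec$ax) + abs(rec$ay) + abs(rec$az)) / 3,
    gender = if (meta$gender == "male") 0 else 1,
    age = meta$age
  )
}
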