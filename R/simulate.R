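# stimulus centers for the three controlled modalities, by regime level;
# moderate levels sit at the exemplar classroom values (400 lx, 26 degC,
# 60 dB), extremes at the values the risk engine labels Low/High
.regime_centers <- list(
  temperature = c("extreme-low" = 15, "moderate" = 26, "extreme-high" = 32),
  noise = c("extreme-low" = 40, "moderate" = 60, "extreme-high" = 80),
  brightness = c("extreme-low" = 100, "moderate" = 400, "extreme-high" = 750)
)

#' Define a controlled environment regime
#'
#' A regime fixes each of the three controlled modalities (temperature,
#' noise, brightness) at `"moderate"`, `"extreme-low"` or `"extreme-high"`,
#' plus humidity and air-pressure baselines. A regime is moderate overall
#' iff all three modalities are moderate.
#'
#' @param temperature,noise,brightness Level for each modality.
#' @param humidity_baseline Humidity baseline in percent.
#' @param pressure_baseline Air pressure baseline in kPa.
#' @param amplitude Named list of Gaussian jitter SDs per channel.
#' @return An `environment_regime` list.
#' @export
environment_regime <- function(temperature = "moderate",
                               noise = "moderate",
                               brightness = "moderate",
                               humidity_baseline = 55,
                               pressure_baseline = 101.3,
                               amplitude = list(
                                 temperature = 0.4, noise = 2,
                                 brightness = 20, humidity = 2,
                                 pressure = 0.1
                               )) {
  levels <- c("moderate", "extreme-low", "extreme-high")
  for (lev in list(temperature, noise, brightness)) {
    if (!lev %in% levels) {
      abort(paste0("unknown regime level: ", lev),
        class = "sensoryrisk_validation_error"
      )
    }
  }
  structure(
    list(
      temperature = temperature, noise = noise, brightness = brightness,
      humidity_baseline = humidity_baseline,
      pressure_baseline = pressure_baseline,
      amplitude = amplitude
    ),
    class = "environment_regime"
  )
}

#' Overall class of a regime
#'
#' @param regime An [environment_regime()].
#' @return `"moderate"` if all three controlled modalities are moderate,
#'   otherwise `"extreme"`.
#' @export
regime_class <- function(regime) {
  stopifnot(inherits(regime, "environment_regime"))
  if (all(c(regime$temperature, regime$noise, regime$brightness) ==
    "moderate")) {
    "moderate"
  } else {
    "extreme"
  }
}

#' Simulate environmental channel streams under a regime
#'
#' Each controlled modality is held at its regime center with Gaussian
#' jitter of the configured amplitude; humidity and pressure fluctuate
#' around their baselines. Reproducible under a fixed seed.
#'
#' @param regime An [environment_regime()].
#' @param length Number of 1 Hz samples (>= 1).
#' @param seed Integer seed.
#' @return Tibble with columns `t`, `temp_c`, `noise_db`, `brightness_lx`,
#'   `humidity_pct`, `pressure_kpa`.
#' @export
#' @examples
#' simulate_environment(environment_regime(), length = 5, seed = 1)
simulate_environment <- function(regime, length, seed = 1) {
  stopifnot(inherits(regime, "environment_regime"), length >= 1)
  set.seed(seed)
  amp <- regime$amplitude
  n <- as.integer(length)
  jitter <- function(center, sd) center + stats::rnorm(n, 0, sd)
  tibble::tibble(
    t = seq_len(n) - 1L,
    temp_c = jitter(
      .regime_centers$temperature[[regime$temperature]],
      amp$temperature
    ),
    noise_db = jitter(.regime_centers$noise[[regime$noise]], amp$noise),
    brightness_lx = pmax(0, jitter(
      .regime_centers$brightness[[regime$brightness]], amp$brightness
    )),
    humidity_pct = pmin(100, pmax(0, jitter(
      regime$humidity_baseline, amp$humidity
    ))),
    pressure_kpa = jitter(regime$pressure_baseline, amp$pressure)
  )
}

#' Simulation configuration
#'
#' Defaults mirror the acquisition protocol the simulator emulates:
#' 35 children, 15 sessions each, roughly 15 minutes at 1 Hz, and about
#' 42.6% of sessions carrying assessor labels (222 labelled out of 521
#' recorded). Physiological baselines are 90 bpm heart rate, 200 GSR sensor
#' units and 0.1 accelerometer mean absolute value, with additive per-level
#' offsets controlled by the gains.
#'
#' @param n_children Number of simulated children.
#' @param sessions_per_child Sessions per child.
#' @param session_length Session length in seconds (>= 60).
#' @param seed Master seed; each session derives its own RNG stream from
#'   (seed, child, session index) so adding or removing sessions does not
#'   perturb the others.
#' @param labelled_fraction Fraction of sessions carrying assessor labels.
#' @param label_noise Probability that a simulated assessor flips a latent
#'   label.
#' @param attention_threshold Task-accuracy cut above which latent attention
#'   is `"normal"`.
#' @param gains Named list of physiological response gains per unit latent
#'   stress index (0 = low, 1 = moderate, 2 = high) and for low attention:
#'   `gsr_stress`, `hr_stress`, `accel_stress`, `gsr_attention`,
#'   `hr_attention`, `accel_attention`.
#' @param baselines Named list: `gsr`, `hr`, `accel_mav`.
#' @param phys_noise Named list of per-second physiological jitter SDs.
#' @param accuracy_concentration Beta concentration for task accuracy.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_children = 35,
                              sessions_per_child = 15,
                              session_length = 900,
                              seed = 1,
                              labelled_fraction = 222 / 521,
                              label_noise = 0.05,
                              attention_threshold = 0.6,
                              gains = list(
                                gsr_stress = 40, hr_stress = 10,
                                accel_stress = 0.15,
                                gsr_attention = 20, hr_attention = 5,
                                accel_attention = 0.05
                              ),
                              baselines = list(
                                gsr = 200, hr = 90, accel_mav = 0.1
                              ),
                              phys_noise = list(
                                gsr = 5, hr = 2, accel = 0.02
                              ),
                              accuracy_concentration = 30) {
  stopifnot(
    n_children >= 1, sessions_per_child >= 1, session_length >= 60,
    labelled_fraction >= 0, labelled_fraction <= 1,
    label_noise >= 0, label_noise <= 1,
    attention_threshold > 0, attention_threshold < 1
  )
  structure(
    list(
      n_children = as.integer(n_children),
      sessions_per_child = as.integer(sessions_per_child),
      session_length = as.integer(session_length),
      seed = as.integer(seed),
      labelled_fraction = labelled_fraction,
      label_noise = label_noise,
      attention_threshold = attention_threshold,
      gains = gains, baselines = baselines, phys_noise = phys_noise,
      accuracy_concentration = accuracy_concentration
    ),
    class = "simulation_config"
  )
}

# deterministic per-session seed from (master, child, session); < 2^31
.session_seed <- function(master, child, sess) {
  as.integer((as.numeric(master) %% 100003 * 30011 +
    child * 523 + sess * 17) %% 2147483629)
}

# mean task accuracy: anchored above the attention threshold in moderate
# regimes, pulled below it under extreme regimes in proportion to the
# child's sensory-sensitivity score
.accuracy_mean <- function(config, regime, sensitivity) {
  base <- config$attention_threshold + 0.15
  if (regime_class(regime) == "extreme") {
    base <- base - 0.10 - 0.25 * sensitivity
  }
  min(0.95, max(0.05, base))
}

#' Simulate one child session with latent attention and stress
#'
#' The latent stress level follows the protocol's label scheme before any
#' assessor noise: relaxing in a moderate regime gives low stress, tasks in
#' moderate regimes moderate stress, and tasks in extreme regimes high
#' stress. Task accuracy is Beta-distributed with a mean that decreases
#' with the child's sensory-sensitivity score under extreme regimes; latent
#' attention is `"normal"` iff accuracy exceeds the configured threshold.
#' GSR, heart rate and movement rise with latent stress and with low
#' attention by the configured gains.
#'
#' @param profile A `sensory_profile`.
#' @param regime An [environment_regime()].
#' @param activity `"relaxing"` or `"task"`.
#' @param config A [simulation_config()].
#' @param seed Integer seed for this session.
#' @param child_id,gender,age Child metadata stored on the session.
#' @return A [sensor_session()] whose metadata carries the latent labels
#'   (before assessor noise) plus attribute `latent` with the latent state.
#' @export
simulate_child_session <- function(profile, regime,
                                   activity = c("task", "relaxing"),
                                   config = simulation_config(),
                                   seed = 1,
                                   child_id = "sim", gender = "male",
                                   age = 5) {
  activity <- match.arg(activity)
  stopifnot(
    inherits(profile, "sensory_profile"),
    inherits(regime, "environment_regime"),
    inherits(config, "simulation_config")
  )
  env <- simulate_environment(regime, config$session_length, seed = seed)
  set.seed(.session_seed(seed, 7L, 11L))
  n <- config$session_length
  stress <- assign_stress_label(activity, regime_class(regime))
  stress_idx <- c(low = 0, moderate = 1, high = 2)[[stress]]
  q <- .profile_scores(profile)
  if (activity == "task") {
    mu <- .accuracy_mean(config, regime, q[["sensory_sensitivity"]])
    k <- config$accuracy_concentration
    task_accuracy <- stats::rbeta(1, mu * k, (1 - mu) * k)
    attention <- assign_attention_label(
      task_accuracy, config$attention_threshold
    )
  } else {
    task_accuracy <- NA_real_
    attention <- "normal"
  }
  attn_idx <- if (attention == "low") 1 else 0
  g <- config$gains
  b <- config$baselines
  pn <- config$phys_noise
  gsr_mu <- b$gsr + g$gsr_stress * stress_idx + g$gsr_attention * attn_idx
  hr_mu <- b$hr + g$hr_stress * stress_idx + g$hr_attention * attn_idx
  mav_mu <- b$accel_mav + g$accel_stress * stress_idx +
    g$accel_attention * attn_idx
  rec <- tibble::tibble(
    t = env$t,
    temp_c = env$temp_c,
    humidity_pct = env$humidity_pct,
    noise_db = env$noise_db,
    brightness_lx = env$brightness_lx,
    pressure_kpa = env$pressure_kpa,
    gsr = pmax(0, gsr_mu + stats::rnorm(n, 0, pn$gsr)),
    hr_bpm = pmax(30, hr_mu + stats::rnorm(n, 0, pn$hr)),
    ax = mav_mu + stats::rnorm(n, 0, pn$accel),
    ay = mav_mu + stats::rnorm(n, 0, pn$accel),
    az = mav_mu + stats::rnorm(n, 0, pn$accel)
  )
  s <- sensor_session(rec,
    child_id = child_id, gender = gender, age = age,
    task_accuracy = task_accuracy
  )
  attr(s, "latent") <- list(
    activity = activity, regime_class = regime_class(regime),
    stress = stress, attention = attention
  )
  s
}

#' Generate a full labelled synthetic dataset
#'
#' Simulates `n_children x sessions_per_child` sessions following the
#' acquisition protocol: each child receives a random sensory profile and
#' cycles through (relaxing, moderate), (task, moderate) and (task,
#' extreme) conditions; a configurable fraction of sessions carries
#' (possibly noisy) assessor labels. Optionally writes every session plus a
#' `manifest.json` recording seed and configuration.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory for session files and the manifest.
#' @param format Session file format when writing.
#' @return A list with `sessions` (list of [sensor_session()]),
#'   `dataset` (per-sample labelled feature tibble with `session_id`,
#'   `child_id`, the 14 features, `task_accuracy`, latent and assessor
#'   labels), `profiles`, and `manifest`.
#' @export
generate_dataset <- function(config = simulation_config(),
                             out_dir = NULL, format = "csv") {
  stopifnot(inherits(config, "simulation_config"))
  map <- load_profile_map()
  conditions <- list(
    list(activity = "relaxing", extreme = FALSE),
    list(activity = "task", extreme = FALSE),
    list(activity = "task", extreme = TRUE)
  )
  extreme_choices <- expand.grid(
    modality = c("temperature", "noise", "brightness"),
    direction = c("extreme-low", "extreme-high"),
    stringsAsFactors = FALSE
  )
  sessions <- list()
  rows <- list()
  profiles <- list()
  for (child in seq_len(config$n_children)) {
    set.seed(.session_seed(config$seed, child, 0L))
    responses <- stats::setNames(
      sample(seq(map$min[1], map$max[1]), nrow(map), replace = TRUE),
      map$item_id
    )
    profile <- score_sensory_profile(responses, map)
    gender <- sample(c("male", "female"), 1, prob = c(29, 6) / 35)
    age <- round(stats::runif(1, 3, 8), 1)
    child_id <- sprintf("child%03d", child)
    profiles[[child_id]] <- profile
    for (sess in seq_len(config$sessions_per_child)) {
      sseed <- .session_seed(config$seed, child, sess)
      set.seed(sseed)
      cond <- conditions[[(sess - 1L) %% 3L + 1L]]
      if (cond$extreme) {
        pick <- extreme_choices[sample(nrow(extreme_choices), 1), ]
        args <- list(
          temperature = "moderate", noise = "moderate",
          brightness = "moderate"
        )
        args[[pick$modality]] <- pick$direction
        regime <- do.call(environment_regime, args)
      } else {
        regime <- environment_regime()
      }
      s <- simulate_child_session(profile, regime,
        activity = cond$activity,
        config = config, seed = sseed + 1L,
        child_id = child_id, gender = gender, age = age
      )
      latent <- attr(s, "latent")
      set.seed(sseed + 2L)
      labelled <- stats::runif(1) < config$labelled_fraction
      if (labelled) {
        attn <- latent$attention
        strs <- latent$stress
        if (stats::runif(1) < config$label_noise) {
          attn <- setdiff(c("low", "normal"), attn)
        }
        if (stats::runif(1) < config$label_noise) {
          strs <- sample(setdiff(c("low", "moderate", "high"), strs), 1)
        }
        s$meta$attention_label <- attn
        s$meta$stress_label <- strs
      }
      session_id <- sprintf("%s_s%02d", child_id, sess)
      sessions[[session_id]] <- s
      feat <- extract_features(s, profile)
      rows[[session_id]] <- dplyr::mutate(feat,
        session_id = session_id,
        child_id = child_id,
        activity = latent$activity,
        regime_class = latent$regime_class,
        task_accuracy = s$meta$task_accuracy,
        attention = latent$attention,
        stress = latent$stress,
        assessor_attention = s$meta$attention_label,
        assessor_stress = s$meta$stress_label,
        .before = 1
      )
    }
  }
  dataset <- dplyr::bind_rows(rows)
  manifest <- list(
    seed = config$seed,
    n_children = config$n_children,
    sessions_per_child = config$sessions_per_child,
    session_length = config$session_length,
    labelled_fraction = config$labelled_fraction,
    label_noise = config$label_noise,
    attention_threshold = config$attention_threshold,
    n_sessions = length(sessions),
    n_labelled = sum(!vapply(
      sessions, function(s) is.na(s$meta$attention_label), logical(1)
    ))
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) {
        abort(paste0("cannot create output directory: ", out_dir),
          class = "sensoryrisk_io_error"
        )
      }
    }
    ext <- if (format == "csv") ".csv" else ".jsonl"
    for (id in names(sessions)) {
      write_session(sessions[[id]], file.path(out_dir, paste0(id, ext)),
        format = format
      )
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(
    sessions = sessions, dataset = dataset,
    profiles = profiles, manifest = manifest
  )
}
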