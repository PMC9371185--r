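# shared fixtures, built in code at test time

make_records <- function(t = 0:9, noise_db = 60, brightness_lx = 400,
                         temp_c = 26, gsr = 200, hr_bpm = 95,
                         ax = 0.1, ay = 0.1, az = 0.1) {
  tibble::tibble(
    t = t, temp_c = temp_c, humidity_pct = 55, noise_db = noise_db,
    brightness_lx = brightness_lx, pressure_kpa = 101.3, gsr = gsr,
    hr_bpm = hr_bpm, ax = ax, ay = ay, az = az
  )
}

make_session <- function(..., child_id = "c01", gender = "male", age = 5,
                         task_accuracy = 0.8) {
  sensor_session(make_records(...),
    child_id = child_id, gender = gender,
    age = age, task_accuracy = task_accuracy
  )
}

flat_profile <- function(level = 3) {
  map <- load_profile_map()
  score_sensory_profile(
    stats::setNames(rep(level, nrow(map)), map$item_id), map
  )
}

# toy 4-item instrument, one item per quadrant, 1-5 Likert
toy_profile_map <- function() {
  tibble::tibble(
    item_id = c("i1", "i2", "i3", "i4"),
    quadrant = c(
      "low_registration", "sensory_seeking",
      "sensory_sensitivity", "sensory_avoiding"
    ),
    min = 1, max = 5
  )
}

# independent information-gain oracle (direct formula, no package code)
oracle_entropy <- function(labels) {
  p <- as.numeric(prop.table(table(labels)))
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_ig <- function(scores, labels, th) {
  n <- length(scores)
  left <- scores <= th
  h <- oracle_entropy(labels)
  for (side in list(left, !left)) {
    if (any(side)) h <- h - sum(side) / n * oracle_entropy(labels[side])
  }
  h
}

oracle_best_split <- function(scores, labels) {
  d <- sort(unique(scores))
  cand <- (d[-length(d)] + d[-1]) / 2
  gains <- vapply(cand, function(th) oracle_ig(scores, labels, th), numeric(1))
  list(threshold = cand[which.max(gains)], gain = max(gains))
}

# one small trained model per target, shared across detection/monitor tests
.tiny_fit_cache <- new.env(parent = emptyenv())

tiny_sim_config <- function(seed = 42) {
  simulation_config(
    n_children = 8, sessions_per_child = 6, session_length = 60,
    label_noise = 0, labelled_fraction = 1, seed = seed
  )
}

tiny_models <- function() {
  if (!is.null(.tiny_fit_cache$models)) {
    return(.tiny_fit_cache$models)
  }
  ds <- generate_dataset(tiny_sim_config())
  grids <- list(RF = tibble::tibble(num_trees = 100, max_depth = 0))
  att <- train_models(ds$dataset, "attention",
    grids = grids,
    families = "RF", seed = 9
  )
  str <- train_models(ds$dataset, "stress",
    grids = grids,
    families = "RF", seed = 9
  )
  .tiny_fit_cache$models <- list(
    attention = att$models$RF, stress = str$models$RF,
    data = ds
  )
  .tiny_fit_cache$models
}
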