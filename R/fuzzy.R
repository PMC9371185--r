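# risk terms in severity order; ties at categorisation break toward higher
.risk_terms <- c("Low Risk", "Medium Risk", "High Risk")

#' Membership functions
#'
#' Three shapes cover the engine: trapezoids (`a <= b <= c <= d`,
#' piecewise-linear 0 -> 1 -> 0; triangles are trapezoids with `b == c`),
#' Gaussians (`exp(-(x - mean)^2 / (2 sigma^2))`), and singletons for the
#' crisp categorical inputs (attention, stress). Parameters are validated
#' at construction, never at evaluation.
#'
#' @param a,b,c,d Trapezoid breakpoints.
#' @param mean,sigma Gaussian centre and width (`sigma > 0`).
#' @param value Singleton location.
#' @return A `membership_function`.
#' @name membership
NULL

#' @rdname membership
#' @export
mf_trapezoid <- function(a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    abort("trapezoid requires a <= b <= c <= d",
      class = "sensoryrisk_config_error"
    )
  }
  structure(list(shape = "trapezoid", params = c(a, b, c, d)),
    class = "membership_function"
  )
}

#' @rdname membership
#' @export
mf_gaussian <- function(mean, sigma) {
  if (sigma <= 0) {
    abort("gaussian sigma must be positive",
      class = "sensoryrisk_config_error"
    )
  }
  structure(list(shape = "gaussian", params = c(mean, sigma)),
    class = "membership_function"
  )
}

#' @rdname membership
#' @export
mf_singleton <- function(value) {
  structure(list(shape = "singleton", params = value),
    class = "membership_function"
  )
}

#' Membership degree
#'
#' @param mf A `membership_function`.
#' @param x Numeric vector (clamped to the variable's universe upstream).
#' @return Degrees in `[0, 1]`.
#' @export
mu <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  p <- mf$params
  switch(mf$shape,
    trapezoid = {
      a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
      up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= a)
      down <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= d)
      pmax(0, pmin(1, up, down))
    },
    gaussian = exp(-(x - p[1])^2 / (2 * p[2]^2)),
    singleton = as.numeric(abs(x - p[1]) < 1e-9)
  )
}

#' A linguistic variable
#'
#' An ordered set of named terms (e.g. Low/Moderate/High), one membership
#' function each, over a bounded universe. Inputs outside the universe are
#' clamped to its bounds before fuzzification.
#'
#' @param name Variable name.
#' @param terms Named list of `membership_function`s, in term order.
#' @param universe Length-2 numeric bounds.
#' @return A `linguistic_variable`.
#' @export
linguistic_variable <- function(name, terms, universe) {
  stopifnot(
    is.list(terms), length(terms) >= 1, !is.null(names(terms)),
    length(universe) == 2, universe[1] < universe[2]
  )
  structure(list(name = name, terms = terms, universe = universe),
    class = "linguistic_variable"
  )
}

#' Fuzzify a crisp value
#'
#' @param variable A [linguistic_variable()].
#' @param x Crisp value (clamped to the universe).
#' @return Named numeric vector of degrees, one per term.
#' @export
#' @examples
#' v <- linguistic_variable("risk", list(
#'   "Low Risk" = mf_trapezoid(0, 0, 0, 4),
#'   "High Risk" = mf_trapezoid(6, 10, 10, 10)
#' ), c(0, 10))
#' fuzzify(v, 7)
fuzzify <- function(variable, x) {
  stopifnot(inherits(variable, "linguistic_variable"), is.finite(x))
  x <- min(max(x, variable$universe[1]), variable$universe[2])
  vapply(variable$terms, mu, numeric(length(x)), x = x)
}

#' A fuzzy rule
#'
#' A conjunction of (variable is term) antecedents implying a risk term.
#'
#' @param antecedents Named character vector/list, variable -> term.
#' @param consequent One of the risk terms.
#' @return A `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedents, consequent) {
  antecedents <- unlist(antecedents)
  if (length(antecedents) == 0) {
    abort("a rule needs at least one antecedent",
      class = "sensoryrisk_config_error"
    )
  }
  if (!consequent %in% .risk_terms) {
    abort(paste0("consequent must be a risk term, got: ", consequent),
      class = "sensoryrisk_config_error"
    )
  }
  structure(list(antecedents = antecedents, consequent = consequent),
    class = "fuzzy_rule"
  )
}

#' Rule activation strength
#'
#' Conjunction is min: the strength is the minimum membership degree over
#' the rule's antecedents.
#'
#' @param rule A [fuzzy_rule()].
#' @param fuzzified Named list: variable -> named degree vector from
#'   [fuzzify()].
#' @return Strength in `[0, 1]`.
#' @export
activate <- function(rule, fuzzified) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  vars <- names(rule$antecedents)
  missing <- setdiff(vars, names(fuzzified))
  if (length(missing) > 0) {
    abort(paste0(
      "no fuzzified input for variable(s): ",
      paste(missing, collapse = ", ")
    ), class = "sensoryrisk_inference_error")
  }
  min(vapply(vars, function(v) {
    deg <- fuzzified[[v]]
    term <- rule$antecedents[[v]]
    if (!term %in% names(deg)) {
      abort(paste0("variable '", v, "' has no term '", term, "'"),
        class = "sensoryrisk_inference_error"
      )
    }
    deg[[term]]
  }, numeric(1)))
}

#' Aggregate clipped consequents (Mamdani max)
#'
#' Each rule's consequent membership is clipped at the rule's activation
#' strength; the aggregated output set is the pointwise max over rules,
#' sampled on a fixed grid of the output universe.
#'
#' @param strengths Named or unnamed numeric vector of rule strengths.
#' @param consequents Character vector of risk terms, aligned with
#'   `strengths`.
#' @param output A [linguistic_variable()] for the risk output.
#' @param grid_points Grid resolution (default 1001).
#' @return A `fuzzy_set`: list with grid `x`, membership `mu`, and an
#'   `empty` flag (all strengths zero).
#' @export
aggregate_rules <- function(strengths, consequents, output,
                            grid_points = 1001) {
  stopifnot(length(strengths) == length(consequents), length(strengths) >= 1)
  x <- seq(output$universe[1], output$universe[2], length.out = grid_points)
  agg <- numeric(grid_points)
  for (i in seq_along(strengths)) {
    if (strengths[i] > 0) {
      agg <- pmax(agg, pmin(strengths[i], mu(output$terms[[consequents[i]]], x)))
    }
  }
  structure(list(x = x, mu = agg, empty = all(strengths == 0)),
    class = "fuzzy_set"
  )
}

#' Defuzzify an aggregated output set
#'
#' LOM (largest of maximum) returns the largest output value whose
#' membership reaches the maximum of the aggregated set; centroid returns
#' the membership-weighted mean of the grid.
#'
#' @param set A `fuzzy_set` from [aggregate_rules()].
#' @param method `"LOM"` or `"centroid"`.
#' @return Crisp value on the output universe.
#' @export
defuzzify <- function(set, method = c("LOM", "centroid")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "fuzzy_set"))
  if (set$empty || max(set$mu) <= 0) {
    abort("cannot defuzzify an empty output set",
      class = "sensoryrisk_defuzzification_error"
    )
  }
  if (method == "LOM") {
    m <- max(set$mu)
    max(set$x[set$mu >= m - 1e-12])
  } else {
    sum(set$x * set$mu) / sum(set$mu)
  }
}

# risk category at a crisp value: argmax term membership, ties -> higher risk
.risk_category <- function(output, crisp) {
  deg <- fuzzify(output, crisp)[.risk_terms]
  m <- max(deg)
  # rev(): prefer the highest-risk term among ties
  names(deg)[length(deg) + 1 - which.max(rev(deg) >= m - 1e-12)]
}

# ---- controllers -----------------------------------------------------------

#' Build a fuzzy risk controller
#'
#' @param modality `"brightness"`, `"temperature"` or `"noise"`.
#' @param stimulus,duration,attention,stress,output
#'   [linguistic_variable()]s.
#' @param rules List of [fuzzy_rule()]s (the shipped engine uses 21 per
#'   controller).
#' @param grid_points Output grid resolution.
#' @return A `fuzzy_controller`.
#' @export
fuzzy_controller <- function(modality, stimulus, duration, attention,
                             stress, output, rules, grid_points = 1001) {
  structure(
    list(
      modality = modality,
      variables = list(
        stimulus = stimulus, duration = duration,
        attention = attention, stress = stress
      ),
      output = output, rules = rules, grid_points = grid_points
    ),
    class = "fuzzy_controller"
  )
}

#' @export
print.fuzzy_controller <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_controller> %s: %d rules, stimulus terms %s\n",
    x$modality, length(x$rules),
    paste(names(x$variables$stimulus$terms), collapse = "/")
  ))
  invisible(x)
}

.attention_points <- c(low = 0, normal = 1)
.stress_points <- c(low = 0, moderate = 0.5, high = 1)

#' Run one controller on crisp inputs
#'
#' Fuzzifies the inputs, activates all rules (min conjunction), aggregates
#' the clipped consequents (max), defuzzifies (LOM by default), categorises
#' the crisp risk and attaches the catalogue strategy for the (modality,
#' stimulus term, category) key. If no rule fires, the risk defaults to Low
#' with a warning.
#'
#' @param controller A [fuzzy_controller()].
#' @param stimulus Crisp stimulus value (lx, degC or dB).
#' @param duration_s Duration of the atypical response in seconds (>= 0).
#' @param attention `"low"` or `"normal"`.
#' @param stress `"low"`, `"moderate"` or `"high"`.
#' @param method Defuzzification method.
#' @param catalog Strategy catalogue from [load_strategy_catalog()].
#' @return A `risk_assessment`: list with `modality`, `crisp`, `category`,
#'   `stimulus_term`, `strategy`, `method`.
#' @export
#' @examples
#' ctrl <- load_fuzzy_controllers()$brightness
#' infer(ctrl, stimulus = 400, duration_s = 40,
#'       attention = "normal", stress = "low")
infer <- function(controller, stimulus, duration_s, attention, stress,
                  method = "LOM", catalog = load_strategy_catalog()) {
  stopifnot(
    inherits(controller, "fuzzy_controller"),
    duration_s >= 0
  )
  if (!attention %in% names(.attention_points)) {
    abort("attention must be 'low' or 'normal'",
      class = "sensoryrisk_validation_error"
    )
  }
  if (!stress %in% names(.stress_points)) {
    abort("stress must be 'low', 'moderate' or 'high'",
      class = "sensoryrisk_validation_error"
    )
  }
  fz <- list(
    stimulus = fuzzify(controller$variables$stimulus, stimulus),
    duration = fuzzify(controller$variables$duration, duration_s),
    attention = fuzzify(
      controller$variables$attention,
      .attention_points[[attention]]
    ),
    stress = fuzzify(
      controller$variables$stress,
      .stress_points[[stress]]
    )
  )
  strengths <- vapply(controller$rules, activate, numeric(1), fuzzified = fz)
  consequents <- vapply(
    controller$rules, function(r) r$consequent,
    character(1)
  )
  set <- aggregate_rules(strengths, consequents, controller$output,
    grid_points = controller$grid_points
  )
  if (set$empty) {
    warn(paste0(
      "no rule fired for ", controller$modality,
      " inputs; defaulting to Low Risk"
    ))
    crisp <- controller$output$universe[1]
    category <- "Low Risk"
  } else {
    crisp <- defuzzify(set, method)
    category <- .risk_category(controller$output, crisp)
  }
  stim_deg <- fz$stimulus
  stimulus_term <- names(stim_deg)[which.max(stim_deg)]
  strategy <- .lookup_strategy(
    catalog, controller$modality,
    stimulus_term, category
  )
  structure(
    list(
      modality = controller$modality,
      crisp = crisp, category = category,
      stimulus = stimulus, stimulus_term = stimulus_term,
      strategy = strategy, method = method
    ),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf(
    "<risk_assessment> %s = %.4g -> %s (risk %.2f, %s)\n  %s\n",
    x$modality, x$stimulus, x$stimulus_term, x$crisp, x$category, x$strategy
  ))
  invisible(x)
}

#' @method glance risk_assessment
#' @export
glance.risk_assessment <- function(x, ...) {
  tibble::tibble(
    modality = x$modality, stimulus = x$stimulus,
    stimulus_term = x$stimulus_term, crisp = x$crisp,
    category = x$category, strategy = x$strategy
  )
}

# ---- configuration ---------------------------------------------------------

.parse_mf <- function(spec) {
  p <- as.numeric(unlist(spec$params))
  switch(spec$shape,
    trapezoid = mf_trapezoid(p[1], p[2], p[3], p[4]),
    gaussian = mf_gaussian(p[1], p[2]),
    singleton = mf_singleton(p[1]),
    abort(paste0("unknown membership shape: ", spec$shape),
      class = "sensoryrisk_config_error"
    )
  )
}

.parse_variable <- function(name, spec) {
  terms <- purrr::map(spec$terms, .parse_mf)
  linguistic_variable(name, terms, as.numeric(spec$universe))
}

#' Load the three fuzzy controllers from a JSON configuration
#'
#' All membership parameters and rules live in one JSON file so that
#' alternative calibrations can be dropped in without code changes. The
#' bundled configuration is a documented reconstruction: its parameters are
#' chosen so that the canonical stimulus exemplars (100/400/750 lx,
#' 15/26/32 degC, 60/70/80 dB) land on their published level terms.
#'
#' @param path Configuration path; default is the bundled file.
#' @return Named list of three [fuzzy_controller()]s.
#' @export
load_fuzzy_controllers <- function(path = system.file("extdata",
                                     "fuzzy_config.json",
                                     package = "sensoryrisk"
                                   )) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  output <- .parse_variable("risk", cfg$output)
  duration <- .parse_variable("duration", cfg$duration)
  attention <- .parse_variable("attention", cfg$attention)
  stress <- .parse_variable("stress", cfg$stress)
  grid_points <- cfg$grid_points %||% 1001
  purrr::imap(cfg$controllers, function(cspec, modality) {
    stimulus <- .parse_variable(modality, cspec$stimulus)
    rules <- purrr::map(cspec$rules, function(r) {
      fuzzy_rule(r$`if`, r$then)
    })
    fuzzy_controller(modality, stimulus, duration, attention, stress,
      output, rules,
      grid_points = grid_points
    )
  })
}

#' Load the strategy catalogue
#'
#' Strategies are keyed by (modality, stimulus term, risk category).
#'
#' @param path Catalogue path; default is the bundled file.
#' @return Tibble with `modality`, `stimulus_term`, `category`, `strategy`.
#' @export
load_strategy_catalog <- function(path = system.file("extdata",
                                    "strategy_catalog.json",
                                    package = "sensoryrisk"
                                  )) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  purrr::map_dfr(raw, tibble::as_tibble)
}

.lookup_strategy <- function(catalog, modality, stimulus_term, category) {
  hit <- catalog$strategy[
    catalog$modality == modality &
      catalog$stimulus_term == stimulus_term &
      catalog$category == category
  ]
  if (length(hit) == 0) {
    return(paste0(
      modality, " level is ", tolower(stimulus_term),
      "; no catalogued strategy for ", category
    ))
  }
  hit[1]
}

# ---- duration tracking -----------------------------------------------------

#' Track the duration of atypical sensory responses
#'
#' Counts, per second, the consecutive run length for which the atypical
#' condition (attention low OR stress high) holds while the stimulus term
#' is non-Moderate; the counter resets to zero whenever the condition
#' clears.
#'
#' @param attention Per-second vector, `"low"`/`"normal"`.
#' @param stress Per-second vector, `"low"`/`"moderate"`/`"high"`.
#' @param stimulus_term Per-second stimulus term for the modality.
#' @return Integer vector of durations (seconds), aligned with the input.
#' @export
#' @examples
#' track_duration(rep("low", 5), rep("low", 5), rep("High", 5)) # 1..5
track_duration <- function(attention, stress, stimulus_term) {
  n <- length(attention)
  stopifnot(length(stress) == n, length(stimulus_term) == n)
  atypical <- (attention == "low" | stress == "high") &
    stimulus_term != "Moderate"
  duration <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (atypical[i]) run + 1L else 0L
    duration[i] <- run
  }
  duration
}

# ---- defuzzifier comparison ------------------------------------------------

#' Compare LOM and centroid defuzzification on a combination suite
#'
#' Runs every suite combination through the matching controller under both
#' methods and reports the fraction whose risk category matches the
#' expected outcome. The bundled suite has 21 combinations; LOM reproduces
#' all of them while centroid, which averages competing consequents, does
#' not.
#'
#' @param controllers Named controller list from
#'   [load_fuzzy_controllers()].
#' @param suite Tibble with columns `modality`, `stimulus`, `duration_s`,
#'   `attention`, `stress`, `expected_category`; default is the bundled
#'   suite ([load_defuzz_suite()]).
#' @param methods Defuzzification methods to compare.
#' @return List with `fractions` (named per method) and `detail` tibble.
#' @export
compare_defuzzifiers <- function(controllers,
                                 suite = load_defuzz_suite(),
                                 methods = c("LOM", "centroid")) {
  suite <- tibble::as_tibble(suite)
  if (nrow(suite) == 0) {
    abort("empty combination suite", class = "sensoryrisk_validation_error")
  }
  catalog <- load_strategy_catalog()
  detail <- purrr::map_dfr(methods, function(m) {
    purrr::pmap_dfr(suite, function(modality, stimulus, duration_s,
                                    attention, stress, expected_category,
                                    ...) {
      a <- infer(controllers[[modality]], stimulus, duration_s,
        attention, stress,
        method = m, catalog = catalog
      )
      tibble::tibble(
        method = m, modality = modality, stimulus = stimulus,
        duration_s = duration_s, attention = attention, stress = stress,
        expected_category = expected_category,
        category = a$category, crisp = a$crisp,
        match = a$category == expected_category
      )
    })
  })
  fractions <- detail |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(fraction = mean(.data$match), .groups = "drop")
  list(
    fractions = stats::setNames(fractions$fraction, fractions$method),
    detail = detail
  )
}

#' Load the bundled 21-combination defuzzifier test suite
#'
#' @param path Suite path; default the bundled file.
#' @return Tibble of input combinations with expected risk categories.
#' @export
load_defuzz_suite <- function(path = system.file("extdata",
                                "defuzz_suite.json",
                                package = "sensoryrisk"
                              )) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' The two-rule defuzzifier divergence scenario
#'
#' A minimal temperature controller with only two rules — high temperature
#' with a short duration is low risk, with a long duration high risk — and
#' a two-term duration variable whose Short and Long sets overlap. At a
#' high temperature with the duration approaching long, both rules fire:
#' centroid averages the competing consequents into the Medium Risk band,
#' while LOM commits to High Risk. This is the design argument for LOM when
#' missing a high-risk state is costlier than over-calling one.
#'
#' @param temperature Crisp temperature (default 32 degC).
#' @param duration_s Crisp duration (default 30 s, where the overlapping
#'   Short and Long terms fire equally).
#' @return Tibble with one row per method: crisp value and category.
#' @export
defuzz_demo_scenario <- function(temperature = 32, duration_s = 30) {
  cfg <- load_fuzzy_controllers()
  temp_var <- cfg$temperature$variables$stimulus
  output <- cfg$temperature$output
  duration <- linguistic_variable("duration", list(
    Short = mf_trapezoid(0, 0, 15, 35),
    Long = mf_trapezoid(25, 45, 600, 600)
  ), c(0, 600))
  rules <- list(
    fuzzy_rule(c(stimulus = "High", duration = "Short"), "Low Risk"),
    fuzzy_rule(c(stimulus = "High", duration = "Long"), "High Risk")
  )
  fz <- list(
    stimulus = fuzzify(temp_var, temperature),
    duration = fuzzify(duration, duration_s)
  )
  strengths <- vapply(rules, activate, numeric(1), fuzzified = fz)
  set <- aggregate_rules(
    strengths,
    vapply(rules, function(r) r$consequent, character(1)),
    output
  )
  purrr::map_dfr(c("LOM", "centroid"), function(m) {
    crisp <- defuzzify(set, m)
    tibble::tibble(
      method = m, crisp = crisp,
      category = .risk_category(output, crisp)
    )
  })
}

# ---- alerts ----------------------------------------------------------------

#' Build an alert payload for a high-risk assessment
#'
#' A message payload (recipient, modality, category, strategy, timestamp)
#' is produced iff the assessment is High Risk and a subscription is
#' active. Transport is out of scope: payloads are returned, not sent.
#'
#' @param assessment A `risk_assessment` from [infer()].
#' @param subscription Phone-number string (digits, optional leading `+`),
#'   or `NULL` for no subscription.
#' @param timestamp Timestamp to stamp on the payload.
#' @return A named list payload, or `NULL` when no alert is due.
#' @export
build_alert <- function(assessment, subscription = NULL, timestamp = 0) {
  stopifnot(inherits(assessment, "risk_assessment"))
  if (!is.null(subscription)) {
    if (!is.character(subscription) ||
      !grepl("^\\+?[0-9]{6,15}$", subscription)) {
      abort("subscription must be a phone-number string (6-15 digits)",
        class = "sensoryrisk_validation_error"
      )
    }
  }
  if (is.null(subscription) || assessment$category != "High Risk") {
    return(NULL)
  }
  list(
    recipient = subscription,
    modality = assessment$modality,
    category = assessment$category,
    strategy = assessment$strategy,
    timestamp = timestamp
  )
}

#' Plot the membership functions of a linguistic variable
#'
#' @param variable A [linguistic_variable()].
#' @param n Grid resolution.
#' @return A ggplot of all term memberships over the universe.
#' @export
plot_membership <- function(variable, n = 400) {
  x <- seq(variable$universe[1], variable$universe[2], length.out = n)
  df <- purrr::imap_dfr(variable$terms, function(mf, term) {
    tibble::tibble(x = x, term = term, mu = mu(mf, x))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$mu, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = variable$name, y = "membership",
      title = paste("Membership functions:", variable$name)
    )
}
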