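ctrl <- load_fuzzy_controllers()
catalog <- load_strategy_catalog()

test_that("membership degrees follow their closed forms", {
  tz <- mf_trapezoid(0, 1, 2, 3)
  expect_equal(mu(tz, 1.5), 1)
  expect_equal(mu(tz, 0.5), 0.5)
  expect_equal(mu(tz, -1), 0)
  expect_equal(mu(tz, 3), 0)
  g <- mf_gaussian(5, 2)
  expect_equal(mu(g, 5), 1)
  expect_equal(mu(g, 7), exp(-0.5))
  expect_error(mf_trapezoid(3, 2, 1, 0), class = "sensoryrisk_config_error")
  expect_error(mf_gaussian(0, -1), class = "sensoryrisk_config_error")
})

test_that("stimulus exemplars fuzzify to their published level terms", {
  argmax <- function(v, x) {
    deg <- fuzzify(ctrl[[v]]$variables$stimulus, x)
    names(deg)[which.max(deg)]
  }
  expect_equal(argmax("brightness", 100), "Low")
  expect_equal(argmax("brightness", 400), "Moderate")
  expect_equal(argmax("brightness", 750), "High")
  expect_equal(argmax("temperature", 15), "Low")
  expect_equal(argmax("temperature", 26), "Moderate")
  expect_equal(argmax("temperature", 32), "High")
  expect_equal(argmax("noise", 60), "Moderate")
  expect_equal(argmax("noise", 80), "High")
})

test_that("rule activation is the min over antecedent degrees", {
  r <- fuzzy_rule(c(stimulus = "High", duration = "Long"), "High Risk")
  fz <- list(
    stimulus = c(Low = 0, Moderate = 0, High = 0.7),
    duration = c(Short = 0, Medium = 0, Long = 0.4)
  )
  expect_equal(activate(r, fz), 0.4)
  fz$stimulus["High"] <- 0
  expect_equal(activate(r, fz), 0)
  fz$stimulus["High"] <- 1
  fz$duration["Long"] <- 1
  expect_equal(activate(r, fz), 1)
  expect_error(activate(r, fz["stimulus"]),
    class = "sensoryrisk_inference_error"
  )
})

test_that("aggregation is the pointwise max of clipped consequents", {
  out <- ctrl$brightness$output
  one <- aggregate_rules(1, "Medium Risk", out)
  expect_equal(max(one$mu), 1)
  expect_equal(one$x[which.max(one$mu)], 5)
  # a zero-strength rule contributes nothing
  two <- aggregate_rules(c(1, 0), c("Medium Risk", "High Risk"), out)
  expect_equal(two$mu, one$mu)
  # equal half-strength rules on disjoint consequents: bimodal at 0.5
  bi <- aggregate_rules(c(0.5, 0.5), c("Low Risk", "High Risk"), out)
  expect_equal(max(bi$mu), 0.5)
  expect_equal(bi$mu[bi$x == 0], 0.5)
  expect_equal(bi$mu[bi$x == 10], 0.5)
  expect_equal(bi$mu[bi$x == 5], 0)
})

test_that("defuzzification matches symmetry and largest-of-maximum identities", {
  out <- ctrl$brightness$output
  med <- aggregate_rules(1, "Medium Risk", out)
  expect_equal(defuzzify(med, "centroid"), 5)
  expect_equal(defuzzify(med, "LOM"), 5)
  # plateau at full membership on [6, 10]: LOM takes the largest point
  hi <- aggregate_rules(1, "High Risk", out)
  expect_equal(defuzzify(hi, "LOM"), 10)
  empty <- aggregate_rules(0, "Low Risk", out)
  expect_error(defuzzify(empty), class = "sensoryrisk_defuzzification_error")
})

test_that("the shipped engine instantiates 3 controllers of 21 rules each", {
  expect_length(ctrl, 3)
  expect_setequal(names(ctrl), c("brightness", "temperature", "noise"))
  for (c in ctrl) expect_length(c$rules, 21)
  # every rule consequent is a valid risk term
  for (c in ctrl) {
    cons <- vapply(c$rules, function(r) r$consequent, character(1))
    expect_true(all(cons %in% c("Low Risk", "Medium Risk", "High Risk")))
  }
})

table5 <- tibble::tibble(
  modality = c(
    "brightness", "brightness", "brightness",
    "temperature", "temperature", "temperature",
    "noise", "noise", "noise"
  ),
  stimulus = c(100, 400, 750, 15, 26, 32, 60, 70, 80),
  attention = c(
    "low", "normal", "normal", "normal", "normal", "low",
    "low", "normal", "low"
  ),
  stress = c(
    "high", "low", "high", "high", "moderate", "high",
    "low", "high", "moderate"
  ),
  duration_s = c(25, 40, 10, 10, 25, 40, 25, 10, 40),
  term = c(
    "Low", "Moderate", "High", "Low", "Moderate", "High",
    "Moderate", "Moderate", "High"
  ),
  category = c(
    "High Risk", "Low Risk", "Medium Risk", "Medium Risk", "Low Risk",
    "High Risk", "Low Risk", "Medium Risk", "High Risk"
  )
)

test_that("the nine published worked examples reproduce term and category", {
  for (i in seq_len(nrow(table5))) {
    row <- table5[i, ]
    a <- infer(ctrl[[row$modality]], row$stimulus, row$duration_s,
      row$attention, row$stress,
      catalog = catalog
    )
    expect_equal(a$stimulus_term, row$term,
      label = paste("term, row", i)
    )
    expect_equal(a$category, row$category,
      label = paste("category, row", i)
    )
  }
  # the benign exemplar advises "No impact"
  benign <- infer(ctrl$brightness, 400, 40, "normal", "low",
    catalog = catalog
  )
  expect_match(benign$strategy, "No impact")
})

test_that("risk is monotone in duration and stress over the crisp grid", {
  stress_lv <- c("low", "moderate", "high")
  rank <- c("Low Risk" = 1, "Medium Risk" = 2, "High Risk" = 3)
  cat_at <- function(m, x, d, a, s) {
    rank[[infer(ctrl[[m]], x, d, a, s, catalog = catalog)$category]]
  }
  stim <- list(
    brightness = c(100, 400, 750), temperature = c(15, 26, 32),
    noise = c(45, 60, 80)
  )
  durations <- c(5, 25, 45)
  for (m in names(stim)) {
    for (x in stim[[m]]) {
      for (a in c("low", "normal")) {
        for (s in stress_lv) { # duration never lowers risk
          cats <- vapply(
            durations, function(d) cat_at(m, x, d, a, s), numeric(1)
          )
          expect_true(all(diff(cats) >= 0))
        }
        for (d in durations) { # stress never lowers risk
          cats <- vapply(
            stress_lv, function(s) cat_at(m, x, d, a, s), numeric(1)
          )
          expect_true(all(diff(cats) >= 0))
        }
      }
    }
  }
})

test_that("controllers are independent across modalities", {
  base <- infer(ctrl$brightness, 400, 10, "normal", "low", catalog = catalog)
  # the noise stimulus plays no role in the brightness controller
  for (noise_val in c(40, 80, 110)) {
    noisy <- infer(ctrl$noise, noise_val, 40, "low", "high",
      catalog = catalog
    )
    again <- infer(ctrl$brightness, 400, 10, "normal", "low",
      catalog = catalog
    )
    expect_equal(again$crisp, base$crisp)
    expect_equal(again$category, base$category)
  }
})

test_that("duration tracking counts consecutive atypical seconds and resets", {
  d <- track_duration(rep("low", 25), rep("low", 25), rep("High", 25))
  expect_equal(d, 1:25)
  a <- c("low", "low", "normal", "low", "low")
  d2 <- track_duration(a, rep("low", 5), rep("High", 5))
  expect_equal(d2, c(1, 2, 0, 1, 2))
  # all-normal stream never accumulates
  d3 <- track_duration(rep("normal", 10), rep("low", 10), rep("High", 10))
  expect_equal(d3, rep(0, 10))
  # a Moderate stimulus term gates the counter
  d4 <- track_duration(rep("low", 5), rep("high", 5), rep("Moderate", 5))
  expect_equal(d4, rep(0, 5))
})

test_that("LOM reproduces the whole combination suite and centroid does not", {
  res <- compare_defuzzifiers(ctrl)
  expect_equal(nrow(load_defuzz_suite()), 21)
  expect_equal(unname(res$fractions[["LOM"]]), 1)
  expect_lt(res$fractions[["centroid"]], 1)
  expect_error(
    compare_defuzzifiers(ctrl, suite = load_defuzz_suite()[0, ]),
    class = "sensoryrisk_validation_error"
  )
})

test_that("the two-rule scenario splits the defuzzifiers across risk bands", {
  demo <- defuzz_demo_scenario()
  expect_equal(demo$category[demo$method == "LOM"], "High Risk")
  expect_equal(demo$category[demo$method == "centroid"], "Medium Risk")
})

test_that("alerts fire only for subscribed high-risk assessments", {
  high <- infer(ctrl$temperature, 32, 40, "low", "high", catalog = catalog)
  low <- infer(ctrl$brightness, 400, 10, "normal", "low", catalog = catalog)
  payload <- build_alert(high, "+8613712345678", timestamp = 42)
  expect_equal(payload$modality, "temperature")
  expect_equal(payload$timestamp, 42)
  expect_match(payload$strategy, "deep pressure")
  expect_null(build_alert(low, "+8613712345678"))
  expect_null(build_alert(high, NULL))
  expect_error(build_alert(high, "not-a-number"),
    class = "sensoryrisk_validation_error"
  )
})
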