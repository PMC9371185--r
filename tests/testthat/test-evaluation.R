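test_that("report-form subscales are sums of their 0/1/2 items", {
  items <- ctrf_synthetic_items()
  zeros <- score_ctrf(stats::setNames(rep(0, 20), names(items)), items)
  expect_equal(zeros$score, c(0, 0))
  twos <- score_ctrf(stats::setNames(rep(2, 20), names(items)), items)
  expect_equal(twos$score[twos$subscale == "attention"], 20)
  # mixed toy form on a 4-item subscale
  toy <- stats::setNames(rep("attention", 4), paste0("q", 1:4))
  mixed <- score_ctrf(c(q1 = 1, q2 = 0, q3 = 2, q4 = 1), toy)
  expect_equal(mixed$score, 4)
  expect_error(
    score_ctrf(c(q1 = 3, q2 = 0, q3 = 0, q4 = 0), toy),
    class = "sensoryrisk_validation_error"
  )
  expect_error(
    score_ctrf(c(q1 = 1), toy),
    class = "sensoryrisk_validation_error"
  )
})

test_that("SUS scoring matches its closed forms and the published group means", {
  expect_equal(score_sus(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(score_sus(rep(3, 10)), 50)
  asd <- c(3.87, 1.67, 3.67, 3.73, 4.20, 1.07, 3.53, 1.13, 3.33, 2.80)
  td <- c(3.67, 2.07, 3.73, 3.93, 4.33, 1.07, 3.40, 1.20, 3.40, 2.93)
  expect_equal(round(score_sus(asd), 1), 70.5)
  expect_equal(round(score_sus(td), 1), 68.3)
  expect_error(score_sus(rep(3, 9)), class = "sensoryrisk_validation_error")
  expect_error(score_sus(c(rep(3, 9), 6)),
    class = "sensoryrisk_validation_error"
  )
})

test_that("SUS of item means equals the mean of per-respondent scores", {
  set.seed(5)
  for (i in 1:10) {
    cohort <- matrix(sample(1:5, 10 * 12, replace = TRUE), ncol = 10)
    per_person <- apply(cohort, 1, score_sus)
    expect_equal(score_sus(colMeans(cohort)), mean(per_person))
  }
})

test_that("effect sizes reproduce the published session contrasts", {
  # ASD group: attention (caregiver, teacher), stress (caregiver, teacher)
  asd <- list(
    list(8.1, 3.5, 6.5, 2.8, 0.505, "moderate"),
    list(8.6, 2.8, 7.0, 2.9, 0.561, "moderate"),
    list(4.3, 3.5, 3.4, 3.3, 0.265, "small"),
    list(4.9, 4.0, 3.7, 3.4, 0.323, "small")
  )
  td <- list(
    list(1.6, 1.6, 1.5, 1.5, 0.065, "negligible"),
    list(2.0, 2.0, 1.8, 2.0, 0.100, "negligible"),
    list(1.6, 1.9, 1.2, 1.8, 0.216, "small"),
    list(1.5, 1.9, 1.3, 1.6, 0.114, "negligible")
  )
  for (case in c(asd, td)) {
    es <- cohens_d(case[[1]], case[[2]], case[[3]], case[[4]])
    # printed summaries are rounded to one decimal, so agreement is to
    # within one unit in the third decimal of d
    expect_lt(abs(es$d - case[[5]]), 1e-3)
    expect_equal(es$magnitude, case[[6]])
  }
})

test_that("effect sizes are antisymmetric and scale-invariant", {
  a <- cohens_d(10, 2, 7, 3)
  b <- cohens_d(7, 3, 10, 2)
  expect_equal(a$d, -b$d)
  scaled <- cohens_d(10 * 4, 2 * 4, 7 * 4, 3 * 4)
  expect_equal(a$d, scaled$d)
  zero <- cohens_d(5, 1, 5, 1)
  expect_equal(zero$d, 0)
  expect_equal(zero$magnitude, "negligible")
  expect_error(cohens_d(1, 0, 2, 0), class = "sensoryrisk_validation_error")
})

test_that("the paired t statistic matches hand arithmetic and stats::t.test", {
  res <- paired_t(c(1, 1, 1, 3))
  expect_equal(res$t, 3)
  expect_equal(res$mean_diff, 1.5)
  expect_equal(res$sd_diff, 1)
  null <- paired_t(rep(0, 6))
  expect_equal(null$t, 0)
  expect_equal(null$p_two_tailed, 1)
  set.seed(9)
  d <- rnorm(15, 0.5)
  ref <- stats::t.test(d)
  mine <- paired_t(d)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p_two_tailed, ref$p.value)
})

test_that("the paired t p-value agrees with a permutation oracle", {
  set.seed(13)
  d <- c(0.9, 1.4, -0.2, 0.7, 1.1, 0.3, -0.5, 0.8, 1.3, 0.2)
  p_t <- paired_t(d)$p_two_tailed
  # sign-flip permutation distribution of |t|
  obs <- abs(mean(d) / (sd(d) / sqrt(length(d))))
  flips <- expand.grid(rep(list(c(-1, 1)), length(d)))
  perm_t <- apply(flips, 1, function(s) {
    x <- d * s
    abs(mean(x) / (sd(x) / sqrt(length(x))))
  })
  p_perm <- mean(perm_t >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("session summaries recover known cohort means", {
  cohort <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:6),
    session = c("no-SMRS", "SMRS#1", "SMRS#2")
  )
  means <- c("no-SMRS" = 8, "SMRS#1" = 9, "SMRS#2" = 6)
  cohort$ctrf_attention_caregiver <- means[cohort$session]
  cohort$wrong_attention <- ifelse(cohort$session == "no-SMRS", NA, 12)
  s <- summarize_sessions(cohort, group = "ASD")
  got <- s[s$measure == "ctrf_attention_caregiver", ]
  expect_equal(
    got$mean[match(names(means), got$session)], unname(means)
  )
  expect_equal(unique(got$sd), 0)
  # single participant: SD flagged, not NA
  one <- summarize_sessions(cohort[cohort$participant == "p01", ], "ASD")
  expect_true(all(one$small_n))
  expect_true(all(one$sd == 0))
  expect_error(summarize_sessions(cohort[0, ]),
    class = "sensoryrisk_validation_error"
  )
})

test_that("the effect-size table contrasts baseline and assisted sessions", {
  set.seed(4)
  cohort <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:20),
    session = c("no-SMRS", "SMRS#2")
  )
  cohort$ctrf_stress_teacher <- rnorm(
    40, ifelse(cohort$session == "no-SMRS", 5, 3.5), 1.5
  )
  s <- summarize_sessions(cohort, group = "ASD")
  tab <- effect_size_table(s)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$d, 0)
  a <- s[s$session == "no-SMRS", ]
  b <- s[s$session == "SMRS#2", ]
  expect_equal(
    tab$d, cohens_d(a$mean, a$sd, b$mean, b$sd)$d
  )
})
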