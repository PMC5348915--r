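test_that("the packaged group table carries the five cohort groups", {
  specs <- read_group_specs()
  expect_setequal(names(specs),
                  c("RC S-E", "RC E-E", "RC S-S", "BC S-E", "BC S-S"))
  expect_equal(specs[["RC S-E"]]$n, 32)
  expect_equal(specs[["RC S-E"]]$mean$age, 60)
  expect_equal(specs[["BC S-E"]]$freq$female, 0.86)
  expect_equal(sum(vapply(specs, `[[`, 1, "n")), 60)
})

test_that("the generator is seed-reproducible and honours n = 0", {
  spec <- read_group_specs()[["RC S-E"]]
  expect_error(generate_cohort(spec), "seed")
  expect_length(generate_cohort(spec, seed = 1, n = 0), 0)
  a <- generate_cohort(spec, seed = 42, n = 5)
  b <- generate_cohort(spec, seed = 42, n = 5)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 43, n = 5)
  expect_false(identical(a, c))
})

test_that("cohort moments recover the group specification (n = 1000)", {
  spec <- read_group_specs()[["RC S-E"]]
  n <- 1000
  cohort <- generate_cohort(spec, seed = 7, n = n)
  get <- function(f) vapply(cohort, function(e) e$patient[[f]], 1)
  within_3se <- function(x, mean, sd) abs(mean(x) - mean) < 3 * sd / sqrt(n)
  expect_true(within_3se(get("age"), spec$mean$age, spec$sd$age))
  expect_true(within_3se(get("height"), spec$mean$height, spec$sd$height))
  expect_true(within_3se(get("weight"), spec$mean$weight, spec$sd$weight))
  expect_true(within_3se(get("hematocrit"), spec$mean$hematocrit,
                         spec$sd$hematocrit))
  # flag frequencies within 3 binomial SEs
  female <- mean(vapply(cohort, function(e) e$patient$sex == "female", TRUE))
  expect_lt(abs(female - spec$freq$female),
            3 * sqrt(spec$freq$female * (1 - spec$freq$female) / n))
  # every draw respects the type invariants (truncation bounds)
  expect_true(all(get("hematocrit") > 0 & get("hematocrit") < 70))
  expect_true(all(vapply(cohort, function(e)
    e$patient$systolic_pressure > e$patient$diastolic_pressure, TRUE)))
  # synthetic DUS values present and positive for every protocol site
  expect_true(all(vapply(cohort, function(e)
    all(e$dus$arterial_diameters > 0) &&
      length(e$dus$arterial_diameters) == length(dus_sites()$arterial), TRUE)))
})

test_that("the QC filter reproduces the exclusion rule on a constructed
           follow-up table", {
  rec <- function(b, r, u, distal = TRUE)
    follow_up_record(b, r, u, distal = distal)
  records12 <- list(
    pass1 = rec(400, 200, 150),          # 400 >= 350
    pass2 = rec(600, 300, 250),
    pass3 = rec(350, 200, 150),          # boundary: equal is consistent
    pass4 = rec(800, NULL, NULL, distal = FALSE),  # proximal AVF
    pass5 = rec(500, 250, 100),
    pass6 = rec(900, 500, 300),
    pass7 = rec(450, 300, 100),
    incon1 = rec(300, 250, 100),         # 300 < 350
    incon2 = rec(500, 400, 200),
    incon3 = rec(200, 150, 100),
    incom1 = rec(300, NULL, 100),        # radial missing on a distal AVF
    incom2 = rec(NA, 200, 100))          # brachial missing
  out <- lapply(records12, qc_follow_up)
  fails <- names(out)[!vapply(out, `[[`, TRUE, "pass")]
  expect_setequal(fails, c("incon1", "incon2", "incon3", "incom1", "incom2"))
  expect_equal(unname(vapply(out[c("incon1", "incon2", "incon3")],
                             `[[`, "", "reason")),
               rep("inconsistent", 3))
  expect_equal(unname(vapply(out[c("incom1", "incom2")], `[[`, "", "reason")),
               rep("incomplete", 2))
  # independent recount with a plain predicate
  recount <- sum(vapply(records12, function(r) {
    miss <- function(x) is.null(x) || !is.finite(x)
    miss(r$brachial_bfv) ||
      (r$distal && (miss(r$radial_bfv) || miss(r$ulnar_bfv) ||
                      r$brachial_bfv < r$radial_bfv + r$ulnar_bfv))
  }, TRUE))
  expect_equal(length(fails), recount)
})

test_that("QC is a pure predicate that commutes with concatenation", {
  set.seed(11)
  make <- function() follow_up_record(runif(1, 200, 900), runif(1, 50, 500),
                                      runif(1, 50, 400))
  a <- replicate(10, make(), simplify = FALSE)
  b <- replicate(10, make(), simplify = FALSE)
  res_concat <- vapply(c(a, b), function(r) qc_follow_up(r)$pass, TRUE)
  res_sep <- c(vapply(a, function(r) qc_follow_up(r)$pass, TRUE),
               vapply(b, function(r) qc_follow_up(r)$pass, TRUE))
  expect_identical(res_concat, res_sep)
})

test_that("regression statistics match the normal-equations oracle on 100
           random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    meas <- runif(n, 300, 1200)
    pred <- 0.8 * meas + rnorm(n, 0, 120) + 50
    got <- regression_stats(pred, meas)
    want <- ols_oracle(pred, meas)
    expect_equal(got$slope, unname(want$slope), tolerance = 1e-10)
    expect_equal(got$intercept, unname(want$intercept), tolerance = 1e-10)
    expect_equal(got$r, unname(want$r), tolerance = 1e-10)
    expect_equal(got$p_value, unname(want$p), tolerance = 1e-10)
  }
})

test_that("regression degenerate cases behave as documented", {
  m <- c(100, 200, 300, 400)
  r <- regression_stats(m, m)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(regression_stats(-m + 50, m)$r, -1)
  expect_error(regression_stats(m, m[1:3]), "equal length")
  expect_error(regression_stats(m, rep(5, 4)), "zero variance")
  expect_error(regression_stats(m[1:2], m[1:2]), "at least 3")
})

test_that("Bland-Altman statistics match hand/sort-based oracles", {
  # hand-evaluated two-pair case
  ba <- bland_altman_stats(c(110, 90), c(100, 100))
  expect_equal(ba$percent_difference, c(10, -10))
  expect_equal(ba$mean_percent_difference, 0)
  expect_equal(ba$sd_percent_difference, sqrt(200), tolerance = 1e-12)
  expect_equal(unname(ba$limits_of_agreement),
               c(-1.96, 1.96) * sqrt(200), tolerance = 1e-12)
  expect_equal(ba$pair_average, c(105, 95))

  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    meas <- runif(n, 300, 1200)
    pred <- meas * exp(rnorm(n, 0, 0.2))
    ba <- bland_altman_stats(pred, meas)
    pd <- 100 * (pred - meas) / meas
    pr <- 100 * pred / meas
    expect_equal(ba$mean_percent_difference, sum(pd) / n, tolerance = 1e-10)
    expect_equal(ba$sd_percent_difference,
                 sqrt(sum((pd - sum(pd) / n)^2) / (n - 1)), tolerance = 1e-10)
    expect_equal(unname(ba$ratio_quartiles),
                 c(quantile7_oracle(pr, 0.25), quantile7_oracle(pr, 0.5),
                   quantile7_oracle(pr, 0.75)), tolerance = 1e-10)
    expect_true(ba$ratio_quartiles["q1"] <= ba$ratio_quartiles["median"])
    expect_true(ba$ratio_quartiles["median"] <= ba$ratio_quartiles["q3"])
    expect_equal(ba$ratio_min, min(pr))
    expect_equal(ba$ratio_max, max(pr))
  }
  expect_error(bland_altman_stats(c(1, 2), c(0, 1)), "positive")
})

test_that("identical predicted and measured series give perfect agreement", {
  x <- c(700, 800, 650, 900)
  ba <- bland_altman_stats(x, x)
  expect_equal(ba$mean_percent_difference, 0)
  expect_true(all(ba$percent_ratio == 100))
})

test_that("noise-free in-silico validation is exact: R = 1, 0% difference", {
  specs <- read_group_specs()[c("RC S-E", "BC S-E")]
  v <- in_silico_validation(specs, seed = 5, settings = quick_settings(),
                            noise_sigma = 0, n_per_group = 2)
  expect_equal(v$regression$r, 1, tolerance = 1e-12)
  expect_equal(v$regression$slope, 1, tolerance = 1e-9)
  expect_equal(v$bland_altman$mean_percent_difference, 0)
  expect_equal(v$qc$n_excluded, 0)
})

test_that("in-silico validation recovers the injected measurement noise on
           the full five-group cohort of 60", {
  v <- in_silico_validation(read_group_specs(), seed = 23,
                            settings = quick_settings(), noise_sigma = 0.2)
  expect_equal(v$qc$n_total, 60)
  # the SD of percent differences estimates the injected lognormal sigma
  sd_expected <- 100 * sqrt((exp(0.2^2) - 1) * exp(0.2^2))
  expect_lt(abs(v$bland_altman$sd_percent_difference - sd_expected) /
              sd_expected, 0.30)
  # QC rejection bookkeeping matches an independent recount
  expect_equal(v$qc$n_excluded, sum(!v$table$qc_pass))
  expect_equal(v$n + v$qc$n_excluded, v$qc$n_total)
})
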