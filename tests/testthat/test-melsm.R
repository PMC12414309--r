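test_that("potential scale reduction behaves as defined", {
  # identical chains: at or just below 1
  expect_lte(psr(list(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(psr(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  # separated means strictly increase it
  expect_gt(psr(list(c(1, 2, 3), c(101, 102, 103))),
            psr(list(c(1, 2, 3), c(1, 2, 3))))
  # zero within-chain variance with equal means: defined as 1
  expect_equal(psr(list(rep(2, 5), rep(2, 5))), 1)
  # long iid chains sit at 1
  set.seed(42)
  expect_equal(psr(list(rnorm(10000), rnorm(10000))), 1, tolerance = 0.02)
})

test_that("credibility intervals use linear-interpolation quantiles", {
  draws <- matrix(as.numeric(1:100), ncol = 1, dimnames = list(NULL, "b"))
  ci <- credibility_intervals(draws, level = 0.95)
  expect_equal(ci$lower, 3.475)
  expect_equal(ci$upper, 97.525)
  expect_true(ci$significant)
  sym <- matrix(c(-(1:50), 1:50), ncol = 1, dimnames = list(NULL, "b"))
  expect_false(credibility_intervals(sym)$significant)
  expect_error(credibility_intervals(matrix(1:50, ncol = 1)), "100")
})

test_that("sampler is seeded-deterministic and rejects degenerate input", {
  coh <- small_cohort()
  lat <- attr(coh, "latent")
  between <- dplyr::transmute(lat, person_id, g, s_int, s_ext)
  ctl <- melsm_control(iter = 300, seed = 8)
  f1 <- fit_melsm(coh$nights, between, outcomes = "duration", control = ctl)
  f2 <- fit_melsm(coh$nights, between, outcomes = "duration", control = ctl)
  expect_identical(f1$draws, f2$draws)

  one <- coh$nights[coh$nights$person_id == coh$nights$person_id[1], ]
  expect_error(
    fit_melsm(one, between[between$person_id == one$person_id[1], ],
              outcomes = "duration", control = ctl),
    "two persons")
})

test_that("collapsed homoscedastic model matches REML random-intercept fit", {
  cfg <- default_paper_config(n_persons = 150L, seed = 11L)
  cfg$invalid_fraction <- 0
  coh <- generate_cohort(cfg)
  lat <- attr(coh, "latent")
  between <- dplyr::transmute(lat, person_id, g, s_int, s_ext)
  fit <- fit_melsm(coh$nights, between, outcomes = "duration",
                   control = melsm_control(iter = 1500, seed = 2),
                   heteroscedastic = FALSE)
  s <- summary(fit)
  d <- coh$nights
  for (v in c("g", "s_int", "s_ext")) d[[v]] <- lat[[v]][match(d$person_id, lat$person_id)]
  m <- lme4::lmer(duration_min ~ night_index + weekend + g + s_int + s_ext +
                    (1 | person_id), data = d)
  fe <- lme4::fixef(m)
  chk <- c("mean_duration~intercept" = "(Intercept)",
           "mean_duration~g" = "g", "mean_duration~s_int" = "s_int",
           "mean_duration~s_ext" = "s_ext",
           "within_duration~night_index" = "night_index",
           "within_duration~weekend" = "weekend")
  for (lab in names(chk)) {
    row <- s[s$label == lab, ]
    expect_lt(abs(row$estimate - fe[[chk[[lab]]]]), 2 * row$post_sd)
  }
})

test_that("within-level weekend effect is recovered", {
  cfg <- default_paper_config(n_persons = 200L, seed = 23L)
  coh <- generate_cohort(cfg)
  lat <- attr(coh, "latent")
  between <- dplyr::transmute(lat, person_id, g, s_int, s_ext)
  fit <- fit_melsm(coh$nights, between, outcomes = "waketime",
                   control = melsm_control(iter = 1200, seed = 4))
  s <- summary(fit)
  row <- s[s$label == "within_waketime~weekend", ]
  expect_lt(abs(row$estimate - cfg$gamma_weekend[3]), 3 * row$post_sd)
  expect_true(row$significant)   # a 60-minute shift is unmissable
})

test_that("standardization preserves null and identity effects", {
  # hand-built posterior: one equation, one predictor with unit-variance x
  n_draws <- 200
  X <- cbind(intercept = 1, g = as.numeric(scale(rnorm(500))))
  make_fit <- function(b, psi) {
    draws <- cbind(`mean_duration~intercept` = rep(0, n_draws),
                   `mean_duration~g` = rep(b, n_draws),
                   `psi[mean_duration,mean_duration]` = rep(psi, n_draws))
    structure(list(draws = list(draws, draws), eq = "mean_duration",
                   predictors = c("intercept", "g"), X = X,
                   outcomes = "duration", heteroscedastic = TRUE),
              class = "melsm_fit")
  }
  # b = 0 -> beta = 0
  b0 <- standardize_effects(make_fit(0, 2))
  expect_equal(b0$beta, 0)
  # b = 1 with SD(x) = SD(y): explained variance 1, psi ~ 0 -> beta = 1
  b1 <- standardize_effects(make_fit(1, 1e-12))
  expect_equal(b1$beta, 1, tolerance = 1e-5)
})

test_that("convergence doubling reports two PSR snapshots and fails loudly", {
  coh <- small_cohort()
  lat <- attr(coh, "latent")
  between <- dplyr::transmute(lat, person_id, g)
  fit <- converge_and_double(coh$nights, between, outcomes = "duration",
                             control = melsm_control(iter = 500, seed = 6))
  expect_named(fit$convergence,
               c("psr_initial", "psr_doubled", "iter_initial", "iter_final"))
  expect_equal(fit$convergence$iter_final, 2L * fit$convergence$iter_initial)
  expect_lt(max(fit$convergence$psr_doubled),
            max(fit$convergence$psr_initial) + 0.02)

  # perfectly collinear predictors cannot converge within the round cap
  bad <- dplyr::mutate(between, g2 = g)
  expect_error(
    converge_and_double(coh$nights, bad, outcomes = "duration",
                        control = melsm_control(iter = 60, seed = 6),
                        max_rounds = 1L),
    "PSR threshold")
})

test_that("icc recovers limiting variance splits and rejects degenerate data", {
  set.seed(5)
  mk <- function(sd_b, sd_w, n = 300, t = 10) {
    tibble::tibble(
      person_id = rep(sprintf("p%03d", 1:n), each = t),
      night_index = rep(0:(t - 1), n), weekend = 0,
      duration_min = rep(rnorm(n, 400, sd_b), each = t) + rnorm(n * t, 0, sd_w),
      bedtime_min = NA_real_, waketime_min = NA_real_
    )
  }
  expect_lt(icc(mk(0, 50), "duration"), 0.03)
  expect_equal(icc(mk(50, 50), "duration"), 0.5, tolerance = 0.1)
  deg <- mk(50, 50, n = 50, t = 1)
  expect_error(icc(deg, "duration"), "two or more nights")
})
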