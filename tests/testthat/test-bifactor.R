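test_that("rater aggregation averages available z-scores", {
  set.seed(1)
  n <- 50
  profiles <- tibble::tibble(person_id = as.character(1:n))
  for (f in facet_names) {
    profiles[[paste0(f, "_cg")]] <- rnorm(n, 50, 10)
    profiles[[paste0(f, "_yr")]] <- rnorm(n, 50, 10)
  }
  panel <- aggregate_raters(profiles)
  zcg <- scale(profiles$ad_cg)[, 1]; zyr <- scale(profiles$ad_yr)[, 1]
  agg <- (zcg + zyr) / 2
  expect_equal(cor(panel$ad, agg), 1, tolerance = 1e-12)
  expect_equal(mean(panel$ad), 0, tolerance = 1e-12)
  expect_equal(sd(panel$ad), 1, tolerance = 1e-12)

  # one missing rater: available rater's z-score stands alone
  profiles$wd_yr <- NA_real_
  panel2 <- aggregate_raters(profiles)
  expect_equal(cor(panel2$wd, scale(profiles$wd_cg)[, 1]), 1, tolerance = 1e-12)

  # identical rater columns agree perfectly with either
  profiles$som_yr <- profiles$som_cg
  panel3 <- aggregate_raters(profiles)
  expect_equal(cor(panel3$som, profiles$som_cg), 1, tolerance = 1e-12)

  # a facet with no data at all is an error naming the facet
  profiles$eri_cg <- NA_real_; profiles$eri_yr <- NA_real_
  expect_error(aggregate_raters(profiles), "eri")
})

test_that("model df counts moments minus free parameters", {
  expect_equal(model_df(bifactor_s1_spec()), 10L)

  # saturated covariance model: no factors, all 36 covariance elements free
  p <- length(facet_names)
  sat <- nightvar:::new_cfa_spec(
    facet_names, character(0),
    matrix(FALSE, p, 0), matrix(0, p, 0),
    matrix(FALSE, 0, 0), matrix(0, 0, 0),
    matrix(TRUE, p, p), matrix(0, p, p),
    matrix(FALSE, p, 0), matrix(0, p, 0), "saturated")
  expect_equal(model_df(sat), 0L)

  # single factor: 8 loadings + 8 residual variances
  one <- nightvar:::new_cfa_spec(
    facet_names, "g",
    matrix(TRUE, p, 1), matrix(0, p, 1),
    matrix(FALSE, 1, 1), matrix(1, 1, 1),
    diag(p) == 1, matrix(0, p, p),
    matrix(FALSE, p, 1), matrix(0, p, 1), "one factor")
  expect_equal(model_df(one), 20L)

  # over-parameterized specs error
  over <- sat
  over$lambda_free <- matrix(TRUE, p, 1)
  over$lambda_fixed <- matrix(0, p, 1)
  over$factors <- "g"
  over$phi_free <- matrix(FALSE, 1, 1); over$phi_fixed <- matrix(1, 1, 1)
  over$fr_free <- matrix(FALSE, p, 1); over$fr_fixed <- matrix(0, p, 1)
  expect_error(model_df(over), "over-parameterized")
})

test_that("FIML fit matches an independent SEM implementation", {
  cfg <- default_paper_config(n_persons = 400L, seed = 55L)
  coh <- generate_cohort(cfg)
  panel <- aggregate_raters(coh)
  Y <- as.matrix(panel[, facet_names])
  fit <- fit_bifactor_s1(panel)
  orc <- oracle_fit_bifactor(Y)
  expect_equal(fit$df, orc$df)
  expect_lt(abs(fit$loglik - orc$loglik), 1e-2)
  lam_g <- fit$est$Lambda[, "g"]
  expect_lt(max(abs(lam_g - orc$lambda_g[names(lam_g)])), 1e-3)
  lam_i <- fit$est$Lambda[int_idx <- c("ad", "wd", "som"), "s_int"]
  lam_e <- fit$est$Lambda[c("odd", "cd", "hyp", "at"), "s_ext"]
  expect_lt(max(abs(lam_i - orc$lambda_s[int_idx])), 1e-3)
  expect_lt(max(abs(lam_e - orc$lambda_s[c("odd", "cd", "hyp", "at")])), 1e-3)

  # the ML solution beats the generating parameters on its own data
  lam_s_full <- rep(0, 8); names(lam_s_full) <- facet_names
  lam_s_full[names(cfg$lambda_specific)] <- cfg$lambda_specific
  ord <- c("ad", "wd", "som", "odd", "cd", "hyp", "at", "eri")
  truth_par <- c(
    unname(cfg$lambda_general[ord]),
    unname(cfg$lambda_specific[c("ad", "wd", "som", "odd", "cd", "hyp", "at")]),
    unname(1 - cfg$lambda_general[ord]^2 - lam_s_full[ord]^2),
    0, 0, 0)
  ll_truth <- -oracle_deviance(truth_par,
                               crossprod(sweep(Y, 2, colMeans(Y))) / nrow(Y),
                               nrow(Y)) / 2
  expect_gte(fit$loglik, ll_truth - 1e-6)

  # refitting the same panel is deterministic
  fit2 <- fit_bifactor_s1(panel)
  expect_identical(fit$par, fit2$par)
})

test_that("fit indices follow their defining formulas", {
  fake <- structure(list(chisq = 20, df = 10, n = 200,
                         chisq_base = 200, df_base = 28,
                         S_sat = diag(2), Sigma = diag(2)),
                    class = "cfa_fit")
  fi <- fit_indices(fake)
  expect_equal(fi$cfi, 1 - 10 / 172, tolerance = 1e-12)
  expect_equal(round(fi$cfi, 4), 0.9419)
  expect_equal(fi$rmsea, sqrt(10 / 2000), tolerance = 1e-12)
  expect_equal(round(fi$rmsea, 4), 0.0707)
  expect_equal(fi$srmr, 0)

  # exact fit limit
  fake$chisq <- 10
  fi2 <- fit_indices(fake)
  expect_equal(fi2$cfi, 1)
  expect_equal(fi2$rmsea, 0)

  # df = 0 with nonzero chi-square has no RMSEA
  fake$df <- 0; fake$chisq <- 5
  expect_error(fit_indices(fake), "RMSEA")
})

test_that("factor scores shrink correctly and respect missingness", {
  coh <- small_cohort()
  panel <- aggregate_raters(coh)
  fit <- fit_bifactor_s1(panel)
  # linearity through the origin
  p0 <- panel[1, ]; p0[facet_names] <- 0
  s0 <- factor_scores(fit, p0)
  expect_equal(unlist(s0[, c("g", "s_int", "s_ext")]), c(g = 0, s_int = 0, s_ext = 0),
               tolerance = 1e-10)
  # only the reference indicator observed: finite g, specifics shrunk to 0
  p1 <- panel[1, ]
  p1[setdiff(facet_names, "eri")] <- NA_real_
  p1$eri <- 2
  s1 <- factor_scores(fit, p1)
  expect_true(is.finite(s1$g) && abs(s1$g) > 0.5)
  expect_equal(s1$s_int, 0, tolerance = 1e-10)
  expect_equal(s1$s_ext, 0, tolerance = 1e-10)
  # all indicators missing: missing scores, row kept
  p2 <- panel[1, ]; p2[facet_names] <- NA_real_
  s2 <- factor_scores(fit, p2)
  expect_equal(nrow(s2), 1L)
  expect_true(all(is.na(s2[, c("g", "s_int", "s_ext")])))
})

test_that("scores recover the generating factors on a large cohort", {
  cfg <- default_paper_config(n_persons = 2000L, seed = 70L)
  coh <- generate_cohort(cfg)
  panel <- aggregate_raters(coh)
  fit <- fit_bifactor_s1(panel)
  sc <- factor_scores(fit, panel)
  lat <- attr(coh, "latent")
  expect_gt(cor(sc$g, lat$g), 0.8)
  expect_gt(cor(sc$s_int, lat$s_int), 0.6)
  expect_gt(cor(sc$s_ext, lat$s_ext), 0.6)
})
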