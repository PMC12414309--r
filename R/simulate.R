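outcome_keys <- c("duration", "bedtime", "waketime")
eq_labels <- function() c(paste0("mean_", outcome_keys), paste0("logv_", outcome_keys))
between_predictors <- c("g", "s_int", "s_ext", "age_z", "sex", "medu_z", "inr_z")

# facets loading on each specific factor
int_facets <- c("ad", "wd", "som")
ext_facets <- c("odd", "cd", "hyp", "at")

#' Configuration of the synthetic cohort generator
#'
#' Bundles every generating parameter of the latent-structure simulator:
#' bifactor measurement loadings with two raters per facet, the between-level
#' coefficient matrix mapping factors and covariates to person-level sleep
#' means (`alpha`) and log residual variances (`omega`), the between-level
#' residual covariance, within-night fixed effects, and the missingness
#' mechanism. [default_paper_config] supplies a fully calibrated instance.
#'
#' @param n_persons number of adolescents.
#' @param n_nights nights requested per person (default 14).
#' @param seed RNG seed; generation is deterministic given the config.
#' @param lambda_general named length-8 vector of general-factor loadings on
#'   the standardized aggregated indicators (names = [facet_names]).
#' @param lambda_specific named length-7 vector of specific-factor loadings
#'   (internalizing: ad/wd/som; externalizing: odd/cd/hyp/at; none for eri).
#' @param rater_reliability correlation between the caregiver and youth
#'   versions of each facet, in (0, 1].
#' @param B 6 x 7 between-level coefficient matrix; rows are the six latent
#'   outcomes (3 means then 3 log variances, dimnames required), columns the
#'   predictors `g, s_int, s_ext, age_z, sex, medu_z, inr_z`.
#' @param alpha0,omega0 length-3 intercepts of the mean and log-variance
#'   equations (minutes; log minutes-squared).
#' @param Psi 6 x 6 positive-definite between-level residual covariance.
#' @param gamma_night,gamma_weekend length-3 within-level fixed effects
#'   (per-night linear trend; weekend shift) for the three metrics.
#' @param icc_targets between-person variance fractions the alpha variances
#'   were calibrated to (recorded for bookkeeping).
#' @param missingness list with `intercept` and `age_slope`: the per-night
#'   missingness probability is `plogis(intercept + age_slope * age_z)`;
#'   a negative slope makes younger adolescents miss more nights.
#' @param invalid_fraction share of persons contributing fewer than 3 nights.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_persons, n_nights = 14L, seed = 1L,
                          lambda_general, lambda_specific,
                          rater_reliability,
                          B, alpha0, omega0, Psi,
                          gamma_night, gamma_weekend,
                          icc_targets = c(NA, NA, NA),
                          missingness = list(intercept = -1.90, age_slope = -0.3),
                          invalid_fraction = 0) {
  stopifnot(
    n_persons >= 2, n_nights >= 1,
    length(lambda_general) == 8, setequal(names(lambda_general), facet_names),
    length(lambda_specific) == 7,
    setequal(names(lambda_specific), c(int_facets, ext_facets)),
    rater_reliability > 0, rater_reliability <= 1,
    all(dim(B) == c(6, 7)), length(alpha0) == 3, length(omega0) == 3,
    all(dim(Psi) == c(6, 6)), length(gamma_night) == 3,
    length(gamma_weekend) == 3,
    invalid_fraction >= 0, invalid_fraction < 1
  )
  if (!isSymmetric(unname(Psi), tol = 1e-8)) stop("Psi must be symmetric")
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Psi is not positive definite (min eigenvalue ",
                         signif(min(ev), 3), ")")
  if (any(is.na(icc_targets)) == FALSE && any(icc_targets <= 0 | icc_targets >= 1)) {
    stop("icc_targets must lie in (0, 1)")
  }
  dimnames(B) <- list(eq_labels(), between_predictors)
  dimnames(Psi) <- list(eq_labels(), eq_labels())
  # admissibility of the two-rater split given the target aggregate loadings
  split <- rater_noise_split(lambda_general, lambda_specific, rater_reliability)
  if (any(split$d < -1e-10)) {
    stop("rater_reliability too low for facet(s) ",
         paste(facet_names[split$d < -1e-10], collapse = ", "),
         ": the aggregated indicator cannot carry the requested loadings")
  }
  structure(list(
    n_persons = as.integer(n_persons), n_nights = as.integer(n_nights),
    seed = as.integer(seed),
    lambda_general = lambda_general[facet_names],
    lambda_specific = lambda_specific,
    rater_reliability = rater_reliability,
    B = B, alpha0 = alpha0, omega0 = omega0, Psi = Psi,
    gamma_night = gamma_night, gamma_weekend = gamma_weekend,
    icc_targets = icc_targets, missingness = missingness,
    invalid_fraction = invalid_fraction
  ), class = "cohort_config")
}

# Variance split for the two-rater construction. Each facet j has a common
# signal c_j = lam_g g + lam_s s + delta (Var(delta) = d); rater scores are
# c_j + e_r with Var(e) = E. Solving for (d, E) so that (i) the two raters
# correlate at `rel` and (ii) the re-standardized mean of the two z-scored
# raters has exactly the target loadings gives the expressions below;
# d >= 0 requires rel >= L / (2 - L).
rater_noise_split <- function(lambda_general, lambda_specific, rel) {
  lam_s <- rep(0, 8); names(lam_s) <- facet_names
  lam_s[names(lambda_specific)] <- lambda_specific
  L <- lambda_general[facet_names]^2 + lam_s^2
  if (any(L >= 1)) stop("loadings imply non-positive indicator uniqueness")
  u2 <- 1 - L
  d <- (2 * rel * u2 - (1 - rel) * L) / (1 + rel)
  E <- (1 - rel) / rel * (L + d)
  list(L = L, d = pmax(d, 0), E = E, lam_s = lam_s)
}

#' Generator configuration calibrated to the published study conditions
#'
#' Loadings follow the reported standardized bifactor s-1 solution (emotion
#' dysregulation 0.918 on the general factor); between-level coefficients
#' equal the reported unstandardized estimates (e.g. general factor to
#' log-variance of sleep duration = 0.121); intercepts and the log-variance
#' scale are anchored to the reported person-level means and SDs of the three
#' metrics; the alpha variances are calibrated so the unconditional ICCs are
#' 0.17 / 0.42 / 0.29; the missingness mechanism yields about 12.1 observed
#' nights of 14 with younger adolescents missing more, and 34/238 of persons
#' contribute fewer than 3 nights.
#'
#' @param n_persons,n_nights,seed overrides of the cohort size and seed.
#' @return a `cohort_config`.
#' @export
default_paper_config <- function(n_persons = 238L, n_nights = 14L, seed = 1L) {
  lambda_general <- c(ad = 0.641, wd = 0.573, som = 0.569, odd = 0.719,
                      cd = 0.509, hyp = 0.558, at = 0.727, eri = 0.918)
  lambda_specific <- c(ad = 0.641, wd = 0.584, som = 0.459,
                       odd = 0.590, cd = 0.611, hyp = 0.428, at = 0.246)
  B <- rbind(
    mean_duration = c(3.434, -4.389,  -3.371,  -4.770, -27.798,  1.762,  1.399),
    mean_bedtime  = c(6.603,  7.973,  -9.731,  14.436,  39.890, -2.784, -6.372),
    mean_waketime = c(3.633,  3.490, -10.355,   8.131,  17.699, -1.901, -2.755),
    logv_duration = c(0.121,  0.051,  -0.005,   0.015,  -0.020, -0.085, -0.019),
    logv_bedtime  = c(0.058,  0.125,   0.098,   0.014,   0.328, -0.055, -0.064),
    logv_waketime = c(0.127,  0.123,  -0.037,   0.071,   0.157, -0.032, -0.064)
  )
  colnames(B) <- between_predictors
  alpha0 <- c(389.54, -3.83, 463.07)
  sd_anchor <- c(79.10, 74.22, 91.92)   # mean person-level nightly SDs
  omega0 <- 2 * log(sd_anchor)
  sigma_omega <- c(0.63, 1.00, 0.70)    # total SD of the log-variance outcomes
  icc_targets <- c(0.17, 0.42, 0.29)

  var_x <- c(1, 1, 1, 1, 0.534 * (1 - 0.534), 1, 1)  # sex is Bernoulli(0.534)
  explained <- drop(B^2 %*% var_x)
  psi_logv <- sigma_omega^2 - explained[4:6]
  mean_within_var <- exp(omega0 + sigma_omega^2 / 2)  # E[exp(omega)]
  var_alpha_tot <- icc_targets / (1 - icc_targets) * mean_within_var
  psi_mean <- var_alpha_tot - explained[1:3]
  if (any(c(psi_logv, psi_mean) <= 0)) stop("calibration yields non-PD Psi")
  sds <- sqrt(c(psi_mean, psi_logv))
  R <- diag(6)
  # modest residual correlations among the between-level outcomes: later
  # bedtimes go with later waketimes and shorter durations; the three
  # variability outcomes share measurement variance
  R[1, 2] <- R[2, 1] <- -0.30
  R[1, 3] <- R[3, 1] <-  0.20
  R[2, 3] <- R[3, 2] <-  0.40
  R[4, 5] <- R[5, 4] <- R[4, 6] <- R[6, 4] <- R[5, 6] <- R[6, 5] <- 0.30
  Psi <- diag(sds) %*% R %*% diag(sds)
  cohort_config(
    n_persons = n_persons, n_nights = n_nights, seed = seed,
    lambda_general = lambda_general, lambda_specific = lambda_specific,
    rater_reliability = 0.80,
    B = B, alpha0 = alpha0, omega0 = omega0, Psi = Psi,
    gamma_night = c(-0.5, 0.5, 0.2), gamma_weekend = c(15, 45, 60),
    icc_targets = icc_targets,
    missingness = list(intercept = -1.90, age_slope = -0.3),
    invalid_fraction = 34 / 238
  )
}

# population moments of the generated demographics, for the generator's own
# (population-level) standardization
demo_population_moments <- function() {
  medu_vals <- c(10, 12, 14, 16)
  medu_p <- c(2.94, 7.98, 44.12, 45.00); medu_p <- medu_p / sum(medu_p)
  medu_mu <- sum(medu_p * medu_vals)
  medu_sd <- sqrt(sum(medu_p * medu_vals^2) - medu_mu^2)
  list(
    age_mu = 16, age_sd = 4 / sqrt(12),
    medu_vals = medu_vals, medu_p = medu_p, medu_mu = medu_mu, medu_sd = medu_sd,
    inr_mu = 2.53, inr_sd = 1.84, p_female = 0.534
  )
}

#' Generate a synthetic cohort
#'
#' Draws demographics, orthogonal latent psychopathology factors (general,
#' specific internalizing, specific externalizing), two rater scores per
#' facet with the configured cross-rater correlation, person-level sleep
#' means and log residual variances from the between-level regression, and
#' nightly records with a linear night trend, a weekend shift (nights
#' beginning Friday or Saturday), heteroscedastic person-specific noise and
#' age-dependent missingness.
#'
#' @param config a [cohort_config].
#' @return a `nightvar_cohort` with attributes `latent` (tibble of the
#'   generating per-person draws) carried for recovery experiments.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_persons
  pm <- demo_population_moments()
  ids <- sprintf("p%04d", seq_len(n))

  age <- stats::runif(n, 14, 18)
  sex <- stats::rbinom(n, 1, pm$p_female)  # 1 = female
  medu <- sample(pm$medu_vals, n, replace = TRUE, prob = pm$medu_p)
  cv2 <- (pm$inr_sd / pm$inr_mu)^2
  inr <- stats::rlnorm(n, meanlog = log(pm$inr_mu) - 0.5 * log1p(cv2),
                       sdlog = sqrt(log1p(cv2)))

  g <- stats::rnorm(n); s_int <- stats::rnorm(n); s_ext <- stats::rnorm(n)
  split <- rater_noise_split(config$lambda_general, config$lambda_specific,
                             config$rater_reliability)
  spec_score <- cbind(
    ad = s_int, wd = s_int, som = s_int,
    odd = s_ext, cd = s_ext, hyp = s_ext, at = s_ext, eri = 0
  )[, facet_names]
  facet_df <- list()
  for (j in facet_names) {
    common <- config$lambda_general[j] * g + split$lam_s[j] * spec_score[, j] +
      stats::rnorm(n, sd = sqrt(split$d[j]))
    for (r in rater_names) {
      raw <- common + stats::rnorm(n, sd = sqrt(split$E[j]))
      facet_df[[paste0(j, "_", r)]] <- 50 + 10 * raw  # T-score-like metric
    }
  }

  x <- cbind(
    g = g, s_int = s_int, s_ext = s_ext,
    age_z = (age - pm$age_mu) / pm$age_sd,
    sex = sex,
    medu_z = (medu - pm$medu_mu) / pm$medu_sd,
    inr_z = (inr - pm$inr_mu) / pm$inr_sd
  )
  mu_eta <- sweep(x %*% t(config$B), 2, c(config$alpha0, config$omega0), `+`)
  eta <- mu_eta + mvrnorm_chol(n, config$Psi)
  alpha <- eta[, 1:3, drop = FALSE]
  omega <- eta[, 4:6, drop = FALSE]

  # nightly records
  start_dow <- sample.int(7, n, replace = TRUE)    # 1 = Monday
  p_miss <- stats::plogis(config$missingness$intercept +
                            config$missingness$age_slope * x[, "age_z"])
  invalid <- stats::runif(n) < config$invalid_fraction
  nights_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- seq_len(config$n_nights) - 1L
    dow <- ((start_dow[i] - 1L + k) %% 7L) + 1L
    wk <- as.integer(dow %in% c(5L, 6L))           # Friday, Saturday
    y <- sapply(1:3, function(s) {
      alpha[i, s] + config$gamma_night[s] * k + config$gamma_weekend[s] * wk +
        stats::rnorm(config$n_nights, sd = exp(omega[i, s] / 2))
    })
    keep <- if (invalid[i]) {
      n_keep <- sample(0:2, 1)
      seq_len(config$n_nights) %in% sample(config$n_nights, n_keep)
    } else {
      stats::runif(config$n_nights) >= p_miss[i]
    }
    if (!any(keep)) { nights_list[[i]] <- NULL; next }
    nights_list[[i]] <- tibble(
      person_id = ids[i], night_index = k[keep], weekend = wk[keep],
      duration_min = pmin(pmax(y[keep, 1], 0), 1440),
      bedtime_min = y[keep, 2], waketime_min = y[keep, 3]
    )
  }
  persons <- dplyr::bind_cols(
    tibble(person_id = ids, age = age, sex = sex,
           maternal_education = medu, income_to_needs = inr),
    as_tibble(facet_df)
  )
  nights <- dplyr::bind_rows(nights_list)
  if (nrow(nights) == 0) stop("no nights generated; check missingness config")
  out <- cohort(persons, nights)
  attr(out, "latent") <- tibble(
    person_id = ids, g = g, s_int = s_int, s_ext = s_ext,
    alpha_duration = alpha[, 1], alpha_bedtime = alpha[, 2],
    alpha_waketime = alpha[, 3],
    omega_duration = omega[, 1], omega_bedtime = omega[, 2],
    omega_waketime = omega[, 3]
  )
  out
}

mvrnorm_chol <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% L
}

#' Flat listing of the generating parameters
#'
#' One row per free generating parameter, labelled to join against the fitted
#' model summaries (between-level coefficients as `<equation>~<predictor>`,
#' within-level effects as `within_<outcome>~...`, covariance entries as
#' `psi[...]`, loadings as `lambda_g~<facet>` / `lambda_s~<facet>`).
#'
#' @param config a [cohort_config].
#' @return tibble with columns `label`, `block`, `value`; labels unique.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  eqs <- eq_labels()
  rows <- list()
  bt <- expand.grid(eq = eqs, pred = between_predictors,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$between <- tibble(
    label = paste0(bt$eq, "~", bt$pred), block = "between",
    value = config$B[cbind(bt$eq, bt$pred)]
  )
  rows$intercepts <- tibble(
    label = paste0(eqs, "~intercept"), block = "between",
    value = c(config$alpha0, config$omega0)
  )
  rows$within <- tibble(
    label = c(paste0("within_", outcome_keys, "~night_index"),
              paste0("within_", outcome_keys, "~weekend")),
    block = "within",
    value = c(config$gamma_night, config$gamma_weekend)
  )
  ut <- which(upper.tri(config$Psi, diag = TRUE), arr.ind = TRUE)
  rows$psi <- tibble(
    label = paste0("psi[", eqs[ut[, 1]], ",", eqs[ut[, 2]], "]"),
    block = "psi", value = config$Psi[ut]
  )
  rows$loadings <- tibble(
    label = c(paste0("lambda_g~", names(config$lambda_general)),
              paste0("lambda_s~", names(config$lambda_specific))),
    block = "measurement",
    value = c(unname(config$lambda_general), unname(config$lambda_specific))
  )
  out <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(out$label))
  out
}
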