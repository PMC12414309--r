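with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

# between-level predictor table: factor scores plus sample-standardized
# demographics (sex stays 0/1); column names line up with truth_table labels
build_between <- function(persons, scores) {
  z <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  dplyr::left_join(scores, persons, by = "person_id") |>
    dplyr::transmute(
      person_id = .data$person_id,
      dplyr::across(dplyr::all_of(setdiff(names(scores), "person_id"))),
      age_z = z(.data$age), sex = .data$sex,
      medu_z = z(.data$maternal_education), inr_z = z(.data$income_to_needs)
    )
}

table3_shape <- function(fit, betas = NULL) {
  eq_order <- c(paste0("logv_", fit$outcomes), paste0("mean_", fit$outcomes))
  s <- summary(fit) |>
    dplyr::filter(.data$equation %in% eq_order, .data$predictor != "intercept",
                  !startsWith(.data$label, "psi["),
                  !startsWith(.data$label, "within_")) |>
    dplyr::mutate(equation = factor(.data$equation, levels = eq_order),
                  predictor = factor(.data$predictor,
                                     levels = unique(.data$predictor))) |>
    dplyr::arrange(.data$equation, .data$predictor) |>
    dplyr::mutate(equation = as.character(.data$equation),
                  predictor = as.character(.data$predictor))
  if (!is.null(betas)) {
    s <- dplyr::left_join(
      s, dplyr::select(betas, "label", std_beta = "beta",
                       std_lower = "lower", std_upper = "upper"),
      by = "label")
  }
  s
}

#' Run the primary analysis
#'
#' Chains the full pipeline: validity filtering of the nightly series, rater
#' aggregation, bifactor s-1 measurement model with factor-score extraction,
#' and the location-scale model of all six between-level sleep outcomes
#' (three log variabilities, three means) on the three psychopathology
#' factor scores and four demographic covariates.
#'
#' @param x a `nightvar_cohort` (or list of `persons`/`nights` paths).
#' @param control a [melsm_control].
#' @param min_nights validity threshold (default 3).
#' @return list with `cfa` (the measurement fit), `scores`, `melsm`,
#'   `betas` (standardized psychopathology effects) and `summary`
#'   (coefficient table: six outcome blocks by seven predictors).
#' @export
run_primary <- function(x, control = melsm_control(), min_nights = 3L) {
  if (!inherits(x, "nightvar_cohort")) {
    x <- with_stage("read", read_cohort(x$persons, x$nights))
  }
  x <- with_stage("validity_filter", apply_validity_filter(x, min_nights))
  panel <- with_stage("aggregate_raters", aggregate_raters(x))
  cfa <- with_stage("cfa", fit_bifactor_s1(panel))
  scores <- with_stage("factor_scores", factor_scores(cfa, panel))
  between <- with_stage("between_design", build_between(x$persons, scores))
  fit <- with_stage("melsm", fit_melsm(x$nights, between, control = control))
  betas <- with_stage("standardize", standardize_effects(
    fit, predictors = c("g", "s_int", "s_ext")))
  list(cfa = cfa, scores = scores, melsm = fit, betas = betas,
       summary = table3_shape(fit, betas))
}

#' Run the demographic moderation model
#'
#' The general-factor score and the four demographics are z-scored, the four
#' products with the general factor are formed from the z-scores (product of
#' z-scores, not z-score of products), and all four interactions enter every
#' between-level equation simultaneously.
#'
#' @inheritParams run_primary
#' @return list with `melsm`, `summary`, and `interactions` (the four
#'   interaction rows per equation).
#' @export
run_moderation <- function(x, control = melsm_control(), min_nights = 3L) {
  if (!inherits(x, "nightvar_cohort")) {
    x <- with_stage("read", read_cohort(x$persons, x$nights))
  }
  x <- with_stage("validity_filter", apply_validity_filter(x, min_nights))
  panel <- with_stage("aggregate_raters", aggregate_raters(x))
  cfa <- with_stage("cfa", fit_bifactor_s1(panel))
  scores <- with_stage("factor_scores", factor_scores(cfa, panel))
  z <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  between <- with_stage("between_design",
    dplyr::left_join(scores, x$persons, by = "person_id") |>
      dplyr::transmute(
        person_id = .data$person_id,
        g = z(.data$g), s_int = .data$s_int, s_ext = .data$s_ext,
        age_z = z(.data$age), sex_z = z(.data$sex),
        medu_z = z(.data$maternal_education),
        inr_z = z(.data$income_to_needs)
      ) |>
      dplyr::mutate(
        g_x_age = .data$g * .data$age_z, g_x_sex = .data$g * .data$sex_z,
        g_x_medu = .data$g * .data$medu_z, g_x_inr = .data$g * .data$inr_z
      ))
  fit <- with_stage("melsm", fit_melsm(x$nights, between, control = control))
  s <- table3_shape(fit)
  list(melsm = fit, summary = s,
       interactions = dplyr::filter(s, startsWith(.data$predictor, "g_x_")))
}

#' Run the correlated-factors supplementary models
#'
#' Replaces the bifactor structure with correlated internalizing,
#' externalizing and (single-indicator) dysregulation factors, extracts
#' their scores, and runs two location-scale models: sleep duration alone,
#' and bedtime plus waketime, each with the demographic covariates of the
#' primary model.
#'
#' @inheritParams run_primary
#' @return list with `cfa`, `scores` and two model summaries
#'   (`duration`, `bedwake`).
#' @export
run_correlated_supplement <- function(x, control = melsm_control(),
                                      min_nights = 3L) {
  if (!inherits(x, "nightvar_cohort")) {
    x <- with_stage("read", read_cohort(x$persons, x$nights))
  }
  x <- with_stage("validity_filter", apply_validity_filter(x, min_nights))
  panel <- with_stage("aggregate_raters", aggregate_raters(x))
  cfa <- with_stage("cfa", fit_bifactor_s1(panel, spec = correlated_factors_spec()))
  scores <- with_stage("factor_scores", factor_scores(cfa, panel))
  between <- with_stage("between_design", build_between(x$persons, scores))
  fit_dur <- with_stage("melsm_duration",
    fit_melsm(x$nights, between, outcomes = "duration", control = control))
  fit_bw <- with_stage("melsm_bedwake",
    fit_melsm(x$nights, between, outcomes = c("bedtime", "waketime"),
              control = control))
  list(cfa = cfa, scores = scores,
       duration = list(melsm = fit_dur, summary = table3_shape(fit_dur)),
       bedwake = list(melsm = fit_bw, summary = table3_shape(fit_bw)))
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a cohort from `config`, runs the primary pipeline,
#' and compares the posterior of every between-level coefficient against the
#' generating value. Replicate seeds derive deterministically from `seed`;
#' replicate failures are recorded, not fatal.
#'
#' @param config a [cohort_config].
#' @param n_replicates number of replicates (>= 2).
#' @param seed master seed.
#' @param control a [melsm_control] used for every replicate fit.
#' @return list with `report` (one row per generating between-level
#'   parameter: generating `value`, mean posterior mean, CrI coverage count,
#'   replicate count) and `failures` (character messages).
#' @export
run_recovery <- function(config, n_replicates = 20L, seed = 1L,
                         control = melsm_control(iter = 1000L)) {
  stopifnot(n_replicates >= 2)
  truth <- truth_table(config) |> dplyr::filter(.data$block == "between")
  est_sum <- stats::setNames(numeric(nrow(truth)), truth$label)
  cover <- stats::setNames(integer(nrow(truth)), truth$label)
  n_ok <- 0L; failures <- character()
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- seed + 131L * r
      coh <- generate_cohort(cfg)
      ctl <- control; ctl$seed <- seed + 131L * r
      run_primary(coh, control = ctl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("replicate ", r, ": ", conditionMessage(res)))
      next
    }
    s <- summary(res$melsm)
    s <- s[match(truth$label, s$label), ]
    hit <- truth$value >= s$lower & truth$value <= s$upper
    cover <- cover + as.integer(hit)
    est_sum <- est_sum + s$estimate
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) stop("all replicates failed: ", failures[1])
  report <- dplyr::mutate(truth,
    mean_estimate = unname(est_sum[.data$label]) / n_ok,
    coverage = unname(cover[.data$label]),
    n_replicates = n_ok)
  list(report = report, failures = failures)
}
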