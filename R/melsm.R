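#' @useDynLib nightvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

metric_for_key <- c(duration = "duration_min", bedtime = "bedtime_min",
                    waketime = "waketime_min")

#' MCMC settings for the location-scale sampler
#'
#' @param chains number of chains (default 2).
#' @param iter iterations per chain; the first `burn` are discarded.
#' @param burn burn-in per chain; default half of `iter`.
#' @param seed master seed; chain seeds are derived deterministically.
#' @param coef_prec prior precision of every regression coefficient
#'   (Normal(0, 1/coef_prec); default variance 1e6).
#' @param psi_df,psi_scale inverse-Wishart prior on the between-level
#'   residual covariance; defaults: identity scale, dimension + 1 df.
#' @return a `melsm_control` list.
#' @export
melsm_control <- function(chains = 2L, iter = 2000L, burn = NULL, seed = 1L,
                          coef_prec = 1e-6, psi_df = NULL, psi_scale = NULL) {
  if (is.null(burn)) burn <- iter %/% 2L
  stopifnot(chains >= 1, iter > burn, burn >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), seed = as.integer(seed),
                 coef_prec = coef_prec, psi_df = psi_df,
                 psi_scale = psi_scale),
            class = "melsm_control")
}

#' Fit the Bayesian mixed-effects location-scale model
#'
#' For each person i, outcome s and observed night t:
#' `y_sit = alpha_si + gamma_s1 * night_it + gamma_s2 * weekend_it + e_sit`,
#' `e_sit ~ N(0, exp(omega_si))`. The person-level vector of means and log
#' residual variances `(alpha_i, omega_i)` is multivariate normal with mean
#' `B x_i` (x from the between-level design) and covariance `Psi`. Persons
#' with no observed nights contribute through the between-level model only
#' and are never dropped. Sampling is by Gibbs with a Metropolis step for
#' omega; chains start from dispersed, seeded initial values.
#'
#' @param nights nightly table (see [cohort]); rows with a missing metric are
#'   simply unobserved for that outcome.
#' @param between person-level predictor table: `person_id` plus numeric
#'   predictor columns (factor scores, covariates). Every person here is
#'   retained. Missing predictor cells are mean-imputed with a message.
#' @param outcomes which metrics to model (default all three).
#' @param control a [melsm_control].
#' @param heteroscedastic `FALSE` collapses the scale part: a single within
#'   variance per outcome, no omega latents (used for oracle checks).
#' @return a `melsm_fit` with per-chain labelled draw matrices, PSR per
#'   parameter, posterior summaries via [summary.melsm_fit].
#' @export
fit_melsm <- function(nights, between,
                      outcomes = c("duration", "bedtime", "waketime"),
                      control = melsm_control(), heteroscedastic = TRUE) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  between <- as_tibble(between)
  stopifnot("person_id" %in% names(between))
  if (inherits(nights, "nightvar_cohort")) nights <- nights$nights
  nights <- as_tibble(nights)
  unknown <- setdiff(nights$person_id, between$person_id)
  if (length(unknown)) stop("nights for person(s) absent from between table: ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  ids <- between$person_id
  N <- length(ids)
  S <- length(outcomes)

  # design matrix; mean-impute missing covariate cells (logged)
  pred <- between[setdiff(names(between), "person_id")]
  n_imp <- sum(is.na(as.matrix(pred)))
  if (n_imp > 0) {
    message("mean-imputing ", n_imp, " missing covariate cell(s)")
    pred <- dplyr::mutate(pred, dplyr::across(
      dplyr::everything(),
      ~ ifelse(is.na(.x), mean(.x, na.rm = TRUE), .x)))
  }
  X <- stats::model.matrix(~ ., data = pred)
  pred_names <- sub("^\\(Intercept\\)$", "intercept", colnames(X))

  # observation blocks, person-sorted, CSR offsets
  pid_idx <- match(nights$person_id, ids)
  obs <- vector("list", S)
  n_two_plus <- 0L
  counts_any <- integer(N)
  for (s in seq_len(S)) {
    col <- metric_for_key[outcomes[s]]
    keep <- !is.na(nights[[col]]) & !is.na(nights$night_index) &
      !is.na(nights$weekend)
    idx <- pid_idx[keep]
    ord <- order(idx)
    yv <- nights[[col]][keep][ord]
    zmat <- cbind(night = nights$night_index[keep][ord],
                  weekend = nights$weekend[keep][ord])
    cnt <- tabulate(idx, nbins = N)
    counts_any <- pmax(counts_any, cnt)
    obs[[s]] <- list(y = as.numeric(yv), z = zmat,
                     ptr = as.integer(c(0, cumsum(cnt))))
  }
  if (sum(counts_any >= 2) < 2) {
    stop("need at least two persons with at least two observed nights")
  }

  q <- if (heteroscedastic) 2L * S else S
  eq <- if (heteroscedastic) {
    c(paste0("mean_", outcomes), paste0("logv_", outcomes))
  } else paste0("mean_", outcomes)
  psi_scale <- control$psi_scale %||% diag(q)
  psi_df <- control$psi_df %||% (q + 1)

  # data-driven initial values, dispersed across chains
  eta0 <- matrix(0, N, q)
  grand <- numeric(S)
  for (s in seq_len(S)) {
    col <- metric_for_key[outcomes[s]]
    v <- nights[[col]]
    grand[s] <- stats::var(v, na.rm = TRUE)
    pm <- tapply(v, factor(pid_idx, levels = seq_len(N)), mean, na.rm = TRUE)
    pv <- tapply(v, factor(pid_idx, levels = seq_len(N)), stats::var, na.rm = TRUE)
    pm[is.na(pm) | is.nan(pm)] <- mean(v, na.rm = TRUE)
    pv[is.na(pv) | pv <= 0] <- grand[s]
    eta0[, s] <- pm
    if (heteroscedastic) eta0[, S + s] <- log(pv)
  }

  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    set.seed(control$seed + 1017L * ch)
    eta_i <- eta0 + matrix(stats::rnorm(N * q), N, q) %*%
      diag(c(0.1 * sqrt(grand), rep(0.25, q - S)), q)
    B_i <- matrix(0, q, ncol(X))
    B_i[, 1] <- colMeans(eta_i) + stats::rnorm(q, sd = 0.1)
    gamma_i <- matrix(stats::rnorm(S * 2, sd = 0.1), S, 2)
    Psi_i <- diag(apply(eta_i, 2, stats::var) + 0.1, q)
    sig2_i <- grand
    chains[[ch]] <- melsm_gibbs_chain(
      X, obs, S, heteroscedastic, eta_i, B_i, gamma_i, Psi_i, sig2_i,
      control$iter, control$burn, control$coef_prec, psi_scale, psi_df)
  }

  # assemble labelled draw matrices
  b_labels <- as.vector(outer(eq, pred_names, function(e, p) paste0(e, "~", p)))
  g_labels <- as.vector(t(outer(outcomes, c("night_index", "weekend"),
                                function(o, z) paste0("within_", o, "~", z))))
  ut <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  p_labels <- paste0("psi[", eq[ut[, 1]], ",", eq[ut[, 2]], "]")
  draw_mats <- lapply(chains, function(chn) {
    m <- cbind(chn$B, chn$gamma, chn$psi)
    cn <- c(b_labels, g_labels, p_labels)
    if (!heteroscedastic) {
      m <- cbind(m, chn$sig2)
      cn <- c(cn, paste0("sigma2_", outcomes))
    }
    colnames(m) <- cn
    m
  })
  eta_mean <- Reduce(`+`, lapply(chains, `[[`, "eta_mean")) / length(chains)
  colnames(eta_mean) <- eq
  fit <- structure(list(
    draws = draw_mats, outcomes = outcomes, eq = eq,
    predictors = pred_names, X = X, ids = ids,
    eta_mean = dplyr::bind_cols(tibble(person_id = ids), as_tibble(eta_mean)),
    heteroscedastic = heteroscedastic, control = control,
    accept = if (heteroscedastic) mean(sapply(chains, function(c) mean(c$accept))) else NA_real_,
    n_persons = N,
    n_obs = vapply(obs, function(o) length(o$y), 0L)
  ), class = "melsm_fit")
  fit$psr <- psr_all(fit)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pooled_draws <- function(fit) do.call(rbind, fit$draws)

psr_all <- function(fit) {
  vapply(colnames(fit$draws[[1]]), function(p) {
    psr(lapply(fit$draws, function(d) d[, p]))
  }, 0)
}

#' Gelman-Rubin potential scale reduction
#'
#' `sqrt(((L-1)/L * W + B/L) / W)` with `W` the mean within-chain variance
#' and `B = L * var(chain means)`. Values near 1 indicate that the chains
#' have mixed; identical chains give a value at or just below 1.
#'
#' @param chains list of equal-length numeric draw vectors (>= 2 chains), or
#'   a matrix with one chain per column.
#' @return scalar PSR.
#' @export
psr <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  stopifnot(length(chains) >= 2)
  L <- unique(lengths(chains))
  stopifnot(length(L) == 1, L >= 2)
  W <- mean(vapply(chains, stats::var, 0))
  B <- L * stats::var(vapply(chains, mean, 0))
  if (W <= 0) {
    if (B <= 1e-12) return(1)
    return(Inf)
  }
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Run the sampler until converged, then double the iterations
#'
#' Repeatedly refits with doubled iterations until the maximum PSR over all
#' parameters falls below `threshold`, then reruns once more with doubled
#' iterations as a stability check. The returned fit is from the doubled run;
#' the convergence report holds the PSR vectors of both runs.
#'
#' @inheritParams fit_melsm
#' @param threshold PSR convergence threshold (default 1.05).
#' @param max_rounds maximum number of doublings before giving up.
#' @return the final `melsm_fit`, with a `convergence` element:
#'   `list(psr_initial, psr_doubled, iter_initial, iter_final)`.
#' @export
converge_and_double <- function(nights, between,
                                outcomes = c("duration", "bedtime", "waketime"),
                                control = melsm_control(),
                                heteroscedastic = TRUE,
                                threshold = 1.05, max_rounds = 5L) {
  iter <- control$iter
  fit <- NULL
  for (round in seq_len(max_rounds)) {
    ctl <- melsm_control(chains = control$chains, iter = iter,
                         seed = control$seed, coef_prec = control$coef_prec,
                         psi_df = control$psi_df, psi_scale = control$psi_scale)
    fit <- fit_melsm(nights, between, outcomes, ctl, heteroscedastic)
    if (max(fit$psr) < threshold) break
    if (round == max_rounds) {
      worst <- names(sort(fit$psr, decreasing = TRUE))[1:3]
      stop("PSR threshold ", threshold, " not reached after ", max_rounds,
           " rounds; worst parameters: ", paste(worst, collapse = ", "),
           " (PSR ", signif(max(fit$psr), 4), ")")
    }
    iter <- iter * 2L
  }
  psr_first <- fit$psr
  ctl2 <- melsm_control(chains = control$chains, iter = iter * 2L,
                        seed = control$seed, coef_prec = control$coef_prec,
                        psi_df = control$psi_df, psi_scale = control$psi_scale)
  fit2 <- fit_melsm(nights, between, outcomes, ctl2, heteroscedastic)
  fit2$convergence <- list(psr_initial = psr_first, psr_doubled = fit2$psr,
                           iter_initial = iter, iter_final = iter * 2L)
  fit2
}

#' Equal-tailed credibility intervals and the zero-exclusion flag
#'
#' Quantile intervals (linear-interpolation quantiles) of the pooled
#' post-burn-in draws; a parameter is flagged significant when the interval
#' excludes zero.
#'
#' @param posterior a `melsm_fit` or a matrix of draws (columns = parameters).
#' @param level interval mass (default 0.95).
#' @return tibble `label`, `lower`, `upper`, `significant`.
#' @export
credibility_intervals <- function(posterior, level = 0.95) {
  draws <- if (inherits(posterior, "melsm_fit")) pooled_draws(posterior) else as.matrix(posterior)
  if (nrow(draws) < 100) stop("need at least 100 pooled draws")
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  tibble(
    label = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    lower = unname(qs[1, ]), upper = unname(qs[2, ]),
    significant = unname(qs[1, ] > 0 | qs[2, ] < 0)
  )
}

#' Posterior summary in the published table layout
#'
#' @param object a `melsm_fit`.
#' @param level credibility level.
#' @param ... unused.
#' @return tibble `label`, `equation`, `predictor`, `estimate` (posterior
#'   mean), `post_sd`, `lower`, `upper`, `significant`.
#' @export
summary.melsm_fit <- function(object, level = 0.95, ...) {
  draws <- pooled_draws(object)
  ci <- credibility_intervals(draws, level)
  lab <- colnames(draws)
  eqp <- strsplit(lab, "~", fixed = TRUE)
  tibble(
    label = lab,
    equation = vapply(eqp, `[`, "", 1L),
    predictor = vapply(eqp, function(x) if (length(x) > 1) x[2] else NA_character_, ""),
    estimate = unname(colMeans(draws)),
    post_sd = unname(apply(draws, 2, stats::sd)),
    lower = ci$lower, upper = ci$upper, significant = ci$significant,
    psr = unname(object$psr[lab])
  )
}

#' @export
print.melsm_fit <- function(x, ...) {
  cat("<melsm_fit> ", x$n_persons, " persons, outcomes: ",
      paste(x$outcomes, collapse = ", "), "\n", sep = "")
  cat("  chains = ", length(x$draws), ", kept draws/chain = ",
      nrow(x$draws[[1]]), ", max PSR = ", signif(max(x$psr), 4), "\n", sep = "")
  invisible(x)
}

#' Standardized between-level coefficients
#'
#' Within each retained draw, `beta = b * SD(x) / SD(y)` where `SD(y)` is the
#' model-implied SD of the between-level outcome (explained variance from the
#' draw's coefficients plus the draw's Psi diagonal). Draws with zero implied
#' outcome variance are dropped with a recorded count.
#'
#' @param fit a `melsm_fit`.
#' @param predictors which design columns to standardize over (default: all
#'   non-intercept predictors).
#' @return tibble `label`, `beta` (posterior median), `lower`, `upper`,
#'   `significant`; attribute `n_dropped`.
#' @export
standardize_effects <- function(fit, predictors = NULL) {
  stopifnot(inherits(fit, "melsm_fit"))
  preds <- setdiff(fit$predictors, "intercept")
  if (!is.null(predictors)) preds <- intersect(preds, predictors)
  draws <- pooled_draws(fit)
  Xp <- fit$X[, match(preds, sub("^\\(Intercept\\)$", "intercept", colnames(fit$X))),
              drop = FALSE]
  covX <- stats::cov(Xp)
  sdx <- sqrt(diag(covX))
  out <- list(); dropped <- 0L
  for (e in fit$eq) {
    bcols <- paste0(e, "~", preds)
    bmat <- draws[, bcols, drop = FALSE]
    psi_col <- paste0("psi[", e, ",", e, "]")
    vy <- rowSums((bmat %*% covX) * bmat) + draws[, psi_col]
    ok <- vy > 0
    dropped <- dropped + sum(!ok)
    beta <- bmat[ok, , drop = FALSE] * rep(sdx, each = sum(ok)) / sqrt(vy[ok])
    qs <- apply(beta, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
    out[[e]] <- tibble(label = bcols, equation = e, predictor = preds,
                       beta = unname(qs[2, ]), lower = unname(qs[1, ]),
                       upper = unname(qs[3, ]),
                       significant = unname(qs[1, ] > 0 | qs[3, ] < 0))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_dropped") <- dropped
  res
}

#' Intraclass correlation of a nightly metric
#'
#' Unconditional two-level random-intercept model (no predictors, common
#' within variance) via REML; ICC = between variance / total variance.
#'
#' @param nights nightly table or `nightvar_cohort`.
#' @param outcome one of `"duration"`, `"bedtime"`, `"waketime"`.
#' @return fraction in `[0, 1]`.
#' @export
icc <- function(nights, outcome = c("duration", "bedtime", "waketime")) {
  outcome <- match.arg(outcome)
  if (inherits(nights, "nightvar_cohort")) nights <- nights$nights
  v <- nights[[metric_for_key[outcome]]]
  d <- data.frame(y = v, id = nights$person_id)[!is.na(v), ]
  tab <- table(d$id)
  if (sum(tab >= 2) < 2) stop("need at least two persons with two or more nights")
  m <- lme4::lmer(y ~ 1 + (1 | id), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  s_b <- vc$vcov[vc$grp == "id"]
  s_w <- vc$vcov[vc$grp == "Residual"]
  s_b / (s_b + s_w)
}
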