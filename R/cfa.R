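#' Aggregate caregiver and youth reports into measurement indicators
#'
#' Each rater column is z-scored over its available cases, the per-facet mean
#' of the available rater z-scores is taken (a single available rater stands
#' alone), and the aggregate is re-standardized to sample mean 0 / variance 1.
#'
#' @param profiles person table carrying the 16 `<facet>_<rater>` columns
#'   (see [cohort]); a `nightvar_cohort` is also accepted.
#' @return tibble `person_id` plus one standardized column per facet.
#' @export
aggregate_raters <- function(profiles) {
  if (inherits(profiles, "nightvar_cohort")) profiles <- profiles$persons
  if (nrow(profiles) < 2) stop("need at least two persons to standardize")
  out <- tibble(person_id = profiles$person_id)
  for (f in facet_names) {
    cols <- paste0(f, "_", rater_names)
    cols <- cols[cols %in% names(profiles)]
    if (!length(cols)) stop("no rater columns found for facet ", f)
    zs <- sapply(cols, function(cl) {
      v <- profiles[[cl]]
      if (all(is.na(v))) return(rep(NA_real_, length(v)))
      (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    })
    agg <- rowMeans(as.matrix(zs), na.rm = TRUE)
    agg[is.nan(agg)] <- NA_real_
    if (all(is.na(agg))) stop("facet ", f, " has no non-missing values")
    out[[f]] <- (agg - mean(agg, na.rm = TRUE)) / stats::sd(agg, na.rm = TRUE)
  }
  out
}

# ---- model specification ---------------------------------------------------

new_cfa_spec <- function(indicators, factors, lambda_free, lambda_fixed,
                         phi_free, phi_fixed, theta_free, theta_fixed,
                         fr_free, fr_fixed, name) {
  stopifnot(isSymmetric(phi_free), isSymmetric(theta_free))
  structure(list(
    indicators = indicators, factors = factors,
    lambda_free = lambda_free, lambda_fixed = lambda_fixed,
    phi_free = phi_free, phi_fixed = phi_fixed,
    theta_free = theta_free, theta_fixed = theta_fixed,
    fr_free = fr_free, fr_fixed = fr_fixed, name = name
  ), class = "cfa_spec")
}

#' The bifactor s-1 measurement model of psychopathology
#'
#' All eight indicators load on the general factor; ad/wd/som additionally on
#' a specific internalizing factor and odd/cd/hyp/at on a specific
#' externalizing factor; emotion dysregulation (eri) is the reference
#' indicator and loads on the general factor only. Factor variances are fixed
#' to 1 and all factor covariances to 0. Three model modifications are
#' included: the (hyp, at) and (wd, hyp) residual covariances, and a
#' covariance between the externalizing factor and the ad residual.
#'
#' @return a `cfa_spec`.
#' @export
bifactor_s1_spec <- function() {
  p <- length(facet_names); facs <- c("g", "s_int", "s_ext")
  lf <- matrix(FALSE, p, 3, dimnames = list(facet_names, facs))
  lf[, "g"] <- TRUE
  lf[int_facets, "s_int"] <- TRUE
  lf[ext_facets, "s_ext"] <- TRUE
  l0 <- matrix(0, p, 3, dimnames = dimnames(lf))
  phi_free <- matrix(FALSE, 3, 3, dimnames = list(facs, facs))
  phi_fixed <- diag(3); dimnames(phi_fixed) <- dimnames(phi_free)
  tf <- diag(p) == 1
  dimnames(tf) <- list(facet_names, facet_names)
  tf["hyp", "at"] <- tf["at", "hyp"] <- TRUE
  tf["wd", "hyp"] <- tf["hyp", "wd"] <- TRUE
  t0 <- matrix(0, p, p, dimnames = dimnames(tf))
  fr <- matrix(FALSE, p, 3, dimnames = dimnames(lf))
  fr["ad", "s_ext"] <- TRUE
  f0 <- matrix(0, p, 3, dimnames = dimnames(lf))
  new_cfa_spec(facet_names, facs, lf, l0, phi_free, phi_fixed, tf, t0, fr, f0,
               "bifactor s-1")
}

#' Correlated three-factor measurement model (supplementary specification)
#'
#' Internalizing (ad/wd/som), externalizing (odd/cd/hyp/at) and a
#' single-indicator dysregulation factor (eri with loading fixed to 1 and a
#' residual fixed to `eri_residual` of the indicator variance), all factors
#' freely correlated. The (hyp, at) and (wd, hyp) residual covariances are
#' retained from the bifactor specification.
#'
#' @param eri_residual fixed eri residual variance on the standardized scale.
#' @return a `cfa_spec`.
#' @export
correlated_factors_spec <- function(eri_residual = 0.05) {
  p <- length(facet_names); facs <- c("int", "ext", "dys")
  lf <- matrix(FALSE, p, 3, dimnames = list(facet_names, facs))
  lf[int_facets, "int"] <- TRUE
  lf[ext_facets, "ext"] <- TRUE
  l0 <- matrix(0, p, 3, dimnames = dimnames(lf))
  l0["eri", "dys"] <- 1
  phi_free <- matrix(TRUE, 3, 3, dimnames = list(facs, facs))
  phi_free["int", "int"] <- phi_free["ext", "ext"] <- FALSE
  phi_fixed <- diag(3); dimnames(phi_fixed) <- dimnames(phi_free)
  tf <- diag(p) == 1
  dimnames(tf) <- list(facet_names, facet_names)
  tf["eri", "eri"] <- FALSE
  tf["hyp", "at"] <- tf["at", "hyp"] <- TRUE
  tf["wd", "hyp"] <- tf["hyp", "wd"] <- TRUE
  t0 <- matrix(0, p, p, dimnames = dimnames(tf))
  t0["eri", "eri"] <- eri_residual
  fr <- matrix(FALSE, p, 3, dimnames = dimnames(lf))
  f0 <- matrix(0, p, 3, dimnames = dimnames(lf))
  new_cfa_spec(facet_names, facs, lf, l0, phi_free, phi_fixed, tf, t0, fr, f0,
               "correlated factors")
}

n_free_cov_params <- function(spec) {
  sum(spec$lambda_free) +
    sum(spec$phi_free[upper.tri(spec$phi_free, diag = TRUE)]) +
    sum(spec$theta_free[upper.tri(spec$theta_free, diag = TRUE)]) +
    sum(spec$fr_free)
}

#' Degrees of freedom of a measurement-model specification
#'
#' `p(p+1)/2` unique covariance moments minus the free covariance-structure
#' parameters (loadings, residual variances/covariances, factor covariances,
#' factor-residual covariances). The mean structure is saturated and
#' contributes no net df.
#'
#' @param spec a `cfa_spec`.
#' @return integer df; an over-parameterized spec errors.
#' @export
model_df <- function(spec) {
  stopifnot(inherits(spec, "cfa_spec"))
  p <- length(spec$indicators)
  df <- p * (p + 1) / 2 - n_free_cov_params(spec)
  if (df < 0) stop("over-parameterized specification: df = ", df)
  as.integer(df)
}

# ---- parameter packing -----------------------------------------------------

cfa_par_skeleton <- function(spec) {
  ut_phi <- which(spec$phi_free & upper.tri(spec$phi_free, diag = TRUE))
  ut_theta <- which(spec$theta_free & upper.tri(spec$theta_free, diag = TRUE))
  list(
    i_lambda = which(spec$lambda_free),
    i_phi = ut_phi,
    i_theta = ut_theta,
    i_fr = which(spec$fr_free),
    p = length(spec$indicators), m = length(spec$factors)
  )
}

cfa_unpack <- function(par, spec, sk) {
  nl <- length(sk$i_lambda); np <- length(sk$i_phi)
  nt <- length(sk$i_theta); nf <- length(sk$i_fr)
  Lambda <- spec$lambda_fixed
  Lambda[sk$i_lambda] <- par[seq_len(nl)]
  Phi <- spec$phi_fixed
  Phi[sk$i_phi] <- par[nl + seq_len(np)]
  Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
  Theta <- spec$theta_fixed
  Theta[sk$i_theta] <- par[nl + np + seq_len(nt)]
  Theta[lower.tri(Theta)] <- t(Theta)[lower.tri(Theta)]
  C <- spec$fr_fixed
  C[sk$i_fr] <- par[nl + np + nt + seq_len(nf)]
  mu <- par[nl + np + nt + nf + seq_len(sk$p)]
  list(Lambda = Lambda, Phi = Phi, Theta = Theta, C = C, mu = mu)
}

cfa_implied_sigma <- function(est) {
  cross <- est$Lambda %*% t(est$C)
  est$Lambda %*% est$Phi %*% t(est$Lambda) + cross + t(cross) + est$Theta
}

cfa_start <- function(spec, sk, ybar, jitter = 0) {
  nl <- length(sk$i_lambda)
  lam <- rep(0.5, nl)
  phi <- ifelse(row(spec$phi_free)[sk$i_phi] == col(spec$phi_free)[sk$i_phi],
                0.9, 0.2)
  theta <- ifelse(row(spec$theta_free)[sk$i_theta] ==
                    col(spec$theta_free)[sk$i_theta], 0.5, 0)
  fr <- rep(0, length(sk$i_fr))
  st <- c(lam, phi, theta, fr, ybar)
  if (jitter > 0) st <- st + stats::rnorm(length(st), sd = jitter)
  st
}

# ---- FIML likelihood -------------------------------------------------------

# group rows of Y by missingness pattern; sufficient statistics per pattern
fiml_patterns <- function(Y) {
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, paste, collapse = "")
  lapply(split(seq_len(nrow(Y)), key), function(idx) {
    o <- which(obs[idx[1], ])
    Yo <- Y[idx, o, drop = FALSE]
    ybar <- colMeans(Yo)
    Yc <- sweep(Yo, 2, ybar)
    list(o = o, n = length(idx), ybar = ybar,
         S = crossprod(Yc) / length(idx), idx = idx)
  })
}

# -2 * casewise Gaussian log-likelihood at (mu, Sigma) given pattern stats
fiml_deviance_at <- function(mu, Sigma, patterns) {
  dev <- 0
  for (pt in patterns) {
    So <- Sigma[pt$o, pt$o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- pt$ybar - mu[pt$o]
    dev <- dev + pt$n * (length(pt$o) * log(2 * pi) + logdet +
                           sum(Sinv * pt$S) + drop(t(d) %*% Sinv %*% d))
  }
  dev
}

# ML estimate of the unrestricted (saturated) MVN via EM over patterns
fiml_saturated <- function(Y, tol = 1e-9, max_iter = 1000) {
  p <- ncol(Y)
  patterns <- fiml_patterns(Y)
  n <- sum(vapply(patterns, `[[`, 0, "n"))
  mu <- vapply(seq_len(p), function(j) mean(Y[, j], na.rm = TRUE), 0)
  v <- vapply(seq_len(p), function(j) stats::var(Y[, j], na.rm = TRUE), 0)
  Sigma <- diag(ifelse(is.na(v) | v <= 0, 1, v), p)
  Yk <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p); T2 <- matrix(0, p, p)
    for (pt in patterns) {
      o <- pt$o; m <- setdiff(seq_len(p), o)
      Yo <- Yk[pt$idx, o, drop = FALSE]
      if (length(m)) {
        A <- Sigma[m, o, drop = FALSE] %*% solve(Sigma[o, o, drop = FALSE])
        Em <- matrix(mu[m], pt$n, length(m), byrow = TRUE) +
          sweep(Yo, 2, mu[o]) %*% t(A)
        Cm <- Sigma[m, m, drop = FALSE] - A %*% Sigma[o, m, drop = FALSE]
      }
      full <- matrix(0, pt$n, p)
      full[, o] <- Yo
      if (length(m)) full[, m] <- Em
      T1 <- T1 + colSums(full)
      T2 <- T2 + crossprod(full)
      if (length(m)) T2[m, m] <- T2[m, m] + pt$n * Cm
    }
    mu_new <- T1 / n
    Sigma_new <- T2 / n - tcrossprod(mu_new)
    dev <- fiml_deviance_at(mu_new, Sigma_new, patterns)
    mu <- mu_new; Sigma <- Sigma_new
    if (is.finite(dev) && abs(dev_old - dev) < tol) break
    dev_old <- dev
  }
  list(mu = mu, Sigma = Sigma, loglik = -dev / 2, n = n)
}

# independence baseline: per-variable ML normal fit on observed cases
fiml_baseline <- function(Y) {
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    v <- Y[, j][!is.na(Y[, j])]
    s2 <- mean((v - mean(v))^2)
    ll <- ll - 0.5 * length(v) * (log(2 * pi) + log(s2) + 1)
  }
  p <- ncol(Y)
  list(loglik = ll, df = p * (p + 1) / 2 - p)
}

# ---- fitting ---------------------------------------------------------------

#' Fit a measurement model by full-information maximum likelihood
#'
#' Maximizes the casewise Gaussian log-likelihood over persons with arbitrary
#' missingness patterns; the mean structure is saturated. Global fit indices
#' are computed against the FIML-saturated and independence models; Heywood
#' cases (negative residual variances) raise a warning, not an error.
#'
#' @param panel tibble from [aggregate_raters]: `person_id` plus one
#'   standardized column per indicator of `spec`.
#' @param spec a `cfa_spec`, e.g. [bifactor_s1_spec].
#' @param n_starts number of optimizer starts; the first is deterministic,
#'   further starts jitter it (seeded).
#' @param seed seed for the jittered restarts.
#' @return a `cfa_fit`: estimates (`Lambda`, `Phi`, `Theta`, `C`, `mu`),
#'   standardized loadings, log-likelihoods, chi-square/df against the
#'   saturated model, `cfi`/`rmsea`/`srmr`, convergence info.
#' @export
fit_bifactor_s1 <- function(panel, spec = bifactor_s1_spec(),
                            n_starts = 1L, seed = 1L) {
  stopifnot(inherits(spec, "cfa_spec"))
  Y <- as.matrix(panel[, spec$indicators, drop = FALSE])
  storage.mode(Y) <- "double"
  df <- model_df(spec)
  sk <- cfa_par_skeleton(spec)
  n_free <- n_free_cov_params(spec) + sk$p
  n <- sum(rowSums(!is.na(Y)) > 0)
  if (n < n_free) stop("fewer persons (", n, ") than free parameters (", n_free, ")")
  patterns <- fiml_patterns(Y)

  obj <- function(par) {
    est <- cfa_unpack(par, spec, sk)
    Sigma <- cfa_implied_sigma(est)
    d <- fiml_deviance_at(est$mu, Sigma, patterns)
    if (!is.finite(d)) 1e10 else d
  }
  ybar <- vapply(seq_len(sk$p), function(j) mean(Y[, j], na.rm = TRUE), 0)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(max(1L, n_starts))) {
    st <- cfa_start(spec, sk, ybar, jitter = if (s == 1) 0 else 0.15)
    opt <- stats::nlminb(st, obj,
                         control = list(iter.max = 1000, eval.max = 3000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (best$objective >= 1e10) {
    stop("measurement model failed to converge; best deviance ", best$objective)
  }
  converged <- best$convergence == 0
  if (!converged && n_starts == 1L) {
    # one jittered retry before reporting non-convergence
    st <- cfa_start(spec, sk, ybar, jitter = 0.1)
    opt <- stats::nlminb(st, obj, control = list(iter.max = 2000, eval.max = 5000))
    if (opt$objective <= best$objective) { best <- opt; converged <- best$convergence == 0 }
  }
  est <- cfa_unpack(best$par, spec, sk)
  Sigma_hat <- cfa_implied_sigma(est)
  if (any(diag(est$Theta) < 0)) {
    warning("Heywood case: negative residual variance for ",
            paste(spec$indicators[diag(est$Theta) < 0], collapse = ", "))
  }
  sat <- fiml_saturated(Y)
  base <- fiml_baseline(Y)
  loglik <- -best$objective / 2
  chisq <- max(0, 2 * (sat$loglik - loglik))
  chisq_base <- max(0, 2 * (sat$loglik - base$loglik))
  std <- est$Lambda %*% diag(sqrt(diag(est$Phi)), length(spec$factors))
  std <- std / sqrt(diag(Sigma_hat))
  dimnames(std) <- dimnames(est$Lambda)
  fit <- structure(list(
    spec = spec, est = est, Sigma = Sigma_hat, std_loadings = std,
    loglik = loglik, df = df,
    chisq = chisq, loglik_sat = sat$loglik, S_sat = sat$Sigma,
    chisq_base = chisq_base, df_base = base$df, loglik_base = base$loglik,
    n = n, npar = n_free, convergence = converged,
    heywood = any(diag(est$Theta) < 0), par = best$par
  ), class = "cfa_fit")
  fit[c("cfi", "rmsea", "srmr")] <- fit_indices(fit)
  fit
}

#' Global fit indices of a fitted measurement model
#'
#' CFI against the independence baseline, RMSEA with `n` in the denominator,
#' and SRMR over the unique variance/covariance elements (standardized by the
#' saturated-model variances).
#'
#' @param fit a `cfa_fit`.
#' @param baseline optional list with `chisq` and `df` overriding the
#'   independence baseline stored in `fit`.
#' @return list `cfi`, `rmsea`, `srmr`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  tm <- fit$chisq - fit$df
  if (is.null(baseline)) baseline <- list(chisq = fit$chisq_base, df = fit$df_base)
  tb <- baseline$chisq - baseline$df
  denom <- max(tb, tm, 0)
  cfi <- if (denom == 0) 1 else 1 - max(tm, 0) / denom
  if (fit$df == 0) {
    if (fit$chisq > 1e-6) stop("RMSEA undefined: df = 0 with nonzero chi-square")
    rmsea <- 0
  } else {
    rmsea <- sqrt(max(tm, 0) / (fit$df * fit$n))
  }
  S <- fit$S_sat; Sig <- fit$Sigma
  sdS <- sqrt(diag(S))
  R <- (S - Sig) / tcrossprod(sdS)
  srmr <- sqrt(mean(R[upper.tri(R, diag = TRUE)]^2))
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

#' Regression-method (posterior mean) factor scores
#'
#' For each person the expected factor vector given the observed subset of
#' indicators under the fitted model: `Cov(eta, y_o) Sigma_oo^{-1} (y_o -
#' mu_o)`. Persons with all indicators missing get missing scores and keep
#' their row.
#'
#' @param fit a `cfa_fit`.
#' @param panel the indicator panel the scores are computed on (defaults must
#'   be supplied; typically the fitting panel).
#' @return tibble `person_id` plus one score column per factor.
#' @export
factor_scores <- function(fit, panel) {
  stopifnot(inherits(fit, "cfa_fit"))
  spec <- fit$spec
  Y <- as.matrix(panel[, spec$indicators, drop = FALSE])
  storage.mode(Y) <- "double"
  cov_eta_y <- fit$est$Phi %*% t(fit$est$Lambda) + t(fit$est$C)  # m x p
  scores <- matrix(NA_real_, nrow(Y), length(spec$factors),
                   dimnames = list(NULL, spec$factors))
  obs <- !is.na(Y)
  key <- apply(obs, 1, paste, collapse = "")
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- which(obs[idx[1], ])
    if (!length(o)) next
    A <- cov_eta_y[, o, drop = FALSE] %*%
      solve(fit$Sigma[o, o, drop = FALSE])
    scores[idx, ] <- sweep(Y[idx, o, drop = FALSE], 2, fit$est$mu[o]) %*% t(A)
  }
  dplyr::bind_cols(tibble(person_id = panel$person_id), as_tibble(scores))
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("<cfa_fit> ", x$spec$name, " model, n = ", x$n, "\n", sep = "")
  cat(sprintf("  chi-square(%d) = %.3f, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$df, x$chisq, x$cfi, x$rmsea, x$srmr))
  cat("  standardized loadings:\n")
  print(round(x$std_loadings, 3))
  if (!x$convergence) cat("  WARNING: optimizer reported non-convergence\n")
  invisible(x)
}
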