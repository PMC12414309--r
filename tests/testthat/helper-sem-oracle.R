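# Self-contained maximum-likelihood SEM fitter used as an independent oracle
# for complete-data panels. Deliberately different from the package's engine:
# RAM formulation over the joint (observed, latent) variable set, sufficient-
# statistic (Wishart-form) deviance, BFGS optimizer.
#
# Parameter vector for the bifactor s-1 structure (covariance part only;
# means are profiled out analytically as the sample means):
#   15 loadings, 8 residual variances, theta(hyp,at), theta(wd,hyp),
#   cov(s_ext, ad residual)
oracle_sigma_bifactor <- function(par) {
  v <- c("ad", "wd", "som", "odd", "cd", "hyp", "at", "eri",
         "g", "s_int", "s_ext")
  nv <- length(v)
  A <- matrix(0, nv, nv, dimnames = list(v, v))   # directed paths
  S <- matrix(0, nv, nv, dimnames = list(v, v))   # symmetric (co)variances
  obs <- v[1:8]
  A[obs, "g"] <- par[1:8]
  A[c("ad", "wd", "som"), "s_int"] <- par[9:11]
  A[c("odd", "cd", "hyp", "at"), "s_ext"] <- par[12:15]
  diag(S)[obs] <- par[16:23]
  S["hyp", "at"] <- S["at", "hyp"] <- par[24]
  S["wd", "hyp"] <- S["hyp", "wd"] <- par[25]
  S["ad", "s_ext"] <- S["s_ext", "ad"] <- par[26]
  diag(S)[c("g", "s_int", "s_ext")] <- 1
  IA <- solve(diag(nv) - A)
  Sigma_all <- IA %*% S %*% t(IA)
  Sigma_all[obs, obs]
}

# ML deviance for complete data given sample moments (ML covariance, /n)
oracle_deviance <- function(par, S_ml, n) {
  Sigma <- oracle_sigma_bifactor(par)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  p <- ncol(S_ml)
  n * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
         sum(chol2inv(ch) * S_ml))
}

oracle_fit_bifactor <- function(Y) {
  stopifnot(!anyNA(Y))
  n <- nrow(Y)
  ybar <- colMeans(Y)
  S_ml <- crossprod(sweep(Y, 2, ybar)) / n
  start <- c(rep(0.6, 8), rep(0.4, 7), rep(0.4, 8), 0, 0, 0)
  opt <- stats::optim(start, oracle_deviance, S_ml = S_ml, n = n,
                      method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  lam_g <- opt$par[1:8]
  names(lam_g) <- c("ad", "wd", "som", "odd", "cd", "hyp", "at", "eri")
  lam_s <- opt$par[9:15]
  names(lam_s) <- c("ad", "wd", "som", "odd", "cd", "hyp", "at")
  # sign indeterminacy: fix each factor's orientation to positive loadings
  if (sum(lam_g) < 0) lam_g <- -lam_g
  if (sum(lam_s[1:3]) < 0) lam_s[1:3] <- -lam_s[1:3]
  if (sum(lam_s[4:7]) < 0) lam_s[4:7] <- -lam_s[4:7]
  # profile the saturated means back in: deviance includes no mean term at
  # mu = ybar, so the full loglik is just -deviance/2
  list(loglik = -opt$value / 2, lambda_g = lam_g, lambda_s = lam_s,
       df = 8 * 9 / 2 - 26, convergence = opt$convergence)
}
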