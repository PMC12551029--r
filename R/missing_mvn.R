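# Estimation core: maximum likelihood for a partially observed multivariate
# normal (EM over missingness patterns), regression derived from the fitted
# moments (FIML regression), couple-cluster-robust sandwich covariance built
# from per-cluster scores of the observed-data likelihood, and chi-square
# based fit statistics.

# ---- missingness patterns ---------------------------------------------------

mvn_patterns <- function(X) {
  obs <- !is.na(X)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  lapply(split(seq_len(nrow(X)), key), function(idx) {
    list(idx = idx, obs = which(obs[idx[1L], ]))
  })
}

# Observed-data log-likelihood, already given patterns.
mvn_loglik_patterns <- function(X, patterns, mu, Sigma) {
  ll <- 0
  for (p in patterns) {
    o <- p$obs
    So <- Sigma[o, o, drop = FALSE]
    ld <- as.numeric(determinant(So, logarithm = TRUE)$modulus)
    K <- solve(So)
    e <- sweep(X[p$idx, o, drop = FALSE], 2L, mu[o])
    ll <- ll - 0.5 * (length(p$idx) * (length(o) * log(2 * pi) + ld) +
                        sum((e %*% K) * e))
  }
  ll
}

#' Observed-data Gaussian log-likelihood
#'
#' Sum over rows of the marginal normal density of each row's observed
#' entries under mean `mu` and covariance `Sigma`.
#'
#' @param X numeric matrix with possible NA entries (no fully missing rows).
#' @param mu mean vector.
#' @param Sigma covariance matrix.
#' @return scalar log-likelihood.
#' @export
mvn_loglik <- function(X, mu, Sigma) {
  X <- as.matrix(X)
  mvn_loglik_patterns(X, mvn_patterns(X), mu, Sigma)
}

# ---- EM ---------------------------------------------------------------------

#' EM estimation of a multivariate normal with missing data
#'
#' Full-information maximum likelihood for the mean and covariance of a
#' multivariate normal observed with arbitrary (missing-at-random)
#' missingness patterns. The E-step computes conditional means and
#' covariances of the missing block per pattern; the M-step pools the
#' expected sufficient statistics. The ML covariance uses the n (not n - 1)
#' denominator; the log-likelihood sequence is non-decreasing.
#'
#' Rows with every variable missing are dropped with a warning.
#' Non-convergence within `max_iter` sets a warning flag on the fit rather
#' than failing; a singular covariance update is ridge-regularized
#' (1e-8 * trace/d on the diagonal) with a warning.
#'
#' @param data numeric matrix or data.frame (observations x variables).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @return object of class `mvn_fit`: variables, `mean`, `cov`, `loglik`,
#'   `ll_trace`, `n`, `n_patterns`, `iterations`, `converged`, `ridge_used`.
#' @export
em_mvn <- function(data, tol = 1e-8, max_iter = 500L) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(X)))
  colnames(X) <- vars
  p <- ncol(X)

  all_missing <- rowSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    dr_warn("dropping %d fully missing row(s)", sum(all_missing))
    X <- X[!all_missing, , drop = FALSE]
  }
  n <- nrow(X)
  n_obs_var <- colSums(!is.na(X))
  if (any(n_obs_var < 2L))
    dr_stop("estimation", "variable(s) observed fewer than twice: %s",
            paste(vars[n_obs_var < 2L], collapse = ", "))

  patterns <- mvn_patterns(X)
  mu <- colMeans(X, na.rm = TRUE)
  v0 <- apply(X, 2L, stats::var, na.rm = TRUE)
  v0[!is.finite(v0) | v0 <= 0] <- 1
  Sigma <- diag(v0, p)
  dimnames(Sigma) <- list(vars, vars)

  ll_trace <- numeric(0L)
  converged <- FALSE
  ridge_used <- FALSE
  iter <- 0L
  ll_old <- -Inf
  repeat {
    iter <- iter + 1L
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (pt in patterns) {
      o <- pt$obs
      m <- setdiff(seq_len(p), o)
      np <- length(pt$idx)
      Xo <- X[pt$idx, o, drop = FALSE]
      So <- Sigma[o, o, drop = FALSE]
      ld <- as.numeric(determinant(So, logarithm = TRUE)$modulus)
      K <- solve(So)
      e <- sweep(Xo, 2L, mu[o])
      ll <- ll - 0.5 * (np * (length(o) * log(2 * pi) + ld) +
                          sum((e %*% K) * e))
      T1[o] <- T1[o] + colSums(Xo)
      T2[o, o] <- T2[o, o] + crossprod(Xo)
      if (length(m)) {
        B <- Sigma[m, o, drop = FALSE] %*% K
        Xm <- matrix(mu[m], np, length(m), byrow = TRUE) + e %*% t(B)
        Cm <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
        T1[m] <- T1[m] + colSums(Xm)
        cross <- crossprod(Xo, Xm)
        T2[o, m] <- T2[o, m] + cross
        T2[m, o] <- T2[m, o] + t(cross)
        T2[m, m] <- T2[m, m] + crossprod(Xm) + np * Cm
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 1e-12 * mean(diag(Sigma))) {
      ridge <- 1e-8 * sum(diag(Sigma)) / p
      Sigma <- Sigma + diag(ridge, p)
      if (!ridge_used) dr_warn("singular covariance update: ridge %.3g added",
                               ridge)
      ridge_used <- TRUE
    }
    dimnames(Sigma) <- list(vars, vars)
  }
  if (!converged)
    dr_warn("em_mvn did not converge in %d iterations (last change %.3g)",
            max_iter, abs(ll - ll_old))
  names(mu) <- vars
  structure(list(variables = vars, mean = mu, cov = Sigma,
                 loglik = ll, ll_trace = ll_trace, n = n,
                 n_patterns = length(patterns), iterations = iter,
                 converged = converged, ridge_used = ridge_used,
                 data = X, patterns = patterns),
            class = "mvn_fit")
}

#' @export
print.mvn_fit <- function(x, ...) {
  cat(sprintf("<mvn_fit> %d obs, %d variables, %d missingness pattern(s)\n",
              x$n, length(x$variables), x$n_patterns))
  cat(sprintf("  logLik %.4f after %d EM iteration(s)%s\n", x$loglik,
              x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Dump an `mvn_fit` as JSON
#'
#' Diagnostic dump of the fitted means, covariance and log-likelihood trace.
#'
#' @param fit an `mvn_fit`.
#' @param path output file path.
#' @export
mvn_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(variables = fit$variables, mean = fit$mean,
         cov = fit$cov, loglik = fit$loglik, ll_trace = fit$ll_trace,
         n = fit$n, n_patterns = fit$n_patterns,
         iterations = fit$iterations, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- scores of the observed-data likelihood --------------------------------

# theta = c(mu, vech(Sigma)); vech over pairs (j <= k).
vech_pairs <- function(p) {
  jk <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  jk[order(jk[, 2L], jk[, 1L]), , drop = FALSE]  # column-major upper triangle
}

pack_theta <- function(mu, Sigma) {
  p <- length(mu)
  jk <- vech_pairs(p)
  c(mu, Sigma[jk])
}

unpack_theta <- function(theta, p) {
  mu <- theta[seq_len(p)]
  v <- theta[-seq_len(p)]
  jk <- vech_pairs(p)
  Sigma <- matrix(if (is.complex(theta)) 0 + 0i else 0, p, p)
  Sigma[jk] <- v
  Sigma[jk[, c(2L, 1L)]] <- v
  list(mu = mu, Sigma = Sigma)
}

# Per-observation score vectors d l_i / d theta. Works for complex theta
# (used for complex-step differentiation of the total score). Returns an
# n x d matrix; for l depending only on observed entries, components of
# theta not touching the observed block have zero score.
mvn_scores <- function(X, patterns, theta, p) {
  th <- unpack_theta(theta, p)
  mu <- th$mu
  Sigma <- th$Sigma
  jk <- vech_pairs(p)
  d <- p + nrow(jk)
  cplx <- is.complex(theta)
  S <- matrix(if (cplx) 0 + 0i else 0, nrow(X), d)
  # column index of vech pair (j, k), j <= k
  vech_col <- matrix(0L, p, p)
  vech_col[jk] <- seq_len(nrow(jk))
  vech_col[jk[, c(2L, 1L)]] <- seq_len(nrow(jk))
  for (pt in patterns) {
    o <- pt$obs
    K <- solve(Sigma[o, o, drop = FALSE])
    e <- sweep(X[pt$idx, o, drop = FALSE], 2L, mu[o])
    U <- e %*% K
    S[pt$idx, o] <- U
    for (a in seq_along(o)) for (b in a:length(o)) {
      j <- o[a]; k <- o[b]
      col <- p + vech_col[j, k]
      if (a == b) {
        S[pt$idx, col] <- S[pt$idx, col] + 0.5 * (U[, a]^2 - K[a, a])
      } else {
        S[pt$idx, col] <- S[pt$idx, col] + U[, a] * U[, b] - K[a, b]
      }
    }
  }
  S
}

# Observed information A = -d(total score)/d(theta), by complex step:
# exact to machine precision because the score is analytic in theta.
mvn_information <- function(X, patterns, theta, p) {
  d <- length(theta)
  A <- matrix(0, d, d)
  h <- 1e-100
  for (j in seq_len(d)) {
    thc <- theta + 0i
    thc[j] <- thc[j] + 1i * h
    A[, j] <- -Im(colSums(mvn_scores(X, patterns, thc, p))) / h
  }
  (A + t(A)) / 2
}

# Complex-step Jacobian of a (vector-valued, analytic) function of theta.
cstep_jacobian <- function(fun, theta) {
  h <- 1e-100
  g0 <- fun(theta + 0i)
  J <- matrix(0, length(g0), length(theta))
  for (j in seq_along(theta)) {
    thc <- theta + 0i
    thc[j] <- thc[j] + 1i * h
    J[, j] <- Im(fun(thc)) / h
  }
  rownames(J) <- names(g0)
  J
}

# ---- FIML regression --------------------------------------------------------

# Regression functionals of theta: intercept, raw slopes, standardized
# slopes, R^2. Written to accept complex theta for the delta method.
regression_functionals <- function(theta, p, iy, ix) {
  th <- unpack_theta(theta, p)
  Sxx <- th$Sigma[ix, ix, drop = FALSE]
  Sxy <- th$Sigma[ix, iy]
  b <- solve(Sxx, Sxy)
  a <- th$mu[iy] - sum(b * th$mu[ix])
  syy <- th$Sigma[iy, iy]
  expl <- sum(b * Sxy)
  sdx <- sqrt(diag(Sxx))
  beta_std <- b * sdx / sqrt(syy)
  c(intercept = a, b, stats::setNames(beta_std, paste0("std_", names(b))),
    r2 = expl / syy)
}

#' FIML regression with cluster-robust standard errors
#'
#' Fits the joint multivariate normal of (outcome, predictors) by [em_mvn()]
#' and derives the linear regression from the fitted moments:
#' b = Sigma_xx^-1 Sigma_xy, intercept from the means,
#' R^2 = b' Sigma_xx b / sigma_yy, and standardized coefficients
#' beta_j = b_j * SD(x_j) / SD(y) using model-implied SDs. This uses every
#' partially observed row (predictors-missing rows included) and is unbiased
#' under missing-at-random.
#'
#' Standard errors are a cluster sandwich over per-cluster score
#' contributions of the observed-data likelihood, mapped to the regression
#' functionals by the delta method; the CR0 meat carries a G/(G-1)
#' small-sample factor (G = number of clusters). With complete data and
#' singleton clusters the coefficient estimates equal ordinary least squares
#' and the SEs equal heteroskedasticity-robust (HC0) SEs. Wald z and
#' two-tailed normal p-values are reported per coefficient.
#'
#' @param data data.frame or matrix holding outcome and predictor columns.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param cluster cluster id vector (length nrow(data)) or the name of a
#'   column of `data`; singleton clusters give observation-level robust SEs.
#' @param tol,max_iter passed to [em_mvn()].
#' @param cr_correction small-sample factor: `"CR1"` (default, G/(G-1)) or
#'   `"CR0"` (none).
#' @return object of class `fiml_fit`: `coef` table (term, b, se, z, p,
#'   beta_std, beta_se), `r2`, `n`, `n_clusters`, `loglik`, `fit_indices`,
#'   `vcov` (raw-coefficient block incl. intercept), and the underlying
#'   `mvn` fit.
#' @export
fiml_regression <- function(data, outcome, predictors, cluster,
                            tol = 1e-8, max_iter = 500L,
                            cr_correction = c("CR1", "CR0")) {
  cr_correction <- match.arg(cr_correction)
  data <- as.data.frame(data)
  miss_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(miss_cols))
    dr_stop("data", "column(s) not found: %s", paste(miss_cols, collapse = ", "))
  if (is.character(cluster) && length(cluster) == 1L) {
    if (!cluster %in% names(data))
      dr_stop("data", "cluster column '%s' not found", cluster)
    cluster <- data[[cluster]]
  }
  if (length(cluster) != nrow(data))
    dr_stop("data", "cluster ids must match the number of observations")

  X <- as.matrix(data[, c(outcome, predictors), drop = FALSE])
  keep <- rowSums(!is.na(X)) > 0L
  if (!all(keep)) {
    dr_warn("dropping %d fully missing row(s)", sum(!keep))
    X <- X[keep, , drop = FALSE]
    cluster <- cluster[keep]
  }
  cluster <- as.character(cluster)
  G <- length(unique(cluster))
  if (G < length(predictors) + 1L)
    dr_stop("estimation", "fewer clusters (%d) than parameters (%d)",
            G, length(predictors) + 1L)

  fit <- em_mvn(X, tol = tol, max_iter = max_iter)
  p <- length(fit$variables)
  iy <- 1L
  ix <- seq_len(p)[-1L]

  Rxx <- stats::cov2cor(fit$cov[ix, ix, drop = FALSE])
  ev <- eigen(Rxx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    off <- abs(Rxx); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1L, ]
    dr_stop("estimation", "collinear predictors: %s and %s (|r| = %.4f)",
            predictors[worst[1L]], predictors[worst[2L]], max(off))
  }

  theta <- pack_theta(fit$mean, fit$cov)
  gfun <- function(th) regression_functionals(th, p, iy, ix)
  est <- gfun(theta)

  # sandwich on theta, delta method to the functionals
  S <- mvn_scores(fit$data, fit$patterns, theta, p)
  Sg <- rowsum(S, cluster)
  meat <- crossprod(Sg)
  if (cr_correction == "CR1") meat <- meat * G / (G - 1)
  A <- mvn_information(fit$data, fit$patterns, theta, p)
  Ainv <- solve(A)
  Vtheta <- Ainv %*% meat %*% t(Ainv)
  J <- cstep_jacobian(gfun, theta)
  Vg <- J %*% Vtheta %*% t(J)
  se <- sqrt(pmax(diag(Vg), 0))

  k <- length(predictors)
  terms <- c("(Intercept)", predictors)
  b <- est[seq_len(k + 1L)]
  b_se <- se[seq_len(k + 1L)]
  z <- b / b_se
  coef_tab <- data.frame(
    term = terms, b = unname(b), se = unname(b_se), z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))),
    beta_std = c(NA, unname(est[k + 1L + seq_len(k)])),
    beta_se = c(NA, unname(se[k + 1L + seq_len(k)])),
    stringsAsFactors = FALSE)

  # The regression model is just-identified given the joint-normal fit, so
  # its implied moment structure is saturated: chi-square 0 against the
  # saturated model, CFI 1 (baseline = independence with free means and
  # variances, itself fitted by FIML).
  ll_base <- independence_loglik(fit$data)
  fi <- fit_indices(model_loglik = fit$loglik, saturated_loglik = fit$loglik,
                    baseline_loglik = ll_base, df_model = 0L,
                    df_baseline = p * (p - 1L) / 2L, n = fit$n)

  structure(list(outcome = outcome, predictors = predictors,
                 coef = coef_tab, r2 = unname(est["r2"]),
                 r2_se = unname(se[length(se)]),
                 n = fit$n, n_clusters = G, loglik = fit$loglik,
                 baseline_loglik = ll_base, fit_indices = fi,
                 vcov = Vg[seq_len(k + 1L), seq_len(k + 1L), drop = FALSE],
                 cr_correction = cr_correction, mvn = fit),
            class = "fiml_fit")
}

#' @export
print.fiml_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<fiml_fit> %s ~ %s\n", x$outcome,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, clusters = %d, R^2 = %.3f, logLik = %.3f\n",
              x$n, x$n_clusters, x$r2, x$loglik))
  tab <- x$coef
  tab$stars <- stars_for(tab$p)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

stars_for <- function(p) ifelse(is.na(p), "",
                                ifelse(p < 0.01, "**",
                                       ifelse(p < 0.05, "*", "")))

# FIML log-likelihood of the independence model (diagonal covariance, free
# means and variances). With a diagonal covariance the observed-data
# likelihood separates across variables, so each variable's univariate ML
# fit over its observed values is the joint MLE.
independence_loglik <- function(X) {
  ll <- 0
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x <- x[!is.na(x)]
    m <- mean(x)
    v <- mean((x - m)^2)
    ll <- ll - 0.5 * length(x) * (log(2 * pi) + log(v) + 1)
  }
  ll
}

#' Increment in explained variance between nested models
#'
#' @param full,reduced `fiml_fit` objects on the same data with the reduced
#'   predictor set a subset of the full one.
#' @return R^2(full) - R^2(reduced).
#' @export
delta_r2 <- function(full, reduced) {
  if (!all(reduced$predictors %in% full$predictors) ||
      !identical(full$outcome, reduced$outcome))
    dr_stop("estimation", "models are not nested (same outcome, predictor subset)")
  if (full$n != reduced$n)
    dr_stop("estimation", "models were fitted on different numbers of observations")
  full$r2 - reduced$r2
}

#' Chi-square based global fit statistics
#'
#' chi2 = 2 (ll_saturated - ll_model);
#' RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)));
#' CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_b - df_b, chi2_m - df_m, eps),
#' with the baseline the independence model. A model with df = 0 reports
#' RMSEA 0 with a note (the statistic is undefined for saturated models).
#'
#' @param model_loglik,saturated_loglik,baseline_loglik log-likelihoods.
#' @param df_model,df_baseline degrees of freedom of model and baseline.
#' @param n number of observations.
#' @return list with `chisq`, `df`, `rmsea`, `cfi`, `chisq_baseline`,
#'   `df_baseline`, `note`.
#' @export
fit_indices <- function(model_loglik, saturated_loglik, baseline_loglik,
                        df_model, df_baseline, n) {
  tol <- 1e-6 * max(1, abs(saturated_loglik))
  if (model_loglik > saturated_loglik + tol ||
      baseline_loglik > model_loglik + tol)
    dr_stop("estimation",
            "expected saturated >= model >= baseline log-likelihood")
  chisq_m <- max(2 * (saturated_loglik - model_loglik), 0)
  chisq_b <- max(2 * (saturated_loglik - baseline_loglik), 0)
  note <- NULL
  if (df_model == 0L) {
    rmsea <- 0
    note <- "df = 0: model is saturated, RMSEA reported as 0"
  } else {
    rmsea <- sqrt(max(chisq_m - df_model, 0) / (df_model * (n - 1)))
  }
  denom <- max(chisq_b - df_baseline, chisq_m - df_model, 1e-12)
  cfi <- 1 - max(chisq_m - df_model, 0) / denom
  list(chisq = chisq_m, df = df_model, rmsea = rmsea, cfi = cfi,
       chisq_baseline = chisq_b, df_baseline = df_baseline, note = note)
}

#' Paired within-person change test across waves
#'
#' One-sample t-test on within-person wave differences (wave 6 minus wave
#' 5), df = number of complete pairs minus one.
#'
#' @param w5,w6 numeric vectors of wave-5 and wave-6 values.
#' @param ids optional person ids for both vectors; when given, pairs are
#'   matched by id, otherwise positionally.
#' @return list with `t`, `df`, `p`, `mean_change`, `sd_change`, `n_pairs`.
#' @export
paired_change_test <- function(w5, w6, ids = NULL) {
  if (!is.null(ids)) {
    if (length(ids) != length(w5) || length(w5) != length(w6))
      dr_stop("data", "w5, w6 and ids must have equal length")
    names(w5) <- names(w6) <- ids
  }
  d <- w6 - w5
  d <- d[!is.na(d)]
  if (length(d) < 2L)
    dr_stop("estimation", "need at least 2 complete pairs, got %d", length(d))
  # essentially-constant differences (to floating-point precision)
  if (stats::sd(d) <= sqrt(.Machine$double.eps) * max(abs(mean(d)), 1e-10)) {
    if (abs(mean(d)) <= 1e-10)
      return(list(t = 0, df = length(d) - 1L, p = 1,
                  mean_change = 0, sd_change = 0, n_pairs = length(d)))
    dr_stop("estimation",
            "all within-person differences identical and nonzero: SD undefined for the t statistic")
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_change = mean(d), sd_change = stats::sd(d),
       n_pairs = length(d))
}
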