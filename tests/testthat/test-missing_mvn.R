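test_that("EM on complete data lands on the closed-form ML estimates", {
  set.seed(21)
  X <- matrix(rnorm(300), 100, 3) %*% chol(matrix(c(1, .4, .2,
                                                    .4, 1, .3,
                                                    .2, .3, 1), 3))
  colnames(X) <- c("a", "b", "c")
  fit <- em_mvn(X)
  n <- nrow(X)
  expect_equal(unname(fit$mean), unname(colMeans(X)), tolerance = 1e-10)
  expect_equal(unname(fit$cov), unname(cov(X) * (n - 1) / n),
               tolerance = 1e-10)
  expect_true(fit$converged)
  expect_equal(fit$loglik, mvn_loglik(X, fit$mean, fit$cov))
})

test_that("EM log-likelihood is monotone non-decreasing on masked data", {
  Sigma <- matrix(0.4, 4, 4); diag(Sigma) <- 1
  for (s in 1:5) {
    X <- masked_mvn(200, Sigma, mu = c(1, -1, 0, 2), miss = 0.25, seed = s)
    fit <- em_mvn(X)
    expect_true(all(diff(fit$ll_trace) >= -1e-8))
    expect_true(fit$converged)
  }
})

test_that("EM recovers known moments from MCAR-masked draws", {
  Sigma <- matrix(c(1, .5, .3,
                    .5, 1.5, .4,
                    .3, .4, 0.8), 3)
  mu <- c(0.5, -1, 2)
  n <- 5000
  X <- masked_mvn(n, Sigma, mu, miss = 0.2, seed = 42)
  fit <- em_mvn(X)
  # Monte-Carlo SEs: mean ~ sqrt(sigma_jj / n_eff); cov entry ~
  # sqrt((sigma_jj sigma_kk + sigma_jk^2) / n_eff), n_eff ~ 0.64 n (both
  # entries observed)
  n_eff <- 0.6 * n
  se_mu <- sqrt(diag(Sigma) / n_eff)
  expect_true(all(abs(fit$mean - mu) < 3 * se_mu))
  se_cov <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n_eff)
  expect_true(all(abs(fit$cov - Sigma) < 3 * se_cov))
})

test_that("singular updates are ridge-regularized with a warning", {
  set.seed(8)
  x <- rnorm(50)
  X <- cbind(a = x, b = x, c = rnorm(50))  # exact duplicate column
  expect_warning(fit <- em_mvn(X), "ridge")
  expect_true(fit$ridge_used)
})

test_that("FIML regression equals OLS and its sandwich equals HC0 with singleton clusters", {
  set.seed(31)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + rnorm(n) * (1 + 0.5 * abs(d$x1))
  f <- fiml_regression(d, "y", c("x1", "x2"), cluster = as.character(1:n),
                       cr_correction = "CR0")
  ols <- lm(y ~ x1 + x2, d)
  expect_equal(f$coef$b, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$r2, summary(ols)$r.squared, tolerance = 1e-8)
  skip_if_not_installed("sandwich")
  hc0 <- sqrt(diag(sandwich::vcovHC(ols, type = "HC0")))
  expect_equal(f$coef$se, unname(hc0), tolerance = 1e-8)
})

test_that("standardized coefficients relate to raw ones through model SDs", {
  set.seed(32)
  n <- 100
  d <- data.frame(x1 = rnorm(n, 0, 3), x2 = rnorm(n, 5, 0.5))
  d$y <- 2 - 0.2 * d$x1 + 1.5 * d$x2 + rnorm(n)
  f <- fiml_regression(d, "y", c("x1", "x2"), cluster = as.character(1:n))
  sds <- sqrt(diag(f$mvn$cov))
  expect_equal(f$coef$beta_std[-1],
               f$coef$b[-1] * sds[c("x1", "x2")] / sds["y"],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the likelihood scales out: duplicating every observation leaves coefficients unchanged", {
  Sigma <- matrix(c(1, .4, .4, 1), 2)
  X <- masked_mvn(120, Sigma, miss = 0.15, seed = 33)
  d <- as.data.frame(X)
  cl <- rep(1:40, 3)
  f1 <- fiml_regression(d, "v1", "v2", cluster = cl)
  f2 <- fiml_regression(rbind(d, d), "v1", "v2", cluster = c(cl, cl + 100))
  expect_equal(f1$coef$b, f2$coef$b, tolerance = 1e-6)
})

test_that("the cluster sandwich is invariant to relabeling and row order", {
  Sigma <- matrix(c(1, .5, .5, 1.2), 2)
  X <- masked_mvn(150, Sigma, miss = 0.2, seed = 34)
  d <- as.data.frame(X)
  cl <- rep(1:50, each = 3)
  f1 <- fiml_regression(d, "v1", "v2", cluster = cl)
  # relabel clusters and shuffle rows together
  set.seed(1)
  perm <- sample(150)
  f2 <- fiml_regression(d[perm, ], "v1", "v2",
                        cluster = paste0("g", 1000 - cl[perm]))
  expect_equal(f1$coef$se, f2$coef$se, tolerance = 1e-8)
  expect_equal(f1$coef$b, f2$coef$b, tolerance = 1e-8)
})

test_that("errors surface for too few clusters, collinearity and bad columns", {
  set.seed(35)
  d <- data.frame(y = rnorm(20), x1 = rnorm(20))
  d$x2 <- d$x1  # exact copy
  expect_error(
    suppressWarnings(fiml_regression(d, "y", c("x1", "x2"),
                                     cluster = as.character(1:20))),
    "collinear.*x[12].*x[12]")
  expect_error(fiml_regression(d, "y", "x1", cluster = rep("c1", 20)),
               "fewer clusters")
  expect_error(fiml_regression(d, "y", "nope", cluster = 1:20),
               "not found")
})

test_that("delta_r2 computes nested R-squared increments", {
  mock <- function(r2, preds) structure(
    list(outcome = "y", predictors = preds, r2 = r2, n = 383L),
    class = "fiml_fit")
  expect_equal(delta_r2(mock(0.312, c("a", "b")), mock(0.277, "a")), 0.035)
  expect_equal(delta_r2(mock(0.5, "a"), mock(0.5, "a")), 0)
  expect_error(delta_r2(mock(0.5, "a"), mock(0.4, "b")), "not nested")
})

test_that("a pure-noise predictor adds almost no explained variance", {
  set.seed(36)
  n <- 5000
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 0.5 * d$x + rnorm(n)
  f1 <- fiml_regression(d, "y", "x", cluster = as.character(1:n))
  f2 <- fiml_regression(d, "y", c("x", "z"), cluster = as.character(1:n))
  expect_lt(delta_r2(f2, f1), 0.01)
  expect_gte(delta_r2(f2, f1), 0)
})

test_that("fit indices follow the chi-square formulas", {
  # worked example, computed by hand:
  # chisq_m = 2(-100 - (-110)) = 20; df 5; n 101
  # RMSEA = sqrt((20 - 5) / (5 * 100)) = sqrt(0.03)
  # chisq_b = 100, df_b 10; CFI = 1 - 15 / 90
  fi <- fit_indices(-110, -100, -150, df_model = 5L, df_baseline = 10L,
                    n = 101)
  expect_equal(fi$chisq, 20)
  expect_equal(fi$rmsea, sqrt(0.03))
  expect_equal(fi$cfi, 1 - 15 / 90)

  # chisq below df floors RMSEA at zero
  fi2 <- fit_indices(-101, -100, -150, df_model = 5L, df_baseline = 10L,
                     n = 101)
  expect_equal(fi2$rmsea, 0)

  # saturated model: chisq 0, CFI 1, df 0 note
  fi3 <- fit_indices(-100, -100, -150, df_model = 0L, df_baseline = 10L,
                     n = 101)
  expect_equal(fi3$chisq, 0)
  expect_equal(fi3$cfi, 1)
  expect_match(fi3$note, "saturated")

  expect_error(fit_indices(-90, -100, -150, 5L, 10L, 101), "saturated")
})

test_that("paired change test handles matched pairs and degenerate input", {
  set.seed(37)
  w5 <- rnorm(50)
  expect_equal(paired_change_test(w5, w5)$t, 0)

  # constant nonzero differences: SD undefined
  expect_error(paired_change_test(w5, w5 + 1), "SD undefined")
  expect_error(paired_change_test(1, 2), "at least 2")

  # id-matched pairs, NA pairs dropped from df
  w6 <- w5 + rnorm(50, 0.3)
  w6[1:5] <- NA
  out <- paired_change_test(w5, w6, ids = paste0("p", 1:50))
  expect_equal(out$n_pairs, 45L)
  expect_equal(out$df, 44L)
  expect_equal(out$t, mean(w6 - w5, na.rm = TRUE) /
                 (sd(w6 - w5, na.rm = TRUE) / sqrt(45)))
})

test_that("the paired test detects a half-SD shift at the study's completer count", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    d <- rnorm(279, mean = 0.5, sd = 1)
    out <- paired_change_test(rep(0, 279), d)
    expect_equal(out$df, 278L)
    if (out$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # > 95% of seeds
})
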