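test_that("mvalue matches the logit transform and its symmetry", {
  expect_equal(mvalue(0.5), 0)
  expect_equal(mvalue(0.8), 2)  # log2(0.8 / 0.2)
  # boundary beta hits the clipping bound
  expect_equal(mvalue(0, epsilon = 1e-6), log2(1e-6 / (1 - 1e-6)))
  expect_error(mvalue(1.2), "outside")
  expect_error(mvalue(0.5, epsilon = 0.7), "epsilon")

  b <- seq(0.01, 0.99, by = 0.01)
  m <- mvalue(b)
  expect_true(all(diff(m) > 0))                    # strictly increasing
  expect_equal(m, -rev(mvalue(rev(1 - b))), tolerance = 1e-12)  # antisymmetry
  expect_equal(1 / (1 + 2^(-m)), b, tolerance = 1e-12)          # bijective
})

test_that("EIS matches the hand-computed weighted M-value example", {
  # betas chosen so M-values are (2, 0, -2) at cgA and 0 at cgB
  bm <- beta_matrix(matrix(c(0.8, 0.5, 0.5, 0.5, 0.2, 0.5), 2, 3,
                           dimnames = list(c("cgA", "cgB"),
                                           c("s1", "s2", "s3"))))
  wt <- weight_table(c("cgA", "cgB"), c(1, -1))
  eis <- compute_eis(bm, wt)
  expect_equal(eis$eis_raw, c(2, 0, -2))
  expect_equal(eis$eis_z, c(1, 0, -1))  # sample SD = 2

  # z-scores invariant to rescaling all weights
  wt2 <- weight_table(c("cgA", "cgB"), c(2, -2))
  expect_equal(compute_eis(bm, wt2)$eis_z, eis$eis_z, tolerance = 1e-12)

  # identical observations cannot be standardized
  bm_const <- beta_matrix(matrix(0.6, 2, 3,
                                 dimnames = list(c("cgA", "cgB"),
                                                 c("s1", "s2", "s3"))))
  expect_error(compute_eis(bm_const, wt), "zero variance")
})

test_that("EIS equals a brute-force per-observation loop oracle", {
  bm <- random_bm(20, 10, seed = 11)
  set.seed(12)
  wt <- weight_table(rownames(bm), rnorm(20, 0, 0.2))
  eis <- compute_eis(bm, wt)

  oracle <- numeric(10)
  for (i in 1:10) {
    acc <- 0
    for (j in 1:20) {
      b <- min(max(unclass(bm)[j, i], 1e-6), 1 - 1e-6)
      acc <- acc + wt$coefficient[j] * log2(b / (1 - b))
    }
    oracle[i] <- acc
  }
  expect_equal(eis$eis_raw, oracle, tolerance = 1e-10)
  expect_equal(eis$eis_z, (oracle - mean(oracle)) / sd(oracle),
               tolerance = 1e-10)
})

test_that("EIS coverage warning fires and missing probes are scored without renormalization", {
  bm <- random_bm(10, 5, seed = 2)
  set.seed(3)
  wt <- weight_table(c(rownames(bm), "cgMISSING1", "cgMISSING2"),
                     rnorm(12, 0, 0.2))
  expect_warning(eis <- compute_eis(bm, wt), "coverage")
  expect_equal(attr(eis, "coverage")$n_found, 10L)
  expect_equal(attr(eis, "coverage")$fraction, 10 / 12)
})

test_that("CRI is the mean beta over available cardiac-risk probes", {
  cfg <- score_config()
  vals <- c(0.6, 0.8, 0.7, 0.7, 0.65, 0.75)
  bm <- beta_matrix(matrix(c(rep(0.7, 6), vals), 6, 2,
                           dimnames = list(cfg$cri_probes, c("s1", "s2"))))
  cri <- compute_cri(bm, cfg)
  expect_equal(cri$cri, c(0.7, 0.7))  # constant c -> exactly c; mean check
  expect_equal(cri$n_cri_probes_used, c(6L, 6L))

  bm5 <- beta_matrix(unclass(bm)[1:5, , drop = FALSE])
  cri5 <- compute_cri(bm5, cfg)
  expect_equal(cri5$n_cri_probes_used, c(5L, 5L))
  expect_equal(cri5$cri[2], mean(vals[1:5]))
  expect_error(compute_cri(bm5, score_config(cri_policy = "strict")),
               "strict CRI")

  none <- beta_matrix(matrix(0.5, 1, 2,
                             dimnames = list("cgZZZ", c("s1", "s2"))))
  expect_error(compute_cri(none, cfg), "none of the")
})

test_that("ATS is the unweighted sum of four per-locus z-scores", {
  ref <- cbind(mean = c(1, 2, 3, 4), sd = c(0.5, 1, 2, 4))
  x <- ref[, "mean"] + 0.5 * ref[, "sd"]
  expect_equal(compute_ats(x, ref), 2.0)
  expect_equal(compute_ats(ref[, "mean"] + 0.6 * ref[, "sd"], ref), 2.4)

  set.seed(4)
  pool <- matrix(rnorm(200, 5, 2), 50, 4)
  z <- sweep(sweep(pool, 2, colMeans(pool)), 2, apply(pool, 2, sd), "/")
  expect_equal(compute_ats(pool), rowSums(z), tolerance = 1e-12)
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12)

  expect_error(compute_ats(c(1, 2, NA, 4), ref), "4-plex")
  expect_error(compute_ats(c(1, 2, 3), ref), "4 locus")
})

test_that("elevated-use classification is strict at the 2.35 boundary", {
  expect_true(classify_elevated(2.36))
  expect_false(classify_elevated(2.35))
  expect_false(classify_elevated(-1.0))
  expect_equal(classify_elevated(c(2.34, 2.35, 2.350001, 10)),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("score_cohort joins sheet and matrix and honours per-wave z", {
  co <- generate_cohort(generator_config(n_couples = 20, n_individuals = 35,
                                         seed = 9))
  wt <- read_weight_table(system.file("extdata", "eis_weights_synthetic.tsv",
                                      package = "dyadrisk"))
  cfg <- score_config(ats_reference = default_ats_reference())
  bm <- embed_betas(co$scores, wt, cfg)
  panel <- score_cohort(bm, wt, co$sheet, cfg)
  expect_equal(nrow(panel), nrow(co$scores))
  expect_equal(mean(panel$eis_z), 0, tolerance = 1e-8)
  expect_equal(sd(panel$eis_z), 1, tolerance = 1e-8)
  expect_equal(panel$elevated, panel$ats > 2.35)

  pw <- score_cohort(bm, wt, co$sheet, score_config(
    ats_reference = default_ats_reference(), per_wave_z = TRUE))
  for (w in c(5, 6)) {
    expect_equal(mean(pw$eis_z[pw$wave == w]), 0, tolerance = 1e-8)
    expect_equal(sd(pw$eis_z[pw$wave == w]), 1, tolerance = 1e-8)
  }
})
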