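test_that("the generator is bit-reproducible under a fixed seed", {
  a <- generate_cohort(generator_config(seed = 123))
  b <- generate_cohort(generator_config(seed = 123))
  expect_identical(a$scores, b$scores)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$mask, b$truth$mask)
})

test_that("the default cohort reproduces the dyad and participation structure", {
  co <- generate_cohort(generator_config(seed = 1))
  truth <- co$truth$complete
  expect_equal(nrow(truth), 383L)
  expect_equal(length(unique(truth$couple_id)), 221L)
  expect_true(all(table(truth$couple_id) <= 2))
  expect_equal(sum(table(co$truth$mask$pattern)), 383L)
  # observed person-wave rows match the realized patterns
  pat <- table(co$truth$mask$pattern)
  expect_equal(nrow(co$scores),
               unname(2L * pat["both"] + pat["w5_only"] + pat["w6_only"]))
  # wave-5 rows exclude w6-only persons and vice versa
  w5_people <- co$scores$person_id[co$scores$wave == 5]
  expect_false(any(w5_people %in%
                     co$truth$mask$person_id[co$truth$mask$pattern == "w6_only"]))
})

test_that("missingness (1, 0, 0) yields a complete two-wave cohort", {
  co <- generate_cohort(generator_config(
    missingness = c(both = 1, w5_only = 0, w6_only = 0), seed = 2))
  expect_equal(nrow(co$scores), 2L * 383L)
  expect_true(all(co$truth$mask$pattern == "both"))
})

test_that("large-n cohorts converge to the target correlations", {
  co <- generate_cohort(generator_config(n_couples = 10000,
                                         n_individuals = 20000,
                                         couple_icc = 0, seed = 77))
  truth <- co$truth$complete
  R <- generator_config()$target_corr
  emp <- cor(truth[, colnames(R)])
  expect_lt(max(abs(emp - R)), 0.02)

  # partners' scores are independent when couple_icc = 0
  idx <- split(seq_len(nrow(truth)), truth$couple_id)
  idx <- idx[lengths(idx) == 2L]
  p1 <- vapply(idx, `[`, 0L, 1L)
  p2 <- vapply(idx, `[`, 0L, 2L)
  expect_lt(abs(cor(truth$ATS5[p1], truth$ATS5[p2])), 0.03)
  expect_lt(abs(cor(truth$EIS5[p1], truth$CRI5[p2])), 0.03)
})

test_that("partners correlate at couple_icc on each score", {
  co <- generate_cohort(generator_config(n_couples = 10000,
                                         n_individuals = 20000,
                                         couple_icc = 0.4, seed = 78))
  truth <- co$truth$complete
  idx <- split(seq_len(nrow(truth)), truth$couple_id)
  idx <- idx[lengths(idx) == 2L]
  p1 <- vapply(idx, `[`, 0L, 1L)
  p2 <- vapply(idx, `[`, 0L, 2L)
  expect_equal(cor(truth$EIS5[p1], truth$EIS5[p2]), 0.4, tolerance = 0.03)
})

test_that("a non-PSD correlation target is rejected with the offending eigenvalue", {
  R <- diag(6)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  expect_error(generator_config(target_corr = R), "eigenvalue")
  expect_error(generator_config(missingness = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(generator_config(couple_icc = 1.2), "couple_icc")
})

test_that("beta embedding inverts the scoring pipeline", {
  co <- generate_cohort(generator_config(n_couples = 30, n_individuals = 50,
                                         seed = 10))
  wt <- read_weight_table(system.file("extdata", "eis_weights_synthetic.tsv",
                                      package = "dyadrisk"))
  cfg <- score_config(ats_reference = default_ats_reference())
  set.seed(11)
  bm <- embed_betas(co$scores, wt, cfg)

  cri <- compute_cri(bm, cfg)
  key <- obs_key(co$scores$person_id, co$scores$wave)
  expect_equal(cri$cri[match(key, cri$sample_id)], co$scores$cri,
               tolerance = 1e-10)

  eis <- compute_eis(bm, wt, cfg)
  expect_gt(cor(eis$eis_z[match(key, eis$sample_id)], co$scores$eis),
            1 - 1e-10)

  ats <- compute_ats(t(unclass(bm)[cfg$ats_probes, ]), cfg$ats_reference)
  expect_equal(unname(ats), co$scores$ats, tolerance = 1e-10)
})

test_that("single-probe noiseless embedding is the inverse logit of the raw score", {
  sc <- data.frame(person_id = c("p1", "p2"), wave = 5,
                   ats = c(0, 1), eis = c(0.5, -1.5), cri = c(0.5, 0.6))
  wt <- weight_table("cgONLY", 1)
  bm <- embed_betas(sc, wt, eis_noise_sd = 0, cri_noise_sd = 0)
  expect_equal(unname(unclass(bm)["cgONLY", ]),
               1 / (1 + 2^(-sc$eis)), tolerance = 1e-12)
  expect_error(embed_betas(sc, weight_table(c("a", "b"), c(0, 0))),
               "all zero")
})

test_that("cohort summaries agree with pairwise statistics on complete data", {
  co <- generate_cohort(generator_config(
    n_couples = 100, n_individuals = 170,
    missingness = c(both = 1, w5_only = 0, w6_only = 0), seed = 12))
  s <- summarize_cohort(co$sheet, co$scores)
  expect_equal(unname(s$fiml_corr), unname(s$pairwise_corr),
               tolerance = 1e-6)
  expect_equal(sum(s$patterns), s$n_individuals)
  expect_equal(s$n_person_waves_observed, s$n_person_waves_patterns)
})
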