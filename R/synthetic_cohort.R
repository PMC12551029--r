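# Synthetic dyadic two-wave cohort generator. Emulates the statistical
# structure of the study cohort: 221 couples / 383 individuals, two waves,
# participation pattern (both = 271, wave-5 only = 77, wave-6 only = 35),
# age ~ N(44.61, 8.22^2), 54% female, and the published correlation
# structure among (ATS, EIS, CRI) at both waves. Optionally embeds
# CpG-level beta matrices so the whole scoring pipeline runs end to end.

SCORE_VARS <- c("ATS5", "EIS5", "CRI5", "ATS6", "EIS6", "CRI6")

#' Default population correlation target for the generator
#'
#' Assembled from the published two-wave descriptives: stabilities
#' ATS 0.846, EIS 0.639, CRI 0.479; within-wave ATS-EIS 0.403 / 0.413,
#' ATS-CRI -0.378 / -0.434, EIS-CRI -0.580 / -0.650 (waves 5 / 6). The six
#' cross-wave cross-trait cells are not published and are filled by the
#' product rule r(X5, Y6) = r(X5, Y5) * r(Y5, Y6), then projected to the
#' nearest positive semi-definite correlation matrix (a numerical no-op for
#' the defaults, which are already positive definite).
#'
#' @return 6 x 6 correlation matrix over (ATS5, EIS5, CRI5, ATS6, EIS6,
#'   CRI6).
#' @export
default_target_corr <- function() {
  R <- diag(6)
  dimnames(R) <- list(SCORE_VARS, SCORE_VARS)
  set2 <- function(a, b, x) {
    R[a, b] <<- x
    R[b, a] <<- x
  }
  set2("ATS5", "EIS5", 0.403); set2("ATS6", "EIS6", 0.413)
  set2("ATS5", "CRI5", -0.378); set2("ATS6", "CRI6", -0.434)
  set2("EIS5", "CRI5", -0.580); set2("EIS6", "CRI6", -0.650)
  set2("ATS5", "ATS6", 0.846); set2("EIS5", "EIS6", 0.639)
  set2("CRI5", "CRI6", 0.479)
  for (x in c("ATS", "EIS", "CRI")) for (y in c("ATS", "EIS", "CRI")) {
    if (x == y) next
    x5 <- paste0(x, "5"); y5 <- paste0(y, "5"); y6 <- paste0(y, "6")
    set2(x5, y6, R[x5, y5] * R[y5, y6])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  R
}

#' Generator configuration for synthetic dyadic cohorts
#'
#' All distributional targets for the simulator. Defaults reproduce the
#' study conditions: cohort size and dyad structure, marginal means/SDs,
#' the two-wave correlation structure, the participation pattern, and a
#' modest within-couple correlation. CRI marginals (mean 0.55, SD 0.05 on
#' the beta scale) are not published and were chosen once as plausible
#' mid-range beta values that avoid boundary clamping.
#'
#' @param n_couples number of couples (default 221).
#' @param n_individuals number of enrolled persons (default 383; couples
#'   beyond `n_individuals - n_couples` contribute a single partner).
#' @param waves two wave labels, default `c(5, 6)`.
#' @param target_corr 6 x 6 PSD correlation matrix over
#'   (ATS5, EIS5, CRI5, ATS6, EIS6, CRI6).
#' @param means,sds named length-6 marginal means and SDs for the same
#'   variables (ATS means 2.201 / 2.195, EIS z-scale, CRI 0.55 (0.05)).
#' @param age_mean,age_sd baseline (wave-5) age distribution, years.
#' @param p_female proportion female (sex coded 1 = female, 0 = male).
#' @param couple_icc within-couple correlation of the person-level latent
#'   score factors, in \[0, 1).
#' @param missingness length-3 probabilities (both, w5_only, w6_only) of a
#'   person's participation pattern; default (271, 77, 35) / 383.
#' @param mar_dropout_beta optional logistic dependence of wave-6 dropout
#'   on the person's (standardized) wave-5 ATS; 0 (default) gives
#'   covariate-independent (MCAR) patterns, nonzero values make the
#'   mechanism MAR-given-W5 for stress-testing FIML.
#' @param binge_ats_corr latent correlation between the self-reported binge
#'   score and wave-5 ATS (self-report underreports heavy use, hence the
#'   modest default 0.3); binge is discretized to a 0+ count via a Poisson
#'   quantile map (rate `binge_rate`) and has no direct effect on outcomes.
#' @param binge_rate Poisson rate of the binge count scale.
#' @param effects optional structural block, see [prediction_effects()] and
#'   [change_effects()]; `NULL` generates all six scores jointly from
#'   `target_corr` ("correlation mode").
#' @param ats_reference 4 x 2 per-locus (mean, sd) reference used when
#'   embedding ATS loci into beta matrices and scoring them back; synthetic
#'   calibration, documented as such.
#' @param seed optional integer seed; seeded runs are bit-reproducible.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_couples = 221L,
                             n_individuals = 383L,
                             waves = c(5L, 6L),
                             target_corr = default_target_corr(),
                             means = c(ATS5 = 2.201, EIS5 = 0, CRI5 = 0.55,
                                       ATS6 = 2.195, EIS6 = 0, CRI6 = 0.55),
                             sds = c(ATS5 = 1, EIS5 = 1, CRI5 = 0.05,
                                     ATS6 = 1, EIS6 = 1, CRI6 = 0.05),
                             age_mean = 44.61, age_sd = 8.22,
                             p_female = 0.54,
                             couple_icc = 0.2,
                             missingness = c(both = 271, w5_only = 77,
                                             w6_only = 35) / 383,
                             mar_dropout_beta = 0,
                             binge_ats_corr = 0.3,
                             binge_rate = 1.5,
                             effects = NULL,
                             ats_reference = default_ats_reference(),
                             seed = NULL) {
  if (n_individuals < n_couples || n_individuals > 2L * n_couples)
    dr_stop("config",
            "n_individuals must lie in [n_couples, 2*n_couples]")
  target_corr <- as.matrix(target_corr)
  if (!is_square_symmetric(target_corr) || nrow(target_corr) != 6L)
    dr_stop("config", "target_corr must be a symmetric 6 x 6 matrix")
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    dr_stop("config",
            "target_corr is not positive semi-definite (eigenvalue %.6g)",
            min(ev))
  if (abs(sum(missingness) - 1) > 1e-8)
    dr_stop("config", "missingness probabilities must sum to 1")
  if (any(sds <= 0)) dr_stop("config", "marginal SDs must be > 0")
  if (couple_icc < 0 || couple_icc >= 1)
    dr_stop("config", "couple_icc must lie in [0, 1)")
  means <- means[SCORE_VARS]
  sds <- sds[SCORE_VARS]
  if (anyNA(means) || anyNA(sds))
    dr_stop("config", "means and sds must be named over %s",
            paste(SCORE_VARS, collapse = ", "))
  structure(list(n_couples = as.integer(n_couples),
                 n_individuals = as.integer(n_individuals),
                 waves = as.integer(waves), target_corr = target_corr,
                 means = means, sds = sds, age_mean = age_mean,
                 age_sd = age_sd, p_female = p_female,
                 couple_icc = couple_icc,
                 missingness = stats::setNames(missingness,
                                               c("both", "w5_only", "w6_only")),
                 mar_dropout_beta = mar_dropout_beta,
                 binge_ats_corr = binge_ats_corr, binge_rate = binge_rate,
                 effects = effects, ats_reference = ats_reference,
                 seed = seed),
            class = "generator_config")
}

#' Structural effect block: prediction of wave-6 cardiac risk
#'
#' Replaces the correlation-mode CRI6 with a linear structural equation on
#' the named baseline predictors, specified through standardized
#' coefficients. Raw slopes are derived as b_j = beta_j * sd(y) / sd(x_j)
#' using the generator's population SDs, and the residual variance is set
#' so the outcome SD equals `outcome_sd`.
#'
#' @param beta named standardized coefficients; allowed names: `age`,
#'   `sex`, `cri5`, `ats5`, `eis5`. Defaults are the published
#'   covariates-plus-dual-risk model (age -0.108, sex 0.112, cri5 0.368,
#'   ats5 -0.193, eis5 -0.042).
#' @param outcome_sd population SD of the generated CRI6 (beta-fraction
#'   units).
#' @return list consumed by [generate_cohort()] via
#'   `generator_config(effects = ...)`.
#' @export
prediction_effects <- function(beta = c(age = -0.108, sex = 0.112,
                                        cri5 = 0.368, ats5 = -0.193,
                                        eis5 = -0.042),
                               outcome_sd = 0.05) {
  allowed <- c("age", "sex", "cri5", "ats5", "eis5")
  if (is.null(names(beta)) || !all(names(beta) %in% allowed))
    dr_stop("config", "prediction_effects beta names must be among: %s",
            paste(allowed, collapse = ", "))
  list(mode = "prediction", beta = beta, outcome_sd = outcome_sd)
}

#' Structural effect block: correlated change in cardiac risk
#'
#' Generates the within-person cardiac-risk change as a linear function of
#' centered age (age - 40), sex, baseline CRI and the within-person ATS and
#' EIS changes, with raw (unstandardized) coefficients. Defaults are the
#' published change-model values (age40 0.0001, sex 0.0106, cri5 0.6098,
#' d_ats -0.0004, d_eis -0.0145). CRI6 is then CRI5 plus the generated
#' change.
#'
#' @param b named raw coefficients; allowed names: `age40`, `sex`, `cri5`,
#'   `d_ats`, `d_eis`.
#' @param resid_sd residual SD of the change equation; `NULL` (default)
#'   solves it so the change variance matches the one implied by
#'   `target_corr` and the CRI marginals.
#' @param mean_change population mean of the cardiac-risk change
#'   (beta-fraction units), default 0.
#' @return list consumed by [generate_cohort()].
#' @export
change_effects <- function(b = c(age40 = 0.0001, sex = 0.0106,
                                 cri5 = 0.6098, d_ats = -0.0004,
                                 d_eis = -0.0145),
                           resid_sd = NULL, mean_change = 0) {
  allowed <- c("age40", "sex", "cri5", "d_ats", "d_eis")
  if (is.null(names(b)) || !all(names(b) %in% allowed))
    dr_stop("config", "change_effects b names must be among: %s",
            paste(allowed, collapse = ", "))
  list(mode = "change", b = b, resid_sd = resid_sd,
       mean_change = mean_change)
}

#' Generate a synthetic dyadic two-wave cohort
#'
#' Draws couple-level and person-level latent normal factors with the
#' configured correlation structure so that person scores follow
#' `target_corr` marginally while partners correlate at `couple_icc` on
#' every score; scales to the marginal means/SDs; draws age and sex
#' independently per person; optionally replaces CRI6 (or the CRI change)
#' with a structural equation; and applies the participation-pattern
#' missingness.
#'
#' @param cfg a [generator_config()].
#' @return list with `sheet` (long sample sheet, observed person-waves
#'   only, including `ats1..ats4` assay values), `scores` (long
#'   score-panel-shaped table of the observed true scores), and `truth`
#'   (complete pre-missingness table, realized pattern per person, and the
#'   exact config used).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  if (!inherits(cfg, "generator_config"))
    dr_stop("config", "cfg must be a generator_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nC <- cfg$n_couples
  nI <- cfg$n_individuals

  couple_id <- sprintf("c%03d", seq_len(nC))
  n_dyads <- nI - nC
  dyad_couples <- sample(nC, n_dyads)
  person_couple <- c(seq_len(nC), dyad_couples)
  ord <- order(person_couple)
  person_couple <- person_couple[ord]
  person_id <- sprintf("p%04d", seq_len(nI))

  # latent scores: sqrt(icc) couple factor + sqrt(1-icc) person factor,
  # both MVN(0, target_corr) -> unit marginals with structure target_corr,
  # cross-partner correlation couple_icc on every score.
  L <- chol(cfg$target_corr)
  draw <- function(n) matrix(stats::rnorm(n * 6L), n, 6L) %*% L
  Gc <- draw(nC)
  U <- draw(nI)
  Z <- sqrt(cfg$couple_icc) * Gc[person_couple, , drop = FALSE] +
    sqrt(1 - cfg$couple_icc) * U
  colnames(Z) <- SCORE_VARS
  scores <- sweep(sweep(Z, 2L, cfg$sds, "*"), 2L, cfg$means, "+")

  age <- stats::rnorm(nI, cfg$age_mean, cfg$age_sd)
  sex <- stats::rbinom(nI, 1L, cfg$p_female)
  # binge: latent correlated with the wave-5 ATS latent, Poisson-quantile
  # discretized to a self-report-like count
  zb <- cfg$binge_ats_corr * Z[, "ATS5"] +
    sqrt(1 - cfg$binge_ats_corr^2) * stats::rnorm(nI)
  binge <- stats::qpois(stats::pnorm(zb), cfg$binge_rate)

  scores <- apply_effects(scores, age, sex, cfg)

  # participation patterns; optional MAR dependence of wave-6 dropout on
  # the standardized wave-5 ATS (odds of w5_only vs both multiplied by
  # exp(beta * z), w6_only probability untouched)
  pm <- cfg$missingness
  probs <- matrix(pm, nI, 3L, byrow = TRUE)
  if (cfg$mar_dropout_beta != 0) {
    z <- (scores[, "ATS5"] - cfg$means["ATS5"]) / cfg$sds["ATS5"]
    odds <- (pm["w5_only"] / pm["both"]) * exp(cfg$mar_dropout_beta * z)
    keep6 <- 1 - pm["w6_only"]
    probs[, 2L] <- keep6 * odds / (1 + odds)
    probs[, 1L] <- keep6 - probs[, 2L]
  }
  u <- stats::runif(nI)
  pattern <- ifelse(u < probs[, 1L], "both",
                    ifelse(u < probs[, 1L] + probs[, 2L], "w5_only",
                           "w6_only"))

  complete <- data.frame(person_id = person_id,
                         couple_id = couple_id[person_couple],
                         age = age, sex = sex, binge = binge,
                         scores, pattern = pattern,
                         stringsAsFactors = FALSE, row.names = NULL)

  long <- make_long(complete, cfg)
  observed <- long$wave == cfg$waves[1L] & pattern[long$row] != "w6_only" |
    long$wave == cfg$waves[2L] & pattern[long$row] != "w5_only"

  sheet <- long$sheet[observed, , drop = FALSE]
  rownames(sheet) <- NULL
  class(sheet) <- c("sample_sheet", class(sheet))
  sc <- long$scores[observed, , drop = FALSE]
  rownames(sc) <- NULL

  list(sheet = sheet, scores = sc,
       truth = list(complete = complete,
                    mask = data.frame(person_id = person_id,
                                      pattern = pattern,
                                      stringsAsFactors = FALSE),
                    config = cfg))
}

# Apply the optional structural effect block to the score matrix.
apply_effects <- function(scores, age, sex, cfg) {
  eff <- cfg$effects
  if (is.null(eff)) return(scores)
  if (eff$mode == "prediction") {
    xs <- list(age = age, sex = sex, cri5 = scores[, "CRI5"],
               ats5 = scores[, "ATS5"], eis5 = scores[, "EIS5"])
    mus <- c(age = cfg$age_mean, sex = cfg$p_female,
             cri5 = cfg$means[["CRI5"]], ats5 = cfg$means[["ATS5"]],
             eis5 = cfg$means[["EIS5"]])
    sds <- c(age = cfg$age_sd,
             sex = sqrt(cfg$p_female * (1 - cfg$p_female)),
             cri5 = cfg$sds[["CRI5"]], ats5 = cfg$sds[["ATS5"]],
             eis5 = cfg$sds[["EIS5"]])
    b <- eff$beta * eff$outcome_sd / sds[names(eff$beta)]
    lp <- Reduce(`+`, lapply(names(b), function(v)
      b[[v]] * (xs[[v]] - mus[[v]])))
    resid_var <- eff$outcome_sd^2 - stats::var(lp)
    if (resid_var <= 0)
      dr_stop("config",
              "prediction effects explain more variance than outcome_sd^2 allows")
    scores[, "CRI6"] <- cfg$means[["CRI6"]] + lp +
      stats::rnorm(length(lp), 0, sqrt(resid_var))
  } else if (eff$mode == "change") {
    xs <- list(age40 = age - 40, sex = sex, cri5 = scores[, "CRI5"],
               d_ats = scores[, "ATS6"] - scores[, "ATS5"],
               d_eis = scores[, "EIS6"] - scores[, "EIS5"])
    mus <- vapply(xs, mean, 0)
    b <- eff$b
    lp <- Reduce(`+`, lapply(names(b), function(v)
      b[[v]] * (xs[[v]] - mus[[v]])))
    resid_sd <- eff$resid_sd
    if (is.null(resid_sd)) {
      r56 <- cfg$target_corr["CRI5", "CRI6"]
      target_var <- cfg$sds[["CRI5"]]^2 + cfg$sds[["CRI6"]]^2 -
        2 * r56 * cfg$sds[["CRI5"]] * cfg$sds[["CRI6"]]
      resid_var <- target_var - stats::var(lp)
      if (resid_var <= 0)
        dr_stop("config",
                "change effects explain more variance than the implied change variance")
      resid_sd <- sqrt(resid_var)
    }
    d_cri <- eff$mean_change + lp + stats::rnorm(length(lp), 0, resid_sd)
    scores[, "CRI6"] <- scores[, "CRI5"] + d_cri
  } else {
    dr_stop("config", "unknown effects mode '%s'", eff$mode)
  }
  scores
}

# Expand the per-person complete table into person-wave long format.
# The sheet's age column is baseline (wave-5) age at both waves, matching
# its use as a baseline covariate; binge is the wave-5 self-report.
make_long <- function(complete, cfg) {
  nI <- nrow(complete)
  row <- rep(seq_len(nI), times = 2L)
  wave <- rep(cfg$waves, each = nI)
  wtag <- rep(c("5", "6"), each = nI)
  ats <- ifelse(wtag == "5", complete$ATS5, complete$ATS6)
  eis <- ifelse(wtag == "5", complete$EIS5, complete$EIS6)
  cri <- ifelse(wtag == "5", complete$CRI5, complete$CRI6)
  ref <- cfg$ats_reference
  assay <- sapply(1:4, function(k) ref[k, "mean"] + ref[k, "sd"] * ats / 4)
  colnames(assay) <- paste0("ats", 1:4)
  sheet <- data.frame(person_id = complete$person_id[row],
                      couple_id = complete$couple_id[row],
                      wave = wave, age = complete$age[row],
                      sex = complete$sex[row], binge = complete$binge[row],
                      assay, stringsAsFactors = FALSE)
  scores <- data.frame(person_id = complete$person_id[row],
                       couple_id = complete$couple_id[row],
                       wave = wave, ats = ats, eis = eis, cri = cri,
                       elevated = ats > 2.35, stringsAsFactors = FALSE)
  list(sheet = sheet, scores = scores, wave = wave, row = row)
}

#' Embed true scores into a CpG-level beta matrix
#'
#' Inverse of the scoring step, enabling end-to-end pipeline runs: builds
#' per-observation M-values whose weighted sum equals each target raw EIS
#' (minimum-norm solution plus noise in the null space of the weight
#' vector, so the weighted sum is untouched), converts them to betas by the
#' inverse logit; sets each of the six CRI probes to
#' `clamp(cri + delta, 0, 1)` with per-observation `sum(delta) = 0` so the
#' probe mean equals the target CRI exactly when no clamping occurs; and
#' writes the four ATS loci from the config's per-locus reference so that
#' fixed-reference scoring recovers the target ATS exactly (pooled-sample
#' scoring recovers it up to an affine map).
#'
#' @param scores long score table from [generate_cohort()] (columns
#'   `person_id`, `wave`, `ats`, `eis`, `cri`).
#' @param wt a [weight_table()] of EIS weights (not all zero).
#' @param cfg a [score_config()] whose `ats_reference` is used for the ATS
#'   loci (required here).
#' @param eis_noise_sd SD of the null-space M-value noise.
#' @param cri_noise_sd SD of the zero-sum CRI probe perturbations (beta
#'   units).
#' @param n_decoys number of additional random decoy probes.
#' @return a [beta_matrix()] with columns keyed `"person@wave"`.
#' @export
embed_betas <- function(scores, wt,
                        cfg = score_config(ats_reference = default_ats_reference()),
                        eis_noise_sd = 0.5, cri_noise_sd = 0.01,
                        n_decoys = 0L) {
  w <- wt$coefficient
  if (all(w == 0)) dr_stop("config", "EIS weights are all zero")
  if (is.null(cfg$ats_reference))
    dr_stop("config", "embed_betas needs a fixed ats_reference in the score config")
  n <- nrow(scores)
  keys <- obs_key(scores$person_id, scores$wave)

  # EIS block: minimum-norm M plus null-space noise
  M <- outer(w, scores$eis) / sum(w^2)
  if (eis_noise_sd > 0) {
    Zn <- matrix(stats::rnorm(length(w) * n, 0, eis_noise_sd), length(w), n)
    Zn <- Zn - outer(w, as.numeric(crossprod(Zn, w))) / sum(w^2)
    M <- M + Zn
  }
  eis_block <- inv_mvalue(M)
  rownames(eis_block) <- wt$cpg

  # CRI block: zero-sum perturbations around the target mean
  D <- matrix(stats::rnorm(6L * n, 0, cri_noise_sd), 6L, n)
  D <- sweep(D, 2L, colMeans(D))
  cri_block <- pmin(pmax(matrix(scores$cri, 6L, n, byrow = TRUE) + D, 0), 1)
  rownames(cri_block) <- cfg$cri_probes

  # ATS block: locus k value mean_k + sd_k * ats / 4, so fixed-reference
  # z-scores are ats / 4 each and sum back to ats
  ref <- cfg$ats_reference
  ats_block <- sapply(seq_len(n), function(i)
    ref[, "mean"] + ref[, "sd"] * scores$ats[i] / 4)
  ats_block <- pmin(pmax(ats_block, 0), 1)
  rownames(ats_block) <- cfg$ats_probes

  blocks <- rbind(eis_block, cri_block, ats_block)
  if (n_decoys > 0L) {
    decoys <- matrix(stats::runif(n_decoys * n, 0.05, 0.95), n_decoys, n)
    rownames(decoys) <- sprintf("cg%08d", 90000000L + seq_len(n_decoys))
    blocks <- rbind(blocks, decoys)
  }
  colnames(blocks) <- keys
  beta_matrix(blocks)
}

#' Descriptive summary of a (synthetic or real) cohort
#'
#' Means, SDs, pairwise-complete and FIML correlations of the six
#' person-wave scores, participation-pattern counts, and the elevated-use
#' percentage per wave. Reports both person-wave counts: observed rows and
#' the pattern identity 2 * both + w5_only + w6_only.
#'
#' @param sheet long sample sheet (observed person-waves).
#' @param scores long score table with `ats`, `eis`, `cri` columns.
#' @param cutoff elevated-use cutoff (strictly greater-than), default 2.35.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(sheet, scores, cutoff = 2.35) {
  wide <- pivot_waves(scores, sheet)
  vars <- intersect(SCORE_VARS_LOWER, names(wide))
  X <- as.matrix(wide[, vars, drop = FALSE])
  fit <- em_mvn(X)
  pw <- stats::cor(X, use = "pairwise.complete.obs")
  have5 <- !is.na(wide$ats5) | !is.na(wide$eis5) | !is.na(wide$cri5)
  have6 <- !is.na(wide$ats6) | !is.na(wide$eis6) | !is.na(wide$cri6)
  patterns <- c(both = sum(have5 & have6), w5_only = sum(have5 & !have6),
                w6_only = sum(!have5 & have6))
  structure(list(
    n_individuals = nrow(wide),
    n_person_waves_observed = nrow(scores),
    n_person_waves_patterns = unname(2L * patterns["both"] +
                                       patterns["w5_only"] +
                                       patterns["w6_only"]),
    patterns = patterns,
    means = fit$mean, sds = sqrt(diag(fit$cov)),
    fiml_corr = stats::cov2cor(fit$cov), pairwise_corr = pw,
    pct_elevated = c(
      w5 = 100 * mean(scores$ats[scores$wave == 5] > cutoff, na.rm = TRUE),
      w6 = 100 * mean(scores$ats[scores$wave == 6] > cutoff, na.rm = TRUE)),
    fit = fit), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<cohort_summary> %d individuals, %d observed person-waves (pattern identity: %d)\n",
              x$n_individuals, x$n_person_waves_observed,
              x$n_person_waves_patterns))
  cat("  patterns:", paste(names(x$patterns), x$patterns, sep = "=",
                           collapse = ", "), "\n")
  cat(sprintf("  %% elevated (> cutoff): W5 %.1f, W6 %.1f\n",
              x$pct_elevated["w5"], x$pct_elevated["w6"]))
  cat("  FIML means (SDs):\n")
  print(round(rbind(mean = x$means, sd = x$sds), digits))
  cat("  FIML correlations:\n")
  print(round(x$fiml_corr, digits))
  invisible(x)
}
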