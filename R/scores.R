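# The three methylation indices: EIS (EWAS-weighted M-value sum,
# z-standardized), CRI (mean beta over six coronary-heart-disease CpGs,
# lower = riskier), and ATS (unweighted sum of four per-locus z-scores with
# an elevated-use cutoff).

CRI_PROBES <- c("cg03725309", "cg12586707", "cg04988978",
                "cg17901584", "cg21161138", "cg12655112")
ATS_PROBES <- c("cg02583484", "cg04987734", "cg09935388", "cg04583842")

#' Synthetic per-locus ATS reference calibration
#'
#' The validated elevated-use cutoff implies an external per-locus
#' calibration that is not published; this synthetic stand-in (documented
#' as such) is what the cohort generator embeds and what fixed-reference
#' scoring of simulated data uses, so that embedding followed by scoring
#' recovers the generated ATS exactly.
#'
#' @return 4 x 2 matrix with columns `mean`, `sd`, rows in locus order.
#' @export
default_ats_reference <- function() {
  cbind(mean = c(0.45, 0.50, 0.55, 0.50), sd = rep(0.05, 4L))
}

#' Scoring configuration
#'
#' Collects the locus lists and numeric policy knobs for the three indices.
#'
#' @param cri_probes six CpG ids for the cardiac risk index.
#' @param ats_probes four CpG ids for the alcohol T-score assay.
#' @param ats_cutoff elevated-consumption threshold on the ATS scale
#'   (default 2.35; classification is strictly greater-than).
#' @param beta_epsilon clipping bound applied to betas before the logit,
#'   in (0, 0.5); the transform is undefined at exactly 0 or 1 and
#'   normalized arrays can produce boundary values.
#' @param ats_reference optional 4 x 2 matrix (columns `mean`, `sd`) of
#'   per-locus reference moments; when `NULL` the scoring sample itself is
#'   pooled as the reference.
#' @param cri_policy `"allow"` scores with whatever subset of the six CRI
#'   probes is present (coverage recorded); `"strict"` requires all six.
#' @param per_wave_z z-standardize the EIS within wave instead of pooling
#'   across waves (pooling preserves between-wave change and is the default).
#' @param coverage_warn warn when the EIS probe coverage fraction falls
#'   below this value.
#' @return list of class `score_config`.
#' @export
score_config <- function(cri_probes = CRI_PROBES,
                         ats_probes = ATS_PROBES,
                         ats_cutoff = 2.35,
                         beta_epsilon = 1e-6,
                         ats_reference = NULL,
                         cri_policy = c("allow", "strict"),
                         per_wave_z = FALSE,
                         coverage_warn = 0.95) {
  cri_policy <- match.arg(cri_policy)
  if (!is.finite(beta_epsilon) || beta_epsilon <= 0 || beta_epsilon >= 0.5)
    dr_stop("config", "beta_epsilon must lie in (0, 0.5)")
  if (!is.finite(ats_cutoff)) dr_stop("config", "ats_cutoff must be finite")
  if (!is.null(ats_reference)) {
    ats_reference <- as.matrix(ats_reference)
    if (nrow(ats_reference) != length(ats_probes) ||
        ncol(ats_reference) != 2L || any(ats_reference[, 2L] <= 0))
      dr_stop("config",
              "ats_reference must be a %d x 2 (mean, sd) matrix with sd > 0",
              length(ats_probes))
    colnames(ats_reference) <- c("mean", "sd")
  }
  structure(list(cri_probes = cri_probes, ats_probes = ats_probes,
                 ats_cutoff = ats_cutoff, beta_epsilon = beta_epsilon,
                 ats_reference = ats_reference, cri_policy = cri_policy,
                 per_wave_z = per_wave_z, coverage_warn = coverage_warn),
            class = "score_config")
}

#' Logit (M-value) transform of methylation betas
#'
#' M = log2(b / (1 - b)) after clamping b into
#' \[epsilon, 1 - epsilon\]. Strictly increasing on (0, 1) and antisymmetric
#' about beta = 0.5: `mvalue(b) == -mvalue(1 - b)`.
#'
#' @param beta numeric vector/matrix of methylation fractions in \[0, 1\]
#'   (NA passes through).
#' @param epsilon clipping bound in (0, 0.5).
#' @return M-values in log2 units, same shape as `beta`.
#' @export
#' @examples
#' mvalue(0.5)  # 0
#' mvalue(0.8)  # log2(4) = 2
mvalue <- function(beta, epsilon = 1e-6) {
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    dr_stop("config", "epsilon must lie in (0, 0.5)")
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    dr_stop("data", "beta value(s) outside [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

inv_mvalue <- function(m) 1 / (1 + 2^(-m))

#' Epigenetic inflammation score (EIS)
#'
#' Per observation, each CpG's M-value is multiplied by its EWAS effect-size
#' coefficient and the products are summed across loci to a raw composite,
#' which is then z-standardized over the scoring sample (sample SD, n - 1
#' denominator) so one unit is one SD. Probes missing from the array are
#' skipped without weight renormalization (z-standardization absorbs the
#' constant offset); coverage below `cfg$coverage_warn` triggers a warning.
#'
#' @param bm a [beta_matrix()].
#' @param wt a [weight_table()] of EWAS coefficients.
#' @param cfg a [score_config()].
#' @return data.frame with `sample_id`, `eis_raw`, `eis_z`; the coverage
#'   report is attached as attribute `"coverage"`.
#' @export
compute_eis <- function(bm, wt, cfg = score_config()) {
  al <- align_probes(bm, wt)
  if (ncol(al$matrix) < 2L)
    dr_stop("estimation", "cannot z-standardize: fewer than 2 observations")
  if (al$coverage$fraction < cfg$coverage_warn)
    dr_warn("EIS probe coverage %.3f below %.2f (%d of %d probes found)",
            al$coverage$fraction, cfg$coverage_warn,
            al$coverage$n_found, al$coverage$n_requested)
  m <- mvalue(unclass(al$matrix), cfg$beta_epsilon)
  raw <- as.numeric(crossprod(m, al$weights))  # sum_j w_j * M_ij
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    dr_stop("estimation", "cannot z-standardize EIS: zero variance across observations")
  out <- data.frame(sample_id = colnames(al$matrix), eis_raw = raw,
                    eis_z = (raw - mean(raw)) / s,
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- al$coverage
  out
}

#' Cardiac risk index (CRI)
#'
#' Mean beta across the six coronary-heart-disease CpGs. Lower methylation
#' indicates greater cardiac risk; the value is reported on the beta scale
#' without a sign flip. Under the default `"allow"` policy the mean is taken
#' over whichever of the six probes are present (and non-missing per
#' observation), with the count recorded; `"strict"` requires all six.
#'
#' @inheritParams compute_eis
#' @return data.frame with `sample_id`, `cri`, `n_cri_probes_used`.
#' @export
compute_cri <- function(bm, cfg = score_config()) {
  present <- intersect(cfg$cri_probes, rownames(bm))
  if (length(present) == 0L)
    dr_stop("data", "none of the %d cardiac-risk probes present",
            length(cfg$cri_probes))
  if (cfg$cri_policy == "strict" && length(present) < length(cfg$cri_probes))
    dr_stop("data", "strict CRI policy: %d of %d probes present",
            length(present), length(cfg$cri_probes))
  sub <- unclass(bm)[present, , drop = FALSE]
  data.frame(sample_id = colnames(sub),
             cri = colMeans(sub, na.rm = TRUE),
             n_cri_probes_used = colSums(!is.na(sub)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Alcohol T-score (ATS)
#'
#' Unweighted sum of the four per-locus z-scores of the
#' methylation-sensitive digital PCR assay. The assay is a fixed 4-plex:
#' a missing locus value is an error, never a partial score. The reference
#' moments are either supplied per locus (`reference` as a 4 x 2 mean/sd
#' matrix, e.g. an external calibration consistent with the validated 2.35
#' cutoff) or pooled from the scoring sample itself, in which case each
#' locus z-score has mean 0 by construction.
#'
#' @param values numeric n x 4 matrix (or length-4 vector) of per-locus
#'   assay values, columns in locus order.
#' @param reference `"pooled"` or a 4 x 2 matrix with columns mean, sd.
#' @return numeric vector of ATS values (sum of four z-scores).
#' @export
compute_ats <- function(values, reference = "pooled") {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  if (ncol(values) != 4L)
    dr_stop("data", "ATS assay needs exactly 4 locus columns, got %d",
            ncol(values))
  if (any(!is.finite(values)))
    dr_stop("data", "missing or non-finite ATS locus value(s): the assay is a fixed 4-plex")
  if (identical(reference, "pooled")) {
    if (nrow(values) < 2L)
      dr_stop("estimation", "pooled ATS reference needs >= 2 observations")
    mu <- colMeans(values)
    sdv <- apply(values, 2L, stats::sd)
  } else {
    reference <- as.matrix(reference)
    if (nrow(reference) != 4L || ncol(reference) != 2L)
      dr_stop("config", "ATS reference must be a 4 x 2 (mean, sd) matrix")
    mu <- reference[, 1L]
    sdv <- reference[, 2L]
  }
  if (any(sdv <= 0)) dr_stop("estimation", "ATS reference SD(s) must be > 0")
  rowSums(sweep(sweep(values, 2L, mu), 2L, sdv, "/"))
}

#' Classify elevated alcohol consumption
#'
#' `TRUE` iff the ATS strictly exceeds the cutoff (validated default 2.35);
#' a value exactly at the boundary is not elevated.
#'
#' @param ats numeric ATS values.
#' @param cutoff threshold, default 2.35.
#' @return logical vector.
#' @export
classify_elevated <- function(ats, cutoff = 2.35) {
  if (any(!is.finite(ats)) || !is.finite(cutoff))
    dr_stop("data", "classify_elevated needs finite inputs")
  ats > cutoff
}

#' Score a cohort: EIS, CRI, ATS and elevated-use flags per person-wave
#'
#' Joins a beta matrix (columns keyed `"person@wave"`, see [obs_key()]) to a
#' sample sheet and computes the full score panel. ATS is taken from the
#' sheet's `ats1..ats4` assay columns when present, otherwise from the four
#' ATS probes of the beta matrix (the array route; supported but not claimed
#' equivalent to the PCR assay).
#'
#' @param bm a [beta_matrix()].
#' @param wt a [weight_table()] for the EIS.
#' @param sheet a validated sample sheet ([read_sample_sheet()]).
#' @param cfg a [score_config()].
#' @return data.frame (class `score_panel`): `person_id`, `couple_id`,
#'   `wave`, `eis_raw`, `eis_z`, `cri`, `ats`, `elevated`, `eis_coverage`,
#'   `n_cri_probes_used`.
#' @export
score_cohort <- function(bm, wt, sheet, cfg = score_config()) {
  sheet <- validate_sample_sheet(sheet)
  keys <- obs_key(sheet$person_id, sheet$wave)
  found <- keys %in% colnames(bm)
  if (!any(found))
    dr_stop("data", "no sample-sheet observation keys match beta matrix columns")
  if (!all(found))
    dr_warn("%d sample-sheet row(s) without beta-matrix columns are dropped",
            sum(!found))
  sheet <- sheet[found, , drop = FALSE]
  keys <- keys[found]
  bm <- beta_matrix(unclass(bm)[, keys, drop = FALSE])

  eis <- compute_eis(bm, wt, cfg)
  if (cfg$per_wave_z) {
    for (w in unique(sheet$wave)) {
      i <- sheet$wave == w
      if (sum(i) < 2L)
        dr_stop("estimation", "per-wave z needs >= 2 observations in wave %s", w)
      eis$eis_z[i] <- (eis$eis_raw[i] - mean(eis$eis_raw[i])) /
        stats::sd(eis$eis_raw[i])
    }
  }
  cri <- compute_cri(bm, cfg)

  if (all(paste0("ats", 1:4) %in% names(sheet)) &&
      !anyNA(sheet[paste0("ats", 1:4)])) {
    assay <- as.matrix(sheet[paste0("ats", 1:4)])
  } else {
    miss <- setdiff(cfg$ats_probes, rownames(bm))
    if (length(miss))
      dr_stop("data", "no ATS assay columns and ATS probe(s) absent from array: %s",
              paste(miss, collapse = ", "))
    assay <- t(unclass(bm)[cfg$ats_probes, , drop = FALSE])
  }
  ref <- if (is.null(cfg$ats_reference)) "pooled" else cfg$ats_reference
  ats <- compute_ats(assay, ref)

  panel <- data.frame(
    person_id = sheet$person_id, couple_id = sheet$couple_id,
    wave = sheet$wave,
    eis_raw = eis$eis_raw, eis_z = eis$eis_z,
    cri = cri$cri, ats = ats,
    elevated = classify_elevated(ats, cfg$ats_cutoff),
    eis_coverage = attr(eis, "coverage")$fraction,
    n_cri_probes_used = cri$n_cri_probes_used,
    stringsAsFactors = FALSE)
  class(panel) <- c("score_panel", class(panel))
  panel
}
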