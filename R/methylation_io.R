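# Tabular I/O for the three inputs the pipeline touches: probe x sample
# beta matrices, EWAS weight tables, and long-format sample sheets.

#' Construct a beta-value matrix
#'
#' A `beta_matrix` is a numeric probes-by-samples matrix of methylation
#' fractions in \[0, 1\] (missing cells allowed), with unique CpG row ids and
#' unique observation column ids.
#'
#' @param values numeric matrix, probes in rows.
#' @param probe_ids,sample_ids optional id vectors; default to dimnames.
#' @return an object of class `beta_matrix` (a classed numeric matrix).
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids))
    dr_stop("data", "beta matrix needs probe and sample identifiers")
  if (anyDuplicated(probe_ids))
    dr_stop("data", "duplicate probe ids: %s",
            paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    dr_stop("data", "duplicate sample ids: %s",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad))
    dr_stop("data", "%d beta value(s) outside [0, 1]", sum(bad))
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, %d missing cell(s)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

infer_sep <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row and a key column of CpG identifiers (or sample
#' identifiers when `orientation = "samples-in-rows"`). Empty cells and the
#' literal `"NA"` are both treated as missing, matching the two dialects of
#' methylation exports. In strict mode any non-numeric or out-of-range cell
#' is an error; otherwise such cells become missing and their count is
#' reported.
#'
#' @param path file path (TSV by default, CSV if the extension is `.csv`).
#' @param orientation `"probes-in-rows"` (default) or `"samples-in-rows"`.
#' @param strict logical; reject rather than blank bad cells.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes-in-rows",
                                             "samples-in-rows"),
                             strict = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) dr_stop("data", "file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  missing_token <- cells == "" | cells == "NA"
  non_numeric <- is.na(vals) & !missing_token
  if (strict && any(non_numeric))
    dr_stop("data", "non-numeric cell(s) in %s (e.g. '%s')", path,
            cells[non_numeric][1L])
  out_of_range <- !is.na(vals) & (vals < 0 | vals > 1)
  if (strict && any(out_of_range))
    dr_stop("data", "%d beta value(s) outside [0, 1] in %s",
            sum(out_of_range), path)
  vals[non_numeric | out_of_range] <- NA_real_
  n_blanked <- sum(missing_token | non_numeric | out_of_range)
  if (n_blanked > 0L)
    message(sprintf("read_beta_matrix: %d missing cell(s) in %s",
                    n_blanked, path))
  dimnames(vals) <- list(ids, colnames(cells))
  if (orientation == "samples-in-rows") vals <- t(vals)
  beta_matrix(vals)
}

#' Write a beta-value matrix to delimited text
#'
#' @param bm a [beta_matrix()].
#' @param path output path; TSV unless the extension is `.csv`.
#' @export
write_beta_matrix <- function(bm, path) {
  df <- data.frame(cpg = rownames(bm),
                   apply(unclass(bm), 2L, num_chr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an EWAS effect-size weight table
#'
#' Two required columns, `cpg` and `coefficient`: the CpG identifier and its
#' published effect-size weight. Probe identifiers are case-sensitive and not
#' checked against any array manifest.
#'
#' @param path delimited text file with a header.
#' @return a data.frame of class `weight_table` with columns `cpg`,
#'   `coefficient`.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) dr_stop("data", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  weight_table(df$cpg, df$coefficient)
}

#' Construct a weight table
#'
#' @param cpg character vector of CpG identifiers.
#' @param coefficient numeric effect sizes, finite.
#' @param score_name,citation optional metadata strings.
#' @return data.frame of class `weight_table`.
#' @export
weight_table <- function(cpg, coefficient, score_name = NULL,
                         citation = NULL) {
  if (is.null(cpg) || is.null(coefficient) ||
      length(cpg) != length(coefficient))
    dr_stop("data", "weight table needs matching cpg and coefficient columns")
  if (anyDuplicated(cpg))
    dr_stop("data", "duplicate CpG ids in weight table")
  if (any(!is.finite(coefficient)))
    dr_stop("data", "non-finite coefficient(s) in weight table")
  out <- data.frame(cpg = as.character(cpg),
                    coefficient = as.numeric(coefficient),
                    stringsAsFactors = FALSE)
  attr(out, "score_name") <- score_name
  attr(out, "citation") <- citation
  class(out) <- c("weight_table", class(out))
  out
}

#' Restrict a beta matrix to the probes of a weight table
#'
#' Array content varies between platforms, so scoring first intersects the
#' requested probe set with what the matrix carries. Output probe order
#' follows the weight table. Idempotent.
#'
#' @param bm a [beta_matrix()].
#' @param wt a [weight_table()].
#' @return list with `matrix` (restricted `beta_matrix`), `weights`
#'   (matching coefficient vector) and `coverage`
#'   (`n_requested`, `n_found`, `fraction`).
#' @export
align_probes <- function(bm, wt) {
  found <- wt$cpg[wt$cpg %in% rownames(bm)]
  if (length(found) == 0L)
    dr_stop("data", "no scoreable probes: weight table and beta matrix share no CpGs")
  list(matrix = beta_matrix(unclass(bm)[found, , drop = FALSE]),
       weights = stats::setNames(wt$coefficient[match(found, wt$cpg)], found),
       coverage = list(n_requested = nrow(wt), n_found = length(found),
                       fraction = length(found) / nrow(wt)))
}

#' Read and validate a long-format sample sheet
#'
#' One row per person-wave. Required columns: `person_id`, `couple_id`,
#' `wave`, `age`, `sex`, `binge`; optional per-locus alcohol assay columns
#' `ats1..ats4`. Integrity rules: a (person, wave) pair appears at most
#' once, a person belongs to exactly one couple, and a couple holds at most
#' two people.
#'
#' @param path delimited text file with a header.
#' @return validated data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) dr_stop("data", "file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df a data.frame to validate in place.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("person_id", "couple_id", "wave", "age", "sex", "binge")
  miss <- setdiff(need, names(df))
  if (length(miss))
    dr_stop("data", "sample sheet lacks column(s): %s",
            paste(miss, collapse = ", "))
  df$person_id <- as.character(df$person_id)
  df$couple_id <- as.character(df$couple_id)
  df$wave <- as.integer(df$wave)
  key <- paste(df$person_id, df$wave)
  if (anyDuplicated(key))
    dr_stop("data", "duplicated (person, wave) row(s): %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  pc <- unique(df[, c("person_id", "couple_id")])
  if (anyDuplicated(pc$person_id))
    dr_stop("data", "person(s) assigned to more than one couple: %s",
            paste(unique(pc$person_id[duplicated(pc$person_id)]),
                  collapse = ", "))
  per_couple <- table(pc$couple_id)
  if (any(per_couple > 2L))
    dr_stop("data", "couple(s) with more than two partners: %s",
            paste(names(per_couple)[per_couple > 2L], collapse = ", "))
  if (!inherits(df, "sample_sheet")) class(df) <- c("sample_sheet", class(df))
  df
}

#' Write or read a score panel
#'
#' `write_scores()` emits one row per person-wave with every score, flag and
#' metadata column at full precision; `read_scores()` reads it back so that a
#' write/read round trip preserves values to better than 1e-12.
#'
#' @param panel a score panel data.frame (see [score_cohort()]).
#' @param path output path.
#' @export
write_scores <- function(panel, path) {
  out <- panel
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], num_chr)
  utils::write.table(out, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) dr_stop("data", "file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = infer_sep(path),
                    stringsAsFactors = FALSE)
}
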