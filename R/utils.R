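# Internal helpers: classed conditions, observation keys, small numerics.

# Condition classes map onto the CLI's exit-code categories:
#   config (bad options / config keys), data (format or integrity problems
#   in inputs), estimation (model fitting failures).
dr_stop <- function(category, msg, ...) {
  stop(structure(
    class = c(paste0("dyadrisk_", category, "_error"), "dyadrisk_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

dr_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

#' Build an observation key from person id and wave
#'
#' Beta-matrix columns are keyed as `"<person_id>@<wave>"` so that a
#' probe-by-sample matrix joins to the long-format sample sheet without a
#' separate mapping file. `@` is reserved and must not occur in person ids.
#'
#' @param person_id character vector of person identifiers.
#' @param wave integer vector of wave labels (recycled).
#' @return character vector of observation keys.
#' @export
#' @examples
#' obs_key(c("p1", "p2"), 5)
obs_key <- function(person_id, wave) {
  if (any(grepl("@", person_id, fixed = TRUE)))
    dr_stop("data", "person ids must not contain the reserved '@' separator")
  paste0(person_id, "@", wave)
}

split_obs_key <- function(key) {
  parts <- strsplit(key, "@", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    dr_stop("data", "malformed observation key (expected 'person@wave'): %s",
            key[lengths(parts) != 2L][1L])
  data.frame(person_id = vapply(parts, `[`, "", 1L),
             wave = as.integer(vapply(parts, `[`, "", 2L)))
}

# Full-precision numeric formatting for text round-trips.
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                   trim = TRUE)
  }, "")
  out
}

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
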