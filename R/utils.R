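# Internal helpers shared across modules.

#' Normalize protein identifiers
#'
#' Protein/gene identifiers are compared case-insensitively throughout the
#' package; the canonical stored form is the trimmed, upper-cased symbol.
#'
#' @param x Character vector of identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_protein(c(" c3", "C3", "hla-dra"))
#' @export
normalize_protein <- function(x) {
  if (!is.character(x)) {
    rlang::abort("protein identifiers must be character", class = "ivignet_error_validation")
  }
  out <- toupper(trimws(x))
  if (any(!nzchar(out) | is.na(out))) {
    rlang::abort("empty protein identifier after trimming", class = "ivignet_error_validation")
  }
  out
}

# Deterministic sub-seed derived from a master seed and a text tag, so each
# generator stage draws from its own stream. Kept well below 2^31.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

abort_parse <- function(msg) rlang::abort(msg, class = "ivignet_error_parse")
abort_validation <- function(msg) rlang::abort(msg, class = "ivignet_error_validation")
abort_config <- function(msg) rlang::abort(msg, class = "ivignet_error_config")

# range helper: c(min, max) with min <= max
check_range <- function(x, name) {
  if (length(x) != 2 || !is.numeric(x) || any(is.na(x)) || x[1] > x[2]) {
    abort_config(sprintf("`%s` must be c(min, max) with min <= max", name))
  }
  invisible(x)
}
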