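#' Round half away from zero
#'
#' Presentation rounding used for all percentage cells: exact halves round
#' up (2.45 -> 2.5), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(48.55, 9.025, 16.134), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# empty tibble constructors -- the canonical column layouts used throughout

empty_proteins <- function() {
  tibble(seq_id = character(), length = integer(), sequence = character())
}

empty_domain_hits <- function() {
  tibble(
    seq_id = character(), model_name = character(), model_acc = character(),
    start = integer(), end = integer(),
    bit_score = double(), evalue = double(), source = character()
  )
}

empty_regions <- function() {
  tibble(
    seq_id = character(), region_type = character(),
    start = integer(), end = integer(), source_tool = character()
  )
}

REGION_TYPES <- c("LC", "TM", "CC", "SP")

check_coords <- function(start, end, what = "interval") {
  if (any(start < 1L) || any(start > end)) {
    abort(sprintf("invalid %s coordinates: need 1 <= start <= end", what))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
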