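#' Round half away from zero
#'
#' Rounds to the nearest integer with exact .5 ties resolved away from zero
#' (so 3.5 -> 4 and -3.5 -> -4), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

VALID_ALLELES <- c("A", "C", "G", "T")

is_ambiguous_pair <- function(a1, a2) {
  p <- paste(sort(c(a1, a2)), collapse = "")
  p %in% c("AT", "CG")
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}
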