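# Internal helpers: classed error conditions and small sequence utilities.

.abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sedapipe_error", "error", "condition")))
}
abort_invalid <- function(msg) .abort(msg, "sedapipe_invalid_parameter")
abort_lookup  <- function(msg) .abort(msg, "sedapipe_lookup_error")
abort_format  <- function(msg) .abort(msg, "sedapipe_format_error")
abort_model   <- function(msg) .abort(msg, "sedapipe_model_invalid")

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scalar fast path (avoids DNAStringSet construction in per-read loops)
.revcomp1 <- function(x) {
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", x))))
}

# N-aware Hamming distance between two equal-length strings: N never matches.
.count_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  nr <- charToRaw("N")
  sum(ra != rb | ra == nr | rb == nr)
}

.check_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x)) {
    abort_format(sprintf("%s contains characters outside ACGTN", what))
  }
  invisible(TRUE)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

.stopifnot_count <- function(x, name, min = 1) {
  if (!.is_count(x) || x < min) {
    abort_invalid(sprintf("`%s` must be an integer >= %s", name, min))
  }
}
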