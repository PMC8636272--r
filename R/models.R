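#' Post-mortem damage model for simulated ancient DNA
#'
#' Cytosine deamination in single-stranded overhangs is read as C->T near the
#' 5' end of a fragment and, mirrored, as G->A near the 3' end. The terminal
#' substitution probability decays exponentially with distance from the
#' fragment end: position i (1-based from the end) is hit with probability
#' `p1 * exp(-lambda_decay * (i - 1))`. Interior positions therefore converge
#' to the sequencing-error background. A uniform per-base sequencing error is
#' applied after damage.
#'
#' @param p1_ct probability of C->T at the 5'-terminal position.
#' @param lambda_decay per-position exponential decay rate (>= 0).
#' @param p1_ga probability of G->A at the 3'-terminal position; defaults to
#'   mirroring `p1_ct`.
#' @param seq_error per-base uniform sequencing-error probability.
#' @return An object of class `damage_model`.
#' @export
damage_model <- function(p1_ct = 0.2, lambda_decay = 0.3, p1_ga = p1_ct,
                         seq_error = 0.001) {
  for (p in list(p1_ct = p1_ct, p1_ga = p1_ga, seq_error = seq_error)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      abort_invalid("damage probabilities must lie in [0, 1]")
    }
  }
  if (!is.numeric(lambda_decay) || length(lambda_decay) != 1L ||
      is.na(lambda_decay) || lambda_decay < 0) {
    abort_invalid("`lambda_decay` must be >= 0")
  }
  structure(list(p1_ct = p1_ct, lambda_decay = lambda_decay,
                 p1_ga = p1_ga, seq_error = seq_error),
            class = "damage_model")
}

#' Fragment-length model for degraded sedaDNA
#'
#' Lengths are drawn from a log-normal with the requested mean and spread,
#' truncated (by rejection) to `[min_len, max_len]`. Defaults emulate
#' permafrost/lake-sediment ancient DNA: mean 55 bp, bounds 30-150 bp.
#'
#' @param mean_len,sd_len mean and standard deviation of fragment length (bp).
#' @param min_len,max_len truncation bounds (bp); `min_len >= 20`.
#' @return An object of class `fragment_model`.
#' @export
fragment_model <- function(mean_len = 55, sd_len = 15, min_len = 30, max_len = 150) {
  if (!is.numeric(min_len) || min_len < 20) abort_invalid("`min_len` must be >= 20")
  if (!is.numeric(max_len) || max_len < min_len) abort_invalid("`max_len` must be >= min_len")
  if (!is.numeric(mean_len) || mean_len <= 0 || !is.numeric(sd_len) || sd_len <= 0) {
    abort_invalid("`mean_len` and `sd_len` must be positive")
  }
  structure(list(mean_len = mean_len, sd_len = sd_len,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "fragment_model")
}

# Truncated log-normal draw (rejection sampling).
.draw_lengths <- function(frag, n) {
  s2 <- log(1 + (frag$sd_len / frag$mean_len)^2)
  mu <- log(frag$mean_len) - s2 / 2
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(max(n, 100), meanlog = mu, sdlog = sqrt(s2)))
    out <- c(out, x[x >= frag$min_len & x <= frag$max_len])
  }
  as.integer(out[seq_len(n)])
}
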