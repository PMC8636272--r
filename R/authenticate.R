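#' Terminal deamination damage profile from aligned reads
#'
#' Tallies, per read position from the 5' end (1-based, strand-corrected so
#' position 1 is always the fragment's biological 5' terminus), the fraction
#' of reference-C sites read as T; mirrored for reference-G read as A from
#' the 3' end. Ancient DNA shows an elevated terminal C->T (and G->A) rate
#' decaying into the read; modern contamination does not. Reads aligned to
#' the minus strand are compared against the reverse complement of their
#' reference window so damage stays at the biological fragment ends. Sites
#' where the read base is N are excluded from numerator and denominator.
#' Mismatch classes other than C->T/G->A are accumulated in a QC table but
#' play no part in the authentication decision.
#'
#' @param hits hit data frame (read_id, seq_id, start, strand, mismatches),
#'   one row per read, e.g. from [truth_hits()] or a best-hit selection from
#'   [match_read()].
#' @param reads the read set (named DNAStringSet or character).
#' @param refs a [reference_db()] or named character vector of references.
#' @param P profile depth in positions (default 25).
#' @param max_mismatches only hits with at most this many mismatches are
#'   admitted (default 3).
#' @return An object of class `damage_profile`: data frame with position,
#'   ct5, ga3, n_obs5, n_obs3, k_ct5, k_ga3 (fractions are NA where the
#'   denominator is 0) and a `mismatch_classes` attribute.
#' @export
damage_profile <- function(hits, reads, refs, P = 25, max_mismatches = 3) {
  .stopifnot_count(P, "P")
  chr <- if (inherits(refs, "reference_db")) refs$chr else refs
  rd <- as.character(reads)
  hits <- hits[hits$mismatches <= max_mismatches, , drop = FALSE]

  n5 <- k5 <- n3 <- k3 <- integer(P)
  classes <- matrix(0L, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  rawN <- charToRaw("N")
  for (i in seq_len(nrow(hits))) {
    read <- rd[[hits$read_id[i]]]
    len <- nchar(read)
    seg <- substr(chr[[hits$seq_id[i]]], hits$start[i], hits$start[i] + len - 1L)
    if (hits$strand[i] == "-") seg <- .revcomp1(seg)
    rv <- strsplit(read, "")[[1]]
    sv <- strsplit(seg, "")[[1]]
    ok <- rv != "N" & sv != "N"
    mism <- ok & rv != sv
    if (any(mism)) {
      tb <- table(factor(sv[mism], DNA_BASES), factor(rv[mism], DNA_BASES))
      classes <- classes + as.integer(tb)
    }
    d <- min(P, len)
    i5 <- seq_len(d)
    isC <- sv[i5] == "C" & ok[i5]
    n5[i5] <- n5[i5] + isC
    k5[i5] <- k5[i5] + (isC & rv[i5] == "T")
    i3 <- len - i5 + 1L
    isG <- sv[i3] == "G" & ok[i3]
    n3[i5] <- n3[i5] + isG
    k3[i5] <- k3[i5] + (isG & rv[i3] == "A")
  }
  prof <- data.frame(position = seq_len(P),
                     ct5 = ifelse(n5 > 0, k5 / n5, NA_real_),
                     ga3 = ifelse(n3 > 0, k3 / n3, NA_real_),
                     n_obs5 = n5, n_obs3 = n3, k_ct5 = k5, k_ga3 = k3)
  structure(prof, class = c("damage_profile", "data.frame"),
            mismatch_classes = classes)
}

#' Write a damage profile as TSV
#' @param profile a [damage_profile()].
#' @param path output path.
#' @export
write_damage_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(profile)
}

#' Ancient-authenticity decision from a damage profile
#'
#' A detection is called ancient-authentic when (i) the terminal C->T rate
#' reaches `min_terminal_rate` and (ii) a one-sided exact binomial test of
#' the position-1 T count against the pooled interior baseline rate rejects
#' at `alpha`. With too few terminal observations the decision is
#' undetermined (NA) rather than negative.
#'
#' @param profile a [damage_profile()].
#' @param min_terminal_rate minimum position-1 C->T fraction (default 0.05).
#' @param baseline_positions interior positions pooled as the background
#'   rate; must exclude position 1 (default 11:25).
#' @param alpha significance level (default 0.05).
#' @param min_obs minimum position-1 reference-C observations for a call
#'   (default 10).
#' @return An object of class `damage_decision`: list(decision, ct1_rate,
#'   baseline_rate, rate_ratio, p_value, n_terminal, n_baseline). `decision`
#'   is TRUE, FALSE, or NA (undetermined).
#' @export
is_ancient <- function(profile, min_terminal_rate = 0.05,
                       baseline_positions = 11:25, alpha = 0.05,
                       min_obs = 10) {
  if (1 %in% baseline_positions) {
    abort_invalid("`baseline_positions` must not include position 1")
  }
  bp <- intersect(baseline_positions, profile$position)
  n1 <- profile$n_obs5[1]
  x1 <- profile$k_ct5[1]
  nb <- sum(profile$n_obs5[bp])
  xb <- sum(profile$k_ct5[bp])
  out <- list(decision = NA, ct1_rate = NA_real_, baseline_rate = NA_real_,
              rate_ratio = NA_real_, p_value = NA_real_,
              n_terminal = n1, n_baseline = nb)
  class(out) <- "damage_decision"
  if (is.na(n1) || n1 < min_obs || nb == 0) return(out)

  p0 <- xb / nb
  out$ct1_rate <- x1 / n1
  out$baseline_rate <- p0
  out$rate_ratio <- if (p0 > 0) out$ct1_rate / p0 else Inf
  test <- stats::binom.test(x1, n1, p = max(p0, 1e-12), alternative = "greater")
  out$p_value <- test$p.value
  out$decision <- (out$ct1_rate >= min_terminal_rate) && (out$p_value < alpha)
  out
}

#' @export
print.damage_decision <- function(x, ...) {
  lab <- if (is.na(x$decision)) "undetermined" else if (x$decision) "ancient" else "not ancient"
  cat(sprintf("<damage_decision> %s: ct5[1]=%.3f baseline=%.4f p=%.3g (n=%d)\n",
              lab, x$ct1_rate, x$baseline_rate, x$p_value, x$n_terminal))
  invisible(x)
}

#' Fit per-sample degradation condition from reads and alignments
#'
#' Summarizes a sample's degradation state as a (fragment, damage) condition
#' usable for condition-matched efficiency estimation: mean observed
#' fragment length and terminal C->T rate, binned for stability.
#'
#' @param hits,reads,refs as in [damage_profile()].
#' @param length_breaks,damage_breaks bin edges for the two summaries.
#' @return list(frag = [fragment_model()], dmg = [damage_model()],
#'   condition_id = character label).
#' @export
fit_sample_condition <- function(hits, reads, refs,
                                 length_breaks = c(30, 45, 60, 90, 150),
                                 damage_breaks = c(0, 0.05, 0.15, 0.3, 1)) {
  prof <- damage_profile(hits, reads, refs)
  lens <- nchar(as.character(reads)[hits$read_id])
  mlen <- mean(lens)
  ct1 <- prof$ct5[1]
  if (is.na(ct1)) ct1 <- 0
  lb <- length_breaks[findInterval(mlen, length_breaks, all.inside = TRUE)]
  dbin <- findInterval(ct1, damage_breaks, all.inside = TRUE)
  # decay so that the fitted terminal rate reproduces the observed one
  list(frag = fragment_model(mean_len = max(lb, 30), sd_len = max(stats::sd(lens), 1)),
       dmg = damage_model(p1_ct = ct1, lambda_decay = 0.3,
                          seq_error = 0.001),
       condition_id = sprintf("len%s_dmg%d", lb, dbin))
}
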