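#' Identification efficiency of the pipeline for one taxon
#'
#' Simulates `n_sim` reads from the taxon under a given degradation
#' condition, runs classification end-to-end, and reports the fraction whose
#' assignment collates back to the taxon at `rank`. Taxa whose genomes are
#' shared with congeners lose reads to the genus LCA and score lower at
#' species rank; heavier damage lowers efficiency by destroying perfect
#' matches.
#'
#' @param db a [reference_db()].
#' @param tax a [taxonomy()].
#' @param taxon taxon id with references in `db`.
#' @param frag a [fragment_model()] (the condition's fragmentation).
#' @param dmg a [damage_model()] (the condition's damage).
#' @param n_sim simulated reads (>= 500 for useful binomial error).
#' @param rank collation rank at which recovery is scored.
#' @param seed integer seed.
#' @return One-row data frame: taxon_id, rank, e, n_sim.
#' @export
estimate_efficiency <- function(db, tax, taxon, frag = fragment_model(),
                                dmg = damage_model(), n_sim = 1000,
                                rank = "species", seed = 1) {
  if (!.is_count(n_sim) || n_sim < 500) abort_invalid("`n_sim` must be >= 500")
  if (taxon %in% db$taxon_id) {
    weights <- stats::setNames(1, taxon)
  } else {
    # internal taxon: draw equally from the species below it
    sids <- taxon_sequences(db, taxon, tax)
    if (!length(sids)) {
      abort_lookup(sprintf("taxon %s has no reference sequences", taxon))
    }
    members <- unique(db$taxon_id[sids])
    weights <- stats::setNames(rep(1, length(members)), members)
  }
  sim <- simulate_sample_reads(db, weights, n_sim,
                               frag = frag, dmg = dmg, seed = seed)
  asn <- classify_reads(sim$reads, db, tax, min_read_length = frag$min_len)
  target <- ancestor_at_rank(tax, taxon, rank)
  got <- ancestor_at_rank(tax, asn$taxon_id, rank)
  data.frame(taxon_id = as.integer(taxon), rank = rank,
             e = mean(!is.na(got) & got == target), n_sim = n_sim)
}

#' Efficiency table over several taxa
#'
#' @inheritParams estimate_efficiency
#' @param taxa vector of taxon ids.
#' @param condition_id label stored with the estimates.
#' @return Data frame: taxon_id, condition_id, rank, e, n_sim.
#' @export
efficiency_table <- function(db, tax, taxa, frag = fragment_model(),
                             dmg = damage_model(), n_sim = 1000,
                             rank = "species", seed = 1,
                             condition_id = "default") {
  rows <- lapply(seq_along(taxa), function(i) {
    estimate_efficiency(db, tax, taxa[i], frag, dmg, n_sim, rank,
                        seed = seed + i)
  })
  out <- do.call(rbind, rows)
  out$condition_id <- condition_id
  out[c("taxon_id", "condition_id", "rank", "e", "n_sim")]
}

#' Efficiency- and depth-corrected relative abundances
#'
#' Divides each taxon's read count by its identification efficiency and
#' renormalizes within sample:
#' \deqn{a_{t,s} = (r_{t,s}/e_{t,s}) / \sum_u (r_{u,s}/e_{u,s}).}
#' Sequencing depth cancels in the within-sample normalization; degradation
#' differences between samples enter through condition-matched efficiencies.
#' Taxa without an efficiency estimate, or with e = 0 despite non-zero
#' counts, are flagged and excluded (with a warning) rather than silently
#' kept.
#'
#' @param counts a `count_matrix`.
#' @param efficiencies data frame with columns taxon_id and e (as from
#'   [efficiency_table()]); optionally condition_id matched per sample via
#'   `sample_conditions`.
#' @param sample_conditions optional named vector mapping sample id to
#'   condition_id; default matches all samples to the single condition
#'   present.
#' @return An object of class `relative_abundance`: list(abundance matrix
#'   with columns summing to 1, rank, taxon_names, flagged).
#' @export
normalize_abundance <- function(counts, efficiencies, sample_conditions = NULL) {
  eff <- efficiencies
  if (!all(c("taxon_id", "e") %in% names(eff))) {
    abort_invalid("`efficiencies` needs columns taxon_id and e")
  }
  if (is.null(eff$condition_id)) eff$condition_id <- "default"
  conds <- unique(eff$condition_id)
  samples <- colnames(counts$counts)
  if (is.null(sample_conditions)) {
    if (length(conds) > 1L) {
      abort_invalid("several conditions present: supply `sample_conditions`")
    }
    sample_conditions <- stats::setNames(rep(conds, length(samples)), samples)
  }
  taxa <- rownames(counts$counts)
  emat <- matrix(NA_real_, length(taxa), length(samples),
                 dimnames = list(taxa, samples))
  for (s in samples) {
    sub <- eff[eff$condition_id == sample_conditions[[s]], ]
    emat[, s] <- sub$e[match(as.integer(taxa), sub$taxon_id)]
  }
  no_e <- rowSums(is.na(emat)) > 0
  zero_e <- !no_e & apply(emat == 0 & counts$counts > 0, 1, any)
  flagged <- taxa[no_e | zero_e]
  if (length(flagged)) {
    warning(sprintf("excluding %d taxa without usable efficiency: %s",
                    length(flagged), paste(flagged, collapse = ", ")))
  }
  keep <- !(taxa %in% flagged)
  r <- counts$counts[keep, , drop = FALSE] / emat[keep, , drop = FALSE]
  tot <- colSums(r)
  a <- sweep(r, 2, ifelse(tot > 0, tot, 1), "/")
  structure(list(abundance = a, rank = counts$rank,
                 taxon_names = counts$taxon_names[rownames(a)],
                 flagged = flagged),
            class = "relative_abundance")
}

#' @export
print.relative_abundance <- function(x, ...) {
  cat(sprintf("<relative_abundance> rank %s: %d taxa x %d samples (%d flagged out)\n",
              x$rank, nrow(x$abundance), ncol(x$abundance), length(x$flagged)))
  invisible(x)
}

#' Write relative abundances as TSV
#' @param ra a [normalize_abundance()] result.
#' @param path output path.
#' @export
write_abundance <- function(ra, path) {
  df <- data.frame(taxon_id = rownames(ra$abundance),
                   name = unname(ra$taxon_names[rownames(ra$abundance)]),
                   ra$abundance, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ra)
}
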