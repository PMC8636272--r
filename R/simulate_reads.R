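# Shared fragment-drawing + damage machinery for the genomic and
# mitochondrial simulators. `refs` is a named character vector of source
# sequences and `pick` names one source per read.
.simulate_fragments <- function(refs, pick, frag, dmg, ids) {
  n <- length(pick)
  lens <- .draw_lengths(frag, n)
  reflen <- nchar(refs)[match(pick, names(refs))]
  lens <- pmin(lens, reflen)
  starts <- floor(stats::runif(n) * (reflen - lens + 1)) + 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)

  out <- character(n)
  dmg_subs <- character(n)
  err_subs <- character(n)
  lam <- dmg$lambda_decay
  for (i in seq_len(n)) {
    fragment <- substr(refs[[pick[i]]], starts[i], starts[i] + lens[i] - 1L)
    if (strands[i] == "-") fragment <- .revcomp1(fragment)
    v <- strsplit(fragment, "")[[1]]
    L <- length(v)
    ds <- character(0)
    if (dmg$p1_ct > 0) {
      iC <- which(v == "C")
      if (length(iC)) {
        hit <- iC[stats::runif(length(iC)) < dmg$p1_ct * exp(-lam * (iC - 1))]
        if (length(hit)) {
          v[hit] <- "T"
          ds <- c(ds, sprintf("%d:C:T", hit))
        }
      }
    }
    if (dmg$p1_ga > 0) {
      iG <- which(v == "G")
      if (length(iG)) {
        hit <- iG[stats::runif(length(iG)) < dmg$p1_ga * exp(-lam * (L - iG))]
        if (length(hit)) {
          v[hit] <- "A"
          ds <- c(ds, sprintf("%d:G:A", hit))
        }
      }
    }
    es <- character(0)
    if (dmg$seq_error > 0) {
      ie <- which(stats::runif(L) < dmg$seq_error)
      for (p in ie) {
        nb <- sample(setdiff(DNA_BASES, v[p]), 1)
        es <- c(es, sprintf("%d:%s:%s", p, v[p], nb))
        v[p] <- nb
      }
    }
    out[i] <- paste(v, collapse = "")
    dmg_subs[i] <- paste(ds, collapse = ";")
    err_subs[i] <- paste(es, collapse = ";")
  }
  list(
    reads = stats::setNames(out, ids),
    truth = data.frame(read_id = ids, seq_id = pick, start = starts,
                       strand = strands, length = lens,
                       damage_subs = dmg_subs, error_subs = err_subs,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a damaged sedaDNA read set from a reference database
#'
#' Reads are drawn from the taxa named in `abundance` proportionally to
#' their weights; for each read a fragment window and a strand are chosen
#' uniformly, deamination damage is applied per [damage_model()] (C->T from
#' the 5' end, G->A mirrored from the 3' end), and uniform sequencing errors
#' are applied afterwards. The returned truth table records, per read, the
#' source taxon, reference window, strand and every introduced substitution
#' (read coordinates, 1-based), so downstream estimates can be checked
#' against the generating process.
#'
#' @param db a [reference_db()].
#' @param abundance named non-negative weights, names are taxon ids present
#'   in `db`; at least one weight must be positive.
#' @param n_reads number of reads to draw.
#' @param frag a [fragment_model()].
#' @param dmg a [damage_model()].
#' @param seed integer seed; identical arguments and seed give byte-identical
#'   output.
#' @param read_prefix prefix for read ids.
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame: read_id, taxon_id, seq_id, start, strand, length,
#'   damage_subs, error_subs).
#' @export
simulate_sample_reads <- function(db, abundance, n_reads,
                                  frag = fragment_model(),
                                  dmg = damage_model(), seed = 1,
                                  read_prefix = "r") {
  if (is.null(names(abundance)) || !is.numeric(abundance)) {
    abort_invalid("`abundance` must be a named numeric vector of taxon weights")
  }
  if (any(abundance < 0) || anyNA(abundance)) {
    abort_invalid("abundance weights must be non-negative")
  }
  if (sum(abundance) <= 0) abort_invalid("at least one abundance weight must be positive")
  taxa <- as.integer(names(abundance))
  missing <- setdiff(taxa, db$taxon_id)
  if (length(missing)) {
    abort_lookup(sprintf("taxa absent from the reference database: %s",
                         paste(missing, collapse = ", ")))
  }
  .stopifnot_count(n_reads, "n_reads")

  withr::with_seed(seed, {
    tax_draw <- sample(names(abundance), n_reads, replace = TRUE,
                       prob = abundance)
    pick <- vapply(tax_draw, function(t) {
      sids <- names(db$taxon_id)[db$taxon_id == as.integer(t)]
      if (length(sids) == 1L) sids else sample(sids, 1)
    }, character(1))
    ids <- sprintf("%s%05d", read_prefix, seq_len(n_reads))
    sim <- .simulate_fragments(db$chr, unname(pick), frag, dmg, ids)
  })
  sim$truth$taxon_id <- db$taxon_id[sim$truth$seq_id]
  sim$truth <- sim$truth[c("read_id", "taxon_id", "seq_id", "start", "strand",
                           "length", "damage_subs", "error_subs")]
  rownames(sim$truth) <- NULL
  list(reads = Biostrings::DNAStringSet(sim$reads), truth = sim$truth)
}

#' Alignment records from simulation ground truth
#'
#' Builds the hit table for each simulated read's true placement, with
#' mismatch counts computed against the reference. Useful for studying
#' damage-profile estimation in isolation from the aligner.
#'
#' @param truth truth table from [simulate_sample_reads()] or
#'   [simulate_mito_reads()].
#' @param reads the matching read set.
#' @param refs a [reference_db()], or a named character vector of reference
#'   sequences keyed by `seq_id`.
#' @return A hit data frame (read_id, seq_id, taxon_id, start, strand,
#'   mismatches, identity).
#' @export
truth_hits <- function(truth, reads, refs) {
  chr <- if (inherits(refs, "reference_db")) refs$chr else refs
  rd <- as.character(reads)[truth$read_id]
  mm <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    seg <- substr(chr[[truth$seq_id[i]]], truth$start[i],
                  truth$start[i] + truth$length[i] - 1L)
    if (truth$strand[i] == "-") seg <- .revcomp1(seg)
    mm[i] <- .count_mismatches(rd[i], seg)
  }
  data.frame(read_id = truth$read_id, seq_id = truth$seq_id,
             taxon_id = truth$taxon_id %||% NA_integer_,
             start = truth$start, strand = truth$strand,
             mismatches = mm, identity = 1 - mm / truth$length,
             stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ qualities are filled with a constant ('I'), as simulated reads
#' carry no base-quality model.
#'
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param format "fasta" or "fastq".
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads, path)
  } else {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  }
  invisible(reads)
}

#' Write a simulation truth table as TSV
#'
#' @param truth truth table data frame.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
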