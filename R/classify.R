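# Core placement search. Reports every (sequence, offset, strand) placement
# of `read` in `subjects` with at most `max_mm` mismatches, gap-free, both
# strands. Mismatch counts are recomputed N-aware in package code so that an
# N on either side never counts as a match.
.find_placements <- function(read, subjects, subject_chr, max_mm) {
  read <- unname(read)
  len <- nchar(read)
  pats <- c(`+` = read, `-` = .revcomp1(read))
  rows <- list()
  for (strand in names(pats)) {
    p <- Biostrings::DNAString(pats[[strand]])
    m <- Biostrings::vmatchPattern(p, subjects, max.mismatch = max_mm, fixed = TRUE)
    for (j in seq_along(m)) {
      st <- Biostrings::startIndex(m)[[j]]
      if (is.null(st) || !length(st)) next
      slen <- nchar(subject_chr[[j]])
      st <- st[st >= 1 & st + len - 1L <= slen]
      if (!length(st)) next
      seg <- substring(subject_chr[[j]], st, st + len - 1L)
      mm <- vapply(seg, .count_mismatches, integer(1), a = pats[[strand]])
      keep <- mm <= max_mm
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = names(subjects)[j], start = st[keep], strand = strand,
        mismatches = unname(mm[keep]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, rows)
}

# Batch exact matcher (0 mismatches) over a whole read set via a PDict with
# a trusted band, orders of magnitude faster than per-read scans. Returns a
# data frame read_idx/seq_id/start/strand.
.batch_exact_placements <- function(read_chr, db) {
  n <- length(read_chr)
  widths <- nchar(read_chr)
  clean <- !grepl("[^ACGT]", read_chr)
  res <- list()
  if (any(clean)) {
    idx <- which(clean)
    sets <- list(`+` = read_chr[idx], `-` = .revcomp(read_chr[idx]))
    tb <- min(widths[idx])
    for (strand in names(sets)) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sets[[strand]]),
                              tb.start = 1, tb.width = tb)
      for (j in seq_along(db$seqs)) {
        m <- Biostrings::matchPDict(pd, db$seqs[[j]], max.mismatch = 0)
        hitlen <- lengths(m)
        if (!sum(hitlen)) next
        which_pat <- rep(seq_along(hitlen), hitlen)
        res[[length(res) + 1L]] <- data.frame(
          read_idx = idx[which_pat],
          seq_id = names(db$seqs)[j],
          start = unlist(Biostrings::startIndex(m), use.names = FALSE),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  # reads containing N take the scan path (N never matches, so recount)
  for (i in which(!clean)) {
    pl <- .find_placements(read_chr[i], db$seqs, db$chr, 0L)
    if (nrow(pl)) {
      pl$read_idx <- i
      res[[length(res) + 1L]] <- pl[c("read_idx", "seq_id", "start", "strand")]
    }
  }
  if (!length(res)) {
    return(data.frame(read_idx = integer(0), seq_id = character(0),
                      start = integer(0), strand = character(0)))
  }
  do.call(rbind, res)
}

#' Exhaustive gap-free read matching against a reference database
#'
#' Every placement of the read (forward or reverse complement) on any
#' database sequence with at most `max_mismatches` substitutions is
#' reported; indels are not considered, which is adequate at sedaDNA
#' fragment lengths (30-90 bp). An N in the read or the reference never
#' counts as a match.
#'
#' @param read a character string or DNAString (ACGTN).
#' @param db a [reference_db()].
#' @param max_mismatches maximum substitutions per placement (0-3).
#' @param min_read_length reads shorter than this are rejected (default 30).
#' @return Hit data frame: read_id (if `read` is named), seq_id, taxon_id,
#'   start (1-based), strand, mismatches, identity.
#' @export
match_read <- function(read, db, max_mismatches = 0, min_read_length = 30) {
  id <- names(read) %||% NA_character_
  read <- as.character(read)
  .check_dna(read, "read")
  if (nchar(read) < min_read_length) {
    abort_invalid(sprintf("read length %d below min_read_length %d",
                          nchar(read), min_read_length))
  }
  if (!.is_count(max_mismatches) || max_mismatches < 0 || max_mismatches > 3) {
    abort_invalid("`max_mismatches` must be between 0 and 3")
  }
  hits <- .find_placements(read, db$seqs, db$chr, max_mismatches)
  data.frame(read_id = if (nrow(hits)) id else character(0),
             seq_id = hits$seq_id,
             taxon_id = unname(db$taxon_id[hits$seq_id]),
             start = hits$start, strand = hits$strand,
             mismatches = hits$mismatches,
             identity = 1 - hits$mismatches / nchar(read),
             stringsAsFactors = FALSE)
}

#' Lowest-common-ancestor assignment of one read from its hits
#'
#' Only perfect hits (identity 1, i.e. zero mismatches) enter the call: a
#' read hitting a single taxon is assigned to it; a read hitting several
#' taxa is assigned to their lowest common ancestor; a read with no perfect
#' hit is left unassigned.
#'
#' @param hits hit data frame for a single read (as from [match_read()]).
#' @param tax a [taxonomy()].
#' @return A one-row data frame (read_id, taxon_id, n_perfect_hits,
#'   n_taxa_hit), or `NULL` when no perfect hit exists.
#' @export
assign_read <- function(hits, tax) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  perfect <- hits[hits$mismatches == 0, , drop = FALSE]
  if (!nrow(perfect)) return(NULL)
  taxa <- unique(perfect$taxon_id)
  assigned <- if (length(taxa) == 1L) taxa else taxa_lca(tax, taxa)
  data.frame(read_id = perfect$read_id[1] %||% NA_character_,
             taxon_id = assigned,
             n_perfect_hits = nrow(perfect),
             n_taxa_hit = length(taxa), stringsAsFactors = FALSE)
}

#' Classify a read set by perfect-hit LCA
#'
#' Applies duplicate removal (identical read sequences are matched once and
#' the result reused), finds perfect placements for every read against the
#' whole database, and assigns each read by [assign_read()]'s LCA rule.
#' Reads shorter than `min_read_length` or with no perfect hit get an NA
#' assignment, so the output has exactly one row per input read and
#' downstream ledgers balance.
#'
#' @param reads a named [Biostrings::DNAStringSet] or named character vector.
#' @param db a [reference_db()].
#' @param tax a [taxonomy()].
#' @param min_read_length minimum usable read length (default 30).
#' @return Data frame: read_id, taxon_id (NA if unassigned), n_perfect_hits,
#'   n_taxa_hit.
#' @export
classify_reads <- function(reads, db, tax, min_read_length = 30) {
  chr <- as.character(reads)
  ids <- names(chr)
  if (is.null(ids)) ids <- sprintf("r%05d", seq_along(chr))
  usable <- nchar(chr) >= min_read_length & !grepl("[^ACGTN]", chr)

  uchr <- unique(chr[usable])
  pl <- if (length(uchr)) .batch_exact_placements(uchr, db) else
    data.frame(read_idx = integer(0), seq_id = character(0))

  # assignment per unique sequence
  utax <- rep(NA_integer_, length(uchr))
  unper <- integer(length(uchr))
  untax <- integer(length(uchr))
  if (nrow(pl)) {
    sp <- split(pl, pl$read_idx)
    for (key in names(sp)) {
      i <- as.integer(key)
      taxa <- unique(unname(db$taxon_id[sp[[key]]$seq_id]))
      utax[i] <- if (length(taxa) == 1L) taxa else taxa_lca(tax, taxa)
      unper[i] <- nrow(sp[[key]])
      untax[i] <- length(taxa)
    }
  }
  m <- match(chr, uchr)  # NA for unusable reads
  data.frame(read_id = ids,
             taxon_id = ifelse(usable, utax[m], NA_integer_),
             n_perfect_hits = ifelse(usable, unper[m], 0L),
             n_taxa_hit = ifelse(usable, untax[m], 0L),
             stringsAsFactors = FALSE)
}

#' Exclusive-alignment confirmation of an animal detection
#'
#' A read confirms a focal taxon exclusively when it aligns perfectly (zero
#' mismatches) to one of that taxon's references and has no placement with
#' up to `slack` mismatches in any other taxon's references. Two different
#' taxa can never both be confirmed by the same read.
#'
#' @param read character string or DNAString.
#' @param focal_taxon taxon id with reference sequences in `db`.
#' @param db a [reference_db()].
#' @param slack mismatch allowance for the cross-taxon exclusion (1 or 2).
#' @param tax optional [taxonomy()]; when given, references of descendant
#'   taxa count as the focal taxon's own.
#' @return TRUE or FALSE.
#' @export
exclusive_confirm <- function(read, focal_taxon, db, slack = 2, tax = NULL) {
  if (!slack %in% c(0, 1, 2)) abort_invalid("`slack` must be 1 or 2 (0 allowed for testing)")
  focal_seqs <- taxon_sequences(db, focal_taxon, tax)
  if (!length(focal_seqs)) {
    abort_lookup(sprintf("taxon %s has no reference sequences", focal_taxon))
  }
  pl <- .find_placements(as.character(read), db$seqs, db$chr, slack)
  focal <- pl$seq_id %in% focal_seqs
  any(focal & pl$mismatches == 0) && !any(!focal)
}

#' All taxa a read confirms exclusively
#'
#' Single-scan form of [exclusive_confirm()] over every candidate taxon:
#' returns the taxa for which the read has a perfect placement and no
#' placement within `slack` mismatches anywhere else. By construction the
#' result holds at most one taxon.
#'
#' @inheritParams exclusive_confirm
#' @return Integer vector of taxon ids (length 0 or 1).
#' @export
confirmed_taxa <- function(read, db, slack = 2) {
  pl <- .find_placements(as.character(read), db$seqs, db$chr, slack)
  if (!nrow(pl)) return(integer(0))
  taxa <- unname(db$taxon_id[pl$seq_id])
  if (length(unique(taxa)) > 1L) return(integer(0))
  if (any(pl$mismatches == 0)) unique(taxa) else integer(0)
}

#' Collate read assignments into a rank-level count matrix
#'
#' Each assigned read contributes to the row that is the ancestor-or-self of
#' its assigned taxon at `rank`. Reads assigned above that rank are excluded
#' from the matrix and counted in the `above_rank` ledger; unassigned reads
#' (NA taxon) are counted in the `unassigned` ledger. Per sample, matrix
#' column sum + above_rank + unassigned equals the number of input reads.
#'
#' @param assignments data frame from [classify_reads()] (read_id, taxon_id).
#' @param tax a [taxonomy()].
#' @param rank collation rank, present in `tax$rank_order`.
#' @param sample_ids named character vector mapping read_id to sample id (or
#'   a data frame with columns read_id, sample_id).
#' @return A `count_matrix`: list(counts, rank, taxon_names, ledger).
#' @export
collate_profile <- function(assignments, tax, rank, sample_ids) {
  if (is.data.frame(sample_ids)) {
    sample_ids <- stats::setNames(sample_ids$sample_id, sample_ids$read_id)
  }
  missing <- setdiff(assignments$read_id, names(sample_ids))
  if (length(missing)) {
    abort_lookup(sprintf("no sample for read(s): %s",
                         paste(utils::head(missing, 3), collapse = ", ")))
  }
  samp <- unname(sample_ids[assignments$read_id])
  samples <- sort(unique(unname(sample_ids)))
  at_rank <- ancestor_at_rank(tax, assignments$taxon_id, rank)

  assigned <- !is.na(assignments$taxon_id)
  in_matrix <- assigned & !is.na(at_rank)
  taxa <- sort(unique(at_rank[in_matrix]))
  counts <- matrix(0L, length(taxa), length(samples),
                   dimnames = list(as.character(taxa), samples))
  if (any(in_matrix)) {
    tb <- table(factor(at_rank[in_matrix], levels = taxa),
                factor(samp[in_matrix], levels = samples))
    counts[] <- as.integer(tb)
  }
  per_sample <- function(flag) {
    v <- stats::setNames(integer(length(samples)), samples)
    if (any(flag)) {
      t2 <- table(factor(samp[flag], levels = samples))
      v[] <- as.integer(t2)
    }
    v
  }
  structure(
    list(counts = counts, rank = rank,
         taxon_names = stats::setNames(taxon_name(tax, taxa), as.character(taxa)),
         ledger = list(above_rank = per_sample(assigned & is.na(at_rank)),
                       unassigned = per_sample(!assigned))),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> rank %s: %d taxa x %d samples, %d reads in matrix\n",
              x$rank, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Subtract laboratory-control taxa from a sample matrix
#'
#' Taxa detected in any control are combined into one list and removed
#' entirely (whole rows) from the sample matrix, regardless of sample
#' counts. Removals are logged in the ledger.
#'
#' @param m a `count_matrix` of samples.
#' @param controls a `count_matrix` or list of them, same rank as `m`.
#' @return The filtered `count_matrix`; removed taxa in
#'   `$ledger$control_removed`.
#' @export
subtract_control_taxa <- function(m, controls) {
  if (inherits(controls, "count_matrix")) controls <- list(controls)
  bad <- character(0)
  for (ctl in controls) {
    if (!identical(ctl$rank, m$rank)) {
      abort_invalid(sprintf("control matrix rank '%s' differs from sample rank '%s'",
                            ctl$rank, m$rank))
    }
    bad <- union(bad, rownames(ctl$counts)[rowSums(ctl$counts) > 0])
  }
  drop <- rownames(m$counts) %in% bad
  m$ledger$control_removed <- rownames(m$counts)[drop]
  m$counts <- m$counts[!drop, , drop = FALSE]
  m$taxon_names <- m$taxon_names[rownames(m$counts)]
  m
}

#' Checklist and threshold authentication filters
#'
#' Conservative post-classification filtering: taxa absent from a regional
#' flora/fauna checklist are dropped (and logged); per-sample counts below
#' `min_reads` are zeroed; taxa left with fewer than `min_samples` non-zero
#' samples are dropped.
#'
#' @param m a `count_matrix`.
#' @param checklist character vector of accepted taxon names.
#' @param min_reads minimum reads per cell (default 3).
#' @param min_samples minimum samples a taxon must appear in (default 1).
#' @return The filtered `count_matrix`, with `$ledger$off_checklist` and
#'   `$ledger$dropped_sparse`.
#' @export
checklist_filter <- function(m, checklist, min_reads = 3, min_samples = 1) {
  .stopifnot_count(min_reads, "min_reads")
  .stopifnot_count(min_samples, "min_samples")
  nm <- unname(m$taxon_names[rownames(m$counts)])
  off <- !(nm %in% checklist)
  m$ledger$off_checklist <- stats::setNames(rownames(m$counts)[off], nm[off])
  m$counts <- m$counts[!off, , drop = FALSE]
  m$counts[m$counts < min_reads] <- 0L
  sparse <- rowSums(m$counts > 0) < min_samples
  m$ledger$dropped_sparse <- rownames(m$counts)[sparse]
  m$counts <- m$counts[!sparse, , drop = FALSE]
  m$taxon_names <- m$taxon_names[rownames(m$counts)]
  m
}

#' Read / write count matrices as TSV
#'
#' Taxa as rows (first column `taxon_id`, second `name`), samples as columns.
#'
#' @param m a `count_matrix`.
#' @param path file path.
#' @param rank rank recorded in the matrix (on read).
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(taxon_id = rownames(m$counts),
                   name = unname(m$taxon_names[rownames(m$counts)]),
                   m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, rank) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(df$taxon_id)
  structure(list(counts = counts, rank = rank,
                 taxon_names = stats::setNames(df$name, df$taxon_id),
                 ledger = list()),
            class = "count_matrix")
}
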