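#' Reference sequence databases
#'
#' A reference database links nucleotide sequences to taxonomy nodes: each
#' entry is a (sequence id, taxon id, sequence) triple. It is the substrate
#' for read matching, exclusive-alignment confirmation and k-mer coverage
#' evaluation.
#'
#' @param seqs a named [Biostrings::DNAStringSet] (names are sequence ids)
#'   or a named character vector. Sequences must be uppercase ACGTN.
#' @param taxon_ids integer vector, one taxon id per sequence.
#' @param tax optional [taxonomy()]; if supplied, every taxon id must resolve.
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(seqs, taxon_ids, tax = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort_format("reference sequences must carry unique names")
  }
  if (length(taxon_ids) != length(seqs)) {
    abort_invalid("`taxon_ids` must have one entry per sequence")
  }
  chr <- as.character(seqs)
  if (any(grepl("[^ACGTN]", chr))) {
    abort_format("reference sequences must be uppercase ACGTN")
  }
  if (!is.null(tax)) .tax_index(tax, unique(taxon_ids))
  structure(
    list(seqs = seqs,
         chr = stats::setNames(chr, names(seqs)),
         taxon_id = stats::setNames(as.integer(taxon_ids), names(seqs))),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d sequences, %d taxa, total %d bp\n",
              length(x$seqs), length(unique(x$taxon_id)),
              sum(Biostrings::width(x$seqs))))
  invisible(x)
}

#' Sequence ids belonging to a taxon
#'
#' Direct sequences of `taxon`; with a taxonomy supplied, sequences of all
#' descendant taxa are included as well.
#'
#' @param db a [reference_db()].
#' @param taxon a taxon id.
#' @param tax optional [taxonomy()] for descendant expansion.
#' @return Character vector of sequence ids.
#' @export
taxon_sequences <- function(db, taxon, tax = NULL) {
  if (is.null(tax)) {
    ids <- names(db$taxon_id)[db$taxon_id == taxon]
  } else {
    keep <- vapply(db$taxon_id, function(t) taxon %in% taxon_ancestors(tax, t),
                   logical(1))
    ids <- names(db$taxon_id)[keep]
  }
  ids
}

#' Generate divergent synthetic reference genomes
#'
#' One genome per species. Congeneric species are independently mutated
#' copies of a shared, random genus-ancestor sequence: each site is
#' substituted (to a different base) with probability
#' `divergence_between_species`, so the realized Hamming distance of a
#' species to its genus ancestor is Binomial(L, divergence). Genomes of
#' different genera are unrelated random sequences.
#'
#' @param tax a [taxonomy()] with genus and species ranks (see
#'   [make_taxonomy()]).
#' @param genome_length genome length in bp (>= 200).
#' @param divergence_between_species per-site substitution probability in
#'   \[0, 0.5\].
#' @param seed integer seed.
#' @return A [reference_db()] with one entry per species; the attribute
#'   `"realized_divergence"` records, per species, the realized Hamming
#'   fraction to its genus ancestor.
#' @export
make_reference_db <- function(tax, genome_length = 1000,
                              divergence_between_species = 0.05, seed = 1) {
  if (!.is_count(genome_length) || genome_length < 200) {
    abort_invalid("`genome_length` must be an integer >= 200")
  }
  d <- divergence_between_species
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 0.5) {
    abort_invalid("`divergence_between_species` must lie in [0, 0.5]")
  }
  species <- tax$nodes[tax$nodes$rank == "species", ]
  if (!nrow(species)) abort_invalid("taxonomy has no species-rank nodes")

  withr::with_seed(seed, {
    realized <- numeric(0)
    out <- character(0)
    taxids <- integer(0)
    for (gid in unique(species$parent_id)) {
      anc <- .random_dna(genome_length)
      anc_v <- strsplit(anc, "")[[1]]
      for (sid in species$taxon_id[species$parent_id == gid]) {
        v <- anc_v
        hit <- which(stats::runif(genome_length) < d)
        if (length(hit)) {
          v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                           character(1))
        }
        nm <- sprintf("seq_%s", tax$nodes$name[match(sid, tax$nodes$taxon_id)])
        out[nm] <- paste(v, collapse = "")
        taxids[nm] <- sid
        realized[nm] <- length(hit) / genome_length
      }
    }
  })
  db <- reference_db(out, taxids, tax)
  attr(db, "realized_divergence") <- realized
  db
}

#' Read / write a reference database as FASTA
#'
#' Headers follow the convention `>seqid taxid=<id>`.
#'
#' @param db a [reference_db()].
#' @param path FASTA file path.
#' @return `read_reference_db()` returns a [reference_db()].
#' @export
write_reference_db <- function(db, path) {
  out <- db$seqs
  names(out) <- sprintf("%s taxid=%d", names(db$seqs), db$taxon_id)
  Biostrings::writeXStringSet(out, path)
  invisible(db)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  m <- regmatches(hdr, regexec("^(\\S+)\\s+taxid=(\\d+)", hdr))
  if (any(lengths(m) != 3L)) {
    abort_format(sprintf("FASTA header without 'seqid taxid=<id>' convention in '%s'", path))
  }
  names(seqs) <- vapply(m, `[[`, character(1), 2)
  reference_db(seqs, as.integer(vapply(m, `[[`, character(1), 3)))
}

# Distinct canonical k-mers (min of forward and reverse-complement form);
# windows containing N are skipped.
.canonical_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  km <- substring(x, seq_len(n - k + 1L), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

#' k-mer coverage of a query genome by a reference database
#'
#' The fraction of the query's distinct canonical k-mers (minimum of the
#' forward and reverse-complement spelling) that occur among the database's
#' canonical k-mers. This measures how well a database represents a taxon:
#' 1.0 when the query itself is an entry, dropping with divergence, and
#' effectively 0 for an unrelated genome at k = 31. Coverage counts distinct
#' k-mers, not k-mer positions, so repeats do not inflate it; k-mers
#' containing N are skipped on both sides.
#'
#' @param db a [reference_db()].
#' @param query_genome a character string or DNAString.
#' @param k k-mer length (>= 11; default 31).
#' @return A fraction in \[0, 1\], with attributes `n_query_kmers` and
#'   `n_found`.
#' @export
kmer_coverage <- function(db, query_genome, k = 31) {
  if (!.is_count(k) || k < 11) abort_invalid("`k` must be an integer >= 11")
  query_genome <- as.character(query_genome)
  if (nchar(query_genome) < k) {
    abort_invalid("query sequence is shorter than k")
  }
  dbk <- unique(unlist(lapply(db$chr, .canonical_kmers, k = k), use.names = FALSE))
  qk <- .canonical_kmers(query_genome, k)
  if (!length(qk)) {
    abort_invalid("query has no N-free k-mers")
  }
  found <- sum(qk %in% dbk)
  structure(found / length(qk), n_query_kmers = length(qk), n_found = found)
}

#' Database coverage report for every taxon's genomes
#'
#' Queries each taxon's sequences against the database built from all other
#' taxa (leave-self-out), mirroring how database representation of a taxon
#' is evaluated before interpreting its detections.
#'
#' @param db a [reference_db()].
#' @param k k-mer length.
#' @param leave_self_out drop the query taxon's own entries from the
#'   database side (default TRUE; with FALSE every covered taxon scores 1).
#' @return Data frame (taxon_id, sequence_id, n_query_kmers, n_found,
#'   coverage).
#' @export
kmer_coverage_report <- function(db, k = 31, leave_self_out = TRUE) {
  rows <- lapply(names(db$chr), function(sid) {
    tid <- db$taxon_id[[sid]]
    keep <- if (leave_self_out) db$taxon_id != tid else rep(TRUE, length(db$taxon_id))
    if (!any(keep)) return(NULL)
    sub <- reference_db(db$seqs[keep], db$taxon_id[keep])
    cov <- kmer_coverage(sub, db$chr[[sid]], k = k)
    data.frame(taxon_id = tid, sequence_id = sid,
               n_query_kmers = attr(cov, "n_query_kmers"),
               n_found = attr(cov, "n_found"),
               coverage = as.numeric(cov))
  })
  do.call(rbind, rows)
}
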