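# Tree helpers on ape::phylo objects with named internal nodes.
.node_labels <- function(tree) c(tree$tip.label, tree$node.label)

.root_index <- function(tree) length(tree$tip.label) + 1L

# edges on the path root -> node, as child-node labels (branch ids)
.path_branches <- function(tree, node_idx) {
  labels <- .node_labels(tree)
  root <- .root_index(tree)
  if (node_idx == root) return(character(0))
  path <- ape::nodepath(tree, root, node_idx)
  labels[path[-1]]
}

.node_depths <- function(tree) {
  labels <- .node_labels(tree)
  n_all <- length(labels)
  depth <- integer(n_all)
  root <- .root_index(tree)
  for (i in seq_len(n_all)) {
    if (i == root) next
    depth[i] <- length(ape::nodepath(tree, root, i)) - 1L
  }
  stats::setNames(depth, labels)
}

#' Call branch-diagnostic markers from a reference alignment
#'
#' For each biallelic, gap-free alignment column the allele carried by the
#' designated outgroup is taken as ancestral. If the set of tips carrying
#' the derived allele coincides exactly with the tip set of one clade, the
#' column is emitted as a marker on that clade's subtending branch
#' (identified by its child node's label); singleton derived alleles mark
#' terminal branches. Columns whose derived tip set matches no clade are
#' homoplasious and are skipped and logged, as are columns with more than
#' two alleles or gaps.
#'
#' @param tree rooted [ape::phylo] with node labels; tips must match
#'   alignment rows.
#' @param alignment named character vector or [Biostrings::DNAStringSet] of
#'   equal-length tip sequences (one per tip; extra rows ignored).
#' @param outgroup tip label used to polarize alleles.
#' @return Data frame of class `branch_markers`: branch, position (1-based
#'   alignment column), ancestral, derived, transversion; skipped columns in
#'   the `"skipped"` attribute (position, reason).
#' @export
call_branch_markers <- function(tree, alignment, outgroup) {
  aln <- if (is.character(alignment)) alignment else
    stats::setNames(as.character(alignment), names(alignment))
  if (!outgroup %in% tree$tip.label) {
    abort_invalid(sprintf("outgroup '%s' is not a tip of the tree", outgroup))
  }
  missing <- setdiff(tree$tip.label, names(aln))
  if (length(missing)) {
    abort_invalid(sprintf("alignment lacks tip(s): %s",
                          paste(missing, collapse = ", ")))
  }
  aln <- aln[tree$tip.label]
  if (length(unique(nchar(aln))) != 1L) {
    abort_format("alignment rows differ in length")
  }
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- tree$tip.label
  L <- ncol(mat)
  labels <- .node_labels(tree)

  # tip-set key -> branch (child node label), for every edge
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  keys <- vapply(desc, function(t) paste(sort(tree$tip.label[t]), collapse = "|"),
                 character(1))
  branch_of <- stats::setNames(labels[tree$edge[, 2]], keys)

  rows <- list()
  skipped <- list()
  ts <- function(a, b) paste(sort(c(a, b)), collapse = "")
  for (pos in seq_len(L)) {
    col <- mat[, pos]
    if (any(!col %in% DNA_BASES)) {
      skipped[[length(skipped) + 1L]] <- data.frame(position = pos, reason = "gap_or_ambiguous")
      next
    }
    alleles <- unique(col)
    if (length(alleles) == 1L) next
    if (length(alleles) > 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(position = pos, reason = "multiallelic")
      next
    }
    anc <- col[[outgroup]]
    der <- setdiff(alleles, anc)
    der_tips <- sort(names(col)[col == der])
    key <- paste(der_tips, collapse = "|")
    branch <- branch_of[key]
    if (is.na(branch)) {
      skipped[[length(skipped) + 1L]] <- data.frame(position = pos, reason = "homoplasy")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      branch = unname(branch), position = pos, ancestral = anc, derived = der,
      transversion = !(ts(anc, der) %in% c("AG", "CT")),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(0), position = integer(0),
               ancestral = character(0), derived = character(0),
               transversion = logical(0))
  rownames(out) <- NULL
  structure(out, class = c("branch_markers", "data.frame"),
            skipped = if (length(skipped)) do.call(rbind, skipped) else
              data.frame(position = integer(0), reason = character(0)))
}

#' Tally marker alleles observed in a read set
#'
#' Maps each read gap-free onto the reference coordinate system (best
#' placement, forward or reverse complement, up to `max_mismatches`
#' substitutions; reads with no placement or with tied best placements at
#' different positions are skipped) and tallies, at every covered marker
#' position, how many reads show the ancestral, the derived, or another
#' allele. Read Ns are never tallied.
#'
#' @param reads named [Biostrings::DNAStringSet] or character vector.
#' @param reference reference sequence in alignment coordinates (character
#'   or DNAString), e.g. the panel root sequence.
#' @param markers a [call_branch_markers()] table.
#' @param max_mismatches per-read placement budget (default 5; degraded
#'   reads carry damage plus genuine derived alleles).
#' @return Data frame: branch, position, ancestral, derived, transversion,
#'   n_anc, n_der, n_other; attribute `n_reads_mapped`.
#' @export
collect_observations <- function(reads, reference, markers, max_mismatches = 5) {
  ref <- as.character(reference)
  subj <- Biostrings::DNAStringSet(stats::setNames(ref, "ref"))
  chr <- stats::setNames(ref, "ref")
  refdb1 <- reference_db(subj, 1L)
  n_anc <- n_der <- n_oth <- stats::setNames(integer(nrow(markers)),
                                             markers$position)
  rd <- as.character(reads)
  # fast path: batch exact placement; only reads without an exact hit take
  # the per-read mismatch scan
  exact <- .batch_exact_placements(rd, refdb1)
  exact$mismatches <- rep(0L, nrow(exact))
  exact_by_read <- split(exact, exact$read_idx)
  mapped <- 0L
  for (i in seq_along(rd)) {
    pl <- exact_by_read[[as.character(i)]]
    if (is.null(pl)) pl <- .find_placements(rd[i], subj, chr, max_mismatches)
    if (!nrow(pl)) next
    best <- pl[pl$mismatches == min(pl$mismatches), , drop = FALSE]
    if (nrow(best) > 1L && length(unique(best$start)) > 1L) next
    best <- best[1L, ]
    mapped <- mapped + 1L
    len <- nchar(rd[i])
    oriented <- if (best$strand == "+") rd[i] else .revcomp1(rd[i])
    cover <- which(markers$position >= best$start &
                     markers$position <= best$start + len - 1L)
    for (j in cover) {
      base <- substr(oriented, markers$position[j] - best$start + 1L,
                     markers$position[j] - best$start + 1L)
      if (base == "N") next
      if (base == markers$derived[j]) n_der[j] <- n_der[j] + 1L
      else if (base == markers$ancestral[j]) n_anc[j] <- n_anc[j] + 1L
      else n_oth[j] <- n_oth[j] + 1L
    }
  }
  out <- data.frame(branch = markers$branch, position = markers$position,
                    ancestral = markers$ancestral, derived = markers$derived,
                    transversion = markers$transversion,
                    n_anc = unname(n_anc), n_der = unname(n_der),
                    n_other = unname(n_oth), stringsAsFactors = FALSE)
  attr(out, "n_reads_mapped") <- mapped
  out
}

#' Place a sample on the tree by branch SNP support and conflict
#'
#' Per branch, support counts markers whose majority observed allele is the
#' derived one and conflict counts markers observed ancestral (majority rule
#' per position; exact ties are discarded). Every root-to-node path is then
#' scored as the sum of (support - conflict) over its branches minus the
#' support observed on off-path branches, so derived alleles private to
#' other clades penalize a placement and chimeric mixtures surface as
#' low-margin calls. The best-scoring node wins; score ties are broken
#' toward the shallower node and flagged ambiguous. In
#' `"transversions-only"` mode markers whose allele pair is a transition
#' (C/T or G/A, the deamination-confusable classes) are excluded, the
#' damage-safe choice for degraded samples.
#'
#' @param tree rooted [ape::phylo] with node labels.
#' @param markers a [call_branch_markers()] table.
#' @param observations a [collect_observations()] table.
#' @param mode "all-sites" or "transversions-only".
#' @param min_markers minimum informative marker observations for a
#'   placement (default 10); below it the sample is "unplaced".
#' @param sample_id optional label carried through.
#' @return An object of class `placement`: list(sample_id, best_node, score,
#'   runner_up, margin, n_markers, status, ambiguous, branch_stats,
#'   node_scores).
#' @export
place_sample <- function(tree, markers, observations,
                         mode = c("all-sites", "transversions-only"),
                         min_markers = 10, sample_id = NULL) {
  mode <- match.arg(mode)
  .stopifnot_count(min_markers, "min_markers")
  obs <- observations
  if (mode == "transversions-only") obs <- obs[obs$transversion, , drop = FALSE]

  maj <- character(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    counts <- c(anc = obs$n_anc[i], der = obs$n_der[i], other = obs$n_other[i])
    if (sum(counts) == 0) { maj[i] <- "unobserved"; next }
    top <- counts == max(counts)
    maj[i] <- if (sum(top) > 1L) "tie" else names(counts)[top]
  }
  informative <- maj %in% c("anc", "der")
  labels <- .node_labels(tree)
  branches <- labels[tree$edge[, 2]]
  support <- stats::setNames(integer(length(branches)), branches)
  conflict <- support
  tab_s <- table(obs$branch[maj == "der"])
  tab_c <- table(obs$branch[maj == "anc"])
  support[names(tab_s)] <- as.integer(tab_s)
  conflict[names(tab_c)] <- as.integer(tab_c)

  branch_stats <- data.frame(branch = branches, support = unname(support),
                             conflict = unname(conflict))
  n_inf <- sum(informative)
  out <- list(sample_id = sample_id, best_node = NA_character_,
              score = NA_real_, runner_up = NA_real_, margin = NA_real_,
              n_markers = n_inf, status = "unplaced", ambiguous = FALSE,
              branch_stats = branch_stats, node_scores = NULL)
  class(out) <- "placement"
  if (n_inf < min_markers) return(out)

  total_support <- sum(support)
  depths <- .node_depths(tree)
  scores <- vapply(seq_along(labels), function(i) {
    path <- .path_branches(tree, i)
    sum(support[path]) - sum(conflict[path]) - (total_support - sum(support[path]))
  }, numeric(1))
  names(scores) <- labels
  ord <- order(-scores, depths[labels], labels)
  best <- ord[1]
  out$node_scores <- data.frame(node = labels, depth = unname(depths[labels]),
                                score = unname(scores))
  out$best_node <- labels[best]
  out$score <- unname(scores[best])
  out$runner_up <- unname(scores[ord[2]])
  out$margin <- out$score - out$runner_up
  out$ambiguous <- out$margin == 0
  out$status <- "placed"
  out
}

#' @export
print.placement <- function(x, ...) {
  if (x$status == "unplaced") {
    cat(sprintf("<placement> unplaced (%d informative markers)\n", x$n_markers))
  } else {
    cat(sprintf("<placement> node %s score %g (margin %g, %d markers%s)\n",
                x$best_node, x$score, x$margin, x$n_markers,
                if (x$ambiguous) ", ambiguous" else ""))
  }
  invisible(x)
}

#' Haplogroup label for a placement
#'
#' Returns the label of the deepest labelled clade whose node is an
#' ancestor-or-self of the placement node. Placements above every labelled
#' clade (e.g. at the shared root of two labelled sister clades) are
#' "basal"; unplaced samples are "unplaced".
#'
#' @param placement a [place_sample()] result.
#' @param tree the tree used for placement.
#' @param clade_labels named character vector: node label -> clade label
#'   (e.g. `c(N3 = "1C", N5 = "2")`).
#' @return A single character label.
#' @export
haplogroup_of <- function(placement, tree, clade_labels) {
  if (placement$status == "unplaced") return("unplaced")
  labels <- .node_labels(tree)
  idx <- match(placement$best_node, labels)
  root <- .root_index(tree)
  path <- if (idx == root) labels[root] else
    labels[ape::nodepath(tree, root, idx)]
  labelled <- path[path %in% names(clade_labels)]
  if (!length(labelled)) return("basal")
  unname(clade_labels[labelled[length(labelled)]])
}

#' Write branch markers / placements as TSV
#'
#' @param markers a [call_branch_markers()] table.
#' @param path output path.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(markers)
}

#' @rdname write_markers
#' @param placements list of [place_sample()] results (optionally with
#'   haplogroup labels in `$haplogroup`).
#' @export
write_placements <- function(placements, path) {
  rows <- lapply(placements, function(p) {
    data.frame(sample = p$sample_id %||% NA_character_,
               node = p$best_node, status = p$status,
               score = p$score, margin = p$margin, n_markers = p$n_markers,
               haplogroup = p$haplogroup %||% NA_character_)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(placements)
}
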