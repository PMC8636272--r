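#' Simulate a mitochondrial reference panel with branch-diagnostic markers
#'
#' Builds a random rooted bifurcating tree whose first tip is an outgroup,
#' then places `mutations_per_branch` substitutions on every branch except
#' the outgroup's terminal edge, each at a distinct alignment site
#' (infinite-sites at generation time), so every branch carries unambiguous
#' diagnostic markers. The outgroup edge is left unmutated because it is the
#' polarization reference: outgroup-polarized marker calling cannot tell a
#' mutation on that edge from one on the ingroup stem. Tip and internal-node
#' sequences equal the root sequence edited by the mutations on their
#' root-to-node paths; the true branch-to-site map is retained for
#' validation.
#'
#' @param n_tips total number of tips including the outgroup (>= 3).
#' @param mutations_per_branch substitutions per mutated branch (>= 1).
#' @param genome_length alignment length in bp.
#' @param seed integer seed.
#' @param outgroup_label tip label for the outgroup.
#' @return An object of class `mito_panel`: list with `tree` (an
#'   [ape::phylo] with node labels), `sequences` (named character vector for
#'   every tip and internal node), `root_seq`, `truth` (data frame branch /
#'   site / ancestral / derived / transversion), `genome_length`, `outgroup`.
#' @export
simulate_mito_panel <- function(n_tips, mutations_per_branch = 5,
                                genome_length = 5000, seed = 1,
                                outgroup_label = "OUT") {
  .stopifnot_count(n_tips, "n_tips", min = 3)
  .stopifnot_count(mutations_per_branch, "mutations_per_branch")
  .stopifnot_count(genome_length, "genome_length", min = 100)

  withr::with_seed(seed, {
    n_in <- n_tips - 1L
    ingroup <- ape::rtree(n_in, tip.label = sprintf("T%d", seq_len(n_in)))
    nwk <- sprintf("(%s:1,%s:1);",
                   outgroup_label,
                   sub(";$", "", ape::write.tree(ingroup)))
    tree <- ape::read.tree(text = nwk)
    tree$edge.length <- rep(1, nrow(tree$edge))
    tree$node.label <- sprintf("N%d", seq_len(tree$Nnode))

    labels <- c(tree$tip.label, tree$node.label)
    out_tip <- match(outgroup_label, labels)
    child <- tree$edge[, 2]
    mut_edges <- which(child != out_tip)
    total <- length(mut_edges) * mutations_per_branch
    if (total > genome_length) {
      abort_invalid(sprintf(
        "site exhaustion: %d mutations requested but alignment is %d bp",
        total, genome_length))
    }
    root_seq <- .random_dna(genome_length)
    root_v <- strsplit(root_seq, "")[[1]]
    sites <- sample(genome_length, total)
    anc <- root_v[sites]
    der <- vapply(anc, function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
    truth <- data.frame(
      branch = labels[child[rep(mut_edges, each = mutations_per_branch)]],
      site = sites, ancestral = anc, derived = unname(der),
      stringsAsFactors = FALSE)
  })
  ts <- function(p) paste(sort(p), collapse = "")
  truth$transversion <- !(mapply(function(a, b) ts(c(a, b)),
                                 truth$ancestral, truth$derived) %in% c("AG", "CT"))
  rownames(truth) <- NULL

  # sequence of every node: root edited by root-to-node path mutations
  labels <- c(tree$tip.label, tree$node.label)
  root_node <- length(tree$tip.label) + 1L
  sequences <- stats::setNames(character(length(labels)), labels)
  root_v <- strsplit(root_seq, "")[[1]]
  apply_down <- function(node, v) {
    sequences[labels[node]] <<- paste(v, collapse = "")
    for (e in which(tree$edge[, 1] == node)) {
      ch <- tree$edge[e, 2]
      v2 <- v
      rows <- truth[truth$branch == labels[ch], ]
      if (nrow(rows)) v2[rows$site] <- rows$derived
      apply_down(ch, v2)
    }
  }
  apply_down(root_node, root_v)

  structure(list(tree = tree, sequences = sequences, root_seq = root_seq,
                 truth = truth, genome_length = as.integer(genome_length),
                 outgroup = outgroup_label),
            class = "mito_panel")
}

#' @export
print.mito_panel <- function(x, ...) {
  cat(sprintf("<mito_panel> %d tips (outgroup %s), %d bp, %d marker sites\n",
              length(x$tree$tip.label), x$outgroup, x$genome_length,
              nrow(x$truth)))
  invisible(x)
}

#' Simulate degraded reads from a panel haplotype
#'
#' Draws reads that tile the chosen source haplotype (a tip, or an internal
#' node representing an ancestral haplotype) at approximately the requested
#' fold coverage; the read count is Poisson with mean
#' `coverage * genome_length / mean_len`. Fragmentation and damage follow
#' [fragment_model()] and [damage_model()].
#'
#' @param panel a [simulate_mito_panel()] result.
#' @param source_node a tip or internal-node label of `panel$tree`.
#' @param mean_coverage target fold coverage.
#' @param frag a [fragment_model()].
#' @param dmg a [damage_model()].
#' @param seed integer seed.
#' @param read_prefix prefix for read ids.
#' @return As [simulate_sample_reads()]: list(reads, truth); `seq_id` in the
#'   truth table is the source node label.
#' @export
simulate_mito_reads <- function(panel, source_node, mean_coverage = 5,
                                frag = fragment_model(), dmg = damage_model(),
                                seed = 1, read_prefix = "m") {
  if (!source_node %in% names(panel$sequences)) {
    abort_lookup(sprintf("unknown panel node '%s'", source_node))
  }
  withr::with_seed(seed, {
    n <- stats::rpois(1, mean_coverage * panel$genome_length / frag$mean_len)
    n <- max(n, 1L)
    ids <- sprintf("%s%05d", read_prefix, seq_len(n))
    sim <- .simulate_fragments(panel$sequences[source_node],
                               rep(source_node, n), frag, dmg, ids)
  })
  list(reads = Biostrings::DNAStringSet(sim$reads), truth = sim$truth)
}

#' Write a mitochondrial panel to disk
#'
#' Writes the tree as Newick (internal node labels kept), all node sequences
#' as FASTA, and the true branch-to-site marker map as TSV.
#'
#' @param panel a [simulate_mito_panel()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_mito_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, c("panel_tree.nwk", "panel_sequences.fasta",
                            "panel_marker_truth.tsv"))
  ape::write.tree(panel$tree, files[1])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$sequences), files[2])
  utils::write.table(panel$truth, files[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}
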