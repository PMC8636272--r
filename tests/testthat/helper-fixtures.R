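# Shared fixtures, built in code at test time.

# small 2-family / 4-genus / 8-species world with clearly divergent congeners
fixture_world <- function(divergence = 0.05, genome_length = 1000, seed = 101) {
  tax <- make_taxonomy(2, 2, 2, seed = seed)
  db <- make_reference_db(tax, genome_length, divergence, seed = seed + 1)
  list(tax = tax, db = db,
       species = tax$nodes$taxon_id[tax$nodes$rank == "species"])
}

no_damage <- function() damage_model(p1_ct = 0, lambda_decay = 0, p1_ga = 0,
                                     seq_error = 0)

short_frags <- function() fragment_model(mean_len = 55, sd_len = 12,
                                         min_len = 35, max_len = 90)

# independent LCA oracle: intersect full ancestor sets, return the deepest
oracle_lca <- function(tax, taxa) {
  sets <- lapply(taxa, function(t) taxon_ancestors(tax, t))
  common <- Reduce(intersect, sets)
  common[which.max(tax$depth[as.character(common)])]
}

# independent canonical k-mer coverage oracle (set arithmetic, no sharing
# of the package's helper)
oracle_kmer_coverage <- function(db_seqs, query, k) {
  canon <- function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- vapply(km, function(x) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
    }, character(1))
    unique(ifelse(km <= rc, km, rc))
  }
  dbk <- unique(unlist(lapply(db_seqs, canon)))
  qk <- canon(query)
  mean(qk %in% dbk)
}

# exhaustive path-score oracle for placements: explicit off-path loop
oracle_node_scores <- function(tree, support, conflict) {
  labels <- c(tree$tip.label, tree$node.label)
  root <- length(tree$tip.label) + 1L
  branches <- labels[tree$edge[, 2]]
  vapply(seq_along(labels), function(i) {
    path <- if (i == root) character(0) else {
      p <- ape::nodepath(tree, root, i)
      labels[p[-1]]
    }
    off <- setdiff(branches, path)
    sum(support[path]) - sum(conflict[path]) - sum(support[off])
  }, numeric(1)) |> stats::setNames(labels)
}
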