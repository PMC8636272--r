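#' Taxonomy objects
#'
#' A taxonomy is a rooted multi-rank tree of taxon nodes, the backbone for
#' lowest-common-ancestor (LCA) read assignment and for collating taxonomic
#' profiles at a chosen rank. Nodes are held in a data frame in the style of
#' the NCBI `nodes.dmp`/`names.dmp` dumps: one row per taxon with a
#' `taxon_id`, a `parent_id` (the root is its own parent), a `rank` and a
#' `name`.
#'
#' @param nodes data frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`. Exactly one row must be the root (`parent_id == taxon_id`).
#' @param rank_order character vector giving ranks from the root down. Rank
#'   comparisons use this list order, not any biological assumption. Defaults
#'   to the ranks present, ordered root-first by tree depth.
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(nodes, rank_order = NULL) {
  req <- c("taxon_id", "parent_id", "rank", "name")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes))) {
    abort_format("`nodes` must be a data frame with columns taxon_id, parent_id, rank, name")
  }
  nodes <- as.data.frame(nodes)[req]
  nodes$taxon_id <- as.integer(nodes$taxon_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$taxon_id)) {
    dup <- nodes$taxon_id[duplicated(nodes$taxon_id)][1]
    abort_format(sprintf("duplicate taxon_id %d", dup))
  }
  is_root <- nodes$parent_id == nodes$taxon_id
  if (sum(is_root) != 1L) {
    abort_format(sprintf("taxonomy must have exactly one root, found %d", sum(is_root)))
  }
  orphan <- !(nodes$parent_id %in% nodes$taxon_id)
  if (any(orphan)) {
    bad <- nodes$taxon_id[orphan][1]
    abort_format(sprintf("taxon %d has parent_id %d absent from the table",
                         bad, nodes$parent_id[nodes$taxon_id == bad]))
  }

  # depth by walking up; also detects cycles
  n <- nrow(nodes)
  parent_idx <- match(nodes$parent_id, nodes$taxon_id)
  depth <- rep(NA_integer_, n)
  depth[is_root] <- 0L
  remaining <- which(!is_root)
  for (step in seq_len(n)) {
    if (!length(remaining)) break
    ready <- remaining[!is.na(depth[parent_idx[remaining]])]
    if (!length(ready)) abort_format("taxonomy contains a cycle")
    depth[ready] <- depth[parent_idx[ready]] + 1L
    remaining <- setdiff(remaining, ready)
  }
  if (anyNA(depth)) abort_format("taxonomy contains a cycle")

  if (is.null(rank_order)) {
    rank_order <- unique(nodes$rank[order(depth)])
  }
  # child rank never above parent rank in list order
  ri <- match(nodes$rank, rank_order)
  rip <- ri[parent_idx]
  bad <- which(!is_root & !is.na(ri) & !is.na(rip) & ri < rip)
  if (length(bad)) {
    abort_format(sprintf("taxon %d has rank '%s' above its parent's rank",
                         nodes$taxon_id[bad[1]], nodes$rank[bad[1]]))
  }

  structure(
    list(nodes = nodes,
         depth = stats::setNames(depth, nodes$taxon_id),
         rank_order = rank_order,
         root = nodes$taxon_id[is_root]),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes, ranks: %s\n",
              nrow(x$nodes), paste(x$rank_order, collapse = " > ")))
  invisible(x)
}

.tax_index <- function(tax, ids) {
  idx <- match(ids, tax$nodes$taxon_id)
  if (anyNA(idx)) {
    abort_lookup(sprintf("unknown taxon_id: %s",
                         paste(ids[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Root-to-node ancestor path
#'
#' @param tax a [taxonomy()].
#' @param id a single taxon id.
#' @return Integer vector of taxon ids from the root down to (and including)
#'   `id`.
#' @export
taxon_ancestors <- function(tax, id) {
  idx <- .tax_index(tax, id)
  path <- integer(tax$depth[idx] + 1L)
  i <- length(path)
  cur <- idx
  repeat {
    path[i] <- tax$nodes$taxon_id[cur]
    parent <- tax$nodes$parent_id[cur]
    if (parent == tax$nodes$taxon_id[cur]) break
    cur <- match(parent, tax$nodes$taxon_id)
    i <- i - 1L
  }
  path
}

#' Ranks and names of taxa
#'
#' @param tax a [taxonomy()].
#' @param ids vector of taxon ids.
#' @return Character vector of ranks (or names).
#' @export
taxon_rank <- function(tax, ids) tax$nodes$rank[.tax_index(tax, ids)]

#' @rdname taxon_rank
#' @export
taxon_name <- function(tax, ids) tax$nodes$name[.tax_index(tax, ids)]

#' Ancestor-or-self of a taxon at a given rank
#'
#' Walks the root-to-node path and returns the node carrying `rank`, or `NA`
#' if the path has no node of that rank (i.e. the taxon sits above the rank).
#'
#' @param tax a [taxonomy()].
#' @param ids vector of taxon ids.
#' @param rank a rank present in `tax$rank_order`.
#' @return Integer vector of taxon ids (NA where no ancestor at the rank).
#' @export
ancestor_at_rank <- function(tax, ids, rank) {
  if (!rank %in% tax$rank_order) {
    abort_invalid(sprintf("rank '%s' not in the taxonomy's rank list", rank))
  }
  vapply(ids, function(id) {
    if (is.na(id)) return(NA_integer_)
    path <- taxon_ancestors(tax, id)
    r <- tax$nodes$rank[match(path, tax$nodes$taxon_id)]
    hit <- path[r == rank]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every input taxon.
#' This is the assignment rule for reads with perfect-identity hits to
#' multiple taxa: the read is assigned conservatively to the LCA of all taxa
#' hit.
#'
#' @param tax a [taxonomy()].
#' @param taxa non-empty vector of taxon ids (duplicates allowed).
#' @return A single taxon id.
#' @export
taxa_lca <- function(tax, taxa) {
  taxa <- unique(as.integer(taxa))
  if (!length(taxa) || anyNA(taxa)) abort_invalid("`taxa` must be a non-empty set of taxon ids")
  .tax_index(tax, taxa)
  paths <- lapply(taxa, function(t) taxon_ancestors(tax, t))
  m <- min(lengths(paths))
  lca <- tax$root
  for (i in seq_len(m)) {
    level <- vapply(paths, `[[`, integer(1), i)
    if (all(level == level[1])) lca <- level[1] else break
  }
  lca
}

#' Generate a balanced synthetic taxonomy
#'
#' Builds a rooted tree with ranks root/family/genus/species, the scaffold
#' for simulated reference databases and read sets.
#'
#' @param n_families,genera_per_family,species_per_genus positive counts.
#' @param seed integer seed (kept for call-signature symmetry with the other
#'   generators; construction is deterministic).
#' @return A [taxonomy()].
#' @export
make_taxonomy <- function(n_families, genera_per_family, species_per_genus, seed = 1) {
  .stopifnot_count(n_families, "n_families")
  .stopifnot_count(genera_per_family, "genera_per_family")
  .stopifnot_count(species_per_genus, "species_per_genus")
  rows <- list(data.frame(taxon_id = 1L, parent_id = 1L, rank = "root", name = "root"))
  nid <- 1L
  for (f in seq_len(n_families)) {
    nid <- nid + 1L
    fid <- nid
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = fid, parent_id = 1L, rank = "family", name = sprintf("Fam%d", f))
    for (g in seq_len(genera_per_family)) {
      nid <- nid + 1L
      gid <- nid
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = gid, parent_id = fid, rank = "genus", name = sprintf("Gen%d.%d", f, g))
      for (s in seq_len(species_per_genus)) {
        nid <- nid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = nid, parent_id = gid, rank = "species",
          name = sprintf("Sp%d.%d.%d", f, g, s))
      }
    }
  }
  taxonomy(do.call(rbind, rows), rank_order = c("root", "family", "genus", "species"))
}

#' Read / write NCBI-style taxonomy dumps
#'
#' Two tab-separated files: a nodes table (`taxon_id`, `parent_id`, `rank`)
#' and a names table (`taxon_id`, `name`). `read_taxonomy()` validates the
#' result; a write-then-read round trip reproduces the taxonomy exactly
#' (modulo row order).
#'
#' @param nodes_path,names_path file paths.
#' @return `read_taxonomy()` returns a [taxonomy()]; `write_taxonomy()`
#'   returns the taxonomy invisibly.
#' @export
read_taxonomy <- function(nodes_path, names_path) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  nms <- utils::read.delim(names_path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "parent_id", "rank") %in% names(nodes))) {
    abort_format(sprintf("'%s' lacks taxon_id/parent_id/rank columns", nodes_path))
  }
  if (!all(c("taxon_id", "name") %in% names(nms))) {
    abort_format(sprintf("'%s' lacks taxon_id/name columns", names_path))
  }
  nodes$name <- nms$name[match(nodes$taxon_id, nms$taxon_id)]
  if (anyNA(nodes$name)) {
    abort_format(sprintf("taxon %d has no row in the names table",
                         nodes$taxon_id[is.na(nodes$name)][1]))
  }
  taxonomy(nodes)
}

#' @rdname read_taxonomy
#' @param tax a [taxonomy()].
#' @export
write_taxonomy <- function(tax, nodes_path, names_path) {
  utils::write.table(tax$nodes[c("taxon_id", "parent_id", "rank")],
                     nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tax$nodes[c("taxon_id", "name")],
                     names_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tax)
}
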