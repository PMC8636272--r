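#' Linear age-depth interpolation for sediment sections
#'
#' For sections with multiple dated horizons and no stratigraphic
#' inversions, undated samples are dated by piecewise-linear interpolation
#' between the bracketing dated depths. Queries outside the dated range are
#' refused (no silent extrapolation). Per-segment sedimentation rates
#' (cm/yr) are reported as an attribute.
#'
#' @param dated data frame with columns `depth` (cm, strictly increasing)
#'   and `age` (calibrated years BP, non-decreasing with depth).
#' @param query_depth depth(s) to date, within the dated range.
#' @return Numeric ages (years BP), one per query, with attribute `"rates"`
#'   (data frame depth_from, depth_to, rate_cm_per_yr).
#' @export
age_depth_interpolate <- function(dated, query_depth) {
  if (!is.data.frame(dated) || !all(c("depth", "age") %in% names(dated))) {
    abort_invalid("`dated` must be a data frame with columns depth and age")
  }
  if (nrow(dated) < 2) abort_invalid("need at least 2 dated points")
  dated <- dated[order(dated$depth), ]
  if (any(diff(dated$depth) <= 0)) {
    i <- which(diff(dated$depth) <= 0)[1]
    abort_model(sprintf("depths not strictly increasing at rows %d-%d", i, i + 1))
  }
  bad <- which(diff(dated$age) < 0)
  if (length(bad)) {
    i <- bad[1]
    abort_model(sprintf(
      "stratigraphic inversion: age decreases from %g to %g between depths %g and %g cm",
      dated$age[i], dated$age[i + 1], dated$depth[i], dated$depth[i + 1]))
  }
  if (any(query_depth < min(dated$depth) | query_depth > max(dated$depth))) {
    abort_model(sprintf("query depth outside dated range [%g, %g] cm: extrapolation refused",
                        min(dated$depth), max(dated$depth)))
  }
  ages <- stats::approx(dated$depth, dated$age, xout = query_depth, ties = "ordered")$y
  dage <- diff(dated$age)
  rates <- data.frame(depth_from = dated$depth[-nrow(dated)],
                      depth_to = dated$depth[-1],
                      rate_cm_per_yr = ifelse(dage > 0, diff(dated$depth) / dage, Inf))
  structure(ages, rates = rates)
}

# --- configuration -----------------------------------------------------------

.default_config <- function() {
  list(
    seed = 42,
    outdir = "sedapipe_run",
    taxonomy = list(n_families = 3, genera_per_family = 2, species_per_genus = 2),
    reference = list(genome_length = 800, divergence = 0.08),
    samples = list(n_samples = 10, reads_per_sample = 200,
                   age_min = 1000, age_max = 19000),
    controls = list(reads_per_control = 60),
    fragment = list(mean_len = 55, sd_len = 12, min_len = 30, max_len = 120),
    damage = list(p1_ct = 0.25, lambda_decay = 0.3, seq_error = 0.001),
    classify = list(rank = "genus", min_reads = 3, min_samples = 1),
    abundance = list(n_sim = 500),
    community = list(bin_width = 2000, nmds_k = 2, nmds_starts = 20,
                     nmds_method = "bray"),
    placement = list(enabled = TRUE, n_tips = 6, mutations_per_branch = 4,
                     genome_length = 3000, coverage = 4,
                     mode = "all-sites", min_markers = 10)
  )
}

.merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort_invalid(sprintf("unknown config key%s: %s",
                          if (length(unknown) > 1) "s" else "",
                          paste0(path, unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      if (!is.list(user[[k]])) abort_invalid(sprintf("config key %s%s must be a mapping", path, k))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     path = paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML key-value file, overlays it on the documented defaults and
#' rejects unknown keys before any computation.
#'
#' @param config a YAML file path, a named list of overrides, or NULL for
#'   the defaults.
#' @return The full validated config list.
#' @export
load_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else abort_invalid("`config` must be a file path or a named list")
  .merge_config(.default_config(), user)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# --- pipeline ----------------------------------------------------------------

#' Run the full synthetic sedaDNA pipeline
#'
#' One reproducible end-to-end run: simulate a taxonomy, reference genomes,
#' per-sample damaged read sets and laboratory controls; classify reads by
#' perfect-hit LCA and collate at the configured rank; subtract control
#' taxa and apply checklist/threshold filters; estimate a damage profile and
#' authentication decision; estimate per-taxon identification efficiencies
#' and corrected relative abundances; compute binned assemblage turnover,
#' an NMDS ordination and growth-form/axis correlations; and, when enabled,
#' place simulated mitochondrial read sets on a marker-annotated panel
#' tree. Every artefact is written under `outdir` as TSV/JSON/FASTA, with a
#' manifest listing each file's MD5; rerunning with the same config
#' reproduces the outputs byte-identically.
#'
#' @param config as for [load_config()].
#' @return Invisibly, a list with the output directory, the config and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  current_stage <- "setup"
  stage <- function(name) current_stage <<- name

  withCallingHandlers({
    seed <- cfg$seed
    frag <- do.call(fragment_model, cfg$fragment)
    dmg <- do.call(damage_model, cfg$damage)

    stage("simulate")
    tax <- make_taxonomy(cfg$taxonomy$n_families, cfg$taxonomy$genera_per_family,
                         cfg$taxonomy$species_per_genus, seed = seed)
    db <- make_reference_db(tax, cfg$reference$genome_length,
                            cfg$reference$divergence, seed = seed + 1)
    write_taxonomy(tax, file.path(outdir, "taxonomy_nodes.tsv"),
                   file.path(outdir, "taxonomy_names.tsv"))
    write_reference_db(db, file.path(outdir, "reference.fasta"))
    files <- c(files, "taxonomy_nodes.tsv", "taxonomy_names.tsv", "reference.fasta")

    species <- tax$nodes$taxon_id[tax$nodes$rank == "species"]
    nsp <- length(species)
    ns <- cfg$samples$n_samples
    ages <- round(seq(cfg$samples$age_min, cfg$samples$age_max, length.out = ns))
    regions <- rep(c("north_atlantic", "nw_central_siberia",
                     "ne_siberia", "north_america"), length.out = ns)
    meta <- data.frame(
      sample_id = sprintf("s%02d", seq_len(ns)),
      site_id = sprintf("site%02d", rep(seq_len(ceiling(ns / 3)), each = 3)[seq_len(ns)]),
      region = regions,
      depth_cm = round(ages / 100, 1),
      age_bp = ages,
      age_sd = rep(100L, ns),
      material = rep(c("lake_sediment", "permafrost"), length.out = ns))
    files <- c(files, basename(.write_tsv(meta, file.path(outdir, "samples.tsv"))))

    stage("age_depth")
    dated <- data.frame(depth = c(0, meta$depth_cm[c(ceiling(ns / 2), ns)]),
                        age = c(0, meta$age_bp[c(ceiling(ns / 2), ns)]))
    est <- age_depth_interpolate(dated, meta$depth_cm)
    ad <- data.frame(sample_id = meta$sample_id, depth_cm = meta$depth_cm,
                     age_interpolated = est)
    files <- c(files, basename(.write_tsv(ad, file.path(outdir, "age_depth.tsv"))))
    files <- c(files, basename(.write_tsv(attr(est, "rates"),
                                          file.path(outdir, "sedimentation_rates.tsv"))))

    stage("simulate_reads")
    # two endmember communities; each sample mixes them by age so younger
    # and older assemblages diverge, plus a contaminant planted in controls
    old_prof <- stats::setNames(exp(-0.8 * seq_len(nsp)), species)
    young_prof <- stats::setNames(rev(old_prof), species)
    contaminant <- species[1]
    all_reads <- character(0)
    sample_of <- character(0)
    truths <- list()
    for (i in seq_len(ns)) {
      w <- (ages[i] / max(ages)) * old_prof + (1 - ages[i] / max(ages)) * young_prof
      sim <- simulate_sample_reads(db, w, cfg$samples$reads_per_sample,
                                   frag = frag, dmg = dmg, seed = seed + 10 + i,
                                   read_prefix = sprintf("s%02d_r", i))
      all_reads <- c(all_reads, as.character(sim$reads))
      sample_of <- c(sample_of,
                     stats::setNames(rep(meta$sample_id[i], length(sim$reads)),
                                     names(sim$reads)))
      truths[[i]] <- sim$truth
    }
    ctl <- simulate_sample_reads(db, stats::setNames(1, contaminant),
                                 cfg$controls$reads_per_control,
                                 frag = frag, dmg = damage_model(0, 0, 0, 0),
                                 seed = seed + 99, read_prefix = "ctl_r")
    files <- c(files, basename(.write_tsv(do.call(rbind, truths),
                                          file.path(outdir, "truth.tsv"))))

    stage("classify")
    rank <- cfg$classify$rank
    asn <- classify_reads(Biostrings::DNAStringSet(all_reads), db, tax,
                          min_read_length = frag$min_len)
    counts <- collate_profile(asn, tax, rank, sample_of)
    ctl_asn <- classify_reads(ctl$reads, db, tax, min_read_length = frag$min_len)
    ctl_counts <- collate_profile(
      ctl_asn, tax, rank,
      stats::setNames(rep("control1", nrow(ctl_asn)), ctl_asn$read_id))
    write_count_matrix(counts, file.path(outdir, "counts_raw.tsv"))
    write_count_matrix(ctl_counts, file.path(outdir, "counts_controls.tsv"))
    files <- c(files, "counts_raw.tsv", "counts_controls.tsv")

    stage("filter")
    counts <- subtract_control_taxa(counts, ctl_counts)
    checklist <- taxon_name(tax, tax$nodes$taxon_id[tax$nodes$rank == rank])
    counts <- checklist_filter(counts, checklist,
                               min_reads = cfg$classify$min_reads,
                               min_samples = cfg$classify$min_samples)
    write_count_matrix(counts, file.path(outdir, "counts_filtered.tsv"))
    filter_log <- data.frame(
      step = c("control_removed", "off_checklist", "dropped_sparse"),
      taxa = c(paste(counts$ledger$control_removed, collapse = ","),
               paste(counts$ledger$off_checklist, collapse = ","),
               paste(counts$ledger$dropped_sparse, collapse = ",")))
    files <- c(files, "counts_filtered.tsv",
               basename(.write_tsv(filter_log, file.path(outdir, "filter_log.tsv"))))

    stage("authenticate")
    truth1 <- truths[[1]]
    reads1 <- Biostrings::DNAStringSet(all_reads[truth1$read_id])
    hits1 <- truth_hits(truth1, reads1, db)
    prof <- damage_profile(hits1, reads1, db, max_mismatches = 4)
    decision <- is_ancient(prof)
    write_damage_profile(prof, file.path(outdir, "damage_profile.tsv"))
    jsonlite::write_json(
      list(sample = meta$sample_id[1],
           decision = if (is.na(decision$decision)) "undetermined"
                      else if (decision$decision) "ancient" else "not_ancient",
           ct1_rate = decision$ct1_rate, baseline_rate = decision$baseline_rate,
           rate_ratio = decision$rate_ratio, p_value = decision$p_value),
      file.path(outdir, "damage_decision.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "damage_profile.tsv", "damage_decision.json")

    stage("abundance")
    row_taxa <- as.integer(rownames(counts$counts))
    eff <- efficiency_table(db, tax, row_taxa, frag = frag, dmg = dmg,
                            n_sim = cfg$abundance$n_sim, rank = rank,
                            seed = seed + 200)
    ra <- normalize_abundance(counts, eff)
    files <- c(files, basename(.write_tsv(eff, file.path(outdir, "efficiency.tsv"))))
    write_abundance(ra, file.path(outdir, "abundance.tsv"))
    files <- c(files, "abundance.tsv")

    stage("community")
    age_map <- stats::setNames(meta$age_bp, meta$sample_id)
    bins <- bin_assemblages(counts, age_map, cfg$community$bin_width)
    tos <- turnover_series(bins)
    files <- c(files, basename(.write_tsv(tos, file.path(outdir, "turnover.tsv"))))
    H <- vapply(colnames(ra$abundance), function(s) {
      v <- ra$abundance[, s]
      if (sum(v) > 0) shannon_index(v) else NA_real_
    }, numeric(1))
    files <- c(files, basename(.write_tsv(
      data.frame(sample_id = names(H), shannon = unname(H)),
      file.path(outdir, "diversity.tsv"))))
    dmat <- if (cfg$community$nmds_method == "bray") {
      sample_dissimilarity(ra, method = "bray")
    } else {
      sample_dissimilarity(counts, method = cfg$community$nmds_method)
    }
    ord <- nmds_ordinate(dmat, k = cfg$community$nmds_k,
                         n_starts = cfg$community$nmds_starts, seed = seed + 300)
    pts <- data.frame(sample_id = rownames(ord$points), ord$points,
                      check.names = FALSE)
    files <- c(files, basename(.write_tsv(pts, file.path(outdir, "nmds_points.tsv"))))
    vocab <- c("tree", "shrub", "dwarf-shrub", "forb", "graminoid", "aquatic")
    genus_names <- unname(counts$taxon_names[rownames(counts$counts)])
    traits <- data.frame(genus = genus_names,
                         form = rep(vocab, length.out = length(genus_names)))
    gf <- growthform_proportions(ra, traits)
    files <- c(files, basename(.write_tsv(
      data.frame(form = rownames(gf$proportions), gf$proportions,
                 check.names = FALSE),
      file.path(outdir, "growthforms.tsv"))))
    corr <- axis_correlations(ord, t(gf$proportions))
    files <- c(files, basename(.write_tsv(corr, file.path(outdir, "axis_correlations.tsv"))))

    stage("placement")
    if (isTRUE(cfg$placement$enabled)) {
      panel <- simulate_mito_panel(cfg$placement$n_tips,
                                   cfg$placement$mutations_per_branch,
                                   cfg$placement$genome_length,
                                   seed = seed + 400)
      write_mito_panel(panel, outdir)
      files <- c(files, "panel_tree.nwk", "panel_sequences.fasta",
                 "panel_marker_truth.tsv")
      markers <- call_branch_markers(panel$tree,
                                     panel$sequences[panel$tree$tip.label],
                                     panel$outgroup)
      write_markers(markers, file.path(outdir, "markers.tsv"))
      files <- c(files, "markers.tsv")
      src <- c(panel$tree$tip.label[2], panel$tree$node.label[2])
      clade_labels <- stats::setNames(
        c("A", "B"), panel$tree$node.label[c(2, min(3, panel$tree$Nnode))])
      placements <- lapply(seq_along(src), function(i) {
        sim <- simulate_mito_reads(panel, src[i], cfg$placement$coverage,
                                   frag = frag, dmg = dmg, seed = seed + 410 + i,
                                   read_prefix = sprintf("edna%d_", i))
        obs <- collect_observations(sim$reads, panel$root_seq, markers)
        p <- place_sample(panel$tree, markers, obs, mode = cfg$placement$mode,
                          min_markers = cfg$placement$min_markers,
                          sample_id = sprintf("edna%d", i))
        p$haplogroup <- haplogroup_of(p, panel$tree, clade_labels)
        p
      })
      write_placements(placements, file.path(outdir, "placements.tsv"))
      files <- c(files, "placements.tsv")
    }

    stage("manifest")
    manifest <- list(
      config = cfg[setdiff(names(cfg), "outdir")],
      package_version = as.character(utils::packageVersion("sedapipe")),
      files = lapply(sort(files), function(f) {
        list(file = f, md5 = unname(tools::md5sum(file.path(outdir, f))))
      }))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    e$message <- sprintf("[stage %s] %s", current_stage, conditionMessage(e))
    # partial-output manifest so the run state is auditable
    try(jsonlite::write_json(
      list(failed_stage = current_stage, files = as.list(sort(files))),
      file.path(outdir, "manifest_partial.json"), auto_unbox = TRUE),
      silent = TRUE)
    stop(e)
  })
  invisible(list(outdir = outdir, config = cfg,
                 manifest = file.path(outdir, "manifest.json")))
}
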