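test_that("match_read finds exact, reverse-complement and near matches", {
  w <- fixture_world()
  g <- w$db$chr[[1]]
  read <- substr(g, 101, 150)

  h <- match_read(read, w$db, max_mismatches = 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 101)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0)
  expect_equal(h$identity, 1)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- match_read(rc, w$db, max_mismatches = 0)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 101)

  # three substitutions, budget two -> nothing
  v <- strsplit(read, "")[[1]]
  for (p in c(5, 25, 45)) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  h3 <- match_read(paste(v, collapse = ""), w$db, max_mismatches = 2)
  expect_equal(nrow(h3), 0)
  # budget-respecting hit at 2 mismatches
  v2 <- strsplit(read, "")[[1]]
  for (p in c(5, 25)) v2[p] <- setdiff(c("A", "C", "G", "T"), v2[p])[1]
  h4 <- match_read(paste(v2, collapse = ""), w$db, max_mismatches = 2)
  expect_true(any(h4$seq_id == names(w$db$chr)[1] & h4$mismatches == 2))

  expect_error(match_read("ACGTX", w$db), class = "sedapipe_format_error")
  expect_error(match_read(substr(g, 1, 20), w$db),
               class = "sedapipe_invalid_parameter")
})

test_that("an N in the read never counts as a match", {
  w <- fixture_world()
  read <- substr(w$db$chr[[1]], 201, 250)
  v <- strsplit(read, "")[[1]]
  v[10] <- "N"
  h <- match_read(paste(v, collapse = ""), w$db, max_mismatches = 0)
  expect_equal(nrow(h), 0)
  h1 <- match_read(paste(v, collapse = ""), w$db, max_mismatches = 1)
  expect_true(all(h1$mismatches >= 1))
})

test_that("assign_read keeps only perfect hits and applies the LCA rule", {
  w <- fixture_world()
  sp <- w$species
  g <- w$tax$nodes$parent_id[match(sp[1], w$tax$nodes$taxon_id)]
  mk <- function(taxon, mm) {
    data.frame(read_id = "r1", seq_id = "x", taxon_id = taxon, start = 1,
               strand = "+", mismatches = mm, identity = 1 - mm / 50)
  }
  # perfect hits in two congeners -> genus
  a <- assign_read(rbind(mk(sp[1], 0), mk(sp[2], 0)), w$tax)
  expect_equal(a$taxon_id, g)
  # perfect hit + imperfect hit elsewhere -> the imperfect hit is discarded
  b <- assign_read(rbind(mk(sp[1], 0), mk(sp[3], 2)), w$tax)
  expect_equal(b$taxon_id, sp[1])
  expect_equal(b$n_taxa_hit, 1)
  # only imperfect hits -> unassigned
  expect_null(assign_read(mk(sp[1], 1), w$tax))
  expect_null(assign_read(NULL, w$tax))
})

test_that("classify_reads agrees with per-read match + assign", {
  w <- fixture_world()
  sim <- simulate_sample_reads(w$db, stats::setNames(rep(1, 8), w$species), 60,
                               dmg = no_damage(), seed = 31)
  batch <- classify_reads(sim$reads, w$db, w$tax)
  for (i in seq(1, 60, by = 7)) {
    hits <- match_read(stats::setNames(as.character(sim$reads)[i],
                                       names(sim$reads)[i]), w$db, 0)
    a <- assign_read(hits, w$tax)
    expect_equal(batch$taxon_id[i], a$taxon_id)
    expect_equal(batch$n_perfect_hits[i], a$n_perfect_hits)
  }
})

test_that("assignments never fall outside the ancestry of the perfect hits", {
  w <- fixture_world()
  sim <- simulate_sample_reads(w$db, stats::setNames(rep(1, 8), w$species), 300,
                               dmg = damage_model(0.2, 0.3, seq_error = 0.002),
                               seed = 33)
  asn <- classify_reads(sim$reads, w$db, w$tax)
  ok <- !is.na(asn$taxon_id)
  for (i in which(ok)) {
    true_taxon <- sim$truth$taxon_id[i]
    # assigned node must be an ancestor-or-self of the source species (the
    # read matched its own genome perfectly or was lost; damage only removes
    # hits, and congeners share a genus)
    expect_true(asn$taxon_id[i] %in% taxon_ancestors(w$tax, true_taxon))
  }
})

test_that("exclusive confirmation requires perfection and uniqueness", {
  w <- fixture_world(divergence = 0.08)
  g1 <- w$db$chr[[1]]
  read <- substr(g1, 301, 360)
  focal <- w$species[1]
  other <- w$species[2]
  expect_true(exclusive_confirm(read, focal, w$db, slack = 2))
  expect_false(exclusive_confirm(read, other, w$db, slack = 2))
  # a 1-mismatch version has no perfect alignment -> fails
  v <- strsplit(read, "")[[1]]
  v[30] <- setdiff(c("A", "C", "G", "T"), v[30])[1]
  expect_false(exclusive_confirm(paste(v, collapse = ""), focal, w$db, slack = 2))
  expect_error(exclusive_confirm(read, 999L, w$db),
               class = "sedapipe_lookup_error")
})

test_that("a read within slack of a second taxon is not exclusive", {
  # two references identical except 2 differences inside the read window:
  # the read is perfect in A and within slack 2 of B
  set.seed(41)
  g <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  v <- strsplit(g, "")[[1]]
  v[210] <- setdiff(c("A", "C", "G", "T"), v[210])[1]
  v[220] <- setdiff(c("A", "C", "G", "T"), v[220])[1]
  db <- reference_db(c(A = g, B = paste(v, collapse = "")), c(1L, 2L))
  read <- substr(g, 191, 250)
  expect_false(exclusive_confirm(read, 1L, db, slack = 2))
  expect_true(exclusive_confirm(read, 1L, db, slack = 1))
  expect_identical(confirmed_taxa(read, db, slack = 2), integer(0))
  expect_identical(confirmed_taxa(read, db, slack = 1), 1L)
})

test_that("no read is exclusively confirmed for two taxa", {
  w <- fixture_world()
  sim <- simulate_sample_reads(w$db, stats::setNames(rep(1, 8), w$species), 120,
                               dmg = no_damage(), seed = 43)
  for (i in seq_along(sim$reads)) {
    ct <- confirmed_taxa(as.character(sim$reads)[i], w$db, slack = 2)
    expect_lte(length(ct), 1)
    if (length(ct) == 1) {
      others <- setdiff(w$species, ct)
      # spot-check the pairwise form on a couple of other taxa
      for (o in others[1:2]) {
        expect_false(exclusive_confirm(as.character(sim$reads)[i], o, w$db, 2))
      }
    }
  }
})

test_that("collate_profile applies the rank rule and balances its ledger", {
  w <- fixture_world()
  sp <- w$species
  gen <- unique(w$tax$nodes$parent_id[match(sp, w$tax$nodes$taxon_id)])
  fam <- unique(w$tax$nodes$parent_id[match(gen, w$tax$nodes$taxon_id)])
  # 10 reads to species under genus gen[1], 2 reads to its family
  asn <- data.frame(
    read_id = sprintf("r%02d", 1:13),
    taxon_id = c(rep(sp[1], 6), rep(sp[2], 4), rep(fam[1], 2), NA),
    n_perfect_hits = 1, n_taxa_hit = 1)
  smap <- stats::setNames(rep("s1", 13), asn$read_id)

  at_genus <- collate_profile(asn, w$tax, "genus", smap)
  expect_equal(unname(at_genus$counts[as.character(gen[1]), "s1"]), 10)
  expect_equal(unname(at_genus$ledger$above_rank[["s1"]]), 2)
  expect_equal(unname(at_genus$ledger$unassigned[["s1"]]), 1)
  expect_equal(sum(at_genus$counts) + sum(at_genus$ledger$above_rank) +
                 sum(at_genus$ledger$unassigned), 13)

  at_family <- collate_profile(asn, w$tax, "family", smap)
  expect_equal(unname(at_family$counts[as.character(fam[1]), "s1"]), 12)

  # a root assignment is excluded at every rank below root
  asn_root <- data.frame(read_id = "rr", taxon_id = w$tax$root,
                         n_perfect_hits = 1, n_taxa_hit = 2)
  cm <- collate_profile(asn_root, w$tax, "genus", c(rr = "s1"))
  expect_equal(sum(cm$counts), 0)
  expect_equal(unname(cm$ledger$above_rank[["s1"]]), 1)

  expect_error(collate_profile(asn, w$tax, "genus", stats::setNames("s1", "zz")),
               class = "sedapipe_lookup_error")
})

test_that("control subtraction removes whole rows regardless of counts", {
  counts <- matrix(c(1000L, 5L, 3L, 7L), 2, 2,
                   dimnames = list(c("4", "5"), c("s1", "s2")))
  m <- structure(list(counts = counts, rank = "species",
                      taxon_names = c(`4` = "Sp1", `5` = "Sp2"),
                      ledger = list()), class = "count_matrix")
  empty_ctl <- structure(list(counts = counts[0, , drop = FALSE] ,
                              rank = "species", taxon_names = character(0),
                              ledger = list()), class = "count_matrix")
  expect_equal(subtract_control_taxa(m, empty_ctl)$counts, counts)

  ctl <- structure(list(counts = matrix(2L, 1, 1, dimnames = list("4", "c1")),
                        rank = "species", taxon_names = c(`4` = "Sp1"),
                        ledger = list()), class = "count_matrix")
  out <- subtract_control_taxa(m, ctl)
  expect_false("4" %in% rownames(out$counts))
  expect_equal(out$ledger$control_removed, "4")

  ctl_all <- m
  expect_equal(nrow(subtract_control_taxa(m, ctl_all)$counts), 0)

  ctl_bad <- ctl
  ctl_bad$rank <- "genus"
  expect_error(subtract_control_taxa(m, ctl_bad),
               class = "sedapipe_invalid_parameter")
})

test_that("checklist filtering drops off-list taxa and thin cells", {
  counts <- matrix(c(1000L, 2L, 4L, 0L, 5L, 9L), 3, 2, byrow = TRUE,
                   dimnames = list(c("4", "5", "6"), c("s1", "s2")))
  m <- structure(list(counts = counts, rank = "species",
                      taxon_names = c(`4` = "OffList", `5` = "Sp2", `6` = "Sp3"),
                      ledger = list()), class = "count_matrix")
  out <- checklist_filter(m, c("Sp2", "Sp3"), min_reads = 3, min_samples = 1)
  expect_false("4" %in% rownames(out$counts))          # off-list despite 1000 reads
  expect_equal(names(out$ledger$off_checklist), "OffList")
  expect_equal(unname(out$counts["5", "s1"]), 4)
  expect_equal(unname(out$counts["5", "s2"]), 0)       # 2 < min_reads zeroed
  expect_equal(unname(out$counts["6", ]), c(5, 9))

  # all on checklist, all cells above threshold, min_samples 1 -> unchanged
  m2 <- m
  m2$taxon_names[["4"]] <- "Sp1"
  m2$counts[] <- 10L
  out2 <- checklist_filter(m2, c("Sp1", "Sp2", "Sp3"), 3, 1)
  expect_equal(out2$counts, m2$counts)

  # min_samples drops taxa left nonzero in too few samples
  out3 <- checklist_filter(m, c("Sp2", "Sp3"), min_reads = 6, min_samples = 1)
  expect_false("5" %in% rownames(out3$counts))
  expect_true("5" %in% out3$ledger$dropped_sparse)
})
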