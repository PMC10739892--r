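test_that("fixture specs validate their parameters", {
  expect_error(fixture_spec(rho = 1.5))
  expect_error(fixture_spec(markers_per_entry = 100, seqs_per_entry = 50))
  expect_s3_class(fixture_spec(), "fixture_spec")
})

test_that("generated taxonomies parse back and expose the planted shape", {
  spec <- fixture_spec(seed = 5, n_lineages = 2, species_per_lineage = 3)
  tax <- make_taxonomy(spec)
  expect_s3_class(tax$tree, "taxonomy_tree")
  expect_equal(nrow(tax$species), 6L)
  expect_equal(nrow(tax$bins), 5L) # 2 lineages + Bacteria/Archaea/Viruses
  # every node reaches the root
  for (t in as.integer(names(tax$tree$parent))) {
    expect_equal(lineage(tax$tree, t)[1], 1L)
  }
  # species sit under their lineage bins
  for (i in seq_len(nrow(tax$species))) {
    expect_equal(assign_bin(tax$tree, tax$species$taxid[i], tax$bins),
                 tax$species$lineage[i])
  }
})

test_that("the same seed reproduces a byte-identical corpus", {
  spec <- fixture_spec(seed = 77, species_per_lineage = 1,
                       seqs_per_entry = 20, markers_per_entry = 8)
  d1 <- tempfile(); d2 <- tempfile()
  make_corpus(spec, d1)
  make_corpus(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("generated inputs satisfy every parser's contract", {
  spec <- fixture_spec(seed = 6, species_per_lineage = 2,
                       seqs_per_entry = 15, markers_per_entry = 5)
  co <- make_corpus(spec, tempfile())
  md <- read_entry_metadata(file.path(co$dir, "metadata.csv"))
  expect_equal(nrow(md), nrow(co$metadata))
  tr <- parse_taxdump(file.path(co$dir, "taxonomy", "nodes.dmp"),
                      file.path(co$dir, "taxonomy", "names.dmp"))
  bins <- read_bin_config(tr, file.path(co$dir, "bins.cfg"))
  expect_equal(nrow(bins), spec$n_lineages + 3L)
  tc <- parse_hmm_thresholds(file.path(co$dir, "hmm_profiles.txt"))
  expect_false(anyNA(tc))
  for (i in seq_len(nrow(md))) {
    eid <- md$entry_id[i]
    fa <- file.path(co$dir, "entries",
                    sprintf("entry_%d.%s", eid,
                            ifelse(md$seq_type[i] == "nt", "fna", "faa")))
    recs <- read_fasta(fa, ifelse(md$seq_type[i] == "nt",
                                  "nucleotide", "amino-acid"))
    expect_equal(nrow(recs), md$n_seqs_raw[i])
    hits <- parse_domtbl(file.path(co$dir, "domtbl",
                                   sprintf("entry_%d.domtblout.tab", eid)))
    expect_true(all(hits$seq_id %in% recs$seq_id))
    ht <- file.path(co$dir, "hits", sprintf("entry_%d.hits.tsv", eid))
    expect_true(file.exists(ht))
    expect_gt(nrow(parse_hit_table(ht)), 0L)
  }
})

test_that("sub-threshold planted hits vanish after trusted filtering", {
  spec <- fixture_spec(seed = 13, species_per_lineage = 1,
                       seqs_per_entry = 40, markers_per_entry = 10,
                       subthreshold_frac = 0.3)
  co <- make_corpus(spec, tempfile())
  tc <- parse_hmm_thresholds(file.path(co$dir, "hmm_profiles.txt"))
  any_sub <- FALSE
  for (eid in names(co$truth)) {
    tr <- co$truth[[eid]]
    if (!length(tr$subthreshold)) next
    any_sub <- TRUE
    hits <- parse_domtbl(file.path(co$dir, "domtbl",
                                   sprintf("entry_%s.domtblout.tab", eid)))
    best <- best_per_sequence(filter_trusted(hits, tc))
    expect_false(any(tr$subthreshold %in% best$seq_id))
    # above-threshold sequences keep their planted family as best
    ok <- setdiff(names(tr$planted), tr$subthreshold)
    expect_equal(unname(tr$planted[best$seq_id]), best$pfam_id)
    expect_setequal(best$seq_id, ok)
  }
  expect_true(any_sub)
})

test_that("marker hit generation honours rho at its extremes", {
  spec <- fixture_spec(seed = 3, n_lineages = 2, species_per_lineage = 2)
  tax <- make_taxonomy(spec)
  ids <- sprintf("m%02d", 1:30)
  mk <- data.frame(seq_id = ids, pfam_id = "PF1")
  for (rho in c(0, 1)) {
    mh <- make_marker_hits(spec, tax, 1L, ids, lineage_idx = 1L, rho = rho)
    rep <- estimate_contamination(1L, tax$species$taxid[1], mk, mh$hits,
                                  tax$tree, tax$bins)
    expect_equal(rep$contam_pct, 100 * rho)
    expect_equal(mh$rho_realized, rho)
  }
  expect_error(make_marker_hits(spec, tax, 1L, ids, 1L, rho = -0.1), "rho")
})

test_that("planted CDS fixtures record a frame the generator can defend", {
  spec <- fixture_spec(seed = 8)
  fix <- make_cds_fixture(spec, frames = c(2, 6))
  expect_equal(fix$planted_frame, c(2L, 6L))
  # determinism
  fix2 <- make_cds_fixture(fixture_spec(seed = 8), frames = c(2, 6))
  expect_identical(fix, fix2)
})
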