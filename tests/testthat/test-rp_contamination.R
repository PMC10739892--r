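# Taxonomy used throughout: two eukaryote lineages (bins A = 10, B = 20)
# with two species each, plus an unbinned branch.
contam_tree <- function() {
  tree_from_parents(
    c("1" = 1, "2" = 1, "10" = 2, "20" = 2,
      "11" = 10, "12" = 10, "21" = 20, "22" = 20, "9" = 1),
    ranks = c("1" = "no rank", "2" = "superkingdom", "10" = "clade",
              "20" = "clade", "11" = "species", "12" = "species",
              "21" = "species", "22" = "species", "9" = "clade"))
}

test_that("marker selection requires a ribosomal name and strict prevalence", {
  best <- do.call(rbind, lapply(1:10, function(e) {
    fams <- data.frame(
      entry_id = e,
      pfam_id = c("PF00177", "PF00181", "PF00069"),
      pfam_name = c("Ribosomal_S7", "Ribosomal_L2", "PK_kinase"))
    if (e == 10) fams <- fams[fams$pfam_id != "PF00181", ] # L2 in 9/10
    fams
  }))
  markers <- select_marker_pfams(best, prevalence_min = 0.90)
  # 10/10 > 0.9 qualifies; 9/10 = 0.9 fails the strict inequality;
  # the ubiquitous kinase family is name-excluded
  expect_equal(markers, "PF00177")

  one <- best[best$entry_id == 1, ]
  expect_equal(select_marker_pfams(one), c("PF00177", "PF00181"))
  expect_warning(select_marker_pfams(one, name_patterns = "^NoSuch"),
                 "no marker")
})

test_that("marker sequences are those whose best annotation is a marker", {
  best <- data.frame(
    seq_id = paste0("s", 1:10),
    pfam_id = c(rep("PF00177", 3), rep("PF00069", 7)),
    stringsAsFactors = FALSE)
  mk <- marker_sequences(best, "PF00177")
  expect_equal(mk$seq_id, c("s1", "s2", "s3"))
  expect_equal(nrow(marker_sequences(best, "PF99999")), 0L)
  # a weaker marker hit does not rescue a sequence best-annotated elsewhere
  hits <- data.frame(seq_id = "sx", pfam_id = c("PF00069", "PF00177"),
                     pfam_name = c("PK_kinase", "Ribosomal_S7"),
                     bitscore = c(80, 40), evalue = c(1e-20, 1e-8))
  best_x <- best_per_sequence(hits)
  expect_equal(nrow(marker_sequences(best_x, "PF00177")), 0L)
})

# hits placing one query cleanly inside the subtree of `taxid`
place_hits <- function(q, taxa) {
  data.frame(query_id = q, subject_taxid = taxa,
             bitscore = c(100, 95), evalue = c(1e-40, 1e-38))
}

test_that("contamination follows the hand-counted formula, excluding Unknown", {
  tr <- contam_tree()
  bins <- bin_set(tr, c("A", "B"), c(10L, 20L))
  mk <- data.frame(seq_id = sprintf("m%02d", 1:10),
                   pfam_id = rep(c("PF1", "PF2"), 5))
  hits <- rbind(
    do.call(rbind, lapply(1:7, function(i) # 7 in expected bin A
      place_hits(sprintf("m%02d", i), c(11L, 12L)))),
    do.call(rbind, lapply(8:9, function(i) # 2 in bin B
      place_hits(sprintf("m%02d", i), c(21L, 22L))))
  ) # m10 has no hits -> Unknown
  rep <- estimate_contamination(1L, 11L, mk, hits, tr, bins)
  expect_equal(rep$tax_group, "A")
  expect_equal(rep$n_seqs, 10L)
  expect_equal(rep$n_pfams, 2L)
  expect_equal(rep$A, 7L)
  expect_equal(rep$B, 2L)
  expect_equal(rep$Unknown, 1L)
  expect_equal(rep$contam_pct, 100 * 2 / 9, tolerance = 1e-12)
  # counting Unknown as outside instead
  rep2 <- estimate_contamination(1L, 11L, mk, hits, tr, bins,
                                 unknown_policy = "count")
  expect_equal(rep2$contam_pct, 100 * 3 / 10, tolerance = 1e-12)
})

test_that("all markers in the expected bin score zero contamination", {
  tr <- contam_tree()
  bins <- bin_set(tr, c("A", "B"), c(10L, 20L))
  mk <- data.frame(seq_id = c("m1", "m2"), pfam_id = "PF1")
  hits <- rbind(place_hits("m1", c(11L, 12L)), place_hits("m2", c(11L, 11L)))
  rep <- estimate_contamination(1L, 11L, mk, hits, tr, bins)
  expect_equal(rep$contam_pct, 0)
  # no placeable marker -> undefined percentage
  rep0 <- estimate_contamination(1L, 11L, mk, hits[0, ], tr, bins)
  expect_true(is.na(rep0$contam_pct))
  expect_equal(rep0$Unknown, 2L)
})

test_that("duplicating every hit row leaves the estimate unchanged", {
  tr <- contam_tree()
  bins <- bin_set(tr, c("A", "B"), c(10L, 20L))
  mk <- data.frame(seq_id = sprintf("m%d", 1:6), pfam_id = "PF1")
  hits <- rbind(
    do.call(rbind, lapply(1:4, function(i) place_hits(paste0("m", i),
                                                      c(11L, 12L)))),
    do.call(rbind, lapply(5:6, function(i) place_hits(paste0("m", i),
                                                      c(21L, 21L)))))
  r1 <- estimate_contamination(1L, 11L, mk, hits, tr, bins)
  r2 <- estimate_contamination(1L, 11L, mk, rbind(hits, hits), tr, bins)
  expect_equal(r1$contam_pct, r2$contam_pct)
})

test_that("an entry whose taxid falls in no bin is reported with a warning", {
  tr <- contam_tree()
  bins <- bin_set(tr, c("A", "B"), c(10L, 20L))
  mk <- data.frame(seq_id = "m1", pfam_id = "PF1")
  expect_warning(
    rep <- estimate_contamination(1L, 9L, mk, place_hits("m1", c(11L, 12L)),
                                  tr, bins),
    "no configured lineage bin")
  expect_equal(rep$tax_group, "Other")
  expect_true(attr(rep, "expected_bin_other"))
})

test_that("report bin columns follow configured order plus Other, Unknown", {
  tr <- contam_tree()
  bins <- bin_set(tr, c("B", "A"), c(20L, 10L)) # deliberate custom order
  mk <- data.frame(seq_id = "m1", pfam_id = "PF1")
  rep <- estimate_contamination(1L, 11L, mk, place_hits("m1", c(11L, 12L)),
                                tr, bins)
  expect_equal(names(rep)[7:10], c("B", "A", "Other", "Unknown"))
  expect_equal(sum(rep[, 7:10]), rep$n_seqs)
})

test_that("estimates sharpen as the marker count grows", {
  spec <- fixture_spec(seed = 123, n_lineages = 2, species_per_lineage = 2)
  tax <- make_taxonomy(spec)
  rho <- 0.3
  err <- vapply(c(50, 200, 800), function(n) {
    devs <- vapply(1:20, function(s) {
      sp <- fixture_spec(seed = 1000 + s, n_lineages = 2,
                         species_per_lineage = 2)
      ids <- sprintf("m%03d", seq_len(n))
      mh <- make_marker_hits(sp, tax, entry_id = 1L, marker_ids = ids,
                             lineage_idx = 1L, rho = rho)
      mk <- data.frame(seq_id = ids, pfam_id = "PF1")
      rep <- estimate_contamination(1L, tax$species$taxid[1], mk, mh$hits,
                                    tax$tree, tax$bins)
      abs(rep$contam_pct - 100 * rho)
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_true(err[2] < err[1])
  expect_true(err[3] < err[2])
})
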