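# A lineage (taxid 10) with species 11, 12, 13; species 11 has strains
# 111 and 112; plus an outgroup lineage 20 with species 21.
ctg_tree <- function() {
  tree_from_parents(
    c("1" = 1, "2" = 1, "10" = 2, "11" = 10, "111" = 11, "112" = 11,
      "12" = 10, "13" = 10, "20" = 2, "21" = 20),
    ranks = c("1" = "no rank", "2" = "superkingdom", "10" = "clade",
              "11" = "species", "111" = "strain", "112" = "strain",
              "12" = "species", "13" = "species", "20" = "clade",
              "21" = "species"))
}

ctg_metadata <- function(tax_ids, data_type = "TSA", accepted = "Y") {
  data.frame(entry_id = seq_along(tax_ids),
             marferret_name = paste0("e", seq_along(tax_ids)),
             tax_id = tax_ids, data_type = data_type, seq_type = "aa",
             n_seqs_raw = 100L, accepted = accepted,
             stringsAsFactors = FALSE)
}

best_of <- function(entry_id, fams) {
  data.frame(entry_id = entry_id, pfam_id = fams, stringsAsFactors = FALSE)
}

test_that("strains collapse to species and presence is the union", {
  tr <- ctg_tree()
  md <- ctg_metadata(c(111L, 112L))
  best <- rbind(best_of(1L, "PF_A"), best_of(2L, "PF_B"))
  m <- build_presence_matrix(md, best, tr, 10L)
  expect_equal(nrow(m), 1L) # one species row
  expect_equal(rownames(m), "11")
  expect_true(all(m["11", c("PF_A", "PF_B")]))
})

test_that("genome-sourced and rejected entries contribute nothing", {
  tr <- ctg_tree()
  md <- ctg_metadata(c(11L, 12L, 13L))
  md$data_type[3] <- "genome"
  best <- rbind(best_of(1L, "PF_A"), best_of(2L, "PF_A"), best_of(3L, "PF_A"))
  m <- build_presence_matrix(md, best, tr, 10L)
  expect_equal(sort(rownames(m)), c("11", "12"))
  expect_equal(unname(colSums(m)["PF_A"]), 2)

  md2 <- ctg_metadata(c(11L, 12L), accepted = c("Y", "N"))
  m2 <- build_presence_matrix(md2, best[1:2, ], tr, 10L)
  expect_equal(rownames(m2), "11")

  expect_error(build_presence_matrix(md, best, tr, 20L), "no accepted")
})

test_that("lineage exclusion removes a subclade from the matrix", {
  tr <- ctg_tree()
  md <- ctg_metadata(c(11L, 12L, 13L))
  best <- rbind(best_of(1L, "PF_A"), best_of(2L, "PF_A"), best_of(3L, "PF_A"))
  m <- build_presence_matrix(md, best, tr, 10L, exclude_taxids = 11L)
  expect_equal(sort(rownames(m)), c("12", "13"))
})

test_that("the 95% criterion over 29 taxa requires 28 observations", {
  # presence matrix with 29 species; families planted in 26..29 of them
  m <- matrix(FALSE, nrow = 29, ncol = 4,
              dimnames = list(paste0("sp", 1:29),
                              c("PF26", "PF27", "PF28", "PF29")))
  for (k in 26:29) m[seq_len(k), paste0("PF", k)] <- TRUE
  cat95 <- derive_ctg(m, threshold = 0.95)
  expect_setequal(cat95$pfam_id, c("PF28", "PF29"))
  expect_equal(attr(cat95, "min_count"), 28L)
  expect_equal(min(cat95$n_taxa_observed), 28L)
})

test_that("catalog membership is monotone in the threshold", {
  set.seed(12)
  m <- matrix(runif(20 * 30) < 0.9, nrow = 20,
              dimnames = list(paste0("s", 1:20), sprintf("PF%03d", 1:30)))
  prev <- NULL
  for (th in c(0, 0.5, 0.8, 0.95, 1)) {
    cat <- derive_ctg(m, th)
    if (!is.null(prev)) expect_true(all(cat$pfam_id %in% prev))
    prev <- cat$pfam_id
  }
  expect_setequal(derive_ctg(m, 0)$pfam_id, colnames(m)[colSums(m) > 0])
  expect_true(all(derive_ctg(m, 0.95)$frequency >= 0.95))
})

test_that("completeness is the covered fraction of the catalog", {
  cat <- data.frame(pfam_id = c("A", "B", "C", "D"),
                    n_taxa_observed = 4L, frequency = 1)
  expect_equal(completeness(c("A", "B", "C"), cat), 75)
  expect_equal(completeness(c("A", "B", "C", "D", "E"), cat), 100)
  expect_equal(completeness(c("X", "Y"), cat), 0)
  expect_error(completeness("A", cat[0, ]), "empty catalog")
})

test_that("a species holding every catalog family scores 100", {
  tr <- ctg_tree()
  md <- ctg_metadata(c(11L, 12L, 13L))
  fams <- sprintf("PF%02d", 1:10)
  best <- do.call(rbind, lapply(1:3, function(e) best_of(e, fams)))
  m <- build_presence_matrix(md, best, tr, 10L)
  cat <- derive_ctg(m, 0.95)
  expect_equal(completeness(fams, cat), 100)
})

test_that("lineage configs parse names, taxids and exclusions", {
  f <- write_tmp(c("Haptophyta\t2830", "Ochrophyta\t2696291\t2836,2837",
                   "# comment"))
  cfg <- read_lineage_config(f)
  expect_equal(cfg$name, c("Haptophyta", "Ochrophyta"))
  expect_equal(cfg$exclude[[2]], c(2836L, 2837L))
  expect_equal(cfg$exclude[[1]], integer(0))
})

test_that("the default lineage roster covers the nine lineages plus Eukaryota", {
  expect_length(CTG_DEFAULT_LINEAGES, 10L)
  expect_true(all(c("Bacillariophyta", "Ochrophyta", "Dinophyceae",
                    "Chlorophyta", "Haptophyta", "Cryptophyceae",
                    "Opisthokonta", "Rhizaria", "Amoebozoa", "Eukaryota")
                  %in% CTG_DEFAULT_LINEAGES))
})
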