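test_that("FASTA parsing splits headers, upper-cases, and preserves order", {
  f <- write_tmp(c(">s1 desc", "acgt", ">s2", "GGTT"), ".fasta")
  recs <- read_fasta(f, "nucleotide")
  expect_equal(recs$seq_id, c("s1", "s2"))
  expect_equal(recs$description, c("desc", ""))
  expect_equal(recs$residues, c("ACGT", "GGTT"))

  f2 <- write_tmp(c(">a", "MK*", ">b", "LLX"), ".fasta")
  aa <- read_fasta(f2, "amino-acid")
  expect_equal(aa$residues, c("MK*", "LLX"))
})

test_that("FASTA rejects empty files and illegal symbols, naming the record", {
  empty <- write_tmp(character(0), ".fasta")
  expect_error(read_fasta(empty, "nucleotide"))
  bad <- write_tmp(c(">s1", "ACGTZ"), ".fasta")
  expect_error(read_fasta(bad, "nucleotide"), "s1.*Z")
  # the same residues are fine as amino acids
  expect_silent(read_fasta(bad, "amino-acid"))
})

test_that("FASTA round-trip preserves id, description and residues", {
  set.seed(11)
  recs <- data.frame(
    seq_id = sprintf("seq%02d", 1:20),
    description = c(rep("", 10), sprintf("desc %d extra words", 11:20)),
    residues = vapply(sample(30:90, 20, TRUE), random_aa, ""),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".faa")
  write_fasta(recs, f)
  back <- read_fasta(f, "amino-acid")
  expect_equal(back$seq_id, recs$seq_id)
  expect_equal(back$description, recs$description)
  expect_equal(back$residues, recs$residues)
  # gzip-transparent
  fgz <- tempfile(fileext = ".faa.gz")
  write_fasta(recs, fgz)
  expect_equal(read_fasta(fgz, "amino-acid")$residues, recs$residues)
})

test_that("taxdump parsing builds a rooted tree and flags structural faults", {
  tr <- tree_from_parents(c("1" = 1, "2" = 1))
  expect_s3_class(tr, "taxonomy_tree")
  expect_equal(tr$root, 1L)
  expect_length(tr$parent, 2L)

  expect_error(tree_from_parents(c("1" = 1, "5" = 99)), "orphan.*5")
  d <- tempfile(); dir.create(d)
  writeLines(c(dmp(1, 1, "no rank"), dmp(2, 1, "x"), dmp(2, 1, "x")),
             file.path(d, "nodes.dmp"))
  writeLines(dmp(1, "root", "", "scientific name"), file.path(d, "names.dmp"))
  expect_error(parse_taxdump(file.path(d, "nodes.dmp"),
                             file.path(d, "names.dmp")), "duplicate")
})

test_that("every node of a generated 50-node tree walks back to the root", {
  tr <- random_tree(50, seed = 42)
  for (t in 1:50) {
    path <- lineage(tr, t)
    expect_equal(path[1], tr$root)
    expect_equal(path[length(path)], t)
    if (length(path) > 1) {
      expect_true(all(tr$parent[as.character(path[-1])] ==
                        path[-length(path)]))
    }
  }
})

domtbl_row <- function(seq, name, acc, eval, score) {
  paste(seq, "-", 100, name, acc, 100, eval, score, "0.1", 1, 1,
        eval, eval, score, "0.1", 1, 100, 1, 100, 1, 100, "0.9", "desc")
}

test_that("domain tables parse field-by-field and skip comments", {
  f <- write_tmp(c("# h1", "# h2", "# footer"))
  expect_equal(nrow(parse_domtbl(f)), 0L)

  f2 <- write_tmp(c("# h",
                    domtbl_row("q1", "Fam_A", "PF00001.21", "1e-10", "55.0"),
                    "# f"))
  h <- parse_domtbl(f2)
  expect_equal(h$pfam_id, "PF00001")
  expect_equal(h$pfam_name, "Fam_A")
  expect_equal(h$bitscore, 55.0)
  expect_equal(h$evalue, 1e-10)

  f3 <- write_tmp(c(domtbl_row("s1", "A", "PF00001.1", "1e-5", "30"),
                    domtbl_row("s1", "B", "PF00002.2", "1e-6", "40"),
                    domtbl_row("s2", "A", "PF00001.1", "1e-7", "50")))
  h3 <- parse_domtbl(f3)
  expect_equal(h3$seq_id, c("s1", "s1", "s2"))
  expect_equal(h3$pfam_id, c("PF00001", "PF00002", "PF00001"))

  bad <- write_tmp("q1 only three fields")
  expect_error(parse_domtbl(bad), "line 1")
})

test_that("trusted cutoffs are read from ACC/TC profile headers", {
  f <- write_tmp(c("HMMER3/f", "NAME  A", "ACC   PF00001.21",
                   "TC    20.40 20.40;", "//",
                   "HMMER3/f", "NAME  B", "ACC   PF00002.3",
                   "TC    31.10 30.00;", "//"))
  tc <- parse_hmm_thresholds(f)
  expect_equal(unname(tc["PF00001"]), 20.40)
  expect_equal(unname(tc["PF00002"]), 31.10)
  expect_length(tc, 2L)

  f2 <- write_tmp(c("HMMER3/f", "ACC   PF00003.1", "//"))
  expect_warning(tc2 <- parse_hmm_thresholds(f2), "PF00003")
  expect_true(is.na(tc2["PF00003"]))
})

test_that("hit tables parse in both dialects and count unmappable rows", {
  f <- write_tmp("q1 7 50.0 1e-20")
  h <- parse_hit_table(f)
  expect_equal(h$query_id, "q1")
  expect_equal(h$subject_taxid, 7L)
  expect_equal(h$bitscore, 50.0)
  expect_equal(h$evalue, 1e-20)

  b12 <- function(q, s, ev, bs) {
    paste(q, s, "99.0", "100", "1", "0", "1", "100", "1", "100", ev, bs,
          sep = "\t")
  }
  f2 <- write_tmp(c(b12("q1", "ref9", "1e-30", "80.5"),
                    b12("q1", "refX", "1e-30", "70.0"),
                    b12("q2", "ref9", "1e-10", "60.0")))
  expect_error(parse_hit_table(f2), "taxid_map")
  h2 <- parse_hit_table(f2, taxid_map = c(ref9 = 12L))
  expect_equal(nrow(h2), 2L)
  expect_equal(unique(h2$subject_taxid), 12L)
  expect_equal(attr(h2, "n_dropped"), 1L)

  corrupt <- write_tmp("q1 7 fifty 1e-20")
  expect_error(parse_hit_table(corrupt), "non-numeric")
})

test_that("entry metadata enforces its schema and preserves extra columns", {
  md <- data.frame(entry_id = 1:2, marferret_name = c("a", "b"),
                   tax_id = c(5L, 6L), data_type = c("TSA", "genome"),
                   seq_type = c("nt", "aa"), n_seqs_raw = c(10L, 20L),
                   accepted = c("Y", "N"), source_link = c("u1", "u2"))
  f <- tempfile(fileext = ".csv")
  write_entry_metadata(md, f)
  back <- read_entry_metadata(f)
  expect_equal(back$source_link, c("u1", "u2"))
  expect_equal(back$entry_id, 1:2)

  expect_error(read_entry_metadata(
    write_tmp(c("entry_id,tax_id", "1,5"), ".csv")), "missing required")
  bad <- md; bad$data_type[1] <- "EST"
  f2 <- tempfile(fileext = ".csv"); write_entry_metadata(bad, f2)
  expect_error(read_entry_metadata(f2), "data_type")
})
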