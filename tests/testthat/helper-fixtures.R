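# Shared fixture builders: all inputs are generated in code at test time.

dmp <- function(...) paste(paste(..., sep = "\t|\t"), "|", sep = "\t")

# Build a taxonomy_tree from a named parent vector (names = taxids) and an
# optional named rank vector, by writing and parsing taxdump files.
tree_from_parents <- function(parents, ranks = NULL, dir = tempfile()) {
  dir.create(dir)
  ids <- as.integer(names(parents))
  if (is.null(ranks)) ranks <- setNames(rep("no rank", length(ids)),
                                        names(parents))
  writeLines(vapply(seq_along(ids), function(i) {
    dmp(ids[i], parents[[i]], ranks[[as.character(ids[i])]])
  }, ""), file.path(dir, "nodes.dmp"))
  writeLines(vapply(ids, function(id) {
    dmp(id, paste0("node", id), "", "scientific name")
  }, ""), file.path(dir, "names.dmp"))
  parse_taxdump(file.path(dir, "nodes.dmp"), file.path(dir, "names.dmp"))
}

# Random rooted tree on n nodes (taxid 1 = root, each node's parent drawn
# from lower-numbered nodes). Deterministic under seed.
random_tree <- function(n, seed) {
  set.seed(seed)
  parents <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                          integer(1)))
  tree_from_parents(setNames(parents, 1:n))
}

# Independent LCA oracle: intersect root paths walked directly over the
# parent map, take the last common element.
brute_lca <- function(tree, taxids) {
  walk <- function(t) {
    p <- integer(0)
    while (TRUE) {
      p <- c(t, p)
      if (t == tree$root) break
      t <- unname(tree$parent[as.character(t)])
    }
    p
  }
  paths <- lapply(taxids, walk)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# Hand-rolled translation oracle for short sequences (standard code only,
# unambiguous bases), independent of the package's codon machinery.
oracle_translate <- function(nt, offset) {
  gc <- Biostrings::GENETIC_CODE
  n <- (nchar(nt) - offset) %/% 3
  if (n <= 0) return("")
  paste0(vapply(seq_len(n), function(i) {
    gc[[substr(nt, offset + 3 * i - 2, offset + 3 * i)]]
  }, ""), collapse = "")
}

oracle_revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", nt), "")[[1]]), collapse = "")
}

# Longest stop-free run oracle over a peptide.
oracle_orf <- function(pep) {
  if (!nchar(pep)) return(0L)
  max(nchar(strsplit(pep, "*", fixed = TRUE)[[1]]), 0L)
}

random_aa <- function(len) {
  paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                replace = TRUE), collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
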