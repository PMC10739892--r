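## Lineage queries, lowest-common-ancestor inference with top-bitscore hit
## retention, and lineage-bin assignment for marker placement reports.

#' The 19 default lineage-bin names of the contamination report
#'
#' Sixteen eukaryote lineages plus Bacteria, Archaea and Viruses. Together
#' with the reserved `Other` and `Unknown` categories they form the 21 bin
#' columns of the contamination report.
#' @export
RP63_BIN_NAMES <- c(
  "Amoebozoa", "Ciliophora", "Colpodellida", "Cryptophyceae", "Dinophyceae",
  "Euglenozoa", "Glaucocystophyceae", "Haptophyta", "Heterolobosea",
  "Opisthokonta", "Palpitomonas", "Perkinsozoa", "Rhizaria", "Rhodophyta",
  "Stramenopiles", "Viridiplantae", "Bacteria", "Archaea", "Viruses"
)

RESERVED_BINS <- c("Other", "Unknown")

# Map a possibly merged/retired taxid onto its current node; unknown taxids
# are an explicit error (curation must be deliberate, never silent).
resolve_taxid <- function(tree, taxid) {
  taxid <- as.integer(taxid)
  key <- as.character(taxid)
  if (!is.na(tree$parent[key])) return(taxid)
  if (length(tree$merged) && key %in% names(tree$merged)) {
    return(unname(tree$merged[key]))
  }
  stop("taxid ", taxid, " not found in taxonomy (and not in merged map)")
}

#' Root-to-node lineage path
#'
#' @param tree A `taxonomy_tree` from [parse_taxdump()].
#' @param taxid Query taxid (merged ids are resolved when a merged map is
#'   loaded; unknown ids are an error).
#' @return Integer vector of taxids from the root down to `taxid`.
#' @export
lineage <- function(tree, taxid) {
  taxid <- resolve_taxid(tree, taxid)
  path <- integer(0)
  node <- taxid
  repeat {
    path <- c(node, path)
    if (node == tree$root) break
    node <- unname(tree$parent[as.character(node)])
    if (length(path) > length(tree$parent)) {
      stop("cycle detected walking parents from taxid ", taxid)
    }
  }
  path
}

#' Lowest common ancestor of a set of taxids
#'
#' The deepest node lying on the root path of every member.
#'
#' @inheritParams lineage
#' @param taxids Non-empty integer vector of taxids.
#' @return A single taxid.
#' @export
lca <- function(tree, taxids) {
  if (!length(taxids)) stop("lca of an empty taxid set is undefined")
  taxids <- unique(vapply(taxids, resolve_taxid, integer(1), tree = tree))
  path <- lineage(tree, taxids[1L])
  for (t in taxids[-1L]) {
    other <- lineage(tree, t)
    n <- min(length(path), length(other))
    agree <- path[seq_len(n)] == other[seq_len(n)]
    k <- if (all(agree)) n else which(!agree)[1L] - 1L
    path <- path[seq_len(k)]
  }
  path[length(path)]
}

#' Taxonomic placement of one query from its alignment hits
#'
#' Hits with E-value above `evalue_max` are discarded; of the survivors, hits
#' scoring within `top_frac` of the best bitscore are retained (mirroring the
#' `--top 10` convention: within 10% of the maximum), and the LCA of their
#' subject taxids is returned. `"unassigned"` is returned when no hit
#' survives.
#'
#' @inheritParams lineage
#' @param hits Data frame of hits for a single query (`subject_taxid`,
#'   `bitscore`, `evalue`).
#' @param evalue_max Maximum E-value retained (default `1e-5`).
#' @param top_frac Bitscore retention band as a fraction of the maximum
#'   (default `0.10`).
#' @return A taxid, or the string `"unassigned"`.
#' @export
lca_from_hits <- function(tree, hits, evalue_max = 1e-5, top_frac = 0.10) {
  keep <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (!nrow(keep)) return("unassigned")
  keep <- keep[keep$bitscore >= (1 - top_frac) * max(keep$bitscore), ,
               drop = FALSE]
  if (!nrow(keep)) return("unassigned")
  lca(tree, keep$subject_taxid)
}

#' Construct a lineage bin set
#'
#' @inheritParams lineage
#' @param names Character vector of bin names (unique; the reserved names
#'   `Other` and `Unknown` are not allowed).
#' @param taxids Matching taxids, all present in `tree`.
#' @return Object of class `bin_set`: data frame `bin_name`, `bin_taxid`.
#' @export
bin_set <- function(tree, names, taxids) {
  if (length(names) != length(taxids)) stop("names/taxids length mismatch")
  if (anyDuplicated(names)) stop("bin names must be unique")
  if (any(names %in% RESERVED_BINS)) {
    stop("'Other' and 'Unknown' are reserved bin names")
  }
  taxids <- vapply(taxids, resolve_taxid, integer(1), tree = tree)
  structure(data.frame(bin_name = names, bin_taxid = as.integer(taxids),
                       stringsAsFactors = FALSE),
            class = c("bin_set", "data.frame"))
}

#' Load a bin set from a two-column config file
#'
#' Each non-comment line holds `name<TAB>taxid`.
#'
#' @inheritParams bin_set
#' @param path Config file path.
#' @export
read_bin_config <- function(tree, path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  bin_set(tree,
          names = vapply(parts, `[`, "", 1L),
          taxids = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Assign a taxid to a lineage bin
#'
#' Returns `"Unknown"` for `"unassigned"` queries; otherwise the deepest bin
#' whose taxid lies on the query's root path, or `"Other"` when no bin does.
#'
#' @inheritParams lineage
#' @param taxid A taxid or the string `"unassigned"`.
#' @param bins A `bin_set`.
#' @return Bin name (character scalar).
#' @export
assign_bin <- function(tree, taxid, bins) {
  if (identical(taxid, "unassigned")) return("Unknown")
  path <- lineage(tree, taxid)
  on_path <- bins$bin_taxid %in% path
  if (!any(on_path)) return("Other")
  depth <- match(bins$bin_taxid, path) # position along root path = depth
  cand <- which(on_path)
  bins$bin_name[cand[which.max(depth[cand])]]
}
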