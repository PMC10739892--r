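## Core transcribed gene (CTG) catalogs: per-lineage Pfam presence-absence
## matrices over species-level transcriptome taxa, frequency thresholding,
## and completeness scoring of taxon bins against a catalog.

#' The default CTG lineage names
#'
#' Nine major marine lineages plus the Eukaryota-wide catalog. `Ochrophyta`
#' is conventionally configured with its Bacillariophyta subclade excluded,
#' since diatoms are catalogued separately.
#' @export
CTG_DEFAULT_LINEAGES <- c(
  "Bacillariophyta", "Ochrophyta", "Dinophyceae", "Chlorophyta",
  "Haptophyta", "Cryptophyceae", "Opisthokonta", "Rhizaria", "Amoebozoa",
  "Eukaryota"
)

# Collapse a (possibly strain-level) taxid to its species-rank ancestor;
# nodes with no species ancestor are used as-is with a warning.
collapse_to_species <- function(tree, taxid) {
  path <- lineage(tree, taxid)
  ranks <- tree$rank[as.character(path)]
  sp <- path[ranks == "species"]
  if (length(sp)) return(sp[length(sp)])
  warning("taxid ", taxid, " has no species-rank ancestor; used as-is")
  taxid
}

#' Build a species-by-Pfam presence matrix for a lineage
#'
#' Restricts to accepted entries of the given data types (transcriptome
#' sources by default; genome and SAG entries contribute nothing) whose
#' taxid falls under `lineage_taxid` and under none of `exclude_taxids`.
#' Strain-level taxids are collapsed to their species-rank ancestors, so two
#' strains of one species form a single row whose presence is the union of
#' their annotations. A cell is 1 iff any collapsed entry of that species has
#' at least one sequence best-annotated to the family.
#'
#' @param metadata Entry metadata (with `accepted`, `data_type`, `tax_id`).
#' @param best Best-annotation table (`entry_id`, `pfam_id`).
#' @param tree Taxonomy tree.
#' @param lineage_taxid Taxid of the lineage of interest.
#' @param exclude_taxids Taxids of subclades to exclude (optional).
#' @param data_types Entry data types included (default transcriptomes:
#'   `TSA` and `SAT`).
#' @return Logical matrix, rows = species taxids, columns = pfam ids.
#' @export
build_presence_matrix <- function(metadata, best, tree, lineage_taxid,
                                  exclude_taxids = integer(0),
                                  data_types = c("TSA", "SAT")) {
  md <- metadata[metadata$accepted == "Y" &
                   metadata$data_type %in% data_types, , drop = FALSE]
  in_lineage <- vapply(md$tax_id, function(tx) {
    path <- lineage(tree, tx)
    lineage_taxid %in% path && !any(exclude_taxids %in% path)
  }, logical(1))
  md <- md[in_lineage, , drop = FALSE]
  if (!nrow(md)) {
    stop("no accepted transcriptome entries under lineage taxid ",
         lineage_taxid)
  }
  species <- vapply(md$tax_id, collapse_to_species, integer(1), tree = tree)
  fams <- sort(unique(best$pfam_id[best$entry_id %in% md$entry_id]))
  sp_ids <- sort(unique(species))
  m <- matrix(FALSE, nrow = length(sp_ids), ncol = length(fams),
              dimnames = list(as.character(sp_ids), fams))
  for (i in seq_len(nrow(md))) {
    f <- unique(best$pfam_id[best$entry_id == md$entry_id[i]])
    m[as.character(species[i]), f] <- TRUE
  }
  m
}

#' Derive a core-gene catalog from a presence matrix
#'
#' A family enters the catalog when it is observed in at least
#' `threshold` of the species rows, i.e. when its observed count reaches the
#' smallest integer `k` with `k / n_taxa >= threshold`.
#'
#' @param presence Logical species-by-family matrix from
#'   [build_presence_matrix()].
#' @param threshold Frequency criterion in `[0, 1]` (default `0.95`).
#' @return Data frame `pfam_id`, `n_taxa_observed`, `frequency` for catalog
#'   families, with attributes `n_taxa`, `threshold` and `min_count` (the
#'   smallest qualifying count).
#' @export
derive_ctg <- function(presence, threshold = 0.95) {
  stopifnot(is.matrix(presence), nrow(presence) >= 1L,
            threshold >= 0, threshold <= 1)
  n <- nrow(presence)
  obs <- colSums(presence)
  keep <- obs / n >= threshold
  out <- data.frame(pfam_id = colnames(presence)[keep],
                    n_taxa_observed = as.integer(obs[keep]),
                    frequency = unname(obs[keep] / n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pfam_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_taxa") <- n
  attr(out, "threshold") <- threshold
  attr(out, "min_count") <- as.integer(ceiling(threshold * n))
  out
}

#' Completeness of a Pfam set against a core-gene catalog
#'
#' The percentage of a lineage's core families observed in the query set;
#' the transcriptome-oriented analogue of a genome completeness score.
#'
#' @param pfam_ids Character vector of families observed in a taxon bin.
#' @param catalog Catalog data frame from [derive_ctg()].
#' @return Percentage in `[0, 100]`.
#' @export
completeness <- function(pfam_ids, catalog) {
  if (!nrow(catalog)) stop("cannot score completeness against an empty catalog")
  100 * length(intersect(unique(pfam_ids), catalog$pfam_id)) /
    nrow(catalog)
}

#' Read a CTG lineage configuration
#'
#' Tab-separated lines `name<TAB>taxid[<TAB>exclude1,exclude2,...]`.
#'
#' @param path Config file path.
#' @return Data frame `name`, `taxid`, and list-column `exclude`.
#' @export
read_lineage_config <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  data.frame(
    name = vapply(parts, `[`, "", 1L),
    taxid = as.integer(vapply(parts, `[`, "", 2L)),
    exclude = I(lapply(parts, function(p) {
      if (length(p) >= 3L && nzchar(p[3L])) {
        as.integer(strsplit(p[3L], ",")[[1L]])
      } else {
        integer(0)
      }
    })),
    stringsAsFactors = FALSE
  )
}

#' Derive catalogs for a set of configured lineages
#'
#' @param metadata,best,tree As in [build_presence_matrix()].
#' @param lineages Lineage config data frame from [read_lineage_config()].
#' @param threshold Frequency criterion (default `0.95`).
#' @return Data frame `lineage`, `n_taxa`, `pfam_id`, `frequency`, where
#'   `n_taxa` is the number of taxa the family was observed in.
#' @export
ctg_catalogs <- function(metadata, best, tree, lineages, threshold = 0.95) {
  rows <- lapply(seq_len(nrow(lineages)), function(i) {
    m <- build_presence_matrix(metadata, best, tree, lineages$taxid[i],
                               exclude_taxids = lineages$exclude[[i]])
    cat <- derive_ctg(m, threshold)
    if (!nrow(cat)) return(NULL)
    data.frame(lineage = lineages$name[i], n_taxa = cat$n_taxa_observed,
               pfam_id = cat$pfam_id, frequency = cat$frequency,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(lineage = character(0), n_taxa = integer(0),
                      pfam_id = character(0), frequency = numeric(0))
  }
  rownames(out) <- NULL
  out
}
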