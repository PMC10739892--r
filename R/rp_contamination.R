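## Cross-contamination screening from ribosomal-protein markers: pick marker
## families prevalent across the corpus, place each marker sequence by LCA of
## its alignment hits, roll placements into lineage bins, and report the
## fraction of markers landing outside the entry's expected lineage.

#' Select ribosomal-protein marker families from a best-annotation corpus
#'
#' A family qualifies when its name matches a ribosomal-protein pattern and
#' it is present in strictly more than `prevalence_min` of the entries.
#'
#' @param best Corpus-wide best annotations (`entry_id`, `pfam_id`,
#'   `pfam_name`).
#' @param name_patterns Regular expressions identifying ribosomal families
#'   (default: names beginning `Ribosomal`).
#' @param prevalence_min Strict prevalence lower bound (default `0.90`).
#' @return Character vector of marker `pfam_id`s (with a warning if empty).
#' @export
select_marker_pfams <- function(best, name_patterns = "^Ribosomal",
                                prevalence_min = 0.90) {
  stopifnot(length(name_patterns) >= 1L)
  n_entries <- length(unique(best$entry_id))
  if (n_entries == 0L) stop("no entries in annotation table")
  ribo <- Reduce(`|`, lapply(name_patterns, grepl, x = best$pfam_name))
  u <- unique(best[ribo, c("entry_id", "pfam_id")])
  prev <- table(u$pfam_id) / n_entries
  markers <- names(prev)[prev > prevalence_min]
  if (!length(markers)) {
    warning("no marker families pass the prevalence criterion")
  }
  sort(markers)
}

#' Marker sequences of one entry
#'
#' Sequences whose best annotation is one of the marker families. A sequence
#' best-annotated to a non-marker family is excluded even if it had a weaker
#' marker hit.
#'
#' @param best Best annotations for one entry (`seq_id`, `pfam_id`).
#' @param markers Marker family ids from [select_marker_pfams()].
#' @return Data frame `seq_id`, `pfam_id` of marker-annotated sequences.
#' @export
marker_sequences <- function(best, markers) {
  out <- best[best$pfam_id %in% markers, c("seq_id", "pfam_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate cross-contamination of one entry from its marker placements
#'
#' Each marker sequence is placed by [lca_from_hits()] on its alignment hits
#' and rolled into a lineage bin with [assign_bin()]; markers with no hit
#' rows (or no surviving hits) count as `Unknown`. The contamination
#' percentage is `100 x (markers in bins other than the expected bin) /
#' (markers in any bin)`, where under the default `unknown_policy =
#' "exclude"` Unknown markers enter neither numerator nor denominator (so an
#' incomplete placement is not mistaken for contamination); with `"count"`
#' they are treated as outside the expected lineage. The percentage is `NA`
#' when the denominator is zero.
#'
#' @param entry_id Entry identifier.
#' @param tax_id Entry taxid; its bin under `bins` is the expected lineage.
#' @param marker_seqs Data frame `seq_id`, `pfam_id` from
#'   [marker_sequences()].
#' @param hits Hit table for the entry's marker queries (`query_id`,
#'   `subject_taxid`, `bitscore`, `evalue`).
#' @param tree,bins Taxonomy and lineage bin set.
#' @param evalue_max,top_frac Passed to [lca_from_hits()].
#' @param unknown_policy `"exclude"` (default) or `"count"`.
#' @return One-row data frame of class `contam_report`: `entry_id`,
#'   `tax_id`, `n_seqs`, `n_pfams`, `tax_group`, `contam_pct`, then one count
#'   column per bin plus `Other` and `Unknown`. Attribute
#'   `expected_bin_other` is `TRUE` (with a warning) when the entry's own
#'   taxid falls in no configured bin.
#' @export
estimate_contamination <- function(entry_id, tax_id, marker_seqs, hits,
                                   tree, bins,
                                   evalue_max = 1e-5, top_frac = 0.10,
                                   unknown_policy = c("exclude", "count")) {
  unknown_policy <- match.arg(unknown_policy)
  expected <- assign_bin(tree, tax_id, bins)
  warn_other <- identical(expected, "Other")
  if (warn_other) {
    warning("entry ", entry_id, ": taxid ", tax_id,
            " maps to no configured lineage bin (expected bin 'Other')")
  }
  categories <- c(bins$bin_name, RESERVED_BINS)
  counts <- setNames(integer(length(categories)), categories)
  by_query <- split(seq_len(nrow(hits)), hits$query_id)
  for (q in marker_seqs$seq_id) {
    h <- hits[by_query[[q]], , drop = FALSE]
    placed <- if (!is.null(by_query[[q]])) {
      lca_from_hits(tree, h, evalue_max, top_frac)
    } else {
      "unassigned"
    }
    b <- assign_bin(tree, placed, bins)
    counts[b] <- counts[b] + 1L
  }
  known <- counts[setdiff(categories, "Unknown")]
  if (unknown_policy == "exclude") {
    denom <- sum(known)
    numer <- sum(known) - sum(known[expected])
  } else {
    denom <- sum(counts)
    numer <- denom - sum(counts[expected])
  }
  contam_pct <- if (denom > 0) 100 * numer / denom else NA_real_
  out <- data.frame(entry_id = entry_id, tax_id = tax_id,
                    n_seqs = nrow(marker_seqs),
                    n_pfams = length(unique(marker_seqs$pfam_id)),
                    tax_group = expected, contam_pct = contam_pct,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(counts), check.names = FALSE))
  class(out) <- c("contam_report", "data.frame")
  attr(out, "expected_bin_other") <- warn_other
  out
}

#' Run the ribosomal-marker contamination screen over a set of entries
#'
#' Convenience wrapper: selects marker families across the corpus, then for
#' each eligible entry extracts its marker sequences and estimates its
#' contamination percentage. Entries with a missing hit table have all their
#' markers counted `Unknown`.
#'
#' @param metadata Entry metadata (see [read_entry_metadata()]).
#' @param best_by_entry Corpus best-annotation table (`seq_id`, `entry_id`,
#'   `pfam_id`, `pfam_name`).
#' @param hits_by_entry Named list of hit tables keyed by `entry_id`.
#' @param tree,bins Taxonomy and bin set.
#' @param eligible Entry ids to screen (default: all in `metadata`).
#' @param markers Optional fixed marker family set; by default recomputed
#'   from the corpus with [select_marker_pfams()].
#' @param name_patterns,prevalence_min Passed to [select_marker_pfams()].
#' @param evalue_max,top_frac,unknown_policy Passed to
#'   [estimate_contamination()].
#' @return Data frame, one row per screened entry, with leading
#'   `entry_handle` column; attribute `markers` holds the marker set used.
#' @export
rp_screen <- function(metadata, best_by_entry, hits_by_entry, tree, bins,
                      eligible = metadata$entry_id, markers = NULL,
                      name_patterns = "^Ribosomal", prevalence_min = 0.90,
                      evalue_max = 1e-5, top_frac = 0.10,
                      unknown_policy = "exclude") {
  if (is.null(markers)) {
    markers <- select_marker_pfams(best_by_entry, name_patterns,
                                   prevalence_min)
  }
  rows <- lapply(eligible, function(eid) {
    md <- metadata[metadata$entry_id == eid, , drop = FALSE]
    if (!nrow(md)) stop("entry ", eid, " absent from metadata")
    best <- best_by_entry[best_by_entry$entry_id == eid, , drop = FALSE]
    mk <- marker_sequences(best, markers)
    hits <- hits_by_entry[[as.character(eid)]]
    if (is.null(hits)) {
      hits <- data.frame(query_id = character(0), subject_taxid = integer(0),
                         bitscore = numeric(0), evalue = numeric(0))
    }
    rep <- estimate_contamination(eid, md$tax_id, mk, hits, tree, bins,
                                  evalue_max, top_frac, unknown_policy)
    cbind(entry_handle = paste(eid, md$marferret_name, sep = "_"), rep)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "markers") <- markers
  out
}

#' Write a contamination screen report
#'
#' CSV with columns `entry_handle`, `entry_id`, `tax_id`, `n_seqs`,
#' `n_pfams`, `tax_group`, `contam_pct`, then one column per lineage bin in
#' configured order, closing with `Other` and `Unknown`.
#'
#' @param report Output of [rp_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rp_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
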