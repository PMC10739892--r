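## Post-processing of raw Pfam domain hits: trusted-cutoff filtering,
## best-per-sequence reduction, and per-entry summaries.

#' Filter Pfam hits by per-family trusted cutoffs
#'
#' Keeps exactly the hits whose full-sequence bitscore is at or above the
#' trusted cutoff of their family. Hits to families with no available cutoff
#' are dropped and counted in attribute `n_no_threshold` (with one warning).
#' Idempotent.
#'
#' @param hits Data frame of hits from [parse_domtbl()].
#' @param thresholds Named numeric vector from [parse_hmm_thresholds()].
#' @return Filtered hits data frame.
#' @export
filter_trusted <- function(hits, thresholds) {
  tc <- unname(thresholds[hits$pfam_id])
  no_tc <- is.na(tc)
  if (any(no_tc)) {
    warning(sum(no_tc), " hit(s) dropped: no trusted cutoff for ",
            paste(unique(hits$pfam_id[no_tc]), collapse = ", "))
  }
  out <- hits[!no_tc & hits$bitscore >= ifelse(no_tc, Inf, tc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_threshold") <- sum(no_tc)
  out
}

#' Reduce hits to the single best Pfam annotation per sequence
#'
#' For sequences with more than one match the highest bitscore wins; ties are
#' broken by lower E-value, then lexicographic Pfam id. Input is expected to
#' be trusted-cutoff filtered already.
#'
#' @param hits Filtered hits data frame.
#' @return Data frame with one row per annotated sequence: `seq_id`,
#'   `pfam_id`, `pfam_name`, `bitscore`, `evalue`.
#' @export
best_per_sequence <- function(hits) {
  if (!nrow(hits)) {
    out <- hits[, c("seq_id", "pfam_id", "pfam_name", "bitscore", "evalue")]
    rownames(out) <- NULL
    return(out)
  }
  ord <- order(hits$seq_id, -hits$bitscore, hits$evalue, hits$pfam_id)
  sorted <- hits[ord, , drop = FALSE]
  best <- sorted[!duplicated(sorted$seq_id), , drop = FALSE]
  best <- best[order(match(best$seq_id, hits$seq_id)), , drop = FALSE]
  rownames(best) <- NULL
  best[, c("seq_id", "pfam_id", "pfam_name", "bitscore", "evalue")]
}

#' Summarise best annotations per entry and family
#'
#' Groups a best-annotation table (with an `entry_id` column) by entry and
#' family, counting sequences. For every entry the counts sum to its number
#' of annotated sequences.
#'
#' @param best Best-annotation data frame with columns `entry_id`, `pfam_id`,
#'   `pfam_name`.
#' @return Data frame `entry_id`, `pfam_id`, `pfam_name`, `n_seqs`.
#' @export
entry_pfam_summary <- function(best) {
  if (!nrow(best)) {
    return(data.frame(entry_id = integer(0), pfam_id = character(0),
                      pfam_name = character(0), n_seqs = integer(0)))
  }
  key <- paste(best$entry_id, best$pfam_id, sep = "\r")
  tab <- table(key)
  first <- best[!duplicated(key), , drop = FALSE]
  first <- first[order(first$entry_id, first$pfam_id), , drop = FALSE]
  out <- data.frame(
    entry_id = first$entry_id,
    pfam_id = first$pfam_id,
    pfam_name = first$pfam_name,
    n_seqs = as.integer(tab[paste(first$entry_id, first$pfam_id, sep = "\r")]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Count distinct Pfam families per entry
#'
#' The quantity consumed by the low-Pfam validation flag: the number of
#' distinct families among an entry's best annotations.
#'
#' @param best Best-annotation data frame with `entry_id`, `pfam_id`.
#' @param count_mode `"families"` (distinct families, default) or
#'   `"sequences"` (total annotated sequences).
#' @return Named integer vector, entry_id -> count.
#' @export
n_pfams_per_entry <- function(best, count_mode = c("families", "sequences")) {
  count_mode <- match.arg(count_mode)
  if (!nrow(best)) return(setNames(integer(0), character(0)))
  if (count_mode == "families") {
    u <- unique(best[, c("entry_id", "pfam_id")])
    tab <- table(u$entry_id)
  } else {
    tab <- table(best$entry_id)
  }
  setNames(as.integer(tab), names(tab))
}
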