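## Within-taxon redundancy reduction: pool accepted entries' proteins by
## taxid, greedy identity clustering against cluster representatives, and
## stable identifier assignment.

#' Pool protein sequences of accepted entries by taxid
#'
#' Sequences of entries sharing an NCBI taxid are combined into one pool,
#' preserving strain-level diversity (distinct strain taxids stay separate).
#' Rejected entries contribute nothing. Stop symbols (`*`) are stripped from
#' the residues, since downstream identity clustering operates on plain
#' amino acid strings.
#'
#' @param seqs_by_entry Named list entry_id -> FASTA table (`seq_id`,
#'   `residues`).
#' @param metadata Entry metadata with `entry_id`, `tax_id`, `accepted`.
#' @return Named list taxid -> data frame (`aa_id`, `entry_id`, `residues`),
#'   ordered by taxid; within a pool, metadata order then input order.
#' @export
pool_by_taxid <- function(seqs_by_entry, metadata) {
  acc <- metadata[metadata$accepted == "Y", , drop = FALSE]
  if (any(is.na(acc$tax_id))) {
    stop("accepted entry without taxid: ",
         paste(acc$entry_id[is.na(acc$tax_id)], collapse = ", "))
  }
  pools <- list()
  for (i in seq_len(nrow(acc))) {
    eid <- acc$entry_id[i]
    recs <- seqs_by_entry[[as.character(eid)]]
    if (is.null(recs)) stop("no sequences supplied for accepted entry ", eid)
    df <- data.frame(aa_id = recs$seq_id, entry_id = eid,
                     residues = gsub("*", "", recs$residues, fixed = TRUE),
                     stringsAsFactors = FALSE)
    key <- as.character(acc$tax_id[i])
    pools[[key]] <- rbind(pools[[key]], df)
  }
  pools[order(as.integer(names(pools)))]
}

# Global (Needleman-Wunsch) alignment statistics between two amino acid
# strings: BLOSUM62 with affine gaps (open 11, extend 1). Identity is exact
# matches over alignment columns; coverage is the fraction of the shorter
# sequence aligned to a residue of the longer.
align_stats <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cols <- length(p)
  both <- p != "-" & s != "-"
  list(identity = sum(both & p == s) / cols,
       coverage_shorter = sum(both) / min(nchar(a), nchar(b)))
}

#' Greedy identity clustering of a protein pool
#'
#' Sequences are processed in descending length (ties: input order). Each
#' sequence joins the first existing cluster whose representative it matches
#' at identity >= `threshold` with shorter-sequence coverage >= `coverage`,
#' otherwise it founds a new cluster with itself as representative. Identity
#' is exact matches over the columns of a global alignment (BLOSUM62, affine
#' gaps open 11 / extend 1). Deterministic.
#'
#' @param pool Data frame (`aa_id`, `entry_id`, `residues`) from
#'   [pool_by_taxid()].
#' @param threshold Identity threshold in `[0, 1]` (default `0.99`).
#' @param coverage Minimum aligned fraction of the shorter sequence
#'   (default `0.8`).
#' @return Data frame with the pool's columns plus `rep_aa_id`; attribute
#'   `threshold`. Representatives are members of their own clusters.
#' @export
greedy_cluster <- function(pool, threshold = 0.99, coverage = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1, coverage >= 0, coverage <= 1)
  n <- nrow(pool)
  if (!n) {
    pool$rep_aa_id <- character(0)
    attr(pool, "threshold") <- threshold
    return(pool)
  }
  ord <- order(-nchar(pool$residues), seq_len(n))
  rep_of <- character(n)
  rep_idx <- integer(0)              # indices (into pool) of representatives
  rep_exact <- new.env(parent = emptyenv()) # residues -> first rep index
  for (i in ord) {
    seq_i <- pool$residues[i]
    len_i <- nchar(seq_i)
    hit <- rep_exact[[seq_i]]
    if (is.null(hit)) {
      for (r in rep_idx) {
        rep_seq <- pool$residues[r]
        # identity <= min/max length ratio: skip unattainable comparisons
        if (len_i / nchar(rep_seq) < threshold) next
        # when ceil(threshold * maxlen) >= maxlen, a passing alignment must
        # match every column, i.e. the strings are identical -- already
        # handled by the exact-match fast path above
        if (ceiling(threshold * nchar(rep_seq)) >= nchar(rep_seq)) next
        st <- align_stats(rep_seq, seq_i)
        if (st$identity >= threshold && st$coverage_shorter >= coverage) {
          hit <- r
          break
        }
      }
    }
    if (is.null(hit)) {
      rep_idx <- c(rep_idx, i)
      if (is.null(rep_exact[[seq_i]])) rep_exact[[seq_i]] <- i
      hit <- i
    }
    rep_of[i] <- pool$aa_id[hit]
  }
  out <- pool
  out$rep_aa_id <- rep_of
  attr(out, "threshold") <- threshold
  out
}

#' Assign stable identifiers to cluster representatives
#'
#' Identifiers are `"mft"` followed by a zero-padded ten-digit integer,
#' consecutive from `mft0000000001`, ordered by (taxid, entry id of the
#' representative, input order). The mapping is bijective.
#'
#' @param clusters_by_taxid Named list taxid -> clustered pool from
#'   [greedy_cluster()].
#' @return Named character vector representative `aa_id` -> identifier.
#' @export
assign_ids <- function(clusters_by_taxid) {
  reps <- do.call(rbind, lapply(names(clusters_by_taxid), function(tx) {
    cl <- clusters_by_taxid[[tx]]
    r <- cl[cl$aa_id %in% unique(cl$rep_aa_id), , drop = FALSE]
    data.frame(tax_id = as.integer(tx), aa_id = r$aa_id,
               entry_id = r$entry_id, ord = match(r$aa_id, cl$aa_id),
               stringsAsFactors = FALSE)
  }))
  if (is.null(reps) || !nrow(reps)) return(setNames(character(0), character(0)))
  if (anyDuplicated(reps$aa_id)) {
    stop("representative ids are not unique across taxa; ",
         "sequence ids must be globally unique")
  }
  reps <- reps[order(reps$tax_id, reps$entry_id, reps$ord), , drop = FALSE]
  n <- nrow(reps)
  if (n > 1e10 - 1) stop("identifier space exhausted (>= 10^10 sequences)")
  setNames(sprintf("mft%010d", seq_len(n)), reps$aa_id)
}
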