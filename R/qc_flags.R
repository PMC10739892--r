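## Entry validation: the five flag metrics and the curation table with
## acceptance decisions.
##
## Flag semantics (strict inequalities):
##   LOW_SEQS   raw sequence count < min_seqs (default 1200)
##   LOW_PFAMS  distinct Pfam families < min_pfams (default 500), only
##              assigned to entries not already LOW_SEQS
##   FLAG_LASEK external contamination flag carried through verbatim
##   FLAG_VV    external contamination estimate > contam_flag_pct, unless the
##              entry is on the override list (entries whose external
##              estimate is known to rest on a wrong taxid)
##   FLAG_RP63  marker-based contamination estimate > contam_flag_pct

#' Entry ids whose external 100%-contamination reports are overridden
#'
#' External ribosomal-protein screening of these eight entries used the wrong
#' NCBI taxid, so their reported 100% contamination estimates are suppressed
#' rather than flagged.
#' @export
VV_OVERRIDE_ENTRY_IDS <- c(378L, 379L, 380L, 381L, 504L, 505L, 506L, 507L)

CURATION_COLUMNS <- c(
  "entry_id", "marferret_name", "tax_id", "taxID_status", "taxID_notes",
  "n_seqs_raw", "n_pfams", "qc_flag", "flag_Lasek", "VV_contam_pct",
  "flag_VanVlierberghe", "rp63_npfams", "rp63_contam_pct", "flag_rp63",
  "flag_sum", "accepted"
)

#' Default validation thresholds
#'
#' @param min_seqs Minimum raw sequence count (flag below; default 1200).
#' @param min_pfams Minimum distinct Pfam families (flag below; default 500).
#' @param contam_flag_pct Contamination percentage above which an entry is
#'   flagged (default 50).
#' @return Named list of thresholds.
#' @export
qc_config <- function(min_seqs = 1200, min_pfams = 500,
                      contam_flag_pct = 50) {
  stopifnot(min_seqs >= 0, min_pfams >= 0, contam_flag_pct >= 0)
  list(min_seqs = min_seqs, min_pfams = min_pfams,
       contam_flag_pct = contam_flag_pct)
}

#' Apply the validation flags to one entry
#'
#' @param entry_id,marferret_name,tax_id Entry identity fields.
#' @param n_seqs_raw Raw sequence count.
#' @param n_pfams Distinct Pfam families among best annotations.
#' @param rp63_npfams Number of distinct marker families observed (optional).
#' @param rp63_contam_pct Marker-screen contamination estimate (optional).
#' @param lasek_flagged Is the entry flagged by the external ciliate study?
#' @param vv_contam_pct External contamination estimate (optional).
#' @param config Thresholds from [qc_config()].
#' @param vv_override_ids Entry ids whose external estimate is suppressed
#'   (default none; see [VV_OVERRIDE_ENTRY_IDS]).
#' @param taxID_status,taxID_notes Pass-through curation provenance fields.
#' @return One-row curation data frame (see [write_curation()] for the
#'   column schema); `accepted` is `"Y"` iff no flag is set.
#' @export
apply_flags <- function(entry_id, marferret_name, tax_id, n_seqs_raw,
                        n_pfams, rp63_npfams = NA_integer_,
                        rp63_contam_pct = NA_real_, lasek_flagged = FALSE,
                        vv_contam_pct = NA_real_, config = qc_config(),
                        vv_override_ids = integer(0),
                        taxID_status = "Unchanged", taxID_notes = "") {
  qc_flag <- if (n_seqs_raw < config$min_seqs) {
    "LOW_SEQS"
  } else if (!is.na(n_pfams) && n_pfams < config$min_pfams) {
    "LOW_PFAMS"
  } else {
    ""
  }
  flag_lasek <- if (isTRUE(lasek_flagged)) "FLAG_LASEK" else ""
  flag_vv <- if (!is.na(vv_contam_pct) &&
                 vv_contam_pct > config$contam_flag_pct &&
                 !(entry_id %in% vv_override_ids)) "FLAG_VV" else ""
  flag_rp63 <- if (!is.na(rp63_contam_pct) &&
                   rp63_contam_pct > config$contam_flag_pct) {
    "FLAG_RP63"
  } else {
    ""
  }
  flag_sum <- sum(nzchar(c(qc_flag, flag_lasek, flag_vv, flag_rp63)))
  data.frame(
    entry_id = as.integer(entry_id), marferret_name = marferret_name,
    tax_id = as.integer(tax_id), taxID_status = taxID_status,
    taxID_notes = taxID_notes, n_seqs_raw = as.integer(n_seqs_raw),
    n_pfams = as.integer(n_pfams), qc_flag = qc_flag,
    flag_Lasek = flag_lasek, VV_contam_pct = vv_contam_pct,
    flag_VanVlierberghe = flag_vv, rp63_npfams = as.integer(rp63_npfams),
    rp63_contam_pct = rp63_contam_pct, flag_rp63 = flag_rp63,
    flag_sum = as.integer(flag_sum),
    accepted = if (flag_sum == 0L) "Y" else "N",
    stringsAsFactors = FALSE
  )
}

#' Stage entries for the contamination screen
#'
#' Entries flagged LOW_SEQS or LOW_PFAMS are rejected early and excluded
#' from contamination estimation; the rest are eligible.
#'
#' @param metadata Entry metadata with `entry_id`, `n_seqs_raw`.
#' @param n_pfams Named vector entry_id -> distinct family count.
#' @param config Thresholds from [qc_config()].
#' @return List with integer vectors `eligible` and `rejected_early`.
#' @export
stage_entries <- function(metadata, n_pfams, config = qc_config()) {
  np <- n_pfams[as.character(metadata$entry_id)]
  np[is.na(np)] <- 0L
  low_seqs <- metadata$n_seqs_raw < config$min_seqs
  low_pfams <- !low_seqs & np < config$min_pfams
  list(eligible = metadata$entry_id[!(low_seqs | low_pfams)],
       rejected_early = metadata$entry_id[low_seqs | low_pfams])
}

#' Build the curation table for a set of entries
#'
#' Applies [apply_flags()] to every entry and optionally overrides the
#' computed acceptance (overrides are recorded in attribute
#' `accept_overrides` and reported with a message).
#'
#' @param metadata Entry metadata.
#' @param n_pfams Named vector entry_id -> distinct family count.
#' @param rp_report Optional contamination report from [rp_screen()].
#' @param lasek_ids Entry ids flagged by the external ciliate study.
#' @param vv_contam External estimates: named numeric vector by entry_id.
#' @param config Thresholds from [qc_config()].
#' @param vv_override_ids See [apply_flags()].
#' @param accept_overrides Named character vector entry_id -> "Y"/"N"
#'   overriding the computed decision.
#' @return Curation data frame, one row per entry, column order fixed.
#' @export
build_curation <- function(metadata, n_pfams, rp_report = NULL,
                           lasek_ids = integer(0), vv_contam = numeric(0),
                           config = qc_config(),
                           vv_override_ids = integer(0),
                           accept_overrides = character(0)) {
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    key <- as.character(md$entry_id)
    rp_np <- NA_integer_; rp_pct <- NA_real_
    if (!is.null(rp_report) && key %in% as.character(rp_report$entry_id)) {
      r <- rp_report[as.character(rp_report$entry_id) == key, ]
      rp_np <- r$n_pfams[1L]; rp_pct <- r$contam_pct[1L]
    }
    apply_flags(
      entry_id = md$entry_id, marferret_name = md$marferret_name,
      tax_id = md$tax_id, n_seqs_raw = md$n_seqs_raw,
      n_pfams = unname(n_pfams[key]) %||% NA_integer_,
      rp63_npfams = rp_np, rp63_contam_pct = rp_pct,
      lasek_flagged = md$entry_id %in% lasek_ids,
      vv_contam_pct = if (key %in% names(vv_contam)) vv_contam[[key]]
                      else NA_real_,
      config = config, vv_override_ids = vv_override_ids,
      taxID_status = md$taxID_status %||% "Unchanged",
      taxID_notes = md$taxID_notes %||% ""
    )
  })
  out <- do.call(rbind, rows)
  if (length(accept_overrides)) {
    hit <- names(accept_overrides)[names(accept_overrides) %in%
                                     as.character(out$entry_id)]
    for (k in hit) {
      out$accepted[as.character(out$entry_id) == k] <- accept_overrides[[k]]
    }
    message("acceptance overridden for entr",
            if (length(hit) == 1L) "y " else "ies ",
            paste(hit, collapse = ", "))
    attr(out, "accept_overrides") <- accept_overrides[hit]
  }
  out[, CURATION_COLUMNS]
}

#' Write the entry curation table
#'
#' Column order and names follow the published curation schema exactly.
#'
#' @param records Curation data frame from [build_curation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curation <- function(records, path) {
  stopifnot(identical(names(records), CURATION_COLUMNS))
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a curation table written by [write_curation()]
#' @param path CSV path.
#' @return Curation data frame.
#' @export
read_curation <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(qc_flag = "character",
                                 flag_Lasek = "character",
                                 flag_VanVlierberghe = "character",
                                 flag_rp63 = "character",
                                 taxID_status = "character",
                                 taxID_notes = "character"))
  miss <- setdiff(CURATION_COLUMNS, names(out))
  if (length(miss)) stop("curation file missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("qc_flag", "flag_Lasek", "flag_VanVlierberghe", "flag_rp63",
                "taxID_status", "taxID_notes")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  out[, CURATION_COLUMNS]
}
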