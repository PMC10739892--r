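## Readers and writers for the standard formats the pipeline touches:
## FASTA, NCBI taxdump, HMMER domain tables and HMM profile headers,
## BLAST-style tabular hit tables, and the entry metadata CSV schema.

NT_ALPHABET <- "ACGTUMRWSYKVHDBN"
AA_ALPHABET_FF <- "ACDEFGHIKLMNPQRSTVWYBJZUOX*"

#' Read a FASTA file into a record table
#'
#' Records are returned in file order. The sequence identifier is the first
#' whitespace-delimited token of the header line; the remainder of the header
#' is kept as the description. Residues are upper-cased and validated against
#' the declared alphabet (IUPAC nucleotide codes, or amino acids including
#' `*` for stop and `X` for unknown). Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param alphabet `"amino-acid"` or `"nucleotide"`.
#' @return A data frame with columns `seq_id`, `description`, `residues` and
#'   attribute `alphabet`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a toy record", "MKLV"), f)
#' read_fasta(f, "amino-acid")
#' @export
read_fasta <- function(path, alphabet = c("amino-acid", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  legal <- if (alphabet == "nucleotide") NT_ALPHABET else AA_ALPHABET_FF
  bad <- !grepl(paste0("^[", gsub("\\*", "\\\\*", legal), "]+$"), residues)
  if (any(bad)) {
    i <- which(bad)[1L]
    sym <- setdiff(strsplit(residues[i], "")[[1L]],
                   strsplit(legal, "")[[1L]])[1L]
    stop("record '", seq_id[i], "' contains symbol '", sym,
         "' illegal for alphabet ", alphabet)
  }
  if (any(nchar(residues) == 0L)) {
    stop("record '", seq_id[which(nchar(residues) == 0L)[1L]],
         "' has empty residues")
  }
  out <- data.frame(seq_id = seq_id, description = description,
                    residues = residues, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a FASTA record table
#'
#' Inverse of [read_fasta()]: round-tripping preserves identifier,
#' description and residues for every record. One sequence line per record.
#'
#' @param records Data frame with `seq_id`, `description`, `residues`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("seq_id", "residues") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  hdr <- ifelse(is.na(desc) | desc == "",
                paste0(">", records$seq_id),
                paste0(">", records$seq_id, " ", desc))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(rbind(hdr, records$residues), con)
  invisible(path)
}

#' Parse NCBI taxdump nodes/names files into a taxonomy tree
#'
#' Reads the pipe-and-tab delimited `nodes.dmp` / `names.dmp` dialect.
#' Scientific names are taken from the names file. The root is the node that
#' is its own parent (conventionally taxid 1). An optional `merged.dmp` maps
#' retired taxids onto their replacements.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @param merged_path Optional path to `merged.dmp`.
#' @return An object of class `taxonomy_tree`: a list with integer-named
#'   vectors `parent`, `rank`, `name`, the `root` taxid, and a `merged` map.
#' @export
parse_taxdump <- function(nodes_path, names_path, merged_path = NULL) {
  split_dmp <- function(lines) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nf <- split_dmp(read_lines_any(nodes_path))
  taxid <- vapply(nf, function(x) as.integer(x[1L]), integer(1))
  parent <- vapply(nf, function(x) as.integer(x[2L]), integer(1))
  rank <- vapply(nf, function(x) x[3L], character(1))
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid(s) in nodes file: ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  }
  orphan <- setdiff(parent, taxid)
  if (length(orphan)) {
    bad <- taxid[parent %in% orphan]
    stop("orphan taxid(s) with dangling parents: ",
         paste(bad, collapse = ", "))
  }
  key <- as.character(taxid)
  parent <- setNames(parent, key)
  rank <- setNames(rank, key)

  name <- setNames(rep(NA_character_, length(taxid)), key)
  for (x in split_dmp(read_lines_any(names_path))) {
    if (length(x) >= 4L && trimws(x[4L]) == "scientific name") {
      name[x[1L]] <- trimws(x[2L])
    }
  }

  merged <- integer(0)
  if (!is.null(merged_path) && file.exists(merged_path)) {
    mm <- split_dmp(read_lines_any(merged_path))
    merged <- setNames(vapply(mm, function(x) as.integer(x[2L]), integer(1)),
                       vapply(mm, function(x) x[1L], character(1)))
  }

  root <- taxid[taxid == parent[key]]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (node that is its own parent); ",
         "found ", length(root))
  }
  structure(list(parent = parent, rank = rank, name = name,
                 root = root, merged = merged),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", length(x$parent), "nodes, root =", x$root, "\n")
  invisible(x)
}

#' Parse a HMMER3 `--domtblout` domain table
#'
#' Comment lines (`#`) are skipped. Each data row yields one hit using the
#' target (sequence) name, the query (Pfam family) name, the query accession
#' with any `.N` version suffix stripped, and the full-sequence E-value and
#' bitscore columns.
#'
#' @param path Path to a domain table file (optionally gzipped).
#' @return Data frame with columns `seq_id`, `pfam_id`, `pfam_name`,
#'   `bitscore`, `evalue`, in file order.
#' @export
parse_domtbl <- function(path) {
  lines <- read_lines_any(path)
  data <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  rows <- lapply(data, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 22L) {
      stop("malformed domain-table row at line ", i, ": ",
           length(f), " fields (expected >= 22)")
    }
    f
  })
  if (!length(rows)) {
    return(data.frame(seq_id = character(0), pfam_id = character(0),
                      pfam_name = character(0), bitscore = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    seq_id = vapply(rows, `[`, "", 1L),
    pfam_id = strip_pfam_version(vapply(rows, `[`, "", 5L)),
    pfam_name = vapply(rows, `[`, "", 4L),
    bitscore = as.numeric(vapply(rows, `[`, "", 8L)),
    evalue = as.numeric(vapply(rows, `[`, "", 7L)),
    stringsAsFactors = FALSE
  )
}

strip_pfam_version <- function(x) sub("\\.\\d+$", "", x)

#' Extract trusted-cutoff bitscores from a text HMM profile file
#'
#' Scans HMMER3 text profiles for `ACC` / `TC` header lines and maps each
#' family accession (version stripped) to its sequence-level trusted cutoff —
#' the first of the two TC values. Profiles lacking a TC line are recorded
#' with `NA` and reported in one warning.
#'
#' @param path Path to a concatenated text HMM file.
#' @return Named numeric vector (pfam_id -> trusted cutoff); families without
#'   a cutoff carry `NA` and are listed in attribute `missing_tc`.
#' @export
parse_hmm_thresholds <- function(path) {
  lines <- read_lines_any(path)
  acc <- NA_character_
  saw_tc <- TRUE
  ids <- character(0); tc <- numeric(0); missing <- character(0)
  flush <- function() {
    if (!is.na(acc) && !saw_tc) missing <<- c(missing, acc)
  }
  for (ln in lines) {
    if (startsWith(ln, "ACC ")) {
      flush()
      acc <- strip_pfam_version(trimws(sub("^ACC\\s+", "", ln)))
      saw_tc <- FALSE
      ids <- c(ids, acc)
      tc <- c(tc, NA_real_)
    } else if (startsWith(ln, "TC ") && !is.na(acc)) {
      val <- strsplit(trimws(sub("^TC\\s+", "", ln)), "\\s+")[[1L]][1L]
      tc[length(tc)] <- as.numeric(sub(";$", "", val))
      saw_tc <- TRUE
    } else if (startsWith(ln, "//")) {
      flush()
      acc <- NA_character_
      saw_tc <- TRUE
    }
  }
  flush()
  if (anyDuplicated(ids)) stop("duplicate ACC in HMM file: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  out <- setNames(tc, ids)
  if (length(missing)) {
    warning("profiles without TC line: ", paste(missing, collapse = ", "))
  }
  attr(out, "missing_tc") <- missing
  out
}

#' Parse an alignment hit table with subject taxon IDs
#'
#' Accepts either the 4-column variant `(query_id, subject_taxid, bitscore,
#' evalue)` or 12-column BLAST tabular output, in which case `taxid_map`
#' (subject id -> taxid) is required; 12-column rows whose subject cannot be
#' mapped are dropped and counted in attribute `n_dropped`. Rows that fail
#' numeric parsing are an error, never silently skipped.
#'
#' @param path Path to the hit table (optionally gzipped).
#' @param taxid_map Named integer vector mapping subject sequence ids to
#'   taxids (12-column input only).
#' @return Data frame `query_id`, `subject_taxid`, `bitscore`, `evalue`, with
#'   attribute `n_dropped`.
#' @export
parse_hit_table <- function(path, taxid_map = NULL) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(query_id = character(0), subject_taxid = integer(0),
                      bitscore = numeric(0), evalue = numeric(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !(ncols %in% c(4L, 12L))) {
    stop("hit table must have uniformly 4 or 12 columns; saw ",
         paste(sort(unique(lengths(fields))), collapse = ", "))
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric ", what, " in hit table: '",
                       x[which(is.na(v))[1L]], "'")
    v
  }
  n_dropped <- 0L
  if (ncols == 4L) {
    out <- data.frame(
      query_id = vapply(fields, `[`, "", 1L),
      subject_taxid = as.integer(num(vapply(fields, `[`, "", 2L), "taxid")),
      bitscore = num(vapply(fields, `[`, "", 3L), "bitscore"),
      evalue = num(vapply(fields, `[`, "", 4L), "evalue"),
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(taxid_map)) {
      stop("12-column BLAST tabular input requires a taxid_map")
    }
    sseqid <- vapply(fields, `[`, "", 2L)
    taxid <- unname(taxid_map[sseqid])
    keep <- !is.na(taxid)
    n_dropped <- sum(!keep)
    fields <- fields[keep]
    out <- data.frame(
      query_id = vapply(fields, `[`, "", 1L),
      subject_taxid = as.integer(taxid[keep]),
      bitscore = num(vapply(fields, `[`, "", 12L), "bitscore"),
      evalue = num(vapply(fields, `[`, "", 11L), "evalue"),
      stringsAsFactors = FALSE
    )
  }
  if (any(out$evalue < 0)) stop("negative E-value in hit table")
  attr(out, "n_dropped") <- n_dropped
  out
}

ENTRY_METADATA_REQUIRED <- c("entry_id", "marferret_name", "tax_id",
                             "data_type", "seq_type", "n_seqs_raw", "accepted")

#' Read an entry metadata table
#'
#' Comma-separated with a header row. The required columns are
#' `entry_id`, `marferret_name`, `tax_id`, `data_type` (TSA, genome, SAG or
#' SAT), `seq_type` (nt or aa), `n_seqs_raw` and `accepted` (Y/N); any extra
#' provenance columns are preserved untouched. Missing required columns,
#' duplicate entry ids, or out-of-vocabulary enum values are errors.
#'
#' @param path Path to the metadata CSV (optionally gzipped).
#' @return Data frame, one row per entry.
#' @export
read_entry_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(ENTRY_METADATA_REQUIRED, names(md))
  if (length(miss)) {
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(md$entry_id)) {
    stop("duplicate entry_id in metadata: ",
         paste(unique(md$entry_id[duplicated(md$entry_id)]), collapse = ", "))
  }
  if (!all(md$data_type %in% c("TSA", "genome", "SAG", "SAT"))) {
    stop("data_type must be one of TSA, genome, SAG, SAT")
  }
  if (!all(md$seq_type %in% c("nt", "aa"))) stop("seq_type must be nt or aa")
  if (!all(md$accepted %in% c("Y", "N"))) stop("accepted must be Y or N")
  md$entry_id <- as.integer(md$entry_id)
  md$tax_id <- as.integer(md$tax_id)
  md$n_seqs_raw <- as.integer(md$n_seqs_raw)
  md
}

#' Write an entry metadata table
#' @param md Metadata data frame (see [read_entry_metadata()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_entry_metadata <- function(md, path) {
  write.csv(md, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
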