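## Six-frame translation and longest-ORF frame selection for nucleotide
## entries. Frames 1-3 are offsets 0-2 on the forward strand; frames 4-6 are
## offsets 0-2 on the reverse complement (a fixed, length-independent
## convention). An ORF is a maximal stop-free run; 'X' does not break a run
## and no start codon is required, since transcriptome contigs are commonly
## 5'-truncated.

# Translate one codon under a genetic code, resolving IUPAC ambiguity codes:
# if every completion of a degenerate codon encodes the same amino acid that
# amino acid is emitted, otherwise 'X'. Results are memoised per code table.
codon_cache <- new.env(parent = emptyenv())

translate_codon <- function(codon, code) {
  key <- paste0(attr(code, "ff_code_id") %||% "std", ":", codon)
  hit <- codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- unname(code[codon])
  if (length(aa) != 1L || is.na(aa)) {
    bases <- strsplit(codon, "")[[1L]]
    expand <- lapply(bases, function(b) {
      e <- Biostrings::IUPAC_CODE_MAP[[b]]
      if (is.null(e)) stop("illegal nucleotide symbol '", b, "'")
      strsplit(e, "")[[1L]]
    })
    combos <- do.call(paste0, expand.grid(expand, stringsAsFactors = FALSE))
    aas <- unique(unname(code[combos]))
    aa <- if (length(aas) == 1L && !is.na(aas)) aas else "X"
  }
  codon_cache[[key]] <- aa
  aa
}

translate_offset <- function(nt, offset, code) {
  l <- nchar(nt)
  n_codon <- (l - offset) %/% 3L
  if (n_codon <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  paste0(vapply(codons, translate_codon, "", code = code), collapse = "")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames 1-3 read the forward strand at offsets 0-2; frames 4-6 read the
#' reverse complement at offsets 0-2. Stop codons render `*`; degenerate
#' codons whose completions all encode one amino acid render that amino acid,
#' otherwise `X`. The standard genetic code is the default.
#'
#' @param residues Nucleotide string (IUPAC codes allowed; `U` is read as `T`).
#' @param code Named character vector codon -> amino acid
#'   (default `Biostrings::GENETIC_CODE`).
#' @return Data frame with columns `frame` (1-6), `peptide`,
#'   `longest_orf_len`.
#' @examples
#' six_frame_translate("ATGAAATAA")
#' @export
six_frame_translate <- function(residues, code = Biostrings::GENETIC_CODE) {
  if (!is_string(residues) || nchar(residues) == 0L) {
    stop("cannot translate an empty sequence")
  }
  nt <- chartr("U", "T", toupper(residues))
  rc <- revcomp(nt)
  pep <- c(
    vapply(0:2, function(k) translate_offset(nt, k, code), ""),
    vapply(0:2, function(k) translate_offset(rc, k, code), "")
  )
  data.frame(frame = 1:6, peptide = pep,
             longest_orf_len = vapply(pep, longest_orf_len, integer(1),
                                      USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Length of the longest open reading frame in a peptide
#'
#' An ORF here is a maximal stop-free substring: `*` breaks a run, `X` does
#' not, and no start codon is required. All-stop strings score 0.
#'
#' @param peptide Amino-acid string (may contain `*` and `X`).
#' @return Integer ORF length.
#' @examples
#' longest_orf_len("MK*LLLL") # 4
#' @export
longest_orf_len <- function(peptide) {
  if (!nzchar(peptide)) return(0L)
  runs <- strsplit(peptide, "*", fixed = TRUE)[[1L]]
  if (!length(runs)) return(0L)
  max(nchar(runs))
}

#' Select the translation frame with the longest open reading frame
#'
#' Translates in six frames and returns the frame maximising
#' [longest_orf_len()]; ties go to the lowest frame number. The full frame
#' peptide is retained (not trimmed to the ORF) unless `orf_only = TRUE`, in
#' which case the peptide is the longest stop-free substring itself.
#'
#' @param residues Nucleotide string.
#' @param code Genetic code table.
#' @param orf_only Keep only the ORF substring instead of the whole frame.
#' @return One-row data frame `frame`, `peptide`, `longest_orf_len`.
#' @export
select_frame <- function(residues, code = Biostrings::GENETIC_CODE,
                         orf_only = FALSE) {
  tr <- six_frame_translate(residues, code)
  best <- which.max(tr$longest_orf_len) # first maximum = lowest frame
  out <- tr[best, , drop = FALSE]
  rownames(out) <- NULL
  if (orf_only) {
    runs <- strsplit(out$peptide, "*", fixed = TRUE)[[1L]]
    out$peptide <- runs[which.max(nchar(runs))]
  }
  out
}

#' Translate every nucleotide record of a FASTA table, keeping the best frame
#'
#' Applies [select_frame()] to each record. Sequence ids are preserved; the
#' selected frame is appended to the description as `frame=<k>`.
#'
#' @param records Nucleotide FASTA table from [read_fasta()].
#' @inheritParams select_frame
#' @return Amino-acid FASTA table (columns `seq_id`, `description`,
#'   `residues`) plus a `frame` column.
#' @export
translate_records <- function(records, code = Biostrings::GENETIC_CODE,
                              orf_only = FALSE) {
  picks <- lapply(records$residues, select_frame, code = code,
                  orf_only = orf_only)
  frame <- vapply(picks, function(p) p$frame, integer(1))
  desc <- records$description %||% rep("", nrow(records))
  out <- data.frame(
    seq_id = records$seq_id,
    description = trimws(paste(desc, paste0("frame=", frame))),
    residues = vapply(picks, function(p) p$peptide, ""),
    frame = frame,
    stringsAsFactors = FALSE
  )
  attr(out, "alphabet") <- "amino-acid"
  out
}
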