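## Deterministic generators for every input the pipeline consumes: a toy
## taxonomy with lineage bins, per-entry proteomes with planted Pfam domain
## content (emitted as HMMER-style domain tables straddling trusted cutoffs),
## contamination-mixed marker hit tables, and CDS-in-flanking-sequence
## nucleotide fixtures. Each generator draws from its own sub-stream of the
## master seed, so adding a generator never perturbs another, and every
## output is a pure function of the spec.

#' Specification of a synthetic fixture corpus
#'
#' Defaults describe a small but complete corpus: two eukaryote lineages of
#' three species each, two transcriptome entries per species (one at the
#' species taxid, one at a strain taxid; one of the two distributed as
#' nucleotide), one genome-type entry, 60 proteins per entry of which 20 are
#' ribosomal markers, a low 5% background cross-contamination rate, and
#' 300 nt planted coding sequences inside 200 nt flanks.
#'
#' @param seed Master seed; every generator derives its own sub-stream.
#' @param n_lineages,species_per_lineage,entries_per_species Corpus shape.
#' @param seqs_per_entry Proteins per entry.
#' @param markers_per_entry Of these, how many carry ribosomal marker
#'   families.
#' @param n_marker_families,n_other_families Size of the planted family
#'   pools.
#' @param rho Cross-contamination mixing fraction in `[0, 1]`.
#' @param contaminant_lineage Index of the lineage contaminating others
#'   (default: the next lineage, cyclically).
#' @param subthreshold_frac Fraction of non-marker sequences whose domain
#'   hit is planted below the family's trusted cutoff.
#' @param dup_frac Fraction of sequences duplicated with one substitution
#'   (near-identical cluster seeds).
#' @param include_genome_entry Add one genome-type entry (excluded from CTG
#'   matrices by construction).
#' @param cds_length,flank_length Planted-CDS fixture geometry (nt).
#' @param entry_overrides Named list (by entry index, as character) of
#'   per-entry overrides: any of `n_seqs`, `rho`, `data_type`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_lineages = 2, species_per_lineage = 3,
                         entries_per_species = 2, seqs_per_entry = 60,
                         markers_per_entry = 20, n_marker_families = 8,
                         n_other_families = 12, rho = 0.05,
                         contaminant_lineage = NULL,
                         subthreshold_frac = 0.1, dup_frac = 0.1,
                         include_genome_entry = TRUE,
                         cds_length = 300, flank_length = 200,
                         entry_overrides = list()) {
  stopifnot(n_lineages >= 1, species_per_lineage >= 1,
            species_per_lineage <= 90,
            entries_per_species >= 1, seqs_per_entry >= 1,
            markers_per_entry >= 1, markers_per_entry <= seqs_per_entry,
            rho >= 0, rho <= 1, cds_length %% 3 == 0, cds_length >= 30,
            flank_length >= 12)
  structure(list(
    seed = seed, n_lineages = n_lineages,
    species_per_lineage = species_per_lineage,
    entries_per_species = entries_per_species,
    seqs_per_entry = seqs_per_entry, markers_per_entry = markers_per_entry,
    n_marker_families = n_marker_families,
    n_other_families = n_other_families, rho = rho,
    contaminant_lineage = contaminant_lineage,
    subthreshold_frac = subthreshold_frac, dup_frac = dup_frac,
    include_genome_entry = include_genome_entry,
    cds_length = cds_length, flank_length = flank_length,
    entry_overrides = entry_overrides
  ), class = "fixture_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

dmp_line <- function(...) paste(paste(..., sep = "\t|\t"), "|", sep = "\t")

#' Generate a toy taxonomy with lineage bins
#'
#' Builds a rooted tree (root, Eukaryota, Bacteria, Archaea, Viruses) with
#' one clade node per lineage under Eukaryota, species below lineages and
#' one strain below each species. Lineage names follow the default bin
#' vocabulary; extra lineages beyond it are numbered. Writes `nodes.dmp` and
#' `names.dmp` in taxdump dialect plus a bin config, all byte-deterministic.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List: `tree` (parsed back through [parse_taxdump()]), `bins`
#'   (a `bin_set` of the lineages plus Bacteria/Archaea/Viruses), `species`
#'   and `strains` data frames, and file `paths`.
#' @export
make_taxonomy <- function(spec, dir = tempfile("tax")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lng_names <- if (spec$n_lineages <= 16L) {
    RP63_BIN_NAMES[seq_len(spec$n_lineages)]
  } else {
    c(RP63_BIN_NAMES[1:16],
      paste0("Lineage", 17:spec$n_lineages))
  }
  nodes <- list(dmp_line(1, 1, "no rank"),
                dmp_line(2, 1, "superkingdom"),
                dmp_line(3, 1, "superkingdom"),
                dmp_line(4, 1, "superkingdom"),
                dmp_line(5, 1, "superkingdom"))
  names_l <- list(dmp_line(1, "root", "", "scientific name"),
                  dmp_line(2, "Eukaryota", "", "scientific name"),
                  dmp_line(3, "Bacteria", "", "scientific name"),
                  dmp_line(4, "Archaea", "", "scientific name"),
                  dmp_line(5, "Viruses", "", "scientific name"))
  species <- NULL; strains <- NULL
  for (i in seq_len(spec$n_lineages)) {
    ltx <- 10L + i
    nodes <- c(nodes, dmp_line(ltx, 2, "clade"))
    names_l <- c(names_l, dmp_line(ltx, lng_names[i], "", "scientific name"))
    for (j in seq_len(spec$species_per_lineage)) {
      stx <- 100L + (i - 1L) * 200L + j
      utx <- stx + 90L # strain node
      sp_name <- paste0(lng_names[i], "_sp", j)
      nodes <- c(nodes, dmp_line(stx, ltx, "species"),
                 dmp_line(utx, stx, "strain"))
      names_l <- c(names_l,
                   dmp_line(stx, sp_name, "", "scientific name"),
                   dmp_line(utx, paste0(sp_name, "_strainA"), "",
                            "scientific name"))
      species <- rbind(species, data.frame(
        taxid = stx, lineage_idx = i, lineage_taxid = ltx,
        lineage = lng_names[i], name = sp_name, stringsAsFactors = FALSE))
      strains <- rbind(strains, data.frame(
        taxid = utx, species_taxid = stx, stringsAsFactors = FALSE))
    }
  }
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(unlist(nodes), nodes_path)
  writeLines(unlist(names_l), names_path)
  bins_path <- file.path(dir, "bins.cfg")
  bin_names <- c(lng_names, "Bacteria", "Archaea", "Viruses")
  bin_taxids <- c(10L + seq_len(spec$n_lineages), 3L, 4L, 5L)
  writeLines(paste(bin_names, bin_taxids, sep = "\t"), bins_path)
  lineages_path <- file.path(dir, "lineages.cfg")
  writeLines(paste(lng_names, 10L + seq_len(spec$n_lineages), sep = "\t"),
             lineages_path)
  tree <- parse_taxdump(nodes_path, names_path)
  list(tree = tree, bins = read_bin_config(tree, bins_path),
       species = species, strains = strains,
       paths = list(nodes = nodes_path, names = names_path,
                    bins = bins_path, lineages = lineages_path))
}

# Planted family pools: marker families carry ribosomal-style names, the
# rest generic domain names. Trusted cutoffs are drawn once per spec.
make_families <- function(spec) {
  n_m <- spec$n_marker_families
  n_o <- spec$n_other_families
  tc <- with_seed(substream_seed(spec$seed, "trusted_cutoffs"),
                  round(runif(n_m + n_o, 20, 30), 1))
  data.frame(
    pfam_id = c(sprintf("PF9%04d", seq_len(n_m)),
                sprintf("PF8%04d", seq_len(n_o))),
    pfam_name = c(paste0("Ribosomal_S", seq_len(n_m)),
                  paste0("Domain_", seq_len(n_o))),
    marker = rep(c(TRUE, FALSE), c(n_m, n_o)),
    tc = tc,
    stringsAsFactors = FALSE
  )
}

write_hmm_thresholds_file <- function(families, path) {
  blocks <- unlist(lapply(seq_len(nrow(families)), function(i) {
    c("HMMER3/f [3.3 | synthetic]",
      paste("NAME ", families$pfam_name[i]),
      paste0("ACC   ", families$pfam_id[i], ".1"),
      sprintf("TC    %.2f %.2f;", families$tc[i], families$tc[i]),
      "//")
  }))
  writeLines(blocks, path)
  invisible(path)
}

random_peptide <- function(len) {
  paste0(sample(AA20, len, replace = TRUE), collapse = "")
}

# codon table inverted once for reverse-translation
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(peptide, cod_by_aa, add_stop = TRUE) {
  aas <- strsplit(peptide, "")[[1L]]
  codons <- vapply(aas, function(a) {
    opts <- cod_by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste0(paste0(codons, collapse = ""), if (add_stop) "TAA" else "")
}

write_domtbl_file <- function(rows, path) {
  hdr <- c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
           "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
           "# synthetic domain table")
  ftr <- c("#", "# Program:         hmmsearch", "# Version:         3.4",
           "# Pipeline mode:   SEARCH", "# Query file:      synthetic.hmm",
           "# Target file:     synthetic.faa", "# Option settings: --domtblout",
           "# Current dir:     .", "# Date:            -", "# [ok]")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    paste(r$seq_id, "-", r$tlen, r$pfam_name, paste0(r$pfam_id, ".1"),
          r$qlen, format(r$evalue, scientific = TRUE, digits = 3),
          sprintf("%.1f", r$bitscore), "0.1", 1, 1,
          format(r$evalue, scientific = TRUE, digits = 3),
          format(r$evalue, scientific = TRUE, digits = 3),
          sprintf("%.1f", r$bitscore), "0.1",
          1, r$qlen, 1, r$tlen, 1, r$tlen, "0.95", "synthetic")
  }, "")
  writeLines(c(hdr, body, ftr), path)
  invisible(path)
}

#' Generate per-entry proteomes, metadata, and domain tables
#'
#' For every entry: amino-acid sequences with one planted family each
#' (markers first, then generic domains, a tail of near-duplicate sequences
#' for clustering), a HMMER-style domain table whose scores straddle the
#' trusted cutoffs (a configurable fraction of non-marker hits are planted
#' below cutoff), and — for nucleotide entries — a coding-sequence FASTA
#' built by reverse-translation. Ground truth (planted family and
#' sub-threshold status per sequence) is recorded.
#'
#' @param spec A [fixture_spec()].
#' @param taxonomy Output of [make_taxonomy()].
#' @param dir Corpus output directory.
#' @return List: `metadata` data frame, `families`, `truth` (per-entry list),
#'   and `paths` (per-entry FASTA/domtbl plus the thresholds file).
#' @export
make_entries <- function(spec, taxonomy, dir = tempfile("entries")) {
  dir.create(file.path(dir, "entries"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "domtbl"), showWarnings = FALSE, recursive = TRUE)
  families <- make_families(spec)
  thr_path <- file.path(dir, "hmm_profiles.txt")
  write_hmm_thresholds_file(families, thr_path)
  cod <- codons_by_aa()

  plan <- list()
  eid <- 0L
  for (si in seq_len(nrow(taxonomy$species))) {
    sp <- taxonomy$species[si, ]
    strain <- taxonomy$strains$taxid[taxonomy$strains$species_taxid ==
                                       sp$taxid]
    for (k in seq_len(spec$entries_per_species)) {
      eid <- eid + 1L
      plan[[eid]] <- list(
        entry_id = eid,
        tax_id = if (k %% 2L == 1L) sp$taxid else strain[1L],
        lineage_idx = sp$lineage_idx,
        data_type = "TSA",
        seq_type = if (k %% 2L == 0L) "nt" else "aa",
        name = paste0(sp$name, if (k %% 2L == 0L) "_strainA" else "",
                      "_e", k)
      )
    }
  }
  if (isTRUE(spec$include_genome_entry)) {
    eid <- eid + 1L
    sp <- taxonomy$species[1L, ]
    plan[[eid]] <- list(entry_id = eid, tax_id = sp$taxid,
                        lineage_idx = sp$lineage_idx, data_type = "genome",
                        seq_type = "aa", name = paste0(sp$name, "_genome"))
  }

  md_rows <- list(); truth <- list(); paths <- list()
  for (p in plan) {
    ov <- spec$entry_overrides[[as.character(p$entry_id)]] %||% list()
    n_seqs <- ov$n_seqs %||% spec$seqs_per_entry
    data_type <- ov$data_type %||% p$data_type
    n_mark <- min(spec$markers_per_entry, n_seqs)
    n_dup <- min(floor(spec$dup_frac * n_seqs), n_seqs - n_mark)

    ent <- with_seed(substream_seed(spec$seed, paste0("entry", p$entry_id)), {
      seq_id <- sprintf("e%d_s%04d", p$entry_id, seq_len(n_seqs))
      mk <- families[families$marker, ]
      ot <- families[!families$marker, ]
      fam_idx <- integer(n_seqs)
      fam_idx[seq_len(n_mark)] <- which(families$marker)[
        rep_len(seq_len(nrow(mk)), n_mark)]
      n_plain <- n_seqs - n_mark - n_dup
      if (n_plain > 0L) {
        fam_idx[n_mark + seq_len(n_plain)] <- which(!families$marker)[
          rep_len(seq_len(nrow(ot)), n_plain)]
      }
      residues <- vapply(seq_len(n_seqs - n_dup),
                         function(i) random_peptide(sample(80:120, 1L)), "")
      if (n_dup > 0L) {
        # near-duplicates of the first n_dup sequences: one substitution
        src <- seq_len(n_dup)
        dups <- vapply(src, function(i) {
          s <- strsplit(residues[i], "")[[1L]]
          pos <- sample.int(length(s), 1L)
          s[pos] <- sample(setdiff(AA20, s[pos]), 1L)
          paste0(s, collapse = "")
        }, "")
        residues <- c(residues, dups)
        fam_idx[n_seqs - n_dup + src] <- fam_idx[src]
      }
      fam <- families[fam_idx, ]
      # sub-threshold planting on non-marker, non-duplicate sequences
      cand <- which(!fam$marker & seq_len(n_seqs) <= n_seqs - n_dup)
      n_sub <- floor(spec$subthreshold_frac * length(cand))
      sub <- if (n_sub > 0L) sort(sample(cand, n_sub)) else integer(0)
      score <- fam$tc + 15 + runif(n_seqs, 0, 10)
      score[sub] <- fam$tc[sub] - runif(length(sub), 1, 5)
      rows <- data.frame(
        seq_id = seq_id, pfam_id = fam$pfam_id, pfam_name = fam$pfam_name,
        bitscore = round(score, 1),
        evalue = 10^-runif(n_seqs, 10, 40),
        tlen = nchar(residues), qlen = 100L,
        stringsAsFactors = FALSE
      )
      # secondary weaker hits on a fifth of the well-scored sequences,
      # exercising best-per-sequence reduction
      sec_i <- setdiff(seq_len(n_seqs), sub)
      sec_i <- sec_i[sec_i %% 5L == 0L]
      if (length(sec_i)) {
        alt <- families[((fam_idx[sec_i]) %% nrow(families)) + 1L, ]
        rows <- rbind(rows, data.frame(
          seq_id = seq_id[sec_i], pfam_id = alt$pfam_id,
          pfam_name = alt$pfam_name, bitscore = round(alt$tc + 0.5, 1),
          evalue = 10^-runif(length(sec_i), 6, 9),
          tlen = nchar(residues)[sec_i], qlen = 100L,
          stringsAsFactors = FALSE
        ))
        rows <- rows[order(match(rows$seq_id, seq_id)), ]
      }
      fasta <- data.frame(seq_id = seq_id, description = "",
                          residues = residues, stringsAsFactors = FALSE)
      nt_fasta <- NULL
      if ((ov$seq_type %||% p$seq_type) == "nt") {
        nt_fasta <- data.frame(
          seq_id = seq_id, description = "",
          residues = vapply(residues, reverse_translate, "",
                            cod_by_aa = cod, USE.NAMES = FALSE),
          stringsAsFactors = FALSE)
      }
      list(fasta = fasta, nt_fasta = nt_fasta, rows = rows,
           planted = setNames(fam$pfam_id, seq_id),
           subthreshold = seq_id[sub])
    })

    seq_type <- ov$seq_type %||% p$seq_type
    fa_path <- file.path(dir, "entries",
                         sprintf("entry_%d.%s", p$entry_id,
                                 if (seq_type == "nt") "fna" else "faa"))
    if (seq_type == "nt") {
      write_fasta(ent$nt_fasta, fa_path)
    } else {
      write_fasta(ent$fasta, fa_path)
    }
    dt_path <- file.path(dir, "domtbl",
                         sprintf("entry_%d.domtblout.tab", p$entry_id))
    write_domtbl_file(ent$rows, dt_path)

    md_rows[[p$entry_id]] <- data.frame(
      entry_id = p$entry_id, marferret_name = p$name, tax_id = p$tax_id,
      data_type = data_type, seq_type = seq_type, n_seqs_raw = n_seqs,
      accepted = "Y", stringsAsFactors = FALSE)
    truth[[as.character(p$entry_id)]] <- list(
      lineage_idx = p$lineage_idx, planted = ent$planted,
      subthreshold = ent$subthreshold,
      aa = ent$fasta, rho = ov$rho %||% spec$rho)
    paths[[as.character(p$entry_id)]] <- list(fasta = fa_path,
                                              domtbl = dt_path)
  }
  metadata <- do.call(rbind, md_rows)
  md_path <- file.path(dir, "metadata.csv")
  write_entry_metadata(metadata, md_path)
  list(metadata = metadata, families = families, truth = truth,
       paths = c(list(thresholds = thr_path, metadata = md_path), paths))
}

#' Generate a contamination-mixed marker hit table for one entry
#'
#' For each marker sequence, with probability `1 - rho` the emitted hits
#' resolve (by LCA of the top-bitscore band) inside the entry's own lineage
#' bin, otherwise inside the contaminant lineage's bin. Each marker gets two
#' in-band hits on two taxa of the target lineage, one out-of-band decoy hit
#' elsewhere, and one E-value-failing hit, so the band semantics are
#' exercised.
#'
#' @param spec A [fixture_spec()].
#' @param taxonomy Output of [make_taxonomy()].
#' @param entry_id Entry identifier (selects the RNG sub-stream).
#' @param marker_ids Character vector of marker sequence ids.
#' @param lineage_idx Index of the entry's own lineage.
#' @param rho Mixing fraction (default from spec).
#' @return List: `hits` data frame, `rho_realized` (fraction of markers
#'   actually planted in the contaminant lineage).
#' @export
make_marker_hits <- function(spec, taxonomy, entry_id, marker_ids,
                             lineage_idx, rho = spec$rho) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  contam_idx <- spec$contaminant_lineage %||%
    (lineage_idx %% spec$n_lineages + 1L)
  if (spec$n_lineages == 1L) contam_idx <- 1L
  pick_taxa <- function(idx) {
    sp <- taxonomy$species$taxid[taxonomy$species$lineage_idx == idx]
    if (length(sp) >= 2L) sp[1:2]
    else c(sp[1L],
           taxonomy$strains$taxid[taxonomy$strains$species_taxid == sp[1L]])
  }
  with_seed(substream_seed(spec$seed, paste0("hits", entry_id)), {
    contaminated <- runif(length(marker_ids)) < rho
    rows <- lapply(seq_along(marker_ids), function(i) {
      idx <- if (contaminated[i]) contam_idx else lineage_idx
      tgt <- pick_taxa(idx)
      other <- pick_taxa(if (idx == lineage_idx && spec$n_lineages > 1L)
                           contam_idx else lineage_idx)
      b1 <- round(runif(1, 95, 105), 1)
      data.frame(
        query_id = marker_ids[i],
        subject_taxid = c(tgt[1L], tgt[2L], other[1L], tgt[1L]),
        bitscore = round(c(b1, 0.93 * b1, 0.85 * b1, b1), 1),
        evalue = c(1e-40, 1e-38, 1e-20, 1e-3),
        stringsAsFactors = FALSE
      )
    })
    list(hits = do.call(rbind, rows),
         rho_realized = mean(contaminated))
  })
}

write_hit_table <- function(hits, path) {
  writeLines(paste(hits$query_id, hits$subject_taxid,
                   sprintf("%.1f", hits$bitscore),
                   format(hits$evalue, scientific = TRUE, digits = 3)),
             path)
  invisible(path)
}

#' Generate nucleotide fixtures with a stop-free CDS planted in one frame
#'
#' Each record embeds a stop-free coding sequence of `spec$cds_length` nt at
#' a chosen frame (1-3 forward, 4-6 reverse-complement) inside random flanks
#' laced with stop codons in all six frames, and the generator verifies that
#' the planted frame is the strict unique maximiser of ORF length
#' (resampling the CDS if an alternative reading of it happens to run long).
#'
#' @param spec A [fixture_spec()].
#' @param frames Integer vector of frames to plant, one record each
#'   (recycled from 1:6 by default).
#' @param n Number of records (default `length(frames)`).
#' @return Data frame `seq_id`, `description`, `residues`, plus a
#'   `planted_frame` truth column.
#' @export
make_cds_fixture <- function(spec, frames = 1:6, n = length(frames)) {
  frames <- rep_len(frames, n)
  stopifnot(all(frames %in% 1:6))
  cod <- codons_by_aa()
  stop_unit <- "TTAATTAATTAA" # stop codons in all six frames; own revcomp
  with_seed(substream_seed(spec$seed, "cds_fixture"), {
    flank <- function(len) {
      blocks <- character(0)
      while (sum(nchar(blocks)) < len) {
        blocks <- c(blocks,
                    paste0(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                           collapse = ""),
                    stop_unit)
      }
      substr(paste0(blocks, collapse = ""), 1L, len)
    }
    rec <- lapply(seq_len(n), function(i) {
      f <- frames[i]
      for (try in 1:100) {
        pep <- random_peptide(spec$cds_length %/% 3L)
        cds <- reverse_translate(pep, cod, add_stop = FALSE)
        if (f <= 3L) {
          o <- f - 1L
          l1 <- spec$flank_length + ((o - spec$flank_length) %% 3L)
          nt <- paste0(flank(l1), cds, flank(spec$flank_length))
        } else {
          r <- f - 4L
          l2 <- spec$flank_length + ((r - spec$flank_length) %% 3L)
          nt <- paste0(flank(spec$flank_length), revcomp(cds), flank(l2))
        }
        runs <- orf_runs_all_frames(nt)
        if (runs[f] > max(runs[-f])) {
          return(data.frame(seq_id = sprintf("cds_%03d", i),
                            description = sprintf("planted_frame=%d", f),
                            residues = nt, planted_frame = f,
                            stringsAsFactors = FALSE))
        }
      }
      stop("could not plant a uniquely recoverable CDS in frame ", f)
    })
    do.call(rbind, rec)
  })
}

# Longest stop-free codon run per frame, computed directly from the codon
# stream (independent of the translation tables used by select_frame).
orf_runs_all_frames <- function(nt) {
  stops <- c("TAA", "TAG", "TGA")
  run1 <- function(s, o) {
    l <- nchar(s)
    nc <- (l - o) %/% 3L
    if (nc <= 0L) return(0L)
    starts <- o + 1L + 3L * (seq_len(nc) - 1L)
    is_stop <- substring(s, starts, starts + 2L) %in% stops
    best <- cur <- 0L
    for (b in is_stop) {
      cur <- if (b) 0L else cur + 1L
      best <- max(best, cur)
    }
    best
  }
  rc <- revcomp(nt)
  c(run1(nt, 0L), run1(nt, 1L), run1(nt, 2L),
    run1(rc, 0L), run1(rc, 1L), run1(rc, 2L))
}

#' Emit a complete synthetic corpus to disk
#'
#' Generates the taxonomy, bin and lineage configs, per-entry FASTA and
#' domain tables, the trusted-cutoff profile file, per-entry marker hit
#' tables, the metadata table, and a `truth.json` ground-truth record.
#' Byte-identical across runs with the same spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Corpus root directory (created).
#' @return List with `dir`, `metadata`, `taxonomy`, `families`, `truth`.
#' @export
make_corpus <- function(spec, dir = tempfile("corpus")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxonomy <- make_taxonomy(spec, file.path(dir, "taxonomy"))
  for (f in c("bins", "lineages")) {
    file.rename(taxonomy$paths[[f]],
                file.path(dir, basename(taxonomy$paths[[f]])))
    taxonomy$paths[[f]] <- file.path(dir, basename(taxonomy$paths[[f]]))
  }
  ent <- make_entries(spec, taxonomy, dir)
  dir.create(file.path(dir, "hits"), showWarnings = FALSE)
  truth <- ent$truth
  for (eid in names(truth)) {
    tr <- truth[[eid]]
    planted <- tr$planted
    marker_fams <- ent$families$pfam_id[ent$families$marker]
    marker_ids <- names(planted)[planted %in% marker_fams &
                                   !(names(planted) %in% tr$subthreshold)]
    mh <- make_marker_hits(spec, taxonomy, as.integer(eid), marker_ids,
                           tr$lineage_idx, rho = tr$rho)
    write_hit_table(mh$hits,
                    file.path(dir, "hits", paste0("entry_", eid,
                                                  ".hits.tsv")))
    truth[[eid]]$rho_realized <- mh$rho_realized
    truth[[eid]]$marker_ids <- marker_ids
  }
  truth_json <- lapply(truth, function(tr) {
    list(lineage_idx = tr$lineage_idx, rho = tr$rho,
         rho_realized = tr$rho_realized,
         subthreshold = as.list(tr$subthreshold),
         planted = as.list(tr$planted))
  })
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(dir = dir, metadata = ent$metadata, taxonomy = taxonomy,
       families = ent$families, truth = truth)
}
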