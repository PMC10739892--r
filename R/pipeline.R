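## End-to-end build over a corpus directory: translate -> annotate ->
## validate (flags + marker contamination screen) -> pool/cluster/rename ->
## core-gene catalogs. Stage outputs are keyed by a hash of the
## configuration so an interrupted run resumes from the last completed
## stage; a manifest records the configuration and per-stage counts.

#' Build configuration
#'
#' Houses every numeric threshold of the pipeline with its default:
#' validation cutoffs (minimum 1200 raw sequences, 500 distinct Pfam
#' families, 50% contamination), marker selection prevalence (strictly above
#' 0.90), LCA hit retention (E-value at most 1e-5, bitscore within 10% of
#' the best), clustering (99% identity, 0.8 shorter-sequence coverage), and
#' the CTG frequency criterion (0.95).
#'
#' @param corpus_dir Corpus directory (layout as written by [make_corpus()]).
#' @param out_dir Output directory for build artifacts.
#' @param min_seqs,min_pfams,contam_flag_pct Validation thresholds.
#' @param marker_prevalence Marker family prevalence bound (strict).
#' @param lca_evalue_max,top_bitscore_frac LCA hit retention parameters.
#' @param cluster_identity,cluster_coverage Clustering parameters.
#' @param ctg_frequency CTG frequency criterion.
#' @param unknown_policy Unplaced-marker policy (`"exclude"` or `"count"`).
#' @param orf_only Keep only the ORF substring when translating.
#' @param vv_override_ids Entry ids whose external contamination flags are
#'   suppressed.
#' @param seed Seed recorded in the manifest (the build itself is
#'   deterministic given its inputs).
#' @return A `build_config` list.
#' @export
build_config <- function(corpus_dir, out_dir,
                         min_seqs = 1200, min_pfams = 500,
                         contam_flag_pct = 50, marker_prevalence = 0.90,
                         lca_evalue_max = 1e-5, top_bitscore_frac = 0.10,
                         cluster_identity = 0.99, cluster_coverage = 0.8,
                         ctg_frequency = 0.95,
                         unknown_policy = "exclude", orf_only = FALSE,
                         vv_override_ids = integer(0), seed = 1) {
  fr <- c(marker_prevalence, top_bitscore_frac, cluster_identity,
          cluster_coverage, ctg_frequency)
  stopifnot(all(fr >= 0 & fr <= 1), min_seqs >= 0, min_pfams >= 0,
            contam_flag_pct >= 0, lca_evalue_max >= 0)
  structure(list(
    corpus_dir = corpus_dir, out_dir = out_dir, min_seqs = min_seqs,
    min_pfams = min_pfams, contam_flag_pct = contam_flag_pct,
    marker_prevalence = marker_prevalence, lca_evalue_max = lca_evalue_max,
    top_bitscore_frac = top_bitscore_frac,
    cluster_identity = cluster_identity,
    cluster_coverage = cluster_coverage, ctg_frequency = ctg_frequency,
    unknown_policy = unknown_policy, orf_only = orf_only,
    vv_override_ids = vv_override_ids, seed = seed
  ), class = "build_config")
}

stage_state_path <- function(out, name) {
  file.path(out, paste0(".stage_", name))
}

stage_done <- function(out, name, hash, outputs) {
  p <- stage_state_path(out, name)
  file.exists(p) && identical(readLines(p, warn = FALSE)[1L], hash) &&
    all(file.exists(outputs))
}

mark_stage <- function(out, name, hash) {
  writeLines(hash, stage_state_path(out, name))
}

corpus_entry_fasta <- function(corpus_dir, entry_id, seq_type) {
  file.path(corpus_dir, "entries",
            sprintf("entry_%d.%s", entry_id,
                    if (seq_type == "nt") "fna" else "faa"))
}

#' Run the full reference-library build
#'
#' Executes translate, annotate, validate (flags plus the ribosomal-marker
#' contamination screen), cluster/rename, and CTG derivation over a corpus
#' directory, writing: `aa/` per-entry translated FASTA,
#' `entry_pfam_sums.csv`, `entry_curation.csv`, `RP63_QC_estimates.csv`,
#' `proteins.faa`, `proteins_info.tab`, `taxonomies.tab`, `best_pfam.csv`,
#' `core_genes.csv`, and `manifest.json`. A failed stage halts with its
#' name; rerunning with an unchanged configuration resumes after the last
#' completed stage.
#'
#' @param config A [build_config()].
#' @return Invisible list: `paths` to every artifact and `counts`, the
#'   per-stage record ledger.
#' @export
run_build <- function(config) {
  cd <- config$corpus_dir
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "aa"), showWarnings = FALSE)
  hash <- config_hash(config)

  metadata <- read_entry_metadata(file.path(cd, "metadata.csv"))
  tree <- parse_taxdump(file.path(cd, "taxonomy", "nodes.dmp"),
                        file.path(cd, "taxonomy", "names.dmp"))
  bins <- read_bin_config(tree, file.path(cd, "bins.cfg"))
  thresholds <- parse_hmm_thresholds(file.path(cd, "hmm_profiles.txt"))

  run_stage <- function(name, outputs, fun) {
    if (stage_done(out, name, hash, outputs)) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     stop("build stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    mark_stage(out, name, hash)
    invisible(NULL)
  }

  aa_paths <- setNames(
    file.path(out, "aa", sprintf("entry_%d.faa", metadata$entry_id)),
    metadata$entry_id)

  ## stage 1: bring every entry into amino acid space
  run_stage("translate", aa_paths, function() {
    for (i in seq_len(nrow(metadata))) {
      eid <- metadata$entry_id[i]
      src <- corpus_entry_fasta(cd, eid, metadata$seq_type[i])
      if (metadata$seq_type[i] == "nt") {
        recs <- read_fasta(src, "nucleotide")
        aa <- translate_records(recs, orf_only = config$orf_only)
      } else {
        aa <- read_fasta(src, "amino-acid")
      }
      write_fasta(aa, aa_paths[[as.character(eid)]])
    }
  })
  seqs_by_entry <- lapply(setNames(nm = as.character(metadata$entry_id)),
                          function(k) read_fasta(aa_paths[[k]], "amino-acid"))

  ## stage 2: trusted-cutoff filtering and best-per-sequence annotation
  best_raw_path <- file.path(out, "best_annotations_seq.csv")
  sums_path <- file.path(out, "entry_pfam_sums.csv")
  run_stage("annotate", c(best_raw_path, sums_path), function() {
    best_all <- do.call(rbind, lapply(metadata$entry_id, function(eid) {
      hits <- parse_domtbl(file.path(cd, "domtbl",
                                     sprintf("entry_%d.domtblout.tab", eid)))
      best <- best_per_sequence(filter_trusted(hits, thresholds))
      if (nrow(best)) cbind(entry_id = eid, best) else NULL
    }))
    write.csv(best_all, best_raw_path, row.names = FALSE, quote = FALSE)
    write.csv(entry_pfam_summary(best_all), sums_path,
              row.names = FALSE, quote = FALSE)
  })
  best_all <- read.csv(best_raw_path, stringsAsFactors = FALSE)

  ## stage 3: validation flags and marker contamination screen
  curation_path <- file.path(out, "entry_curation.csv")
  rp_path <- file.path(out, "RP63_QC_estimates.csv")
  qc_cfg <- qc_config(config$min_seqs, config$min_pfams,
                      config$contam_flag_pct)
  run_stage("validate", c(curation_path, rp_path), function() {
    npf <- n_pfams_per_entry(best_all)
    staged <- stage_entries(metadata, npf, qc_cfg)
    hit_files <- file.path(cd, "hits",
                           sprintf("entry_%d.hits.tsv", staged$eligible))
    hits_by_entry <- setNames(lapply(hit_files, function(f) {
      if (file.exists(f)) parse_hit_table(f) else NULL
    }), staged$eligible)
    rp <- rp_screen(metadata, best_all, hits_by_entry, tree, bins,
                    eligible = staged$eligible,
                    prevalence_min = config$marker_prevalence,
                    evalue_max = config$lca_evalue_max,
                    top_frac = config$top_bitscore_frac,
                    unknown_policy = config$unknown_policy)
    write_rp_report(rp, rp_path)
    cur <- build_curation(metadata, npf, rp_report = rp, config = qc_cfg,
                          vv_override_ids = config$vv_override_ids)
    write_curation(cur, curation_path)
  })
  curation <- read_curation(curation_path)
  metadata$accepted <- curation$accepted[match(metadata$entry_id,
                                               curation$entry_id)]

  ## stage 4: pool by taxid, cluster, assign stable identifiers
  proteins_path <- file.path(out, "proteins.faa")
  info_path <- file.path(out, "proteins_info.tab")
  taxmap_path <- file.path(out, "taxonomies.tab")
  best_pfam_path <- file.path(out, "best_pfam.csv")
  run_stage("cluster", c(proteins_path, info_path, taxmap_path,
                         best_pfam_path), function() {
    pools <- pool_by_taxid(seqs_by_entry, metadata)
    clustered <- lapply(pools, greedy_cluster,
                        threshold = config$cluster_identity,
                        coverage = config$cluster_coverage)
    ids <- assign_ids(clustered)
    reps <- do.call(rbind, lapply(names(clustered), function(tx) {
      cl <- clustered[[tx]]
      r <- cl[cl$aa_id %in% unique(cl$rep_aa_id), , drop = FALSE]
      cbind(tax_id = as.integer(tx), r)
    }))
    reps$mft <- unname(ids[reps$aa_id])
    reps <- reps[order(reps$mft), , drop = FALSE]
    write_fasta(data.frame(seq_id = reps$mft, description = "",
                           residues = reps$residues), proteins_path)
    con <- file(info_path, "wt")
    writeLines(c("aa_id\tentry_id\tsource_defline",
                 paste(reps$mft, reps$entry_id, reps$aa_id, sep = "\t")), con)
    close(con)
    con <- file(taxmap_path, "wt")
    writeLines(c("accession\taccession.version\ttaxid\tgi",
                 paste("NA", reps$mft, reps$tax_id, "NA", sep = "\t")), con)
    close(con)
    bp <- merge(reps[, c("mft", "aa_id", "entry_id")],
                best_all[, c("entry_id", "seq_id", "pfam_name", "pfam_id")],
                by.x = c("entry_id", "aa_id"),
                by.y = c("entry_id", "seq_id"))
    bp <- bp[order(bp$mft), c("mft", "entry_id", "aa_id", "pfam_name",
                              "pfam_id")]
    names(bp) <- c("aa_id", "entry_id", "source_defline", "pfam_name",
                   "pfam_id")
    write.csv(bp, best_pfam_path, row.names = FALSE, quote = FALSE)
  })

  ## stage 5: core transcribed gene catalogs
  core_path <- file.path(out, "core_genes.csv")
  run_stage("ctg", core_path, function() {
    lineages <- read_lineage_config(file.path(cd, "lineages.cfg"))
    cg <- ctg_catalogs(metadata, best_all, tree, lineages,
                       threshold = config$ctg_frequency)
    write.csv(cg, core_path, row.names = FALSE, quote = FALSE)
  })

  ## manifest: configuration and the record-count ledger
  info <- read.table(info_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  taxmap <- read.table(taxmap_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  prot <- read_fasta(proteins_path, "amino-acid")
  counts <- list(
    n_entries = nrow(metadata),
    n_accepted = sum(curation$accepted == "Y"),
    n_annotated_seqs = nrow(best_all),
    n_proteins = nrow(prot),
    n_proteins_info = nrow(info),
    n_taxonomies = nrow(taxmap)
  )
  manifest <- list(tool = "ferretforge",
                   config = unclass(config), config_hash = hash,
                   counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    paths = list(curation = curation_path, rp = rp_path,
                 proteins = proteins_path, proteins_info = info_path,
                 taxonomies = taxmap_path, best_pfam = best_pfam_path,
                 core_genes = core_path,
                 entry_pfam_sums = sums_path,
                 manifest = file.path(out, "manifest.json")),
    counts = counts
  ))
}
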