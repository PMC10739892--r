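---
title: "Building and validating a reference protein library with ferretforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating a reference protein library with ferretforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferretforge)
```

## The problem

Marine microbial eukaryote metatranscriptomes are annotated against
reference protein libraries assembled from hundreds of independently
sequenced genomes and transcriptomes. Each candidate entry — one organism's
sequence set — arrives in a different state: nucleotide contigs or
translated peptides, with inconsistent identifiers, variable completeness,
and a real risk of cross-contamination between cultures sequenced together.
`ferretforge` implements the construction and validation workflow for such
a library: it standardises entries into amino acid space, annotates and
filters protein domains, screens entries for contamination with ribosomal
protein markers, applies acceptance flags, collapses redundancy within
taxa, and derives per-lineage core-gene catalogs against which transcriptome
completeness can be scored.

## The procedure, stage by stage

### Six-frame translation and frame selection

Nucleotide entries are translated in all six reading frames; the frame
containing the longest open reading frame is kept. An ORF here is a maximal
stop-free run of residues: `X` (unknown) does not break a run and no start
codon is required, because transcriptome contigs are frequently 5′-truncated.
Degenerate IUPAC codons translate to an amino acid only when every
completion encodes that amino acid (`GCN` → `A`), otherwise to `X`.

Two conventions were genuinely open and are fixed as follows:

* **Frame numbering.** Frames 1–3 are offsets 0–2 of the forward strand,
  frames 4–6 offsets 0–2 of the reverse complement. The widely used EMBOSS
  translator numbers reverse frames differently depending on sequence
  length modulo 3; the convention here is deterministic and
  length-independent.
* **Retained peptide.** The whole selected frame's peptide is kept, not
  just the ORF substring, preserving partial flanking coding signal for
  domain annotation. `orf_only = TRUE` switches to the trimmed behaviour.

Ties in ORF length go to the lowest frame number.

### Domain annotation post-processing

Raw domain-table hits (HMMER3 `--domtblout` dialect) are filtered by each
family's **trusted cutoff** — the curated per-family bitscore above which a
match is considered reliable — applied to the full-sequence bitscore. The
first TC value of each profile's header is used; domain-level scores are
carried but not thresholded. A sequence with several surviving hits keeps
the highest-scoring one, with ties broken by lower E-value and then
lexicographic family id so the reduction is deterministic. Pfam accession
version suffixes (`.N`) are stripped everywhere so hits join cutoffs across
releases.

The per-entry count of *distinct* annotated families (`n_pfams_per_entry`)
feeds the validation flags; counting total annotated sequences instead is
exposed via `count_mode` since published descriptions admit either reading.

### Ribosomal-marker contamination screening

Cross-contamination is estimated by taxonomically placing each entry's
ribosomal protein sequences:

1. **Marker selection.** Families whose names match a ribosomal pattern
   (default prefix `Ribosomal`) and that occur in strictly more than 90% of
   entries are markers. The selection is recomputed from the input corpus
   by default; a fixed published list can be supplied instead.
2. **Placement.** Each marker's alignment hits are filtered at E-value
   ≤ 1e-5; hits scoring within 10% of the best bitscore are retained
   (mirroring the `--top 10` convention of the cited aligner), and the
   lowest common ancestor of their subject taxids is taken.
3. **Binning.** The LCA is rolled into the deepest configured lineage bin
   on its root path; taxa under no bin report `Other`, unplaceable markers
   `Unknown`. The default report schema has 21 bin columns: sixteen
   eukaryote lineages, Bacteria, Archaea, Viruses, Other and Unknown.
   (Published materials disagree on whether Metazoa or Opisthokonta names
   the sixteenth lineage; the data-record schema's Opisthokonta is used.)
4. **Estimate.** `contam_pct` is 100 × (markers in bins other than the
   expected bin) / (markers in any bin). Under the default
   `unknown_policy = "exclude"`, Unknown markers enter neither numerator
   nor denominator — penalising missing placements would conflate
   incompleteness with contamination. `"count"` treats them as outside the
   expected lineage. The percentage is undefined (NA) when no marker is
   placeable.

### Validation flags

Five metrics flag entries for exclusion, with strict inequalities at the
boundaries: fewer than 1,200 raw sequences (`LOW_SEQS`); fewer than 500
distinct Pfam families (`LOW_PFAMS`, only assigned when `LOW_SEQS` is
absent, reproducing the published accounting); two external contamination
studies carried through as flag tables (`FLAG_LASEK`; `FLAG_VV` for
external estimates over 50%); and the marker screen (`FLAG_RP63` for
estimates over 50%). Entries flagged for low sequences or low Pfams are
excluded from contamination estimation altogether. An entry is accepted
exactly when no flag is set; acceptance can be overridden afterwards, with
overrides logged. The eight entries whose external 100% estimates rest on a
wrong taxid are shipped as `VV_OVERRIDE_ENTRY_IDS` for suppression.

### Clustering and identifier assignment

Accepted entries' proteins are pooled by NCBI taxid (preserving strain-level
pools) and reduced at 99% amino acid identity. The clustering is greedy and
longest-first: each sequence joins the first cluster whose representative it
matches at identity ≥ 0.99, else founds a new cluster. Identity is exact
matches over all columns of a global alignment (BLOSUM62, affine gaps open
11 / extend 1) — a fully specified, reproducible definition. Because end
gaps count as columns, a short fragment of a long protein scores low
identity and stays separate; the additional shorter-sequence coverage knob
(default 0.8) is therefore rarely binding under global alignment but is
applied as configured. Two provable shortcuts skip alignments that cannot
reach the threshold (length-ratio bound; and when
`ceil(threshold × maxlen) ≥ maxlen`, only identical strings can pass), so
large pools cluster quickly without changing any result.

Representatives receive identifiers `mft` + ten zero-padded digits,
consecutive from `mft0000000001`, ordered by (taxid, representative's entry
id, input order). Published materials fix only the ten-digit width; the
start value and ordering key are fixed here and documented.

### Core transcribed genes and completeness

For a lineage, the core transcribed genes (CTGs) are the Pfam families
observed in at least 95% of its species-level transcriptome taxa — a
transcriptome-oriented analogue of genome completeness markers. The
presence matrix uses accepted transcriptome entries only (TSA and
single-cell transcriptome types; genome and SAG entries are excluded), and
strain taxids are collapsed to their species-rank ancestors so presence is
the union over strains; taxa already above species rank are used as-is with
a warning. With `n` taxa, a family qualifies at the smallest integer `k`
with `k/n ≥ 0.95` — for 29 taxa, 28. Completeness of any Pfam set against
a catalog is the covered percentage of catalog families. Lineages are
configured as (name, include-taxid, exclude-taxids), which expresses
clade subtractions such as Ochrophyta-excluding-diatoms.

## The synthetic corpus

All tests run on generated fixtures (`make_corpus()` and friends). The
generator emulates: a rooted toy taxonomy with lineage/species/strain
structure and bin configs; per-entry proteomes with one planted family per
sequence; domain tables whose scores straddle the trusted cutoffs (with a
configurable sub-threshold fraction); marker hit tables mixed at a planted
contamination fraction ρ, built so the top-bitscore band resolves by LCA
inside the intended lineage; and nucleotide fixtures with a stop-free CDS
planted at a known frame inside flanks laced with stop codons in all six
frames (the generator verifies the planted frame is the strict ORF-length
maximiser, resampling when an alternative reading of the CDS runs long).

Default study conditions, chosen once: 2 lineages × 3 species × 2 entries
(plus one genome entry), 60 proteins per entry of which 20 are markers,
ρ = 0.05 background contamination, 300 nt CDS in 200 nt flanks. Acceptance
checks use 29-species lineages (the CTG worked example), 200 markers × 20
seeds for mixing recovery, 200 planted-CDS fixtures, and 1,000-sequence
clustering pools. A single master seed drives per-generator sub-streams, so
outputs are byte-identical per seed and adding a generator perturbs nothing.

What passing these tests does **not** show about real data: the generator
draws residues uniformly (no realistic protein evolution), bitscores have
no biological distribution beyond the band semantics the LCA rule needs,
and contamination is planted independently per marker. Conclusions about
thresholds on real corpora (e.g. that 1,200 sequences separates usable
entries) are corpus properties, not algorithm properties — which is why the
pipeline configuration, not the code, carries them, and desk-scale runs set
proportionally smaller floors.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the flags (`< 1200`, `< 500`, `> 50%`)
  and marker prevalence (`> 0.90`); the CTG criterion is non-strict
  (`≥ 0.95`), matching the published 28-of-29 example.
* `contam_pct` with an empty denominator is NA, never 0 — an unscreenable
  entry is not a clean entry.
* Empty FASTA files, orphaned or duplicated taxids, malformed domain-table
  rows and non-numeric hit fields are errors, never silently skipped;
  profiles without trusted cutoffs and unmappable alignment subjects are
  dropped with counted warnings.
* LCA of a single taxon is itself; `lca_from_hits` with nothing surviving
  returns `"unassigned"`, which bins as Unknown.
* All-stop peptides have ORF length 0; ties in frame selection go to the
  lowest frame.
* Merged taxids resolve through `merged.dmp` when present; unknown taxids
  are an explicit error, because taxid curation must be deliberate.

## Known limitations

* The greedy clustering approximates, but is not parameter-identical to,
  the production clustering tools used at million-sequence scale; an
  external-tool adapter would be the right choice there.
* Name-based marker selection ("families whose names begin `Ribosomal`")
  is a heuristic stand-in for a curated marker list; the screen accepts a
  fixed list to reproduce published selections.
* Taxonomic curation (resolving wrong or retired taxids against external
  databases) is out of scope; the pipeline trusts the metadata taxid after
  merged-id resolution.
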