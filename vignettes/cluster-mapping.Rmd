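---
title: "Mapping r-protein gene clusters: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping r-protein gene clusters: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpclustermap)
```

## What the pipeline computes

Given an annotated prokaryotic genome, `rpclustermap` answers one question
per cluster model: *where, and in what shape, does this canonical run of
ribosomal-protein genes occur?* The analysis is purely gene-order based —
contiguity on the chromosome, not transcription-unit inference. The stages
are:

1. **Canonicalization.** Every gene record is resolved to a canonical gene
   name through the alias table (symbols first, then product strings, both
   case-insensitive after whitespace normalization). Labels of the
   "hypothetical protein" kind deliberately resolve to nothing; they are
   reserved for the rescue stage.
2. **Rescue.** Unresolved records with a protein sequence are aligned
   against a reference panel (Smith-Waterman, BLOSUM62, gap open 11 /
   extend 1). The best-scoring panel entry yields a call, accepted at
   identity ≥ 0.30 and reference coverage ≥ 0.50. Accepted calls overlay
   the annotation for the mapping stage; the annotation itself is never
   mutated.
3. **Mapping.** Member genes of a model are grouped per contig, left to
   right, into maximal runs in which consecutive members are separated by
   at most `gap_tolerance` foreign genes. Model accessory genes inside a
   run neither break it nor count as insertions. Segments never span
   contigs; contig-edge flags mark where continuity is merely unprovable.
4. **Comparison.** Occurrences aggregate into a genomes-by-families status
   matrix, per-genome dispersion/completeness summaries, and
   assembly-concern flags.

## The cluster registry

The registry defines five top-level families: `S10-spc`, `str-L30e`,
`alpha-L18e`, `L7ae-S24e` and `L31e-L11`. Two grouping decisions make the
family-level co-occurrence count well defined: the small S10 cluster
(*uL3-uL4-uL23-uL2*, core *uL3-uL4-uL23*) is a sub-model of `S10-spc`, and
the S24e–S27ae cluster shares a family with the L7ae cluster, whose
arrangements interleave in the genomes that carry both. With this grouping
a single contiguous super-arrangement of the str, S10-spc, alpha and
L7ae/S24e regions counts as four co-occurring families, with `L31e-L11`
apart.

Membership choices that were genuinely open:

* **uS19.** The archaeal S10-spc core is stored as the 14 genes
  *uL22-uS3-uL29-uS17-uL14-uL24-uL5-uS14-uS8-uL6-uL18-uS5-uL30-uL15*;
  uS19 is a regular, non-core member. Summaries that include uS19 in the
  core would count 15; the registry keeps the 14-gene definition and the
  mapper reports uS19 like any other member.
* **Archaea-Eukarya additions.** RNP1, S4e, L32e and L19e interleave the
  archaeal core (after uL29, uL24, uL6 and L32e respectively, the order
  attested by the complete single-scaffold arrangements). They carry the
  category `archaea-eukarya-rprotein`, which is how "additions relative to
  the bacterial cluster" are counted: uS19 is also absent from the
  bacterial core model but is a universal protein, not an addition.
* **The bacterial str/L30e core.** Its size (nine contiguous genes,
  cooccurring with the L11 cluster in *B. subtilis*) is attested but not
  enumerated gene by gene. The registry transcribes it from the structure
  of the *B. subtilis* rif/str superblock: the beta-operon pair
  *uL10-uL12*, *rpoB-rpoC*, the str operon *uS12-uS7-fusA-tufA*, and the
  adjacent *ybaC*. This is a transcription choice, recorded here; the
  archaeal variant follows the explicit enumeration
  (*rpoH-rpoB-rpoA1-rpoA2-L30e-nusA-uS12-uS7-fusA-EF1a-uS10*, conserved
  core *rpoA1-rpoA2-L30e-nusA-uS12*).
* **A "5-gene" core listing four names.** The conserved L31e-family core is
  stored as the four listed genes *S19e-COG2118-L39e-L31e*; the
  discrepancy with the stated count of five is preserved as data rather
  than silently padded.
* **Accessory genes.** Genes attested inside cluster blocks without being
  cluster members — the SUI1 translation-factor homolog and secY inside
  the archaeal S10-spc block, tRNA-Leu and the L34e/L14e/Cbf5 trio around
  the alpha cluster, dUTPase inside L7ae, and (bacterial core only) uS19
  and uL16, which belong to the operon but not to the shared 14-gene
  core — are *accessory*: tolerated inside segments, never reported as
  insertions, never counted as found members.

Registry and alias table ship as editable JSON under `inst/extdata/`, so
curation errors are auditable and fixable without touching code.

## Classification rules and numerical choices

* **Status.** `complete_contiguous` = all members found, one segment;
  `split` = at least two segments and at most `allowed_missing` (default 2)
  members absent; `absent` = nothing found; `partial` otherwise.
  Pseudogene members count as present (a complete core with a pseudogenized
  uL18 is still a complete core) but are listed in `pseudo_members` and can
  raise the `universal_gene_pseudo` concern.
* **Gap tolerance, default 2.** Attested cluster interiors tolerate one or
  two unrelated ORFs; a run of five hypothetical proteins between two
  clusters must split segments. Hence a deliberately small per-segment
  tolerance, with the wider family-level `adjacency_window` (default 12)
  restoring "these clusters co-occur contiguously" across short spacer
  runs (the largest attested intra-group spacer is ten ORFs; 12 leaves one
  gene of slack). Both knobs are exposed; the defaults are calibrated to
  the published arrangements and recorded as such.
* **Hypothetical-protein spacers.** Unnamed genes count against the gap
  tolerance (they are foreign), but only genes resolving to a registered
  name are *reported* as insertions. This keeps insertion reports about
  identifiable acquisitions (e.g. the Hsp20 heat-shock gene inside the
  Thorarchaeote core) instead of enumerating anonymous ORFs.
* **Orientation.** A segment is `reverse` when its member hits run against
  the model order (majority of descending adjacent pairs); ties fall back
  to the majority hit strand, and a single-gene segment is `forward` by
  convention. Hits are stored in genome order and presented flipped, so
  reports always read in model order; mapping results are invariant under
  reverse-complementing the genome (a property the tests assert).
* **Paralogs.** Runs that contribute no member name beyond those carried
  by larger runs are set aside as extra copies rather than counted as
  additional segments; adjacent duplicate copies inside a run are likewise
  reported as extras. Tie-breaks are deterministic (run size, span,
  position).
* **Rescue thresholds.** The acceptance rule (identity ≥ 0.30 of aligned
  columns and coverage ≥ 0.50 of the reference) replaces an external
  BLAST significance criterion with two interpretable knobs; both are
  config-exposed. Score ties resolve to the lexicographically smallest
  gene name, making call lists independent of panel order.
* **Partial genes.** A gene is partial when its coding length falls below
  `min_length_fraction` (default 0.7) of its family's typical length, or
  when it is truncated at a contig edge. The genome-wide partial fraction
  is computed over cluster genes (the denominator the published
  percentages leave unstated; the choice is documented here).
* **Dispersion metrics.** `dispersion(g)` = mean segment count over
  present families; `completeness(g)` = fraction of present families that
  are complete and contiguous. These two formulas are this package's own
  summaries of a qualitative notion ("the more dispersed the
  arrangement…"); reports label them accordingly. The family cell behind
  them is the occurrence of the family's most informative model (most
  members found), so a split 18-gene core is not masked by a complete
  4-gene sub-cluster.
* **Degenerate inputs.** Empty genomes and genomes without members map to
  `absent` without error; unknown products never throw; duplicate locus
  tags are suffixed `_2`, `_3`, … deterministically with a warning.

## The synthetic genomes

`build_from_template()` generates annotation bundles (GFF3 + protein FASTA
+ feature table + truth JSON) from nine templates transcribed from the
published arrangements: the complete archaeal core (`asgard_core`), the
bacterial 21-gene S10+spc block (`ecoli_s10_spc`), the *B. subtilis*
str/L11 region (`bsubtilis_str`), the three-way Heimdallarchaeote core
split (`bin6_split`), six core members relabelled "hypothetical protein"
(`b35_misannotated`), the Hsp20 insertion with a uL18 pseudogene
(`thor_hsp20`), the missing *uL3-uL4-uL23* trio (`bin132_missing`), the
complete single-scaffold super-arrangement of four cluster families
(`ar10`), and the strand-mosaic L31e/L11 region (`pr6_strand_mix`). Each
block in a template records the arrangement it was transcribed from, so
transcription errors are auditable.

Protein sequences are synthetic: every registered gene has a fixed base
sequence (length 60–250 residues from a per-gene frozen table — real family
lengths are not modelled) and genomes carry it point-mutated at the
template's `mutation_rate` (0.05 by default; 0.10 for the relabelled-gene
template, putting rescued members near 90% identity). Background genes are
rejection-sampled to stay below 20% global identity to every panel entry
*and* below the rescue acceptance rule (with a 10% safety margin), so
rescue cannot fire on background by construction. `perturb()` applies
seeded pathology operations (split, relabel, pseudogenize, truncate,
delete, insert, fragment, invert) while updating the planted truth.

What passing the planted-truth suite shows: the pipeline's bookkeeping —
segment grouping, status classification, rescue overlay, concern flags —
is correct on genomes whose structure is known exactly. What it does not
show: performance on real sequence divergence (synthetic mutations are
uniform point substitutions; there are no indels, domain fusions or
compositional biases), on real annotation noise beyond the modelled
pathologies, or on nucleotide-level problems (no six-frame translation is
attempted; feature-table input without a protein FASTA cannot be rescued
and says so with a warning).

## Problem sizes in the test suite

Module tests run on toy genomes of 5–30 genes and the nine templates
(36–143 genes). The aligner is checked against an independent
dynamic-programming oracle on sequences up to 20 residues; segment
grouping against a definition-based oracle on genomes up to 30 genes; and
planted-truth recovery over 100 seeded synthetic specifications with
randomized perturbations, a suite sized to run in a few minutes on one
CPU.

## Known limitations

* Contiguity is gene-order only; intergenic distances and transcription
  signals are out of scope, so "cluster" here never asserts "operon".
* The registry covers the r-protein cluster families above, with the
  gene-name vocabulary the arrangements use; it is not a general-purpose
  r-protein nomenclature service (no eL/eS renaming beyond those names).
* Rescue has no E-value model; the identity/coverage thresholds stand in
  for BLAST significance and should be tightened for large real panels.
* The `universal_genes_missing` concern fires on any genome whose mapped
  models find none of *uL3-uL4-uL23*; for partial genome fragments (rather
  than whole assemblies) that flag should be read accordingly.
* Figures are text cluster maps; no graphical rendering is produced.
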