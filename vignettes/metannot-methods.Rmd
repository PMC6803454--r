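---
title: "metannot: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metannot: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metannot)
```

## Overview

metannot annotates assembled metagenome contigs and metagenome-assembled
genomes (MAGs). It does not run search binaries itself: it consumes the
*output dialects* of the standard tools (BLAST/DIAMOND 12/13-column tabular
hits, HMMER3 `domtblout` domain tables, MetaBat
`jgi_summarize_bam_contig_depths` depth tables, generic TSV feature calls)
and concentrates on everything downstream of the searches: structural
conflict resolution and masking, evidence merging, per-gene taxonomy and
MAG-level contamination detection, parsimony pathway reconstruction, and
abundance profiling. A deterministic fixture generator stands in for the
external binaries and reference databases, so the entire workflow is
testable offline with planted ground truth.

## Sequence preprocessing

Input FASTA records are validated (duplicate identifiers reject the whole
run — no partial processing), uppercased, stripped of gaps (`-`) and pads
(`*`), and every remaining character outside `A,C,G,T` becomes `N`. `U` is
treated as ambiguous because the declared alphabet is DNA. Contigs shorter
than `minContigLen` (default 200 bp; the threshold is user-defined in the
original tooling, with no published default) are removed. All "shorter
than" thresholds in the package are strict: a sequence exactly at the
threshold is kept.

## Structural annotation

rRNA genes are detected upstream by domain-of-life HMMs (Bacteria,
Archaea, Eukaryota), so one genomic region can attract hits from several
models. Conflicts are resolved by E-value: within each group of mutually
overlapping hits only the hits at the group-minimum E-value survive, and
exact ties are all kept. Two interpretation choices are deliberate and
pinned by a brute-force oracle in the tests:

* *overlap* means sharing at least 1 bp on the same contig (no minimum
  overlap fraction), ignoring strand and rRNA type, because transitively
  overlapping regions have to be resolved together;
* conflict groups are the connected components of the pairwise-overlap
  graph. For 1-D intervals these components coincide with the merged
  (reduced) ranges, which is how they are computed.

Detected noncoding features (CRISPR, tRNA, rRNA) are then masked with `N`
so that no artefactual protein gene can be called on top of them; masking
preserves sequence length and every position outside the masked union.
ORFs spanning fewer than 180 nt (default; stop codon included, partial
calls treated like complete ones) are excluded. Detected rRNA genes are
classified by their best pairwise hit against a lineage-labelled rRNA
reference.

## Evidence merging

For each retained ORF the evidence bundle holds pairwise hits (SwissProt
and a lineage-labelled genome database) and profile domains (Pfam,
TIGRFAM, FOAM, metabolic and cas-gene HMMs). Merging rules:

* pairwise sources contribute their single best hit, minimising
  `(evalue, -bitscore, subject_id)` — the subject-id tie-break makes
  results independent of hit order;
* profile sources contribute *all* significant domains, repeated domains
  included (a gene with two copies of the same domain reports both);
* significance is `evalue <= 1e-5` by default for both kinds (the cutoff
  is exposed per database; no published default exists);
* `allec_ids` is the ordered de-duplicated union with SwissProt ECs first,
  then FOAM ECs; `allko_ids` puts FOAM KOs first, then SwissProt KOs.
  This ordering is cosmetic and mirrors the master-table convention of
  the original pipeline's worked example;
* the product is the SwissProt best-hit description when present,
  otherwise the first significant domain description in priority order
  TIGRFAM > Pfam > FOAM > metabolic > cas-gene; genes with no functional
  evidence at all are `"hypothetical protein"`. A gene whose only
  evidence is a (taxonomic) genome-database hit also reads
  `"hypothetical protein"` — the hypothetical rule is about functional
  evidence;
* GO terms are the union of SwissProt- and TIGRFAM-derived terms. FOAM
  KO/EC accessions are parsed from the model-name grammar
  `KO:K#####[_EC]*` with comma-separated KO alternatives.

Motif evidence (signal peptides, transmembrane helix counts) is attached
verbatim from ingested tables; the package performs no motif prediction.

## Taxonomy and contamination

Each gene inherits the lineage of its best genome-database hit (single
best hit, not a lowest common ancestor of the top hits; LCA assignment is
a plausible extension but is not what the best-hit contract specifies).
Lineages follow the GTDB convention `d__;p__;c__;o__;f__;g__;s__` and may
terminate early.

For profiling, every gene is padded to the full 7-rank depth with an
explicit `unclassified` pseudo-taxon. The weighted taxon tree then has a
simple conservation law — each node's weight equals the sum of its
children — and every ring (rank) partitions the total weight, so ring
proportions are directly the segment areas of a sunburst display. Weights
are gene counts by default and per-sample sequencing depths when a depth
table is supplied.

A MAG's taxonomic coherence is summarised per rank by the plurality taxon
and the discordant fraction `1 - plurality count / classified count`,
with genes unclassified at the rank excluded from the denominator and
plurality ties broken lexicographically. A high discordant fraction flags
a chimeric or contaminated bin.

## Minimal pathway reconstruction

Observed gene families (KOs from the gene-to-KO map, ECs from the
gene-to-EC map, as two independent runs) are explained by the smallest
possible set of pathways — a set-cover objective that yields a
conservative pathway estimate. The exact solver is an iterative-deepening
depth-first search over candidate pathways in sorted-id order with a
coverage bound: the first cover found at the smallest feasible
cardinality is also the lexicographically smallest id-set of that
cardinality, making ties deterministic. Exact mode is used automatically
when at most 20 candidate pathways intersect the observation (a tunable);
above that a greedy cover (largest uncovered gain, ties to the smallest
id) provides the upper bound. The tests pin the exact solver to an
exhaustive subset-enumeration oracle on hundreds of random instances, and
verify `|exact| <= |greedy|` everywhere.

Observed ECs may carry `-` wildcards (e.g. `7.1.1.-`); such a family
matches any pathway member that agrees on all specified fields. Families
observed but absent from every pathway are reported as uncovered, never
silently dropped. Per-pathway *fill* is the fraction of member families
observed.

## Abundance profiles

Gene weight is the mean per-sample depth of the gene's contig (depth is
reported per contig by the upstream depth tool, so no per-base
recomputation is attempted; `depth_x_len` and plain `count` weighting are
available as switches). Spectral counts are taken as already normalized;
genes absent from the spectral table have zero expression. Category
profiles (taxa, functions, pathways) sum gene weights per category and
normalise per sample; genes without a category accumulate under an
explicit `unassigned` row so each column still sums to one. A sample with
zero total weight is flagged and reports zero abundance rather than
failing. A gene mapped to several families contributes its full weight to
each family (fractional splitting is deliberately not the default — the
contract is documented and symmetric for pathway activity, where a gene
supporting two member families of one pathway is counted once per
family).

## Fixture generator: what it emulates and what it does not

`fixtureSet()` emulates a small mock community: by default 12 random
A/C/G/T contigs of 2–6 kb binned round-robin into 3 MAGs, with
non-overlapping planted CRISPR/tRNA/rRNA/CDS features (expected 0.6
features per kb), 3 replicate samples with 10% multiplicative log-normal
depth noise (mirroring a replicate mock-community design), an 8-pathway
world with a planted, provably unique 3-pathway minimum cover (each
planted pathway owns a private observed family), 10% decoy homology
hits that never outrank the planted best hit, and 10% of genes left
without functional evidence. Contamination is planted by reassigning a
chosen fraction of a MAG's genes to another MAG's lineage, so the
discordant fraction is recoverable exactly by construction.

These fixtures exercise every parser, the planted-truth recovery paths,
and the determinism contracts. They do not simulate sequence evolution,
read-level noise, assembly artefacts, or realistic E-value distributions,
so passing tests demonstrate correctness of the downstream logic — not
the sensitivity of any upstream search tool.

## Numerical and design choices

* All writers are deterministic: fixed row ordering (radix sort,
  locale-independent), depths and abundances at 4 decimals, E-values at 1
  significant digit. Identical inputs give byte-identical outputs, which
  makes resume and diff meaningful.
* E-value ties are exact decimal equality after parsing; no tolerance.
* Coordinates are 1-based inclusive everywhere internally (GFF3
  convention).
* Stage resume: each pipeline stage records an md5 hash of its canonical
  parameter subset; a stage is skipped only when the hash matches and all
  recorded outputs exist. Hashes chain, so changing e.g. the ORF length
  threshold re-runs the structural stage and everything downstream.
* Master-table tags are normalized to the `sprot_` spelling throughout
  (the published example mixes `sprot_`/`sport_`).
* The KO-ontology field is filled only when an optional KO-to-ontology
  map is supplied; it is blank otherwise.

Test problem sizes (a dozen contigs, hundreds of random oracle instances,
a thousand random overlap sets) were chosen so the whole suite runs in
about a minute while still exercising every contract; the generator
scales to larger worlds through its arguments.

## Known limitations

* Gene taxonomy is single-best-hit; databases with uneven taxon sampling
  bias it accordingly.
* Eukaryotic gene models and viral contig identification are out of
  scope, as is executing any search binary.
* Spectral counts are consumed as provided; no normalization is applied.
* The HTML report is a static index with embedded JSON data contracts,
  not an interactive viewer.
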