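---
title: "Methods: paired-chain TCR clonality and convergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-chain TCR clonality and convergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synovitcr)
```

# Scope and model

`synovitcr` analyses single-cell T-cell receptor (TCR) repertoires sampled
from two paired compartments per patient — typically peripheral blood
mononuclear cells (PBMC) and synovial fluid mononuclear cells (SFMC) in
inflammatory arthritis. The questions it answers are:

1. Which T-cell clones are over-represented (clonally expanded) in one
   compartment relative to its pair?
2. Are cells of those enriched clones concentrated in particular phenotype
   clusters (e.g. an activated HLA-DR-high cluster)?
3. Do clones from the same or different patients converge on similar
   beta-chain CDR3 sequences, suggesting shared antigen specificity?

It deliberately consumes upstream products as inputs: contig annotation
tables from VDJ assembly, phenotype cluster labels from an expression
clustering pipeline, and cell QC metric tables. Assembly, normalisation,
clustering and differential expression are out of scope.

# Cell partitioning and multiplet rules

Each cell barcode's productive TRA/TRB chains form a partition.
A barcode is a **multiplet** when it has more than 1 beta chain or more
than 2 alpha chains — one productive beta rearrangement per T cell is the
rule (allelic exclusion), while up to two productive alpha chains are
biologically common. Barcodes with alpha chains only are `ALPHA_ONLY`;
they carry no usable clonotype because all downstream logic keys on the
beta chain. Classification is a pure function of the per-barcode chain
counts, after collapsing duplicate consensus rows (identical locus, CDR3
nucleotide sequence, V and J call; the highest-UMI copy is kept) so that
redundant assembler output cannot masquerade as a multiplet.

# Clonotype definition

A cell's clonotype is the combination of its alpha- and beta-chain CDR3
*nucleotide* sequences; the alpha set is sorted before keying so the key is
invariant to chain order. Nucleotide (not amino-acid) identity is the right
granularity for clonal descent: convergent recombination can produce the
same amino-acid CDR3 from different rearrangements.

Partitions with two beta chains are ambiguous — the alpha/beta pairing
cannot be deduced — so they are handled two ways behind one flag:

* `include_multiplet_beta = TRUE` (pure clonality analysis): the partition
  is treated as a single clone keyed on its sorted beta CDR3-nt tuple.
* `include_multiplet_beta = FALSE` (expression-linked analysis): multiplets
  are excluded outright, since their transcriptome is a mixture.

A consequence worth knowing: per-cell alpha dropout splits one biological
clone into several called clonotype keys (with and without the alpha).
This is inherent to combined-chain keying on droplet data, affects real
data equally, and is why truth-recovery evaluations in the test-suite map
called clones back to true clones through the beta chain.

# Enrichment statistics

For each clone in a patient's sample pair the 2x2 table
(clone cells / other cells) x (sample A / sample B) is tested with a
**two-sided Fisher's exact test**: the p-value sums hypergeometric
probabilities of all tables with the observed margins whose probability
does not exceed the observed one (relative tolerance 1e-7, the usual
guard against floating-point ties). The reported odds ratio is the
unconditional cross-product ratio `a*d / (b*c)` — simple, reproducible,
and immaterial to calls that are made on p-values; zero cells yield
`Inf`/`NaN` rather than a continuity correction. The family for
**Benjamini-Hochberg** adjustment is all clones of one patient's pair;
`p_adj <= 0.05` (inclusive) flags a clone as enriched in whichever sample
holds the higher proportion. The denominator is eligible (clone-assigned)
cells per sample: alpha-only and empty barcodes carry no clonotype and are
not part of the sampled clone universe.

Cluster association then asks, per phenotype cluster, whether cells of
enriched clones are over-represented (Fisher again), with **Bonferroni**
correction over the number of clusters actually tested; clusters with no
cells are excluded from the multiplier.

`subsample_equal_depth()` supports equal-cells-per-sample designs (its
canonical use: six samples subsampled to 6,867 cells each, 41,202 total)
with seeded, reproducible uniform subsampling.

# Convergence (specificity) groups

Grouping follows the GLIPH v1.0 recipe on beta-chain CDR3 amino-acid
sequences only. Two edge types connect sequence entries:

* **global** — equal CDR3 length and Hamming distance <= 1;
* **local** — both sequences contain a motif that is enriched in the
  sample relative to a naive reference repertoire.

Motifs are contiguous k-mers (k in {2, 3, 4}) from the CDR3 *interior*,
with 3 residues trimmed from each end to exclude the germline-templated
anchors; a motif counts once per sequence. Enrichment is
`fold_change = observed_freq / reference_freq` plus a resampled p-value:
the fraction of 1000 random reference subsets (of the sample's size) whose
motif frequency reaches the observed one, floored at 1/1000 — so the
smallest reportable p is exactly 0.001. Local edges require
`fold_change >= 10`, `p_resampled <= 0.001` and support from >= 3 sample
sequences. The tool and thresholds follow GLIPH v1.0 conventions; they are
exposed as arguments because published analyses rarely state them.
Convergence groups are connected components with >= 2 members of the union
graph, ordered by size then lexicographically smallest member; no
iterative refinement or HLA partitioning is attempted.

Multi-beta partitions contribute each beta as its own entry with a
`-v<k>` variant suffix (pairing is unknowable but the sequences are real);
alpha-only partitions are dropped with a counter.

# QC filter engine

Three named presets encode the droplet and plate filtering schemes, all
strict inequalities, all overridable:

| preset | mitochondrial | genes | counts |
|---|---|---|---|
| `droplet_fluid_blood` | > 10% | < 500 or > 3500 | UMIs > 25,000 |
| `droplet_tissue` | > 10% | < 200 or > 2000 | UMIs > 10,000 |
| `plate` | > median + 5 MAD | < 1000 or > 6000 | reads < 500,000 or > 5,000,000, or > median + 3 MAD |

MAD is the unscaled median absolute deviation; MAD-based rules are
recomputed on whatever cohort they are given, so only the absolute rules
are strictly idempotent. The plate mitochondrial rule is genuinely
ambiguous in the field's descriptions (a robust "5 MAD" rule versus a
realised absolute cutoff near 8.35%); both readings are shipped
(`plate` and `plate_abs_mito`) and neither is asserted as the original
intent. A removed cell records *all* rules that fired on it.

# V-J usage and analyte panels

`vj_usage()` computes beta-chain V-J pairing frequencies per patient
(each patient's matrix sums to 1) and averages patients *with equal
weight* within each sample type, so deeply sequenced patients do not
dominate the compartment-level picture. Usage is counted per cell by
default; collapsing to clones first is a caller-side `distinct()` away.

`paired_panel_test()` applies a two-sided paired t test per analyte with
Bonferroni correction over analytes, dropping incomplete pairs pairwise.
Zero-variance differences yield `NaN` with a warning — never a fabricated
0 or 1. The reported difference is the second condition minus the first,
in order of first appearance in the table. Concentration panels are
approximately log-normal; the calibration and power studies in the test
suite therefore run the test on log concentrations, which is also the
recommendation for real panels.

# The synthetic-data generator

`simulate_repertoire()` exists so every stage can be tested against known
truth. Per patient it builds a clone pool:

* **background clones** (default 300) with truncated power-law weights
  (exponent 2.5, maximum 50), reproducing the few-large-many-small clone
  geometry of real repertoires without claiming a fitted distribution;
* **planted enriched clones** (default 10 per patient) present in both
  samples at a 10-fold proportion ratio, expecting ~30 cells in the
  enriched sample;
* **planted convergence-group clones** carrying a fixed interior motif
  (default `NQNT` on a TRBV28/TRBJ1-1 background) in every patient.

CDR3s are a V-anchored amino-acid prefix, a random insert of 4-8 residues
and a J-anchored suffix, back-translated codon-wise so nucleotide length
is divisible by 3 and translation is consistent. The insert length keeps
simulated CDR3 beta chains at 13-18 residues, matching typical human
length distributions; shorter inserts would give the simulated repertoire
collision rates (identical or 1-mismatch CDR3s between unrelated clones)
orders of magnitude above anything seen in real data, and the convergence
stage would be dominated by those artefacts rather than by planted signal.
There is no biophysical recombination model — inserts are uniform over
residues — because the generator's job is to test statistics, not
biology.

Cells are allocated to samples multinomially from per-sample clone
probabilities (exact sample sizes, planted ratios in expectation). Alpha
chains drop out per cell at rate 0.15; 10% of clones carry a second
productive alpha; 5% of barcodes receive a second cell's chains (doublet
contamination, drawn from the same sample's clone distribution but never
the host's own clone, whose chains would be undetectable). Cluster labels
follow a six-cluster base distribution, with cells of planted enriched
clones biased toward an activated cluster at odds ratio 5. Default rates
are ordinary droplet single-cell values; every one is a config field.
A `TruthTable` maps every cell and clone to its generative role.

`simulate_reference()` draws naive-reference CDR3s from the same
machinery with no planted motifs; the generator-matched reference is what
makes motif fold changes interpretable in tests. A user-supplied reference
file overrides it in the pipeline. What the generator does **not**
emulate: biased thymic selection, insertion/deletion hotspots, expression
counts, batch effects, or cluster structure learned from expression —
so passing tests demonstrate the statistics are correctly calibrated on
clean planted signal, not that the pipeline is robust to every real-data
pathology.

# Numerical and design choices

* **Problem sizes in the test-suite.** Calibration and power studies run
  at one patient, paired samples of 2000 cells and ~300 clones (200
  replicates); convergence recovery runs three patients at ~50 sequence
  entries against a 10,000-sequence reference (50 replicates). These sizes
  give stable Monte-Carlo estimates while keeping the default `R CMD
  check`-style run desk-scale.
* **Truth conditioning.** Power is measured over planted clones whose
  *realised* truth meets the stated premise (>= 20 cells in the enriched
  sample, >= 10x realised ratio) — multinomial sampling can leave a
  planted clone below its nominal size, and such clones are no test of
  the detector. Convergence recovery conditions analogously on realised
  groups of >= 5 member sequences; the doublet rate is zero in that
  geometry so group recovery measures the motif machinery, not doublet
  splitting.
* **Determinism.** All pipeline randomness flows from one top-level seed
  through stage-tagged derived seeds (`derive_seed()`), so stages are
  independently reproducible, and two runs with the same seed produce
  byte-identical outputs.
* **Ties and ordering.** Convergence groups order by descending size,
  then smallest member id; enrichment tables order by adjusted then raw
  p; all outputs are written with fixed column orders so diffs are
  meaningful.
* **Degenerate inputs.** Empty contig files return empty tables with a
  warning; barcodes with no productive chains become `EMPTY` partitions;
  a constant metric vector collapses MAD bounds onto the median; a clone
  absent from both samples is never tested.

# Known limitations

* The per-patient BH family follows the per-patient reporting convention;
  a pooled family across patients is a caller-side concatenation but is
  not the default.
* Alpha-only cells are excluded from clonotypes and hence from enrichment
  denominators; whether they should count as "other cells" is a judgment
  call on which reasonable analyses differ.
* GLIPH v1.0 parameter defaults (k-mer lengths 2-4, flank trim 3,
  fold >= 10, p <= 0.001, depth >= 3) are conventions, not reproductions
  of any particular published run.
* Global similarity edges do not require V-gene identity; on large
  samples of short CDR3s this is permissive, and convergence groups can
  chain through shared-motif run-ons into larger components than the
  planted truth.

# A worked run

```{r, eval = FALSE}
out <- tempfile("synovitcr_run_")
manifest <- run_pipeline(out, config = list(), seed = 20200921)
manifest
enr <- readr::read_tsv(file.path(out, "enrichment.tsv"))
dplyr::count(dplyr::filter(enr, !is.na(enriched_in)), patient_id, enriched_in)
```

The manifest lists every output (simulated inputs, partition table,
clonotypes, enrichment and association tables, motif and convergence-group
tables, QC splits, V-J usage, analyte panel statistics) with its row count
and the effective parameters.
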