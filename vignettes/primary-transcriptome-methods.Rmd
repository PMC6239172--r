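---
title: "Methods: dRNA-seq primary transcriptome analysis with primaryTx"
author: "primaryTx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dRNA-seq primary transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primaryTx)
```

## Scope and model

`primaryTx` reimplements, as tested and reusable R code, a complete
bacterial primary-transcriptome analysis built around differential RNA-seq
(dRNA-seq). dRNA-seq compares two library types per sample: an RPP+
library, in which 5'-pyrophosphatase treatment converts the
5'-triphosphate ends of primary transcripts into ligatable ends so that
true transcription start sites (TSSs) are enriched, and an untreated RPP-
library dominated by processed 5'-monophosphate ends. A genuine TSS shows
a sharp 5'-end peak in RPP+ that exceeds the RPP- signal at the same
position, reproducibly across biological replicates.

The pipeline covers five analytic layers, each usable on its own:

1. **TSS calling** from stranded per-position 5'-end counts:
   size-factor normalization, candidate peak detection, two-stage peak
   clustering, twofold RPP+/RPP- enrichment filtering, replicate
   consensus, and cross-condition merging.
2. **TSS classification** into primary (P), secondary (S), internal (I),
   antisense (A) and intergenic (N) categories relative to gene
   annotation, with 5'-UTR extraction, start-codon usage and nucleotide
   context profiling, and TSS-to-operon assignment.
3. **Regulatory element scanning**: -10/-35 promoter boxes and
   Shine-Dalgarno (SD) motifs by mismatch-tolerant consensus matching.
4. **5'-UTR secondary structure**: minimum free energy (MFE) under a
   simplified, oracle-verifiable pair-energy model with a pluggable
   engine interface.
5. **Condition-responsive expression grouping**: a transparent
   negative-binomial Wald test, BH-FDR, DEG filtering, K-means/SSE
   clustering, rank-sum group comparisons and attenuator read-through
   ratios.

A sixth module generates synthetic genomes, 5'-end profiles, count
matrices and UTR sequence sets with known ground truth, so every stage of
the analysis is testable end to end without external downloads.

## TSS calling

**Normalization.** Libraries are scaled by median-of-ratios size factors
(`computeSizeFactors()`): each count is divided by its row's geometric
mean across libraries, and the library factor is the median ratio over
rows with all-positive counts. For dRNA-seq libraries without a gene-level
count table, `binProfiles()` sums raw 5'-end counts in fixed 200-bp bins
to build the input matrix; the bin width is a compromise between having
enough nonzero bins (bins must be nonzero in every library to enter the
median) and keeping single spike positions from dominating a bin.

**Peak grouping.** Candidate positions (normalized density at least
`minDensity`, default 5 normalized units — a configurable floor that
suppresses stochastic single-read positions) are first chained into
initial clusters wherever consecutive gaps are at most 300 bp. Within an
initial cluster, only adjacent peak pairs are compared: a pair is joined
into one sub-cluster when its population standard deviation, half the
gap, is below 15 bp — equivalently, when the gap is below 30 bp. Each
sub-cluster is represented by its highest-density member, with density
ties broken toward the most upstream position (strand-aware) so output is
deterministic. Two-point standard deviation is deliberately the
*population* flavour; the sample flavour would shift the effective gap
cutoff from 30 to ~21 bp, and the population reading matches the stated
pairwise rule most literally.

**Enrichment and reproducibility.** A representative survives when
`(dPlus + c) / (dMinus + c) >= 2` with pseudocount `c = 1` normalized
unit. The pseudocount guards against zero RPP- background while
penalizing low-coverage spikes; the ratio is evaluated at the
representative position itself (window half-width 0 by default,
configurable). A condition TSS then requires representatives from every
replicate within ±4 bp — the only positional tolerance the workflow
states anywhere, reused here for replicate consensus and configurable via
`replicateWindow`. The reported position and density are those of the
highest-density supporting replicate. With a single replicate the
reproducibility filter is skipped with a warning.

**Merging.** Per-condition TSS lists are merged greedily: the unmerged
TSS of highest density seeds a total TSS and absorbs everything within
±4 bp on the same strand, unioning condition labels; the process repeats
until all TSSs are merged. Greedy seeding by density makes the
100/104/108 chain collapse onto the central density seed rather than
fragmenting. Merged TSSs are labelled constitutive (all conditions),
conditional (at least two) or specific (one).

## Classification and 5'-UTRs

For each gene, a candidate window runs from 299 bp upstream to 100 bp
downstream of the first base of its start codon (offsets read literally
from the category definitions; both bounds configurable). Same-strand
TSSs inside at least one window are assigned to the gene with the nearest
start codon — ties, as arise between tandem genes with overlapping
windows, go to the lexicographically smaller gene id, a deterministic
stand-in for a curation decision the category rules do not specify. Per
gene the highest-density assigned TSS is primary and the rest secondary;
of the remaining TSSs, those inside a same-strand gene body are internal,
those antisense to a gene body (zero flank) are antisense, and the rest
intergenic. The precedence P/S > I > A > N is itself a design choice: a
TSS in a downstream neighbour's upstream window is read as that gene's
promoter signal rather than as an internal start.

5'-UTR length is the strand-aware distance from the primary TSS to the
first base of the start codon; transcripts with leaders shorter than
10 nt are counted leaderless, reading the "leaders longer than 10 nt"
convention as the cutoff (configurable via `leaderlessMax`). Negative or
zero lengths give empty sequences and are leaderless by definition.

TSS-to-operon assignment follows the validation logic of operon tables:
an operon inherits every P/S TSS of its first (5'-most) gene and is then
"TSS-validated"; operons without such a TSS remain "coverage-only".

## Promoter boxes and SD motifs

De novo motif discovery is out of scope; instead the canonical sigma-70
consensus boxes are localized by mismatch-tolerant scanning in 50-nt
upstream windows. The -10 hexamer `TATAAT` must lie fully within offsets
[-20, -5] relative to the TSS and the -35 hexamer `TTGACA` within
[-36, -23]; at most one mismatch is allowed by default, ties prefer fewer
mismatches then the 3'-most position, and the spacer is the gap in bp
between the -35 box end and the -10 box start (~17 bp for canonical
promoters). The SD scan looks for at least 4 of 6 identities to `AGGAGG`
within [-20, -5] of the start codon; the identity threshold and window
are unstated in the source analyses and are configurable defaults here.

## Simplified RNA folding

The builtin engine minimizes the summed pair energy over all nested
(pseudoknot-free) structures: GC/CG -3.0, AU/UA -2.0, GU/UG
-1.0 kcal/mol, minimum hairpin loop 3 nt, no stacking, dangling ends,
loop penalties or temperature dependence. This is intentionally not a
Turner-parameter thermodynamic model: absolute MFE values are not
comparable with full folders, and with per-pair (rather than per-stack)
energies the model substantially over-scores pairing in random sequence,
so the structured-vs-shuffled contrast it reports is compressed relative
to a thermodynamic folder. What the model preserves — and what the tests
rely on — is the ordering: planted perfect hairpins fold below matched
shuffles, and every reported energy is verifiable. `bruteForceFold()`
exhaustively enumerates all legal structures up to length 18 and serves
as the oracle; the dynamic program (`foldMfe()`) must match it exactly,
and its traceback is deterministic (whenever pairing the 5'-most base
attains the optimum it is paired, with the smallest admissible partner).
`utrMfeTable()` accepts any engine function with the same contract, so a
thermodynamic folder can be plugged in without touching the pipeline;
folding temperature is recorded as metadata only.

## Expression analysis

The differential stage is deliberately transparent rather than
shrinkage-based: normalized counts, log2 fold change of pseudocounted
group means, per-gene method-of-moments NB dispersion floored at 0
(Poisson), and a Wald statistic on the log2 scale via the delta method.
Because the plug-in variance with 3-4 replicates is noisy, p-values use a
t reference with `nA + nB - 2` degrees of freedom rather than the
standard normal; under a pure null NB simulation this keeps the p < 0.05
fraction near nominal where the normal reference is anti-conservative.
The DE engine is swappable: downstream selection and clustering only
consume a per-gene `log2FC`/`padj` table, however produced.

DEG selection requires `padj < 0.01` and `|log2FC| > 1` in at least
`minContrasts` contrasts (1 by default; 2 mirrors a "responsive under two
or more conditions" reading). K-means grouping uses Lloyd's algorithm
with best-of-restarts per `k`, reports the SSE curve, and selects `k` by
the knee heuristic (largest perpendicular distance to the line joining
the curve's endpoints) unless fixed by the user; a user-supplied merge of
clusters after inspection is supported simply by relabelling. Group
metrics are compared with the Wilcoxon-Mann-Whitney test: exact by
enumeration for tie-free samples with `n + m <= 16`, otherwise a
tie- and continuity-corrected normal approximation (whose worst-case
two-sided deviation from exact at n = m = 8 is about 0.011). Quartiles
use linear interpolation (type 7) for reproducibility.

## What the synthetic data emulate — and what they do not

`generateGenomeAnnotation()` plants one true TSS per gene at a uniform
20-150 bp offset upstream of the start codon, with `TATAAT` embedded so
its hexamer lies in [-20, -5], `TTGACA` a 17±1 bp spacer further
upstream, and `AGGAGG` starting 12±2 nt before the start codon; about a
fifth of genes form 2-4-gene operons, and intergenic gaps are at least
400 bp. Because the -10 box position is drawn across its full [-20, -10]
start range while the spacer is fixed near 17 bp, a fraction of planted
-35 boxes necessarily falls 5' of the scannable [-36, -23] range — the
-35 detection rate is therefore structurally below 100%, which mirrors
the behaviour of -35 boxes in real promoter sets without being tuned to
it.

`simulateEndProfiles()` gives RPP- libraries a processed-end background
(Poisson counts at 5% of transcribed-span positions, mean 2) plus
Poisson(depth) primary signal at each true TSS, and RPP+ libraries
Poisson(depth × enrichment) at the TSS with single-base jitter (80%
exact, 10% each ±1 bp — consistent with the near-single-base precision
the ±4 bp merge tolerance implies) over a halved background leak.
Poisson rather than NB spikes keep single-position count behaviour
analytically checkable. Per-library depth factors from [0.5, 1.5]
must be undone by the size-factor normalization.

`simulateCountMatrix()` draws NB counts (log-normal base means, default
dispersion 0.05) with planted groups: a "C7-like" block up-regulated
fourfold in all three non-reference conditions, a "C1-like" block
up-regulated in the autotrophic conditions only, and a null block;
library size factors come from [0.5, 2]. `generateStructuredUtrs()`
plants perfect GC-stem hairpins and pairs each structured sequence with
its own mononucleotide shuffle, preserving length and composition
exactly.

These generators reproduce the *statistical structure* the analysis
assumes — enriched, reproducible, near-base-precise 5' ends over a
diffuse background; block-patterned fold changes; hairpin-driven energy
contrasts. They do not model sequencing error, mappability, operon-
internal processing sites, RNA decay gradients, or the sequence
composition biases of a real genome (the background is uniform random,
so, e.g., the +1 nucleotide context of called TSSs is flat rather than
purine-biased as in real promoters, and real 5'-UTR media lengths differ
from the uniform-offset median here). Passing the recovery tests
therefore demonstrates the correctness of the algorithms under their own
assumptions, not performance on real libraries.

## Numerical choices and degenerate inputs

Problem sizes in the tests and in `scripts/acceptance.R` are chosen so
each stage demonstrates its property at comfortable statistical margins
on a single CPU: 200 planted TSSs for caller recovery, 2000 null genes
for calibration, all 4096 hexamers plus 200 random 12-mers for the
folding oracle, 100 sequences per class for the MFE contrast, and a
60-gene genome for the end-to-end pipeline run.

Other fixed choices: internal coordinates are the 1-based, closed
`GRanges` convention, converted exactly once at the bedGraph/BED (0-based)
boundaries; empty TSS sets produce header-only TSV, empty BED and
all-zero JSON summaries; all-zero genes are excluded from the DE test
with `NA` results; zero leader coverage makes the read-through ratio
undefined rather than infinite; and every stochastic routine takes an
explicit seed, making reruns bit-identical. The folding and promoter
stages of `runPipeline()` are optional — a failure there warns, is
recorded in the manifest and does not abort the run, since both are
analyses of the TSS product rather than prerequisites for it.

## Known limitations

- Absolute ΔG values from the builtin folding engine are not comparable
  to thermodynamic folders; only orderings are meaningful, and the
  structured-vs-shuffled gap is compressed (see above).
- The DE test is per-gene; it does not share dispersion information
  across genes and will be underpowered at very low replication compared
  to shrinkage-based engines.
- Promoter/SD detection is consensus-anchored; promoters diverging far
  from the canonical boxes are invisible to it, and detection rates are
  not comparable to probabilistic motif discovery.
- The TSS caller assumes 5'-end profiles are already aligned and
  strand-resolved; BAM ingestion is out of scope by design
  (bedGraph pairs are the interchange format).

## A worked end-to-end run

```{r pipeline, eval = FALSE}
library(primaryTx)
res <- runPipeline(pipelineConfig(seed = 7), "run1")
res$summary$nTss          # total merged TSSs
res$summary$categories    # P/S/I/A/N counts
head(res$utrs)            # per-gene 5'-UTR records
head(res$mfe)             # folded leaders, dot-bracket + MFE
head(res$promoters)       # -10/-35/SD hits
res$clusters$k            # selected expression cluster number
```

The run directory contains `run.tss.tsv` (1-based reporting
coordinates), `run.tss.bed` (0-based browser track), `utrs.tsv`,
`mfe.tsv`, `promoters.tsv`, `deg.tsv`, `clusters.tsv`, `sse.tsv`,
`summary.json` and `manifest.json` with the verbatim configuration.
`scoreTssRecovery()` scores any called set against the generator's
planted truth.
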