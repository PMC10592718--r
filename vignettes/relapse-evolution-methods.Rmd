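---
title: "Methods: clonal and epigenetic evolution in paired diagnosis-relapse AML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal and epigenetic evolution in paired diagnosis-relapse AML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Acute myeloid leukemia (AML) frequently returns after chemotherapy, and a
substantial fraction of relapses occur without any change in the driver
mutations detectable at diagnosis. `relapseEvo` implements the analytical
machinery to study this phenomenon from two complementary angles: the
*genetic* one (how variant allele frequencies of driver mutations move
between diagnosis and relapse, and what that implies for survival) and the
*epigenetic* one (how chromatin accessibility and mitochondrially-defined
subclones evolve in patients whose mutations do not change). This vignette
documents the models, the tunable parameters, and the design decisions
behind each stage, together with what the synthetic-data generators do and
do not emulate.

## Mutation dynamics and clonal bins

A mutation observed at both timepoints is classified from its variant
allele frequency (VAF) pair:

* **gained** — VAF below 0.05 at diagnosis and above 0.1 at relapse;
* **lost** — VAF above 0.1 at diagnosis and below 0.05 at relapse;
* **stable** — everything else.

All inequalities are strict: a VAF sitting exactly on 0.05 or 0.1 does not
cross the threshold. The dead zone between 0.05 and 0.1 exists on purpose —
it separates the detection floor of typical clinical NGS panels from a
level that confidently indicates clonal expansion, so that assay noise near
the detection limit cannot flip a call. A consequence worth noting is that
a mutation can move a long way (e.g. 0.35 of VAF) and remain *stable* as
long as it never crosses both thresholds; no additional magnitude-based
tolerance is layered on top. Mutations whose VAF cannot be meaningfully
quantified (FLT3 internal tandem duplications, NPM1 insertions) are
classified on presence/absence instead.

Patients are then binned from their mutation classes: `stable` (no gained,
no lost), `gain`, `loss`, or `gain_and_loss`. Binning operates at the
mutation level — if one variant of a gene is gained while another is
stable, the gained variant drives the bin. Relapse-free survival of stable
versus unstable (any non-stable bin) patients is compared with a
Kaplan-Meier estimate, a log-rank test, and a Cox proportional-hazards
model with age and sex as covariates. The Cox model uses Efron tie
handling because day-resolution relapse times tie frequently; sex enters
as a binary indicator.

## Consensus peaks and accessibility matrices

Per-sample peak calls are standardized to fixed 500-bp intervals centered
on the summit (or interval midpoint when no summit is available). Because
peak scores from different samples live on different scales, each sample's
scores are converted to score-per-million before pooling. The pooled peaks
are then resolved by iterative overlap removal: rank by normalized score,
keep the best peak, discard everything it overlaps, repeat. A retained
peak enters the consensus only when standardized peaks from at least two
distinct samples overlap it, which removes sample-private artifacts. The
output is coordinate-sorted, pairwise non-overlapping, and idempotent
under re-merging. Ties in the ranking are broken by coordinate and then by
source sample so the procedure is fully deterministic. The exact
normalization used before pooling is a design choice (score-per-million);
any monotone within-sample rescaling that makes samples comparable would
serve.

Tn5 cut sites are counted per peak with BED semantics throughout: 0-based,
half-open intervals, so a cut site at the start coordinate counts and one
at the end coordinate does not. The +4/−5 Tn5 offset correction is assumed
to have been applied upstream by whatever produced the cut sites.
Counts-per-million normalization scales each sample to a total of one
million and refuses to run twice on the same matrix. Diagnosis-relapse
similarity per patient is the Pearson correlation of CPM profiles after
averaging replicates within each timepoint.

## Gene accessibility scores

Chromatin accessibility near a gene predicts its expression well enough to
act as an expression proxy. Scores are computed from a 5-kb tile matrix
with an exponential-decay weighting: tiles whose midpoint falls inside the
window from 5 kb upstream of the TSS through the TTS (in strand
orientation) get weight $1 + e^{-1}$; flanking tiles at distance $d$ get
$e^{-d/5000} + e^{-1}$; tiles farther than 20 kb from the window, or past
the nearest boundary of an adjacent gene, get 0. The constant $e^{-1}$
term keeps distal-but-nearby tiles from vanishing too quickly; the hard
20-kb stop and the neighbor-boundary stop prevent a gene from absorbing
signal that plainly belongs to its neighbor. The weight function is
continuous at the window boundary (a flank at distance zero equals the
in-body weight) and non-increasing with distance. Tile counts are
depth-normalized per column (constant total of $10^4$) before weighting so
that scores are comparable across columns of different depth.

## Differential accessibility and the relapse signature

Differential accessibility between paired diagnosis and relapse samples
uses the standard negative-binomial count framework (DESeq2): median-of-
ratios size factors, dispersion shrinkage, and a Wald test, with design
`~ patient + condition` so the contrast is estimated within patients.
Benjamini-Hochberg adjustment is applied wherever an adjusted p-value
threshold appears. Gene scores are rounded to integers when fed to the
count model; at typical score magnitudes the rounding error is negligible
relative to biological variation. The model needs at least two patients
with both timepoints — otherwise patient and condition are confounded and
the function refuses to fit.

The relapse signature is derived from the mutationally *stable* patients
only: genes are ranked by their paired relapse-versus-diagnosis log2 fold
change, and the top and bottom 500 (configurable; shrunk with a warning
when fewer genes exist) form the signature. The per-cell relapse score is
the sum of depth-normalized scores over the top set minus the sum over the
bottom set — zero by construction for a cell with a flat profile, positive
for relapse-like chromatin. Scores are used on the linear (not log) scale;
a flag exists because the literature is split on this point.

The locus scan slides a 100-kb window in 25-kb steps (defaults motivated
by the scale of recurrent chromosomal regions reported for relapsed AML;
both are configurable) and asks, separately for significantly opened and
closed peaks, whether a window holds more of them than the genome-wide
fraction (one-sided binomial test, BH-adjusted across all windows).

## Projection to a healthy hematopoietic reference

To place leukemic cells on a map of normal hematopoiesis, a labeled
healthy reference is embedded by latent semantic indexing: term frequency
(each cell scaled to unit total), inverse document frequency
$\log(1 + n_{cells}/(1 + n_{carrying}))$, truncated SVD to $k = 30$
components by default. Binarization is off by default but available, and
component signs are fixed by forcing the largest-magnitude loading
positive, so refits are reproducible. The first component is retained by
default (it often correlates with depth in accessibility data; dropping it
is the caller's choice). Query cells — true single cells, or 250
pseudo-single cells multinomially subsampled from each bulk profile at
10,000 fragments each — are projected with the *stored* IDF weights and
loadings; the reference embedding is never recomputed, which is what makes
self-projection exactly reproduce the stored embedding and projection
linear in the query. Each query cell is classified by majority vote of its
10 Euclidean-nearest reference cells, with exact ties going to the tied
label with the smallest mean neighbor distance. Embeddings are not
L2-normalized before the neighbor search (flag available).

## Mitochondrial clones and convergent evolution

Mitochondrial heteroplasmy — the fraction of a cell's mitochondrial
genomes carrying a variant — acts as an endogenous clonal barcode.
Heteroplasmy is the pooled-strand alternate fraction; a cell with zero
coverage at a variant is *missing*, never zero. Variants pass quality
filtering when detected in more than 3 cells, with strand correlation
above 0.65 and mean coverage above 10 reads — all strictly; the strand
correlation is Pearson's over cells with any alternate signal and is
undefined (and failing) below two such cells.

Cells are clustered on the binarized heteroplasmy matrix (carrier cutoff
0.1 by default — low enough to catch true carriers through sampling noise,
high enough to ignore sequencing error) via a shared-nearest-neighbor
Jaccard graph (k = 20, prune 1/15) and Louvain modularity optimization.
Two post-steps keep the clustering honest: clusters below a minimum size
are merged into the nearest cluster, and clusters whose mean binary
genotypes are indistinguishable (centroid distance below 0.5) are
collapsed — modularity optimization happily over-partitions blocks of
identical binary profiles, while genuinely distinct clones differ by at
least one variant and sit near distance 1. The resolution parameter is
exposed because real analyses select it manually.

The clone tree is reconstructed from shared and exclusive variants: a
clone whose variant set strictly contains another's is its descendant
(the largest strict subset is the parent). Clones whose sets overlap
without containment violate a perfect phylogeny; they are attached to
their deepest compatible ancestor and *reported* as conflicts rather than
silently resolved, mirroring how such trees are curated by hand in
practice.

Convergent epigenetic evolution is tested on clone pseudobulks (summed
per clone and timepoint, CPM-normalized, clones under 20 cells excluded
for stability): all clone pairs are Pearson-correlated within each
timepoint, and the diagnosis and relapse correlation sets are compared
with an unpaired two-sided Student's t-test (equal variances; Welch
available). Convergence is declared when the mean relapse correlation
exceeds the diagnosis one at p < 0.05. The pairwise correlations within a
timepoint share clones and are therefore not independent; the declared
false-positive rate of the directional rule was verified empirically on
the synthetic null (0.05 over 200 seeds) rather than taken on faith from
the t reference distribution.

## What the synthetic data emulates — and what it does not

No public accession exists for the source sequencing data, so every input
class is generated with planted, recorded ground truth:

* **VAF cohorts** plant a clonal bin per patient and draw VAF pairs that
  reproduce the bin under the thresholds, spanning all threshold regions
  (both-high, both-low, dead-zone, and one-sided near-crossings);
  relapse-free survival is exponential with proportional hazards
  (planted HR between stable and unstable, ~20% independent censoring).
* **Bulk accessibility** is negative-binomial (dispersion 0.2 by default)
  with log-normal peak baselines, patient-level multiplicative shifts, and
  planted symmetric log2 fold changes at relapse.
* **References** give each cell type a block of peaks whose mean is
  scaled by $e^{separation}$; separation 0 makes types exchangeable, so
  chance-level classification is a designed property, not a failure.
* **Mitochondrial experiments** plant a clone hierarchy with per-branch
  variants at heteroplasmy 0.9, per-strand Poisson coverage (identical
  strand counts unless a `strand_noise` fraction of cells has strands
  redrawn independently), artifact variants designed to fail the quality
  filter, and clone-specific accessibility centroids. At relapse every
  clone's centroid drifts independently at the same deviation scale;
  planting convergence additionally pulls the drifted centroids toward a
  common relapse centroid with weight $\alpha = 0.7$. The independent
  drift is what makes the null of the convergence test meaningful — with
  frozen centroids the diagnosis and relapse correlation sets would be
  near-identical numbers and the test could never reject.

The generators are deliberately simple: Poisson/negative-binomial counts
with no GC or fragment-length structure, no doublets, no batch effects, no
chromatin co-accessibility correlation between nearby peaks, idealized
binomial heteroplasmy with no allelic dropout structure beyond coverage,
and survival times that genuinely follow proportional hazards. Passing
tests therefore demonstrate that the implementation does what it claims
under its stated model — they do not certify performance on real data,
where all of the above violations occur.

## Problem sizes, numerical choices, degenerate inputs

The shipped tests and the acceptance script exercise the pipeline at
deliberately modest sizes — cohorts of 200–500 patients, 150–1000 peaks,
4–8 sample pairs, 300–600 cells, 3 clones — chosen so the full suite runs
in minutes while every statistical check retains adequate power; all are
parameters, and nothing in the implementation depends on these scales.
Other choices worth recording:

* Seeds: every generator takes an explicit seed and restores the caller's
  RNG state; the workflow derives per-stage seeds by hashing stage names
  so stages are stochastically isolated.
* CPM refuses to double-normalize; zero-total columns are an error unless
  explicitly allowed.
* All-zero features are excluded by the count model (NA), never reported
  significant; all-zero query cells embed at the origin with a warning.
* The empty consensus (no inputs, or nothing supported by two samples) is
  a warning plus an empty, well-typed table, not an error.
* Degenerate convergence inputs (identical clone profiles, zero-variance
  correlation sets) yield an explicit `degenerate` flag with `p = NA`
  rather than a fabricated p-value.

## Known limitations

* The consensus-merge score normalization before pooling is one of
  several reasonable conventions; results are insensitive to monotone
  rescalings within a sample but not across radically different score
  definitions.
* Clone-tree reconstruction assumes variant presence is binary per clone
  at the chosen threshold; gradual heteroplasmy drift between parent and
  child clones can blur containment and will surface as conflicts.
* The convergence t-test treats pairwise correlations as exchangeable
  units; its null calibration was verified for the default three-clone
  design and should be re-checked empirically for very different clone
  counts.
* The lineage-bias chi-square switches to a Monte Carlo p-value for
  sparse tables, which makes that p-value seed-dependent (the seed is an
  argument).
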