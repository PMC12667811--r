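---
title: "Methods and design notes for neurodevatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for neurodevatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodevatlas)
```

This vignette explains the statistical procedures the package implements,
the assumptions behind them, the conventions adopted where several
reasonable choices existed, and what the synthetic-data generator does and
does not emulate. It is the place to look before trusting a number the
package produces.

## Pseudobulk aggregation and dynamic thresholding

Single-cell UMI data from a compact nervous system is sparse: a typical
cell carries a few hundred UMIs, so absence of a transcript from one cell
is weak evidence. The unit of inference is therefore the neuron class.
For each class we record two summaries per gene: the *detection
proportion* (fraction of the class's cells with at least one raw UMI) and
a *TPM-scale mean* (mean size-factor-normalized expression, with each
class column rescaled to sum to 1,000,000). Size factors are each cell's
total UMI count divided by the geometric mean of all totals, so the
factors themselves have geometric mean 1 and a cell with average depth is
left unchanged. A cell with zero total UMIs has no defined factor and is
rejected by name rather than silently dropped.

"Detected" always means at least one raw UMI. Because normalization is a
positive per-cell scaling, a normalized value is positive exactly when
the raw count was, so detection computed on the normalized matrix equals
detection on raw counts; the code relies on this equivalence.

Distinguishing real expression from ambient noise uses a per-gene
*dynamic threshold*: the cutoff for gene $g$ at stringency fraction $f$
is $f \cdot \max_c p_{gc}$, where $p_{gc}$ is the detection proportion.
TPM is set to 0 in classes whose proportion is *strictly below* the
cutoff; a class sitting exactly at the cutoff keeps its value. Zeroing is
deliberately one-way — retained entries keep their continuous TPM — which
makes thresholding idempotent and makes the zeroed set at a smaller
fraction a subset of the zeroed set at any larger fraction (both
properties are tested).

Two prefilters run before thresholding. Genes detected above 1% in
*every* class are kept wholesale as ubiquitous (their maximal proportion
is an unreliable anchor precisely because their expression is flat), and
genes below 2% in every class are removed as unexpressed. A gene
satisfying both rules is pathological (the bands overlap only for very
flat, very low genes); the ubiquitous rule wins and a warning is raised
rather than an error, since such genes are harmless to retain.

### Calibration against a ground truth

Candidate fractions are scored against a curated binary gene-by-class
truth matrix: TPR $= TP/(TP+FN)$, FPR $= FP/(FP+TN)$, and FDR
$= FP/(TP+FP)$, with FDR defined as 0 when no positives are called so a
maximally stringent threshold does not produce `NaN` in the grid.
Confidence intervals come from stratified bootstraps of the ground-truth
*genes* (classes are not resampled — the class panel is fixed by the
atlas) summarized with the bias-corrected-and-accelerated (BCa)
percentile method from the `boot` package, which also supplies the
jackknife acceleration.

Two details are conventions of this package:

* **Stratification variable.** Genes are binned into quartiles of their
  positive-class fraction in the truth matrix, so each resample preserves
  the mix of broadly and narrowly expressed genes — the property the
  point estimates are most sensitive to. Bins with fewer than two genes
  are merged into their nearest neighbor with a warning.
* **Degenerate intervals.** When a rate is constant across bootstrap
  replicates (e.g. TPR is exactly 1 at fraction 0 on an easy fixture)
  BCa is undefined; the interval collapses to the point estimate, which
  preserves the `lower <= point <= upper` invariant consumers rely on.

Point estimates never depend on the bootstrap seed, only the intervals
do; a fixed seed reproduces the table byte-identically. The default
candidate grid is 272 evenly spaced fractions on $[0, 1]$ inclusive; even
spacing is the minimal assumption for a grid of that published size, and
the grid is an ordinary function argument wherever it is consumed.
`select_levels` matches a calibration table to target (TPR, FPR, FDR)
triples by minimal summed absolute deviation, breaking ties — including
ties up to numerical precision — toward the smaller (less destructive)
fraction.

## Cross-stage comparison

Differential expression between stages runs per neuron class on cells
merged across stages and then jointly size-factor normalized and
log-transformed (merge-then-normalize, so the two stages share one
scale). The test is the two-sided Wilcoxon rank-sum, exact by
enumeration when both groups have at most 25 untied observations and the
tie-corrected normal approximation otherwise. The reported effect size is
`log2(mean(expm1(a)) + pc) − log2(mean(expm1(b)) + pc)` with group `a`
the older stage, so positive values mean higher expression at the older
stage. The pseudocount `pc` defaults to 1 on the normalized scale but is
an explicit argument, because reference single-cell toolkits have changed
this convention between versions and equivalence checks need to vary it.

Retention requires all four of: BH-adjusted p (within class, across
genes) below 0.05; absolute fold change at least 1; detection in strictly
more than 10% of the cells of the higher-expressing stage; detection in
strictly more than 5 of those cells. The higher-expressing stage is read
off the sign of the fold change. An exclusion list (genes whose loci are
unreliable, e.g. overexpressed in reporter strains) is applied last.
Filtering is idempotent.

Stability of a gene is the fraction of younger-stage-expressing classes
that still express it at the older stage; the Jaccard index additionally
penalizes gained expression. Stability is undefined for genes expressed
nowhere at the younger stage and Jaccard for genes expressed at neither
stage; both are reported as `NA` rather than 0 because "never expressed"
and "completely unstable" are different findings. The two metrics
coincide exactly when no class gains expression, which is tested.

Broad downregulation in early post-mitotic life requires differential
expression in strictly more than 10 classes in the L1-vs-L4 comparison
with at least 75% of those cases higher at L1, *and* in strictly more
than 40 classes in the embryo-vs-L1 comparison with at least 75% higher
in the embryo. Both count thresholds are strict and both direction
thresholds inclusive, following the stated criteria verbatim.

Fold enrichment of a query set in an annotation category is
$(k/n)/(K/N)$ with a one-sided Fisher exact test and Bonferroni
correction across the categories of the batch; $K = 0$ yields an
undefined fold (`NA`), not infinity.

## Transcription-factor activity

A neuron's per-gene log2 fold-change vector is regressed on *all* regulon
weight columns jointly, plus an intercept, by ordinary least squares; the
activity score of a TF is the t-statistic of its coefficient. Fitting
jointly matters: regulons overlap, and the multivariate fit attributes
shared targets rather than double-counting them. The intercept absorbs
any global shift in fold changes, making scores shift-invariant (tested).

Scores are t-statistics rather than standardized coefficients — the two
differ by a column-norm factor that would reorder TFs with very different
regulon sizes — and this is stated in the function documentation.
Rank-deficient designs (duplicated or linearly dependent regulons) drop
the collinear columns with a warning and report those TFs as untested
instead of silently regularizing: a ridge penalty would change the
statistic being reported. Perfect fits (zero residual variance) follow
two conventions needed for degenerate inputs: a zero coefficient scores
0 with p 1, a nonzero coefficient scores signed infinity with p 0.

Significance filtering applies BH within each neuron across its tested
TFs and additionally requires the TF transcript itself to be detected in
that neuron at one or more of the compared stages — activity inferred for
a TF that is never transcribed there is treated as an artifact of regulon
overlap.

## Maturation index

Within a newly born neuron class, maturation is measured as the Euclidean
distance of each cell from a baseline coordinate in the 2-D embedding.
The baseline is supplied by the user — it is the branch point between the
progenitor cluster and the post-mitotic cells, a judgment call made by
inspecting the embedding, and automating it would invent a method the
analysis does not contain. The Manhattan distance is computed for
completeness but never consumed. Gene-wise Pearson correlations against
the index use log2 of normalized expression plus one (the scale on which
such trends are usually displayed; the correlation itself is unchanged by
the monotone choice only for the noiseless case, so the scale is fixed
rather than left implicit). Constant genes have no defined correlation;
they are flagged `NA` and excluded from the Bonferroni denominator so an
uninformative gene cannot dilute the correction.

## Neuropeptide signaling networks

For one ligand–receptor pair, the directed edge from class $i$ to class
$j$ exists when $i$ expresses the neuropeptide precursor, $j$ expresses
the receptor, and the classes are mutually reachable:
$A(i,j) = NPP(i) \times GPCR(j) \times reachable(i,j)$. Reachability is
anatomical: same process bundle at short range, same body region (head,
midbody, tail — with bundles nesting inside regions) at mid range.
Interaction tables are filtered to high-potency pairs (EC50 at or below
500 nM, boundary inclusive) whose two genes are each expressed somewhere
at every stage under comparison, so cross-stage network differences
reflect rewiring rather than gene drop-in/drop-out.

Self-edges are retained by default: the product formula permits them and
autocrine signaling is biologically real; they can be removed by masking
the diagonal of the proximity matrix. Pair layers sum into a weighted
network whose weights count connecting pairs; degree is computed on the
*binarized* directed network (weights encode multiplicity, not strength).
Topology classification counts expressing neurons (via an optional
class-size table, otherwise classes) with the restricted/broad boundary
inclusive at 50.

Cross-stage comparison classifies every ordered class pair in the union
of the two edge sets by its pair-set relation: identical sets, shared but
not identical, disjoint (edge conserved but molecularly re-implemented),
or stage-specific. The categories partition the edge union (tested), and
conserved fractions are reported against each stage's own edge count,
since the two stages generally differ in connectivity density.

## Connectome-conditioned enrichment

EM reconstructions resolve single cells; expression resolves classes.
Cell-level adjacency matrices are collapsed by summing member-cell
entries, and an entry survives only if its class-level counterpart is
nonzero in every confirmer reconstruction — connections seen in a single
animal are treated as unreliable. Contact matrices are symmetrized by
elementwise max (membrane contact is mutual); synapse matrices stay
directed. A synapse without a backing contact (possible after confirmer
filtering) is zeroed with a warning, keeping the containment invariant.

Enrichment asks, per focal neuron and candidate gene: is the gene's
thresholded TPM higher in the classes contacting the focal neuron than in
those not contacting it (contact enrichment), or higher in synaptic
partners than in adjacent-but-non-synaptic classes (synaptic enrichment,
separately for presynaptic inputs and postsynaptic outputs)? The test is
Welch's unequal-variance t with Welch–Satterthwaite degrees of freedom,
two-sided, implemented in closed form so that a gene absent from both
groups yields t 0 and p 1 instead of an error. Fold changes add 1e-5 to
each group mean before the log2 ratio, so a gene expressed at mean 0.5 in
one group and absent from the other reports
$\log_2(0.50001/0.00001) \approx 15.61$. P-values are BH-adjusted across
the genes actually tested for that focal neuron (genes expressed in none
of the grouped classes are not tested, and the denominator choice is
visible in the output row count). Focal neurons with fewer than three
synaptic partners in the requested direction are skipped entirely, and
groups smaller than two classes are reported untested rather than forced
through a variance estimate.

This design detects genes expressed broadly across one group. A gene
restricted to one or two partners of a single circuit shows a large fold
change but cannot reach significance — such candidates are found by
ranking fold changes among non-significant rows, and the tests assert
this behavior rather than "fixing" it.

## The synthetic-data generator

The generator exists so every analysis can be exercised against inputs
with known truth. It emulates:

* **Counts.** A hurdle model: gene $g$ is detected in a cell of class $c$
  with probability $p_{gc}$; detected entries draw a zero-truncated
  negative binomial (mean 2 UMI, dispersion 1 by default) scaled by a
  per-cell log-normal library factor (sigma 0.3). The truncation makes
  detection exactly Bernoulli in $p_{gc}$, which is what the thresholding
  calibration assumes; means are centered so the library factor has unit
  expectation. The low default mean matches the few-hundred-UMI regime of
  whole-animal larval dissociation.
* **Ground truth.** Expressed means planted detection probability at or
  above a cutoff `p_on` (boundary inclusive — a convention that must be
  fixed for reproducible fixtures), restricted to a designated gene
  subset playing the role of the curated panel.
* **Lineages.** A progenitor cluster at the origin with branches
  radiating at equal angles; planted genes are linear in true distance
  (the simplest monotone signal whose recovery can be scored by a
  correlation sign) with Gaussian noise, sd 0.5 by default.
* **Interaction tables, bundles, connectomes.** EC50-annotated pair
  tables with a controllable high-potency fraction; bundle and region
  assignments with bundles nested in regions; symmetric contact graphs
  with directed synapse subgraphs drawn from contact edges (containment
  by construction); and per-class log-scale expression,
  $\max(N(2, 1), 0)$, with planted shifts added to the synaptic-partner
  sets of designated focal classes and the truth recorded.

It does **not** emulate doublets, ambient RNA contamination, batch
effects, gene-length or capture biases, realistic gene catalogs, or
spatially continuous anatomy. Passing tests on synthetic data therefore
demonstrate that the procedures are implemented correctly and recover
planted signal under the stated statistical model — not that the model
captures every failure mode of real droplet data.

## Problem sizes, determinism and numerical conventions

The test suite runs at desk scale: calibration fixtures use 40
ground-truth genes over 10 classes with a few hundred bootstrap
replicates; differential-expression recovery uses 300 genes and 100 cells
per group with a planted 4-fold change in 20 genes; TF-activity ranking
uses 200 genes, 8 TFs and 100 replicates; enrichment calibration uses
about 700 gene–neuron null tests and 50 planted-recovery replicates.
These sizes were chosen so the full suite completes in well under a
minute per module while leaving the binomial/replicate standard errors
small relative to the asserted margins.

Every generator takes an explicit integer seed and restores the caller's
RNG state, so fixtures are byte-reproducible and generators can be nested
without interference. Comparisons against closed-form oracles use
tolerances of 1e-8 to 1e-12; statistical assertions use 3-standard-error
bands around their nominal values.

## Known limitations

* The BCa machinery targets tables of tens-to-hundreds of ground-truth
  genes; with very few genes per stratum the intervals fall back to
  extreme order statistics and should be read qualitatively.
* Statistical power of the synaptic-enrichment test at its boundary
  conditions is limited: with an expression shift of 2 (two noise SDs),
  groups near 8 versus 20 classes, and BH correction over ~40 candidate
  genes, per-replicate recovery sits near 75–90% rather than above 90% —
  the multiplicity burden dominates exactly at the smallest admissible
  partner sets. Recovery improves quickly with partner count, effect
  size, or the number of genuinely enriched genes sharing the BH
  budget. One property-style test asserting ≥90% recovery at this
  boundary documents the shortfall by failing, deliberately, rather than
  relaxing the generator's noise model post hoc.
* Degree, topology and conservation summaries describe the binarized
  networks; no statistical model of edge uncertainty is attached to them.
* The maturation baseline is user-supplied; results inherit that
  judgment.
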