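---
title: "Scoring two-dimensional screens and droplet QC with zeta statistics"
author: "ZetaScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring two-dimensional screens and droplet QC with zeta statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ZetaScreen)
```

# The problem

A two-dimensional high-throughput screen perturbs thousands of genes
(siRNA/shRNA pools, CRISPR guides) and reads each perturbation out on
hundreds of functional measurements — alternative-splicing isoform ratios,
per-cell-line dependency scores, and so on. Classical one-dimensional hit
calling (per-readout Z statistics with multiple-testing correction)
collapses in this setting: with hundreds of readouts per gene, small
per-readout error rates accumulate until most "hits" among genes that are
not even expressed in the assay cells are false positives. Tightening the
per-test threshold (Bonferroni, BH, or extreme-value models on per-gene
maximum |Z|) does not rescue specificity, because a single extreme readout
is exactly what noise produces; what distinguishes a real regulator is
*many moderately strong readouts at once*.

The zeta statistic formalises that intuition as an area. `ZetaScreen`
implements it end to end: Z-scoring against negative controls, survival
curves over a Z-cutoff grid, an SVM background boundary learned from
control curves, hit selection on the Screen Strength curve, siRNA
off-target flagging, consensus gene networks, a per-cell variant for
droplet single-cell QC, the multiple-testing baselines used for
comparison, and a synthetic-data generator that makes the whole pipeline
testable offline.

# The zeta score

## Z matrix

For raw measurements $N_{ij}$ (perturbation $i$, readout $j$),

$$Z_{ij} = \frac{N_{ij} - \mu_j}{\sigma_j},$$

with $\mu_j$, $\sigma_j$ the mean and *sample* standard deviation of the
negative-control rows in column $j$ (`zTransform()`). Columns whose
negative controls are constant carry no usable scale and are dropped with
a warning. Upstream, `filterDropouts()` removes rows and then columns
whose missing-value counts exceed $Q_3 + 3(Q_3 - Q_1)$ of the per-row
(per-column) missing counts — quartiles by linear interpolation (R type
7), a single pass, rows first — and `imputeKNN()` (default $k = 10$)
fills remaining gaps from the $k$ nearest rows by Euclidean distance over
mutually observed columns, scaled by the fraction observed, ties broken
by row order.

## Survival curves

The cutoff grid spans $[2, Z_{\max}]$ in the positive direction and
$[-Z_{\max}, -2]$ in the negative, where $Z_{\max}$ is the entry of rank
$\lfloor NM \times 0.999\rfloor$ in the ascending $|Z|$ values — the top
0.1% of entries are treated as outliers, and $|Z| < 2$ (two-sided tail
0.046) as experimental noise. The grid is divided into 100 equal bins;
for every perturbation, the fraction of readouts at or beyond each bin
edge gives the survival curve $P_m$ (`buildZetaCurves()`). We evaluate
$P$ at all 101 bin edges so that each bin contributes a trapezoid; this
also realises the "cutoff at the bin edge nearer zero" convention, since
every edge is a cutoff.

## Boundary and area

With enough controls of both classes, a radial-kernel SVM
(`fitSvmBoundary()`, via e1071) is trained on the (cutoff, fraction)
points of positive- versus negative-control curves. The boundary value
$S_m$ at each cutoff is the fraction at which the decision function
changes sign, extracted by bisection on $[0, 1]$ to $10^{-6}$; bins where
the decision function does not change sign clamp to 0 or 1 according to
the predicted class at the bin's base. Cutoffs are standardised before
training; the kernel width uses the median heuristic on the training
points, cost defaults to 1, and the RNG seed is recorded in the model
parameters. Non-separable controls produce a warning, not an error: the
boundary is still returned and drives scores toward zero.

The per-gene score integrates the excess of the gene's curve over the
boundary:

$$\mathrm{Area}_m = \begin{cases}
\dfrac{(P_{m+1} + P_m) - (S_{m+1} + S_m)}{2}\,\mathrm{step} &
  \text{if } (P_{m+1}+P_m) > (S_{m+1}+S_m)\\[2pt]
0 & \text{otherwise,}
\end{cases}$$

and without a boundary $\mathrm{Area}_m = (P_{m+1}+P_m)\,\mathrm{step}/2$.
The *weighted* score multiplies each bin's area by the absolute Z value
of the bin midpoint, so responses at high $|Z|$ count more; the absolute
value makes both directions accumulate non-negative scores (the weight
could equally be the bin edge or index — the midpoint is the natural
choice for a trapezoid and is symmetric in both directions). By default
the two directional scores are summed into one global-activity score
(`combineDirections()`); both are available separately.

Two invariants worth knowing: $\zeta_{\text{no SVM}} \ge
\zeta_{\text{SVM}} \ge 0$ for every gene, and $\zeta$ is invariant under
permutation of readout columns.

# Hit selection: Screen Strength

Non-expressors — genes not expressed in the assay cells, whose reagents
can only act through noise or off-targets — serve as internal true
negatives. With `bFDR` their overall fraction among scored genes and
`aFDR(c)` their fraction among hits at zeta cutoff $c$,

$$SS(c) = 1 - \frac{aFDR(c)}{bFDR}$$

measures how much better the cutoff does than a random draw
(`screenStrength()`; 100 even cutoffs from the smallest to the largest
score, tail cutoffs without hits trimmed). Control rows are not screened
genes and are excluded from the universe.

**Balance points.** The source concept — the cutoff beyond which more
stringency buys little more SS — needs an operational definition, which
this package fixes as follows (`findBalancePoints()`): cutoffs with fewer
than 5 hits are discarded (tiny aFDR denominators); SS is smoothed by a
centred moving average of width 5; a balance point is the first cutoff of
each maximal run where the absolute forward slope stays below
$0.05 \times \mathrm{range}(SS)/\mathrm{range}(c)$ for at least 5
consecutive steps, provided smoothed SS is positive there and exceeds the
previous balance point's value. The *first* balance point must
additionally be preceded by a net SS rise of at least 25% of the SS
range. That last condition is what makes permuted (information-free)
rankings return an empty result: a permuted score multiset produces long,
perfectly flat SS stretches hovering near zero — plateaus without any
preceding climb — and a plateau only deserves the name if the curve
climbed to it. The absolute value in the slope criterion likewise stops
noisy *decreases* from registering as plateaus.

**Empirical false-positive levels.** `fplCutoffs()` returns, for each
level (defaults 0.05 and 0.01), the smallest grid cutoff at which the
fraction of non-expressors scoring at or above it drops to the level.
Levels live in $(0, 1]$ (level 1 returns the minimum score). FPL is
defined on non-expressors, not negative controls: it estimates the error
rate among *genes*, which is what a screener acts on.

`callHits()` labels genes none / candidate (between BP1 and BP2) /
high-confidence (at or above BP2), with FPL and manual cutoffs as
fallback modes when fewer than two balance points exist.

# Off-target flagging

RNAi reagents silence unintended transcripts through partial
complementarity. A hit pool is flagged (`flagOfftargets()`) only when two
independent lines of evidence coincide:

1. **sequence** — one of its single-siRNA guides has $\ge 11$ nt of
   contiguous reverse-complement identity to another hit gene's
   transcript (`complementarityScan()`; U and T equivalent, strict
   Watson–Crick, no G·U wobble — conservative, since wobble pairing
   would only add candidate matches);
2. **response** — that same siRNA (in the secondary screen of
   deconvolved single siRNAs; or the pool itself when no secondary
   screen exists, reported at lower confidence) correlates with the
   other gene's primary response at Pearson $r \ge 0.6$.

The correlation filter is evaluated first because it is vectorised and
cheap; sequence scans run only on surviving pairs. The scan itself walks
the alignment diagonals and reports every maximal run of at least the
minimum length with 1-based inclusive transcript coordinates; it agrees
with a quadratic-time longest-common-substring oracle by construction
and by test. `attributeToSingleSirna()` implements the companion logic:
two or more correlated singles mean genes of genuinely related function,
exactly one suggests an off-target artefact.

After flagging, `removeOfftargets()` rebuilds the SS curve with the
flagged pools dropped from the hit side while *keeping the baseline FDR
fixed at the original screen's value*. Removal is an editorial act on the
hit table, not a change of assay: re-deriving bFDR from the reduced gene
set would let SS dip at cutoffs where the removed pool was not a hit,
which would misreport what filtering did. With the baseline fixed,
removing a flagged non-expressor can only raise SS.

# Consensus networks

`consensusCluster()` builds gene–gene distances $1 - |r|$ under both
Pearson and Spearman correlation of the hits' Z profiles, runs seeded
k-means restarts (default 50 per distance and per $k$) on classical MDS
coordinates of each distance matrix, and scores each pair by the
fraction of runs in which it lands in one cluster. Final labels come
from average-linkage hierarchical clustering of $1 - \text{consensus}$,
cut at the $k$ with the largest second difference of the total
within-cluster sum of squares across the candidate range (the "elbow" as
a maximum-curvature rule). Edges keep pairs with consensus $\ge 0.5$,
signed by the Pearson correlation, so antagonistic regulators appear as
anti-correlated edges; disconnected nodes are trimmed and the graph
exports as GraphML with zeta as node size and cluster as colour
(`exportNetwork()`).

# Droplet single-cell QC

A cell's quality shows jointly in its depth (nCount), gene diversity
(nFeature) and mitochondrial share; each single metric fails on some
class of bad droplet. The per-cell zeta integrates the full count curve:
with ten dataset-global thresholds $t_1 < \dots < t_{10}$, the curve
$y_b$ = number of genes with count $\ge t_b$ is integrated by trapezoids
(`cellZeta()`) — no boundary, no weighting (rank order is all that is
used downstream). Thresholds are log-spaced from 1 to the 99.9th
percentile of pooled nonzero counts, reflecting the skew of count data;
the y axis uses raw gene numbers, so the score's unit
(gene × count-threshold) matters only relatively.

The pass cutoff (`zetaCutoff()`) is data-driven: a kernel-density
estimate of $\log(1+\zeta)$ (Silverman bandwidth), the two largest modes
located (ambient/empty droplets low, intact cells high), and the cutoff
placed at the *first* convex-to-concave inflection of the density after
the inter-mode valley — the base of the second population, where the
intact-cell mass starts to rise. Between the valley and the peak a
mixture density can flip curvature more than once; taking the crossing
nearest the peak would sit at roughly one bandwidth below the mode and
would by construction cut a double-digit percentage of any
Gaussian-like population, which is not a usable QC rule. If no inflection
exists the inter-mode minimum is used; a unimodal density warns and
falls back to $Q_1 - 1.5\,\mathrm{IQR}$ with an explicit
`bimodal = FALSE` flag. `compareMetrics()` reports per-metric ROC AUCs
(pROC), each oriented so that the reported AUC is $\ge 0.5$ with the
orientation stated.

# Multiple-testing baselines

`bonferroniZThreshold()` converts a family level over $m$ tests to the
two-sided normal quantile ($\alpha = 0.01$, $m = 15{,}000$ gives a
per-test p of $6.67\times10^{-7}$ and $Z = 4.97$ — the 4.97 is
consistent only with a two-sided reading, which is why the package states
two-sided explicitly). `gumbelThreshold()` fits a Gumbel law to the
per-row maximum $|Z|$ by maximum likelihood (moment start values,
BFGS at relative tolerance $10^{-8}$; the MLE is written out directly
rather than delegated, and is cross-checked in the tests against a
general-purpose distribution fitter) and converts corrected per-row
p values (Bonferroni or BH) to a $|Z|$ cutoff. A property worth noting:
on iid normal data the fitted location grows with the readout count, but
the family cutoff itself is nearly flat in $M$ because the fitted scale
shrinks in step — extreme-value corrections are uniformly stringent
rather than increasingly so. `downsampleReadoutEval()` reruns the zeta
pipeline on column subsets drawn without replacement (defaults 50–300 in
steps of 50, 3 replicates) and reports the fraction of full-set
reference hits recovered.

# The synthetic generators

`simulateScreen()` emulates the structure the pipeline assumes, with
defaults fixed at the study conditions the package is validated under:
300 readouts; 1,800 regulators and 200 non-expressors (2,000 screened
genes); each regulator perturbs 30% of readouts by 6 measurement units
against noise sd 1 (so perturbed readouts sit near $|Z| = 6$), signs
split evenly between directions; 10 positive controls replicate one
strong regulator's profile (as repeated wells of a reference siRNA
would); 30 negative controls. Effects are additive on the measurement
scale *before* Z-scoring, so effect size in Z units is
`effectSize / noiseSd` and recovery thresholds stay interpretable.
Optionally it plants off-target artefacts: a non-expressor pool inherits
a regulator's response, exactly one of its four single siRNAs carries
that response in the generated secondary screen, and that guide receives
a 21-nt reverse-complement island to the regulator's transcript at a
recorded position. Everything is deterministic given the seed.

`simulateDroplets()` emulates the four droplet classes of a dissociated
tissue run: high-quality cells (negative-binomial counts, median depth
4,000, overdispersion 0.5), empty droplets (ambient-pool Poisson counts,
median depth 250), broken cells and stripped nuclei (depleted
mitochondrial and ribosomal content at reduced depth). Two modelling
choices matter and are deliberate. First, broken cells leak cytoplasmic
mRNA *selectively by abundance*: a gene's loss is the cell's lysis
severity (uniform 0.5–0.95) times its cytoplasmic fraction, which grows
with abundance rank from 0.3 to 0.9, mitochondrial genes exempt. Broken
cells therefore keep moderate total counts and near-normal gene
diversity while their mitochondrial share rises — the configuration that
makes single metrics unreliable and an integrated score necessary.
Second, *every* droplet captures ambient RNA, not only the empty ones.
Gene-group count shares are pinned (8% mitochondrial, 25% ribosomal in
intact cells) so composition does not swing with the seed, and the
cell-depth spread (sdlog 0.12) keeps the high-quality zeta mode tight
and well separated from the ambient mode — the regime in which a
density-based cutoff is the right tool.

What the generators do *not* model: plate and edge effects, batch
structure, guide-specific efficacy, realistic transcript sequence
composition, doublets, and UMI saturation. Tests passing on this
synthetic data show the algorithms do what they claim under their own
assumptions; they do not certify performance on any real screen.

# Numerical choices and degenerate inputs

* Quantiles are linear-interpolation (type 7) throughout; standard
  deviations are sample ($n-1$) standard deviations.
* The 99.9% rank uses $\lfloor NM \times 0.999 \rfloor$ on ascending
  $|Z|$ with ties in stable order; a range not exceeding $|Z| = 2$ is an
  error ("signal range does not exceed noise threshold").
* SVM bisection tolerance $10^{-6}$; at most 25 halvings.
* KNN imputation reduces $k$ with a warning when fewer candidate rows
  observe a column; a row with no observed values is an error.
* An all-zero cell has zeta 0 and simply fails any positive cutoff; an
  empty hit list is a valid result everywhere.
* k-means uses 50 iterations per restart; duplicate profiles make the
  MDS embedding rank-deficient, which is tolerated (fewer informative
  axes).
* All stochastic steps (SVM fit, clustering restarts, generators) take
  explicit seeds and restore the caller's RNG state.

# Problem sizes in the test suite

The packaged tests validate the full study conditions directly: the
screen recovery checks run the complete 2,000 × 300 screen, the droplet
checks the complete 10,000-droplet mixture, and the oracle comparisons
100 random curves and 1,000 random guide/transcript pairs; unit tests
use smaller instances of the same generators. The whole suite and the
acceptance script each complete in a few minutes on a single CPU.

# Known limitations

* The balance-point detector is *an* operationalisation of an informal
  concept; its parameters (window 5, slope tolerance 0.05, minimum rise
  0.25) reproduce the intended qualitative behaviour — two plateaus on
  curves with two quality tiers, none on permuted data — but published
  balance points from other implementations will not be matched
  numerically.
* The density-based droplet cutoff assumes a visibly bimodal zeta
  distribution. With broad per-cell depth variation the low flank of the
  intact-cell mode stretches, and the inflection cutoff will trim
  genuine low-depth cells; the `bimodal` flag and the returned density
  should be inspected before trusting the pass list.
* Off-target detection is limited to contiguous complementarity; seed
  enrichment and thermodynamic models are out of scope, and the 11-nt
  criterion is position-agnostic (no seed-region requirement is
  imposed).
* The consensus network reduces the SC3-style pipeline to two
  correlation distances with MDS + k-means; it is a similarity summary,
  not a causal structure.
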