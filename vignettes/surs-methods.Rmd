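---
title: "Designing and characterizing synthetic upstream regulatory sequences"
author: "surs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and characterizing synthetic upstream regulatory sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surs)
```

This vignette is the package's account of its methods: the generative and
statistical models it implements, the parameters that matter and their
defaults, the numerical decisions, and what the built-in simulator does and
does not establish about real data.

## The experimental design the package encodes

A synthetic upstream regulatory sequence (sURS) is a 101-bp "desert"
chassis — a sequence computationally scrubbed of known transcription-factor
binding sites — carrying 0 to 3 binding motifs at fixed positions: base 46
for single-motif variants, bases 28 and 66 for doubles, bases 18, 46 and 74
for triples (1-based starts). With nominal 10-nt motifs this gives 17-bp
spacing between motifs; longer motifs (the catalog allows up to 13 nt) keep
the same fixed starts, so spacing shrinks accordingly, and a motif that
would overrun the next slot is rejected as a placement error rather than
shifted. For an *m*-motif catalog, enumerating every ordered arrangement
with repetition yields $\sum_{k=0}^{3} m^k$ variants; the 41-motif
configuration gives 70,644, including the motif-free desert variant.

Each variant is synthesized behind one or more 15-nt barcodes. Barcodes are
rejection-sampled under the design constraints — pairwise Levenshtein
distance at least 3, GC fraction within [0.35, 0.65], homopolymer runs of at
most 3, and no SpeI (`ACTAGT`) or EagI (`CGGCCG`) site — and oligos are
assembled as `5' primer + SpeI + barcode + variable region + EagI + 3'
primer`. The design-side constraint is enforced as Levenshtein distance
(which implies Hamming distance at least 3 for equal-length barcodes) while
read matching uses Hamming distance; this reconciles the two distance
notions that appear in the assay's design and read-processing stages.
Restriction sites are also excluded from the chassis and checked at every
junction, because a single internal site would be cut during cloning; for
mixed-base designs the check treats K/M as ambiguity codes so that no
realization of the oligo can contain a site.

Two deliberate interpretations are worth recording. First, the reference
library reports 189,990 designed oligos, while 70,644 variants at 2 barcodes
each plus 2,435 deep variants at 22 barcodes gives
$70{,}644 \cdot 2 + 2{,}435 \cdot 20 = 189{,}988$; the manifest reports its
own row count and does not force the printed figure. Second, whether the
deep-barcode draw excluded the desert variant is unspecified; the package
draws uniformly from all variants.

## Mixed-base motifs

Motifs are encoded for mixed-base synthesis over `{A,C,G,T,K,M}` with
`K` = G/T and `M` = A/C, at most four mixed positions per motif. PWM
encoding proceeds column-wise with single-base dominance checked before the
pair rules: a column whose top base reaches the pair threshold emits that
base (so a column with G at 0.9 emits `G`, not `K`); otherwise a combined
G+T or A+C frequency at or above the threshold emits `K` or `M` (K checked
first); otherwise the single most probable base is emitted, ties broken
alphabetically. The threshold defaults to 0.70 and is exposed as a
parameter: the empirically observed 73% in the reference design is a
property of that design's PWMs, not a rule, and the package does not try to
reproduce it. Only K and M are supported, matching the two-base mixtures the
synthesis chemistry provides; R/Y/S/W degenerate codes are rejected at
parse time.

A motif with $k$ mixed positions expands into exactly $2^k$ concrete
sub-motifs (up to 16 at $k=4$), listed in lexicographic order of the
assignment string. Expansion and collapse are exact inverses, a property
the test suite asserts over random motifs.

## Read processing

Merged reads are processed in a fixed pipeline whose first failure is the
read's rejection reason: length filter (default minimum 200 bases), forward
primer location, bin-barcode demultiplexing (only when reads arrive pooled;
with one file per bin, the file determines the bin), variant-barcode
matching, and full variable-region verification. Barcode matching uses
Hamming distance with undetermined bases (N) counted as mismatches, capped
at 2 — below the designed minimum distance of 3, so a single error can
never switch identity, while two errors can create ties, which are rejected
as ambiguous rather than guessed. Body verification is exact outside mixed
positions (configurable tolerance, default 0); at K/M positions the observed
base must belong to the allowed pair and is recorded as the read's
sub-variant assignment, so sub-variant tallies always marginalize exactly to
variant tallies.

## Expression quantification

Counts $r_{vb}$ for variant $v$ in bin $b$ with per-bin totals $T_b$ are
normalized in the assay's six steps: fractions $r_{vb}/T_b$ are scaled by
the percentage histogram area $\%Bin_b$ of each bin in the sort, summed per
variant, and renormalized, giving a per-variant distribution
$(x, y, z, w)$. Expression is the bin-weighted mean
$\sum_b MeanBin_b \cdot n_{vb}$ with default calibration means
$(607, 1364, 2596, 7541)$ A.U., so expression is bounded by the extreme bin
means and is strictly increased by moving probability mass upward. Per-bin
sequencing depth cancels exactly. The bin areas are a required calibration
input read from the FACS histogram; they default to uniform (25% each),
which is also what the simulator's quartile gate placement produces.

Variants are classified into quality groups: group 3 below 40 total reads
(under-sampled), group 2 at or above 40 reads but with more than 90% of
normalized mass in the top bin (saturated), group 1 otherwise. The source
description uses both "at least 40" and "below 40" for the boundary; the
package defines group 3 strictly as `total_reads < 40`, so a variant with
exactly 40 reads lands in groups 1/2. Downstream analyses use group 1.

Expression is computed per barcode and aggregated per variant by
read-weighted averaging of the normalized vectors (the default), which
preserves the pooled-bin estimate when barcodes have similar depth; pooling
raw counts before normalization is available as an explicit mode, since the
assay description does not fix the aggregation order.

Cohort statistics mirror the assay's descriptive analyses: per-motif
expression distributions over variants containing a motif at least once
(the "desert motif" group is defined as variants with an unfilled motif
slot, i.e. arity below the design maximum); a rank-shift screen comparing
each motif group against the pooled groups ranked at least 5 medians away
(two-sided Wilcoxon rank-sum, Benjamini–Hochberg at FDR 0.10); Pearson
correlations between same-variant barcode pairs computed on the normalized
4-bin vectors; and the correlation between group medians and group sizes.

## Minimum-hypergeometric enrichment

For a motif, variants are ranked by expression — descending to detect
activating enrichment, ascending for repressing — and labeled 1 when they
contain the motif. With $N$ variants, $B$ labeled, and $b(n)$ labels in the
top $n$, the mHG statistic is

$$\mathrm{mHG} = \min_{1 \le n \le N-1} P\big(X \ge b(n)\big), \qquad
X \sim \mathrm{Hypergeom}(N, B, n),$$

the minimal prefix tail (the full list, where the tail is 1, is excluded;
no maximal-prefix restriction is applied). Tails are computed in log space.
The exact p-value is the probability that a uniformly random arrangement of
$B$ ones attains a minimum at most the observed score. It is computed by
dynamic programming on the $(n, b)$ lattice: the hypergeometric random walk
is propagated step by step while every cell whose tail is at most the score
(within a $10^{-9}$ log-space tolerance) is zeroed; one minus the surviving
mass at $(N, B)$ is the exact p-value. The DP is validated in the test
suite against exhaustive enumeration of all arrangements for every
$N \le 12$ and every $B$, and satisfies
$\mathrm{mHG} \le p \le \min(1, N \cdot \mathrm{mHG})$ everywhere. Because
the statistic is order-sensitive, expression ties are broken by a stable
sort on variant id.

Motifs are tested in both directions at a fixed cutoff (default
$\alpha = 10^{-4}$; chosen in the reference analysis from the desert
motif's score and the empirical jump in the p-value spectrum, and therefore
not multiplicity-corrected further): activating when significant up but not
down, repressing for the reverse, undetermined otherwise; the
never-expected both-significant case is flagged as a conflict rather than
silently assigned. Sub-motif enrichment expands every mixed-base motif,
realizes each observed sub-variant's variable region, labels records by
substring containment, and runs the same test per sub-motif — so parent
motifs pool their sub-variants while sub-motif analyses split them, and a
21-plain / 20-mixed catalog yields 21 plain motifs plus the expanded
sub-motifs as analysis units.

## Regulatory models

**Motif-additive model (MAM).** Predicted expression is multiplicative in
the core promoter level: `core × fold`, with
`fold = (intercept + slope · Σ boosts) × attenuation^[any repressor]`.
Boost weights default to $-\log_{10}$ of each activating motif's exact
up-direction mHG p-value, with every occurrence counting (repetition adds).
Attenuation is a single factor (default 0.5, the observed constant roughly
two-fold down-regulation) applied once regardless of how many repressors
are present — the observed asymmetry between additive boosting and
saturating attenuation. The exact functional form linking summed evidence
to fold is not published; the package adopts a linear calibration fitted by
least squares to measured folds against mean $-\log_{10} p$, which is the
closest reading of the observed linear dependence, and flags it as a
modeling choice (`fit_mam_calibration` reports the fit and its Pearson r).
The intercept defaults to 1 so a motif-free cassette predicts the bare core
level.

**Convolutional ensemble.** The sequence model is a 1-D convolution (ReLU)
over one-hot DNA, global max pooling, a dense ReLU layer and a linear
output for expression — or a 4-way softmax for the bin distribution, with a
weighted cross-entropy whose per-bin weights are inversely proportional to
each bin's read mass (normalized to mean 1); the exact per-bin weighting of
the reference loss is unspecified, and this inverse-mass choice is
documented here as the package's own. Training uses Adam at the
framework-conventional learning rate of $10^{-3}$, squared-error loss on
internally standardized targets, optional sample weights proportional to
read support (normalized to sum to 1 so the loss scale is batch-invariant),
and an ensemble of independently initialized members whose mean is the
prediction. Inputs shorter than the maximum length are uniform-padded at
0.25 per channel, which keeps column sums at 1 and lets a model trained on
101-nt library variants score longer (e.g. 186-nt) designs. The hybrid
configuration concatenates a per-catalog motif-count vector after the
pooling layer, combining sequence-level features with motif occurrences.
The barcode region is excluded from the input by default, since including
it was observed not to change predictive performance.

No deep-learning framework is used: the network and its training loop are
implemented in base R matrix algebra, which is entirely adequate at the
package's scale. Defaults are desk-scale — 64 kernels of width 6, 16 dense
units, 5 epochs, batch 32, ensemble of 5 — chosen so that ensembles train
in seconds on one CPU; `cnn_config(paper_config = TRUE)` restores the
full-scale reference setting (1024 kernels, 100 members). Hyperparameters
beyond these are deliberately not searched. Training cohorts follow the
three standard selections: all-data (top variants by read support),
all-motif (deep-barcode variants) and mixed-base-only (deep-barcode
variants containing a mixed motif, a subset of the former by construction).

**Evaluation.** Pearson correlation with two bootstrap schemes: exhaustive
subsets of size $n-2$ for small validation sets (all 55 subsets of 9 from
11 points), and 100 random subsets of fixed size (30, or 16 for small
condition datasets) otherwise.

## The simulator: what it emulates and what it does not

The simulator provides ground truth for every stage. Each variant's latent
log-expression is $\mu_0 + \sum_i \beta_i \cdot \text{count}_i +
\mathcal{N}(0, \sigma_v)$ — additive motif effects on the log scale,
i.e. multiplicative regulation, mirroring the motif-additive picture. Cell
fluorescence is log-normal around the latent value with spread $\sigma_c$;
gates default to the quartiles of the pooled distribution (as a sorter
operator would place them), giving each variant a 4-bin membership
distribution with the expected first-order stochastic-dominance behavior.
Per-bin read counts are multinomial across variants with probability
proportional to abundance times membership; abundance is uniform by default
(one integrated locus per cell), configurable for stress tests. Read
simulation emits full oligos inside fixed amplicon pads (so standard
designs always pass the 200-base filter), realizes K/M positions uniformly,
and applies independent substitution errors only — no indels, matching the
barcode-matching tolerance model. Everything is seeded and byte-identical
across runs.

Defaults: $\mu_0 = \log 1500$ (centering the fluorescence range of the
four-bin calibration), $\sigma_v = 0.05$, $\sigma_c = 0.4$. The recovery
checks in the test suite run at the stated study conditions: planted
effects of magnitude $1.5\sigma_c$ across roughly 2,000 variants at 50
reads per variant for motif classification, and 1,000 reads per variant
for the expression-consistency check. The reduced-scale hybrid-model check
trains a 3-member, 32-kernel ensemble on noise-free additive truth and
evaluates on 300 held-out variants.

The simulator does **not** model PCR amplification bias, sorting impurity,
growth effects between sorting and sequencing, chromatin context, indels,
or barcode-specific sequence effects. Passing recovery tests therefore
demonstrates the correctness and statistical power of the pipeline under
the stated generative model, not the biological fidelity of that model;
with real data, the noise sources above can and do dominate (which is
precisely why the deep-barcode subset and quality groups exist).

## Numerical and degenerate-input decisions

- Hypergeometric tails and the DP run in log space / probability space with
  a $10^{-9}$ tolerance when testing membership in the rejection region;
  for lists with no labeled items ($B = 0$, or $B = N$) the score and
  p-value are 1 with an undefined cutoff.
- Zero-read variants are flagged and excluded from expression rather than
  producing NaNs; zero-variance vectors in correlation computations are
  flagged as undefined rather than silently dropped.
- Rejection-sampled generators (chassis, barcodes) are seeded and fail with
  an explicit infeasibility error when their attempt budget is exhausted,
  reporting what was achieved; they never silently relax a constraint.
- The exclusion-database filter follows the retention contract exactly:
  all-upper-case motifs need only length ≥ 5, motifs containing lower-case
  characters need more than 5 upper-case characters, and retained
  lower-case positions become `N` wildcards.
- `workflow` orchestration is exposed as the `run_pipeline()` function (and
  the package's function surface) rather than a shell entry point, since
  the package's users drive it from R.

## Known limitations

- The mHG analysis assumes a total order on expression; heavy ties (e.g.
  many saturated variants) make results depend on the documented
  tie-break. Use group-1 variants as intended.
- The exact p-value DP is $O(NB)$ per motif; for very deep analysis sets
  (hundreds of thousands of variants) a bound-based short-circuit would be
  needed.
- The MAM's linear calibration is an interpolation over the observed
  evidence range; extrapolating fold predictions far beyond the calibrated
  $-\log_{10} p$ range is not meaningful.
- The CNN is intentionally small; at desk scale it demonstrates recovery of
  additive structure, not state-of-the-art sequence-to-expression accuracy.
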