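---
title: "Methods: scoring and calibrating a barcoded yeast one-hybrid deep mutational scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and calibrating a barcoded yeast one-hybrid deep mutational scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and its model

`y1hscan` analyses deep mutational scans in which a transcription factor's
DNA-binding domain (the motivating system is the 150-residue PAX6 paired
domain plus flanking sequence) is fused to an activation domain and
expressed in yeast carrying a DNA bait element upstream of an antibiotic
resistance gene. Variants that bind the bait confer resistance; in
competitive growth under antibiotic, binding-competent variants enrich and
binding-dead variants deplete. Each expression plasmid carries a random
30-nt barcode, many barcodes per variant, and barcode frequencies are read
out by sequencing at successive timepoints.

The generative model the scorer assumes is exponential competitive growth:
a barcode $b$ carrying variant $v$ has latent abundance

$$n_b(t) = n_b(0)\, e^{(r_0 + s_v)\, t / t_{\max}},$$

where $r_0$ is the shared baseline growth rate and $s_v$ a variant-specific
selection coefficient. Sequencing draws a fixed read depth per timepoint
multinomially from the current abundance frequencies. Time is normalized to
$x = t/t_{\max} \in [0,1]$ (for the default 0/12/24/36 h design,
$x = 0, \frac13, \frac23, 1$), so selection coefficients and fitness scores
share a per-experiment scale. The cited scoring tool does not document its
internal time scaling; any affine choice of $x$ only rescales all scores by
a common factor, so this choice is cosmetic but fixed.

# Preprocessing

Barcodes are the first 30 nt of read 1 (the sequencing primer anneals
immediately upstream), taken verbatim with no error correction: the
upstream protocol trims flanks and counts exact sequences, and a mismatch
tolerance would require an error model the data do not constrain. Reads
shorter than the barcode or containing `N` in the barcode window are
tallied as unmatched. Counting is restricted to barcodes present in the
barcode–variant map; unmapped barcodes are tallied per timepoint. The
25-read floor is applied to the first timepoint (T = 0, antibiotic
addition) *after* mapping — whether the original pipeline filtered before
or after mapping is unstated, and filtering after is the conservative
reading (an unmapped barcode can never consume a mapped barcode's floor).
The first four timepoints are then retained.

# Wild-type handling

The wild type enters the analysis twice, and the package makes both roles
explicit:

* **Reference series** — all wild-type barcode counts are summed into a
  single series $w_t$, the denominator of every variant's log-ratio.
* **Pseudo-variants** — the wild-type barcodes are also partitioned at
  random (seeded) into groups of 19 barcodes (the library's median
  barcode multiplicity), each scored exactly like a variant. Their score
  distribution estimates the null spread of a typical variant, and its
  mean defines the zero point: all scores are shifted so the average
  wild-type pseudo-variant is exactly 0.

Whether "the average of wild-type variants" in the motivating analysis
means barcode groups or the aggregate plus synonymous variants is not
stated; pseudo-variant grouping was chosen because it yields a null
distribution with variant-like sampling noise, and the group size is a
parameter.

# Scoring

Per variant and timepoint, with 0.5 pseudocounts,

$$L_t = \ln\frac{c_t + 0.5}{w_t + 0.5}, \qquad
  V_t = \frac{1}{c_t + 0.5} + \frac{1}{w_t + 0.5},$$

and the fitness score is the slope of the weighted least-squares fit of
$L_t$ on $x_t$ with weights $1/V_t$. This is the standard weighted
log-ratio regression of barcode-count scoring tools; the motivating work
delegates it to such a tool without printing the formula, so it is
reimplemented here to keep the pipeline self-contained. The slope standard
error uses the residual variance on $n-2$ degrees of freedom, which makes
it invariant to a common rescaling of the weights; a floor of $10^{-8}$ is
applied when residuals vanish so downstream z-tests stay finite. A
consequence worth knowing: at fixed frequencies, doubling all counts
changes the reported se only through the pseudocount (order $10^{-4}$),
because the residual-based estimate absorbs the weight scale. The
alternative (treating $V_t$ as known variances) would shrink se as
$1/\sqrt{\text{depth}}$ but ignores model misfit; the residual-based
contract was chosen and is asserted as such in the tests.

Growth lineages are scored separately and combined by inverse-variance
(fixed-effect) averaging. Two lineages give an unusable heterogeneity
estimate, so a random-effects model is deliberately not fitted.

# Dual-null tests and categories

Each variant is tested against two references by a two-sided z-test
$z = (s - s_{\mathrm{ref}})/\sqrt{se^2 + se_{\mathrm{ref}}^2}$: the
wild-type null (reference = mean and standard error of the wild-type
pseudo-variant scores) and the nonsense null (reference = mean and
standard error of the mean of nonsense-variant scores — the minimal
reading of "behaves like a nonsense variant", isolated in one operation so
it can be swapped). P-values are Benjamini–Hochberg adjusted per test
family.

Categories follow the published rules evaluated in first-match order:
increased, toxic, hypomorphic, then the two fail-to-reject categories
neutral and lof. The published conditions are not mutually exclusive (a
noisy variant can fail to reject both nulls); placing evidence-bearing
rules first and preferring neutral over lof on double failure makes the
assignment total and deterministic while preserving the printed
conditions verbatim. Rows matching more than one rule are flagged. One
measure-zero corner remains undefined by the published rules (a score of
exactly 0 that rejects both nulls); it is reported as missing rather than
silently forced.

# Structural context

The structural covariates mirror a protein–DNA co-crystal analysis: the
construct partitions into NTS (4–63), Linker (64–79), CTS (80–136) and
"other" (1–3, 137–150); residue burial uses Shrake–Rupley sampling
(probe 1.4 Å, deterministic golden-spiral points, 200/atom by default)
normalised by the Tien et al. theoretical maximum ASA per residue, with
accessibility defined as > 25%; residue–DNA proximity is the Euclidean
minimum over all residue heavy atoms × DNA non-hydrogen atoms, binned into
1 Å half-open bins. All residue heavy atoms are used (side-chain-only was
the plausible alternative; the source does not say). Distances are
computed on the deposited coordinates regardless of bait sequence — in a
threading model, base identity does not move backbone heavy atoms.
Occlusion in the SASA computation includes every atom supplied, so burial
is measured in the complex; pass protein atoms alone to measure the free
protein.

# Clinical evidence calibration

Classification uses absolute scores: deviation from wild type in either
direction can be pathogenic, so gain and loss of function are folded
together. ROC analysis treats pathogenic as the positive class, computes
AUC by the tie-corrected rank statistic, picks the threshold maximising
$\mathrm{tpr} - \mathrm{fpr}$, and reports accuracy
$(TP + TN)/\text{total}$ at that threshold. Predictors oriented the wrong
way are inverted by $\min(x) - x + \max(x)$.

The evidence calibration orders labelled variants by score (descending
for the pathogenic sweep, ascending for the benign sweep; ties broken by
variant id) and grows a rank-symmetric window around each labelled
variant — alternating sides, truncating at the list ends — until it holds
at least 20 variants including at least 2 of the globally minority class.
With prior $P_1$ (the labelled-set class proportion) and weight
$w = \frac{(1-P_1)\,n_{\mathrm{path}}}{n_{\mathrm{ben}}\,P_1}$, each
window's posterior is
$P_2 = \frac{n^{\mathrm{win}}_{\mathrm{path}}}{n^{\mathrm{win}}_{\mathrm{path}} + w\, n^{\mathrm{win}}_{\mathrm{ben}}}$
and its odds of pathogenicity
$\mathrm{oddsPath} = \frac{P_2 (1 - P_1)}{(1 - P_2) P_1}$. Note that with
$P_1$ taken from the labelled data itself — the stated choice — the weight
$w$ is identically 1 and $P_2$ reduces to the window's pathogenic
fraction; the formulas are kept verbatim so an external population prior
can be substituted. The benign sweep mirrors every quantity (prior,
posterior and odds of benignity); for a window with identical contents the
benign odds equal 1/oddsPath exactly.

Tier boundaries default to the cited ACMG/AMP functional-evidence
calibration (pathogenic oddsPath ≥ 2.1 supporting, ≥ 4.3 moderate,
≥ 18.7 strong, ≥ 350 very strong; benign mirrored at ≤ 0.48, ≤ 0.23,
≤ 0.053, ≤ 0.0029), supplied as a configurable table since the source
cites but does not print them. The mapping from window odds to one score
threshold per tier is not fully specified there either; the default
**sustained-crossing** rule takes the maximal run of labelled variants,
from the extreme end inward, whose windows all meet the boundary, and sets
the threshold at the least extreme score in that run (a first-crossing
alternative sits behind a flag). Thresholds applied to the full score
table assign each variant the strongest tier it reaches; a variant exactly
at a threshold gets the stronger tier; variants meeting no supporting
boundary are indeterminate.

# The synthetic world

The generator's defaults state the world the tests run in: a 150-residue
construct mutable at positions 2–150 (2831 missense, 149 nonsense
identities), 227 synonymous pseudo-variants, negative-binomial barcode
multiplicity with median 19 (size 3, mean 21, truncated at 1), 8655
wild-type barcodes, four 12-h timepoints, and multinomial sequencing at
$10^6$ reads per timepoint. True missense effects come from a five-part
mixture — tolerated 45% ($N(0, 0.08)$), hypomorphic 20%
($U(-2, -0.4)$), loss-of-function 22% ($N(-2.5, 0.15)$, matching the
nonsense null-binding coefficient $s_{\mathrm{null}} = -2.5$),
gain-of-function 8% ($N(0.8, 0.25)$) and toxic 5% ($N(-3.6, 0.25)$).
These fractions are illustrative, chosen once to resemble the reported
category proportions (~20% partial loss of function, ~9–16% molecular
gain of function); they are not calibrated to the real data. The
no-antibiotic arm is anticorrelated,
$s_- = -0.6\, s_+ + \varepsilon,\ \varepsilon \sim N(0, 0.15)$, mimicking
the observed sign reversal between arms without calibrating its
magnitude. Label generation links pathogenicity to $|s_+|$ through a
logistic link ($k = 6$, midpoint 1.0) or through exact rank-based
proportions with an overlap dial.

What a green test does establish: the scorer recovers the stated
generative model (exactly in the infinite-depth limit, $r > 0.95$ at
depth $10^6$), preprocessing conserves counts, the category rules match
their truth table, the calibration recovers an analytically known
crossing. What it does not: barcode-level error modes absent from the
generator (PCR jackpots, index hopping, barcode sequencing errors,
bottlenecks beyond multinomial resampling, plasmid copy-number variation)
and any claim about the real deposited data, which require the optional
download path.

# Numerical choices and degenerate inputs

* Pseudocounts 0.5 keep $L_t$ and $V_t$ finite at zero counts; two zero
  series give $L = 0$ exactly.
* se floor $10^{-8}$; z-tests require strictly positive se.
* BH adjustment excludes missing p-values and propagates them as missing.
* Rank-sum tests use the exact null only when both groups have ≤ 10
  observations and no ties; otherwise the tie-corrected normal
  approximation without continuity correction (so the test statistic has
  a closed form checked against an independent oracle).
* Windows near the list ends become one-sided by truncation; window
  growth alternates sides deterministically, so results are reproducible.
* Score ties in the calibration sweeps are broken by variant id.
* An empty filtered count table is valid output of filtering and a hard
  error for scoring.
* Barcode collisions in the generator are regenerated for up to 100
  rounds ($4^{30}$ space makes this cosmetic) and then fail hard.

# Known limitations

* The scorer's se is residual-based on two degrees of freedom (four
  timepoints); per-variant se is noisy, which is why the dual-null tests
  use distribution-level references.
* The calibration reports no confidence intervals on oddsPath;
  bootstrapping the windows is the natural extension.
* The real-data reproduction path (deposited score tables and curated
  label sets) is implemented as I/O (MaveDB-style CSV, label CSV) but not
  exercised by the tests, which are download-free by design.
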