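---
title: "Spatial proximity metrics and PP3/BP4 calibration: methods and design"
author: "spdvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial proximity metrics and PP3/BP4 calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdvkit)
```

## The problem

Large, structurally complex disease genes accumulate variants of
uncertain significance faster than they can be functionally tested, and
sequence-based variant effect predictors perform worst exactly where the
disease mechanism is gain of function: such variants are rarely
destabilising, so conservation and stability signals miss them. What
gain-of-function and dominant-negative variants do reliably show is
spatial clustering — they hit a functional surface, a channel gate, a
binding site. `spdvkit` operationalises that observation twice over:
as a descriptive statistic (EDC: *is* this variant set clustered?) and
as a per-residue predictor (SPDV: *how close* is this residue to the
known cluster?), and then carries the predictor through to ACMG/AMP
PP3/BP4 evidence so it can be used in actual variant curation.

## The metrics

### SPDV

For a query residue with C&alpha; position $x_q$ and a site set $S$ of
unique disease-variant positions, the distances
$d_s = \lVert x_q - x_s \rVert$ for $s \in S \setminus \{q\}$ are ranked
ascending and

$$\mathrm{SPDV}_K(q) = \frac{1}{K}\sum_{k=1}^{K} d_{(k)}.$$

Design points, each load-bearing:

* **Self-exclusion.** When the query is itself a disease site, its own
  site is removed before ranking. This is what makes evaluation on known
  pathogenic variants non-circular: a variant's score never reflects its
  own pathogenicity, only its neighbours'.
* **Unique positions, not variant counts.** Multiple reported variants
  at one residue collapse to one site, so recurrently mutated positions
  do not weight the metric.
* **C&alpha; atoms only.** Backbone positions are reliably resolved at
  the moderate (3–4 Å) resolutions typical of large cryo-EM complexes,
  where side-chain placement is noise.
* **Ties and undefinedness.** Ranking uses a stable sort and takes
  exactly the $K$ smallest values (ties never expand $K$). If fewer than
  $K$ eligible sites remain, the value is `NA`, never imputed — silent
  imputation would distort downstream AUCs.
* **Modes.** `intra` restricts sites to the query's chain (the default
  analysis on one protomer); `inter` pools sites across all chains of an
  oligomer. Only the query residue itself is self-excluded in `inter`
  mode — symmetry mates on other protomers are legitimate neighbours.
* **Orientation.** SPDV is a lower-is-more-pathogenic score. The profile
  carries an orientation attribute rather than negating values, and the
  evaluation layer honours it.

$\mathrm{SPDV}_K$ is non-decreasing in $K$ (a mean over a superset of
the smallest distances), invariant under rigid-body motion, and can only
increase when a site is removed; the test suite asserts all three as
properties and checks equality with a brute-force enumeration oracle.

### EDC

$$\mathrm{EDC} = \frac{\langle \min_{s \in S \setminus \{r\}} d(r, s) \rangle_{r \in \text{all residues}}}
                      {\langle \min_{s' \in S \setminus \{s\}} d(s, s') \rangle_{s \in S}}$$

The numerator asks how far a typical residue is from the variant set;
the denominator how far a typical *site* is from its nearest fellow
site. Uniformly scattered sites make the two means comparable
(EDC ≈ 1); clustered sites shrink the denominator (EDC > 1); and when
every residue is a site the two means are identical, so EDC = 1 exactly
— a degenerate case the tests pin down. The literature the ratio
descends from states its qualitative behaviour rather than a closed
formula, so this package commits to the definition above and validates
it against those qualitative statements via simulation (uniform planting:
mean EDC over 100 seeds within [0.95, 1.05]; tight single-cluster
planting: EDC > 1.1 in ≥ 95% of seeds).

## From score to clinical evidence

### Evidence ladder

With prior probability of pathogenicity $\pi$ and a posterior target
$p_{vs}$ for very-strong evidence, the very-strong odds of pathogenicity
is

$$\mathrm{OP}_{vs} = \frac{p_{vs}/(1-p_{vs})}{\pi/(1-\pi)},$$

and strong / moderate / supporting thresholds are
$\mathrm{OP}_{vs}^{1/2}, \mathrm{OP}_{vs}^{1/4}, \mathrm{OP}_{vs}^{1/8}$,
so four supporting-level observations combine to strong and eight to
very strong. Benign thresholds are exact reciprocals. At the default
$\pi = 0.1$, $p_{vs} = 0.99$: $\mathrm{OP}_{vs} = 891$, supporting
$\approx 2.337$, moderate $\approx 5.464$, strong $\approx 29.85$. Both
$\pi$ and $p_{vs}$ are arguments — the 0.99 posterior is a convention,
not a constant of nature, so it is configurable rather than hard-coded.

### Likelihood-ratio curve

`fit_lr_curve()` estimates $\mathrm{lr}^+(s) = \hat f_{P}(s)/\hat
f_{B}(s)$ with Gaussian KDEs of the pathogenic and benign reference
score sets on a 512-point grid spanning the pooled scores. Numerical
choices:

* **Bandwidth**: Silverman's rule (`bw.nrd0`) per reference set —
  standard, deterministic, and re-applied inside each bootstrap refit so
  the band reflects bandwidth variability too. A fixed numeric bandwidth
  can be supplied instead.
* **Bootstrap band**: 1000 refits by default, resampling each reference
  set with replacement. The 5%/95% band edges are symmetric order
  statistics (50th smallest / 50th largest at 1000 refits) rather than
  interpolated quantiles, and each reference set's resampling indices
  come from an identically seeded stream. Together these make the fitted
  band *exactly* reciprocal when the reference sets are swapped, which
  in turn makes PP3 and BP4 calls swap exactly — a symmetry the test
  suite asserts literally.
* **Conservative edge**: pathogenic evidence is claimed only if the
  *lower* band edge clears the threshold; benign evidence only if the
  *upper* edge does. The point estimate is reported but never drives a
  call.
* **Extrapolation**: scores outside the reference span are clamped to
  the span boundary (KDE tails beyond the data are meaningless) and
  flagged. Where the benign density underflows, lr⁺ is capped at a
  configurable ceiling (default 10⁶) and the event logged.
* **Reference floor**: each reference set must have at least 10 scores
  (configurable); below that a KDE ratio is an illusion of precision.

The curation truth set is an *input*: the package never labels its own
reference variants.

### Classification

A variant's call is the strongest pathogenic level whose threshold the
conservative lr⁺ meets, else the strongest benign level, else
indeterminate — an ordered 9-level factor from `BP4_very_strong` to
`PP3_very_strong`. Given a monotone lr curve, calls are monotone in the
score; KDE wiggles can in principle break curve monotonicity, which is
why the monotonicity invariant is asserted on the classification logic
under a monotone curve, and the two-Gaussian recovery test checks the
curve itself against the analytic ratio $e^{2s-2}$ within ×1.5 at
$s \in \{0, 1, 2\}$.

## Evaluation layer

ROC AUC is computed as the midrank Mann–Whitney statistic
$(\sum_{i \in P} R_i - n_P(n_P+1)/2) / (n_P n_B)$ — ties count ½, missing
scores are deleted pairwise per predictor (predictors differ in
coverage, and a shared complete-case subset would change the question),
and lower-is-pathogenic orientations are reversed before ranking.
Default comparisons pool the dominant phenotype classes against benign
and also run each class separately; recessive variants are excluded from
discrimination analysis because they circulate heterozygously in healthy
populations. Rank-sum comparisons between variant classes use the
tie-corrected normal approximation (`stats::wilcox.test`), with raw
p-values — no multiplicity correction is applied or implied.

## The synthetic generator

`synthetic_spec()` fixes the study conditions; the other generators are
deterministic functions of it.

* **Geometries**: `line` (3.8 Å C&alpha; spacing — the trans peptide
  virtual-bond length), `helix` (1.5 Å rise, 100° twist, 2.3 Å radius —
  ideal α-helix parameters), `random_globule` (uniform points in a
  sphere at 0.6 residues/nm³, giving a ~43 Å-radius ball at 200
  residues). Defaults: 200-residue globule, 20 sites — large enough for
  stable EDC envelopes, small enough that a 100-seed sweep runs in
  seconds.
* **Planting**: uniform = sampling positions without replacement;
  clustered = sampling with probability ∝ a Gaussian kernel
  ($\sigma$ = `cluster_spread`, default study condition 5 Å around one
  centre) of the distance to the nearest centre.
* **Scores**: Gaussian per class, default N(2,1) pathogenic vs N(0,1)
  benign — separation 2 gives the closed-form AUC
  $\Phi(2/\sqrt2) \approx 0.921$ and the analytic likelihood ratio
  $e^{2s-2}$, both used as oracles.
* **Seeding**: every draw flows from the spec's single mandatory seed
  (structure from `seed`, planting from `seed + 1`), so an instance is
  its spec.

What the generator does *not* emulate — excluded volume, secondary
structure in the globule, realistic variant ascertainment bias,
correlated predictor errors, multi-domain architecture — bounds what
green tests mean: they demonstrate the metrics and calibration behave
correctly on geometry with known ground truth, not that any particular
protein's variants will be as cleanly clustered as a 5 Å planted blob.
On real structures the expected regime is EDC in the 1.0–1.4 range and
SPDV AUCs around 0.7–0.8, far from the near-perfect recovery the
synthetic cluster allows.

## Residue mapping

Sequence numbering and structure numbering only ever meet through a
`ResidueMap` built from an explicit pairwise alignment (any aligner's
output is accepted; the map does not recompute alignments). Human
positions aligned to structure-row gaps, to residues without a C&alpha;,
or to residues with no standard parent amino acid are reported unmapped
with that reason; aligned columns with different letters are mapped but
flagged as ortholog substitutions. altLoc handling keeps the
first-listed alternate C&alpha; (deterministic, standard practice at
moderate resolution); insertion codes are part of the residue key;
modified residues such as selenomethionine translate to their parent
code. Variant reference residues are validated against the mapped
sequence — a mismatch is an error, not a warning, because it almost
always means an off-by-one or wrong-isoform variant table.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
instances: 200-instance oracle sweeps for SPDV, 100-seed EDC envelopes
on 200-residue globules, AUC checks at 1000 variants per class, and
calibration recovery at 2000 reference scores per class with 1000
bootstrap refits — sizes chosen so the full-protein analyses they stand
in for (a 5038-residue channel, ~5000 resolved residues per protomer)
are exercised at the same code paths while the whole suite completes in
well under a minute. Applying the package to a real complex is the same
calls with a real PDB/mmCIF file, alignment and variant tables.

## Known limitations

* EDC is a global statistic; it says nothing about *which* cluster
  drives the signal and has no null distribution attached — compare
  regimes by simulation (as the acceptance script does) rather than
  reading a p-value off a single value.
* SPDV inherits the site set's ascertainment: under-reported regions
  look "far from disease" regardless of biology.
* The KDE calibration assumes the reference sets are exchangeable with
  the variants being scored; a truth set enriched for one phenotype
  calibrates only that phenotype's regime.
* Likelihood ratios outside the reference span are clamped flat, so
  extreme scores can never earn more evidence than the span boundary
  supports — deliberately conservative.
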