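# spdvkit

Structure-based spatial clustering features for missense variant
interpretation.

Pathogenic missense variants in many dominant disease genes — the
skeletal-muscle ryanodine receptor RyR1 being a prime example — act
through gain-of-function or dominant-negative mechanisms and cluster
tightly in the protein's three-dimensional structure, while sequence-based
variant effect predictors (VEPs) struggle with exactly these variants.
`spdvkit` turns that clustering into a predictor and into clinical-grade
evidence. It is aimed at structural bioinformaticians and
variant-curation groups who have a solved structure, a set of known
disease variants, and a stream of variants of uncertain significance to
triage.

## What it computes

**SPDV** (Spatial Proximity to Disease Variants). For a residue *i* with
C&alpha; coordinate **x**<sub>i</sub> and a set *S* of unique
disease-variant positions,

&nbsp;&nbsp;&nbsp;&nbsp;SPDV<sub>K</sub>(i) = (1/K) &Sigma;<sub>k=1..K</sub>
d<sub>(k)</sub>,&nbsp;&nbsp; d<sub>(1)</sub> &le; d<sub>(2)</sub> &le; … over
{ ‖**x**<sub>i</sub> − **x**<sub>s</sub>‖ : s &in; S \ {i} }

i.e. the mean of the K smallest C&alpha;–C&alpha; distances to disease
sites, always excluding the residue's own site so known pathogenic
positions are scored without circularity. Lower values mean "closer to
the disease cluster", so SPDV is a lower-is-more-pathogenic score. A 1D
analog (`spdv_1d`) uses sequence separation instead of spatial distance;
intra- and inter-chain modes handle homo-oligomers.

**EDC** (Extent of Disease Clustering). The ratio of the mean
nearest-site distance over *all* residues to the mean
nearest-*other*-site distance over the site residues themselves.
Randomly dispersed sites give EDC &approx; 1; clustered sites give
EDC &gt; 1.

**Evaluation and calibration.** ROC AUC through the Mann–Whitney rank
statistic (ties counted ½), per-phenotype predictor benchmarking, and
ACMG/AMP PP3/BP4 evidence assignment: a bootstrap Gaussian-KDE estimate
of the positive likelihood ratio lr⁺(s) = f<sub>P/LP</sub>(s) /
f<sub>B/LB</sub>(s) against reference ClinVar-style variant sets, looked
up in an evidence ladder derived from a prior probability of
pathogenicity (default 10%): the very-strong threshold is the
posterior/prior odds ratio (891 at prior 0.1, posterior 0.99) and each
weaker level is its successive square root. Classification uses the
conservative bootstrap band edge so evidence is never overstated.

Supporting machinery: PDB/mmCIF reading (via `bio3d`),
sequence-to-structure residue mapping through pairwise alignments,
variant-dataset assembly with disjoint pathogenic/benign sets, score
segmentation with overlap averaging, rank normalisation, and a
synthetic-data generator (line / helix / random-globule structures with
planted clustered or uniform sites, plus two-Gaussian score models).

## Worked example

```r
library(spdvkit)

# a 200-residue globular fold with 20 disease sites planted around one centre
spec   <- synthetic_spec(n_residues = 200, site_count = 20,
                         cluster_centers = 1, cluster_spread = 5, seed = 42)
struct <- make_structure(spec)
sites  <- plant_sites(struct, spec)

edc(struct, sites)
#> EDC = 3.513 (20 sites, 200 residues; num 27.03 A / den 7.69 A)

prof <- spdv_profile(struct, sites, K_set = c(1, 2, 4, 8))
is_site <- prof$resno[prof$K == 4] %in% sites$sites$resno
roc_auc(prof$spdv[prof$K == 4], is_site, orientation = "lower_pathogenic")
#> [1] 0.9652778

# calibrate a two-Gaussian score model into PP3/BP4 evidence
sim    <- simulate_scores(500, 500, path_mean = 2, seed = 43)
sc     <- as.data.frame(sim$scores); is_p <- sim$truth$label == "pathogenic"
model  <- fit_lr_curve(sc$score[is_p], sc$score[!is_p], n_boot = 1000, seed = 44)
ladder <- evidence_ladder(prior = 0.1)
ladder
#> EvidenceLadder (prior 0.1, posterior 0.99): OP_vs = 891
#>   pathogenic lr+ >=: supporting 2.337, moderate 5.463, strong 29.85, very_strong 891
#>   benign lr+ <=:    supporting 0.4278, moderate 0.183, strong 0.0335, very_strong 0.001122

table(classify_variants(model, ladder, sc[, c("variant", "score")])$level)
#> BP4_very_strong      BP4_strong    BP4_moderate  BP4_supporting   indeterminate
#>              11              24             202             114             293
#>  PP3_supporting    PP3_moderate      PP3_strong PP3_very_strong
#>             135             171              33              17
```

The EDC of 3.5 says the planted sites are far more clustered than chance
(1.0); the SPDV₄ AUC of 0.97 says proximity to those sites almost
perfectly recovers site residues; and the evidence table shows how a
score distribution with unit-separated classes splits into graded
PP3/BP4 calls under the 10% prior.

A command-line interface wrapping the same functions is installed at
`inst/cli/spdvkit.R`:

```sh
Rscript inst/cli/spdvkit.R simulate --n-residues 200 --sites 20 \
    --spread 5 --centers 1 --seed 42 --out simdir/
Rscript inst/cli/spdvkit.R edc --structure simdir/structure.pdb \
    --map map.tsv --variants variants.tsv --out edc.json
```

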