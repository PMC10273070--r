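---
title: "Methods: genomewide prediction and postdiction in a simulated fruit breeding program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomewide prediction and postdiction in a simulated fruit breeding program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gwsel` evaluates genomewide (genomic) selection for harvest fruit-quality
traits in the setting of a clonally propagated, hub-parent breeding program:
a few elite parents recur in many crosses, seedlings are unreplicated, and
multi-trait culling decisions are made once per individual at harvest. The
package carries the whole chain — breeding-population simulation, phenotype
adjustment, marker curation, RR-BLUP prediction under the standard
training/test schemes, fixed-effect handling of major QTLs, and a
retrospective culling audit — so that every stage can be tested without
access to proprietary program data. This vignette records the models, the
defaults and why they were chosen, and what the simulation does and does not
establish about real data.

## The synthetic breeding germplasm

`build_germplasm_set()` generates a pedigreed population from phased founder
haplotypes. The default design mirrors a representative program: a genetic
map of 17 chromosomes with 57 SNPs each (71.8 cM chromosomes, even spacing,
~1.27 cM between adjacent SNPs), 13 full-sib families of 23–150 offspring
(852 in total), and 103 further individuals — 14 breeding parents, 9
unrelated progenitors, and 80 advanced selections assigned to four selection
eras. Two hub parents dominate: `P01` parents 8 of the 13 families and its
own offspring `P02` parents 4, so half-sib relationships tie most of the
population together. This relatedness is deliberate — it is what makes
moderate marker densities sufficient for prediction in such programs, and it
is the property several of the package's checks exercise.

Meiosis follows the Haldane model: crossover counts per chromosome are
Poisson(length/100) with positions uniform and no interference. This is the
simplest recombination model consistent with a cM map; nothing downstream
depends on interference. Founder allele frequencies are drawn uniformly from
a configurable range (default 0.1–0.5). Monomorphic SNPs can arise by
sampling and are intentionally left for the QC stage to remove, as with real
array data.

Advanced selections are simulated as offspring of random pairs of the
breeding parents. Their "eras" drive the three chronological postdiction
rounds; genetically they are ordinary program material. The real pedigree
depth of such selections is unknowable from published information, so no
attempt is made to model it beyond one generation.

## Trait architecture and phenotype generation

Each trait has a variance partition (year, individual, year×individual,
residual), a grand mean and a phenotypic SD on its field scale. The seven
default traits reproduce the reported pattern for this crop: year explains
~0.07 of phenotypic variance on average and individual ~0.53, with
individual ≥ 0.50 for overcolor, weight, the firmness measures M1/M2 and
acidity TA, ≤ 0.40 for crispness Cn and soluble solids SSC, and an
interaction of 0.13–0.34 where present (M1, M2, SSC, TA). Grand means and
SDs are field-plausible values on the traits' units (1–5 rating, g, lbs,
°Brix, g/L); they affect nothing but scale.

Genetic values are polygenic — a random 20% of mapped SNPs per trait act as
causal loci with normal effects — plus optional major-QTL terms: a dominant
red-colour locus on chromosome 9 (30% of phenotypic variance), a firmness
locus on chromosome 16 (10%) and two acidity loci on chromosomes 8 and 16
(10% and 8%). Causal loci are a subset of the mapped SNPs, so markers tag
the QTLs imperfectly but not anonymously; the major-QTL SNPs are excluded
from the polygenic causal set. The QTL term is `a·d + δ·a·[d = 0]` in the
dosage `d ∈ {−1, 0, 1}`, with dominance ratio δ; its effect size is set by
closed-form rescaling so the term's realized variance equals its target
fraction exactly (the term is linear in `a`, so no iterative calibration is
needed).

Records are `value(i, y, r) = μ + g_i + year_y + (gy)_{iy} + e_{iyr}` with
`n_reps` replicate measurements (fruit) per tree-year cell, and whole cells
dropped with probability `missingness` (default 0.10). Two generator
decisions deserve emphasis:

* **Within-cell replication (default 3 fruit).** With a single record per
  individual-year cell the interaction variance is formally confounded with
  the residual — both enter each cell's variance only through their sum — so
  no fitting procedure could separate them. Real programs measure several
  fruit (and duplicate chemistry assays) per tree-year; the generator
  reflects that, and the interaction component is estimable exactly when
  `n_reps ≥ 2`.
* **Exact component standardization.** Each simulated component is centered
  and rescaled so its realized sample variance equals its target, rather
  than matching only in expectation. With only ~5 year levels the realized
  year variance would otherwise have ≈ 70% relative standard deviation,
  making any recovery check at the reported precision meaningless at any
  population size. The cost is a slight distortion of the components'
  distribution (they are no longer exactly i.i.d. normal); none of the
  fitted models is sensitive to this.

The generator returns true genetic values alongside the records, enabling
parameter-recovery tests. An optional `clip_to_scale()` transform emulates
bounded rating scales; it is off by default since rating traits are treated
as continuous throughout, matching field practice.

## Across-year BLUP adjustment

Per trait, `fit_trait_model()` fits the two-way random-effects model
`value = μ + year + individual (+ year:individual) + ε` by REML, through
lme4 — the standard tool for exactly this model. Under `interaction =
"auto"` both models are fitted and the interaction is kept when it lowers
the REML AIC by more than 2 (the conventional "worth mentioning" margin;
configurable). Both candidate models share the intercept-only fixed
structure, so comparing their REML AICs is valid; the parameter count is the
number of variance components plus one. Individuals observed in a single
year are retained — unreplicated seedlings are the norm here — and simply
receive more strongly shrunk BLUPs.

The phenotypic value used by all downstream stages is the *adjusted BLUP*:
individual BLUP plus the model grand mean (the REML intercept). In balanced
data this equals `μ + k (ȳ_i − ȳ)` with shrinkage factor
`k = σ²_I / (σ²_I + σ²_E / n_years)`, a closed form the tests verify. The
test suite also checks the REML fit against an independent dense-likelihood
maximizer and a coarse likelihood grid.

A degenerate constant trait returns zero components and zero BLUPs without
invoking the optimizer. Total variance of zero makes proportions undefined
and raises an error rather than returning NaNs.

## SNP quality control

`filter_snps()` applies, in a fixed logged order: (1) removal of SNPs with
more than 20% missing calls; (2) imputation of the rest (population mode per
SNP by default, or a family-aware mode that restricts candidates to
Mendelian-consistent dosages given the parents); (3) removal of monomorphic
SNPs; (4) per-chromosome redundancy pruning by backwards elimination — while
any within-chromosome pair has |r| > 0.80, the lower-MAF member of the worst
pair is removed, with equal-MAF ties going to the SNP later in map order.
Absolute correlation is used because the sign of r flips under arbitrary
allele relabeling. The ordering matters (imputation changes correlations and
MAFs) and is therefore fixed rather than configurable.

Backwards elimination with the lower-MAF rule is a greedy procedure. On
clique-structured redundancy — tight blocks of near-duplicate probes, the
situation array data actually presents — it retains a maximum valid subset,
and the tests verify this against brute-force enumeration. On adversarial
chain-structured correlation it can remove one SNP more than strictly
necessary; the procedure is kept as specified since the eliminated-SNP
report makes every removal auditable.

## RR-BLUP prediction engine

`fit_rrblup()` fits `y = Xβ + Zu + ε`, `u ~ N(0, σ²_u I)`,
`ε ~ N(0, σ²_e I)`, with the marker dosages used exactly as coded (−1/0/1,
not column-centered — the intercept absorbs the mean shift, and uncentered
coding keeps results reproducible against the coding contract). The
restricted likelihood is profiled to the single ratio φ = σ²_u/σ²_e via the
spectral decomposition of Z Zᵀ projected on the orthogonal complement of X,
and maximized by bounded search in log φ (tolerance 10⁻⁸ on the profiled
criterion; search range e±25, with an explicit boundary comparison at
σ²_u = 0). For the intercept-only case the projection is plain
double-centering; a general X uses an orthonormal null-space basis. Solutions
are recovered from the same decomposition through the REML projection
identity `û = σ²_u Zᵀ P y`, and β̂ from the first block of the mixed-model
equations. At any fixed λ = σ²_e/σ²_u the result equals the closed-form
ridge solution of the augmented normal equations to 10⁻⁸, which is the
oracle the tests enforce. A boundary estimate σ²_u = 0 is legal: predictions
collapse to the fixed effects and a warning is logged.

Predictions for new individuals are `X_new β̂ + Z_new û`; predictive ability
is the Pearson correlation between predicted and observed trait BLUPs in the
test set. Undefined correlations (zero variance on either side, or fewer
than 3 observed pairs) raise distinct errors; the CV layer records them as
missing values with reason codes — never as 0, which would silently bias
scheme summaries.

## Training/test schemes

Five schemes mirror the standard designs: random training fractions
(10/25/50/75%, reference design 500 iterations), leave-one-family-out,
within-family delete-one, random family subsets of 20–120 offspring
(reference 100 iterations), and 5–30 SNPs sampled per chromosome from the
QC-retained panel with leave-one-family-out evaluation (reference 100
iterations). All sampling is without replacement; iteration *i* draws under
seed `seed + i`, so every training/test split is reconstructible from the
tidy results table alone, and the same iteration index shares its split
across fractions for paired comparisons. Training sizes use the floor of
`fraction × N`. The CV population is restricted to unselected offspring by
default (advanced selections and parents are excluded), matching how such
schemes are run; a flag admits everyone.

Families whose phenotyped membership falls below the minimum for a defined
correlation are reported with reason codes. A family of genotypic clones is
explicitly flagged: each delete-one fit would still produce a number, but
the predictions carry no genotypic information.

## Fixed-effect QTL models

`fit_rrblup_fixed()` moves designated SNPs from the random panel into the
fixed design. The default encoding is categorical (dummy columns per
observed genotype class), which captures dominance — essential for loci like
the red-colour locus, where the heterozygote is the high class; an additive
encoding is available. Multiple fixed SNPs contribute separable column
blocks. A SNP monomorphic in the training set is dropped with a warning
(its class effect is inestimable). The design spec is stored in the fit so
prediction rebuilds identical columns from test genotypes. Genotype-class
differences are assessed by one-way ANOVA with Tukey HSD mean separation
(compact letters by insert-and-absorb, ordered by class mean), and
fixed-versus-random predictive abilities are compared by a paired t-test
across test families.

## Postdiction

The retrospective audit replays independent culling over three chronological
rounds. Round 1 trains on the first-wave families plus cultivars, parents,
progenitors and pre-1995 selections and tests the 1995–2005 selections;
round 2 adds round 1's test set and the second hub's families and tests the
2006–2015 selections; round 3 adds those and tests the 2016–2020 selections.
Training sets are nested by construction and each round's predictions use
only that round's training data, so no information leaks backward in time.

Five threshold scenarios are built in: reference-cultivar ± SD (A),
advanced-selection mean ± SD (B), and percentile rules (C/D/E: weight culled
at the 90th percentile; M1/M2/SSC/TA culled low at the 10th or 25th).
Overcolor and Cn are keep-all in every scenario. Thresholds are computed
from the round's training data only; percentile rules use type-7 (linear
interpolation) quantiles of the training offspring's BLUPs — the R default,
stated explicitly because cull counts at small n depend on the quantile
definition. The SD in scenarios A and B defaults to the SD over training-set
unselected offspring, with `sd_source` exposing the alternatives since the
convention is genuinely ambiguous. Comparisons are inclusive: an individual
exactly at a threshold is culled. Missing trait values flag the trait as
unevaluated and the decision is made from the remaining traits.

Advanced selections receive strictly out-of-training predictions in their
own round. Unselected offspring are in training throughout — the historical
reality the audit replays — so their "genomewide" values are in-sample GEBVs
from the final round's model. This choice is recorded here because the
alternative (per-family hold-out for offspring) answers a different
question; in-sample GEBVs are still shrunken toward the mean, which is the
property driving the phenotypic-versus-genomewide asymmetry at tail
thresholds.

## What the simulation shows — and what it cannot

Passing tests establish that each stage implements its model correctly and
that the pipeline reproduces the *directional* phenomena of interest: larger
training sets and denser marker panels raise predictive ability with
saturation between 25 and 30 SNPs per chromosome; within-family prediction
improves with family size; a dominant major QTL helps as a fixed effect
precisely when the test family segregates for it, while a null fixed SNP is
harmless; and genomewide selection culls fewer tail individuals than
phenotypic selection, because predictions are shrunken.

Absolute numbers are more favourable than any real program would see.
The synthetic genome has no genotyping error, its causal loci are mapped
SNPs, all relevant variance is additive-by-construction within individual,
and the hub-parent design concentrates relatedness; predictive abilities of
0.6–0.9 and decision concordances above 90% follow. Real array data,
genotype-by-environment structure beyond a single interaction term,
non-genetic persistent effects (tree age, rootstock, orchard position) and
maturity-confounded phenotyping would all lower these numbers substantially.
Conclusions about a real program should rest on the scheme comparisons, not
the absolute correlations.

## Problem sizes and numerical choices

The package's own test suite runs the statistically demanding checks at
sizes chosen for power per unit time: the REML recovery study at n = 400
individuals × 200 markers × 50 replicates; variance-partition recovery at
900 individuals × 5 years × 2 replicate measurements; training-fraction
monotonicity on the full 955-individual germplasm at 100 iterations per
fraction; the marker-density, fixed-QTL and family-size studies on scaled
germplasm of ~300–450 individuals with 12–20 iterations or replicates. The
acceptance script re-runs the full default pipeline (955 individuals, 969
SNPs) with 40 CV iterations per fraction and 8 SNP-subsampling iterations.
Numerical tolerances: ridge-oracle agreement at 10⁻⁸; REML profile
optimization at 10⁻¹⁰ in log φ; variance components floored at zero with an
explicit boundary check. Ties: equal-MAF pruning removes the later SNP in
map order; compact letters order groups by ascending class mean.

## Known limitations

* The redundancy pruner is greedy (see above); its removals are logged, not
  provably minimal on arbitrary correlation structures.
* Advanced selections' pedigrees are one generation deep; era labels are
  structural, not genetic.
* No selection-over-generations forward simulation: the germplasm is a
  single cross-sectional cohort, so the simulated selections are not
  actually "selected" material and postdiction cull rates on them are
  higher than a real program's would be.
* Single-trait models only; multi-trait indices and economic weights are out
  of scope.
* The VCF exporter stores cM positions in an INFO tag with POS = round(cM ×
  10⁵) since VCF requires integer base-pair coordinates; round-tripping
  through tools that rewrite POS will lose sub-0.00001 cM precision.
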