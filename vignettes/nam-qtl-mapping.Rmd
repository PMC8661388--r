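---
title: "Stepwise and joint-linkage QTL mapping in NAM RIL panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise and joint-linkage QTL mapping in NAM RIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namqtl)
```

`namqtl` implements the quantitative-genetics workflow used to dissect
quantitative traits — leaf carbon-isotope composition, specific leaf area,
leaf elemental concentrations and the like — in maize nested association
mapping (NAM) panels: several biparental recombinant-inbred-line (RIL)
families that share one common parent (classically B73). This vignette is
the package's own account of the models it fits, the parameters that
matter, and the places where the design was genuinely open and a choice
had to be made.

## The data model

Genotypes are held as numeric biparental codes per RIL and marker:
0 for the common-parent homozygote, 1 for a heterozygote, 2 for the
alternative-parent homozygote. This coding makes every marker an additive
covariate; an effect size is expressed in trait units per allele-code
unit, so a homozygote substitution (0 to 2) moves the trait by twice the
reported effect. A positive effect always means the alternative parent's
allele raises the trait. Whether published effect tables in this field
report per-code or per-substitution effects is usually not stated; the
package reports per allele-code unit and says so here once.

Heterozygous calls (residual heterozygosity of near-fixed RILs) are kept
in the additive coding as 1 rather than being discarded; rows missing a
genotype at the test marker are dropped for that marker's fit only.

## BLUE estimation from augmented blocked trials

Field trials for RIL panels are typically augmented incomplete-block
designs: each block holds ~20 unreplicated test lines plus 2 replicated
checks (the common parent in every block), about 10% of all plots, over
one or more years. `fit_blue()` fits

$$y_{ijk} = g_i + u_j + b_{jk} + e_{ijk}, \qquad
  u_j \sim N(0, \sigma^2_{year}),\;
  b_{jk} \sim N(0, \sigma^2_{block}),\;
  e_{ijk} \sim N(0, \sigma^2_e),$$

with genotype $g_i$ fixed, year and block-nested-in-year random. Variance
components are REML estimates obtained through `lme4::lmer()`, and the
genotype estimates are the generalized-least-squares (least-squares-mean)
solutions at those components — since genotype is the only fixed factor,
the fixed-effect solution *is* the LS-mean, so no separate marginal-means
machinery is needed. With a single year the year component is dropped
automatically. Replicated plant measurements within one plot are averaged
to a single plot value before fitting (the model is a plot-level model;
whether to average or model plants individually is rarely stated in field
studies — averaging is this package's choice, and with equal plant counts
per plot the two give identical genotype estimates).

The replicated checks are what connect blocks. If no genotype is shared
across blocks the design is disconnected, block effects are confounded
with genotype contrasts, and `fit_blue()` warns but still returns
estimates.

## Single-family stepwise QTL mapping

The scan statistic is deliberately elementary: for each marker, regress
the phenotype on the marker's numeric code (plus any markers already in
the model) and keep the partial F-test p-value — exactly the p-value
`anova(lm(pheno ~ accepted_markers + marker))` prints for the last term.
The unit tests hold this equality to 1e-10 against a brute-force
`anova(lm())` oracle.

**Genome-wide threshold.** Significance is calibrated by permutation:
shuffle the phenotype across RILs (breaking all marker-trait association
while leaving the linkage structure of the markers intact), rerun the
whole scan, record the minimum p-value, and repeat `n_permutations`
times. The threshold is the lower order statistic
$\lceil \alpha \cdot n_{perm} \rceil$ of the minima — with the
conventional 200 permutations at $\alpha = 0.05$, the 10th smallest
minimum. Taking the order statistic at the ceiling rather than an
interpolated quantile is deliberate: it is reproducible, slightly
conservative, and under exchangeability gives a declaration probability
of $k/(n_{perm}+1) \approx \alpha$ exactly, which the acceptance suite
verifies empirically on null simulations.

**Stepwise selection.** Forward only: accept the minimum-p marker if it
beats the threshold, condition on it, rescan, and stop at the first
non-significant minimum. Ties in the minimum p (possible with fully
linked markers) break deterministically to the lowest chromosome, then
lowest position. Two open choices were resolved as follows:

* *Is the threshold recomputed after each acceptance?* Default no: the
  unconditioned threshold is reused across steps, which keeps the
  genome-wide error interpretation of the first step and is by far the
  cheaper option. `recompute_threshold = TRUE` recomputes it with the
  conditioned markers permuted together with the phenotype, preserving
  their joint relationship.
* *What is "LOD" for a regression scan?* The nested-model equivalence
  $\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_{reduced}/\mathrm{RSS}_{full})$,
  the standard regression-mapping definition. Support intervals are the
  maximal contiguous marker run around the peak within `lod_drop`
  (default 1) LOD of the peak, reported in Mb.

Each accepted QTL is reported with the p-value at its acceptance step,
its additive effect from the final joint model, the cumulative TPVE
(total percent of variation explained, $100 R^2$ of the model truncated
at that step — non-decreasing by construction), and the 1-LOD interval
from a final scan conditioned on the other accepted QTL.

## Joint-linkage mapping across families

With several families sharing a common parent, each marker is tested in

$$y \sim \text{family} + \text{marker}{:}\text{family},$$

a family mean term plus one marker slope per family. The family term
absorbs between-family mean differences (an invariant the tests check
exactly); nesting the slopes lets each family carry its own QTL allele.
The test is the partial F over the whole nested block, with numerator
degrees of freedom equal to the number of families in which the marker
segregates — families where the marker is monomorphic contribute no
column and are flagged through the reported `df1`. With one family the
model collapses to the single-family scan, and the tests hold the two
equal to machine precision.

**Permutations within family.** The null must preserve family structure,
so permutations shuffle the phenotype within each family independently;
every family's mean is preserved exactly, and the threshold is again the
$\lceil \alpha \cdot n_{perm} \rceil$ order statistic of genome-wide
minima. 1000 permutations is the conventional joint-linkage choice;
validation studies in this package run 200 (see "Problem sizes" below).

**Reporting.** Published joint-linkage tables print a single family and
effect per QTL without stating the rule. This package assigns the family
whose nested effect has the smallest marginal p-value in the final
model, and keeps the full per-family effect table in the
`nested_effects` attribute so nothing is hidden by the convention.

**Joint TPVE.** With a family term in the model, "variation explained"
is ambiguous: family mean differences can dwarf within-family genetic
variation. The package defines joint cumulative TPVE as the percent of
*within-family* phenotypic variation (the residual variation of the
family-means-only model) explained by the QTL terms up to each step.
This keeps the quantity about QTL rather than about founder differences,
and keeps it non-decreasing across steps.

## Genotype file handling

HapMap text (11 metadata columns, then one column per sample) is read
and written directly; both the two-letter diploid dialect (`AA`, `AT`,
`NN`) and the single-letter IUPAC dialect (`A`, `W`, `N`) occur in
public maize exports and both are accepted. Strand is ignored — the
biparental coding depends only on matching parent alleles. Calls
matching neither parent become missing and are counted; markers
monomorphic between the parents are dropped with a warning. MAF
filtering computes allele frequencies from non-missing calls (a
heterozygote contributes one allele each way) and removes markers
*strictly below* the threshold, so a marker at exactly the cutoff is
retained.

Missing codes are imputed from the nearest informative flanking markers
under the RIL transmission model: a neighbour with code $v$ at RIL
recombination fraction $R$ implies alternative-allele probability
$p = (v/2)(1-R) + (1-v/2)R$; two flanks combine multiplicatively under
the Markov assumption, and the expected code $2p$ is rounded to the
nearest of $\{0, 1, 2\}$. The published analyses this workflow mirrors
cite an external imputation procedure whose details are not recoverable;
the flanking-expectation rule is this package's own, chosen because it
is simple, testable, and matches RIL linkage structure. A cell with no
informative marker on its chromosome within its family cannot be dropped
"for that family" in a rectangular code matrix; it is filled with the
rounded cross-family expectation under a warning instead.

## The synthetic-data generator

The simulator exists so that every stage of the pipeline is testable
without external downloads. It emulates:

* **Maps** with a chosen mean marker spacing (1.6 cM reproduces the
  classic ~836-marker joint-linkage set on 10 chromosomes); spacings are
  moderately dispersed and rescaled so the realized mean is exact.
  Physical positions are placed at 1 Mb/cM — only ordering and reporting
  use them, so a constant rate is sufficient.
* **RIL genotypes** as a two-state Markov chain along each chromosome
  with switch probability $R = 2r/(1+2r)$, $r$ from the Haldane map
  function — the closed-form recombinant fraction of selfed
  single-seed-descent RILs, accounting for map expansion over selfing
  generations. The test suite checks the chain against an independent
  gamete-level selfing Monte Carlo. Residual heterozygosity is injected
  per cell (default 0.1%, reflecting near-fixed NAM RILs; real rates
  are not published for the classic panels, so the default is the
  module's own), as is optional missingness.
* **Traits** as $y_i = \mu_{fam(i)} + \sum_k a_k x_{ik} + e_i$ with the
  residual variance set from the realized genetic variance so the
  genetic fraction equals the target $h^2$ exactly in expectation. A
  target of $h^2 = 0$ yields pure noise (a fixed nonzero effect cannot
  coexist with zero heritability); $h^2 = 1$ yields an exact linear
  function of the codes.
* **Field trials** with the augmented layout described above: fresh
  randomization of test lines to blocks each year, the common parent in
  every block, and additive year, block-within-year and residual noise.

What it does *not* emulate — and therefore what passing tests cannot
certify about real data: crossover interference (Haldane is
interference-free), segregation distortion, dominance or epistasis at
the trait level, genotyping error beyond missingness,
genotype-by-environment interaction beyond additive year effects, and
spatial field trends within blocks. All randomness flows from one
user-supplied seed with fixed substream offsets per operation, so equal
seeds give byte-identical outputs.

## Numerical choices

* Scans use QR-based residualization; a test marker whose residual
  against the conditioned design drops below $10^{-8}$ of its original
  scale is declared collinear and recorded with $p = 1$ and a flag
  rather than an arbitrary value. (The rank reported by R's pivoted QR
  counts a column that is tiny from the outset as independent, so the
  collinearity check is done against pre-residualization column norms.)
* Exact fits (RSS of zero) are clamped so p-values underflow to 0 and
  LOD to infinity instead of producing negative residual sums.
* REML fits floor variance components at zero (lme4's boundary
  behaviour) and singular fits are accepted silently — a zero block
  variance is a legitimate estimate on a balanced design.
* The Holm adjustment is `stats::p.adjust(method = "holm")` behind a
  validated interface; the test oracle is an independent implementation
  written straight from the step-down definition. The adjustment family
  is all off-diagonal pairs of the requested correlation matrix.
* Correlations default to pairwise-complete observations (the behaviour
  of the classic `corr.test`-style tools this mirrors); strict listwise
  deletion is available via `use = "listwise"` since the phrase
  "complete observations" is genuinely ambiguous.

## Problem sizes used in validation

The acceptance suite and `scripts/acceptance.R` validate operating
characteristics at sizes chosen to mirror a realistic single study while
remaining comfortable to re-run: type-I error of the single-family
procedure over 200 null replicates (156 RILs, 10 chromosomes × 20
markers at 1.6 cM, 200 permutations, $\alpha = 0.05$); the joint
procedure over 100 null replicates (4 families × 150 RILs, 200 markers,
200 within-family permutations); power and parameter recovery for a
single 12%-variance QTL over 100 replicates; BLUE quality over 100
simulated augmented trials; and simulator calibration at $n = 10{,}000$
lines. The scans are vectorized (crossproduct form over all markers and
permutations at once), which is what makes hundreds of
permutation-calibrated replicates cheap.

## Known limitations

QTL positions are restricted to marker locations — there is no interval
mapping between markers, and no composite-interval or multiple-QTL model
search beyond forward selection. The permutation threshold reuses the
unconditioned null across stepwise rounds by default, which is slightly
conservative for later steps. Mixed-model BLUEs assume homoscedastic
residuals and exchangeable blocks (no row/column spatial modelling). The
joint model assumes a common residual variance across families. None of
these restrictions are fundamental to the containers or interfaces, but
they delimit what the current implementation claims.
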