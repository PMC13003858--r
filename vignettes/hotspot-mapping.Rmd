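---
title: "Mapping trans-regulatory hotspots across omics layers in inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-regulatory hotspots across omics layers in inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotqtl)
```

## The problem

In a reference panel of fully inbred strains — of the kind used to map the
genetics of complex disease in the mouse — every strain can be measured on
several omics layers at once: genotypes at tens of thousands of SNPs,
transcript abundances in a tissue of interest under control and treated
conditions, and CpG methylation from reduced-representation bisulfite
sequencing (RRBS). Three families of association scans connect these layers:

* **eQTL** — a SNP associated with a gene's expression;
* **mQTL** — a SNP associated with a CpG's percent methylation;
* **emQTL** — a CpG's methylation associated with a gene's expression.

Most such associations are local (*cis*). The scientifically interesting
exceptions are **hotspots**: single genomic windows whose variants (or CpGs)
are associated with far more distant features than chance allows, marking a
master regulator — a transcription factor, a chromatin modifier, a secreted
signalling molecule. `hotspotqtl` implements the full path from raw
matrices to called hotspots, candidate genes, and pathway-level follow-up
tests, together with a synthetic panel generator that makes every stage
testable without any external download.

## Models

### Kinship linear mixed model (eQTL, mQTL)

Related strains share trait values for reasons that have nothing to do with
the SNP being tested. The engine therefore fits, for each trait $y$ and SNP
$x$,

$$y = m + x b + u + e, \qquad
  \mathrm{var}(u) = \sigma_u^2 K, \quad \mathrm{var}(e) = \sigma_e^2 I,$$

with $K$ the kinship matrix computed from the genotypes as a centered
cross-product and standardized so that $\mathrm{tr}(K)/n = 1$ (under this
normalization $h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_e^2)$ is
interpretable as heritability). Variance components are estimated by
restricted maximum likelihood (REML) through one spectral decomposition of
$K$ and a one-dimensional search over $h^2$: a 64-point coarse grid
followed by bounded refinement, so a multi-modal 1-D profile cannot trap
the optimizer. Tests and their tolerances treat a dense-matrix evaluation
of the restricted likelihood as the independent oracle.

For genome-wide scans the variance components are estimated **once per
trait under the null** and then fixed for all SNP tests of that trait (the
standard fast approximation in kinship mixed-model association). Each SNP's
allele effect is then a generalized-least-squares estimate, tested by Wald
F with $(1, n-2)$ degrees of freedom. An `exact = TRUE` mode re-fits REML
per SNP for small scans; on simulated panels the two agree to a fraction of
an order of magnitude in $p$, and the approximation's type-I error at
$\alpha = 0.05$ stays inside $[0.035, 0.065]$ on a structured null (checked
by the test suite). Missing strains are dropped pairwise per (trait, SNP);
the kinship sub-matrix is *not* re-standardized per pair — the trace
condition holds globally, a documented approximation.

### Binomial mixed model (emQTL)

RRBS produces counts, not continuous values: $y_i$ methylated reads out of
$r_i$ total for strain $i$. The emQTL engine models

$$y_i \sim \mathrm{Bin}(r_i, \pi_i), \qquad
  \mathrm{logit}(\pi_i) = w_i^\top \alpha + x_i \beta + g_i + e_i,$$

with $g \sim \mathrm{MVN}(0, \sigma^2 h^2 K)$ capturing population
structure and $e \sim \mathrm{MVN}(0, \sigma^2 (1-h^2) I)$ capturing
independent overdispersion; $x_i$ is the (per-gene standardized) expression
of the gene under test and the reported test is Wald on $H_0: \beta = 0$.

**Estimator choice.** The model is fitted by penalized quasi-likelihood:
the logit-binomial likelihood is linearized to a working response, the
working linear mixed model's two variance components are estimated by REML
(Cholesky-based, warm-started across iterations), and the loop is iterated
to convergence. This estimator is deterministic, runs in ~0.1 s per CpG at
$n = 96$, and its calibration is demonstrated rather than assumed: under a
simulated null ($n = 96$, mean depth 20, $h^2 = 0.3$) 1000 fits give
KS-uniform p-values, with calibration holding at mean depths 5 and 50 as
well, and a planted $\beta = 0.5$ is recovered with near-nominal
$\pm 2\,\mathrm{se}$ coverage. With $K$ absent the fit reduces to an
overdispersed logistic regression and matches an independent
Laplace-approximation GLMM implementation. Every fit is stamped with its
approximation label.

### Feature filters

The scans run on filtered feature sets, with every rule exposed as a
parameter and every application emitting an auditable report:

| filter | rule | default | boundary |
|---|---|---|---|
| genes | mean abundance and coefficient of variation | mean > 5, CV > 10% | strict `>` |
| SNPs | minor allele frequency over non-missing strains | MAF ≥ 5% | inclusive `≥` |
| CpG depth | total reads per cell | depth > 3 (i.e. ≥ 4) | cells masked, never imputed |
| CpG at SNP | SNP at either dyad position (pos, pos + 1) | — | masked in minor-allele carriers only |
| hypervariable CpGs | strains shifted > 25 percentage points from the across-strain **median** percent methylation | ≥ `ceil(5% · n)` strains | strict `>` on the shift |

Two of these rules required interpretation. "Shifts by over 25%" is read as
25 *percentage points* of percent methylation (not a relative 25%), because
the quantity being shifted is itself a percentage; and the reference point
is the across-strain median, which is robust to exactly the outlier strains
the rule is trying to detect. "At least 5% of strains" is `ceil` over the
CpG's non-missing strains. Both readings are documented at the function and
locked by tests.

## The hotspot statistic

The genome is tiled into 500 kb windows (0-based half-open; terminal
windows truncated, so a 2.7 Gb genome yields exactly 5400). For each
feature, its association profile is reduced to the **lowest p-value per
window**; the window's hotspot strength is the number of features whose
window minimum falls below the suggestive threshold 4.2 × 10⁻⁵ (one order
of magnitude above the genome-wide 4.2 × 10⁻⁶). Counts are z-transformed
against the empirical mean and SD over all windows (empty windows count as
zero), and windows are called significant below the Bonferroni threshold
9.3 × 10⁻⁶ = 0.05 / 5400.

**Choice of null tail.** The z-score's normal upper tail is exact only
when per-window counts are approximately Gaussian, i.e. when the mean
count is large. At desk scale — a thousand features, a few hundred windows,
mean counts well below 1 — the count distribution is strongly right-skewed
and the normal tail is badly anti-conservative: in simulation, a pure-null
landscape with mean count 0.3 produces at least one "significant" window
in over 60% of runs. The package therefore defaults to a **Poisson upper
tail at the empirical mean** (`null_method = "poisson"`), which preserves
the empirical-null spirit, converges to the normal-tail answer as counts
grow, and controls the family-wise false hotspot rate below 10% in the
package's null simulations. The normal tail (`"empirical"`) and a
feature-label permutation null (`"permute"`) remain available for
sensitivity analysis, and z-scores are always reported.

Adjacent significant windows merge into loci; a locus' percent-regulated
summary uses the union of its member windows' feature sets. Overlap with a
prior GWAS/EWAS locus list is tested by counting loci with any-bp
intersection and comparing against a **circular-shift null**: per
permutation, each chromosome's loci are shifted by one uniform offset
(wrapping at the chromosome end), which preserves locus sizes, spacing and
chromosome occupancy. Because loci on one chromosome shift jointly, the
test's resolution comes from chromosomes shifting independently — a locus
set concentrated on a single chromosome cannot reach extreme significance,
which is the honest behaviour for a positional enrichment test. Permutation
p-values use the add-one rule throughout, bounded below by
$1/(n_\mathrm{perm}+1)$.

## Candidate genes and pathway follow-up

Within 1 Mb of a merged locus (the typical extent of linkage
disequilibrium in an inbred panel), genes accumulate one evidence point
each for: a coding variant (from an input annotation table), a cis eQTL
below the genome-wide threshold inside the flank, and a phenotype
correlation below 0.05. Ranking is deterministic (score, then ascending cis
p, then gene id). Literature evidence is deliberately out of scope.

The pathway test asks whether a candidate's expression is more correlated
with a gene set than expected: the statistic is the **mean absolute
Pearson correlation** between the target and each pathway member, compared
with random gene sets of equal size drawn without replacement from all
scanned genes, target excluded from both its own pathway and the draws.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` produces a panel whose statistical structure matches
the assumptions above, with full ground truth:

* **Genotypes**: fully inbred strains as founder mosaics — 16 founder
  haplotypes per 2 Mb block, strains grouped into 6 families that inherit
  their family's founder with probability 0.7. This yields block LD and a
  non-trivial kinship matrix without a separate kinship simulation.
  Per-SNP minor allele frequencies are targeted uniformly on [0.05, 0.5]
  by subset-sum over founder usage (realized MAFs land within ~0.05 of the
  range).
* **Expression**: per-gene mean and CV drawn to straddle the expression
  filters with wide margins (20% of genes designed to fail, half by mean,
  half by CV), so designed and realized filter outcomes coincide; a
  kinship-structured polygenic background ($h^2_{bg} = 0.3$) shared
  between conditions; cis effects at each cis gene's nearest SNP; planted
  trans hotspots (a master SNP shifting a configured set of target genes);
  and per-gene treatment shifts. A "delta"-condition hotspot is planted in
  the treated condition only, so the treated-minus-control contrast
  carries it while the shared polygenic term cancels.
* **Methylation**: negative-binomial depth (mean 20, size 5) and
  beta-binomial counts with overdispersion ρ = 0.05 (which makes the
  independent residual of the binomial mixed model identifiable).
  Non-hypervariable CpGs sit near fully methylated/unmethylated
  (|logit| ≈ 4.6), as RRBS islands do; this also keeps beta-binomial noise
  well inside the 25-point hypervariability band, so designed and realized
  hypervariability coincide. Hypervariable CpGs shift a strain subset
  (8–50% of strains) by 4.4 logits; a configurable fraction tie the shift
  to the nearest SNP's minor-allele carriers (planted cis mQTLs). An
  emQTL hotspot is a latent strain factor loading on a 500 kb window of
  CpGs (logit scale) and on a set of target genes; the coupling strength
  (gene loading 0.8 in the demo) is chosen so planted pairs sit clearly
  beyond the suggestive threshold at n = 96, mirroring the strongly
  significant emQTL hotspots real panels produce.
* **Phenotypes**: a heart-weight-like trait driven by one gene's
  expression at a configured correlation (0.6), plus a pure-noise trait.

The generator does **not** emulate microarray saturation, bisulfite
non-conversion, cell-type composition shifts, batch structure, or
sequence-level variation. Green tests therefore demonstrate that the
*statistics* behave as claimed under the model's own assumptions — correct
calibration, correct recovery of planted structure, correct bookkeeping —
not that the pipeline is robust to the technical artefacts of any
particular assay.

## Study sizes and numerical choices

The demo configuration (`default_demo_config()`) is a 96-strain panel on
3 × 50 Mb chromosomes with 2000 SNPs, 1000 genes and 2000 CpGs, one trans
hotspot whose master SNP regulates 10% of genes in the delta condition,
one emQTL hotspot, and one planted pathway; a full delta eQTL scan plus
hotspot call runs in a few seconds, and the repeated-recovery studies in
the test suite (20 planted panels, 50 null panels) complete in minutes on
one CPU. Other conventions:

* p-values are floored at the smallest positive double, so `p` ∈ (0, 1];
* REML searches $h^2$ on [10⁻⁶, 1 − 10⁻⁶]; optima within 10⁻⁵ of an
  endpoint are flagged `"boundary"`;
* the PQL loop caps at 100 iterations; non-convergence leaves `p` missing
  and is flagged, never silently reported;
* degenerate inputs (constant traits, constant predictors, all-zero or
  saturated count responses, all-missing SNPs) are flagged or raise classed
  errors (`hotspotqtl_input_error`, `hotspotqtl_invariant_error`), never
  produce numbers;
* every stochastic operation takes an explicit seed and restores the
  caller's RNG state; `simulate_panel()` is bit-reproducible given its
  config.

## Known limitations

* The EMMAX-style approximation slightly misstates per-SNP variance
  components when a SNP explains a large trait fraction; the `exact` mode
  exists for follow-up of top signals.
* PQL is known to bias variance components for binary-like data; at RRBS
  depths (≥ 4 reads after filtering) the simulation suite shows calibrated
  tests, but single-digit depths with extreme π deserve caution.
* The circular-shift overlap null preserves within-chromosome spacing
  exactly, which is conservative when loci cluster on few chromosomes.
* Percent methylation (not logit) is the default mQTL trait, matching the
  continuous-trait machinery's usual input; a logit option with 0.5
  pseudo-counts is provided.
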