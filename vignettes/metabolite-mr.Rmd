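---
title: "Metabolite GWAS and one-sample Mendelian randomization for gestational dysglycemia: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite MR methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the causal model

Observational associations between maternal blood metabolites and glucose
regulation in pregnancy are heavily confounded: adiposity, diet and social
circumstances move both. `gestmr` implements the standard genetic answer —
one-sample Mendelian randomization (MR). Allele dosages fixed at conception
are used as instruments for a metabolite $X$, and the causal effect of $X$
on a log-transformed glucose outcome $Y$ is estimated by two-stage least
squares (TSLS):

$$X = \pi_0 + \pi_1 \,\mathrm{GRS} + \varepsilon_1, \qquad
  Y = \beta_0 + \beta_\mathrm{IV} \hat X + \varepsilon_2 ,$$

where the genetic risk score $\mathrm{GRS}_i = \sum_j w_j \, g_{ij}$ weights
each instrument SNP by its estimated per-allele effect $w_j$ on the
metabolite from the same cohort's GWAS. The analysis is fully stratified by
ancestry group: allele frequencies, linkage disequilibrium (LD), metabolite
preparation, GWAS and MR are all per stratum, and stratum estimates are only
ever combined by an explicit inverse-variance meta-analysis.

MR rests on the instrument (i) being associated with the exposure, (ii)
sharing no common cause with the outcome, and (iii) affecting the outcome
only through the exposure. The package operationalises (i) with the
first-stage partial F (weak below 10), and probes (iii) with leave-one-out
refits, named-SNP-removal refits, and the Wu-Hausman endogeneity test in its
control-function form (the outcome regressed on exposure plus first-stage
residual; the residual's t-test contrasts IV and OLS).

## The association scan

Metabolite GWAS in a pregnancy cohort with related individuals uses a mixed
linear model: $y = C\gamma + x_j b_j + u + e$ with $u \sim N(0, A\sigma^2_g)$,
where $A$ is the genetic relationship matrix (GRM) of standardised dosages
and $C$ holds parity and the first two genotype principal components.
Gestational age is deliberately not a covariate: sampling in this design
happens in a narrow window, so it carries almost no variance.

Three numerical decisions matter here:

* **Leave-one-chromosome-out (LOCO).** The tested SNP must not sit in both
  the fixed and the random part. The default rebuilds the GRM excluding the
  tested SNP's whole chromosome (cheap: per-chromosome cross-product
  matrices are precomputed and subtracted). A strict per-SNP exclusion mode
  exists for small problems; it costs a dense solve per SNP.
* **Variance components are estimated once per (phenotype, left-out
  chromosome)** under the no-SNP null model and reused for that
  chromosome's SNPs. Restricted maximum likelihood is profiled down to the
  single ratio $\lambda = \sigma^2_g/\sigma^2_e$ after one symmetric
  eigendecomposition, and optimised in one dimension on the log scale.
  Per-SNP REML would change estimates negligibly for the small effects a
  metabolite GWAS hunts, at hundreds of times the cost. At the boundary
  $\hat\sigma^2_g = 0$ the scan's betas collapse exactly to per-SNP OLS;
  the standard errors keep the null-model residual variance, so they differ
  from per-SNP OLS standard errors at order of the SNP's $R^2$.
* **Wald p-values** from the normal approximation, matching mixed-model
  GWAS tool conventions.

Calibration is audited by the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$ in fixed minor-allele-frequency
bins ($<0.001$ up to $\ge 0.1$), with $\lambda \ge 1.1$ flagged. SNPs with
MAF $< 0.05$ are excluded by default — in this design that is the least
stringent cut keeping $\lambda$ near 1.

## Instruments

SNPs reaching the genome-wide *suggestive* level ($p \le 10^{-5}$,
inclusive) are pooled within each metabolite class and thinned greedily by
in-sample dosage LD: ordered by ascending p (ties by chromosome, position),
a SNP is kept iff $r^2 < 0.2$ against everything already kept. Each
metabolite's instrument is its own suggestive SNPs that survived the class
thinning, weighted by its own GWAS betas. A metabolite with no surviving
SNP simply has no instrument and is excluded with a trace — in realistic
architectures a noticeable minority of metabolites end up uninstrumented.
In-sample LD is used rather than an external reference panel: a synthetic
cohort has no 1000-Genomes counterpart, and this is the one deliberate
deviation from reference-panel practice; it is recorded in each
instrument's audit trail. Thinning keeps the most significant SNP of each
LD block, the universal retention rule.

The GRS is unstandardised (weights in mmol/L per allele), so the
first-stage coefficient keeps an interpretable scale. Estimates are exactly
invariant to allele-coding flips and to positive rescaling of all weights —
both asserted in tests, not assumed.

## TSLS details

With the GRS as the single excluded instrument, the TSLS estimate equals
the covariate-projected ratio $\mathrm{cov}(Y, \mathrm{GRS}) /
\mathrm{cov}(X, \mathrm{GRS})$; the implementation is the general
projection form and the ratio identity is asserted to $10^{-10}$ in tests.
Standard errors follow the homoskedastic 2SLS convention — residuals from
the *observed* exposure with the second-stage coefficient,
$\widehat{\mathrm{var}} = \hat\sigma^2_u (\hat X^\top \hat X)^{-1}$ — the
default of the classical IV regression implementations. No covariates enter
the MR stage by default (the stratification carries the structure);
supplying them enters them in both stages symmetrically, and the choice is
recorded in the result object.

Significance throughout means the 95% CI excludes zero. Wu-Hausman p-values
below 0.05 flag deviation between IV and OLS — confounding of the
observational slope, or pleiotropy of the instrument; the sensitivity
refits are the tool for telling these apart.

## Composite class exposures

Correlated metabolites within a class make single-metabolite attributions
fragile, so classes are also analysed collectively: member metabolites are
screened with the stringent median-anchored outlier rule
(median $\pm$ 3·IQR — distinct from the quartile-anchored Tukey fences used
in single-metabolite preparation), standardised, and summarised by the
first principal component. A class is an eligible exposure iff it has more
than two usable members and PC1 explains at least 70% of the class
variance. PC1's sign is fixed (loading sum positive) for backend
determinism, and results are flagged as having no interpretable direction —
a PC1 coordinate has no intrinsic sign. The composite then rides the
*identical* GWAS → thinning → GRS → TSLS code path as any metabolite.

Where the eligibility wording could be read as allowing two-member classes,
the stricter more-than-two rule was adopted; a one-member "class" still
returns the standardised metabolite as its scores but is never eligible.

## Power

Post-hoc power for a continuous-outcome MR uses the non-centrality
parameter

$$\mathrm{NCP} = \frac{n\, R^2_{XZ}\, \beta^2 \,\sigma^2_X}
                      {\sigma^2_Y - \beta(2\beta_\mathrm{obs} - \beta)\sigma^2_X},$$

where the denominator is the residual outcome variance implied by the
causal slope $\beta$ and the observational slope $\beta_\mathrm{obs}$
(their gap identifies the exposure–confounder covariance). Among the
published variants of this calculation, this bookkeeping was chosen and
then validated against the package's own Monte-Carlo power simulator;
power is $P(\chi^2_1(\mathrm{NCP}) > \chi^2_{1,1-\alpha})$ and equals
$\alpha$ exactly at $\beta = 0$. Adequate power is 80% at $\alpha = 0.05$;
when met, the 1% level is evaluated as well. The "true" effect defaults to
the MR estimate, with the observational estimate as the accepted
alternative.

The asymptotic formula overstates power when the instrument is weak: the
2SLS t-test is conservative because the estimate's sampling error inflates
the residual-variance estimate quadratically. `mr_power(method = "finite")`
integrates the exact rejection region of
$t^2 = (bQ + \eta)^2 / (1 + \eta^2/Q^2)$ over the first-stage signal
$Q \sim N(\sqrt{n R^2_{XZ}}, 1)$, with no fitted constants, and tracks
simulated rejection rates within ~2 percentage points from first-stage NCP
5 up to 500 — at the price that its null rejection is below $\alpha$ for
weak designs, exactly as the real test's is. The asymptotic method stays
the default; the finite method is the reference when $n R^2_{XZ} \lesssim 30$.

## The synthetic cohort

Every stage above is exercised on simulated cohorts with known truth, so
parameter recovery, test calibration and diagnostic behaviour are all
checkable without any restricted data.

What the generator emulates, and the chosen defaults:

* **Two strata with different allele-frequency spectra** (per-SNP target
  MAF uniform in a per-stratum range, Hardy-Weinberg draws within
  stratum). Divergent ranges make PC1 separate merged strata, as it should.
* **Relatedness as family blocks.** Pairs share each allele
  identical-by-descent with probability $2\kappa$; the expected genotypic
  correlation within a pair is then exactly $2\kappa$ for any kinship
  $\kappa \in [0, 0.5]$, with $\kappa = 0.25$ the full-sib case in
  expectation. This is the simplest structure that gives the GRM real
  off-diagonal mass and makes the mixed model earn its keep; Mendelian
  transmission from explicit parents would add nothing the GRM can see.
  Deeper pedigrees and inbreeding (consanguinity) are not modelled.
* **Sparse polygenic metabolite architecture**: a handful of causal SNPs
  per metabolite (per-allele effects in mmol/L), an independent residual,
  and an optional class-shared residual factor yielding within-class
  correlation. Reported effect-size scales for suggestive metabolite SNPs
  are not available, so defaults were chosen to land first-stage F in the
  tens-to-hundreds range reported for real instruments (e.g. four SNPs of
  0.205 mmol/L per allele at MAF 0.3 give an instrument $R^2 \approx 5\%$
  and F near 260 at n = 5000).
* **Multiplicative glucose outcomes**:
  $\mathrm{glucose} = \exp(\mu + \sum_k \beta_k \tilde m_k + \lambda_Y U +
  \text{direct SNP effects} + \varepsilon)$, so the natural log is the
  correct normalisation, by construction. $\mu$ targets clinical medians
  (4.5 / 6.0 mmol/L fasting / 2-hour); the default log-scale residual SD of
  0.12 matches a realistic coefficient of variation. Gestational diabetes
  flags use the strict thresholds (fasting > 6.1 or 2-hour > 7.8 mmol/L).
* **One shared confounder** $U$ with configurable loadings on metabolites,
  outcomes, BMI and maternal age; enough to bias OLS and exercise
  Wu-Hausman. Multiple confounders are a config extension, not a default.
* **Optional horizontal pleiotropy**: named SNPs get direct log-outcome
  effects, so leave-one-out and named-removal refits have something real to
  find. Causal effects can differ by stratum, which is how an
  ethnic-specific finding is simulated.

What it does **not** emulate — and what passing tests therefore cannot
show: realistic LD beyond family structure (thinning is exercised on
engineered correlated blocks, not genome-like LD decay), imputation
uncertainty, genotyping batch structure, X-chromosome and indels,
measurement error in the metabolite assay, missing-data mechanisms beyond
outlier masking, and selection into the cohort.

## Metabolite preparation choices

Outliers are masked per stratum with quartile-anchored Tukey fences
(type-7 interpolated quartiles; single pass, fences never re-estimated),
default multiplier 1.5; a constant series masks nothing. Transforms: log,
square root, or the rank-based normal-score transform (Blom offsets,
average ranks for ties). `auto` minimises the absolute sample skewness but
prefers log/sqrt whenever they come within 0.05 of the minimum — the rank
transform trivially achieves near-zero skewness, so without the preference
it would always win, which would defeat the purpose of recording *which*
parametric shape fitted. The original analysis chose transforms by visual
inspection, which is not automatable; the chosen transform is logged per
metabolite for audit. Outliers are removed before transformation, matching
the stated processing order.

## Problem sizes

The shipped simulation studies run at: TSLS recovery, 100 cohorts of
n = 5000; Wu-Hausman size, 2000 null replicates at n = 1000; inflation
study, 300 sib pairs × 5000 SNPs with a 10-chromosome LOCO scheme; power
grid, 27 cells × 2000 Monte-Carlo replicates; end-to-end demonstration,
two strata of 1000 with 2000 SNPs, 10 metabolites in 3 classes. These sizes
give Monte-Carlo error comfortably inside each check's tolerance while
keeping a full run on one core in minutes.

## Known limitations

Single-instrument TSLS per exposure means no MR-Egger or weighted-median
sensitivity estimators (they need multiple independent instruments treated
separately) — the design follows the one-sample GRS approach throughout.
In-sample weight estimation induces winner's-curse-flavoured weak-instrument
bias toward OLS; with the F values this design produces the bias is
negligible, but the F statistic should always be read alongside the
estimate. Selection of stratum-specific suggestive SNPs before
meta-analysis induces winner's curse in the pooled estimates; the workflow
reproduces the stated procedure and does not correct it. The composite-PC1
exposure has no interpretable direction, only magnitude and significance.
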