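---
title: "Variance-components association analysis of a candidate locus in extended pedigrees"
author: "famvc developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-components association analysis of a candidate locus in extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvc)
```

## The statistical problem

famvc implements the full analysis stack of a family-based candidate-gene
study of type-2-diabetes-related traits: a set of SNPs in one genomic region
is tested against quantitative (glucose, insulin, HOMA indices) and binary
(prevalent/incident/ever T2D) traits measured on members of large extended
pedigrees. Because relatives share polygenic background, every test is run
inside a variance-components (VC) mixed model that absorbs kinship:

$$\Omega = \sigma^2_P\,(2\Phi\,h_r^2 + 2\mathbf{E}\,h_{geff}^2 + \mathbf{I}\,e^2),$$

where $\Phi$ is the theoretical kinship matrix computed from the pedigree,
$\mathbf{E}$ an empirical kinship matrix computed from the locus dosages,
$h_r^2$ the residual polygenic fraction, $h_{geff}^2$ the gene-specific
fraction, and $e^2$ the environmental remainder. The four analysis levels
are:

1. **Measured-genotype association (MGA)** — each SNP's dosage enters the
   polygenic model as a fixed effect; a 1-df likelihood-ratio test (LRT)
   against the dosage-free model gives the per-SNP p-value
   (`mga_scan()`). Multiple testing is corrected by the Li–Ji effective
   number of tests $M_\mathrm{eff}$ from the eigenvalues of the absolute
   inter-marker correlation matrix (`li_ji_meff()`,
   `corrected_threshold()`), and a cross-trait probability score
   $PS=\sum_t -\log_{10} p_t$ summarizes each SNP over the trait panel
   (`ps_score()`).
2. **Interaction** — dosage × binarized-age (45 y) and dosage × sex
   products, screened at a liberal global rate (default 0.2) with the same
   $M_\mathrm{eff}$ correction, plus per-stratum refits
   (`interaction_scan()`, `subgroup_fit()`).
3. **BQTN model selection** — all $2^s$ subsets of a pre-screened SNP panel
   are fitted jointly and scored by
   $\mathrm{BIC}_k = -\Lambda_{k0} + \mathrm{df}_k \ln N_e$, where
   $\Lambda_{k0}$ is the LRT statistic of subset $k$ against the
   covariates-only model (`bqtn_scan()`); the null model scores 0, so
   negative BICs mark subsets that beat the complexity penalty.
4. **Gene burden** — the two-component model above, testing
   $h_{geff}^2 = 0$ with an LRT whose null is the ½:½ mixture of a point
   mass at zero and $\chi^2_1$ (`burden_test()`, `mixture_p()`).

## Fitting machinery and numerical choices

All fits are maximum likelihood (not REML): every inferential step is an LRT
between nested models, and ML keeps those likelihoods directly comparable.
Fractions live on the unit simplex; $\beta$ and $\sigma^2$ are profiled out
in closed form.

* **Single-kernel fast path.** With one kernel $K$, the model covariance is
  $\sigma^2[\gamma K + (1-\gamma)I]$. A one-time eigendecomposition of $K$
  diagonalizes every candidate covariance, so each likelihood evaluation
  costs $O(np^2)$ and the 1-d profile over $\gamma$ uses Brent search
  (tolerance 1e-9). Scans, BQTN (which reuses one rotation for all $2^s$
  subsets) and calibration loops live on this path.
* **Two-kernel fits** profile over the mixing weight
  $\lambda = h_{geff}^2/(h_r^2+h_{geff}^2)$: $K(\lambda) = (1-\lambda)2\Phi
  + \lambda 2\mathbf{E}$ is eigendecomposed per candidate $\lambda$ (grid,
  default 21 points, plus golden-section refinement). Calibration loops use
  a fixed precomputed grid that is log-dense near $\lambda = 0$, because
  under the null the boundary overfit bump can sit at very small mixing
  weights.
* **Boundaries are results, not errors**: $\hat h^2 = 0$ or 1 is returned
  as fitted. On likelihood ties (within 1e-8) the boundary $\gamma = 0$ is
  preferred, so an unrelated-individuals design collapses exactly to OLS.
* **Burden SE**: the SE of $\hat h_{geff}^2$ comes from the observed
  information of the profile likelihood (central differences through a
  Cholesky-based likelihood independent of the eigen path). At a boundary
  estimate a one-sided inward curvature is used and the row flagged; a flat
  one-sided curvature yields SE 0, which is also how rows with
  $\hat h_{geff}^2 = 0$, SE 0, p 1 should be read in burden tables.
* **Degenerate inputs**: monomorphic SNPs are excluded from kinship and
  skipped in scans with a logged reason; scans with under 30 complete cases
  per SNP (50 for burden) are skipped; an empirical kinship proportional to
  the pedigree kinship (off-diagonal correlation > 0.999) raises an
  identifiability error; negative eigenvalues of $\mathbf{E}$ are repaired
  by the smallest ridge $\delta I$ restoring positive semi-definiteness,
  with $\delta$ logged.
* **Binary traits** (prevalent/incident/ever T2D) are fitted as 0/1
  indicators in the same Gaussian machinery and flagged as such in outputs.
  This linear-probability treatment keeps every stage inside one likelihood
  framework; a probit-liability fit is a declared extension point, not
  implemented.

## Trait preparation and covariates

Continuous traits are inverse-normalized before analysis with the Blom
rank transform $\Phi^{-1}((r_i - 3/8)/(n + 1/4))$, average ranks for ties,
missing values preserved — effect sizes B are therefore in
transformed-trait SD units. The fixed-effect design is the intercept, age,
age², sex, age×sex, age²×sex (age terms centered and scaled for
conditioning) and, optionally, the top four dosage principal components as
ancestry covariates.

### Locus-derived PCs and the burden test: a caveat

In the study design famvc emulates, admixture PCs come from genome-wide
genotyping. When only a single locus is available — as in the synthetic
datasets here — PCs computed from that locus are the top eigenvectors of
the very empirical kinship matrix the burden test probes, and they load on
every locus dosage. Including them as fixed effects therefore (i) absorbs
part of any true SNP effect and (ii) makes the burden LRT severely
conservative (in our factor experiments the null boundary mass rose from
the theoretical ~½ to ~0.99). Consequently the calibration harness
(`null_calibration()`, `recovery_simulation()`) fits its models without
locus PCs — the synthetic cohort is ancestrally homogeneous, so there is no
admixture to adjust for — while `mga_scan()` and `burden_test()` keep `pcs`
as an explicit argument for data where genome-wide PCs exist. Do not feed
locus-derived PCs to the burden test.

## The synthetic cohort

The generator (`sim_config()`, `simulate_pedigrees()`,
`simulate_genotypes()`, `simulate_traits()`) states one fixed world chosen
to match the cohort structure the analysis assumes; its defaults are not
tuning knobs:

* **Pedigrees**: 42 three-generation outbred families (founder couple,
  5 children with unrelated spouses, 4 grandchildren per couple → 32
  members), 1,344 individuals, within 5% of the ~1,383 emulated. Child and
  grandchild sexes are Bernoulli(0.594 female).
* **Ages**: gamma-distributed (right-skewed) within generation, means
  75 / 52 / 29.17 y, chosen so the cohort mean is 39.17 y; the ≥45 y
  stratum is about a third of the sample, so both interaction strata are
  well populated.
* **Genotypes**: 118 SNPs in a ~100 kb window. MAFs are drawn uniformly
  within three bins — <1%, 1–5%, >5% in proportions 10:13:95 — spanning
  0.007–0.4989. Founder haplotypes come from a Gaussian copula with
  block-exchangeable latent correlation ρ = 0.85 in blocks of 10 (strong
  LD within blocks, none across); non-founders inherit one whole parental
  haplotype per meiosis (no recombination within the window), which
  preserves LD and guarantees Mendelian consistency. SNPs monomorphic in
  the realized sample are re-dropped, since every analysis stage requires
  MAF > 0. Two mid-locus SNPs are tagged "coding" to exercise the coding
  SNP set of the burden panel.
* **Traits**: each latent trait is $X\beta + \sum_j \beta_j x_j + g + e$
  with $g \sim N(0, 2\Phi h^2)$ drawn family block by family block.
  Default per-trait heritabilities (0.65/0.66 liabilities, 0.26–0.42
  continuous) mirror the polygenic fractions typical of these traits.
  Continuous traits are mapped monotonically to lognormal natural scales
  (fasting glucose mean 4.82 mmol/L, insulin 14.11 µU/mL, …) and the HOMA
  indices are *derived* from those columns by their defining formulas, so
  the derivation operations are honest consumers of the generated data.
  The HOMA-β formula is singular at glucose 3.5 mmol/L; such values are
  flagged missing rather than erroring, because ~2% of realistic draws fall
  there.
* **Binary traits**: prevalent T2D thresholds a liability at the quantile
  matching 15% baseline prevalence (moment-matched to the covariate mean
  and variance); incident T2D applies a second liability, sharing the
  polygenic component, thresholded empirically within the followed at-risk
  subset (77.7% of the unaffected) to a 16.3% incidence. Longitudinal
  person-time is not modeled. Continuous traits are masked for prevalent
  individuals, mirroring cohorts that report metabolic traits only for the
  initially unaffected; this also exercises per-trait complete-case
  handling.

What a green calibration test does establish: type-I error and parameter
recovery of the fitting machinery under the stated covariance structure.
What it does not: robustness to genotyping error, imputation uncertainty,
ascertainment, real admixture, non-Gaussian trait tails, or longitudinal
follow-up mechanics — none of which the generator emulates.

## Design choices where the field leaves options open

* **Effective sample size $N_e$** in the BIC penalty defaults to the
  complete-case n of the trait, recorded in every report; a
  pedigree-adjusted effective n can be supplied via `n_e`.
* **"Models in window"** counts candidate subsets with BIC strictly below
  the null's 0 (a Δ-window rule is available); ties on BIC break toward
  fewer SNPs, then lexicographic ids.
* **PS threshold** (default 4.3010) is a configurable preset: with eight
  traits it corresponds to an average per-trait p just under 0.3 per trait
  jointly, but no standard derivation reproduces it from the trait count
  and a per-trait criterion, so it is treated as a preset rather than
  derived.
* **Empirical kinship** uses the allele-frequency-standardized GRM divided
  by two, so $2\mathbf{E}$ and $2\Phi$ enter the burden model on the same
  scale; allele frequencies come from the full sample by default
  (founders-only via `freq_from`), and a raw-covariance dialect is behind
  `style = "covariance"`.
* **Bonferroni** is the default $M_\mathrm{eff}$ correction (0.05/49 ≈
  0.001, $-\log_{10} ≈ 2.99$, matching the printed thresholds the package
  reproduces); Šidák is behind a flag.

## Known limitations

* The Gaussian treatment of binary traits is an approximation; its LRTs
  calibrate well in the null simulations here, but a liability-threshold
  fit would be preferable for strongly unbalanced prevalences.
* With small SNP panels (a few dozen markers) the gene-specific component
  is weakly identified ($\mathbf{E} \approx \Phi$ + noise) and the burden
  mixture test becomes severely finite-sample conservative; the emulated
  118-SNP locus restores near-nominal behavior. Even then the ½:½ mixture
  is asymptotic: with ~18 extended families (n ≈ 600) the null boundary
  mass is ~0.53–0.55 rather than 0.5 and the measured type-I error at
  α = 0.05 is ~0.036–0.041 — mildly conservative, never anticonservative —
  converging into the nominal band at study scale (42 families, n ≈ 1,344,
  measured 0.044).
* The two-kernel profile optimizes $\lambda$ on a grid (plus refinement);
  with a cache the optimum is grid-limited, which is immaterial at the grid
  densities used but worth knowing when reusing `vc_cache()`.
* `run_pipeline()` analyses SNP sets of order $10^2$–$10^3$; there are no
  genome-wide-scale optimizations, by design.
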