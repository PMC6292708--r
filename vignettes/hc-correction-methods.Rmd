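---
title: "Heteroscedasticity- and censoring-corrected chromosome partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heteroscedasticity- and censoring-corrected chromosome partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcpart)
```

## The model and why the standard test fails

Chromosome partitioning fits, for each chromosome $c$, the mixed model
$y = \mu + g_c + e$ with $\mathrm{var}(g_c) = \sigma^2_c A_c$ and
$\mathrm{var}(e) = \sigma^2_e I$, where $A_c$ is the genomic relationship
matrix (GRM) built from the $m_c$ SNPs on that chromosome. The quantity of
interest is $h^2_c = \sigma^2_c / \sigma^2_P$. Polygenicity is then asserted
from a one-tailed OLS regression of $h^2_c$ on chromosome size (base pairs,
or SNP count as its proxy), testing $H_0\!: \beta \le 0$.

Two facts undermine the OLS assumptions:

1. **Heteroscedasticity.** Under linkage equilibrium the information a GRM
   carries about $\sigma^2_c$ under the null scales as $n^2/m_c$, so
   $\mathrm{SE}(h^2_c) \propto \sqrt{m_c}$: big chromosomes have noisy
   estimates exactly where the regression has the most leverage.
2. **Censoring.** Constrained REML cannot return negative variance
   proportions; boundary estimates are reported as $10^{-6}$. Under the null
   roughly half of all fits hit the boundary, so the per-chromosome *mean*
   of censored estimates is approximately
   $\mathrm{SE}_c/\sqrt{2\pi} \propto \sqrt{m_c}$ — a spurious positive
   trend of $h^2_c$ with size even for a trait with no genetic basis.

Either violation alone is survivable: heteroscedasticity without censoring
leaves $E[\hat\beta] = 0$, and censoring with homoscedastic errors adds the
same offset everywhere. Their combination biases both $\hat\beta$ and the
one-tailed P value upward, with severity governed by the number of
chromosomes and the spread of their sizes — mild for the human karyotype,
severe for bird-like karyotypes with many micro-chromosomes.

## The HC-correction

Rather than permuting phenotypes and re-fitting every GRM, the correction
resamples at the level of the regression inputs. Given the observed table
$\{(x_c, h^2_c, \mathrm{SE}_c)\}$:

1. compute the observed one-tailed OLS P value $P_{obs}$;
2. per replicate, draw $h^{2*}_c \sim N(0, \mathrm{SE}_c)$ for every
   chromosome, censor negatives to $10^{-6}$, and recompute the one-tailed
   OLS P value on the fixed design $x_c$;
3. estimate $\Pr(P^*_{null} \le P_{obs})$ with an adaptive Monte Carlo
   stopping rule.

Because a sample standard deviation is proportional to a standard error for
fixed $n$, the resampled tables carry the same pattern of heteroscedasticity
and censoring as the data; their null P value distribution is
indistinguishable from the one obtained by full simulation (this equivalence
is asserted by a test comparing the two routes). The resulting corrected P
value is calibrated: on censored-normal null tables the corrected P values
are uniform and about 5% fall below 0.05.

### Adaptive stopping

`adaptive_mc_pvalue()` draws null replicates one at a time and stops either
at $a$ successes (a replicate at least as significant as observed; ties
count as successes, the conservative convention where a strict inequality
would be the anti-conservative alternative) with $\hat P = a/B$, or at $b$ replicates
with $\hat P = (R+1)/(b+1)$. The defaults $a = 34$, $b = 475$ guarantee a
precision level $c = \mathrm{SE}(\hat P)/\alpha = 0.2$ at $\alpha = 0.05$;
these constants are taken as given configuration (their derivation is
outside this package's scope). The smallest reportable P value is
$1/(b+1) \approx 0.0021$; `adaptive_mc_config(b = 499975, a = 120)` is the
high-precision pair appropriate for reanalyses that must resolve
Bonferroni-scale thresholds. One printed source reads "49,9975"; it is
interpreted as 499,975, consistent with the stated precision goal.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `a`, `b` | 34, 475 | replicates | sequential stopping thresholds |
| `alpha`, `c` | 0.05, 0.2 | — | error rate and precision the defaults guarantee |
| `size_column` | `n_snp` if present | — | regressor: SNP count (simulated tables) or base pairs |
| censoring floor | $10^{-6}$ | variance proportion | the boundary-reporting convention of GREML software |
| `maf_min` | 0.05 | frequency | biallelic SNP filter in the simulator |
| `k` | 1 | — | SE scale in resample-mode experiments; all null P values are invariant to it |

Censoring applies to strictly negative values only; exact zeros pass
through. Perfect-fit regressions return P = 0 (positive slope) or 1
(negative); constant-response tables return $t = 0$, one-tailed P = 0.5.

The QQ inflation factor $\lambda$ is the slope of observed on expected
$-\log_{10} P$, expected quantiles $(i - 0.5)/n$, fitted through the origin;
a free-intercept option exists for sensitivity analysis but the
through-origin fit is canonical here (the source this convention descends
from does not pin either choice down).

## The simulation engine: what it emulates, what it does not

The validation experiments replace a coalescent simulator + GCTA pipeline
with an in-package engine chosen deliberately for transparency and speed:

* genotypes are **linkage-equilibrium binomial draws**: allele frequencies
  uniform on (0.05, 0.95), $x_{ij} \sim \mathrm{Bin}(2, p_i)$, loci failing
  the empirical MAF $\ge$ 0.05 filter redrawn;
* SNP counts are allocated to chromosomes multinomially by length (with a
  floor of 3 SNPs so every per-chromosome model is identifiable);
* phenotypes follow $y_j = \sum_i w_{ij} u_i + \varepsilon_j$ with
  standardized genotypes $w_{ij} = (x_{ij} - 2p_i)/\sqrt{2p_i(1-p_i)}$,
  standard-normal allelic effects, and
  $\sigma^2_e = \mathrm{var}(g)(1/h^2 - 1)$ computed from the realized
  sample variance of $g$, so the realized heritability matches the target up
  to residual sampling noise. (Printed formulas for this residual variance
  sometimes carry the algebraically impossible divisor $1 - 1/h^2$, negative
  for $h^2 < 1$; the convention above is the standard one and the one
  implemented.)
* REML is computed by one spectral decomposition of each GRM followed by a
  1-D profile likelihood over the ratio
  $h = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$ on $[0, 1)$, the total variance
  solved in closed form.

Everything the package must reproduce — the $\mathrm{SE} \propto \sqrt{m_c}$
law, the ~50% boundary pileup, the genome-dependence of the inflation, the
calibration and the permutation agreement — is driven by GRM sampling noise
and chromosome-size structure, which this engine captures. What it does
*not* carry is linkage disequilibrium. LD matters quantitatively in one
place: in coalescent data the effective number of independent segments grows
sublinearly with SNP count on short, high-LD chromosomes, which flattens the
SE-vs-$\sqrt{m_c}$ relation and therefore dampens the inflation somewhat.
Consequently the inflation factors measured here for the chicken preset
(λ ≈ 3.9–4.2 across seeds at 1000 datasets) sit somewhat above the ≈3.4
obtained with coalescent genotypes, while the human preset (λ ≈ 1.5) is
insensitive because its SE spread is modest either way. The exact
SE-vs-size slope of a coalescent/GCTA pipeline is likewise tied to that
pipeline; only the linearity of the relation is treated as reproducible.
Passing tests therefore demonstrate the mechanism and the calibration of the
correction, not LD-specific magnitudes. No population structure, selfing,
overlapping generations or multi-GRM joint fitting is modeled.

## Numerical choices

* **REML optimum.** The profile likelihood is evaluated on a 21-point
  coarse grid and refined by golden-section search in the bracketing
  interval (guarding against the occasional multimodality a pure local
  search could miss); the boundary $h = 0$ wins ties. A fit at the boundary
  is reported as $h^2_c = 10^{-6}$ after censoring, mirroring constrained
  GREML plus the censoring convention.
* **Standard errors.** The SE of $h^2_c$ is the delta-method transform of
  the inverse observed information of $(\sigma^2_g, \sigma^2_e)$, computed
  by central finite differences at the optimum. Where that matrix is not
  usable (degenerate boundary cases) the curvature of the profile
  likelihood, and as a final fallback the half-unit likelihood-drop width,
  is used; `se_method` records which route produced the value. On
  recovery simulations at $n = 500$ the mean reported SE is within ~12% of
  the empirical spread of the estimates.
* **GRM validity.** Eigenvalues below $-10^{-8}\lambda_{max}$ fail the PSD
  check; small negative eigenvalues from roundoff are clipped to zero.
* **Degenerate inputs.** Tables need $\ge 3$ chromosomes, unique labels,
  strictly positive SEs and a non-constant size column; a 1-row
  "partitioning" is rejected rather than silently producing an
  unregressable object.
* **Reproducibility.** Every driver takes a master seed; per-dataset
  streams are derived deterministically from it, and the HC and permutation
  procedures on the same dataset use independent derived streams so their
  agreement cannot be a shared-randomness artifact.

## Problem sizes used in the shipped experiments

The packaged validation suite runs at desk scale, chosen to keep each
experiment's Monte Carlo error well inside the asserted tolerances: 1000
resampled null datasets of 10,000 SNPs per genome preset for the inflation
and false-positive measurements; 1000 tables for the calibration check; 80
full datasets ($n_i = 200$, $n_l = 1000$, 40 per genome, half at $h^2 = 0$
and half at $h^2 = 0.5$ with 50 causal loci) for the permutation-agreement
measurement; 100 replicates at $n_i = 500$ for parameter recovery; and 100
full null datasets ($n_i = 150$, $n_l = 1000$) for the
$\mathrm{SE} \propto \sqrt{m_c}$ law.

## Genome presets

Only *relative* chromosome sizes enter any computation. `human22` carries
the GRCh37 autosome lengths (48–249 Mb). `chicken28` carries the 28 chicken
autosomes of at least 1 Mb (2.8–198 Mb, many micro-chromosomes); the
digit-level values approximate the modern reference assembly, and the
sub-1 Mb micro-chromosomes are excluded because they receive too few SNPs
for a stable per-chromosome fit. The two presets bracket the mild and
severe regimes of the censoring-heteroscedasticity bias.

## Known limitations

* The correction fixes the *regression test* given per-chromosome
  $(h^2_c, \mathrm{SE}_c)$ inputs; it does not correct biases in those
  inputs themselves, e.g. from population stratification affecting
  separate per-chromosome fits.
* The permutation null permutes uniformly over individuals and is only
  valid for panmictic samples; the function warns when that assumption is
  disclaimed.
* λ and $\lambda_{cor}$ quantify inflation on different scales
  ($-\log_{10}$ QQ slope vs a plain P value ratio) and are not numerically
  interchangeable.
* HC-corrected P values inherit the Monte Carlo resolution floor
  $1/(b+1)$; genuinely tiny P values require raising $b$.

## A worked run

```{r example, eval = FALSE}
tab <- read_partition_table(
  system.file("extdata", "synthetic_partition_table.tsv", package = "hcpart"))
hc <- hc_correct(tab, adaptive_mc_config(seed = 1))
summary(hc)

ex <- run_null_experiment("chicken28", n_datasets = 1000, seed = 1)
qq_lambda(ex$p)
plot(ex)
```
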