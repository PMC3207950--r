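---
title: "Statistical methods for G' bulk segregant scans"
author: "gprimescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for G' bulk segregant scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gprimescan)
```

## The problem

Bulk segregant analysis (BSA) maps quantitative trait loci by phenotyping a
segregating population (here an F2 of size $N$), pooling the $n$ most extreme
individuals from each phenotypic tail into a *low* and a *high* bulk, and
sequencing each pool at mean coverage $C$ per site.  At every biallelic SNP
the data are the four allele depths of a $2\times2$ table (high/low-parent
allele $\times$ low/high bulk).  Away from any QTL both bulks are random
samples of the segregant population and the allele frequencies agree in
expectation; near a QTL they diverge.

## The G statistic and its null inflation

`gStatistic()` computes the likelihood-ratio goodness-of-fit statistic

$$G = 2\sum_{\text{cells}} O \,\ln(O/E),$$

with independence-model expected counts $E$, the convention $0\ln 0 = 0$, and
no continuity correction.  Monomorphic tables get $G = 0$ so scans stay dense
for smoothing.

If the bulks were fixed and only sequencing varied, $G$ would be approximately
$\chi^2_1$.  In a real experiment the allele frequency in each bulk is itself
random: $a$ alleles are sampled into a bulk ($a = 2n$ for diploid F2
segregants, $a = n$ for homozygous diploids), adding binomial variance
$p_0q_0/a$ on top of the read-sampling variance $\approx p_0q_0/C$.  The
contingency-table test calibrates itself against the read-sampling level only,
so under the null the statistic is inflated by the variance ratio.
`nullMomentsG()` implements the resulting leading-order approximations

$$\mathrm{E}[G] \approx \frac{1/a + 1/C}{1/C} = 1 + C/a,
\qquad \mathrm{Var}[G] \approx 2\,(1 + C/a)^2,$$

treating $G$ as a scaled $\chi^2_1$.  Both reduce to $(1, 2)$ when $C \ll a$.
Because both variance components are proportional to $p_0(1-p_0)$, the
inflation factor is unchanged under segregation distortion ($p_0 \neq 0.5$) at
this order; the distorted null therefore nests the $p_0 = 0.5$ case, and `p0`
is carried in the design for interface completeness and for the simulator.
These are deliberately *leading-order* formulas: they ignore
$O(1/C)$ discreteness corrections, and the package's own simulations (below)
show they run 1–2% low in the mean and a few percent low in the variance at
$C = 50$, $a = 300$.  We keep the simple closed forms because that is the
accuracy regime the downstream log-normal tail approximation needs.

## G': Nadaraya–Watson smoothing

A large share of the noise in $G$ is site-local (the random read margin), while
true QTL signal is shared by linked sites.  `smoothGprime()` replaces each
site's $G$ by the kernel-weighted average over all sites within a
half-bandwidth $W$,

$$G'_i = \sum_{|x_j - x_i| \le W} k_j \, G_j,$$

with tricube weights $k_j \propto (1 - D_j^3)^3$, $D_j = |x_j - x_i|/W$,
normalized to sum to one (a rectangular kernel is available; boundary sites at
$D = 1$ carry weight zero under the tricube, and are included under the
rectangular kernel).  Chromosomes are smoothed independently.  At chromosome
ends the $(x, G)$ pairs inside the terminal half-bandwidth are reflected about
the terminal site, the smoother is run, and the appended values are trimmed —
so a constant series is reproduced exactly at the edges.

`kernelWeightSumsq()` returns $k' = \sum_j k_j^2$ per site, the variance-
reduction factor of the smoother on independent inputs ($1/m$ for a
rectangular kernel over $m$ sites).

### Null moments of G'

Weights sum to one, so $\mathrm{E}[G'] = \mathrm{E}[G]$.  For the variance,
`nullMomentsGprime()` offers two modes:

* **sequencing_only** — bulks fixed (e.g. two sequencing runs of the same
  pools): the $G_j$ are approximately iid $\chi^2_1$ and a weighted central
  limit argument gives $G' \sim$ approximately normal with mean 1 and variance
  $2k'$.
* **hierarchical** — the full design: read noise is independent across sites,
  but every site in a window shares the same draw of segregants into bulks.
  For the shared component we use its tight-linkage value, giving

  $$\mathrm{Var}[G'_i] \approx \sum_j k_j^2\,\mathrm{Var}[G] +
  \sum_{j \ne l} k_j k_l \, 2\,(C/a)^2 .$$

  Treating in-window SNPs as completely linked is a deliberate simplification:
  with a Haldane map, the pair covariance is attenuated by $(1-2r_{jl})^2$,
  about an 8–10% effect across a $\pm 5$ cM window.  The attenuated version is
  available (`linkageDecay = TRUE`); the unattenuated form is the default
  because it is the closed form the rest of the pipeline (and the reference
  calibration below) is built on, and because it errs on the conservative side
  (it over-predicts the null variance slightly, as the calibration shows:
  predicted 0.065 against an observed 0.058–0.060).

The null distribution of $G'$ is right-skewed; its upper tail is well
approximated by a log-normal whose parameters `lognormalFromMoments()` solves
from the mean and variance:
$\mu = \ln(m^2/\sqrt{v + m^2})$, $\sigma^2 = \ln(1 + v/m^2)$.
`pvaluesLognormal()` turns a scan into upper-tail p-values and z-scores of
$\ln G'$.

### Choosing W

The matched-filter argument says the best smoothing kernel mirrors the signal
shape.  `expectedGprimeProfile()` computes the expected $G$ as a function of
map distance from a QTL: the bulk allele-frequency divergence attenuates
through the recombination fraction ($p(x) = 0.5 + (p-0.5)(1-2r(x))$, Haldane
map), expected depths are plugged into the $G$ formula, and the hierarchical
null expectation $1 + C/a$ is the baseline.  For a locus fixed in one bulk at
frequency 0.5 in the other, the half-width at half-maximum comes out near
10 cM (FWHM $\approx$ 20 cM) under this plug-in form.  `recommendBandwidth()`
returns a kernel of $\approx$ 30 cM full width for single-peak scans
(smoothing ratio 1–1.5) and $\approx 0.7\times$FWHM to resolve adjacent peaks,
converted to physical distance by a single user-supplied cM/kb rate
(per-chromosome rates can be passed by scanning chromosomes separately;
regional recombination maps are out of scope).

## Robust empirical null

On real data the theoretical design parameters may be unreliable.
`estimateNullRobust()` fits the log-normal null directly from the observed
genome-wide $G'$, treating it as a mixture of null sites and right-shifted QTL
regions: (1) log-transform; (2) compute the scaled *left* MAD (spread from
observations at or below the median only — immune to the QTL tail);
(3) flag upper outliers by Hampel's rule at $g = 5.2$; (4) trim;
(5) set $\hat\mu = \ln(\mathrm{median})$ and
$\hat\sigma^2 = \ln(\mathrm{median}) - \ln(\mathrm{mode})$ of the trimmed
unlogged values, the log-normal identity $\text{median}/\text{mode} =
e^{\sigma^2}$.  The mode is estimated by the half-sample mode (iterated
shortest halves, lower interval on ties), with a kernel-density mode available
behind `modeEstimator = "kde"`.

Two practical notes, both visible in the calibration:

* Mode estimation converges slowly ($n^{-1/3}$); $\hat\mu$ is excellent at
  $10^5$ sites but $\hat\sigma$ should be expected to carry ~10% noise even on
  genome-scale scans.
* On a *single short chromosome* the scan is strongly autocorrelated: the
  whole $G'$ curve shares one draw of segregants into bulks, so a per-scan fit
  can only see the within-scan spread, which is smaller than the
  across-experiment variance of any one site, and the median–mode identity is
  frequently degenerate (mode $\ge$ median).  In that case the estimator falls
  back to the scaled left MAD of the trimmed logs for $\hat\sigma$.  The
  consequence, quantified below, is a strongly conservative test in the
  single-chromosome simulation geometry.  On multi-chromosome genomes the
  effective number of independent windows is much larger and the procedure is
  close to calibrated; it remains the recommended default for real data.

## Calling QTL regions

`bhFdr()` applies the Benjamini–Hochberg step-up rule at target FDR $q$
(default 0.01) over all sites; `callRegions()` turns the significance mask
into maximal runs of consecutive significant sites per chromosome (an optional
`maxGapSites` bridges short gaps; the default is 0), recording each region's
peak — the leftmost in-region maximum of $G'$ — as the QTL point estimate.
Smoothed values are heavily autocorrelated, so BH over all sites is
conservative in the count of "discoveries" but matches how the scan is used in
practice.  `runGprimeScan()` chains all steps and logs its effective
configuration.

## The simulator and the reference conditions

`simulateF2Bulks()` implements the full generative model: Mendelian QTL
genotypes at probabilities (1/4, 1/2, 1/4) with additive values
$(-\delta/2, 0, +\delta/2)$; phenotype = value + Normal(0, residual SD);
truncation selection of the $n$ lowest and highest into bulks; marker
haplotypes built outward from each selected QTL allele, recombining between
adjacent markers with the Haldane fraction for their spacing, independently
per interval and per gamete (two independent gametes per diploid F2
individual; one gamete, doubled, for homozygous designs, so the effective
allele count is $n$); and finally two *independent* Poisson read counts per
site and bulk with means $Cp$ and $C(1-p)$ — so the total site depth is
Poisson($C$), not conditioned on a fixed total.  Ties in phenotype are
measure-zero and broken by individual index; all drivers accept a seed and
reproduce scans bit-identically.

The package's reference conditions — the defaults of `SimDesign()` — are:
$N = 1000$, $n = 150$ per tail (15%, inside the 10–20% bulk-fraction
recommendation), $C = 50$ per bulk, one 10 cM chromosome carrying uniformly
spaced markers at 40 SNPs/cM with the causal locus at its center, residual SD
1, tricube half-bandwidth $W = 5$ cM, and a "weak QTL" whose homozygote
difference $\delta = \sqrt{8 h^2/(1-h^2)}$ explains $h^2 = 2\%$ of the
phenotypic variance (`qtlEffectForVariance()`).  These values were fixed once,
jointly, as the conditions under which the closed-form predictions and the
simulator tell one consistent story (the calibration numbers quoted here are
produced by `scripts/acceptance.R` and the acceptance test suite at these
exact settings); they are realistic for a yeast-style cross sequenced at
moderate depth.

What the simulator deliberately does *not* model: crossover interference
(Haldane, independent intervals), sequencing error and reference bias
(depth-only Poisson noise), multi-QTL architectures (one causal locus per
chromosome), and RIL/backcross/outcross designs.  Passing calibration here
shows the statistics behave as derived **under the hierarchical sampling
model**; on real data, mapping bias or non-Poisson depth would surface as a
misfit that the robust null (not the theoretical one) is designed to absorb.

### What the calibration shows

At the reference conditions (10,000 replicates in `scripts/acceptance.R`;
scaled-down counts with Monte-Carlo-error bands in the test suite):

* Raw $G$ at the focal SNP has null mean $\approx 1.18$ and variance
  $\approx 2.6$–$2.9$ — inflated above $\chi^2_1$ exactly as
  $\mathrm{E}[G] = 1 + C/a = 7/6 \approx 1.17$ predicts; the naive
  $\chi^2_1$ test is mildly anticonservative (type-I $\approx 7\%$ at nominal
  5%) and badly underpowered for the weak QTL ($\approx 36\%$).
* $G'$ has null mean $\approx 1.18$ and variance $\approx 0.059$–$0.061$
  against the closed-form prediction 0.065; the log-normal theoretical null
  gives type-I $\approx 5$–$6\%$ at nominal 5% and raises weak-QTL power to
  $\gtrsim 92\%$ at the 1% level.
* The per-replicate robust fit is strongly conservative in this
  single-chromosome geometry (type-I below 1% at nominal 5%), for the
  autocorrelation reason discussed above.

## Numerical choices and edge cases

* Window membership is the closed interval $|x_j - x_i| \le W$; consequential
  only for the rectangular kernel (tricube boundary weight is 0).
* bp-to-cM conversion is one constant rate (`cmPerKb`); simulated coordinates
  use 1 cM = 1 kb.
* Zero-depth sites are excluded at read time (logged); zero $G'$ values are
  dropped (with a count) before the robust log-transform.
* `lognormalFromMoments(m, 0)` returns the degenerate $(\ln m, 0)$; p-values
  under a degenerate model are 0/1 step functions.
* Half-sample-mode ties take the lower-indexed shortest half; all estimators
  are deterministic given the data.
* The MAD consistency constant 1.4826 is applied to the left MAD so that
  $g = 5.2$ keeps its conventional normal-theory meaning.

## Known limitations

* The null-moment formulas are leading-order; at low coverage
  ($C \lesssim 20$) Poisson discreteness inflates $G$ beyond them.
* The tight-linkage covariance in the $G'$ variance over-predicts by
  $\approx$ 10% for windows spanning several cM (use `linkageDecay = TRUE`
  for the sharper value).
* The robust null estimator needs many effectively independent windows; on a
  single short chromosome it is identifiable only through its left-MAD
  fallback and is then conservative.
* BH is applied to autocorrelated per-site p-values; region-level error rates
  are controlled indirectly.
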