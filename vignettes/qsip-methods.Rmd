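---
title: "Quantitative 13C stable isotope probing: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 13C stable isotope probing: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosip)
```

## The measurement problem

Quantitative DNA stable isotope probing (qSIP) asks, taxon by taxon, how much
of a 13C-labeled substrate a microbial community assimilated into new DNA.
After incubation with a labeled substrate (here: bicarbonate, acetate or
formate, each with and without added H2), community DNA is separated by
isopycnic CsCl centrifugation, the gradient is fractionated, and each
fraction is both quantified (qPCR of 16S rRNA gene copies) and sequenced
(16S amplicons clustered into OTUs). DNA that incorporated 13C is heavier
and bands at a higher buoyant density; the size of a taxon's density shift,
relative to an unlabeled control incubation of the same substrate, measures
its excess atom fraction 13C (EAF).

`isosip` implements the full chain: table filtering, per-taxon density
estimation, the isotope model, replicate-level bootstrap uncertainty,
treatment summaries, phylogenetic-signal tests, and a ground-truthed
gradient simulator used to validate all of it.

## From counts to weighted average densities

For gradient fraction $k$ with buoyant density $x_k$ (g/ml) and total 16S
copy number $f_k$ (qPCR), a taxon $i$ with read count $c_{ik}$ out of a
fraction total $\sum_i c_{ik}$ is assigned

$$\mathrm{copies}_{ik} = f_k \frac{c_{ik}}{\sum_i c_{ik}}, \qquad
  y_{ik} = \frac{\mathrm{copies}_{ik}}{\sum_k \mathrm{copies}_{ik}}, \qquad
  W_i = \sum_k x_k\, y_{ik}.$$

$W_i$ is the taxon's copy-weighted average density (WAD) in that gradient.
Fractions with zero reads or zero qPCR copies contribute nothing (portion
zero); a taxon with no copies anywhere in a gradient has no WAD there and is
flagged absent rather than erroring.

## The isotope model

The model ties GC content, DNA molecular weight and buoyant density together
with the standard qSIP calibration constants (`isotope_params()`):

* light density: $W_\mathrm{light} = 0.083506\,G + 1.646057$ (g/ml), so
  $G = (W_\mathrm{light} - 1.646057)/0.083506$;
* unlabeled molecular weight: $M_\mathrm{light} = 0.496\,G + 307.691$
  (g/mol per average nucleotide);
* maximum mass gain at complete 13C substitution:
  $M_\mathrm{heavymax} - M_\mathrm{light} = -0.4987282\,G + 9.974564$;
* natural 13C atom fraction: $0.01111233$.

Given a labeled-incubation WAD $W_\mathrm{lab}$ and the light baseline
$W_\mathrm{light}$ (mean of the unlabeled-control replicate WADs of the same
substrate), the shift is converted to a molecular weight
$M_\mathrm{lab} = (\Delta W / W_\mathrm{light} + 1) M_\mathrm{light}$ and

$$A = \frac{M_\mathrm{lab} - M_\mathrm{light}}
          {M_\mathrm{heavymax} - M_\mathrm{light}}\,(1 - 0.01111233).$$

$A = 0$ exactly when $\Delta W = 0$ and $A = 1 - 0.01111233$ at complete
labeling. Negative estimates are reported as-is — truncating at zero would
bias treatment means and hide gradient problems. The simulator's band
placement (`expected_band_center()`) is the algebraic inverse of this chain,
which the tests exploit as an exact round-trip identity.

Noisy WADs can imply GC contents slightly outside $[0, 1]$; these are
clamped with a warning and the unclamped value is kept as a diagnostic
attribute. The constants themselves are deliberately locked: overriding them
requires an explicit `allow_override = TRUE`.

## Uncertainty: replicate-level bootstrap

The unit of resampling is the biological replicate gradient (three per arm
in the emulated design), not reads or fractions: labeled and control
replicate WADs are resampled independently with replacement, the EAF is
recomputed `n_boot = 1000` times, and the two-sided 90% percentile interval
(stock `quantile()` percentiles) is reported. An OTU is called a
13C-assimilator when the lower bound exceeds 0% EAF. OTUs absent from a
treatment's controls are "not evaluable" — a distinct state from unlabeled,
because no baseline exists for them.

With three replicates per arm the bootstrap distribution has at most
$27 \times 27 = 729$ atoms, so it can be enumerated exhaustively; the test
suite checks the Monte-Carlo labeling calls against that enumeration and the
convergence of the resampled EAF distribution to it.

Two properties of this small-sample design are worth knowing:

* the percentile CI at $n = 3$ is anti-conservative: the realized one-sided
  false-labeling rate on null communities exceeds the nominal 5% (the
  acceptance script reports the realized rate as
  `false_labeling_rate_null`);
* tube-level noise (e.g. qPCR error shared by all taxa in one gradient) makes
  false calls correlated across taxa, so the realized rate in any single
  experiment scatters widely around its expectation.

```{r null-rate, eval = FALSE}
# the intrinsic one-sided error of the 3+3 percentile-bootstrap rule,
# independent of any gradient model
idx <- as.matrix(expand.grid(1:3, 1:3, 1:3))
mean(replicate(5000, {
  a <- rnorm(3); b <- rnorm(3)
  d <- outer(rowMeans(matrix(a[idx], 27)), rowMeans(matrix(b[idx], 27)), "-")
  quantile(d, 0.05, names = FALSE) > 0
}))
```

## Filtering rules

Both filters mirror common qSIP practice and are applied in a fixed order —
contaminants first, then abundance — with read totals and removal
percentages reported at each step:

* **Contaminants.** An OTU is kept only if its total reads across all
  samples are *strictly greater* than 10 times its aggregate read count in
  laboratory contamination controls (dust blanks). The inequality is strict:
  100 sample reads against 10 contaminant reads is removed. OTUs absent from
  the contaminant profile are kept. Contaminant counts are aggregated over
  all control samples before the comparison.
* **Low abundance.** Within each treatment (substrate x H2 arm), an OTU
  enters the qSIP analysis only if it has *strictly more than* 12 reads,
  summed across density fractions, in every replicate gradient of that
  treatment (labeled and control alike). Low-abundance taxa produce
  artificially volatile WADs. The rule is applied per treatment: an OTU may
  be evaluable for acetate but not for formate; `filter_low_abundance()`
  returns the per-treatment keep matrix alongside the filtered table and the
  per-treatment status is visible in the fit (`evaluable`). We read the
  replicate scope of this rule as "each replicate of the treatment being
  analysed" rather than study-wide, since qSIP is computed within a
  treatment.

Both filters are idempotent and conserve reads
(`kept + removed = total`), and the contamination rule is monotone in its
ratio; the tests verify all three properties on randomized tables.

## Treatment summaries

`summary()` on a fit reports, per treatment, labeled and unlabeled counts,
the percentage labeled ($100\,n_\mathrm{lab}/(n_\mathrm{lab} +
n_\mathrm{unlab})$, printed to one decimal) and the mean/SD of EAF.
`h2_effect()` contrasts a substrate's arms as
$100\,(\bar A_{+H2} - \bar A_{-H2})/\bar A_{-H2}$ (printed as a whole
percent). Means are taken over all evaluated OTUs by default — restricting
to labeled OTUs is available as a sensitivity flag (`labeled_only`) — and
the uncertainty attached to the percent change is a bootstrap over OTUs
(1000 resamples). Percent change is undefined at a zero baseline and errors
there; it is also numerically unstable when the baseline mean is near zero,
which is worth remembering when contrasting weakly labeled arms.
Community-level context uses the classic Chao1 estimator
($S_\mathrm{obs} + f_1^2/2f_2$, bias-corrected branch when $f_2 = 0$), a
Welch t-test on per-sample Chao1 values, and ANOSIM on Bray-Curtis
dissimilarities of relative abundances (computed by vegan, 999 label
permutations, average rank ties).

## Phylogenetic signal

Whether 13C assimilation is phylogenetically organized is tested per
treatment on the EAF trait (or, optionally, the binary labeled indicator —
the continuous trait is the default because it preserves effect sizes).
OTUs not evaluable in a treatment are pruned from the tree first.

* **Blomberg's K** compares the observed ratio of the ordinary mean squared
  error (around the GLS mean) to the phylogenetic GLS error with the ratio
  expected under Brownian motion,
  $(\mathrm{tr}(C) - n/\mathbf{1}'C^{-1}\mathbf{1})/(n - 1)$; $K \approx 1$
  under Brownian evolution, $K \approx 0$ for tree-independent traits.
  Significance comes from 999 tip permutations of the MSE ratio, observed
  value included in numerator and denominator.
* **Pagel's lambda** scales the off-diagonal of the Brownian covariance; the
  mean and rate are profiled analytically and lambda is maximised by
  bounded scalar optimization (tolerance $10^{-8}$) on $[0, \lambda_{max}]$,
  with $\lambda_{max} = 1$ for ultrametric trees and otherwise the largest
  value keeping the covariance positive-definite. Endpoints are evaluated
  explicitly so boundary optima are never missed. The likelihood-ratio test
  against $\lambda = 0$ uses the boundary-corrected 50:50
  mixture null. ML (not REML) estimation is used, matching the usual
  implementations of this test.

Degenerate inputs are handled explicitly: constant traits and fewer than 4
matched tips are errors; zero-length terminal branches are perturbed by
$10^{-8}$ of tree depth (with a warning) to keep the covariance invertible;
and on a star tree lambda is reported as non-identifiable rather than as a
number, since there is no off-diagonal covariance to scale.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates the full study design: 3 biological
replicates per arm for both the labeled and control incubations, substrates
crossed with H2, ~600 taxa with lognormal abundances (sdlog 1.5), GC drawn
from a Beta(5, 5) scaled to [0.30, 0.70], a 20-fraction gradient spanning
1.640-1.780 g/ml, and laboratory contaminants present in the contaminant
profile and leaking faintly into the samples.

Numerical choices, each a configuration field:

* **Band shape.** Each taxon's DNA is a Gaussian in density (the isopycnic
  diffusion approximation) with SD 0.006 g/ml, chosen so a band spans on
  the order of ten informative fractions, matching how many fractions per
  gradient are typically selected for sequencing. The simulator can emit
  all fractions (default) or the top-k by qPCR signal.
* **Counts.** Per fraction, reads are multinomial at depth 10,000 from the
  taxon mass proportions; qPCR totals get multiplicative lognormal noise
  with CV 20% (mean-one parameterization), a typical inter-fraction qPCR
  variability. Neither the per-fraction depth nor the qPCR CV of the
  original experiments is published; these defaults are stated assumptions,
  not fitted values.
* **Truth.** True EAF is assigned i.i.d. (35% of taxa labeled at
  truncated-normal levels) or as a Brownian trait with configurable Pagel's
  lambda for end-to-end signal tests; band centers are placed by the exact
  inverse of the EAF estimator, so the noise-free pipeline recovers truth
  identically up to grid discretization.
* **Determinism.** A single integer seed drives every draw; equal seeds give
  byte-identical outputs.

Discretization is the one systematic gap between the analytic band center
and a measured WAD: on the default 20-fraction grid the discretized-Gaussian
mean differs from the continuous center by up to about $10^{-4}$ g/ml
(quantization, largest near the grid edges). Because the same discretization
applies to labeled and control gradients it largely cancels in $\Delta W$;
the exact round-trip identity is tested on a fine grid where the effect is
below $10^{-6}$.

The simulator does not attempt: centrifugation physics (rotor speed, run
time, gradient relaxation), PCR/chimera bias, taxon-specific extraction
efficiency, read-level error, or biological between-replicate variation in
true EAF. Passing recovery tests therefore show that the estimator chain is
correct and well calibrated under the modeled noise sources — not that real
gradients contain no additional structure.

## Validation problem sizes

The shipped tests and the acceptance script validate at these scales, chosen
to exercise every claim while keeping a full run in the order of seconds to
a few minutes: exhaustive 27x27 bootstrap enumeration against Monte-Carlo
calls on 50 random 3+3 cases; null calibration on 200 zero-EAF taxa;
recovery on the 600-taxon full design (median absolute EAF error for
taxa above 0.5% relative abundance, threshold 0.05); Blomberg's K over 500
Brownian replicates on a 64-tip tree and Pagel's lambda over 200 replicates
on a 100-tip tree, with a $10^{-3}$-step grid oracle for the lambda
optimizer.

## Known limitations

* 90% percentile CIs from three replicates are approximate and
  anti-conservative (see above); labeling calls near the boundary should be
  read accordingly, and raising the replicate count is the only real cure.
* No between-gradient density standardization is applied; densities are
  taken as recorded per fraction. Systematic tube-to-tube density offsets
  would appear as spurious (positive or negative) EAF.
* GC inferred from control WADs inherits control-arm noise; the clamp to
  $[0, 1]$ flags gross cases but mild GC error propagates into EAF through
  the molecular-weight terms.
* The H2 percent-change summary divides by the baseline mean and is
  unstable when that mean approaches zero.
* Binary labeled/unlabeled traits passed to the signal tests are analysed
  with the Gaussian machinery; results for that mode are heuristic, which
  is why the continuous EAF trait is the default.
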