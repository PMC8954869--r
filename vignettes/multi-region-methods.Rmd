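---
title: "Functional multi-gene-region association tests: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional multi-gene-region association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fregion)
```

## The problem

Single-marker association tests lose power on rare variants because each
locus carries a tiny effect. Region-based methods pool information across a
gene region; functional-data methods go one step further and treat an
individual's ordered 0/1/2 genotype profile across a region as noisy
evaluations of a smooth *genotype function* $X_i(t)$ on a normalized genomic
interval. The quantitative-trait model for $P$ regions is

$$ y_i \;=\; \mu_0 + \sum_{p=1}^{P} \int_0^{T} X_{pi}(t)\,\beta_p(t)\,dt
   + \varepsilon_i,\qquad \varepsilon_i \sim N(0,\sigma^2), $$

where $\beta_p(t)$ is the effect function of region $p$. A region is
associated exactly when $\beta_p \not\equiv 0$. Modelling all $P$ regions
jointly removes the other regions' genetic signal from the residual, which
is what gives multi-region tests their power advantage over testing one
region at a time.

## Genotype smoothing

Each region's genotype rows are expanded on `K = 25` orthonormal Fourier
basis functions (constant plus sine/cosine pairs) evaluated at the marker
grid, with a second-derivative roughness penalty:

$$ \hat d_i = (\Phi^\top\Phi + \lambda_x R_2)^{-1}\Phi^\top X_i^\top, $$

with the penalty matrix $R_2$ available in closed form (diagonal, entries
$\omega^{2m}$ per frequency pair). Markers are placed at their ordinal index
(`(j-1)/(M-1)` on the unit interval); physical base-pair positions can be
used instead via an affine rescale, but the simulation designs here have
equidistant markers, so the ordinal mapping is the default. The default
`lambda_x = 0` (interpolating regression onto the basis); if the normal
equations are singular — e.g. more basis functions than markers — a small
automatic ridge `1e-8 * trace(PhiᵀPhi)/K` is substituted with a message.

Because the genotype and effect bases of the Step methods are the *same*
orthonormal family, the basis cross-product matrix is the identity and the
functional model collapses exactly onto the coefficient blocks
$d_{pi} \in \mathbb{R}^{25}$.

## The Step and LW-Step tests

Step treats each region's coefficient block as one grouped variable of an
ordinary linear model and performs backward elimination: starting from all
$P$ blocks, the block whose deletion most reduces
$\mathrm{AIC} = n\ln(\mathrm{Rss}/n) + 2K$ (with $K$ the count of active
coefficients) is removed, until no deletion improves the criterion. Ties
break toward the lowest region index, for determinism. Each surviving region
is then assigned the block partial F statistic

$$ F = \frac{(\mathrm{SSE}_{red} - \mathrm{SSE}_{full})/q}
           {\mathrm{SSE}_{full}/(n - K_{full} - 1)},\qquad q = 25, $$

with its $F(q,\,n-K_{full}-1)$ p-value. Regions deleted during selection are
reported with `p_value = 1`: the selection is part of the test, and the
power/false-positive accounting needs a value for every region. Forward
selection is available behind `direction = "forward"`; backward is the
default because forward selection trades a small power gain for a much
larger false-positive rate.

LW-Step is Step applied after *locus weighting*: genotype column $j$ is
scaled by the Beta(1, 10) density evaluated at its folded minor allele
frequency ($\Theta = \mathrm{diag}\,f_{\beta}( \mathrm{MAF}_j; a_1, a_2)$),
which upweights rare loci by up to three orders of magnitude relative to
common ones. Because the same smoother is applied to $X\Theta$, weighting
commutes with smoothing and the weighted model is again an ordinary linear
model in the weighted coefficient blocks. The weight is the Beta *density*
at the per-locus MAF: the weight matrix is shared by all individuals, since
allele frequency is a property of the locus, not the person.

## Multi-SLoS, W-SLoS and LW-SLoS

The locally sparse estimator minimizes

$$ \frac1n\sum_i\Big(y_i-\mu_0-\sum_p \int X_{pi}\beta_p\Big)^2
 + \sum_p \gamma_p \lVert D^2\beta_p\rVert^2
 + \sum_p \frac{M_p}{T}\int_0^T p_{\lambda_p}(|\beta_p(t)|)\,dt, $$

where $p_\lambda$ is the SCAD function (shape $a = 3.7$, the Fan–Li
convention) and the last term — the fSCAD penalty — can compress
$\beta_p(t)$ *exactly to zero* on subintervals, and hence whole regions to
null. $\gamma_p$ is the smoothing parameter and $\lambda_p$ the compression
parameter of region $p$; giving region types different $(\gamma_p,
\lambda_p)$ yields W-SLoS, and fitting on Beta-weighted genotypes yields
LW-SLoS.

Numerical realization:

* **Effect basis.** Order-4 B-splines with knots at the region's equispaced
  marker grid, in *marker-index units* (domain $[0, M-1]$, unit knot
  spacing). The marker-unit domain is deliberate: on it the roughness and
  compression magnitudes commonly quoted for these methods (0.1, 0.05,
  0.01, 0.001) span the operative range from strong compression to none.
  On a unit-normalized domain the same numbers are dominated by the
  $1/M^4$-scaled curvature term and compress everything, associated or not.
* **Standardization.** Each region's design block is scaled by a single
  scalar to unit average column variance before penalization — the usual
  convention in penalized regression — and estimates are back-transformed
  afterwards. A scalar per region preserves the shape of $\beta_p$ and puts
  regions of different variance on one penalty scale.
* **fSCAD evaluation.** The penalty integral is evaluated per knot
  subinterval through the SCAD function of the local root-mean-square
  $u_j = \sqrt{(M/T)\int_{I_j}\beta^2}$, computed exactly from the local
  B-spline Gram matrices (4-point Gauss–Legendre per subinterval, exact for
  the polynomial degrees involved). An alternative grouping by
  basis-coefficient support is available (`scadGroups = "support"`).
* **Optimizer.** Local quadratic approximation: each iteration solves a
  generalized ridge system in which the SCAD term contributes weights
  $p'_\lambda(u_j)/(2u_j)$. The surrogate majorizes the objective, so the
  loss path is monotone. The argument $u_j$ is floored at the freeze
  threshold so the weight stays finite; once a subinterval's $u_j$ falls
  below `nullTol * lambda` (default `1e-3 * lambda`, deep inside the SCAD
  linear zone where the weight diverges), coefficients whose whole support
  has collapsed are set exactly to zero and removed from the system.
  Convergence is declared at relative coefficient change below `tol = 1e-4`
  (cap `maxIter = 50`); non-convergence returns the best iterate flagged
  `converged = FALSE`.
* **Adjusted partial F.** After fitting, let $B$ be the non-null regions and
  $k_p$ the count of non-null coefficients in region $p$. Region $b \in B$
  is tested by the nested comparison of the full model (all of $B$) against
  the reduced model ($B \setminus b$), with numerator df $k_b$ and
  denominator df $n - \sum_{p\in B}k_p - 1$: degrees of freedom count only
  coefficients the sparsity stage left alive. The nested SSEs are
  recomputed by unpenalized least squares on the surviving coefficients
  (`sseRefit = "ols"`, the default). A penalized-refit variant is
  available, but shrinkage makes the two nested penalized RSS values nearly
  equal even for strongly associated regions, collapsing the F statistic —
  so the unpenalized refit is the meaningful default. Fully null regions
  are reported unselected with `p_value = 1`.

Default parameter values by study layout (smoothing $\gamma$ / compression
$\lambda$): common-variant layouts 0.1/0.1, rare 0.01/0.01, hybrid
0.05/0.05, loci-weighted mixed layout 0.001/0.001; W-SLoS assigns common
regions 0.02/0.05 and rare regions 0.01/0.0025. No cross-validation is
performed — the values are fixed study conventions, though every fitting
function accepts per-region vectors.

## The synthetic-data engine

The generator emulates a SKAT-style simulation design:

* **Haplotype pools.** $H = 10{,}000$ haplotypes. Common variants: per-locus
  allele frequencies Uniform(0.05, 0.5) (a truncated-normal option mirrors
  the normal-frequency variant), loci independent. Rare variants: per-locus
  frequencies from a left-skewed Beta(0.5, 200) truncated to $(1/H, 0.01)$,
  assembled into a long panel from which each region is a contiguous slice
  at a random offset — a synthetic stand-in for cutting 5 kb segments out of
  a long simulated European-ancestry rare-variant panel. Every locus is
  kept polymorphic. A first-order Markov option generates haplotypes with
  adjacent-pair LD tuned into a target $r^2$ band.
* **Diploids.** $n = 2000$ individuals, each the sum of two independent
  uniform haplotype draws; Hardy–Weinberg holds marginally.
* **Layouts.** 25 all-rare or all-common regions; 15 common + 10 rare in
  random order; 25 regions with a random 40% of each rare region's columns
  replaced by the paired common region's columns; and a 10-region mixed
  layout with fixed rare-variant proportions
  (0.7, 0.8, 0.6, 0.95, 0.9, 0.95, 0.7, 0.9, 0.8, 0.6) at random column
  positions, with associated regions fixed at 2, 4, 5, 7, 10 and eligible
  associated loci restricted to MAF < 0.02.
* **Effects.** Three loci per associated region (drawn fresh each
  replicate), magnitudes $|\beta| = |\log_{10}(2\,\mathrm{MAF})|/4 \times
  1.5$ — zero at MAF 0.5, 0.75 at MAF 0.005. Sign scenarios: I all
  positive; II all loci flipped in two associated regions (a random two in
  the 25-region layouts, the fixed regions 4 and 7 in the mixed layout);
  III one random locus flipped per region.
* **Traits.** $y_i = \sum_j x_{ij}\beta_j + \varepsilon_i$ with
  $\varepsilon\sim N(0, 0.1^2)$; null phenotypes are pure
  $N(0, \mathrm{sd}=0.1)$ noise. The residual scale matches the null-trait
  convention, reading "N(0, 0.1)" as a standard deviation of 0.1; nothing
  in the study states the power-run residual separately.

What the generator does *not* emulate: realistic LD block structure
(coalescent haplotypes), population stratification or relatedness, missing
genotypes, and the exact MAF spectrum of the original European-ancestry
SKAT panel. Rare-variant power in particular depends strongly on that
spectrum, so rare-layout results here are comparable only qualitatively,
not numerically, with studies built on the original panel.

## Problem sizes and reproducibility

Power and false-positive rates are Monte-Carlo estimates: with 5 associated
regions and $R$ replicates, the standard error of a power estimate $r$ is
$\sqrt{r(1-r)/(5R)}$. The package's own acceptance runs use the generator
defaults — 25 regions × 2000 individuals, 60 markers per region — over 50
replicates, enough for standard errors of about 0.01–0.02 on the power
scale. The auxiliary property runs (method orderings on the mixed layout,
null-trait calibration) use 30 markers per region and 20–50 replicates to
keep the test suite fast. Every replicate is seeded (`baseSeed + index` in
the harness), so results are bit-reproducible and independent of any
parallel scheduling.

## Known limitations

* Only quantitative traits under an additive within-locus coding.
* No covariates, kinship, or population-structure terms.
* Missing genotypes are an error by design, not imputed.
* The compression/smoothing parameters are fixed conventions, not tuned per
  dataset; on real data a cross-validation sweep over the exposed grids
  would be the first thing to add.
* The fSCAD scale is tied to the marker-unit domain and per-region
  standardization described above; comparisons with other implementations
  must account for those conventions.
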