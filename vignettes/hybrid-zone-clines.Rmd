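---
title: "Geographic cline analysis for hybrid zones: models, algorithms, and design choices"
author: "zoneclines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographic cline analysis for hybrid zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoneclines)
```

This vignette is the package's own account of the science it implements:
the models, the estimation machinery, the synthetic data that calibrates
it, and the decisions taken where the methodology was genuinely open.

## The setting

A hybrid zone is a region where two diverged taxa meet and interbreed.
When the zone is maintained by a balance between dispersal and selection
against hybrids (a tension zone), allele frequencies and trait means change
along a transect through the zone as *geographic clines*: sigmoid curves
characterized by a center (the inflection point) and a width (the inverse
of the maximum slope). Characters under different selection regimes can
have displaced centers or different widths, and alleles escaping the
barrier by repeated backcrossing produce shallow exponential
*introgression tails*. The motivating system is a contact zone between two
Joshua tree species with semi-diagnostic nuclear SNPs, a nearly fixed
chloroplast haplotype difference, clinal floral and vegetative traits, and
two host-specific pollinating yucca moths.

## From coordinates to a transect

Sampling is two-dimensional, so the first task is a one-dimensional
transect. The pipeline:

1. projects longitude/latitude to a local planar frame (equirectangular
   about the centroid, $x = R\,\Delta\lambda\cos\bar\phi$,
   $y = R\,\Delta\phi$, $R = 6\,371$ km — sub-meter distortion over the
   few-kilometer extents involved);
2. interpolates the per-tree hybrid index over a regular grid and traces
   the 0.5 iso-contour, taken as the zone center. The interpolator is a
   thin-plate regression spline (`mgcv::gam`, REML smoothing). The
   original workflow used a proprietary GIS kriging tool whose exact
   semantics ("eight sectors") are not reproducible; a thin-plate spline
   is a standard smooth interpolant with one tunable knob, which is all
   iso-contour extraction needs. Marching squares is provided by
   `grDevices::contourLines`, and the longest connected polyline is kept,
   treating the center as a single line;
3. assigns each tree the minimum Euclidean distance to that polyline,
   signed negative on the side of a reference point — conventionally the
   centroid of the western parental pool, so the western taxon sits at
   negative distances. Whether the original distances were signed by
   contour side or by raw easting is not stated in the source workflow;
   the side-of-contour rule is this package's documented choice, and it is
   exact for curved contours;
4. bins trees every 250 m (configurable), collapsing any bin with fewer
   than 3 trees into its neighbor; among the two neighbors the one whose
   center is nearer the zone center absorbs the under-filled bin (ties go
   to the smaller neighbor). Binning is performed once, on the genotyped
   trees, and the same standard bins serve every character, mirroring the
   "standard bins used for all cline analyses" convention. Bin distance is
   the mean distance of member trees.

## Cline curves

The core curve is a logistic sigmoid in signed distance $d$:

$$\Phi(d) = \frac{1}{1 + e^{-4 (d - c)/w}}, \qquad
p(d) = p_{\min} + (p_{\max} - p_{\min})\,\Phi(d).$$

The factor 4 makes $w$ the inverse of the maximum slope of $\Phi$.
Decreasing characters are encoded by $p_{\min} > p_{\max}$ rather than by
reflecting $d$. Model I is this two-parameter curve (plus the two end
values). Models II and III attach exponential tails beyond attachment
points $a_L = c - \delta_L$ and $a_R = c + \delta_R$:

$$\Phi(d \le a_L) = \Phi(a_L)\, e^{\lambda_L (d - a_L)}, \qquad
\lambda_L = \tau_L \frac{\Phi'(a_L)}{\Phi(a_L)},$$

mirrored on the right. $\delta \ge 0$ is the attachment distance in meters
and $\tau \in (0, 1]$ the ratio of the tail's log-slope to the sigmoid's:
$\tau = 1$ joins with a continuous first derivative, small $\tau$ gives a
long shallow tail. Model II shares one $(\delta, \tau)$ pair between the
two sides (symmetric tails); model III frees them (asymmetric). The null
model is the straight line through the two ends of the data span. These
are the functional forms of the Szymura–Barton cline-fitting tradition;
the source analysis names its tail parameters after an existing MCMC
package's internals without printing equations, so exact algebraic
equivalence to that package's parameterization is not claimed — curve
shape, nesting structure, and parameter count are.

Likelihoods: a bin with $n_i$ sampled alleles (2 per genotyped tree, 1 for
the haploid chloroplast) and $k_i$ focal alleles contributes the binomial
term $k_i \ln \hat p_i + (n_i - k_i)\ln(1 - \hat p_i)$, with $\hat p_i$
clamped to $[10^{-6}, 1 - 10^{-6}]$ so fitted frequencies of exactly 0 or
1 (the chloroplast reaches $p_{\max} = 1$) keep the likelihood finite. A
trait bin with mean $m_i$ and variance $v_i$ over $n_i$ trees contributes
$-\tfrac12 \ln(2\pi v_i/n_i) - n_i (m_i - \hat\mu_i)^2 / (2 v_i)$; bins
with $n_i < 2$ borrow the pooled within-bin variance. Traits are first
transformed (log for tree height, square root for trunk height — domain
violations name the offending tree) and min–max standardized to $[0, 1]$
with the inverse map retained.

## Fitting, selection, uncertainty

Sampling is component-wise random-walk Metropolis–Hastings on transformed
scales: identity for $c$, $\log w$, $\log(1 + \delta)$, logit for
$p_{\min}, p_{\max}, \tau$. Priors are uniform on the natural scale within
bounds derived from the data span ($c$ within span ± span, $w \in (1\,
\mathrm{m}, 10\,\mathrm{span}]$, $\delta \in [0, 5\,\mathrm{span}]$), so
the sampled target includes the Jacobian of the transform. Chains start
from a coarse $(c, w)$ grid-search optimum perturbed per chain; proposal
scales adapt toward 44% acceptance during burn-in only, which keeps the
post-burn-in kernel fixed (and the chain valid). Defaults — 3 chains,
$10^5$ scans, $10^4$ burn-in, thinning 10 — are deliberately generous for
19-bin tables; the replicate experiments in the test suite use 2 chains of
8000 scans, which the grid-equivalence check shows is already enough for
these likelihood surfaces. Convergence is monitored by Gelman–Rubin
$\hat R$ (flagging, never silently accepted, at $\hat R \ge 1.1$); a chain
that rejects essentially everything raises an error suggesting a proposal
rescale.

Because the best *visited* state is not necessarily a stationary point,
the maximum-likelihood state is polished with a Nelder–Mead local search
before reporting; the polished point joins the sample set so that every
support interval contains the reported estimate. AIC is $2k - 2\ln
L_{\max}$ with $k$ = 2 (null), 4 (I), 6 (II), 8 (III) — the end values
count as free parameters, since they are estimated per cline. Among
candidates the simplest model within 2 AIC units of the minimum wins.
Trait characters pass first through a frequentist gate: a linear
regression of bin means on distance whose slope must be significant at
$\alpha = 0.05$, otherwise the character is declared cline-free. This
frequency/trait asymmetry (AIC null vs regression null) mirrors the
published procedure deliberately. A Shapiro–Wilk check on the gate
residuals is advisory only — one character (bimodal moth frequency) is
expected to fail any normality transform and is fitted anyway, as a
binomial frequency cline by default.

Uncertainty is the 2-log-likelihood support interval: the min and max of a
parameter over all samples within 2 units of the maximum. The phrase "2
log likelihood (95% credible interval)" in the field's tables is ambiguous
between this superlevel-set reading and a posterior quantile; the
superlevel set is implemented because it is what "2 log likelihood unit"
estimates mean in the cline literature, and for a quadratic likelihood it
reproduces ±2σ (verified against a dense-grid oracle in the tests). Two
clines differ in a parameter when their intervals are disjoint; a shared
endpoint counts as overlap (conservative — fewer significant differences).
Comparing one cline against a category *mean* has no natural interval, so
the reference is the interval of the category's central cline (the member
whose center is the category median), recorded in the output. Null-model
clines are excluded from category means, and no multiple-testing
correction is applied across the pairwise matrix (none was in the source
procedure; users should read the matrix accordingly).

## Hybrid classes

For each individual, over its non-missing loci, the hybrid index is
$\mathrm{HI} = \sum_l g_l / (2 L)$ (proportion of eastern alleles) and the
interclass heterozygosity $H$ the proportion of loci with $g_l = 1$. Every
genotype obeys $H \le 2\min(\mathrm{HI}, 1 - \mathrm{HI})$ — the triangle.
With loci fixed between parents, F1s sit exactly at $(0.5, 1.0)$, F2s at
$(0.5, 0.5)$ in expectation, first backcrosses at $(0.25, 0.5)$ and
$(0.75, 0.5)$; semi-diagnostic loci pull every cloud toward the interior,
which is why classification uses simulation rather than the analytic
corners. Crosses are individual-based: each offspring draws one parent per
pool and one allele per locus per parent (free recombination, $r = 0.5$),
preserving within-pool structure; 500 individuals per cross type is the
default. The published analysis classified individuals by visual overlap
with the simulated clouds; this package replaces that with a formal,
testable surrogate — minimum squared Mahalanobis distance to the cloud,
gated at the $\chi^2_{2}$ 0.99 quantile (configurable), beyond which a
point is "advanced/unassigned". If some of the marker loci are in fact
tightly linked, free-recombination simulations understate the generations
needed to produce a given class — a caveat inherited from the method
itself.

## Pollinator host choice

Host choice is modeled two ways: a Pearson correlation between tree hybrid
index and transect position ($t = r\sqrt{(n-2)/(1-r^2)}$, $df = n - 2$),
and a binomial GLM of per-tree moth counts (eastern-moth successes vs
western-moth failures) on hybrid index and position, fitted by IRLS
(`stats::glm`, convergence tightened to $10^{-12}$). A per-moth Bernoulli
long format gives the identical likelihood and is therefore equally
acceptable input. The two predictors are strongly collinear in a hybrid
zone by construction (r ≈ 0.76 in the motivating study); the fit warns
beyond |r| > 0.95 but proceeds. Complete separation raises an error rather
than returning a silently diverged estimate.

## The synthetic zone

`zoneConfig()`/`generateZone()` produce datasets with known truth: trees
uniform over a rectangle (an optional excluded band mimics unoccupied
ground such as a dry lakebed west of the zone); a straight or sinusoidal
center contour; the true hybrid index a sigmoid in signed distance from
that contour; genotypes $\mathrm{Binomial}(2, p_l(d))$ with per-locus
center/width jitter and an optional fraction of flat (null) loci;
chloroplast haplotypes from their own offset, much steeper cline; traits
Gaussian around clinal means; moth counts Poisson on a flowering subset
with logistic species identity. Defaults are the study-scale conditions: a
2236.39 m wide hybrid-index cline (the motivating zone's genomic width)
crossed by a 12 × 8 km window, 101 semi-diagnostic loci at parental
frequencies 0.1/0.9 (the parental differentials were not published; the
generator exposes them per locus rather than assuming fixation), a
chloroplast cline 276 m wide centered 852 m west of the nuclear center,
and a strong host-genotype effect on moth identity (log-odds coefficient 4
vs $10^{-4}$ per meter). Trap totals average 5 moths per flowering tree —
the published analysis reports only frequencies, so totals are a free
choice. Missingness is uniform per call, default 0. Identical
configurations are bit-identical.

What the generator does *not* emulate: linkage disequilibrium (loci are
drawn independently given distance, matching the free-recombination
assumption of the class simulations), drift or migration dynamics
(no forward simulation), opportunistic/clustered field sampling, spatial
autocorrelation of traits beyond the cline, and genotyping error. Passing
recovery tests therefore demonstrates correctness of the estimators under
the model's own assumptions, not robustness to real-data pathologies.

## Numerical choices and problem sizes

* Frequency clamp $10^{-6}$; covariance ridge $10^{-6}$ before Mahalanobis
  inversion; tau is kept off its open boundary at $10^{-9}$.
* Degenerate inputs: a single-bin table leaves width unidentifiable — the
  support interval then spans essentially the whole bound, which is the
  flag; constant traits standardize to 0.5 with a warning; an all-missing
  individual, an empty parental pool, and a contour that never crosses the
  level are errors that name the offender.
* The replicate experiments in the tests use: 100 seeds × (19 bins × 40
  alleles) for center recovery; 50 seeds for model-family recovery on
  tail-free data; 20 seeds × (41 bins × 100 alleles over ±10 km) for
  tail-model recovery — shallow tails ($\tau = 0.1$) differ from a
  re-tuned plain sigmoid mainly far from the center, so a dense, wide
  transect is where a tailed family earns its extra AIC penalty; 100
  simulations for GLM calibration. These sizes keep the full suite under
  a few minutes while leaving the binomial noise realistic.

## Limitations

Signed perpendicular distance, not arc length along a curved transect;
biallelic/binary characters only; no spatially explicit (unbinned)
likelihood; no reversible-jump model averaging — model choice is the AIC
rule; no likelihood-based multigeneration class inference (a
NewHybrids-style posterior would supersede the Mahalanobis surrogate);
kriging variance maps and geodesic-accurate projections are out of scope.
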