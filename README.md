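# zoneclines

Geographic cline analysis for hybrid zones between two parental taxa, built
for studies like the Joshua tree contact zone where *Yucca brevifolia* and
*Y. jaegeriana* meet: georeferenced trees genotyped at semi-diagnostic SNPs,
scored for a chloroplast haplotype and quantitative traits, and visited by
two species of obligate pollinating yucca moths. The package turns those
per-individual tables into fitted geographic clines, cline comparisons,
hybrid-class assignments, and pollinator host-choice models — with a
synthetic-zone generator providing ground truth for every stage.

## What it computes

**Transect.** Tree coordinates are projected to a local planar frame, the
0.5 hybrid-index iso-contour (the zone center) is extracted from a
thin-plate-spline interpolation by marching squares, each tree gets a
signed perpendicular distance to that contour (western taxon negative), and
trees are grouped into 250 m bins, collapsing bins with fewer than three
trees into their zone-ward neighbor.

**Cline models.** For a character with western value `pmin` and eastern
value `pmax`, the expected value at signed distance `d` is

    p(d) = pmin + (pmax - pmin) * Phi(d)
    Phi(d) = 1 / (1 + exp(-4 (d - c) / w))        (model I)

with center `c` and width `w` (the inverse of the maximum slope). Models II
and III replace `Phi` beyond attachment points `c - deltaL` and
`c + deltaR` with exponential introgression tails

    Phi(d) = Phi(a) * exp(lambda (d - a)),  lambda = tau * Phi'(a) / Phi(a)

(mirrored on the right), where `delta` is the attachment distance in meters
and `tau` in (0, 1] the ratio of tail slope to sigmoid slope at the
attachment; model II shares one (delta, tau) pair between the two sides,
model III estimates them separately. A null model is the straight line
between the two ends of the data span. Binned allele counts enter a
binomial likelihood; binned trait means enter a Gaussian likelihood using
the observed within-bin variances.

**Fitting and selection.** Component-wise Metropolis–Hastings MCMC with
uniform priors inside data-driven bounds, grid-search initialization,
burn-in proposal adaptation, Gelman–Rubin diagnostics, and a final local
polish of the best visited state. Candidate models (null, I, II, III for
frequencies; a linear-regression null gate then I–III for traits) compete
by AIC, keeping the simplest model within 2 AIC units of the best.
Parameter uncertainty is summarized by 2-log-likelihood support intervals
(all posterior samples within 2 units of the maximum); two clines differ in
center (coincidence) or width (concordance) when those intervals are
disjoint.

**Hybrid classes.** Hybrid index HI (proportion of eastern alleles) and
interclass heterozygosity H (proportion of heterozygous loci) place every
individual in the triangle plot; in-silico crosses of the parental pools
(F1, F2, both backcrosses, 500 individuals each, free recombination)
generate reference clouds, and individuals are assigned by Mahalanobis
distance with a chi-squared gate — or labelled advanced/unassigned, as
late-generation hybrids are.

**Pollinators.** Pearson correlation of hybrid index with transect
position, and a binomial GLM of per-tree moth species counts on hybrid
index and position.

## Worked example

```r
library(zoneclines)

cfg  <- zoneConfig(nTrees = 400L, nSnps = 12L, seed = 42L)
zone <- generateZone(cfg)
td   <- treeData(zone)

ctr  <- estimateContour(td$x, td$y, td$qTrue, gridResolution = 250)
ref  <- c(mean(td$x[td$qTrue <= 0.15]), mean(td$y[td$qTrue <= 0.15]))
d    <- signedDistance(td$x, td$y, ctr, ref)
bins <- makeBins(d, ids = td$treeId)

tab  <- binnedFrequencyTable(genotypes(zone)["L001", bins$id], bins)
fit  <- selectClineModel(tab, fitConfig(nChains = 2L, nSteps = 20000L,
                                        burnIn = 5000L, seed = 1L))
fit
```

```
ClineFit (frequency data): best model I
  lnL_max -315.663, k = 4
  AIC: null 745.91, I 639.33, II 642.39, III 646.35
  2-lnL support intervals:
    center  [-231, 192]
    width   [921.9, 2151]
    pmin    [0.07114, 0.1352]
    pmax    [0.8423, 0.9126]
  max R-hat 1.000 (converged)
```

The simple sigmoid (model I) wins by AIC. The locus was simulated with
parental frequencies 0.1 and 0.9 around the zone center: the fitted `pmin`
and `pmax` intervals bracket those values, the center interval brackets 0,
and `deltaP(fit)` reports 0.778 — the total allele-frequency change across
the zone. `runPipeline()` chains all stages (contour, distances, bins, per
character fits, comparisons, hybrid classes, pollinator models) from
tabular inputs and writes a publication-style cline table plus a manifest
of checksummed outputs.

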