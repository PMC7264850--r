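#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Configure a synthetic hybrid zone
#'
#' Builds a [ZoneConfig-class] describing a two-taxon hybrid zone: trees
#' scattered over a planar rectangle, a (possibly curved) zone-center
#' contour, a sigmoid hybrid-index cline in signed distance from that
#' contour, semi-diagnostic nuclear SNPs whose per-locus clines jitter
#' around the zone cline, an offset steep chloroplast cline, clinal trait
#' means with Gaussian noise, and yucca-moth trap counts whose species
#' identity follows a logistic model in host genotype and location.
#'
#' Defaults describe a zone of the size and differentiation this kind of
#' contact zone shows: a ~2.2 km wide hybrid-index cline crossed by a 12 x
#' 8 km sampling window, 101 semi-diagnostic loci with parental frequencies
#' 0.1/0.9, a chloroplast cline offset ~850 m west of the nuclear center
#' and only ~280 m wide, and a strong host-genotype effect on moth
#' identity.
#'
#' @param nTrees trees to place (default 600).
#' @param extent \code{c(xmin, xmax, ymin, ymax)} in m.
#' @param contourShape \code{"straight"} or \code{"sinusoid"}.
#' @param contourAmplitude,contourPeriod sinusoid parameters (m).
#' @param trueCenter x-position of the center contour (m).
#' @param trueWidth hybrid-index cline width (m).
#' @param nSnps nuclear loci (default 101).
#' @param snpPmin,snpPmax western/eastern parental focal-allele
#'   frequencies of non-null loci.
#' @param snpCenterSd per-locus center jitter (m).
#' @param snpWidthLogSd sd of the per-locus log width multiplier.
#' @param fractionNull fraction of loci with flat frequency.
#' @param cpCenterOffset,cpWidth chloroplast cline center (m) and width (m).
#' @param traits data.frame (\code{name}, \code{meanWest}, \code{meanEast},
#'   \code{noiseSd}, \code{transform}).
#' @param mothIntercept,mothCoefQ,mothCoefDist log-odds model of a trapped
#'   moth being \emph{T. antithetica}.
#' @param trapRate mean moths per flowering tree.
#' @param floweringFraction fraction of trees flowering.
#' @param missingRate per-call genotype missingness.
#' @param gapBand optional excluded x-interval \code{c(lo, hi)} (m).
#' @param seed RNG seed.
#' @return a validated [ZoneConfig-class].
#' @export
zoneConfig <- function(nTrees = 600L,
                       extent = c(-6000, 6000, 0, 8000),
                       contourShape = c("straight", "sinusoid"),
                       contourAmplitude = 1000, contourPeriod = 4000,
                       trueCenter = 0, trueWidth = 2236.39,
                       nSnps = 101L, snpPmin = 0.1, snpPmax = 0.9,
                       snpCenterSd = 250, snpWidthLogSd = 0.2,
                       fractionNull = 0,
                       cpCenterOffset = -852, cpWidth = 276.4,
                       traits = data.frame(
                         name = c("tree_height", "trunk_height", "style_length"),
                         meanWest = c(4.0, 0.6, 2.0),
                         meanEast = c(2.2, 1.6, 4.0),
                         noiseSd = c(0.6, 0.12, 0.5),
                         transform = c("log", "sqrt", "none"),
                         stringsAsFactors = FALSE),
                       mothIntercept = -2, mothCoefQ = 4,
                       mothCoefDist = 1e-4,
                       trapRate = 5, floweringFraction = 0.5,
                       missingRate = 0, gapBand = NULL, seed = 1L) {
  contourShape <- match.arg(contourShape)
  new("ZoneConfig", nTrees = as.integer(nTrees), extent = as.numeric(extent),
      contourShape = contourShape,
      contourAmplitude = contourAmplitude, contourPeriod = contourPeriod,
      trueCenter = trueCenter, trueWidth = trueWidth,
      nSnps = as.integer(nSnps), snpPmin = snpPmin, snpPmax = snpPmax,
      snpCenterSd = snpCenterSd, snpWidthLogSd = snpWidthLogSd,
      fractionNull = fractionNull,
      cpCenterOffset = cpCenterOffset, cpWidth = cpWidth, traits = traits,
      mothIntercept = mothIntercept, mothCoefQ = mothCoefQ,
      mothCoefDist = mothCoefDist, trapRate = trapRate,
      floweringFraction = floweringFraction, missingRate = missingRate,
      gapBand = gapBand, seed = as.integer(seed))
}

setMethod("show", "ZoneConfig", function(object) {
  cat(sprintf("ZoneConfig: %d trees over [%g, %g] x [%g, %g] m\n",
              object@nTrees, object@extent[1], object@extent[2],
              object@extent[3], object@extent[4]))
  cat(sprintf("  %s center at x = %g m, cline width %g m\n",
              object@contourShape, object@trueCenter, object@trueWidth))
  cat(sprintf("  %d SNPs (p %g -> %g, %.0f%% null), cp cline %g m wide at %g m\n",
              object@nSnps, object@snpPmin, object@snpPmax,
              100 * object@fractionNull, object@cpWidth,
              object@cpCenterOffset))
  cat(sprintf("  %d traits; seed %d\n", nrow(object@traits), object@seed))
  invisible(object)
})

# x-position of the center contour at height y
.contourX <- function(config, y) {
  config@trueCenter + switch(config@contourShape,
    straight = 0,
    sinusoid = config@contourAmplitude *
      sin(2 * pi * y / config@contourPeriod))
}

#' Dense polyline of a configured zone-center contour
#'
#' @param config a [ZoneConfig-class].
#' @param nVertices polyline resolution (default 400).
#' @return a [ContourLine-class] tracing the configured center.
#' @export
trueContour <- function(config, nVertices = 400L) {
  ys <- seq(config@extent[3], config@extent[4], length.out = nVertices)
  new("ContourLine", vertices = cbind(x = .contourX(config, ys), y = ys),
      gridResolution = diff(config@extent[3:4]) / (nVertices - 1),
      interpolation = "generating curve", level = 0.5)
}

#' Generate a synthetic hybrid zone
#'
#' Places trees uniformly over the configured extent (skipping the optional
#' gap band), computes each tree's signed distance to the configured center
#' contour, and draws every character from its configured model: the true
#' hybrid index from the zone sigmoid, genotypes as Binomial(2, p_locus(d))
#' with per-locus cline jitter (null loci flat), the chloroplast haplotype
#' from its own offset cline, traits from clinal Gaussian means, and moth
#' trap counts on a flowering subset with logistic species identity.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config a [ZoneConfig-class].
#' @return a [HybridZoneExperiment-class].
#' @examples
#' zone <- generateZone(zoneConfig(nTrees = 50L, nSnps = 20L, seed = 3L))
#' zone
#' @export
generateZone <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTrees
  ext <- config@extent

  xy <- matrix(numeric(0), 0, 2)
  need <- n
  while (need > 0L) {
    cand <- cbind(runif(need, ext[1], ext[2]), runif(need, ext[3], ext[4]))
    if (!is.null(config@gapBand)) {
      keep <- cand[, 1] < config@gapBand[1] | cand[, 1] > config@gapBand[2]
      cand <- cand[keep, , drop = FALSE]
    }
    xy <- rbind(xy, cand)
    need <- n - nrow(xy)
  }
  x <- xy[, 1]
  y <- xy[, 2]

  d <- if (n > 0) {
    contour <- trueContour(config)
    ref <- c(ext[1] - diff(ext[1:2]), mean(ext[3:4]))  # far west
    signedDistance(x, y, contour, ref)
  } else numeric(0)
  q <- plogis(4 * d / config@trueWidth)

  L <- config@nSnps
  isNull <- runif(L) < config@fractionNull
  locCenter <- rnorm(L, 0, config@snpCenterSd)
  locWidth <- config@trueWidth * exp(rnorm(L, 0, config@snpWidthLogSd))
  pFlat <- (config@snpPmin + config@snpPmax) / 2
  geno <- matrix(NA_integer_, L, n)
  for (l in seq_len(L)) {
    p <- if (isNull[l]) rep(pFlat, n)
         else config@snpPmin + (config@snpPmax - config@snpPmin) *
           plogis(4 * (d - locCenter[l]) / locWidth[l])
    geno[l, ] <- rbinom(n, 2L, p)
  }
  if (config@missingRate > 0 && length(geno))
    geno[runif(length(geno)) < config@missingRate] <- NA_integer_

  pEast <- plogis(4 * (d - config@cpCenterOffset) / config@cpWidth)
  cp <- ifelse(rbinom(n, 1L, pEast) == 1L, "east", "west")

  cd <- DataFrame(
    treeId = sprintf("T%04d", seq_len(n)),
    x = x, y = y, distanceTrue = d, qTrue = q, cpHaplotype = cp
  )
  for (i in seq_len(nrow(config@traits))) {
    tr <- config@traits[i, ]
    mu <- tr$meanWest + (tr$meanEast - tr$meanWest) * plogis(4 * d / config@trueWidth)
    cd[[tr$name]] <- rnorm(n, mu, tr$noiseSd)
  }
  flowering <- runif(n) < config@floweringFraction
  total <- ifelse(flowering, rpois(n, config@trapRate), NA_integer_)
  pAnt <- plogis(config@mothIntercept + config@mothCoefQ * q +
                   config@mothCoefDist * d)
  nAnt <- rep(NA_integer_, n)
  nAnt[flowering] <- rbinom(sum(flowering), total[flowering], pAnt[flowering])
  cd$flowering <- flowering
  cd$mothAntithetica <- nAnt
  cd$mothSynthetica <- total - nAnt

  rd <- DataFrame(
    locus = sprintf("L%03d", seq_len(L)),
    pmin = ifelse(isNull, pFlat, config@snpPmin),
    pmax = ifelse(isNull, pFlat, config@snpPmax),
    center = ifelse(isNull, NA_real_, locCenter),
    width = ifelse(isNull, NA_real_, locWidth),
    isNull = isNull
  )
  dimnames(geno) <- list(rd$locus, cd$treeId)
  se <- SummarizedExperiment(assays = list(genotype = geno),
                             rowData = rd, colData = cd)
  S4Vectors::metadata(se)$config <- config
  new("HybridZoneExperiment", se)
}

setMethod("genotypes", "HybridZoneExperiment", function(x) assay(x, "genotype"))

setMethod("treeData", "HybridZoneExperiment", function(x) {
  as.data.frame(colData(x))
})

setMethod("show", "HybridZoneExperiment", function(object) {
  cat(sprintf("HybridZoneExperiment: %d loci x %d trees\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

#' Split a zone into pure parental pools by true hybrid index
#'
#' Trees with \code{qTrue <= qLow} form the western pool and those with
#' \code{qTrue >= qHigh} the eastern pool; intermediates (hybrids) are
#' excluded.
#'
#' @param zone a [HybridZoneExperiment-class] with a \code{qTrue} column.
#' @param qLow,qHigh pool thresholds, \code{0 <= qLow < qHigh <= 1}
#'   (defaults 0.15 / 0.85, the conventional parental cutoffs).
#' @return list with elements \code{west} and \code{east}, both
#'   \code{HybridZoneExperiment}s.
#' @export
generatePurePools <- function(zone, qLow = 0.15, qHigh = 0.85) {
  if (!(qLow >= 0 && qLow < qHigh && qHigh <= 1))
    stop("need 0 <= qLow < qHigh <= 1")
  q <- colData(zone)$qTrue
  west <- which(q <= qLow)
  east <- which(q >= qHigh)
  if (!length(west))
    stop(sprintf("no trees with qTrue <= %g: western pool is empty", qLow))
  if (!length(east))
    stop(sprintf("no trees with qTrue >= %g: eastern pool is empty", qHigh))
  list(west = zone[, west], east = zone[, east])
}

#' Simulate a binned allele-count table directly from a cline curve
#'
#' A direct fixture generator for cline-fitting experiments: per bin the
#' focal-allele count is Binomial(n_i, p(d_i)) under the given cline.
#'
#' @param model a frequency [ClineModel-class].
#' @param binDistances bin positions (m).
#' @param nPerBin alleles sampled per bin (recycled).
#' @param seed RNG seed.
#' @return a [frequencyBinTable()].
#' @export
generateBinTable <- function(model, binDistances, nPerBin, seed = 1L) {
  nPerBin <- rep_len(nPerBin, length(binDistances))
  if (any(nPerBin <= 0)) stop("all bin sizes must be positive")
  p <- clineValue(model, binDistances)
  if (any(p < 0 | p > 1))
    stop("cline predicts frequencies outside [0, 1]")
  set.seed(seed)
  frequencyBinTable(distance = binDistances, n = nPerBin,
                    count = rbinom(length(binDistances), nPerBin, p))
}
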