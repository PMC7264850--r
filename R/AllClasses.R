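#' @import methods
#' @importFrom stats plogis qlogis rbinom rnorm rpois runif setNames
#'   complete.cases
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

CLINE_MODEL_TYPES <- c("null", "I", "II", "III")

#' Container for a sampled (or simulated) hybrid zone
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"genotype"} assay
#' holds per-locus focal-allele counts (0/1/2, \code{NA} for missing) with
#' loci as rows and trees as columns; \code{rowData} carries per-locus cline
#' parameters when the object was simulated; \code{colData} carries tree
#' coordinates, chloroplast haplotype, trait measurements and moth trap
#' counts.
#'
#' @seealso [generateZone()], [genotypes()], [treeData()]
#' @export
setClass("HybridZoneExperiment", contains = "SummarizedExperiment")

#' Configuration of a synthetic hybrid zone
#'
#' Holds every parameter of the synthetic-zone generator: the sampling
#' extent, the shape of the zone center (a straight or sinusoidal contour),
#' the sigmoid cline that maps signed distance from that center to the
#' expected hybrid index, the per-locus allele-frequency model for nuclear
#' SNPs, an offset cline for the chloroplast haplotype, clinal trait means,
#' and a logistic model of pollinator species identity. Construct with
#' [zoneConfig()].
#'
#' @slot nTrees number of trees to place.
#' @slot extent planar sampling rectangle, \code{c(xmin, xmax, ymin, ymax)}
#'   in meters.
#' @slot contourShape \code{"straight"} or \code{"sinusoid"}.
#' @slot contourAmplitude,contourPeriod sinusoid amplitude and period (m).
#' @slot trueCenter x-position of the zone center contour (m).
#' @slot trueWidth width of the hybrid-index cline (m).
#' @slot nSnps number of nuclear loci.
#' @slot snpPmin,snpPmax parental (west/east) focal-allele frequencies for
#'   non-null loci.
#' @slot snpCenterSd per-locus cline-center jitter (m, Gaussian sd).
#' @slot snpWidthLogSd per-locus log-width jitter (Gaussian sd of the log
#'   width multiplier).
#' @slot fractionNull proportion of loci with no cline (flat frequency).
#' @slot cpCenterOffset,cpWidth center (m, relative to the nuclear center)
#'   and width of the chloroplast haplotype cline.
#' @slot traits data.frame with columns \code{name}, \code{meanWest},
#'   \code{meanEast}, \code{noiseSd}, \code{transform}.
#' @slot mothIntercept,mothCoefQ,mothCoefDist log-odds model of
#'   \emph{T. antithetica} (vs \emph{T. synthetica}) identity per moth.
#' @slot trapRate mean moths trapped per flowering tree (Poisson).
#' @slot floweringFraction proportion of trees that flower (and get traps).
#' @slot missingRate per-call genotype missingness.
#' @slot gapBand optional x-interval (m) excluded from sampling, mimicking
#'   unoccupied ground such as a dry lakebed; \code{NULL} for none.
#' @slot seed integer RNG seed.
#' @export
setClass("ZoneConfig",
  slots = c(
    nTrees = "integer", extent = "numeric",
    contourShape = "character", contourAmplitude = "numeric",
    contourPeriod = "numeric",
    trueCenter = "numeric", trueWidth = "numeric",
    nSnps = "integer", snpPmin = "numeric", snpPmax = "numeric",
    snpCenterSd = "numeric", snpWidthLogSd = "numeric",
    fractionNull = "numeric",
    cpCenterOffset = "numeric", cpWidth = "numeric",
    traits = "data.frame",
    mothIntercept = "numeric", mothCoefQ = "numeric",
    mothCoefDist = "numeric",
    trapRate = "numeric", floweringFraction = "numeric",
    missingRate = "numeric",
    gapBand = "ANY",
    seed = "integer"
  )
)

setValidity("ZoneConfig", function(object) {
  msg <- character()
  num_slots <- c(
    "extent", "contourAmplitude", "contourPeriod", "trueCenter",
    "trueWidth", "snpPmin", "snpPmax", "snpCenterSd", "snpWidthLogSd",
    "fractionNull", "cpCenterOffset", "cpWidth", "mothIntercept",
    "mothCoefQ", "mothCoefDist", "trapRate", "floweringFraction",
    "missingRate"
  )
  for (s in num_slots) {
    if (!all(is.finite(slot(object, s))))
      msg <- c(msg, sprintf("slot '%s' must be finite", s))
  }
  if (object@nTrees < 0L) msg <- c(msg, "nTrees must be >= 0")
  if (length(object@extent) != 4L ||
      object@extent[2] <= object@extent[1] ||
      object@extent[4] <= object@extent[3])
    msg <- c(msg, "extent must be c(xmin, xmax, ymin, ymax) with xmax > xmin, ymax > ymin")
  if (!object@contourShape %in% c("straight", "sinusoid"))
    msg <- c(msg, "contourShape must be 'straight' or 'sinusoid'")
  if (object@trueWidth <= 0) msg <- c(msg, "trueWidth must be > 0")
  if (object@cpWidth <= 0) msg <- c(msg, "cpWidth must be > 0")
  for (s in c("snpPmin", "snpPmax", "fractionNull", "floweringFraction",
              "missingRate")) {
    v <- slot(object, s)
    if (any(v < 0 | v > 1)) msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (nrow(object@traits) &&
      !all(c("name", "meanWest", "meanEast", "noiseSd", "transform") %in%
           names(object@traits)))
    msg <- c(msg, "traits needs columns name, meanWest, meanEast, noiseSd, transform")
  if (!is.null(object@gapBand) &&
      (length(object@gapBand) != 2L || !all(is.finite(object@gapBand))))
    msg <- c(msg, "gapBand must be NULL or a finite length-2 interval")
  if (length(msg)) msg else TRUE
})

#' Zone-center contour polyline
#'
#' An ordered planar polyline (meters) marking the estimated center of the
#' hybrid zone, usually the 0.5 iso-contour of an interpolated hybrid-index
#' surface. Produced by [estimateContour()].
#'
#' @slot vertices two-column matrix of planar vertices (m).
#' @slot gridResolution spacing of the interpolation grid (m).
#' @slot interpolation tag describing the interpolator used.
#' @slot level the iso-level the contour traces.
#' @export
setClass("ContourLine",
  slots = c(vertices = "matrix", gridResolution = "numeric",
            interpolation = "character", level = "numeric")
)

setValidity("ContourLine", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 2L) return("a contour needs at least 2 vertices")
  if (!all(is.finite(v))) return("contour vertices must be finite")
  TRUE
})

#' Parametric geographic cline curve
#'
#' A sigmoid cline with optional exponential introgression tails, mapping
#' signed transect distance (m) to an expected allele frequency or
#' standardized trait value. Four families are supported: \code{"null"}
#' (a straight line between the two ends of the data span), \code{"I"}
#' (plain sigmoid: center and width), \code{"II"} (symmetric exponential
#' tails shared between the two sides) and \code{"III"} (independent left
#' and right tails). Tails are parameterized by an attachment distance
#' \code{delta} (m from the center) and a slope ratio \code{tau} in (0, 1];
#' \code{tau = 1} joins the tail with a continuous first derivative.
#' Construct with [clineModel()]; evaluate with [clineValue()].
#'
#' @slot modelType one of \code{"null"}, \code{"I"}, \code{"II"}, \code{"III"}.
#' @slot center,width sigmoid center and width (m); \code{NA} for null.
#' @slot pmin,pmax values at the western and eastern ends; a decreasing
#'   cline is encoded by \code{pmin > pmax}.
#' @slot deltaL,tauL,deltaR,tauR tail parameters (present per model type;
#'   model II stores its shared tail in the left slots).
#' @slot span data span \code{c(dmin, dmax)} (m); used by the null model's
#'   straight line.
#' @export
setClass("ClineModel",
  slots = c(modelType = "character", center = "numeric", width = "numeric",
            pmin = "numeric", pmax = "numeric",
            deltaL = "numeric", tauL = "numeric",
            deltaR = "numeric", tauR = "numeric",
            span = "numeric")
)

setValidity("ClineModel", function(object) {
  msg <- character()
  ty <- object@modelType
  if (length(ty) != 1L || !ty %in% CLINE_MODEL_TYPES)
    return("modelType must be one of 'null', 'I', 'II', 'III'")
  if (any(!is.finite(c(object@pmin, object@pmax))) ||
      any(c(object@pmin, object@pmax) < 0 | c(object@pmin, object@pmax) > 1))
    msg <- c(msg, "pmin and pmax must lie in [0, 1]")
  if (ty != "null") {
    if (!is.finite(object@center)) msg <- c(msg, "center must be finite")
    if (!is.finite(object@width) || object@width <= 0)
      msg <- c(msg, "width must be > 0")
  }
  chk_tail <- function(delta, tau, side) {
    m <- character()
    if (!is.finite(delta) || delta < 0)
      m <- c(m, sprintf("delta%s must be >= 0", side))
    if (!is.finite(tau) || tau <= 0 || tau > 1)
      m <- c(m, sprintf("tau%s must lie in (0, 1]", side))
    m
  }
  if (ty %in% c("II", "III"))
    msg <- c(msg, chk_tail(object@deltaL, object@tauL, "L"))
  if (ty == "III")
    msg <- c(msg, chk_tail(object@deltaR, object@tauR, "R"))
  if (ty %in% c("null", "I") &&
      !all(is.na(c(object@deltaL, object@tauL, object@deltaR, object@tauR))))
    msg <- c(msg, sprintf("model %s carries no tail parameters", ty))
  if (ty == "II" && !all(is.na(c(object@deltaR, object@tauR))))
    msg <- c(msg, "model II stores its shared tail in deltaL/tauL only")
  if (ty == "null" && (length(object@span) != 2L || any(!is.finite(object@span))))
    msg <- c(msg, "null model needs a finite span c(dmin, dmax)")
  if (length(msg)) msg else TRUE
})

#' MCMC and model-selection settings for cline fitting
#'
#' Construct with [fitConfig()]. Proposal scales are on the transformed
#' sampling scale (identity for center, log for width, log(1+x) for tail
#' attachment distances, logit for frequencies and slope ratios) and are
#' adapted during burn-in toward an acceptance rate of 0.44.
#'
#' @slot nChains,nSteps,burnIn,thin chain count, scans per chain, burn-in
#'   scans and thinning interval.
#' @slot proposalScales named numeric of initial proposal scales for
#'   \code{center, width, pmin, pmax, deltaL, tauL, deltaR, tauR}.
#' @slot bounds optional 8 x 2 matrix of natural-scale parameter bounds
#'   overriding the data-driven defaults; \code{NULL} to derive from the
#'   data span.
#' @slot rhatThreshold Gelman-Rubin threshold above which a fit is flagged
#'   unconverged.
#' @slot alpha two-sided significance level of the linear-regression gate
#'   applied to trait data before any cline is fitted.
#' @slot daicThreshold AIC margin within which the simpler model is kept.
#' @slot epsilon frequency clamp keeping the binomial log-likelihood finite.
#' @slot seed integer seed.
#' @export
setClass("FitConfig",
  slots = c(nChains = "integer", nSteps = "integer", burnIn = "integer",
            thin = "integer", proposalScales = "numeric", bounds = "ANY",
            rhatThreshold = "numeric", alpha = "numeric",
            daicThreshold = "numeric", epsilon = "numeric", seed = "integer")
)

setValidity("FitConfig", function(object) {
  msg <- character()
  if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
  if (object@nSteps <= object@burnIn)
    msg <- c(msg, "nSteps must exceed burnIn")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (length(object@proposalScales) != 8L ||
      any(object@proposalScales <= 0))
    msg <- c(msg, "proposalScales must be 8 positive values")
  if (!is.null(object@bounds) &&
      (!is.matrix(object@bounds) || !identical(dim(object@bounds), c(8L, 2L)) ||
       any(object@bounds[, 2] < object@bounds[, 1])))
    msg <- c(msg, "bounds must be NULL or a well-ordered 8 x 2 matrix")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@epsilon <= 0 || object@epsilon >= 0.5)
    msg <- c(msg, "epsilon must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' A fitted geographic cline
#'
#' The result of [fitCline()] or [selectClineModel()]: the best
#' (maximum-likelihood) cline curve, the AIC of every candidate model type
#' that was fitted, thinned posterior samples with their log-likelihoods,
#' per-parameter 2-log-likelihood support intervals, and convergence
#' diagnostics. Access with [bestModel()], [aicTable()],
#' [supportIntervals()], [isNullCline()].
#'
#' @slot model the best-fitting [ClineModel-class].
#' @slot modelType its type.
#' @slot logLik maximum log-likelihood found.
#' @slot k number of free parameters of the chosen model.
#' @slot aic named numeric, AIC per candidate model type.
#' @slot intervals matrix (free parameters x \code{low, high}) of
#'   2-log-likelihood support intervals.
#' @slot samples data.frame of thinned post-burn-in samples (natural scale)
#'   with columns for each free parameter, \code{lnL} and \code{chain}.
#' @slot rhat named Gelman-Rubin statistics per free parameter.
#' @slot converged all rhat below the configured threshold.
#' @slot isNull TRUE when the character is best described by no cline.
#' @slot dataKind \code{"frequency"} or \code{"trait"}.
#' @slot details list of auxiliary results (e.g. the trait-gate regression
#'   p-value, normality advisories).
#' @export
setClass("ClineFit",
  slots = c(model = "ClineModel", modelType = "character",
            logLik = "numeric", k = "integer", aic = "numeric",
            intervals = "matrix", samples = "data.frame", rhat = "numeric",
            converged = "logical", isNull = "logical", dataKind = "character",
            details = "list")
)

setValidity("ClineFit", function(object) {
  msg <- character()
  if (!object@dataKind %in% c("frequency", "trait"))
    msg <- c(msg, "dataKind must be 'frequency' or 'trait'")
  if (nrow(object@intervals) &&
      !identical(colnames(object@intervals), c("low", "high")))
    msg <- c(msg, "intervals needs columns low, high")
  if (length(msg)) msg else TRUE
})

#' Simulated hybrid-class cloud in (hybrid index, heterozygosity) space
#'
#' The joint distribution of hybrid index and interclass heterozygosity for
#' one simulated cross type (F1, F2, backcross, or a pure parental pool),
#' summarized by its point cloud, mean vector and 2 x 2 covariance.
#' Produced by [buildClassClouds()].
#'
#' @slot className one of \code{"pure_west"}, \code{"pure_east"},
#'   \code{"F1"}, \code{"F2"}, \code{"BC_west"}, \code{"BC_east"}.
#' @slot points n x 2 matrix, columns \code{hybridIndex}, \code{heterozygosity}.
#' @slot center mean vector.
#' @slot covariance 2 x 2 covariance matrix.
#' @export
setClass("HybridClassCloud",
  slots = c(className = "character", points = "matrix",
            center = "numeric", covariance = "matrix")
)

setValidity("HybridClassCloud", function(object) {
  msg <- character()
  if (ncol(object@points) != 2L)
    msg <- c(msg, "points must have 2 columns")
  if (nrow(object@points) < 2L)
    msg <- c(msg, "a cloud needs at least 2 points")
  ev <- eigen(object@covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    msg <- c(msg, "covariance must be positive semidefinite")
  if (length(msg)) msg else TRUE
})
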