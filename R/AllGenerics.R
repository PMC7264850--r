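#' Extract the genotype matrix
#'
#' Returns the per-locus focal-allele count matrix (loci x trees, values
#' 0/1/2 or \code{NA}) of a [HybridZoneExperiment-class].
#'
#' @param x a \code{HybridZoneExperiment}.
#' @return integer matrix, loci as rows, trees as columns.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Per-tree metadata as a data.frame
#'
#' Coordinates, true hybrid index (for simulated zones), chloroplast
#' haplotype, traits and moth counts of every tree.
#'
#' @param x a \code{HybridZoneExperiment}.
#' @return a \code{data.frame} with one row per tree.
#' @export
setGeneric("treeData", function(x) standardGeneric("treeData"))

#' Evaluate a cline curve
#'
#' Expected allele frequency or standardized trait value at signed transect
#' distance \code{d} (m).
#'
#' @param model a [ClineModel-class].
#' @param d numeric vector of finite distances (m).
#' @return numeric vector of expected values.
#' @export
setGeneric("clineValue", function(model, d) standardGeneric("clineValue"))

#' Total frequency change across a cline
#'
#' The difference between the two asymptotic ends of the cline,
#' \eqn{|pmax - pmin|} -- a measure of how differentiated the character is
#' across the zone.
#'
#' @param object a [ClineModel-class] or [ClineFit-class].
#' @return nonnegative numeric scalar.
#' @export
setGeneric("deltaP", function(object) standardGeneric("deltaP"))

#' @describeIn ClineFit-class the best-fitting [ClineModel-class].
#' @param object a \code{ClineFit}.
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))

#' @describeIn ClineFit-class named AIC per candidate model type.
#' @export
setGeneric("aicTable", function(object) standardGeneric("aicTable"))

#' @describeIn ClineFit-class matrix of per-parameter 2-log-likelihood
#'   support intervals.
#' @export
setGeneric("supportIntervals", function(object) standardGeneric("supportIntervals"))

#' @describeIn ClineFit-class whether the character was judged to have no
#'   cline.
#' @export
setGeneric("isNullCline", function(object) standardGeneric("isNullCline"))

#' Contour vertices
#'
#' @param x a [ContourLine-class].
#' @return two-column numeric matrix of planar vertices (m).
#' @export
setGeneric("contourVertices", function(x) standardGeneric("contourVertices"))
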