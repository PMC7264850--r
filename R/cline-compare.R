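#' Do two clines differ in a parameter?
#'
#' Two fitted clines are declared different in their center (coincidence)
#' or width (concordance) when their 2-log-likelihood support intervals are
#' disjoint; intervals touching at a single point count as overlapping
#' (the conservative reading).
#'
#' @param fitA,fitB non-null [ClineFit-class] objects.
#' @param parameter \code{"center"} or \code{"width"}.
#' @return logical flag; the two intervals in attribute
#'   \code{"intervals"}.
#' @export
compareClinePair <- function(fitA, fitB, parameter = c("center", "width")) {
  parameter <- match.arg(parameter)
  for (f in list(fitA, fitB)) {
    if (isNullCline(f))
      stop("cline best fit the null model; exclude it before comparing")
    if (!parameter %in% rownames(supportIntervals(f)))
      stop(sprintf("fit has no '%s' interval", parameter))
  }
  ia <- supportIntervals(fitA)[parameter, ]
  ib <- supportIntervals(fitB)[parameter, ]
  differ <- ia["high"] < ib["low"] || ib["high"] < ia["low"]
  structure(unname(differ), intervals = rbind(a = ia, b = ib))
}

# interval disjointness on raw (low, high) pairs
.disjoint <- function(a, b) a[2] < b[1] || b[2] < a[1]

#' Pairwise coincidence/concordance matrix
#'
#' Applies [compareClinePair()] to every pair of non-null fits, for centers
#' and for widths, mirroring the pairwise yes/no comparison tables of
#' hybrid-zone studies. Overlap is not transitive, so the matrix is
#' reported pairwise and no transitivity is implied.
#'
#' @param fits named list of [ClineFit-class]s (null fits rejected).
#' @return list of two logical matrices, \code{centers} and \code{widths}
#'   (TRUE = intervals disjoint = clines differ).
#' @export
comparisonMatrix <- function(fits) {
  if (any(vapply(fits, isNullCline, TRUE)))
    stop("exclude null-model fits before building the comparison matrix")
  nm <- names(fits)
  if (is.null(nm)) nm <- sprintf("cline%d", seq_along(fits))
  out <- lapply(c(center = "center", width = "width"), function(p) {
    m <- matrix(NA, length(fits), length(fits), dimnames = list(nm, nm))
    for (i in seq_along(fits)) for (j in seq_along(fits)) {
      if (i == j) next
      m[i, j] <- compareClinePair(fits[[i]], fits[[j]], p)
    }
    m
  })
  names(out) <- c("centers", "widths")
  out
}

#' Summarize a category of fitted clines
#'
#' Means of center, width and delta-P over the non-null fits of a category
#' (e.g. high-FST SNPs, random SNPs, trait-associated SNPs), the count of
#' null fits excluded, the per-cline value lists for distribution plots,
#' and the fraction of fits choosing each model type.
#'
#' @param fits list of [ClineFit-class]s.
#' @param name category label.
#' @return list with \code{name}, \code{n}, \code{nNull},
#'   \code{meanCenter}, \code{meanWidth}, \code{meanDeltaP},
#'   \code{modelFractions}, and per-cline vectors \code{centers},
#'   \code{widths}, \code{deltaPs}.
#' @export
summarizeCategory <- function(fits, name = "category") {
  isn <- vapply(fits, isNullCline, TRUE)
  if (all(isn))
    stop(sprintf("all %d clines in '%s' are null; nothing to summarize",
                 length(fits), name))
  types <- vapply(fits, function(f) f@modelType, "")
  keep <- fits[!isn]
  centers <- vapply(keep, function(f) bestModel(f)@center, 0)
  widths <- vapply(keep, function(f) bestModel(f)@width, 0)
  dps <- vapply(keep, deltaP, 0)
  list(name = name, n = length(fits), nNull = sum(isn),
       meanCenter = mean(centers), meanWidth = mean(widths),
       meanDeltaP = mean(dps),
       modelFractions = table(factor(types, CLINE_MODEL_TYPES)) / length(fits),
       centers = centers, widths = widths, deltaPs = dps)
}

#' Classify clines as offset from a reference category
#'
#' Each cline is compared against the 2-log-likelihood center interval of
#' the category's central cline (the member fit whose center is the
#' category median): disjoint intervals with a lower center give
#' \code{"west-offset"}, disjoint with a higher center \code{"east-offset"}
#' (west is the negative-distance side), and overlapping intervals
#' \code{"not-offset"}.
#'
#' @param fits named list of non-null [ClineFit-class]s to classify.
#' @param referenceFits list of non-null fits defining the reference
#'   category.
#' @return data.frame: \code{cline}, \code{offset}, \code{center};
#'   the reference interval in attribute \code{"reference"}.
#' @export
offsetReport <- function(fits, referenceFits) {
  if (any(vapply(referenceFits, isNullCline, TRUE)))
    stop("reference category must contain non-null fits only")
  refCenters <- vapply(referenceFits, function(f) bestModel(f)@center, 0)
  medIdx <- which.min(abs(refCenters - median(refCenters)))
  refIv <- supportIntervals(referenceFits[[medIdx]])["center", ]
  nm <- names(fits)
  if (is.null(nm)) nm <- sprintf("cline%d", seq_along(fits))
  offs <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (isNullCline(f))
      stop("cline best fit the null model; exclude it before comparing")
    iv <- supportIntervals(f)["center", ]
    if (!.disjoint(iv, refIv)) "not-offset"
    else if (iv["high"] < refIv["low"]) "west-offset"
    else "east-offset"
  }, "")
  structure(
    data.frame(cline = nm, offset = offs,
               center = vapply(fits, function(f) bestModel(f)@center, 0),
               stringsAsFactors = FALSE),
    reference = refIv)
}
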