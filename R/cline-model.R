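#' @useDynLib zoneclines, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PARAM_NAMES <- c("center", "width", "pmin", "pmax",
                 "deltaL", "tauL", "deltaR", "tauR")

.modelTypeInt <- function(type) {
  match(type, CLINE_MODEL_TYPES) - 1L
}

# free parameters per model type (pmin/pmax always free; see aicTable docs)
.freeParams <- function(type) {
  switch(type,
    null = c("pmin", "pmax"),
    I = c("center", "width", "pmin", "pmax"),
    II = c("center", "width", "pmin", "pmax", "deltaL", "tauL"),
    III = PARAM_NAMES
  )
}

# full 8-slot natural-scale vector for the C++ kernel; unused tail slots get
# neutral values that the kernel never reads for this model type
.modelTheta <- function(model) {
  th <- c(model@center, model@width, model@pmin, model@pmax,
          model@deltaL, model@tauL, model@deltaR, model@tauR)
  th[is.na(th)] <- c(0, 1, 0, 0, 0, 1, 0, 1)[is.na(th)]
  names(th) <- PARAM_NAMES
  th
}

.thetaToModel <- function(type, theta, span) {
  # the sampler/optimizer can land on the open tau boundary in floating point
  theta[c(6, 8)] <- pmin(pmax(theta[c(6, 8)], 1e-9), 1)
  clineModel(
    type = type,
    center = if (type == "null") NA_real_ else theta[1],
    width = if (type == "null") NA_real_ else theta[2],
    pmin = theta[3], pmax = theta[4],
    deltaL = if (type %in% c("II", "III")) theta[5] else NA_real_,
    tauL = if (type %in% c("II", "III")) theta[6] else NA_real_,
    deltaR = if (type == "III") theta[7] else NA_real_,
    tauR = if (type == "III") theta[8] else NA_real_,
    span = span
  )
}

#' Construct a cline model
#'
#' @param type model family: \code{"null"}, \code{"I"}, \code{"II"} or
#'   \code{"III"}. Model II takes a single shared tail via \code{deltaL} /
#'   \code{tauL}.
#' @param center,width sigmoid center and width in meters (not used by the
#'   null model).
#' @param pmin,pmax values at the western (negative-distance) and eastern
#'   ends; swap them (\code{pmin > pmax}) for a decreasing cline.
#' @param deltaL,tauL left (and, for model II, shared) tail: attachment
#'   distance from the center (m, >= 0) and slope ratio in (0, 1].
#' @param deltaR,tauR right tail (model III only).
#' @param span data span \code{c(dmin, dmax)} in meters; required for the
#'   null model's straight line, optional otherwise.
#' @return a validated [ClineModel-class].
#' @examples
#' m <- clineModel("I", center = 0, width = 2000, pmin = 0, pmax = 1)
#' clineValue(m, c(-1000, 0, 1000))
#' @export
clineModel <- function(type = c("I", "II", "III", "null"),
                       center = NA_real_, width = NA_real_,
                       pmin = 0, pmax = 1,
                       deltaL = NA_real_, tauL = NA_real_,
                       deltaR = NA_real_, tauR = NA_real_,
                       span = c(NA_real_, NA_real_)) {
  type <- match.arg(type)
  new("ClineModel", modelType = type,
      center = as.numeric(center), width = as.numeric(width),
      pmin = as.numeric(pmin), pmax = as.numeric(pmax),
      deltaL = as.numeric(deltaL), tauL = as.numeric(tauL),
      deltaR = as.numeric(deltaR), tauR = as.numeric(tauR),
      span = as.numeric(span))
}

#' @rdname clineValue
setMethod("clineValue", "ClineModel", function(model, d) {
  if (any(!is.finite(d))) stop("'d' must be finite")
  span <- model@span
  if (model@modelType == "null" && any(!is.finite(span)))
    stop("null model needs a finite span")
  if (any(!is.finite(span))) span <- c(0, 0)
  .cline_eval_cpp(as.numeric(d), .modelTypeInt(model@modelType),
                  .modelTheta(model), span[1], span[2])
})

#' @rdname deltaP
setMethod("deltaP", "ClineModel", function(object) {
  abs(object@pmax - object@pmin)
})

#' @rdname deltaP
setMethod("deltaP", "ClineFit", function(object) deltaP(object@model))

setMethod("show", "ClineModel", function(object) {
  cat(sprintf("ClineModel (type %s)\n", object@modelType))
  if (object@modelType != "null")
    cat(sprintf("  center %.4g m, width %.4g m\n", object@center, object@width))
  cat(sprintf("  pmin %.4g (west), pmax %.4g (east)\n",
              object@pmin, object@pmax))
  if (object@modelType == "II")
    cat(sprintf("  shared tail: delta %.4g m, tau %.3g\n",
                object@deltaL, object@tauL))
  if (object@modelType == "III")
    cat(sprintf("  tails: left (delta %.4g, tau %.3g), right (delta %.4g, tau %.3g)\n",
                object@deltaL, object@tauL, object@deltaR, object@tauR))
  invisible(object)
})

#' Build a binned allele-frequency table
#'
#' One row per transect bin: mean signed distance, number of alleles sampled
#' (2 per genotyped tree for nuclear loci, 1 for a haploid chloroplast) and
#' the count of the focal allele. This is the unit of data consumed by the
#' frequency cline likelihood.
#'
#' @param distance numeric, mean signed distance of each bin (m).
#' @param n number of alleles sampled per bin.
#' @param count focal-allele count per bin.
#' @param bin optional bin labels.
#' @return a \code{data.frame} of class \code{"FrequencyBinTable"}.
#' @export
frequencyBinTable <- function(distance, n, count,
                              bin = as.character(seq_along(distance))) {
  stopifnot(length(distance) == length(n), length(n) == length(count))
  if (any(!is.finite(distance))) stop("distances must be finite")
  if (any(n <= 0)) stop("each bin must sample at least one allele")
  if (any(count < 0 | count > n)) stop("counts must lie in [0, n]")
  out <- data.frame(bin = as.character(bin), distance = as.numeric(distance),
                    n = as.numeric(n), count = as.numeric(count),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("FrequencyBinTable", "data.frame")
  out
}

#' Build a binned trait table
#'
#' One row per transect bin: mean signed distance, number of individuals,
#' and the mean and variance of the standardized (and transformed) trait.
#'
#' @param distance numeric, mean signed distance of each bin (m).
#' @param n individuals per bin.
#' @param mean,variance per-bin mean and variance of the standardized trait.
#' @param bin optional bin labels.
#' @return a \code{data.frame} of class \code{"TraitBinTable"}.
#' @export
traitBinTable <- function(distance, n, mean, variance,
                          bin = as.character(seq_along(distance))) {
  stopifnot(length(distance) == length(n), length(n) == length(mean),
            length(mean) == length(variance))
  if (any(!is.finite(distance))) stop("distances must be finite")
  if (any(n < 1)) stop("each bin needs at least one individual")
  if (any(variance < 0, na.rm = TRUE)) stop("variances must be >= 0")
  out <- data.frame(bin = as.character(bin), distance = as.numeric(distance),
                    n = as.numeric(n), mean = as.numeric(mean),
                    variance = as.numeric(variance), stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TraitBinTable", "data.frame")
  out
}

.freqDataMatrix <- function(table) {
  stopifnot(all(c("distance", "n", "count") %in% names(table)))
  as.matrix(table[, c("distance", "n", "count")])
}

.traitDataMatrix <- function(table, pooledVariance = TRUE) {
  stopifnot(all(c("distance", "n", "mean", "variance") %in% names(table)))
  v <- table$variance
  small <- table$n < 2 | v <= 0
  if (any(small)) {
    if (!pooledVariance || all(small))
      stop("bins with n < 2 or zero variance need the pooled-variance fallback")
    pooled <- sum((table$n[!small] - 1) * v[!small]) / sum(table$n[!small] - 1)
    v[small] <- pooled
  }
  cbind(as.matrix(table[, c("distance", "n", "mean")]), variance = v)
}

#' Binomial log-likelihood of a frequency cline
#'
#' \eqn{\sum_i k_i \log \hat p_i + (n_i - k_i) \log(1 - \hat p_i)} over the
#' bins, with the predicted frequency clamped to
#' \eqn{[\epsilon, 1-\epsilon]}; the binomial coefficient is omitted (it is
#' constant across models on fixed data).
#'
#' @param model a [ClineModel-class].
#' @param table a [frequencyBinTable()].
#' @param epsilon frequency clamp (default 1e-6).
#' @return log-likelihood (numeric scalar).
#' @export
clineLogLikFreq <- function(model, table, epsilon = 1e-6) {
  if (!nrow(table)) stop("empty bin table")
  span <- .tableSpan(model, table)
  .cline_loglik_cpp(.modelTypeInt(model@modelType), 0L,
                    .freqDataMatrix(table), .modelTheta(model),
                    span[1], span[2], epsilon)
}

#' Gaussian log-likelihood of a trait cline
#'
#' \eqn{\sum_i -\tfrac12 \log(2\pi v_i / n_i) - n_i (m_i - \hat\mu_i)^2 /
#' (2 v_i)}, the likelihood of the bin means given the cline curve, using
#' each bin's observed variance; bins with fewer than two individuals fall
#' back to the pooled within-bin variance when \code{pooledVariance} is
#' \code{TRUE}.
#'
#' @param model a [ClineModel-class].
#' @param table a [traitBinTable()].
#' @param pooledVariance allow the pooled-variance fallback for tiny bins.
#' @return log-likelihood (numeric scalar).
#' @export
clineLogLikTrait <- function(model, table, pooledVariance = TRUE) {
  if (!nrow(table)) stop("empty bin table")
  span <- .tableSpan(model, table)
  .cline_loglik_cpp(.modelTypeInt(model@modelType), 1L,
                    .traitDataMatrix(table, pooledVariance),
                    .modelTheta(model), span[1], span[2], 1e-6)
}

.tableSpan <- function(model, table) {
  if (all(is.finite(model@span))) model@span else range(table$distance)
}

#' Standardize a trait to the unit interval
#'
#' Applies the requested transform, then min-max scales the individual
#' values to [0, 1], recording everything needed to invert the map. A
#' constant input maps to 0.5 everywhere with \code{constant = TRUE}.
#'
#' @param values numeric trait measurements.
#' @param transform \code{"none"}, \code{"log"} (positive values only) or
#'   \code{"sqrt"} (nonnegative values only).
#' @param ids optional identifiers used in domain-violation messages.
#' @return list with \code{values} (standardized), \code{transform},
#'   \code{min}, \code{max} (on the transformed scale), \code{constant},
#'   and \code{invert}, a function mapping standardized values back to the
#'   original scale.
#' @export
standardizeTrait <- function(values, transform = c("none", "log", "sqrt"),
                             ids = seq_along(values)) {
  transform <- match.arg(transform)
  ok <- !is.na(values)
  v <- values
  if (transform == "log") {
    bad <- ok & values <= 0
    if (any(bad))
      stop(sprintf("log transform needs positive values; offending: %s",
                   paste(ids[bad], collapse = ", ")))
    v[ok] <- log(values[ok])
  } else if (transform == "sqrt") {
    bad <- ok & values < 0
    if (any(bad))
      stop(sprintf("sqrt transform needs nonnegative values; offending: %s",
                   paste(ids[bad], collapse = ", ")))
    v[ok] <- sqrt(values[ok])
  }
  lo <- min(v[ok])
  hi <- max(v[ok])
  constant <- !is.finite(hi - lo) || hi == lo
  out <- v
  if (constant) {
    warning("constant trait: all standardized values set to 0.5")
    out[ok] <- 0.5
  } else {
    out[ok] <- (v[ok] - lo) / (hi - lo)
  }
  invert <- function(s) {
    t <- if (constant) rep(lo, length(s)) else lo + s * (hi - lo)
    switch(transform, none = t, log = exp(t), sqrt = t^2)
  }
  list(values = out, transform = transform, min = lo, max = hi,
       constant = constant, invert = invert)
}
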