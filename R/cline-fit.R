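#' @importFrom stats optim lm coef var cor sd shapiro.test qchisq
#'   quantile residuals
NULL

#' MCMC fitting configuration
#'
#' @param nChains number of independent chains (default 3).
#' @param nSteps scans per chain (default 1e5); each scan updates every free
#'   parameter once.
#' @param burnIn burn-in scans discarded from the sample (default 1e4).
#' @param thin keep one scan in \code{thin} (default 10).
#' @param proposalScales initial random-walk proposal scales on the
#'   transformed sampling scale, named
#'   \code{center, width, pmin, pmax, deltaL, tauL, deltaR, tauR}; adapted
#'   during burn-in, so only their order of magnitude matters.
#' @param bounds optional 8 x 2 natural-scale bounds matrix; \code{NULL}
#'   derives bounds from the data span (center within span +/- span, width
#'   in (1 m, 10 span], tail attachments in [0, 5 span], frequencies and
#'   slope ratios in their unit ranges).
#' @param rhatThreshold Gelman-Rubin convergence threshold (default 1.1).
#' @param alpha significance level of the trait linear-regression null gate
#'   (default 0.05).
#' @param daicThreshold keep the simpler model when its AIC is within this
#'   margin of the best (default 2).
#' @param epsilon binomial frequency clamp (default 1e-6).
#' @param seed integer seed; every chain derives its own stream from it.
#' @return a [FitConfig-class].
#' @export
fitConfig <- function(nChains = 3L, nSteps = 1e5L, burnIn = 1e4L, thin = 10L,
                      proposalScales = c(center = 50, width = 0.1,
                                         pmin = 0.3, pmax = 0.3,
                                         deltaL = 0.3, tauL = 0.5,
                                         deltaR = 0.3, tauR = 0.5),
                      bounds = NULL, rhatThreshold = 1.1, alpha = 0.05,
                      daicThreshold = 2.0, epsilon = 1e-6, seed = 1L) {
  new("FitConfig", nChains = as.integer(nChains), nSteps = as.integer(nSteps),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      proposalScales = proposalScales, bounds = bounds,
      rhatThreshold = rhatThreshold, alpha = alpha,
      daicThreshold = daicThreshold, epsilon = epsilon,
      seed = as.integer(seed))
}

.tableKind <- function(table) {
  if (inherits(table, "FrequencyBinTable")) return("frequency")
  if (inherits(table, "TraitBinTable")) return("trait")
  if (all(c("distance", "n", "count") %in% names(table))) return("frequency")
  if (all(c("distance", "n", "mean", "variance") %in% names(table)))
    return("trait")
  stop("table is neither a frequency nor a trait bin table")
}

.defaultBounds <- function(span) {
  spanw <- max(diff(span), 1)
  b <- rbind(
    center = c(span[1] - spanw, span[2] + spanw),
    width = c(1, 10 * spanw),
    pmin = c(0, 1), pmax = c(0, 1),
    deltaL = c(0, 5 * spanw), tauL = c(0, 1),
    deltaR = c(0, 5 * spanw), tauR = c(0, 1)
  )
  colnames(b) <- c("low", "high")
  b
}

# coarse deterministic (center, width) grid search used to seed the chains
.gridInit <- function(type, kind, dataMat, span, epsilon) {
  ends <- .endValues(kind, dataMat)
  spanw <- max(diff(span), 1)
  th <- c(center = mean(span), width = spanw / 2,
          pmin = ends[1], pmax = ends[2],
          deltaL = spanw / 4, tauL = 0.9, deltaR = spanw / 4, tauR = 0.9)
  if (type == "null") return(th)
  cs <- seq(span[1], span[2], length.out = 25)
  ws <- exp(seq(log(spanw / 50), log(2 * spanw), length.out = 25))
  best <- -Inf
  ti <- .modelTypeInt(type)
  for (cc in cs) for (ww in ws) {
    cand <- th
    cand[1] <- cc
    cand[2] <- ww
    ll <- .cline_loglik_cpp(ti, if (kind == "frequency") 0L else 1L,
                            dataMat, cand, span[1], span[2], epsilon)
    if (is.finite(ll) && ll > best) {
      best <- ll
      th[1] <- cc
      th[2] <- ww
    }
  }
  th
}

# observed values at the two ends of the transect, pulled slightly off the
# unit boundary so logit-scale chains can start there
.endValues <- function(kind, dataMat) {
  val <- if (kind == "frequency") dataMat[, 3] / dataMat[, 2] else dataMat[, 3]
  k <- min(3, nrow(dataMat))
  lo <- mean(val[seq_len(k)])
  hi <- mean(val[seq(nrow(dataMat) - k + 1, nrow(dataMat))])
  pmin(pmax(c(lo, hi), 0.02), 0.98)
}

.transformPhi <- function(th) {
  c(th[1], log(th[2]), qlogis(th[3]), qlogis(th[4]),
    log1p(th[5]), qlogis(th[6]), log1p(th[7]), qlogis(th[8]))
}

.inversePhi <- function(phi) {
  c(phi[1], exp(phi[2]), plogis(phi[3]), plogis(phi[4]),
    expm1(phi[5]), plogis(phi[6]), expm1(phi[7]), plogis(phi[8]))
}

#' Gelman-Rubin potential scale reduction
#'
#' @param chains list of numeric vectors, one per chain.
#' @return the R-hat statistic (1 when between-chain variance vanishes).
#' @export
gelmanRubin <- function(chains) {
  m <- length(chains)
  n <- min(lengths(chains))
  if (m < 2L || n < 2L) return(NA_real_)
  x <- vapply(chains, function(ch) ch[seq_len(n)], numeric(n))
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  if (W <= .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.twoLL <- function(samples, lnl, parameter, cutoff = 2) {
  keep <- lnl >= max(lnl) - cutoff
  range(samples[keep, parameter])
}

#' 2-log-likelihood support interval
#'
#' The approximate 95\% support interval of a parameter: the min and max of
#' the parameter over all posterior samples whose log-likelihood is within
#' \code{cutoff} units of the maximum.
#'
#' @param samples data.frame of posterior samples.
#' @param lnl numeric log-likelihood per sample.
#' @param parameter column name.
#' @param cutoff log-likelihood drop defining the interval (default 2).
#' @return \code{c(low, high)}.
#' @export
twoLLInterval <- function(samples, lnl, parameter, cutoff = 2) {
  if (nrow(samples) < 100L)
    stop("need at least 100 post-burn-in samples")
  if (!parameter %in% names(samples))
    stop(sprintf("unknown parameter '%s'", parameter))
  if (!any(is.finite(lnl))) stop("no finite log-likelihoods: degenerate fit")
  .twoLL(samples, lnl, parameter, cutoff)
}

#' Fit one cline model family by Metropolis-Hastings MCMC
#'
#' Runs component-wise random-walk MCMC (uniform priors within bounds,
#' proposals on transformed scales, burn-in scale adaptation) from a
#' coarse grid-search start, polishes the best visited state with a local
#' optimizer, and summarizes the posterior with 2-log-likelihood support
#' intervals and Gelman-Rubin diagnostics.
#'
#' @param table a [frequencyBinTable()] or [traitBinTable()].
#' @param modelType \code{"null"}, \code{"I"}, \code{"II"} or \code{"III"}.
#' @param config a [fitConfig()].
#' @param fixed optional named numeric of parameters to hold fixed (e.g.
#'   \code{c(pmin = 0, pmax = 1)}); fixed parameters are not counted in k.
#' @return a [ClineFit-class].
#' @examples
#' tab <- frequencyBinTable(distance = seq(-3000, 3000, length.out = 10),
#'                          n = rep(40, 10),
#'                          count = round(40 * plogis(seq(-3, 3, length.out = 10))))
#' fit <- fitCline(tab, "I", fitConfig(nChains = 2L, nSteps = 4000L,
#'                                     burnIn = 1000L, seed = 7L))
#' bestModel(fit)
#' @export
fitCline <- function(table, modelType = c("I", "II", "III", "null"),
                     config = fitConfig(), fixed = NULL) {
  modelType <- match.arg(modelType)
  kind <- .tableKind(table)
  if (!nrow(table)) stop("empty bin table")
  dataMat <- if (kind == "frequency") .freqDataMatrix(table)
             else .traitDataMatrix(table)
  dataMat <- dataMat[order(dataMat[, 1]), , drop = FALSE]
  span <- range(dataMat[, 1])
  bounds <- if (is.null(config@bounds)) .defaultBounds(span) else config@bounds
  ti <- .modelTypeInt(modelType)
  ki <- if (kind == "frequency") 0L else 1L

  free <- .freeParams(modelType)
  mask <- setNames(PARAM_NAMES %in% free, PARAM_NAMES)
  init <- .gridInit(modelType, kind, dataMat, span, config@epsilon)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), PARAM_NAMES)
    if (length(bad)) stop("unknown fixed parameters: ", paste(bad, collapse = ", "))
    init[names(fixed)] <- fixed
    mask[names(fixed)] <- FALSE
    free <- setdiff(free, names(fixed))
  }
  init <- pmin(pmax(init, bounds[, 1] + 1e-9), bounds[, 2] - 1e-9)
  init[c("pmin", "pmax", "tauL", "tauR")] <-
    pmin(init[c("pmin", "pmax", "tauL", "tauR")], 1 - 1e-9)
  if (!is.null(fixed)) init[names(fixed)] <- fixed

  chains <- vector("list", config@nChains)
  for (ch in seq_len(config@nChains)) {
    set.seed(config@seed + 1009L * ch + 17L * ti)
    start <- .transformPhi(init)
    start[mask] <- start[mask] + rnorm(sum(mask), 0, 0.05)
    th0 <- .inversePhi(start)
    th0 <- pmin(pmax(th0, bounds[, 1]), bounds[, 2])
    th0[!mask] <- init[!mask]
    chains[[ch]] <- .mh_chain_cpp(ti, ki, dataMat, th0,
                                  config@proposalScales, bounds, mask,
                                  config@nSteps, config@burnIn, config@thin,
                                  config@epsilon, span[1], span[2])
  }

  acc <- vapply(chains, function(z) max(z$accept[mask], na.rm = TRUE), 0)
  if (any(acc < 1e-3))
    stop("an MCMC chain rejected essentially every proposal; ",
         "rescale proposalScales or widen bounds")

  samp <- do.call(rbind, lapply(seq_along(chains), function(i) {
    s <- as.data.frame(chains[[i]]$samples)
    names(s) <- PARAM_NAMES
    s$lnL <- chains[[i]]$lnl
    s$chain <- i
    s
  }))

  bi <- which.max(vapply(chains, function(z) z$best_lnl, 0))
  bestTh <- setNames(chains[[bi]]$best, PARAM_NAMES)
  bestLl <- chains[[bi]]$best_lnl

  # local polish so lnL_max is a genuine (local) maximum, not just the best
  # visited state
  if (length(free)) {
    obj <- function(phiFree) {
      phi <- .transformPhi(bestTh)
      phi[mask] <- phiFree
      th <- .inversePhi(phi)
      th[!mask] <- bestTh[!mask]
      if (any(th < bounds[, 1] - 1e-12) || any(th > bounds[, 2] + 1e-12))
        return(1e10)
      -.cline_loglik_cpp(ti, ki, dataMat, th, span[1], span[2], config@epsilon)
    }
    op <- tryCatch(
      optim(.transformPhi(bestTh)[mask], obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && -op$value > bestLl) {
      phi <- .transformPhi(bestTh)
      phi[mask] <- op$par
      th <- .inversePhi(phi)
      th[!mask] <- bestTh[!mask]
      bestTh <- setNames(pmin(pmax(th, bounds[, 1]), bounds[, 2]), PARAM_NAMES)
      bestLl <- -op$value
    }
  }

  # the best point participates in the support intervals so they always
  # contain the reported estimate
  bestRow <- as.data.frame(as.list(bestTh))
  bestRow$lnL <- bestLl
  bestRow$chain <- NA_integer_
  sampAll <- rbind(samp, bestRow)

  rhat <- vapply(free, function(p) {
    gelmanRubin(lapply(split(samp[[p]], samp$chain), as.numeric))
  }, 0)
  converged <- !any(is.finite(rhat) & rhat >= config@rhatThreshold)

  iv <- t(vapply(free, function(p) .twoLL(sampAll, sampAll$lnL, p), numeric(2)))
  if (length(free)) colnames(iv) <- c("low", "high")
  else iv <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("low", "high")))

  k <- length(free)
  model <- .thetaToModel(modelType, bestTh, span)
  new("ClineFit", model = model, modelType = modelType, logLik = bestLl,
      k = as.integer(k),
      aic = setNames(2 * k - 2 * bestLl, modelType),
      intervals = iv, samples = sampAll[, c(free, "lnL", "chain")],
      rhat = rhat, converged = converged, isNull = modelType == "null",
      dataKind = kind, details = list(accept = lapply(chains, `[[`, "accept")))
}

#' Fit all candidate cline models and select one by AIC
#'
#' For frequency data, fits the null, I, II and III families and keeps the
#' model with the lowest AIC, preferring the simplest model whose AIC lies
#' within \code{daicThreshold} of the best (simplicity order
#' null < I < II < III). For trait data, a linear regression of bin means on
#' distance is run first: a non-significant slope (two-sided p >= alpha)
#' declares the character cline-free, otherwise models I-III compete by the
#' same AIC rule. A Shapiro-Wilk advisory on the gate-regression residuals
#' is recorded (never blocking).
#'
#' @param table a [frequencyBinTable()] or [traitBinTable()].
#' @param config a [fitConfig()].
#' @return a [ClineFit-class] whose \code{aic} slot lists every candidate.
#' @export
selectClineModel <- function(table, config = fitConfig()) {
  kind <- .tableKind(table)
  if (kind == "trait") {
    gate <- lm(mean ~ distance, data = table)
    pSlope <- summary(gate)$coefficients["distance", "Pr(>|t|)"]
    normP <- if (nrow(table) >= 3 && nrow(table) <= 5000)
      tryCatch(shapiro.test(residuals(gate))$p.value, error = function(e) NA_real_)
    else NA_real_
    if (is.finite(normP) && normP < 0.01)
      message("advisory: bin-mean residuals deviate from normality ",
              sprintf("(Shapiro-Wilk p = %.3g)", normP))
    if (pSlope >= config@alpha) {
      span <- range(table$distance)
      m0 <- mean(table$mean)
      model <- clineModel("null", pmin = m0, pmax = m0, span = span)
      return(new("ClineFit", model = model, modelType = "null",
                 logLik = clineLogLikTrait(model, table), k = 2L,
                 aic = setNames(NA_real_, "null"),
                 intervals = matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("low", "high"))),
                 samples = data.frame(), rhat = numeric(0), converged = TRUE,
                 isNull = TRUE, dataKind = "trait",
                 details = list(gate_p = pSlope, shapiro_p = normP)))
    }
    candidates <- c("I", "II", "III")
    extras <- list(gate_p = pSlope, shapiro_p = normP)
  } else {
    candidates <- c("null", "I", "II", "III")
    extras <- list()
  }
  fits <- lapply(candidates, function(ty) fitCline(table, ty, config))
  names(fits) <- candidates
  aics <- vapply(fits, function(f) unname(f@aic), 0)
  chosen <- candidates[which(aics <= min(aics) + config@daicThreshold)[1]]
  out <- fits[[chosen]]
  out@aic <- aics
  out@isNull <- chosen == "null"
  out@details <- c(out@details, extras)
  out
}

setMethod("bestModel", "ClineFit", function(object) object@model)
setMethod("aicTable", "ClineFit", function(object) object@aic)
setMethod("supportIntervals", "ClineFit", function(object) object@intervals)
setMethod("isNullCline", "ClineFit", function(object) object@isNull)

setMethod("show", "ClineFit", function(object) {
  cat(sprintf("ClineFit (%s data): best model %s%s\n", object@dataKind,
              object@modelType, if (object@isNull) " [no cline]" else ""))
  cat(sprintf("  lnL_max %.3f, k = %d\n", object@logLik, object@k))
  if (length(object@aic) > 1)
    cat("  AIC:", paste(sprintf("%s %.2f", names(object@aic), object@aic),
                        collapse = ", "), "\n")
  if (nrow(object@intervals)) {
    cat("  2-lnL support intervals:\n")
    for (p in rownames(object@intervals))
      cat(sprintf("    %-7s [%.4g, %.4g]\n", p,
                  object@intervals[p, 1], object@intervals[p, 2]))
  }
  if (length(object@rhat) && any(is.finite(object@rhat)))
    cat(sprintf("  max R-hat %.3f (%s)\n", max(object@rhat, na.rm = TRUE),
                if (object@converged) "converged" else "NOT converged"))
  invisible(object)
})
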