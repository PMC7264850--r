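#' @importFrom stats cor.test glm binomial pt pnorm cov
NULL

#' Correlation between hybrid index and transect position
#'
#' Pearson product-moment correlation of per-tree hybrid index (Q) against
#' signed transect distance, with the t statistic on n - 2 degrees of
#' freedom and its two-sided p-value.
#'
#' @param q hybrid-index values.
#' @param distance signed transect distances (m).
#' @return list with \code{r}, \code{t}, \code{df}, \code{p}.
#' @export
pearsonQDistance <- function(q, distance) {
  ok <- is.finite(q) & is.finite(distance)
  q <- q[ok]; distance <- distance[ok]
  if (length(q) < 3L) stop("need at least 3 complete records")
  if (sd(q) == 0 || sd(distance) == 0)
    stop("zero variance in q or distance")
  ct <- cor.test(q, distance, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Binomial GLM of pollinator host choice
#'
#' Logistic regression of per-tree moth species composition
#' (\emph{T. antithetica} successes vs \emph{T. synthetica} failures) on
#' host hybrid index and signed transect distance, fitted by iteratively
#' reweighted least squares. Reports Wald z and two-sided p per
#' coefficient, flags strong collinearity between the predictors, and
#' refuses to return silently diverged estimates under complete
#' separation.
#'
#' @param q host hybrid index per tree.
#' @param distance signed transect distance (m) per tree.
#' @param nAntithetica,nSynthetica per-tree moth counts.
#' @return data.frame with one row per term: \code{estimate}, \code{se},
#'   \code{z}, \code{p}; the fitted \code{glm} object in attribute
#'   \code{"fit"}.
#' @export
hostChoiceGLM <- function(q, distance, nAntithetica, nSynthetica) {
  dat <- data.frame(q = q, distance = distance,
                    ant = nAntithetica, syn = nSynthetica)
  dat <- dat[complete.cases(dat) & (dat$ant + dat$syn) > 0, ]
  if (nrow(dat) < 3L) stop("need at least 3 usable records")
  rqd <- abs(cor(dat$q, dat$distance))
  if (is.finite(rqd) && rqd > 0.95)
    warning(sprintf("q and distance are nearly collinear (|r| = %.2f)", rqd))
  fit <- glm(cbind(ant, syn) ~ q + distance, family = binomial(),
             data = dat, control = list(epsilon = 1e-12, maxit = 100))
  co <- summary(fit)$coefficients
  if (!fit$converged || any(abs(co[, "Estimate"]) > 25 &
                            co[, "Std. Error"] > 1e3))
    stop("complete separation detected: coefficients diverge")
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], z = co[, "z value"],
                    p = co[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}
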