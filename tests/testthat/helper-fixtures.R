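# Shared fixtures: all built in code, nothing read from disk.

# two parental pools fixed for alternate alleles at every locus
diagnosticPools <- function(nLoci = 101L, nPer = 50L) {
  list(
    west = matrix(0L, nLoci, nPer,
                  dimnames = list(sprintf("L%03d", seq_len(nLoci)),
                                  sprintf("W%02d", seq_len(nPer)))),
    east = matrix(2L, nLoci, nPer,
                  dimnames = list(sprintf("L%03d", seq_len(nLoci)),
                                  sprintf("E%02d", seq_len(nPer))))
  )
}

# semi-diagnostic pools: allele frequencies pw (west) and pe (east)
semiDiagnosticPools <- function(nLoci = 101L, nPer = 50L, pw = 0.1, pe = 0.9,
                                seed = 42L) {
  set.seed(seed)
  list(
    west = matrix(rbinom(nLoci * nPer, 2L, pw), nLoci, nPer),
    east = matrix(rbinom(nLoci * nPer, 2L, pe), nLoci, nPer)
  )
}

# short chains for unit tests; experiments that need the full defaults set
# their own configuration
quickFitConfig <- function(seed = 1L, ...) {
  fitConfig(nChains = 2L, nSteps = 8000L, burnIn = 2000L, thin = 5L,
            seed = as.integer(seed), ...)
}

# a minimal ClineFit carrying just what the comparison operations read
fitStub <- function(center, centerIv, width = 1000, widthIv = width + c(-100, 100),
                    pmin = 0, pmax = 1, isNull = FALSE) {
  iv <- rbind(center = centerIv, width = widthIv)
  colnames(iv) <- c("low", "high")
  model <- if (isNull) clineModel("null", pmin = pmin, pmax = pmax,
                                  span = c(-1e4, 1e4))
           else clineModel("I", center = center, width = width,
                           pmin = pmin, pmax = pmax)
  ty <- if (isNull) "null" else "I"
  new("ClineFit", model = model,
      modelType = ty, logLik = 0, k = if (isNull) 2L else 4L,
      aic = setNames(0, ty),
      intervals = if (isNull) iv[0, , drop = FALSE] else iv,
      samples = data.frame(), rhat = numeric(0),
      converged = TRUE, isNull = isNull, dataKind = "frequency",
      details = list())
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
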