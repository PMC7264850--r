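#' Hybrid index and interclass heterozygosity per individual
#'
#' For each individual, the hybrid index HI is the proportion of its
#' non-missing alleles that come from the designated eastern pool
#' (sum of focal-allele counts over twice the loci used), and the
#' interclass heterozygosity H is the proportion of non-missing loci at
#' which it carries one allele of each type. Both are invariant to locus
#' order and to loci missing in that individual.
#'
#' @param genotypes matrix of focal-allele counts (0/1/2, \code{NA}
#'   allowed), loci as rows and individuals as columns, or a
#'   [HybridZoneExperiment-class].
#' @return data.frame with columns \code{id}, \code{hybridIndex},
#'   \code{heterozygosity}, \code{nLociUsed}.
#' @examples
#' g <- matrix(c(2, 1, 0, 1), 4, 1, dimnames = list(NULL, "tree1"))
#' ancestryPoints(g)  # HI 0.5, H 0.5
#' @export
ancestryPoints <- function(genotypes) {
  g <- if (is(genotypes, "HybridZoneExperiment")) {
    SummarizedExperiment::assay(genotypes, "genotype")
  } else as.matrix(genotypes)
  if (is.null(colnames(g))) colnames(g) <- sprintf("ind%d", seq_len(ncol(g)))
  used <- colSums(!is.na(g))
  if (any(used == 0L))
    stop("all loci missing for: ",
         paste(colnames(g)[used == 0L], collapse = ", "))
  hi <- colSums(g, na.rm = TRUE) / (2 * used)
  het <- colSums(g == 1L, na.rm = TRUE) / used
  data.frame(id = colnames(g), hybridIndex = unname(hi),
             heterozygosity = unname(het), nLociUsed = unname(used),
             stringsAsFactors = FALSE)
}

.poolMatrix <- function(pool) {
  g <- if (is(pool, "HybridZoneExperiment")) genotypes(pool) else as.matrix(pool)
  if (!ncol(g)) stop("empty parental pool")
  g
}

# one gamete per parent column: per locus, one of the parent's two alleles
# chosen uniformly (free recombination, r = 0.5); missing locus stays missing
.gametes <- function(g, parentIdx) {
  gp <- g[, parentIdx, drop = FALSE]
  pr <- gp / 2
  pr[is.na(pr)] <- 0  # placeholder; the call is masked to NA below
  ga <- matrix(rbinom(length(pr), 1L, pr), nrow(gp), ncol(gp))
  ga[is.na(gp)] <- NA_integer_
  ga
}

#' Cross two pools in silico
#'
#' Each offspring draws one parent uniformly (with replacement) from each
#' pool; every parent contributes a gamete carrying, per locus, one of its
#' two alleles chosen independently and uniformly -- markers recombine
#' freely (r = 0.5). A locus missing in either parent is missing in the
#' offspring.
#'
#' @param poolA,poolB genotype matrices (loci x individuals) or
#'   [HybridZoneExperiment-class] objects with identical locus sets.
#' @param nOffspring offspring to produce (default 500, the conventional
#'   cloud size per cross type).
#' @param seed RNG seed.
#' @return integer genotype matrix, loci x offspring.
#' @export
simulateCross <- function(poolA, poolB, nOffspring = 500L, seed = 1L) {
  ga <- .poolMatrix(poolA)
  gb <- .poolMatrix(poolB)
  if (nrow(ga) != nrow(gb)) stop("pools must share the same loci")
  set.seed(seed)
  pa <- sample.int(ncol(ga), nOffspring, replace = TRUE)
  pb <- sample.int(ncol(gb), nOffspring, replace = TRUE)
  off <- .gametes(ga, pa) + .gametes(gb, pb)
  dimnames(off) <- list(rownames(ga), sprintf("off%04d", seq_len(nOffspring)))
  off
}

.makeCloud <- function(label, points) {
  pts <- as.matrix(points[, c("hybridIndex", "heterozygosity")])
  colnames(pts) <- c("hybridIndex", "heterozygosity")
  new("HybridClassCloud", className = label, points = pts,
      center = colMeans(pts), covariance = stats::cov(pts))
}

setMethod("show", "HybridClassCloud", function(object) {
  cat(sprintf("HybridClassCloud '%s': %d points, mean (HI %.3f, H %.3f)\n",
              object@className, nrow(object@points),
              object@center[1], object@center[2]))
  invisible(object)
})

#' Simulate early-generation hybrid-class clouds
#'
#' From two pure parental pools, simulates F1 (west x east), F2 (F1 x F1)
#' and the two first-generation backcrosses, converts every group
#' (including the parental pools) to (hybrid index, heterozygosity) points,
#' and summarizes each as a [HybridClassCloud-class]. These clouds are the
#' reference against which empirical individuals are classified in the
#' triangle plot.
#'
#' @param poolWest,poolEast parental genotype matrices or
#'   [HybridZoneExperiment-class]s (the eastern pool carries the focal
#'   alleles).
#' @param nPerClass simulated individuals per cross type (default 500).
#' @param seed RNG seed.
#' @return named list of \code{HybridClassCloud}s:
#'   \code{pure_west, pure_east, F1, F2, BC_west, BC_east}.
#' @export
buildClassClouds <- function(poolWest, poolEast, nPerClass = 500L, seed = 1L) {
  gw <- .poolMatrix(poolWest)
  ge <- .poolMatrix(poolEast)
  f1 <- simulateCross(gw, ge, nPerClass, seed = seed)
  f2 <- simulateCross(f1, f1, nPerClass, seed = seed + 1L)
  bcw <- simulateCross(f1, gw, nPerClass, seed = seed + 2L)
  bce <- simulateCross(f1, ge, nPerClass, seed = seed + 3L)
  groups <- list(pure_west = gw, pure_east = ge, F1 = f1, F2 = f2,
                 BC_west = bcw, BC_east = bce)
  mapply(function(label, g) .makeCloud(label, ancestryPoints(g)),
         names(groups), groups, SIMPLIFY = FALSE)
}

#' Classify individuals against simulated hybrid-class clouds
#'
#' Assigns each (hybrid index, heterozygosity) point to the cloud with the
#' smallest squared Mahalanobis distance, provided that distance falls
#' under the chi-squared (2 df) gate; points beyond every gate -- typically
#' later-generation backcrosses and advanced hybrids -- are labelled
#' \code{"advanced/unassigned"}. Degenerate cloud covariances get a small
#' ridge before inversion.
#'
#' @param points data.frame from [ancestryPoints()] (or any frame with
#'   \code{hybridIndex} and \code{heterozygosity} columns).
#' @param clouds list of [HybridClassCloud-class]s from
#'   [buildClassClouds()].
#' @param gate chi-squared quantile of the assignment gate (default 0.99).
#' @param ridge covariance ridge (default 1e-6).
#' @return data.frame: \code{id}, \code{class}, and one squared-distance
#'   column per cloud.
#' @export
classifyHybrids <- function(points, clouds, gate = 0.99, ridge = 1e-6) {
  if (!length(clouds)) stop("no clouds to classify against")
  pts <- as.matrix(points[, c("hybridIndex", "heterozygosity")])
  d2 <- vapply(clouds, function(cl) {
    S <- cl@covariance + diag(ridge, 2)
    stats::mahalanobis(pts, cl@center, S)
  }, numeric(nrow(pts)))
  d2 <- matrix(d2, nrow = nrow(pts),
               dimnames = list(NULL, names(clouds)))
  cut <- qchisq(gate, df = 2)
  best <- apply(d2, 1, which.min)
  label <- names(clouds)[best]
  label[d2[cbind(seq_len(nrow(d2)), best)] > cut] <- "advanced/unassigned"
  out <- data.frame(id = if ("id" %in% names(points)) points$id
                         else seq_len(nrow(pts)),
                    class = label, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(d2))
}
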