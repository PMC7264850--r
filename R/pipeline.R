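#' Run the full hybrid-zone cline analysis
#'
#' Orchestrates the stages end-to-end from tabular inputs: project
#' coordinates, estimate the 0.5 hybrid contour, compute signed distances,
#' build standard transect bins from the genotyped trees, bin every
#' character, fit and select cline models, compare the non-locus clines
#' and summarize the SNP category, simulate hybrid-class clouds and
#' classify the genotyped trees, and model pollinator host choice.
#' Optional stages (traits, haplotypes, moths) are skipped with a notice
#' when their inputs are absent. Identical configuration and seed give
#' identical outputs.
#'
#' @param config a list (or path to a JSON file encoding one) with
#'   elements:
#'   \describe{
#'     \item{paths}{named list of input files: \code{coordinates} (CSV:
#'       \code{tree_id} plus \code{lon}/\code{lat} or \code{x}/\code{y}),
#'       \code{hybridIndex} (TSV: \code{tree_id} plus hybrid-index
#'       columns), \code{genotypes} (tsv012), and optionally
#'       \code{traits}, \code{haplotypes}, \code{moths}.}
#'     \item{outputDir}{directory for all stage outputs.}
#'     \item{transectQColumn, fitQColumn}{hybrid-index columns used for
#'       contouring and for cline fitting (default \code{"q"} for both).}
#'     \item{gridResolution}{contour grid spacing, m (default 250).}
#'     \item{binWidth, minPerBin}{transect binning (defaults 250 m, 3).}
#'     \item{parentalQ}{parental thresholds (default \code{c(0.15, 0.85)}).}
#'     \item{traitTransforms}{named character, trait -> \code{"none"},
#'       \code{"log"} or \code{"sqrt"}.}
#'     \item{fit}{list of [fitConfig()] arguments.}
#'     \item{nPerClass}{simulated individuals per cross type (default 500).}
#'     \item{seed}{integer seed.}
#'   }
#' @return the run manifest (a list, also written to
#'   \code{manifest.json}): config echo, package version, per-stage output
#'   files with MD5 checksums, wall-clock seconds per stage, and warnings.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- config
  cfg$transectQColumn <- cfg$transectQColumn %||% "q"
  cfg$fitQColumn <- cfg$fitQColumn %||% "q"
  cfg$gridResolution <- cfg$gridResolution %||% 250
  cfg$binWidth <- cfg$binWidth %||% 250
  cfg$minPerBin <- cfg$minPerBin %||% 3L
  cfg$parentalQ <- cfg$parentalQ %||% c(0.15, 0.85)
  cfg$nPerClass <- cfg$nPerClass %||% 500L
  cfg$seed <- cfg$seed %||% 1L
  if (is.null(cfg$outputDir)) stop("config needs an outputDir")
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  fitCfg <- do.call(fitConfig, c(cfg$fit, list(seed = cfg$seed)))

  manifest <- list(config = cfg[setdiff(names(cfg), "fit")],
                   version = as.character(packageVersion("zoneclines")),
                   stages = list(), warnings = character())
  outputs <- character()
  note <- function(msg) {
    manifest$warnings <<- c(manifest$warnings, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  emit <- function(name, path) outputs[name] <<- path

  set.seed(cfg$seed)

  trees <- stage("project", {
    co <- readTreeTable(cfg$paths$coordinates, sep = ",")
    projectCoordinates(co)
  })
  qtab <- readTreeTable(cfg$paths$hybridIndex)
  trees <- merge(trees, qtab, by = "tree_id", sort = FALSE)
  qT <- trees[[cfg$transectQColumn]]
  if (is.null(qT)) stop("transectQColumn not found in hybrid-index table")

  contour <- stage("contour", {
    ctr <- estimateContour(trees$x, trees$y, qT, cfg$gridResolution)
    p <- file.path(cfg$outputDir, "contour.tsv")
    write.table(as.data.frame(contourVertices(ctr)), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("contour", p)
    ctr
  })

  trees$distance <- stage("distances", {
    lowQ <- qT <= cfg$parentalQ[1]
    if (!any(lowQ))
      stop(sprintf("no trees with q <= %g to anchor the negative (western) side",
                   cfg$parentalQ[1]))
    ref <- c(mean(trees$x[lowQ]), mean(trees$y[lowQ]))
    d <- signedDistance(trees$x, trees$y, contour, ref)
    p <- file.path(cfg$outputDir, "distances.tsv")
    write.table(data.frame(tree_id = trees$tree_id, distance_m = d), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("distances", p)
    d
  })

  geno <- readGenotypeMatrix(cfg$paths$genotypes)
  gTrees <- intersect(trees$tree_id, colnames(geno))
  bins <- stage("bins", {
    idx <- match(gTrees, trees$tree_id)
    b <- makeBins(trees$distance[idx], ids = gTrees,
                  binWidth = cfg$binWidth, minPerBin = cfg$minPerBin)
    p <- file.path(cfg$outputDir, "bins.tsv")
    write.table(b, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("bins", p)
    b
  })

  tables <- stage("bin_tables", {
    tl <- list()
    gm <- geno[, bins$id, drop = FALSE]
    for (l in rownames(gm))
      tl[[l]] <- binnedFrequencyTable(gm[l, ], bins, ploidy = 2L)
    qf <- readTreeTable(cfg$paths$hybridIndex)
    qFit <- qf[[cfg$fitQColumn]][match(bins$id, qf$tree_id)]
    tl[["hybrid_index"]] <- binnedTraitTable(qFit, bins)
    if (!is.null(cfg$paths$haplotypes)) {
      hap <- readTreeTable(cfg$paths$haplotypes)
      hv <- hap$cp_haplotype[match(bins$id, hap$tree_id)]
      tl[["cp_haplotype"]] <- binnedFrequencyTable(
        ifelse(hv == "east", 1L, ifelse(hv == "west", 0L, NA)), bins,
        ploidy = 1L)
    } else note("haplotype table absent: chloroplast cline skipped")
    if (!is.null(cfg$paths$traits)) {
      tr <- readTreeTable(cfg$paths$traits)
      for (nmv in setdiff(names(tr), "tree_id")) {
        tt <- cfg$traitTransforms
        trf <- if (!is.null(tt) && nmv %in% names(tt)) as.character(tt[[nmv]])
               else "none"
        std <- standardizeTrait(tr[[nmv]], trf, ids = tr$tree_id)
        tl[[nmv]] <- binnedTraitTable(std$values[match(bins$id, tr$tree_id)],
                                      bins)
      }
    } else note("trait table absent: trait clines skipped")
    if (!is.null(cfg$paths$moths)) {
      mo <- readTreeTable(cfg$paths$moths)
      idx <- match(bins$id, mo$tree_id)
      tot <- mo$n_antithetica[idx] + mo$n_synthetica[idx]
      keep <- !is.na(tot) & tot > 0
      if (sum(keep) >= cfg$minPerBin) {
        mb <- makeBins(bins$distance[keep], ids = bins$id[keep],
                       binWidth = cfg$binWidth, minPerBin = cfg$minPerBin)
        frac <- mo$n_antithetica[idx][keep]
        tl[["moth_frequency"]] <- frequencyBinTable(
          distance = tapply(mb$distance, mb$bin, mean),
          n = tapply(tot[keep], mb$bin, sum),
          count = tapply(frac, mb$bin, sum))
      }
    }
    for (nmv in names(tl))
      writeBinTable(tl[[nmv]],
                    file.path(cfg$outputDir, sprintf("bins_%s.tsv", nmv)))
    tl
  })

  fits <- stage("fits", {
    fl <- lapply(tables, selectClineModel, config = fitCfg)
    p <- file.path(cfg$outputDir, "clines.tsv")
    writeTable2Style(fl, p)
    emit("clines", p)
    pj <- file.path(cfg$outputDir, "fits.json")
    jsonlite::write_json(lapply(fl, .fitToList), pj, auto_unbox = TRUE,
                         digits = NA, na = "null")
    emit("fits", pj)
    fl
  })

  stage("comparisons", {
    locusFits <- fits[intersect(names(fits), rownames(geno))]
    otherFits <- fits[setdiff(names(fits), rownames(geno))]
    if (length(locusFits) && !all(vapply(locusFits, isNullCline, TRUE))) {
      cs <- summarizeCategory(locusFits, "snp")
      jsonlite::write_json(cs[setdiff(names(cs), "modelFractions")],
                           file.path(cfg$outputDir, "snp_category.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("snp_category", file.path(cfg$outputDir, "snp_category.json"))
    }
    ok <- otherFits[!vapply(otherFits, isNullCline, TRUE)]
    if (length(ok) >= 2L) {
      cm <- comparisonMatrix(ok)
      for (w in names(cm)) {
        p <- file.path(cfg$outputDir, sprintf("compare_%s.tsv", w))
        write.table(cm[[w]], p, sep = "\t", quote = FALSE, na = "NA",
                    col.names = NA)
        emit(paste0("compare_", w), p)
      }
    }
    NULL
  })

  stage("hybrid_classes", {
    qf <- readTreeTable(cfg$paths$hybridIndex)
    qAll <- qf[[cfg$fitQColumn]][match(colnames(geno), qf$tree_id)]
    west <- geno[, which(qAll <= cfg$parentalQ[1]), drop = FALSE]
    east <- geno[, which(qAll >= cfg$parentalQ[2]), drop = FALSE]
    if (!ncol(west) || !ncol(east)) {
      note("parental pools empty: hybrid-class stage skipped")
    } else {
      clouds <- buildClassClouds(west, east, nPerClass = cfg$nPerClass,
                                 seed = cfg$seed)
      pts <- ancestryPoints(geno)
      cls <- classifyHybrids(pts, clouds)
      p <- file.path(cfg$outputDir, "ancestry.tsv")
      write.table(pts, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("ancestry", p)
      p2 <- file.path(cfg$outputDir, "classes.tsv")
      write.table(cls, p2, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("classes", p2)
      jsonlite::write_json(
        lapply(clouds, function(cl) list(class = cl@className,
                                         mean = cl@center,
                                         covariance = cl@covariance)),
        file.path(cfg$outputDir, "clouds.json"), digits = NA,
        auto_unbox = TRUE, matrix = "rowmajor")
      emit("clouds", file.path(cfg$outputDir, "clouds.json"))
    }
    NULL
  })

  stage("pollinator", {
    if (is.null(cfg$paths$moths)) {
      note("moth table absent: pollinator stage skipped")
    } else {
      mo <- readTreeTable(cfg$paths$moths)
      qf <- readTreeTable(cfg$paths$hybridIndex)
      idx <- match(mo$tree_id, trees$tree_id)
      qv <- qf[[cfg$fitQColumn]][match(mo$tree_id, qf$tree_id)]
      used <- !is.na(mo$n_antithetica + mo$n_synthetica) &
        (mo$n_antithetica + mo$n_synthetica) > 0 & !is.na(idx) & !is.na(qv)
      pear <- pearsonQDistance(qv[used], trees$distance[idx][used])
      gl <- hostChoiceGLM(qv[used], trees$distance[idx][used],
                          mo$n_antithetica[used], mo$n_synthetica[used])
      p <- file.path(cfg$outputDir, "pollinator.tsv")
      write.table(gl, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit("pollinator", p)
      jsonlite::write_json(pear, file.path(cfg$outputDir, "pearson.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("pearson", file.path(cfg$outputDir, "pearson.json"))
    }
    NULL
  })

  manifest$outputs <- lapply(outputs, function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  mp <- file.path(cfg$outputDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fitToList <- function(f) {
  m <- bestModel(f)
  list(model = f@modelType, isNull = f@isNull, logLik = f@logLik, k = f@k,
       aic = as.list(f@aic),
       center = m@center, width = m@width, pmin = m@pmin, pmax = m@pmax,
       deltaL = m@deltaL, tauL = m@tauL, deltaR = m@deltaR, tauR = m@tauR,
       intervals = if (nrow(f@intervals))
         setNames(lapply(rownames(f@intervals),
                         function(p) as.numeric(f@intervals[p, ])),
                  rownames(f@intervals)) else NULL,
       rhat = as.list(f@rhat), converged = f@converged)
}
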