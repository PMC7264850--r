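#' @importFrom utils read.table write.table packageVersion
NULL

.readDelim <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}

#' Read a per-tree table (TSV)
#'
#' Generic reader for the tab-separated per-tree tables the pipeline
#' consumes (coordinates, hybrid index, traits, haplotypes, moth counts).
#' Requires a header containing \code{tree_id}.
#'
#' @param path file path.
#' @param sep field separator (tab; pass "," for CSV coordinates).
#' @return data.frame.
#' @export
readTreeTable <- function(path, sep = "\t") {
  out <- .readDelim(path, sep)
  if (!"tree_id" %in% names(out))
    stop("table must carry a 'tree_id' column: ", path)
  if (anyDuplicated(out$tree_id))
    stop("duplicated tree id: ",
         out$tree_id[duplicated(out$tree_id)][1])
  out
}

#' Read a genotype matrix
#'
#' \code{tsv012}: tab-separated, first column \code{tree_id}, remaining
#' columns one locus each holding focal-allele counts 0/1/2 (\code{NA} for
#' missing). \code{vcf}: biallelic records of a VCF (via the vcfR package);
#' multiallelic sites are skipped with a message.
#'
#' @param path file path.
#' @param format \code{"tsv012"} or \code{"vcf"}.
#' @return integer matrix, loci as rows, trees as columns.
#' @export
readGenotypeMatrix <- function(path, format = c("tsv012", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(.readVcfGenotypes(path))
  tab <- readTreeTable(path)
  if (ncol(tab) < 2L) stop("genotype table has no locus columns: ", path)
  loci <- setdiff(names(tab), "tree_id")
  g <- t(as.matrix(tab[, loci, drop = FALSE]))
  bad <- which(!is.na(g) & !g %in% c(0, 1, 2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid genotype %s at locus '%s', tree '%s' (use 0/1/2/NA)",
                 g[bad[1, 1], bad[1, 2]], loci[bad[1, 1]],
                 tab$tree_id[bad[1, 2]]))
  storage.mode(g) <- "integer"
  dimnames(g) <- list(loci, tab$tree_id)
  g
}

.readVcfGenotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    message(sprintf("skipped %d multiallelic site(s)", sum(multi)))
  gt <- vcfR::extract.gt(v[!multi, ], element = "GT")
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  counts[clean %in% c("0/0")] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean %in% c("1/1")] <- 2L
  counts
}

#' Write a genotype matrix as tsv012
#'
#' @param genotypes integer matrix, loci x trees.
#' @param path output path.
#' @export
writeGenotypeMatrix <- function(genotypes, path) {
  tab <- data.frame(tree_id = colnames(genotypes),
                    t(genotypes), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read or write a bin table
#'
#' Bin tables travel as TSV with a header: \code{bin, distance, n, count}
#' for allele frequencies or \code{bin, distance, n, mean, variance} for
#' traits (the pipeline's HZAR-format analogue).
#'
#' @param path file path.
#' @return a [frequencyBinTable()] or [traitBinTable()], by column set.
#' @export
readBinTable <- function(path) {
  tab <- .readDelim(path, "\t")
  if (all(c("distance", "n", "count") %in% names(tab)))
    frequencyBinTable(tab$distance, tab$n, tab$count, bin = tab$bin)
  else if (all(c("distance", "n", "mean", "variance") %in% names(tab)))
    traitBinTable(tab$distance, tab$n, tab$mean, tab$variance, bin = tab$bin)
  else stop("unrecognized bin-table columns in ", path)
}

#' @rdname readBinTable
#' @param table a bin table.
#' @export
writeBinTable <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the standard input tables of a synthetic zone
#'
#' Emits the tabular files a field study would provide -- coordinates CSV,
#' genotype TSV (0/1/2/NA), hybrid-index TSV, traits TSV, chloroplast
#' haplotype TSV, moth trap TSV -- plus \code{truth.json} holding the
#' generating parameters for test harnesses.
#'
#' @param zone a [HybridZoneExperiment-class] from [generateZone()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
writeZoneTables <- function(zone, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  td <- treeData(zone)
  cfg <- S4Vectors::metadata(zone)$config
  paths <- c(
    coordinates = file.path(dir, "coordinates.csv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    hybrid_index = file.path(dir, "hybrid_index.tsv"),
    traits = file.path(dir, "traits.tsv"),
    haplotypes = file.path(dir, "haplotypes.tsv"),
    moths = file.path(dir, "moths.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write.table(data.frame(tree_id = td$treeId, x = td$x, y = td$y),
              paths["coordinates"], sep = ",", quote = FALSE,
              row.names = FALSE)
  writeGenotypeMatrix(genotypes(zone), paths["genotypes"])
  write.table(data.frame(tree_id = td$treeId, q = td$qTrue),
              paths["hybrid_index"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  traitCols <- if (!is.null(cfg)) cfg@traits$name
               else setdiff(names(td), c("treeId", "x", "y", "distanceTrue",
                                         "qTrue", "cpHaplotype", "flowering",
                                         "mothAntithetica", "mothSynthetica"))
  write.table(cbind(data.frame(tree_id = td$treeId),
                    td[, traitCols, drop = FALSE]),
              paths["traits"], sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  write.table(data.frame(tree_id = td$treeId, cp_haplotype = td$cpHaplotype),
              paths["haplotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write.table(data.frame(tree_id = td$treeId,
                         n_antithetica = td$mothAntithetica,
                         n_synthetica = td$mothSynthetica),
              paths["moths"], sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(cfg)) {
    truth <- list(
      trueCenter = cfg@trueCenter, trueWidth = cfg@trueWidth,
      contourShape = cfg@contourShape, snpPmin = cfg@snpPmin,
      snpPmax = cfg@snpPmax, fractionNull = cfg@fractionNull,
      cpCenterOffset = cfg@cpCenterOffset, cpWidth = cfg@cpWidth,
      seed = cfg@seed,
      loci = as.data.frame(rowData(zone))
    )
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  } else paths <- paths[names(paths) != "truth"]
  paths
}

#' Bin a per-tree character into an allele-frequency table
#'
#' @param values per-tree focal-allele counts in \code{0..ploidy}
#'   (\code{NA} allowed), aligned with \code{binAssignment} rows.
#' @param binAssignment output of [makeBins()].
#' @param ploidy 2 for nuclear SNPs, 1 for a haploid chloroplast.
#' @return a [frequencyBinTable()].
#' @export
binnedFrequencyTable <- function(values, binAssignment, ploidy = 2L) {
  stopifnot(length(values) == nrow(binAssignment))
  keep <- !is.na(values)
  b <- binAssignment$bin[keep]
  v <- values[keep]
  d <- binAssignment$distance[keep]
  n <- tapply(v, b, length) * ploidy
  frequencyBinTable(distance = tapply(d, b, mean), n = n,
                    count = tapply(v, b, sum), bin = names(n))
}

#' Bin a standardized trait into a trait table
#'
#' @param values per-tree standardized trait values, aligned with
#'   \code{binAssignment} rows.
#' @param binAssignment output of [makeBins()].
#' @return a [traitBinTable()].
#' @export
binnedTraitTable <- function(values, binAssignment) {
  stopifnot(length(values) == nrow(binAssignment))
  keep <- !is.na(values)
  b <- binAssignment$bin[keep]
  v <- values[keep]
  d <- binAssignment$distance[keep]
  n <- tapply(v, b, length)
  traitBinTable(distance = tapply(d, b, mean), n = n,
                mean = tapply(v, b, mean),
                variance = tapply(v, b, function(z) {
                  if (length(z) > 1) var(z) else NA_real_
                }),
                bin = names(n))
}

#' Summarize fitted clines in a publication-style table
#'
#' One row per character, sorted by center: best model, center, width, the
#' center's 2-log-likelihood interval, and the two end values (pmin on the
#' western, pmax on the eastern side).
#'
#' @param fits named list of [ClineFit-class]s.
#' @param path optional TSV output path.
#' @return data.frame (invisibly written to \code{path} when given).
#' @export
writeTable2Style <- function(fits, path = NULL) {
  if (!length(fits)) stop("need at least one fit")
  nm <- names(fits)
  if (is.null(nm)) nm <- sprintf("cline%d", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    m <- bestModel(f)
    iv <- supportIntervals(f)
    hasC <- "center" %in% rownames(iv)
    data.frame(character = nm[i], best_model = f@modelType,
               center = m@center, width = m@width,
               center_low = if (hasC) iv["center", "low"] else NA_real_,
               center_high = if (hasC) iv["center", "high"] else NA_real_,
               pmin_west = m@pmin, pmax_east = m@pmax,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$center), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  out
}
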