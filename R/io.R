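## Schema-checked table reading. All on-disk tables are UTF-8 with a header
## row; missing values are encoded "NA". Error messages carry 1-based file
## line numbers (header = line 1).
.readTable <- function(path, columns, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          na.strings = "NA", fileEncoding = "UTF-8")
  miss <- setdiff(columns, names(df))
  if (length(miss))
    stop(basename(path), ": missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

.writeTable <- function(df, path, sep) {
  ## numeric columns keep >= 15 significant digits through as.character()
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

.dupLines <- function(values, what, path) {
  dup <- which(duplicated(values))
  if (length(dup))
    stop(basename(path), ": duplicate ", what, " '", values[dup[1L]],
         "' at line ", dup[1L] + 1L)
}

#' Read / write a marker map
#'
#' Tab-separated, header \code{marker\tchrom\tpos\tallele_A\tallele_B},
#' 1-based positions, strictly increasing within chromosome.
#'
#' @param path File path.
#' @param geneticRate Map rate in cM per kb to attach (default 0.35); the
#'   on-disk format carries coordinates only.
#'
#' @return [readMarkerMap()] returns a [MarkerMap-class];
#'   [writeMarkerMap()] returns \code{path} invisibly.
#' @export
readMarkerMap <- function(path, geneticRate = 0.35) {
  df <- .readTable(path, c("marker", "chrom", "pos", "allele_A", "allele_B"),
                   sep = "\t")
  .dupLines(df$marker, "marker id", path)
  bychrom <- split(seq_len(nrow(df)), factor(df$chrom, unique(df$chrom)))
  for (rows in bychrom) {
    bad <- which(diff(df$pos[rows]) <= 0)
    if (length(bad))
      stop(basename(path), ": positions not strictly increasing at line ",
           rows[bad[1L] + 1L] + 1L, " (", df$chrom[rows[1L]], ")")
  }
  MarkerMap(df$marker, df$chrom, df$pos, df$allele_A, df$allele_B,
            geneticRate = geneticRate)
}

#' @rdname readMarkerMap
#' @param map A [MarkerMap-class].
#' @export
writeMarkerMap <- function(map, path) {
  mc <- S4Vectors::mcols(markerRanges(map))
  .writeTable(data.frame(marker = markerIds(map), chrom = markerChrom(map),
                         pos = markerPos(map),
                         allele_A = mc$allele_A, allele_B = mc$allele_B,
                         stringsAsFactors = FALSE),
              path, sep = "\t")
}

#' Read / write a genotype matrix
#'
#' Tab-separated matrix: first column \code{marker}, one column per strain,
#' cells "A"/"B", rows in map order.
#'
#' @param path File path.
#' @param map The [MarkerMap-class] the genotypes are defined on.
#'
#' @return [readGenotypes()] returns a [SegregantPopulation-class];
#'   [writeGenotypes()] returns \code{path} invisibly.
#' @export
readGenotypes <- function(path, map) {
  df <- .readTable(path, "marker", sep = "\t")
  .dupLines(df$marker, "marker id", path)
  if (!identical(df$marker, markerIds(map)))
    stop(basename(path), ": marker column does not match the map order")
  g <- as.matrix(df[, setdiff(names(df), "marker"), drop = FALSE])
  rownames(g) <- df$marker
  .dupLines(colnames(g), "strain id", path)
  methods::new("SegregantPopulation", genotypes = g, map = map)
}

#' @rdname readGenotypes
#' @param population A [SegregantPopulation-class].
#' @export
writeGenotypes <- function(population, path) {
  g <- genotypes(population)
  .writeTable(data.frame(marker = rownames(g), g, check.names = FALSE,
                         stringsAsFactors = FALSE),
              path, sep = "\t")
}

#' Read / write a phenotype table
#'
#' Comma-separated with header \code{strain,co2_at_checkpoint,group}; group
#' is one of parentA, parentB, segregant, hybrid.
#'
#' @param path File path.
#'
#' @return [readPhenotypes()] returns the data.frame;
#'   [writePhenotypes()] returns \code{path} invisibly.
#' @export
readPhenotypes <- function(path) {
  df <- .readTable(path, c("strain", "co2_at_checkpoint", "group"), sep = ",")
  .dupLines(df$strain, "strain id", path)
  ok <- df$group %in% c("parentA", "parentB", "segregant", "hybrid")
  if (!all(ok))
    stop(basename(path), ": invalid group '", df$group[which(!ok)[1L]],
         "' at line ", which(!ok)[1L] + 1L)
  df
}

#' @rdname readPhenotypes
#' @param phenotypes data.frame with the three schema columns.
#' @export
writePhenotypes <- function(phenotypes, path) {
  .writeTable(phenotypes[, c("strain", "co2_at_checkpoint", "group")],
              path, sep = ",")
}

#' Read / write a fermentation curve
#'
#' Comma-separated; either \code{time_h,co2_g_per_L} (a converted curve) or
#' \code{time_h,mass_g} (raw fermenter mass, convert with [co2FromMass()]).
#'
#' @param path File path.
#' @param volume_L Fermentation volume, used when the file holds a mass
#'   series (default 1.2 L).
#'
#' @return [readCurve()] returns a [FermentationCurve-class];
#'   [writeCurve()] returns \code{path} invisibly.
#' @export
readCurve <- function(path, volume_L = 1.2) {
  df <- .readTable(path, "time_h", sep = ",")
  if ("co2_g_per_L" %in% names(df)) {
    if (any(diff(df$time_h) <= 0))
      stop(basename(path), ": time not strictly increasing")
    cv <- FermentationCurve(df$time_h, df$co2_g_per_L)
    if ("rate_g_per_L_h" %in% names(df)) cv@rate <- df$rate_g_per_L_h
    cv
  } else if ("mass_g" %in% names(df)) {
    co2FromMass(df$time_h, df$mass_g, volume_L)
  } else {
    stop(basename(path), ": need a co2_g_per_L or mass_g column")
  }
}

#' @rdname readCurve
#' @param curve A [FermentationCurve-class].
#' @export
writeCurve <- function(curve, path) {
  df <- data.frame(time_h = curveTime(curve), co2_g_per_L = curveCO2(curve))
  if (length(curveRate(curve))) df$rate_g_per_L_h <- curveRate(curve)
  .writeTable(df, path, sep = ",")
}

#' Read / write an allelic-difference signal table
#'
#' Tab-separated with header \code{probe\tchrom\tpos\tsample\tblock\td}.
#'
#' @param path File path.
#' @param normalized Whether the stored values are already
#'   parental-anchor normalized (default FALSE).
#'
#' @return [readSignals()] returns an [AllelicDifferenceTable-class];
#'   [writeSignals()] returns \code{path} invisibly.
#' @export
readSignals <- function(path, normalized = FALSE) {
  df <- .readTable(path, c("probe", "chrom", "pos", "sample", "block", "d"),
                   sep = "\t")
  bad <- !df$sample %in% .ADT_SAMPLES
  if (any(bad))
    stop(basename(path), ": invalid sample '", df$sample[which(bad)[1L]],
         "' at line ", which(bad)[1L] + 1L)
  methods::new("AllelicDifferenceTable", data = df, normalized = normalized)
}

#' @rdname readSignals
#' @param x An [AllelicDifferenceTable-class].
#' @export
writeSignals <- function(x, path) {
  .writeTable(adtData(x), path, sep = "\t")
}

#' Write called regions as BED and as a statistics TSV
#'
#' The BED file converts the 1-based inclusive region coordinates to BED's
#' 0-based half-open convention (\code{start - 1}, \code{end}); the score
#' column is \code{-log10(min adjusted p)}. The TSV keeps 1-based inclusive
#' coordinates together with the full per-region statistics and enrichment
#' directions.
#'
#' @param regions A \link[GenomicRanges]{GRanges} from [callRegions()].
#' @param path Output path (\code{.bed} or \code{.tsv} per function).
#'
#' @return \code{path}, invisibly.
#' @export
writeRegionsBED <- function(regions, path) {
  n <- length(regions)
  mc <- S4Vectors::mcols(regions)
  df <- data.frame(
    chrom = if (n) as.character(GenomicRanges::seqnames(regions)) else character(),
    start = if (n) GenomicRanges::start(regions) - 1L else integer(),
    end = if (n) GenomicRanges::end(regions) else integer(),
    name = if (n) sprintf("region_%03d", seq_len(n)) else character(),
    score = if (n) -log10(pmax(mc$min_adj_p, .Machine$double.xmin)) else numeric(),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeRegionsBED
#' @export
writeRegionsTSV <- function(regions, path) {
  n <- length(regions)
  mc <- as.data.frame(S4Vectors::mcols(regions))
  df <- cbind(
    data.frame(
      chrom = if (n) as.character(GenomicRanges::seqnames(regions)) else character(),
      start_bp = if (n) GenomicRanges::start(regions) else integer(),
      end_bp = if (n) GenomicRanges::end(regions) else integer(),
      stringsAsFactors = FALSE),
    mc)
  .writeTable(df, path, sep = "\t")
}
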