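#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

## Sample labels allowed in an allelic-difference table.
.ADT_SAMPLES <- c("parentA", "parentB", "bulk_low", "bulk_high")

#' MarkerMap: the genomic scaffold of biallelic markers
#'
#' An ordered set of biallelic marker coordinates (one probe pair per marker)
#' together with the parental allele labels and a genome-wide genetic map
#' rate. Positions are 1-based. Marker order is the scan order: markers must
#' be strictly increasing in position within each chromosome.
#'
#' @slot markers A \link[GenomicRanges]{GRanges} of width-1 marker positions,
#'   named by marker id, with metadata columns \code{allele_A} and
#'   \code{allele_B} (the two parental alleles, which must differ).
#' @slot geneticRate Genetic map rate in cM per kb, applied genome-wide.
#'
#' @seealso [MarkerMap()], [yeastMarkerMap()]
#' @export
setClass("MarkerMap",
  slots = c(markers = "GRanges", geneticRate = "numeric"))

setValidity("MarkerMap", function(object) {
  gr <- object@markers
  msg <- character()
  if (length(object@geneticRate) != 1L || is.na(object@geneticRate) ||
      object@geneticRate < 0)
    msg <- c(msg, "geneticRate must be a single non-negative number (cM/kb)")
  if (length(gr)) {
    ids <- names(gr)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msg <- c(msg, "every marker must have a non-empty id")
    else if (anyDuplicated(ids))
      msg <- c(msg, "marker ids must be unique")
    mc <- S4Vectors::mcols(gr)
    if (!all(c("allele_A", "allele_B") %in% colnames(mc)))
      msg <- c(msg, "markers need metadata columns allele_A and allele_B")
    else {
      if (any(as.character(mc$allele_A) == as.character(mc$allele_B)))
        msg <- c(msg, "markers must be biallelic (allele_A != allele_B)")
    }
    if (any(GenomicRanges::width(gr) != 1L))
      msg <- c(msg, "marker positions must be single base pairs")
    if (any(GenomicRanges::start(gr) < 1L))
      msg <- c(msg, "positions must be >= 1")
    pos <- GenomicRanges::start(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    bad <- unlist(lapply(split(pos, factor(chrom, unique(chrom))),
                         function(p) any(diff(p) <= 0)))
    if (any(bad))
      msg <- c(msg, paste0("positions must be strictly increasing within ",
                           "each chromosome (violated on ",
                           paste(names(bad)[bad], collapse = ", "), ")"))
  }
  if (length(msg)) msg else TRUE
})

#' SegregantPopulation: haploid genotypes of an F2 cross
#'
#' Per-marker parental-origin calls for a set of haploid segregants. Origins
#' are coded \code{"A"} (high-capacity parent 2029-C5 lineage) or \code{"B"}
#' (low-capacity parent 1782-B1 lineage).
#'
#' @slot genotypes Character matrix, rows = markers (in map order),
#'   columns = strains, values in \code{c("A","B")}.
#' @slot map The [MarkerMap-class] the genotypes are defined on.
#'
#' @export
setClass("SegregantPopulation",
  slots = c(genotypes = "matrix", map = "MarkerMap"))

setValidity("SegregantPopulation", function(object) {
  g <- object@genotypes
  msg <- character()
  if (!is.character(g))
    msg <- c(msg, "genotypes must be a character matrix")
  else if (!all(g %in% c("A", "B")))
    msg <- c(msg, "genotype values must be 'A' or 'B'")
  if (nrow(g) != nMarkers(object@map))
    msg <- c(msg, "genotype rows must match the marker count of the map")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msg <- c(msg, "strains must have unique ids (column names)")
  if (length(msg)) msg else TRUE
})

#' QTLEffectModel: planted phenotype architecture
#'
#' The additive (optionally epistatic) genetic model used by
#' [assignPhenotypes()]. Each locus contributes \code{effect} phenotype units
#' when a segregant carries the beneficial parental origin at the nearest
#' marker.
#'
#' @slot loci data.frame with columns \code{chrom}, \code{pos},
#'   \code{effect}, \code{beneficial} ("A" or "B").
#' @slot interactions data.frame with columns \code{locus1}, \code{locus2}
#'   (row indices into \code{loci}) and \code{effect}; the pairwise term is
#'   added when both loci carry their beneficial origin. Empty by default.
#' @slot baseline Baseline phenotype (g CO2 per L at the checkpoint).
#' @slot targetH2 Target broad-sense heritability, in (0, 1].
#' @slot envSdParent Environmental sd of parental replicate measurements; if
#'   \code{NA}, the sd derived from \code{targetH2} is used.
#'
#' @export
setClass("QTLEffectModel",
  slots = c(loci = "data.frame", interactions = "data.frame",
            baseline = "numeric", targetH2 = "numeric",
            envSdParent = "numeric"))

setValidity("QTLEffectModel", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "effect", "beneficial")
  if (!all(need %in% names(object@loci)))
    msg <- c(msg, paste("loci must have columns:", paste(need, collapse = ", ")))
  else if (nrow(object@loci) && !all(object@loci$beneficial %in% c("A", "B")))
    msg <- c(msg, "beneficial origin must be 'A' or 'B'")
  if (nrow(object@interactions) &&
      !all(c("locus1", "locus2", "effect") %in% names(object@interactions)))
    msg <- c(msg, "interactions must have columns locus1, locus2, effect")
  if (length(object@targetH2) != 1L || is.na(object@targetH2) ||
      object@targetH2 <= 0 || object@targetH2 > 1)
    msg <- c(msg, "targetH2 must lie in (0, 1]")
  if (length(object@baseline) != 1L || is.na(object@baseline))
    msg <- c(msg, "baseline must be a single number")
  if (length(object@envSdParent) != 1L ||
      (!is.na(object@envSdParent) && object@envSdParent < 0))
    msg <- c(msg, "envSdParent must be a single non-negative number or NA")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: sizes and noise levels of the simulated study
#'
#' Defaults mirror the study design: 133 F2 segregants, two bulks of 15,
#' 8 replicate blocks per array and 3 replicate fermentations per parent.
#'
#' @slot seed Integer seed used by [runPipeline()] to derive per-stage
#'   substreams.
#' @slot nSegregants Number of F2 haploid segregants (default 133).
#' @slot bulkSize Segregants per phenotypic bulk (default 15).
#' @slot nBlocks Replicate blocks per probe and sample on the array
#'   (default 8).
#' @slot probeNoiseSd Gaussian probe noise sd, log-ratio units (default 0.1).
#' @slot nParentReplicates Replicate phenotype measurements per parent
#'   (default 3).
#'
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", nSegregants = "integer", bulkSize = "integer",
            nBlocks = "integer", probeNoiseSd = "numeric",
            nParentReplicates = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nSegregants = object@nSegregants, bulkSize = object@bulkSize,
           nBlocks = object@nBlocks,
           nParentReplicates = object@nParentReplicates)
  if (anyNA(cnt) || any(cnt < 1L))
    msg <- c(msg, "all counts must be positive integers")
  if (!anyNA(cnt) && 2L * object@bulkSize > object@nSegregants)
    msg <- c(msg, "need 2*bulkSize <= nSegregants")
  if (object@nParentReplicates < 2L)
    msg <- c(msg, "nParentReplicates must be >= 2")
  if (is.na(object@probeNoiseSd) || object@probeNoiseSd < 0)
    msg <- c(msg, "probeNoiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FermentationCurve: cumulative CO2 release over time
#'
#' @slot time Time since inoculation, hours, strictly increasing.
#' @slot co2 Cumulative CO2 released, g per L, non-decreasing.
#' @slot rate CO2 production rate, g per L per h; \code{NA} where the
#'   trailing estimation window is incomplete. Length 0 until [co2Rate()]
#'   has been applied.
#'
#' @export
setClass("FermentationCurve",
  slots = c(time = "numeric", co2 = "numeric", rate = "numeric"))

setValidity("FermentationCurve", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@co2) != n)
    msg <- c(msg, "time and co2 must have equal length")
  if (n >= 2L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(object@rate) && length(object@rate) != n)
    msg <- c(msg, "rate, when present, must have the same length as time")
  if (length(msg)) msg else TRUE
})

#' AllelicDifferenceTable: normalized allelic-difference signals
#'
#' Long-format table of per-probe allelic-difference values \code{d}
#' (difference of centered log2 ratios between the two allele-specific probes
#' of a locus) for the two parents and the two phenotypic bulks, with one row
#' per probe, sample and replicate block. After [normalizeParental()] the
#' parentA mean is exactly +1.5 and the parentB mean exactly -1.5.
#'
#' @slot data data.frame with columns \code{probe}, \code{chrom}, \code{pos},
#'   \code{sample} (one of parentA, parentB, bulk_low, bulk_high),
#'   \code{block}, \code{d}.
#' @slot normalized Has the parental-anchor normalization been applied?
#'
#' @export
setClass("AllelicDifferenceTable",
  slots = c(data = "data.frame", normalized = "logical"))

setValidity("AllelicDifferenceTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("probe", "chrom", "pos", "sample", "block", "d")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(d$sample %in% .ADT_SAMPLES))
    msg <- c(msg, paste("sample labels must be among:",
                        paste(.ADT_SAMPLES, collapse = ", ")))
  if (!is.numeric(d$d) || !is.numeric(d$pos))
    msg <- c(msg, "columns pos and d must be numeric")
  if (nrow(d)) {
    tab <- table(unique(d[, c("probe", "sample")])$probe)
    nsamp <- length(unique(d$sample))
    if (any(tab < nsamp))
      msg <- c(msg, "every probe needs at least one row per sample")
  }
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "normalized must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' ScanParameters: tuning of the bulk-segregant scan
#'
#' @slot windowSize Probes per sliding window (default 20).
#' @slot probeAlpha BH-adjusted p threshold of the one-tailed parental probe
#'   test (default 0.05).
#' @slot windowAlpha BH-adjusted p threshold of the window t tests
#'   (default 0.01).
#' @slot parentalFraction Fraction of the parental allelic difference the
#'   bulk difference must exceed at a retained probe (default 1/3; the
#'   stricter published alternative is 1/2).
#' @slot step Window step in probes (default 1, maximally overlapping).
#' @slot mergeGap Retained probes separated by at most this many
#'   non-retained informative probes are merged into one region (default 2).
#'
#' @export
setClass("ScanParameters",
  slots = c(windowSize = "integer", probeAlpha = "numeric",
            windowAlpha = "numeric", parentalFraction = "numeric",
            step = "integer", mergeGap = "integer"))

setValidity("ScanParameters", function(object) {
  msg <- character()
  if (is.na(object@windowSize) || object@windowSize < 2L)
    msg <- c(msg, "windowSize must be >= 2")
  for (a in c("probeAlpha", "windowAlpha")) {
    v <- slot(object, a)
    if (is.na(v) || v <= 0 || v >= 1)
      msg <- c(msg, paste(a, "must lie in (0, 1)"))
  }
  pf <- object@parentalFraction
  if (is.na(pf) || pf <= 0 || pf > 1)
    msg <- c(msg, "parentalFraction must lie in (0, 1]")
  if (is.na(object@step) || object@step < 1L)
    msg <- c(msg, "step must be >= 1")
  if (is.na(object@mergeGap) || object@mergeGap < 0L)
    msg <- c(msg, "mergeGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' HeritabilityResult: broad-sense heritability estimate
#'
#' @slot H2Percent Broad-sense heritability in percent,
#'   \eqn{H^2 = 100 (Var_{seg} - Var_{env}) / Var_{seg}}. Reported
#'   unclipped; see \code{flagged}.
#' @slot varSeg Sample variance of the segregant phenotypes.
#' @slot varEnv Pooled (df-weighted) variance of the parental replicates.
#' @slot flagged TRUE when \code{varEnv > varSeg} (negative estimate).
#'
#' @export
setClass("HeritabilityResult",
  slots = c(H2Percent = "numeric", varSeg = "numeric", varEnv = "numeric",
            flagged = "logical"))

#' TransgressionResult: transgressive segregation summary
#'
#' Segregants beyond 2 pooled parental standard deviations outside the
#' parental means (boundary inclusive).
#'
#' @slot nHigh Count above \code{max(parental means) + 2 sigma}.
#' @slot nLow Count below \code{min(parental means) - 2 sigma}.
#' @slot percent 100 * (nHigh + nLow) / population size.
#' @slot sigma Pooled parental standard deviation.
#' @slot thresholds Named numeric, \code{c(low_cut=, high_cut=)}.
#'
#' @export
setClass("TransgressionResult",
  slots = c(nHigh = "integer", nLow = "integer", percent = "numeric",
            sigma = "numeric", thresholds = "numeric"))
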