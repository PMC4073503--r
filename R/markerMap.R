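#' Construct a marker map
#'
#' @param marker Character vector of unique marker ids.
#' @param chrom Chromosome label per marker (16 chromosomes in the default
#'   yeast map).
#' @param pos 1-based position in bp, strictly increasing within chromosome.
#' @param alleleA,alleleB Parental allele labels at each marker (must differ).
#' @param geneticRate Map-distance rate in cM per kb, applied genome-wide
#'   (default 0.35, a standard yeast-scale figure).
#'
#' @return A [MarkerMap-class].
#' @examples
#' mm <- MarkerMap(c("m1", "m2"), c("chrI", "chrI"), c(100L, 5000L),
#'                 c("A", "C"), c("G", "T"))
#' nMarkers(mm)
#' @export
MarkerMap <- function(marker, chrom, pos, alleleA, alleleB,
                      geneticRate = 0.35) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L))
  names(gr) <- as.character(marker)
  S4Vectors::mcols(gr)$allele_A <- as.character(alleleA)
  S4Vectors::mcols(gr)$allele_B <- as.character(alleleB)
  methods::new("MarkerMap", markers = gr, geneticRate = geneticRate)
}

## Approximate S288C chromosome lengths (bp), used by the default fixture.
.YEAST_CHROM_LEN <- c(
  chrI = 230218L,   chrII = 813184L,  chrIII = 316620L, chrIV = 1531933L,
  chrV = 576874L,   chrVI = 270161L,  chrVII = 1090940L, chrVIII = 562643L,
  chrIX = 439888L,  chrX = 745751L,   chrXI = 666816L,  chrXII = 1078177L,
  chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L)

#' Default yeast-scale marker map
#'
#' Builds a biallelic marker map spanning the 16 yeast chromosomes with
#' markers uniformly spaced within each chromosome and chromosome marker
#' counts proportional to physical length. The default emulates the array
#' used for the scan: 6,318 biallelic probe pairs.
#'
#' @param nMarkers Total marker count (default 6318).
#' @param geneticRate Map rate in cM per kb (default 0.35).
#'
#' @return A [MarkerMap-class].
#' @export
yeastMarkerMap <- function(nMarkers = 6318L, geneticRate = 0.35) {
  nMarkers <- as.integer(nMarkers)
  stopifnot(nMarkers >= 16L)
  len <- .YEAST_CHROM_LEN
  raw <- nMarkers * (as.numeric(len) / sum(as.numeric(len)))
  cnt <- pmax(1L, as.integer(floor(raw)))
  rem <- nMarkers - sum(cnt)
  if (rem > 0) {                      # largest remainders get the leftovers
    ord <- order(raw - floor(raw), decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(raw - floor(raw))
    take <- head(ord[cnt[ord] > 1L], -rem)
    cnt[take] <- cnt[take] - 1L
  }
  chrom <- rep(names(len), cnt)
  pos <- unlist(lapply(seq_along(len), function(i) {
    as.integer(round(seq(1, len[i], length.out = cnt[i] + 1L)[-1L]))
  }), use.names = FALSE)
  ids <- sprintf("%s_p%04d", chrom, unlist(lapply(cnt, seq_len)))
  ## Allele labels: alternating nucleotides; only distinctness matters.
  MarkerMap(ids, chrom, pos,
            alleleA = rep(c("A", "G"), length.out = nMarkers),
            alleleB = rep(c("T", "C"), length.out = nMarkers),
            geneticRate = geneticRate)
}

#' @describeIn MarkerMap-class Number of markers.
#' @param x,object A \code{MarkerMap}.
#' @export
nMarkers <- function(x) length(x@markers)

#' @describeIn MarkerMap-class Marker ids, in map order.
#' @export
markerIds <- function(x) names(x@markers)

#' @describeIn MarkerMap-class Chromosome label per marker.
#' @export
markerChrom <- function(x) as.character(GenomicRanges::seqnames(x@markers))

#' @describeIn MarkerMap-class 1-based position per marker.
#' @export
markerPos <- function(x) GenomicRanges::start(x@markers)

#' @describeIn MarkerMap-class Genetic map rate, cM per kb.
#' @export
geneticRate <- function(x) x@geneticRate

#' @describeIn MarkerMap-class Underlying \link[GenomicRanges]{GRanges}.
#' @export
markerRanges <- function(x) x@markers

setMethod("show", "MarkerMap", function(object) {
  chrom <- markerChrom(object)
  cat("MarkerMap with", nMarkers(object), "markers on",
      length(unique(chrom)), "chromosomes\n")
  cat("  genetic rate:", geneticRate(object), "cM/kb\n")
})

## Per-chromosome marker indices and inter-marker distances in Morgans.
## Computed once per population build; shared by all meioses.
.mapIntervals <- function(map) {
  chrom <- markerChrom(map)
  pos <- markerPos(map)
  idx <- split(seq_along(pos), factor(chrom, levels = unique(chrom)))
  morgansPerBp <- geneticRate(map) / 100 / 1000
  list(index = idx,
       dist = lapply(idx, function(i) diff(pos[i]) * morgansPerBp))
}

## Index of the marker nearest to (chrom, pos); errors if the chromosome is
## absent from the map.
.nearestMarker <- function(map, chrom, pos) {
  mchrom <- markerChrom(map)
  mpos <- markerPos(map)
  vapply(seq_along(chrom), function(i) {
    on <- which(mchrom == chrom[i])
    if (!length(on))
      stop("locus chromosome '", chrom[i], "' is not on the map")
    on[which.min(abs(mpos[on] - pos[i]))]
  }, integer(1))
}
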