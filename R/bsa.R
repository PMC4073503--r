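#' Scan parameters
#'
#' @param windowSize Probes per sliding window (default 20).
#' @param probeAlpha Adjusted-p threshold of the parental probe test
#'   (default 0.05).
#' @param windowAlpha Adjusted-p threshold of the window tests
#'   (default 0.01).
#' @param parentalFraction Required fraction of the parental allelic
#'   difference (default 1/3; 1/2 is the stricter published preset).
#' @param step Window step in probes (default 1).
#' @param mergeGap Largest run of non-retained informative probes bridged
#'   when merging retained probes into regions (default 2).
#'
#' @return A [ScanParameters-class].
#' @export
ScanParameters <- function(windowSize = 20L, probeAlpha = 0.05,
                           windowAlpha = 0.01, parentalFraction = 1 / 3,
                           step = 1L, mergeGap = 2L) {
  methods::new("ScanParameters", windowSize = as.integer(windowSize),
               probeAlpha = as.numeric(probeAlpha),
               windowAlpha = as.numeric(windowAlpha),
               parentalFraction = as.numeric(parentalFraction),
               step = as.integer(step), mergeGap = as.integer(mergeGap))
}

setMethod("show", "ScanParameters", function(object) {
  cat(sprintf(
    "ScanParameters: window %d (step %d), probe alpha %.3g, window alpha %.3g,\n  parental fraction %.4g, merge gap %d\n",
    object@windowSize, object@step, object@probeAlpha, object@windowAlpha,
    object@parentalFraction, object@mergeGap))
})

#' Construct an allelic-difference table
#'
#' @param data data.frame with columns \code{probe}, \code{chrom},
#'   \code{pos}, \code{sample}, \code{block}, \code{d}.
#' @param normalized Whether the parental-anchor normalization has already
#'   been applied (default FALSE).
#'
#' @return An [AllelicDifferenceTable-class].
#' @export
AllelicDifferenceTable <- function(data, normalized = FALSE) {
  methods::new("AllelicDifferenceTable",
               data = as.data.frame(data), normalized = normalized)
}

#' @describeIn AllelicDifferenceTable-class The underlying long-format
#'   data.frame.
#' @param x,object An \code{AllelicDifferenceTable}.
#' @export
adtData <- function(x) x@data

#' @describeIn AllelicDifferenceTable-class Has [normalizeParental()] been
#'   applied?
#' @export
isNormalized <- function(x) x@normalized

setMethod("show", "AllelicDifferenceTable", function(object) {
  d <- object@data
  cat("AllelicDifferenceTable:", length(unique(d$probe)), "probes,",
      length(unique(d$block)), "blocks,", nrow(d), "rows",
      if (object@normalized) "(normalized)" else "(raw)", "\n")
})

#' Center log2 ratios per block
#'
#' Computes \code{log2(green/red)} per probe and subtracts the block mean, so
#' each block's centered ratios sum to zero.
#'
#' @param raw data.frame with columns \code{probe}, \code{block},
#'   \code{green}, \code{red} (positive intensities); extra columns (e.g.
#'   \code{sample}) are preserved. When a \code{sample} column is present,
#'   centering is done within each sample-block combination (each array is
#'   centered on its own blocks).
#'
#' @return The input data.frame with an added column \code{ratio} (centered
#'   log2 ratio).
#' @export
centerLogRatios <- function(raw) {
  need <- c("probe", "block", "green", "red")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(raw$green <= 0 | raw$red <= 0))
    stop("intensities must be positive")
  r <- log2(raw$green / raw$red)
  grp <- if ("sample" %in% names(raw))
    interaction(raw$sample, raw$block, drop = TRUE)
  else factor(raw$block)
  raw$ratio <- r - stats::ave(r, grp)
  raw
}

#' Allelic differences at biallelic loci
#'
#' For each locus, subtracts the centered log2 ratio of the B-allele probe
#' from that of the A-allele probe within each block (and sample, when
#' present): \code{d = ratio(A probe) - ratio(B probe)}.
#'
#' @param centered data.frame from [centerLogRatios()] (columns \code{probe},
#'   \code{block}, \code{ratio}, optionally \code{sample}).
#' @param pairs data.frame probe-pair index with columns \code{locus},
#'   \code{probe_A}, \code{probe_B}.
#'
#' @return data.frame with columns \code{probe} (the locus id),
#'   \code{sample} (if present), \code{block} and \code{d}.
#' @export
allelicDifference <- function(centered, pairs) {
  need <- c("locus", "probe_A", "probe_B")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  hasSample <- "sample" %in% names(centered)
  rows <- split(seq_len(nrow(centered)), centered$probe)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ia <- rows[[as.character(pairs$probe_A[i])]]
    ib <- rows[[as.character(pairs$probe_B[i])]]
    if (is.null(ia) || is.null(ib))
      stop("locus '", pairs$locus[i], "': missing probe pair member")
    a <- centered[ia, , drop = FALSE]
    b <- centered[ib, , drop = FALSE]
    ka <- if (hasSample) paste(a$sample, a$block) else as.character(a$block)
    kb <- if (hasSample) paste(b$sample, b$block) else as.character(b$block)
    mi <- match(ka, kb)
    if (anyNA(mi))
      stop("locus '", pairs$locus[i],
           "': probe pair members measured in different blocks")
    res <- data.frame(probe = as.character(pairs$locus[i]),
                      block = a$block, d = a$ratio - b$ratio[mi],
                      stringsAsFactors = FALSE)
    if (hasSample) res$sample <- a$sample
    res
  }))
  rownames(out) <- NULL
  out
}

#' Parental-anchor normalization
#'
#' Solves the single affine map \code{d' = a d + b} that sends the mean of
#' all parentA rows to +1.5 and the mean of all parentB rows to -1.5, and
#' applies it to every sample. After normalization the parental means are
#' exactly +/-1.5 (to numerical tolerance).
#'
#' @param x An [AllelicDifferenceTable-class] whose raw parental means
#'   differ.
#'
#' @return The normalized [AllelicDifferenceTable-class].
#' @export
normalizeParental <- function(x) {
  d <- x@data
  mA <- mean(d$d[d$sample == "parentA"])
  mB <- mean(d$d[d$sample == "parentB"])
  if (!is.finite(mA) || !is.finite(mB) || mA == mB)
    stop("degenerate normalization: parental means are equal (", mA, ")")
  a <- 3 / (mA - mB)
  b <- 1.5 - a * mA
  d$d <- a * d$d + b
  methods::new("AllelicDifferenceTable", data = d, normalized = TRUE)
}

## Per-probe summary statistics (n, mean, var of d over blocks) for one
## sample, aligned to the given probe order.
.probeStats <- function(dat, sample, probeLevels) {
  s <- dat[dat$sample == sample, ]
  f <- factor(s$probe, levels = probeLevels)
  n <- as.integer(table(f))
  sm <- as.numeric(rowsum(s$d, f))
  sq <- as.numeric(rowsum(s$d^2, f))
  mu <- sm / n
  v <- ifelse(n > 1L, (sq - n * mu^2) / (n - 1L), NA_real_)
  list(n = n, mean = mu, var = pmax(v, 0))
}

## Probes in genome order with their coordinates.
.probeIndex <- function(dat) {
  u <- unique(dat[, c("probe", "chrom", "pos")])
  u <- u[order(factor(u$chrom, levels = unique(u$chrom)), u$pos), ]
  rownames(u) <- NULL
  u
}

#' Select informative probes by the parental criterion
#'
#' Per probe, a one-tailed two-sample Welch t test of the alternative
#' \emph{mean d(parentA) > mean d(parentB)} over the replicate blocks,
#' followed by Benjamini-Hochberg adjustment across all probes. Probes with
#' adjusted p below \code{probeAlpha} are marked informative: their two
#' allele probes separate the parental genotypes reliably.
#'
#' @param x A (normalized) [AllelicDifferenceTable-class] with >= 2 replicate
#'   blocks per parent per probe.
#' @param probeAlpha Adjusted-p threshold (default 0.05).
#'
#' @return data.frame in genome order with columns \code{probe},
#'   \code{chrom}, \code{pos}, \code{t}, \code{df}, \code{p}, \code{adj_p},
#'   \code{selected}.
#' @export
selectParentalProbes <- function(x, probeAlpha = 0.05) {
  dat <- x@data
  pix <- .probeIndex(dat)
  a <- .probeStats(dat, "parentA", pix$probe)
  b <- .probeStats(dat, "parentB", pix$probe)
  if (any(a$n < 2L) || any(b$n < 2L))
    stop("parental t test undefined: need >= 2 replicate blocks per parent ",
         "per probe")
  se2 <- a$var / a$n + b$var / b$n
  delta <- a$mean - b$mean
  tstat <- ifelse(se2 > 0, delta / sqrt(se2),
                  ifelse(delta > 0, Inf, ifelse(delta < 0, -Inf, 0)))
  df <- ifelse(se2 > 0,
               se2^2 / ((a$var / a$n)^2 / (a$n - 1L) +
                        (b$var / b$n)^2 / (b$n - 1L)),
               a$n + b$n - 2L)
  p <- stats::pt(tstat, df, lower.tail = FALSE)   # H1: parentA > parentB
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(probe = pix$probe, chrom = pix$chrom, pos = pix$pos,
             t = tstat, df = df, p = p, adj_p = adj,
             selected = adj < probeAlpha, stringsAsFactors = FALSE,
             row.names = NULL)
}

## Per-probe bulk statistics table used by windowScan and callRegions:
## informative probes in genome order with per-probe means over blocks.
.bulkProbeTable <- function(x, informative) {
  dat <- x@data
  if (is.data.frame(informative))
    informative <- informative$probe[informative$selected]
  pix <- .probeIndex(dat)
  pix <- pix[pix$probe %in% informative, , drop = FALSE]
  if (!nrow(pix)) stop("no informative probes")
  lo <- .probeStats(dat, "bulk_low", pix$probe)
  hi <- .probeStats(dat, "bulk_high", pix$probe)
  pa <- .probeStats(dat, "parentA", pix$probe)
  pb <- .probeStats(dat, "parentB", pix$probe)
  data.frame(probe = pix$probe, chrom = pix$chrom, pos = pix$pos,
             mean_low = lo$mean, mean_high = hi$mean,
             bulk_diff = hi$mean - lo$mean,
             parent_diff = pa$mean - pb$mean,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sliding-window bulk comparison
#'
#' Builds sliding windows of \code{windowSize} informative probes (step
#' \code{step}) per chromosome, in positional order. In each window a paired
#' t test is applied to the per-probe differences of bulk means,
#' \code{mean d(bulk_high) - mean d(bulk_low)}, testing whether the window's
#' mean bulk difference departs from zero. P-values are Benjamini-Hochberg
#' adjusted across all windows genome-wide. A chromosome with fewer
#' informative probes than \code{windowSize} contributes a single truncated
#' window, flagged in the output.
#'
#' @param x A normalized [AllelicDifferenceTable-class].
#' @param informative The data.frame returned by [selectParentalProbes()]
#'   (or a character vector of informative probe ids).
#' @param params A [ScanParameters-class].
#'
#' @return data.frame with one row per window: \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{first_idx}, \code{last_idx}
#'   (indices into the informative-probe order), \code{n_probes},
#'   \code{mean_diff}, \code{t}, \code{p}, \code{adj_p}, \code{truncated}.
#' @export
windowScan <- function(x, informative, params = ScanParameters()) {
  bt <- .bulkProbeTable(x, informative)
  w <- params@windowSize
  step <- params@step
  chromLev <- unique(bt$chrom)
  res <- lapply(chromLev, function(ch) {
    rows <- which(bt$chrom == ch)
    xs <- bt$bulk_diff[rows]
    n <- length(xs)
    if (n < w) {
      starts <- 1L
      sizes <- n
      trunc <- TRUE
    } else {
      starts <- seq.int(1L, n - w + 1L, by = step)
      sizes <- rep(w, length(starts))
      trunc <- FALSE
    }
    cs <- c(0, cumsum(xs))
    cs2 <- c(0, cumsum(xs^2))
    ends <- starts + sizes - 1L
    m <- (cs[ends + 1L] - cs[starts]) / sizes
    ss <- (cs2[ends + 1L] - cs2[starts]) - sizes * m^2
    sdw <- sqrt(pmax(ss, 0) / (sizes - 1L))
    tstat <- ifelse(sdw > 0, m / (sdw / sqrt(sizes)),
                    ifelse(m == 0, 0, sign(m) * Inf))
    p <- 2 * stats::pt(abs(tstat), sizes - 1L, lower.tail = FALSE)
    data.frame(chrom = ch,
               start_bp = bt$pos[rows[starts]],
               end_bp = bt$pos[rows[ends]],
               first_idx = rows[starts], last_idx = rows[ends],
               n_probes = sizes, mean_diff = m, t = tstat, p = p,
               truncated = trunc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("chrom", "start_bp", "end_bp", "first_idx", "last_idx",
          "n_probes", "mean_diff", "t", "p", "adj_p", "truncated")]
}

#' Call QTL regions
#'
#' Retains informative probes that are covered by at least one window with
#' adjusted p below \code{windowAlpha} \emph{and} whose absolute bulk
#' difference exceeds \code{parentalFraction} times the absolute parental
#' difference at that probe. Retained probes are merged into regions along
#' each chromosome, bridging gaps of at most \code{mergeGap} non-retained
#' informative probes. Each region reports its peak probe (largest absolute
#' bulk difference), the smallest window adjusted p among windows overlapping
#' the region, the mean bulk difference, and the enriched parental origin of
#' each bulk (see [assignDirection()]).
#'
#' @inheritParams windowScan
#' @param windows The window table from [windowScan()] (recomputed when
#'   omitted).
#'
#' @return A \link[GenomicRanges]{GRanges} of called regions (1-based
#'   inclusive coordinates) with metadata columns \code{n_probes},
#'   \code{peak_probe}, \code{peak_pos}, \code{min_adj_p},
#'   \code{mean_bulk_difference}, \code{enriched_low}, \code{enriched_high}
#'   and \code{ambiguous_direction}.
#' @export
callRegions <- function(x, informative, params = ScanParameters(),
                        windows = NULL) {
  bt <- .bulkProbeTable(x, informative)
  if (is.null(windows)) windows <- windowScan(x, informative, params)
  nprobe <- nrow(bt)
  ## probe covered by >= 1 significant window
  covered <- logical(nprobe)
  minAdj <- rep(NA_real_, nprobe)
  sig <- windows[windows$adj_p < params@windowAlpha, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      idx <- sig$first_idx[i]:sig$last_idx[i]
      covered[idx] <- TRUE
      minAdj[idx] <- pmin(minAdj[idx], sig$adj_p[i], na.rm = TRUE)
    }
  }
  fracOK <- abs(bt$bulk_diff) > params@parentalFraction * abs(bt$parent_diff)
  retained <- covered & fracOK
  ## merge retained probes into regions per chromosome, bridging small gaps
  regions <- list()
  for (ch in unique(bt$chrom)) {
    rows <- which(bt$chrom == ch)
    keep <- which(retained[rows])
    if (!length(keep)) next
    brk <- c(0L, which(diff(keep) > params@mergeGap + 1L), length(keep))
    for (s in seq_len(length(brk) - 1L)) {
      kk <- keep[(brk[s] + 1L):brk[s + 1L]]
      memb <- rows[kk]                       # retained member probes
      peak <- memb[which.max(abs(bt$bulk_diff[memb]))]
      meanLow <- mean(bt$mean_low[memb])
      meanHigh <- mean(bt$mean_high[memb])
      dirOf <- function(m) if (m > 0) "A" else if (m < 0) "B" else NA_character_
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = min(bt$pos[memb]), end = max(bt$pos[memb]),
        n_probes = length(memb),
        peak_probe = bt$probe[peak], peak_pos = bt$pos[peak],
        min_adj_p = min(minAdj[memb], na.rm = TRUE),
        mean_bulk_difference = mean(bt$bulk_diff[memb]),
        enriched_low = dirOf(meanLow), enriched_high = dirOf(meanHigh),
        ambiguous_direction = meanLow == 0 || meanHigh == 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      n_probes = integer(), peak_probe = character(),
      peak_pos = integer(), min_adj_p = numeric(),
      mean_bulk_difference = numeric(), enriched_low = character(),
      enriched_high = character(), ambiguous_direction = logical())
    return(gr)
  }
  df <- do.call(rbind, regions)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    df[, c("n_probes", "peak_probe", "peak_pos", "min_adj_p",
           "mean_bulk_difference", "enriched_low", "enriched_high",
           "ambiguous_direction")])
  gr
}

#' Direction of enrichment of a called region
#'
#' For each bulk, the enriched parental origin over a region's probes is "A"
#' when the bulk's mean allelic difference across the region is positive
#' (the +1.5 parental pole) and "B" when negative. A mean of exactly zero is
#' flagged as ambiguous (\code{NA} origin).
#'
#' @param regions A \link[GenomicRanges]{GRanges} of regions (e.g. from
#'   [callRegions()]).
#' @param x The normalized [AllelicDifferenceTable-class].
#'
#' @return \code{regions} with recomputed metadata columns
#'   \code{enriched_low}, \code{enriched_high} and
#'   \code{ambiguous_direction}.
#' @export
assignDirection <- function(regions, x) {
  dat <- x@data
  lows <- highs <- numeric(length(regions))
  for (i in seq_along(regions)) {
    ch <- as.character(GenomicRanges::seqnames(regions))[i]
    from <- GenomicRanges::start(regions)[i]
    to <- GenomicRanges::end(regions)[i]
    inreg <- dat$chrom == ch & dat$pos >= from & dat$pos <= to
    lows[i] <- mean(dat$d[inreg & dat$sample == "bulk_low"])
    highs[i] <- mean(dat$d[inreg & dat$sample == "bulk_high"])
  }
  dirOf <- function(m) ifelse(m > 0, "A", ifelse(m < 0, "B", NA_character_))
  S4Vectors::mcols(regions)$enriched_low <- dirOf(lows)
  S4Vectors::mcols(regions)$enriched_high <- dirOf(highs)
  S4Vectors::mcols(regions)$ambiguous_direction <- lows == 0 | highs == 0
  regions
}

#' Run the full bulk-segregant scan
#'
#' Convenience chain: parental-anchor normalization (if not yet applied),
#' informative-probe selection, sliding-window scan and region calling.
#'
#' @param x An [AllelicDifferenceTable-class].
#' @param params A [ScanParameters-class].
#'
#' @return list with elements \code{table} (normalized table),
#'   \code{probes}, \code{windows} and \code{regions}.
#' @export
bsaScan <- function(x, params = ScanParameters()) {
  if (!isNormalized(x)) x <- normalizeParental(x)
  probes <- selectParentalProbes(x, params@probeAlpha)
  windows <- windowScan(x, probes, params)
  regions <- callRegions(x, probes, params, windows)
  list(table = x, probes = probes, windows = windows, regions = regions)
}
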