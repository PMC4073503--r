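test_that("log ratios are centered to zero mean within each block", {
  raw <- data.frame(probe = c("p1", "p2", "p1", "p2"),
                    block = c("b1", "b1", "b2", "b2"),
                    green = c(100, 400, 300, 300),
                    red = c(100, 400, 300, 300))
  expect_true(all(centerLogRatios(raw)$ratio == 0))   # green == red

  doubled <- within(raw, green <- 2 * red)            # ratio 1 everywhere
  expect_true(all(centerLogRatios(doubled)$ratio == 0))

  two <- data.frame(probe = c("p1", "p2"), block = "b1",
                    green = c(2, 8), red = c(1, 1))    # ratios 1 and 3
  expect_equal(centerLogRatios(two)$ratio, c(-1, 1))

  set.seed(60)
  rnd <- data.frame(probe = sprintf("p%02d", 1:40),
                    block = rep(c("b1", "b2"), each = 20),
                    green = runif(40, 10, 1000), red = runif(40, 10, 1000))
  cc <- centerLogRatios(rnd)
  expect_equal(as.numeric(tapply(cc$ratio, cc$block, sum)), c(0, 0),
               tolerance = 1e-12)

  raw$green[1] <- 0
  expect_error(centerLogRatios(raw), "positive")
})

test_that("allelic difference subtracts the B-allele probe ratio", {
  centered <- data.frame(
    probe = rep(c("pA1", "pB1", "pA2", "pB2"), 2),
    block = rep(c("b1", "b2"), each = 4),
    ratio = c(0.4, 0.4, 0.8, -0.7, 0.1, 0.1, 0.2, 0.2))
  pairs <- data.frame(locus = c("L1", "L2"),
                      probe_A = c("pA1", "pA2"),
                      probe_B = c("pB1", "pB2"))
  d <- allelicDifference(centered, pairs)
  expect_equal(d$d[d$probe == "L1" & d$block == "b1"], 0)   # equal signal
  expect_equal(d$d[d$probe == "L2" & d$block == "b1"], 1.5) # 0.8 - (-0.7)

  swapped <- pairs
  names(swapped)[2:3] <- c("probe_B", "probe_A")
  ds <- allelicDifference(centered, swapped)
  expect_equal(ds$d, -d$d)                                  # antisymmetry

  bad <- data.frame(locus = "L3", probe_A = "pA1", probe_B = "missing")
  expect_error(allelicDifference(centered, bad), "missing probe pair")
})

test_that("parental-anchor normalization is an exact affine map", {
  map <- smallMap()
  m <- nMarkers(map)

  # raw parental means 2 and 0: gain 1.5, offset -1.5; raw value 1 -> 0
  adt <- adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 2)
  dat <- adtData(adt)
  dat$d[dat$sample == "parentA"] <- 2
  dat$d[dat$sample == "parentB"] <- 0
  dat$d[dat$sample == "bulk_low"] <- 1
  shifted <- AllelicDifferenceTable(dat)
  nn <- normalizeParental(shifted)
  expect_true(all(adtData(nn)$d[adtData(nn)$sample == "bulk_low"] == 0))

  # anchors already at +/-1.5: identity
  anchored <- adtFromFreq(map, rep(0.2, m), rep(0.9, m), nBlocks = 2)
  id <- normalizeParental(anchored)
  expect_equal(adtData(id)$d, adtData(anchored)$d, tolerance = 1e-12)

  # exactness on arbitrary non-degenerate tables
  for (s in 1:5) {
    noisy <- adtFromFreq(map, runif(m), runif(m), nBlocks = 3,
                         noiseSd = 0.4, seed = 70 + s)
    dd <- adtData(noisy)
    dd$d <- 0.7 * dd$d + 2.3            # arbitrary raw scale
    nz <- normalizeParental(AllelicDifferenceTable(dd))
    out <- adtData(nz)
    expect_lt(abs(mean(out$d[out$sample == "parentA"]) - 1.5), 1e-9)
    expect_lt(abs(mean(out$d[out$sample == "parentB"]) + 1.5), 1e-9)
    expect_true(isNormalized(nz))
  }

  dd <- adtData(anchored)
  dd$d <- 0 * dd$d + 1                   # equal parental means
  expect_error(normalizeParental(AllelicDifferenceTable(dd)), "degenerate")
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.5), method = "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  for (s in 1:20) {
    set.seed(80 + s)
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("parental probe selection is a Welch one-tailed test with BH", {
  map <- smallMap(c(c1 = 12L))
  m <- nMarkers(map)
  adt <- adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 5,
                     noiseSd = 0.6, seed = 90)
  sel <- selectParentalProbes(adt, probeAlpha = 0.05)
  dat <- adtData(adt)
  for (pr in sel$probe[c(1, 5, 12)]) {
    a <- dat$d[dat$sample == "parentA" & dat$probe == pr]
    b <- dat$d[dat$sample == "parentB" & dat$probe == pr]
    tt <- t.test(a, b, alternative = "greater")
    i <- match(pr, sel$probe)
    expect_equal(sel$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(sel$p[i], tt$p.value, tolerance = 1e-9)
  }
  expect_equal(sel$adj_p, p.adjust(sel$p, method = "BH"))

  # null: parents indistinguishable -> selection rate bounded by alpha
  nullrate <- vapply(1:10, function(s) {
    dd <- adtData(adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 5,
                              noiseSd = 0.5, seed = 200 + s))
    dd$d[dd$sample %in% c("parentA", "parentB")] <-
      rnorm(sum(dd$sample %in% c("parentA", "parentB")))
    mean(selectParentalProbes(AllelicDifferenceTable(dd), 0.05)$selected)
  }, numeric(1))
  expect_lte(mean(nullrate), 0.05)

  # strong anchors: every probe is informative
  strong <- adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 5,
                        noiseSd = 0.05, seed = 91)
  expect_true(all(selectParentalProbes(strong, 0.05)$selected))

  one <- adtData(adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 1))
  expect_error(selectParentalProbes(AllelicDifferenceTable(one)),
               ">= 2 replicate blocks")
})

test_that("window construction follows the size/step combinatorics", {
  map <- smallMap(c(c1 = 40L))
  adt <- adtFromFreq(map, rep(0.5, 40), rep(0.5, 40), nBlocks = 3,
                     noiseSd = 0.1, seed = 100)
  inf <- markerIds(map)
  w1 <- windowScan(adt, inf, ScanParameters(windowSize = 20, step = 20))
  expect_identical(nrow(w1), 2L)
  w2 <- windowScan(adt, inf, ScanParameters(windowSize = 20, step = 1))
  expect_identical(nrow(w2), 21L)
  expect_false(any(w1$truncated))

  short <- smallMap(c(c1 = 5L))
  adts <- adtFromFreq(short, rep(0.5, 5), rep(0.5, 5), nBlocks = 3,
                      noiseSd = 0.1, seed = 101)
  ws <- windowScan(adts, markerIds(short), ScanParameters(windowSize = 20))
  expect_identical(nrow(ws), 1L)
  expect_true(ws$truncated)
  expect_identical(ws$n_probes, 5L)
})

test_that("window statistics equal the textbook paired t test", {
  map <- smallMap(c(c1 = 30L))
  m <- nMarkers(map)
  adt <- adtFromFreq(map, runif(m), runif(m), nBlocks = 4, noiseSd = 0.2,
                     seed = 110)
  ws <- windowScan(adt, markerIds(map), ScanParameters(windowSize = 10))
  dat <- adtData(adt)
  probeMean <- function(sample) {
    s <- dat[dat$sample == sample, ]
    tapply(s$d, factor(s$probe, levels = markerIds(map)), mean)
  }
  diffs <- probeMean("bulk_high") - probeMean("bulk_low")
  ord <- order(markerPos(map))
  for (i in c(1, 7, nrow(ws))) {
    x <- diffs[ord][ws$first_idx[i]:ws$last_idx[i]]
    tt <- t.test(x)                        # paired t == one-sample on diffs
    expect_equal(ws$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(ws$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(ws$mean_diff[i], unname(mean(x)), tolerance = 1e-12)
  }
  expect_equal(ws$adj_p, p.adjust(ws$p, method = "BH"))
})

test_that("a planted allele-frequency block drives window p far below 0.01", {
  map <- smallMap(c(c1 = 80L, c2 = 80L))
  m <- nMarkers(map)
  fLow <- rep(0.5, m); fHigh <- rep(0.5, m)
  inRegion <- which(markerChrom(map) == "c1")[26:55]   # 30-probe QTL block
  fLow[inRegion] <- 0                                   # bulk_low all B
  fHigh[inRegion] <- 1                                  # bulk_high all A
  adt <- adtFromFreq(map, fLow, fHigh, nBlocks = 8, noiseSd = 0.1,
                     seed = 120)
  sc <- bsaScan(adt)
  inside <- sc$windows$chrom == "c1" &
    sc$windows$start_bp >= markerPos(map)[inRegion[1]] &
    sc$windows$end_bp <= markerPos(map)[inRegion[30]]
  expect_true(any(inside))
  expect_true(all(sc$windows$adj_p[inside] < 1e-6))

  # region calling: exactly one region on that chromosome, covering the block
  reg <- sc$regions
  onC1 <- reg[as.character(GenomicRanges::seqnames(reg)) == "c1"]
  expect_length(onC1, 1L)
  expect_lte(GenomicRanges::start(onC1), markerPos(map)[inRegion[1]])
  expect_gte(GenomicRanges::end(onC1), markerPos(map)[inRegion[30]])
  expect_length(reg[as.character(GenomicRanges::seqnames(reg)) == "c2"], 0L)

  # direction: bulk_high is enriched for the A origin, bulk_low for B
  expect_identical(S4Vectors::mcols(onC1)$enriched_high, "A")
  expect_identical(S4Vectors::mcols(onC1)$enriched_low, "B")
})

test_that("region calling respects the null and the mixture bound", {
  map <- smallMap(c(c1 = 60L))
  m <- nMarkers(map)
  # identical bulks: nothing clears the parental-fraction threshold
  nullAdt <- adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 8,
                         noiseSd = 0.1, seed = 130)
  sc0 <- bsaScan(nullAdt)
  expect_length(sc0$regions, 0L)

  # parentalFraction = 1: strict mixtures can never exceed the parents
  mix <- adtFromFreq(map, rep(0.2, m), rep(0.8, m), nBlocks = 8,
                     noiseSd = 0, seed = 131)
  sc1 <- bsaScan(mix, ScanParameters(parentalFraction = 1))
  expect_length(sc1$regions, 0L)
})

test_that("enrichment direction follows the sign of the bulk mean", {
  map <- smallMap(c(c1 = 10L))
  m <- nMarkers(map)
  adt <- adtFromFreq(map, rep(0.1, m), rep(0.9, m), nBlocks = 4)
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1e6))
  out <- assignDirection(gr, adt)
  expect_identical(S4Vectors::mcols(out)$enriched_high, "A")  # mean +1.2
  expect_identical(S4Vectors::mcols(out)$enriched_low, "B")

  balanced <- adtFromFreq(map, rep(0.5, m), rep(0.5, m), nBlocks = 4)
  amb <- assignDirection(gr, balanced)
  expect_true(S4Vectors::mcols(amb)$ambiguous_direction)
})
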