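# Fixtures are built in code: small marker maps and directly constructed
# signal tables (pool allele frequencies chosen by the test).

# A compact two-chromosome map with evenly spaced markers.
smallMap <- function(nPerChrom = c(c1 = 30L, c2 = 20L), spacing = 5000L,
                     rate = 0.35) {
  chrom <- rep(names(nPerChrom), nPerChrom)
  pos <- unlist(lapply(nPerChrom, function(n) seq_len(n) * spacing),
                use.names = FALSE)
  ids <- sprintf("%s_m%03d", chrom,
                 unlist(lapply(nPerChrom, seq_len), use.names = FALSE))
  MarkerMap(ids, chrom, pos, alleleA = "A", alleleB = "T",
            geneticRate = rate)
}

# Signal table built directly from per-probe pool allele frequencies:
# parents are pure pools (f = 1 and f = 0), bulks follow fLow / fHigh.
adtFromFreq <- function(map, fLow, fHigh, nBlocks = 4L, noiseSd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nMarkers(map)
  stopifnot(length(fLow) == m, length(fHigh) == m)
  one <- function(f, sample) data.frame(
    probe = rep(markerIds(map), nBlocks),
    chrom = rep(markerChrom(map), nBlocks),
    pos = rep(markerPos(map), nBlocks),
    sample = sample,
    block = rep(sprintf("b%02d", seq_len(nBlocks)), each = m),
    d = rep(3 * f - 1.5, nBlocks) + rnorm(m * nBlocks, 0, noiseSd),
    stringsAsFactors = FALSE)
  AllelicDifferenceTable(
    rbind(one(rep(1, m), "parentA"), one(rep(0, m), "parentB"),
          one(fLow, "bulk_low"), one(fHigh, "bulk_high")))
}

# Brute-force Benjamini-Hochberg step-up: adjusted p_(i) =
# min_{j >= i} ( m p_(j) / j ), capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- running
  }
  adj
}

# Standard heritability estimate from an assignPhenotypes() table.
estimateH2 <- function(phen) {
  H2Percent(heritability(
    phen$co2_at_checkpoint[phen$group == "segregant"],
    phen$co2_at_checkpoint[phen$group == "parentA"],
    phen$co2_at_checkpoint[phen$group == "parentB"]))
}
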