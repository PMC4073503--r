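#' Simulation configuration
#'
#' @param seed Integer seed (used by [runPipeline()] to derive per-stage
#'   substreams; individual generators take their own \code{seed} argument).
#' @param nSegregants Number of F2 haploid segregants (default 133).
#' @param bulkSize Segregants per phenotypic bulk (default 15).
#' @param nBlocks Replicate blocks per probe and sample (default 8).
#' @param probeNoiseSd Gaussian probe noise sd in log-ratio units
#'   (default 0.1).
#' @param nParentReplicates Replicate phenotype measurements per parent
#'   (default 3).
#'
#' @return A [SimulationConfig-class].
#' @export
SimulationConfig <- function(seed = 1L, nSegregants = 133L, bulkSize = 15L,
                             nBlocks = 8L, probeNoiseSd = 0.1,
                             nParentReplicates = 3L) {
  methods::new("SimulationConfig", seed = as.integer(seed),
               nSegregants = as.integer(nSegregants),
               bulkSize = as.integer(bulkSize),
               nBlocks = as.integer(nBlocks),
               probeNoiseSd = as.numeric(probeNoiseSd),
               nParentReplicates = as.integer(nParentReplicates))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@nSegregants, "segregants, bulks of", object@bulkSize, "\n")
  cat("  blocks:", object@nBlocks,
      " probe noise sd:", object@probeNoiseSd,
      " parent replicates:", object@nParentReplicates,
      " seed:", object@seed, "\n")
})

#' Planted QTL effect model
#'
#' @param loci data.frame with columns \code{chrom}, \code{pos},
#'   \code{effect} (phenotype units added when the beneficial origin is
#'   carried) and \code{beneficial} ("A" or "B").
#' @param baseline Baseline phenotype, g CO2 per L at the checkpoint.
#' @param targetH2 Target broad-sense heritability in (0, 1].
#' @param envSdParent Environmental sd of parental replicate phenotypes;
#'   \code{NA} (default) uses the sd derived from \code{targetH2}.
#' @param interactions Optional data.frame (\code{locus1}, \code{locus2},
#'   \code{effect}) of pairwise interaction terms added when both loci carry
#'   their beneficial origin.
#'
#' @return A [QTLEffectModel-class].
#' @export
QTLEffectModel <- function(loci, baseline = 70, targetH2 = 0.98,
                           envSdParent = NA_real_,
                           interactions = data.frame(locus1 = integer(),
                                                     locus2 = integer(),
                                                     effect = numeric())) {
  methods::new("QTLEffectModel", loci = loci, interactions = interactions,
               baseline = as.numeric(baseline),
               targetH2 = as.numeric(targetH2),
               envSdParent = as.numeric(envSdParent))
}

setMethod("show", "QTLEffectModel", function(object) {
  cat("QTLEffectModel with", nrow(object@loci), "loci, baseline",
      object@baseline, ", target H2", object@targetH2, "\n")
  if (nrow(object@loci)) print(object@loci)
})

#' Default planted QTL architecture
#'
#' Four additive loci of equal effect placed at the midpoints of the mapped
#' regions (two on chrVII, one each on chrXIII and chrXIV). Three beneficial
#' alleles originate from parent B (the low-capacity lineage) and one from
#' parent A, mirroring the reported direction pattern.
#'
#' @param effect Effect size per locus, g CO2 per L (default 2).
#' @param baseline Baseline phenotype (default 70).
#' @param targetH2 Target broad-sense heritability (default 0.98).
#'
#' @return A [QTLEffectModel-class].
#' @export
defaultQTLModel <- function(effect = 2, baseline = 70, targetH2 = 0.98) {
  QTLEffectModel(
    loci = data.frame(
      chrom = c("chrVII", "chrVII", "chrXIII", "chrXIV"),
      pos = c(122908L, 683172L, 462216L, 392167L),
      effect = rep(as.numeric(effect), 4L),
      beneficial = c("A", "B", "B", "B"),
      stringsAsFactors = FALSE),
    baseline = baseline, targetH2 = targetH2)
}

## One gamete's strand-of-origin vector (0 = parent1, 1 = parent2) under a
## Poisson crossover process: the count of crossovers between adjacent
## markers at map distance d Morgans is Poisson(d), so the recombination
## fraction follows Haldane's function r = (1 - exp(-2 d)) / 2. The origin
## at each chromosome start is a fair coin.
.gameteSource <- function(iv) {
  src <- integer(sum(lengths(iv$index)))
  for (k in seq_along(iv$index)) {
    i <- iv$index[[k]]
    d <- iv$dist[[k]]
    x <- if (length(d)) stats::rpois(length(d), d) else integer()
    src[i] <- (stats::rbinom(1L, 1L, 0.5) + c(0L, cumsum(x))) %% 2L
  }
  src
}

#' Simulate one meiosis
#'
#' Produces a single recombinant haploid from two haploid parents defined on
#' the same marker map. Crossovers are placed per chromosome as a Poisson
#' process with intensity given by the map's genetic rate, so the
#' recombination fraction between markers at map distance \eqn{d} Morgans is
#' Haldane's \eqn{r = (1 - e^{-2d})/2}. The origin at each chromosome start
#' is chosen fairly at random.
#'
#' @param parent1,parent2 Character vectors of per-marker origins (any
#'   labels), equal in length to the map.
#' @param map A [MarkerMap-class].
#' @param seed Optional integer seed.
#'
#' @return Character vector of the recombinant haploid's per-marker origins.
#' @export
simulateMeiosis <- function(parent1, parent2, map, seed = NULL) {
  if (length(parent1) != nMarkers(map) || length(parent2) != nMarkers(map))
    stop("parent haplotypes must match the map length (",
         nMarkers(map), " markers)")
  if (!is.null(seed)) set.seed(seed)
  src <- .gameteSource(.mapIntervals(map))
  ifelse(src == 0L, parent1, parent2)
}

#' Simulate an F2 segregant population
#'
#' Reproduces the cross design: the two founder haploids (pure A and pure B)
#' are crossed; F1 haploids are produced by meiosis of the founder hybrid; F2
#' diploids are formed by random pairing of distinct F1 haploids; one haploid
#' spore per F2 diploid is sampled through a second meiosis.
#'
#' @param map A [MarkerMap-class].
#' @param config A [SimulationConfig-class].
#' @param seed Optional integer seed (deterministic output under a fixed
#'   seed).
#'
#' @return A [SegregantPopulation-class] with \code{config@nSegregants}
#'   strains.
#' @export
makeF2Population <- function(map, config = SimulationConfig(), seed = NULL) {
  n <- config@nSegregants
  if (n < 1L) stop("nSegregants must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  iv <- .mapIntervals(map)
  m <- nMarkers(map)
  nF1 <- max(2L, n)
  ## F1 haploids: gametes of the pure-A x pure-B founder hybrid, so the
  ## strand-of-origin vector *is* the genotype.
  f1 <- matrix("B", nrow = m, ncol = nF1)
  for (k in seq_len(nF1)) f1[.gameteSource(iv) == 0L, k] <- "A"
  geno <- matrix(NA_character_, nrow = m, ncol = n)
  for (k in seq_len(n)) {
    pair <- sample.int(nF1, 2L)      # distinct F1 parents of the F2 diploid
    src <- .gameteSource(iv)
    geno[, k] <- ifelse(src == 0L, f1[, pair[1L]], f1[, pair[2L]])
  }
  rownames(geno) <- markerIds(map)
  colnames(geno) <- sprintf("seg%03d", seq_len(n))
  methods::new("SegregantPopulation", genotypes = geno, map = map)
}

#' @describeIn SegregantPopulation-class Genotype matrix (markers x strains).
#' @param x,object A \code{SegregantPopulation}.
#' @export
genotypes <- function(x) x@genotypes

#' @describeIn SegregantPopulation-class Strain ids.
#' @export
strainIds <- function(x) colnames(x@genotypes)

#' @describeIn SegregantPopulation-class The underlying [MarkerMap-class].
#' @export
popMap <- function(x) x@map

setMethod("show", "SegregantPopulation", function(object) {
  cat("SegregantPopulation:", ncol(object@genotypes), "segregants x",
      nrow(object@genotypes), "markers\n")
})

#' Assign phenotypes under a planted QTL architecture
#'
#' The phenotype of each segregant is \code{baseline + sum(effect *
#' [origin at the marker nearest each locus == beneficial origin]) +
#' Gaussian noise}. The noise variance is derived from the realized genetic
#' variance of the population so that the expected broad-sense heritability
#' equals \code{model@targetH2}:
#' \eqn{\sigma^2_e = Var_g (1 - H^2) / H^2}. Parental replicate measurements
#' are emitted with sd \code{model@envSdParent} (defaulting to the same
#' derived sd).
#'
#' @param population A [SegregantPopulation-class].
#' @param model A [QTLEffectModel-class]; loci must lie on chromosomes of the
#'   population's map.
#' @param config A [SimulationConfig-class] (supplies
#'   \code{nParentReplicates}).
#' @param seed Optional integer seed.
#'
#' @return A data.frame with columns \code{strain},
#'   \code{co2_at_checkpoint} and \code{group} (\code{"segregant"},
#'   \code{"parentA"} or \code{"parentB"}); parental replicates appear as
#'   strains \code{parentA_r1}, ... The derived environmental sd is attached
#'   as attribute \code{"env_sd"}.
#' @export
assignPhenotypes <- function(population, model, config = SimulationConfig(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- popMap(population)
  geno <- genotypes(population)
  n <- ncol(geno)
  loci <- model@loci
  geneticValue <- function(gmat) {
    g <- numeric(ncol(gmat))
    if (nrow(loci)) {
      mi <- .nearestMarker(map, loci$chrom, loci$pos)
      carr <- gmat[mi, , drop = FALSE] ==
        matrix(loci$beneficial, nrow(loci), ncol(gmat))
      g <- as.numeric(crossprod(carr, loci$effect))
      if (nrow(model@interactions)) {
        for (r in seq_len(nrow(model@interactions))) {
          i1 <- model@interactions$locus1[r]
          i2 <- model@interactions$locus2[r]
          g <- g + model@interactions$effect[r] * (carr[i1, ] & carr[i2, ])
        }
      }
    }
    g
  }
  g <- geneticValue(geno)
  varG <- if (n >= 2L) stats::var(g) else 0
  h2 <- model@targetH2
  if (varG > 0) {
    envSd <- sqrt(varG * (1 - h2) / h2)
  } else {
    if (is.na(model@envSdParent))
      stop("no genetic variance and no envSdParent: environmental sd ",
           "cannot be derived from targetH2")
    envSd <- model@envSdParent
  }
  parentSd <- if (is.na(model@envSdParent)) envSd else model@envSdParent
  segv <- model@baseline + g + stats::rnorm(n, 0, envSd)
  m <- nMarkers(map)
  gA <- geneticValue(matrix("A", m, 1L))
  gB <- geneticValue(matrix("B", m, 1L))
  nr <- config@nParentReplicates
  pa <- model@baseline + gA + stats::rnorm(nr, 0, parentSd)
  pb <- model@baseline + gB + stats::rnorm(nr, 0, parentSd)
  out <- data.frame(
    strain = c(strainIds(population),
               sprintf("parentA_r%d", seq_len(nr)),
               sprintf("parentB_r%d", seq_len(nr))),
    co2_at_checkpoint = c(segv, pa, pb),
    group = c(rep("segregant", n), rep("parentA", nr), rep("parentB", nr)),
    stringsAsFactors = FALSE)
  attr(out, "env_sd") <- envSd
  out
}

#' Simulate a fermentation curve
#'
#' Generates a cumulative CO2 release curve whose value at the 89-h
#' checkpoint equals \code{capacity} exactly (at zero noise). The kinetic
#' shape is a gamma-CDF ramp: the production rate rises during the growth
#' phase, peaks, and declines through stationary phase, scaled so that a
#' higher capacity gives a strictly higher cumulative CO2 at every positive
#' time.
#'
#' @param capacity Phenotype: cumulative CO2 (g/L) at the 89-h checkpoint.
#' @param duration_h Total duration in hours (default 89).
#' @param step_min Sampling interval in minutes (default 20, the fermenter
#'   weighing interval).
#' @param noiseSd Additive measurement noise sd, g/L (default 0); noisy
#'   curves are clamped to their running maximum so cumulative CO2 stays
#'   non-decreasing.
#' @param seed Optional integer seed.
#'
#' @return A [FermentationCurve-class].
#' @export
simulateFermentationCurve <- function(capacity, duration_h = 89,
                                      step_min = 20, noiseSd = 0,
                                      seed = NULL) {
  if (duration_h <= 0) stop("duration_h must be positive")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration_h, by = step_min / 60)
  shape <- stats::pgamma(tt, shape = 2, scale = 20) /
    stats::pgamma(89, shape = 2, scale = 20)
  co2 <- capacity * shape
  if (noiseSd > 0) {
    co2 <- co2 + stats::rnorm(length(co2), 0, noiseSd)
    co2[1L] <- 0
    co2 <- cummax(pmax(co2, 0))
  }
  methods::new("FermentationCurve", time = tt, co2 = co2,
               rate = numeric())
}

#' Simulate pooled probe signals for one sample
#'
#' For each probe the pool's A-allele frequency \eqn{f} is computed from the
#' member genotypes and mapped linearly onto the normalized
#' allelic-difference scale, \eqn{d = 3f - 1.5} (so a pure-A pool sits at
#' +1.5, a pure-B pool at -1.5 and a balanced pool at 0). One noisy
#' replicate is emitted per block.
#'
#' @param bulk Character matrix of member genotypes (markers x strains,
#'   values "A"/"B"), e.g. a column subset of [genotypes()].
#' @param map The [MarkerMap-class].
#' @param config A [SimulationConfig-class] (supplies \code{nBlocks} and
#'   \code{probeNoiseSd}).
#' @param sample Sample label for the emitted rows (one of
#'   \code{"parentA"}, \code{"parentB"}, \code{"bulk_low"},
#'   \code{"bulk_high"}).
#' @param seed Optional integer seed.
#'
#' @return data.frame with columns probe, chrom, pos, sample, block, d.
#' @export
simulatePoolSignals <- function(bulk, map, config = SimulationConfig(),
                                sample = "bulk_high", seed = NULL) {
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1L)
  if (ncol(bulk) == 0L) stop("bulk must contain at least one genotype")
  if (nrow(bulk) != nMarkers(map))
    stop("bulk genotypes must match the map length")
  sample <- match.arg(sample, .ADT_SAMPLES)
  if (!is.null(seed)) set.seed(seed)
  f <- rowMeans(bulk == "A")
  d0 <- 3 * f - 1.5
  nb <- config@nBlocks
  m <- nMarkers(map)
  data.frame(
    probe = rep(markerIds(map), nb),
    chrom = rep(markerChrom(map), nb),
    pos = rep(markerPos(map), nb),
    sample = sample,
    block = rep(sprintf("b%02d", seq_len(nb)), each = m),
    d = rep(d0, nb) + stats::rnorm(m * nb, 0, config@probeNoiseSd),
    stringsAsFactors = FALSE)
}

#' Simulate the full four-sample signal table
#'
#' Convenience wrapper building an [AllelicDifferenceTable-class] holding
#' pooled signals for the two parents (pure-A and pure-B pools) and the two
#' phenotypic bulks.
#'
#' @param population A [SegregantPopulation-class].
#' @param lowIds,highIds Strain ids of the low and high bulks (e.g. from
#'   [selectBulks()]).
#' @param config A [SimulationConfig-class].
#' @param seed Optional integer seed.
#'
#' @return An [AllelicDifferenceTable-class] (not yet normalized).
#' @export
simulateSignalTable <- function(population, lowIds, highIds,
                                config = SimulationConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- popMap(population)
  geno <- genotypes(population)
  m <- nMarkers(map)
  pureA <- matrix("A", m, 1L)
  pureB <- matrix("B", m, 1L)
  dat <- rbind(
    simulatePoolSignals(pureA, map, config, "parentA"),
    simulatePoolSignals(pureB, map, config, "parentB"),
    simulatePoolSignals(geno[, lowIds, drop = FALSE], map, config,
                        "bulk_low"),
    simulatePoolSignals(geno[, highIds, drop = FALSE], map, config,
                        "bulk_high"))
  methods::new("AllelicDifferenceTable", data = dat, normalized = FALSE)
}
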