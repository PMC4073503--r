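test_that("meiosis with zero map rate returns an intact parental haplotype", {
  mm <- MarkerMap(sprintf("m%02d", 1:12), rep("c1", 12),
                  seq(1e4, 12e4, by = 1e4), "A", "T", geneticRate = 0)
  p1 <- rep(c("A", "B"), 6)          # distinguishable patterns
  p2 <- rep(c("B", "A"), 6)
  set.seed(11)
  got1 <- 0L
  for (i in 1:200) {
    g <- simulateMeiosis(p1, p2, mm)
    expect_true(identical(g, p1) || identical(g, p2))
    if (identical(g, p1)) got1 <- got1 + 1L
  }
  # fair coin per chromosome: 200 draws, 3 binomial SEs around 1/2
  expect_lt(abs(got1 / 200 - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("recombination between markers follows Haldane's map function", {
  # two markers 100 cM apart: d = 1 Morgan -> r = (1 - exp(-2))/2
  mm <- MarkerMap(c("m1", "m2"), c("c1", "c1"), c(1L, 285715L),
                  c("A", "A"), c("T", "T"), geneticRate = 0.35)
  expected <- (1 - exp(-2)) / 2
  set.seed(7)
  rec <- replicate(10000, {
    g <- simulateMeiosis(c("A", "A"), c("B", "B"), mm)
    g[1] != g[2]
  })
  expect_lt(abs(mean(rec) - expected),
            3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("meiosis rejects parents defined on a different map", {
  mm <- smallMap()
  expect_error(simulateMeiosis(rep("A", 3), rep("B", nMarkers(mm)), mm),
               "match the map length")
})

test_that("F2 population has the configured size and segregates 1:1", {
  map <- smallMap()
  cfg <- SimulationConfig(nSegregants = 133L)
  pop <- makeF2Population(map, cfg, seed = 5)
  expect_identical(dim(genotypes(pop)), c(nMarkers(map), 133L))
  expect_true(all(genotypes(pop) %in% c("A", "B")))

  # Mendelian segregation at scale: 1000 segregants, A-frequency ~ 1/2
  big <- makeF2Population(map, SimulationConfig(nSegregants = 1000L),
                          seed = 6)
  f <- rowMeans(genotypes(big) == "A")
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(f) - 0.5), 3 * se)
  expect_gt(mean(abs(f - 0.5) < 3 * se), 0.95)
})

test_that("population generation is deterministic under a fixed seed", {
  map <- smallMap()
  p1 <- makeF2Population(map, SimulationConfig(nSegregants = 40L), seed = 42)
  p2 <- makeF2Population(map, SimulationConfig(nSegregants = 40L), seed = 42)
  expect_identical(genotypes(p1), genotypes(p2))
})

test_that("phenotypes with no genetic variance give near-zero heritability", {
  map <- smallMap()
  pop <- makeF2Population(map, SimulationConfig(nSegregants = 133L),
                          seed = 2)
  model <- QTLEffectModel(
    loci = data.frame(chrom = "c1", pos = 50000L, effect = 0,
                      beneficial = "B"),
    baseline = 10, targetH2 = 0.98, envSdParent = 1)
  # single-seed estimates are noisy ratios; the mean should sit near zero,
  # far from any real genetic signal
  h2 <- vapply(1:10, function(s)
    estimateH2(assignPhenotypes(pop, model,
                                SimulationConfig(nParentReplicates = 50L),
                                seed = 100 + s)),
    numeric(1))
  expect_lt(abs(mean(h2)), 20)
})

test_that("a single noiseless locus yields two phenotype classes at 1:1", {
  map <- smallMap()
  pop <- makeF2Population(map, SimulationConfig(nSegregants = 133L),
                          seed = 9)
  model <- QTLEffectModel(
    loci = data.frame(chrom = "c1", pos = 50000L, effect = 10,
                      beneficial = "B"),
    baseline = 0, targetH2 = 1)    # H2 = 1 -> derived noise sd 0
  phen <- assignPhenotypes(pop, model, SimulationConfig(), seed = 10)
  segv <- phen$co2_at_checkpoint[phen$group == "segregant"]
  expect_setequal(unique(segv), c(0, 10))
  expect_lt(abs(mean(segv == 10) - 0.5), 3 * sqrt(0.25 / 133))
})

test_that("heritability calibration: estimates track the 98% target", {
  map <- yeastMarkerMap(1000L)     # same chromosomes, light marker set
  model <- defaultQTLModel()
  h2 <- vapply(1:20, function(s) {
    pop <- makeF2Population(map, SimulationConfig(), seed = 300 + s)
    estimateH2(assignPhenotypes(pop, model, SimulationConfig(),
                                seed = 600 + s))
  }, numeric(1))
  expect_lt(abs(mean(h2) - 98), 2)
})

test_that("pool signals are an exact affine map of pool allele frequency", {
  map <- smallMap()
  cfg <- SimulationConfig(nBlocks = 3L, probeNoiseSd = 0)
  m <- nMarkers(map)

  pureA <- matrix("A", m, 4L)
  sA <- simulatePoolSignals(pureA, map, cfg, "parentA")
  expect_true(all(sA$d == 1.5))

  half <- cbind(matrix("A", m, 5L), matrix("B", m, 5L))
  s0 <- simulatePoolSignals(half, map, cfg, "bulk_low")
  expect_true(all(s0$d == 0))

  bulk <- cbind(matrix("A", m, 12L), matrix("B", m, 3L))  # 12/15 A
  s12 <- simulatePoolSignals(bulk, map, cfg, "bulk_high")
  expect_equal(unique(s12$d), 3 * 0.8 - 1.5)              # = 0.9

  # affine in f for arbitrary mixtures
  set.seed(21)
  rnd <- matrix(sample(c("A", "B"), m * 15, replace = TRUE), m, 15)
  sr <- simulatePoolSignals(rnd, map, cfg, "bulk_high")
  f <- rowMeans(rnd == "A")
  expect_equal(sr$d, rep(3 * f - 1.5, cfg@nBlocks))
  expect_error(simulatePoolSignals(rnd[, 0], map, cfg), "at least one")
})

test_that("fermentation curves are monotone, ordered by capacity, and exact
           on the sampling grid", {
  c1 <- simulateFermentationCurve(60, duration_h = 89, step_min = 20)
  c2 <- simulateFermentationCurve(55, duration_h = 89, step_min = 20)
  expect_length(curveTime(c1), 268L)        # 89 h * 60 / 20 min + 1
  expect_true(all(diff(curveCO2(c1)) >= 0))
  expect_gt(phenotypeAt(c1, 89), phenotypeAt(c2, 89))
  expect_equal(phenotypeAt(c1, 89), 60)     # capacity anchored at 89 h

  n1 <- simulateFermentationCurve(60, noiseSd = 0.3, seed = 4)
  n2 <- simulateFermentationCurve(60, noiseSd = 0.3, seed = 4)
  expect_identical(curveCO2(n1), curveCO2(n2))
  expect_true(all(diff(curveCO2(n1)) >= 0))
})
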