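test_that("offspring of two distinct inbred strains are heterozygous wherever the strains differ", {
  map <- makeGeneticMap(1, 10, 50)
  founders <- rbind(rep(0L, 10), rep(1L, 10))
  founders[, 1] <- c(0L, 0L)  # one locus where the strains agree
  pop <- simulatePopulation(map, nStrains = 2, nFamilies = 1, litterSize = 2,
                            nGenerations = 1, founders = founders, seed = 5)
  off <- genotypeCodes(pop)[!is.na(pedTable(pop)$family), , drop = FALSE]
  expect_true(all(off[, -1] == 1L))
  expect_true(all(off[, 1] == 0L))
})

test_that("zero map distance never recombines: two-locus haplotypes stay parental", {
  map <- data.frame(locus_id = c("a", "b"), chromosome = 1L,
                    position_cM = c(10, 10.000))
  # strictly increasing positions are required; use an epsilon gap of 0.001
  map$position_cM <- c(10, 10.001)
  pop <- simulatePopulation(map, nStrains = 4, nFamilies = 10,
                            litterSize = 10, nGenerations = 4,
                            nBreeders = 20, seed = 7)
  # r over 0.001 cM is ~1e-5; with a few hundred meioses expect none
  parental <- rbind(pop@hap1[1:4, ], pop@hap2[1:4, ])
  pat <- unique(apply(parental, 1, paste, collapse = ""))
  obs <- unique(c(apply(pop@hap1, 1, paste, collapse = ""),
                  apply(pop@hap2, 1, paste, collapse = "")))
  expect_true(all(obs %in% pat))
})

test_that("recombination fraction at 50 cM matches the Haldane map function", {
  # 10,000 meioses between two loci 50 cM apart; informative double
  # heterozygote parent in known phase
  map <- data.frame(locus_id = c("a", "b"), chromosome = 1L,
                    position_cM = c(0, 50))
  founders <- rbind(c(1L, 1L), c(0L, 0L))
  pop <- simulatePopulation(map, nStrains = 2, nFamilies = 1000,
                            litterSize = 10, nGenerations = 2,
                            nBreeders = 2, founders = founders, seed = 11)
  ped <- pedTable(pop)
  off <- ped$id[ped$generation == 2]
  # both parents are F1 (1,1)/(0,0); a transmitted gamete is recombinant
  # iff its two alleles differ
  gam <- rbind(pop@hap1[off, ], pop@hap2[off, ])
  rf <- mean(gam[, 1] != gam[, 2])
  expect_equal(rf, 0.5 * (1 - exp(-1)), tolerance = 0.02 / 0.3161)
  expect_equal(nrow(gam), 20000)
})

test_that("gene dropping is Mendelian-consistent and deterministic given the seed", {
  st <- tinyStudy()
  expect_equal(mendelianConsistency(st), 1)
  map <- locusMap(st)
  pop2 <- simulatePopulation(makeGeneticMap(3, 30, 80), nStrains = 8,
                             nFamilies = 24, litterSize = 8,
                             nGenerations = 6, nBreeders = 40, seed = 42)
  expect_identical(genotypeCodes(pop2), genotypeCodes(st))
})

test_that("invalid maps and configurations are rejected", {
  expect_error(makeGeneticMap(1, 1, 50), "at least 2 loci")
  map <- makeGeneticMap(1, 5, 50)
  expect_error(simulatePopulation(map, nStrains = 1, seed = 1),
               "nStrains")
  expect_error(simulatePopulation(map, nGenerations = 0, seed = 1),
               "nGenerations")
})

test_that("degenerate architectures collapse the phenotype as expected", {
  st <- tinyStudy()
  pop <- new("SimulatedStudy", genotypes = st@genotypes, hap1 = st@hap1,
             hap2 = st@hap2, pedigree = st@pedigree,
             phenotypes = data.frame(), trueBreedingValues = matrix(0, 0, 0),
             qtl = list(), architectures = list())
  # no genetic or cage variance: phenotype = fixed effects + residual
  archNull <- traitArchitecture(additiveVariance = 0, dominanceVariance = 0,
                                epistaticVariance = 0, cageVariance = 0,
                                residualVariance = 1)
  s0 <- simulatePhenotypes(pop, list(T0 = archNull),
                           covariatePlan = list(gender = 0, age = 0,
                                                monthSD = 0, density = 0),
                           seed = 9)
  expect_equal(var(trueBreedingValues(s0, "T0")), 0)
  expect_equal(var(s0@phenotypes$T0), 1, tolerance = 1e-8)
  # purely additive, no residual, no covariates: phenotype = breeding value
  archAdd <- traitArchitecture(additiveVariance = 1, dominanceVariance = 0,
                               epistaticVariance = 0, cageVariance = 0,
                               residualVariance = 0)
  s1 <- simulatePhenotypes(pop, list(T1 = archAdd),
                           covariatePlan = list(gender = 0, age = 0,
                                                monthSD = 0, density = 0),
                           seed = 10)
  expect_equal(cor(s1@phenotypes$T1, trueBreedingValues(s1, "T1")), 1,
               tolerance = 1e-12)
  expect_error(traitArchitecture(additiveVariance = -1), "variances")
})

test_that("realized heritability and breeding-value regression hit their targets", {
  # Monte-Carlo oracle: h2 = 0.5 target, n ~ 2000, slope of phenotype on
  # true breeding value near 1
  arch <- traitArchitecture(additiveVariance = 0.5, dominanceVariance = 0,
                            epistaticVariance = 0, cageVariance = 0.1,
                            residualVariance = 0.4)
  h2s <- slopes <- numeric(5)
  map <- makeGeneticMap(3, 30, 80)
  for (i in seq_len(5)) {
    pop <- simulatePopulation(map, nFamilies = 200, litterSize = 10,
                              nGenerations = 5, nBreeders = 40, seed = 20 + i)
    s <- simulatePhenotypes(pop, list(TR = arch), seed = 30 + i)
    y <- s@phenotypes$TR
    tbv <- trueBreedingValues(s, "TR")
    h2s[i] <- var(tbv) / var(y)
    slopes[i] <- coef(lm(y ~ tbv))[2]
  }
  expect_lt(abs(mean(h2s) - 0.5), 0.07)
  expect_lt(abs(mean(slopes) - 1), 0.1)
})

test_that("linkage disequilibrium decays with map distance", {
  st <- tinyStudy()
  codes <- genotypeCodes(st)[st@phenotypes$id, ]
  map <- locusMap(st)
  sameChr <- outer(map$chromosome, map$chromosome, "==")
  dd <- abs(outer(map$position_cM, map$position_cM, "-"))
  r2 <- suppressWarnings(cor(codes))^2
  up <- upper.tri(r2) & sameChr & is.finite(r2)
  bins <- cut(dd[up], c(0, 5, 20, 80))
  means <- tapply(r2[up], bins, mean)
  expect_true(all(diff(means) < 0))
})

test_that("inbreeding accumulates over generations and is absent in strain crosses", {
  map <- makeGeneticMap(2, 10, 60)
  pop <- simulatePopulation(map, nStrains = 4, nFamilies = 10,
                            litterSize = 4, nGenerations = 8,
                            nBreeders = 12, seed = 3)
  ped <- pedTable(pop)
  A <- numeratorRelationship(pop@pedigree)
  Fcoef <- diag(A) - 1
  g1 <- ped$generation == 1
  expect_true(all(Fcoef[g1] == 0))
  byGen <- tapply(Fcoef, ped$generation, mean)
  expect_gt(byGen[length(byGen)], byGen["1"])
})
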