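test_that("across-family splits keep whole families together", {
  ped <- data.frame(id = sprintf("i%02d", 1:30),
                    sire = NA, dam = NA, generation = 1L,
                    family = rep(c("f1", "f2", "f3"), each = 10),
                    cage = rep(c("c1", "c2", "c3"), each = 10))
  sp <- makeSplit(ped, ped$id, "across", fraction = 2/3, seed = 1)
  famTrain <- unique(ped$family[ped$id %in% sp@trainIds])
  famTest <- unique(ped$family[ped$id %in% sp@testIds])
  expect_length(intersect(famTrain, famTest), 0)
  expect_equal(length(famTrain), 2)
  expect_equal(length(sp@trainIds), 20)
  # single family cannot satisfy the across layout
  ped1 <- ped[ped$family == "f1", ]
  expect_error(makeSplit(ped1, ped1$id, "across", seed = 1), "families")
})

test_that("within-family splits put every family on both sides", {
  ped <- data.frame(id = sprintf("i%02d", 1:9),
                    sire = NA, dam = NA, generation = 1L,
                    family = rep(c("f1", "f2", "f3"), each = 3),
                    cage = "c")
  sp <- makeSplit(ped, ped$id, "within", fraction = 2/3, seed = 2)
  for (f in c("f1", "f2", "f3")) {
    ids <- ped$id[ped$family == f]
    expect_equal(sum(ids %in% sp@trainIds), 2)   # round(2/3 * 3)
    expect_equal(sum(ids %in% sp@testIds), 1)
  }
  expect_setequal(c(sp@trainIds, sp@testIds), ped$id)
})

test_that("across splits have lower train-test relatedness than within splits", {
  st <- tinyStudy()
  A <- numeratorRelationship(st@pedigree)
  ids <- st@phenotypes$id
  crossMean <- function(layout, seed) {
    sp <- makeSplit(st@pedigree, ids, layout, seed = seed)
    mean(A[sp@trainIds, sp@testIds])
  }
  ac <- vapply(1:20, function(s) crossMean("across", s), 1)
  wi <- vapply(1:20, function(s) crossMean("within", s), 1)
  expect_lt(mean(ac), mean(wi))
})

test_that("metrics match hand computations", {
  expect_equal(predictiveCorrelation(1:4, 1:4), 1)
  expect_equal(predictiveCorrelation(1:4, -(1:4)), -1)
  expect_equal(predictiveCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(predictiveCorrelation(rep(1, 4), 1:4), "zero variance")
  expect_equal(pmse(c(0, 0), c(1, 3)), 5)
  expect_equal(pmse(1:5, 1:5), 0)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pmse(x + 3, y + 3), pmse(x, y), tolerance = 1e-12)
})

test_that("the experiment is deterministic and degenerates correctly at masking 0", {
  st <- tinyStudy()
  settings <- list(blIter = 400L, blBurnIn = 100L, rkhsIter = 400L,
                   rkhsBurnIn = 100L, brannEpochs = 5L, brannRestarts = 2L,
                   maxRefHaps = 40L)
  p <- ncol(genotypeCodes(suppressWarnings(
    filterLoci(recodeByMajorAllele(st@genotypes)$genotypes))$genotypes))
  run1 <- suppressWarnings(
    runExperiment(st, traits = "BW", layouts = "within",
                  panelSizes = p, models = c("BL", "RKHS", "BRANN"),
                  seed = 5, settings = settings))
  run2 <- suppressWarnings(
    runExperiment(st, traits = "BW", layouts = "within",
                  panelSizes = p, models = c("BL", "RKHS", "BRANN"),
                  seed = 5, settings = settings))
  expect_identical(run1$results, run2$results)
  expect_identical(run1$imputation, run2$imputation)
  # masking rate 0: the three genotype conditions coincide
  for (m in c("BL", "RKHS", "BRANN")) {
    rows <- run1$results[run1$results$model == m, ]
    expect_equal(rows$correlation[rows$genotype_set == "imputed"],
                 rows$correlation[rows$genotype_set == "full"],
                 tolerance = 1e-12)
    expect_equal(rows$correlation[rows$genotype_set == "reduced"],
                 rows$correlation[rows$genotype_set == "full"],
                 tolerance = 1e-12)
  }
  expect_equal(run1$imputation$masking_rate, 0)
})

test_that("training artifacts are untouched by test-set phenotypes (no leakage)", {
  st <- tinyStudy()
  cp <- suppressWarnings(precorrectPhenotypes(st, "BW"))
  ids <- st@phenotypes$id
  sp <- makeSplit(st@pedigree, ids, "within", seed = 3)
  g <- suppressWarnings(
    filterLoci(recodeByMajorAllele(st@genotypes)$genotypes))$genotypes
  X <- genotypeCodes(g)
  y <- cp@yStar
  yShuffled <- y
  yShuffled[sp@testIds] <- withSeed(99, sample(y[sp@testIds]))
  f1 <- fitBL(y[sp@trainIds], X[sp@trainIds, ], nIter = 500, burnIn = 100,
              seed = 4)
  f2 <- fitBL(yShuffled[sp@trainIds], X[sp@trainIds, ], nIter = 500,
              burnIn = 100, seed = 4)
  expect_identical(f1@beta, f2@beta)
  expect_identical(predict(f1, X[sp@testIds, ]), predict(f2, X[sp@testIds, ]))
  # imputation reference is the training set only: posteriors identical
  # whatever happens to test phenotypes, and reference rows exclude targets
  panel <- selectEquallySpaced(ncol(X), 20)
  masked <- maskToPanel(g, panel, sp@testIds)
  haps <- referenceHaplotypes(st, g)
  imp1 <- imputeGenotypes(masked, haps, refIds = sp@trainIds,
                          maxRefHaps = 40, seed = 6)
  imp2 <- imputeGenotypes(masked, haps, refIds = sp@trainIds,
                          maxRefHaps = 40, seed = 6)
  expect_identical(imp1@posteriors, imp2@posteriors)
  expect_length(intersect(sp@trainIds, sp@testIds), 0)
})

test_that("experiment output has the factorial structure of the design", {
  st <- tinyStudy()
  settings <- list(blIter = 300L, blBurnIn = 100L, maxRefHaps = 30L)
  p <- ncol(genotypeCodes(suppressWarnings(
    filterLoci(recodeByMajorAllele(st@genotypes)$genotypes))$genotypes))
  out <- suppressWarnings(
    runExperiment(st, traits = "BW", layouts = c("across", "within"),
                  panelSizes = c(round(p / 2), round(p / 10)),
                  models = "BL", seed = 9, settings = settings,
                  outDir = file.path(tempdir(), "gpexp")))
  expect_equal(nrow(out$results), 2 * 2 * 3)   # layouts x panels x sets
  expect_setequal(unique(out$results$genotype_set),
                  c("full", "imputed", "reduced"))
  expect_true(all(out$results$correlation >= -1 &
                  out$results$correlation <= 1, na.rm = TRUE))
  expect_true(all(out$results$pmse >= 0))
  expect_equal(nrow(out$imputation), 4)
  expect_true(file.exists(file.path(tempdir(), "gpexp", "results.tsv")))
  expect_true(file.exists(file.path(tempdir(), "gpexp", "imputation.tsv")))
})
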