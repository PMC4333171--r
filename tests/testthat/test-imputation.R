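test_that("masking hides exactly the non-panel loci of target individuals", {
  st <- tinyStudy()
  g <- st@genotypes
  p <- ncol(genotypeCodes(g))
  panel <- selectEquallySpaced(p, round(p * 0.2))
  targets <- head(st@phenotypes$id, 10)
  masked <- maskToPanel(g, panel, targets)
  expect_equal(sum(masked@mask), length(targets) * (p - panel@nTarget))
  obs <- genotypeCodes(masked@observed)
  expect_true(all(is.na(obs[targets, -panel@indices])))
  expect_identical(obs[targets, panel@indices],
                   genotypeCodes(g)[targets, panel@indices])
  ref <- setdiff(individualIds(g), targets)
  expect_identical(obs[ref, ], genotypeCodes(g)[ref, ])
  # round trip via the stored truth
  expect_identical(genotypeCodes(unmaskWithTruth(masked)),
                   genotypeCodes(g))
  # full panel: nothing masked
  m0 <- maskToPanel(g, selectEquallySpaced(p, p), targets)
  expect_equal(sum(m0@mask), 0)
  expect_error(maskToPanel(g, selectEquallySpaced(p - 1, 3), targets),
               "different locus set")
})

test_that("a 1809-locus matrix masked to the 201 panel hides 1608 loci per target", {
  codes <- matrix(1L, 3, 1809)
  colnames(codes) <- sprintf("m%04d", 1:1809)
  g <- genotypeMatrix(codes)
  masked <- maskToPanel(g, selectEquallySpaced(1809, 201), "ind0001")
  expect_equal(sum(masked@mask["ind0001", ]), 1608)
})

test_that("HMM posteriors match exhaustive path enumeration", {
  Hm <- rbind(c(0L, 1L, 0L), c(1L, 1L, 1L))
  s <- c(0, 0.3, 0.15)
  for (obs in list(c(0L, -1L, 1L), c(-1L, -1L, 2L), c(1L, 0L, -1L))) {
    oracle <- enumDiploidPosterior(Hm, obs, s, 0.05)
    got <- gpimpute:::.lsDiploidPosterior(Hm, matrix(obs, 1), s, 0.05)
    expect_lt(max(abs(oracle - matrix(got[1, , ], 3, 3))), 1e-10)
  }
  # 3 haplotypes, 4 loci
  Hm2 <- rbind(c(0L, 1L, 0L, 1L), c(1L, 1L, 1L, 0L), c(0L, 0L, 1L, 1L))
  s2 <- c(0, 0.2, 0.4, 0.1)
  obs2 <- c(1L, -1L, -1L, 0L)
  oracle2 <- enumDiploidPosterior(Hm2, obs2, s2, 0.02)
  got2 <- gpimpute:::.lsDiploidPosterior(Hm2, matrix(obs2, 1), s2, 0.02)
  expect_lt(max(abs(oracle2 - matrix(got2[1, , ], 4, 3))), 1e-10)
})

test_that("posteriors are proper and invariant to reference haplotype order", {
  st <- tinyStudy()
  g <- st@genotypes
  p <- ncol(genotypeCodes(g))
  panel <- selectEquallySpaced(p, round(p * 0.3))
  targets <- head(st@phenotypes$id, 4)
  masked <- maskToPanel(g, panel, targets)
  refIds <- setdiff(st@phenotypes$id, targets)[1:20]
  haps <- referenceHaplotypes(st)
  H <- rbind(haps$hap1[refIds, ], haps$hap2[refIds, ])
  imp1 <- imputeGenotypes(masked, H)
  expect_equal(apply(imp1@posteriors, c(1, 2), sum),
               matrix(1, 4, p, dimnames = dimnames(imp1@posteriors)[1:2]),
               tolerance = 1e-9)
  set.seed(61)
  imp2 <- imputeGenotypes(masked, H[sample(nrow(H)), ])
  expect_equal(imp1@posteriors, imp2@posteriors, tolerance = 1e-9)
  # imputed codes are the posterior argmax at masked entries
  id <- targets[1]
  hidden <- which(masked@mask[id, ])
  am <- apply(imp1@posteriors[id, hidden, ], 1, which.max) - 1L
  expect_identical(unname(genotypeCodes(imp1@imputed)[id, hidden]),
                   unname(am))
})

test_that("a target whose haplotypes are in the reference is imputed perfectly", {
  st <- tinyStudy()
  g <- st@genotypes
  p <- ncol(genotypeCodes(g))
  panel <- selectEquallySpaced(p, round(p * 0.5))
  id <- st@phenotypes$id[1]
  masked <- maskToPanel(g, panel, id)
  haps <- referenceHaplotypes(st)
  # reference = the target's own two haplotypes plus one decoy
  decoy <- st@phenotypes$id[2]
  H <- rbind(haps$hap1[id, ], haps$hap2[id, ], haps$hap1[decoy, ])
  imp <- imputeGenotypes(masked, H, epsilon = 1e-4, switchRate = 1e-6)
  imp <- scoreImputation(imp, masked)
  expect_equal(imputationAccuracy(imp), 1)
})

test_that("scoring counts accuracy and error categories as stated", {
  truth <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L, 2L), 1)
  imputed <- truth
  imputed[1, 1] <- 1L   # 0 -> 1 error
  imputed[1, 3] <- 1L   # 2 -> 1 error
  codes <- imputed
  colnames(codes) <- sprintf("s%02d", 1:10)
  rownames(codes) <- "t1"
  gm <- genotypeMatrix(codes)
  res <- new("ImputationResult", imputed = gm,
             posteriors = array(0, c(1, 10, 3)), targetIds = "t1",
             accuracy = NA_real_, errorDecomposition = rep(NA_real_, 3))
  tr <- matrix(NA_integer_, 1, 10, dimnames = dimnames(codes))
  tr[1, ] <- truth
  res <- scoreImputation(res, tr)
  expect_equal(imputationAccuracy(res), 0.8)
  expect_equal(unname(errorDecomposition(res)), c(0.5, 0.5, 0))
  # all correct: accuracy 1, decomposition undefined
  res2 <- new("ImputationResult", imputed = gm,
              posteriors = array(0, c(1, 10, 3)), targetIds = "t1",
              accuracy = NA_real_, errorDecomposition = rep(NA_real_, 3))
  tr2 <- tr; tr2[1, ] <- imputed
  res2 <- scoreImputation(res2, tr2)
  expect_equal(imputationAccuracy(res2), 1)
  expect_true(all(is.na(errorDecomposition(res2))))
})

test_that("a random imputer scores about one third on balanced truth", {
  set.seed(62)
  n <- 10000
  truth <- matrix(sample(0:2, n, TRUE), 1)
  guess <- matrix(sample(0:2, n, TRUE), 1)
  storage.mode(guess) <- "integer"
  colnames(guess) <- sprintf("s%05d", 1:n); rownames(guess) <- "t"
  gm <- genotypeMatrix(guess)
  res <- new("ImputationResult", imputed = gm,
             posteriors = array(0, c(1, n, 3)), targetIds = "t",
             accuracy = NA_real_, errorDecomposition = rep(NA_real_, 3))
  tr <- matrix(as.integer(truth), 1, n, dimnames = dimnames(guess))
  res <- scoreImputation(res, tr)
  expect_equal(imputationAccuracy(res), 1 / 3, tolerance = 0.02 / (1 / 3))
})

test_that("confident posteriors are empirically accurate (calibration)", {
  st <- tinyStudy()
  rec <- recodeByMajorAllele(st@genotypes)
  g <- suppressWarnings(filterLoci(rec$genotypes))$genotypes
  p <- ncol(genotypeCodes(g))
  ids <- st@phenotypes$id
  sp <- makeSplit(st@pedigree, ids, "within", seed = 8)
  panel <- selectEquallySpaced(p, round(p * 0.25))
  masked <- maskToPanel(g, panel, sp@testIds)
  haps <- referenceHaplotypes(st, g)
  imp <- imputeGenotypes(masked, haps, refIds = sp@trainIds,
                         maxRefHaps = 100)
  pm <- apply(imp@posteriors, c(1, 2), max)
  best <- apply(imp@posteriors, c(1, 2), which.max) - 1L
  hit <- conf <- 0
  for (id in sp@testIds) {
    hidden <- masked@mask[id, ]
    sel <- hidden & pm[id, ] >= 0.9
    conf <- conf + sum(sel)
    hit <- hit + sum(best[id, sel] == masked@truth[id, sel])
  }
  expect_gt(conf, 50)
  expect_gte(hit / conf, 0.85)
})
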