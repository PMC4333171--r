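test_that("relationship matrix reproduces textbook pedigrees", {
  # two unrelated founders
  ped0 <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  expect_equal(unname(numeratorRelationship(ped0)), diag(2))
  # two parents, two full sibs
  ped1 <- data.frame(id = c("s", "d", "o1", "o2"),
                     sire = c(NA, NA, "s", "s"),
                     dam = c(NA, NA, "d", "d"))
  A <- numeratorRelationship(ped1)
  expect_equal(A["s", "o1"], 0.5)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["o1", "o1"], 1)
  # offspring of a full-sib mating: F = 0.25
  ped2 <- rbind(ped1, data.frame(id = "x", sire = "o1", dam = "o2"))
  expect_equal(numeratorRelationship(ped2)["x", "x"], 1.25)
})

test_that("tabular method matches the recursive oracle on a simulated pedigree", {
  st <- tinyStudy()
  ped <- pedTable(st)[1:150, ]
  # drop offspring whose parents fall outside the slice
  keep <- is.na(ped$sire) | (ped$sire %in% ped$id & ped$dam %in% ped$id)
  ped <- ped[keep, ]
  A <- numeratorRelationship(ped)
  expect_equal(A, naiveRelationship(ped), tolerance = 1e-12)
})

test_that("unordered pedigrees are reordered and cycles rejected", {
  ped <- data.frame(id = c("o", "s", "d"), sire = c("s", NA, NA),
                    dam = c("d", NA, NA))
  A <- numeratorRelationship(ped)
  expect_equal(A["o", "s"], 0.5)
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(numeratorRelationship(cyc), "cyclic")
})

test_that("with no random effects the corrected phenotype equals OLS residuals", {
  set.seed(41)
  n <- 60
  X <- cbind(1, rnorm(n), sample(0:1, n, TRUE))
  y <- setNames(drop(X %*% c(2, 1, -1)) + rnorm(n), paste0("i", 1:n))
  fit <- fitMixedModel(y, X, W = NULL, A = NULL)
  ols <- residuals(lm(y ~ X - 1))
  expect_equal(unname(fit@yStar), unname(ols), tolerance = 1e-6)
})

test_that("a single individual with no random structure is centered", {
  y <- setNames(c(3.7), "only")
  f1 <- fitMixedModel(y, matrix(1, 1, 1), NULL, NULL)
  expect_equal(unname(f1@thetaHat), 3.7)
  expect_equal(unname(f1@yStar), 0)
  y5 <- setNames(rep(c(2, 4), c(3, 2)), paste0("i", 1:5))
  fit <- fitMixedModel(y5, matrix(1, 5, 1), NULL, NULL)
  expect_equal(unname(fit@thetaHat), mean(y5))
  expect_equal(unname(fit@yStar), unname(y5 - mean(y5)))
})

test_that("mixed-model solutions satisfy Henderson's normal equations", {
  st <- tinyStudy()
  phen <- st@phenotypes
  y <- setNames(phen$BW, phen$id)
  X <- model.matrix(~ age + factor(gender), data = phen)
  W <- model.matrix(~ 0 + factor(cage), data = phen)
  A <- numeratorRelationship(st@pedigree)
  fit <- suppressWarnings(fitMixedModel(y, X, W, A))
  vc <- fit@varianceComponents
  As <- A[names(y), names(y)]
  sol <- gpimpute:::solveMME(y, X, W, As, vc["sigma_u2"], vc["sigma_c2"],
                             vc["sigma_e2"])
  resid <- sol$C %*% sol$sol - sol$rhs
  expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(sol$rhs^2)))
})

test_that("corrected phenotype is invariant to the fixed-effect parameterization", {
  st <- tinyStudy()
  phen <- st@phenotypes
  y <- setNames(phen$BW, phen$id)
  W <- model.matrix(~ 0 + factor(cage), data = phen)
  A <- numeratorRelationship(st@pedigree)
  Xtreat <- model.matrix(~ factor(month) + factor(gender), data = phen)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  Xsum <- model.matrix(~ factor(month) + factor(gender), data = phen)
  options(old)
  f1 <- suppressWarnings(fitMixedModel(y, Xtreat, W, A))
  f2 <- suppressWarnings(fitMixedModel(y, Xsum, W, A))
  expect_equal(f1@yStar, f2@yStar, tolerance = 1e-6)
})

test_that("REML recovers known variance components on average", {
  # truth (sigma_u2, sigma_c2, sigma_e2) = (2, 1, 3); u drawn with the
  # pedigree covariance, cages partly split so the components separate
  map <- makeGeneticMap(2, 10, 60)
  est <- matrix(0, 12, 3)
  for (i in seq_len(12)) {
    pop <- simulatePopulation(map, nFamilies = 30, litterSize = 10,
                              nGenerations = 5, nBreeders = 40,
                              splitCageFraction = 0.3, seed = 50 + i)
    ped <- pedTable(pop)
    ids <- ped$id[!is.na(ped$family)]
    A <- numeratorRelationship(pop@pedigree)[ids, ids]
    set.seed(150 + i)
    n <- length(ids)
    u <- drop(crossprod(chol(A + diag(1e-8, n)), rnorm(n))) * sqrt(2)
    cage <- ped$cage[match(ids, ped$id)]
    W <- model.matrix(~ 0 + factor(cage))
    y <- setNames(10 + u + drop(W %*% rnorm(ncol(W))) +
                    rnorm(n, 0, sqrt(3)), ids)
    fit <- suppressWarnings(fitMixedModel(y, matrix(1, n, 1), W, A))
    est[i, ] <- fit@varianceComponents
  }
  expect_lt(max(abs(colMeans(est) / c(2, 1, 3) - 1)), 0.35)
})

test_that("pre-correction removes fixed and cage signal but keeps genetic signal", {
  st <- tinyStudy()
  cp <- suppressWarnings(precorrectPhenotypes(st, "BW"))
  phen <- st@phenotypes
  ys <- cp@yStar[phen$id]
  # corrected response no longer tracks the gender effect
  fitG <- lm(ys ~ factor(phen$gender))
  expect_lt(abs(coef(fitG)[2]), abs(coef(lm(phen$BW ~ factor(phen$gender)))[2]) + 1e-8)
  # genetic signal retained: correlation with true breeding values persists
  tbv <- trueBreedingValues(st, "BW")[phen$id]
  expect_gt(cor(ys, tbv), 0.4)
  expect_equal(length(ys), nrow(phen))
})
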