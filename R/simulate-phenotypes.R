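#' Construct a trait architecture
#'
#' Variance components on the phenotype scale.  The defaults give a
#' moderately heritable, mostly additive body-weight-like trait; see
#' \code{bmiLikeArchitecture()} for a low-heritability alternative.
#'
#' @param nQtl number of causal loci
#' @param additiveVariance,dominanceVariance,epistaticVariance,cageVariance,residualVariance
#'   variance components, all >= 0
#' @param qtlEffectDistribution "normal" or "gamma" additive-effect draws
#' @return a \linkS4class{TraitArchitecture}
#' @export
traitArchitecture <- function(nQtl = 30,
                              additiveVariance = 0.40,
                              dominanceVariance = 0.05,
                              epistaticVariance = 0.05,
                              cageVariance = 0.15,
                              residualVariance = 0.35,
                              qtlEffectDistribution = c("normal", "gamma")) {
  qtlEffectDistribution <- match.arg(qtlEffectDistribution)
  if (any(c(additiveVariance, dominanceVariance, epistaticVariance,
            cageVariance, residualVariance) < 0))
    stop("validation error: variances must be >= 0")
  new("TraitArchitecture", nQtl = as.integer(nQtl),
      additiveVariance = additiveVariance,
      dominanceVariance = dominanceVariance,
      epistaticVariance = epistaticVariance,
      cageVariance = cageVariance, residualVariance = residualVariance,
      qtlEffectDistribution = qtlEffectDistribution)
}

#' @rdname traitArchitecture
#' @details \code{bwLikeArchitecture()} and \code{bmiLikeArchitecture()} are
#'   the two default study traits: a higher-heritability (h2 = 0.40) and a
#'   lower-heritability (h2 = 0.15) architecture, both with modest
#'   non-additive variance and a cage component confounded with family.
#' @export
bwLikeArchitecture <- function() traitArchitecture()

#' @rdname traitArchitecture
#' @export
bmiLikeArchitecture <- function() {
  traitArchitecture(nQtl = 30, additiveVariance = 0.15,
                    dominanceVariance = 0.05, epistaticVariance = 0.05,
                    cageVariance = 0.20, residualVariance = 0.55)
}

#' Narrow-sense heritability of an architecture
#' @param arch TraitArchitecture
#' @export
heritability <- function(arch) {
  tot <- arch@additiveVariance + arch@dominanceVariance +
    arch@epistaticVariance + arch@cageVariance + arch@residualVariance
  arch@additiveVariance / tot
}

#' Simulate phenotypes on a simulated population
#'
#' Adds, for each trait architecture, a phenotype built as fixed covariate
#' effects (age, gender, month, cage density) + additive + dominance +
#' pairwise additive-by-additive epistatic genetic values + cage effect +
#' Gaussian residual.  Each random component is rescaled so its realized
#' variance equals the architecture's target exactly; covariate effect
#' sizes come from \code{covariatePlan}.  Only the final (family-structured)
#' generation is phenotyped.
#'
#' @param study SimulatedStudy from \code{\link{simulatePopulation}}
#' @param architectures named list of \linkS4class{TraitArchitecture}
#'   objects, one per trait (names become phenotype columns)
#' @param covariatePlan list of fixed-effect sizes on the phenotype scale:
#'   \code{gender} (additive shift for males), \code{age} (slope per week,
#'   ages drawn uniformly from 8-12 weeks), \code{monthSD} (SD of monthly
#'   batch effects, months assigned per family), \code{density} (slope per
#'   cage mate).  Set any to 0 to drop it.
#' @param seed integer
#' @return the study with phenotype table, true breeding values and QTL
#'   effects filled in
#' @export
simulatePhenotypes <- function(study,
                               architectures = list(BW = bwLikeArchitecture(),
                                                    BMI = bmiLikeArchitecture()),
                               covariatePlan = list(gender = 0.5, age = 0.1,
                                                    monthSD = 0.3,
                                                    density = 0.05),
                               seed = 1L) {
  stopifnot(is(study, "SimulatedStudy"), length(architectures) >= 1)
  for (a in architectures) validObject(a)
  ped <- pedTable(study)
  phen <- ped[!is.na(ped$family), c("id", "family", "cage")]
  n <- nrow(phen)
  if (!n) stop("no family-structured generation to phenotype")
  codes <- genotypeCodes(study)[phen$id, , drop = FALSE]
  p <- ncol(codes)

  withSeed(seed, {
    # shared covariates across traits (as in a single measured cohort)
    phen$age <- sample(8:12, n, replace = TRUE)
    phen$gender <- sample(c("F", "M"), n, replace = TRUE)
    famMonth <- setNames(sample(1:6, length(unique(phen$family)),
                                replace = TRUE), unique(phen$family))
    phen$month <- famMonth[phen$family]
    phen$cage_density <- as.integer(table(phen$cage)[phen$cage])

    monthEff <- setNames(rnorm(6, 0, covariatePlan$monthSD %||% 0), 1:6)
    fixed <- (covariatePlan$age %||% 0) * (phen$age - mean(phen$age)) +
      (covariatePlan$gender %||% 0) * (phen$gender == "M") +
      monthEff[as.character(phen$month)] +
      (covariatePlan$density %||% 0) *
        (phen$cage_density - mean(phen$cage_density))

    tbv <- matrix(0, n, length(architectures),
                  dimnames = list(phen$id, names(architectures)))
    qtlInfo <- list()
    for (tr in names(architectures)) {
      arch <- architectures[[tr]]
      segregating <- which(apply(codes, 2, var) > 0)
      nq <- min(arch@nQtl, length(segregating))
      qtl <- sort(sample(segregating, nq))
      Z <- scale(codes[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
      addEff <- switch(arch@qtlEffectDistribution,
                       normal = rnorm(nq),
                       gamma = rgamma(nq, shape = 0.4) * sample(c(-1, 1), nq,
                                                                replace = TRUE))
      aVal <- scaleToVar(drop(Z %*% addEff), arch@additiveVariance)
      het <- (codes[, qtl, drop = FALSE] == 1L) * 1
      domEff <- rnorm(nq)
      dVal <- scaleToVar(drop(het %*% domEff), arch@dominanceVariance)
      nPairs <- nq
      pr1 <- sample(nq, nPairs, replace = TRUE)
      pr2 <- sample(nq, nPairs, replace = TRUE)
      keepPair <- pr1 != pr2
      epiEff <- rnorm(nPairs)
      eRaw <- if (any(keepPair))
        drop((Z[, pr1[keepPair], drop = FALSE] *
              Z[, pr2[keepPair], drop = FALSE]) %*% epiEff[keepPair])
      else rep(0, n)
      eVal <- scaleToVar(eRaw, arch@epistaticVariance)
      cageEff <- setNames(rnorm(length(unique(phen$cage))),
                          unique(phen$cage))
      cVal <- scaleToVar(cageEff[phen$cage], arch@cageVariance)
      resid <- scaleToVar(rnorm(n), arch@residualVariance)
      tbv[, tr] <- aVal
      phen[[tr]] <- as.numeric(fixed + aVal + dVal + eVal + cVal + resid)
      qtlInfo[[tr]] <- list(loci = qtl,
                            additive = addEff * (if (sd(drop(Z %*% addEff)) > 0)
                              sqrt(arch@additiveVariance) / sd(drop(Z %*% addEff)) else 0),
                            dominance = domEff)
    }
    rownames(phen) <- NULL
    study@phenotypes <- phen
    study@trueBreedingValues <- tbv
    study@qtl <- qtlInfo
    study@architectures <- architectures
    study
  })
}

#' True breeding values of a simulated study
#' @param study SimulatedStudy
#' @param trait trait name (default first)
#' @export
trueBreedingValues <- function(study, trait = NULL) {
  tb <- study@trueBreedingValues
  if (is.null(trait)) trait <- colnames(tb)[1]
  setNames(tb[, trait], rownames(tb))
}
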