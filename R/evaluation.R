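#' Family-structured training/testing split
#'
#' "across": whole families are randomly assigned to training or testing,
#' so no family spans both sets.  "within": individuals of each family are
#' randomized to both sets (every family with at least 2 members
#' contributes to both).  The achieved training fraction is kept within
#' 5\% of the target.
#'
#' @param pedigree \linkS4class{Pedigree} (or data.frame) defining families
#' @param eligibleIds individuals eligible for the experiment (those with
#'   both phenotype and genotype)
#' @param layout "across" or "within"
#' @param fraction target training fraction (default 2/3)
#' @param seed integer
#' @return a \linkS4class{SplitPlan}
#' @export
makeSplit <- function(pedigree, eligibleIds, layout = c("across", "within"),
                      fraction = 2/3, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(fraction > 0, fraction < 1)
  ped <- if (is(pedigree, "Pedigree")) pedTable(pedigree) else pedigree
  fam <- setNames(as.character(ped$family), as.character(ped$id))[eligibleIds]
  fam[is.na(fam)] <- paste0("solo_", eligibleIds[is.na(fam)])
  n <- length(eligibleIds)
  withSeed(seed, {
    if (layout == "across") {
      fams <- unique(fam)
      if (length(fams) < 2)
        stop("across-family layout needs at least 2 families")
      ord <- sample(fams)
      sizes <- table(fam)[ord]
      cum <- cumsum(sizes)
      k <- which.min(abs(cum - fraction * n))
      if (k == length(ord)) k <- length(ord) - 1L
      train <- eligibleIds[fam %in% ord[seq_len(k)]]
    } else {
      train <- unlist(lapply(split(eligibleIds, fam), function(ids) {
        m <- length(ids)
        if (m == 1) return(if (runif(1) < fraction) ids else character(0))
        k <- min(max(1L, round(fraction * m)), m - 1L)
        sample(ids, k)
      }), use.names = FALSE)
    }
    test <- setdiff(eligibleIds, train)
    plan <- new("SplitPlan", layout = layout, trainIds = as.character(train),
                testIds = as.character(test), fraction = fraction,
                seed = as.integer(seed))
    achieved <- length(train) / n
    if (abs(achieved - fraction) > 0.05 && layout == "within")
      warning(sprintf("achieved training fraction %.3f misses target %.3f",
                      achieved, fraction))
    plan
  })
}

#' Pearson correlation between predicted and observed phenotypes
#'
#' @param predicted,observed numeric vectors of equal length >= 3
#' @return correlation, or NA with a warning when a variance is zero
#' @export
predictiveCorrelation <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (sd(predicted) == 0 || sd(observed) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(predicted, observed)
}

#' Prediction mean squared error
#'
#' @param predicted,observed numeric vectors of equal length
#' @export
pmse <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1)
  mean((predicted - observed)^2)
}

# fit one model on training data and predict the test set
fitAndPredict <- function(model, yTrain, XTrain, XTest, seed, settings) {
  switch(model,
    BL = {
      fit <- fitBL(yTrain, XTrain, nIter = settings$blIter %||% 6000L,
                   burnIn = settings$blBurnIn %||% 1000L, seed = seed)
      list(fit = fit, train = predict(fit, XTrain),
           test = predict(fit, XTest))
    },
    RKHS = {
      ks <- buildKernels(XTrain)
      fit <- fitRKHS(yTrain, ks, nIter = settings$rkhsIter %||% 6000L,
                     burnIn = settings$rkhsBurnIn %||% 1000L, seed = seed)
      list(fit = fit, train = predict(fit, XTrain),
           test = predict(fit, XTest))
    },
    BRANN = {
      fit <- trainBRANN(XTrain, yTrain,
                        hidden = settings$brannHidden %||% 5L,
                        epochs = settings$brannEpochs %||% 30L,
                        restarts = settings$brannRestarts %||% 20L,
                        seed = seed)
      list(fit = fit, train = predict(fit, XTrain),
           test = predict(fit, XTest))
    },
    stop("unknown model: ", model))
}

#' Run the imputation-and-prediction experiment
#'
#' Orchestrates, for each trait x family layout x masking rate, the full
#' comparison: phenotypes are pre-corrected with the pedigree mixed model;
#' the eligible individuals are split by family layout; test-set genotypes
#' are masked to the low-density panel and imputed back using the training
#' individuals' haplotypes as the only reference (no leakage); and each
#' model is evaluated on the test set under three genotype conditions -
#' the full panel, the imputed-to-full panel, and the reduced panel (for
#' which the model is re-trained on the training set restricted to the
#' panel loci).  The same split (same seed) is shared by all models within
#' a scenario.
#'
#' @param study \linkS4class{SimulatedStudy} with phenotypes
#' @param traits phenotype columns to analyse (default all simulated traits)
#' @param layouts family layouts (default both)
#' @param panelSizes low-density panel sizes; the default thirds mirror
#'   50/75/90\% masking of the full panel
#' @param models any of "BL", "RKHS", "BRANN"
#' @param seed integer master seed; every stochastic step derives its own
#'   seed from it, so results are byte-identical across reruns
#' @param settings list of per-model chain/epoch settings (see
#'   \code{fitAndPredict} defaults) plus imputation controls
#'   \code{epsilon}, \code{switchRate}, \code{maxRefHaps}
#' @param genotypeSets test-set genotype conditions to evaluate, any of
#'   "full", "imputed", "reduced" (default all three); the imputation
#'   report is produced whenever a panel is masked
#' @param qc apply locus QC filters before panel building (default TRUE)
#' @param outDir optional directory for TSV reports (results, imputation,
#'   per-scenario log)
#' @return list with \code{results} (per-scenario correlations and PMSE),
#'   \code{imputation} (per layout x masking accuracy and error
#'   decomposition) and \code{qcReport}
#' @export
runExperiment <- function(study, traits = NULL, layouts = c("across", "within"),
                          panelSizes = NULL, models = c("BL", "RKHS", "BRANN"),
                          seed = 1L, settings = list(),
                          genotypeSets = c("full", "imputed", "reduced"),
                          qc = TRUE, outDir = NULL) {
  genotypeSets <- match.arg(genotypeSets, several.ok = TRUE)
  stopifnot(is(study, "SimulatedStudy"), nrow(study@phenotypes) > 0)
  if (is.null(traits))
    traits <- names(study@architectures)
  phen <- study@phenotypes

  # genotypes: recode to major-allele coding, then QC
  rec <- recodeByMajorAllele(study@genotypes)
  g <- rec$genotypes
  qcReport <- NULL
  if (qc) {
    fl <- filterLoci(g)
    g <- fl$genotypes
    qcReport <- fl$report
  }
  pFull <- ncol(genotypeCodes(g))
  if (is.null(panelSizes))
    panelSizes <- pmax(2L, round(pFull * c(0.5, 0.25, 0.1)))
  haps <- referenceHaplotypes(study, g)

  results <- list()
  imput <- list()
  for (trait in traits) {
    eligible <- phen$id[!is.na(phen[[trait]])]
    corr <- precorrectPhenotypes(study, trait)
    ystar <- corr@yStar[eligible]
    for (layout in layouts) {
      split <- makeSplit(study@pedigree, eligible, layout,
                         seed = deriveSeed(seed, paste0("split_", trait, "_",
                                                        layout)))
      trainIds <- split@trainIds; testIds <- split@testIds
      codes <- genotypeCodes(g)
      XTrainFull <- codes[trainIds, , drop = FALSE]
      XTestFull <- codes[testIds, , drop = FALSE]

      # models trained once per layout on the full-panel training set
      fullFits <- list()
      for (model in models) {
        fullFits[[model]] <- fitAndPredict(
          model, ystar[trainIds], XTrainFull, XTestFull,
          seed = deriveSeed(seed, paste0("fit_", trait, "_", layout, "_",
                                         model)),
          settings = settings)
      }

      for (ps in panelSizes) {
        panel <- selectEquallySpaced(pFull, ps)
        masked <- maskToPanel(g, panel, testIds)
        imp <- imputeGenotypes(masked, haps, refIds = trainIds,
                               epsilon = settings$epsilon %||% 0.01,
                               switchRate = settings$switchRate %||% 0.05,
                               maxRefHaps = settings$maxRefHaps %||% 200L,
                               seed = deriveSeed(seed, paste0("imp_", trait,
                                                              "_", layout,
                                                              "_", ps)))
        imp <- suppressWarnings(scoreImputation(imp, masked))
        mrate <- panel@maskingRate
        imput[[length(imput) + 1L]] <- data.frame(
          trait = trait, layout = layout, panel_size = ps,
          masking_rate = mrate, accuracy = imputationAccuracy(imp),
          err_0_1 = errorDecomposition(imp)[1],
          err_1_2 = errorDecomposition(imp)[2],
          err_0_2 = errorDecomposition(imp)[3], row.names = NULL)

        XTestImputed <- genotypeCodes(imp@imputed)[testIds, , drop = FALSE]
        XTrainRed <- XTrainFull[, panel@indices, drop = FALSE]
        XTestRed <- XTestFull[, panel@indices, drop = FALSE]

        for (model in models) {
          ff <- fullFits[[model]]
          predFull <- ff$test
          predImp <- if ("imputed" %in% genotypeSets)
            predict(ff$fit, XTestImputed) else NULL
          # a panel covering every locus degenerates to the full condition
          rf <- if (!"reduced" %in% genotypeSets) NULL
            else if (panel@nTarget == pFull) ff
            else fitAndPredict(model, ystar[trainIds], XTrainRed, XTestRed,
                               seed = deriveSeed(seed,
                                 paste0("fit_", trait, "_", layout, "_",
                                        model, "_red", ps)),
                               settings = settings)
          obs <- ystar[testIds]
          for (gs in genotypeSets) {
            pred <- switch(gs, full = predFull, imputed = predImp,
                           reduced = rf$test)
            results[[length(results) + 1L]] <- data.frame(
              trait = trait, layout = layout, panel_size = ps,
              masking_rate = mrate, genotype_set = gs, model = model,
              correlation = suppressWarnings(
                predictiveCorrelation(pred, obs)),
              pmse = pmse(pred, obs),
              train_correlation = suppressWarnings(
                predictiveCorrelation(ff$train, ystar[trainIds])),
              row.names = NULL)
          }
        }
      }
    }
  }
  results <- do.call(rbind, results)
  imput <- do.call(rbind, imput)
  out <- list(results = results, imputation = imput, qcReport = qcReport)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fwrite(as.data.table(results), file.path(outDir, "results.tsv"),
           sep = "\t")
    fwrite(as.data.table(imput), file.path(outDir, "imputation.tsv"),
           sep = "\t")
    if (!is.null(qcReport))
      fwrite(as.data.table(qcReport), file.path(outDir, "qc_report.tsv"),
             sep = "\t")
  }
  out
}
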