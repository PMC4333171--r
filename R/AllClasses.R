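#' @title Core S4 classes
#' @description S4 containers used throughout the pipeline: genotypes,
#'   pedigrees, simulated studies, masked/imputed sets, corrected phenotypes,
#'   cross-validation plans and fitted prediction models.
#' @name gpimpute-classes
NULL

#' Genotype matrix with locus metadata
#'
#' Individuals x loci integer codes in \{0, 1, 2\} (copies of the coded
#' allele) with \code{NA} for missing.  Locus metadata (\code{locus_id},
#' \code{chromosome}, \code{position_cM}) lives in the \code{map} slot, in
#' map order (chromosome, then position).  \code{codedAllele} records, per
#' locus, which allele label the code counts (simulator allele \code{"1"} or
#' \code{"0"}, or \code{"ALT"}/\code{"REF"} for VCF input).
#'
#' @slot codes integer matrix, rownames = individual ids, colnames = locus ids
#' @slot map data.frame with columns locus_id, chromosome, position_cM
#' @slot codedAllele character vector, one entry per locus
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(codes = "matrix", map = "data.frame",
                 codedAllele = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  cd <- object@codes
  if (!all(is.na(cd) | cd %in% c(0L, 1L, 2L)))
    msg <- c(msg, "codes must be 0, 1, 2 or NA")
  if (is.null(rownames(cd)) || anyDuplicated(rownames(cd)))
    msg <- c(msg, "individual ids (rownames) must be present and unique")
  if (ncol(cd) > 0 && (is.null(colnames(cd)) || anyDuplicated(colnames(cd))))
    msg <- c(msg, "locus ids (colnames) must be present and unique")
  if (!all(c("locus_id", "chromosome", "position_cM") %in% names(object@map)))
    msg <- c(msg, "map must have locus_id, chromosome, position_cM")
  else if (nrow(object@map) != ncol(cd) ||
           (ncol(cd) > 0 &&
            !identical(as.character(object@map$locus_id), colnames(cd))))
    msg <- c(msg, "map rows must match code columns (same loci, same order)")
  if (length(object@codedAllele) != ncol(cd))
    msg <- c(msg, "codedAllele must have one entry per locus")
  if (length(msg)) msg else TRUE
})

#' Pedigree
#'
#' Individual/sire/dam triples with generation, full-sib family and cage
#' labels.  Rows are topologically ordered: parents precede offspring.
#'
#' @slot ped data.frame with columns id, sire, dam, generation, family, cage
#'   (sire/dam NA for founders; family/cage NA outside the phenotyped
#'   generation)
#' @exportClass Pedigree
setClass("Pedigree", representation(ped = "data.frame"))

setValidity("Pedigree", function(object) {
  p <- object@ped
  need <- c("id", "sire", "dam", "generation", "family", "cage")
  if (!all(need %in% names(p)))
    return(paste("pedigree needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$id)) return("duplicated individual ids")
  pos <- seq_len(nrow(p))
  names(pos) <- as.character(p$id)
  for (col in c("sire", "dam")) {
    par <- as.character(p[[col]])
    known <- !is.na(par)
    if (!all(par[known] %in% names(pos)))
      return(sprintf("unknown %s ids", col))
    if (any(pos[par[known]] >= pos[known]))
      return("parents must precede offspring (topological order)")
  }
  TRUE
})

#' Trait architecture for the phenotype simulator
#'
#' Variance components are on the phenotype scale; narrow-sense
#' heritability is additive / total.
#'
#' @slot nQtl integer
#' @slot additiveVariance,dominanceVariance,epistaticVariance,cageVariance,residualVariance numeric, all >= 0
#' @slot qtlEffectDistribution "normal" or "gamma"
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(nQtl = "integer", additiveVariance = "numeric",
                 dominanceVariance = "numeric", epistaticVariance = "numeric",
                 cageVariance = "numeric", residualVariance = "numeric",
                 qtlEffectDistribution = "character"))

setValidity("TraitArchitecture", function(object) {
  v <- c(object@additiveVariance, object@dominanceVariance,
         object@epistaticVariance, object@cageVariance,
         object@residualVariance)
  if (any(!is.finite(v)) || any(v < 0)) return("variances must be finite and >= 0")
  if (sum(v) <= 0) return("total variance must be positive")
  if (object@nQtl < 1L) return("nQtl must be >= 1")
  if (!object@qtlEffectDistribution %in% c("normal", "gamma"))
    return("qtlEffectDistribution must be 'normal' or 'gamma'")
  TRUE
})

#' Simulated study
#'
#' A pedigreed population with phased haplotypes, genotype codes, a
#' phenotype/covariate table for the final generation, true breeding values
#' and the QTL effects that generated them.
#'
#' @slot genotypes GenotypeMatrix (codes count simulator allele "1")
#' @slot hap1,hap2 integer 0/1 matrices, phase retained from gene dropping
#' @slot pedigree Pedigree
#' @slot phenotypes data.frame: id, trait columns, age, gender, month,
#'   cage_density, cage, family
#' @slot trueBreedingValues matrix individuals x traits
#' @slot qtl list per trait with locus indices and effects
#' @slot architectures list of TraitArchitecture per trait
#' @exportClass SimulatedStudy
setClass("SimulatedStudy",
  representation(genotypes = "GenotypeMatrix", hap1 = "matrix",
                 hap2 = "matrix", pedigree = "Pedigree",
                 phenotypes = "data.frame", trueBreedingValues = "matrix",
                 qtl = "list", architectures = "list"))

setValidity("SimulatedStudy", function(object) {
  n <- nrow(object@genotypes@codes)
  if (!identical(dim(object@hap1), dim(object@genotypes@codes)) ||
      !identical(dim(object@hap2), dim(object@genotypes@codes)))
    return("haplotype matrices must match the genotype matrix")
  if (nrow(object@pedigree@ped) != n)
    return("pedigree size must match genotype rows")
  if (nrow(object@phenotypes) > 0 &&
      !all(object@phenotypes$id %in% rownames(object@genotypes@codes)))
    return("phenotyped ids must be genotyped")
  TRUE
})

#' Equally spaced low-density panel selection
#'
#' @slot indices integer, strictly increasing 1-based locus indices
#' @slot nFull integer, size of the source panel
#' @slot nTarget integer, panel size
#' @slot maskingRate numeric, 1 - nTarget/nFull
#' @exportClass PanelSelection
setClass("PanelSelection",
  representation(indices = "integer", nFull = "integer",
                 nTarget = "integer", maskingRate = "numeric"))

setValidity("PanelSelection", function(object) {
  i <- object@indices
  if (length(i) != object@nTarget) return("length(indices) != nTarget")
  if (any(diff(i) <= 0)) return("indices must be strictly increasing")
  if (min(i) < 1L || max(i) > object@nFull) return("indices out of range")
  if (abs(object@maskingRate - (1 - object@nTarget / object@nFull)) > 1e-12)
    return("maskingRate inconsistent with panel sizes")
  TRUE
})

#' Masked genotype set
#'
#' Target individuals keep only panel loci; the hidden codes are retained
#' for scoring only.
#'
#' @slot observed GenotypeMatrix on the full locus set with NA at masked entries
#' @slot mask logical matrix, TRUE where an entry was hidden
#' @slot truth integer matrix holding the hidden codes (NA elsewhere)
#' @slot panel PanelSelection
#' @slot targetIds character
#' @exportClass MaskedSet
setClass("MaskedSet",
  representation(observed = "GenotypeMatrix", mask = "matrix",
                 truth = "matrix", panel = "PanelSelection",
                 targetIds = "character"))

setValidity("MaskedSet", function(object) {
  cd <- object@observed@codes
  if (!identical(dim(object@mask), dim(cd))) return("mask dim mismatch")
  if (!all(is.na(cd[object@mask]))) return("masked entries must be NA in observed")
  nonpanel <- setdiff(seq_len(ncol(cd)), object@panel@indices)
  tgt <- rownames(cd) %in% object@targetIds
  if (length(nonpanel) && any(tgt) && !all(object@mask[tgt, nonpanel]))
    return("mask must cover all non-panel loci for target individuals")
  if (any(object@mask[!tgt, ])) return("non-target rows must be unmasked")
  TRUE
})

#' Imputation result
#'
#' @slot imputed GenotypeMatrix on the full panel (argmax-posterior codes at
#'   masked entries, observed codes elsewhere)
#' @slot posteriors array n_target x n_loci x 3 of genotype probabilities
#' @slot targetIds character
#' @slot accuracy numeric, fraction of masked entries imputed correctly (NA
#'   until scored)
#' @slot errorDecomposition numeric(3): conditional shares of 0<->1, 1<->2,
#'   0<->2 errors among erroneous entries
#' @exportClass ImputationResult
setClass("ImputationResult",
  representation(imputed = "GenotypeMatrix", posteriors = "array",
                 targetIds = "character", accuracy = "numeric",
                 errorDecomposition = "numeric"))

#' Corrected phenotype
#'
#' The mixed-model pre-corrected response y* = y - X theta_hat - W c_hat,
#' which deliberately retains all genetic signal.
#'
#' @slot yStar numeric, named by individual id
#' @slot thetaHat numeric fixed-effect solutions
#' @slot cHat numeric cage BLUPs
#' @slot uHat numeric additive-genetic BLUPs (reported, not subtracted)
#' @slot varianceComponents numeric: sigma_u2, sigma_c2, sigma_e2 (REML)
#' @slot converged logical
#' @slot logLik numeric restricted log-likelihood at the optimum
#' @exportClass CorrectedPhenotype
setClass("CorrectedPhenotype",
  representation(yStar = "numeric", thetaHat = "numeric", cHat = "numeric",
                 uHat = "numeric", varianceComponents = "numeric",
                 converged = "logical", logLik = "numeric"))

#' Family-structured cross-validation plan
#'
#' @slot layout "across" (whole families in one set) or "within" (each
#'   family split between sets)
#' @slot trainIds,testIds character, disjoint, union = eligible individuals
#' @slot fraction numeric target training fraction
#' @slot seed integer
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(layout = "character", trainIds = "character",
                 testIds = "character", fraction = "numeric",
                 seed = "integer"))

setValidity("SplitPlan", function(object) {
  if (!object@layout %in% c("across", "within"))
    return("layout must be 'across' or 'within'")
  if (length(intersect(object@trainIds, object@testIds)))
    return("train and test sets overlap")
  if (!length(object@trainIds) || !length(object@testIds))
    return("both sets must be non-empty")
  TRUE
})

#' Fitted Bayesian LASSO model
#'
#' @slot mu numeric posterior mean intercept
#' @slot beta numeric posterior mean marker effects (named by locus)
#' @slot betaSD numeric posterior SDs
#' @slot center numeric training column means used for centering
#' @slot keep integer indices of retained (non-constant) columns
#' @slot samples data.frame thinned samples of mu, sigma_e2, lambda2, logPost
#' @slot settings list chain settings and priors
#' @exportClass BLFit
setClass("BLFit",
  representation(mu = "numeric", beta = "numeric", betaSD = "numeric",
                 center = "numeric", keep = "integer", samples = "data.frame",
                 settings = "list"))

#' Gaussian kernel set for RKHS regression
#'
#' @slot D matrix of squared Euclidean distances between training individuals
#' @slot q50 numeric sample median of off-diagonal distances
#' @slot multipliers numeric bandwidth multipliers a
#' @slot h numeric effective bandwidths |a| / q50
#' @slot K list of kernel matrices exp(-h_m D)
#' @slot X matrix centered training genotype codes
#' @slot center numeric column means used for centering
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(D = "matrix", q50 = "numeric", multipliers = "numeric",
                 h = "numeric", K = "list", X = "matrix", center = "numeric"))

#' Fitted RKHS kernel-averaging model
#'
#' @slot mu numeric posterior mean intercept
#' @slot f matrix n x nKernels posterior mean genotypic-value components
#' @slot alpha matrix n x nKernels implied kernel-space coefficients
#' @slot varComp numeric posterior means of per-kernel and residual variances
#' @slot kernels KernelSpec training kernels (for cross-kernel prediction)
#' @slot samples data.frame thinned scalar samples
#' @slot settings list
#' @exportClass RKHSFit
setClass("RKHSFit",
  representation(mu = "numeric", f = "matrix", alpha = "matrix",
                 varComp = "numeric", kernels = "KernelSpec",
                 samples = "data.frame", settings = "list"))

#' Trained Bayesian-regularized neural-network ensemble
#'
#' @slot nets list of per-restart weight sets and diagnostics
#' @slot hidden integer hidden-layer size
#' @slot xRange matrix 2 x p training min/max used for [-1, 1] scaling
#' @slot yCenter,yScale numeric target standardization
#' @slot diagnostics data.frame per-restart E_D, E_w, alpha, gamma,
#'   effective parameters, convergence flags
#' @slot settings list
#' @exportClass BRANNFit
setClass("BRANNFit",
  representation(nets = "list", hidden = "integer", xRange = "matrix",
                 yCenter = "numeric", yScale = "numeric",
                 diagnostics = "data.frame", settings = "list"))
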