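#' @rdname GenotypeMatrix-class
#' @param x a GenotypeMatrix (or object containing one)
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("locusMap", function(x) standardGeneric("locusMap"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("codedAllele", function(x) standardGeneric("codedAllele"))

#' @rdname Pedigree-class
#' @param x a Pedigree (or object containing one)
#' @export
setGeneric("pedTable", function(x) standardGeneric("pedTable"))

setMethod("genotypeCodes", "GenotypeMatrix", function(x) x@codes)
setMethod("locusMap", "GenotypeMatrix", function(x) x@map)
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@codes))
setMethod("codedAllele", "GenotypeMatrix", function(x) x@codedAllele)
setMethod("genotypeCodes", "SimulatedStudy", function(x) x@genotypes@codes)
setMethod("locusMap", "SimulatedStudy", function(x) x@genotypes@map)
setMethod("individualIds", "SimulatedStudy", function(x) rownames(x@genotypes@codes))
setMethod("pedTable", "Pedigree", function(x) x@ped)
setMethod("pedTable", "SimulatedStudy", function(x) x@pedigree@ped)

#' @describeIn GenotypeMatrix-class number of individuals and loci
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@codes))

#' Subset a GenotypeMatrix by individuals and/or loci
#'
#' @param x GenotypeMatrix
#' @param i individual selector (ids, indices or logical)
#' @param j locus selector
#' @param ... ignored
#' @param drop ignored, always FALSE
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@codes))
  if (missing(j)) j <- seq_len(ncol(x@codes))
  cd <- x@codes[i, j, drop = FALSE]
  jj <- seq_len(ncol(x@codes))
  names(jj) <- colnames(x@codes)
  jidx <- if (is.character(j)) jj[j] else jj[j]
  new("GenotypeMatrix", codes = cd,
      map = x@map[jidx, , drop = FALSE],
      codedAllele = x@codedAllele[jidx])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cd <- object@codes
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci (%d chromosome%s)\n",
              nrow(cd), ncol(cd), length(unique(object@map$chromosome)),
              if (length(unique(object@map$chromosome)) == 1) "" else "s"))
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(cd))))
})

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  cat(sprintf("Pedigree: %d individuals, %d generations, %d families\n",
              nrow(p), length(unique(p$generation)),
              length(unique(p$family[!is.na(p$family)]))))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy\n")
  show(object@genotypes)
  show(object@pedigree)
  tr <- setdiff(names(object@phenotypes),
                c("id", "age", "gender", "month", "cage_density", "cage",
                  "family"))
  cat(sprintf("  phenotyped: %d individuals; traits: %s\n",
              nrow(object@phenotypes), paste(tr, collapse = ", ")))
})

setMethod("show", "MaskedSet", function(object) {
  cat(sprintf("MaskedSet: %d target individuals, panel %d/%d loci (masking %.1f%%)\n",
              length(object@targetIds), object@panel@nTarget,
              object@panel@nFull, 100 * object@panel@maskingRate))
})

setMethod("show", "ImputationResult", function(object) {
  cat(sprintf("ImputationResult: %d targets, %d loci\n",
              length(object@targetIds), ncol(object@imputed@codes)))
  if (length(object@accuracy) && is.finite(object@accuracy))
    cat(sprintf("  accuracy at masked entries: %.3f\n", object@accuracy))
})

setMethod("show", "CorrectedPhenotype", function(object) {
  vc <- object@varianceComponents
  cat(sprintf("CorrectedPhenotype: n = %d\n", length(object@yStar)))
  cat(sprintf("  REML variances: sigma_u2 = %.4g, sigma_c2 = %.4g, sigma_e2 = %.4g\n",
              vc["sigma_u2"], vc["sigma_c2"], vc["sigma_e2"]))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan (%s families): %d train / %d test\n",
              object@layout, length(object@trainIds), length(object@testIds)))
})

setMethod("show", "BLFit", function(object) {
  cat(sprintf("BLFit: %d markers, chain %d iterations (burn-in %d)\n",
              length(object@beta), object@settings$nIter,
              object@settings$burnIn))
})

setMethod("show", "RKHSFit", function(object) {
  cat(sprintf("RKHSFit: %d kernels (h = %s), n = %d\n",
              length(object@kernels@h),
              paste(signif(object@kernels@h, 3), collapse = ", "),
              nrow(object@f)))
})

setMethod("show", "BRANNFit", function(object) {
  cat(sprintf("BRANNFit: %d hidden neurons, %d restarts\n",
              object@hidden, length(object@nets)))
})
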