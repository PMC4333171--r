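#' Mask target genotypes down to a low-density panel
#'
#' Target individuals retain only the panel loci; reference individuals
#' are untouched.  The hidden codes are stored for scoring only and are
#' never visible to the imputer.
#'
#' @param full GenotypeMatrix on the full locus set
#' @param panel \linkS4class{PanelSelection} over the full locus set
#' @param targetIds individuals to mask
#' @return a \linkS4class{MaskedSet}
#' @export
maskToPanel <- function(full, panel, targetIds) {
  cd <- genotypeCodes(full)
  if (panel@nFull != ncol(cd))
    stop("panel was built for a different locus set")
  if (!length(panel@indices)) stop("empty panel")
  if (!all(targetIds %in% rownames(cd)))
    stop("unknown target ids")
  mask <- matrix(FALSE, nrow(cd), ncol(cd), dimnames = dimnames(cd))
  nonpanel <- setdiff(seq_len(ncol(cd)), panel@indices)
  tgt <- rownames(cd) %in% targetIds
  mask[tgt, nonpanel] <- TRUE
  truth <- matrix(NA_integer_, nrow(cd), ncol(cd), dimnames = dimnames(cd))
  truth[mask] <- cd[mask]
  obs <- cd
  obs[mask] <- NA_integer_
  observed <- new("GenotypeMatrix", codes = obs, map = locusMap(full),
                  codedAllele = codedAllele(full))
  new("MaskedSet", observed = observed, mask = mask, truth = truth,
      panel = panel, targetIds = as.character(targetIds))
}

#' Restore a masked set to the full matrix using the stored truth
#' @param masked MaskedSet
#' @return GenotypeMatrix identical to the pre-masking input
#' @export
unmaskWithTruth <- function(masked) {
  cd <- genotypeCodes(masked@observed)
  cd[masked@mask] <- masked@truth[masked@mask]
  new("GenotypeMatrix", codes = cd, map = locusMap(masked@observed),
      codedAllele = codedAllele(masked@observed))
}

#' Impute masked genotypes with a diploid Li-Stephens haplotype HMM
#'
#' For each target individual a hidden-Markov model over ordered pairs of
#' reference haplotypes is evaluated by forward-backward, conditioning on
#' the observed panel genotypes.  Template switch probabilities between
#' adjacent loci are 1 - exp(-switchRate * d) for map distance d cM
#' (independent chromosomes switch freely); the emission model allows a
#' per-allele error rate epsilon > 0.  Per-locus genotype posteriors and
#' their argmax codes are returned; pedigree information is deliberately
#' not used.
#'
#' @param masked \linkS4class{MaskedSet}
#' @param refHaps list(hap1, hap2) of 0/1 matrices (individuals x full
#'   locus set) holding reference haplotypes in the same allele coding as
#'   the masked genotypes, or a single stacked haplotype matrix
#' @param refIds reference individuals to use (rows of the haplotype
#'   matrices); required when \code{refHaps} is a list
#' @param epsilon per-allele emission error rate (default 0.01)
#' @param switchRate template switch intensity per cM (default 0.05)
#' @param maxRefHaps cap on reference haplotypes; excess haplotypes are
#'   subsampled deterministically given \code{seed} (default 200)
#' @param seed integer used only for reference subsampling
#' @return an \linkS4class{ImputationResult}
#' @export
imputeGenotypes <- function(masked, refHaps, refIds = NULL, epsilon = 0.01,
                            switchRate = 0.05, maxRefHaps = 200L, seed = 1L) {
  stopifnot(is(masked, "MaskedSet"), epsilon > 0, epsilon < 0.5)
  obs <- genotypeCodes(masked@observed)
  map <- locusMap(masked@observed)
  L <- ncol(obs)
  if (is.list(refHaps)) {
    if (is.null(refIds)) stop("refIds required when refHaps is a list")
    missingLoci <- setdiff(colnames(obs), colnames(refHaps[[1]]))
    if (length(missingLoci))
      stop("loci absent from the reference: ", missingLoci[1])
    H <- rbind(refHaps[[1]][refIds, colnames(obs), drop = FALSE],
               refHaps[[2]][refIds, colnames(obs), drop = FALSE])
  } else {
    H <- refHaps[, colnames(obs), drop = FALSE]
  }
  if (nrow(H) < 2) stop("need at least 2 reference haplotypes")
  if (nrow(H) > maxRefHaps) {
    pick <- withSeed(seed, sample(nrow(H), maxRefHaps))
    H <- H[pick, , drop = FALSE]
  }
  storage.mode(H) <- "integer"

  d <- c(0, diff(map$position_cM))
  newChrom <- c(TRUE, diff(map$chromosome) != 0)
  s <- 1 - exp(-switchRate * d)
  s[newChrom] <- 1  # fresh uniform template draw across chromosomes
  s[1] <- 0

  targets <- masked@targetIds
  obsT <- obs[targets, , drop = FALSE]
  obsT[is.na(obsT)] <- -1L
  storage.mode(obsT) <- "integer"
  post <- .lsDiploidPosterior(H, obsT, s, epsilon)
  dimnames(post) <- list(targets, colnames(obs), c("0", "1", "2"))

  imputedCodes <- obs
  best <- apply(post, c(1, 2), which.max) - 1L
  for (id in targets) {
    hidden <- masked@mask[id, ]
    imputedCodes[id, hidden] <- as.integer(best[id, hidden])
  }
  imputed <- new("GenotypeMatrix", codes = imputedCodes, map = map,
                 codedAllele = codedAllele(masked@observed))
  new("ImputationResult", imputed = imputed, posteriors = post,
      targetIds = targets, accuracy = NA_real_,
      errorDecomposition = setNames(rep(NA_real_, 3),
                                    c("0<->1", "1<->2", "0<->2")))
}

#' Score an imputation against the held-back truth
#'
#' Accuracy is the fraction of masked entries whose imputed code equals the
#' truth.  The error decomposition gives the conditional shares of the
#' three error categories (0<->1, 1<->2, 0<->2) among erroneous entries
#' only, summing to 1 when any errors exist.
#'
#' @param result \linkS4class{ImputationResult}
#' @param masked the \linkS4class{MaskedSet} holding the truth (or an
#'   integer truth matrix)
#' @return the result with \code{accuracy} and \code{errorDecomposition}
#'   filled in; retrieve them with \code{imputationAccuracy()} and
#'   \code{errorDecomposition()}
#' @export
scoreImputation <- function(result, masked) {
  truth <- if (is(masked, "MaskedSet")) masked@truth else masked
  maskM <- if (is(masked, "MaskedSet")) masked@mask else !is.na(truth)
  cd <- genotypeCodes(result@imputed)
  idx <- which(maskM, arr.ind = TRUE)
  if (!nrow(idx)) {
    warning("no masked entries: accuracy undefined")
    return(result)
  }
  imp <- cd[idx]
  tru <- truth[idx]
  acc <- mean(imp == tru)
  err <- imp != tru
  dec <- c("0<->1" = 0, "1<->2" = 0, "0<->2" = 0)
  if (any(err)) {
    pair <- paste(pmin(imp[err], tru[err]), pmax(imp[err], tru[err]),
                  sep = "<->")
    tab <- table(factor(pair, levels = c("0<->1", "1<->2", "0<->2")))
    dec <- as.numeric(tab) / sum(tab)
    names(dec) <- c("0<->1", "1<->2", "0<->2")
  } else {
    dec[] <- NA_real_
  }
  result@accuracy <- acc
  result@errorDecomposition <- dec
  result
}

#' @rdname scoreImputation
#' @param result an ImputationResult
#' @export
imputationAccuracy <- function(result) result@accuracy

#' @rdname scoreImputation
#' @export
errorDecomposition <- function(result) result@errorDecomposition

#' Reference haplotypes of a simulated study
#'
#' Phased haplotypes from the simulator, expressed as indicators of each
#' locus's coded allele so they align with a (possibly recoded)
#' GenotypeMatrix.
#'
#' @param study SimulatedStudy
#' @param genotypes GenotypeMatrix whose coding to match (default: the
#'   study's own, which counts simulator allele "1")
#' @return list(hap1, hap2) of 0/1 matrices
#' @export
referenceHaplotypes <- function(study, genotypes = NULL) {
  h1 <- study@hap1; h2 <- study@hap2
  if (!is.null(genotypes)) {
    ca <- codedAllele(genotypes)
    loci <- colnames(genotypeCodes(genotypes))
    h1 <- h1[, loci, drop = FALSE]
    h2 <- h2[, loci, drop = FALSE]
    flip <- ca == "0"
    if (any(flip)) {
      h1[, flip] <- 1L - h1[, flip, drop = FALSE]
      h2[, flip] <- 1L - h2[, flip, drop = FALSE]
    }
  }
  list(hap1 = h1, hap2 = h2)
}
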