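#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-df chi-square goodness-of-fit of observed genotype counts against
#' expectations from the sample allele frequency (no continuity
#' correction).  An exact test (full enumeration of heterozygote counts
#' conditional on the allele counts) is available via \code{method}.
#'
#' @param n0,n1,n2 counts of the three genotype classes (codes 0, 1, 2)
#' @param method "chisq" (default) or "exact"
#' @return p-value in [0, 1]
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions -> p = 1
#' hweTest(10, 10, 10)
#' @export
hweTest <- function(n0, n1, n2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n0 + n1 + n2
  if (n < 1) stop("undefined: no genotyped individuals")
  pa <- (2 * n2 + n1) / (2 * n)     # frequency of the counted allele
  if (pa == 0 || pa == 1) return(1) # monomorphic: trivially in HWE
  if (method == "chisq") {
    e <- n * c((1 - pa)^2, 2 * pa * (1 - pa), pa^2)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    # exact test of Levene/Haldane: P(n_het | allele counts) enumerated
    nA <- 2 * n2 + n1   # counted allele copies
    nB <- 2 * n - nA
    hets <- seq(nA %% 2, min(nA, nB), by = 2)
    logp <- vapply(hets, function(h) {
      nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
      h * log(2) + lfactorial(n) - lfactorial(nAA) - lfactorial(h) -
        lfactorial(nBB) +
        lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
    }, 1)
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[hets == n1] * (1 + 1e-12)])
  }
}

#' Locus quality-control filters
#'
#' Retains loci passing minor allele frequency >= \code{mafMin}, call rate
#' >= \code{callRateMin} and Hardy-Weinberg p >= \code{hweAlpha}.  MAF is
#' computed ignoring missing entries.  The report records, per locus, the
#' three statistics and the first failing rule (call rate checked first,
#' then MAF, then HWE).
#'
#' @param g GenotypeMatrix
#' @param mafMin minimum minor allele frequency (default 0.05)
#' @param callRateMin minimum call rate (default 0.95)
#' @param hweAlpha Hardy-Weinberg significance level (default 0.01)
#' @param hweMethod test variant passed to \code{\link{hweTest}}
#' @return list with \code{genotypes} (filtered GenotypeMatrix) and
#'   \code{report} (per-locus data.frame: locus_id, maf, call_rate, hwe_p,
#'   retained, failed_rule)
#' @export
filterLoci <- function(g, mafMin = 0.05, callRateMin = 0.95,
                       hweAlpha = 0.01, hweMethod = "chisq") {
  stopifnot(mafMin > 0, mafMin < 1, callRateMin > 0, callRateMin <= 1,
            hweAlpha > 0, hweAlpha < 1)
  cd <- genotypeCodes(g)
  n <- nrow(cd)
  callRate <- colMeans(!is.na(cd))
  freq <- colMeans(cd, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  hweP <- vapply(seq_len(ncol(cd)), function(j) {
    x <- cd[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hweTest(sum(x == 0L), sum(x == 1L), sum(x == 2L), method = hweMethod)
  }, 1)
  failed <- rep(NA_character_, ncol(cd))
  failed[is.na(failed) & callRate < callRateMin] <- "call_rate"
  failed[is.na(failed) & maf < mafMin] <- "maf"
  failed[is.na(failed) & !is.na(hweP) & hweP < hweAlpha] <- "hwe"
  keep <- is.na(failed)
  if (!any(keep)) warning("no loci retained by QC filters")
  report <- data.frame(locus_id = colnames(cd), maf = maf,
                       call_rate = callRate, hwe_p = hweP,
                       retained = keep, failed_rule = failed,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(genotypes = g[, which(keep)], report = report)
}

#' Select an equally spaced locus panel
#'
#' Indices are the floor points of a uniform grid over the available loci
#' (first locus always included), matching the construction of low-density
#' panels from a full panel; deterministic.
#'
#' @param nAvailable number of available loci, or a numeric vector of map
#'   positions when \code{spacingBasis = "position"}
#' @param nTarget panel size
#' @param spacingBasis "index" (default) or "position"
#' @return a \linkS4class{PanelSelection} with 1-based indices
#' @examples
#' selectEquallySpaced(10, 5)@indices       # 1 3 5 7 9
#' sel <- selectEquallySpaced(1809, 201)    # the 90% masking panel
#' sel@maskingRate
#' @export
selectEquallySpaced <- function(nAvailable, nTarget,
                                spacingBasis = c("index", "position")) {
  spacingBasis <- match.arg(spacingBasis)
  pos <- NULL
  if (length(nAvailable) > 1) {
    pos <- as.numeric(nAvailable)
    nAvailable <- length(pos)
  }
  nAvailable <- as.integer(nAvailable)
  nTarget <- as.integer(nTarget)
  if (nTarget < 1 || nTarget > nAvailable)
    stop("nTarget must be between 1 and nAvailable")
  if (spacingBasis == "index" || is.null(pos)) {
    idx <- as.integer(floor((seq_len(nTarget) - 1) * nAvailable / nTarget)) + 1L
  } else {
    grid <- seq(min(pos), max(pos), length.out = nTarget)
    idx <- vapply(grid, function(gp) which.min(abs(pos - gp)), 1L)
    idx[1] <- 1L
    idx <- as.integer(sort(unique(idx)))
    # positional grid points can collide on dense maps; fill the shortfall
    # with evenly chosen remaining loci
    if (length(idx) < nTarget) {
      cand <- setdiff(seq_len(nAvailable), idx)
      need <- nTarget - length(idx)
      pick <- cand[as.integer(floor((seq_len(need) - 1) *
                                    length(cand) / need)) + 1L]
      idx <- sort(unique(c(idx, pick)))
    }
  }
  new("PanelSelection", indices = idx, nFull = nAvailable,
      nTarget = length(idx), maskingRate = 1 - length(idx) / nAvailable)
}
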