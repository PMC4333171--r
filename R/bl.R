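#' Prior settings for the Bayesian LASSO
#'
#' Defaults: residual scaled-inverse-chi-square scale S = 1 with df = 1,
#' and Gamma(shape alpha1 = 1.2, rate alpha2 = 1e-5) on lambda^2 (a flat,
#' weakly informative prior on the regularization parameter).
#'
#' @param S,df scaled-inverse-chi-square parameters for the residual variance
#' @param alpha1,alpha2 Gamma shape and rate for lambda^2
#' @return list of validated prior parameters
#' @export
blPriors <- function(S = 1, df = 1, alpha1 = 1.2, alpha2 = 1e-5) {
  stopifnot(S > 0, df > 0, alpha1 > 0, alpha2 > 0)
  list(S = S, df = df, alpha1 = alpha1, alpha2 = alpha2)
}

#' Fit the Bayesian LASSO by Gibbs sampling
#'
#' Whole-genome regression y = mu + X beta + e with independent
#' double-exponential priors on the marker effects, represented as a
#' scale mixture of normals and sampled by Gibbs (Gaussian conditional for
#' each beta_j, inverse-Gaussian for 1/tau2_j, scaled-inverse-chi-square
#' for sigma2, Gamma for lambda2).  Marker covariates are centered (not
#' standardized) with training means; an intercept is always included.
#'
#' @param y numeric response (typically a pre-corrected phenotype)
#' @param X genotype code matrix, individuals x markers, no missing values
#' @param priors list from \code{\link{blPriors}}
#' @param nIter,burnIn,thin chain settings (defaults 6000/1000/5; the
#'   full-scale analysis uses 70000/5000)
#' @param seed integer seed, chain is deterministic given it
#' @param fixTau2,fixSigma2,fixLambda2 optionally freeze a variance at the
#'   given value (NULL = sample); freezing tau2 turns the model into ridge
#'   regression with known shrinkage, used for validation
#' @return a \linkS4class{BLFit}
#' @export
fitBL <- function(y, X, priors = blPriors(), nIter = 6000L, burnIn = 1000L,
                  thin = 5L, seed = 1L, fixTau2 = NULL, fixSigma2 = NULL,
                  fixLambda2 = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), nIter > burnIn, burnIn >= 0)
  if (length(y) < 2) stop("need at least 2 observations")
  if (anyNA(X)) stop("X must be complete (impute or drop missing entries)")
  keep <- which(apply(X, 2, var) > 0)
  if (length(keep) < ncol(X))
    warning(sprintf("dropped %d constant marker column(s)",
                    ncol(X) - length(keep)))
  Xk <- X[, keep, drop = FALSE]
  ctr <- colMeans(Xk)
  Xc <- sweep(Xk, 2, ctr)
  res <- withSeed(seed, .blGibbs(as.numeric(y), Xc,
                                 as.integer(nIter), as.integer(burnIn),
                                 as.integer(thin),
                                 priors$S, priors$df, priors$alpha1,
                                 priors$alpha2,
                                 fixTau2 %||% -1, fixSigma2 %||% -1,
                                 fixLambda2 %||% -1))
  beta <- setNames(drop(res$betaMean), colnames(Xk))
  samples <- as.data.frame(res$samples)
  names(samples) <- c("mu", "sigma_e2", "lambda2", "logPost")
  new("BLFit", mu = res$muMean, beta = beta,
      betaSD = setNames(drop(res$betaSD), colnames(Xk)),
      center = ctr, keep = as.integer(keep), samples = samples,
      settings = list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                      thin = as.integer(thin), seed = as.integer(seed),
                      priors = priors, p = ncol(X)))
}

#' Predict phenotypes from a fitted Bayesian LASSO
#'
#' yhat = mu_hat + X_new beta_hat, with new genotypes centered by the
#' training column means.
#'
#' @param object BLFit
#' @param newdata genotype matrix with the training markers (columns
#'   matched by name when available)
#' @param ... ignored
#' @export
setMethod("predict", "BLFit", function(object, newdata, ...) {
  Xn <- alignColumns(as.matrix(newdata), names(object@beta), object@keep)
  Xc <- sweep(Xn, 2, object@center)
  drop(object@mu + Xc %*% object@beta)
})

# match prediction columns to training markers: by name if both sides are
# named, else by the stored column indices
alignColumns <- function(Xn, markerNames, keep) {
  if (!is.null(colnames(Xn)) && !is.null(markerNames) &&
      all(markerNames %in% colnames(Xn))) {
    Xn[, markerNames, drop = FALSE]
  } else if (ncol(Xn) >= max(keep)) {
    Xn[, keep, drop = FALSE]
  } else {
    stop("column mismatch: cannot align prediction markers with training")
  }
}

#' Exact moments of the Bayesian LASSO full conditional for one effect
#'
#' The Gaussian full conditional used by the sampler for beta_j at fixed
#' (tau2_j, sigma2): mean x'r / (x'x + 1/tau2) and variance
#' sigma2 / (x'x + 1/tau2), with r the residual excluding marker j.
#' Exposed for validation against numerical integration.
#'
#' @param r residual vector excluding the marker's contribution
#' @param x marker covariate vector (centered)
#' @param tau2,sigma2 fixed variance parameters
#' @return list(mean, var)
#' @export
blConditionalMoments <- function(r, x, tau2, sigma2) {
  prec <- sum(x^2) + 1 / tau2
  list(mean = sum(x * r) / prec, var = sigma2 / prec)
}

#' Geweke convergence z-score for a chain segment
#'
#' Compares the means of the first fraction and last fraction of a sample
#' path with a spectral-density-free (batch) variance estimate; |z| < 3 is
#' the working no-trend criterion.
#'
#' @param x numeric sample path (post burn-in)
#' @param frac1,frac2 fractions used for the head and tail windows
#' @export
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[seq.int(n - floor(frac2 * n) + 1, n)]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (se == 0) return(0)
  (mean(a) - mean(b)) / se
}
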