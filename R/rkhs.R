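#' Build Gaussian kernels for RKHS regression with kernel averaging
#'
#' Squared Euclidean distances d_ii' between individuals' (centered)
#' genotype codes; the bandwidth of kernel m is h_m = |a_m| / q0.5 with
#' q0.5 the sample median of the off-diagonal distances, and
#' K_m = exp(-h_m d).  The default multipliers (-5, -1, -1/5) span a
#' local, an intermediate and a global kernel; their magnitudes set the
#' effective bandwidths (see the methods vignette for the sign
#' convention).
#'
#' @param X genotype code matrix, individuals x markers, complete
#' @param multipliers bandwidth multipliers a
#' @return a \linkS4class{KernelSpec}
#' @examples
#' X <- matrix(rbinom(40, 2, 0.5), 10, 4)
#' ks <- buildKernels(X)
#' ks@h
#' @export
buildKernels <- function(X, multipliers = c(-5, -1, -1/5)) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 individuals")
  if (anyNA(X)) stop("X must be complete")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  D <- as.matrix(dist(Xc))^2
  q50 <- median(D[upper.tri(D)])
  if (q50 <= 0)
    stop("median genotype distance is zero (identical rows); ",
         "check loci or add jitter")
  h <- abs(multipliers) / q50
  K <- lapply(h, function(hm) exp(-hm * D))
  new("KernelSpec", D = D, q50 = q50, multipliers = multipliers, h = h,
      K = K, X = Xc, center = ctr)
}

#' Fit RKHS regression with kernel averaging by Gibbs sampling
#'
#' Genotypic values are the sum of one component per kernel,
#' g = f_1 + ... + f_M with f_m ~ N(0, K_m sigma2_m); the component and
#' residual variances carry scaled-inverse-chi-square priors with df = 5
#' and scale S = var(y)/2 * (df - 2) by default.  Sampling is done in
#' each kernel's eigenbasis (eigenvalues below \code{eigTol} dropped,
#' which also enforces positive semi-definiteness).
#'
#' @param y numeric response
#' @param kernels \linkS4class{KernelSpec} from \code{\link{buildKernels}}
#' @param df,S prior degrees of freedom and scale (S = NULL uses the
#'   var(y)-based default)
#' @param nIter,burnIn,thin chain settings (defaults 6000/1000/5; the
#'   full-scale analysis uses 50000/5000)
#' @param seed integer
#' @param fixVarComp optional numeric vector (length M + 1: per-kernel
#'   variances then residual) freezing the variances, for validation
#' @param fixMu optional fixed intercept (NULL = sampled); fixing it makes
#'   the genotypic values identifiable on their own, used for validation
#' @param eigTol eigenvalue floor
#' @return an \linkS4class{RKHSFit}
#' @export
fitRKHS <- function(y, kernels, df = 5, S = NULL, nIter = 6000L,
                    burnIn = 1000L, thin = 5L, seed = 1L,
                    fixVarComp = NULL, fixMu = NULL, eigTol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  M <- length(kernels@K)
  stopifnot(n == nrow(kernels@D), nIter > burnIn)
  if (is.null(S)) S <- var(y) / 2 * (df - 2)
  eig <- lapply(kernels@K, function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8)
      stop("kernel is not positive semi-definite beyond tolerance")
    keep <- which(e$values > eigTol)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  withSeed(seed, {
    mu <- fixMu %||% mean(y)
    a <- lapply(eig, function(e) rep(0, length(e$d)))    # eigen coefficients
    f <- matrix(0, n, M)
    s2a <- rep(var(y) / (2 * M), M)
    s2e <- var(y) / 2
    if (!is.null(fixVarComp)) {
      s2a <- fixVarComp[seq_len(M)]
      s2e <- fixVarComp[M + 1]
    }
    nSamp <- floor((nIter - burnIn) / thin) + 1L
    samples <- matrix(NA_real_, nSamp, M + 2)
    aSum <- lapply(a, function(z) z * 0)
    fSum <- matrix(0, n, M); muSum <- 0; vcSum <- rep(0, M + 1)
    nKept <- 0L; row <- 0L
    for (it in seq_len(nIter)) {
      resid <- y - mu - rowSums(f)
      if (is.null(fixMu)) {
        r <- resid + mu
        mu <- rnorm(1, mean(r), sqrt(s2e / n))
        resid <- r - mu
      }
      # kernel components, each in its eigenbasis
      for (m in seq_len(M)) {
        e <- eig[[m]]
        rm <- resid + f[, m]
        z <- drop(crossprod(e$U, rm))
        v <- 1 / (1 / s2e + 1 / (e$d * s2a[m]))
        aNew <- rnorm(length(z), v * z / s2e, sqrt(v))
        fNew <- drop(e$U %*% aNew)
        resid <- rm - fNew
        a[[m]] <- aNew
        f[, m] <- fNew
        if (is.null(fixVarComp))
          s2a[m] <- (sum(aNew^2 / e$d) + S) / rchisq(1, df + length(e$d))
      }
      if (is.null(fixVarComp))
        s2e <- (sum(resid^2) + S) / rchisq(1, df + n)
      if (it > burnIn) {
        nKept <- nKept + 1L
        muSum <- muSum + mu
        fSum <- fSum + f
        for (m in seq_len(M)) aSum[[m]] <- aSum[[m]] + a[[m]]
        vcSum <- vcSum + c(s2a, s2e)
        if ((it - burnIn - 1L) %% thin == 0L && row < nSamp) {
          row <- row + 1L
          samples[row, ] <- c(mu, s2a, s2e)
        }
      }
    }
    fBar <- fSum / nKept
    alpha <- vapply(seq_len(M), function(m) {
      e <- eig[[m]]
      drop(e$U %*% (aSum[[m]] / nKept / e$d))
    }, numeric(n))
    vc <- vcSum / nKept
    names(vc) <- c(sprintf("sigma2_k%d", seq_len(M)), "sigma_e2")
    samples <- as.data.frame(samples[seq_len(row), , drop = FALSE])
    names(samples) <- c("mu", sprintf("sigma2_k%d", seq_len(M)), "sigma_e2")
    new("RKHSFit", mu = muSum / nKept, f = fBar, alpha = alpha,
        varComp = vc, kernels = kernels, samples = samples,
        settings = list(nIter = as.integer(nIter),
                        burnIn = as.integer(burnIn), thin = as.integer(thin),
                        seed = as.integer(seed), df = df, S = S))
  })
}

#' Predict phenotypes from a fitted RKHS model
#'
#' yhat = mu_hat + sum_m K_m(new, train) alpha_m, with the cross-kernels
#' built at the training bandwidths from distances between new and
#' training genotypes (centered with training means).
#'
#' @param object RKHSFit
#' @param newdata genotype matrix on the training loci
#' @param ... ignored
#' @export
setMethod("predict", "RKHSFit", function(object, newdata, ...) {
  ks <- object@kernels
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(ks@X))
    stop("locus mismatch: expected ", ncol(ks@X), " markers")
  Xc <- sweep(Xn, 2, ks@center)
  # squared Euclidean cross-distances
  Dx <- outer(rowSums(Xc^2), rowSums(ks@X^2), "+") - 2 * Xc %*% t(ks@X)
  Dx[Dx < 0] <- 0
  pred <- rep(object@mu, nrow(Xn))
  for (m in seq_along(ks@h))
    pred <- pred + drop(exp(-ks@h[m] * Dx) %*% object@alpha[, m])
  unname(pred)
})
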