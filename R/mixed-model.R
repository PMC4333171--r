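#' Numerator relationship matrix from a pedigree
#'
#' Tabular recursion: a_jj = 1 + 0.5 a_{sire(j), dam(j)} and
#' a_ij = 0.5 (a_{i, sire(j)} + a_{i, dam(j)}) for i < j, over a
#' topologically ordered pedigree (parents before offspring).  Unordered
#' pedigrees are reordered internally; cycles are an error.
#'
#' @param ped a \linkS4class{Pedigree} or a data.frame with id, sire, dam
#' @return symmetric matrix A with dimnames = individual ids; diagonal
#'   1 + F with F the inbreeding coefficient
#' @examples
#' ped <- data.frame(id = c("a", "b", "x", "y"),
#'                   sire = c(NA, NA, "a", "a"),
#'                   dam  = c(NA, NA, "b", "b"))
#' numeratorRelationship(ped)
#' @export
numeratorRelationship <- function(ped) {
  if (is(ped, "Pedigree")) ped <- pedTable(ped)
  id <- as.character(ped$id); sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  n <- length(id)
  ord <- topoOrder(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  pos <- seq_len(n); names(pos) <- id
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    A[j, j] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (j > 1) {
      i <- seq_len(j - 1L)
      aij <- 0.5 * ((if (s > 0) A[i, s] else rep(0, j - 1L)) +
                    (if (d > 0) A[i, d] else rep(0, j - 1L)))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}

# Kahn topological sort over parent -> offspring edges; error on cycles.
topoOrder <- function(id, sire, dam) {
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  parents <- cbind(ifelse(is.na(sire), 0L, pos[sire]),
                   ifelse(is.na(dam), 0L, pos[dam]))
  if (any(is.na(parents))) stop("pedigree refers to unknown parent ids")
  done <- logical(n); ord <- integer(0)
  repeat {
    ready <- which(!done &
                   (parents[, 1] == 0L | done[pmax(parents[, 1], 1L)]) &
                   (parents[, 2] == 0L | done[pmax(parents[, 2], 1L)]))
    if (!length(ready)) break
    ord <- c(ord, ready); done[ready] <- TRUE
  }
  if (length(ord) < n) stop("cyclic pedigree: no topological order exists")
  ord
}

#' Fit the pedigree mixed model and pre-correct phenotypes
#'
#' Fits y = X theta + W c + Z u + e with u ~ N(0, A sigma_u2),
#' c ~ N(0, I sigma_c2), e ~ N(0, I sigma_e2).  Variance components are
#' estimated by REML (direct maximization of the restricted log-likelihood
#' over the two variance ratios, residual variance profiled out); fixed
#' effects and random-effect solutions come from Henderson's mixed-model
#' equations at the REML estimates.  The corrected response is
#' y* = y - X theta_hat - W c_hat: additive values are estimated but NOT
#' subtracted, so y* retains all genetic signal.
#'
#' @param y numeric response, names = individual ids
#' @param X fixed-effect design matrix (aliased columns dropped internally)
#' @param W cage incidence matrix (n x nCages); NULL drops the cage term
#' @param A numerator relationship matrix covering at least the phenotyped
#'   individuals (row/colnames = ids)
#' @param maxIter maximum optimizer iterations
#' @return a \linkS4class{CorrectedPhenotype}
#' @export
fitMixedModel <- function(y, X, W, A, maxIter = 200L) {
  n <- length(y)
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by individual id")
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  hasCage <- !is.null(W) && ncol(W) > 0
  if (hasCage) W <- as.matrix(W)
  hasA <- !is.null(A)
  if (hasA) {
    As <- A[ids, ids]
    As <- (As + t(As)) / 2
  }

  nr <- n - ncol(X)

  # Work in the eigenbasis of A so that V0 = diag(1 + gu*d) + gc * Wt Wt',
  # invertible in O(n q^2) by Woodbury; gc is the cage/residual variance
  # ratio, gu the additive/residual ratio.
  if (hasA) {
    eg <- eigen(As, symmetric = TRUE)
    U <- eg$vectors
    dA <- pmax(eg$values, 0)
    Xt <- crossprod(U, X)
    yt <- drop(crossprod(U, y))
    Wt <- if (hasCage) crossprod(U, W) else NULL
  } else {
    U <- NULL
    dA <- rep(0, n)
    Xt <- X; yt <- y
    Wt <- if (hasCage) W else NULL
  }
  q <- if (hasCage) ncol(Wt) else 0L

  applyVi <- function(M, dg, gc) {
    M <- as.matrix(M)
    Dm <- M / dg
    if (!hasCage || gc <= 0) return(Dm)
    Wd <- Wt / dg
    Mm <- diag(q) / gc + crossprod(Wt, Wd)
    Dm - Wd %*% solve(Mm, crossprod(Wt, Dm))
  }

  restrictedNegLogLik <- function(par) {
    gu <- if (hasA) exp(par[1]) else 0
    gc <- if (hasCage) exp(par[length(par)]) else 0
    dg <- 1 + gu * dA
    ViX <- applyVi(Xt, dg, gc)
    Viy <- drop(applyVi(yt, dg, gc))
    XtViX <- crossprod(Xt, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(1e10)
    XtViy <- drop(crossprod(Xt, Viy))
    yPy <- sum(yt * Viy) -
      drop(crossprod(XtViy, chol2inv(chX) %*% XtViy))
    if (!is.finite(yPy) || yPy <= 0) return(1e10)
    s2 <- yPy / nr
    logDetV0 <- sum(log(dg))
    if (hasCage && gc > 0) {
      Mm <- diag(q) / gc + crossprod(Wt, Wt / dg)
      chM <- tryCatch(chol(Mm), error = function(e) NULL)
      if (is.null(chM)) return(1e10)
      logDetV0 <- logDetV0 + q * log(gc) + 2 * sum(log(diag(chM)))
    }
    0.5 * (nr * log(s2) + logDetV0 + 2 * sum(log(diag(chX))) + nr)
  }

  nPar <- sum(hasA, hasCage)
  if (nPar == 0) {
    # pure fixed-effects model: OLS
    fit <- stats::lm.fit(X, y)
    theta <- fit$coefficients
    ystar <- y - drop(X %*% theta)
    s2 <- if (nr > 0) sum(ystar^2) / nr else NA_real_
    return(new("CorrectedPhenotype", yStar = setNames(ystar, ids),
               thetaHat = theta, cHat = numeric(0), uHat = numeric(0),
               varianceComponents = c(sigma_u2 = 0, sigma_c2 = 0,
                                      sigma_e2 = s2),
               converged = TRUE, logLik = NA_real_))
  }
  opt <- optim(rep(log(0.5), nPar), restrictedNegLogLik, method = "L-BFGS-B",
               lower = rep(-12, nPar), upper = rep(8, nPar),
               control = list(maxit = maxIter))
  if (opt$convergence != 0)
    stop("REML did not converge: ", opt$message %||% opt$convergence,
         " (value ", signif(opt$value, 6), ")")
  if (any(abs(opt$par) >= 11.9))
    warning("variance ratio estimate pinned at boundary")
  gu <- if (hasA) exp(opt$par[1]) else 0
  gc <- if (hasCage) exp(opt$par[nPar]) else 0

  dg <- 1 + gu * dA
  ViX <- applyVi(Xt, dg, gc)
  Viy <- drop(applyVi(yt, dg, gc))
  XtViX <- crossprod(Xt, ViX)
  XtViy <- drop(crossprod(Xt, Viy))
  yPy <- sum(yt * Viy) -
    drop(crossprod(XtViy, chol2inv(chol(XtViX)) %*% XtViy))
  s2e <- yPy / nr
  s2u <- gu * s2e
  s2c <- gc * s2e

  # Henderson MME at the REML estimates (Z = I on the phenotyped set)
  sol <- solveMME(y, X, if (hasCage) W else NULL, if (hasA) As else NULL,
                  s2u, s2c, s2e)
  ystar <- y - drop(X %*% sol$theta) -
    (if (hasCage) drop(W %*% sol$c) else 0)
  new("CorrectedPhenotype", yStar = setNames(ystar, ids),
      thetaHat = sol$theta, cHat = sol$c, uHat = sol$u,
      varianceComponents = c(sigma_u2 = s2u, sigma_c2 = s2c, sigma_e2 = s2e),
      converged = TRUE, logLik = -opt$value)
}

# Henderson's mixed-model equations; returns solutions and the coefficient
# matrix/rhs so callers can verify the normal equations.
solveMME <- function(y, X, W, As, s2u, s2c, s2e) {
  n <- length(y)
  blocks <- list(X = X)
  if (!is.null(W)) blocks$W <- W
  if (!is.null(As)) blocks$Z <- diag(n)
  M <- do.call(cbind, blocks)
  C <- crossprod(M)
  rhs <- crossprod(M, y)
  px <- ncol(X)
  off <- px
  if (!is.null(W)) {
    qc <- ncol(W)
    i <- off + seq_len(qc)
    C[i, i] <- C[i, i] + diag(qc) * (s2e / max(s2c, 1e-12))
    off <- off + qc
  }
  if (!is.null(As)) {
    i <- off + seq_len(n)
    Ainv <- chol2inv(chol(As + diag(1e-10, n)))
    C[i, i] <- C[i, i] + Ainv * (s2e / max(s2u, 1e-12))
  }
  sol <- solve(C, rhs)
  theta <- drop(sol[seq_len(px)])
  names(theta) <- colnames(X)
  cHat <- if (!is.null(W)) {
    v <- drop(sol[px + seq_len(ncol(W))]); names(v) <- colnames(W); v
  } else numeric(0)
  uHat <- if (!is.null(As)) {
    v <- drop(sol[(length(sol) - n + 1):length(sol)]); names(v) <- names(y); v
  } else numeric(0)
  list(theta = theta, c = cHat, u = uHat, C = C, rhs = rhs, sol = drop(sol))
}

#' Pre-correct a simulated study's phenotypes
#'
#' Convenience wrapper: builds the fixed-effect design (age, gender, month,
#' cage density; treatment coding, first level reference), the cage
#' incidence and the pedigree relationship matrix, then calls
#' \code{\link{fitMixedModel}}.
#'
#' @param study SimulatedStudy with phenotypes
#' @param trait phenotype column to correct
#' @return a \linkS4class{CorrectedPhenotype}
#' @export
precorrectPhenotypes <- function(study, trait) {
  phen <- study@phenotypes
  if (!trait %in% names(phen)) stop("unknown trait: ", trait)
  keep <- !is.na(phen[[trait]])
  phen <- phen[keep, , drop = FALSE]
  y <- setNames(phen[[trait]], phen$id)
  X <- model.matrix(~ age + factor(gender) + factor(month) + cage_density,
                    data = phen)
  W <- model.matrix(~ 0 + factor(cage), data = phen)
  colnames(W) <- sub("^factor\\(cage\\)", "", colnames(W))
  A <- numeratorRelationship(study@pedigree)
  fitMixedModel(y, X, W, A)
}
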