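# Bayesian-regularized single-hidden-layer network, trained by
# Levenberg-Marquardt on f = gamma*E_D + alpha*E_w with evidence-framework
# updates of (alpha, gamma) after each accepted step.  E_D is the sum of
# squared residuals, E_w the sum of squared weights (all parameters).

# weight vector layout: [W1 (s x R, row-major by neuron), b1 (s), w2 (s), b2]
brannUnpack <- function(w, R, s) {
  W1 <- matrix(w[seq_len(s * R)], s, R)
  b1 <- w[s * R + seq_len(s)]
  w2 <- w[s * R + s + seq_len(s)]
  b2 <- w[s * R + 2 * s + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

brannForward <- function(w, X, R, s) {
  pars <- brannUnpack(w, R, s)
  A <- sweep(X %*% t(pars$W1), 2, pars$b1, "+")   # n x s pre-activations
  Hh <- tanh(A)
  yhat <- drop(Hh %*% pars$w2) + pars$b2
  list(H = Hh, yhat = yhat)
}

# Jacobian d yhat / d w (n x P) from a forward pass; the input-weight block
# is ordered column-major (by input, then neuron) to match brannUnpack
brannJacobian <- function(w, X, fw, R, s) {
  pars <- brannUnpack(w, R, s)
  dH <- 1 - fw$H^2                       # n x s
  dHw2 <- sweep(dH, 2, pars$w2, "*")
  J1 <- dHw2[, rep(seq_len(s), R), drop = FALSE] *
    X[, rep(seq_len(R), each = s), drop = FALSE]
  cbind(J1, dHw2, fw$H, 1, deparse.level = 0)
}

brannObjective <- function(w, X, y, alpha, gamma, R, s) {
  fw <- brannForward(w, X, R, s)
  r <- y - fw$yhat
  ED <- sum(r^2)
  EW <- sum(w^2)
  list(f = gamma * ED + alpha * EW, ED = ED, EW = EW, r = r, fw = fw)
}

# analytic gradient of the regularized objective
brannGradient <- function(w, X, y, alpha, gamma, R, s) {
  fw <- brannForward(w, X, R, s)
  J <- brannJacobian(w, X, fw, R, s)
  drop(-2 * gamma * crossprod(J, y - fw$yhat) + 2 * alpha * w)
}

#' Train a Bayesian-regularized neural network ensemble
#'
#' Single hidden layer (tangent-sigmoid) feeding a linear output neuron,
#' trained by Levenberg-Marquardt on the regularized objective
#' f = gamma*E_D + alpha*E_w.  After each accepted step the regularization
#' parameters are re-estimated by the evidence framework: the effective
#' number of parameters is N - 2*alpha*tr(H^-1) with H the Gauss-Newton
#' Hessian of f, then alpha = effN/(2 E_w) and gamma = (n - effN)/(2 E_D).
#' Inputs are scaled per column to [-1, 1] with training min/max; the
#' target is standardized and back-transformed for prediction.  The
#' ensemble averages predictions over random restarts.
#'
#' @param X genotype matrix (individuals x markers)
#' @param y numeric response
#' @param hidden hidden-layer size (default 5)
#' @param epochs Levenberg-Marquardt epochs per restart (default 30)
#' @param restarts random restarts averaged into the ensemble (default 20)
#' @param seed integer
#' @param muInit,muMax initial and maximal LM damping
#' @return a \linkS4class{BRANNFit}
#' @export
trainBRANN <- function(X, y, hidden = 5L, epochs = 30L, restarts = 20L,
                       seed = 1L, muInit = 0.005, muMax = 1e10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), epochs >= 1, restarts >= 1)
  n <- nrow(X); R <- ncol(X); s <- as.integer(hidden)
  xmin <- apply(X, 2, min); xmax <- apply(X, 2, max)
  rng <- xmax - xmin
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(X, 2, xmin), 2, rng, "/") * 2 - 1
  yc <- mean(y); ys <- sd(y)
  if (ys == 0) ys <- 1
  yz <- (y - yc) / ys
  P <- s * (R + 1) + s + 1

  trainOne <- function() {
    # input weights as random directions of moderate norm (covering the
    # [-1,1] input cube), output layer small
    W1 <- matrix(rnorm(s * R), s, R)
    W1 <- W1 / sqrt(rowSums(W1^2)) * 0.7
    w <- c(as.vector(W1), runif(s, -0.7, 0.7), runif(s, -0.5, 0.5),
           runif(1, -0.5, 0.5))
    # start over-regularized: all parameters nominally active, then let the
    # evidence updates relax the penalty (stable direction when P > n)
    ob0 <- brannObjective(w, Xs, yz, 1, 1, R, s)
    alpha <- P / (2 * max(ob0$EW, 1e-12))
    gamma <- if (n > P) (n - P) / (2 * max(ob0$ED, 1e-12)) else 1
    mu <- muInit
    ok <- TRUE
    monotone <- TRUE
    effN <- NA_real_
    for (ep in seq_len(epochs)) {
      ob <- brannObjective(w, Xs, yz, alpha, gamma, R, s)
      if (!is.finite(ob$f)) { ok <- FALSE; break }
      J <- brannJacobian(w, Xs, ob$fw, R, s)
      sv <- svd(J, nu = 0)             # right singular vectors + values
      V <- sv$v; d2 <- sv$d^2          # eigvals of J'J (top k), rest 0
      g <- drop(-2 * gamma * crossprod(J, ob$r) + 2 * alpha * w)
      gv <- drop(crossprod(V, g))
      accepted <- FALSE
      while (mu <= muMax) {
        denomV <- 2 * gamma * d2 + 2 * alpha + mu
        denom0 <- 2 * alpha + mu
        delta <- -(g - drop(V %*% gv)) / denom0 - drop(V %*% (gv / denomV))
        obNew <- brannObjective(w + delta, Xs, yz, alpha, gamma, R, s)
        if (is.finite(obNew$f) && obNew$f < ob$f) {
          if (obNew$f > ob$f + 1e-12) monotone <- FALSE
          w <- w + delta
          ob <- obNew
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
          break
        }
        mu <- mu * 10
      }
      if (!accepted) break             # damping exhausted: local optimum
      # evidence updates at the new point (Gauss-Newton Hessian spectrum)
      trHinv <- sum(1 / (2 * gamma * d2 + 2 * alpha)) +
        (P - length(d2)) / (2 * alpha)
      effN <- P - 2 * alpha * trHinv
      effN <- min(max(effN, 1e-3), P)
      alpha <- max(effN / (2 * max(ob$EW, 1e-12)), 1e-12)
      gamma <- max((n - effN) / (2 * max(ob$ED, 1e-12)), 1e-12)
    }
    ob <- brannObjective(w, Xs, yz, alpha, gamma, R, s)
    list(w = w, alpha = alpha, gamma = gamma, ED = ob$ED, EW = ob$EW,
         effN = effN, ok = ok && is.finite(ob$f), monotone = monotone,
         trainPred = ob$fw$yhat * ys + yc)
  }

  nets <- withSeed(seed, lapply(seq_len(restarts), function(i) trainOne()))
  good <- vapply(nets, function(z) isTRUE(z$ok), TRUE)
  if (!any(good)) stop("all restarts diverged")
  if (!all(good))
    warning(sprintf("%d restart(s) diverged and were excluded",
                    sum(!good)))
  diag <- data.frame(restart = seq_len(restarts),
                     E_D = vapply(nets, `[[`, 1, "ED"),
                     E_w = vapply(nets, `[[`, 1, "EW"),
                     alpha = vapply(nets, `[[`, 1, "alpha"),
                     gamma = vapply(nets, `[[`, 1, "gamma"),
                     effective_params = vapply(nets, `[[`, 1, "effN"),
                     monotone = vapply(nets, function(z)
                       isTRUE(z$monotone), TRUE),
                     converged = good)
  new("BRANNFit", nets = nets[good], hidden = s,
      xRange = rbind(min = xmin, max = xmax), yCenter = yc, yScale = ys,
      diagnostics = diag,
      settings = list(epochs = as.integer(epochs),
                      restarts = as.integer(restarts),
                      seed = as.integer(seed), nInputs = R))
}

#' Predict phenotypes from a trained network ensemble
#'
#' Per-network forward pass on inputs scaled with the training min/max,
#' averaged over restarts and back-transformed to the phenotype scale.
#'
#' @param object BRANNFit
#' @param newdata genotype matrix with the training markers
#' @param ... ignored
#' @export
setMethod("predict", "BRANNFit", function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  R <- object@settings$nInputs
  if (ncol(Xn) != R)
    stop("feature mismatch: expected ", R, " inputs")
  rng <- object@xRange["max", ] - object@xRange["min", ]
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(Xn, 2, object@xRange["min", ]), 2, rng, "/") * 2 - 1
  preds <- vapply(object@nets, function(nt)
    brannForward(nt$w, Xs, R, object@hidden)$yhat, numeric(nrow(Xn)))
  preds <- matrix(preds, nrow = nrow(Xn))
  rowMeans(preds) * object@yScale + object@yCenter
})
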