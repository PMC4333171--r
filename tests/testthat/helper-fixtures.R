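# Shared fixtures and independent oracles, built in code at test time.

# moderate pedigreed study reused across test files (memoized)
tinyStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- makeGeneticMap(3, 30, 80)
      pop <- simulatePopulation(map, nStrains = 8, nFamilies = 24,
                                litterSize = 8, nGenerations = 6,
                                nBreeders = 40, seed = 42)
      cache <<- simulatePhenotypes(pop, seed = 43)
    }
    cache
  }
})

# independent top-down recursive oracle for additive relationships
# (memoized pairwise recursion, distinct from the package's tabular method)
naiveRelationship <- function(ped) {
  if (is(ped, "Pedigree")) ped <- pedTable(ped)
  id <- as.character(ped$id)
  sire <- setNames(as.character(ped$sire), id)
  dam <- setNames(as.character(ped$dam), id)
  memo <- new.env()
  a <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    pos <- match(c(i, j), id)
    val <- if (i == j) {
      s <- sire[i]; d <- dam[i]
      1 + if (!is.na(s) && !is.na(d)) 0.5 * a(s, d) else 0
    } else {
      young <- if (pos[1] > pos[2]) i else j
      old <- if (pos[1] > pos[2]) j else i
      s <- sire[young]; d <- dam[young]
      0.5 * ((if (!is.na(s)) a(old, s) else 0) +
             (if (!is.na(d)) a(old, d) else 0))
    }
    memo[[key]] <- val
    val
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- a(id[i], id[j])
  A
}

# exhaustive-path oracle for the diploid haplotype-copying HMM: enumerates
# all (H^2)^L state paths and accumulates per-locus template-dosage
# posteriors
enumDiploidPosterior <- function(H, obs, s, eps) {
  nh <- nrow(H); L <- ncol(H)
  em <- function(g, b1, b2) {
    if (g < 0) return(1)
    q <- function(b) if (b == 1) 1 - eps else eps
    qa <- q(b1); qb <- q(b2)
    switch(g + 1, (1 - qa) * (1 - qb), qa * (1 - qb) + (1 - qa) * qb, qa * qb)
  }
  states <- expand.grid(j = seq_len(nh), k = seq_len(nh))
  paths <- as.matrix(expand.grid(rep(list(seq_len(nrow(states))), L)))
  post <- matrix(0, L, 3)
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    pr <- 1 / nh^2
    for (l in seq_len(L)) {
      j <- states$j[pth[l]]; k <- states$k[pth[l]]
      if (l > 1) {
        T1 <- (1 - s[l]) * diag(nh) + s[l] / nh
        pr <- pr * T1[states$j[pth[l - 1]], j] * T1[states$k[pth[l - 1]], k]
      }
      pr <- pr * em(obs[l], H[j, l], H[k, l])
    }
    tot <- tot + pr
    for (l in seq_len(L)) {
      d <- H[states$j[pth[l]], l] + H[states$k[pth[l]], l]
      post[l, d + 1] <- post[l, d + 1] + pr
    }
  }
  post / tot
}

# brute-force per-locus QC reimplementation (plain loops, no shared code)
bruteForceQC <- function(codes, mafMin = 0.05, callRateMin = 0.95,
                         hweAlpha = 0.01) {
  keep <- logical(ncol(codes))
  for (j in seq_len(ncol(codes))) {
    x <- codes[, j]
    cr <- mean(!is.na(x))
    x <- x[!is.na(x)]
    pa <- if (length(x)) mean(x) / 2 else NA
    maf <- if (is.na(pa)) 0 else min(pa, 1 - pa)
    pval <- 1
    if (length(x) && pa > 0 && pa < 1) {
      nn <- length(x)
      e <- nn * c((1 - pa)^2, 2 * pa * (1 - pa), pa^2)
      o <- c(sum(x == 0), sum(x == 1), sum(x == 2))
      pval <- stats::pchisq(sum((o - e)^2 / e), 1, lower.tail = FALSE)
    }
    keep[j] <- cr >= callRateMin && maf >= mafMin && pval >= hweAlpha
  }
  keep
}
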