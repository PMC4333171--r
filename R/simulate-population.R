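#' Simulate a pedigreed outbred population from inbred founder strains
#'
#' Gene dropping in the style of a heterogeneous stock: fully homozygous
#' inbred founder strains are crossed and randomly mated for several
#' generations (recombination under the Haldane model, no interference),
#' and the final generation is organised into full-sib families with cage
#' assignment confounded with family.
#'
#' @param map genetic map data.frame from \code{\link{makeGeneticMap}}
#' @param nStrains number of inbred founder strains (>= 2)
#' @param nFamilies number of full-sib families in the final generation
#' @param litterSize offspring per family (>= 1)
#' @param nGenerations number of generations after the founders (>= 1); the
#'   final one is the family-structured, phenotyped generation
#' @param nBreeders breeding individuals per intermediate generation
#' @param splitCageFraction fraction of families split across two cages
#'   (cage is otherwise identical to family)
#' @param founders optional n_strains x n_loci 0/1 matrix of strain
#'   haplotypes; by default strains are drawn so every locus segregates
#' @param seed integer seed; the result is deterministic given the seed
#' @return a \linkS4class{SimulatedStudy} with phased haplotypes, genotype
#'   codes counting simulator allele "1", and an empty phenotype table
#'   (see \code{\link{simulatePhenotypes}})
#' @examples
#' map <- makeGeneticMap(2, 20, 50)
#' pop <- simulatePopulation(map, nStrains = 4, nFamilies = 10,
#'                           litterSize = 4, nGenerations = 3, seed = 1)
#' pop
#' @export
simulatePopulation <- function(map, nStrains = 8, nFamilies = 60,
                               litterSize = 10, nGenerations = 12,
                               nBreeders = 64, splitCageFraction = 0.1,
                               founders = NULL, seed = 1L) {
  validateGeneticMap(map)
  if (nStrains < 2) stop("configuration error: nStrains must be >= 2")
  if (nGenerations < 1) stop("configuration error: nGenerations must be >= 1")
  if (litterSize < 1) stop("configuration error: litterSize must be >= 1")
  if (nBreeders < 2) stop("configuration error: nBreeders must be >= 2")
  p <- nrow(map)
  withSeed(seed, {
    if (is.null(founders)) {
      founders <- matrix(rbinom(nStrains * p, 1L, 0.5), nStrains, p)
      # resample loci fixed across strains so every locus segregates
      fixed <- which(colSums(founders) %in% c(0L, nStrains))
      while (length(fixed)) {
        founders[, fixed] <- rbinom(nStrains * length(fixed), 1L, 0.5)
        fixed <- which(colSums(founders) %in% c(0L, nStrains))
      }
    } else {
      if (nrow(founders) != nStrains || ncol(founders) != p)
        stop("configuration error: founders must be nStrains x nLoci")
    }
    storage.mode(founders) <- "integer"

    # per-interval transmission: within a chromosome, switch parental strand
    # with the Haldane recombination fraction; strands independent across
    # chromosomes
    chrom <- map$chromosome
    recFrac <- haldaneRecFraction(c(0, diff(map$position_cM)))
    newChrom <- c(TRUE, diff(chrom) != 0)
    recFrac[newChrom] <- 0.5   # re-draw the starting strand each chromosome

    gamete <- function(h1, h2) {
      sw <- rbinom(p, 1L, recFrac)
      sw[1] <- rbinom(1, 1L, 0.5)
      strand <- cumsum(sw) %% 2L
      ifelse(strand == 0L, h1, h2)
    }

    ids <- sprintf("S%02d", seq_len(nStrains))
    ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                      generation = 0L, family = NA_character_,
                      cage = NA_character_, stringsAsFactors = FALSE)
    hap1 <- founders
    hap2 <- founders
    rownames(hap1) <- rownames(hap2) <- ids

    prev <- ids
    if (nGenerations > 1) {
      for (g in seq_len(nGenerations - 1L)) {
        kids <- sprintf("G%02d_%03d", g, seq_len(nBreeders))
        sires <- character(nBreeders); dams <- character(nBreeders)
        h1 <- matrix(0L, nBreeders, p); h2 <- matrix(0L, nBreeders, p)
        for (k in seq_len(nBreeders)) {
          pr <- sample(prev, 2L)
          sires[k] <- pr[1]; dams[k] <- pr[2]
          h1[k, ] <- gamete(hap1[pr[1], ], hap2[pr[1], ])
          h2[k, ] <- gamete(hap1[pr[2], ], hap2[pr[2], ])
        }
        rownames(h1) <- rownames(h2) <- kids
        ped <- rbind(ped, data.frame(id = kids, sire = sires, dam = dams,
                                     generation = g, family = NA_character_,
                                     cage = NA_character_,
                                     stringsAsFactors = FALSE))
        hap1 <- rbind(hap1, h1); hap2 <- rbind(hap2, h2)
        prev <- kids
      }
    }

    # final generation: nFamilies sire-dam pairs, full-sib litters,
    # cage ~ family with a fraction of families split into two cages
    gF <- nGenerations
    if (length(prev) < 2) stop("configuration error: too few breeders")
    pairs <- vector("list", nFamilies)
    for (f in seq_len(nFamilies)) pairs[[f]] <- sample(prev, 2L)
    splitFam <- runif(nFamilies) < splitCageFraction
    n_off <- nFamilies * litterSize
    kids <- sprintf("F%03d_%02d", rep(seq_len(nFamilies), each = litterSize),
                    rep(seq_len(litterSize), nFamilies))
    fams <- sprintf("fam%03d", rep(seq_len(nFamilies), each = litterSize))
    cages <- character(n_off)
    h1 <- matrix(0L, n_off, p); h2 <- matrix(0L, n_off, p)
    sires <- character(n_off); dams <- character(n_off)
    k <- 0L
    for (f in seq_len(nFamilies)) {
      pr <- pairs[[f]]
      half <- ceiling(litterSize / 2)
      for (j in seq_len(litterSize)) {
        k <- k + 1L
        sires[k] <- pr[1]; dams[k] <- pr[2]
        h1[k, ] <- gamete(hap1[pr[1], ], hap2[pr[1], ])
        h2[k, ] <- gamete(hap1[pr[2], ], hap2[pr[2], ])
        cages[k] <- if (splitFam[f] && j > half)
          sprintf("cage%03db", f) else sprintf("cage%03da", f)
      }
    }
    rownames(h1) <- rownames(h2) <- kids
    ped <- rbind(ped, data.frame(id = kids, sire = sires, dam = dams,
                                 generation = gF, family = fams, cage = cages,
                                 stringsAsFactors = FALSE))
    hap1 <- rbind(hap1, h1); hap2 <- rbind(hap2, h2)

    codes <- hap1 + hap2
    storage.mode(codes) <- "integer"
    colnames(codes) <- map$locus_id
    colnames(hap1) <- colnames(hap2) <- map$locus_id
    gm <- new("GenotypeMatrix", codes = codes, map = map,
              codedAllele = rep("1", p))
    new("SimulatedStudy", genotypes = gm, hap1 = hap1, hap2 = hap2,
        pedigree = new("Pedigree", ped = ped),
        phenotypes = data.frame(), trueBreedingValues = matrix(0, 0, 0),
        qtl = list(), architectures = list())
  })
}

#' Check Mendelian consistency of a simulated study
#'
#' Verifies, at every (individual, locus) pair with known parents, that each
#' transmitted haplotype allele occurs in the corresponding parent.
#'
#' @param study a SimulatedStudy
#' @return fraction of (individual, locus) pairs that are Mendelian-consistent
#' @export
mendelianConsistency <- function(study) {
  ped <- pedTable(study)
  off <- which(!is.na(ped$sire))
  if (!length(off)) return(1)
  ok <- 0; tot <- 0
  for (i in off) {
    id <- ped$id[i]
    for (side in 1:2) {
      h <- if (side == 1) study@hap1[id, ] else study@hap2[id, ]
      par <- if (side == 1) ped$sire[i] else ped$dam[i]
      okv <- h == study@hap1[par, ] | h == study@hap2[par, ]
      ok <- ok + sum(okv); tot <- tot + length(okv)
    }
  }
  ok / tot
}
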