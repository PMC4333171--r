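#' Build a genetic map
#'
#' Regularly or randomly spaced loci on one or more chromosomes, positions
#' in centimorgans.  Positions are rounded to 0.001 cM so they survive
#' integer-position file formats losslessly.
#'
#' @param nChromosomes number of chromosomes (>= 1)
#' @param lociPerChromosome loci per chromosome (>= 2), recycled
#' @param lengthCM chromosome length in centimorgans, recycled
#' @param spacing "uniform" for an even grid (endpoints included) or
#'   "random" for sorted uniform draws
#' @param seed integer, used only when \code{spacing = "random"}
#' @return data.frame with columns locus_id, chromosome, position_cM,
#'   ordered by chromosome then position
#' @examples
#' map <- makeGeneticMap(2, 20, 100)
#' head(map)
#' @export
makeGeneticMap <- function(nChromosomes = 5, lociPerChromosome = 60,
                           lengthCM = 100, spacing = c("uniform", "random"),
                           seed = 1L) {
  spacing <- match.arg(spacing)
  stopifnot(nChromosomes >= 1)
  lociPerChromosome <- rep_len(as.integer(lociPerChromosome), nChromosomes)
  lengthCM <- rep_len(lengthCM, nChromosomes)
  if (any(lociPerChromosome < 2))
    stop("invalid map: each chromosome needs at least 2 loci")
  build <- function() {
    do.call(rbind, lapply(seq_len(nChromosomes), function(ch) {
      L <- lociPerChromosome[ch]
      pos <- switch(spacing,
        uniform = seq(0, lengthCM[ch], length.out = L),
        random  = sort(runif(L, 0, lengthCM[ch])))
      pos <- round(pos, 3)
      # enforce strict increase after rounding/deduplication
      while (anyDuplicated(pos)) {
        pos[duplicated(pos)] <- pos[duplicated(pos)] + 0.001
        pos <- sort(round(pos, 3))
      }
      data.frame(locus_id = sprintf("chr%d_%04d", ch, seq_len(L)),
                 chromosome = ch, position_cM = pos,
                 stringsAsFactors = FALSE)
    }))
  }
  map <- if (spacing == "random") withSeed(seed, build()) else build()
  rownames(map) <- NULL
  validateGeneticMap(map)
  map
}

# Invariants: >=1 chromosome, >=2 loci per chromosome, strictly increasing
# positions within chromosome.
validateGeneticMap <- function(map) {
  if (!all(c("locus_id", "chromosome", "position_cM") %in% names(map)))
    stop("invalid map: need locus_id, chromosome, position_cM columns")
  if (anyDuplicated(map$locus_id)) stop("invalid map: duplicated locus ids")
  sp <- split(map$position_cM, map$chromosome)
  if (any(vapply(sp, length, 1L) < 2))
    stop("invalid map: each chromosome needs at least 2 loci")
  if (any(vapply(sp, function(p) any(diff(p) <= 0), TRUE)))
    stop("invalid map: positions must be strictly increasing within chromosome")
  invisible(map)
}

# Haldane map function: recombination fraction between loci d cM apart.
haldaneRecFraction <- function(dCM) 0.5 * (1 - exp(-2 * dCM / 100))
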