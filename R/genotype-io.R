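#' Construct a GenotypeMatrix
#'
#' @param codes integer matrix of 0/1/2 codes (NA = missing), rownames =
#'   individual ids, colnames = locus ids
#' @param map locus metadata (locus_id, chromosome, position_cM); default is
#'   a trivial single-chromosome map with unit spacing
#' @param codedAllele per-locus label of the counted allele
#' @return a \linkS4class{GenotypeMatrix}, loci reordered to map order
#'   (chromosome, then position, ties by locus id)
#' @export
genotypeMatrix <- function(codes, map = NULL, codedAllele = NULL) {
  storage.mode(codes) <- "integer"
  if (is.null(colnames(codes)))
    colnames(codes) <- if (!is.null(map)) as.character(map$locus_id)
      else sprintf("snp%04d", seq_len(ncol(codes)))
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("ind%04d", seq_len(nrow(codes)))
  if (is.null(map))
    map <- data.frame(locus_id = colnames(codes), chromosome = 1L,
                      position_cM = seq_len(ncol(codes)) - 1,
                      stringsAsFactors = FALSE)
  if (is.null(codedAllele)) codedAllele <- rep("counted", ncol(codes))
  o <- order(map$chromosome, map$position_cM, map$locus_id)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  codes <- codes[, as.character(map$locus_id), drop = FALSE]
  new("GenotypeMatrix", codes = codes, map = map,
      codedAllele = codedAllele[o])
}

#' Read genotypes from TSV or VCF
#'
#' The TSV dialect is tab-separated with a header row of locus ids and the
#' individual id in the first column; cells are 0/1/2 or "NA".  The VCF
#' reader (4.2, GT field only) codes genotypes as ALT-allele dosage, so
#' "0/1", "1/0" and "0|1" all map to 1; positions are interpreted as
#' milli-centimorgans (the writer's convention).
#'
#' @param path file path
#' @param format "tsv" or "vcf"
#' @param map optional locus metadata for TSV input (data.frame or path to
#'   a map TSV written by \code{\link{writeGeneticMap}})
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                colClasses = list(character = 1))
    ids <- dt[[1]]
    if (anyDuplicated(ids)) stop("validation error: duplicated individual ids")
    m <- as.matrix(dt[, -1, drop = FALSE])
    bad <- which(!(is.na(m) | m %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("parse error at line %d: unknown genotype symbol '%s'",
                   bad[1, 1] + 1L, m[bad[1, 1], bad[1, 2]]))
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    if (is.character(map)) map <- readGeneticMap(map)
    genotypeMatrix(m, map = map)
  } else {
    vcf <- suppressWarnings(readVcf(path, genome = "synthetic"))
    gt <- geno(vcf)$GT
    if (is.null(gt)) stop("parse error: VCF has no GT field")
    dose <- function(x) {
      if (x %in% c(".", "./.", ".|.")) return(NA_integer_)
      al <- strsplit(x, "[/|]")[[1]]
      if (!all(al %in% c("0", "1")))
        stop("parse error: unknown allele symbol '", x, "'")
      sum(al == "1")
    }
    m <- t(apply(gt, c(1, 2), dose))
    if (anyDuplicated(rownames(m)))
      stop("validation error: duplicated individual ids")
    rr <- SummarizedExperiment::rowRanges(vcf)
    map <- data.frame(locus_id = names(rr),
                      chromosome = as.integer(as.character(seqnames(rr))),
                      position_cM = start(rr) / 1000,
                      stringsAsFactors = FALSE)
    colnames(m) <- map$locus_id
    genotypeMatrix(m, map = map,
                   codedAllele = rep("ALT", ncol(m)))
  }
}

#' Write genotypes to TSV or VCF 4.2
#'
#' The VCF writer emits one biallelic record per locus (REF "A" = the
#' non-counted allele, ALT "C" = the counted allele), POS = map position in
#' milli-centimorgans, and GT as ALT dosage.  If phased haplotypes are
#' supplied GT is phased ("0|1"), otherwise unphased.
#'
#' @param g GenotypeMatrix
#' @param path output file
#' @param format "tsv" or "vcf"
#' @param haplotypes optional list(hap1, hap2) of 0/1 matrices for phased GT
#' @return path, invisibly
#' @export
writeGenotypes <- function(g, path, format = c("tsv", "vcf"),
                           haplotypes = NULL) {
  format <- match.arg(format)
  cd <- genotypeCodes(g)
  if (format == "tsv") {
    dt <- data.table(id = rownames(cd))
    for (j in colnames(cd)) dt[[j]] <- cd[, j]
    fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    map <- locusMap(g)
    p <- nrow(map); n <- nrow(cd)
    if (is.null(haplotypes)) {
      gtChar <- matrix("./.", p, n)
      gtChar[!is.na(t(cd)) & t(cd) == 0L] <- "0/0"
      gtChar[!is.na(t(cd)) & t(cd) == 1L] <- "0/1"
      gtChar[!is.na(t(cd)) & t(cd) == 2L] <- "1/1"
    } else {
      h1 <- t(haplotypes[[1]][rownames(cd), colnames(cd), drop = FALSE])
      h2 <- t(haplotypes[[2]][rownames(cd), colnames(cd), drop = FALSE])
      gtChar <- matrix(paste0(as.vector(h1), "|", as.vector(h2)), p, n)
      gtChar[is.na(t(cd))] <- ".|."
    }
    dimnames(gtChar) <- list(map$locus_id, rownames(cd))
    gr <- GRanges(as.character(map$chromosome),
                  IRanges(start = as.integer(round(map$position_cM * 1000)),
                          width = 1L))
    names(gr) <- map$locus_id
    vcf <- VCF(rowRanges = gr,
               colData = DataFrame(Samples = seq_len(n),
                                   row.names = rownames(cd)),
               fixed = DataFrame(REF = DNAStringSet(rep("A", p)),
                                 ALT = DNAStringSetList(as.list(rep("C", p))),
                                 QUAL = rep(NA_real_, p),
                                 FILTER = rep("PASS", p)),
               geno = SimpleList(GT = gtChar))
    geno(header(vcf)) <- DataFrame(Number = "1", Type = "String",
                                   Description = "Genotype",
                                   row.names = "GT")
    hd <- header(vcf)
    meta(hd)$fileformat <- DataFrame(Value = "VCFv4.2", row.names = "fileformat")
    header(vcf) <- hd
    writeVcf(vcf, path)
  }
  invisible(path)
}

#' Read/write helpers for maps, pedigrees and phenotype tables
#'
#' Plain-text side formats: map TSV (locus_id, chromosome, position_cM),
#' pedigree CSV (id, sire, dam, generation, family, cage) and phenotype CSV.
#'
#' @param map,ped,phen objects to write
#' @param path file path
#' @name side-io
NULL

#' @rdname side-io
#' @export
writeGeneticMap <- function(map, path) {
  fwrite(as.data.table(map), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname side-io
#' @export
readGeneticMap <- function(path) {
  map <- as.data.frame(fread(path, sep = "\t"))
  map$locus_id <- as.character(map$locus_id)
  validateGeneticMap(map)
  map
}

#' @rdname side-io
#' @export
writePedigree <- function(ped, path) {
  if (is(ped, "Pedigree")) ped <- pedTable(ped)
  fwrite(as.data.table(ped), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname side-io
#' @export
readPedigree <- function(path) {
  p <- as.data.frame(fread(path, na.strings = c("NA", "")))
  for (col in c("id", "sire", "dam", "family", "cage"))
    p[[col]] <- as.character(p[[col]])
  new("Pedigree", ped = p)
}

#' @rdname side-io
#' @export
writePhenotypes <- function(phen, path) {
  fwrite(as.data.table(phen), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname side-io
#' @export
readPhenotypes <- function(path) {
  as.data.frame(fread(path, na.strings = c("NA", "")))
}

#' Recode genotypes so the counted allele is the sample-major allele
#'
#' Loci at which the currently counted allele has sample frequency below
#' 0.5 (missing entries ignored) are flipped (code c to 2 - c); exact 50/50
#' ties keep the current coding (tie broken toward the allele first seen).
#' Monomorphic loci are kept and flagged.
#'
#' @param g GenotypeMatrix
#' @return list with \code{genotypes} (recoded GenotypeMatrix),
#'   \code{flipped} (logical per locus) and \code{monomorphic} (logical)
#' @export
recodeByMajorAllele <- function(g) {
  cd <- genotypeCodes(g)
  freq <- colMeans(cd, na.rm = TRUE) / 2   # frequency of the counted allele
  flip <- !is.na(freq) & freq < 0.5
  cd[, flip] <- 2L - cd[, flip, drop = FALSE]
  mono <- apply(cd, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && (all(x == 0L) || all(x == 2L))
  })
  ca <- codedAllele(g)
  ca[flip] <- flipAlleleLabel(ca[flip])
  out <- new("GenotypeMatrix", codes = cd, map = locusMap(g),
             codedAllele = ca)
  list(genotypes = out, flipped = flip, monomorphic = mono)
}

flipAlleleLabel <- function(x) {
  swap <- c("1" = "0", "0" = "1", "ALT" = "REF", "REF" = "ALT")
  out <- ifelse(x %in% names(swap), swap[x], paste0("other:", x))
  unname(out)
}
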