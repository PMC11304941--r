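# Population simulator: homozygous founders, circular chain-crossing
# pedigree, Poisson crossovers with uniform bp placement, allele-flip
# genotyping errors, full recombination truth.

#' Simulate founder haplotypes
#'
#' Each founder receives one fully homozygous haplotype. The minor-allele
#' frequency of every locus is drawn uniformly from `mafRange` and each
#' founder's allele at that locus is minor (code 2) with that probability,
#' independently across loci. Founders are forced pairwise distinct at one or
#' more loci.
#'
#' @param nFounders number of founder lines (>= 2).
#' @param nLoci number of loci (>= 1).
#' @param mafRange length-2 numeric, bounds of the uniform MAF draw.
#' @return integer matrix `nFounders x nLoci` of allele codes 1/2, rownames
#'   `F1..Fn`.
#' @export
simulateFounders <- function(nFounders, nLoci, mafRange = c(0.1, 0.5)) {
  stopifnot(nFounders >= 2)
  if (nLoci < 1) stop("locus count must be positive")
  maf <- stats::runif(nLoci, mafRange[1], mafRange[2])
  hap <- matrix(1L, nFounders, nLoci)
  hap[stats::runif(nFounders * nLoci) <
        matrix(maf, nFounders, nLoci, byrow = TRUE)] <- 2L
  rownames(hap) <- paste0("F", seq_len(nFounders))
  # force pairwise-distinct founders
  repeat {
    dup <- which(duplicated(hap))
    if (!length(dup)) break
    for (i in dup) {
      j <- sample.int(nLoci, 1L)
      hap[i, j] <- 3L - hap[i, j]
    }
  }
  hap
}

#' Simulate one meiosis
#'
#' The number of crossovers is Poisson with mean `meanCO`; breakpoint bp
#' positions are uniform over the chromosome span (between the first and last
#' marker). The gamete is the alternating mosaic of the two parental
#' homologs, starting from a fair-coin choice.
#'
#' @param hap1,hap2 the parent's two homolog allele vectors.
#' @param bp marker bp positions (sorted).
#' @param meanCO mean crossover count per meiosis.
#' @param f1,f2 optional companion vectors (e.g. founder-of-origin) inherited
#'   alongside the alleles.
#' @return list with `gamete`, `breakpoints` (numeric bp vector), and
#'   `origin` (the companion mosaic, when `f1` given).
#' @export
meiosis <- function(hap1, hap2, bp, meanCO = 1.5, f1 = NULL, f2 = NULL) {
  stopifnot(length(hap1) == length(hap2))
  nCO <- stats::rpois(1L, meanCO)
  span <- range(bp)
  bks <- sort(stats::runif(nCO, span[1], span[2]))
  start <- sample.int(2L, 1L)
  # homolog in use at each locus: start, switching at every breakpoint
  seg <- (start - 1L + findInterval(bp, bks)) %% 2L
  gamete <- ifelse(seg == 0L, hap1, hap2)
  out <- list(gamete = gamete, breakpoints = bks)
  if (!is.null(f1)) out$origin <- ifelse(seg == 0L, f1, f2)
  out
}

#' Simulate a multiparental population with recombination truth
#'
#' Builds a chain-crossing pedigree from homozygous founders: generation G1
#' consists of the circular chain of founder crosses (founder j x founder
#' j+1); in every later generation, cross j mates an offspring of cross j
#' with an offspring of the adjacent cross j+1, so founder genomes keep
#' accumulating along the chain and mates are never full sibs. Each cross
#' contributes `offspringPerCross` offspring (all genotyped and all carrying
#' two evaluable meioses; the firstborn breeds on), down to generation
#' `depth`. Every meiosis draws a Poisson number of crossovers placed
#' uniformly in bp; each child's homolog records the founder line of origin
#' at every locus and the true breakpoint positions. All generations are
#' genotyped. Genotyping errors, if requested, are injected with
#' [injectErrors()] after genotypes are assembled.
#'
#' @param nFounders number of founder lines.
#' @param depth last generation index (`depth = 4` gives G0..G4).
#' @param offspringPerCross offspring per cross.
#' @param nLoci number of SNP loci.
#' @param chromLen chromosome length in bp; marker positions are a sorted
#'   sample without replacement of `1..chromLen`.
#' @param meanCO mean crossovers per meiosis per chromosome.
#' @param mafRange founder minor-allele-frequency range.
#' @param geRates genotyping-error rates: `NULL` for none, a scalar applied
#'   to generations 2..depth, or a named vector mapping generation to rate.
#' @param seed optional RNG seed for full reproducibility.
#' @return list with `geno` (a [MagicGeno-class]) and `truth`: `breakpoints`
#'   (data.frame `id`, `homolog`, `bp` — the meiosis producing that child's
#'   homolog), `founderOrigins` (per individual, per homolog, founder id per
#'   locus), and `nErrors` (injected error count per generation).
#' @export
simulatePopulation <- function(nFounders = 8, depth = 4, offspringPerCross = 2,
                               nLoci = 500, chromLen = 1e6, meanCO = 1.5,
                               mafRange = c(0.1, 0.5), geRates = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(depth >= 1, offspringPerCross >= 1)
  if (nFounders < 2) stop("chain crossing needs at least 2 founders")
  bp <- sort(sample.int(chromLen, nLoci))
  map <- data.frame(chrom = "1", marker = sprintf("snp%05d", seq_len(nLoci)),
                    bp = bp, stringsAsFactors = FALSE)
  fhap <- simulateFounders(nFounders, nLoci, mafRange)

  haps <- list()   # per id: list(pat, mat) allele vectors
  forig <- list()  # per id: list(pat, mat) founder-of-origin vectors
  ped <- data.frame(id = rownames(fhap), father = NA_character_,
                    mother = NA_character_, stringsAsFactors = FALSE)
  for (f in rownames(fhap)) {
    haps[[f]] <- list(pat = fhap[f, ], mat = fhap[f, ])
    forig[[f]] <- list(pat = rep(f, nLoci), mat = rep(f, nLoci))
  }
  bkRows <- list()
  # chain of nFounders crosses: cross j of G1 is founder j x founder j+1
  # (circular); in later generations cross j mates an offspring of cross j
  # with an offspring of the adjacent cross j+1, so founders keep
  # accumulating along the chain and mates are never full sibs
  nCross <- nFounders
  crossRep <- rownames(fhap)  # representative parent contributed by cross j
  for (g in seq_len(depth)) {
    firstborn <- character(nCross)
    cur <- character(0)
    for (i in seq_len(nCross)) {
      fa <- crossRep[i]
      mo <- crossRep[if (i == nCross) 1L else i + 1L]
      for (o in seq_len(offspringPerCross)) {
        id <- sprintf("G%d_%d_%d", g, i, o)
        mp <- meiosis(haps[[fa]]$pat, haps[[fa]]$mat, bp, meanCO,
                      forig[[fa]]$pat, forig[[fa]]$mat)
        mm <- meiosis(haps[[mo]]$pat, haps[[mo]]$mat, bp, meanCO,
                      forig[[mo]]$pat, forig[[mo]]$mat)
        haps[[id]] <- list(pat = mp$gamete, mat = mm$gamete)
        forig[[id]] <- list(pat = mp$origin, mat = mm$origin)
        if (length(mp$breakpoints)) {
          bkRows[[length(bkRows) + 1L]] <-
            data.frame(id = id, homolog = "P", bp = mp$breakpoints)
        }
        if (length(mm$breakpoints)) {
          bkRows[[length(bkRows) + 1L]] <-
            data.frame(id = id, homolog = "M", bp = mm$breakpoints)
        }
        ped <- rbind(ped, data.frame(id = id, father = fa, mother = mo,
                                     stringsAsFactors = FALSE))
        if (o == 1L) firstborn[i] <- id
        cur <- c(cur, id)
      }
    }
    crossRep <- firstborn
  }
  ids <- ped$id
  a1 <- t(vapply(ids, function(id) pmin(haps[[id]]$pat, haps[[id]]$mat),
                 integer(nLoci)))
  a2 <- t(vapply(ids, function(id) pmax(haps[[id]]$pat, haps[[id]]$mat),
                 integer(nLoci)))
  geno <- magicGeno(ped, a1, a2, map,
                    metadata = list(meanCO = meanCO, nFounders = nFounders,
                                    depth = depth))
  nErrors <- setNames(integer(depth + 1L), as.character(0:depth))
  if (!is.null(geRates)) {
    inj <- injectErrors(geno, geRates)
    geno <- inj$geno
    nErrors[names(inj$nErrors)] <- inj$nErrors
  }
  breakpoints <- if (length(bkRows)) do.call(rbind, bkRows) else
    data.frame(id = character(0), homolog = character(0), bp = numeric(0))
  list(geno = geno,
       truth = list(breakpoints = breakpoints, founderOrigins = forig,
                    founderHaplotypes = fhap, nErrors = nErrors))
}

#' Inject genotyping errors into a genotype table
#'
#' Independently for every genotype cell of an error-bearing generation, with
#' the configured probability one of the two alleles (chosen uniformly) is
#' flipped to the other allele code. Missing genotypes are left untouched.
#'
#' @param geno a [MagicGeno-class] object.
#' @param geRates scalar rate (applied to generations 2 and later) or a named
#'   vector mapping generation index to rate; rates in `[0,1]`.
#' @return list with the perturbed `geno` and `nErrors`, the per-generation
#'   count of perturbed genotypes.
#' @export
injectErrors <- function(geno, geRates) {
  ped <- geno@pedigree
  gens <- sort(unique(ped$generation))
  if (is.null(names(geRates))) {
    stopifnot(length(geRates) == 1L)
    geRates <- setNames(rep(geRates, sum(gens >= 2L)),
                        as.character(gens[gens >= 2L]))
  }
  if (any(geRates < 0 | geRates > 1)) stop("error rates must lie in [0,1]")
  a1 <- geno@alleles1
  a2 <- geno@alleles2
  nErrors <- setNames(integer(length(geRates)), names(geRates))
  for (g in names(geRates)) {
    rate <- geRates[[g]]
    if (rate == 0) next
    ids <- ped$id[ped$generation == as.integer(g)]
    ids <- ids[ids %in% rownames(a1)]
    if (!length(ids)) next
    sub1 <- a1[ids, , drop = FALSE]
    sub2 <- a2[ids, , drop = FALSE]
    hit <- matrix(stats::runif(length(sub1)) < rate, nrow(sub1)) & sub1 != 0L
    pickFirst <- matrix(stats::runif(length(sub1)) < 0.5, nrow(sub1))
    flip1 <- hit & pickFirst
    flip2 <- hit & !pickFirst
    sub1[flip1] <- 3L - sub1[flip1]
    sub2[flip2] <- 3L - sub2[flip2]
    norm <- normalizeAllelePairs(sub1, sub2)
    a1[ids, ] <- norm$a1
    a2[ids, ] <- norm$a2
    nErrors[[g]] <- sum(hit)
  }
  geno@alleles1 <- a1
  geno@alleles2 <- a2
  geno@metadata$nErrors <- nErrors
  list(geno = geno, nErrors = nErrors)
}
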