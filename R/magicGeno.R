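#' Construct a MagicGeno container
#'
#' Assembles pedigree, genotypes and marker map into a validated
#' [MagicGeno-class] object. Generation indices are derived from the parent
#' links (founders, i.e. individuals with no parents, are generation 0; any
#' other individual is one generation above its deepest parent). Allele pairs
#' are stored unordered: each pair is sorted, and a pair with one missing
#' allele is promoted to fully missing.
#'
#' @param pedigree data.frame with columns `id`, `father`, `mother`; parent
#'   entries may be `NA` or `"0"` for absent (founder) parents.
#' @param alleles1,alleles2 integer matrices (individuals x loci) of allele
#'   codes in `{0,1,2}`; rownames must be individual ids.
#' @param map data.frame with columns `chrom`, `marker`, `bp`.
#' @param metadata optional list stored alongside.
#' @return a [MagicGeno-class] object
#' @export
magicGeno <- function(pedigree, alleles1, alleles2, map, metadata = list()) {
  pedigree$father[pedigree$father %in% "0"] <- NA_character_
  pedigree$mother[pedigree$mother %in% "0"] <- NA_character_
  pedigree$id <- as.character(pedigree$id)
  pedigree$father <- as.character(pedigree$father)
  pedigree$mother <- as.character(pedigree$mother)
  pedigree$generation <- computeGenerations(pedigree$id, pedigree$father,
                                            pedigree$mother)
  storage.mode(alleles1) <- "integer"
  storage.mode(alleles2) <- "integer"
  norm <- normalizeAllelePairs(alleles1, alleles2)
  map$chrom <- as.character(map$chrom)
  map$marker <- as.character(map$marker)
  map$bp <- as.integer(map$bp)
  colnames(norm$a1) <- map$marker
  colnames(norm$a2) <- map$marker
  new("MagicGeno", pedigree = pedigree, alleles1 = norm$a1, alleles2 = norm$a2,
      map = map, metadata = metadata)
}

# sort each allele pair and promote half-missing pairs to missing
normalizeAllelePairs <- function(a1, a2) {
  half <- (a1 == 0L) != (a2 == 0L)
  if (any(half)) {
    a1[half] <- 0L
    a2[half] <- 0L
  }
  swap <- a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  list(a1 = a1, a2 = a2)
}

# generation = recursive parent depth; errors on unknown parents and cycles
computeGenerations <- function(id, father, mother) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  for (p in c(father, mother)) {
    if (!is.na(p) && !(p %in% id)) {
      stop("pedigree names unknown parent '", p, "'")
    }
  }
  gen <- rep(NA_integer_, n)
  visiting <- rep(FALSE, n)
  visit <- function(i) {
    if (!is.na(gen[i])) return(gen[i])
    if (visiting[i]) stop("pedigree contains a cycle involving '", id[i], "'")
    visiting[i] <<- TRUE
    f <- father[i]
    m <- mother[i]
    g <- if (is.na(f) && is.na(m)) {
      0L
    } else if (is.na(f) || is.na(m)) {
      # single known parent still defines a depth
      1L + visit(idx[[if (is.na(f)) m else f]])
    } else {
      1L + max(visit(idx[[f]]), visit(idx[[m]]))
    }
    visiting[i] <<- FALSE
    gen[i] <<- g
    g
  }
  for (i in seq_len(n)) visit(i)
  gen
}

# genotype pair of one individual across loci; list(a1, a2) integer vectors
genotypeOf <- function(geno, id) {
  list(a1 = geno@alleles1[id, ], a2 = geno@alleles2[id, ])
}

# column index groups per chromosome, in map order
chromSegments <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}
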