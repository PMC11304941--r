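#' @import methods
NULL

#' Container for pedigreed SNP genotype data
#'
#' `MagicGeno` holds the three pieces a multiparental-population analysis
#' needs: the pedigree (with generation indices derived from parent links),
#' the diploid genotypes as two individuals-by-loci allele matrices on the
#' 0/1/2 code (0 missing, 1 major, 2 minor), and the marker map (chromosome,
#' marker id, physical position in bp).
#'
#' Genotypes are unordered allele pairs: the constructor sorts each pair and
#' promotes half-missing genotypes (one allele 0) to fully missing, because
#' Mendelian segregation logic needs both alleles or neither.
#'
#' @slot pedigree data.frame with columns `id`, `father`, `mother`
#'   (`NA` for founders) and `generation` (founders are generation 0).
#' @slot alleles1,alleles2 integer matrices (individuals x loci) holding the
#'   smaller and larger allele code of each genotype.
#' @slot map data.frame with columns `chrom`, `marker`, `bp`; within a
#'   chromosome positions strictly increase.
#' @slot metadata free-form list (simulation parameters, error counts, logs).
#'
#' @seealso [readPed()], [readMap()], [magicGeno()], [simulatePopulation()]
#' @export
setClass("MagicGeno",
  slots = c(
    pedigree = "data.frame",
    alleles1 = "matrix",
    alleles2 = "matrix",
    map = "data.frame",
    metadata = "list"
  )
)

setValidity("MagicGeno", function(object) {
  ped <- object@pedigree
  a1 <- object@alleles1
  a2 <- object@alleles2
  map <- object@map
  msgs <- character()
  need <- c("id", "father", "mother", "generation")
  if (!all(need %in% names(ped))) {
    return(paste("pedigree must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ped$id)) msgs <- c(msgs, "duplicated individual ids in pedigree")
  if (!identical(dim(a1), dim(a2))) msgs <- c(msgs, "allele matrices differ in shape")
  if (!all(a1 %in% 0:2) || !all(a2 %in% 0:2)) {
    msgs <- c(msgs, "allele codes must be in {0,1,2}")
  }
  if (any((a1 == 0L) != (a2 == 0L))) {
    msgs <- c(msgs, "half-missing genotypes must be promoted to missing")
  }
  if (any(a1 > a2)) msgs <- c(msgs, "allele pairs must be stored sorted")
  if (!is.null(rownames(a1)) && !all(rownames(a1) %in% ped$id)) {
    msgs <- c(msgs, "genotyped individuals absent from pedigree")
  }
  if (nrow(map) != ncol(a1)) {
    msgs <- c(msgs, "marker map length differs from genotype locus count")
  }
  if (anyDuplicated(map$marker)) msgs <- c(msgs, "duplicated marker ids in map")
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (any(diff(bp) <= 0)) {
      msgs <- c(msgs, sprintf("positions on chromosome %s not strictly increasing", ch))
      break
    }
  }
  # parent links must resolve and generations must be consistent
  known <- ped$id
  bad <- !is.na(ped$father) & !(ped$father %in% known)
  bad <- bad | (!is.na(ped$mother) & !(ped$mother %in% known))
  if (any(bad)) {
    msgs <- c(msgs, sprintf(
      "parent of individual '%s' absent from pedigree", ped$id[which(bad)[1]]
    ))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Result of the phasing / origin-inference / event-detection pipeline
#'
#' @slot geno the input [MagicGeno-class].
#' @slot phases named list (one entry per phased individual): each a list with
#'   integer vectors `pat`, `mat` (allele 1/2, `NA` unresolved) and character
#'   vectors `patState`, `matState` over `"R"` (resolved), `"TH"`, `"MD"`,
#'   `"ME"`, `"I"` (imputed).
#' @slot origins named list per analysed individual: per homolog a list with
#'   `origin` (`"P"`/`"M"`/`NA`), `informative` (logical) and `sym`
#'   (`"*"` noninformative, `"?"` unphased, `"!"` Mendelian error).
#' @slot events data.frame of recombination events (one row per origin
#'   transition) with interval coordinates, class (`"CO"`/`"GC"`) and the
#'   founder lines flanking the event when traced.
#' @slot founders named list per individual: per homolog a character vector of
#'   founder-line ids (or `NA`) per locus.
#' @slot config the pipeline configuration used (see [magicConfig()]).
#' @slot generationStats data.frame of per-generation bookkeeping (individuals
#'   phased, resolved and informative fractions, event counts).
#'
#' @export
setClass("MagicResult",
  slots = c(
    geno = "MagicGeno",
    phases = "list",
    origins = "list",
    events = "data.frame",
    founders = "list",
    config = "list",
    generationStats = "data.frame"
  )
)

#' Linear calibration between genotyping-error and Mendelian-error rates
#'
#' Fitted by simulating populations over a grid of genotyping-error (GE)
#' rates, measuring the Mendelian-error (ME) rate each induces in trios, and
#' regressing ME on GE. [invertCalibration()] maps an observed ME rate back
#' to the GE rate that would produce it.
#'
#' @slot slope,intercept coefficients of the least-squares fit ME = slope*GE
#'   + intercept.
#' @slot grid data.frame with one row per simulated replicate: `ge`, `me`.
#'
#' @export
setClass("CalibrationCurve",
  slots = c(slope = "numeric", intercept = "numeric", grid = "data.frame")
)

setValidity("CalibrationCurve", function(object) {
  if (length(unique(object@grid$ge)) < 3) {
    return("calibration needs at least 3 distinct GE rates")
  }
  TRUE
})
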