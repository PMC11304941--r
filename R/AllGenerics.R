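#' @rdname MagicGeno-class
#' @param object,x a `MagicGeno` or `MagicResult`
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname MagicGeno-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname MagicGeno-class
#' @param which which allele matrix (1 or 2)
#' @export
setGeneric("alleles", function(x, which = 1L) standardGeneric("alleles"))

#' @rdname MagicResult-class
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname MagicResult-class
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' @rdname MagicResult-class
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname MagicResult-class
#' @export
setGeneric("founderOrigins", function(x) standardGeneric("founderOrigins"))

#' @export
#' @rdname MagicGeno-class
setMethod("pedigree", "MagicGeno", function(x) x@pedigree)

#' @export
#' @rdname MagicGeno-class
setMethod("markerMap", "MagicGeno", function(x) x@map)

#' @export
#' @rdname MagicGeno-class
setMethod("alleles", "MagicGeno", function(x, which = 1L) {
  if (which == 1L) x@alleles1 else x@alleles2
})

#' @export
#' @rdname MagicResult-class
setMethod("pedigree", "MagicResult", function(x) x@geno@pedigree)

#' @export
#' @rdname MagicResult-class
setMethod("markerMap", "MagicResult", function(x) x@geno@map)

#' @export
#' @rdname MagicResult-class
setMethod("phases", "MagicResult", function(x) x@phases)

#' @export
#' @rdname MagicResult-class
setMethod("origins", "MagicResult", function(x) x@origins)

#' @export
#' @rdname MagicResult-class
setMethod("events", "MagicResult", function(x) x@events)

#' @export
#' @rdname MagicResult-class
setMethod("founderOrigins", "MagicResult", function(x) x@founders)

setMethod("show", "MagicGeno", function(object) {
  ped <- object@pedigree
  gens <- table(ped$generation)
  cat("MagicGeno:", nrow(ped), "individuals,",
      nrow(object@map), "loci on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  cat("  generations:",
      paste(sprintf("G%s=%d", names(gens), as.integer(gens)), collapse = " "),
      "\n")
  miss <- mean(object@alleles1 == 0L)
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
})

setMethod("show", "MagicResult", function(object) {
  cat("MagicResult:", length(object@phases), "phased individuals,",
      nrow(object@events), "recombination events\n")
  cfg <- object@config
  cat(sprintf("  settings: min=%s imp=%s cor=%s thr=%g\n",
              paste(cfg$min, collapse = "/"), cfg$imp, cfg$cor, cfg$thr))
  if (nrow(object@events)) {
    cat("  classes:", paste(names(table(object@events$class)),
                            table(object@events$class),
                            sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: ME = %.4f * GE + %.5f (%d points)\n",
              object@slope, object@intercept, nrow(object@grid)))
})
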