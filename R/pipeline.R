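#' Pipeline configuration
#'
#' Validates and completes the filtering/imputation settings. `imp =
#' "imputeNot"` forces `cor = "correctNot"`; supplying any other correction
#' with `imputeNot` is a usage error. When `cor` is omitted it defaults to
#' the recommended companion of the chosen imputation
#' (`imputeTHonly` -> `correctFalseHom`, `imputeAll` -> `correctAll`).
#'
#' @param min minimum informative alleles per haploblock: a scalar or a named
#'   vector per generation (see [resolveMin()]).
#' @param imp phase imputation mode: `"imputeNot"`, `"imputeTHonly"` or
#'   `"imputeAll"`.
#' @param cor post-imputation correction: `"correctNot"`,
#'   `"correctFalseHom"`, `"reImpute"` or `"correctAll"`.
#' @param thr bp threshold separating gene conversions (flanking haploblock
#'   shorter than `thr`) from crossovers; 0 disables discrimination.
#' @return a validated configuration list.
#' @export
magicConfig <- function(min = 1L, imp = "imputeNot", cor = NULL, thr = 0) {
  imp <- match.arg(imp, c("imputeNot", "imputeTHonly", "imputeAll"))
  if (imp == "imputeNot") {
    if (!is.null(cor) && cor != "correctNot") {
      stop("imp = imputeNot forces cor = correctNot (got cor = ", cor, ")")
    }
    cor <- "correctNot"
  } else if (is.null(cor)) {
    cor <- if (imp == "imputeTHonly") "correctFalseHom" else "correctAll"
  } else {
    cor <- match.arg(cor, c("correctNot", "correctFalseHom", "reImpute",
                            "correctAll"))
    if (cor == "correctNot") {
      message("note: cor = correctNot with imputation is not recommended")
    }
  }
  if (any(min < 1)) stop("min must be >= 1")
  if (thr < 0) stop("thr must be >= 0")
  list(min = min, imp = imp, cor = cor, thr = thr)
}

# founder "phase": its homozygous genotype on both homologs
founderPhase <- function(g, id) {
  checkFounderHomozygous(g, id)
  n <- length(g$a1)
  ph <- newPhase(n)
  ok <- g$a1 != 0L
  ph$pat[ok] <- g$a1[ok]
  ph$mat[ok] <- g$a1[ok]
  ph$patState[ok] <- "R"
  ph$matState[ok] <- "R"
  ph
}

#' Run the full phasing / origin / event-detection pipeline
#'
#' Processes generations in ascending order. Founders (G0) must be
#' homozygous; G1 phases are inferred directly from the founder genotypes.
#' From G2 on, each individual is phased by family-trio Mendelian
#' segregation, its grandparental origins are assigned against the parents'
#' phases, haploblocks are completed and filtered by the per-generation
#' `min` threshold, and unresolved phases are optionally imputed from the
#' surviving origins and corrected — the post-imputation phases feed the next
#' generation. Finally recombination events are detected and classified and
#' every allele is traced back to a founder line.
#'
#' Individuals lacking a full genotyped/phased trio are skipped with a
#' warning, as are their descendants.
#'
#' @param geno a [MagicGeno-class] object.
#' @param config a configuration from [magicConfig()].
#' @param checkConsistency assert phase/genotype consistency after every
#'   stage (resolved loci at every stage; imputed loci after correction).
#' @return a [MagicResult-class] object.
#' @export
phasePopulation <- function(geno, config = magicConfig(),
                            checkConsistency = FALSE) {
  ped <- geno@pedigree
  map <- geno@map
  nLoci <- nrow(map)
  gens <- sort(unique(ped$generation))
  phasesEnv <- list()
  originsList <- list()
  allEvents <- list()
  stats <- list()
  genotyped <- rownames(geno@alleles1)

  if (max(gens) == 0L) {
    warning("input contains only founders; nothing to phase")
  }

  for (g in gens[gens >= 1L]) {
    ids <- ped$id[ped$generation == g]
    nPhased <- 0L
    for (id in ids) {
      row <- ped[ped$id == id, ]
      fa <- row$father
      mo <- row$mother
      if (is.na(fa) || is.na(mo)) {
        warning("individual '", id, "' lacks a full parent pair; skipped")
        next
      }
      faFounder <- ped$generation[ped$id == fa] == 0L
      moFounder <- ped$generation[ped$id == mo] == 0L
      if (faFounder && moFounder) {
        if (!(fa %in% genotyped) || !(mo %in% genotyped)) {
          warning("founder parent of '", id, "' not genotyped; skipped")
          next
        }
        ph <- phaseG1(genotypeOf(geno, fa), genotypeOf(geno, mo), fa, mo)
        faPhase <- phasesEnv[[fa]] %||% founderPhase(genotypeOf(geno, fa), fa)
        moPhase <- phasesEnv[[mo]] %||% founderPhase(genotypeOf(geno, mo), mo)
        phasesEnv[[fa]] <- faPhase
        phasesEnv[[mo]] <- moPhase
      } else {
        if (is.null(phasesEnv[[fa]]) && faFounder && fa %in% genotyped) {
          phasesEnv[[fa]] <- founderPhase(genotypeOf(geno, fa), fa)
        }
        if (is.null(phasesEnv[[mo]]) && moFounder && mo %in% genotyped) {
          phasesEnv[[mo]] <- founderPhase(genotypeOf(geno, mo), mo)
        }
        if (is.null(phasesEnv[[fa]]) || is.null(phasesEnv[[mo]])) {
          warning("parents of '", id, "' not phased; skipped")
          next
        }
        if (!(id %in% genotyped)) {
          warning("individual '", id, "' not genotyped; skipped")
          next
        }
        faPhase <- phasesEnv[[fa]]
        moPhase <- phasesEnv[[mo]]
        og <- genotypeOf(geno, id)
        fg <- effectiveGenotype(
          if (fa %in% genotyped) genotypeOf(geno, fa) else emptyGenotype(nLoci),
          faPhase)
        mg <- effectiveGenotype(
          if (mo %in% genotyped) genotypeOf(geno, mo) else emptyGenotype(nLoci),
          moPhase)
        ph <- phaseTrio(fg, mg, og)
      }
      gid <- if (id %in% genotyped) genotypeOf(geno, id) else emptyGenotype(nLoci)
      if (checkConsistency) checkPhaseConsistency(ph, gid, TRUE, id)

      # grandparental origins, haploblock completion and filtering
      mosaic <- assignOrigins(ph, phasesEnv[[fa]], phasesEnv[[mo]])
      mosaic <- completeHaploblocks(mosaic, map)
      minG <- resolveMin(config$min, g)
      mosaic <- filterHaploblocks(mosaic, map, minG)
      originsList[[id]] <- mosaic

      # phase imputation and correction feed the next generation
      if (config$imp != "imputeNot") {
        pre <- ph
        ph <- imputePhases(ph, mosaic, phasesEnv[[fa]], phasesEnv[[mo]],
                           config$imp)
        if (checkConsistency) checkPhaseConsistency(ph, gid, FALSE, id)
        ph <- correctPhases(ph, pre, gid, config$cor)
        if (checkConsistency) {
          checkPhaseConsistency(ph, gid,
                                strictImputed = config$cor %in%
                                  c("correctFalseHom", "correctAll"),
                                id = id, exclude = pre$patState == "ME")
        }
      }
      phasesEnv[[id]] <- ph
      nPhased <- nPhased + 1L

      ev <- detectEvents(mosaic, map, id)
      ev <- classifyEvents(ev, config$thr)
      if (nrow(ev)) allEvents[[id]] <- ev
    }
    genIds <- intersect(ids, names(originsList))
    stats[[as.character(g)]] <- data.frame(
      generation = g, n_individuals = length(ids), n_phased = nPhased,
      informative_fraction = if (length(genIds)) {
        mean(vapply(originsList[genIds], informativeFraction, 0))
      } else NA_real_,
      resolved_fraction = if (nPhased) {
        mean(vapply(intersect(ids, names(phasesEnv)), function(i) {
          mean(phasesEnv[[i]]$patState %in% c("R", "I"))
        }, 0))
      } else NA_real_,
      n_events = sum(vapply(allEvents[intersect(ids, names(allEvents))],
                            nrow, 0L)))
  }

  events <- if (length(allEvents)) do.call(rbind, unname(allEvents)) else {
    ev <- emptyEvents()
    ev$class <- character(0)
    ev
  }
  rownames(events) <- NULL
  founders <- traceFounders(originsList, ped, nLoci)
  events <- annotateEventFounders(events, founders)
  statsDf <- if (length(stats)) do.call(rbind, unname(stats)) else
    data.frame(generation = integer(0), n_individuals = integer(0),
               n_phased = integer(0), informative_fraction = numeric(0),
               resolved_fraction = numeric(0), n_events = integer(0))
  new("MagicResult", geno = geno, phases = phasesEnv, origins = originsList,
      events = events, founders = founders, config = config,
      generationStats = statsDf)
}

emptyGenotype <- function(n) list(a1 = rep(0L, n), a2 = rep(0L, n))

`%||%` <- function(a, b) if (is.null(a)) b else a
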