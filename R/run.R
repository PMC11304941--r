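# High-level entry points mirroring the command-line interface: phase a
# PED/MAP pair, simulate a population to files, evaluate detections against
# truth. The Rscript wrapper in inst/scripts/magicphase.R is a thin layer
# over these.

#' Phase a PED/MAP dataset and write the output tables
#'
#' Reads the PLINK flat files, runs [phasePopulation()] with the given
#' settings, writes the phase/origin/event tables (see [writeTables()]) and
#' logs per-generation counts.
#'
#' @param pedPath,mapPath input PLINK files.
#' @param outPrefix output path prefix.
#' @param min,imp,cor,thr pipeline settings, see [magicConfig()]; `min` may
#'   be a scalar or a string like `"2/5/3"` assigning thresholds to the
#'   non-founder generations G2, G3, ... in order.
#' @param verbose print per-generation statistics.
#' @return invisibly, the [MagicResult-class].
#' @export
runPhase <- function(pedPath, mapPath, outPrefix, min = 1, imp = "imputeNot",
                     cor = NULL, thr = 0, verbose = TRUE) {
  config <- magicConfig(parseMinSpec(min), imp, cor, thr)
  map <- readMap(mapPath)
  geno <- readPed(pedPath, map)
  result <- phasePopulation(geno, config)
  writeTables(result, outPrefix)
  if (verbose) {
    st <- result@generationStats
    for (k in seq_len(nrow(st))) {
      message(sprintf(
        "G%d: %d/%d phased, %.1f%% informative, %.1f%% resolved, %d events",
        st$generation[k], st$n_phased[k], st$n_individuals[k],
        100 * st$informative_fraction[k], 100 * st$resolved_fraction[k],
        st$n_events[k]))
    }
  }
  invisible(result)
}

#' Parse a per-generation min specification
#'
#' `"2/5/3"` becomes `c("2" = 2, "3" = 5, "4" = 3)` (thresholds for G2, G3,
#' G4 in order); scalars pass through unchanged.
#'
#' @param min scalar or slash-separated string.
#' @return integer scalar or named integer vector.
#' @export
parseMinSpec <- function(min) {
  if (is.character(min) && grepl("/", min)) {
    vals <- as.integer(strsplit(min, "/")[[1]])
    setNames(vals, as.character(seq_along(vals) + 1L))
  } else {
    as.integer(min)
  }
}

#' Simulate a population to PLINK and truth files
#'
#' Runs [simulatePopulation()] and writes `<prefix>.ped`, `<prefix>.map` and
#' the truth TSVs (see [writeTruth()]); the files are directly consumable by
#' [runPhase()].
#'
#' @param outPrefix output path prefix.
#' @param seed RNG seed (the run is fully reproducible under it).
#' @param ... passed to [simulatePopulation()].
#' @return invisibly, the simulation list.
#' @export
runSimulate <- function(outPrefix, seed = 1, ...) {
  sim <- simulatePopulation(seed = seed, ...)
  writePlink(sim$geno, outPrefix)
  writeTruth(sim$truth, outPrefix)
  invisible(sim)
}

#' Sweep pipeline settings over simulated genotyping-error rates
#'
#' Reproduces the simulation benchmark at desk scale: for each replicate
#' seed, a population is simulated once per GE rate, the pipeline is run at
#' every `min` threshold (plus a `min = 1`/`imputeNot` raw run for the
#' filtered percentage), and each run is scored against the simulation
#' truth.
#'
#' @param geRates genotyping-error rates to simulate.
#' @param mins haploblock filter thresholds to apply.
#' @param imp,cor,thr pipeline settings shared across the sweep.
#' @param nReps replicates per rate.
#' @param seed base RNG seed; replicate r of rate g uses a seed derived
#'   deterministically from it.
#' @param simArgs list of arguments for [simulatePopulation()].
#' @return data.frame with one row per (rate, min, replicate): the
#'   performance report plus `ge`, `min`, `rep`.
#' @export
sweepPerformance <- function(geRates = c(0, 0.02, 0.06, 0.10),
                             mins = c(1, 2, 3, 4), imp = "imputeNot",
                             cor = NULL, thr = 0, nReps = 5, seed = 1,
                             simArgs = list()) {
  rows <- list()
  for (r in seq_len(nReps)) {
    for (gi in seq_along(geRates)) {
      ge <- geRates[gi]
      simSeed <- (seed * 10000L + r * 100L + gi) %% .Machine$integer.max
      sim <- do.call(simulatePopulation,
                     c(list(geRates = ge, seed = simSeed), simArgs))
      rawRes <- phasePopulation(sim$geno, magicConfig(1, "imputeNot"))
      for (mn in mins) {
        res <- if (mn == 1 && imp == "imputeNot") rawRes else {
          phasePopulation(sim$geno, magicConfig(mn, imp, cor, thr))
        }
        rep_ <- performanceReport(res, sim$truth, rawRes)
        rep_$ge <- ge
        rep_$min <- mn
        rep_$rep <- r
        rows[[length(rows) + 1L]] <- rep_
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate detector output against a truth file
#'
#' Re-reads a phased run's events and a simulation truth from disk and
#' scores them; aggregation over meioses is a mean per setting.
#'
#' @param result a [MagicResult-class] (e.g. from [runPhase()]).
#' @param truthPrefix prefix of the truth files written by [writeTruth()].
#' @return one-row performance report data.frame.
#' @export
runEvaluate <- function(result, truthPrefix) {
  truth <- readTruth(truthPrefix)
  performanceReport(result, truth)
}
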