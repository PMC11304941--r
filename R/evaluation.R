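# Scoring of detected recombination events against simulated truth, QC
# statistics (Mendelian-error rates), GE/ME calibration and per-interval
# crossover maps.

#' Match detected recombination events against true breakpoints
#'
#' A detected event matches a true breakpoint when the breakpoint's bp lies
#' within the event's closed interval `[start_bp, end_bp]` on the same
#' meiosis (same child and homolog). An event containing several true
#' breakpoints counts once as matched; every true breakpoint counts in the
#' recall denominator. The meioses considered are those of the `scopeIds`
#' individuals (by default every individual appearing in the truth whose
#' origins could be analysed — founder meioses, being invisible between
#' identical homozygous homologs, carry no usable truth).
#'
#' @param events classified events data.frame (see [detectEvents()]).
#' @param truth truth list from [simulatePopulation()].
#' @param scopeIds individual ids whose meioses are in scope; `n_true` counts
#'   the truth breakpoints of exactly these meioses.
#' @return list with `n_matched`, `n_detected`, `n_true`, and `matched`
#'   (logical per detected event).
#' @export
matchEvents <- function(events, truth, scopeIds) {
  bk <- truth$breakpoints
  bk <- bk[bk$id %in% scopeIds, , drop = FALSE]
  if (nrow(events) && !all(events$id %in% scopeIds)) {
    stop("detected events reference meioses outside the evaluation scope")
  }
  matched <- logical(nrow(events))
  if (nrow(events)) {
    key <- paste(events$id, events$homolog)
    bkey <- paste(bk$id, bk$homolog)
    for (k in seq_len(nrow(events))) {
      pos <- bk$bp[bkey == key[k]]
      matched[k] <- any(pos >= events$start_bp[k] & pos <= events$end_bp[k])
    }
  }
  list(n_matched = sum(matched), n_detected = nrow(events),
       n_true = nrow(bk), matched = matched)
}

#' Precision, recall and F1 of recombination-event detection
#'
#' `precision = n_matched / n_detected`, `recall = n_matched / n_true`,
#' `F1 = 2 * precision * recall / (precision + recall)`. A zero denominator
#' yields 0 for the affected metric.
#'
#' @param nMatched,nDetected,nTrue non-negative counts, with
#'   `nMatched <= min(nDetected, nTrue)`.
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
precisionRecallF1 <- function(nMatched, nDetected, nTrue) {
  if (nMatched > nDetected || nMatched > nTrue) {
    stop("matched count exceeds a denominator")
  }
  precision <- if (nDetected > 0) nMatched / nDetected else 0
  recall <- if (nTrue > 0) nMatched / nTrue else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Resolution and adjusted resolution of detected events
#'
#' Resolution is the inverse of the median number of SNP intervals per
#' recombination interval (the candidate breakpoint positions between the
#' event's boundary loci). Adjusted resolution multiplies it by precision:
#' the probability that a given SNP interval inside a detected event is the
#' true location of a real event.
#'
#' @param precision precision of the event set.
#' @param nIntervals integer vector, SNP intervals spanned per event (the
#'   `n_intervals` column of [detectEvents()] output).
#' @return named numeric `resolution`, `adjusted`; `NA` when no events.
#' @export
adjustedResolution <- function(precision, nIntervals) {
  if (!length(nIntervals)) {
    return(c(resolution = NA_real_, adjusted = NA_real_))
  }
  res <- 1 / stats::median(nIntervals)
  c(resolution = res, adjusted = precision * res)
}

#' Percentage of events removed by filtering
#'
#' Compares a filtered run with the raw run of the same data (`min = 1`,
#' `imputeNot`).
#'
#' @param nRaw,nFiltered event counts of the raw and filtered runs.
#' @return percentage removed; `NA` when the raw run has no events.
#' @export
pctFiltered <- function(nRaw, nFiltered) {
  if (nRaw == 0) return(NA_real_)
  100 * (nRaw - nFiltered) / nRaw
}

# per-locus Mendelian violation indicators for one trio (vectors over loci);
# NA where the trio is incomplete at that locus
trioViolations <- function(fg, mg, og) {
  miss <- fg$a1 == 0L | mg$a1 == 0L | og$a1 == 0L
  fHas <- function(a) fg$a1 == a | fg$a2 == a
  mHas <- function(a) mg$a1 == a | mg$a2 == a
  ok <- (fHas(og$a1) & mHas(og$a2)) | (fHas(og$a2) & mHas(og$a1))
  out <- !ok
  out[miss] <- NA
  out
}

#' Mendelian-error rate of a genotyped pedigree
#'
#' Fraction of offspring-locus trio comparisons that violate Mendelian
#' segregation, among loci where all three genotypes are present. Each
#' offspring with two genotyped parents contributes one comparison per
#' marker.
#'
#' @param geno a [MagicGeno-class] object.
#' @param scope `"global"` (one rate), `"per-generation"` (named vector over
#'   non-founder generations) or `"per-marker"` (vector over markers).
#' @return the requested rate(s); `NA` where no complete trios exist.
#' @export
meRate <- function(geno, scope = c("global", "per-generation", "per-marker")) {
  scope <- match.arg(scope)
  ped <- geno@pedigree
  genotyped <- rownames(geno@alleles1)
  kids <- ped[!is.na(ped$father) & !is.na(ped$mother) &
                ped$id %in% genotyped &
                ped$father %in% genotyped & ped$mother %in% genotyped, ,
              drop = FALSE]
  nLoci <- nrow(geno@map)
  if (!nrow(kids)) {
    return(switch(scope, global = NA_real_,
                  `per-generation` = setNames(numeric(0), character(0)),
                  `per-marker` = rep(NA_real_, nLoci)))
  }
  viol <- matrix(NA, nrow(kids), nLoci, dimnames = list(kids$id, NULL))
  for (k in seq_len(nrow(kids))) {
    viol[k, ] <- trioViolations(genotypeOf(geno, kids$father[k]),
                                genotypeOf(geno, kids$mother[k]),
                                genotypeOf(geno, kids$id[k]))
  }
  switch(scope,
    global = mean(viol, na.rm = TRUE),
    `per-generation` = {
      gens <- kids$generation
      vapply(split(seq_len(nrow(kids)), gens), function(rows) {
        mean(viol[rows, , drop = FALSE], na.rm = TRUE)
      }, 0)
    },
    `per-marker` = colMeans(viol, na.rm = TRUE))
}

#' Drop markers exceeding a Mendelian-error rate threshold
#'
#' Removes from the genotype table and map every marker whose per-marker ME
#' rate is strictly above `threshold` (default 10%).
#'
#' @param geno a [MagicGeno-class] object.
#' @param threshold rate in `(0, 1]`.
#' @return the filtered [MagicGeno-class].
#' @export
filterMarkersByMe <- function(geno, threshold = 0.10) {
  stopifnot(threshold > 0, threshold <= 1)
  rate <- meRate(geno, "per-marker")
  drop <- !is.na(rate) & rate > threshold
  if (all(drop)) stop("all markers exceed the ME-rate threshold")
  if (!any(drop)) return(geno)
  keep <- !drop
  magicGeno(geno@pedigree, geno@alleles1[, keep, drop = FALSE],
            geno@alleles2[, keep, drop = FALSE],
            geno@map[keep, , drop = FALSE], geno@metadata)
}

#' Calibrate genotyping-error rate from Mendelian-error rate
#'
#' Simulates replicate populations over a grid of genotyping-error (GE)
#' rates, measures the global Mendelian-error (ME) rate of each, and fits
#' `ME = slope * GE + intercept` by least squares. The fitted curve converts
#' an ME rate observed in real data into the GE rate that would induce it
#' (see [invertCalibration()]).
#'
#' @param geGrid numeric vector of at least 3 distinct GE rates.
#' @param nReps simulated replicates per rate.
#' @param seed RNG seed.
#' @param simArgs list of arguments passed on to [simulatePopulation()].
#' @return a [CalibrationCurve-class].
#' @export
calibrateGeFromMe <- function(geGrid, nReps = 2, seed = NULL,
                              simArgs = list()) {
  if (length(unique(geGrid)) < 3) stop("calibration grid needs >= 3 rates")
  if (stats::var(geGrid) == 0) stop("degenerate calibration grid")
  if (nReps < 1) stop("nReps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ge in geGrid) {
    for (r in seq_len(nReps)) {
      sim <- do.call(simulatePopulation, c(list(geRates = ge), simArgs))
      rows[[length(rows) + 1L]] <-
        data.frame(ge = ge, me = meRate(sim$geno, "global"))
    }
  }
  grid <- do.call(rbind, rows)
  fit <- stats::lm(me ~ ge, data = grid)
  new("CalibrationCurve", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), grid = grid)
}

#' @rdname calibrateGeFromMe
#' @param curve a [CalibrationCurve-class].
#' @param me observed Mendelian-error rate(s).
#' @return the genotyping-error rate(s) implied by the fit.
#' @export
invertCalibration <- function(curve, me) {
  (me - curve@intercept) / curve@slope
}

#' Gap-normalized per-SNP-interval crossover counts
#'
#' Builds a recombination map: each detected event distributes weight 1
#' evenly across the SNP intervals its recombination gap spans, so the
#' weight of every gap sums to one event and the map total equals the event
#' count exactly.
#'
#' @param events events data.frame with `start_idx`, `end_idx`.
#' @param map the marker map.
#' @return data.frame with one row per SNP interval: `chrom`,
#'   `left_marker`, `right_marker`, `count`.
#' @export
coCountMap <- function(events, map) {
  segs <- chromSegments(map)
  out <- do.call(rbind, lapply(names(segs), function(ch) {
    idx <- segs[[ch]]
    if (length(idx) < 2L) return(NULL)
    data.frame(chrom = ch, left_marker = map$marker[idx[-length(idx)]],
               right_marker = map$marker[idx[-1L]],
               left_idx = idx[-length(idx)], count = 0,
               stringsAsFactors = FALSE)
  }))
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      span <- events$start_idx[k]:(events$end_idx[k] - 1L)
      w <- 1 / length(span)
      out$count[match(span, out$left_idx)] <-
        out$count[match(span, out$left_idx)] + w
    }
  }
  out$left_idx <- NULL
  out
}

#' Score a pipeline run against simulated truth
#'
#' Computes the full performance report of a [phasePopulation()] result on a
#' simulated population: precision, recall, F1, resolution, adjusted
#' resolution, and (when a raw run is supplied) the percentage of events
#' removed by filtering. Evaluation covers the meioses of analysed
#' individuals of generation 2 and later — transitions on a G1 homolog are
#' undetectable because founders are homozygous.
#'
#' @param result a [MagicResult-class] from a simulated population.
#' @param truth the matching truth list.
#' @param rawResult optional raw-run result (`min = 1`, `imputeNot`) for the
#'   filtered percentage.
#' @return one-row data.frame (a performance report).
#' @export
performanceReport <- function(result, truth, rawResult = NULL) {
  ped <- pedigree(result)
  scope <- intersect(names(origins(result)),
                     ped$id[ped$generation >= 2L])
  ev <- events(result)
  ev <- ev[ev$id %in% scope, , drop = FALSE]
  m <- matchEvents(ev, truth, scope)
  prf <- precisionRecallF1(m$n_matched, m$n_detected, m$n_true)
  res <- adjustedResolution(prf[["precision"]], ev$n_intervals)
  pf <- if (!is.null(rawResult)) {
    raw <- events(rawResult)
    pctFiltered(sum(raw$id %in% scope), nrow(ev))
  } else NA_real_
  data.frame(precision = prf[["precision"]], recall = prf[["recall"]],
             f1 = prf[["f1"]], resolution = res[["resolution"]],
             adjusted_resolution = res[["adjusted"]],
             n_detected = m$n_detected, n_true = m$n_true,
             n_matched = m$n_matched, pct_filtered = pf)
}
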