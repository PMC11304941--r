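#' Detect recombination events as grandparental-origin transitions
#'
#' Within each homolog and chromosome, adjacent haploblocks of different
#' origins define one recombination event. The reported interval runs from
#' the last locus of the left block to the first locus of the right block
#' (closed), so it contains any unassigned gap between them and the true
#' breakpoint lies strictly within `[start_bp, end_bp]`. Events on the
#' paternal homolog are recombinations of the father's meiosis; maternal of
#' the mother's.
#'
#' @param mosaic a completed, filtered origin mosaic.
#' @param map the marker map.
#' @param id individual id recorded in the output.
#' @return data.frame with one row per event: `id`, `homolog` (`"P"`/`"M"`),
#'   `chrom`, locus indices `start_idx`/`end_idx` (map row numbers), marker
#'   ids, `start_bp`/`end_bp`, flanking origins, `n_intervals` (number of SNP
#'   intervals spanned), and flanking-block bp lengths used by
#'   [classifyEvents()].
#' @export
detectEvents <- function(mosaic, map, id = "?") {
  segs <- chromSegments(map)
  rows <- list()
  for (h in c("pat", "mat")) {
    org <- mosaic[[h]]
    for (ch in names(segs)) {
      idx <- segs[[ch]]
      blocks <- segmentBlocks(org$origin[idx], org$informative[idx])
      if (nrow(blocks) < 2L) next
      for (k in seq_len(nrow(blocks) - 1L)) {
        li <- idx[blocks$end[k]]       # last locus of left block
        ri <- idx[blocks$start[k + 1L]] # first locus of right block
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, homolog = if (h == "pat") "P" else "M", chrom = ch,
          start_idx = li, end_idx = ri,
          start_marker = map$marker[li], end_marker = map$marker[ri],
          start_bp = map$bp[li], end_bp = map$bp[ri],
          left_origin = blocks$origin[k], right_origin = blocks$origin[k + 1L],
          n_intervals = ri - li,
          left_len_bp = map$bp[idx[blocks$end[k]]] - map$bp[idx[blocks$start[k]]],
          right_len_bp = map$bp[idx[blocks$end[k + 1L]]] - map$bp[idx[blocks$start[k + 1L]]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(emptyEvents())
  do.call(rbind, rows)
}

emptyEvents <- function() {
  data.frame(id = character(0), homolog = character(0), chrom = character(0),
             start_idx = integer(0), end_idx = integer(0),
             start_marker = character(0), end_marker = character(0),
             start_bp = integer(0), end_bp = integer(0),
             left_origin = character(0), right_origin = character(0),
             n_intervals = integer(0), left_len_bp = integer(0),
             right_len_bp = integer(0), stringsAsFactors = FALSE)
}

#' Classify recombination events as crossovers or gene conversions
#'
#' A gene conversion manifests as a short interior haploblock, so an event is
#' classified `GC` when the smaller of its two flanking haploblock physical
#' lengths (bp span from the block's first to last locus) falls below the
#' threshold `thr`; otherwise `CO`. With `thr = 0` no discrimination is
#' applied and every event is a crossover.
#'
#' @param events data.frame from [detectEvents()].
#' @param thr non-negative bp threshold.
#' @return the events with a `class` column.
#' @export
classifyEvents <- function(events, thr = 0) {
  stopifnot(thr >= 0)
  if (!nrow(events)) {
    events$class <- character(0)
    return(events)
  }
  events$class <- if (thr == 0) "CO" else {
    ifelse(pmin(events$left_len_bp, events$right_len_bp) < thr, "GC", "CO")
  }
  events
}

#' Trace phased alleles back to founder lines
#'
#' Lifts grandparental origins recursively through the pedigree: an allele on
#' an individual's paternal homolog with origin P comes from the father's own
#' paternal homolog at the same locus, whose founder assignment is reused;
#' the recursion bottoms out at G1, whose paternal/maternal homologs are the
#' father/mother founder lines themselves. Loci crossing an unassigned origin
#' anywhere along the chain stay unassigned.
#'
#' @param allOrigins named list of origin mosaics for every analysed
#'   individual.
#' @param ped pedigree data.frame (with `generation`).
#' @param nLoci number of loci.
#' @return named list per individual: list with character vectors `pat`,
#'   `mat` of founder ids (or `NA`).
#' @export
traceFounders <- function(allOrigins, ped, nLoci) {
  memo <- new.env(parent = emptyenv())
  gen <- setNames(ped$generation, ped$id)
  father <- setNames(ped$father, ped$id)
  mother <- setNames(ped$mother, ped$id)

  homologAssign <- function(id, homolog) {
    key <- paste0(id, ".", homolog)
    hit <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    parent <- if (homolog == "pat") father[[id]] else mother[[id]]
    out <- if (is.na(gen[[id]]) || gen[[id]] == 0L) {
      # founder homolog: the founder itself
      rep(id, nLoci)
    } else if (gen[[id]] == 1L) {
      rep(parent, nLoci)
    } else if (is.null(allOrigins[[id]])) {
      rep(NA_character_, nLoci)
    } else {
      org <- allOrigins[[id]][[homolog]]$origin
      pp <- homologAssign(parent, "pat")
      pm <- homologAssign(parent, "mat")
      ifelse(is.na(org), NA_character_, ifelse(org == "P", pp, pm))
    }
    assign(key, out, envir = memo)
    out
  }

  ids <- names(allOrigins)
  out <- lapply(ids, function(id) {
    list(pat = homologAssign(id, "pat"), mat = homologAssign(id, "mat"))
  })
  names(out) <- ids
  out
}

# founder line flanking each event side, from the traced assignments
annotateEventFounders <- function(events, founders) {
  if (!nrow(events)) {
    events$founder_left <- character(0)
    events$founder_right <- character(0)
    return(events)
  }
  h <- ifelse(events$homolog == "P", "pat", "mat")
  events$founder_left <- vapply(seq_len(nrow(events)), function(k) {
    fa <- founders[[events$id[k]]]
    if (is.null(fa)) NA_character_ else fa[[h[k]]][events$start_idx[k]]
  }, "")
  events$founder_right <- vapply(seq_len(nrow(events)), function(k) {
    fa <- founders[[events$id[k]]]
    if (is.null(fa)) NA_character_ else fa[[h[k]]][events$end_idx[k]]
  }, "")
  events
}

#' Export recombination intervals as BED-like records
#'
#' Uses the 0-based half-open convention: each event yields
#' `(chrom, start_bp - 1, end_bp, name)`.
#'
#' @param events classified events data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEventsBed <- function(events, path) {
  bed <- data.frame(chrom = events$chrom, start = events$start_bp - 1L,
                    end = events$end_bp,
                    name = sprintf("%s.%s.%s", events$id, events$homolog,
                                   events$class))
  utils::write.table(bed, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}
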