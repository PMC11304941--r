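#' Read a PLINK PED file
#'
#' Parses a whitespace-separated PED file: six leading columns (family id,
#' individual id, father id, mother id, sex, phenotype; sex and phenotype are
#' read and ignored) followed by two allele columns per SNP coded 0 (missing),
#' 1 (major), 2 (minor). Parent id `"0"` marks an absent parent (founder).
#'
#' @param path path to the PED file.
#' @param map optional marker map (data.frame from [readMap()]); when given,
#'   the locus count is validated against it and the returned object carries
#'   the map. Without it a placeholder single-chromosome map with unit-spaced
#'   positions is attached.
#' @param markerCount optional expected number of SNPs; rows are validated to
#'   have `6 + 2*markerCount` fields.
#' @return a [MagicGeno-class] object.
#' @export
readPed <- function(path, map = NULL, markerCount = NULL) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (is.null(markerCount)) {
    if (!is.null(map)) markerCount <- nrow(map)
    else {
      markerCount <- (nf[1] - 6L) %/% 2L
    }
  }
  expected <- 6L + 2L * markerCount
  bad <- which(nf != expected)
  if (length(bad)) {
    stop(sprintf("PED line %d has %d fields, expected %d",
                 bad[1], nf[bad[1]], expected))
  }
  m <- do.call(rbind, fields)
  ids <- m[, 2]
  if (anyDuplicated(ids)) stop("duplicated individual id in PED: ", ids[duplicated(ids)][1])
  ped <- data.frame(id = ids, father = m[, 3], mother = m[, 4],
                    stringsAsFactors = FALSE)
  gm <- m[, -(1:6), drop = FALSE]
  suppressWarnings(storage.mode(gm) <- "integer")
  if (anyNA(gm) || !all(gm %in% 0:2)) {
    bad <- which(apply(gm, 1, function(r) anyNA(r) || !all(r %in% 0:2)))[1]
    stop(sprintf("PED line %d: allele code outside {0,1,2}", bad))
  }
  a1 <- gm[, seq(1L, ncol(gm), by = 2L), drop = FALSE]
  a2 <- gm[, seq(2L, ncol(gm), by = 2L), drop = FALSE]
  rownames(a1) <- ids
  rownames(a2) <- ids
  if (is.null(map)) {
    map <- data.frame(chrom = "1",
                      marker = sprintf("snp%d", seq_len(markerCount)),
                      bp = seq_len(markerCount), stringsAsFactors = FALSE)
  } else if (nrow(map) != markerCount) {
    stop(sprintf("map has %d loci but PED carries %d", nrow(map), markerCount))
  }
  magicGeno(ped, a1, a2, map)
}

#' Read a PLINK MAP file
#'
#' Four-column dialect: chromosome, marker id, genetic distance, physical
#' position (bp). The genetic-distance column is parsed and discarded. Loci
#' are grouped by chromosome and ordered by position; rows out of order are
#' reordered with a warning, duplicate positions on one chromosome and
#' duplicate marker ids are rejected.
#'
#' @param path path to the MAP file.
#' @return data.frame with columns `chrom`, `marker`, `bp`.
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("MAP file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "marker", "cm", "bp"),
                          colClasses = c("character", "character", "character",
                                         "character"))
  bp <- suppressWarnings(as.numeric(df$bp))
  if (anyNA(bp)) stop("non-numeric bp position in MAP line ", which(is.na(bp))[1])
  if (any(bp <= 0)) stop("bp positions must be positive")
  if (anyDuplicated(df$marker)) {
    stop("duplicated marker id in MAP: ", df$marker[duplicated(df$marker)][1])
  }
  out <- data.frame(chrom = df$chrom, marker = df$marker, bp = as.integer(bp),
                    stringsAsFactors = FALSE)
  reordered <- FALSE
  pieces <- lapply(split(out, factor(out$chrom, levels = unique(out$chrom))),
    function(d) {
      if (anyDuplicated(d$bp)) {
        stop("duplicate bp position on chromosome ", d$chrom[1])
      }
      if (is.unsorted(d$bp)) {
        reordered <<- TRUE
        d <- d[order(d$bp), , drop = FALSE]
      }
      d
    })
  if (reordered) warning("MAP rows were not ordered by bp; reordered")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write PLINK PED and MAP files
#'
#' @param geno a [MagicGeno-class] object.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
writePlink <- function(geno, prefix) {
  ped <- geno@pedigree
  a1 <- geno@alleles1
  a2 <- geno@alleles2
  gm <- matrix(0L, nrow(a1), 2L * ncol(a1))
  gm[, seq(1L, ncol(gm), by = 2L)] <- a1
  gm[, seq(2L, ncol(gm), by = 2L)] <- a2
  rows <- cbind("FAM1", ped$id[match(rownames(a1), ped$id)],
                ifelse(is.na(ped$father), "0", ped$father)[match(rownames(a1), ped$id)],
                ifelse(is.na(ped$mother), "0", ped$mother)[match(rownames(a1), ped$id)],
                "0", "-9", gm)
  pedPath <- paste0(prefix, ".ped")
  mapPath <- paste0(prefix, ".map")
  utils::write.table(rows, pedPath, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  map <- geno@map
  utils::write.table(data.frame(map$chrom, map$marker, 0, map$bp),
                     mapPath, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(c(ped = pedPath, map = mapPath))
}

# per-locus display code for one homolog of a phase
phaseStrings <- function(phase) {
  enc <- function(allele, state) {
    out <- as.character(allele)
    out[state %in% c("TH", "MD", "ME")] <- state[state %in% c("TH", "MD", "ME")]
    out[is.na(out)] <- state[is.na(out)]
    out
  }
  list(P = enc(phase$pat, phase$patState), M = enc(phase$mat, phase$matState))
}

# per-locus display code for one homolog of an origin mosaic
originStrings <- function(org) {
  enc <- function(h) ifelse(is.na(h$origin), h$sym, h$origin)
  list(P = enc(org$pat), M = enc(org$mat))
}

#' Write the pipeline's tabular outputs
#'
#' Emits three TSV files sharing the marker ordering of the input:
#' `<prefix>.phases.tsv` with one row per individual homolog and one column
#' per marker holding the phased allele (1/2) or the unresolved tag (TH
#' triple heterozygote, MD missing data, ME Mendelian error);
#' `<prefix>.origins.tsv` with the grandparental origin codes (P paternal,
#' M maternal, `*` noninformative, `?` unphased, `!` Mendelian error); and
#' `<prefix>.events.tsv` with one row per recombination event (individual,
#' meiosis, flanking markers and bp, class, flanking founder lines).
#'
#' @param result a [MagicResult-class] object.
#' @param prefix output path prefix.
#' @return invisibly, the vector of file paths.
#' @export
writeTables <- function(result, prefix) {
  geno <- result@geno
  markers <- geno@map$marker
  mkTable <- function(lst, stringsFun) {
    rows <- list()
    for (id in names(lst)) {
      ss <- stringsFun(lst[[id]])
      if (length(ss$P) != length(markers)) {
        stop("table length mismatch for individual ", id)
      }
      rows[[paste0(id, ".P")]] <- c(id, "P", ss$P)
      rows[[paste0(id, ".M")]] <- c(id, "M", ss$M)
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- c("id", "homolog", markers)
    tab
  }
  phasePath <- paste0(prefix, ".phases.tsv")
  originPath <- paste0(prefix, ".origins.tsv")
  eventPath <- paste0(prefix, ".events.tsv")
  utils::write.table(mkTable(result@phases, phaseStrings), phasePath,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  utils::write.table(mkTable(result@origins, originStrings), originPath,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  ev <- result@events
  cols <- c("id", "homolog", "chrom", "start_marker", "end_marker",
            "start_bp", "end_bp", "class", "left_origin", "right_origin",
            "founder_left", "founder_right")
  if (!nrow(ev)) {
    ev <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    ev <- ev[, cols]
  }
  utils::write.table(ev, eventPath, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(c(phases = phasePath, origins = originPath, events = eventPath))
}

#' Write and read simulation truth
#'
#' The truth of a simulated population is serialized as two TSVs:
#' `<prefix>.breakpoints.tsv` (child id, homolog, crossover bp) and
#' `<prefix>.founders.tsv` (id, homolog, run-length-encoded founder-of-origin
#' string, e.g. `F1:120,F3:380`).
#'
#' @param truth truth list from [simulatePopulation()].
#' @param prefix path prefix.
#' @return invisibly, the file paths.
#' @export
writeTruth <- function(truth, prefix) {
  bpPath <- paste0(prefix, ".breakpoints.tsv")
  foPath <- paste0(prefix, ".founders.tsv")
  utils::write.table(truth$breakpoints, bpPath, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  rows <- list()
  for (id in names(truth$founderOrigins)) {
    fo <- truth$founderOrigins[[id]]
    for (h in c("pat", "mat")) {
      r <- rle(fo[[h]])
      rows[[paste(id, h)]] <- c(id, if (h == "pat") "P" else "M",
                                paste(r$values, r$lengths, sep = ":",
                                      collapse = ","))
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("id", "homolog", "founder_rle")
  utils::write.table(tab, foPath, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(c(breakpoints = bpPath, founders = foPath))
}

#' @rdname writeTruth
#' @param prefix path prefix used by `writeTruth`.
#' @export
readTruth <- function(prefix) {
  bp <- utils::read.table(paste0(prefix, ".breakpoints.tsv"), header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  fo <- utils::read.table(paste0(prefix, ".founders.tsv"), header = TRUE,
                          stringsAsFactors = FALSE)
  founders <- list()
  for (i in seq_len(nrow(fo))) {
    parts <- strsplit(strsplit(fo$founder_rle[i], ",")[[1]], ":")
    vec <- rep(vapply(parts, `[`, "", 1L),
               as.integer(vapply(parts, `[`, "", 2L)))
    h <- if (fo$homolog[i] == "P") "pat" else "mat"
    founders[[fo$id[i]]][[h]] <- vec
  }
  list(breakpoints = bp, founderOrigins = founders)
}
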