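# Origin mosaic representation: per homolog a list with
#   origin      "P"/"M"/NA        grandparental origin after completion
#   informative logical           TRUE iff assigned directly from a
#                                 heterozygous phased parent (never imputed)
#   sym         "*"/"?"/"!"       display symbol where origin is unassigned:
#                                 noninformative / unphased (TH,MD) / ME
# Block building treats all unassigned causes identically; they differ only
# in phase-imputation eligibility.

#' Assign grandparental haplotype origins to a phased individual
#'
#' For each locus of the offspring's paternal homolog, the phased allele is
#' compared with the father's phase: if the father is heterozygous there and
#' the allele matches exactly one of his homologs, the origin is that homolog
#' (P = the father's own paternal, M = his maternal) and the locus is
#' informative. Alleles descending from a homozygous parent are
#' noninformative (`*`); unphased offspring loci are `?` (TH/MD) or `!` (ME);
#' an allele matching neither parental homolog at a resolved locus is `!`.
#' The maternal homolog is treated symmetrically against the mother's phase.
#'
#' @param offspringPhase,fatherPhase,motherPhase phase lists (see
#'   [phaseTrio()]); parent phases are the previous generation's
#'   post-imputation phases.
#' @return an origin mosaic: list with entries `pat`, `mat`, each carrying
#'   `origin`, `informative`, `sym`.
#' @export
assignOrigins <- function(offspringPhase, fatherPhase, motherPhase) {
  list(pat = assignOriginsHomolog(offspringPhase$pat, offspringPhase$patState,
                                  fatherPhase),
       mat = assignOriginsHomolog(offspringPhase$mat, offspringPhase$matState,
                                  motherPhase))
}

assignOriginsHomolog <- function(allele, state, parentPhase) {
  n <- length(allele)
  origin <- rep(NA_character_, n)
  sym <- rep("*", n)
  sym[state %in% c("TH", "MD")] <- "?"
  sym[state == "ME"] <- "!"
  pp <- parentPhase$pat
  pm <- parentPhase$mat
  known <- !is.na(allele) & !is.na(pp) & !is.na(pm)
  hetPar <- known & pp != pm
  isP <- hetPar & pp == allele
  isM <- hetPar & pm == allele
  origin[isP] <- "P"
  origin[isM] <- "M"
  # resolved allele matching neither homolog of a resolved parent
  sym[known & !hetPar & pp != allele] <- "!"
  list(origin = origin, informative = isP | isM, sym = sym)
}

# fill unassigned runs from informative/anchored origins within one
# chromosome segment: runs flanked by the same origin take it, border runs
# take the single adjacent origin, runs between different origins stay NA
completeOriginVector <- function(anchor) {
  out <- rep(NA_character_, length(anchor))
  pos <- which(!is.na(anchor))
  if (!length(pos)) return(out)
  out[pos] <- anchor[pos]
  out[seq_len(pos[1])] <- anchor[pos[1]]
  out[seq(pos[length(pos)], length(anchor))] <- anchor[pos[length(pos)]]
  if (length(pos) > 1L) {
    for (k in seq_len(length(pos) - 1L)) {
      i <- pos[k]; j <- pos[k + 1L]
      if (j > i + 1L && anchor[i] == anchor[j]) {
        out[(i + 1L):(j - 1L)] <- anchor[i]
      }
    }
  }
  out
}

#' Complete haploblocks by imputing noninformative origins
#'
#' Each maximal run of unassigned loci flanked on both sides by the same
#' origin receives that origin; runs at a chromosome border adopt the single
#' adjacent origin; runs between blocks of different origins stay unassigned
#' and become the recombination interval. Informative loci are never changed.
#'
#' @param mosaic an origin mosaic from [assignOrigins()].
#' @param map the marker map (chromosome grouping bounds the completion).
#' @return the completed mosaic.
#' @export
completeHaploblocks <- function(mosaic, map) {
  segs <- chromSegments(map)
  for (h in c("pat", "mat")) {
    org <- mosaic[[h]]
    anchor <- ifelse(org$informative, org$origin, NA_character_)
    for (idx in segs) {
      org$origin[idx] <- completeOriginVector(anchor[idx])
    }
    mosaic[[h]] <- org
  }
  mosaic
}

# maximal runs of equal non-NA origin within one segment; data.frame of
# blocks with start/end (segment-local), origin, informative count
segmentBlocks <- function(origin, informative) {
  r <- rle(ifelse(is.na(origin), ".", origin))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "."
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      origin = character(0), ninf = integer(0)))
  }
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(start = starts, end = ends, origin = r$values[keep],
             ninf = vapply(seq_along(starts), function(k) {
               sum(informative[starts[k]:ends[k]])
             }, 0L))
}

#' Filter haploblocks by informative-allele count
#'
#' Removes every haploblock carrying fewer than `min` informative alleles:
#' its loci are reset to noninformative, completion is re-applied from the
#' surviving informative loci, and the remove-and-recomplete cycle repeats
#' until every block holds at least `min` informative alleles (a fixpoint,
#' since removing a block can merge its neighbours into a block that must be
#' re-checked). `min = 1` is the identity.
#'
#' @param mosaic a completed origin mosaic.
#' @param map the marker map.
#' @param min positive integer threshold of informative alleles per block.
#' @return the filtered, re-completed mosaic.
#' @export
filterHaploblocks <- function(mosaic, map, min = 1L) {
  stopifnot(min >= 1L)
  segs <- chromSegments(map)
  for (h in c("pat", "mat")) {
    org <- mosaic[[h]]
    for (idx in segs) {
      inf <- org$informative[idx]
      orig <- org$origin[idx]
      anchor <- ifelse(inf, orig, NA_character_)
      repeat {
        comp <- completeOriginVector(anchor)
        blocks <- segmentBlocks(comp, inf)
        bad <- blocks$ninf < min
        if (!any(bad)) {
          org$origin[idx] <- comp
          break
        }
        for (k in which(bad)) {
          span <- blocks$start[k]:blocks$end[k]
          inf[span] <- FALSE
          anchor[span] <- NA_character_
        }
      }
      filtered <- org$informative[idx] & !inf
      org$informative[idx] <- inf
      org$sym[idx][filtered] <- "*"
    }
    mosaic[[h]] <- org
  }
  mosaic
}

#' Resolve the per-generation haploblock filter threshold
#'
#' `min` may be a single threshold applied to every generation or a named
#' vector mapping generation index to threshold (e.g. `c("2" = 2, "3" = 5,
#' "4" = 3)`), mirroring generation-specific genotyping-error rates.
#'
#' @param min scalar or named numeric vector.
#' @param generation generation index of the individual being filtered.
#' @return the threshold for that generation.
#' @export
resolveMin <- function(min, generation) {
  if (length(min) == 1L && is.null(names(min))) return(as.integer(min))
  key <- as.character(generation)
  if (!key %in% names(min)) {
    stop("no min threshold configured for generation ", generation)
  }
  as.integer(min[[key]])
}

# fraction of informative homolog-loci of one mosaic
informativeFraction <- function(mosaic) {
  mean(c(mosaic$pat$informative, mosaic$mat$informative))
}
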