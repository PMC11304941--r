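# Shared fixtures and independent oracles, all built in code.

# Three-generation, 8-member, 10-SNP family: four homozygous founders
# (P1..P4), two G1 hybrids (H1 = P1 x P2, H2 = P3 x P4), two G2 offspring of
# H1 x H2. X1 carries one paternal crossover (father's homolog switches from
# P1 to P2 between loci 5 and 6); X2 carries none but has one Mendelian
# error (locus 3 forced to 2/2) and one missing genotype (locus 5).
figFamily <- function() {
  fndAllele <- rbind(
    P1 = c(1, 1, 1, 1, 1, 2, 1, 1, 0, 1),
    P2 = c(2, 2, 1, 2, 2, 1, 2, 2, 1, 1),
    P3 = c(1, 2, 2, 1, 1, 2, 2, 1, 1, 2),
    P4 = c(2, 1, 2, 2, 1, 1, 1, 2, 1, 2))
  hap <- list(
    H1 = list(pat = fndAllele["P1", ], mat = fndAllele["P2", ]),
    H2 = list(pat = fndAllele["P3", ], mat = fndAllele["P4", ]),
    X1 = list(pat = c(fndAllele["P1", 1:5], fndAllele["P2", 6:10]),
              mat = fndAllele["P3", ]),
    X2 = list(pat = fndAllele["P2", ], mat = fndAllele["P4", ]))
  ids <- c("P1", "P2", "P3", "P4", "H1", "H2", "X1", "X2")
  a1 <- matrix(0L, 8, 10, dimnames = list(ids, NULL))
  a2 <- a1
  for (f in rownames(fndAllele)) {
    a1[f, ] <- a2[f, ] <- as.integer(fndAllele[f, ])
  }
  for (id in names(hap)) {
    a1[id, ] <- pmin(hap[[id]]$pat, hap[[id]]$mat)
    a2[id, ] <- pmax(hap[[id]]$pat, hap[[id]]$mat)
  }
  # founder P1 misses locus 9, so H1 and X1 genotypes there stay as truth
  a1["X2", 3] <- 2L; a2["X2", 3] <- 2L   # Mendelian error
  a1["X2", 5] <- 0L; a2["X2", 5] <- 0L   # missing data
  ped <- data.frame(
    id = ids,
    father = c(NA, NA, NA, NA, "P1", "P3", "H1", "H1"),
    mother = c(NA, NA, NA, NA, "P2", "P4", "H2", "H2"),
    stringsAsFactors = FALSE)
  map <- data.frame(chrom = "A01", marker = sprintf("m%02d", 1:10),
                    bp = seq(100L, 1000L, by = 100L),
                    stringsAsFactors = FALSE)
  magicGeno(ped, a1, a2, map)
}

# origin mosaic for one individual from per-homolog strings over
# {P, M, *, ?, !}: P/M are informative anchors, the rest unassigned
mkMosaic <- function(patStr, matStr = patStr) {
  mk <- function(s) {
    ch <- strsplit(s, "")[[1]]
    list(origin = ifelse(ch %in% c("P", "M"), ch, NA_character_),
         informative = ch %in% c("P", "M"),
         sym = ifelse(ch %in% c("P", "M"), "*", ch))
  }
  list(pat = mk(patStr), mat = mk(matStr))
}

mkMap <- function(n, chrom = "1", bp = NULL) {
  data.frame(chrom = chrom, marker = sprintf("s%03d", seq_len(n)),
             bp = if (is.null(bp)) seq_len(n) * 10L else as.integer(bp),
             stringsAsFactors = FALSE)
}

originString <- function(mosaicHomolog) {
  paste(ifelse(is.na(mosaicHomolog$origin), ".", mosaicHomolog$origin),
        collapse = "")
}

# ---- independent oracles -------------------------------------------------

# single-locus trio phasing by explicit gamete enumeration
oracleTrioLocus <- function(f, m, o) {
  if (f[1] == 0 || m[1] == 0 || o[1] == 0) {
    return(list(state = "MD", pat = NA, mat = NA))
  }
  pairs <- expand.grid(pat = unique(f), mat = unique(m))
  ok <- pairs[pairs$pat + pairs$mat == sum(o) &
                pmin(pairs$pat, pairs$mat) == min(o), , drop = FALSE]
  ok <- ok[!duplicated(ok), , drop = FALSE]
  if (!nrow(ok)) return(list(state = "ME", pat = NA, mat = NA))
  if (length(unique(ok$pat)) == 1L) {
    return(list(state = "R", pat = ok$pat[1], mat = ok$mat[1]))
  }
  list(state = "TH", pat = NA, mat = NA)
}

# single-locus origin assignment by enumerating the transmitting homolog
oracleOriginLocus <- function(childAllele, childState, parPat, parMat) {
  if (is.na(childAllele)) return(if (childState == "ME") "!" else "?")
  if (is.na(parPat) || is.na(parMat)) return("*")
  cand <- c(P = parPat == childAllele, M = parMat == childAllele)
  if (sum(cand) == 2L) "*"
  else if (sum(cand) == 0L) "!"
  else names(cand)[cand]
}

# run-enumeration oracle for haploblock completion + min filtering on one
# homolog: nearest-anchor completion, explicit block scan, anchor removal
oracleCompleteFilter <- function(chars, min) {
  anchors <- which(chars %in% c("P", "M"))
  repeat {
    comp <- vapply(seq_along(chars), function(i) {
      L <- anchors[anchors <= i]
      R <- anchors[anchors >= i]
      lo <- if (length(L)) chars[max(L)] else NA_character_
      ro <- if (length(R)) chars[min(R)] else NA_character_
      if (is.na(lo)) ro
      else if (is.na(ro)) lo
      else if (lo == ro) lo
      else NA_character_
    }, "")
    # scan blocks and their anchor counts
    bad <- integer(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      if (is.na(comp[i])) { i <- i + 1L; next }
      j <- i
      while (j < n && !is.na(comp[j + 1L]) && comp[j + 1L] == comp[i]) j <- j + 1L
      if (sum(anchors >= i & anchors <= j) < min) bad <- c(bad, i:j)
      i <- j + 1L
    }
    if (!length(bad)) return(comp)
    anchors <- setdiff(anchors, bad)
  }
}

# all homozygous-or-missing founder genotypes
founderGenoSpace <- list(c(0L, 0L), c(1L, 1L), c(2L, 2L))
anyGenoSpace <- list(c(0L, 0L), c(1L, 1L), c(1L, 2L), c(2L, 2L))
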