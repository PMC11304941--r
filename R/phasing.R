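# Phase representation: list(pat, mat, patState, matState).
# pat/mat are integer allele vectors (1/2, NA where unresolved); states are
# "R" resolved, "TH" triple heterozygote, "MD" missing data, "ME" Mendelian
# error, "I" imputed. Unresolved states carry no allele value.

newPhase <- function(n) {
  list(pat = rep(NA_integer_, n), mat = rep(NA_integer_, n),
       patState = rep("MD", n), matState = rep("MD", n))
}

#' Phase a first-generation (G1) individual from its founder parents
#'
#' Founder lines are assumed fully homozygous, so a G1 offspring's phase is
#' known without its own genotype: at every locus the paternal allele is the
#' father's allele and the maternal allele is the mother's. Loci where a
#' founder genotype is missing are tagged `MD`.
#'
#' @param fatherGeno,motherGeno lists with integer vectors `a1`, `a2`
#'   (the founder's unordered genotype; see [alleles()]).
#' @param fatherId,motherId ids used in the heterozygous-founder error.
#' @return a phase (see package internals): `pat`, `mat`, `patState`,
#'   `matState`.
#' @export
phaseG1 <- function(fatherGeno, motherGeno, fatherId = "father",
                    motherId = "mother") {
  checkFounderHomozygous(fatherGeno, fatherId)
  checkFounderHomozygous(motherGeno, motherId)
  n <- length(fatherGeno$a1)
  ph <- newPhase(n)
  fOk <- fatherGeno$a1 != 0L
  mOk <- motherGeno$a1 != 0L
  ok <- fOk & mOk
  ph$pat[ok] <- fatherGeno$a1[ok]
  ph$mat[ok] <- motherGeno$a1[ok]
  ph$patState[ok] <- "R"
  ph$matState[ok] <- "R"
  ph
}

checkFounderHomozygous <- function(g, id) {
  het <- g$a1 != 0L & g$a1 != g$a2
  if (any(het)) {
    stop(sprintf("founder '%s' is heterozygous at locus %d%s", id,
                 which(het)[1],
                 if (!is.null(names(g$a1))) paste0(" (", names(g$a1)[which(het)[1]], ")")
                 else ""))
  }
  invisible(TRUE)
}

#' Phase one individual by family-trio Mendelian segregation
#'
#' Compares an offspring's unordered genotype with its parents' genotypes at
#' every locus and assigns each allele to the paternal or maternal homolog
#' where Mendelian segregation admits a unique assignment. Per-locus
#' outcomes: a homozygous offspring a/a is phased paternal=maternal=a when
#' both parents can transmit a, else tagged `ME`; a heterozygous offspring is
#' phased when exactly one assignment of its two alleles to the parents is
#' consistent, tagged `TH` when all three genotypes are heterozygous (both
#' assignments consistent), and `ME` when none is; any missing genotype in
#' the trio gives `MD`.
#'
#' @param fatherGeno,motherGeno,offspringGeno lists with vectors `a1`, `a2`.
#' @return a phase list (`pat`, `mat`, `patState`, `matState`).
#' @export
phaseTrio <- function(fatherGeno, motherGeno, offspringGeno) {
  f1 <- fatherGeno$a1; f2 <- fatherGeno$a2
  m1 <- motherGeno$a1; m2 <- motherGeno$a2
  o1 <- offspringGeno$a1; o2 <- offspringGeno$a2
  n <- length(o1)
  ph <- newPhase(n)
  miss <- f1 == 0L | m1 == 0L | o1 == 0L
  hom <- !miss & o1 == o2
  het <- !miss & o1 != o2
  # homozygous offspring: both parents must carry the allele
  fHas <- function(a) f1 == a | f2 == a
  mHas <- function(a) m1 == a | m2 == a
  homOk <- hom & fHas(o1) & mHas(o1)
  ph$pat[homOk] <- o1[homOk]
  ph$mat[homOk] <- o1[homOk]
  homME <- hom & !homOk
  # heterozygous offspring (alleles are o1 < o2): two candidate assignments
  assignA <- het & fHas(o1) & mHas(o2)  # paternal = o1
  assignB <- het & fHas(o2) & mHas(o1)  # paternal = o2
  onlyA <- assignA & !assignB
  onlyB <- assignB & !assignA
  th <- assignA & assignB
  hetME <- het & !assignA & !assignB
  ph$pat[onlyA] <- o1[onlyA]; ph$mat[onlyA] <- o2[onlyA]
  ph$pat[onlyB] <- o2[onlyB]; ph$mat[onlyB] <- o1[onlyB]
  state <- rep("MD", n)
  state[homOk | onlyA | onlyB] <- "R"
  state[th] <- "TH"
  state[homME | hetME] <- "ME"
  ph$patState <- state
  ph$matState <- state
  ph
}

#' Impute unresolved phases from assigned haplotype origins
#'
#' Once a locus's grandparental origin is known (by haploblock completion),
#' the allele the parent's corresponding haplotype carries can fill the
#' unresolved phase. `imputeTHonly` imputes only triply heterozygous (`TH`)
#' loci; `imputeAll` also imputes `MD` and `ME` loci; `imputeNot` is the
#' identity. Loci whose origin is still unassigned, or whose source parental
#' allele is itself unresolved, are left unchanged.
#'
#' @param phase the individual's phase.
#' @param originMosaic the individual's origin mosaic (see [assignOrigins()]),
#'   completed and filtered.
#' @param fatherPhase,motherPhase the parents' phases.
#' @param imp one of `"imputeNot"`, `"imputeTHonly"`, `"imputeAll"`.
#' @return the updated phase; imputed loci get state `"I"`.
#' @export
imputePhases <- function(phase, originMosaic, fatherPhase, motherPhase,
                         imp = c("imputeNot", "imputeTHonly", "imputeAll")) {
  imp <- match.arg(imp)
  if (imp == "imputeNot") return(phase)
  states <- if (imp == "imputeTHonly") "TH" else c("TH", "MD", "ME")
  imputeHomolog <- function(allele, state, org, parent) {
    src <- ifelse(is.na(org$origin), NA_integer_,
                  ifelse(org$origin == "P", parent$pat, parent$mat))
    do <- state %in% states & !is.na(org$origin) & !is.na(src)
    allele[do] <- src[do]
    state[do] <- "I"
    list(allele = allele, state = state)
  }
  p <- imputeHomolog(phase$pat, phase$patState, originMosaic$pat, fatherPhase)
  m <- imputeHomolog(phase$mat, phase$matState, originMosaic$mat, motherPhase)
  phase$pat <- p$allele; phase$patState <- p$state
  phase$mat <- m$allele; phase$matState <- m$state
  phase
}

#' Correct imputed phases against the observed genotype
#'
#' Post-imputation correction of triply heterozygous loci.
#' `correctFalseHom` undoes both imputations at any locus where the observed
#' genotype is heterozygous but the two homologs were imputed to the same
#' allele (a false homozygote); the loci revert to their pre-imputation
#' unresolved states. `reImpute` fills, at a heterozygous-genotype locus
#' where exactly one homolog carries an allele and the other is unresolved,
#' the unresolved homolog with the remaining genotype allele. `correctAll`
#' applies `correctFalseHom` then `reImpute`; `correctNot` is the identity.
#'
#' @param phase phase after [imputePhases()].
#' @param prePhase the same individual's phase before imputation (used to
#'   restore undone states).
#' @param genotype list with vectors `a1`, `a2`.
#' @param cor one of `"correctNot"`, `"correctFalseHom"`, `"reImpute"`,
#'   `"correctAll"`.
#' @return the corrected phase.
#' @export
correctPhases <- function(phase, prePhase, genotype,
                          cor = c("correctNot", "correctFalseHom", "reImpute",
                                  "correctAll")) {
  cor <- match.arg(cor)
  if (cor == "correctNot") return(phase)
  het <- genotype$a1 != 0L & genotype$a1 != genotype$a2
  if (cor %in% c("correctFalseHom", "correctAll")) {
    undo <- het & phase$patState == "I" & phase$matState == "I" &
      phase$pat == phase$mat
    undo[is.na(undo)] <- FALSE
    phase$pat[undo] <- prePhase$pat[undo]
    phase$mat[undo] <- prePhase$mat[undo]
    phase$patState[undo] <- prePhase$patState[undo]
    phase$matState[undo] <- prePhase$matState[undo]
  }
  if (cor %in% c("reImpute", "correctAll")) {
    patKnown <- !is.na(phase$pat)
    matKnown <- !is.na(phase$mat)
    fixMat <- het & patKnown & !matKnown
    # remaining allele: the genotype allele the resolved homolog does not use
    phase$mat[fixMat] <- ifelse(phase$pat[fixMat] == genotype$a1[fixMat],
                                genotype$a2[fixMat], genotype$a1[fixMat])
    phase$matState[fixMat] <- "I"
    fixPat <- het & matKnown & !patKnown
    phase$pat[fixPat] <- ifelse(phase$mat[fixPat] == genotype$a1[fixPat],
                                genotype$a2[fixPat], genotype$a1[fixPat])
    phase$patState[fixPat] <- "I"
  }
  phase
}

# effective genotype of a phased parent for trio segregation: the observed
# genotype, with missing loci filled from the (possibly imputed) phase
effectiveGenotype <- function(genotype, phase) {
  fill <- genotype$a1 == 0L & !is.na(phase$pat) & !is.na(phase$mat)
  if (any(fill)) {
    a1 <- pmin(phase$pat[fill], phase$mat[fill])
    a2 <- pmax(phase$pat[fill], phase$mat[fill])
    genotype$a1[fill] <- a1
    genotype$a2[fill] <- a2
  }
  genotype
}

# consistency of carried alleles with the observed genotype; used as a
# pipeline assertion. strictImputed=TRUE also checks imputed pairs; exclude
# masks loci where imputation may legitimately override an erroneous
# genotype (pre-imputation Mendelian errors).
checkPhaseConsistency <- function(phase, genotype, strictImputed = TRUE,
                                  id = "?", exclude = FALSE) {
  states <- if (strictImputed) c("R", "I") else "R"
  both <- phase$patState %in% states & phase$matState %in% states
  nonMissing <- genotype$a1 != 0L
  chk <- both & nonMissing & !exclude
  ok <- pmin(phase$pat, phase$mat)[chk] == genotype$a1[chk] &
    pmax(phase$pat, phase$mat)[chk] == genotype$a2[chk]
  if (!all(ok)) {
    stop(sprintf("phase of '%s' inconsistent with genotype at locus %d",
                 id, which(chk)[which(!ok)[1]]))
  }
  invisible(TRUE)
}
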