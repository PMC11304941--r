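geno1 <- function(...) {
  # build a genotype list from per-locus pairs
  p <- list(...)
  list(a1 = vapply(p, min, 0L), a2 = vapply(p, max, 0L))
}

test_that("G1 phase is inferred directly from homozygous founders", {
  fa <- geno1(c(1L, 1L), c(1L, 1L), c(0L, 0L))
  mo <- geno1(c(2L, 2L), c(1L, 1L), c(2L, 2L))
  ph <- phaseG1(fa, mo)
  expect_equal(ph$pat, c(1L, 1L, NA))
  expect_equal(ph$mat, c(2L, 1L, NA))
  expect_equal(ph$patState, c("R", "R", "MD"))
  # heterozygous founder violates the G0 assumption
  faHet <- geno1(c(1L, 2L))
  expect_error(phaseG1(faHet, geno1(c(1L, 1L)), "F1", "F2"),
               "founder 'F1' is heterozygous")
})

test_that("trio phasing resolves, tags TH/MD/ME per Mendelian rules", {
  fa <- geno1(c(1L, 1L), c(1L, 2L), c(1L, 1L), c(0L, 0L))
  mo <- geno1(c(1L, 2L), c(1L, 2L), c(1L, 1L), c(1L, 1L))
  of <- geno1(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 1L))
  ph <- phaseTrio(fa, mo, of)
  expect_equal(ph$pat, c(1L, NA, NA, NA))
  expect_equal(ph$mat, c(2L, NA, NA, NA))
  expect_equal(ph$patState, c("R", "TH", "ME", "MD"))
})

test_that("trio phasing agrees with gamete-enumeration oracle on all configs", {
  for (f in anyGenoSpace) for (m in anyGenoSpace) for (o in anyGenoSpace) {
    got <- phaseTrio(list(a1 = f[1], a2 = f[2]), list(a1 = m[1], a2 = m[2]),
                     list(a1 = o[1], a2 = o[2]))
    exp <- oracleTrioLocus(f, m, o)
    lbl <- sprintf("f=%d/%d m=%d/%d o=%d/%d", f[1], f[2], m[1], m[2], o[1], o[2])
    expect_equal(got$patState[1], exp$state, label = lbl)
    if (exp$state == "R") {
      expect_equal(got$pat[1], exp$pat, label = lbl)
      expect_equal(got$mat[1], exp$mat, label = lbl)
    } else {
      expect_true(is.na(got$pat[1]), label = lbl)
    }
  }
})

test_that("trio phasing is symmetric under relabeling alleles 1 and 2", {
  swapG <- function(g) {
    s1 <- ifelse(g$a1 == 0L, 0L, 3L - g$a1)
    s2 <- ifelse(g$a2 == 0L, 0L, 3L - g$a2)
    list(a1 = pmin(s1, s2), a2 = pmax(s1, s2))
  }
  set.seed(11)
  for (rep in 1:20) {
    draw <- function() {
      p <- anyGenoSpace[[sample.int(4, 1)]]
      list(a1 = p[1], a2 = p[2])
    }
    f <- draw(); m <- draw(); o <- draw()
    a <- phaseTrio(f, m, o)
    b <- phaseTrio(swapG(f), swapG(m), swapG(o))
    expect_equal(b$patState, a$patState)
    expect_equal(b$pat, ifelse(is.na(a$pat), NA_integer_, 3L - a$pat))
    expect_equal(b$mat, ifelse(is.na(a$mat), NA_integer_, 3L - a$mat))
  }
})

test_that("phase imputation fills unresolved loci from assigned origins", {
  # loci: 1 TH with origin P, 2 ME with origin M, 3 TH with unassigned origin
  phase <- list(pat = c(NA, NA, NA), mat = c(NA, NA, NA),
                patState = c("TH", "ME", "TH"), matState = c("TH", "ME", "TH"))
  mosaic <- list(
    pat = list(origin = c("P", "M", NA), informative = c(FALSE, FALSE, FALSE),
               sym = c("?", "!", "?")),
    mat = list(origin = c("M", "M", NA), informative = c(FALSE, FALSE, FALSE),
               sym = c("?", "!", "?")))
  faPhase <- list(pat = c(2L, 1L, 1L), mat = c(1L, 2L, 2L),
                  patState = rep("R", 3), matState = rep("R", 3))
  moPhase <- list(pat = c(1L, 1L, 1L), mat = c(1L, 1L, 2L),
                  patState = rep("R", 3), matState = rep("R", 3))
  thOnly <- imputePhases(phase, mosaic, faPhase, moPhase, "imputeTHonly")
  expect_equal(thOnly$pat, c(2L, NA, NA))     # TH locus, origin P -> father's pat
  expect_equal(thOnly$patState, c("I", "ME", "TH"))
  expect_equal(thOnly$mat, c(1L, NA, NA))
  all_ <- imputePhases(phase, mosaic, faPhase, moPhase, "imputeAll")
  expect_equal(all_$pat, c(2L, 2L, NA))       # ME locus too, origin M -> father's mat
  expect_equal(all_$patState, c("I", "I", "TH"))
  expect_identical(imputePhases(phase, mosaic, faPhase, moPhase, "imputeNot"),
                   phase)
})

test_that("phase correction undoes false homozygotes and re-imputes", {
  g <- geno1(c(1L, 2L), c(1L, 2L), c(1L, 2L))
  pre <- list(pat = c(NA, NA, NA), mat = c(NA, NA, NA),
              patState = c("TH", "TH", "TH"), matState = c("TH", "TH", "TH"))
  # locus 1: both imputed to 1 (false hom); locus 2: pat imputed, mat open;
  # locus 3: untouched
  phase <- list(pat = c(1L, 1L, NA), mat = c(1L, NA, NA),
                patState = c("I", "I", "TH"), matState = c("I", "TH", "TH"))
  fh <- correctPhases(phase, pre, g, "correctFalseHom")
  expect_equal(fh$patState, c("TH", "I", "TH"))
  expect_true(is.na(fh$pat[1]))
  ri <- correctPhases(phase, pre, g, "reImpute")
  expect_equal(ri$mat[2], 2L)                 # remaining genotype allele
  expect_equal(ri$matState[2], "I")
  expect_equal(ri$pat[1], 1L)                 # reImpute alone keeps the false hom
  ca <- correctPhases(phase, pre, g, "correctAll")
  expect_true(is.na(ca$pat[1]))               # undone first, nothing to re-impute
  expect_equal(ca$mat[2], 2L)
  expect_identical(correctPhases(phase, pre, g, "correctNot"), phase)
})

test_that("correctFalseHom never touches directly resolved loci", {
  set.seed(23)
  for (rep in 1:20) {
    n <- 10
    pat <- sample(1:2, n, replace = TRUE)
    mat <- 3L - pat
    states <- sample(c("R", "I"), n, replace = TRUE)
    phase <- list(pat = pat, mat = mat, patState = states, matState = states)
    # force a few false-hom imputed loci
    idx <- sample(n, 3)
    phase$mat[idx] <- phase$pat[idx]
    phase$patState[idx] <- "I"
    phase$matState[idx] <- "I"
    g <- list(a1 = rep(1L, n), a2 = rep(2L, n))
    pre <- list(pat = rep(NA_integer_, n), mat = rep(NA_integer_, n),
                patState = rep("TH", n), matState = rep("TH", n))
    out <- correctPhases(phase, pre, g, "correctFalseHom")
    resolved <- which(phase$patState == "R")
    expect_equal(out$pat[resolved], phase$pat[resolved])
    expect_equal(out$patState[resolved], phase$patState[resolved])
  }
})
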