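test_that("PED parsing maps fields to pedigree and unordered genotypes", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("FAM P1 0 0 0 0 1 1 2 2",
               "FAM P2 0 0 0 0 2 1 1 1",
               "FAM K1 P1 P2 0 0 1 2 1 2"), ped)
  g <- readPed(ped, markerCount = 2)
  expect_equal(pedigree(g)$generation, c(0L, 0L, 1L))
  expect_true(is.na(pedigree(g)$father[1]))
  expect_equal(unname(alleles(g, 1)["P1", ]), c(1L, 2L))
  expect_equal(unname(alleles(g, 2)["P1", ]), c(1L, 2L))
  # pairs are stored sorted regardless of PED column order
  expect_equal(unname(alleles(g, 1)["P2", ]), c(1L, 1L))
  expect_equal(unname(alleles(g, 2)["P2", ]), c(2L, 1L))
})

test_that("PED structural errors are rejected with line context", {
  f <- tempfile(fileext = ".ped")
  writeLines(c("FAM A 0 0 0 0 1 1", "FAM B 0 0 0 0 1"), f)
  expect_error(readPed(f, markerCount = 1), "line 2")
  writeLines(c("FAM A 0 0 0 0 1 3"), f)
  expect_error(readPed(f, markerCount = 1), "allele code")
  writeLines(c("FAM A 0 0 0 0 1 1", "FAM B A GHOST 0 0 1 1"), f)
  expect_error(readPed(f, markerCount = 1), "unknown parent")
  # a cycle: two individuals naming each other as parents
  writeLines(c("FAM A B B 0 0 1 1", "FAM B A A 0 0 1 1"), f)
  expect_error(readPed(f, markerCount = 1), "cycle")
})

test_that("half-missing genotypes are promoted to fully missing", {
  f <- tempfile(fileext = ".ped")
  writeLines("FAM A 0 0 0 0 1 0", f)
  g <- readPed(f, markerCount = 1)
  expect_equal(unname(alleles(g, 1)["A", ]), 0L)
  expect_equal(unname(alleles(g, 2)["A", ]), 0L)
})

test_that("the three-generation family fixture derives generations G0/G1/G2", {
  g <- figFamily()
  gen <- setNames(pedigree(g)$generation, pedigree(g)$id)
  expect_equal(unname(gen[c("P1", "P4", "H1", "H2", "X1", "X2")]),
               c(0L, 0L, 1L, 1L, 2L, 2L))
})

test_that("MAP parsing discards genetic distance and enforces order", {
  f <- tempfile(fileext = ".map")
  writeLines(c("A03 s1 0 100", "A03 s2 7.3 500", "A03 s3 0 900"), f)
  m <- readMap(f)
  expect_equal(m$marker, c("s1", "s2", "s3"))
  expect_equal(m$bp, c(100L, 500L, 900L))
  # genetic distance column has no effect
  writeLines(c("A03 s1 0 100", "A03 s2 0 500", "A03 s3 0 900"), f)
  expect_identical(readMap(f), m)
  # out-of-order rows are reordered with a warning
  writeLines(c("A03 s1 0 500", "A03 s2 0 100"), f)
  expect_warning(m2 <- readMap(f), "reordered")
  expect_equal(m2$marker, c("s2", "s1"))
  writeLines(c("A03 s1 0 100", "A03 s1 0 200"), f)
  expect_error(readMap(f), "duplicated marker")
  writeLines(c("A03 s1 0 100", "A03 s2 0 100"), f)
  expect_error(readMap(f), "duplicate bp")
  writeLines(c("A03 s1 0 abc"), f)
  expect_error(readMap(f), "non-numeric")
})

test_that("PED/MAP round trip reproduces identical structures", {
  g <- figFamily()
  prefix <- tempfile()
  writePlink(g, prefix)
  g2 <- readPed(paste0(prefix, ".ped"), readMap(paste0(prefix, ".map")))
  expect_equal(pedigree(g2), pedigree(g))
  expect_equal(alleles(g2, 1), alleles(g, 1))
  expect_equal(alleles(g2, 2), alleles(g, 2))
  expect_equal(markerMap(g2), markerMap(g))
})

test_that("generation labels are invariant under PED row permutation", {
  g <- figFamily()
  prefix <- tempfile()
  writePlink(g, prefix)
  lines <- readLines(paste0(prefix, ".ped"))
  set.seed(7)
  writeLines(sample(lines), paste0(prefix, ".ped"))
  g2 <- readPed(paste0(prefix, ".ped"), readMap(paste0(prefix, ".map")))
  gen1 <- setNames(pedigree(g)$generation, pedigree(g)$id)
  gen2 <- setNames(pedigree(g2)$generation, pedigree(g2)$id)
  expect_equal(gen2[names(gen1)], gen1)
})

test_that("output tables carry phase tags, origin codes and events", {
  g <- figFamily()
  res <- phasePopulation(g, magicConfig(1, "imputeNot"))
  prefix <- tempfile()
  paths <- writeTables(res, prefix)
  ph <- utils::read.table(paths["phases"], header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  x1p <- unlist(ph[ph$id == "X1" & ph$homolog == "P", -(1:2)])
  expect_equal(unname(x1p),
               c("1", "TH", "1", "1", "1", "TH", "2", "TH", "MD", "1"))
  org <- utils::read.table(paths["origins"], header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  x1o <- paste(unlist(org[org$id == "X1" & org$homolog == "P", -(1:2)]),
               collapse = "")
  expect_equal(x1o, "PPPPP?MMMM")
  ev <- utils::read.table(paths["events"], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_bp, 500L)
  expect_equal(ev$end_bp, 700L)
  # no events: header-only file
  res2 <- phasePopulation(g, magicConfig(2, "imputeNot"))
  paths2 <- writeTables(res2, tempfile())
  ev2 <- utils::read.table(paths2["events"], header = TRUE, sep = "\t")
  expect_equal(nrow(ev2), 0L)
})

test_that("simulation truth round-trips through its TSV serialization", {
  sim <- simulatePopulation(seed = 5, depth = 2, nLoci = 40,
                            offspringPerCross = 1)
  prefix <- tempfile()
  writeTruth(sim$truth, prefix)
  back <- readTruth(prefix)
  expect_equal(back$breakpoints$bp, sim$truth$breakpoints$bp)
  id <- sim$geno@pedigree$id[20]
  expect_equal(back$founderOrigins[[id]]$pat,
               sim$truth$founderOrigins[[id]]$pat)
})
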