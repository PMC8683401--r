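# Packaged tables and synthetic-data generators.

test_that("the packaged family table matches its published shape", {
  t1 <- loadTable1()
  expect_equal(nrow(t1), 30L)   # 29 members + the discarded accession
  br4 <- t1[t1$gene == "BrCNGC4" & !is.na(t1$gene), ]
  expect_equal(br4$chromosome, "A01")
  expect_equal(br4$strand, "+")
  expect_equal(br4$length, 556L)
  coords <- t1[!is.na(t1$start), ]
  expect_true(all(coords$start < coords$stop))
  expect_true(all(coords$strand %in% c("+", "-")))
  # group blocks fill down to the published clade sizes
  expect_equal(unname(table(coords$group)[c("I", "II", "III", "IV-a", "IV-b")]),
               c(7L, 5L, 6L, 3L, 8L), ignore_attr = TRUE)
})

test_that("the packaged property table has the published length spread", {
  t3 <- loadTable3()
  expect_equal(nrow(t3), 29L)
  expect_true(all(t3$length >= 556 & t3$length <= 786))
  expect_true(all(t3$gravy >= -4.5 & t3$gravy <= 4.5))
})

test_that("family generator plants the motif and reproduces under a seed", {
  a <- generateFamily(n = 8, seed = 99)
  b <- generateFamily(n = 8, seed = 99)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(as.character(a$msa), as.character(b$msa))
  c <- generateFamily(n = 8, seed = 100)
  expect_false(identical(as.character(a$sequences), as.character(c$sequences)))

  # planted consensus sits at the recorded alignment columns in every row
  msa <- as.character(a$msa)
  reg <- a$truth$region
  cons <- paste(a$truth$consensus, collapse = "")
  hits <- vapply(msa, function(s)
    sum(strsplit(substr(s, reg[1], reg[2]), "")[[1]] ==
        a$truth$consensus), integer(1))
  expect_true(all(hits >= floor(0.95 * length(a$truth$consensus)) - 1))

  # degapped alignment equals the unaligned sequences
  expect_equal(unname(gsub("-", "", msa)), unname(as.character(a$sequences)))

  expect_equal(length(generateFamily(n = 0)$sequences), 0L)
  expect_error(generateFamily(motif = "A-X(1,3)-C"), "fixed-span")
})

test_that("at full conservation the induced key recovers the planted tokens", {
  fam <- generateFamily(n = 10, motif = "W-S-P-E-L", conservation = 1, seed = 41)
  ik <- induceKey(fam$msa, region = fam$truth$region, mode = "strict")
  expect_equal(ik@pattern@elements$residues, fam$truth$consensus)
  expect_true(all(ik@pattern@elements$kind == "fixed-residue"))
  expect_equal(ik@coverage, 1)
})

test_that("GFF generator is seed-reproducible and phases are its own truth", {
  a <- generateGff(nGenes = 5, seed = 7)
  b <- generateGff(nGenes = 5, seed = 7)
  expect_equal(a$truth, b$truth)
  expect_equal(lapply(a$models, function(m) IRanges::start(m@cds)),
               lapply(b$models, function(m) IRanges::start(m@cds)))
  # single-exon genes appear in models but contribute no introns
  single <- generateGff(nGenes = 4, exonRange = c(1, 1), seed = 5)
  expect_equal(nrow(single$truth), 0L)
  expect_true(all(vapply(single$models,
                         function(m) length(m@cds) == 1L, logical(1))))
})

test_that("expression generator is seed-reproducible with a consistent truth", {
  a <- generateExpression(nGenes = 20, seed = 3)
  b <- generateExpression(nGenes = 20, seed = 3)
  expect_identical(a$mat, b$mat)
  expect_identical(a$truth, b$truth)
  # zero effect size means planted up/down collapse to ties only when fc is 0;
  # with no up/down planted, everything is unchanged or silent
  flat <- generateExpression(nGenes = 15, propUp = 0, propDown = 0,
                             propSilent = 0, seed = 4)
  calls <- foldChange(flat$mat, flat$pairing)
  expect_true(all(calls$call == "unchanged"))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateFamily(n = 4, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})
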