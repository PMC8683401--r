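# Gene models, intron phases, chromosome/strand bookkeeping.

makeModel <- function(cdsLengths, intronLengths, strand = "+",
                      chrom = "chr1", gid = "toy", offset = 1000L) {
  # genomic intervals from transcription-order lengths
  n <- length(cdsLengths)
  starts <- integer(n); ends <- integer(n)
  pos <- offset
  for (i in seq_len(n)) {
    starts[i] <- pos; ends[i] <- pos + cdsLengths[i] - 1L
    if (i < n) pos <- ends[i] + intronLengths[i] + 1L
  }
  if (strand == "-") {
    span <- ends[n]
    s2 <- span - ends + offset; e2 <- span - starts + offset
    starts <- s2; ends <- e2
  }
  ord <- order(starts)
  ir <- IRanges::IRanges(starts[ord], ends[ord])
  new("GeneModel", geneId = gid, chromosome = chrom, strand = strand,
      exons = ir, cds = ir)
}

test_that("intron phases follow the cumulative-CDS mod-3 rule", {
  expect_equal(intronPhases(makeModel(c(99, 150), 100))$phase, "0")
  expect_equal(intronPhases(makeModel(c(100, 149), 100))$phase, "1")
  expect_equal(intronPhases(makeModel(c(101, 148), 100))$phase, "2")
})

test_that("phases agree with an independent codon-walk oracle", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    lens <- sample(30:300, k)
    total <- sum(lens)
    lens[k] <- lens[k] + (3 - total %% 3) %% 3  # make CDS a codon multiple
    introns <- sample(60:500, k - 1, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    m <- makeModel(lens, introns, strand = strand)
    ph <- intronPhases(m)
    expect_equal(ph$phase, codonWalkPhases(lens),
                 info = sprintf("rep %d strand %s", rep, strand))
    expect_equal(ph$length, introns)
  }
})

test_that("strand reversal preserves intron lengths and phases", {
  lens <- c(120, 88, 92); lens[3] <- lens[3] + (3 - sum(lens) %% 3) %% 3
  introns <- c(150, 99)
  plus <- intronPhases(makeModel(lens, introns, strand = "+"))
  minus <- intronPhases(makeModel(lens, introns, strand = "-"))
  expect_equal(plus$phase, minus$phase)
  expect_equal(plus$length, minus$length)
})

test_that("single-exon genes have no introns", {
  m <- makeModel(300, integer(0))
  expect_equal(nrow(intronPhases(m)), 0L)
})

test_that("a CDS length off a codon multiple warns but still phases", {
  m <- makeModel(c(100, 100), 50)
  expect_warning(ph <- intronPhases(m), "not divisible by 3")
  expect_equal(ph$phase, "1")
})

test_that("GFF3 round trip: written models re-import identically", {
  g <- generateGff(nGenes = 8, exonRange = c(1, 11), seed = 17,
                   path = tempfile(fileext = ".gff3"))
  models <- readGeneModels(g$path)
  expect_setequal(names(models), names(g$models))
  for (gid in names(models)) {
    expect_equal(IRanges::start(models[[gid]]@cds),
                 IRanges::start(g$models[[gid]]@cds))
    expect_equal(models[[gid]]@strand, g$models[[gid]]@strand)
  }
  unlink(g$path)
})

test_that("hand-written multi-exon GFF3 yields the written intron lengths", {
  tmp <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t700\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t101\t700\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttoy\tCDS\t101\t199\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chr1\ttoy\tCDS\t300\t400\t.\t+\t0\tID=c2;Parent=g1.t1",
    "chr1\ttoy\tCDS\t501\t700\t.\t+\t1\tID=c3;Parent=g1.t1"), tmp)
  models <- readGeneModels(tmp)
  expect_length(models, 1L)
  ph <- suppressWarnings(intronPhases(models$g1))
  expect_equal(ph$length, c(100L, 100L))  # 200..299 and 401..500
  expect_equal(ph$phase[1], "0")          # 99 mod 3
  expect_equal(ph$phase[2], "2")          # 200 mod 3
  unlink(tmp)
})

test_that("family summary histogram balances exon counts", {
  g <- generateGff(nGenes = 12, exonRange = c(1, 9), seed = 23)
  s <- familyStructureSummary(g$models)
  expect_equal(sum(s$phaseHistogram), sum(s$exonCounts - 1L))
  # generator truth is reproduced exactly
  m <- merge(s$introns, g$truth, by = c("gene_id", "index"))
  expect_equal(nrow(m), nrow(g$truth))
  expect_equal(m$phase.x, m$phase.y)
  # empty set gives zeros
  empty <- familyStructureSummary(list())
  expect_true(all(empty$phaseHistogram == 0L))
})

test_that("chromosome summary reproduces the family's published distribution", {
  t1 <- loadTable1()
  cs <- chromosomeSummary(t1)
  expect_equal(cs$chromosomes[["A01"]], 6L)
  expect_false("A08" %in% names(cs$chromosomes))
  expect_equal(cs$strands, c(forward = 15L, reverse = 14L))
  one <- chromosomeSummary(data.frame(chromosome = "A03", strand = "+"))
  expect_equal(one$chromosomes[["A03"]], 1L)
})
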