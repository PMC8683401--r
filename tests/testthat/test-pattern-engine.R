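# Pattern parsing, scanning, counting and PTM profiling.

test_that("simple patterns parse into ordered elements", {
  p <- parsePattern("A-X-C")
  expect_s4_class(p, "MotifPattern")
  expect_equal(length(p), 3L)
  expect_equal(p@elements$kind, c("fixed-residue", "wildcard", "fixed-residue"))
  expect_equal(p@elements$residues, c("A", "", "C"))
  expect_equal(minSpan(p), 3L)
  expect_equal(maxSpan(p), 3L)
})

test_that("bracketed single residues parse like plain letters", {
  a <- parsePattern("[L]-X-[G]")
  b <- parsePattern("L-X-G")
  keep <- c("kind", "residues", "min", "max")
  expect_equal(a@elements[, keep], b@elements[, keep])
  # but the written form is remembered
  expect_true(all(a@elements$bracketed[c(1, 3)]))
  expect_equal(patternToString(a), "[L]-X-[G]")
})

test_that("dash dialects and whitespace are tolerated", {
  variants <- c("[ST]-X(2)-[DE]",
                "[ST] – X (2) — [DE]",
                "[ST]- X(2) -[DE]")
  parsed <- lapply(variants, parsePattern)
  for (p in parsed[-1])
    expect_equal(p@elements, parsed[[1]]@elements)
})

test_that("the bundled family key parses to 22 elements spanning 39-53", {
  key <- brcngcKey()
  expect_equal(length(key), 22L)
  # arithmetic oracle: spans are the sums of per-element repeat bounds
  expect_equal(minSpan(key), sum(key@elements$min))
  expect_equal(maxSpan(key), sum(key@elements$max))
  expect_equal(minSpan(key), 39L)
  expect_equal(maxSpan(key), 53L)
})

test_that("malformed patterns are rejected with the offending token named", {
  expect_error(parsePattern(""), "empty pattern")
  expect_error(parsePattern("A-X(3,2)-C", ), "X\\(3,2\\)")
  expect_error(parsePattern("A-?-C"), "\\?")
  expect_error(parsePattern("[B]-X"), "\\[B\\]")
  expect_error(parsePattern("A(0)-C"), "A\\(0\\)")
})

test_that("parse -> serialize -> parse is the identity on elements", {
  set.seed(42)
  for (i in 1:50) {
    p <- randomPattern()
    q <- parsePattern(patternToString(p))
    expect_equal(q@elements, p@elements)
  }
})

test_that("scanning reports 1-based leftmost-shortest matches per start", {
  hits <- scanPattern("A-X-C", "AAC")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 3L)
  expect_equal(hits$matched, "AAC")

  # overlapping matches at distinct starts are all reported
  ck2 <- scanPattern("[ST]-X(2)-[DE]", "STTEDE")
  expect_equal(ck2$start, 1:3)
  expect_equal(ck2$matched, c("STTE", "TTED", "TEDE"))

  # at one start, the shortest satisfying expansion wins
  h <- scanPattern("A-X(1,3)-C", "AACXXC")
  expect_equal(h$matched[1], "AAC")
})

test_that("empty sequences yield empty results, not errors", {
  expect_equal(nrow(scanPattern("A-X-C", "")), 0L)
  expect_equal(countMatches("A-X-C", ""), 0L)
})

test_that("unknown sequence letters match wildcards but not residue positions", {
  expect_equal(countMatches("A-X-C", "ABC"), 1L)       # B under the wildcard
  expect_equal(countMatches("A-A-C", "AXC"), 0L)       # X never matches fixed A
  expect_equal(countMatches("[AC]-C", "XC"), 0L)       # nor classes
  expect_equal(countMatches("{P}-C", "XC"), 0L)        # nor exclusions
  expect_equal(countMatches("X-C", "ZC"), 1L)          # wildcard takes anything
})

test_that("anchors restrict matches to the termini", {
  expect_equal(countMatches("<A-X-C", "AACAAC"), 1L)
  expect_equal(scanPattern("<A-X-C", "AACAAC")$start, 1L)
  expect_equal(scanPattern(parsePattern("A-X-C>"), "AACAAC")$start, 4L)
  expect_equal(countMatches("<A-C>", "ACAC"), 0L)
})

test_that("scan agrees with the brute-force enumeration oracle", {
  set.seed(1001)
  n_cases <- 1200L
  for (i in seq_len(n_cases)) {
    p <- randomPattern()
    s <- randomSeq()
    got <- scanPattern(p, s)
    expect_identical(got$start, oracleMatchStarts(p, s),
                     info = sprintf("case %d: %s vs %s", i, patternToString(p), s))
  }
})

test_that("fixed-length patterns never exceed the start-position bound", {
  set.seed(7)
  for (i in 1:50) {
    p <- randomPattern()
    if (minSpan(p) != maxSpan(p)) next
    s <- randomSeq()
    expect_lte(countMatches(p, s), max(0L, nchar(s) - minSpan(p) + 1L))
  }
})

test_that("AAStringSet scanning tags matches with sequence ids", {
  seqs <- Biostrings::AAStringSet(c(one = "STTEDE", two = "PPPP"))
  hits <- scanPattern(parsePattern("[ST]-X(2)-[DE]"), seqs)
  expect_equal(unique(hits$seq_id), "one")
  cnt <- countMatches(parsePattern("[ST]-X(2)-[DE]"), seqs)
  expect_equal(unname(cnt), c(3L, 0L))
})

test_that("PTM profiling counts the bundled site classes", {
  res <- ptmScan("NGSA")
  expect_equal(res$count[res$site_class == "ASN_GLYCOSYLATION"], 1L)
  expect_equal(res$positions[res$site_class == "ASN_GLYCOSYLATION"], "1")

  allzero <- ptmScan("PPPP")
  expect_true(all(allzero$count == 0L))

  # every bundled pattern parses and serializes cleanly
  pats <- ptmPatterns()
  expect_length(pats, 9L)
  for (nm in names(pats))
    expect_equal(parsePattern(patternToString(pats[[nm]]))@elements,
                 pats[[nm]]@elements)
})

test_that("pattern files round-trip through the NAME<TAB>PATTERN dialect", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "ck2\t[ST]-X(2)-[DE]", "ploop\t[AG]-X(4)-G-K-[ST]"), tmp)
  pats <- readPatternFile(tmp)
  expect_named(pats, c("ck2", "ploop"))
  expect_equal(minSpan(pats$ploop), 8L)
  unlink(tmp)
})
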