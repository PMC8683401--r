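# Physicochemical profiling.

test_that("molecular weight is residue masses plus one water", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecularWeight("GG"), 132.12, tolerance = 1e-4)
  expect_error(molecularWeight(""), "empty")
  expect_error(molecularWeight("GXG"), "non-standard")
})

test_that("molecular weight is additive up to one condensation water", {
  set.seed(3)
  for (i in 1:20) {
    s1 <- randomSeq(3, 30); s2 <- randomSeq(3, 30)
    expect_equal(molecularWeight(paste0(s1, s2)),
                 molecularWeight(s1) + molecularWeight(s2) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("GRAVY hits the hydropathy-scale extremes and stays bounded", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("R"), -4.5)
  set.seed(4)
  for (i in 1:20) {
    g <- gravy(randomSeq())
    expect_gte(g, -4.5); expect_lte(g, 4.5)
  }
})

test_that("GRAVY of a concatenation is the length-weighted mean of the parts", {
  set.seed(5)
  for (i in 1:10) {
    s1 <- randomSeq(3, 30); s2 <- randomSeq(3, 30)
    n1 <- nchar(s1); n2 <- nchar(s2)
    expect_equal(gravy(paste0(s1, s2)),
                 (n1 * gravy(s1) + n2 * gravy(s2)) / (n1 + n2),
                 tolerance = 1e-12)
  }
})

test_that("aliphatic index applies the relative-volume coefficients", {
  expect_equal(aliphaticIndex("AAAA"), 100)
  expect_equal(aliphaticIndex("VVV"), 290)
  expect_equal(aliphaticIndex(strrep("I", 5)), 390)
  expect_equal(aliphaticIndex("AV"), 100 * (0.5 + 2.9 * 0.5))
})

test_that("instability index follows the dipeptide-weight closed form", {
  expect_warning(ii1 <- instabilityIndex("A"), "shorter than 2")
  expect_equal(ii1, 0)
  # DIWV(A,A) = 1, so poly-A gives 10*(L-1)/L
  for (L in c(2, 5, 40))
    expect_equal(instabilityIndex(strrep("A", L)), 10 * (L - 1) / L)
  # a known strongly negative dipeptide weight: DIWV(Y,R) = -15.91
  expect_equal(instabilityIndex("YR"), 10 / 2 * -15.91)
})

test_that("net charge decreases monotonically in pH and balances at the pI", {
  set.seed(6)
  for (i in 1:10) {
    s <- randomSeq(10, 40)
    ph <- seq(1, 13, by = 0.5)
    ch <- vapply(ph, function(p) netCharge(s, p), numeric(1))
    expect_true(all(diff(ch) < 0))
    expect_lt(abs(netCharge(s, isoelectricPoint(s))), 1e-3)
  }
  expect_gt(netCharge("K", 7), 0.5)  # lysine is positive at neutral pH
})

test_that("bisection pI matches the fine-grid scan oracle within 2e-3", {
  set.seed(8)
  for (i in 1:25) {
    s <- randomSeq(30, 30)
    expect_equal(isoelectricPoint(s), gridScanPI(s), tolerance = 2e-3)
  }
})

test_that("pI responds to charged residues in the expected direction", {
  set.seed(9)
  for (i in 1:10) {
    s <- randomSeq(10, 30)
    expect_gte(isoelectricPoint(paste0(s, "K")) + 1e-3, isoelectricPoint(s))
    expect_lte(isoelectricPoint(paste0(s, "D")) - 1e-3, isoelectricPoint(s))
  }
})

test_that("compositions are normalized fractions and element counts", {
  comp <- aaComposition("AAG")
  expect_equal(comp[["A"]], 2 / 3)
  expect_equal(comp[["G"]], 1 / 3)
  expect_equal(sum(comp), 1, tolerance = 1e-12)

  atoms <- atomicComposition("G")  # glycine residue + water = C2H5NO2
  expect_equal(unname(atoms[c("C", "H", "N", "O", "S")]), c(2, 5, 1, 2, 0))
})

test_that("the aggregated report is internally consistent", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  r <- physchemReport(s, accession = "demo")
  expect_s4_class(r, "PhyschemReport")
  expect_equal(r@length, nchar(s))
  expect_equal(r@avgResidueWeight, r@mw / r@length)
  expect_equal(r@mw, molecularWeight(s))
  expect_equal(r@gravy, gravy(s))
  expect_equal(sum(r@aaComposition), 1, tolerance = 1e-9)
  # hydrogen is the most abundant atom in typical proteins
  expect_equal(names(which.max(r@atomicComposition)), "H")

  tab <- physchemTable(c(p1 = s, p2 = strrep("AV", 20)))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$length, c(nchar(s), 40L))
})

test_that("lenient mode tolerates ambiguous letters, strict mode refuses", {
  expect_error(gravy("AXA"), "non-standard")
  expect_equal(gravy("AXA", ambiguous = "lenient"), gravy("AA"))
  expect_equal(aliphaticIndex("AXA", ambiguous = "lenient"), 100)
  expect_gt(molecularWeight("AXA", ambiguous = "lenient"), molecularWeight("AA"))
})
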