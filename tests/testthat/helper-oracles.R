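# Independent oracles and random-case generators for property tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# --- brute-force scan oracle -------------------------------------------------
# Enumerates every start position and every span between the pattern's min
# and max span, testing each substring against an anchored regex translation
# of the pattern. Wholly independent of the package's reachable-set matcher.
# Only valid for sequences over the 20 standard letters.

oracleElementRegex <- function(kind, residues, lo, hi) {
  core <- switch(kind,
    "fixed-residue" = residues,
    "residue-class" = paste0("[", residues, "]"),
    "excluded-class" = paste0("[", paste(setdiff(AA20, strsplit(residues, "")[[1]]),
                                         collapse = ""), "]"),
    "wildcard" = "[A-Z]")
  if (lo == 1 && hi == 1) core
  else paste0(core, "{", lo, ",", hi, "}")
}

oraclePatternRegex <- function(pattern) {
  el <- pattern@elements
  paste0("^", paste(vapply(seq_len(nrow(el)), function(i)
    oracleElementRegex(el$kind[i], el$residues[i], el$min[i], el$max[i]),
    character(1)), collapse = ""), "$")
}

# matching start positions by exhaustive span enumeration
oracleMatchStarts <- function(pattern, seq) {
  n <- nchar(seq)
  lo <- sum(pattern@elements$min)
  hi <- sum(pattern@elements$max)
  rx <- oraclePatternRegex(pattern)
  starts <- integer(0)
  for (s in seq_len(max(0L, n - lo + 1L))) {
    for (L in lo:min(hi, n - s + 1L)) {
      if (grepl(rx, substr(seq, s, s + L - 1L))) {
        starts <- c(starts, s)
        break
      }
    }
  }
  starts
}

randomPattern <- function(maxElements = 8L) {
  k <- sample(2:maxElements, 1L)
  toks <- character(k)
  for (i in seq_len(k)) {
    kind <- sample(c("fixed", "class", "excl", "wild"), 1L,
                   prob = c(0.35, 0.25, 0.1, 0.3))
    if (kind == "wild") {
      lo <- sample(0:2, 1L); hi <- lo + sample(0:2, 1L)
      core <- "X"
    } else {
      lo <- sample(1:2, 1L); hi <- lo + sample(0:1, 1L)
      core <- switch(kind,
        fixed = sample(AA20, 1L),
        class = paste0("[", paste(sample(AA20, sample(2:4, 1L)), collapse = ""), "]"),
        excl = paste0("{", paste(sample(AA20, sample(1:3, 1L)), collapse = ""), "}"))
    }
    toks[i] <- if (lo == 1 && hi == 1) core
               else if (lo == hi) paste0(core, "(", lo, ")")
               else paste0(core, "(", lo, ",", hi, ")")
  }
  txt <- paste(toks, collapse = "-")
  p <- try(parsePattern(txt), silent = TRUE)
  if (inherits(p, "try-error")) return(randomPattern(maxElements))  # min span 0
  p
}

randomSeq <- function(minLen = 5L, maxLen = 60L) {
  paste(sample(AA20, sample(minLen:maxLen, 1L), replace = TRUE), collapse = "")
}

# --- codon-walk intron-phase oracle ------------------------------------------
# Assigns codon positions 1,2,3,1,2,... along the spliced CDS (transcription
# order) and reads the phase of each intron from the codon position of the
# last exonic base before it: after position 3 -> phase 0, after 1 -> phase 1,
# after 2 -> phase 2.
codonWalkPhases <- function(cdsLengths) {
  if (length(cdsLengths) < 2L) return(character(0))
  codonPos <- rep_len(1:3, sum(cdsLengths))
  ends <- cumsum(cdsLengths)[-length(cdsLengths)]
  vapply(ends, function(e) {
    c("1" = "1", "2" = "2", "3" = "0")[[as.character(codonPos[e])]]
  }, character(1))
}

# --- fine-grid pI oracle ------------------------------------------------------
# Vectorized Henderson-Hasselbalch charge over a dense pH grid; the pI is the
# grid point with charge closest to zero. Independent of the bisection path.
gridScanPI <- function(seq, step = 5e-4) {
  chars <- strsplit(toupper(seq), "")[[1]]
  cnt <- table(factor(chars, levels = AA20))
  pk <- list(K = 10.0, R = 12.0, H = 5.98, D = 4.05, E = 4.45,
             C = 9.0, Y = 10.0)
  ntermTab <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.7)
  ctermTab <- c(D = 4.55, E = 4.75)
  first <- chars[1]; last <- chars[length(chars)]
  pkN <- if (first %in% names(ntermTab)) ntermTab[[first]] else 7.5
  pkC <- if (last %in% names(ctermTab)) ctermTab[[last]] else 3.55
  ph <- seq(0, 14, by = step)
  charge <- 1 / (1 + 10^(ph - pkN)) - 1 / (1 + 10^(pkC - ph))
  for (r in c("K", "R", "H"))
    charge <- charge + cnt[[r]] / (1 + 10^(ph - pk[[r]]))
  for (r in c("D", "E", "C", "Y"))
    charge <- charge - cnt[[r]] / (1 + 10^(pk[[r]] - ph))
  ph[which.min(abs(charge))]
}

# minimal-span instance of any pattern: each element contributes its min
# repeat of one admissible residue
instantiatePattern <- function(pattern) {
  el <- pattern@elements
  paste(vapply(seq_len(nrow(el)), function(i) {
    res <- strsplit(el$residues[i], "")[[1]]
    ch <- switch(el$kind[i],
      "fixed-residue" = res,
      "residue-class" = res[1],
      "excluded-class" = setdiff(AA20, res)[1],
      "wildcard" = "A")
    strrep(ch, el$min[i])
  }, character(1)), collapse = "")
}
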