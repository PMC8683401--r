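# ProtParam-style physicochemical protein profiling.

.cleanSeq <- function(seq, ambiguous = c("strict", "lenient"), caller = "physchem") {
  ambiguous <- match.arg(ambiguous)
  if (is(seq, "AAString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- !(chars %in% STANDARD_AA)
  if (any(bad)) {
    if (ambiguous == "strict")
      stop(sprintf("%s: non-standard residue letter(s) %s (use ambiguous = 'lenient' to tolerate)",
                   caller, paste(unique(chars[bad]), collapse = ",")))
    chars[bad] <- "X"
  }
  chars
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param seq protein sequence (string or \code{AAString}).
#' @param ambiguous \code{"strict"} errors on non-standard letters;
#'   \code{"lenient"} assigns them the mean residue mass.
#' @return weight in Da.
#' @examples
#' molecularWeight("G")  # 75.07
#' @export
molecularWeight <- function(seq, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "molecularWeight")
  if (!length(chars)) stop("empty sequence")
  m <- AA_MONOMER_MASS[chars]
  m[is.na(m)] <- mean(AA_MONOMER_MASS)
  sum(m) + WATER_MASS
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over residues; positive values are
#' hydrophobic, negative hydrophilic. Bounded by the scale extremes
#' [-4.5, 4.5].
#'
#' @inheritParams molecularWeight
#' @return dimensionless mean hydropathy. In lenient mode, ambiguous letters
#'   are excluded from the mean.
#' @export
gravy <- function(seq, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "gravy")
  if (!length(chars)) stop("empty sequence")
  h <- KYTE_DOOLITTLE[chars]
  mean(h, na.rm = TRUE)
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' \code{100 * (fA + 2.9 fV + 3.9 (fI + fL))} with \code{f} the mole
#' fractions. A thermostability proxy for globular proteins.
#'
#' @inheritParams molecularWeight
#' @return dimensionless index (>= 0).
#' @export
aliphaticIndex <- function(seq, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "aliphaticIndex")
  chars <- chars[chars %in% STANDARD_AA]
  if (!length(chars)) stop("empty sequence")
  f <- table(factor(chars, levels = STANDARD_AA)) / length(chars)
  100 * (f[["A"]] + ALIPHATIC_COEF[["V"]] * f[["V"]] +
         ALIPHATIC_COEF[["IL"]] * (f[["I"]] + f[["L"]]))
}

#' Guruprasad instability index
#'
#' \code{(10/L) * sum DIWV(x_i, x_{i+1})} over the L-1 dipeptides, using the
#' bundled 400-entry dipeptide weight table. Values above 40 predict
#' instability in the test tube.
#'
#' @inheritParams molecularWeight
#' @return dimensionless index; 0 (with a warning) for single-residue input.
#'   In lenient mode dipeptides containing an ambiguous letter are skipped.
#' @export
instabilityIndex <- function(seq, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "instabilityIndex")
  L <- length(chars)
  if (L < 2L) {
    warning("instability index undefined for sequences shorter than 2 residues; returning 0")
    return(0)
  }
  a <- chars[-L]; b <- chars[-1L]
  keep <- a %in% STANDARD_AA & b %in% STANDARD_AA
  (10 / L) * sum(DIWV[cbind(a[keep], b[keep])])
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable side chains (D, E, C, Y, H, K,
#' R) and the termini, with the Bjellqvist pKa set used by ProtParam
#' (terminal pKas are residue-specific). Strictly decreasing in pH.
#'
#' @inheritParams molecularWeight
#' @param pH pH at which to evaluate the charge (default 7.0).
#' @return signed net charge.
#' @export
netCharge <- function(seq, pH = 7.0, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "netCharge")
  chars <- chars[chars %in% STANDARD_AA]
  if (!length(chars)) stop("empty sequence")
  pka <- PKA_BJELLQVIST
  cnt <- table(factor(chars, levels = STANDARD_AA))
  first <- chars[1L]; last <- chars[length(chars)]
  pkN <- if (first %in% names(pka$ntermByResidue))
    pka$ntermByResidue[[first]] else pka$positive[["Nterm"]]
  pkC <- if (last %in% names(pka$ctermByResidue))
    pka$ctermByResidue[[last]] else pka$negative[["Cterm"]]

  pos <- 1 / (1 + 10^(pH - pkN))
  for (r in c("K", "R", "H"))
    pos <- pos + cnt[[r]] / (1 + 10^(pH - pka$positive[[r]]))
  neg <- 1 / (1 + 10^(pkC - pH))
  for (r in c("D", "E", "C", "Y"))
    neg <- neg + cnt[[r]] / (1 + 10^(pka$negative[[r]] - pH))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' The pH at which [netCharge()] is zero, located by bisection on [0, 14]
#' (charge is monotone decreasing in pH) to a tolerance of 1e-4 pH units.
#'
#' @inheritParams molecularWeight
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(seq, ambiguous = c("strict", "lenient")) {
  ambiguous <- match.arg(ambiguous)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (netCharge(seq, mid, ambiguous) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Amino-acid composition
#'
#' @inheritParams molecularWeight
#' @return named numeric of residue fractions over the 20 standard residues
#'   (sums to 1; ambiguous letters excluded in lenient mode).
#' @export
aaComposition <- function(seq, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "aaComposition")
  chars <- chars[chars %in% STANDARD_AA]
  if (!length(chars)) stop("empty sequence")
  cnt <- table(factor(chars, levels = STANDARD_AA))
  stats::setNames(as.numeric(cnt) / length(chars), STANDARD_AA)
}

#' Atomic composition
#'
#' Element counts (C, H, N, O, S) summed over residues plus one water per
#' chain.
#'
#' @inheritParams molecularWeight
#' @return named numeric of atom counts.
#' @export
atomicComposition <- function(seq, ambiguous = c("strict", "lenient")) {
  chars <- .cleanSeq(seq, ambiguous, "atomicComposition")
  chars <- chars[chars %in% STANDARD_AA]
  if (!length(chars)) stop("empty sequence")
  counts <- colSums(AA_ATOMS[chars, , drop = FALSE])
  counts["H"] <- counts["H"] + 2
  counts["O"] <- counts["O"] + 1
  counts
}

#' Full physicochemical report for one protein
#'
#' Aggregates length, molecular weight, pI, instability index, aliphatic
#' index, GRAVY, average residue weight, net charge at \code{chargePH}, and
#' amino-acid / atomic compositions into a [PhyschemReport-class].
#'
#' @inheritParams molecularWeight
#' @param accession identifier stored on the report.
#' @param chargePH pH for the net-charge entry (default 7.0; the published
#'   family table's charge convention is unstated, so the pH used is always
#'   recorded on the report).
#' @return a [PhyschemReport-class].
#' @export
physchemReport <- function(seq, accession = NA_character_, chargePH = 7.0,
                           ambiguous = c("strict", "lenient")) {
  ambiguous <- match.arg(ambiguous)
  chars <- .cleanSeq(seq, ambiguous, "physchemReport")
  L <- length(chars)
  mw <- molecularWeight(seq, ambiguous)
  new("PhyschemReport",
      accession = accession,
      length = L,
      mw = mw,
      pI = isoelectricPoint(seq, ambiguous),
      instability = suppressWarnings(instabilityIndex(seq, ambiguous)),
      aliphatic = as.numeric(aliphaticIndex(seq, ambiguous)),
      gravy = gravy(seq, ambiguous),
      avgResidueWeight = mw / L,
      netCharge = netCharge(seq, chargePH, ambiguous),
      chargePH = chargePH,
      aaComposition = aaComposition(seq, ambiguous),
      atomicComposition = atomicComposition(seq, ambiguous))
}

setMethod("show", "PhyschemReport", function(object) {
  cat(sprintf("PhyschemReport for %s\n",
              ifelse(is.na(object@accession), "<unnamed>", object@accession)))
  cat(sprintf("  length %d aa, MW %.2f kDa, pI %.2f\n",
              object@length, object@mw / 1000, object@pI))
  cat(sprintf("  II %.1f, Ai %.2f, GRAVY %.3f, AW %.3f, charge %.1f (pH %.1f)\n",
              object@instability, object@aliphatic, object@gravy,
              object@avgResidueWeight, object@netCharge, object@chargePH))
})

#' Physicochemical property table for a set of proteins
#'
#' One row per sequence, mirroring the published family table's column order:
#' protein, length, MW (kDa), pI, II, Ai, GRAVY, AW, charge.
#'
#' @param seqs [Biostrings::AAStringSet] or named character vector.
#' @inheritParams physchemReport
#' @return data.frame.
#' @export
physchemTable <- function(seqs, chargePH = 7.0,
                          ambiguous = c("strict", "lenient")) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    r <- physchemReport(seqs[[i]], accession = nm[i], chargePH = chargePH,
                        ambiguous = ambiguous)
    data.frame(protein = nm[i], length = r@length,
               mw_kda = round(r@mw / 1000, 2),
               pi = round(r@pI, 2), ii = round(r@instability, 1),
               ai = round(r@aliphatic, 2), gravy = round(r@gravy, 3),
               aw = round(r@avgResidueWeight, 3),
               charge = round(r@netCharge, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
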