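# Consensus-key induction from a protein multiple sequence alignment.
#
# Conserved columns (top non-gap residue at or above the conservation
# threshold) become fixed or class tokens; maximal runs of everything else
# become bounded wildcards whose repeat bounds are the fewest / most non-gap
# residues any row contributes across the run.

.msaMatrix <- function(msa) {
  if (is(msa, "AAMultipleAlignment")) msa <- as(msa, "AAStringSet")
  if (is(msa, "AAStringSet")) msa <- as.character(msa)
  stopifnot(is.character(msa))
  if (length(msa) < 1L) stop("alignment must contain at least one row")
  w <- nchar(msa)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: rows differ in width")
  do.call(rbind, strsplit(toupper(msa), ""))
}

#' Per-column conservation profiles of an alignment
#'
#' For each column: residue counts over the rows, the gap count, the most
#' frequent non-gap residue and its fraction among non-gap rows.
#'
#' @param msa aligned sequences of equal width: character vector,
#'   [Biostrings::AAStringSet] or \code{AAMultipleAlignment}; gap character
#'   \code{"-"}.
#' @return data.frame with one row per column: \code{column} (1-based),
#'   \code{top_residue}, \code{top_fraction}, \code{gap_count}, \code{n_rows};
#'   the full residue-count matrix (residues x columns) is attached as
#'   attribute \code{"counts"}.
#' @export
columnProfiles <- function(msa) {
  m <- .msaMatrix(msa)
  nr <- nrow(m); nc <- ncol(m)
  lv <- c(STANDARD_AA, "-")
  counts <- apply(m, 2L, function(col) table(factor(col, levels = lv)))
  gap <- counts["-", ]
  aa <- counts[STANDARD_AA, , drop = FALSE]
  top_i <- apply(aa, 2L, which.max)
  top_res <- STANDARD_AA[top_i]
  top_n <- aa[cbind(top_i, seq_len(nc))]
  nongap <- nr - gap
  top_frac <- ifelse(nongap > 0L, top_n / nongap, NA_real_)
  top_res[nongap == 0L] <- NA_character_
  out <- data.frame(column = seq_len(nc), top_residue = top_res,
                    top_fraction = top_frac, gap_count = as.integer(gap),
                    n_rows = nr, stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  out
}

#' Induce a consensus motif key from an alignment
#'
#' Columns whose top non-gap residue reaches the conservation threshold become
#' fixed tokens (plain letter when 100% conserved and gap-free, bracketed
#' otherwise); maximal runs of the remaining columns become bounded wildcards
#' \code{X(min,max)}, where min/max are the fewest/most non-gap residues any
#' row contributes across the run (a run no row contributes to is dropped).
#' Columns with more than 50% gaps never fix. In \code{cover} mode a conserved
#' but imperfect column is widened to the class of all residues observed in
#' it (and any column containing a gap is folded into a wildcard run), which
#' guarantees the key matches every training sequence. Leading and trailing
#' wildcard runs are trimmed.
#'
#' @param msa aligned sequences (see [columnProfiles()]); at least 2 rows.
#' @param threshold conservation threshold in (0.5, 1]; default 0.90.
#' @param region optional integer(2) 1-based column interval to use.
#' @param mode \code{"cover"} (default; coverage 1 by construction) or
#'   \code{"strict"} (top residue fixed even when imperfect).
#' @param strictGreater require conservation strictly above the threshold
#'   rather than at-or-above (default FALSE).
#' @param name label for the induced pattern.
#' @return an [InducedKey-class]: the pattern plus per-sequence matched flags
#'   and their coverage fraction over the (degapped) training sequences.
#' @examples
#' induceKey(c("LAC", "LGC"), threshold = 0.9)  # key L-X-C
#' @export
induceKey <- function(msa, threshold = 0.90, region = NULL,
                      mode = c("cover", "strict"), strictGreater = FALSE,
                      name = "induced-key") {
  mode <- match.arg(mode)
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  m <- .msaMatrix(msa)
  if (nrow(m) < 2L) stop("need at least 2 aligned sequences")
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1] > region[2] ||
        region[1] < 1L || region[2] > ncol(m))
      stop("empty or out-of-range region")
    m <- m[, region[1]:region[2], drop = FALSE]
  }
  prof <- columnProfiles(apply(m, 1L, paste, collapse = ""))
  counts <- attr(prof, "counts")
  nr <- nrow(m)

  pass <- if (strictGreater) prof$top_fraction > threshold
          else prof$top_fraction >= threshold
  pass[is.na(pass)] <- FALSE
  conserved <- pass & (prof$gap_count / nr) <= 0.5
  if (mode == "cover") conserved <- conserved & prof$gap_count == 0L

  elements <- list()
  i <- 1L; nc <- ncol(m)
  while (i <= nc) {
    if (conserved[i]) {
      observed <- STANDARD_AA[counts[STANDARD_AA, i] > 0L]
      perfect <- prof$top_fraction[i] == 1 && prof$gap_count[i] == 0L
      if (perfect) {
        el <- data.frame(kind = "fixed-residue", residues = prof$top_residue[i],
                         min = 1L, max = 1L, bracketed = FALSE)
      } else if (mode == "cover") {
        el <- data.frame(kind = "residue-class",
                         residues = paste(sort(observed), collapse = ""),
                         min = 1L, max = 1L, bracketed = TRUE)
      } else {
        el <- data.frame(kind = "fixed-residue", residues = prof$top_residue[i],
                         min = 1L, max = 1L, bracketed = TRUE)
      }
      elements[[length(elements) + 1L]] <- el
      i <- i + 1L
    } else {
      j <- i
      while (j < nc && !conserved[j + 1L]) j <- j + 1L
      contrib <- rowSums(m[, i:j, drop = FALSE] != "-")
      lo <- min(contrib); hi <- max(contrib)
      if (hi > 0L)
        elements[[length(elements) + 1L]] <-
          data.frame(kind = "wildcard", residues = "",
                     min = as.integer(lo), max = as.integer(hi),
                     bracketed = FALSE)
      i <- j + 1L
    }
  }
  if (!length(elements))
    stop("no columns left to induce a key from")
  el <- do.call(rbind, elements)
  # trim flanking wildcard runs; they carry no signal and can have min 0
  while (nrow(el) && el$kind[1] == "wildcard") el <- el[-1L, , drop = FALSE]
  while (nrow(el) && el$kind[nrow(el)] == "wildcard")
    el <- el[-nrow(el), , drop = FALSE]
  if (!nrow(el))
    stop(sprintf("no conserved columns at threshold %.2f", threshold))
  rownames(el) <- NULL
  pattern <- new("MotifPattern", name = name,
                 source = sprintf("induced (threshold %.2f, mode %s)",
                                  threshold, mode),
                 elements = el, nterm = FALSE, cterm = FALSE)

  seqs <- gsub("-", "", apply(m, 1L, paste, collapse = ""))
  nm <- rownames(m)
  if (is.null(nm)) {
    nm <- names(msa)
    if (is.null(nm) || length(nm) != length(seqs))
      nm <- as.character(seq_along(seqs))
  }
  names(seqs) <- nm
  cov <- validateKey(pattern, seqs)
  new("InducedKey", pattern = pattern, coverage = cov$coverage,
      matched = cov$matched,
      region = if (is.null(region)) integer(0) else region,
      threshold = threshold, mode = mode)
}

setMethod("show", "InducedKey", function(object) {
  cat(sprintf("InducedKey (threshold %.2f, mode %s): coverage %.3f over %d sequences\n",
              object@threshold, object@mode, object@coverage,
              length(object@matched)))
  cat("  ", patternToString(object@pattern), "\n", sep = "")
})

#' Validate a motif key against unaligned sequences
#'
#' Scans each sequence with the key and reports which are matched and the
#' overall coverage fraction.
#'
#' @param key a [MotifPattern-class] or pattern string.
#' @param seqs character vector or [Biostrings::AAStringSet] of protein
#'   sequences (gaps are removed first).
#' @return list with \code{matched} (named logical) and \code{coverage}
#'   (fraction in [0, 1]).
#' @export
validateKey <- function(key, seqs) {
  if (is.character(key)) key <- parsePattern(key)
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs))
  if (!length(seqs))
    stop("coverage undefined: no sequences supplied")
  seqs <- gsub("-", "", seqs)
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_along(seqs))
  matched <- vapply(seqs, function(s) nrow(.scanOne(key, s)) > 0L, logical(1))
  names(matched) <- nm
  list(matched = matched, coverage = mean(matched))
}
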