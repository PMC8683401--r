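# Pattern scanning. Every start position is tested; at a given start the
# leftmost-shortest satisfying expansion is reported, so match counts equal
# the number of matching start positions (fixed-length patterns behave exactly
# like classic PROSITE scanning).

# Per-position element compatibility. Unknown letters (X, B, Z, U, ...) match
# wildcards only -- never fixed residues, classes, or excluded classes.
.elementMask <- function(el, chars) {
  if (el$kind == "wildcard") return(rep(TRUE, length(chars)))
  std <- chars %in% STANDARD_AA
  res <- strsplit(el$residues, "")[[1]]
  switch(el$kind,
    "fixed-residue" = std & chars == res,
    "residue-class" = std & chars %in% res,
    "excluded-class" = std & !(chars %in% res))
}

# Shortest end position (exclusive, 1-based) of a match starting at `start`,
# or NA. Reachable-position set propagation over elements; `masks` is a
# list of per-element logical vectors over the sequence.
.shortestMatchEnd <- function(el, masks, n, start, cterm = FALSE) {
  pos <- start  # next unmatched position(s)
  for (i in seq_len(nrow(el))) {
    minr <- el$min[i]; maxr <- el$max[i]
    mask <- masks[[i]]
    nxt <- integer(0)
    for (p in pos) {
      # run of consecutive compatible residues from p
      r <- 0L
      while (r < maxr && (p + r) <= n && mask[p + r]) r <- r + 1L
      if (r >= minr) nxt <- c(nxt, p + (minr:r))
    }
    pos <- unique(nxt)
    if (!length(pos)) return(NA_integer_)
  }
  if (cterm) {
    if ((n + 1L) %in% pos) n + 1L else NA_integer_
  } else {
    min(pos)
  }
}

.scanOne <- function(pattern, seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  el <- pattern@elements
  lo <- minSpan(pattern)
  if (n == 0L || lo > n)
    return(data.frame(start = integer(0), end = integer(0),
                      matched = character(0), stringsAsFactors = FALSE))
  chars <- strsplit(seq, "")[[1]]
  masks <- lapply(seq_len(nrow(el)), function(i) .elementMask(el[i, ], chars))
  starts <- if (pattern@nterm) 1L else seq_len(n - lo + 1L)
  hitS <- integer(0); hitE <- integer(0)
  for (s in starts) {
    e <- .shortestMatchEnd(el, masks, n, s, cterm = pattern@cterm)
    if (!is.na(e)) { hitS <- c(hitS, s); hitE <- c(hitE, e - 1L) }
  }
  data.frame(start = hitS, end = hitE,
             matched = if (length(hitS)) substring(seq, hitS, hitE)
                       else character(0),
             stringsAsFactors = FALSE)
}

#' Scan a protein sequence with a motif pattern
#'
#' Reports one match per matching start position: the leftmost-shortest
#' expansion of any variable-length wildcards (deterministic; identical to
#' classic PROSITE behavior for fixed-length patterns). Overlapping matches at
#' distinct starts are all reported. Coordinates are 1-based inclusive.
#'
#' @param pattern a [MotifPattern-class] or a pattern string (parsed on the fly).
#' @param subject a protein sequence: single character string,
#'   [Biostrings::AAString] or [Biostrings::AAStringSet].
#' @return For a single sequence, a data.frame with columns \code{start},
#'   \code{end}, \code{matched}. For an \code{AAStringSet}, the same with a
#'   leading \code{seq_id} column (one block per record).
#' @examples
#' scanPattern("[ST]-X(2)-[DE]", "STTEDE")  # 3 matches, starts 1..3
#' @export
setGeneric("scanPattern", function(pattern, subject) standardGeneric("scanPattern"))

#' @rdname scanPattern
#' @export
setMethod("scanPattern", signature("character", "ANY"), function(pattern, subject) {
  scanPattern(parsePattern(pattern), subject)
})

#' @rdname scanPattern
#' @export
setMethod("scanPattern", signature("MotifPattern", "character"),
  function(pattern, subject) {
    if (length(subject) == 1L) .scanOne(pattern, subject)
    else scanPattern(pattern, Biostrings::AAStringSet(subject))
  })

#' @rdname scanPattern
#' @export
setMethod("scanPattern", signature("MotifPattern", "AAString"),
  function(pattern, subject) .scanOne(pattern, as.character(subject)))

#' @rdname scanPattern
#' @export
setMethod("scanPattern", signature("MotifPattern", "AAStringSet"),
  function(pattern, subject) {
    ids <- names(subject)
    if (is.null(ids)) ids <- as.character(seq_along(subject))
    out <- lapply(seq_along(subject), function(i) {
      df <- .scanOne(pattern, as.character(subject[[i]]))
      if (nrow(df)) cbind(seq_id = ids[i], df, stringsAsFactors = FALSE)
      else cbind(seq_id = character(0), df)
    })
    do.call(rbind, out)
  })

#' Count pattern matches in a sequence
#'
#' The number of start positions at which the pattern matches (length of the
#' [scanPattern()] output).
#'
#' @inheritParams scanPattern
#' @return non-negative integer (named vector for an \code{AAStringSet}).
#' @examples
#' countMatches("[ST]-X(2)-[DE]", "STTEDE")  # 3
#' @export
countMatches <- function(pattern, subject) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  if (is(subject, "AAStringSet") ||
      (is.character(subject) && length(subject) > 1L)) {
    if (is.character(subject)) subject <- Biostrings::AAStringSet(subject)
    hits <- scanPattern(pattern, subject)
    ids <- names(subject)
    if (is.null(ids)) ids <- as.character(seq_along(subject))
    cnt <- table(factor(hits$seq_id, levels = ids))
    stats::setNames(as.integer(cnt), ids)
  } else {
    nrow(scanPattern(pattern, subject))
  }
}

#' Bundled post-translational-modification site patterns
#'
#' The standard PROSITE site classes used for PTM profiling of family
#' proteins: casein kinase II, protein kinase C, cAMP/cGMP-dependent kinase and
#' tyrosine kinase phosphorylation sites, N-glycosylation, N-myristoylation,
#' amidation, leucine zipper, and the P-loop ATP/GTP-binding motif A.
#'
#' @return named list of [MotifPattern-class] objects.
#' @export
ptmPatterns <- function() {
  path <- system.file("extdata", "ptm_patterns.tsv", package = "famscreen",
                      mustWork = TRUE)
  readPatternFile(path)
}

#' Profile PTM site classes in a protein
#'
#' Scans the sequence with every bundled PTM pattern (see [ptmPatterns()]) and
#' tabulates match counts and 1-based match start positions per site class.
#'
#' @param seq protein sequence (string or \code{AAString}).
#' @param patterns optional named list of [MotifPattern-class] to use instead
#'   of the bundled set.
#' @return data.frame with columns \code{site_class}, \code{pattern},
#'   \code{count}, \code{positions} (comma-separated 1-based starts).
#' @examples
#' ptmScan("NGSA")  # one N-glycosylation site
#' @export
ptmScan <- function(seq, patterns = ptmPatterns()) {
  if (is(seq, "AAString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  rows <- lapply(names(patterns), function(nm) {
    hits <- scanPattern(patterns[[nm]], seq)
    data.frame(site_class = nm,
               pattern = patternToString(patterns[[nm]]),
               count = nrow(hits),
               positions = paste(hits$start, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
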