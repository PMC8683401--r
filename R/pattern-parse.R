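# PROSITE-dialect pattern parsing and serialization.
#
# Supported tokens, separated by '-' (en/em dashes and whitespace tolerated):
#   A          fixed residue
#   [L]        bracketed single residue -- matched exactly like plain L
#   [ABC]      residue class
#   {ABC}      excluded class
#   X / x      wildcard (any residue)
#   suffix (n) or (n,m) on any token bounds the repeat count
#   < / >      optional N-/C-terminal anchors

.normalizePatternText <- function(text) {
  text <- gsub("[‐‑‒–—―−]", "-", text)
  gsub("[[:space:]]+", "", text)
}

# repeat suffix accepts (n), (n,m) and the enumerated form (n1,n2,...) used by
# printed keys (e.g. X(0,1,2)); an enumeration is read as its min..max range
.tokenRegex <- "^(?:([A-Za-z])|\\[([A-Za-z]+)\\]|\\{([A-Za-z]+)\\})(?:\\((\\d+(?:,\\d+)*)\\))?$"

#' Parse a PROSITE-dialect pattern string
#'
#' Tokens are separated by dashes (ASCII or typographic); whitespace is
#' ignored. A bracketed single residue (\code{[L]}) matches exactly like the
#' plain letter; the bracketed form is remembered for serialization.
#' \code{X(n)} and \code{X(n,m)} are bounded wildcards; \code{\{ABC\}} excludes
#' a class; leading \code{<} and trailing \code{>} anchor the match to the
#' sequence termini.
#'
#' @param text pattern string, e.g. \code{"[ST]-X(2)-[DE]"}.
#' @param name optional label stored on the pattern.
#' @param source optional provenance string (e.g. \code{"PROSITE PS00006"}).
#' @return a [MotifPattern-class].
#' @examples
#' p <- parsePattern("[ST]-X(2)-[DE]", name = "CK2")
#' minSpan(p)  # 4
#' @export
parsePattern <- function(text, name = NA_character_, source = NA_character_) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("empty pattern")
  txt <- .normalizePatternText(text)
  nterm <- FALSE
  cterm <- FALSE
  if (startsWith(txt, "<")) { nterm <- TRUE; txt <- substring(txt, 2L) }
  if (endsWith(txt, ">")) { cterm <- TRUE; txt <- substring(txt, 1L, nchar(txt) - 1L) }
  txt <- sub("^-+", "", sub("-+$", "", txt))
  if (!nzchar(txt)) stop("empty pattern")
  tokens <- strsplit(txt, "-+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty pattern")

  rows <- lapply(tokens, .parseToken)
  el <- do.call(rbind, rows)
  rownames(el) <- NULL
  new("MotifPattern", name = name, source = source, elements = el,
      nterm = nterm, cterm = cterm)
}

.parseToken <- function(tok) {
  m <- regmatches(tok, regexec(.tokenRegex, tok))[[1]]
  if (!length(m))
    stop(sprintf("malformed pattern token: '%s'", tok))
  plain <- m[2]; classed <- m[3]; excluded <- m[4]
  reps <- m[5]
  if (nzchar(reps)) {
    vals <- as.integer(strsplit(reps, ",")[[1]])
    if (length(vals) == 2L && vals[2] < vals[1])
      stop(sprintf("malformed pattern token: '%s' (max repeat %d < min repeat %d)",
                   tok, vals[2], vals[1]))
    minr <- min(vals); maxr <- max(vals)
  } else {
    minr <- 1L; maxr <- 1L
  }
  if (nzchar(plain)) {
    up <- toupper(plain)
    if (up == "X") {
      kind <- "wildcard"; residues <- ""; bracketed <- FALSE
    } else {
      kind <- "fixed-residue"; residues <- up; bracketed <- FALSE
    }
  } else if (nzchar(classed)) {
    res <- unique(strsplit(toupper(classed), "")[[1]])
    if (length(res) == 1L) {
      if (res == "X") {
        kind <- "wildcard"; residues <- ""; bracketed <- FALSE
      } else {
        kind <- "fixed-residue"; residues <- res; bracketed <- TRUE
      }
    } else {
      kind <- "residue-class"; residues <- paste(res, collapse = ""); bracketed <- TRUE
    }
  } else {
    res <- unique(strsplit(toupper(excluded), "")[[1]])
    kind <- "excluded-class"; residues <- paste(res, collapse = ""); bracketed <- FALSE
  }
  if (nzchar(residues)) {
    bad <- setdiff(strsplit(residues, "")[[1]], STANDARD_AA)
    if (length(bad))
      stop(sprintf("malformed pattern token: '%s' (non-standard residue '%s')",
                   tok, paste(bad, collapse = "")))
  }
  if (minr == 0L && kind != "wildcard")
    stop(sprintf("malformed pattern token: '%s' (zero repeat only allowed on X)", tok))
  data.frame(kind = kind, residues = residues, min = minr, max = maxr,
             bracketed = bracketed, stringsAsFactors = FALSE)
}

#' Serialize a MotifPattern back to its string form
#'
#' Inverse of [parsePattern()]: \code{parsePattern(patternToString(p))} has
#' identical elements to \code{p}.
#'
#' @param pattern a [MotifPattern-class].
#' @return single pattern string.
#' @export
patternToString <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  el <- pattern@elements
  toks <- vapply(seq_len(nrow(el)), function(i) {
    core <- switch(el$kind[i],
      "wildcard" = "X",
      "fixed-residue" = if (el$bracketed[i])
        paste0("[", el$residues[i], "]") else el$residues[i],
      "residue-class" = paste0("[", el$residues[i], "]"),
      "excluded-class" = paste0("{", el$residues[i], "}"))
    if (el$min[i] == 1L && el$max[i] == 1L) core
    else if (el$min[i] == el$max[i]) paste0(core, "(", el$min[i], ")")
    else paste0(core, "(", el$min[i], ",", el$max[i], ")")
  }, character(1))
  out <- paste(toks, collapse = "-")
  if (pattern@nterm) out <- paste0("<", out)
  if (pattern@cterm) out <- paste0(out, ">")
  out
}

#' Minimum and maximum span of a pattern
#'
#' Sum over elements of the minimum (maximum) repeat counts: the shortest and
#' longest sequence stretch the pattern can match.
#'
#' @param pattern a [MotifPattern-class].
#' @return integer span in residues.
#' @export
minSpan <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  sum(pattern@elements$min)
}

#' @rdname minSpan
#' @export
maxSpan <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  sum(pattern@elements$max)
}

#' @describeIn parsePattern number of elements in the pattern.
#' @param x a MotifPattern.
#' @export
setMethod("length", "MotifPattern", function(x) nrow(x@elements))

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s' (%d elements, span %d-%d)\n",
              ifelse(is.na(object@name), "<unnamed>", object@name),
              nrow(object@elements), minSpan(object), maxSpan(object)))
  if (!is.na(object@source)) cat("  source:", object@source, "\n")
  cat("  ", patternToString(object), "\n", sep = "")
})

#' Read a pattern file (NAME<TAB>PATTERN per line)
#'
#' Lines starting with '#' and blank lines are ignored.
#'
#' @param path file path.
#' @return named list of [MotifPattern-class] objects.
#' @export
readPatternFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pats <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("malformed pattern file line: '%s'", ln))
    nm <- parts[1]
    src <- if (length(parts) >= 3L) parts[3] else NA_character_
    pats[[nm]] <- parsePattern(parts[2], name = nm, source = src)
  }
  pats
}

#' The bundled BrCNGC consensus motif key
#'
#' The family-specific consensus motif key spanning the phosphate-binding
#' cassette (PBC) and hinge region of the cyclic-nucleotide-binding domain,
#' induced from the BrCNGC multiple sequence alignment at >90% conservation.
#' It recognizes every member of the 29-gene family.
#'
#' @return a [MotifPattern-class] with 22 elements (span 39-53 residues).
#' @examples
#' key <- brcngcKey()
#' length(key)
#' @export
brcngcKey <- function() {
  path <- system.file("extdata", "brcngc_key.txt", package = "famscreen",
                      mustWork = TRUE)
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")][1]
  parsePattern(txt, name = "BrCNGC-key", source = "CNBD consensus (PBC + hinge)")
}
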