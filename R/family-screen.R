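# Family-membership screening: full length, required domains, optional
# motif-key validation.

.splitDomains <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  lapply(strsplit(ifelse(is.na(x), "", x), "[,;|[:space:]]+"),
         function(d) d[nzchar(d)])
}

#' Screen candidate family members
#'
#' A candidate is accepted iff its protein length exceeds \code{minLength}
#' (strictly, by default), it carries every required domain, and -- when a
#' motif key is supplied and the candidate has a sequence -- the key matches
#' the sequence. Every failed rule is reported as a reason; accepted records
#' have none.
#'
#' @param candidates data.frame with columns \code{accession}, \code{length},
#'   \code{domains} (comma/semicolon-separated labels or a list column), and
#'   optionally \code{sequence}. [loadTable1()] produces a suitable table.
#' @param minLength length threshold in residues (default 500).
#' @param requiredDomains character vector of domain labels that must all be
#'   present (default \code{c("cNMP", "IT")}: the cyclic-nucleotide-binding
#'   and ion-transport domains).
#' @param key optional [MotifPattern-class] (or pattern string) that must
#'   match the candidate sequence; only applied to candidates that carry a
#'   sequence.
#' @param strict if TRUE (default) the length rule is \code{length >
#'   minLength}; if FALSE, \code{>=}.
#' @return data.frame of decisions: \code{accession}, \code{accepted},
#'   \code{reasons} (comma-joined failed-rule labels, empty when accepted).
#' @examples
#' cands <- data.frame(accession = c("a", "b"), length = c(650, 400),
#'                     domains = c("cNMP,IT", "IT"))
#' screenCandidates(cands)
#' @export
screenCandidates <- function(candidates, minLength = 500,
                             requiredDomains = c("cNMP", "IT"),
                             key = NULL, strict = TRUE) {
  stopifnot(is.data.frame(candidates))
  if (!nrow(candidates))
    return(data.frame(accession = character(0), accepted = logical(0),
                      reasons = character(0), stringsAsFactors = FALSE))
  need <- c("accession", "length", "domains")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidates table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(candidates$length))
    stop("candidate(s) missing length: ",
         paste(candidates$accession[is.na(candidates$length)], collapse = ", "))
  if (is.character(key)) key <- parsePattern(key)
  doms <- .splitDomains(candidates$domains)
  haveSeq <- "sequence" %in% names(candidates)

  decide <- function(i) {
    reasons <- character(0)
    lenOK <- if (strict) candidates$length[i] > minLength
             else candidates$length[i] >= minLength
    if (!lenOK) reasons <- c(reasons, "short-length")
    missing <- setdiff(requiredDomains, doms[[i]])
    if (length(missing))
      reasons <- c(reasons, paste0("missing-domain:", missing))
    if (!is.null(key) && haveSeq && !is.na(candidates$sequence[i]) &&
        nzchar(candidates$sequence[i]) &&
        nrow(.scanOne(key, candidates$sequence[i])) == 0L)
      reasons <- c(reasons, "key-no-match")
    reasons
  }
  reasonList <- lapply(seq_len(nrow(candidates)), decide)
  data.frame(accession = candidates$accession,
             accepted = lengths(reasonList) == 0L,
             reasons = vapply(reasonList, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Summarize screening decisions
#'
#' @param decisions output of [screenCandidates()].
#' @return list with \code{accepted} and \code{rejected} counts plus
#'   \code{byReason}, a named integer vector counting each failed rule.
#' @export
summarizeDecisions <- function(decisions) {
  stopifnot(is.data.frame(decisions), all(c("accepted", "reasons") %in% names(decisions)))
  reasons <- unlist(strsplit(decisions$reasons[!decisions$accepted], ","))
  reasons <- reasons[nzchar(reasons)]
  list(accepted = sum(decisions$accepted),
       rejected = sum(!decisions$accepted),
       byReason = if (length(reasons)) table(reasons) else
         table(factor(character(0))))
}
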