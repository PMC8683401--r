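#' @import methods
NULL

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ELEMENT_KINDS <- c("fixed-residue", "residue-class", "excluded-class", "wildcard")

#' MotifPattern: a parsed PROSITE-dialect motif
#'
#' Ordered list of pattern elements, each a fixed residue, a residue class
#' (\code{[ABC]}), an excluded class (\code{\{ABC\}}) or a bounded wildcard
#' (\code{X}, \code{X(n)}, \code{X(n,m)}). Elements are stored as a data.frame
#' with one row per token: \code{kind}, \code{residues} (collapsed string, empty
#' for wildcards), \code{min} and \code{max} repeat counts, and \code{bracketed}
#' (whether a single residue was written \code{[L]} rather than \code{L}; the
#' two forms match identically but the emitted form is preserved).
#'
#' @slot name label for the pattern.
#' @slot source free-text provenance (e.g. a PROSITE accession).
#' @slot elements data.frame of parsed tokens (see Description).
#' @slot nterm,cterm logical; \code{<} / \code{>} anchors.
#'
#' @seealso [parsePattern()], [scanPattern()], [patternToString()]
#' @export
setClass("MotifPattern",
  representation(
    name = "character",
    source = "character",
    elements = "data.frame",
    nterm = "logical",
    cterm = "logical"
  ),
  prototype(name = NA_character_, source = NA_character_,
            nterm = FALSE, cterm = FALSE)
)

setValidity("MotifPattern", function(object) {
  el <- object@elements
  msg <- character(0)
  if (nrow(el) == 0L)
    return("pattern must contain at least one element")
  need <- c("kind", "residues", "min", "max", "bracketed")
  if (!all(need %in% names(el)))
    return(paste("elements must have columns:", paste(need, collapse = ", ")))
  if (!all(el$kind %in% ELEMENT_KINDS))
    msg <- c(msg, "unknown element kind")
  for (i in seq_len(nrow(el))) {
    res <- strsplit(el$residues[i], "")[[1]]
    if (length(res) && !all(res %in% STANDARD_AA))
      msg <- c(msg, sprintf("element %d: non-standard residue letter", i))
    if (el$kind[i] == "fixed-residue" && length(res) != 1L)
      msg <- c(msg, sprintf("element %d: fixed residue must be a single letter", i))
    if (el$kind[i] == "wildcard" && length(res) != 0L)
      msg <- c(msg, sprintf("element %d: wildcard carries no residues", i))
    if (el$max[i] < el$min[i] || el$min[i] < 0L)
      msg <- c(msg, sprintf("element %d: repeat bounds must satisfy max >= min >= 0", i))
    if (el$min[i] == 0L && el$kind[i] != "wildcard")
      msg <- c(msg, sprintf("element %d: zero min repeat allowed only for wildcards", i))
  }
  if (sum(el$min) < 1L)
    msg <- c(msg, "pattern minimum span must be >= 1")
  if (length(msg)) msg else TRUE
})

#' InducedKey: a consensus motif key induced from an alignment
#'
#' @slot pattern the induced [MotifPattern-class].
#' @slot coverage fraction of the training sequences the key matches.
#' @slot matched named logical, per-sequence matched flags.
#' @slot region integer(2) column interval used, or integer(0) for all columns.
#' @slot threshold conservation threshold used.
#' @slot mode "strict" or "cover".
#'
#' @seealso [induceKey()], [validateKey()]
#' @export
setClass("InducedKey",
  representation(
    pattern = "MotifPattern",
    coverage = "numeric",
    matched = "logical",
    region = "integer",
    threshold = "numeric",
    mode = "character"
  )
)

setValidity("InducedKey", function(object) {
  if (length(object@coverage) == 1L &&
      (object@coverage < 0 || object@coverage > 1))
    return("coverage must lie in [0, 1]")
  TRUE
})

#' PhyschemReport: physicochemical profile of one protein
#'
#' Mirrors a ProtParam-style summary row: length, molecular weight (Da),
#' theoretical pI, instability index, aliphatic index, GRAVY, average residue
#' weight (Da), net charge at a stated pH, and amino-acid / atomic compositions.
#'
#' @slot accession sequence identifier.
#' @slot length residue count.
#' @slot mw molecular weight in Da (average isotopic masses).
#' @slot pI theoretical isoelectric point.
#' @slot instability Guruprasad instability index (>40 predicts instability
#'   in vitro).
#' @slot aliphatic aliphatic index (thermostability proxy).
#' @slot gravy grand average of hydropathicity (Kyte-Doolittle).
#' @slot avgResidueWeight mw / length.
#' @slot netCharge Henderson-Hasselbalch net charge at \code{chargePH}.
#' @slot chargePH pH at which netCharge was evaluated.
#' @slot aaComposition named numeric, residue fractions (sums to 1).
#' @slot atomicComposition named numeric, element counts (C,H,N,O,S).
#'
#' @seealso [physchemReport()]
#' @export
setClass("PhyschemReport",
  representation(
    accession = "character",
    length = "integer",
    mw = "numeric",
    pI = "numeric",
    instability = "numeric",
    aliphatic = "numeric",
    gravy = "numeric",
    avgResidueWeight = "numeric",
    netCharge = "numeric",
    chargePH = "numeric",
    aaComposition = "numeric",
    atomicComposition = "numeric"
  )
)

setValidity("PhyschemReport", function(object) {
  msg <- character(0)
  if (object@mw <= 0) msg <- c(msg, "mw must be positive")
  if (object@gravy < -4.5 || object@gravy > 4.5)
    msg <- c(msg, "GRAVY must lie in [-4.5, 4.5]")
  if (object@aliphatic < 0) msg <- c(msg, "aliphatic index must be >= 0")
  if (length(object@aaComposition) &&
      abs(sum(object@aaComposition) - 1) > 1e-9)
    msg <- c(msg, "amino-acid composition must sum to 1")
  if (length(msg)) msg else TRUE
})

#' GeneModel: exon/CDS structure of one gene
#'
#' Exons and CDS segments are stored in genomic (ascending) coordinate order as
#' [IRanges::IRanges]; transcription order is derived from the strand when
#' intron phases are computed.
#'
#' @slot geneId gene identifier.
#' @slot chromosome chromosome/sequence name.
#' @slot strand "+" or "-".
#' @slot exons exon intervals (1-based inclusive, genomic order).
#' @slot cds CDS intervals (1-based inclusive, genomic order).
#'
#' @seealso [readGeneModels()], [intronPhases()]
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    chromosome = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  for (nm in c("exons", "cds")) {
    ir <- slot(object, nm)
    if (length(ir) > 1L) {
      s <- IRanges::start(ir); e <- IRanges::end(ir)
      if (is.unsorted(s))
        msg <- c(msg, sprintf("%s must be sorted by start", nm))
      else if (any(s[-1L] <= e[-length(e)]))
        msg <- c(msg, sprintf("%s intervals must not overlap", nm))
    }
  }
  if (length(object@cds) == 0L && length(object@exons) == 0L)
    msg <- c(msg, "gene model needs at least one exon or CDS segment")
  if (length(msg)) msg else TRUE
})
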