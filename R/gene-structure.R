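# Gene models from GFF3; exon counts, intron lengths and phases;
# chromosome/strand bookkeeping.

#' Read gene models from a GFF3 file
#'
#' Imports via \pkg{rtracklayer}, groups CDS (and exon) features by gene
#' through the Parent chain, and keeps the transcript with the longest total
#' CDS when a gene has several. Coordinates stay 1-based inclusive, in
#' genomic order; transcription order is derived from the strand downstream.
#'
#' @param path GFF3 file path.
#' @param genes optional character vector restricting to these gene IDs.
#' @return named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path, genes = NULL) {
  gr <- rtracklayer::import(path, format = "GFF3")
  typ <- as.character(gr$type)
  idOf <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  ids <- idOf(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  # map feature -> owning gene: walk Parent chain (CDS -> mRNA -> gene)
  geneOf <- ids
  isGene <- typ == "gene"
  lookup <- stats::setNames(parents, ids)
  resolve <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !is.na(lookup[id]) && !(id %in% seen)) {
      seen <- c(seen, id)
      id <- lookup[[id]]
    }
    id
  }
  txOf <- parents  # immediate parent (transcript) of each feature

  sel <- typ %in% c("CDS", "exon")
  feats <- gr[sel]
  fTx <- txOf[sel]
  fGene <- vapply(fTx, function(p) {
    g <- resolve(p)
    if (is.na(g)) p else g
  }, character(1))

  out <- list()
  for (g in unique(fGene)) {
    if (!is.null(genes) && !(g %in% genes)) next
    sub <- feats[fGene == g]
    subTx <- fTx[fGene == g]
    chr <- unique(as.character(GenomicRanges::seqnames(sub)))
    str <- unique(as.character(GenomicRanges::strand(sub)))
    str <- setdiff(str, "*")
    if (length(chr) != 1L)
      stop(sprintf("gene %s spans multiple chromosomes", g))
    if (length(str) != 1L)
      stop(sprintf("gene %s has inconsistent strand", g))
    isCds <- as.character(sub$type) == "CDS"
    if (!any(isCds))
      stop(sprintf("gene %s has no CDS features", g))
    # pick the transcript with the longest total CDS
    cdsBy <- split(sub[isCds], subTx[isCds])
    lens <- vapply(cdsBy, function(x) sum(GenomicRanges::width(x)), numeric(1))
    best <- names(cdsBy)[which.max(lens)]
    keep <- is.na(subTx) | subTx == best
    sub <- sub[keep]
    isCds <- as.character(sub$type) == "CDS"
    mk <- function(x) {
      if (!length(x)) return(IRanges::IRanges())
      ir <- IRanges::IRanges(GenomicRanges::start(x), GenomicRanges::end(x))
      ir <- IRanges::reduce(ir)  # merge book-ended duplicates defensively
      ir[order(IRanges::start(ir))]
    }
    cds <- mk(sub[isCds])
    ex <- mk(sub[!isCds])
    if (!length(ex)) ex <- cds
    out[[g]] <- new("GeneModel", geneId = g, chromosome = chr, strand = str,
                    exons = ex, cds = cds)
  }
  out
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s%s): %d exon(s), %d CDS segment(s)\n",
              object@geneId, object@chromosome, object@strand,
              length(object@exons), length(object@cds)))
})

#' @describeIn readGeneModels accessor for the gene identifier.
#' @param model a [GeneModel-class].
#' @export
geneId <- function(model) model@geneId

#' Intron lengths and phases of a gene model
#'
#' Introns are the gaps between consecutive exons in transcription order. The
#' phase of a coding intron is the cumulative CDS length transcriptionally
#' upstream of it, mod 3: phase 0 falls between complete codons, phase 1
#' after the first nucleotide of a codon, phase 2 between the second and
#' third. Introns outside the CDS (UTR introns) get phase \code{"-"}.
#'
#' @param model a [GeneModel-class] with CDS present.
#' @return data.frame: \code{gene_id}, \code{index} (1-based, transcription
#'   order), \code{length} (bp), \code{phase} (\code{"0"}, \code{"1"},
#'   \code{"2"} or \code{"-"}).
#' @export
intronPhases <- function(model) {
  stopifnot(is(model, "GeneModel"))
  if (!length(model@cds)) stop("gene model has no CDS")
  ex <- model@exons
  if (!length(ex)) ex <- model@cds
  cdsLen <- sum(IRanges::width(model@cds))
  if (cdsLen %% 3L != 0L)
    warning(sprintf("gene %s: total CDS length %d not divisible by 3",
                    model@geneId, cdsLen))
  minus <- model@strand == "-"
  ord <- if (minus) rev(seq_along(ex)) else seq_along(ex)
  ex <- ex[ord]
  n <- length(ex)
  if (n < 2L)
    return(data.frame(gene_id = character(0), index = integer(0),
                      length = integer(0), phase = character(0),
                      stringsAsFactors = FALSE))
  s <- IRanges::start(ex); e <- IRanges::end(ex)
  res <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    # genomic interval of the intron between transcribed exon i and i+1
    if (minus) {
      iStart <- e[i + 1L] + 1L; iEnd <- s[i] - 1L
    } else {
      iStart <- e[i] + 1L; iEnd <- s[i + 1L] - 1L
    }
    ilen <- iEnd - iStart + 1L
    # CDS bases transcriptionally upstream of the intron
    up <- 0L
    inCds <- FALSE
    for (j in seq_along(model@cds)) {
      cs <- IRanges::start(model@cds)[j]; ce <- IRanges::end(model@cds)[j]
      if (minus) {
        ov <- max(0L, ce - max(cs, iEnd + 1L) + 1L)
      } else {
        ov <- max(0L, min(ce, iStart - 1L) - cs + 1L)
      }
      up <- up + ov
    }
    inCds <- up > 0L && up < cdsLen
    res[[i]] <- data.frame(gene_id = model@geneId, index = i,
                           length = ilen,
                           phase = if (inCds) as.character(up %% 3L) else "-",
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Exon-count and intron-phase summary over a gene family
#'
#' @param models list of [GeneModel-class] objects.
#' @return list with \code{exonCounts} (named integer, exons per gene),
#'   \code{phaseHistogram} (counts over phases "0","1","2","-") and
#'   \code{introns} (the concatenated per-intron table).
#' @export
familyStructureSummary <- function(models) {
  lv <- c("0", "1", "2", "-")
  if (!length(models))
    return(list(exonCounts = stats::setNames(integer(0), character(0)),
                phaseHistogram = stats::setNames(rep(0L, 4L), lv),
                introns = data.frame()))
  exonCounts <- vapply(models, function(m) {
    ex <- if (length(m@exons)) m@exons else m@cds
    length(ex)
  }, integer(1))
  names(exonCounts) <- vapply(models, geneId, character(1))
  introns <- do.call(rbind, lapply(models, intronPhases))
  hist <- table(factor(introns$phase, levels = lv))
  list(exonCounts = exonCounts,
       phaseHistogram = stats::setNames(as.integer(hist), lv),
       introns = introns)
}

#' Chromosome and strand distribution of family genes
#'
#' @param coords data.frame with columns \code{chromosome} and \code{strand}
#'   (\code{"+"}/\code{"-"}), e.g. from [loadTable1()]; rows without a
#'   chromosome are dropped.
#' @return list with \code{chromosomes} (named integer counts) and
#'   \code{strands} (\code{c(forward=, reverse=)}).
#' @export
chromosomeSummary <- function(coords) {
  stopifnot(is.data.frame(coords),
            all(c("chromosome", "strand") %in% names(coords)))
  keep <- !is.na(coords$chromosome) & nzchar(coords$chromosome)
  coords <- coords[keep, ]
  chr <- table(coords$chromosome)
  list(chromosomes = stats::setNames(as.integer(chr), names(chr)),
       strands = c(forward = sum(coords$strand == "+"),
                   reverse = sum(coords$strand == "-")))
}
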