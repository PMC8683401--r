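# Tandem-duplication detection from chromosomal coordinates and family
# grouping; heuristic segmental-candidate labelling.

#' Find tandemly duplicated gene pairs
#'
#' Two family genes form a tandem pair when they lie on the same chromosome,
#' share a phylogenetic group, their intergenic gap (start of the downstream
#' gene minus stop of the upstream gene; 0 for overlapping loci) is at most
#' \code{maxGap}, and at most \code{maxIntervening} other family genes lie
#' between them. Each pair is reported once, members in lexicographic order.
#'
#' @param coords data.frame with columns \code{gene} (or \code{accession}),
#'   \code{chromosome}, \code{start}, \code{stop}, \code{group}.
#' @param maxGap maximum intergenic distance in bp (default 50000).
#' @param maxIntervening maximum number of family genes allowed between the
#'   pair (default 1).
#' @return data.frame: \code{gene_a}, \code{gene_b}, \code{chromosome},
#'   \code{gap_bp}, \code{group}.
#' @export
findTandemPairs <- function(coords, maxGap = 50000, maxIntervening = 1) {
  stopifnot(is.data.frame(coords))
  if ("gene" %in% names(coords)) idcol <- "gene"
  else if ("accession" %in% names(coords)) idcol <- "accession"
  else stop("coords needs a 'gene' or 'accession' column")
  need <- c("chromosome", "start", "stop", "group")
  miss <- setdiff(need, names(coords))
  if (length(miss))
    stop("coords lacks column(s): ", paste(miss, collapse = ", "))
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      chromosome = character(0), gap_bp = numeric(0),
                      group = character(0), stringsAsFactors = FALSE)
  if (!nrow(coords)) return(empty)
  if (anyNA(coords$start) || anyNA(coords$stop))
    stop("record(s) missing coordinates: ",
         paste(coords[[idcol]][is.na(coords$start) | is.na(coords$stop)],
               collapse = ", "))

  out <- list()
  for (chr in unique(coords$chromosome)) {
    onChr <- coords[coords$chromosome == chr, ]
    onChr <- onChr[order(onChr$start), ]
    n <- nrow(onChr)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (is.na(onChr$group[i]) || is.na(onChr$group[j]) ||
          onChr$group[i] != onChr$group[j]) next
      gap <- max(0, onChr$start[j] - onChr$stop[i])
      if (gap > maxGap) next
      intervening <- j - i - 1L  # family genes strictly between, any group
      if (intervening > maxIntervening) next
      pair <- sort(c(onChr[[idcol]][i], onChr[[idcol]][j]))
      out[[length(out) + 1L]] <- data.frame(
        gene_a = pair[1], gene_b = pair[2], chromosome = chr,
        gap_bp = gap, group = onChr$group[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Label genes by duplication class
#'
#' Genes in a tandem pair are \code{"tandem"}; genes that share a group with
#' at least one family gene on a different chromosome are
#' \code{"candidate-segmental"} (an explicitly heuristic call -- confirming
#' segmental duplication needs collinearity analysis, which is out of scope);
#' the rest are \code{"singleton"}.
#'
#' @param coords as in [findTandemPairs()].
#' @param pairs output of [findTandemPairs()]; computed with defaults when
#'   omitted.
#' @return data.frame: \code{gene}, \code{label}.
#' @export
labelDuplicationClasses <- function(coords, pairs = findTandemPairs(coords)) {
  if (!nrow(coords))
    return(data.frame(gene = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  idcol <- if ("gene" %in% names(coords)) "gene" else "accession"
  genes <- coords[[idcol]]
  tandem <- unique(c(pairs$gene_a, pairs$gene_b))
  label <- vapply(seq_len(nrow(coords)), function(i) {
    if (genes[i] %in% tandem) return("tandem")
    g <- coords$group[i]
    if (!is.na(g)) {
      others <- coords$group == g & genes != genes[i] &
        coords$chromosome != coords$chromosome[i]
      if (any(others, na.rm = TRUE)) return("candidate-segmental")
    }
    "singleton"
  }, character(1))
  data.frame(gene = genes, label = label, stringsAsFactors = FALSE)
}
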