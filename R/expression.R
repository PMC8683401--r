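# FPKM expression handling: expressed-gene calling, log2 fold change versus
# paired controls, and up/down classification.

.checkMatrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  if (is.null(rownames(mat))) stop("matrix needs gene rownames")
  if (is.null(colnames(mat))) stop("matrix needs condition colnames")
  invisible(mat)
}

#' Expressed genes per condition
#'
#' A gene counts as expressed in a condition when its FPKM is strictly above
#' \code{minFpkm} (default 1).
#'
#' @param mat numeric matrix, genes x conditions (FPKM), with dimnames.
#' @param minFpkm expression threshold (strict).
#' @return named list of character vectors, one per condition.
#' @export
expressedGenes <- function(mat, minFpkm = 1) {
  .checkMatrix(mat)
  lapply(stats::setNames(seq_len(ncol(mat)), colnames(mat)),
         function(j) rownames(mat)[mat[, j] > minFpkm])
}

#' Log2 fold change and up/down classification
#'
#' For each treatment/control column pair, computes
#' \code{fc = log2((t + pseudo) / (c + pseudo))} per gene and classifies:
#' \code{up} when fc > 0, \code{down} when fc < 0, \code{unchanged} when
#' fc = 0, and \code{not-expressed} when neither treatment nor control
#' exceeds \code{minFpkm}. A zero fold change is "unchanged", never both up
#' and down. Both the log2 and the linear ratio are reported.
#'
#' @param mat numeric FPKM matrix (genes x conditions, with dimnames).
#' @param pairing data.frame with columns \code{treatment} and \code{control}
#'   naming matrix columns, or a named character vector
#'   (\code{c(treatmentCol = controlCol)}).
#' @param pseudo pseudo-count added before the ratio (default 1).
#' @param minFpkm expression filter for the \code{not-expressed} call
#'   (strict; default 1).
#' @return data.frame: \code{gene}, \code{condition} (treatment column),
#'   \code{fpkm_treatment}, \code{fpkm_control}, \code{log2fc},
#'   \code{linear_fc}, \code{call}.
#' @export
foldChange <- function(mat, pairing, pseudo = 1.0, minFpkm = 1) {
  .checkMatrix(mat)
  if (is.character(pairing))
    pairing <- data.frame(treatment = names(pairing), control = unname(pairing),
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(pairing),
            all(c("treatment", "control") %in% names(pairing)))
  missing <- setdiff(c(pairing$treatment, pairing$control), colnames(mat))
  if (length(missing))
    stop("pairing references unknown column(s): ",
         paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairing)), function(k) {
    tcol <- pairing$treatment[k]; ccol <- pairing$control[k]
    t <- mat[, tcol]; c <- mat[, ccol]
    fc <- log2((t + pseudo) / (c + pseudo))
    call <- ifelse(pmax(t, c) <= minFpkm, "not-expressed",
                   ifelse(fc > 0, "up", ifelse(fc < 0, "down", "unchanged")))
    data.frame(gene = rownames(mat), condition = tcol,
               fpkm_treatment = unname(t), fpkm_control = unname(c),
               log2fc = unname(fc),
               linear_fc = unname((t + pseudo) / (c + pseudo)),
               call = unname(call), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Up/down counts per condition
#'
#' @param calls output of [foldChange()].
#' @return data.frame with one row per condition and columns \code{up},
#'   \code{down}, \code{unchanged}, \code{not_expressed}.
#' @export
conditionSummary <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("condition", "call") %in% names(calls)))
  lv <- c("up", "down", "unchanged", "not-expressed")
  conds <- unique(calls$condition)
  rows <- lapply(conds, function(cn) {
    tab <- table(factor(calls$call[calls$condition == cn], levels = lv))
    data.frame(condition = cn, up = as.integer(tab[["up"]]),
               down = as.integer(tab[["down"]]),
               unchanged = as.integer(tab[["unchanged"]]),
               not_expressed = as.integer(tab[["not-expressed"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
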