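# Packaged family tables and seeded synthetic-data generators. Every
# generator returns a machine-readable truth object alongside its data and is
# byte-reproducible under a seed.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Load the packaged family coordinate/domain/group table
#'
#' The 29 confirmed family members (accession, chromosome, coordinates,
#' strand, domain calls, phylogenetic group, ortholog number) plus the one
#' discarded truncated accession (Bra022235: carries only the ion-transport
#' domain; its length, 221 aa, is a synthetic stand-in for "short truncated
#' sequence" -- the source prints no length for it). Protein lengths for the
#' 29 members are joined in from the packaged property table.
#'
#' @return data.frame with columns \code{gene}, \code{accession},
#'   \code{chromosome}, \code{start}, \code{stop}, \code{strand},
#'   \code{domains}, \code{secondary_domains}, \code{group},
#'   \code{at_ortholog}, \code{length}.
#' @export
loadTable1 <- function() {
  path <- system.file("extdata", "table1_candidates.tsv",
                      package = "famscreen", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  names(df)[names(df) == "primary_domains"] <- "domains"
  props <- loadTable3()
  df$length <- props$length[match(df$gene, props$gene)]
  df$length[is.na(df$length) & df$accession == "Bra022235"] <- 221L
  df
}

#' Load the packaged physicochemical property table
#'
#' The published per-protein property rows for the 29 family members: length,
#' molecular weight (kDa), pI, instability index, aliphatic index, GRAVY,
#' average residue weight, charge, predicted localization.
#'
#' @return data.frame, one row per protein.
#' @export
loadTable3 <- function() {
  path <- system.file("extdata", "table3_properties.tsv",
                      package = "famscreen", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Generate a synthetic protein family with a planted motif
#'
#' Builds \code{n} family members, each a random left flank, an instance of
#' the motif, and a random right flank. Per motif column, exactly
#' \code{floor((1 - conservation) * n)} members carry a random substituted
#' residue, so every column's conservation is at least \code{conservation}.
#' The alignment pads the variable flanks with gaps, so the motif occupies a
#' fixed, recorded column interval.
#'
#' @param n number of members (default 29, the family size this package's
#'   fixtures mirror).
#' @param motif [MotifPattern-class] or pattern string to plant; must have a
#'   fixed span (no variable-length elements). Classes/wildcards are
#'   instantiated once to a reference residue per column.
#' @param conservation minimum per-column conservation of planted residues
#'   (default 0.95).
#' @param flankRange integer(2), inclusive range of flank lengths (default
#'   \code{c(20, 60)}).
#' @param seed RNG seed; same seed, same output.
#' @return list: \code{sequences} ([Biostrings::AAStringSet], unaligned),
#'   \code{msa} (\code{AAStringSet}, gap-padded alignment), \code{truth}
#'   (list with \code{region} = motif column interval in the alignment,
#'   \code{consensus} = planted reference residues, \code{conservation},
#'   \code{seed}).
#' @export
generateFamily <- function(n = 29, motif = "L-W-C-N-G-C-P-S", conservation = 0.95,
                           flankRange = c(20, 60), seed = 1L) {
  if (is.character(motif)) motif <- parsePattern(motif)
  stopifnot(is(motif, "MotifPattern"))
  if (minSpan(motif) != maxSpan(motif))
    stop("generateFamily needs a fixed-span motif (no variable-length elements)")
  if (conservation <= 0 || conservation > 1)
    stop("conservation must lie in (0, 1]")
  if (n == 0L)
    return(list(sequences = Biostrings::AAStringSet(),
                msa = Biostrings::AAStringSet(),
                truth = list(region = integer(0), consensus = character(0),
                             conservation = conservation, seed = seed)))
  .withSeed(seed, {
    el <- motif@elements
    # instantiate one reference residue per motif column
    consensus <- unlist(lapply(seq_len(nrow(el)), function(i) {
      res <- strsplit(el$residues[i], "")[[1]]
      pick <- switch(el$kind[i],
        "fixed-residue" = res,
        "residue-class" = sample(res, 1L),
        "excluded-class" = sample(setdiff(STANDARD_AA, res), 1L),
        "wildcard" = sample(STANDARD_AA, 1L))
      rep(pick, el$min[i])
    }))
    w <- length(consensus)
    motifMat <- matrix(rep(consensus, each = n), nrow = n)
    nMut <- floor((1 - conservation) * n)
    if (nMut > 0L) for (j in seq_len(w)) {
      rows <- sample(n, nMut)
      motifMat[rows, j] <- sample(setdiff(STANDARD_AA, consensus[j]),
                                  nMut, replace = TRUE)
    }
    leftLen <- sample(flankRange[1]:flankRange[2], n, replace = TRUE)
    rightLen <- sample(flankRange[1]:flankRange[2], n, replace = TRUE)
    rnd <- function(k) paste(sample(STANDARD_AA, k, replace = TRUE),
                             collapse = "")
    left <- vapply(leftLen, rnd, character(1))
    right <- vapply(rightLen, rnd, character(1))
    motifStr <- apply(motifMat, 1L, paste, collapse = "")
    seqs <- paste0(left, motifStr, right)
    maxL <- max(leftLen); maxR <- max(rightLen)
    pad <- function(k) strrep("-", k)
    msa <- paste0(vapply(maxL - leftLen, pad, character(1)), left,
                  motifStr,
                  right, vapply(maxR - rightLen, pad, character(1)))
    ids <- sprintf("synth%02d", seq_len(n))
    sequences <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    alignment <- Biostrings::AAStringSet(stats::setNames(msa, ids))
    list(sequences = sequences, msa = alignment,
         truth = list(region = c(maxL + 1L, maxL + w),
                      consensus = consensus,
                      conservation = conservation, seed = seed))
  })
}

#' Generate a synthetic GFF3 gene set with planted intron phases
#'
#' Plants the desired phase of every intron first, then constructs CDS exon
#' lengths realizing them (\code{len_i mod 3 = (phase_{i+1} - phase_i) mod
#' 3}; the last exon tops the total up to a multiple of 3), so the recorded
#' truth is an oracle by construction for [intronPhases()]. Genes are placed
#' on random chromosomes and strands.
#'
#' @param nGenes number of genes.
#' @param exonRange integer(2), inclusive range of exon counts per gene.
#' @param intronRange integer(2), inclusive range of intron lengths (bp).
#' @param path optional file path; when given, the models are exported as
#'   GFF3 (gene/mRNA/CDS features) via \pkg{rtracklayer}.
#' @param seed RNG seed.
#' @return list: \code{models} (named list of [GeneModel-class]),
#'   \code{truth} (data.frame \code{gene_id}, \code{index}, \code{phase}),
#'   \code{path} (the GFF3 path or NULL).
#' @export
generateGff <- function(nGenes = 10, exonRange = c(1, 11),
                        intronRange = c(80, 500), path = NULL, seed = 1L) {
  .withSeed(seed, {
    models <- list()
    truthRows <- list()
    for (g in seq_len(nGenes)) {
      gid <- sprintf("synthgene%03d", g)
      chr <- sprintf("chr%d", sample(1:5, 1L))
      strand <- sample(c("+", "-"), 1L)
      nEx <- sample(exonRange[1]:exonRange[2], 1L)
      phases <- if (nEx > 1L) sample(0:2, nEx - 1L, replace = TRUE) else integer(0)
      # exon lengths in transcription order realizing the planted phases
      lens <- integer(nEx)
      prev <- 0L
      for (i in seq_len(nEx)) {
        if (i < nEx) {
          resid <- (phases[i] - prev) %% 3L
          lens[i] <- 3L * sample(20:120, 1L) + resid
          if (lens[i] == 0L) lens[i] <- 3L
          prev <- phases[i]
        } else {
          lens[i] <- 3L * sample(20:120, 1L) + ((3L - prev) %% 3L)
        }
      }
      intronLens <- if (nEx > 1L)
        sample(intronRange[1]:intronRange[2], nEx - 1L, replace = TRUE)
      else integer(0)
      gStart <- sample(1000:500000, 1L)
      # genomic intervals: transcription order equals genomic order on '+',
      # reversed on '-'
      txStarts <- integer(nEx); txEnds <- integer(nEx)
      pos <- gStart
      for (i in seq_len(nEx)) {
        txStarts[i] <- pos
        txEnds[i] <- pos + lens[i] - 1L
        if (i < nEx) pos <- txEnds[i] + intronLens[i] + 1L
      }
      if (strand == "-") {
        span <- txEnds[nEx]
        s2 <- span - txEnds + gStart
        e2 <- span - txStarts + gStart
        txStarts <- s2; txEnds <- e2
      }
      ord <- order(txStarts)
      ir <- IRanges::IRanges(txStarts[ord], txEnds[ord])
      models[[gid]] <- new("GeneModel", geneId = gid, chromosome = chr,
                           strand = strand, exons = ir, cds = ir)
      if (nEx > 1L)
        truthRows[[gid]] <- data.frame(gene_id = gid,
                                       index = seq_len(nEx - 1L),
                                       phase = as.character(phases),
                                       stringsAsFactors = FALSE)
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows)
             else data.frame(gene_id = character(0), index = integer(0),
                             phase = character(0), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    if (!is.null(path)) .writeModelsGff3(models, path)
    list(models = models, truth = truth, path = path)
  })
}

# export gene/mRNA/CDS features through rtracklayer
.writeModelsGff3 <- function(models, path) {
  feats <- lapply(models, function(m) {
    ex <- m@exons
    n <- length(ex)
    gid <- m@geneId; tid <- paste0(gid, ".t1")
    span <- IRanges::IRanges(min(IRanges::start(ex)), max(IRanges::end(ex)))
    gr <- GenomicRanges::GRanges(
      rep(m@chromosome, 2L + n),
      c(span, span, ex),
      strand = m@strand)
    gr$type <- c("gene", "mRNA", rep("CDS", n))
    gr$ID <- c(gid, tid, paste0(tid, ".cds", seq_len(n)))
    gr$Parent <- IRanges::CharacterList(
      c(list(character(0)), list(gid), rep(list(tid), n)))
    # GFF3 CDS phase: bases to skip to reach the next codon start, walked in
    # transcription order
    lens <- IRanges::width(ex)
    ord <- if (m@strand == "-") rev(seq_len(n)) else seq_len(n)
    cum <- c(0L, cumsum(lens[ord]))[seq_len(n)]
    ph <- integer(n); ph[ord] <- (3L - cum %% 3L) %% 3L
    gr$phase <- c(NA_integer_, NA_integer_, ph)
    gr
  })
  gr <- suppressWarnings(do.call(c, unname(feats)))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Generate a synthetic FPKM matrix with planted effects
#'
#' Control FPKM is drawn log-normally (with a floor of 2 for expressed genes
#' so the expression filter never masks a planted effect); each gene is
#' assigned up / down / unchanged / not-expressed, and the treatment column
#' applies a 2^\code{effect}-fold change in the planted direction.
#'
#' @param nGenes number of genes.
#' @param nConditions number of treatment/control pairs.
#' @param effect absolute log2 effect size for up/down genes (default 2).
#' @param propUp,propDown,propSilent fractions of genes planted up, down and
#'   not-expressed (the remainder is unchanged).
#' @param seed RNG seed.
#' @return list: \code{mat} (genes x columns, controls named
#'   \code{ctrl<k>}, treatments \code{trt<k>}), \code{pairing} (data.frame
#'   treatment/control), \code{truth} (data.frame \code{gene},
#'   \code{condition}, \code{call}).
#' @export
generateExpression <- function(nGenes = 29, nConditions = 2, effect = 2,
                               propUp = 0.3, propDown = 0.2,
                               propSilent = 0.1, seed = 1L) {
  stopifnot(propUp + propDown + propSilent <= 1)
  .withSeed(seed, {
    genes <- sprintf("gene%03d", seq_len(nGenes))
    mat <- matrix(0, nrow = nGenes, ncol = 2L * nConditions,
                  dimnames = list(genes,
                    as.vector(rbind(sprintf("ctrl%d", seq_len(nConditions)),
                                    sprintf("trt%d", seq_len(nConditions))))))
    truthRows <- list()
    nUp <- round(propUp * nGenes); nDown <- round(propDown * nGenes)
    nSilent <- round(propSilent * nGenes)
    for (k in seq_len(nConditions)) {
      lab <- rep("unchanged", nGenes)
      idx <- sample(nGenes)
      lab[idx[seq_len(nUp)]] <- "up"
      lab[idx[nUp + seq_len(nDown)]] <- "down"
      if (nSilent > 0L) lab[idx[nUp + nDown + seq_len(nSilent)]] <- "not-expressed"
      ctrl <- pmax(2, stats::rlnorm(nGenes, meanlog = 2, sdlog = 1))
      trt <- ctrl
      trt[lab == "up"] <- ctrl[lab == "up"] * 2^effect
      trt[lab == "down"] <- ctrl[lab == "down"] / 2^effect
      ctrl[lab == "not-expressed"] <- stats::runif(sum(lab == "not-expressed"), 0, 0.5)
      trt[lab == "not-expressed"] <- stats::runif(sum(lab == "not-expressed"), 0, 0.5)
      mat[, sprintf("ctrl%d", k)] <- ctrl
      mat[, sprintf("trt%d", k)] <- trt
      truthRows[[k]] <- data.frame(gene = genes,
                                   condition = sprintf("trt%d", k),
                                   call = lab, stringsAsFactors = FALSE)
    }
    list(mat = mat,
         pairing = data.frame(treatment = sprintf("trt%d", seq_len(nConditions)),
                              control = sprintf("ctrl%d", seq_len(nConditions)),
                              stringsAsFactors = FALSE),
         truth = do.call(rbind, truthRows))
  })
}
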