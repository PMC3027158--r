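## CpG-island prediction in promoter windows: windowed %GC and
## observed/expected CpG following the Gardiner-Garden & Frommer criteria
## (window 200 bp, GC >= 0.5, OE >= 0.6, island >= 200 bp by default).

#' G+C fraction of a sequence window
#'
#' @param window character scalar or \link[Biostrings]{DNAString}; must be
#'   non-empty uppercase A/C/G/T (masked or ambiguous bases are an error --
#'   callers pre-screen windows).
#' @return Fraction of G and C bases.
#' @examples
#' gcFraction("ACGT") # 0.5
#' @export
gcFraction <- function(window) {
  ch <- .seqChars(window)
  if (length(ch) == 0L) stop("empty window")
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("window must contain only uppercase A/C/G/T")
  }
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Observed/expected CpG ratio of a sequence window
#'
#' Computes \code{(N_CpG * L) / (N_C * N_G)} where \code{N_CpG} counts
#' (overlapping) CG dinucleotides. Returns 0 when the window has no C or no
#' G.
#'
#' @inheritParams gcFraction
#' @return Observed/expected CpG ratio (>= 0; may exceed 1).
#' @examples
#' cpgObsExp("CGCG") # 2
#' @export
cpgObsExp <- function(window) {
  ch <- .seqChars(window)
  if (length(ch) == 0L) stop("empty window")
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("window must contain only uppercase A/C/G/T")
  }
  nC <- sum(ch == "C")
  nG <- sum(ch == "G")
  if (nC == 0L || nG == 0L) return(0)
  L <- length(ch)
  nCG <- sum(ch[-L] == "C" & ch[-1L] == "G")
  nCG * L / (nC * nG)
}

#' Call CpG islands on one sequence
#'
#' A window of \code{windowLen} bases starting at position \code{i}
#' qualifies iff it contains no soft-masked (lowercase) or N base, its G+C
#' fraction is at least \code{gcMin} and its observed/expected CpG ratio at
#' least \code{oeMin}. A position is covered iff at least one qualifying
#' window overlaps it; islands are maximal runs of covered positions. Each
#' island's GC and OE are then recomputed over its full span, and islands
#' failing either threshold -- or shorter than \code{minIslandLen} -- are
#' dropped. Rolling counts make the scan linear in sequence length.
#'
#' @param sequence character scalar or \link[Biostrings]{DNAString}; may
#'   contain lowercase (masked) and N bases.
#' @param params A \code{\link{CgiParams}} object.
#' @return data.frame with 0-based half-open \code{start}, \code{end}, plus
#'   \code{length}, \code{gc} and \code{oe} recomputed over the island span.
#'   Sequences shorter than the window yield zero rows.
#' @export
findCgis <- function(sequence, params = CgiParams()) {
  empty <- data.frame(
    start = integer(), end = integer(), length = integer(),
    gc = numeric(), oe = numeric()
  )
  ch <- .seqChars(sequence)
  n <- length(ch)
  W <- params@windowLen
  if (n < W) return(empty)

  masked <- .isMaskedChar(ch)
  isC <- ch == "C"
  isG <- ch == "G"
  isCG <- isC & c(ch[-1L] == "G", FALSE) # CG dinucleotide starting here

  cumM <- c(0L, cumsum(masked))
  cumC <- c(0L, cumsum(isC))
  cumG <- c(0L, cumsum(isG))
  cumCG <- c(0L, cumsum(isCG))

  starts <- seq_len(n - W + 1L) # 1-based window starts
  nM <- cumM[starts + W] - cumM[starts]
  nC <- cumC[starts + W] - cumC[starts]
  nG <- cumG[starts + W] - cumG[starts]
  # dinucleotides fully inside the window: starts i .. i+W-2
  nCG <- cumCG[starts + W - 1L] - cumCG[starts]

  gc <- (nC + nG) / W
  oe <- ifelse(nC > 0L & nG > 0L, nCG * W / (nC * nG), 0)
  ok <- nM == 0L & gc >= params@gcMin & oe >= params@oeMin
  if (!any(ok)) return(empty)

  covered <- IRanges::reduce(IRanges::IRanges(start = which(ok), width = W))
  res <- lapply(seq_along(covered), function(i) {
    s <- IRanges::start(covered)[i]
    e <- IRanges::end(covered)[i]
    len <- e - s + 1L
    nc <- cumC[e + 1L] - cumC[s]
    ng <- cumG[e + 1L] - cumG[s]
    ncg <- cumCG[e] - cumCG[s] # dinucleotide starts s .. e-1
    g <- (nc + ng) / len
    o <- if (nc > 0L && ng > 0L) ncg * len / (nc * ng) else 0
    if (len < params@minIslandLen || g < params@gcMin || o < params@oeMin) {
      return(NULL)
    }
    data.frame(start = s - 1L, end = e, length = len, gc = g, oe = o)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

# Resolve the 0-based TSS of transcript ranges (GRanges, 1-based inclusive):
# 5' end on the plus strand is start-1, on the minus strand end-1.
.tss0 <- function(gr) {
  ifelse(
    as.character(GenomicRanges::strand(gr)) == "-",
    GenomicRanges::end(gr) - 1L,
    GenomicRanges::start(gr) - 1L
  )
}

#' Strand-aware promoter windows around transcript 5' ends
#'
#' For a plus-strand TSS at 0-based position t the window is
#' \code{[t - upstream, t + downstream)}; minus-strand windows are mirrored
#' so that \code{upstream} bases lie transcriptionally upstream:
#' \code{[t - downstream + 1, t + upstream + 1)}. Windows are clipped to the
#' chromosome and identical windows from multiple transcripts of one gene
#' are collapsed.
#'
#' @param annotation A \code{\link{GenomeAnnotation}} or a
#'   \link[GenomicRanges]{GRanges} of transcripts with a \code{gene_id}
#'   metadata column and seqlengths set.
#' @param params A \code{\link{CgiParams}} (only \code{upstream} /
#'   \code{downstream} are used).
#' @return \code{GRanges} of promoter windows (1-based inclusive, as usual
#'   for \code{GRanges}) with a \code{gene_id} column.
#' @export
promoterWindows <- function(annotation, params = CgiParams()) {
  if (is(annotation, "GenomeAnnotation")) {
    genes <- geneRanges(annotation)
    chrlen <- stats::setNames(
      Biostrings::width(genomeSeq(annotation)), names(genomeSeq(annotation))
    )
  } else {
    genes <- annotation
    chrlen <- GenomeInfoDb::seqlengths(genes)
    if (any(is.na(chrlen))) stop("annotation must carry seqlengths")
  }
  chn <- as.character(GenomicRanges::seqnames(genes))
  if (!all(chn %in% names(chrlen))) {
    stop(
      "transcript(s) on unknown chromosome: ",
      paste(unique(setdiff(chn, names(chrlen))), collapse = ", ")
    )
  }
  t0 <- .tss0(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  s0 <- ifelse(minus, t0 - params@downstream + 1L, t0 - params@upstream)
  e0 <- ifelse(minus, t0 + params@upstream + 1L, t0 + params@downstream)
  s0 <- pmax(s0, 0L)
  e0 <- pmin(e0, chrlen[chn])
  win <- GenomicRanges::GRanges(
    seqnames = chn,
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = GenomicRanges::strand(genes),
    gene_id = genes$gene_id,
    seqlengths = chrlen
  )
  key <- paste(chn, s0, e0, genes$gene_id)
  win[!duplicated(key)]
}

#' Predict CpG islands inside each gene's promoter window
#'
#' Calls \code{\link{findCgis}} on the sub-sequence of every promoter
#' window and reports islands in genomic coordinates. An island overlapping
#' the windows of two genes is listed under both.
#'
#' @inheritParams promoterWindows
#' @param params A \code{\link{CgiParams}}.
#' @return \code{GRanges} of islands (possibly repeated across genes) with
#'   metadata columns \code{gene_id}, \code{island_id}, \code{gc},
#'   \code{oe}. Use \code{split(x, x$gene_id)} for the per-gene view; genes
#'   without islands are absent.
#' @export
promoterCgis <- function(annotation, params = CgiParams()) {
  stopifnot(is(annotation, "GenomeAnnotation"))
  win <- promoterWindows(annotation, params)
  genome <- genomeSeq(annotation)
  out <- list()
  for (i in seq_along(win)) {
    chrom <- as.character(GenomicRanges::seqnames(win))[i]
    ws <- GenomicRanges::start(win)[i]
    we <- GenomicRanges::end(win)[i]
    sub <- Biostrings::subseq(genome[[chrom]], start = ws, end = we)
    isl <- findCgis(sub, params)
    if (nrow(isl) == 0L) next
    out[[length(out) + 1L]] <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(
        start = isl$start + ws, # isl$start 0-based within window
        end = isl$end + ws - 1L
      ),
      gene_id = win$gene_id[i], gc = isl$gc, oe = isl$oe
    )
  }
  if (!length(out)) {
    g <- GenomicRanges::GRanges()
    mcols(g) <- DataFrame(
      gene_id = character(), island_id = character(),
      gc = numeric(), oe = numeric()
    )
    return(g)
  }
  g <- unname(do.call(c, out))
  key <- paste(
    GenomicRanges::seqnames(g), GenomicRanges::start(g),
    GenomicRanges::end(g), g$gene_id
  )
  g <- g[!duplicated(key)]
  ord <- order(
    g$gene_id, as.character(GenomicRanges::seqnames(g)),
    GenomicRanges::start(g)
  )
  g <- g[ord]
  idx <- stats::ave(seq_along(g), g$gene_id, FUN = seq_along)
  g$island_id <- sprintf("%s:%d", g$gene_id, idx)
  g[, c("gene_id", "island_id", "gc", "oe")]
}

#' Convert island coordinates between conventions
#'
#' Internally islands are 0-based half-open; published tables are 1-based
#' inclusive (so half-open \code{[33649013, 33649398)} is printed as
#' \code{33649014 - 33649398}).
#'
#' @param start,end island coordinates.
#' @return A two-column data.frame in the other convention.
#' @export
islandToOneBased <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname islandToOneBased
#' @export
islandToZeroBased <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' Write predicted islands as BED6 and a statistics TSV
#'
#' The BED name is the island id and the score is \code{round(1000 * oe)}
#' capped at 1000.
#'
#' @param islands \code{GRanges} from \code{\link{promoterCgis}}.
#' @param bedPath,tsvPath output paths (either may be NULL to skip).
#' @return Invisibly, the written island table.
#' @export
writeIslands <- function(islands, bedPath = NULL, tsvPath = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(islands)),
    start = GenomicRanges::start(islands) - 1L, # BED half-open
    end = GenomicRanges::end(islands),
    name = islands$island_id,
    score = pmin(1000L, as.integer(round(1000 * islands$oe))),
    strand = ".",
    gene_id = islands$gene_id,
    gc = islands$gc,
    oe = islands$oe
  )
  if (!is.null(bedPath)) {
    utils::write.table(df[, 1:6], bedPath,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  if (!is.null(tsvPath)) {
    utils::write.table(df, tsvPath,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(df)
}
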