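## 60-mer probe tiling across predicted CGIs at 25-bp spacing with full
## coverage, genome-uniqueness filtering by exact 55-mer occurrence counts
## on both strands, and array-manifest accounting.

# Pull an uppercase probe sequence; NULL when it runs over the chromosome
# or touches masked/ambiguous bases.
.probeSeq <- function(genome, chrom, start0, len, requireClean = TRUE) {
  chromSeq <- genome[[chrom]]
  if (is.null(chromSeq)) stop("unknown chromosome: ", chrom)
  if (start0 < 0L || start0 + len > length(chromSeq)) return(NULL)
  s <- as.character(Biostrings::subseq(chromSeq, start0 + 1L, start0 + len))
  if (requireClean && any(.isMaskedChar(.seqChars(s)))) return(NULL)
  toupper(s)
}

#' Tile probes across one CpG island
#'
#' Probes of \code{probeLen} bases start at the island start and every
#' \code{step} bases thereafter while they fit; if the last stepped probe
#' stops short of the island end, one additional probe is right-anchored at
#' \code{end - probeLen} so the island is covered end to end. Islands
#' shorter than a probe get a single probe centered on the island and
#' extended into unmasked flank sequence when available; otherwise the
#' island is skipped with a reason.
#'
#' @param island one-row data.frame or list with \code{chrom},
#'   0-based half-open \code{start}, \code{end}, and optionally
#'   \code{island_id} and \code{gene_id}.
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param params A \code{\link{ProbeParams}}.
#' @return list with \code{probes} (a \link[GenomicRanges]{GRanges} with
#'   \code{probe_id}, \code{sequence}, \code{island_id}, \code{gene_ids})
#'   and \code{skipped} (data.frame \code{island_id}, \code{reason}).
#' @export
tileProbes <- function(island, genome, params = ProbeParams()) {
  chrom <- as.character(island$chrom)
  s0 <- as.integer(island$start)
  e0 <- as.integer(island$end)
  iid <- if (!is.null(island$island_id)) as.character(island$island_id) else {
    sprintf("%s:%d-%d", chrom, s0, e0)
  }
  gid <- if (!is.null(island$gene_id)) as.character(island$gene_id) else ""
  L <- params@probeLen
  skipped <- data.frame(island_id = character(), reason = character())
  chromSeq <- genome[[chrom]]
  if (is.null(chromSeq)) stop("unknown chromosome: ", chrom)
  if (s0 < 0L || e0 > length(chromSeq) || e0 <= s0) {
    stop("island coordinates invalid on genome")
  }

  if (e0 - s0 >= L) {
    starts <- seq.int(s0, e0 - L, by = params@step)
    if (starts[length(starts)] + L < e0) starts <- c(starts, e0 - L)
  } else {
    # sub-probe-length island: center and extend into flanks where possible
    mid <- (s0 + e0) %/% 2L
    st <- mid - L %/% 2L
    st <- max(0L, min(st, length(chromSeq) - L))
    if (st + L > length(chromSeq) || st < 0L) {
      return(list(
        probes = .emptyProbes(),
        skipped = data.frame(island_id = iid, reason = "insufficient flank")
      ))
    }
    if (is.null(.probeSeq(genome, chrom, st, L))) {
      return(list(
        probes = .emptyProbes(),
        skipped = data.frame(island_id = iid, reason = "masked flank")
      ))
    }
    starts <- st
  }
  seqs <- vapply(
    starts,
    function(st) {
      s <- .probeSeq(genome, chrom, st, L, requireClean = FALSE)
      if (is.null(s)) NA_character_ else s
    },
    character(1)
  )
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts + 1L, width = L),
    probe_id = sprintf("%s_p%02d", iid, seq_along(starts)),
    sequence = seqs,
    island_id = iid,
    gene_ids = gid
  )
  list(probes = gr, skipped = skipped)
}

.emptyProbes <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- DataFrame(
    probe_id = character(), sequence = character(),
    island_id = character(), gene_ids = character()
  )
  gr
}

#' Tile probes across a set of islands
#'
#' @param islands \code{GRanges} (e.g. from \code{\link{promoterCgis}}) or
#'   data.frame with 0-based half-open coordinates.
#' @inheritParams tileProbes
#' @return As \code{\link{tileProbes}}, concatenated. Islands shared by
#'   several genes yield one probe set with their gene ids joined by commas.
#' @export
tileAllProbes <- function(islands, genome, params = ProbeParams()) {
  if (is(islands, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(islands)),
      start = GenomicRanges::start(islands) - 1L,
      end = GenomicRanges::end(islands),
      island_id = if (!is.null(islands$island_id)) islands$island_id else NA,
      gene_id = if (!is.null(islands$gene_id)) islands$gene_id else ""
    )
  } else {
    df <- as.data.frame(islands)
  }
  # one physical island may be listed under several genes
  key <- paste(df$chrom, df$start, df$end)
  geneMap <- tapply(df$gene_id, key, function(g) {
    paste(sort(unique(g[nzchar(g)])), collapse = ",")
  })
  df <- df[!duplicated(key), , drop = FALSE]
  df$gene_id <- as.character(geneMap[paste(df$chrom, df$start, df$end)])
  out <- lapply(seq_len(nrow(df)), function(i) {
    tileProbes(df[i, ], genome, params)
  })
  probes <- do.call(c, c(lapply(out, `[[`, "probes"), list(.emptyProbes())))
  skipped <- do.call(rbind, lapply(out, `[[`, "skipped"))
  list(probes = unname(probes), skipped = skipped)
}

# Count exact occurrences of each k-mer in the genome, both strands,
# uppercase, using Biostrings dictionary matching.
.kmerGenomeCounts <- function(kmers, genome) {
  up <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  uniq <- unique(kmers)
  dict <- Biostrings::DNAStringSet(uniq)
  rc <- as.character(Biostrings::reverseComplement(dict))
  pd <- Biostrings::PDict(dict)
  pdRc <- Biostrings::PDict(Biostrings::DNAStringSet(rc))
  fwd <- rowSums(as.matrix(Biostrings::vcountPDict(pd, up)))
  rcc <- rowSums(as.matrix(Biostrings::vcountPDict(pdRc, up)))
  # a k-mer equal to its own reverse complement names one duplex location
  tot <- fwd + ifelse(rc == uniq, 0L, rcc)
  stats::setNames(tot, uniq)[kmers]
}

#' Remove probes that are not genome-unique at k-mer resolution
#'
#' A probe is removed iff any of its \code{probeLen - uniqLen + 1}
#' substrings of \code{uniqLen} bases occurs at more than one genomic
#' location, counting both strands (a hit of the reverse complement counts)
#' and counting the probe's own locus once. Uniqueness is established by
#' exact occurrence counting over the genome rather than alignment.
#'
#' @param probeSet \code{GRanges} of probes (see \code{\link{tileProbes}}).
#' @param genome A \link[Biostrings]{DNAStringSet}.
#' @param params A \code{\link{ProbeParams}}.
#' @return list with \code{kept} and \code{removed} \code{GRanges}; removed
#'   probes carry a \code{reason} column naming the offending k-mer.
#' @export
specificityFilter <- function(probeSet, genome, params = ProbeParams()) {
  if (!length(probeSet)) {
    return(list(kept = probeSet, removed = probeSet))
  }
  K <- params@uniqLen
  L <- params@probeLen
  nsub <- L - K + 1L
  seqs <- probeSet$sequence
  stopifnot(!anyNA(seqs), all(nchar(seqs) == L))
  kmers <- unlist(lapply(seqs, function(s) {
    substring(s, seq_len(nsub), seq_len(nsub) + K - 1L)
  }), use.names = FALSE)
  counts <- .kmerGenomeCounts(kmers, genome)
  cmat <- matrix(counts, nrow = nsub)
  hitmat <- matrix(kmers, nrow = nsub)
  bad <- apply(cmat, 2L, function(x) any(x > 1L))
  removed <- probeSet[bad]
  if (length(removed)) {
    reason <- vapply(which(bad), function(j) {
      k <- hitmat[which(cmat[, j] > 1L)[1L], j]
      sprintf("non-unique %d-mer %s", K, k)
    }, character(1))
    removed$reason <- reason
  } else {
    removed$reason <- character(0)
  }
  list(kept = probeSet[!bad], removed = removed)
}

#' Assemble an array design with feature accounting
#'
#' @param keptProbes \code{GRanges} of probes passing the specificity
#'   filter; probe ids must be unique.
#' @param params A \code{\link{ProbeParams}} carrying the control and blank
#'   feature counts, or the counts directly via \code{nControlFeatures} /
#'   \code{nBlankFeatures}.
#' @param nControlFeatures,nBlankFeatures overrides of the counts in
#'   \code{params}.
#' @return An \code{\link{ArrayDesign}}; its \code{\link{totalFeatures}} is
#'   \code{length(probes) + controls + blanks}.
#' @examples
#' # the 4x44k layout: 43,960 probes + 1,227 controls + 33 blanks = 45,220
#' @export
buildDesign <- function(keptProbes, params = ProbeParams(),
                        nControlFeatures = params@nControlFeatures,
                        nBlankFeatures = params@nBlankFeatures) {
  new("ArrayDesign",
    probes = keptProbes,
    nControlFeatures = .asCount(nControlFeatures, "nControlFeatures"),
    nBlankFeatures = .asCount(nBlankFeatures, "nBlankFeatures")
  )
}

#' Write / read an array-design manifest
#'
#' Tab-separated probe table (\code{probe_id, chrom, start, end, strand,
#' sequence, island_id, gene_ids, status}) preceded by comment lines with
#' the feature accounting. \code{readDesignManifest} round-trips a written
#' design exactly.
#'
#' @param design An \code{\link{ArrayDesign}}.
#' @param path file path.
#' @return \code{writeDesignManifest}: invisibly, \code{path};
#'   \code{readDesignManifest}: an \code{ArrayDesign}.
#' @export
writeDesignManifest <- function(design, path) {
  pr <- probes(design)
  df <- data.frame(
    probe_id = pr$probe_id,
    chrom = as.character(GenomicRanges::seqnames(pr)),
    start = GenomicRanges::start(pr) - 1L, # manifest is 0-based half-open
    end = GenomicRanges::end(pr),
    strand = "+",
    sequence = pr$sequence,
    island_id = pr$island_id,
    gene_ids = pr$gene_ids,
    status = "kept"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_probes=%d", length(pr)),
    sprintf("# n_control_features=%d", nControlFeatures(design)),
    sprintf("# n_blank_features=%d", nBlankFeatures(design)),
    sprintf("# total_features=%d", totalFeatures(design)),
    paste(colnames(df), collapse = "\t")
  ), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname writeDesignManifest
#' @export
readDesignManifest <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  counts <- stats::setNames(as.integer(kv[, 2L]), kv[, 1L])
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, comment.char = "#",
    colClasses = c(
      "character", "character", "integer", "integer",
      "character", "character", "character", "character", "character"
    )
  )
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    probe_id = df$probe_id, sequence = df$sequence,
    island_id = df$island_id, gene_ids = df$gene_ids
  )
  buildDesign(gr,
    nControlFeatures = counts[["n_control_features"]],
    nBlankFeatures = counts[["n_blank_features"]]
  )
}
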