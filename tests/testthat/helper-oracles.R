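# Independent brute-force oracles and small simulators used across tests.
# These deliberately re-derive results from first principles, without using
# the package's internal scanning machinery.

# Per-window brute-force CGI caller: tests every window independently,
# marks covered positions, extracts maximal runs, recomputes span stats.
oracleCgis <- function(s, params = CgiParams()) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  W <- params@windowLen
  stats <- function(w) {
    nC <- sum(w == "C")
    nG <- sum(w == "G")
    L <- length(w)
    ncg <- if (L > 1L) sum(w[-L] == "C" & w[-1L] == "G") else 0L
    c(
      gc = (nC + nG) / L,
      oe = if (nC > 0L && nG > 0L) ncg * L / (nC * nG) else 0
    )
  }
  covered <- logical(n)
  if (n >= W) {
    for (i in seq_len(n - W + 1L)) {
      w <- ch[i:(i + W - 1L)]
      if (any(w %in% c("a", "c", "g", "t", "n", "N"))) next
      st <- stats(w)
      if (st[["gc"]] >= params@gcMin && st[["oe"]] >= params@oeMin) {
        covered[i:(i + W - 1L)] <- TRUE
      }
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (j in which(r$values)) {
    w <- ch[starts[j]:ends[j]]
    st <- stats(w)
    len <- length(w)
    if (len < params@minIslandLen || st[["gc"]] < params@gcMin ||
      st[["oe"]] < params@oeMin) {
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts[j] - 1L, end = ends[j], length = len,
      gc = st[["gc"]], oe = st[["oe"]]
    )
  }
  if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      start = integer(), end = integer(), length = integer(),
      gc = numeric(), oe = numeric()
    )
  }
}

# Random test sequence: CpG-poor background with optional planted CG-rich
# tracts and masked (lowercase) tracts. Independent of the package's Markov
# generator.
randomTestSeq <- function(len, nIslands = 1, islandLen = 300, nMasked = 1,
                          maskedLen = 150) {
  bg <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
    prob = c(0.32, 0.18, 0.18, 0.32))
  # crude CpG depletion: break CG dinucleotides
  cg <- which(bg[-len] == "C" & bg[-1L] == "G")
  if (length(cg)) bg[cg + 1L][stats::runif(length(cg)) < 0.8] <- "A"
  placeTract <- function(bg, tract) {
    start <- sample.int(len - length(tract), 1L)
    bg[start:(start + length(tract) - 1L)] <- tract
    bg
  }
  for (i in seq_len(nIslands)) {
    unit <- c("C", "G", sample(c("A", "C", "G", "T"), 2L, replace = TRUE,
      prob = c(0.2, 0.3, 0.3, 0.2)))
    tract <- rep(unit, length.out = islandLen)
    bg <- placeTract(bg, tract)
  }
  for (i in seq_len(nMasked)) {
    start <- sample.int(len - maskedLen, 1L)
    span <- start:(start + maskedLen - 1L)
    bg[span] <- tolower(bg[span])
  }
  paste(bg, collapse = "")
}

# Brute-force k-mer occurrence table over a genome (both strands, exact).
oracleKmerTable <- function(genome, K) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  fwd <- unlist(lapply(as.character(genome), function(s) {
    s <- toupper(s)
    n <- nchar(s)
    substring(s, seq_len(n - K + 1L), seq_len(n - K + 1L) + K - 1L)
  }), use.names = FALSE)
  tbl <- table(fwd)
  lookup <- function(kmer) {
    cnt <- tbl[kmer]
    cnt <- ifelse(is.na(cnt), 0L, cnt)
    rc <- vapply(kmer, revcomp, character(1))
    rcCnt <- tbl[rc]
    rcCnt <- ifelse(is.na(rcCnt), 0L, rcCnt)
    unname(as.integer(cnt + ifelse(rc == kmer, 0L, rcCnt)))
  }
  lookup
}

# Which probes would the brute-force scan remove?
oracleRemoved <- function(probeSeqs, genome, K) {
  lookup <- oracleKmerTable(genome, K)
  vapply(probeSeqs, function(s) {
    n <- nchar(s)
    kmers <- substring(s, seq_len(n - K + 1L), seq_len(n - K + 1L) + K - 1L)
    any(lookup(kmers) > 1L)
  }, logical(1), USE.NAMES = FALSE)
}

# Textbook Welch formulas, written independently of the package.
oracleWelch <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sa2 <- sum((a - mean(a))^2) / (na - 1)
  sb2 <- sum((b - mean(b))^2) / (nb - 1)
  t <- (mean(a) - mean(b)) / sqrt(sa2 / na + sb2 / nb)
  df <- (sa2 / na + sb2 / nb)^2 /
    ((sa2 / na)^2 / (na - 1) + (sb2 / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exhaustive hypergeometric upper tail.
oracleHyper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Shared small random study for chip tests.
smallStudy <- function(seed = 42, ...) {
  makeExampleStudy(
    nProbes = 400, nHypo = 20, nHyper = 5, nTumor = 4, nControl = 4,
    seed = seed, ...
  )
}
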