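## Synthetic substrate for the whole pipeline: genomes with CpG-depleted
## background and planted promoter CGIs, bimodal per-region methylation with
## tumor effects, two-channel array signals with control samples, bisulfite
## traces and HPLC profiles. Every generator is deterministic in its seed;
## each stage draws from its own sub-stream so stages stay decoupled.

.BASES <- c("A", "C", "G", "T")

# First-order Markov sequence with stationary base composition set by `gc`
# (split evenly between C and G, and between A and T) and the C->G
# transition damped or boosted so the CpG observed/expected ratio is ~`oe`.
.markovSeq <- function(n, gc, oe) {
  pi0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  pG <- min(oe * pi0[["G"]], 0.95)
  rest <- pi0[c("A", "C", "T")]
  fromC <- c(rest * (1 - pG) / sum(rest), G = pG)[c("A", "C", "G", "T")]
  cumBg <- cumsum(pi0)
  cumC <- cumsum(fromC)
  u <- stats::runif(n)
  out <- integer(n)
  cur <- findInterval(u[1L], cumBg) + 1L
  out[1L] <- cur
  for (i in seq_len(n - 1L) + 1L) {
    p <- if (cur == 2L) cumC else cumBg
    cur <- findInterval(u[i], p) + 1L
    out[i] <- cur
  }
  paste(.BASES[out], collapse = "")
}

# Whole-span GC / OE of an uppercase sequence without masking checks.
.spanStats <- function(s) {
  ch <- .seqChars(s)
  nC <- sum(ch == "C")
  nG <- sum(ch == "G")
  L <- length(ch)
  nCG <- sum(ch[-L] == "C" & ch[-1L] == "G")
  c(
    gc = (nC + nG) / L,
    oe = if (nC > 0 && nG > 0) nCG * L / (nC * nG) else 0
  )
}

# TRUE when every fully-interior window of `W` bases meets (gcMin, oeMin).
# Covering the island with qualifying interior windows is the planting
# guarantee that makes truth islands detectable by the windowed caller.
.windowsPass <- function(s, W, gcMin, oeMin) {
  ch <- .seqChars(s)
  n <- length(ch)
  if (n < W) return(FALSE)
  isC <- ch == "C"
  isG <- ch == "G"
  isCG <- isC & c(ch[-1L] == "G", FALSE)
  cumC <- c(0L, cumsum(isC))
  cumG <- c(0L, cumsum(isG))
  cumCG <- c(0L, cumsum(isCG))
  starts <- seq_len(n - W + 1L)
  nC <- cumC[starts + W] - cumC[starts]
  nG <- cumG[starts + W] - cumG[starts]
  nCG <- cumCG[starts + W - 1L] - cumCG[starts]
  gc <- (nC + nG) / W
  oe <- ifelse(nC > 0L & nG > 0L, nCG * W / (nC * nG), 0)
  all(gc >= gcMin & oe >= oeMin)
}

# Draw one island sequence at (gcTarget, oeTarget); when guarded, redraw
# until the realized whole-span stats reach the targets and all interior
# windows meet the detection thresholds.
.islandSeq <- function(len, gcTarget, oeTarget, config, maxTries = 200L) {
  for (i in seq_len(maxTries)) {
    s <- .markovSeq(len, gcTarget, oeTarget)
    if (!config@ensureDetectable) return(s)
    st <- .spanStats(s)
    if (st[["gc"]] >= min(gcTarget, config@detectGc) &&
      st[["oe"]] >= min(oeTarget, config@detectOe) &&
      st[["gc"]] >= config@detectGc && st[["oe"]] >= config@detectOe &&
      .windowsPass(s, config@detectWindow, config@detectGc, config@detectOe)) {
      return(s)
    }
  }
  stop(
    "could not draw a detectable island after ", maxTries, " tries; ",
    "raise islandGcRange/islandOeRange or set ensureDetectable = FALSE"
  )
}

#' Generate a synthetic genome with planted promoter CpG islands
#'
#' Background sequence is drawn from a first-order Markov model with the
#' configured G+C content and CpG depletion. Genes are packed onto the
#' chromosomes in non-overlapping promoter slots; each gene receives one
#' island (length, GC and OE drawn from the configured ranges) planted
#' uniformly within its promoter window (1.5 kb upstream to 1 kb downstream
#' of the TSS by default). A fraction of the background outside promoter
#' windows is soft-masked (lowercased) as repeats. The same config (which
#' includes the seed) always returns a byte-identical genome.
#'
#' @param config A \code{\link{GenomeConfig}}.
#' @param upstream,downstream promoter extent used for the slots (defaults
#'   match \code{\link{CgiParams}}).
#' @return A \code{\link{GenomeAnnotation}}; \code{\link{truthIslands}}
#'   holds the planted coordinates with realized GC/OE.
#' @export
makeGenome <- function(config = GenomeConfig(), upstream = 1500,
                       downstream = 1000) {
  winLen <- upstream + downstream
  slotLen <- winLen + 100L # margin between promoter windows
  perChrom <- ceiling(config@nGenes / config@nChromosomes)
  if (perChrom * slotLen + 200L > config@chromLength) {
    stop(sprintf(
      paste0(
        "cannot place %d promoter windows of %d bp (plus margins) on a ",
        "%d bp chromosome"
      ),
      perChrom, winLen, config@chromLength
    ))
  }
  .withSeed(.opSeed(config@seed, "make_genome"), {
    chromNames <- sprintf("chr%d", seq_len(config@nChromosomes))
    geneIdx <- split(
      seq_len(config@nGenes),
      rep(seq_len(config@nChromosomes), length.out = config@nGenes)
    )
    seqs <- character(config@nChromosomes)
    geneRows <- list()
    islandRows <- list()
    for (ci in seq_len(config@nChromosomes)) {
      ch <- .seqChars(.markovSeq(
        config@chromLength, config@backgroundGc, config@backgroundCpgOe
      ))
      genes <- geneIdx[[ci]]
      nPer <- length(genes)
      windows <- matrix(0L, nrow = nPer, ncol = 2L)
      if (nPer > 0L) {
        slotStarts <- 100L +
          floor((config@chromLength - 200L) / nPer) * (seq_len(nPer) - 1L)
        for (k in seq_len(nPer)) {
          gi <- genes[k]
          strand <- sample(c("+", "-"), 1L)
          w0 <- slotStarts[k] # 0-based window start
          w1 <- w0 + winLen # half-open end
          # TSS consistent with the window arithmetic of promoterWindows
          t0 <- if (strand == "+") w0 + upstream else w1 - upstream - 1L
          len <- sample(seq(config@islandLenRange[1L],
            config@islandLenRange[2L]), 1L)
          gcT <- stats::runif(1L, config@islandGcRange[1L],
            config@islandGcRange[2L])
          oeT <- stats::runif(1L, config@islandOeRange[1L],
            config@islandOeRange[2L])
          iStart <- w0 + sample.int(winLen - len + 1L, 1L) - 1L
          iseq <- .islandSeq(len, gcT, oeT, config)
          ch[(iStart + 1L):(iStart + len)] <- .seqChars(iseq)
          st <- .spanStats(iseq)
          windows[k, ] <- c(w0, w1)
          geneRows[[length(geneRows) + 1L]] <- data.frame(
            chrom = chromNames[ci], strand = strand, tss0 = t0,
            gene_id = sprintf("gene%03d", gi)
          )
          islandRows[[length(islandRows) + 1L]] <- data.frame(
            chrom = chromNames[ci], start = iStart, end = iStart + len,
            gene_id = sprintf("gene%03d", gi),
            gc = st[["gc"]], oe = st[["oe"]]
          )
        }
      }
      # soft-mask repeat tracts outside promoter windows
      if (config@repeatFraction > 0) {
        target <- config@repeatFraction * config@chromLength
        inWindow <- logical(config@chromLength)
        if (nPer > 0L) {
          for (k in seq_len(nPer)) {
            inWindow[(windows[k, 1L] + 1L):windows[k, 2L]] <- TRUE
          }
        }
        maskedTotal <- 0
        tries <- 0L
        while (maskedTotal < target && tries < 10000L) {
          tries <- tries + 1L
          tlen <- sample(200:1000, 1L)
          tstart <- sample.int(config@chromLength - tlen, 1L)
          span <- tstart:(tstart + tlen - 1L)
          if (any(inWindow[span])) next
          ch[span] <- tolower(ch[span])
          inWindow[span] <- TRUE # avoid double-masking
          maskedTotal <- maskedTotal + tlen
        }
      }
      seqs[ci] <- .collapseChars(ch)
    }
    geneDf <- do.call(rbind, geneRows)
    islDf <- do.call(rbind, islandRows)
    # BStringSet preserves the lowercase soft-masking that DNAStringSet
    # would fold away
    genome <- Biostrings::BStringSet(stats::setNames(seqs, chromNames))
    # transcript ranges: 1 kb gene bodies starting at the TSS
    bodyLen <- 1000L
    gstart0 <- ifelse(geneDf$strand == "+", geneDf$tss0,
      pmax(0L, geneDf$tss0 - bodyLen + 1L))
    gend0 <- ifelse(geneDf$strand == "+",
      pmin(config@chromLength, geneDf$tss0 + bodyLen), geneDf$tss0 + 1L)
    genes <- GenomicRanges::GRanges(
      seqnames = geneDf$chrom,
      ranges = IRanges::IRanges(start = gstart0 + 1L, end = gend0),
      strand = geneDf$strand,
      gene_id = geneDf$gene_id,
      transcript_id = paste0(geneDf$gene_id, ".1"),
      seqlengths = stats::setNames(
        rep(config@chromLength, config@nChromosomes), chromNames
      )
    )
    islands <- GenomicRanges::GRanges(
      seqnames = islDf$chrom,
      ranges = IRanges::IRanges(start = islDf$start + 1L, end = islDf$end),
      island_id = paste0(islDf$gene_id, ":1"),
      gene_id = islDf$gene_id, gc = islDf$gc, oe = islDf$oe
    )
    new("GenomeAnnotation", genome = genome, genes = genes, islands = islands)
  })
}

#' Odds-scale methylation shift
#'
#' Shifts a methylation fraction by \code{fold} on the odds scale:
#' \code{hypo} divides the odds \code{m/(1-m)} by \code{fold}, \code{hyper}
#' multiplies them, keeping the result in [0, 1]. A baseline of 0.9 shifted
#' hypo by 2.5 gives 0.9 / (0.9 + 2.5 * 0.1) ~ 0.783.
#'
#' @param m methylation fraction(s) in [0, 1].
#' @param fold odds-scale fold (> 1).
#' @param direction \code{"hypo"} or \code{"hyper"}.
#' @return Shifted fraction(s).
#' @export
logitFoldShift <- function(m, fold, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  stopifnot(fold > 1)
  f <- if (direction == "hypo") 1 / fold else fold
  ifelse(m >= 1, 1, ifelse(m <= 0, 0, {
    odds <- m / (1 - m) * f
    odds / (1 + odds)
  }))
}

#' Simulate per-region, per-sample methylation truth
#'
#' Baseline fractions come from a two-component mixture (low ~ 0.05 for the
#' mostly unmethylated promoter CGIs, high ~ 0.9 for a fully methylated
#' minority). Tumor samples have \code{nHypo} regions shifted down and
#' \code{nHyper} shifted up by \code{effectFold} on the odds scale (the two
#' sets are disjoint); every sample gets Gaussian replicate jitter clipped
#' to [0, 1]. Positive-control samples are overridden to 1 everywhere,
#' negative-control samples to 0.
#'
#' @param truthIslands \code{GRanges} with an \code{island_id} column, or a
#'   character vector of region ids.
#' @param groups named character vector mapping sample id to
#'   \code{control}, \code{tumor}, \code{positive} or \code{negative}.
#' @param baselineHighProb probability of the methylated mixture component.
#' @param nHypo,nHyper planted effect counts (disjoint region sets).
#' @param effectFold odds-scale fold (> 1).
#' @param replicateSd sd of per-replicate jitter on the fraction scale.
#' @param lowLevel,highLevel mixture component means.
#' @param seed integer seed.
#' @return A \code{\link{MethylationTruth}}.
#' @export
makeMethylation <- function(truthIslands, groups, baselineHighProb = 0.1,
                            nHypo = NULL, nHyper = NULL, effectFold = 2.5,
                            replicateSd = 0.05, lowLevel = 0.05,
                            highLevel = 0.9, seed = 1) {
  ids <- if (is(truthIslands, "GRanges")) {
    as.character(truthIslands$island_id)
  } else {
    as.character(truthIslands)
  }
  n <- length(ids)
  if (is.null(nHypo)) nHypo <- round(0.08 * n)
  if (is.null(nHyper)) nHyper <- round(0.02 * n)
  if (nHypo + nHyper > n) stop("nHypo + nHyper exceeds the number of islands")
  stopifnot(effectFold > 1)
  .withSeed(.opSeed(seed, "make_methylation"), {
    high <- stats::runif(n) < baselineHighProb
    base <- ifelse(high, highLevel, lowLevel)
    # planted effects: hypomethylation needs methylated baseline to lose,
    # hypermethylation needs unmethylated baseline to gain
    hypoPool <- order(base, decreasing = TRUE)
    hypoIdx <- if (nHypo > 0) sort(hypoPool[seq_len(nHypo)]) else integer()
    hyperPool <- setdiff(order(base, decreasing = FALSE), hypoIdx)
    hyperIdx <- if (nHyper > 0) sort(hyperPool[seq_len(nHyper)]) else integer()
    if (length(intersect(hypoIdx, hyperIdx))) {
      stop("hypo and hyper sets overlap")
    }
    tumorMean <- base
    tumorMean[hypoIdx] <- logitFoldShift(base[hypoIdx], effectFold, "hypo")
    tumorMean[hyperIdx] <- logitFoldShift(base[hyperIdx], effectFold, "hyper")
    m <- matrix(0, nrow = n, ncol = length(groups),
      dimnames = list(ids, names(groups)))
    for (s in names(groups)) {
      mu <- switch(groups[[s]],
        control = base, tumor = tumorMean,
        positive = rep(1, n), negative = rep(0, n),
        stop("unknown group: ", groups[[s]])
      )
      if (groups[[s]] %in% c("control", "tumor") && replicateSd > 0) {
        mu <- pmin(1, pmax(0, mu + stats::rnorm(n, 0, replicateSd)))
      }
      m[, s] <- mu
    }
    effects <- data.frame(
      region_id = c(ids[hypoIdx], ids[hyperIdx]),
      direction = rep(c("hypo", "hyper"), c(length(hypoIdx), length(hyperIdx))),
      effect_fold = rep(effectFold, length(hypoIdx) + length(hyperIdx))
    )
    MethylationTruth(m = m, groups = groups, effects = effects)
  })
}

#' Simulate two-channel array intensities from methylation truth
#'
#' Per probe p and sample s, \code{Cy5 = B_p * (alpha + beta * m[p, s]) *
#' eps} and \code{Cy3 = B_p * eps'}, with \code{B_p} a lognormal probe
#' affinity shared across samples and \code{eps} multiplicative lognormal
#' noise of coefficient of variation \code{noiseCv} (unit mean). The
#' present flag is \code{Cy5 > detectionThreshold}. With zero noise the
#' ratio Cy5/Cy3 equals \code{alpha + beta * m} exactly, so truth is
#' recoverable as \code{(ratio - alpha) / beta}.
#'
#' @param design An \code{\link{ArrayDesign}}; every probe's
#'   \code{island_id} must be a row of the truth matrix.
#' @param truth A \code{\link{MethylationTruth}}.
#' @param model A \code{\link{SignalModel}}.
#' @param seed integer seed.
#' @return A \code{\link{ChannelSet}} (probes x samples).
#' @export
simulateArray <- function(design, truth, model = SignalModel(), seed = 1) {
  pr <- probes(design)
  m <- methLevels(truth)
  idx <- match(pr$island_id, rownames(m))
  if (anyNA(idx)) {
    stop(
      "probe(s) without a truth region: ",
      paste(utils::head(pr$probe_id[is.na(idx)], 3L), collapse = ", ")
    )
  }
  groups <- sampleGroups(truth)
  nP <- length(pr)
  nS <- ncol(m)
  .withSeed(.opSeed(seed, "simulate_array"), {
    B <- if (model@affinitySigma > 0) {
      stats::rlnorm(nP, meanlog = 0, sdlog = model@affinitySigma)
    } else {
      rep(1, nP)
    }
    sdlog <- sqrt(log(1 + model@noiseCv^2))
    noise <- function() {
      if (model@noiseCv > 0) {
        matrix(
          stats::rlnorm(nP * nS, meanlog = -sdlog^2 / 2, sdlog = sdlog),
          nP, nS
        )
      } else {
        matrix(1, nP, nS)
      }
    }
    mu <- model@alphaNonspecific + model@betaEnrichment * m[idx, , drop = FALSE]
    cy5 <- B * mu * noise()
    cy3 <- B * matrix(1, nP, nS) * noise()
    dimnames(cy5) <- dimnames(cy3) <- list(pr$probe_id, colnames(m))
    present <- cy5 > model@detectionThreshold
    ChannelSet(cy5 = cy5, cy3 = cy3, present = present, groups = groups)
  })
}

#' Simulate a direct bisulfite-sequencing trace for one region
#'
#' Each CpG site emits a C peak proportional to the methylation fraction m
#' and a T peak proportional to 1 - m; non-CpG cytosines emit T in
#' proportion to the bisulfite conversion rate (and residual C otherwise).
#' Gaussian noise of sd \code{noiseSd} is added to every peak and clipped
#' at zero. Peak areas are on a unit scale (a noise-free fully methylated
#' CpG has C = 1, T = 0).
#'
#' @param islandSequence character scalar or DNAString containing at least
#'   one CpG (uppercase is used; the plus strand is read).
#' @param m methylation fraction in [0, 1], shared by all CpGs of the
#'   region.
#' @param noiseSd Gaussian sd of peak areas.
#' @param conversionRate bisulfite conversion rate in (0, 1].
#' @param regionId,sampleId,group trace metadata.
#' @param seed integer seed.
#' @return A \code{\link{BisulfiteTrace}}.
#' @export
simulateTraces <- function(islandSequence, m, noiseSd = 0.05,
                           conversionRate = 1, regionId = "region",
                           sampleId = "s1", group = "control", seed = 1) {
  stopifnot(m >= 0, m <= 1, conversionRate > 0, conversionRate <= 1)
  ch <- toupper(.seqChars(islandSequence))
  isC <- ch == "C"
  n <- length(ch)
  nextG <- c(ch[-1L] == "G", FALSE)
  cpgPos <- which(isC & nextG)
  nonCpgPos <- which(isC & !nextG)
  if (!length(cpgPos)) stop("sequence contains no CpG site")
  .withSeed(.opSeed(seed, paste("simulate_traces", regionId, sampleId)), {
    pos <- sort(c(cpgPos, nonCpgPos))
    type <- ifelse(pos %in% cpgPos, "cpg", "non_cpg_c")
    cMean <- ifelse(type == "cpg", m, 1 - conversionRate)
    tMean <- ifelse(type == "cpg", 1 - m, conversionRate)
    jitter <- function(mu) {
      if (noiseSd > 0) pmax(0, mu + stats::rnorm(length(mu), 0, noiseSd)) else mu
    }
    BisulfiteTrace(
      regionId = regionId, sampleId = sampleId, group = group,
      sites = data.frame(
        position = pos - 1L, # 0-based like the island coordinates
        site_type = type,
        c_area = jitter(cMean),
        t_area = jitter(tMean)
      )
    )
  })
}

#' Simulate an HPLC mononucleotide peak profile
#'
#' Distributes \code{totalArea} over the four deoxynucleotide peaks
#' according to the genomic G+C fraction, splits the cytosine share between
#' dC and 5-methyl-dC so that \code{m5dC / (dC + m5dC)} equals
#' \code{percent5mc / 100}, and leaves the uracil peak at zero unless RNA
#' contamination is simulated. Gaussian noise of sd \code{noiseSd} is added
#' per peak and clipped at zero.
#'
#' @param percent5mc percentage of cytosines methylated, in [0, 100].
#' @param totalArea total area of the four dN peaks.
#' @param noiseSd Gaussian sd per peak area.
#' @param rnaContamination logical; emit a nonzero uracil peak.
#' @param gcFractionGenome genomic G+C fraction used for the peak split.
#' @param seed integer seed.
#' @return An \code{\link{HplcProfile}}.
#' @export
simulateHplc <- function(percent5mc, totalArea = 100, noiseSd = 0,
                         rnaContamination = FALSE, gcFractionGenome = 0.4,
                         seed = 1) {
  stopifnot(percent5mc >= 0, percent5mc <= 100)
  cShare <- totalArea * gcFractionGenome / 2
  atShare <- totalArea * (1 - gcFractionGenome) / 2
  areas <- c(
    dA = atShare, dC = cShare * (1 - percent5mc / 100), dG = cShare,
    dT = atShare, m5dC = cShare * percent5mc / 100,
    U = if (rnaContamination) 0.05 * totalArea else 0
  )
  if (noiseSd > 0) {
    areas <- .withSeed(
      .opSeed(seed, "simulate_hplc"),
      pmax(0, areas + stats::rnorm(length(areas), 0, noiseSd))
    )
  }
  HplcProfile(areas)
}

#' Simulate a complete MeDIP-chip study
#'
#' One-stop simulator for power and calibration experiments: builds a bare
#' one-probe-per-region design, a methylation truth with planted tumor
#' effects, and simulated channels. Unaffected regions draw their baseline
#' from the usual bimodal mixture. Hypomethylation is planted on
#' moderately methylated baselines and hypermethylation on low baselines:
#' under the affine MeDIP response \code{alpha + beta * m}, an odds-scale
#' fold expresses as a comparable signal-ratio fold only away from the
#' saturated top of the methylation scale (see the vignette).
#'
#' @param nProbes number of probes (= regions).
#' @param nHypo,nHyper planted effect counts.
#' @param effectFold odds-scale fold for planted effects.
#' @param hypoBaseline,hyperBaseline control-group baselines of the
#'   affected regions.
#' @param baselineHighProb,lowLevel,highLevel mixture of unaffected
#'   baselines.
#' @param nTumor,nControl biological group sizes.
#' @param withControls include one positive and one negative control
#'   sample.
#' @param model A \code{\link{SignalModel}}.
#' @param replicateSd sd of biological replicate jitter on the fraction
#'   scale.
#' @param seed integer seed.
#' @return list with \code{design} (\code{\link{ArrayDesign}}),
#'   \code{truth} (\code{\link{MethylationTruth}}) and \code{channels}
#'   (\code{\link{ChannelSet}}).
#' @export
makeExampleStudy <- function(nProbes = 10000, nHypo = 500, nHyper = 100,
                             effectFold = 2.5, hypoBaseline = 0.25,
                             hyperBaseline = 0.05, baselineHighProb = 0.1,
                             lowLevel = 0.05, highLevel = 0.9,
                             nTumor = 6, nControl = 6, withControls = TRUE,
                             model = SignalModel(), replicateSd = 0,
                             seed = 1) {
  stopifnot(nHypo + nHyper <= nProbes)
  ids <- sprintf("region%05d", seq_len(nProbes))
  groups <- c(
    stats::setNames(rep("control", nControl), sprintf("C%d", seq_len(nControl))),
    stats::setNames(rep("tumor", nTumor), sprintf("T%d", seq_len(nTumor)))
  )
  if (withControls) groups <- c(groups, P1 = "positive", N1 = "negative")
  .withSeed(.opSeed(seed, "make_example_study"), {
    base <- ifelse(stats::runif(nProbes) < baselineHighProb,
      highLevel, lowLevel)
    hypoIdx <- seq_len(nHypo)
    hyperIdx <- nHypo + seq_len(nHyper)
    base[hypoIdx] <- hypoBaseline
    base[hyperIdx] <- hyperBaseline
    tumorMean <- base
    tumorMean[hypoIdx] <- logitFoldShift(base[hypoIdx], effectFold, "hypo")
    tumorMean[hyperIdx] <- logitFoldShift(base[hyperIdx], effectFold, "hyper")
    m <- matrix(0, nProbes, length(groups),
      dimnames = list(ids, names(groups)))
    for (s in names(groups)) {
      mu <- switch(groups[[s]],
        control = base, tumor = tumorMean,
        positive = rep(1, nProbes), negative = rep(0, nProbes)
      )
      if (groups[[s]] %in% c("control", "tumor") && replicateSd > 0) {
        mu <- pmin(1, pmax(0, mu + stats::rnorm(nProbes, 0, replicateSd)))
      }
      m[, s] <- mu
    }
    effects <- data.frame(
      region_id = ids[c(hypoIdx, hyperIdx)],
      direction = rep(c("hypo", "hyper"), c(nHypo, nHyper)),
      effect_fold = rep(effectFold, nHypo + nHyper)
    )
    truth <- MethylationTruth(m = m, groups = groups, effects = effects)
    gr <- GenomicRanges::GRanges(
      seqnames = "sim",
      ranges = IRanges::IRanges(start = seq_len(nProbes) * 100L, width = 60L),
      probe_id = paste0(ids, "_p01"),
      sequence = NA_character_,
      island_id = ids,
      gene_ids = sub("region", "gene", ids)
    )
    design <- buildDesign(gr)
    channels <- simulateArray(design, truth, model, seed = seed)
    list(design = design, truth = truth, channels = channels)
  })
}

## ---------------------------------------------------------------------------
## Serialization of the synthetic substrate
## ---------------------------------------------------------------------------

#' Write a synthetic genome to FASTA / GFF3 / BED
#'
#' FASTA is wrapped at 60 columns with soft-masked repeats lowercase; the
#' GFF3 carries \code{gene} and \code{mRNA} features (1-based inclusive);
#' truth islands go to BED6 (0-based half-open).
#'
#' @param annotation A \code{\link{GenomeAnnotation}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
writeGenome <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "truth_islands.bed")
  Biostrings::writeXStringSet(genomeSeq(annotation), fa, width = 60L)
  genes <- geneRanges(annotation)
  gene <- genes
  mcols(gene) <- NULL
  gene$source <- "medipTile"
  gene$type <- "gene"
  gene$ID <- genes$gene_id
  mrna <- genes
  mcols(mrna) <- NULL
  mrna$source <- "medipTile"
  mrna$type <- "mRNA"
  mrna$ID <- genes$transcript_id
  mrna$Parent <- genes$gene_id
  rtracklayer::export(c(gene, mrna), gff, format = "gff3")
  isl <- truthIslands(annotation)
  utils::write.table(
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(isl)),
      start = GenomicRanges::start(isl) - 1L,
      end = GenomicRanges::end(isl),
      name = isl$island_id,
      score = pmin(1000L, as.integer(round(1000 * isl$oe))),
      strand = "."
    ),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}

#' Read / write a two-channel intensity table
#'
#' Long-format TSV with header \code{sample_id, group, probe_id, cy3, cy5,
#' present}.
#'
#' @param channels A \code{\link{ChannelSet}}.
#' @param path file path.
#' @return \code{writeChannelTable}: invisibly, \code{path};
#'   \code{readChannelTable}: a \code{ChannelSet}.
#' @export
writeChannelTable <- function(channels, path) {
  groups <- sampleGroups(channels)
  cy5 <- SummarizedExperiment::assay(channels, "cy5")
  cy3 <- SummarizedExperiment::assay(channels, "cy3")
  present <- SummarizedExperiment::assay(channels, "present")
  df <- data.frame(
    sample_id = rep(colnames(cy5), each = nrow(cy5)),
    group = rep(unname(groups[colnames(cy5)]), each = nrow(cy5)),
    probe_id = rep(rownames(cy5), times = ncol(cy5)),
    cy3 = as.vector(cy3),
    cy5 = as.vector(cy5),
    present = as.integer(as.vector(present))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeChannelTable
#' @export
readChannelTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "probe_id", "cy3", "cy5", "present")
  stopifnot(all(need %in% colnames(df)))
  samples <- unique(df$sample_id)
  probesIds <- unique(df$probe_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(probesIds), length(samples),
      dimnames = list(probesIds, samples))
    m[cbind(match(df$probe_id, probesIds), match(df$sample_id, samples))] <-
      df[[col]]
    m
  }
  groups <- stats::setNames(
    df$group[match(samples, df$sample_id)], samples
  )
  ChannelSet(
    cy5 = shape("cy5"), cy3 = shape("cy3"),
    present = shape("present") > 0, groups = groups
  )
}
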