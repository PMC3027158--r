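#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Parameters for promoter CpG-island prediction
#'
#' Holds the windowed Gardiner-Garden/Frommer criteria used to call CpG
#' islands (CGIs), together with the promoter-window extent around each
#' transcription start site (TSS).
#'
#' @slot windowLen integer, sliding-window length in bases.
#' @slot gcMin numeric, minimum G+C fraction for a qualifying window.
#' @slot oeMin numeric, minimum observed/expected CpG ratio.
#' @slot minIslandLen integer, minimum island length in bases.
#' @slot upstream integer, bases upstream of the TSS in a promoter window.
#' @slot downstream integer, bases downstream of the TSS.
#'
#' @export
setClass("CgiParams",
  representation(
    windowLen = "integer", gcMin = "numeric", oeMin = "numeric",
    minIslandLen = "integer", upstream = "integer", downstream = "integer"
  ),
  prototype(
    windowLen = 200L, gcMin = 0.5, oeMin = 0.6,
    minIslandLen = 200L, upstream = 1500L, downstream = 1000L
  )
)

setValidity("CgiParams", function(object) {
  if (object@windowLen < 1L) return("windowLen must be >= 1")
  if (object@gcMin < 0 || object@gcMin > 1) return("gcMin must be in [0,1]")
  if (object@oeMin < 0) return("oeMin must be >= 0")
  if (object@minIslandLen < 1L) return("minIslandLen must be >= 1")
  if (object@upstream < 0L || object@downstream < 0L) {
    return("upstream and downstream must be >= 0")
  }
  TRUE
})

#' @param windowLen,gcMin,oeMin,minIslandLen,upstream,downstream see slots.
#' @return A \code{CgiParams} object.
#' @rdname CgiParams-class
#' @export
CgiParams <- function(windowLen = 200, gcMin = 0.5, oeMin = 0.6,
                      minIslandLen = 200, upstream = 1500, downstream = 1000) {
  new("CgiParams",
    windowLen = .asCount(windowLen, "windowLen"), gcMin = gcMin, oeMin = oeMin,
    minIslandLen = .asCount(minIslandLen, "minIslandLen"),
    upstream = .asCount(upstream, "upstream"),
    downstream = .asCount(downstream, "downstream")
  )
}

#' Parameters for tiling-probe design
#'
#' @slot probeLen integer, probe length (60-mers by default).
#' @slot step integer, spacing between successive probe starts.
#' @slot uniqLen integer, k-mer length at which genome uniqueness is enforced.
#' @slot nControlFeatures integer, count of manufacturer control features.
#' @slot nBlankFeatures integer, count of blank features.
#'
#' @export
setClass("ProbeParams",
  representation(
    probeLen = "integer", step = "integer", uniqLen = "integer",
    nControlFeatures = "integer", nBlankFeatures = "integer"
  ),
  prototype(
    probeLen = 60L, step = 25L, uniqLen = 55L,
    nControlFeatures = 0L, nBlankFeatures = 0L
  )
)

setValidity("ProbeParams", function(object) {
  if (object@uniqLen > object@probeLen) return("uniqLen must be <= probeLen")
  if (object@step < 1L) return("step must be >= 1")
  if (object@nControlFeatures < 0L || object@nBlankFeatures < 0L) {
    return("feature counts must be >= 0")
  }
  TRUE
})

#' @param probeLen,step,uniqLen,nControlFeatures,nBlankFeatures see slots.
#' @return A \code{ProbeParams} object.
#' @rdname ProbeParams-class
#' @export
ProbeParams <- function(probeLen = 60, step = 25, uniqLen = 55,
                        nControlFeatures = 0, nBlankFeatures = 0) {
  new("ProbeParams",
    probeLen = .asCount(probeLen, "probeLen"), step = .asCount(step, "step"),
    uniqLen = .asCount(uniqLen, "uniqLen"),
    nControlFeatures = .asCount(nControlFeatures, "nControlFeatures"),
    nBlankFeatures = .asCount(nBlankFeatures, "nBlankFeatures")
  )
}

#' Parameters for two-channel methylation array analysis
#'
#' Defaults follow the GeneSpring-style workflow: probes must be flagged
#' present in at least 4 of the 10 samples, probes with mean raw intensity
#' below 25 or replicate standard deviation above 1.4 are removed, and
#' differential calls require a 1.5-fold change with Welch p < 0.05.
#'
#' @slot presentMin integer, minimum number of samples with a present flag.
#' @slot nSamplesForPresent integer, nominal sample count the presence rule
#'   refers to (documentation only; counting uses all samples in the set).
#' @slot intensityMin numeric, minimum mean raw Cy5 intensity.
#' @slot sdMax numeric, maximum within-group standard deviation of
#'   normalized ratios.
#' @slot fcCut numeric, fold-change cut-off (> 1).
#' @slot alpha numeric, two-sided Welch test level.
#' @slot medianFold numeric, fold relative to the median used for the
#'   higher/lower methylation classes.
#' @slot enrichmentFdr numeric, BH false-discovery-rate cut for term
#'   enrichment.
#'
#' @export
setClass("AnalysisParams",
  representation(
    presentMin = "integer", nSamplesForPresent = "integer",
    intensityMin = "numeric", sdMax = "numeric", fcCut = "numeric",
    alpha = "numeric", medianFold = "numeric", enrichmentFdr = "numeric"
  ),
  prototype(
    presentMin = 4L, nSamplesForPresent = 10L, intensityMin = 25,
    sdMax = 1.4, fcCut = 1.5, alpha = 0.05, medianFold = 2,
    enrichmentFdr = 0.05
  )
)

setValidity("AnalysisParams", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@fcCut <= 1) return("fcCut must be > 1")
  if (object@medianFold <= 1) return("medianFold must be > 1")
  if (object@enrichmentFdr <= 0 || object@enrichmentFdr >= 1) {
    return("enrichmentFdr must be in (0,1)")
  }
  TRUE
})

#' @param presentMin,nSamplesForPresent,intensityMin,sdMax,fcCut,alpha,medianFold,enrichmentFdr
#'   see slots.
#' @return An \code{AnalysisParams} object.
#' @rdname AnalysisParams-class
#' @export
AnalysisParams <- function(presentMin = 4, nSamplesForPresent = 10,
                           intensityMin = 25, sdMax = 1.4, fcCut = 1.5,
                           alpha = 0.05, medianFold = 2,
                           enrichmentFdr = 0.05) {
  new("AnalysisParams",
    presentMin = .asCount(presentMin, "presentMin"),
    nSamplesForPresent = .asCount(nSamplesForPresent, "nSamplesForPresent"),
    intensityMin = intensityMin, sdMax = sdMax, fcCut = fcCut,
    alpha = alpha, medianFold = medianFold, enrichmentFdr = enrichmentFdr
  )
}

#' MeDIP-chip signal model
#'
#' Affine response of the immunoprecipitated (Cy5) channel to the region
#' methylation fraction m: the expected ratio to the genomic reference (Cy3)
#' channel is \code{alpha + beta * m}. \code{alpha} is the non-specific
#' binding baseline seen as a uniform low signal on the amplified,
#' unmethylated negative control; \code{alpha + beta} is the uniformly high
#' signal of the fully methylated positive control. Probe affinity acts as a
#' shared multiplicative lognormal factor on both channels and measurement
#' noise is multiplicative with coefficient of variation \code{noiseCv}.
#'
#' @slot alphaNonspecific numeric, baseline ratio (> 0).
#' @slot betaEnrichment numeric, enrichment gain (> 0).
#' @slot affinitySigma numeric, log-scale sd of per-probe affinity.
#' @slot noiseCv numeric, coefficient of variation of channel noise.
#' @slot detectionThreshold numeric, Cy5 level above which a probe is
#'   flagged present.
#'
#' @export
setClass("SignalModel",
  representation(
    alphaNonspecific = "numeric", betaEnrichment = "numeric",
    affinitySigma = "numeric", noiseCv = "numeric",
    detectionThreshold = "numeric"
  ),
  prototype(
    alphaNonspecific = 20, betaEnrichment = 1000, affinitySigma = 0.5,
    noiseCv = 0.15, detectionThreshold = 40
  )
)

setValidity("SignalModel", function(object) {
  if (object@alphaNonspecific <= 0) return("alphaNonspecific must be > 0")
  if (object@betaEnrichment <= 0) return("betaEnrichment must be > 0")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  if (object@affinitySigma < 0) return("affinitySigma must be >= 0")
  TRUE
})

#' @param alphaNonspecific,betaEnrichment,affinitySigma,noiseCv,detectionThreshold
#'   see slots.
#' @return A \code{SignalModel} object.
#' @rdname SignalModel-class
#' @export
SignalModel <- function(alphaNonspecific = 20, betaEnrichment = 1000,
                        affinitySigma = 0.5, noiseCv = 0.15,
                        detectionThreshold = 40) {
  new("SignalModel",
    alphaNonspecific = alphaNonspecific, betaEnrichment = betaEnrichment,
    affinitySigma = affinitySigma, noiseCv = noiseCv,
    detectionThreshold = detectionThreshold
  )
}

#' Configuration of the synthetic genome generator
#'
#' Describes a CpG-depleted background genome with one CpG island planted in
#' the promoter window of each gene, and a fraction of the background
#' soft-masked (lowercased) as repeats.
#'
#' @slot nChromosomes integer, number of chromosomes.
#' @slot chromLength integer, length of each chromosome in bases.
#' @slot nGenes integer, number of genes across the genome.
#' @slot backgroundGc numeric, background G+C fraction.
#' @slot backgroundCpgOe numeric, background observed/expected CpG ratio
#'   (< 1 encodes CpG depletion).
#' @slot islandGcRange numeric(2), range from which island G+C targets are
#'   drawn.
#' @slot islandOeRange numeric(2), range for island observed/expected CpG.
#' @slot islandLenRange integer(2), range for island lengths in bases.
#' @slot repeatFraction numeric, fraction of background bases soft-masked.
#' @slot ensureDetectable logical, whether planted islands are redrawn until
#'   every interior window meets the detection thresholds below (the
#'   generator's planting guarantee).
#' @slot detectWindow integer, window length for the planting guarantee.
#' @slot detectGc,detectOe numeric, thresholds for the planting guarantee.
#' @slot seed integer, seed that fully determines the generated genome.
#'
#' @export
setClass("GenomeConfig",
  representation(
    nChromosomes = "integer", chromLength = "integer", nGenes = "integer",
    backgroundGc = "numeric", backgroundCpgOe = "numeric",
    islandGcRange = "numeric", islandOeRange = "numeric",
    islandLenRange = "integer", repeatFraction = "numeric",
    ensureDetectable = "logical", detectWindow = "integer",
    detectGc = "numeric", detectOe = "numeric", seed = "integer"
  ),
  prototype(
    nChromosomes = 2L, chromLength = 150000L, nGenes = 40L,
    backgroundGc = 0.40, backgroundCpgOe = 0.20,
    islandGcRange = c(0.60, 0.70), islandOeRange = c(0.80, 1.05),
    islandLenRange = c(250L, 800L), repeatFraction = 0.10,
    ensureDetectable = TRUE, detectWindow = 200L, detectGc = 0.5,
    detectOe = 0.6, seed = 1L
  )
)

setValidity("GenomeConfig", function(object) {
  fr <- c(
    object@backgroundGc, object@backgroundCpgOe, object@repeatFraction,
    object@islandGcRange
  )
  if (any(fr < 0 | fr > 1)) return("fractions must be in [0,1]")
  if (any(object@islandOeRange < 0)) return("islandOeRange must be >= 0")
  if (length(object@islandGcRange) != 2L || length(object@islandOeRange) != 2L ||
    length(object@islandLenRange) != 2L) {
    return("island ranges must have length 2")
  }
  if (diff(object@islandGcRange) < 0 || diff(object@islandOeRange) < 0 ||
    diff(object@islandLenRange) < 0) {
    return("island ranges must be nondecreasing")
  }
  if (object@islandLenRange[1L] < object@detectWindow) {
    return("islandLenRange lower bound must be >= detectWindow")
  }
  TRUE
})

#' @param nChromosomes,chromLength,nGenes,backgroundGc,backgroundCpgOe,islandGcRange,islandOeRange,islandLenRange,repeatFraction,ensureDetectable,detectWindow,detectGc,detectOe,seed
#'   see slots.
#' @return A \code{GenomeConfig} object.
#' @rdname GenomeConfig-class
#' @export
GenomeConfig <- function(nChromosomes = 2, chromLength = 150000, nGenes = 40,
                         backgroundGc = 0.40, backgroundCpgOe = 0.20,
                         islandGcRange = c(0.60, 0.70),
                         islandOeRange = c(0.80, 1.05),
                         islandLenRange = c(250, 800),
                         repeatFraction = 0.10, ensureDetectable = TRUE,
                         detectWindow = 200, detectGc = 0.5, detectOe = 0.6,
                         seed = 1) {
  new("GenomeConfig",
    nChromosomes = .asCount(nChromosomes, "nChromosomes"),
    chromLength = .asCount(chromLength, "chromLength"),
    nGenes = .asCount(nGenes, "nGenes"),
    backgroundGc = backgroundGc, backgroundCpgOe = backgroundCpgOe,
    islandGcRange = as.numeric(islandGcRange),
    islandOeRange = as.numeric(islandOeRange),
    islandLenRange = as.integer(round(islandLenRange)),
    repeatFraction = repeatFraction,
    ensureDetectable = isTRUE(ensureDetectable),
    detectWindow = .asCount(detectWindow, "detectWindow"),
    detectGc = detectGc, detectOe = detectOe,
    seed = as.integer(seed)
  )
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Synthetic genome with annotation and planted-island truth
#'
#' @slot genome A \link[Biostrings]{BStringSet} (case-preserving, so that
#'   soft-masked repeats stay lowercase; \code{DNAStringSet} would fold
#'   them to uppercase), one entry per chromosome.
#' @slot genes A \link[GenomicRanges]{GRanges} of transcripts with metadata
#'   columns \code{gene_id} and \code{transcript_id}; the 5' end of each
#'   range is the TSS.
#' @slot islands A \code{GRanges} of planted truth islands with metadata
#'   columns \code{island_id}, \code{gene_id}, \code{gc}, \code{oe}
#'   (realized whole-span values).
#'
#' @export
setClass("GenomeAnnotation",
  representation(
    genome = "XStringSet", genes = "GRanges", islands = "GRanges"
  )
)

setValidity("GenomeAnnotation", function(object) {
  chr <- names(object@genome)
  if (is.null(chr) || anyDuplicated(chr)) {
    return("genome must have unique chromosome names")
  }
  bad <- !(as.character(GenomicRanges::seqnames(object@genes)) %in% chr)
  if (any(bad)) return("gene records on unknown chromosomes")
  if (is.null(object@genes$gene_id)) return("genes need a gene_id column")
  TRUE
})

#' @describeIn GenomeAnnotation-class chromosome sequences.
#' @param x,object A \code{GenomeAnnotation}.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname GenomeAnnotation-class
#' @export
setMethod("genomeSeq", "GenomeAnnotation", function(x) x@genome)

#' @describeIn GenomeAnnotation-class transcript ranges.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname GenomeAnnotation-class
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)

#' @describeIn GenomeAnnotation-class planted truth islands.
#' @export
setGeneric("truthIslands", function(x) standardGeneric("truthIslands"))
#' @rdname GenomeAnnotation-class
#' @export
setMethod("truthIslands", "GenomeAnnotation", function(x) x@islands)

setMethod("show", "GenomeAnnotation", function(object) {
  cat(
    "GenomeAnnotation:", length(object@genome), "chromosome(s),",
    sum(Biostrings::width(object@genome)), "bp;",
    length(unique(object@genes$gene_id)), "gene(s);",
    length(object@islands), "truth island(s)\n"
  )
})

#' Per-region, per-sample methylation truth
#'
#' @slot m numeric matrix, regions x samples, methylation fractions in
#'   [0, 1].
#' @slot groups named character vector mapping sample id to one of
#'   \code{control}, \code{tumor}, \code{positive}, \code{negative}.
#' @slot effects data.frame ledger of planted effects with columns
#'   \code{region_id}, \code{direction} (\code{hypo}/\code{hyper}) and
#'   \code{effect_fold} (odds-scale fold).
#'
#' @export
setClass("MethylationTruth",
  representation(m = "matrix", groups = "character", effects = "data.frame")
)

setValidity("MethylationTruth", function(object) {
  if (any(object@m < 0 | object@m > 1)) return("m must be in [0,1]")
  if (!identical(colnames(object@m), names(object@groups))) {
    return("colnames(m) must match names(groups)")
  }
  if (!all(object@groups %in% c("control", "tumor", "positive", "negative"))) {
    return("unknown group label")
  }
  pos <- names(object@groups)[object@groups == "positive"]
  neg <- names(object@groups)[object@groups == "negative"]
  if (length(pos) && any(object@m[, pos] != 1)) {
    return("positive-control samples must have m = 1 everywhere")
  }
  if (length(neg) && any(object@m[, neg] != 0)) {
    return("negative-control samples must have m = 0 everywhere")
  }
  if (nrow(object@effects) &&
    !all(object@effects$region_id %in% rownames(object@m))) {
    return("effect ledger regions must be a subset of truth regions")
  }
  TRUE
})

#' @param m,groups,effects see slots.
#' @return A \code{MethylationTruth} object.
#' @rdname MethylationTruth-class
#' @export
MethylationTruth <- function(m, groups,
                             effects = data.frame(
                               region_id = character(),
                               direction = character(),
                               effect_fold = numeric()
                             )) {
  new("MethylationTruth", m = m, groups = groups, effects = effects)
}

#' @describeIn MethylationTruth-class the region x sample fraction matrix.
#' @param x A \code{MethylationTruth}.
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))
#' @rdname MethylationTruth-class
#' @export
setMethod("methLevels", "MethylationTruth", function(x) x@m)

#' @describeIn MethylationTruth-class sample-to-group map.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname MethylationTruth-class
#' @export
setMethod("sampleGroups", "MethylationTruth", function(x) x@groups)

#' @describeIn MethylationTruth-class planted-effect ledger.
#' @export
setGeneric("effectLedger", function(x) standardGeneric("effectLedger"))
#' @rdname MethylationTruth-class
#' @export
setMethod("effectLedger", "MethylationTruth", function(x) x@effects)

setMethod("show", "MethylationTruth", function(object) {
  cat(
    "MethylationTruth:", nrow(object@m), "regions x", ncol(object@m),
    "samples; groups:",
    paste(sprintf("%s=%d", names(table(object@groups)), table(object@groups)),
      collapse = ", "
    ),
    sprintf("; %d planted effect(s)\n", nrow(object@effects))
  )
})

#' Tiling-array design
#'
#' Probe records plus manufacturer control / blank feature accounting.
#'
#' @slot probes A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{probe_id}, \code{sequence}, \code{island_id}, \code{gene_ids}
#'   (comma-separated when a probe serves several genes).
#' @slot nControlFeatures,nBlankFeatures integer feature counts.
#'
#' @export
setClass("ArrayDesign",
  representation(
    probes = "GRanges", nControlFeatures = "integer",
    nBlankFeatures = "integer"
  ),
  prototype(nControlFeatures = 0L, nBlankFeatures = 0L)
)

setValidity("ArrayDesign", function(object) {
  ids <- object@probes$probe_id
  if (length(object@probes)) {
    if (is.null(ids)) return("probes need a probe_id column")
    if (anyDuplicated(ids)) return("duplicate probe ids")
  }
  if (object@nControlFeatures < 0L || object@nBlankFeatures < 0L) {
    return("feature counts must be >= 0")
  }
  TRUE
})

#' @describeIn ArrayDesign-class probe records.
#' @param x,object An \code{ArrayDesign}.
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))
#' @rdname ArrayDesign-class
#' @export
setMethod("probes", "ArrayDesign", function(x) x@probes)

#' @describeIn ArrayDesign-class total printed features (probes + control +
#'   blank).
#' @export
setGeneric("totalFeatures", function(x) standardGeneric("totalFeatures"))
#' @rdname ArrayDesign-class
#' @export
setMethod("totalFeatures", "ArrayDesign", function(x) {
  length(x@probes) + x@nControlFeatures + x@nBlankFeatures
})

#' @describeIn ArrayDesign-class control-feature count.
#' @export
setGeneric("nControlFeatures", function(x) standardGeneric("nControlFeatures"))
#' @rdname ArrayDesign-class
#' @export
setMethod("nControlFeatures", "ArrayDesign", function(x) x@nControlFeatures)

#' @describeIn ArrayDesign-class blank-feature count.
#' @export
setGeneric("nBlankFeatures", function(x) standardGeneric("nBlankFeatures"))
#' @rdname ArrayDesign-class
#' @export
setMethod("nBlankFeatures", "ArrayDesign", function(x) x@nBlankFeatures)

setMethod("show", "ArrayDesign", function(object) {
  cat(
    "ArrayDesign:", length(object@probes), "probes +",
    object@nControlFeatures, "control +", object@nBlankFeatures,
    "blank =", totalFeatures(object), "features\n"
  )
})

#' Two-channel probe intensities
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with assays
#' \code{cy5} (immunoprecipitated test channel), \code{cy3} (genomic
#' reference channel) and \code{present} (logical detection flags);
#' \code{colData} carries the sample \code{group}.
#'
#' @export
setClass("ChannelSet", contains = "SummarizedExperiment")

setValidity("ChannelSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("cy5", "cy3", "present")
  if (!all(need %in% an)) {
    return(paste("missing assay(s):", paste(setdiff(need, an), collapse = ", ")))
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object))) {
    return("colData must contain 'group'")
  }
  TRUE
})

#' @param cy5,cy3 numeric matrices (probes x samples).
#' @param present logical matrix of detection flags.
#' @param groups named character vector of sample groups (names = sample
#'   ids, matching the matrix columns).
#' @return A \code{ChannelSet}.
#' @rdname ChannelSet-class
#' @export
ChannelSet <- function(cy5, cy3, present, groups) {
  stopifnot(identical(dim(cy5), dim(cy3)), identical(dim(cy5), dim(present)))
  if (is.null(colnames(cy5))) colnames(cy5) <- names(groups)
  groups <- groups[colnames(cy5)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cy5 = cy5, cy3 = cy3, present = present),
    colData = S4Vectors::DataFrame(group = unname(groups), row.names = colnames(cy5))
  )
  new("ChannelSet", se)
}

#' @describeIn ChannelSet-class sample-to-group map.
#' @param x A \code{ChannelSet}.
#' @export
setMethod("sampleGroups", "ChannelSet", function(x) {
  stats::setNames(
    as.character(SummarizedExperiment::colData(x)$group), colnames(x)
  )
})

#' Normalized methylation-ratio matrix
#'
#' Output of \code{\link{normalizeToControl}} /
#' \code{\link{filterProbes}}: per-probe, per-sample ratios of the Cy5 test
#' signal to the Cy3 genomic reference, scaled so that the mean over
#' control-group biological samples is 1 for every probe.
#'
#' @slot ratios numeric matrix of normalized ratios (probes x samples).
#' @slot rawRatios numeric matrix of raw Cy5/Cy3 ratios.
#' @slot groups named character vector of sample groups.
#' @slot filterStatus data.frame with columns \code{probe_id},
#'   \code{retained}, \code{reason}.
#'
#' @export
setClass("NormalizedMatrix",
  representation(
    ratios = "matrix", rawRatios = "matrix", groups = "character",
    filterStatus = "data.frame"
  )
)

setValidity("NormalizedMatrix", function(object) {
  if (!identical(dim(object@ratios), dim(object@rawRatios))) {
    return("ratios and rawRatios must have identical shape")
  }
  if (!identical(colnames(object@ratios), names(object@groups))) {
    return("colnames(ratios) must match names(groups)")
  }
  TRUE
})

#' @describeIn NormalizedMatrix-class normalized ratio matrix.
#' @param x,object A \code{NormalizedMatrix}.
#' @export
setGeneric("normalizedRatios", function(x) standardGeneric("normalizedRatios"))
#' @rdname NormalizedMatrix-class
#' @export
setMethod("normalizedRatios", "NormalizedMatrix", function(x) x@ratios)

#' @describeIn NormalizedMatrix-class raw Cy5/Cy3 ratios.
#' @export
setGeneric("rawRatios", function(x) standardGeneric("rawRatios"))
#' @rdname NormalizedMatrix-class
#' @export
setMethod("rawRatios", "NormalizedMatrix", function(x) x@rawRatios)

#' @rdname NormalizedMatrix-class
#' @export
setMethod("sampleGroups", "NormalizedMatrix", function(x) x@groups)

#' @describeIn NormalizedMatrix-class per-probe retention status.
#' @export
setGeneric("filterStatus", function(x) standardGeneric("filterStatus"))
#' @rdname NormalizedMatrix-class
#' @export
setMethod("filterStatus", "NormalizedMatrix", function(x) x@filterStatus)

setMethod("show", "NormalizedMatrix", function(object) {
  cat(
    "NormalizedMatrix:", nrow(object@ratios), "probes x",
    ncol(object@ratios), "samples;",
    sum(object@filterStatus$retained), "retained\n"
  )
})

#' Direct bisulfite-sequencing trace quantification input
#'
#' Per-site C and T peak areas from direct sequencing of bisulfite-treated,
#' PCR-amplified DNA. Methylated cytosines at CpG sites read as C,
#' unmethylated ones as T; non-CpG cytosines should read as T and serve as
#' the bisulfite-conversion control.
#'
#' @slot regionId,sampleId,group character scalars.
#' @slot sites data.frame with columns \code{position} (strictly
#'   increasing), \code{site_type} (\code{cpg} or \code{non_cpg_c}),
#'   \code{c_area}, \code{t_area} (non-negative).
#'
#' @export
setClass("BisulfiteTrace",
  representation(
    regionId = "character", sampleId = "character", group = "character",
    sites = "data.frame"
  )
)

setValidity("BisulfiteTrace", function(object) {
  s <- object@sites
  need <- c("position", "site_type", "c_area", "t_area")
  if (!all(need %in% colnames(s))) return("sites missing required columns")
  if (any(s$c_area < 0) || any(s$t_area < 0)) return("areas must be >= 0")
  if (!all(s$site_type %in% c("cpg", "non_cpg_c"))) {
    return("site_type must be 'cpg' or 'non_cpg_c'")
  }
  if (sum(s$site_type == "cpg") < 1L) return("need at least one CpG site")
  if (is.unsorted(s$position, strictly = TRUE)) {
    return("positions must be strictly increasing")
  }
  TRUE
})

#' @param regionId,sampleId,group,sites see slots.
#' @return A \code{BisulfiteTrace}.
#' @rdname BisulfiteTrace-class
#' @export
BisulfiteTrace <- function(regionId, sampleId = "s1", group = "control",
                           sites) {
  new("BisulfiteTrace",
    regionId = as.character(regionId), sampleId = as.character(sampleId),
    group = as.character(group), sites = as.data.frame(sites)
  )
}

#' @describeIn BisulfiteTrace-class per-site table.
#' @param x,object A \code{BisulfiteTrace}.
#' @export
setGeneric("traceSites", function(x) standardGeneric("traceSites"))
#' @rdname BisulfiteTrace-class
#' @export
setMethod("traceSites", "BisulfiteTrace", function(x) x@sites)

setMethod("show", "BisulfiteTrace", function(object) {
  cat(
    "BisulfiteTrace:", object@regionId, "/", object@sampleId,
    sprintf("(%s);", object@group),
    sum(object@sites$site_type == "cpg"), "CpG site(s),",
    sum(object@sites$site_type == "non_cpg_c"), "non-CpG C site(s)\n"
  )
})

#' HPLC mononucleotide peak profile
#'
#' Peak areas for the five standard deoxynucleotides plus uracil, with
#' optional molar response factors, used for global 5-methylcytosine
#' quantification.
#'
#' @slot areas named numeric vector with entries \code{dA}, \code{dC},
#'   \code{dG}, \code{dT}, \code{m5dC}, \code{U}.
#' @slot responseFactors named numeric vector of per-peak response factors
#'   (areas are divided by these before ratioing).
#'
#' @export
setClass("HplcProfile",
  representation(areas = "numeric", responseFactors = "numeric")
)

.hplcPeaks <- c("dA", "dC", "dG", "dT", "m5dC", "U")

setValidity("HplcProfile", function(object) {
  if (!all(.hplcPeaks %in% names(object@areas))) {
    return(paste("areas must be named with:", paste(.hplcPeaks, collapse = ", ")))
  }
  if (any(object@areas < 0)) return("areas must be >= 0")
  if (any(object@responseFactors <= 0)) {
    return("response factors must be > 0")
  }
  TRUE
})

#' @param areas,responseFactors see slots; factors default to 1.
#' @return An \code{HplcProfile}.
#' @rdname HplcProfile-class
#' @export
HplcProfile <- function(areas, responseFactors = NULL) {
  if (is.null(responseFactors)) {
    responseFactors <- stats::setNames(rep(1, length(.hplcPeaks)), .hplcPeaks)
  }
  new("HplcProfile",
    areas = areas[.hplcPeaks],
    responseFactors = responseFactors[.hplcPeaks]
  )
}

#' @describeIn HplcProfile-class peak areas.
#' @param x,object An \code{HplcProfile}.
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))
#' @rdname HplcProfile-class
#' @export
setMethod("peakAreas", "HplcProfile", function(x) x@areas)

setMethod("show", "HplcProfile", function(object) {
  cat("HplcProfile:\n")
  print(round(object@areas, 4))
})
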