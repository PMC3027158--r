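---
title: "Methods: CpG-island tiling-array design and MeDIP-chip analysis"
author: "medipTile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG-island tiling-array design and MeDIP-chip analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipTile)
```

# Scope

`medipTile` implements the computational side of a promoter CpG-island
(CGI) methylation-profiling workflow built around methyl-DNA
immunoprecipitation (MeDIP) hybridized to a custom two-channel tiling
microarray, together with the two orthogonal quantification methods that
typically accompany such a study: direct bisulfite-sequencing PCR (BSP)
trace quantification and HPLC-based global 5-methylcytosine measurement.
The package covers five stages:

1. **CGI prediction** in strand-aware promoter windows (`findCgis`,
   `promoterWindows`, `promoterCgis`);
2. **tiling-probe design** with genome-uniqueness filtering
   (`tileProbes`, `specificityFilter`, `buildDesign`);
3. **two-channel analysis** — normalization, filtering, differential
   calling, median-relative classes, PCA quality control, term
   enrichment, expression concordance (`normalizeToControl`,
   `filterProbes`, `differentialProbes`, `medianClasses`, `pcaScores`,
   `termEnrichment`, `expressionOverlap`);
4. **bisulfite-trace and HPLC quantification** (`siteMethylation`,
   `regionMethylation`, `conversionQc`, `compareRegions`,
   `globalMethylationPercent`);
5. a **deterministic simulator** of genomes, methylation states, array
   channels, traces and HPLC profiles (`makeGenome`, `makeMethylation`,
   `simulateArray`, `simulateTraces`, `simulateHplc`,
   `makeExampleStudy`) so that every downstream stage is testable
   without external data.

# CGI prediction

Islands are called with the classical windowed criteria: a sliding
window of `windowLen` = 200 bp qualifies when its G+C fraction is at
least `gcMin` = 0.50 and its observed/expected CpG ratio

$$\mathrm{OE} = \frac{N_{CpG} \cdot L}{N_C \cdot N_G}$$

is at least `oeMin` = 0.60. We use the *covered-union* construction: a
position belongs to an island iff at least one qualifying window
overlaps it, islands are maximal runs of covered positions, and each
island's GC/OE are recomputed over its full span. Islands failing the
recomputed thresholds, or shorter than `minIslandLen` = 200 bp, are
dropped rather than trimmed — dropping is simpler, and the dual
recomputation guards against unions whose interior is carried by a few
strong windows. This construction was chosen over
merge-then-shrink alternatives because it is unambiguous and directly
testable against a brute-force per-window oracle; the test suite checks
coordinate-identical agreement on hundreds of randomized sequences
(2–3 kb, with planted islands and masked tracts), and the same check is
re-run by `scripts/acceptance.R`.

Windows containing any soft-masked (lowercase) or ambiguous base are
disqualified outright. Genome sequences are therefore carried in
case-preserving containers (`BStringSet`); note that `DNAStringSet`
folds lowercase input to uppercase and would silently erase the
masking.

Promoter windows span 1.5 kb upstream to 1 kb downstream of each
transcript 5′ end (the putative TSS), mirrored on the minus strand so
that the 1.5 kb arm is always transcriptionally upstream, clipped at
chromosome bounds. With a 0-based TSS $t$, the plus-strand window is
$[t-1500,\, t+1000)$ and the minus-strand window $[t-999,\, t+1501)$.
When several transcripts of a gene share a 5′ end, identical windows are
collapsed; an island overlapping the windows of two genes is reported
under both. Internally all island coordinates are 0-based half-open;
`islandToOneBased` converts to the 1-based inclusive convention of
published tables.

# Probe design

Probes of `probeLen` = 60 nt start at the island start and every
`step` = 25 bp; if the stepped series stops short of the island end,
one extra probe is right-anchored at `end − probeLen`, which guarantees
the island is covered end to end ("average spacing of 25 bp" is thus
realized as fixed stepping plus one anchor). A 385 bp island yields 14
probes. Islands shorter than a probe get a single probe centered on the
island and extended into unmasked flanks when available; when flanks
are masked or truncated by the chromosome, the island is skipped with a
logged reason, never silently.

Genome uniqueness is enforced at `uniqLen` = 55 nt resolution: a probe
is removed iff any of its six 55-mers occurs at more than one genomic
location, counting both strands and counting the probe's own locus
once. We filter by exact 55-mer occurrence counting (Biostrings
dictionary matching) rather than alignment: it is deterministic,
dependency-free, and directly captures the "identical 55-bp alignment"
criterion; near-identical (54/55) matches are deliberately not chased.
The 55-mer counting is validated against a brute-force substring-table
oracle on a 500 kb genome with an engineered duplication. Odd k-mer
lengths cannot be reverse-complement palindromes, so double-counting a
self-complementary site only needs handling when `uniqLen` is set even
(the counter special-cases it).

`buildDesign` adds manufacturer control and blank feature counts, so
`totalFeatures()` reproduces printed-slide accounting (for instance
43,960 probes + 1,227 controls + 33 blanks = 45,220 features), and the
manifest writer/reader round-trips designs exactly.

# Two-channel analysis

The Cy5 channel carries the immunoprecipitated test sample, Cy3 the
genomic reference pool. Per probe and sample the raw ratio is
`cy5/cy3`; entries with a non-positive reference are invalidated.
Normalization divides each probe's ratios by the mean raw ratio of the
control-group *biological* samples, so control means are exactly 1 and
fold changes read directly off the normalized values. This per-probe
reading of "normalized to the mean of the control group" is an
interpretation (a per-array scalar is the alternative); it was chosen
because it makes the fold-change cut interpretable probe by probe.
Positive (fully methylated) and negative (amplified, unmethylated)
control samples are excluded from the reference mean and from testing
but participate in presence counting and PCA.

Filters, in order, with defaults from the GeneSpring-style workflow:

| rule | default | applied to |
|---|---|---|
| presence | flagged present in ≥ 4 samples | detection flags |
| intensity | mean raw Cy5 ≥ 25 | biological samples |
| variability | sd of normalized ratios ≤ 1.4 | within each biological group |

The intensity rule uses the mean across biological samples (the
per-sample alternative is not distinguishable from the workflow
description), and the variability rule is evaluated per group, either
group failing removes the probe. An audit table records removals per
rule.

Differential probes are called with a Welch two-sample t-test between
tumor and control normalized ratios plus a fold-change cut:
hypermethylated iff `fc ≥ 1.5` and `p < 0.05`, hypomethylated iff
`fc ≤ 1/1.5` and `p < 0.05`. Tests run on the linear ratio scale by
default (matching the original workflow's convention), with
`log2scale = TRUE` available. No multiple-testing correction is applied
at the probe level — the workflow this reproduces reported raw
p-values gated by the fold filter — while term enrichment does use
Benjamini-Hochberg FDR. Genes aggregate their significant probes and
keep discordant directions visible (`mixed`), since real promoter CGIs
do carry probes moving in both directions.

A calibration note: the Welch–Satterthwaite test is conservative at
n = 4 per group. Monte-Carlo at 100,000 replicates on Gaussian nulls
puts its true size near 0.042 at a nominal 0.05, and near 0.039 on the
simulated ratio nulls here; `scripts/acceptance.R` reports the observed
rate (`null_p_rate`). This is a property of the statistic, shared by
`stats::t.test`, not an implementation artifact — the package's Welch
implementation agrees with `stats::t.test` and with the closed-form
textbook formulas to 10⁻¹⁰ or better in the tests.

`medianClasses` reproduces the control-sample methylation-level view:
per-gene mean signal across control biological samples, classed at
least 2-fold above the gene-median as higher-methylated and at most
half of it as lower-methylated, boundaries included. `pcaScores` runs
PCA with samples as observations on mean-centered, unscaled data, with
a deterministic sign convention (the largest-magnitude loading per
component is made positive) so repeated runs are identical.
`expressionOverlap` books the funnel expression-significant → has
promoter CGI → represented on the array → methylation-significant and
reports the concordance percentage among co-represented genes.

# Bisulfite-trace and HPLC quantification

Direct sequencing of bisulfite-converted PCR products reads methylated
cytosines as C and unmethylated ones as T, so per-site methylation is
`100·C/(C+T)` from the trace peak areas, and a region is the unweighted
mean over its non-missing CpG sites (sites with both areas zero are
excluded, not imputed). Conversion QC pools non-CpG cytosines — which
must read as T after complete conversion — and requires a pooled rate
of ≥ 0.98 by default; with no non-CpG cytosine in the amplicon the QC
is reported unavailable rather than passed. Group comparisons pool
per-site percentages across replicates within tumor and control and
apply the Welch test; because neighboring CpGs on one amplicon are not
independent, this pseudoreplicates and the p-value is optimistic — the
same caveat applies to any per-site pooled comparison of trace data.
The `classifyRegion` cutoffs (≤ 10% unmethylated, ≥ 90% methylated)
operationalize the qualitative calls "completely un-methylated /
completely methylated" used in screen readouts.

Global methylation from HPLC is simplified to response-factor-corrected
peak-area proportion, `100·A(5mdC)/(A(5mdC)+A(dC))`; chromatographic
details of the underlying protocol are out of scope, and response
factors default to 1 but are configurable. A nonzero uracil peak warns
about RNA contamination (uracil serves as the RNA reference peak).

# The simulator and what it does (not) emulate

The simulator exists so that the pipeline's claims are testable without
external downloads; its defaults are the package's study conditions and
were fixed up front.

**Genome** (`makeGenome`): background drawn from a first-order Markov
model with G+C 0.40 and CpG observed/expected 0.20 (vertebrate-like CpG
depletion); one island per gene planted uniformly within its promoter
window, with island GC drawn from 0.60–0.70, OE from 0.80–1.05 and
length from 250–800 bp; 10% of the background soft-masked in 200–1000 bp
tracts. Planted islands are redrawn (bounded retries) until the realized
whole-span statistics reach their drawn targets and every interior
200 bp window meets the 0.50/0.60 detection thresholds. This is the
generator's *planting guarantee*: a planted island is a real island
under the windowed definition, which is what makes truth-recovery tests
meaningful. Same configuration (including its seed) gives byte-identical
FASTA/GFF3/BED output; each generator stage derives its own RNG
sub-stream from the seed and the operation name so stages stay
decoupled.

**Methylation** (`makeMethylation`): baselines from a two-component
mixture — low 0.05 for the typical unmethylated promoter CGI, high 0.9
for a fully methylated minority (probability 0.1 by default, echoing
screens in which a single region out of ~14 turns out methylated).
Tumor effects multiply or divide the odds `m/(1−m)` by `effectFold`,
which keeps fractions in [0, 1]; a 0.9 baseline shifted down 2.5-fold
becomes 0.9/(0.9 + 2.5·0.1) ≈ 0.783. Hypomethylation is planted on the
most-methylated baselines and hypermethylation on the least-methylated
ones, because each needs headroom in its direction. Positive-control
samples are overridden to m = 1 everywhere and negative controls to
m = 0.

**Array signal** (`simulateArray`): Cy5 = B·(α + β·m)·ε and Cy3 = B·ε′,
with per-probe affinity B lognormal (log-sd 0.5) shared across samples
and ε multiplicative lognormal noise of unit mean and CV 0.15. The
affine form is the simplest model consistent with the two calibration
endpoints a MeDIP array provides: a uniform low non-specific signal on
the amplified negative control (α = 20) and a uniformly high signal on
the fully methylated positive control (α + β = 1020). The present flag
is Cy5 above a detection threshold (40 by default) — a stand-in for
scanner-software detection calls, which are not otherwise defined.
With zero noise, `(cy5/cy3 − α)/β` recovers the truth to machine
precision (tested).

A deliberate consequence of the affine response: an odds-scale fold
near the top of the methylation scale barely moves the signal ratio
(0.9 → 0.783 is only a 0.88× signal fold), so strongly methylated
regions losing methylation 2.5-fold on the odds scale are *not*
detectable at a 1.5-fold signal cut. `makeExampleStudy` therefore
plants hypo effects at baseline 0.25 and hyper effects at 0.05, where
the same odds fold expresses as a ≈ 2× signal fold. Real MeDIP data
behave the same way — saturation compresses folds at high methylation —
and this is documented rather than hidden.

**What the simulator does not emulate:** dye bias, spatial artifacts,
probe cross-hybridization and sequence-dependent affinity, read-level
bisulfite chemistry (no AB1 chromatograms), biological co-methylation
structure along chromosomes, and any quantitative noise
characterization of a specific scanner. Passing tests demonstrate
correct computation and calibrated recovery under this idealized model,
not performance on any particular laboratory dataset.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to make the statistics
stable while staying desk-scale: 100 randomized 2–3 kb sequences for
the CGI oracle; a 500 kb genome with one engineered 200 bp duplication
for the uniqueness filter; 10,000 probes with 4 + 4 samples for the
null calibration; 10,000 probes (500 hypo at 2.5-fold, 100 hyper) with
6 + 6 biological samples for recovery — 6 per group because, at channel
CV 0.15, the joint fold-and-p rule at 4 per group caps sensitivity near
0.76 by the fold-estimate noise alone, and the recovery experiment is
meant to measure the pipeline, not that ceiling; the PCA check uses the
cohort layout of a typical study (4 tumor, 4 control, 1 positive, 1
negative). Ties and degenerate cases are pinned by convention: Welch
with two identical constant groups returns t = 0, p = 1; OE of a window
with no C or no G is 0; zero-variance PCA returns all-zero scores;
`medianClasses` includes its boundaries; missing trace sites are
excluded rather than imputed.

# Known limitations

- The windowed CGI definition is the classical one; stricter modern
  definitions (longer windows, higher thresholds, HMM-based callers)
  will call fewer, longer islands. Only promoter-window calling is
  first-class.
- Probe-level inference uses raw p-values with a fold gate; genome-wide
  error control is intentionally left to the enrichment stage.
- The uniqueness filter is exact-match; a 54/55 near-duplicate passes.
- Trace quantification assumes peak areas proportional to base
  incorporation, a semi-quantitative approximation of real four-dye
  chemistry.
- The group comparison of trace data pseudoreplicates sites, as noted
  above.
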