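#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# synthetic-data classes
# ---------------------------------------------------------------------------

#' Repeat-unit architecture parameters for the synthetic fibroin generator
#'
#' Describes one H-fibroin repeat unit as the four ordered motif regions found
#' in bagworm silk: a poly-alanine run with a central glutamic acid
#' (`(A)nE(A)n`), a pure `(GA)n` region, a short isoleucine/valine linker, and
#' a serine-containing `(GA)n` region. Defaults correspond to the canonical
#' bagworm architecture: a 23-residue poly-A-E motif (`polyAHalfLen = 11`),
#' 40-residue pure GA and 90-residue GA-S regions.
#'
#' @slot nUnits number of repeat units in the tandem array.
#' @slot polyAHalfLen residues of each alanine run flanking the central E.
#' @slot gaPureLen residues of the pure GA region (even, starts with G).
#' @slot linkerLen residues of the I/V linker.
#' @slot gaSerLen residues of the serine-containing GA region (even).
#' @slot serRate fraction of the GA-S region's alanine capacity replaced by
#'   serine; serines are placed deterministically at evenly spaced block
#'   centres so boundaries stay unambiguous.
#' @slot jitter per-unit multiplicative half-width of length noise, applied to
#'   the GA and linker regions only (the poly-A-E motif length is conserved
#'   across bagworm species and is held fixed).
#' @slot terminalLen length of each unique terminal domain (0 disables them).
#'
#' @seealso [architectureParams()], [generateFibroinProtein()]
#' @exportClass ArchitectureParams
setClass("ArchitectureParams",
  slots = c(
    nUnits = "integer",
    polyAHalfLen = "integer",
    gaPureLen = "integer",
    linkerLen = "integer",
    gaSerLen = "integer",
    serRate = "numeric",
    jitter = "numeric",
    terminalLen = "integer"
  )
)

setValidity("ArchitectureParams", function(object) {
  if (!.isCount(object@nUnits, 1)) return("nUnits must be an integer >= 1")
  if (!.isCount(object@polyAHalfLen, 1)) {
    return("polyAHalfLen must be an integer >= 1")
  }
  if (!.isCount(object@gaPureLen, 2) || object@gaPureLen %% 2 != 0) {
    return("gaPureLen must be an even integer >= 2")
  }
  if (!.isCount(object@linkerLen, 2)) {
    return("linkerLen must be an integer >= 2")
  }
  if (!.isCount(object@gaSerLen, 2) || object@gaSerLen %% 2 != 0) {
    return("gaSerLen must be an even integer >= 2")
  }
  if (!.isNumber(object@serRate) || object@serRate <= 0 ||
      object@serRate > 0.5) {
    return("serRate must satisfy 0 < serRate <= 0.5")
  }
  if (!.isNumber(object@jitter) || object@jitter < 0 || object@jitter >= 0.5) {
    return("jitter must satisfy 0 <= jitter < 0.5")
  }
  if (!.isCount(object@terminalLen, 0)) {
    return("terminalLen must be an integer >= 0")
  }
  TRUE
})

#' Construct architecture parameters
#'
#' @param nUnits,polyAHalfLen,gaPureLen,linkerLen,gaSerLen,serRate,jitter,terminalLen
#'   see the slots of [ArchitectureParams-class].
#' @return an `ArchitectureParams` object.
#' @examples
#' architectureParams(nUnits = 1, polyAHalfLen = 5, gaPureLen = 8,
#'                    linkerLen = 5, gaSerLen = 10, serRate = 0.4,
#'                    jitter = 0, terminalLen = 0)
#' @export
architectureParams <- function(nUnits = 5, polyAHalfLen = 11, gaPureLen = 40,
                               linkerLen = 6, gaSerLen = 90, serRate = 0.25,
                               jitter = 0.1, terminalLen = 120) {
  methods::new("ArchitectureParams",
    nUnits = as.integer(nUnits), polyAHalfLen = as.integer(polyAHalfLen),
    gaPureLen = as.integer(gaPureLen), linkerLen = as.integer(linkerLen),
    gaSerLen = as.integer(gaSerLen), serRate = as.numeric(serRate),
    jitter = as.numeric(jitter), terminalLen = as.integer(terminalLen))
}

#' A simulated fibroin gene with ground-truth annotation
#'
#' Holds the designed protein, optionally its coding sequence, and the exact
#' spans of the terminal domains, repeat units and motif regions, against
#' which curation and segmentation are tested.
#'
#' @slot geneId gene identifier.
#' @slot protein the designed amino-acid sequence ([Biostrings::AAString]).
#' @slot cds the coding sequence; empty until built by [generateFibroinGene()].
#' @slot nTermSpan,cTermSpan spans of the unique terminal domains in protein
#'   coordinates (empty when terminals are disabled).
#' @slot unitSpans spans of the repeat units, tiling the repetitive domain.
#' @slot regionTruth an [IRanges::IRanges] with metadata columns `motif` and
#'   `unit`: the ground-truth segmentation.
#' @exportClass SimulatedFibroinGene
setClass("SimulatedFibroinGene",
  slots = c(
    geneId = "character",
    protein = "AAString",
    cds = "DNAString",
    nTermSpan = "IRanges",
    cTermSpan = "IRanges",
    unitSpans = "IRanges",
    regionTruth = "IRanges"
  )
)

setValidity("SimulatedFibroinGene", function(object) {
  p <- .seqChar(object@protein)
  if (length(object@cds) > 0) {
    if (length(object@cds) != 3L * nchar(p)) {
      return("cds length must be 3 x protein length")
    }
    tr <- as.character(Biostrings::translate(object@cds))
    if (tr != p) return("translate(cds) must equal protein")
  }
  truth <- object@regionTruth
  mc <- S4Vectors::mcols(truth)
  if (length(truth) > 0) {
    if (is.null(mc$motif) || is.null(mc$unit)) {
      return("regionTruth needs 'motif' and 'unit' metadata columns")
    }
    if (!all(mc$motif %in% .CANONICAL_MOTIFS)) {
      return("regionTruth motifs must be canonical motif types")
    }
    for (u in unique(mc$unit)) {
      sub <- truth[mc$unit == u]
      ord <- match(S4Vectors::mcols(sub)$motif, .CANONICAL_MOTIFS)
      if (is.unsorted(ord, strictly = TRUE)) {
        return("regionTruth motifs within a unit must follow canonical order")
      }
      if (any(diff(IRanges::start(sub)) <= 0)) {
        return("regionTruth intervals within a unit must be ordered")
      }
    }
  }
  us <- object@unitSpans
  if (length(us) > 1) {
    gaps <- IRanges::start(us)[-1] - IRanges::end(us)[-length(us)]
    if (any(gaps != 1L)) return("unitSpans must tile without gaps or overlaps")
  }
  TRUE
})

#' Short-read simulation parameters
#'
#' Substitution-only error model over uniformly placed, optionally
#' strand-flipped reads; 150 bp reads emulate the Illumina short reads the
#' curation algorithm is designed for. No indels, pairing or quality model:
#' the curation algorithm consumes reads individually and ignores qualities.
#'
#' @slot readLength read length in bases.
#' @slot coverage mean fold-coverage of the template.
#' @slot errorRate per-base substitution probability (< 0.1).
#' @slot rngSeed seed making the simulation bit-reproducible.
#' @slot bothStrands if `TRUE` each read is reverse-complemented with
#'   probability 1/2.
#' @exportClass ReadSimParams
setClass("ReadSimParams",
  slots = c(
    readLength = "integer",
    coverage = "numeric",
    errorRate = "numeric",
    rngSeed = "integer",
    bothStrands = "logical"
  )
)

setValidity("ReadSimParams", function(object) {
  if (!.isCount(object@readLength, 1)) {
    return("readLength must be an integer >= 1")
  }
  if (!.isNumber(object@coverage) || object@coverage <= 0) {
    return("coverage must be a positive number")
  }
  if (!.isNumber(object@errorRate) || object@errorRate < 0 ||
      object@errorRate >= 0.1) {
    return("errorRate must satisfy 0 <= errorRate < 0.1")
  }
  if (!.isCount(object@rngSeed, 0)) return("rngSeed must be an integer >= 0")
  if (!is.logical(object@bothStrands) || length(object@bothStrands) != 1L) {
    return("bothStrands must be a single logical")
  }
  TRUE
})

#' @rdname ReadSimParams-class
#' @param readLength,coverage,errorRate,rngSeed,bothStrands see slots.
#' @return a `ReadSimParams` object.
#' @export
readSimParams <- function(readLength = 150, coverage = 30, errorRate = 0,
                          rngSeed = 1, bothStrands = TRUE) {
  methods::new("ReadSimParams",
    readLength = as.integer(readLength), coverage = as.numeric(coverage),
    errorRate = as.numeric(errorRate), rngSeed = .checkSeed(rngSeed),
    bothStrands = bothStrands)
}

# ---------------------------------------------------------------------------
# curation classes
# ---------------------------------------------------------------------------

#' Configuration of the seed-extension curation algorithm
#'
#' The "strict threshold" of the seed-extension strategy is quantified by
#' `minDepth` and `minDominantFrac`; `k` is the exact-match k-mer used to
#' harvest reads ("extremely large" relative to typical assembler k-mers:
#' half a 150 bp read by default).
#'
#' @slot k k-mer length in bases used for exact-match read harvesting.
#' @slot minDepth minimum reads voting in a PWM column.
#' @slot minDominantFrac minimum fraction of the modal base in a column;
#'   threshold comparisons are inclusive (`>=`).
#' @slot maxExtension hard cap on appended bases.
#' @slot repeatWindow k-mer length used for repeat-entry detection
#'   (`NA` means "same as `k`").
#' @exportClass CurationConfig
setClass("CurationConfig",
  slots = c(
    k = "integer",
    minDepth = "integer",
    minDominantFrac = "numeric",
    maxExtension = "integer",
    repeatWindow = "integer"
  )
)

setValidity("CurationConfig", function(object) {
  if (!.isCount(object@k, 1)) return("k must be an integer >= 1")
  if (!.isCount(object@minDepth, 1)) return("minDepth must be an integer >= 1")
  if (!.isNumber(object@minDominantFrac) || object@minDominantFrac <= 0.5 ||
      object@minDominantFrac > 1) {
    return("minDominantFrac must satisfy 0.5 < minDominantFrac <= 1")
  }
  if (!.isCount(object@maxExtension, 1)) {
    return("maxExtension must be an integer >= 1")
  }
  if (!is.na(object@repeatWindow) && !.isCount(object@repeatWindow, 1)) {
    return("repeatWindow must be NA or an integer >= 1")
  }
  TRUE
})

#' @rdname CurationConfig-class
#' @param k,minDepth,minDominantFrac,maxExtension,repeatWindow see slots.
#' @return a `CurationConfig` object.
#' @export
curationConfig <- function(k = 75, minDepth = 3, minDominantFrac = 0.9,
                           maxExtension = 10000, repeatWindow = NA) {
  methods::new("CurationConfig",
    k = as.integer(k), minDepth = as.integer(minDepth),
    minDominantFrac = as.numeric(minDominantFrac),
    maxExtension = as.integer(maxExtension),
    repeatWindow = as.integer(repeatWindow))
}

#' A terminal seed for curation
#'
#' A contig (fragment) homologous to a fibroin N- or C-terminal domain,
#' strand-normalised so that extension proceeds 3'-ward on the stored
#' sequence.
#'
#' @slot seedId seed identifier.
#' @slot sequence the strand-normalised nucleotide sequence.
#' @slot sourceContig id of the contig the seed came from.
#' @slot strand `"+"` or `"-"`; `"-"` means the stored sequence is the
#'   reverse complement of the source contig.
#' @slot alignmentScore local-alignment score against the reference terminus.
#' @exportClass FibroinSeed
setClass("FibroinSeed",
  slots = c(
    seedId = "character",
    sequence = "DNAString",
    sourceContig = "character",
    strand = "character",
    alignmentScore = "numeric"
  )
)

setValidity("FibroinSeed", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  TRUE
})

#' Result of seed extension
#'
#' @slot sequence curated nucleotide sequence (starts with the seed).
#' @slot support per-appended-base support track: `data.frame` with columns
#'   `position` (1-based position in the curated sequence), `base`, `depth`
#'   and `dominantFrac`.
#' @slot termination one of `NO_READS`, `LOW_DEPTH`, `AMBIGUOUS`,
#'   `REPEAT_DETECTED`, `MAX_LENGTH`.
#' @slot rounds number of harvest/call iterations performed.
#' @slot seedLength length of the original seed within `sequence`.
#' @exportClass ExtensionResult
setClass("ExtensionResult",
  slots = c(
    sequence = "DNAString",
    support = "data.frame",
    termination = "character",
    rounds = "integer",
    seedLength = "integer"
  )
)

setValidity("ExtensionResult", function(object) {
  if (!object@termination %in% .TERMINATIONS) {
    return(sprintf("termination must be one of %s",
                   paste(.TERMINATIONS, collapse = ", ")))
  }
  if (nrow(object@support) !=
      length(object@sequence) - object@seedLength) {
    return("support must have one row per appended base")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# motif-architecture classes
# ---------------------------------------------------------------------------

#' Segmentation tolerances
#'
#' @slot minPolyARun minimum consecutive alanines to open a poly-A anchor
#'   (4 by default, so the isolated alanines of a GA region can never seed
#'   one).
#' @slot minLinkerRun minimum consecutive I/V residues for a linker anchor.
#' @slot maxImpurityFrac tolerated fraction of non-canonical residues inside
#'   a GA region.
#' @slot requireSer whether a post-linker GA region must contain at least one
#'   serine to be typed `GA_SER` (else it is left `UNASSIGNED`).
#' @exportClass SegConfig
setClass("SegConfig",
  slots = c(
    minPolyARun = "integer",
    minLinkerRun = "integer",
    maxImpurityFrac = "numeric",
    requireSer = "logical"
  )
)

setValidity("SegConfig", function(object) {
  if (!.isCount(object@minPolyARun, 1)) {
    return("minPolyARun must be an integer >= 1")
  }
  if (!.isCount(object@minLinkerRun, 1)) {
    return("minLinkerRun must be an integer >= 1")
  }
  if (!.isNumber(object@maxImpurityFrac) || object@maxImpurityFrac < 0 ||
      object@maxImpurityFrac >= 0.5) {
    return("maxImpurityFrac must satisfy 0 <= maxImpurityFrac < 0.5")
  }
  if (!is.logical(object@requireSer) || length(object@requireSer) != 1L) {
    return("requireSer must be a single logical")
  }
  TRUE
})

#' @rdname SegConfig-class
#' @param minPolyARun,minLinkerRun,maxImpurityFrac,requireSer see slots.
#' @return a `SegConfig` object.
#' @export
segConfig <- function(minPolyARun = 4, minLinkerRun = 2,
                      maxImpurityFrac = 0.1, requireSer = TRUE) {
  methods::new("SegConfig",
    minPolyARun = as.integer(minPolyARun),
    minLinkerRun = as.integer(minLinkerRun),
    maxImpurityFrac = as.numeric(maxImpurityFrac),
    requireSer = requireSer)
}

#' Motif segmentation of a fibroin protein
#'
#' An ordered, non-overlapping typing of every residue of a protein into the
#' four repeat-motif regions plus `TERMINAL` (before the first / after the
#' last anchored region) and `UNASSIGNED` (inter-anchor gaps failing the
#' composition checks).
#'
#' @slot proteinId identifier of the segmented protein.
#' @slot protein the protein sequence.
#' @slot regions an [IRanges::IRanges] with metadata column `motif`, sorted,
#'   disjoint, jointly covering the protein.
#' @slot repeatDomain span of the repetitive domain (empty if no anchors).
#' @exportClass Segmentation
setClass("Segmentation",
  slots = c(
    proteinId = "character",
    protein = "AAString",
    regions = "IRanges",
    repeatDomain = "IRanges"
  )
)

setValidity("Segmentation", function(object) {
  reg <- object@regions
  mc <- S4Vectors::mcols(reg)
  if (length(reg) > 0 && (is.null(mc$motif) ||
                          !all(mc$motif %in% .MOTIF_TYPES))) {
    return("regions need a 'motif' metadata column with valid motif types")
  }
  if (sum(IRanges::width(reg)) != length(object@protein)) {
    return("regions must jointly cover the protein")
  }
  if (length(reg) > 1) {
    if (any(IRanges::start(reg)[-1] !=
            IRanges::end(reg)[-length(reg)] + 1L)) {
      return("regions must be sorted, disjoint and contiguous")
    }
  }
  TRUE
})

#' One repeat unit of a segmented fibroin
#'
#' @slot unitIndex 1-based index of the unit along the repetitive domain.
#' @slot spans the typed intervals of the unit (an [IRanges::IRanges] with a
#'   `motif` metadata column, in canonical order; trailing types may be
#'   missing in a final partial unit).
#' @slot unitSpan the interval covered by the unit.
#' @exportClass RepeatUnit
setClass("RepeatUnit",
  slots = c(
    unitIndex = "integer",
    spans = "IRanges",
    unitSpan = "IRanges"
  )
)

setValidity("RepeatUnit", function(object) {
  mc <- S4Vectors::mcols(object@spans)
  if (length(object@spans) == 0) return("a repeat unit needs at least 1 span")
  ord <- match(mc$motif, .CANONICAL_MOTIFS)
  if (anyNA(ord) || is.unsorted(ord, strictly = TRUE)) {
    return("unit spans must be canonical motif types in canonical order")
  }
  if (mc$motif[1] != "POLY_A_E") return("a unit must open with POLY_A_E")
  TRUE
})

#' Per-species motif architecture statistics
#'
#' @slot lengthStats `data.frame` of per species x motif length statistics
#'   (`n`, `mean`, `median`, `q1`, `q3`).
#' @slot aaFreq matrix of amino-acid frequencies of the repetitive domain,
#'   one row per species, 20 columns summing to 1.
#' @slot crystallinity `data.frame` of per-species predicted crystalline
#'   fractions.
#' @exportClass ArchitectureStats
setClass("ArchitectureStats",
  slots = c(
    lengthStats = "data.frame",
    aaFreq = "matrix",
    crystallinity = "data.frame"
  )
)

# ---------------------------------------------------------------------------
# statistics classes
# ---------------------------------------------------------------------------

#' Pearson correlation result
#'
#' @slot r product-moment correlation coefficient.
#' @slot n sample size.
#' @slot p two-sided p-value from the t-transform with n - 2 df.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(r = "numeric", n = "integer", p = "numeric"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
  if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
  TRUE
})

#' Welch two-sample t-test result
#'
#' @slot t test statistic.
#' @slot df Welch-Satterthwaite degrees of freedom.
#' @slot p two-sided p-value.
#' @slot groupMeans the two group means.
#' @exportClass TTestResult
setClass("TTestResult",
  slots = c(t = "numeric", df = "numeric", p = "numeric",
            groupMeans = "numeric"))

setValidity("TTestResult", function(object) {
  if (object@df <= 0) return("df must be > 0")
  if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
  TRUE
})

#' Crystallinity-mechanics trend result
#'
#' @slot property name of the mechanical property analysed.
#' @slot r Pearson correlation of species-mean property vs crystalline
#'   fraction.
#' @slot p two-sided p-value of the correlation.
#' @slot slope least-squares slope, in property units per unit crystalline
#'   fraction.
#' @slot monotoneDecreasing `TRUE` iff species ranked by crystalline fraction
#'   have strictly decreasing property means.
#' @slot speciesMeans the joined per-species table the trend was computed on.
#' @exportClass TrendResult
setClass("TrendResult",
  slots = c(property = "character", r = "numeric", p = "numeric",
            slope = "numeric", monotoneDecreasing = "logical",
            speciesMeans = "data.frame"))

# ---------------------------------------------------------------------------
# pipeline config
# ---------------------------------------------------------------------------

#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations of the demonstration pipeline
#' (simulate, curate, annotate, stats) with a single global seed from which
#' every stochastic stage derives its own.
#'
#' @slot geneId identifier for the simulated gene.
#' @slot arch [ArchitectureParams-class] of the simulated gene.
#' @slot readSim [ReadSimParams-class] for read simulation (its `rngSeed` is
#'   overridden by a seed derived from `rngSeed`).
#' @slot curation [CurationConfig-class] for seed extension.
#' @slot seg [SegConfig-class] for motif segmentation.
#' @slot mech named list of arguments to [generateMechDataset()].
#' @slot rngSeed global seed.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(
    geneId = "character",
    arch = "ArchitectureParams",
    readSim = "ReadSimParams",
    curation = "CurationConfig",
    seg = "SegConfig",
    mech = "list",
    rngSeed = "integer"
  )
)

#' @rdname PipelineConfig-class
#' @param geneId,arch,readSim,curation,seg,mech,rngSeed see slots.
#' @return a `PipelineConfig` object.
#' @export
pipelineConfig <- function(geneId = "synthetic_fibroin",
                           arch = architectureParams(),
                           readSim = readSimParams(),
                           curation = curationConfig(),
                           seg = segConfig(),
                           mech = list(),
                           rngSeed = 1) {
  methods::new("PipelineConfig", geneId = geneId, arch = arch,
               readSim = readSim, curation = curation, seg = seg,
               mech = mech, rngSeed = .checkSeed(rngSeed))
}
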