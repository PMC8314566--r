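#' @include AllClasses.R
NULL

#' Accessors for fibroinArch objects
#'
#' Small accessor generics so that slot layout stays private: sequences,
#' interval annotations and curation support can be read without `@`.
#'
#' @param x a fibroinArch object.
#' @return `proteinSequence` / `cdsSequence` / `curatedSequence` return the
#'   corresponding [Biostrings::XString]; `regionTruth`, `regions`,
#'   `unitSpans`, `motifSpans` return [IRanges::IRanges] (with a `motif`
#'   metadata column where applicable); `repeatDomainSpan` an `IRanges`;
#'   `supportTrack` a `data.frame`; `termination` a string;
#'   `repetitiveDomain` an [Biostrings::AAString].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))
#' @rdname accessors
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))
#' @rdname accessors
#' @export
setGeneric("regionTruth", function(x) standardGeneric("regionTruth"))
#' @rdname accessors
#' @export
setGeneric("unitSpans", function(x) standardGeneric("unitSpans"))
#' @rdname accessors
#' @export
setGeneric("curatedSequence", function(x) standardGeneric("curatedSequence"))
#' @rdname accessors
#' @export
setGeneric("supportTrack", function(x) standardGeneric("supportTrack"))
#' @rdname accessors
#' @export
setGeneric("termination", function(x) standardGeneric("termination"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("repeatDomainSpan", function(x) {
  standardGeneric("repeatDomainSpan")
})
#' @rdname accessors
#' @export
setGeneric("repetitiveDomain", function(x) {
  standardGeneric("repetitiveDomain")
})
#' @rdname accessors
#' @export
setGeneric("motifSpans", function(x) standardGeneric("motifSpans"))

#' Predicted crystalline fraction of repeat units
#'
#' Fraction of a repeat unit assigned to the beta-sheet-forming (crystalline)
#' regions: the poly-A-E motif plus the pure GA region; the I/V linker and
#' the serine-containing GA region form the amorphous remainder. For a whole
#' segmentation (or a list of them) the value is the length-weighted mean
#' over repeat units.
#'
#' @param x a [RepeatUnit-class], a [Segmentation-class], or a list of either.
#' @param ... unused.
#' @return a numeric fraction in `[0, 1]`.
#' @export
setGeneric("crystallineFraction", function(x, ...) {
  standardGeneric("crystallineFraction")
})

# ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("proteinSequence", "SimulatedFibroinGene", function(x) x@protein)
#' @rdname accessors
setMethod("proteinSequence", "Segmentation", function(x) x@protein)
#' @rdname accessors
setMethod("cdsSequence", "SimulatedFibroinGene", function(x) x@cds)
#' @rdname accessors
setMethod("regionTruth", "SimulatedFibroinGene", function(x) x@regionTruth)
#' @rdname accessors
setMethod("unitSpans", "SimulatedFibroinGene", function(x) x@unitSpans)
#' @rdname accessors
setMethod("curatedSequence", "ExtensionResult", function(x) x@sequence)
#' @rdname accessors
setMethod("supportTrack", "ExtensionResult", function(x) x@support)
#' @rdname accessors
setMethod("termination", "ExtensionResult", function(x) x@termination)
#' @rdname accessors
setMethod("regions", "Segmentation", function(x) x@regions)
#' @rdname accessors
setMethod("repeatDomainSpan", "Segmentation", function(x) x@repeatDomain)
#' @rdname accessors
setMethod("motifSpans", "RepeatUnit", function(x) x@spans)

#' @rdname accessors
setMethod("repetitiveDomain", "Segmentation", function(x) {
  dom <- x@repeatDomain
  if (length(dom) == 0) return(Biostrings::AAString(""))
  Biostrings::subseq(x@protein, IRanges::start(dom), IRanges::end(dom))
})

# ---- show methods --------------------------------------------------------

setMethod("show", "ArchitectureParams", function(object) {
  cat("ArchitectureParams:", object@nUnits, "unit(s) of",
      sprintf("polyA-E %d | GA %d | linker %d | GA-S %d aa",
              2L * object@polyAHalfLen + 1L, object@gaPureLen,
              object@linkerLen, object@gaSerLen),
      sprintf("(serRate %.2f, jitter %.2f, terminals %d aa)\n",
              object@serRate, object@jitter, object@terminalLen))
})

setMethod("show", "SimulatedFibroinGene", function(object) {
  cat("SimulatedFibroinGene", object@geneId, "\n")
  cat("  protein:", length(object@protein), "aa; cds:",
      length(object@cds), "nt\n")
  cat("  units:", length(object@unitSpans), "| truth regions:",
      length(object@regionTruth), "\n")
})

setMethod("show", "FibroinSeed", function(object) {
  cat(sprintf("FibroinSeed %s (%s strand %s, score %.1f, %d nt)\n",
              object@seedId, object@sourceContig, object@strand,
              object@alignmentScore, length(object@sequence)))
})

setMethod("show", "ExtensionResult", function(object) {
  cat(sprintf(
    "ExtensionResult: %d nt (seed %d + %d appended), %s after %d rounds\n",
    length(object@sequence), object@seedLength, nrow(object@support),
    object@termination, object@rounds))
})

setMethod("show", "Segmentation", function(object) {
  mc <- S4Vectors::mcols(object@regions)$motif
  cat("Segmentation of", object@proteinId,
      sprintf("(%d aa)\n", length(object@protein)))
  if (length(object@repeatDomain) > 0) {
    cat(sprintf("  repetitive domain: [%d, %d]\n",
                IRanges::start(object@repeatDomain),
                IRanges::end(object@repeatDomain)))
  }
  tab <- table(factor(mc, levels = .MOTIF_TYPES))
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "RepeatUnit", function(object) {
  cat(sprintf("RepeatUnit %d [%d, %d]: %s\n", object@unitIndex,
              IRanges::start(object@unitSpan), IRanges::end(object@unitSpan),
              paste(S4Vectors::mcols(object@spans)$motif,
                    IRanges::width(object@spans),
                    sep = ":", collapse = " ")))
})

setMethod("show", "ArchitectureStats", function(object) {
  cat("ArchitectureStats:", nrow(object@aaFreq), "species\n")
  print(object@lengthStats, row.names = FALSE)
  cat("crystalline fractions:\n")
  print(object@crystallinity, row.names = FALSE)
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson correlation: r = %.4f (n = %d, p = %.3g)\n",
              object@r, object@n, object@p))
})

setMethod("show", "TTestResult", function(object) {
  cat(sprintf(
    "Welch t-test: t = %.4f, df = %.2f, p = %.3g (means %.3f vs %.3f)\n",
    object@t, object@df, object@p,
    object@groupMeans[1], object@groupMeans[2]))
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf(
    "Trend of %s vs crystalline fraction: r = %.3f (p = %.3g), slope = %.1f%s\n",
    object@property, object@r, object@p, object@slope,
    if (object@monotoneDecreasing) ", strictly decreasing" else ""))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig for", object@geneId, "(seed", object@rngSeed, ")\n")
})
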