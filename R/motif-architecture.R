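#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# translation
# ---------------------------------------------------------------------------

#' Translate the longest open reading frame of a curated transcript
#'
#' Scans the three forward frames (curated transcripts are sense-stranded),
#' preferring the longest stop-free ORF that starts at ATG; when no frame
#' contains one, the longest stop-free frame fragment is returned instead.
#' Ties are broken by the lowest frame index, then the leftmost start.
#'
#' @param cds nucleotide sequence (character or [Biostrings::DNAString]).
#' @param minCodons minimum acceptable length of the best ORF/fragment.
#' @return a [Biostrings::AAString].
#' @export
translateLongestOrf <- function(cds, minCodons = 10) {
  s <- .seqChar(cds)
  if (nchar(s) < 3L) .stopf("sequence too short to translate")
  candidates <- list()
  for (f in 0:2) {
    len <- 3L * ((nchar(s) - f) %/% 3L)
    if (len < 3L) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, f + 1L, f + len)),
      if.fuzzy.codon = "X"))
    # stop-free segments of the frame, with their start offset (in aa)
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    off <- 0L
    for (seg in segs) {
      if (nchar(seg) > 0) {
        mStart <- regexpr("M", seg, fixed = TRUE)
        candidates[[length(candidates) + 1L]] <- list(
          frame = f, start = off + 1L, seq = seg,
          orf = if (mStart > 0) substr(seg, mStart, nchar(seg)) else NULL,
          orfStart = if (mStart > 0) off + as.integer(mStart) else NA_integer_)
      }
      off <- off + nchar(seg) + 1L
    }
  }
  if (length(candidates) == 0) .stopf("no translatable frame found")

  pick <- function(items, lens, frames, starts) {
    ord <- order(-lens, frames, starts)
    items[[ord[1]]]
  }
  withOrf <- Filter(function(c) !is.null(c$orf), candidates)
  best <- if (length(withOrf) > 0) {
    pick(lapply(withOrf, `[[`, "orf"),
         vapply(withOrf, function(c) nchar(c$orf), numeric(1)),
         vapply(withOrf, `[[`, numeric(1), "frame"),
         vapply(withOrf, `[[`, numeric(1), "orfStart"))
  } else {
    pick(lapply(candidates, `[[`, "seq"),
         vapply(candidates, function(c) nchar(c$seq), numeric(1)),
         vapply(candidates, `[[`, numeric(1), "frame"),
         vapply(candidates, `[[`, numeric(1), "start"))
  }
  if (nchar(best) < minCodons) {
    .stopf("no frame yields an ORF/fragment of >= %d codons", minCodons)
  }
  Biostrings::AAString(best)
}

# ---------------------------------------------------------------------------
# segmentation
# ---------------------------------------------------------------------------

.compositionFrac <- function(s, letters) {
  chars <- strsplit(s, "")[[1]]
  sum(chars %in% letters) / length(chars)
}

# length of the maximal prefix of `s` drawn from `letters`
.prefixRun <- function(s, letters) {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% letters)
  if (length(bad) == 0) length(chars) else bad[1] - 1L
}

#' Segment a fibroin protein into its repeat-motif regions
#'
#' Anchor-based segmentation of the H-fibroin repetitive domain. An anchor
#' pass locates all poly-A-E regions (maximal alanine runs of at least
#' `minPolyARun`, optionally interrupted by exactly one glutamic acid with
#' qualifying alanine runs on both sides) and all I/V linker runs. Gaps
#' between a poly-A-E anchor and the following linker are typed `GA_PURE`;
#' gaps between a linker and the next poly-A-E are typed `GA_SER` -- gap
#' typing is positional, composition only validates it (a gap whose
#' canonical-residue fraction falls below `1 - maxImpurityFrac`, or a
#' post-linker gap without serine when `requireSer`, is left `UNASSIGNED`).
#' Residues before the first and after the last anchored region are
#' `TERMINAL`; after the final linker the maximal G/A/S prefix is still
#' typed `GA_SER` so the trailing repeat unit is not lost to the C-terminal
#' domain.
#'
#' @param protein amino-acid sequence (character, [Biostrings::AAString], or
#'   a [SimulatedFibroinGene-class]).
#' @param config a [SegConfig-class].
#' @param proteinId identifier stored in the result.
#' @return a [Segmentation-class]; a protein with no anchors yields an
#'   all-`TERMINAL` segmentation.
#' @examples
#' seg <- segmentRepetitiveDomain("AAAAAEAAAAAGAGAGAGAIVIVIGASGAGASGA")
#' regions(seg)
#' @export
segmentRepetitiveDomain <- function(protein, config = segConfig(),
                                    proteinId = "protein") {
  stopifnot(methods::is(config, "SegConfig"))
  methods::validObject(config)
  if (methods::is(protein, "SimulatedFibroinGene")) {
    if (identical(proteinId, "protein")) proteinId <- protein@geneId
    protein <- protein@protein
  }
  p <- .seqChar(protein)
  n <- nchar(p)
  if (n == 0) .stopf("protein must be non-empty")

  m <- config@minPolyARun
  polyA <- .regexRanges(p, sprintf("A{%d,}(?:EA{%d,})?", m, m))
  linker <- .regexRanges(p, sprintf("[IV]{%d,}", config@minLinkerRun))

  anchors <- c(polyA, linker)
  types <- c(rep("POLY_A_E", length(polyA)), rep("LINKER_IV", length(linker)))
  ord <- order(IRanges::start(anchors))
  anchors <- anchors[ord]
  types <- types[ord]

  # Boundary disambiguation: a GA region ends on ...GA, so its final alanine
  # is swallowed by the maximal A-run of the following poly-A anchor, leaving
  # the gap with a dangling G. When an internal linker->poly-A gap ends in G,
  # give one alanine back to the gap (only if the anchor's leading A-run
  # stays above minPolyARun).
  aStart <- IRanges::start(anchors)
  aEnd <- IRanges::end(anchors)
  for (i in seq_along(anchors)) {
    if (types[i] == "POLY_A_E" && i > 1L && types[i - 1L] == "LINKER_IV" &&
        aStart[i] > aEnd[i - 1L] + 1L &&
        substr(p, aStart[i] - 1L, aStart[i] - 1L) == "G") {
      lead <- attr(regexpr("^A+", substr(p, aStart[i], aEnd[i])),
                   "match.length")
      if (lead > m) aStart[i] <- aStart[i] + 1L
    }
  }
  anchors <- IRanges::IRanges(start = aStart, end = aEnd)

  starts <- ends <- integer(0)
  motifs <- character(0)
  addRegion <- function(s, e, motif) {
    starts <<- c(starts, s); ends <<- c(ends, e); motifs <<- c(motifs, motif)
  }

  if (length(anchors) == 0) {
    addRegion(1L, n, "TERMINAL")
  } else {
    aStart <- IRanges::start(anchors)
    aEnd <- IRanges::end(anchors)
    if (aStart[1] > 1L) addRegion(1L, aStart[1] - 1L, "TERMINAL")
    for (i in seq_along(anchors)) {
      addRegion(aStart[i], aEnd[i], types[i])
      gapS <- aEnd[i] + 1L
      gapE <- if (i < length(anchors)) aStart[i + 1L] - 1L else n
      if (gapE < gapS) next
      gap <- substr(p, gapS, gapE)
      if (i < length(anchors)) {
        pair <- c(types[i], types[i + 1L])
        if (identical(pair, c("POLY_A_E", "LINKER_IV"))) {
          ok <- .compositionFrac(gap, c("G", "A")) >=
            1 - config@maxImpurityFrac
          addRegion(gapS, gapE, if (ok) "GA_PURE" else "UNASSIGNED")
        } else if (identical(pair, c("LINKER_IV", "POLY_A_E"))) {
          ok <- .compositionFrac(gap, c("G", "A", "S")) >=
            1 - config@maxImpurityFrac
          if (ok && config@requireSer && !grepl("S", gap, fixed = TRUE)) {
            ok <- FALSE
            warning("post-linker GA region without serine left UNASSIGNED",
                    call. = FALSE)
          }
          addRegion(gapS, gapE, if (ok) "GA_SER" else "UNASSIGNED")
        } else {
          addRegion(gapS, gapE, "UNASSIGNED")
        }
      } else if (types[i] == "LINKER_IV") {
        # trailing gap after the last linker: the maximal G/A/S prefix is the
        # final unit's serine-containing GA region, the rest is TERMINAL
        q <- .prefixRun(gap, c("G", "A", "S"))
        if (q > 0) {
          pre <- substr(gap, 1L, q)
          ok <- !config@requireSer || grepl("S", pre, fixed = TRUE)
          if (!ok) {
            warning("post-linker GA region without serine left UNASSIGNED",
                    call. = FALSE)
          }
          addRegion(gapS, gapS + q - 1L, if (ok) "GA_SER" else "UNASSIGNED")
        }
        if (gapS + q <= gapE) addRegion(gapS + q, gapE, "TERMINAL")
      } else {
        addRegion(gapS, gapE, "TERMINAL")
      }
    }
  }

  reg <- IRanges::IRanges(start = starts, end = ends)
  S4Vectors::mcols(reg) <- S4Vectors::DataFrame(motif = motifs)
  nonTerm <- which(motifs != "TERMINAL")
  dom <- if (length(nonTerm) > 0) {
    IRanges::IRanges(min(starts[nonTerm]), max(ends[nonTerm]))
  } else IRanges::IRanges()

  methods::new("Segmentation",
    proteinId = proteinId,
    protein = Biostrings::AAString(p),
    regions = reg,
    repeatDomain = dom)
}

#' Decompose a segmentation into repeat units
#'
#' A unit opens at each `POLY_A_E` region and collects the contiguous run of
#' canonically ordered regions that follows it, closing before the next
#' `POLY_A_E`. A trailing partial unit is kept with its missing types
#' absent.
#'
#' @param seg a [Segmentation-class].
#' @return a list of [RepeatUnit-class] objects (possibly empty).
#' @export
splitRepeatUnits <- function(seg) {
  stopifnot(methods::is(seg, "Segmentation"))
  reg <- seg@regions
  motifs <- S4Vectors::mcols(reg)$motif
  openers <- which(motifs == "POLY_A_E")
  units <- list()
  for (u in seq_along(openers)) {
    i <- openers[u]
    take <- i
    rank <- 1L  # POLY_A_E
    j <- i + 1L
    while (j <= length(reg)) {
      r <- match(motifs[j], .CANONICAL_MOTIFS)
      if (is.na(r) || r <= rank) break
      take <- c(take, j)
      rank <- r
      j <- j + 1L
    }
    spans <- reg[take]
    units[[u]] <- methods::new("RepeatUnit",
      unitIndex = u,
      spans = spans,
      unitSpan = IRanges::IRanges(min(IRanges::start(spans)),
                                  max(IRanges::end(spans))))
  }
  units
}

# ---------------------------------------------------------------------------
# statistics over architectures
# ---------------------------------------------------------------------------

.asSegList <- function(x) {
  if (methods::is(x, "Segmentation")) return(list(x))
  stopifnot(is.list(x))
  x
}

#' Motif-length statistics per species
#'
#' Collects the lengths of every canonical motif region across the
#' segmentations of each species and summarises them (the tabular analogue
#' of per-motif length boxplots). A final partial unit contributes only the
#' types it contains, so type means are not deflated by truncation.
#'
#' @param segsBySpecies named list: one [Segmentation-class] (or list of
#'   them) per species.
#' @return a `data.frame` with columns `species`, `motif`, `n`, `mean`,
#'   `median`, `q1`, `q3`, ordered by species then motif; types absent in a
#'   species get an `n = 0` row with `NA` statistics.
#' @export
motifLengthStats <- function(segsBySpecies) {
  if (is.null(names(segsBySpecies)) || any(names(segsBySpecies) == "")) {
    .stopf("segsBySpecies must be a named list (one entry per species)")
  }
  rows <- list()
  for (sp in sort(names(segsBySpecies))) {
    segs <- .asSegList(segsBySpecies[[sp]])
    lens <- list()
    for (seg in segs) {
      for (unit in splitRepeatUnits(seg)) {
        mc <- S4Vectors::mcols(unit@spans)$motif
        wd <- IRanges::width(unit@spans)
        for (i in seq_along(mc)) {
          lens[[mc[i]]] <- c(lens[[mc[i]]], wd[i])
        }
      }
    }
    for (motif in sort(.CANONICAL_MOTIFS)) {
      v <- lens[[motif]]
      rows[[length(rows) + 1L]] <- if (is.null(v)) {
        data.frame(species = sp, motif = motif, n = 0L, mean = NA_real_,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      } else {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(species = sp, motif = motif, n = length(v),
                   mean = mean(v), median = q[2], q1 = q[1], q3 = q[3])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amino-acid frequency of a protein region
#'
#' @param region non-empty amino-acid sequence (character or
#'   [Biostrings::AAString]).
#' @return a named numeric vector over the 20 standard residues, summing
#'   to 1.
#' @examples
#' aaFrequency("GAGA")[c("G", "A")]
#' @export
aaFrequency <- function(region) {
  s <- .seqChar(region)
  if (nchar(s) == 0) .stopf("region must be non-empty")
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad) > 0) {
    .stopf("non-standard residue(s): %s", paste(bad, collapse = ", "))
  }
  counts <- table(factor(chars, levels = .AA20))
  freq <- as.numeric(counts) / length(chars)
  names(freq) <- .AA20
  freq
}

#' @rdname crystallineFraction
setMethod("crystallineFraction", "RepeatUnit", function(x, ...) {
  mc <- S4Vectors::mcols(x@spans)$motif
  if (!all(c("POLY_A_E", "GA_PURE") %in% mc)) {
    .stopf("unit %d lacks a POLY_A_E or GA_PURE span", x@unitIndex)
  }
  wTot <- IRanges::width(x@unitSpan)
  if (wTot == 0) .stopf("zero-length unit")
  wCryst <- sum(IRanges::width(x@spans)[mc %in% c("POLY_A_E", "GA_PURE")])
  wCryst / wTot
})

setMethod("crystallineFraction", "Segmentation", function(x, ...) {
  units <- splitRepeatUnits(x)
  if (length(units) == 0) .stopf("segmentation contains no repeat units")
  crystallineFraction(units)
})

setMethod("crystallineFraction", "list", function(x, ...) {
  # length-weighted mean over repeat units (lists of units or segmentations)
  units <- list()
  for (el in x) {
    units <- c(units, if (methods::is(el, "RepeatUnit")) list(el) else {
      splitRepeatUnits(el)
    })
  }
  if (length(units) == 0) .stopf("no repeat units supplied")
  wTot <- vapply(units, function(u) IRanges::width(u@unitSpan), numeric(1))
  fr <- vapply(units, crystallineFraction, numeric(1))
  sum(fr * wTot) / sum(wTot)
})

#' Summarise the motif architecture of several species
#'
#' Bundles per-species motif-length statistics, amino-acid frequency vectors
#' of the repetitive domains, and predicted crystalline fractions.
#'
#' @inheritParams motifLengthStats
#' @return an [ArchitectureStats-class].
#' @export
architectureStats <- function(segsBySpecies) {
  lengthStats <- motifLengthStats(segsBySpecies)
  species <- sort(names(segsBySpecies))
  freq <- t(vapply(species, function(sp) {
    segs <- .asSegList(segsBySpecies[[sp]])
    dom <- paste(vapply(segs, function(s) {
      as.character(repetitiveDomain(s))
    }, character(1)), collapse = "")
    aaFrequency(dom)
  }, numeric(20)))
  cryst <- data.frame(
    species = species,
    crystalline_fraction = vapply(species, function(sp) {
      crystallineFraction(.asSegList(segsBySpecies[[sp]]))
    }, numeric(1)),
    row.names = NULL)
  methods::new("ArchitectureStats", lengthStats = lengthStats,
               aaFreq = freq, crystallinity = cryst)
}
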