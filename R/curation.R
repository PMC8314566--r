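#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# seed finding
# ---------------------------------------------------------------------------

.asDNAStringSet <- function(x, what = "sequences") {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "XStringSet")) {
    return(Biostrings::DNAStringSet(as.character(x)))
  }
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(out))) names(out) <- paste0("seq_", seq_along(out))
    return(out)
  }
  .stopf("cannot interpret %s as a DNAStringSet", what)
}

# protein translations of the 3 forward frames of a nucleotide sequence,
# stops mapped to X so they can be aligned under BLOSUM62
.frameTranslations <- function(dna) {
  n <- length(dna)
  vapply(0:2, function(f) {
    len <- 3L * ((n - f) %/% 3L)
    if (len < 3L) return("")
    aa <- Biostrings::translate(Biostrings::subseq(dna, f + 1L, f + len),
                                if.fuzzy.codon = "X")
    gsub("\\*", "X", as.character(aa))
  }, character(1))
}

#' Find terminal seed candidates by local alignment
#'
#' Screens assembly contigs for fragments homologous to reference fibroin
#' N/C-terminal sequences using Smith-Waterman local alignment (the in-R
#' analogue of the BLAST screen used to pick terminal seeds). Both strands
#' are searched; in `translated` mode all three reading frames per strand
#' are translated and scored against a protein reference under BLOSUM62.
#' Contigs reaching `minScore` are returned as strand-normalised seeds,
#' sorted by score (ties broken by contig id).
#'
#' @param contigs contig sequences ([Biostrings::DNAStringSet] or named
#'   character).
#' @param termini reference terminus sequences: nucleotide in `nucleotide`
#'   mode, protein ([Biostrings::AAStringSet] or character) in `translated`
#'   mode.
#' @param minScore minimum local-alignment score for a seed.
#' @param mode alignment mode. Nucleotide mode scores match +2 / mismatch -3
#'   with affine gaps (opening 5, extension 2, charged as
#'   `opening + n * extension` for an n-base gap); translated mode uses
#'   BLOSUM62 with gap opening 11 / extension 1.
#' @return a list of [FibroinSeed-class] objects (possibly empty).
#' @export
findTerminalSeeds <- function(contigs, termini, minScore = 60,
                              mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  contigs <- .asDNAStringSet(contigs, "contigs")
  if (length(contigs) == 0) .stopf("no contigs supplied")

  if (mode == "nucleotide") {
    termini <- .asDNAStringSet(termini, "termini")
    if (length(termini) == 0) .stopf("no reference termini supplied")
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE)
    scoreSet <- function(set) {
      apply(vapply(seq_along(termini), function(j) {
        Biostrings::pairwiseAlignment(
          set, termini[[j]], type = "local", substitutionMatrix = mat,
          gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
      }, numeric(length(set))), 1L, max)
    }
    plus <- scoreSet(contigs)
    minus <- scoreSet(Biostrings::reverseComplement(contigs))
  } else {
    termini <- if (methods::is(termini, "XStringSet")) {
      as.character(termini)
    } else as.character(termini)
    if (length(termini) == 0) .stopf("no reference termini supplied")
    termini <- toupper(termini)
    data("BLOSUM62", package = "Biostrings", envir = environment())
    blosum <- get("BLOSUM62", envir = environment())
    scoreOne <- function(dna) {
      frames <- .frameTranslations(dna)
      frames <- frames[nchar(frames) > 0]
      if (length(frames) == 0) return(-Inf)
      max(vapply(frames, function(fr) {
        max(vapply(termini, function(tm) {
          Biostrings::pairwiseAlignment(
            Biostrings::AAString(fr), Biostrings::AAString(tm),
            type = "local", substitutionMatrix = blosum,
            gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
        }, numeric(1)))
      }, numeric(1)))
    }
    plus <- vapply(seq_along(contigs), function(i) scoreOne(contigs[[i]]),
                   numeric(1))
    minus <- vapply(seq_along(contigs), function(i) {
      scoreOne(Biostrings::reverseComplement(contigs[[i]]))
    }, numeric(1))
  }

  best <- pmax(plus, minus)
  strand <- ifelse(minus > plus, "-", "+")
  keep <- which(best >= minScore)
  if (length(keep) == 0) return(list())

  ids <- names(contigs)[keep]
  ord <- order(-best[keep], ids)
  keep <- keep[ord]
  lapply(keep, function(i) {
    seqi <- if (strand[i] == "-") {
      Biostrings::reverseComplement(contigs[[i]])
    } else contigs[[i]]
    methods::new("FibroinSeed",
      seedId = paste0(names(contigs)[i], "_seed"),
      sequence = Biostrings::DNAString(as.character(seqi)),
      sourceContig = names(contigs)[i],
      strand = strand[i],
      alignmentScore = best[i])
  })
}

# ---------------------------------------------------------------------------
# read harvesting and PWM
# ---------------------------------------------------------------------------

# reads in both orientations as plain character vectors; minus-orientation
# entries carry the reverse-complemented sequence
.orientedReads <- function(reads, bothStrands) {
  reads <- .asDNAStringSet(reads, "reads")
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  out <- data.frame(readId = ids,
                    sequence = as.character(reads),
                    orientation = "+",
                    stringsAsFactors = FALSE)
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(reads))
    out <- rbind(out, data.frame(readId = ids, sequence = rc,
                                 orientation = "-",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Harvest reads matching the terminal k-mer of a growing sequence
#'
#' Returns every read (and, when `bothStrands`, every reverse-complemented
#' read) containing the terminal `k`-mer of `growing` as an exact substring,
#' anchored at the match. A read matching in both orientations is reported
#' once per orientation, and a read matching at several positions
#' contributes one anchor per position. Offsets are 0-based: `offset` is the
#' position of the read's first base in the coordinate system of `growing`,
#' so the terminal k-mer starts at read position `(len(growing) - k) -
#' offset`. Reads whose anchored extent ends at or before the growing 3'
#' end are still returned (they simply contribute no PWM votes).
#'
#' @param growing the current curated sequence (character or
#'   [Biostrings::DNAString]), at least `k` long.
#' @param reads short reads ([Biostrings::DNAStringSet] or character).
#' @param k exact-match k-mer length; must not exceed the read length.
#' @param bothStrands also search reverse-complemented reads.
#' @return an [S4Vectors::DataFrame] with columns `readId`, `orientation`,
#'   `offset` and `sequence` (orientation-normalised).
#' @export
harvestMatchingReads <- function(growing, reads, k, bothStrands = TRUE) {
  g <- .seqChar(growing)
  n <- nchar(g)
  if (!.isCount(k, 1)) .stopf("k must be a positive integer")
  if (n < k) .stopf("growing sequence (%d nt) is shorter than k = %d", n, k)
  oriented <- .orientedReads(reads, bothStrands)
  if (any(k > nchar(oriented$sequence))) {
    .stopf("k = %d exceeds the length of at least one read", k)
  }
  kmer <- substr(g, n - k + 1L, n)
  hits <- Biostrings::vmatchPattern(
    kmer, Biostrings::DNAStringSet(oriented$sequence))
  starts <- Biostrings::startIndex(hits)
  nHits <- lengths(starts)
  idx <- rep.int(seq_len(nrow(oriented)), nHits)
  matchStart <- unlist(starts, use.names = FALSE)
  if (length(idx) == 0) {
    return(S4Vectors::DataFrame(readId = character(0),
                                orientation = character(0),
                                offset = integer(0),
                                sequence = character(0)))
  }
  S4Vectors::DataFrame(
    readId = oriented$readId[idx],
    orientation = oriented$orientation[idx],
    offset = (n - k) - (matchStart - 1L),
    sequence = oriented$sequence[idx])
}

#' Build a position weight matrix past the 3' end
#'
#' Column `j` (0-based coordinate `growingLen + j`) counts the base of every
#' anchored read covering that coordinate; columns are emitted until the
#' first coordinate no read reaches.
#'
#' @param anchored anchored reads as returned by [harvestMatchingReads()].
#' @param growingLen length of the growing sequence the anchors refer to.
#' @return a `data.frame` with columns `position` (0-based coordinate), `A`,
#'   `C`, `G`, `T` and `depth`; zero rows when nothing extends.
#' @export
buildPwm <- function(anchored, growingLen) {
  empty <- data.frame(position = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), depth = integer(0))
  if (length(anchored$offset) == 0) return(empty)
  offs <- anchored$offset
  seqs <- anchored$sequence
  lens <- nchar(seqs)
  cols <- list()
  j <- 0L
  repeat {
    coord <- growingLen + j
    covering <- which(offs <= coord & coord < offs + lens)
    if (length(covering) == 0) break
    bases <- substr(seqs[covering], coord - offs[covering] + 1L,
                    coord - offs[covering] + 1L)
    counts <- c(A = sum(bases == "A"), C = sum(bases == "C"),
                G = sum(bases == "G"), T = sum(bases == "T"))
    if (sum(counts) == 0) break
    cols[[j + 1L]] <- data.frame(position = coord, A = counts[["A"]],
                                 C = counts[["C"]], G = counts[["G"]],
                                 T = counts[["T"]], depth = sum(counts))
    j <- j + 1L
  }
  if (length(cols) == 0) return(empty)
  do.call(rbind, cols)
}

#' Call the consensus base of a PWM column
#'
#' The modal base is called iff the column depth reaches `minDepth` and the
#' modal fraction reaches `minDominantFrac` (both inclusive). Ties between
#' modal bases are never broken arbitrarily: they fail as `AMBIGUOUS`.
#'
#' @param column a one-row `data.frame` from [buildPwm()], or a named numeric
#'   vector of counts with names `A`, `C`, `G`, `T`.
#' @param config a [CurationConfig-class].
#' @return a single string: `"A"`, `"C"`, `"G"` or `"T"`, or the verdict
#'   `"LOW_DEPTH"` / `"AMBIGUOUS"`.
#' @export
callConsensus <- function(column, config = curationConfig()) {
  if (is.data.frame(column)) {
    counts <- c(A = column$A[1], C = column$C[1], G = column$G[1],
                T = column$T[1])
  } else {
    counts <- column[c("A", "C", "G", "T")]
  }
  .callColumn(counts, config)
}

.callColumn <- function(counts, config) {
  depth <- sum(counts)
  if (depth < config@minDepth) return("LOW_DEPTH")
  m <- max(counts)
  if (sum(counts == m) > 1L) return("AMBIGUOUS")
  if (m / depth < config@minDominantFrac) return("AMBIGUOUS")
  names(counts)[which.max(counts)]
}

# ---------------------------------------------------------------------------
# seed extension
# ---------------------------------------------------------------------------

# Exact k-mer hash index over oriented reads. Entries are encoded as
# (row - 1) * 1024 + position (1-based k-mer start), which bounds read
# length at 1023 bases -- ample for the short reads this algorithm consumes.
.kmerIndex <- function(orientedSeqs, k) {
  if (any(nchar(orientedSeqs) >= 1024L)) {
    .stopf("reads longer than 1023 bases are not supported")
  }
  env <- new.env(hash = TRUE, parent = emptyenv(), size = 2L^16)
  for (r in seq_along(orientedSeqs)) {
    s <- orientedSeqs[r]
    nk <- nchar(s) - k + 1L
    if (nk < 1L) next
    kms <- substring(s, seq_len(nk), seq.int(k, nchar(s)))
    enc <- (r - 1L) * 1024L + seq_len(nk)
    for (i in seq_len(nk)) {
      km <- kms[i]
      env[[km]] <- c(env[[km]], enc[i])
    }
  }
  env
}

#' Extend a terminal seed through short reads by PWM consensus
#'
#' Implements the seed-extension curation loop: reads containing the
#' terminal `k`-mer of the growing sequence as an exact match are harvested
#' and aligned on the 3' side of the match; the base past the 3' end is
#' called from the resulting position-weight-matrix column under the strict
#' depth/dominance threshold, and the sequence grows one base per call.
#' Reads are re-harvested at every appended base (via a prebuilt exact k-mer
#' index, so each harvest is a hash lookup).
#'
#' Extension terminates with:
#' \describe{
#'   \item{`NO_READS`}{no read anchors, or none extends past the 3' end;}
#'   \item{`LOW_DEPTH` / `AMBIGUOUS`}{the next column fails the threshold;}
#'   \item{`REPEAT_DETECTED`}{the terminal `repeatWindow`-mer that the next
#'     base would create already occurs at an earlier position of the
#'     curated sequence -- the operational signature of having entered the
#'     next repeat unit. The offending base is not appended;}
#'   \item{`MAX_LENGTH`}{`maxExtension` bases were appended.}
#' }
#'
#' Extension is strictly 3'-ward; to curate from the C-terminal side,
#' reverse-complement the seed and reads.
#'
#' @param seed a [FibroinSeed-class], or a sequence (character /
#'   [Biostrings::DNAString]) at least `k` long.
#' @param reads short reads ([Biostrings::DNAStringSet] or character).
#' @param config a [CurationConfig-class].
#' @param bothStrands harvest reverse-complemented reads too.
#' @return an [ExtensionResult-class].
#' @export
extendSeed <- function(seed, reads, config = curationConfig(),
                       bothStrands = TRUE) {
  stopifnot(methods::is(config, "CurationConfig"))
  methods::validObject(config)
  seedSeq <- if (methods::is(seed, "FibroinSeed")) {
    as.character(seed@sequence)
  } else {
    .seqChar(seed)
  }
  k <- config@k
  w <- if (is.na(config@repeatWindow)) k else config@repeatWindow
  n0 <- nchar(seedSeq)
  if (n0 < k) .stopf("seed (%d nt) is shorter than k = %d", n0, k)

  oriented <- .orientedReads(reads, bothStrands)
  if (any(k > nchar(oriented$sequence))) {
    .stopf("k = %d exceeds the length of at least one read", k)
  }
  idx <- .kmerIndex(oriented$sequence, k)
  readLens <- nchar(oriented$sequence)

  seen <- new.env(hash = TRUE, parent = emptyenv(), size = 2L^14)
  curated <- seedSeq
  n <- n0
  if (n >= w) {
    for (km in .kmers(curated, w)) seen[[km]] <- TRUE
  }

  posv <- basev <- depthv <- fracv <- NULL
  appended <- 0L
  rounds <- 0L
  term <- NULL
  repeat {
    rounds <- rounds + 1L
    kmer <- substr(curated, n - k + 1L, n)
    hits <- idx[[kmer]]
    if (is.null(hits)) { term <- "NO_READS"; break }
    ri <- hits %/% 1024L + 1L
    rp <- hits %% 1024L + k          # read position of the base past the 3' end
    ok <- rp <= readLens[ri]
    if (!any(ok)) { term <- "NO_READS"; break }
    bases <- substr(oriented$sequence[ri[ok]], rp[ok], rp[ok])
    counts <- c(A = sum(bases == "A"), C = sum(bases == "C"),
                G = sum(bases == "G"), T = sum(bases == "T"))
    if (sum(counts) == 0) { term <- "NO_READS"; break }
    call <- .callColumn(counts, config)
    if (call %in% c("LOW_DEPTH", "AMBIGUOUS")) { term <- call; break }

    if (n + 1L >= w) {
      prospective <- paste0(substr(curated, n - w + 2L, n), call)
      if (!is.null(seen[[prospective]])) { term <- "REPEAT_DETECTED"; break }
      seen[[prospective]] <- TRUE
    }
    curated <- paste0(curated, call)
    n <- n + 1L
    appended <- appended + 1L
    posv <- c(posv, n)
    basev <- c(basev, call)
    depthv <- c(depthv, sum(counts))
    fracv <- c(fracv, max(counts) / sum(counts))
    if (appended >= config@maxExtension) { term <- "MAX_LENGTH"; break }
  }

  support <- data.frame(
    position = as.integer(posv %||% integer(0)),
    base = as.character(basev %||% character(0)),
    depth = as.integer(depthv %||% integer(0)),
    dominantFrac = as.numeric(fracv %||% numeric(0)),
    stringsAsFactors = FALSE)

  methods::new("ExtensionResult",
    sequence = Biostrings::DNAString(curated),
    support = support,
    termination = term,
    rounds = rounds,
    seedLength = n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
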