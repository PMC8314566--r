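#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# protein / gene generation
# ---------------------------------------------------------------------------

# One GA-alternation starting with G; even length by construction.
.gaRun <- function(len) {
  substr(strrep("GA", len %/% 2L + 1L), 1L, len)
}

# GA alternation of arbitrary length, starting with G
.gaAlt <- function(len) {
  substr(strrep("GA", len %/% 2L + 1L), 1L, len)
}

# Serine-containing GA region: round(serRate * len / 2) serines placed at
# evenly spaced block centres of an even-length GA region, with the GA
# alternation re-phasing (restarting at G) after each serine, e.g.
# GA S GAGA S GA. Deterministic placement keeps region boundaries
# unambiguous and reproducible; serRate <= 0.5 guarantees the region still
# starts with G.
.gaSerRun <- function(len, serRate) {
  nS <- round(serRate * len / 2)
  if (nS == 0) return(.gaRun(len))
  pos <- floor((seq_len(nS) - 0.5) * len / nS) + 1L
  # keep the post-serine tail even so the region always closes on ...GA;
  # a region ending in a dangling G would blur the boundary with the next
  # unit's poly-A run
  trailing <- len - pos[nS]
  if (trailing %% 2L == 1L) {
    pos[nS] <- pos[nS] + (if (trailing == 1L) -1L else 1L)
  }
  out <- character(len)
  prevEnd <- 0L
  for (i in seq_len(nS)) {
    segLen <- pos[i] - prevEnd - 1L
    if (segLen > 0) {
      out[(prevEnd + 1L):(pos[i] - 1L)] <- strsplit(.gaAlt(segLen), "")[[1]]
    }
    out[pos[i]] <- "S"
    prevEnd <- pos[i]
  }
  if (prevEnd < len) {
    out[(prevEnd + 1L):len] <- strsplit(.gaAlt(len - prevEnd), "")[[1]]
  }
  paste(out, collapse = "")
}

.polyAERun <- function(halfLen) {
  paste0(strrep("A", halfLen), "E", strrep("A", halfLen))
}

.linkerRun <- function(len) {
  substr(strrep("IV", len %/% 2L + 1L), 1L, len)
}

# Random terminal domain: alanine capped at ~5% and never consecutive, no
# two consecutive I/V residues, so a synthetic terminal can never contain a
# poly-A or linker anchor. The N-terminal side may not end in A/E and the
# C-terminal side may not start with G/A/S/E, so terminals never extend an
# adjacent repeat-unit region. Draws from the current RNG stream.
.randomTerminalDomain <- function(len, side = c("N", "C")) {
  side <- match.arg(side)
  w <- stats::setNames(rep((1 - 0.05) / 19, 20), .AA20)
  w["A"] <- 0.05
  out <- character(len)
  prev <- ""
  for (i in seq_len(len)) {
    repeat {
      r <- sample(.AA20, 1L, prob = w)
      if (r == "A" && prev == "A") next
      if (r %in% c("I", "V") && prev %in% c("I", "V")) next
      if (side == "N" && i == len && r %in% c("A", "E")) next
      if (side == "C" && i == 1L && r %in% c("G", "A", "S", "E")) next
      break
    }
    out[i] <- r
    prev <- r
  }
  paste(out, collapse = "")
}

# Draw jittered region lengths for one unit. Jitter is multiplicative
# uniform on [1 - j, 1 + j] and applies to the GA regions and the linker
# only; the poly-A-E motif is held at its fixed length. GA lengths are
# rounded to the nearest even integer (>= 2) so regions keep starting with G
# and ending with A.
.unitLengths <- function(params) {
  j <- params@jitter
  if (j == 0) {
    return(list(gaPure = params@gaPureLen, linker = params@linkerLen,
                gaSer = params@gaSerLen))
  }
  f <- stats::runif(3L, 1 - j, 1 + j)
  list(
    gaPure = .evenize(params@gaPureLen * f[1]),
    linker = max(2L, as.integer(round(params@linkerLen * f[2]))),
    gaSer = .evenize(params@gaSerLen * f[3])
  )
}

#' Generate a synthetic fibroin protein with ground-truth motif annotation
#'
#' Builds an H-fibroin-like protein: two unique terminal domains flanking a
#' tandem array of repeat units, each unit the ordered concatenation of a
#' poly-alanine motif with a central glutamic acid, a pure GA region, an I/V
#' linker and a serine-containing GA region. The exact span and motif type
#' of every region is recorded as ground truth for recovery tests.
#'
#' @param params an [ArchitectureParams-class].
#' @param rngSeed integer seed; generation is bit-reproducible.
#' @param geneId identifier stored in the result.
#' @return a [SimulatedFibroinGene-class] with an empty CDS (see
#'   [generateFibroinGene()] for the nucleotide-level version).
#' @examples
#' p <- architectureParams(nUnits = 1, polyAHalfLen = 5, gaPureLen = 8,
#'                         linkerLen = 5, gaSerLen = 10, serRate = 0.4,
#'                         jitter = 0, terminalLen = 0)
#' as.character(proteinSequence(generateFibroinProtein(p)))
#' @export
generateFibroinProtein <- function(params = architectureParams(),
                                   rngSeed = 1, geneId = "synthetic_fibroin") {
  stopifnot(methods::is(params, "ArchitectureParams"))
  methods::validObject(params)
  rngSeed <- .checkSeed(rngSeed)

  withr::with_seed(rngSeed, {
    nterm <- if (params@terminalLen > 0) {
      .randomTerminalDomain(params@terminalLen, "N")
    } else ""
    unitParts <- lapply(seq_len(params@nUnits), function(i) {
      lens <- .unitLengths(params)
      list(
        POLY_A_E = .polyAERun(params@polyAHalfLen),
        GA_PURE = .gaRun(lens$gaPure),
        LINKER_IV = .linkerRun(lens$linker),
        GA_SER = .gaSerRun(lens$gaSer, params@serRate)
      )
    })
    cterm <- if (params@terminalLen > 0) {
      .randomTerminalDomain(params@terminalLen, "C")
    } else ""
  })

  pos <- nchar(nterm)
  starts <- ends <- integer(0)
  motifs <- character(0)
  units <- integer(0)
  unitStart <- unitEnd <- integer(0)
  for (i in seq_along(unitParts)) {
    unitStart[i] <- pos + 1L
    for (m in .CANONICAL_MOTIFS) {
      wid <- nchar(unitParts[[i]][[m]])
      starts <- c(starts, pos + 1L)
      ends <- c(ends, pos + wid)
      motifs <- c(motifs, m)
      units <- c(units, i)
      pos <- pos + wid
    }
    unitEnd[i] <- pos
  }

  protein <- paste0(nterm, paste(vapply(unitParts, function(u) {
    paste(unlist(u), collapse = "")
  }, character(1)), collapse = ""), cterm)

  truth <- IRanges::IRanges(start = starts, end = ends)
  S4Vectors::mcols(truth) <- S4Vectors::DataFrame(motif = motifs, unit = units)

  nTermSpan <- if (nchar(nterm) > 0) {
    IRanges::IRanges(1L, nchar(nterm))
  } else IRanges::IRanges()
  cTermSpan <- if (nchar(cterm) > 0) {
    IRanges::IRanges(nchar(protein) - nchar(cterm) + 1L, nchar(protein))
  } else IRanges::IRanges()

  methods::new("SimulatedFibroinGene",
    geneId = geneId,
    protein = Biostrings::AAString(protein),
    cds = Biostrings::DNAString(""),
    nTermSpan = nTermSpan, cTermSpan = cTermSpan,
    unitSpans = IRanges::IRanges(start = unitStart, end = unitEnd),
    regionTruth = truth)
}

# ---------------------------------------------------------------------------
# reverse translation
# ---------------------------------------------------------------------------

.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  tab <- split(names(gc), gc)
  lapply(tab, sort)
}

#' Reverse-translate a protein into a coding sequence
#'
#' @param protein amino-acid sequence over the 20 standard residues
#'   (character or [Biostrings::AAString]).
#' @param codonPolicy `"first_codon"` picks the alphabetically first codon of
#'   each residue (fully deterministic); `"uniform_random"` samples codons
#'   uniformly, reproducibly under `rngSeed`.
#' @param rngSeed seed for the `uniform_random` policy.
#' @return a [Biostrings::DNAString] whose standard-code translation equals
#'   `protein`.
#' @examples
#' as.character(reverseTranslate("M"))          # "ATG"
#' as.character(reverseTranslate("GA"))         # "GGAGCA"
#' @export
reverseTranslate <- function(protein,
                             codonPolicy = c("first_codon", "uniform_random"),
                             rngSeed = 1) {
  codonPolicy <- match.arg(codonPolicy)
  p <- .seqChar(protein)
  chars <- strsplit(p, "")[[1]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad) > 0) {
    .stopf("non-standard residue(s) in protein: %s",
           paste(bad, collapse = ", "))
  }
  tab <- .codonTable()
  codons <- if (codonPolicy == "first_codon") {
    vapply(tab[chars], `[`, character(1), 1L)
  } else {
    withr::with_seed(.checkSeed(rngSeed), {
      vapply(tab[chars], function(cs) cs[sample.int(length(cs), 1L)],
             character(1))
    })
  }
  Biostrings::DNAString(paste(codons, collapse = ""))
}

#' Generate a synthetic fibroin gene with its coding sequence
#'
#' Extends [generateFibroinProtein()] to the nucleotide level. The terminal
#' domains are reverse-translated with independent uniform-random codons,
#' while all repeat units share one per-unit codon stream (each unit is
#' reverse-translated under the same derived seed). Tandem repeat units are
#' therefore nucleotide-identical wherever their amino acids agree --
#' emulating the nucleotide homogeneity of recently expanded silk-gene
#' repeats -- yet free of short internal periodicity, which is what makes
#' entry into the next repeat unit detectable by exact k-mer recurrence
#' during curation.
#'
#' @inheritParams generateFibroinProtein
#' @param codonPolicy codon choice within each unit template and terminal;
#'   see [reverseTranslate()].
#' @return a [SimulatedFibroinGene-class] with a populated CDS.
#' @export
generateFibroinGene <- function(params = architectureParams(), rngSeed = 1,
                                geneId = "synthetic_fibroin",
                                codonPolicy = c("uniform_random",
                                                "first_codon")) {
  codonPolicy <- match.arg(codonPolicy)
  rngSeed <- .checkSeed(rngSeed)
  gene <- generateFibroinProtein(params, rngSeed = rngSeed, geneId = geneId)
  p <- .seqChar(gene@protein)

  # derived sub-seeds, kept within 32-bit range
  subSeed <- function(i) (rngSeed %% 1000000L) * 1000L + i
  unitSeed <- subSeed(1L)

  pieces <- character(0)
  if (length(gene@nTermSpan) > 0) {
    nterm <- substr(p, IRanges::start(gene@nTermSpan),
                    IRanges::end(gene@nTermSpan))
    pieces <- c(pieces, as.character(
      reverseTranslate(nterm, codonPolicy, rngSeed = subSeed(2L))))
  }
  for (i in seq_along(gene@unitSpans)) {
    unit <- substr(p, IRanges::start(gene@unitSpans)[i],
                   IRanges::end(gene@unitSpans)[i])
    pieces <- c(pieces, as.character(
      reverseTranslate(unit, codonPolicy, rngSeed = unitSeed)))
  }
  if (length(gene@cTermSpan) > 0) {
    cterm <- substr(p, IRanges::start(gene@cTermSpan),
                    IRanges::end(gene@cTermSpan))
    pieces <- c(pieces, as.character(
      reverseTranslate(cterm, codonPolicy, rngSeed = subSeed(3L))))
  }
  gene@cds <- Biostrings::DNAString(paste(pieces, collapse = ""))
  methods::validObject(gene)
  gene
}

# ---------------------------------------------------------------------------
# read simulation
# ---------------------------------------------------------------------------

#' Simulate uniform-coverage substitution-error short reads
#'
#' Read start positions are uniform over the valid range, the read count is
#' `round(coverage * length(template) / readLength)`, each read is
#' reverse-complemented with probability 1/2 when `bothStrands`, and
#' substitutions are i.i.d. per base to a uniformly chosen different base.
#' The true origin of every read is kept in the metadata columns (`start`,
#' 1-based on the template; `strand`; `nErrors`) for oracle tests.
#'
#' @param template nucleotide template (character or
#'   [Biostrings::DNAString]), at least one read length long.
#' @param params a [ReadSimParams-class].
#' @return a [Biostrings::DNAStringSet] of reads named `read_000001, ...`.
#' @export
simulateReads <- function(template, params = readSimParams()) {
  stopifnot(methods::is(params, "ReadSimParams"))
  methods::validObject(params)
  tmpl <- .seqChar(template)
  n <- nchar(tmpl)
  L <- params@readLength
  if (n < L) {
    .stopf("template (%d nt) is shorter than readLength (%d nt)", n, L)
  }
  nReads <- as.integer(round(params@coverage * n / L))

  withr::with_seed(params@rngSeed, {
    starts <- sample.int(n - L + 1L, nReads, replace = TRUE)
    revFlag <- if (params@bothStrands) {
      stats::runif(nReads) < 0.5
    } else rep(FALSE, nReads)
    seqs <- substring(tmpl, starts, starts + L - 1L)
    if (any(revFlag)) {
      rc <- Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[revFlag]))
      seqs[revFlag] <- as.character(rc)
    }
    nErr <- if (params@errorRate > 0) {
      stats::rbinom(nReads, L, params@errorRate)
    } else integer(nReads)
    if (any(nErr > 0)) {
      bases <- c("A", "C", "G", "T")
      for (i in which(nErr > 0)) {
        chars <- strsplit(seqs[i], "")[[1]]
        pos <- sample.int(L, nErr[i])
        for (j in pos) {
          chars[j] <- sample(setdiff(bases, chars[j]), 1L)
        }
        seqs[i] <- paste(chars, collapse = "")
      }
    }
  })

  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read_%06d", seq_len(nReads))
  S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
    start = starts,
    strand = ifelse(revFlag, "-", "+"),
    nErrors = nErr)
  reads
}

# ---------------------------------------------------------------------------
# mechanics tables
# ---------------------------------------------------------------------------

.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < 0
  }
  x
}

#' Generate synthetic fibre-mechanics and crystallinity tables
#'
#' Per-fibre tensile records are drawn from normal distributions truncated at
#' zero; species-mean tensile strengths follow a configurable linear
#' relationship in crystalline fraction
#' (`strengthIntercept + strengthSlope * fraction`, negative slope by
#' default, matching the observation that silks with a higher crystalline
#' fraction tend to be weaker). The default five species span the
#' crystalline-fraction and strength ranges typical of spider draglines down
#' to silkworm cocoon silk (roughly 1300 down to 700 MPa).
#'
#' @param species species labels.
#' @param crystallineFraction per-species crystalline fraction in `[0, 1]`.
#' @param nPerSpecies fibres measured per species.
#' @param strengthIntercept,strengthSlope line defining species-mean tensile
#'   strength (MPa) as a function of crystalline fraction.
#' @param strengthSd per-fibre SD of tensile strength (MPa).
#' @param modulusMean,modulusSd Young's modulus (GPa) mean and SD, recycled
#'   across species.
#' @param extensibilityMean,extensibilitySd extensibility (%) mean and SD.
#' @param toughnessMean,toughnessSd toughness (MJ/m3) mean and SD.
#' @param rngSeed integer seed.
#' @return a list with elements `mech` (`data.frame`: `species`,
#'   `tensile_strength`, `youngs_modulus`, `extensibility`, `toughness`; one
#'   row per fibre) and `cryst` (`data.frame`: `species`,
#'   `crystalline_fraction`).
#' @export
generateMechDataset <- function(species = paste0("species_", LETTERS[1:5]),
                                crystallineFraction = c(0.20, 0.28, 0.35,
                                                        0.42, 0.50),
                                nPerSpecies = 8,
                                strengthIntercept = 1700,
                                strengthSlope = -2000,
                                strengthSd = 50,
                                modulusMean = 8, modulusSd = 1,
                                extensibilityMean = 25, extensibilitySd = 3,
                                toughnessMean = 150, toughnessSd = 20,
                                rngSeed = 1) {
  nSp <- length(species)
  if (length(crystallineFraction) != nSp) {
    .stopf("need one crystallineFraction per species")
  }
  if (any(crystallineFraction < 0 | crystallineFraction > 1)) {
    .stopf("crystallineFraction values must lie in [0, 1]")
  }
  sds <- c(strengthSd, modulusSd, extensibilitySd, toughnessSd)
  if (any(sds < 0)) .stopf("standard deviations must be non-negative")
  nPerSpecies <- rep_len(as.integer(nPerSpecies), nSp)
  modulusMean <- rep_len(modulusMean, nSp)
  extensibilityMean <- rep_len(extensibilityMean, nSp)
  toughnessMean <- rep_len(toughnessMean, nSp)

  strengthMean <- strengthIntercept + strengthSlope * crystallineFraction
  withr::with_seed(.checkSeed(rngSeed), {
    rows <- lapply(seq_len(nSp), function(i) {
      ni <- nPerSpecies[i]
      data.frame(
        species = rep(species[i], ni),
        tensile_strength = .rtruncnorm0(ni, strengthMean[i], strengthSd),
        youngs_modulus = .rtruncnorm0(ni, modulusMean[i], modulusSd),
        extensibility = .rtruncnorm0(ni, extensibilityMean[i],
                                     extensibilitySd),
        toughness = .rtruncnorm0(ni, toughnessMean[i], toughnessSd),
        stringsAsFactors = FALSE)
    })
  })
  list(
    mech = do.call(rbind, rows),
    cryst = data.frame(species = species,
                       crystalline_fraction = crystallineFraction,
                       stringsAsFactors = FALSE)
  )
}
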