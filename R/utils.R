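# Internal helpers shared across modules. All user-facing coordinates for
# sequence intervals are IRanges (1-based, closed); file exports use the
# BED convention (0-based, half-open). Read-anchoring offsets follow the
# 0-based convention used throughout the curation module.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.MOTIF_TYPES <- c("POLY_A_E", "GA_PURE", "LINKER_IV", "GA_SER",
                  "TERMINAL", "UNASSIGNED")
.CANONICAL_MOTIFS <- .MOTIF_TYPES[1:4]
.TERMINATIONS <- c("NO_READS", "LOW_DEPTH", "AMBIGUOUS",
                   "REPEAT_DETECTED", "MAX_LENGTH")

.isCount <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == round(x) && x >= min
}

.isNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

# coerce sequence-ish inputs (XString, XStringSet element, character) to a
# single upper-case character scalar
.seqChar <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    .stopf("expected a single sequence (character or XString)")
  }
  toupper(unname(x))
}

.revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all k-mers of a string, in order of start position
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq.int(k, n))
}

# maximal matches of a regex as an IRanges
.regexRanges <- function(s, pattern) {
  m <- gregexpr(pattern, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(IRanges::IRanges())
  IRanges::IRanges(start = as.integer(m),
                   width = attr(m, "match.length"))
}

.letterFreq <- function(s, letters) {
  chars <- strsplit(s, "")[[1]]
  sum(chars %in% letters) / length(chars)
}

# round to nearest even integer, never below `min`
.evenize <- function(x, min = 2L) {
  max(min, 2L * round(x / 2))
}

.checkSeed <- function(rngSeed) {
  if (!.isCount(rngSeed, min = 0)) {
    .stopf("rngSeed must be a single non-negative integer")
  }
  as.integer(rngSeed)
}
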