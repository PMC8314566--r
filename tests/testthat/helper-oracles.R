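# Shared fixtures and independent oracles, built in code at test time.

TOY_PROTEIN <- "AAAAAEAAAAAGAGAGAGAIVIVIGASGAGASGA"

toyParams <- function() {
  architectureParams(nUnits = 1, polyAHalfLen = 5, gaPureLen = 8,
                     linkerLen = 5, gaSerLen = 10, serRate = 0.4,
                     jitter = 0, terminalLen = 0)
}

# architecture used for curation tests: many short units so that the
# (n-1)/n vote at the array-exit junction clears the 0.9 dominance
# threshold, total ~3 kb of CDS
curationArch <- function(nUnits = 17) {
  architectureParams(nUnits = nUnits, polyAHalfLen = 5, gaPureLen = 10,
                     linkerLen = 4, gaSerLen = 18, serRate = 0.25,
                     jitter = 0, terminalLen = 120)
}

randomDna <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

regionsDf <- function(ir) {
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir),
             motif = S4Vectors::mcols(ir)$motif,
             stringsAsFactors = FALSE)
}

canonicalRegions <- function(seg) {
  reg <- regions(seg)
  reg[S4Vectors::mcols(reg)$motif %in%
        c("POLY_A_E", "GA_PURE", "LINKER_IV", "GA_SER")]
}

# fraction of agreeing positions over the shared prefix
prefixIdentity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  mean(av == bv)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# quadratic-DP Smith-Waterman oracle, affine gaps charged as
# opening + n * extension (the convention of the implementation's scorer)
swOracle <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[, 1] <- 0
  M[1, ] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      M[i, j] <- max(M[i, j], 0)
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      best <- max(best, M[i, j])
    }
  }
  best
}

# naive O(N * L) read-anchoring oracle: scan every read (both orientations)
# for every occurrence of the terminal k-mer
naiveHarvest <- function(growing, reads, k) {
  n <- nchar(growing)
  kmer <- substr(growing, n - k + 1, n)
  out <- list()
  seqs <- as.character(reads)
  for (i in seq_along(seqs)) {
    for (orient in c("+", "-")) {
      s <- if (orient == "+") seqs[i] else revcomp(seqs[i])
      starts <- c()
      from <- 1
      repeat {
        hit <- regexpr(kmer, substr(s, from, nchar(s)), fixed = TRUE)
        if (hit == -1) break
        starts <- c(starts, from + hit - 1)
        from <- from + hit
      }
      for (st in starts) {
        out[[length(out) + 1]] <- data.frame(
          readId = names(reads)[i], orientation = orient,
          offset = (n - k) - (st - 1), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(readId = character(0), orientation = character(0),
                      offset = integer(0)))
  }
  do.call(rbind, out)
}
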