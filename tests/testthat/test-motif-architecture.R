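# ORF translation, motif segmentation, repeat-unit decomposition and
# architecture statistics.

test_that("translation picks the longest ATG-anchored ORF", {
  expect_identical(as.character(translateLongestOrf("ATGGCTGAA",
                                                    minCodons = 1)), "MAE")
  p <- withr::with_seed(61, paste(sample(strsplit(
    "ACDEFGHIKLNPQRSTVWY", "")[[1]], 30, replace = TRUE), collapse = ""))
  cds <- paste0("ATG", as.character(reverseTranslate(p, "uniform_random", 62)))
  expect_identical(as.character(translateLongestOrf(cds)), paste0("M", p))
  expect_error(translateLongestOrf("ATGTTT"), "codons")
})

test_that("a planted ORF beats background in an exhaustive frame scan", {
  orfAa <- withr::with_seed(63, paste0("M", paste(sample(strsplit(
    "ACDEFGHIKLNPQRSTVWY", "")[[1]], 59, replace = TRUE), collapse = "")))
  orfNt <- paste0(as.character(reverseTranslate(orfAa, "uniform_random", 64)),
                  "TAA")
  cds <- paste0(randomDna(61, seed = 65), orfNt, randomDna(56, seed = 66))
  got <- as.character(translateLongestOrf(cds))
  # independent oracle: enumerate all ATG-to-stop ORFs in the 3 frames
  best <- ""
  for (f in 0:2) {
    len <- 3 * ((nchar(cds) - f) %/% 3)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, f + 1, f + len)),
      if.fuzzy.codon = "X"))
    for (seg in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      m <- regexpr("M", seg, fixed = TRUE)
      if (m > 0 && nchar(seg) - m + 1 > nchar(best)) {
        best <- substr(seg, m, nchar(seg))
      }
    }
  }
  expect_identical(got, best)
  expect_identical(got, orfAa)
})

test_that("the toy unit segments exactly; anchor-free proteins are TERMINAL", {
  seg <- segmentRepetitiveDomain(TOY_PROTEIN)
  df <- regionsDf(regions(seg))
  expect_equal(df$start, c(1, 12, 20, 25))
  expect_equal(df$end, c(11, 19, 24, 34))
  expect_equal(df$motif, c("POLY_A_E", "GA_PURE", "LINKER_IV", "GA_SER"))
  expect_equal(IRanges::start(repeatDomainSpan(seg)), 1L)
  expect_equal(IRanges::end(repeatDomainSpan(seg)), 34L)

  flat <- segmentRepetitiveDomain("GAGAGA")
  expect_equal(regionsDf(regions(flat))$motif, "TERMINAL")
  expect_length(repeatDomainSpan(flat), 0L)
})

test_that("segmentation reproduces generator ground truth at zero jitter", {
  p <- architectureParams(nUnits = 5, polyAHalfLen = 11, gaPureLen = 40,
                          linkerLen = 6, gaSerLen = 90, jitter = 0,
                          terminalLen = 0)
  g <- generateFibroinProtein(p, rngSeed = 1)
  seg <- segmentRepetitiveDomain(g)
  expect_identical(regionsDf(canonicalRegions(seg)),
                   regionsDf(regionTruth(g))[, c("start", "end", "motif")])

  # terminals enabled: canonical regions still recover the truth exactly,
  # and the flanks are TERMINAL
  pT <- architectureParams(nUnits = 5, jitter = 0, terminalLen = 120)
  gT <- generateFibroinProtein(pT, rngSeed = 2)
  segT <- segmentRepetitiveDomain(gT)
  expect_identical(regionsDf(canonicalRegions(segT)),
                   regionsDf(regionTruth(gT))[, c("start", "end", "motif")])
  motifs <- regionsDf(regions(segT))$motif
  expect_identical(motifs[1], "TERMINAL")
  expect_identical(motifs[length(motifs)], "TERMINAL")
})

test_that("segmentation also recovers truth with jitter and conserves residues", {
  for (seed in 1:5) {
    p <- architectureParams(nUnits = 4, jitter = 0.2, terminalLen = 80)
    g <- generateFibroinProtein(p, rngSeed = seed)
    seg <- segmentRepetitiveDomain(g)
    expect_identical(regionsDf(canonicalRegions(seg)),
                     regionsDf(regionTruth(g))[, c("start", "end", "motif")])
    # conservation: every residue typed exactly once
    expect_equal(sum(IRanges::width(regions(seg))),
                 length(proteinSequence(g)))
  }
})

test_that("repeat units tile the domain and match an anchor-count oracle", {
  seg1 <- segmentRepetitiveDomain(TOY_PROTEIN)
  units1 <- splitRepeatUnits(seg1)
  expect_length(units1, 1L)
  expect_length(motifSpans(units1[[1]]), 4L)

  p <- architectureParams(nUnits = 5, jitter = 0.1, terminalLen = 100)
  g <- generateFibroinProtein(p, rngSeed = 4)
  seg <- segmentRepetitiveDomain(g)
  units <- splitRepeatUnits(seg)
  expect_length(units, 5L)
  spans <- vapply(units, function(u) {
    c(IRanges::start(u@unitSpan), IRanges::end(u@unitSpan))
  }, numeric(2))
  expect_true(all(spans[1, -1] == spans[2, -ncol(spans)] + 1))  # tiling
  # independent anchor count: poly-A-E regex occurrences
  prot <- as.character(proteinSequence(g))
  m <- gregexpr("A{4,}(?:EA{4,})?", prot, perl = TRUE)[[1]]
  expect_length(units, length(m))
})

test_that("a trailing partial unit keeps only the types it contains", {
  # truncate the 2-unit toy protein right after the second linker
  p2 <- architectureParams(nUnits = 2, polyAHalfLen = 5, gaPureLen = 8,
                           linkerLen = 5, gaSerLen = 10, serRate = 0.4,
                           jitter = 0, terminalLen = 0)
  prot <- as.character(proteinSequence(generateFibroinProtein(p2)))
  truncated <- substr(prot, 1, 34 + 24)
  seg <- segmentRepetitiveDomain(truncated)
  units <- splitRepeatUnits(seg)
  expect_length(units, 2L)
  expect_equal(S4Vectors::mcols(motifSpans(units[[2]]))$motif,
               c("POLY_A_E", "GA_PURE", "LINKER_IV"))
  stats <- motifLengthStats(list(toy = seg))
  expect_equal(stats$n[stats$motif == "GA_SER"], 1L)   # not zero-padded
  expect_equal(stats$n[stats$motif == "POLY_A_E"], 2L)
})

test_that("motif length statistics summarise per species and motif", {
  seg <- segmentRepetitiveDomain(TOY_PROTEIN)
  stats <- motifLengthStats(list(toy = seg))
  want <- c(GA_PURE = 8, GA_SER = 10, LINKER_IV = 5, POLY_A_E = 11)
  expect_equal(stats$mean, unname(want[stats$motif]))
  expect_equal(stats$n, rep(1L, 4))
  # mean/median arithmetic on a 3-sample motif
  p3 <- architectureParams(nUnits = 3, jitter = 0.3, terminalLen = 0)
  g3 <- generateFibroinProtein(p3, rngSeed = 6)
  s3 <- motifLengthStats(list(sp = segmentRepetitiveDomain(g3)))
  truth <- regionsDf(regionTruth(g3))
  gw <- with(truth, end - start + 1)[truth$motif == "GA_PURE"]
  row <- s3[s3$motif == "GA_PURE", ]
  expect_equal(row$mean, mean(gw))
  expect_equal(row$median, median(gw))
})

test_that("amino-acid frequencies count residues exactly and sum to one", {
  f <- aaFrequency("GAGA")
  expect_equal(f[["G"]], 0.5)
  expect_equal(f[["A"]], 0.5)
  expect_equal(sum(f), 1)

  # counting oracle on the toy unit
  chars <- strsplit(TOY_PROTEIN, "")[[1]]
  ft <- aaFrequency(TOY_PROTEIN)
  for (aa in c("A", "G", "S", "E", "I", "V")) {
    expect_equal(ft[[aa]], sum(chars == aa) / length(chars))
  }
  expect_equal(ft[["A"]], 18 / 34)

  # concatenation invariance
  x <- "GASGA"
  y <- withr::with_seed(67, paste(sample(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40, replace = TRUE), collapse = ""))
  fx <- aaFrequency(x); fy <- aaFrequency(y)
  expect_equal(aaFrequency(paste0(x, y)),
               (nchar(x) * fx + nchar(y) * fy) / (nchar(x) + nchar(y)))
  expect_lt(abs(sum(aaFrequency(y)) - 1), 1e-9)
  expect_error(aaFrequency(""), "non-empty")
  expect_error(aaFrequency("GAX*"), "non-standard")
})

test_that("crystalline fraction scores beta-sheet regions of a unit", {
  seg <- segmentRepetitiveDomain(TOY_PROTEIN)
  unit <- splitRepeatUnits(seg)[[1]]
  expect_equal(crystallineFraction(unit), 19 / 34)
  expect_equal(crystallineFraction(seg), 19 / 34)

  # invariant under unit duplication
  p5 <- architectureParams(nUnits = 5, jitter = 0, terminalLen = 0)
  p1 <- architectureParams(nUnits = 1, jitter = 0, terminalLen = 0)
  f5 <- crystallineFraction(segmentRepetitiveDomain(
    generateFibroinProtein(p5)))
  f1 <- crystallineFraction(segmentRepetitiveDomain(
    generateFibroinProtein(p1)))
  expect_equal(f5, f1)

  # strictly monotone: halving the amorphous GA-S region raises the fraction
  pHalf <- architectureParams(nUnits = 5, gaSerLen = 44, jitter = 0,
                              terminalLen = 0)
  fHalf <- crystallineFraction(segmentRepetitiveDomain(
    generateFibroinProtein(pHalf)))
  expect_gt(fHalf, f5)

  # a unit with no amorphous spans is fully crystalline
  spans <- IRanges::IRanges(start = c(1, 12), end = c(11, 19))
  S4Vectors::mcols(spans) <- S4Vectors::DataFrame(
    motif = c("POLY_A_E", "GA_PURE"))
  bare <- new("RepeatUnit", unitIndex = 1L, spans = spans,
              unitSpan = IRanges::IRanges(1, 19))
  expect_equal(crystallineFraction(bare), 1.0)
})

test_that("architectureStats bundles lengths, composition and crystallinity", {
  gA <- generateFibroinProtein(architectureParams(nUnits = 3, jitter = 0.1),
                               rngSeed = 8)
  gB <- generateFibroinProtein(
    architectureParams(nUnits = 3, gaPureLen = 20, gaSerLen = 44,
                       jitter = 0.1), rngSeed = 9)
  st <- architectureStats(list(
    bam_like = segmentRepetitiveDomain(gA),
    cpu_like = segmentRepetitiveDomain(gB)))
  expect_equal(rownames(st@aaFreq), c("bam_like", "cpu_like"))
  expect_equal(unname(rowSums(st@aaFreq)), c(1, 1))
  expect_equal(st@crystallinity$species, c("bam_like", "cpu_like"))
  # halving both GA regions shifts the balance toward the fixed poly-A-E,
  # so the short-GA architecture is the more crystalline one
  expect_gt(st@crystallinity$crystalline_fraction[2],
            st@crystallinity$crystalline_fraction[1])
})
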