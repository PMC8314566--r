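# Seed finding, read harvesting, PWM construction, consensus calling and
# seed extension.

test_that("a perfect-match contig scores 2L and minus-strand hits normalise", {
  terminus <- randomDna(100, seed = 31)
  contigs <- c(hit = terminus, rc_hit = revcomp(terminus))
  seeds <- findTerminalSeeds(contigs, c(ref = terminus), minScore = 60)
  expect_length(seeds, 2L)
  expect_equal(vapply(seeds, function(s) s@alignmentScore, numeric(1)),
               c(200, 200))
  strands <- vapply(seeds, function(s) s@strand, character(1))
  bySrc <- strands[order(vapply(seeds, function(s) s@sourceContig,
                                character(1)))]
  expect_equal(unname(bySrc), c("+", "-"))
  # strand-normalised: both stored sequences read 3'-ward along the terminus
  expect_true(all(vapply(seeds, function(s) {
    as.character(s@sequence) == terminus
  }, logical(1))))
})

test_that("only a planted terminus among decoys is seeded; scores match a DP oracle", {
  terminus <- randomDna(80, seed = 32)
  decoys <- vapply(1:10, function(i) randomDna(120, seed = 100 + i),
                   character(1))
  names(decoys) <- sprintf("decoy_%02d", 1:10)
  planted <- c(planted = paste0(randomDna(20, seed = 33), terminus,
                                randomDna(20, seed = 34)))
  seeds <- findTerminalSeeds(c(decoys, planted), c(ref = terminus),
                             minScore = 60)
  expect_length(seeds, 1L)
  expect_identical(seeds[[1]]@sourceContig, "planted")
  expect_equal(seeds[[1]]@alignmentScore, 160)

  # every contig's score (no threshold) equals the quadratic DP oracle
  all <- findTerminalSeeds(c(decoys[1:3], planted), c(ref = terminus),
                           minScore = 0)
  for (s in all) {
    contig <- c(decoys[1:3], planted)[[s@sourceContig]]
    expect_equal(s@alignmentScore,
                 max(swOracle(contig, terminus),
                     swOracle(revcomp(contig), terminus)))
  }
})

test_that("translated mode finds protein-level homology on either strand", {
  protein <- withr::with_seed(35, paste(sample(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, replace = TRUE), collapse = ""))
  cds <- as.character(reverseTranslate(protein, "uniform_random", 36))
  contigs <- c(fwd = paste0(randomDna(10, 37), cds, randomDna(10, 38)),
               rev = revcomp(paste0(randomDna(7, 39), cds)),
               noise = randomDna(200, seed = 40))
  seeds <- findTerminalSeeds(contigs, c(ref = protein), minScore = 100,
                             mode = "translated")
  expect_equal(sort(vapply(seeds, function(s) s@sourceContig, character(1))),
               c("fwd", "rev"))
  strands <- vapply(seeds, function(s) s@strand, character(1))
  names(strands) <- vapply(seeds, function(s) s@sourceContig, character(1))
  expect_equal(unname(strands[c("fwd", "rev")]), c("+", "-"))
  expect_error(findTerminalSeeds(Biostrings::DNAStringSet(), c(ref = protein)),
               "no contigs")
})

test_that("harvested reads agree with the template when reads are error-free", {
  tmpl <- randomDna(600, seed = 41)
  reads <- simulateReads(tmpl, readSimParams(coverage = 30, rngSeed = 42))
  growing <- substr(tmpl, 1, 100)
  anc <- harvestMatchingReads(growing, reads, k = 75)
  expect_gt(length(anc$offset), 0)
  for (i in seq_len(length(anc$offset))) {
    off <- anc$offset[i]
    s <- anc$sequence[i]
    overlapLen <- min(nchar(s), 600 - off)
    expect_identical(substr(s, 1, overlapLen),
                     substr(tmpl, off + 1, off + overlapLen))
  }
  # vacuous case: k equal to read length and no read equals the k-mer
  none <- harvestMatchingReads(paste(rep("A", 150), collapse = ""),
                               reads, k = 150)
  expect_equal(length(none$offset), 0L)
  expect_error(harvestMatchingReads(substr(tmpl, 1, 200), reads, k = 151),
               "exceeds")
})

test_that("harvest equals a naive substring-scan oracle", {
  tmpl <- randomDna(600, seed = 43)
  reads <- simulateReads(tmpl, readSimParams(coverage = 50, errorRate = 0.01,
                                             rngSeed = 44))
  growing <- substr(tmpl, 1, 220)
  got <- harvestMatchingReads(growing, reads, k = 31)
  want <- naiveHarvest(growing, reads, k = 31)
  key <- function(d) sort(paste(d$readId, d$orientation, d$offset))
  expect_identical(key(as.data.frame(got)), key(want))
})

test_that("PWM columns count votes and match an interval-stabbing oracle", {
  offsets <- c(0L, 2L, 4L, 6L, 8L)
  unanimous <- S4Vectors::DataFrame(
    readId = paste0("r", 1:5), orientation = "+", offset = offsets,
    sequence = vapply(offsets, function(o) {
      paste0(strrep("C", 10 - o), "A")  # all reads end with A at coord 10
    }, character(1)))
  pwm <- buildPwm(unanimous, growingLen = 10)
  expect_equal(pwm$A[1], 5)
  expect_equal(pwm$depth[1], 5)
  expect_identical(callConsensus(pwm[1, ]), "A")

  split <- S4Vectors::DataFrame(
    readId = paste0("r", 1:5), orientation = "+", offset = 0L,
    sequence = c(rep("CCCCCG", 4), "CCCCCT"))
  pwm2 <- buildPwm(split, growingLen = 5)
  expect_equal(pwm2$depth[1], 5)
  expect_equal(max(pwm2[1, c("A", "C", "G", "T")]) / pwm2$depth[1], 0.8)

  # random anchors: per-column depth equals brute-force coverage counting
  set.seed(45)
  offs <- sample(0:40, 30, replace = TRUE)
  lens <- sample(20:60, 30, replace = TRUE)
  anc <- S4Vectors::DataFrame(
    readId = paste0("r", 1:30), orientation = "+", offset = offs,
    sequence = vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1)))
  gl <- 50
  pwm3 <- buildPwm(anc, growingLen = gl)
  for (j in seq_len(nrow(pwm3))) {
    coord <- gl + j - 1
    stab <- sum(offs <= coord & coord < offs + nchar(anc$sequence))
    expect_equal(pwm3$depth[j], stab)
  }
  expect_equal(nrow(buildPwm(anc[0, ], 10)), 0L)
})

test_that("consensus thresholds are inclusive and ties always fail", {
  cfg <- curationConfig(minDepth = 3, minDominantFrac = 0.9)
  expect_identical(callConsensus(c(A = 9, C = 0, G = 1, T = 0), cfg), "A")
  expect_identical(callConsensus(c(A = 5, C = 0, G = 5, T = 0), cfg),
                   "AMBIGUOUS")
  expect_identical(callConsensus(c(A = 2, C = 0, G = 0, T = 0), cfg),
                   "LOW_DEPTH")
  expect_identical(callConsensus(c(A = 8, C = 0, G = 1, T = 0), cfg),
                   "AMBIGUOUS")   # 8/9 < 0.9
})

test_that("extension reproduces the explicit harvest->PWM->consensus path", {
  tmpl <- randomDna(700, seed = 46)
  reads <- simulateReads(tmpl, readSimParams(coverage = 40, errorRate = 0.005,
                                             rngSeed = 47))
  cfg <- curationConfig(k = 75, maxExtension = 200)
  ext <- extendSeed(substr(tmpl, 1, 150), reads, cfg)
  st <- supportTrack(ext)
  expect_gt(nrow(st), 20)
  cur <- as.character(curatedSequence(ext))
  for (n in unique(round(seq(150, nrow(st) + 149, length.out = 5)))) {
    growing <- substr(cur, 1, n)
    anc <- harvestMatchingReads(growing, reads, k = 75)
    pwm <- buildPwm(anc, growingLen = n)
    call <- callConsensus(pwm[1, ], cfg)
    i <- n - 149
    expect_identical(call, st$base[i])
    expect_equal(pwm$depth[1], st$depth[i])
  }
})

test_that("extension enters the tandem array and stops at the repeat", {
  gene <- generateFibroinGene(curationArch(), rngSeed = 7)
  cds <- as.character(cdsSequence(gene))
  reads <- simulateReads(cds, readSimParams(coverage = 30, rngSeed = 11))
  ext <- extendSeed(substr(cds, 1, 200), reads, curationConfig())
  expect_identical(termination(ext), "REPEAT_DETECTED")
  cur <- as.character(curatedSequence(ext))
  expect_identical(cur, substr(cds, 1, nchar(cur)))
  # tip = nucleotide start of unit 2 (0-based) + repeatWindow - 1
  unit2Start0 <- 3 * (IRanges::start(unitSpans(gene))[2] - 1)
  expect_equal(nchar(cur), unit2Start0 + 75 - 1)
})

test_that("read starvation terminates immediately without false calls", {
  tmpl <- randomDna(1000, seed = 48)
  onlySeedReads <- simulateReads(substr(tmpl, 1, 250),
                                 readSimParams(coverage = 20, rngSeed = 49))
  ext <- extendSeed(substr(tmpl, 1, 200), onlySeedReads, curationConfig())
  expect_true(termination(ext) %in% c("NO_READS", "LOW_DEPTH"))
  expect_lt(nrow(supportTrack(ext)), 60)
  cur <- as.character(curatedSequence(ext))
  expect_identical(cur, substr(tmpl, 1, nchar(cur)))
  expect_error(extendSeed(substr(tmpl, 1, 50), onlySeedReads,
                          curationConfig(k = 75)), "shorter than k")
})

test_that("a non-repetitive template is reconstructed exactly until coverage collapses", {
  tmpl <- randomDna(1200, seed = 50)
  reads <- simulateReads(tmpl, readSimParams(coverage = 50, rngSeed = 51))
  ext <- extendSeed(substr(tmpl, 1, 150), reads,
                    curationConfig(maxExtension = 10000))
  cur <- as.character(curatedSequence(ext))
  expect_identical(cur, substr(tmpl, 1, nchar(cur)))  # no false calls at all
  expect_gte(nchar(cur), 1200 - 150)   # reaches the tail-taper zone
  expect_true(termination(ext) %in% c("NO_READS", "LOW_DEPTH"))
})

test_that("raising thresholds never lengthens the extension", {
  tmpl <- randomDna(1000, seed = 52)
  reads <- simulateReads(tmpl, readSimParams(coverage = 40, errorRate = 0.01,
                                             rngSeed = 53))
  lens <- vapply(c(0.6, 0.75, 0.9, 1.0), function(f) {
    ext <- extendSeed(substr(tmpl, 1, 150), reads,
                      curationConfig(minDominantFrac = f))
    nrow(supportTrack(ext))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
  lensD <- vapply(c(3, 6, 12, 24), function(d) {
    ext <- extendSeed(substr(tmpl, 1, 150), reads,
                      curationConfig(minDepth = d))
    nrow(supportTrack(ext))
  }, numeric(1))
  expect_true(all(diff(lensD) <= 0))
})

test_that("extension is deterministic for identical inputs", {
  tmpl <- randomDna(800, seed = 54)
  reads <- simulateReads(tmpl, readSimParams(coverage = 30, errorRate = 0.005,
                                             rngSeed = 55))
  e1 <- extendSeed(substr(tmpl, 1, 150), reads, curationConfig())
  e2 <- extendSeed(substr(tmpl, 1, 150), reads, curationConfig())
  expect_identical(as.character(curatedSequence(e1)),
                   as.character(curatedSequence(e2)))
  expect_identical(supportTrack(e1), supportTrack(e2))
  expect_identical(termination(e1), termination(e2))
})
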