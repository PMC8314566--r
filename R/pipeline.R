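#' @include AllClasses.R
NULL

# halve the GA regions of an architecture (the contrast observed between
# bagworm species whose GA motifs are about half the length of the others')
.halveGaParams <- function(arch) {
  architectureParams(
    nUnits = arch@nUnits, polyAHalfLen = arch@polyAHalfLen,
    gaPureLen = .evenize(arch@gaPureLen / 2),
    linkerLen = arch@linkerLen,
    gaSerLen = .evenize(arch@gaSerLen / 2),
    serRate = arch@serRate, jitter = arch@jitter,
    terminalLen = arch@terminalLen)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain the sections `gene_id`, `rng_seed`, `arch`,
#' `read_sim`, `curation`, `seg` and `mech`; each section holds the
#' arguments of the corresponding constructor
#' (e.g. `arch: {nUnits: 5, gaPureLen: 40}`). Omitted values keep their
#' defaults, so every unstated parameter is visible in one place.
#'
#' @param path YAML file path.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pipelineConfig(
    geneId = y$gene_id %||% "synthetic_fibroin",
    arch = do.call(architectureParams, y$arch %||% list()),
    readSim = do.call(readSimParams, y$read_sim %||% list()),
    curation = do.call(curationConfig, y$curation %||% list()),
    seg = do.call(segConfig, y$seg %||% list()),
    mech = y$mech %||% list(),
    rngSeed = y$rng_seed %||% 1)
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Executes simulate -> curate -> annotate -> stats on synthetic data: a
#' fibroin gene (plus a companion "species" with halved GA regions) is
#' generated, short reads simulated, the gene re-curated from the reads by
#' seed extension, both proteins segmented into motif regions,
#' architecture/mechanics statistics computed, and every intermediate
#' written under `outdir`. All stage seeds derive from `config@rngSeed`, so
#' two runs with the same config produce identical data artifacts (the JSON
#' report additionally carries a timestamp).
#'
#' @param config a [PipelineConfig-class].
#' @param outdir output directory (created if needed).
#' @return the run report, a nested list with the tool version, timestamp,
#'   config snapshot and per-stage metrics, also written to
#'   `outdir/report.json`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile()) {
  stopifnot(methods::is(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config@rngSeed
  report <- list(
    tool = "fibroinArch",
    version = as.character(utils::packageVersion("fibroinArch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = seed,
    stages = list())

  # --- stage 1: simulate --------------------------------------------------
  geneA <- generateFibroinGene(config@arch, rngSeed = seed,
                               geneId = config@geneId)
  geneB <- generateFibroinGene(.halveGaParams(config@arch),
                               rngSeed = seed + 1L,
                               geneId = paste0(config@geneId, "_shortGA"))
  readSim <- config@readSim
  readSim@rngSeed <- seed + 2L
  reads <- simulateReads(geneA@cds, readSim)

  writeFasta(Biostrings::DNAStringSet(stats::setNames(
    c(as.character(geneA@cds), as.character(geneB@cds)),
    c(geneA@geneId, geneB@geneId))), file.path(outdir, "genes.fasta"))
  writeFasta(Biostrings::AAStringSet(stats::setNames(
    c(as.character(geneA@protein), as.character(geneB@protein)),
    c(geneA@geneId, geneB@geneId))), file.path(outdir, "proteins.fasta"))
  writeFastq(reads, file.path(outdir, "reads.fastq"))
  truth <- rbind(writeRegionsTsv(geneA), writeRegionsTsv(geneB))
  utils::write.table(truth, file.path(outdir, "region_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    gene_id = config@geneId, rng_seed = seed,
    arch = list(nUnits = config@arch@nUnits,
                polyAHalfLen = config@arch@polyAHalfLen,
                gaPureLen = config@arch@gaPureLen,
                linkerLen = config@arch@linkerLen,
                gaSerLen = config@arch@gaSerLen,
                serRate = config@arch@serRate,
                jitter = config@arch@jitter,
                terminalLen = config@arch@terminalLen),
    read_sim = list(readLength = readSim@readLength,
                    coverage = readSim@coverage,
                    errorRate = readSim@errorRate,
                    rngSeed = readSim@rngSeed,
                    bothStrands = readSim@bothStrands))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$stages$simulate <- list(
    seed = seed, genes = 2L, reads_out = length(reads),
    template_length = length(geneA@cds))

  # --- stage 2: curate ----------------------------------------------------
  cds <- as.character(geneA@cds)
  ntermNt <- if (length(geneA@nTermSpan) > 0) {
    3L * IRanges::width(geneA@nTermSpan)
  } else 3L * 20L
  seedLen <- max(config@curation@k, min(ntermNt, 300L))
  refTerminus <- substr(cds, 1L, seedLen)
  decoys <- withr::with_seed(seed + 3L, {
    vapply(1:2, function(i) {
      paste(sample(c("A", "C", "G", "T"), seedLen, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  contigs <- Biostrings::DNAStringSet(
    c(nterm_contig = substr(cds, 1L, seedLen), decoy_1 = decoys[1],
      decoy_2 = decoys[2]))
  seeds <- findTerminalSeeds(contigs, Biostrings::DNAStringSet(
    c(ref_nterm = refTerminus)), minScore = 0.8 * 2 * seedLen)
  if (length(seeds) == 0) .stopf("curate stage: no seed found")
  ext <- extendSeed(seeds[[1]], reads, config@curation,
                    bothStrands = readSim@bothStrands)
  curated <- as.character(curatedSequence(ext))
  identity <- {
    cmp <- min(nchar(curated), nchar(cds))
    a <- strsplit(substr(curated, 1, cmp), "")[[1]]
    b <- strsplit(substr(cds, 1, cmp), "")[[1]]
    mean(a == b)
  }
  writeFasta(stats::setNames(curated, paste0(config@geneId, "_curated")),
             file.path(outdir, "curated.fasta"))
  utils::write.table(supportTrack(ext), file.path(outdir, "support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$curate <- list(
    reads_in = length(reads), seeds_found = length(seeds),
    bases_extended = nrow(supportTrack(ext)),
    termination = termination(ext), rounds = ext@rounds,
    identity_to_truth = identity)

  # --- stage 3: annotate --------------------------------------------------
  segA <- segmentRepetitiveDomain(geneA, config@seg)
  segB <- segmentRepetitiveDomain(geneB, config@seg)
  segsBySpecies <- stats::setNames(list(segA, segB),
                                   c(geneA@geneId, geneB@geneId))
  stats <- architectureStats(segsBySpecies)
  segBed <- rbind(writeRegionsTsv(segA), writeRegionsTsv(segB))
  utils::write.table(segBed, file.path(outdir, "segmentation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stats@lengthStats,
                     file.path(outdir, "motif_length_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  aaCorr <- pearsonR(stats@aaFreq[1, ], stats@aaFreq[2, ])
  report$stages$annotate <- list(
    proteins = 2L,
    units_segmented = length(splitRepeatUnits(segA)) +
      length(splitRepeatUnits(segB)),
    aa_frequency_pearson_r = aaCorr@r,
    crystalline_fractions = stats::setNames(
      as.list(stats@crystallinity$crystalline_fraction),
      stats@crystallinity$species))

  # --- stage 4: stats -----------------------------------------------------
  mechArgs <- config@mech
  mechArgs$rngSeed <- mechArgs$rngSeed %||% (seed + 4L)
  ds <- do.call(generateMechDataset, mechArgs)
  utils::write.table(ds$mech, file.path(outdir, "mech.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$cryst, file.path(outdir, "crystallinity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trend <- crystallinityTrend(ds$mech, ds$cryst, "tensile_strength")
  summ <- tensileSummary(ds$mech)
  utils::write.table(summ, file.path(outdir, "tensile_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  strongest <- summ$species[summ$property == "tensile_strength"][
    which.max(summ$mean[summ$property == "tensile_strength"])]
  contrast <- welchT(
    ds$mech$tensile_strength[ds$mech$species == strongest],
    ds$mech$tensile_strength[ds$mech$species != strongest])
  report$stages$stats <- list(
    seed = mechArgs$rngSeed,
    species = nrow(ds$cryst), fibres = nrow(ds$mech),
    trend_r = trend@r, trend_slope = trend@slope,
    monotone_decreasing = trend@monotoneDecreasing,
    strongest_species = strongest,
    strongest_vs_rest_p = contrast@p,
    stats_emitted = nrow(summ))

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
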