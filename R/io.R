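#' @include AllClasses.R
NULL

#' Read and write FASTA
#'
#' Thin wrappers around the Biostrings readers/writers with the conventions
#' used throughout this package: sequences are upper-cased on read, written
#' wrapped at 60 columns, and ids/sequences round-trip unchanged.
#'
#' @param path file path (`.gz` handled transparently).
#' @param type `"auto"` infers DNA vs protein from the residue alphabet.
#' @return `readFasta`: a [Biostrings::DNAStringSet] or
#'   [Biostrings::AAStringSet]; an empty file yields an empty set.
#' @export
readFasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  if (type == "auto") {
    letters <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    type <- if (all(letters %in% c("A", "C", "G", "T", "N", "U"))) {
      "dna"
    } else "protein"
  }
  out <- if (type == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  names(out) <- names(raw)
  out
}

#' @rdname readFasta
#' @param x sequences to write: an [Biostrings::XStringSet] or a named
#'   character vector.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    nm <- names(x)
    x <- Biostrings::BStringSet(x)
    names(x) <- nm
  }
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  Biostrings::writeXStringSet(x, path, width = 60,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read and write FASTQ
#'
#' 4-line FASTQ with qualities preserved verbatim; `.gz` paths are
#' compressed/decompressed transparently by extension.
#'
#' @param path file path.
#' @return `readFastq`: a [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  # the reader parks qualities in mcols before constructing the
  # quality-scaled set, which emits a spurious "metadata columns dropped"
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' @rdname readFastq
#' @param reads a [Biostrings::DNAStringSet] (a constant Q40 quality string
#'   is written, since the curation pipeline never uses qualities but FASTQ
#'   must be well-formed) or a [Biostrings::QualityScaledDNAStringSet]
#'   (qualities written verbatim).
#' @export
writeFastq <- function(reads, path) {
  compress <- endsWith(path, ".gz")
  if (methods::is(reads, "QualityScaledDNAStringSet")) {
    Biostrings::writeQualityScaledXStringSet(reads, path,
                                             compress = compress)
  } else {
    reads <- .asDNAStringSet(reads, "reads")
    if (is.null(names(reads))) {
      names(reads) <- paste0("read_", seq_along(reads))
    }
    S4Vectors::mcols(reads) <- NULL  # simulation truth stays in memory only
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals, compress = compress)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# tabular exports (BED-like TSVs, 0-based half-open)
# ---------------------------------------------------------------------------

.regionsToBed <- function(id, ranges) {
  data.frame(
    id = id,
    start = IRanges::start(ranges) - 1L,
    end = IRanges::end(ranges),
    motif_type = S4Vectors::mcols(ranges)$motif,
    stringsAsFactors = FALSE)
}

#' Export motif regions as a BED-like table
#'
#' @param x a [Segmentation-class] or [SimulatedFibroinGene-class] (ground
#'   truth).
#' @param path optional TSV destination; when `NULL` the `data.frame` is
#'   returned only.
#' @return invisibly (or visibly when `path` is `NULL`) a `data.frame` with
#'   columns `id`, `start`, `end`, `motif_type`, 0-based half-open.
#' @export
writeRegionsTsv <- function(x, path = NULL) {
  bed <- if (methods::is(x, "Segmentation")) {
    .regionsToBed(x@proteinId, x@regions)
  } else if (methods::is(x, "SimulatedFibroinGene")) {
    .regionsToBed(x@geneId, x@regionTruth)
  } else {
    .stopf("cannot export regions from a %s", class(x)[1])
  }
  if (is.null(path)) return(bed)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bed)
}
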