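#' Read and write standard sequence and table formats
#'
#' Thin wrappers around Biostrings and base utils used at the pipeline's I/O
#' boundary. Sequences are plain named character vectors internally. Files
#' ending in `.gz` are transparently compressed.
#'
#' @param seqs named character vector of sequences (or reads).
#' @param path output file path.
#' @name io
NULL

#' @rdname io
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = endsWith(path, ".gz"),
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @param df data.frame to serialize.
#' @export
write_tsv <- function(df, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a CDS annotation as a BED-like 4+1 column table
#'
#' Columns: transcript, cds_start, cds_end (0-based half-open), gene.
#'
#' @param cds CDS annotation from [cds_annotation()].
#' @param path output path.
#' @export
write_cds_bed <- function(cds, path) {
  write_tsv(cds[c("transcript", "cds_start", "cds_end", "gene")], path)
}

#' @rdname write_cds_bed
#' @export
read_cds_bed <- function(path) {
  cds <- read_tsv(path)
  stopifnot(all(c("transcript", "cds_start", "cds_end", "gene") %in%
                  names(cds)))
  if (any((cds$cds_end - cds$cds_start) %% 3L != 0L)) {
    stop("CDS lengths must be divisible by 3")
  }
  cds$n_codons <- (cds$cds_end - cds$cds_start) %/% 3L
  cds
}

#' Write a cytosine report with 1-based positions
#'
#' The on-disk convention is 1-based inclusive positions (column `pos_1based`),
#' matching common pileup formats; in-memory reports are 0-based.
#'
#' @param report a `CytosineReport`.
#' @param path output path.
#' @export
write_cytosine_report <- function(report, path) {
  out <- report
  out$pos_1based <- out$pos + 1L
  out$pos <- NULL
  write_tsv(out[c("transcript", "pos_1based", "coverage", "nonconverted",
                  "converted", "other")], path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  x <- read_tsv(path)
  x$pos <- x$pos_1based - 1L
  x$pos_1based <- NULL
  x <- x[c("transcript", "pos", "coverage", "nonconverted", "converted",
           "other")]
  class(x) <- c("CytosineReport", "data.frame")
  x
}
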