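#' @include simulate-genome.R
NULL

#' Write a toy genome as FASTA
#'
#' @param genome A [GenomeModel-class].
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome@seqs, path)
  invisible(path)
}

#' Read a genome from FASTA, indexing every GATC motif
#'
#' All literal \code{GATC} occurrences are recorded as motif positions.
#'
#' @param path FASTA path.
#' @param binSize Bin width recorded on the genome.
#' @return A [GenomeModel-class] (no repeat annotation).
#' @export
readGenomeFasta <- function(path, binSize = 1000L) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  gatc <- lapply(as.character(dss), function(s) {
    h <- gregexpr("GATC", s, fixed = TRUE)[[1]]
    as.integer(h[h > 0])
  })
  methods::new("GenomeModel", seqs = dss, gatcPositions = gatc,
               binSize = as.integer(binSize),
               repeatRegions = GenomicRanges::GRanges())
}

#' Write simulated reads as gzipped FASTQ plus a truth sidecar
#'
#' Read 1 carries UMI + barcode + insert; constant quality is emitted. The
#' hidden ground-truth columns are written to \code{<path>.truth.tsv}.
#'
#' @param reads data.table from [simulateReads()].
#' @param path Output path (\code{.fastq.gz}).
#' @return \code{path}, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads$sequence), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", reads$name, "\n", reads$sequence, "\n+\n", qual),
             con)
  truthCols <- grep("^(name|true|isDuplicate|clean)", colnames(reads),
                    value = TRUE)
  data.table::fwrite(reads[, truthCols, with = FALSE],
                     paste0(path, ".truth.tsv"), sep = "\t")
  invisible(path)
}

#' Read a (gzipped) FASTQ into a read table
#'
#' @param path FASTQ path (.gz allowed).
#' @return data.table with \code{name} and \code{sequence}.
#' @export
readReadsFastq <- function(path) {
  ln <- readLines(con <- gzfile(path)); close(con)
  stopifnot(length(ln) %% 4L == 0L)
  data.table::data.table(
    name = sub("^@", "", sub("\\s.*$", "", ln[seq(1, length(ln), 4)])),
    sequence = ln[seq(2, length(ln), 4)]
  )
}

#' Read / write a barcode whitelist TSV
#'
#' @param path TSV with columns \code{barcode}, \code{cell}.
#' @return data.table.
#' @export
readBarcodeTable <- function(path) {
  bt <- data.table::fread(path, colClasses = "character")
  if (!all(c("barcode", "cell") %in% colnames(bt)))
    stop("barcode table needs 'barcode' and 'cell' columns")
  bt
}

#' @rdname readBarcodeTable
#' @param barcodeTable data.table from [makeBarcodeTable()].
#' @export
writeBarcodeTable <- function(barcodeTable, path) {
  data.table::fwrite(barcodeTable, path, sep = "\t")
  invisible(path)
}

#' Write / read per-cell event tables as sorted TSV
#'
#' Columns: cell, chrom, pos (1-based), strand, umi, modality, allele,
#' weight.
#'
#' @param eventTable An [EventTable-class].
#' @param path Output TSV path.
#' @export
writeEventTable <- function(eventTable, path) {
  data.table::fwrite(eventTable@events, path, sep = "\t")
  invisible(path)
}

#' @rdname writeEventTable
#' @param ploidy Ploidy label restored on read.
#' @export
readEventTable <- function(path, ploidy = "haploid_or_allelic") {
  ev <- data.table::fread(path)
  methods::new("EventTable", events = ev, ploidy = ploidy)
}

#' Write a DomainSet as BED (0-based half-open) with a score column
#'
#' @param domainSet A [DomainSet-class].
#' @param path Output BED path.
#' @param scores Optional numeric score per domain (default width).
#' @export
writeDomainsBed <- function(domainSet, path, scores = NULL) {
  gr <- domainSet@ranges
  if (is.null(scores)) scores <- GenomicRanges::width(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = sprintf("domain%03d", seq_along(gr)),
                   score = scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a matrix as MatrixMarket with row/column sidecars
#'
#' @param m Matrix (cells x features).
#' @param prefix Output prefix; writes \code{<prefix>.mtx},
#'   \code{<prefix>.rows.tsv}, \code{<prefix>.cols.tsv}.
#' @export
writeMatrixMtx <- function(m, prefix) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
             else rownames(m), paste0(prefix, ".rows.tsv"))
  writeLines(if (is.null(colnames(m))) as.character(seq_len(ncol(m)))
             else colnames(m), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}
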