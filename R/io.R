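## File-format helpers. FASTA/FASTQ through Biostrings; GFF3 through
## rtracklayer when available. A light structural pre-validation wraps FASTQ
## reading so that malformed records abort with the record number.

#' Read a FASTQ file
#'
#' Validates the 4-line record structure (marker lines, equal sequence and
#' quality lengths) before parsing with Biostrings, so a malformed record
#' aborts with its record number.
#'
#' @param path FASTQ path (Phred+33).
#' @return A named `DNAStringSet` of read sequences; per-read quality strings
#'   are attached as the `quality` attribute (a `BStringSet`).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seq <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad)) stop("malformed FASTQ record ", bad[1L])
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- sub("^@", "", hdr)
  attr(out, "quality") <- Biostrings::BStringSet(qual)
  out
}

#' Write reads to FASTQ
#'
#' @param reads Named `DNAStringSet` or character vector.
#' @param path Output path.
#' @param quality Optional quality strings; defaults to constant Phred 40
#'   (`I`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = NULL) {
  if (!inherits(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  if (is.null(quality)) {
    quality <- Biostrings::BStringSet(
      vapply(Biostrings::width(reads),
             function(w) strrep("I", w), character(1))
    )
  }
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quality)
  invisible(path)
}

#' Write a collapsed clean-read set as FASTA
#'
#' Headers follow the collapsed-read dialect `seq_<N>_x<COUNT>`.
#'
#' @param clean A [clean_read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(clean, path) {
  stopifnot(inherits(clean, "clean_reads"))
  x <- Biostrings::DNAStringSet(clean$seq)
  names(x) <- sprintf("seq_%d_x%s", seq_len(nrow(clean)),
                      format(clean$count, trim = TRUE, scientific = FALSE))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_collapsed_fasta
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- as.numeric(sub(".*_x", "", names(x)))
  clean_read_set(as.character(x), counts)
}

#' Export a miRNA annotation as GFF3
#'
#' Writes `miRNA_primary_transcript` features for precursors and `miRNA`
#' features for matures (genomic coordinates, 1-based inclusive,
#' strand-aware). Requires the rtracklayer package.
#'
#' @param annotation A [mirna_annotation()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "mirna_annotation"))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to write GFF3")
  }
  pre <- annotation$precursors
  mat <- annotation$matures
  mat_g <- merge(mat, pre[, c("precursor_id", "chrom", "start", "end", "strand")],
                 by = "precursor_id", suffixes = c("", "_pre"))
  # mature genomic interval from its position on the precursor
  plus <- mat_g$strand == "+"
  g_start <- ifelse(plus, mat_g$start_pre + mat_g$start - 1L,
                    mat_g$end_pre - mat_g$end + 1L)
  g_end <- ifelse(plus, mat_g$start_pre + mat_g$end - 1L,
                  mat_g$end_pre - mat_g$start + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = c(pre$chrom, mat_g$chrom),
    ranges = IRanges::IRanges(
      start = c(pre$start, g_start), end = c(pre$end, g_end)
    ),
    strand = c(pre$strand, mat_g$strand)
  )
  gr$type <- c(rep("miRNA_primary_transcript", nrow(pre)),
               rep("miRNA", nrow(mat_g)))
  gr$ID <- c(pre$precursor_id, mat_g$mature_id)
  gr$Parent <- c(rep(NA_character_, nrow(pre)), mat_g$precursor_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
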