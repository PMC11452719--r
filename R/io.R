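## File-format surfaces: FASTA/FASTQ via Biostrings, GFF3/BED via rtracklayer,
## MTX via Matrix, plus a minimal SAM writer/reader for the aligner interface.

#' Write reads to FASTQ
#'
#' @param seqs character vector of read sequences.
#' @param ids read identifiers.
#' @param path output file.
#' @export
write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with read_id and seq.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## internal 0-based half-open records -> GFF3 (1-based closed on disk)
write_annotation_gff3 <- function(records, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand)
  S4Vectors::mcols(gr)$type <- records$biotype
  S4Vectors::mcols(gr)$ID <- records$name
  S4Vectors::mcols(gr)$Name <- records$name
  S4Vectors::mcols(gr)$Parent <- records$parent
  S4Vectors::mcols(gr)$aa <- records$aa
  S4Vectors::mcols(gr)$anticodon <- records$anticodon
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## internal records -> BED6 (0-based half-open on disk)
write_annotation_bed <- function(records, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand)
  S4Vectors::mcols(gr)$name <- records$name
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write alignment records as SAM
#'
#' One record per placement; soft clips in the CIGAR, the UMI in the RX tag,
#' the counted mismatch number in NM, and (when present) the UMI-cluster size
#' in the XC tag. Secondary placements of a multi-mapping read get flag 256.
#'
#' @param placements data.frame with read_id, chrom, start (0-based), strand,
#'   mm, clip5, clip3, maplen.
#' @param reads data.frame with read_id, seq, umi and optionally cluster_size.
#' @param genome named character vector (for header lengths).
#' @param path output SAM path.
#' @export
write_sam <- function(placements, reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (chrom in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(genome[[chrom]])), con)
  if (nrow(placements) == 0L) return(invisible(path))
  p <- placements[order(placements$read_id, placements$chrom,
                        placements$start, placements$strand), , drop = FALSE]
  first <- !duplicated(p$read_id)
  ri <- match(p$read_id, reads$read_id)
  seqs <- reads$seq[ri]
  neg <- p$strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  lead <- ifelse(neg, p$clip3, p$clip5)
  trail <- ifelse(neg, p$clip5, p$clip3)
  cigar <- paste0(ifelse(lead > 0L, paste0(lead, "S"), ""),
                  p$maplen, "M",
                  ifelse(trail > 0L, paste0(trail, "S"), ""))
  flag <- ifelse(neg, 16L, 0L) + ifelse(first, 0L, 256L)
  tags <- sprintf("NM:i:%d\tRX:Z:%s", p$mm, reads$umi[ri])
  if (!is.null(reads$cluster_size))
    tags <- paste0(tags, sprintf("\tXC:i:%d", reads$cluster_size[ri]))
  writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\t%s",
                     p$read_id, flag, p$chrom, p$start + 1L, cigar,
                     seqs, strrep("I", nchar(seqs)), tags), con)
  invisible(path)
}

#' Read a SAM file written by \code{\link{write_sam}}
#'
#' @param path SAM path.
#' @return data.frame of placements with read_id, flag, chrom, start (0-based),
#'   strand, cigar, seq, mm, umi and cluster_size (NA when absent).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(), flag = integer(),
                      chrom = character(), start = integer(),
                      strand = character(), cigar = character(),
                      seq = character(), mm = integer(), umi = character(),
                      cluster_size = integer(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  tag_val <- function(prefix) {
    vapply(f, function(x) {
      hit <- grep(prefix, x[-(1:11)], value = TRUE, fixed = TRUE)
      if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  flag <- as.integer(get(2))
  data.frame(read_id = get(1), flag = flag, chrom = get(3),
             start = as.integer(get(4)) - 1L,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             cigar = get(6), seq = get(10),
             mm = as.integer(tag_val("NM:i:")),
             umi = tag_val("RX:Z:"),
             cluster_size = as.integer(tag_val("XC:i:")),
             stringsAsFactors = FALSE)
}

#' Write a cells-by-features count matrix as MTX + TSV sidecars
#'
#' @param mat integer matrix, cells in rows, features in columns.
#' @param dir output directory.
#' @param prefix file name prefix (e.g. the biotype).
#' @export
write_count_matrix <- function(mat, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                  file.path(dir, paste0(prefix, ".mtx")))
  writeLines(colnames(mat), file.path(dir, paste0(prefix, ".features.tsv")))
  writeLines(rownames(mat), file.path(dir, paste0(prefix, ".barcodes.tsv")))
  invisible(dir)
}
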