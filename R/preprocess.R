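## ---------------------------------------------------------------------------
## Read preprocessing: UMI extraction into read names, 3' adapter/polyA
## trimming with the Small-seq retention rules (error rate 0.1, minimum
## overlap 3, kept length in [18, 81], at least 10 nt of tail removed).
## ---------------------------------------------------------------------------

UMI_LENGTH <- 8L
UMI_FILLER <- 2L          # bases discarded after the UMI (cutadapt -u 2)
TRIM_MIN_LEN <- 18L       # -m 18
TRIM_MAX_LEN <- 81L       # -M 81
TRIM_MIN_TAIL <- 10L      # minimum adapter/polyA bases removed
TRIM_ERROR_RATE <- 0.1    # -e 0.1
TRIM_MIN_OVERLAP <- 3L    # -o 3
POLYA_MIN_RUN <- 4L       # shorter terminal A-runs are treated as NTA, not tail

#' Extract the UMI from raw reads into the read name
#'
#' The first 8 nt become the UMI, appended to the read id with an underscore;
#' the following 2 nt are discarded. Reads of 10 nt or shorter are dropped
#' and tallied.
#'
#' @param seqs raw read sequences.
#' @param ids read identifiers.
#' @return list(reads = data.frame(read_id, umi, seq), n_dropped).
#' @export
extract_umi <- function(seqs, ids) {
  keep <- nchar(seqs) > UMI_LENGTH + UMI_FILLER
  umi <- substr(seqs[keep], 1L, UMI_LENGTH)
  remainder <- substr(seqs[keep], UMI_LENGTH + UMI_FILLER + 1L,
                      nchar(seqs[keep]))
  list(reads = data.frame(read_id = paste0(ids[keep], "_", umi),
                          umi = umi, seq = remainder,
                          stringsAsFactors = FALSE),
       kept = keep,
       n_dropped = sum(!keep))
}

## best semi-global 3' adapter match: no indels, mismatch budget
## floor(error_rate * overlap), overlap >= min_overlap; among valid matches
## the longest overlap wins (ties: the leftmost). Returns the match start
## (1-based) or NA.
find_adapter <- function(seq, adapter,
                         error_rate = TRIM_ERROR_RATE,
                         min_overlap = TRIM_MIN_OVERLAP) {
  L <- nchar(seq); A <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  s_ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  a_ch <- strsplit(adapter, "", fixed = TRUE)[[1]]
  best_start <- NA_integer_; best_ov <- -1L
  ## full-overlap starts, vectorised over positions
  nfull <- L - A + 1L
  if (nfull >= 1L) {
    mm <- integer(nfull)
    for (j in seq_len(A))
      mm <- mm + (s_ch[j:(j + nfull - 1L)] != a_ch[j])
    hit <- which(mm <= floor(error_rate * A))
    if (length(hit)) { best_ov <- A; best_start <- hit[1L] }
  }
  ## partial overlaps hanging off the 3' end (shorter overlap never beats a
  ## full-overlap match)
  if (is.na(best_start)) {
    for (s in max(1L, nfull + 1L):(L - min_overlap + 1L)) {
      ov <- L - s + 1L
      mm <- sum(s_ch[s:L] != a_ch[seq_len(ov)])
      if (mm <= floor(error_rate * ov) && ov > best_ov) {
        best_ov <- ov; best_start <- s
      }
    }
  }
  best_start
}

#' Trim adapter and polyA from a UMI-extracted read
#'
#' Finds the 3' adapter (semi-global, error rate 0.1, minimum overlap 3, no
#' indels), removes it together with the adenosine run immediately preceding
#' it, and keeps the read only if the remaining insert length lies in
#' [18, 81] and at least 10 tail bases were removed.
#'
#' @param seq read sequence after UMI extraction.
#' @param adapter adapter sequence.
#' @return list(keep, insert, tail_length, reason); reason is NA when kept,
#'   else one of "no_tail", "tail_lt_10", "too_short", "too_long".
#' @export
trim_read <- function(seq, adapter) {
  stopifnot(nchar(adapter) > 0L)
  s <- find_adapter(seq, adapter)
  if (is.na(s)) {
    ## no adapter: a terminal polyA run can still count as trimmable tail
    run <- trailing_run(seq, "A")
    if (run < TRIM_MIN_OVERLAP)
      return(list(keep = FALSE, insert = NA_character_, tail_length = 0L,
                  reason = "no_tail"))
    s <- nchar(seq) - run + 1L
  } else {
    ## extend trimming through an oligo-dA run abutting the adapter; runs of
    ## 1-3 adenosines are left in place (plausible non-templated additions,
    ## not tail)
    run <- trailing_run(substr(seq, 1L, s - 1L), "A")
    if (run >= POLYA_MIN_RUN) s <- s - run
  }
  tail_length <- nchar(seq) - s + 1L
  insert <- substr(seq, 1L, s - 1L)
  if (tail_length < TRIM_MIN_TAIL)
    return(list(keep = FALSE, insert = insert, tail_length = tail_length,
                reason = "tail_lt_10"))
  if (nchar(insert) < TRIM_MIN_LEN)
    return(list(keep = FALSE, insert = insert, tail_length = tail_length,
                reason = "too_short"))
  if (nchar(insert) > TRIM_MAX_LEN)
    return(list(keep = FALSE, insert = insert, tail_length = tail_length,
                reason = "too_long"))
  list(keep = TRUE, insert = insert, tail_length = tail_length,
       reason = NA_character_)
}

#' Preprocess one cell's raw reads
#'
#' UMI extraction followed by adapter/polyA trimming; every discarded read is
#' tallied by reason so kept + discarded equals the input count.
#'
#' @param seqs raw read sequences.
#' @param ids read identifiers.
#' @param adapter adapter sequence.
#' @param cell cell identifier attached to the output.
#' @return list(reads = data.frame(read_id, umi, cell, seq), report).
#' @export
preprocess_reads <- function(seqs, ids, adapter, cell = NA_character_) {
  n_in <- length(seqs)
  cellv <- rep_len(cell, max(n_in, 1L))
  ex <- extract_umi(seqs, ids)
  cellk <- cellv[seq_len(n_in)][ex$kept]
  ## identical remainders trim identically: process unique sequences once
  useq <- unique(ex$reads$seq)
  tr <- lapply(useq, trim_read, adapter = adapter)
  ui <- match(ex$reads$seq, useq)
  keep <- vapply(tr, `[[`, logical(1), "keep")[ui]
  reason <- vapply(tr, `[[`, character(1), "reason")[ui]
  insert <- vapply(tr, function(x)
    if (is.na(x$insert)) NA_character_ else x$insert, character(1))[ui]
  tailn <- vapply(tr, `[[`, integer(1), "tail_length")[ui]
  out <- data.frame(read_id = ex$reads$read_id[keep],
                    umi = ex$reads$umi[keep],
                    cell = cellk[keep],
                    seq = insert[keep],
                    tail_length = tailn[keep],
                    stringsAsFactors = FALSE)
  reasons <- table(factor(reason[!keep],
                          levels = c("no_tail", "tail_lt_10",
                                     "too_short", "too_long")))
  report <- c(list(cell = paste(unique(cellv[seq_len(n_in)]), collapse = ","),
                   input = n_in,
                   dropped_short_raw = ex$n_dropped,
                   kept = sum(keep)),
              as.list(setNames(as.integer(reasons), names(reasons))))
  list(reads = out, report = report)
}

#' Preprocess a FASTQ file
#'
#' @param fastq_path raw FASTQ.
#' @param adapter adapter sequence.
#' @param cell cell identifier (defaults to the file stem).
#' @param out_fastq optional trimmed-FASTQ output path (UMI in the read name).
#' @param report_json optional per-cell JSON trim-report path.
#' @return see \code{\link{preprocess_reads}}.
#' @export
preprocess_fastq <- function(fastq_path, adapter, cell = NULL,
                             out_fastq = NULL, report_json = NULL) {
  if (is.null(cell))
    cell <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_path))
  fq <- read_fastq(fastq_path)
  res <- preprocess_reads(fq$seq, fq$read_id, adapter, cell = cell)
  if (!is.null(out_fastq) && nrow(res$reads) > 0L)
    write_fastq(res$reads$seq, res$reads$read_id, out_fastq)
  if (!is.null(report_json))
    jsonlite::write_json(res$report, report_json, auto_unbox = TRUE)
  res
}
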