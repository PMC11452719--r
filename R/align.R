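## ---------------------------------------------------------------------------
## Best-stratum short-read placement with length-dependent mismatch filters
## and recursive 3'/5' soft-clip rescue.
##
## Semantics mirror bowtie1 "-a --best --strata -v 2 -m 50" for the full-length
## pass and "-v 1 -m 50" for clipped passes:
##   * all placements in the minimal-mismatch stratum are reported;
##   * a read whose best stratum holds more than 50 placements is suppressed
##     (terminally: suppressed reads are not soft-clip rescued);
##   * a mismatch at the read's original 3'-terminal base never counts
##     (tRNA CCA addition and miRNA 3' modification tolerance);
##   * full-length reads < 20 nt with any counted mismatch, and 20-40 nt reads
##     with two counted mismatches, are rejected (then eligible for rescue);
##   * soft clipping proceeds 1..3 nt from the 3' end, then 1..3 nt from the
##     5' end of the original read, stopping at the first success; clipped
##     placements only face the 17 nt mapping-length floor.
## ---------------------------------------------------------------------------

#' Build an alignment index over a genome
#'
#' Stores integer-coded chromosome sequences for the vectorised mismatch scan.
#' Brute-force by design: the pipeline targets toy-scale genomes.
#'
#' @param genome named character vector of chromosome sequences.
#' @return an object of class \code{sncatlas_index}.
#' @export
build_index <- function(genome) {
  stopifnot(length(genome) > 0L, !is.null(names(genome)))
  fwd <- lapply(genome, function(s) {
    v <- dna_to_int(s)
    v[is.na(v)] <- 0L   # ambiguity codes never match
    v
  })
  structure(list(genome = genome, fwd = fwd, chroms = names(genome)),
            class = "sncatlas_index")
}

## mismatch counts of `q` at every offset of every chromosome;
## `exempt` is a query position excluded from counting (0 = none)
scan_hits <- function(q, index, max_mm, exempt = 0L) {
  L <- length(q)
  out <- vector("list", length(index$chroms))
  for (ci in seq_along(index$chroms)) {
    g <- index$fwd[[ci]]
    n <- length(g) - L + 1L
    if (n < 1L) next
    mm <- integer(n)
    for (j in seq_len(L)) {
      if (j == exempt) next
      mm <- mm + (g[j:(j + n - 1L)] != q[j])
    }
    keep <- which(mm <= max_mm)
    if (length(keep))
      out[[ci]] <- data.frame(chrom = index$chroms[ci], start = keep - 1L,
                              mm = mm[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## both-strand candidate placements of a (sub)read. The exempt position is the
## read's original 3'-terminal base when it is part of the aligned core:
## query position L on "+", query position 1 (of the reverse complement) on "-".
strand_hits <- function(qplus, max_mm, index, exempt_terminal) {
  L <- length(qplus)
  hp <- scan_hits(qplus, index, max_mm, exempt = if (exempt_terminal) L else 0L)
  qminus <- rev(5L - qplus)
  qminus[qminus > 4L | qminus < 1L] <- 0L
  hm <- scan_hits(qminus, index, max_mm, exempt = if (exempt_terminal) 1L else 0L)
  if (!is.null(hp)) hp$strand <- "+"
  if (!is.null(hm)) hm$strand <- "-"
  rbind(hp, hm)
}

MAX_BEST_STRATUM_HITS <- 50L
MIN_MAPPING_LENGTH <- 17L

finish_hits <- function(hits, clip5, clip3, maplen) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  best <- min(hits$mm)
  hits <- hits[hits$mm == best, , drop = FALSE]
  hits$clip5 <- clip5; hits$clip3 <- clip3; hits$maplen <- maplen
  hits[order(hits$chrom, hits$start, hits$strand),
       c("chrom", "start", "strand", "mm", "clip5", "clip3", "maplen")]
}

#' Full-length placement of one read
#'
#' Returns every placement in the minimal-mismatch stratum (at most two
#' counted mismatches), or a status: "suppressed" when the best stratum holds
#' more than 50 placements, "unmapped" when nothing places or the
#' length-dependent mismatch filters reject the read (<20 nt with any counted
#' mismatch; 20-40 nt with two). A mismatch at the read's 3'-terminal base is
#' never counted.
#'
#' @param read read sequence (>= 18 nt).
#' @param index from \code{\link{build_index}}.
#' @return list(status, hits); hits is a data.frame of placements (0-based
#'   start) or NULL.
#' @export
map_full <- function(read, index) {
  L <- nchar(read)
  q <- dna_to_int(read)
  q[is.na(q)] <- 0L
  hits <- finish_hits(strand_hits(q, 2L, index, exempt_terminal = TRUE),
                      0L, 0L, L)
  if (is.null(hits)) return(list(status = "unmapped", hits = NULL))
  if (nrow(hits) > MAX_BEST_STRATUM_HITS)
    return(list(status = "suppressed", hits = NULL))
  best <- hits$mm[1]
  if (L < 20L && best >= 1L) return(list(status = "unmapped", hits = NULL))
  if (L >= 20L && L <= 40L && best == 2L)
    return(list(status = "unmapped", hits = NULL))
  list(status = "mapped", hits = hits)
}

#' Recursive soft-clip rescue of an unmapped read
#'
#' Clips 1, 2, then 3 nt from the 3' end (at most one counted mismatch per
#' attempt), stopping at the first success; if still unmapped, repeats from
#' the 5' end of the original read. Attempts whose mapping length would fall
#' below 17 nt are not made; a best stratum above 50 placements ends the
#' rescue as "suppressed". Clipped bases are kept with the result (they feed
#' non-templated-addition calling). The 3'-terminal-base exemption applies
#' only while that base is part of the aligned core (5' clips), never after
#' it has been clipped away.
#'
#' @param read read sequence.
#' @param index from \code{\link{build_index}}.
#' @return list(status, hits, clipped5, clipped3).
#' @export
rescue_clip <- function(read, index) {
  L <- nchar(read)
  q <- dna_to_int(read)
  q[is.na(q)] <- 0L
  for (c3 in 1:3) {
    core <- L - c3
    if (core < MIN_MAPPING_LENGTH) break
    hits <- finish_hits(strand_hits(q[seq_len(core)], 1L, index,
                                    exempt_terminal = FALSE),
                        0L, c3, core)
    if (is.null(hits)) next
    if (nrow(hits) > MAX_BEST_STRATUM_HITS)
      return(list(status = "suppressed", hits = NULL,
                  clipped5 = "", clipped3 = ""))
    return(list(status = "mapped", hits = hits, clipped5 = "",
                clipped3 = substr(read, core + 1L, L)))
  }
  for (c5 in 1:3) {
    core <- L - c5
    if (core < MIN_MAPPING_LENGTH) break
    hits <- finish_hits(strand_hits(q[(c5 + 1L):L], 1L, index,
                                    exempt_terminal = TRUE),
                        c5, 0L, core)
    if (is.null(hits)) next
    if (nrow(hits) > MAX_BEST_STRATUM_HITS)
      return(list(status = "suppressed", hits = NULL,
                  clipped5 = "", clipped3 = ""))
    return(list(status = "mapped", hits = hits,
                clipped5 = substr(read, 1L, c5), clipped3 = ""))
  }
  list(status = "unmapped", hits = NULL, clipped5 = "", clipped3 = "")
}

## full pipeline for one read sequence: full-length pass then rescue
place_read <- function(read, index) {
  full <- map_full(read, index)
  if (full$status == "mapped")
    return(list(status = "mapped", hits = full$hits, clipped5 = "", clipped3 = ""))
  if (full$status == "suppressed")
    return(list(status = "suppressed", hits = NULL, clipped5 = "", clipped3 = ""))
  rescue_clip(read, index)
}

#' Align a batch of trimmed reads
#'
#' Places each distinct insert sequence once (full-length pass, then soft-clip
#' rescue) and expands the result over reads. Optionally writes a SAM file
#' with UMIs in RX tags and clip metadata in the CIGAR.
#'
#' @param reads data.frame with read_id, umi, cell, seq (trimmed inserts).
#' @param index from \code{\link{build_index}}.
#' @param sam_path optional SAM output path.
#' @return list(reads, placements, tally): \code{reads} gains status/clip
#'   columns; \code{placements} holds one row per retained placement;
#'   \code{tally} counts mapped/unmapped/suppressed per cell.
#' @export
align_batch <- function(reads, index, sam_path = NULL) {
  stopifnot(all(c("read_id", "umi", "cell", "seq") %in% names(reads)))
  useq <- unique(reads$seq)
  res <- lapply(useq, place_read, index = index)
  status_u <- vapply(res, `[[`, character(1), "status")
  clip5_u <- vapply(res, `[[`, character(1), "clipped5")
  clip3_u <- vapply(res, `[[`, character(1), "clipped3")
  ui <- match(reads$seq, useq)
  reads$status <- status_u[ui]
  reads$clipped5 <- clip5_u[ui]
  reads$clipped3 <- clip3_u[ui]

  placements <- vector("list", length(useq))
  for (k in seq_along(useq)) {
    h <- res[[k]]$hits
    if (is.null(h)) next
    h$useq <- k
    placements[[k]] <- h
  }
  placements <- do.call(rbind, placements)
  if (!is.null(placements)) {
    nhit <- tabulate(placements$useq, nbins = length(useq))
    idx <- which(reads$status == "mapped")
    ord <- order(placements$useq)
    placements <- placements[ord, , drop = FALSE]
    offset <- c(0L, cumsum(nhit))   # row offsets per unique sequence
    take <- unlist(lapply(idx, function(i)
      offset[ui[i]] + seq_len(nhit[ui[i]])), use.names = FALSE)
    expanded <- placements[take, , drop = FALSE]
    expanded$read_id <- rep(reads$read_id[idx], nhit[ui[idx]])
    expanded$cell <- rep(reads$cell[idx], nhit[ui[idx]])
    expanded$nhits <- nhit[expanded$useq]
    expanded$useq <- NULL
    rownames(expanded) <- NULL
    placements <- expanded
  } else {
    placements <- data.frame(chrom = character(), start = integer(),
                             strand = character(), mm = integer(),
                             clip5 = integer(), clip3 = integer(),
                             maplen = integer(), read_id = character(),
                             cell = character(), nhits = integer(),
                             stringsAsFactors = FALSE)
  }
  tally <- if (nrow(reads) == 0L) {
    data.frame(cell = character(), status = character(), n = integer(),
               stringsAsFactors = FALSE)
  } else {
    t0 <- as.data.frame(table(cell = reads$cell, status = reads$status),
                        stringsAsFactors = FALSE)
    names(t0)[3] <- "n"
    t0
  }
  if (!is.null(sam_path))
    write_sam(placements, reads, index$genome, sam_path)
  list(reads = reads, placements = placements, tally = tally)
}

#' Align one cell's FASTQ of trimmed reads
#'
#' Thin wrapper over \code{\link{align_batch}} for file-based use; read names
#' must carry the UMI as an underscore-delimited suffix (as produced by
#' \code{\link{extract_umi}}).
#'
#' @param fastq_path FASTQ of trimmed inserts.
#' @param index from \code{\link{build_index}}.
#' @param cell cell identifier.
#' @param sam_path optional SAM output.
#' @return see \code{\link{align_batch}}.
#' @export
align_cell_fastq <- function(fastq_path, index, cell, sam_path = NULL) {
  fq <- read_fastq(fastq_path)
  umi <- sub("^.*_", "", fq$read_id)
  if (any(nchar(umi) != 8L))
    stopf("malformed read name (no 8 nt UMI suffix): %s",
          fq$read_id[which(nchar(umi) != 8L)[1]])
  reads <- data.frame(read_id = fq$read_id, umi = umi, cell = cell,
                      seq = fq$seq, stringsAsFactors = FALSE)
  align_batch(reads, index, sam_path = sam_path)
}
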