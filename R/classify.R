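## ---------------------------------------------------------------------------
## isomiR and tRNA-derived-fragment classification.
##
## isomiRs: end shifts of -3..+3 relative to the annotated mature miRNA plus
## 3' non-templated additions (NTAs). The NTA is the maximal 3'-terminal run
## of read bases (soft-clipped or aligned) that mismatch the genome at their
## implied positions; the templated 3' end is what remains, and the shifts
## are computed from the templated ends in mature-strand orientation. Calling
## NTAs from soft clips alone would miss 1-2 nt adenosine tails, which map
## full length because the terminal mismatch is exempted and a single
## internal mismatch is tolerated.
##
## tRFs: 5' halves (length < 50, 3' end shifted <= -10 into the gene, 5' end
## not), 3' halves (mirror image), full length (length > 50, neither end
## shifted <= -10); everything else, including length exactly 50, is
## unclassified.
## ---------------------------------------------------------------------------

ISOMIR_MAX_SHIFT <- 3L

## is each read base templated at its implied genome position?
## p: 1-based read positions; returns logical
templated_bases <- function(seq, positions, chrom, start, maplen, clip5,
                            strand, genome) {
  g <- genome[[chrom]]
  glen <- nchar(g)
  vapply(positions, function(p) {
    b <- substr(seq, p, p)
    if (strand == "+") {
      gpos <- start + (p - clip5 - 1L)        # 0-based
      if (gpos < 0L || gpos >= glen) return(FALSE)
      substr(g, gpos + 1L, gpos + 1L) == b
    } else {
      gpos <- (start + maplen - 1L) - (p - clip5 - 1L)
      if (gpos < 0L || gpos >= glen) return(FALSE)
      chartr("ACGT", "TGCA", substr(g, gpos + 1L, gpos + 1L)) == b
    }
  }, logical(1))
}

## classify one miRNA molecule against its mature reference
classify_isomir_one <- function(seq, chrom, start, strand, maplen, clip5, clip3,
                                mature_start, mature_end, mature_strand,
                                genome) {
  L <- nchar(seq)
  ## maximal non-templated 3'-terminal run (clipped and aligned bases alike)
  run <- 0L
  while (run < L) {
    p <- L - run
    if (templated_bases(seq, p, chrom, start, maplen, clip5, strand, genome))
      break
    run <- run + 1L
  }
  nta <- if (run > 0L) substr(seq, L - run + 1L, L) else ""
  ## genomic boundaries of the templated segment
  if (strand == "+") {
    g5 <- start                                   # 0-based inclusive
    g3 <- start + (L - run - clip5 - 1L) + 1L     # 0-based exclusive
    shift5 <- mature_start - g5
    shift3 <- g3 - mature_end
  } else {
    g5 <- start + maplen                          # exclusive, feature 5' side
    g3 <- (start + maplen - 1L) - (L - run - clip5 - 1L)  # inclusive
    shift5 <- g5 - mature_end
    shift3 <- mature_start - g3
  }
  excluded <- abs(shift5) > ISOMIR_MAX_SHIFT || abs(shift3) > ISOMIR_MAX_SHIFT ||
    run > 3L
  length_class <-
    if (shift5 == 0L && shift3 == 0L) "canonical"
    else if (shift3 == 0L) if (shift5 > 0L) "5'-elong" else "5'-trim"
    else if (shift5 == 0L) if (shift3 > 0L) "3'-elong" else "3'-trim"
    else "mixed"
  list(shift5 = shift5, shift3 = shift3, nta = nta,
       length_class = length_class,
       has_nta = nta != "",
       is_canonical = length_class == "canonical" && nta == "",
       excluded = excluded)
}

#' Classify miRNA molecules into isomiR categories
#'
#' @param assigned annotated molecules (from \code{\link{annotate_molecules}});
#'   only rows with category "miRNA" are used.
#' @param placements molecule placements.
#' @param annotations an \code{annotation_set}.
#' @param genome named character vector of chromosome sequences.
#' @return list(records, n_excluded): one record per classified molecule with
#'   shift5/shift3 (positive = elongation beyond the annotated end), the NTA
#'   string, the length-variation class and flags; molecules shifted beyond
#'   +-3 are excluded and tallied.
#' @export
classify_isomir <- function(assigned, placements, annotations, genome) {
  mir <- assigned[!is.na(assigned$category) & assigned$category == "miRNA", ,
                  drop = FALSE]
  recs <- annotations$records
  mat <- recs[recs$biotype == "miRNA", , drop = FALSE]
  by_mol <- split(seq_len(nrow(placements)), placements$molecule_id)
  fi <- match(mir$feature, mat$name)
  n <- nrow(mir)
  shift5 <- shift3 <- integer(n)
  nta <- length_class <- character(n)
  has_nta <- is_canonical <- excluded <- logical(n)
  for (i in seq_len(n)) {
    f <- mat[fi[i], , drop = FALSE]
    pl <- placements[by_mol[[mir$molecule_id[i]]], , drop = FALSE]
    pl <- pl[pl$chrom == f$chrom & pl$strand == f$strand &
               pl$start < f$end & (pl$start + pl$maplen) > f$start, ,
             drop = FALSE]
    if (nrow(pl) == 0L)
      stopf("molecule %s assigned to miRNA %s has no placement overlapping the mature interval",
            mir$molecule_id[i], mir$feature[i])
    ov <- pmin(pl$start + pl$maplen, f$end) - pmax(pl$start, f$start)
    pl <- pl[order(-ov, pl$chrom, pl$start), , drop = FALSE][1L, ]
    r <- classify_isomir_one(mir$seq[i], pl$chrom, pl$start, pl$strand,
                             pl$maplen, pl$clip5, pl$clip3,
                             f$start, f$end, f$strand, genome)
    shift5[i] <- r$shift5; shift3[i] <- r$shift3; nta[i] <- r$nta
    length_class[i] <- r$length_class; has_nta[i] <- r$has_nta
    is_canonical[i] <- r$is_canonical; excluded[i] <- r$excluded
  }
  recsdf <- data.frame(molecule_id = mir$molecule_id, cell = mir$cell,
                       mirna = mir$feature, shift5 = shift5, shift3 = shift3,
                       nta = nta, length_class = length_class,
                       has_nta = has_nta, is_canonical = is_canonical,
                       excluded = excluded, stringsAsFactors = FALSE)
  list(records = recsdf[!recsdf$excluded, , drop = FALSE],
       n_excluded = sum(recsdf$excluded))
}

ISOMIR_CLASSES <- c("canonical", "5'-trim", "5'-elong", "3'-trim", "3'-elong",
                    "mixed")

#' Per-day isomiR summary tables
#'
#' @param records isomiR records (from \code{\link{classify_isomir}}).
#' @param metadata cell metadata with day labels.
#' @return list(by_day, nta_composition): per-day fractions of strictly
#'   canonical molecules, of each length-variation class (summing to 1), and
#'   of NTA-bearing molecules; NTA composition counts adenosine runs of
#'   length 1-3 distinctly.
#' @export
summarize_isomir <- function(records, metadata) {
  stopifnot(nrow(records) > 0L)
  day <- metadata$day[match(records$cell, metadata$cell)]
  by_day <- do.call(rbind, lapply(split(seq_len(nrow(records)), day),
                                  function(idx) {
    r <- records[idx, , drop = FALSE]
    cls <- vapply(ISOMIR_CLASSES,
                  function(k) mean(r$length_class == k), numeric(1))
    data.frame(day = day[idx][1L], n = nrow(r),
               frac_canonical = mean(r$is_canonical),
               t(cls), frac_nta = mean(r$has_nta),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(by_day) <- NULL
  nta <- records[records$has_nta, , drop = FALSE]
  comp <- data.frame(
    nta = c("A", "AA", "AAA"),
    n = vapply(c("A", "AA", "AAA"), function(s) sum(nta$nta == s), integer(1)),
    stringsAsFactors = FALSE)
  comp$other <- nrow(nta) - sum(comp$n)
  list(by_day = by_day, nta_composition = comp)
}

TRF_HALF_MAX_LEN <- 50L     # halves are shorter than this
TRF_FULL_MIN_LEN <- 50L     # full-length exceeds this
TRF_SHIFT_CUTOFF <- -10L    # "a shift of at least -10" (inclusive)

#' tRF class from read length and end shifts
#'
#' Pure rule table: shifts are relative to the annotated tRNA ends in gene
#' orientation, negative values pointing into the gene.
#'
#' @param length read length (nt).
#' @param shift5,shift3 end shifts.
#' @return character vector in {five_prime_half, three_prime_half,
#'   full_length, unclassified}.
#' @export
classify_trf <- function(length, shift5, shift3) {
  ifelse(length < TRF_HALF_MAX_LEN & shift3 <= TRF_SHIFT_CUTOFF &
           shift5 > TRF_SHIFT_CUTOFF, "five_prime_half",
  ifelse(length < TRF_HALF_MAX_LEN & shift5 <= TRF_SHIFT_CUTOFF &
           shift3 > TRF_SHIFT_CUTOFF, "three_prime_half",
  ifelse(length > TRF_FULL_MIN_LEN & shift5 > TRF_SHIFT_CUTOFF &
           shift3 > TRF_SHIFT_CUTOFF, "full_length", "unclassified")))
}

#' Classify tRNA molecules into tRF classes
#'
#' @param assigned annotated molecules; rows with category "tRNA" are used.
#' @param placements molecule placements.
#' @param annotations an \code{annotation_set}.
#' @return data.frame of TRF records (tRNA name, amino acid, anticodon,
#'   length, shifts, klass).
#' @export
classify_trf_molecules <- function(assigned, placements, annotations) {
  trna <- assigned[!is.na(assigned$category) & assigned$category == "tRNA", ,
                   drop = FALSE]
  recs <- annotations$records
  tref <- recs[recs$biotype == "tRNA", , drop = FALSE]
  if (nrow(trna) == 0L)
    return(data.frame(molecule_id = character(), cell = character(),
                      trna = character(), aa = character(),
                      anticodon = character(), length = integer(),
                      shift5 = integer(), shift3 = integer(),
                      klass = character(), stringsAsFactors = FALSE))
  f <- tref[match(trna$feature, tref$name), , drop = FALSE]
  ## the placement overlapping the assigned tRNA
  pl <- placements[order(placements$molecule_id, placements$chrom,
                         placements$start), , drop = FALSE]
  by_mol <- split(seq_len(nrow(pl)), pl$molecule_id)
  n <- nrow(trna)
  s5 <- s3 <- integer(n)
  for (i in seq_len(n)) {
    pm <- pl[by_mol[[trna$molecule_id[i]]], , drop = FALSE]
    p <- pm[pm$chrom == f$chrom[i] & pm$strand == f$strand[i] &
              pm$start < f$end[i] & (pm$start + pm$maplen) > f$start[i], ,
            drop = FALSE][1L, ]
    astart <- p$start; aend <- p$start + p$maplen
    if (f$strand[i] == "+") {
      s5[i] <- f$start[i] - astart
      s3[i] <- aend - f$end[i]
    } else {
      s5[i] <- aend - f$end[i]
      s3[i] <- f$start[i] - astart
    }
  }
  res <- data.frame(molecule_id = trna$molecule_id, cell = trna$cell,
                    trna = trna$feature, aa = f$aa, anticodon = f$anticodon,
                    length = nchar(trna$seq), shift5 = s5, shift3 = s3,
                    stringsAsFactors = FALSE)
  res$klass <- classify_trf(res$length, res$shift5, res$shift3)
  res
}

#' Per-day amino-acid usage tables per tRF class
#'
#' @param trf_records from \code{\link{classify_trf_molecules}}.
#' @param metadata cell metadata with day labels.
#' @return data.frame(klass, day, aa, n, proportion); proportions sum to 1
#'   within each (klass, day).
#' @export
codon_usage <- function(trf_records, metadata) {
  stopifnot(nrow(trf_records) > 0L)
  r <- trf_records[trf_records$klass != "unclassified", , drop = FALSE]
  r$day <- metadata$day[match(r$cell, metadata$cell)]
  tab <- as.data.frame(table(klass = r$klass, day = r$day, aa = r$aa),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab <- tab[tab$n >= 0, , drop = FALSE]
  totals <- stats::aggregate(n ~ klass + day, tab, sum)
  ti <- match(paste(tab$klass, tab$day), paste(totals$klass, totals$day))
  tab$proportion <- ifelse(totals$n[ti] > 0, tab$n / totals$n[ti], NA_real_)
  tab
}
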