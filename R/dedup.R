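## ---------------------------------------------------------------------------
## Directional UMI deduplication and remapping.
##
## Reads are grouped per cell by (chromosome, strand, template 5' position)
## of their lexicographically first placement (template start adjusted for a
## 5' soft clip); within a group, UMIs are clustered with the directional
## rule: a directed edge a -> b exists when Hamming(a, b) <= 1 and
## count(a) >= 2 * count(b) - 1. Components are grown breadth-first from
## local count maxima taken in decreasing-count order (ties broken
## lexicographically), so a low-count UMI reachable from two maxima joins the
## higher-count one.
## ---------------------------------------------------------------------------

## character matrix of UMIs (rows) for vectorised Hamming distance
umi_char_matrix <- function(umis) {
  do.call(rbind, strsplit(umis, "", fixed = TRUE))
}

## directional clustering of one position group; returns cluster id per UMI
directional_clusters <- function(umis, counts) {
  n <- length(umis)
  if (n == 1L) return(1L)
  ord <- order(-counts, umis)
  M <- umi_char_matrix(umis)
  cluster <- integer(n)
  cid <- 0L
  for (i in ord) {
    if (cluster[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    cluster[i] <- cid
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      cand <- which(cluster == 0L)
      if (!length(cand)) break
      d <- colSums(t(M[cand, , drop = FALSE]) != M[u, ])
      ok <- cand[d <= 1L & counts[u] >= 2L * counts[cand] - 1L]
      if (length(ok)) {
        cluster[ok] <- cid
        queue <- c(queue, ok)
      }
    }
  }
  cluster
}

#' Collapse PCR amplicons to molecules by directional UMI clustering
#'
#' @param reads aligned reads: data.frame with read_id, umi, cell, seq and
#'   clip columns (from \code{\link{align_batch}}).
#' @param placements their placements (one row per read x placement).
#' @return list(molecules, placements): one molecule per UMI cluster with the
#'   highest-count UMI's (lexicographically first) read as representative;
#'   placements are the representative's placement set.
#' @export
dedup_directional <- function(reads, placements) {
  if (any(nchar(reads$umi) != 8L))
    stopf("all UMIs must be 8 nt")
  mapped <- reads[reads$read_id %in% placements$read_id, , drop = FALSE]
  if (nrow(mapped) == 0L)
    return(list(molecules = empty_molecules(), placements = placements[0, ]))

  ## lexicographically first placement per read -> grouping key
  p <- placements[order(placements$read_id, placements$chrom,
                        placements$start, placements$strand), , drop = FALSE]
  p1 <- p[!duplicated(p$read_id), , drop = FALSE]
  ri <- match(mapped$read_id, p1$read_id)
  tpl5 <- ifelse(p1$strand[ri] == "+",
                 p1$start[ri] - p1$clip5[ri],
                 p1$start[ri] + p1$maplen[ri] + p1$clip5[ri])
  key <- paste(mapped$cell, p1$chrom[ri], p1$strand[ri], tpl5, sep = "\r")

  rep_row_v <- integer(0)
  n_umis_v <- integer(0)
  n_reads_v <- integer(0)
  for (grp in split(seq_len(nrow(mapped)), key)) {
    umi_counts <- table(mapped$umi[grp])
    umis <- names(umi_counts)
    counts <- as.integer(umi_counts)
    cl <- directional_clusters(umis, counts)
    for (cid in unique(cl)) {
      members <- umis[cl == cid]
      mcounts <- counts[cl == cid]
      top <- members[order(-mcounts, members)][1L]
      rows <- grp[mapped$umi[grp] %in% members]
      rep_rows <- rows[mapped$umi[rows] == top]
      rep_row_v <- c(rep_row_v, rep_rows[order(mapped$read_id[rep_rows])][1L])
      n_umis_v <- c(n_umis_v, length(members))
      n_reads_v <- c(n_reads_v, length(rows))
    }
  }
  molecules <- data.frame(
    cell = mapped$cell[rep_row_v],
    rep_read_id = mapped$read_id[rep_row_v],
    umi = mapped$umi[rep_row_v],
    n_umis = n_umis_v,
    n_reads = n_reads_v,
    seq = mapped$seq[rep_row_v],
    clipped5 = mapped$clipped5[rep_row_v],
    clipped3 = mapped$clipped3[rep_row_v],
    stringsAsFactors = FALSE)
  molecules$molecule_id <- sprintf("mol%06d", seq_len(nrow(molecules)))
  mp <- placements[placements$read_id %in% molecules$rep_read_id, , drop = FALSE]
  mp$molecule_id <- molecules$molecule_id[match(mp$read_id, molecules$rep_read_id)]
  list(molecules = molecules, placements = mp)
}

empty_molecules <- function() {
  data.frame(cell = character(), rep_read_id = character(), umi = character(),
             n_umis = integer(), n_reads = integer(), seq = character(),
             clipped5 = character(), clipped3 = character(),
             molecule_id = character(), stringsAsFactors = FALSE)
}

#' Remap molecule representatives to restore multi-mapping information
#'
#' Each representative insert is re-run through the full placement procedure
#' (full-length pass, then soft-clip rescue); the molecule's placement set is
#' replaced by the fresh result and molecules that no longer place are
#' dropped with a tally.
#'
#' @param dedup result of \code{\link{dedup_directional}}.
#' @param index from \code{\link{build_index}}.
#' @return list(molecules, placements, n_dropped).
#' @export
remap_molecules <- function(dedup, index) {
  mol <- dedup$molecules
  if (nrow(mol) == 0L)
    return(list(molecules = mol, placements = dedup$placements, n_dropped = 0L))
  useq <- unique(mol$seq)
  res <- lapply(useq, place_read, index = index)
  ui <- match(mol$seq, useq)
  status <- vapply(res, `[[`, character(1), "status")[ui]
  keep <- status == "mapped"
  hits_all <- do.call(rbind, lapply(seq_along(useq), function(k) {
    h <- res[[k]]$hits
    if (is.null(h)) return(NULL)
    h$useq <- k
    h
  }))
  nhit <- tabulate(hits_all$useq, nbins = length(useq))
  hits_all <- hits_all[order(hits_all$useq), , drop = FALSE]
  offset <- c(0L, cumsum(nhit))
  idx <- which(keep)
  take <- unlist(lapply(idx, function(i)
    offset[ui[i]] + seq_len(nhit[ui[i]])), use.names = FALSE)
  placements <- hits_all[take, , drop = FALSE]
  placements$read_id <- rep(mol$rep_read_id[idx], nhit[ui[idx]])
  placements$cell <- rep(mol$cell[idx], nhit[ui[idx]])
  placements$molecule_id <- rep(mol$molecule_id[idx], nhit[ui[idx]])
  placements$nhits <- nhit[placements$useq]
  placements$useq <- NULL
  rownames(placements) <- NULL
  mol2 <- mol[keep, , drop = FALSE]
  ## clip metadata may change on remap (fresh rescue of the insert)
  clip5_u <- vapply(res, `[[`, character(1), "clipped5")
  clip3_u <- vapply(res, `[[`, character(1), "clipped3")
  mol2$clipped5 <- clip5_u[match(mol2$seq, useq)]
  mol2$clipped3 <- clip3_u[match(mol2$seq, useq)]
  list(molecules = mol2, placements = placements, n_dropped = sum(!keep))
}
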