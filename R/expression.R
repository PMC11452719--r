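## ---------------------------------------------------------------------------
## Cell QC, feature filtering, normalisation, and Wilcoxon marker /
## differential-expression statistics.
##
## Count matrices are cells x features throughout. QC thresholds follow the
## study design: at least 0.5 million sequenced reads per cell, mitochondrial
## UMI fraction below 25%, and more than 100 miRNA molecules.
## ---------------------------------------------------------------------------

QC_MIN_READS <- 5e5
QC_MAX_MITO <- 0.25
QC_MIN_MIRNA <- 100L

#' Per-cell QC statistics from annotated molecules
#'
#' @param assigned annotated molecules (with category and cell).
#' @param placements molecule placements (to locate mitochondrial molecules).
#' @param metadata cell metadata with a sequenced_reads column (raw
#'   sequencing depth).
#' @param mito_chroms chromosome names counted as mitochondrial.
#' @return data.frame cell, sequenced_reads, mito_fraction, mirna_molecules.
#' @export
compute_cell_stats <- function(assigned, placements, metadata,
                               mito_chroms = c("chrM", "MT")) {
  p1 <- placements[order(placements$molecule_id, placements$chrom,
                         placements$start), , drop = FALSE]
  p1 <- p1[!duplicated(p1$molecule_id), , drop = FALSE]
  mito <- p1$molecule_id[p1$chrom %in% mito_chroms]
  stats_df <- data.frame(cell = metadata$cell,
                         sequenced_reads = metadata$sequenced_reads,
                         stringsAsFactors = FALSE)
  tot <- table(factor(assigned$cell, levels = metadata$cell))
  mt <- table(factor(assigned$cell[assigned$molecule_id %in% mito],
                     levels = metadata$cell))
  mir <- table(factor(assigned$cell[!is.na(assigned$category) &
                                      assigned$category == "miRNA"],
                      levels = metadata$cell))
  stats_df$mito_fraction <- ifelse(tot == 0, 0, as.numeric(mt) / as.numeric(tot))
  stats_df$mirna_molecules <- as.integer(mir)
  stats_df
}

#' Cell quality control
#'
#' A cell passes when it has at least \code{min_reads} sequenced reads, a
#' mitochondrial UMI fraction below \code{max_mito}, and more than
#' \code{min_mirna} miRNA molecules. Failing cells are removed from every
#' supplied matrix; failure reasons are recorded.
#'
#' @param cell_stats from \code{\link{compute_cell_stats}} (cell,
#'   sequenced_reads, mito_fraction, mirna_molecules).
#' @param matrices optional named list of cells x features matrices to filter.
#' @param min_reads,max_mito,min_mirna thresholds.
#' @return list(records, matrices): records carries pass flags and
#'   comma-separated failure reasons.
#' @export
qc_cells <- function(cell_stats, matrices = NULL,
                     min_reads = QC_MIN_READS, max_mito = QC_MAX_MITO,
                     min_mirna = QC_MIN_MIRNA) {
  needed <- c("cell", "sequenced_reads", "mito_fraction", "mirna_molecules")
  if (!all(needed %in% names(cell_stats)))
    stopf("cell_stats must have columns: %s", paste(needed, collapse = ", "))
  if (anyNA(cell_stats$sequenced_reads))
    stopf("missing read tally for cell(s): %s",
          paste(cell_stats$cell[is.na(cell_stats$sequenced_reads)],
                collapse = ", "))
  fail_reads <- cell_stats$sequenced_reads < min_reads
  fail_mito <- cell_stats$mito_fraction >= max_mito
  fail_mirna <- cell_stats$mirna_molecules <= min_mirna
  reasons <- mapply(function(a, b, c)
    paste(c(if (a) "reads", if (b) "mito", if (c) "mirna"), collapse = ","),
    fail_reads, fail_mito, fail_mirna)
  rec <- cell_stats
  rec$pass <- !(fail_reads | fail_mito | fail_mirna)
  rec$fail_reasons <- ifelse(rec$pass, "", reasons)
  keep <- rec$cell[rec$pass]
  if (!is.null(matrices))
    matrices <- lapply(matrices, function(m)
      m[rownames(m) %in% keep, , drop = FALSE])
  list(records = rec, matrices = matrices)
}

#' Keep features with at least one count in at least two cells
#'
#' @param mat cells x features count matrix.
#' @return the filtered matrix.
#' @export
filter_features <- function(mat) {
  mat[, colSums(mat >= 1) >= 2L, drop = FALSE]
}

#' Log-normalise counts with batch-comparable size factors
#'
#' Size factors are library sizes scaled by the median library size of the
#' cell's batch, then rescaled by the batch's depth relative to the
#' shallowest batch so that normalised values are comparable across batches
#' (the rescaled factor is simply library size over the smallest batch-median
#' library size). Normalised values are log2(count / factor + 1).
#'
#' @param mat cells x features count matrix.
#' @param batch batch label per cell (single batch: plain library-size
#'   factors against the median cell).
#' @return list(lognorm, size_factors, centered_factors): centered factors
#'   have median 1 within each batch.
#' @export
normalize_counts <- function(mat, batch = NULL) {
  stopifnot(nrow(mat) > 0L, ncol(mat) > 0L)
  lib <- rowSums(mat)
  if (any(lib == 0))
    stopf("cell(s) with zero total counts (should have failed QC): %s",
          paste(rownames(mat)[lib == 0], collapse = ", "))
  if (is.null(batch)) batch <- rep("all", nrow(mat))
  med <- tapply(lib, batch, median)
  centered <- as.numeric(lib / med[batch])
  sf <- as.numeric(centered * (med[batch] / min(med)))   # = lib / min(med)
  lognorm <- log2(mat / sf + 1)
  list(lognorm = lognorm, size_factors = unname(sf),
       centered_factors = unname(centered))
}

## two-sided rank-sum p; exact enumeration for small tie-free groups,
## normal approximation with tie correction otherwise
rank_sum_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  exact <- length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
  suppressWarnings(wilcox.test(x, y, exact = exact)$p.value)
}

#' Wilcoxon differential expression between two groups
#'
#' Per feature: two-sided rank-sum p, log2 fold change of expm-scale group
#' means (difference of log2(mean(2^norm - 1) + 1)), expressing-cell
#' fractions, BH adjustment across features, and the significance call:
#' FDR below \code{fdr_threshold}, |log2FC| above \code{log2fc_threshold},
#' and more than \code{min_frac} expressing cells in the favoured group.
#'
#' @param norm cells x features log-normalised matrix.
#' @param groups two-level factor (or coercible) over cells; the fold change
#'   is first level over second.
#' @param log2fc_threshold fold-change cutoff (0.1 for miRNA stage contrasts,
#'   0.25 for ICM-vs-TE gene contrasts).
#' @param fdr_threshold BH FDR cutoff.
#' @param min_frac minimum expressing fraction in the favoured group.
#' @return data.frame feature, log2fc, p, fdr, pct1, pct2, significant.
#' @export
wilcoxon_de <- function(norm, groups, log2fc_threshold = 0.1,
                        fdr_threshold = 0.05, min_frac = 1 / 3) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stopf("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stopf("both groups need at least 2 cells")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  feats <- colnames(norm)
  p <- numeric(length(feats))
  l2fc <- numeric(length(feats))
  pct1 <- numeric(length(feats))
  pct2 <- numeric(length(feats))
  for (j in seq_along(feats)) {
    x <- norm[g1, j]; y <- norm[g2, j]
    p[j] <- rank_sum_p(x, y)
    l2fc[j] <- log2(mean(2^x - 1) + 1) - log2(mean(2^y - 1) + 1)
    pct1[j] <- mean(x > 0); pct2[j] <- mean(y > 0)
  }
  fdr <- p.adjust(p, method = "BH")
  favored_frac <- ifelse(l2fc >= 0, pct1, pct2)
  data.frame(feature = feats, log2fc = l2fc, p = p, fdr = fdr,
             pct1 = pct1, pct2 = pct2,
             significant = fdr < fdr_threshold &
               abs(l2fc) > log2fc_threshold & favored_frac > min_frac,
             stringsAsFactors = FALSE)
}

#' One-vs-rest marker detection per cluster
#'
#' @param norm cells x features log-normalised matrix.
#' @param clusters cluster label per cell.
#' @param padj_threshold adjusted-p cutoff for reported markers.
#' @return named list (one data.frame per cluster) of positive markers with
#'   adjusted p below the cutoff, ranked by log2 fold change; singleton
#'   clusters are skipped with a warning.
#' @export
find_markers <- function(norm, clusters, padj_threshold = 0.001) {
  clusters <- as.character(clusters)
  out <- list()
  for (cl in sort(unique(clusters))) {
    if (sum(clusters == cl) < 2L) {
      warnf("cluster '%s' has fewer than 2 cells; skipped", cl)
      next
    }
    grp <- factor(ifelse(clusters == cl, "this", "rest"),
                  levels = c("this", "rest"))
    de <- wilcoxon_de(norm, grp)
    mk <- de[de$fdr < padj_threshold & de$log2fc > 0, , drop = FALSE]
    out[[cl]] <- mk[order(-mk$log2fc), , drop = FALSE]
  }
  out
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stopf("cannot parse region '%s'", region)
    return(list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4])))
  }
  region
}

#' Aggregate expression over a genomic region and locate markers in it
#'
#' @param mat cells x features matrix.
#' @param annotations an \code{annotation_set}.
#' @param region "chrom:start-end" string or list(chrom, start, end)
#'   (0-based half-open).
#' @param markers optional character vector of marker feature names.
#' @return list(aggregate = per-cell sum over member features,
#'   members, marker_proportion = fraction of markers inside the region).
#' @export
aggregate_locus <- function(mat, annotations, region, markers = NULL) {
  region <- parse_region(region)
  r <- annotations$records
  inside <- r$chrom == region$chrom & r$start < region$end & r$end > region$start
  members <- intersect(r$name[inside], colnames(mat))
  if (length(members) == 0L) {
    warnf("region contains no features present in the matrix")
    agg <- setNames(rep(0, nrow(mat)), rownames(mat))
  } else {
    agg <- rowSums(mat[, members, drop = FALSE])
  }
  marker_prop <- if (is.null(markers) || length(markers) == 0L) {
    data.frame(region = character(), n_markers = integer(),
               n_inside = integer(), proportion = numeric())
  } else {
    n_in <- sum(markers %in% r$name[inside])
    data.frame(region = paste0(region$chrom, ":", region$start, "-", region$end),
               n_markers = length(markers), n_inside = n_in,
               proportion = n_in / length(markers))
  }
  list(aggregate = agg, members = members, marker_proportion = marker_prop)
}
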