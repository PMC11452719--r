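## ---------------------------------------------------------------------------
## Pseudotime branch alignment, trajectory-associated miRNA selection and
## pattern clustering, pseudobulk miRNA-target anticorrelation, and the
## four-criterion novel-miRNA filter.
## ---------------------------------------------------------------------------

#' Rescale ICM pseudotime onto the TE branch's time axis
#'
#' ICM and TE pseudotimes are inferred per branch and must be aligned. With
#' Psd_pre_max, Psd_ICM_max and Psd_TE_max the latest pseudotimes of the
#' pre-lineage, ICM and TE cells:
#' \deqn{scale = (Psd_{TEmax} - Psd_{premax}) / (Psd_{ICMmax} - Psd_{premax})}
#' and every ICM cell beyond the pre-lineage maximum is mapped to
#' \deqn{Psd' = (Psd - Psd_{premax}) \cdot scale + Psd_{premax}.}
#' TE and pre-lineage cells are unchanged; the rescaled ICM maximum equals
#' the TE maximum, and the transform is the identity when the two branch
#' maxima coincide.
#'
#' @param pseudotime data.frame with cell, lineage (pre-lineage / ICM / TE)
#'   and pseudotime columns.
#' @return list(alignment = the three maxima and the scale factor,
#'   table = input with a pseudotime_mod column).
#' @export
rescale_pseudotime <- function(pseudotime) {
  stopifnot(all(c("cell", "lineage", "pseudotime") %in% names(pseudotime)))
  lin <- pseudotime$lineage
  need <- c("pre-lineage", "ICM", "TE")
  if (!all(need %in% lin))
    stopf("all three cell classes are required (missing: %s)",
          paste(setdiff(need, lin), collapse = ", "))
  pre_max <- max(pseudotime$pseudotime[lin == "pre-lineage"])
  icm_max <- max(pseudotime$pseudotime[lin == "ICM"])
  te_max <- max(pseudotime$pseudotime[lin == "TE"])
  if (icm_max == pre_max)
    stopf("degenerate rescaling: the ICM and pre-lineage maxima coincide")
  scale_factor <- (te_max - pre_max) / (icm_max - pre_max)
  tab <- pseudotime
  tab$pseudotime_mod <- tab$pseudotime
  resc <- lin == "ICM" & tab$pseudotime > pre_max
  tab$pseudotime_mod[resc] <-
    (tab$pseudotime[resc] - pre_max) * scale_factor + pre_max
  list(alignment = list(pre_max = pre_max, icm_max = icm_max,
                        te_max = te_max, scale_factor = scale_factor),
       table = tab)
}

#' Pseudobulk mean log-expression per group
#'
#' @param norm cells x features log-normalised matrix.
#' @param groups group label per cell; empty (all-NA) groups are dropped
#'   with a warning.
#' @return groups x features matrix of means (cell order invariant).
#' @export
pseudobulk <- function(norm, groups) {
  groups <- as.character(groups)
  keep <- !is.na(groups)
  if (!all(keep)) warnf("%d cell(s) without a group dropped", sum(!keep))
  g <- factor(groups[keep])
  m <- rowsum(norm[keep, , drop = FALSE], g) / as.vector(table(g))
  m[order(rownames(m)), , drop = FALSE]
}

#' Select miRNAs associated with a trajectory
#'
#' Per feature, fits expression ~ pseudotime (+ batch as an additive
#' covariate), takes the slope's t-test p-value, adjusts across features
#' (BH), keeps FDR < \code{fdr_threshold}, and intersects with the
#' stage-differential feature set.
#'
#' @param norm cells x features log-normalised matrix (branch cells only).
#' @param pseudotime per-cell (rescaled) pseudotime.
#' @param batch per-cell batch label; a single level drops the covariate
#'   with a warning.
#' @param de_features features differentially expressed between stages
#'   (adjacent stages or any later stage vs the first).
#' @param fdr_threshold BH FDR cutoff.
#' @return data.frame feature, slope, p, fdr, associated, selected.
#' @export
select_trajectory_mirnas <- function(norm, pseudotime, batch = NULL,
                                     de_features = character(),
                                     fdr_threshold = 0.05) {
  stopifnot(nrow(norm) >= 10L)
  use_batch <- !is.null(batch) && length(unique(batch)) > 1L
  if (!is.null(batch) && !use_batch)
    warnf("single batch: covariate dropped")
  feats <- colnames(norm)
  p <- numeric(length(feats)); slope <- numeric(length(feats))
  for (j in seq_along(feats)) {
    y <- norm[, j]
    fit <- if (use_batch) lm(y ~ pseudotime + factor(batch))
           else lm(y ~ pseudotime)
    co <- summary(fit)$coefficients
    if ("pseudotime" %in% rownames(co)) {
      slope[j] <- co["pseudotime", 1]
      p[j] <- co["pseudotime", 4]
    } else {             # constant feature: no slope estimable
      slope[j] <- 0; p[j] <- 1
    }
  }
  fdr <- p.adjust(p, method = "BH")
  data.frame(feature = feats, slope = slope, p = p, fdr = fdr,
             associated = fdr < fdr_threshold,
             selected = fdr < fdr_threshold & feats %in% de_features,
             stringsAsFactors = FALSE)
}

#' Cluster trajectory miRNA expression patterns into C1/C2/C3
#'
#' Binned (20 equal-width pseudotime bins), z-scored profiles are clustered
#' with k-means (k = 3, 25 restarts, fixed seed). Clusters are labelled by
#' centroid shape: C2 for the largest positive last-third minus first-third
#' difference (Low to High), C3 for the most negative (High to Low), C1 for
#' the remaining centroid (Low to High to Low).
#'
#' @param norm cells x features log-normalised matrix.
#' @param pseudotime per-cell pseudotime.
#' @param features features to cluster (>= 3).
#' @param n_bins number of equal-width pseudotime bins.
#' @param k number of clusters.
#' @param seed RNG seed for the k-means restarts.
#' @return list(labels = data.frame(feature, cluster),
#'   centroids = k x bins matrix, profiles).
#' @export
cluster_patterns <- function(norm, pseudotime, features, n_bins = 20L,
                             k = 3L, seed = 1L) {
  features <- intersect(features, colnames(norm))
  if (length(features) < k)
    stopf("need at least %d miRNAs to cluster, got %d", k, length(features))
  breaks <- seq(min(pseudotime), max(pseudotime), length.out = n_bins + 1L)
  bin <- cut(pseudotime, breaks, include.lowest = TRUE, labels = FALSE)
  prof <- t(vapply(features, function(f)
    tapply(norm[, f], bin, mean), numeric(length(unique(bin)))))
  keep_bins <- colSums(is.na(prof)) == 0L
  prof <- prof[, keep_bins, drop = FALSE]
  z <- t(scale(t(prof)))
  z[is.na(z)] <- 0                      # flat profiles
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = 25L)
  nb <- ncol(z)
  third <- max(1L, floor(nb / 3))
  shape <- t(apply(km$centers, 1L, function(ce) {
    c(first = mean(ce[seq_len(third)]),
      mid = mean(ce[(third + 1L):(nb - third)]),
      last = mean(ce[(nb - third + 1L):nb]))
  }))
  d <- shape[, "last"] - shape[, "first"]
  lab <- rep("C1", k)
  lab[which.max(d)] <- "C2"
  lab[which.min(d)] <- "C3"
  data.frame(feature = features, cluster = lab[km$cluster],
             stringsAsFactors = FALSE) -> labels
  list(labels = labels, centroids = km$centers, profiles = z,
       centroid_class = lab)
}

#' Pseudobulk Pearson anticorrelation between miRNAs and candidate targets
#'
#' For each candidate pair, the Pearson coefficient r between the miRNA and
#' gene pseudobulk profiles, the t statistic r sqrt(n-2)/sqrt(1-r^2), and
#' one-sided p-values for negative and positive correlation.
#'
#' @param mirna_pb groups x miRNA pseudobulk matrix.
#' @param gene_pb groups x gene pseudobulk matrix (same group rows).
#' @param pairs data.frame with mirna and gene columns.
#' @param alpha significance level for the filtered pair lists.
#' @return list(results, significant_negative, significant_positive,
#'   skipped).
#' @export
correlate_targets <- function(mirna_pb, gene_pb, pairs, alpha = 0.05) {
  stopifnot(nrow(mirna_pb) == nrow(gene_pb), nrow(mirna_pb) >= 3L)
  n <- nrow(mirna_pb)
  res <- list(); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    mi <- pairs$mirna[i]; ge <- pairs$gene[i]
    if (!(mi %in% colnames(mirna_pb)) || !(ge %in% colnames(gene_pb))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(mirna = mi, gene = ge, reason = "feature_absent")
      next
    }
    x <- mirna_pb[, mi]; y <- gene_pb[, ge]
    if (sd(x) == 0 || sd(y) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(mirna = mi, gene = ge, reason = "zero_variance")
      next
    }
    r <- cor(x, y)
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p_neg <- pt(t_stat, df = n - 2)
    p_pos <- pt(t_stat, df = n - 2, lower.tail = FALSE)
    res[[length(res) + 1L]] <- data.frame(
      mirna = mi, gene = ge, n = n, r = r, t = t_stat,
      p_neg = p_neg, p_pos = p_pos,
      direction = if (r < 0) "negative" else "positive",
      stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(mirna = character(), gene = character(), n = integer(),
               r = numeric(), t = numeric(), p_neg = numeric(),
               p_pos = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  list(results = results,
       significant_negative = results[results$p_neg < alpha, , drop = FALSE],
       significant_positive = results[results$p_pos < alpha, , drop = FALSE],
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

## parse "cell1:21,22;cell2:20" into a list of integer vectors
parse_read_lengths <- function(s) {
  if (is.na(s) || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]])
  })
  names(out) <- vapply(strsplit(parts, ":", fixed = TRUE), `[[`, character(1), 1L)
  out
}

#' Four-criterion filter for novel miRNA candidates
#'
#' A candidate is accepted iff it (1) is flagged significant by the hairpin
#' randomisation test, (2) has a positive discovery score, (3) is expressed
#' in at least two batches or developmental timepoints, and (4) has
#' overlapping reads in at least \code{min_cells} cells with at least
#' \code{min_len_frac} of all overlapping reads in the
#' [\code{len_range}] nt window (pooled across cells).
#'
#' @param candidates data.frame with candidate_id, significant_randfold
#'   ("yes"/"no" or logical), mirdeep_score, contexts (";"-separated batch /
#'   timepoint labels), cell_read_lengths ("cell:len,len;cell:len" encoding).
#' @param min_cells,min_len_frac,len_range criterion-4 parameters.
#' @return data.frame with per-criterion flags, accepted flag and a
#'   rejection reason; rows with missing fields are rejected with reason
#'   "missing_field".
#' @export
filter_novel <- function(candidates, min_cells = 30L, min_len_frac = 0.75,
                         len_range = c(20L, 25L)) {
  needed <- c("candidate_id", "significant_randfold", "mirdeep_score",
              "contexts", "cell_read_lengths")
  if (!all(needed %in% names(candidates)))
    stopf("candidate table must have columns: %s", paste(needed, collapse = ", "))
  n <- nrow(candidates)
  c1 <- c2 <- c3 <- c4 <- logical(n)
  missing_field <- logical(n)
  for (i in seq_len(n)) {
    row <- candidates[i, ]
    if (anyNA(row[needed])) { missing_field[i] <- TRUE; next }
    c1[i] <- isTRUE(row$significant_randfold == TRUE) ||
      tolower(as.character(row$significant_randfold)) %in% c("yes", "true")
    c2[i] <- row$mirdeep_score > 0
    c3[i] <- length(unique(strsplit(row$contexts, ";", fixed = TRUE)[[1]])) >= 2L
    lens <- parse_read_lengths(row$cell_read_lengths)
    n_cells <- sum(vapply(lens, length, integer(1)) > 0L)
    pooled <- unlist(lens, use.names = FALSE)
    c4[i] <- n_cells >= min_cells && length(pooled) > 0L &&
      mean(pooled >= len_range[1] & pooled <= len_range[2]) >= min_len_frac
  }
  accepted <- c1 & c2 & c3 & c4 & !missing_field
  reason <- ifelse(missing_field, "missing_field",
            ifelse(!c1, "not_significant_randfold",
            ifelse(!c2, "nonpositive_score",
            ifelse(!c3, "single_context",
            ifelse(!c4, "insufficient_read_support", "")))))
  data.frame(candidate_id = candidates$candidate_id,
             significant_randfold = c1, positive_score = c2,
             multi_context = c3, read_support = c4,
             accepted = accepted, reason = reason,
             stringsAsFactors = FALSE)
}
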