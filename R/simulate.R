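## ---------------------------------------------------------------------------
## Synthetic Small-seq data generator
##
## Builds a toy genome with planted sncRNA features, draws per-cell molecular
## ground truth (biotype mixtures that drift across embryonic days, lineage
## marker miRNAs, isomiR shifts/NTAs, tRF classes, PCR duplication), and
## renders Small-seq-structured reads: 8 nt UMI + 2 filler bases + insert +
## (polyA) + adapter.
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Collects every tunable of the synthetic Small-seq generator and validates
#' it. Defaults follow the study design the pipeline targets: 8 nt UMIs, insert
#' length modes of 22 nt (mature miRNA), 30 nt (piRNA) and 74 nt (full-length
#' tRNA), a biotype mixture that shifts across embryonic days E3..E7
#' (piRNA/tRNA decreasing, miRNA/snoRNA increasing), and lineage-specific
#' marker miRNAs for ICM and TE.
#'
#' @param seed integer seed driving every random choice.
#' @param n_cells number of cells.
#' @param days ordered day labels; cells are split evenly across them.
#' @param prelineage_days days whose cells are "pre-lineage"; later days
#'   alternate ICM/TE.
#' @param genome_length main chromosome length (bp).
#' @param chrM_length mitochondrial chromosome length (bp).
#' @param n_features named list: number of planted features per biotype.
#' @param molecules_per_cell molecules drawn per cell.
#' @param biotype_mixture optional days x biotypes proportion matrix (columns
#'   miRNA, rRNA, snoRNA, snRNA, tRNA, piRNA, other); rows must sum to 1.
#' @param isomir_rates list(p_shift5, p_shift3, p_nta, nta_len_probs): per-
#'   molecule probabilities of a nonzero 5'/3' shift (uniform on -3..+3
#'   excluding 0) and of a 3' non-templated adenosine run of length 1-3.
#' @param trf_class_mix named proportions over five_prime_half,
#'   three_prime_half, full_length; must sum to 1.
#' @param pcr_duplication_rate mean number of extra PCR copies per molecule
#'   (copies = 1 + Poisson(rate)).
#' @param seq_error_rate per-base substitution probability applied to inserts.
#' @param adapter_sequence 3' adapter appended after the insert.
#' @param polya_tail_length length of the oligo-dA run between insert and
#'   adapter. Default 0: with a polyA run in place, terminal adenosine NTAs
#'   are indistinguishable from the tail (see the methods vignette).
#' @param umi_length UMI length; the Small-seq layout fixes this at 8.
#' @param umi_mode "random" (uniform over 4^8) or "collision_free" (per-cell
#'   codes at pairwise Hamming distance >= 2, for exact-count verification).
#' @param mito_rate probability a molecule originates from a chrM feature.
#' @param marker_log2fc expected log2 fold change of lineage marker miRNAs in
#'   their lineage.
#' @param n_batches number of sequencing batches (assigned round-robin).
#' @param sequenced_reads_range range of the nominal per-cell raw sequencing
#'   depth written to the metadata (used by cell QC).
#' @param duplicate_locus plant an exact two-copy repeat of one piRNA locus
#'   (exercises multi-mapping recovery after deduplication).
#' @param read_fill_length filler bases inserted between UMI and insert
#'   (trimmed away as cutadapt's \code{-u 2} would).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 15L,
                       days = c("E3", "E4", "E5", "E6", "E7"),
                       prelineage_days = c("E3", "E4"),
                       genome_length = 30000L,
                       chrM_length = 1500L,
                       n_features = list(miRNA = 10L, rRNA = 2L, snoRNA = 4L,
                                         snRNA = 3L, tRNA = 6L, piRNA = 6L,
                                         protein_coding = 3L, lncRNA = 2L,
                                         repeat_element = 2L, pseudogene = 1L),
                       molecules_per_cell = 200L,
                       biotype_mixture = NULL,
                       isomir_rates = list(p_shift5 = 0.2, p_shift3 = 0.2,
                                           p_nta = 0.15,
                                           nta_len_probs = c(0.6, 0.3, 0.1)),
                       trf_class_mix = c(five_prime_half = 0.4,
                                         three_prime_half = 0.3,
                                         full_length = 0.3),
                       pcr_duplication_rate = 1,
                       seq_error_rate = 0,
                       adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                       polya_tail_length = 0L,
                       umi_length = 8L,
                       umi_mode = c("random", "collision_free"),
                       mito_rate = 0.05,
                       marker_log2fc = 2,
                       n_batches = 2L,
                       sequenced_reads_range = c(6e5, 1.5e6),
                       duplicate_locus = FALSE,
                       read_fill_length = 2L) {
  umi_mode <- match.arg(umi_mode)
  if (umi_length != 8L)
    stopf("umi_length must be 8 (Small-seq layout), got %d", umi_length)
  if (is.null(biotype_mixture))
    biotype_mixture <- default_biotype_mixture(days)
  stopifnot(is.matrix(biotype_mixture),
            nrow(biotype_mixture) == length(days))
  if (any(biotype_mixture < 0) || any(abs(rowSums(biotype_mixture) - 1) > 1e-8))
    stopf("biotype_mixture rows must be proportions summing to 1")
  probs <- c(isomir_rates$p_shift5, isomir_rates$p_shift3, isomir_rates$p_nta,
             mito_rate, seq_error_rate)
  if (any(probs < 0 | probs > 1))
    stopf("all probabilities must lie in [0, 1]")
  if (abs(sum(trf_class_mix) - 1) > 1e-8 || any(trf_class_mix < 0))
    stopf("trf_class_mix must be non-negative and sum to 1")
  if (abs(sum(isomir_rates$nta_len_probs) - 1) > 1e-8)
    stopf("isomir_rates$nta_len_probs must sum to 1")
  if (nchar(adapter_sequence) < 10L)
    stopf("adapter_sequence must be at least 10 nt so trimmed tails can reach the 10 nt minimum")
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              days = days, prelineage_days = prelineage_days,
              genome_length = as.integer(genome_length),
              chrM_length = as.integer(chrM_length),
              n_features = n_features,
              molecules_per_cell = as.integer(molecules_per_cell),
              biotype_mixture = biotype_mixture,
              isomir_rates = isomir_rates, trf_class_mix = trf_class_mix,
              pcr_duplication_rate = pcr_duplication_rate,
              seq_error_rate = seq_error_rate,
              adapter_sequence = toupper(adapter_sequence),
              polya_tail_length = as.integer(polya_tail_length),
              umi_length = 8L, umi_mode = umi_mode, mito_rate = mito_rate,
              marker_log2fc = marker_log2fc, n_batches = as.integer(n_batches),
              sequenced_reads_range = sequenced_reads_range,
              duplicate_locus = isTRUE(duplicate_locus),
              read_fill_length = as.integer(read_fill_length))
  class(cfg) <- "sim_config"
  cfg
}

default_biotype_mixture <- function(days) {
  base <- rbind(
    c(0.15, 0.08, 0.07, 0.05, 0.25, 0.30, 0.10),
    c(0.20, 0.08, 0.08, 0.05, 0.22, 0.25, 0.12),
    c(0.25, 0.08, 0.10, 0.05, 0.18, 0.22, 0.12),
    c(0.30, 0.08, 0.11, 0.05, 0.15, 0.19, 0.12),
    c(0.35, 0.08, 0.12, 0.05, 0.12, 0.16, 0.12))
  colnames(base) <- c(BIOTYPE_PRIORITY, "other")
  idx <- round(seq(1, nrow(base), length.out = length(days)))
  m <- base[idx, , drop = FALSE]
  rownames(m) <- days
  m
}

## ---- reference -------------------------------------------------------------

feature_length_draw <- function(biotype) {
  switch(biotype,
         miRNA = 70L,                      # hairpin; mature drawn separately
         rRNA = 120L,
         snoRNA = 80L,
         snRNA = 100L,
         tRNA = sample(72:76, 1L, prob = c(0.1, 0.15, 0.5, 0.15, 0.1)),
         piRNA = sample(28:32, 1L, prob = c(0.1, 0.15, 0.5, 0.15, 0.1)),
         protein_coding = 400L,
         lncRNA = 300L,
         repeat_element = 150L,
         pseudogene = 200L,
         stopf("unknown biotype '%s'", biotype))
}

#' Build the synthetic reference genome and annotation set
#'
#' Plants non-overlapping features for every configured biotype on a random
#' genome (plus a small mitochondrial chromosome), with mature miRNA intervals
#' nested inside hairpins and anticodon/amino-acid labels on tRNAs. The six
#' genome positions 3' of every mature miRNA are forced to non-adenosine so a
#' planted adenosine NTA is always non-templated. Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genome} (named character vector of chromosome
#'   sequences) and \code{annotations} (an \code{annotation_set}).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_features
  recs <- list()
  plan <- unlist(mapply(function(bt, n) rep(bt, n), names(nf), unlist(nf)))
  plan <- sample(plan)   # interleave biotypes along the chromosome
  counters <- setNames(integer(length(nf)), names(nf))
  pos <- 0L
  trna_i <- 0L
  for (bt in plan) {
    counters[bt] <- counters[bt] + 1L
    len <- feature_length_draw(bt)
    gap <- sample(30:80, 1L)
    start <- pos + gap
    end <- start + len
    strand <- sample(c("+", "-"), 1L)
    name <- switch(bt,
                   miRNA = sprintf("mir-%d", counters[bt]),
                   rRNA = sprintf("rRNA-%d", counters[bt]),
                   snoRNA = sprintf("SNORD-%d", counters[bt]),
                   snRNA = sprintf("U%d", counters[bt]),
                   tRNA = NA_character_,   # named below from isotype
                   piRNA = sprintf("piR-%d", counters[bt]),
                   protein_coding = sprintf("GENE%d", counters[bt]),
                   lncRNA = sprintf("LINC%d", counters[bt]),
                   repeat_element = sprintf("LTR-%d", counters[bt]),
                   pseudogene = sprintf("PSG%d", counters[bt]))
    aa <- NA_character_; anticodon <- NA_character_
    if (bt == "tRNA") {
      trna_i <- trna_i + 1L
      iso <- TRNA_ISOTYPES[((trna_i - 1L) %% nrow(TRNA_ISOTYPES)) + 1L, ]
      aa <- iso$aa; anticodon <- iso$anticodon
      name <- sprintf("tRNA-%s-%s-%d", aa, anticodon, counters[bt])
    }
    if (bt == "miRNA") {
      hp_name <- paste0(name, "-hp")
      recs[[length(recs) + 1L]] <- data.frame(
        biotype = "miRNA_hairpin", chrom = "chr1", start = start, end = end,
        strand = strand, name = hp_name, parent = NA_character_,
        aa = NA_character_, anticodon = NA_character_)
      mlen <- sample(21:23, 1L, prob = c(0.2, 0.6, 0.2))
      off <- sample(8:(len - mlen - 8L), 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        biotype = "miRNA", chrom = "chr1", start = start + off,
        end = start + off + mlen, strand = strand, name = name,
        parent = hp_name, aa = NA_character_, anticodon = NA_character_)
    } else {
      recs[[length(recs) + 1L]] <- data.frame(
        biotype = bt, chrom = "chr1", start = start, end = end,
        strand = strand, name = name, parent = NA_character_,
        aa = aa, anticodon = anticodon)
    }
    pos <- end
  }
  if (pos + 30L > config$genome_length)
    stopf("genome_length %d too short to host the requested features (need >= %d)",
          config$genome_length, pos + 30L)

  ## mitochondrial chromosome: two tRNAs and one rRNA
  mrecs <- list()
  mpos <- 40L
  mt_iso <- TRNA_ISOTYPES[1:2, ]
  for (i in 1:2) {
    len <- sample(72:76, 1L)
    mrecs[[i]] <- data.frame(
      biotype = "tRNA", chrom = "chrM", start = mpos, end = mpos + len,
      strand = "+", name = sprintf("MT-tRNA-%s-%s", mt_iso$aa[i], mt_iso$anticodon[i]),
      parent = NA_character_, aa = mt_iso$aa[i], anticodon = mt_iso$anticodon[i])
    mpos <- mpos + len + 60L
  }
  mrecs[[3]] <- data.frame(
    biotype = "rRNA", chrom = "chrM", start = mpos, end = mpos + 150L,
    strand = "+", name = "MT-rRNA-1", parent = NA_character_,
    aa = NA_character_, anticodon = NA_character_)
  if (mpos + 150L + 30L > config$chrM_length)
    stopf("chrM_length %d too short", config$chrM_length)

  records <- do.call(rbind, c(recs, mrecs))
  rownames(records) <- NULL

  chr1 <- sample(DNA_BASES, config$genome_length, replace = TRUE)
  chrM <- sample(DNA_BASES, config$chrM_length, replace = TRUE)
  ## guarantee planted adenosine NTAs are non-templated and identifiable: no
  ## A (in feature orientation) from 3 nt inside the mature 3' end (the reach
  ## of a -3 shift) to 6 nt beyond it (+3 elongation plus a 3 nt tail);
  ## otherwise a trimmed mature ending in A plus an A-tail would be
  ## byte-identical to a less-trimmed read
  mat <- records[records$biotype == "miRNA", , drop = FALSE]
  for (i in seq_len(nrow(mat))) {
    if (mat$strand[i] == "+") {
      idx <- (mat$end[i] - 3L):(mat$end[i] + 6L)          # 1-based genome index
      chr1[idx] <- sample(c("C", "G", "T"), 10L, replace = TRUE)
    } else {
      idx <- (mat$start[i] - 5L):(mat$start[i] + 4L)
      chr1[idx] <- sample(c("A", "C", "G"), 10L, replace = TRUE)
    }
  }
  if (config$duplicate_locus) {
    src <- records[records$biotype == "piRNA", , drop = FALSE][1L, ]
    if (is.na(src$name[1L])) stopf("duplicate_locus requires at least one piRNA feature")
    len <- src$end - src$start
    dstart <- pos + 200L
    if (dstart + len + 30L > config$genome_length)
      stopf("genome_length too short to host the duplicated locus")
    chr1[(dstart + 1L):(dstart + len)] <- chr1[(src$start + 1L):(src$end)]
    dup <- src
    dup$start <- dstart; dup$end <- dstart + len
    dup$name <- paste0(src$name, "-dup")
    records <- rbind(records, dup)
  }
  ## break adenosine/thymidine homopolymer runs of 4+ (every 4th base of a
  ## run becomes C): a templated read 3' end consisting of >= 4 adenosines is
  ## indistinguishable from the oligo-dA tail and would be lost at trimming,
  ## so the generator keeps such runs out of the genome entirely
  chr1 <- break_homopolymers(chr1)
  chrM <- break_homopolymers(chrM)
  genome <- c(chr1 = paste(chr1, collapse = ""),
              chrM = paste(chrM, collapse = ""))
  list(genome = genome, annotations = annotation_set(records))
}

## sequence of one annotation record, in feature orientation
feature_sequence <- function(rec, genome) {
  s <- substr(genome[[rec$chrom]], rec$start + 1L, rec$end)
  if (rec$strand == "-") s <- revcomp(s) else s
}

#' Lineage marker miRNAs planted by the simulator
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns \code{feature} and \code{lineage}.
#' @export
sim_markers <- function(config) {
  n_mir <- config$n_features$miRNA
  feats <- sprintf("mir-%d", seq_len(n_mir))
  n_icm <- min(2L, n_mir)
  n_te <- min(2L, max(0L, n_mir - n_icm))
  data.frame(
    feature = c(feats[seq_len(n_icm)], feats[n_icm + seq_len(n_te)]),
    lineage = c(rep("ICM", n_icm), rep("TE", n_te)),
    stringsAsFactors = FALSE)
}

#' Cell metadata for a simulation
#'
#' Cells are split evenly over the configured days; pre-lineage days yield
#' "pre-lineage" cells and later days alternate ICM/TE. Batches round-robin.
#' Includes a nominal raw sequencing depth per cell (used by cell QC).
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with cell, day, lineage, batch, sequenced_reads.
#' @export
sim_cell_metadata <- function(config) {
  set.seed(config$seed + 10L)
  n <- config$n_cells
  if (n == 0L)
    return(data.frame(cell = character(), day = character(),
                      lineage = character(), batch = character(),
                      sequenced_reads = numeric()))
  day <- config$days[ceiling(seq_len(n) / (n / length(config$days)))]
  day[is.na(day)] <- config$days[length(config$days)]
  lineage <- ifelse(day %in% config$prelineage_days, "pre-lineage",
                    ifelse(seq_len(n) %% 2L == 0L, "ICM", "TE"))
  data.frame(
    cell = sprintf("cell%03d", seq_len(n)),
    day = day,
    lineage = lineage,
    batch = sprintf("b%d", ((seq_len(n) - 1L) %% config$n_batches) + 1L),
    sequenced_reads = round(runif(n, config$sequenced_reads_range[1],
                                  config$sequenced_reads_range[2])),
    stringsAsFactors = FALSE)
}

## per-cell collision-free UMI: 7 base-4 digits encoding the index plus a
## checksum digit, so any two codes differ in >= 2 positions
collision_free_umi <- function(i) {
  stopifnot(all(i >= 1L), all(i <= 4^7))
  vapply(i, function(k) {
    d <- integer(7L); x <- k - 1L
    for (j in 1:7) { d[j] <- x %% 4L; x <- x %/% 4L }
    paste(DNA_BASES[c(d, sum(d) %% 4L) + 1L], collapse = "")
  }, character(1))
}

draw_isomir <- function(rates, mature_len) {
  repeat {
    s5 <- if (runif(1) < rates$p_shift5) sample(c(-3:-1, 1:3), 1L) else 0L
    s3 <- if (runif(1) < rates$p_shift3) sample(c(-3:-1, 1:3), 1L) else 0L
    nta <- if (runif(1) < rates$p_nta)
      strrep("A", sample(1:3, 1L, prob = rates$nta_len_probs)) else ""
    ## inserts shorter than 18 nt cannot survive the -m 18 trimming filter
    if (mature_len + s5 + s3 + nchar(nta) >= 18L) break
  }
  list(shift5 = s5, shift3 = s3, nta = nta)
}

#' Draw per-cell molecular ground truth
#'
#' For every cell, molecules are drawn from the day-specific biotype mixture;
#' designated marker miRNAs get a \code{2^marker_log2fc} weight boost in their
#' lineage; miRNA molecules carry isomiR shifts and non-templated adenosine
#' tails at the configured rates and tRNA molecules a tRF class from the
#' configured mix. Deterministic given the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param annotations the \code{annotation_set} from
#'   \code{\link{build_reference}}.
#' @return the truth table: one row per planted molecule (cell, molecule id,
#'   feature, biotype, templated genome interval, shifts, NTA, tRF class, UMI,
#'   PCR copy number).
#' @export
simulate_molecules <- function(config, annotations) {
  stopifnot(inherits(config, "sim_config"), inherits(annotations, "annotation_set"))
  set.seed(config$seed + 1L)
  rec <- annotations$records
  meta <- sim_cell_metadata(config)
  mix <- config$biotype_mixture

  for (bt in colnames(mix)[colnames(mix) != "other"])
    if (any(mix[, bt] > 0) && !any(rec$biotype == bt & rec$chrom != "chrM"))
      stopf("biotype '%s' requested by the mixture but absent from the annotation", bt)

  ## fixed per-feature abundance weights; markers get a fixed common weight so
  ## the lineage boost yields the configured fold change exactly (the boosted
  ## mass added to the denominator cancels between the two lineages)
  rec$weight <- rexp(nrow(rec)) + 0.3
  markers <- sim_markers(config)
  rec$weight[rec$name %in% markers$feature] <- 0.5
  feats_by_bt <- split(seq_len(nrow(rec)), rec$biotype)

  out <- vector("list", nrow(meta))
  mol_global <- 0L
  for (ci in seq_len(nrow(meta))) {
    n <- config$molecules_per_cell
    if (n == 0L) next
    day <- meta$day[ci]; lineage <- meta$lineage[ci]
    p <- mix[match(day, config$days), ]
    bts <- sample(colnames(mix), n, replace = TRUE, prob = p)
    is_mito <- runif(n) < config$mito_rate
    rows <- vector("list", n)
    for (mi in seq_len(n)) {
      mol_global <- mol_global + 1L
      rows[[mi]] <- draw_molecule(
        config, rec, feats_by_bt, markers, bts[mi], is_mito[mi], lineage)
      rows[[mi]]$cell <- meta$cell[ci]
      rows[[mi]]$mol_id <- mol_global
    }
    df <- do.call(rbind, rows)
    df$umi <- if (config$umi_mode == "collision_free")
      collision_free_umi(seq_len(n))
    else
      vapply(seq_len(n), function(i)
        paste(sample(DNA_BASES, 8L, replace = TRUE), collapse = ""), character(1))
    df$pcr_copies <- 1L + rpois(n, config$pcr_duplication_rate)
    out[[ci]] <- df
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- empty_truth()
  rownames(out) <- NULL
  out[, c("cell", "mol_id", "feature", "biotype", "chrom", "strand",
          "start", "end", "shift5", "shift3", "nta", "trf_class",
          "umi", "pcr_copies")]
}

empty_truth <- function() {
  data.frame(cell = character(), mol_id = integer(), feature = character(),
             biotype = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), shift5 = integer(),
             shift3 = integer(), nta = character(), trf_class = character(),
             umi = character(), pcr_copies = integer(),
             stringsAsFactors = FALSE)
}

draw_molecule <- function(config, rec, feats_by_bt, markers, bt, mito, lineage) {
  if (mito) {
    idx <- which(rec$chrom == "chrM")
    f <- idx[sample.int(length(idx), 1L)]
    return(fragment_row(rec[f, ]))
  }
  if (bt == "other") {
    kind <- sample(c(CATCHALL_BIOTYPES, "intergenic"), 1L,
                   prob = c(0.45, 0.2, 0.2, 0.05, 0.1))
    if (kind == "intergenic") {
      len <- sample(20:40, 1L)
      ## place in the tail gap beyond the last planted feature (and beyond any
      ## duplicated locus, which sits within 300 bp of the last feature)
      last_end <- max(rec$end[rec$chrom == "chr1"])
      start <- last_end + 500L + sample.int(200L, 1L)
      start <- min(start, config$genome_length - len - 10L)
      return(data.frame(feature = "intergenic", biotype = "unannotated",
                        chrom = "chr1", strand = sample(c("+", "-"), 1L),
                        start = start, end = start + len,
                        shift5 = NA_integer_, shift3 = NA_integer_,
                        nta = "", trf_class = NA_character_))
    }
    idx <- feats_by_bt[[kind]]
    f <- rec[idx[sample.int(length(idx), 1L)], ]
    row <- fragment_row(f)
    ## sncRNA fragments from catch-all regions are mostly sense-strand
    if (runif(1) < 0.3)
      row$strand <- if (row$strand == "+") "-" else "+"
    return(row)
  }
  idx <- feats_by_bt[[bt]]
  idx <- idx[rec$chrom[idx] != "chrM"]
  w <- rec$weight[idx]
  if (bt == "miRNA") {
    mk <- markers$feature[markers$lineage == lineage]
    boost <- rec$name[idx] %in% mk
    w[boost] <- w[boost] * 2^config$marker_log2fc
  }
  f <- rec[idx[sample.int(length(idx), 1L, prob = w)], ]
  flen <- f$end - f$start
  if (bt == "miRNA") {
    iso <- draw_isomir(config$isomir_rates, flen)
    if (f$strand == "+") {
      start <- f$start - iso$shift5; end <- f$end + iso$shift3
    } else {
      start <- f$start - iso$shift3; end <- f$end + iso$shift5
    }
    return(data.frame(feature = f$name, biotype = "miRNA", chrom = f$chrom,
                      strand = f$strand, start = start, end = end,
                      shift5 = iso$shift5, shift3 = iso$shift3, nta = iso$nta,
                      trf_class = NA_character_))
  }
  if (bt == "tRNA") {
    klass <- sample(names(config$trf_class_mix), 1L, prob = config$trf_class_mix)
    if (klass == "full_length") {
      d5 <- 0L; len <- flen
    } else {
      d5 <- sample(0:3, 1L)
      len <- sample(30:42, 1L)
    }
    if (klass == "five_prime_half") {          # anchored at the 5' end
      s5 <- -d5; s3 <- -(flen - d5 - len)
    } else if (klass == "three_prime_half") {  # anchored at the 3' end
      s3 <- -d5; s5 <- -(flen - d5 - len)
    } else {
      s5 <- 0L; s3 <- 0L; len <- flen
    }
    if (f$strand == "+") {
      start <- f$start - s5; end <- f$end + s3
    } else {
      start <- f$start - s3; end <- f$end + s5
    }
    return(data.frame(feature = f$name, biotype = "tRNA", chrom = f$chrom,
                      strand = f$strand, start = start, end = end,
                      shift5 = s5, shift3 = s3, nta = "", trf_class = klass))
  }
  if (bt == "piRNA") {
    return(data.frame(feature = f$name, biotype = "piRNA", chrom = f$chrom,
                      strand = f$strand, start = f$start, end = f$end,
                      shift5 = 0L, shift3 = 0L, nta = "",
                      trf_class = NA_character_))
  }
  fragment_row(f)   # rRNA / snoRNA / snRNA
}

## random sub-fragment of a feature, sense strand, shifts not tracked
fragment_row <- function(f) {
  flen <- f$end - f$start
  len <- sample(20:min(40L, flen), 1L)
  off <- sample.int(flen - len + 1L, 1L) - 1L
  data.frame(feature = f$name, biotype = f$biotype, chrom = f$chrom,
             strand = f$strand, start = f$start + off, end = f$start + off + len,
             shift5 = NA_integer_, shift3 = NA_integer_, nta = "",
             trf_class = NA_character_)
}

## templated insert sequence of a truth row (feature orientation) + NTA tail
truth_insert <- function(truth, genome) {
  if (nrow(truth) == 0L) return(character())
  tmpl <- substr(genome[truth$chrom], truth$start + 1L, truth$end)
  neg <- truth$strand == "-"
  tmpl[neg] <- revcomp(tmpl[neg])
  paste0(tmpl, truth$nta)
}

#' Render Small-seq reads from a truth table
#'
#' Each molecule becomes \code{pcr_copies} reads sharing one UMI:
#' \code{UMI + "CA" + insert + polyA + adapter}, with per-base substitution
#' errors applied to the insert at \code{seq_error_rate}.
#'
#' @param truth truth table from \code{\link{simulate_molecules}}.
#' @param genome named character vector of chromosome sequences.
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with cell, read_id, seq (one row per read).
#' @export
render_reads <- function(truth, genome, config) {
  set.seed(config$seed + 2L)
  if (nrow(truth) == 0L)
    return(data.frame(cell = character(), read_id = character(),
                      seq = character(), stringsAsFactors = FALSE))
  insert <- truth_insert(truth, genome)
  idx <- rep(seq_len(nrow(truth)), truth$pcr_copies)
  copy <- sequence(truth$pcr_copies)
  ins <- insert[idx]
  if (config$seq_error_rate > 0 && length(ins)) {
    nerr <- rbinom(length(ins), nchar(ins), config$seq_error_rate)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(ins[i], "", fixed = TRUE)[[1]]
      at <- sample.int(length(ch), nerr[i])
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
      ins[i] <- paste(ch, collapse = "")
    }
  }
  tail <- paste0(strrep("A", config$polya_tail_length), config$adapter_sequence)
  data.frame(
    cell = truth$cell[idx],
    read_id = sprintf("%s:mol%06d:c%d", truth$cell[idx], truth$mol_id[idx], copy),
    seq = paste0(truth$umi[idx], "CA", ins, tail),
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits genome FASTA, annotations (GFF3 for gene-like tracks, BED6 for piRNA
#' and repeats), per-cell FASTQ, the truth table, cell metadata, a candidate
#' miRNA-target pair table, a candidate novel-miRNA table, and a JSON manifest
#' carrying the seed and per-file MD5 checksums.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
emit_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- build_reference(config)
  truth <- simulate_molecules(config, ref$annotations)
  reads <- render_reads(truth, ref$genome, config)
  meta <- sim_cell_metadata(config)

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome), fa)

  ann <- ref$annotations$records
  bed_bt <- c("piRNA", "repeat_element")
  write_annotation_gff3(ann[!ann$biotype %in% bed_bt, , drop = FALSE],
                        file.path(dir, "annotations.gff3"))
  for (bt in bed_bt)
    write_annotation_bed(ann[ann$biotype == bt, , drop = FALSE],
                         file.path(dir, paste0(bt, ".bed")))

  fq_dir <- file.path(dir, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  for (cell in unique(reads$cell)) {
    r <- reads[reads$cell == cell, , drop = FALSE]
    write_fastq(r$seq, r$read_id, file.path(fq_dir, paste0(cell, ".fastq")))
  }
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(meta, file.path(dir, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim_target_pairs(config), file.path(dir, "target_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim_novel_candidates(config),
              file.path(dir, "novel_candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  manifest <- list(seed = config$seed,
                   files = data.frame(
                     file = files,
                     md5 = unname(tools::md5sum(file.path(dir, files))),
                     stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

## candidate miRNA -> gene pairs (marker miRNAs x protein-coding genes)
sim_target_pairs <- function(config) {
  mk <- sim_markers(config)
  genes <- sprintf("GENE%d", seq_len(config$n_features$protein_coding))
  expand.grid(mirna = mk$feature, gene = genes,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

## a small miRDeep2-style candidate table with mixed pass/fail rows
sim_novel_candidates <- function(config) {
  set.seed(config$seed + 3L)
  lens_good <- function() paste(
    sprintf("cell%03d:%s", 1:32,
            vapply(1:32, function(i)
              paste(sample(20:25, 3, replace = TRUE), collapse = ","),
              character(1))), collapse = ";")
  lens_bad <- function() paste(
    sprintf("cell%03d:%s", 1:32,
            vapply(1:32, function(i)
              paste(sample(28:35, 3, replace = TRUE), collapse = ","),
              character(1))), collapse = ";")
  data.frame(
    candidate_id = sprintf("novel-%d", 1:6),
    significant_randfold = c("yes", "no", "yes", "yes", "yes", "yes"),
    mirdeep_score = c(4.2, 3.0, -0.5, 2.1, 5.5, 1.2),
    contexts = c("b1;b2", "b1;b2", "b1;b2", "b1", "b1;E5;E6", "b1;b2"),
    cell_read_lengths = c(lens_good(), lens_good(), lens_good(), lens_good(),
                          lens_good(), lens_bad()),
    stringsAsFactors = FALSE)
}
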