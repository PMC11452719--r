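# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

## small collision-free, error-free end-to-end run used by several files
small_pipeline <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(seed = 101L, n_cells = 6L, molecules_per_cell = 60L,
                      umi_mode = "collision_free", seq_error_rate = 0,
                      isomir_rates = list(p_shift5 = 0.3, p_shift3 = 0.3,
                                          p_nta = 0.3,
                                          nta_len_probs = c(0.5, 0.3, 0.2)))
    .fixture_cache$small <- run_small_rna_pipeline(cfg)
  }
  .fixture_cache$small
}

## map pipeline molecules back to truth rows (read names encode molecule ids)
mol_truth_index <- function(molecule_ids, molecules, truth) {
  rep_ids <- molecules$rep_read_id[match(molecule_ids, molecules$molecule_id)]
  mid <- as.integer(sub("mol", "",
                        vapply(strsplit(rep_ids, ":"), `[[`, character(1), 2L)))
  match(mid, truth$mol_id)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random UMI multisets concentrated around a few seeds so Hamming-1
## neighbours are common
random_umi_multiset <- function(max_distinct = 12L) {
  base <- random_dna_str(8L)
  n <- sample.int(max_distinct, 1L)
  umis <- character(n)
  umis[1] <- base
  for (i in seq_len(n - 1L) + 1L) {
    if (runif(1) < 0.7) {       # mutate an existing UMI at 1-2 positions
      u <- strsplit(sample(umis[seq_len(i - 1L)], 1L), "", fixed = TRUE)[[1]]
      k <- sample(1:2, 1L)
      at <- sample.int(8L, k)
      u[at] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      umis[i] <- paste(u, collapse = "")
    } else {
      umis[i] <- random_dna_str(8L)
    }
  }
  umis <- unique(umis)
  counts <- sample.int(30L, length(umis), replace = TRUE)
  list(umis = umis, counts = counts)
}

## reads/placements pair for hand-constructed dedup cases: every read sits at
## the same template position unless pos is varied
make_umi_reads <- function(umis, counts, pos = 100L, cell = "c1") {
  umi <- rep(umis, counts)
  n <- length(umi)
  reads <- data.frame(read_id = sprintf("r%03d", seq_len(n)), umi = umi,
                      cell = cell, seq = strrep("A", 22L),
                      status = "mapped", clipped5 = "", clipped3 = "",
                      stringsAsFactors = FALSE)
  placements <- data.frame(chrom = "chr1", start = rep(pos, n), strand = "+",
                           mm = 0L, clip5 = 0L, clip3 = 0L, maplen = 22L,
                           read_id = reads$read_id, cell = cell, nhits = 1L,
                           stringsAsFactors = FALSE)
  list(reads = reads, placements = placements)
}

make_pseudotime <- function(pre, icm, te) {
  data.frame(cell = sprintf("c%03d", seq_len(length(pre) + length(icm) +
                                               length(te))),
             lineage = rep(c("pre-lineage", "ICM", "TE"),
                           c(length(pre), length(icm), length(te))),
             pseudotime = c(pre, icm, te), stringsAsFactors = FALSE)
}

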