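make_genome <- function(n, seed = 1) {
  set.seed(seed)
  setNames(random_dna_str(n), "chr1")
}

mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  paste(ch, collapse = "")
}

test_that("exact placements are found on both strands", {
  g <- make_genome(1000)
  idx <- build_index(g)
  q <- substr(g[["chr1"]], 101, 122)
  r <- map_full(q, idx)
  expect_identical(r$status, "mapped")
  expect_equal(r$hits$start, 100L)
  expect_identical(r$hits$strand, "+")
  rc <- map_full(oracle_revcomp(q), idx)
  expect_identical(rc$status, "mapped")
  expect_equal(rc$hits$start, 100L)
  expect_identical(rc$hits$strand, "-")
  ## an absent query has no placements at all
  expect_identical(map_full(strrep("ACGT", 6), idx)$status, "unmapped")
})

test_that("length-dependent mismatch filters and the last-base exemption apply", {
  g <- make_genome(2000, seed = 2)
  idx <- build_index(g)
  ## 19 nt read with one internal mismatch: rejected outright
  q19 <- mutate_at(substr(g[["chr1"]], 301, 319), 10)
  expect_identical(map_full(q19, idx)$status, "unmapped")
  ## 25 nt read, two mismatches, one at the final base: kept, count 1
  q25 <- mutate_at(mutate_at(substr(g[["chr1"]], 501, 525), 12), 25)
  r <- map_full(q25, idx)
  expect_identical(r$status, "mapped")
  expect_true(any(r$hits$start == 500L & r$hits$mm == 1L))
  ## 25 nt read with two internal mismatches: filtered (20-40 nt rule)
  q25b <- mutate_at(mutate_at(substr(g[["chr1"]], 501, 525), 12), 20)
  expect_identical(map_full(q25b, idx)$status, "unmapped")
  ## 45 nt read with two internal mismatches: outside the 20-40 nt rule, kept
  q45 <- mutate_at(mutate_at(substr(g[["chr1"]], 601, 645), 12), 30)
  expect_identical(map_full(q45, idx)$status, "mapped")
})

test_that("reads matching more than 50 loci are suppressed", {
  set.seed(3)
  motif <- random_dna_str(22)
  spacers <- replicate(51, random_dna_str(20))
  g <- setNames(paste0(paste0(spacers, motif, collapse = ""),
                       random_dna_str(200)), "chr1")
  idx <- build_index(g)
  expect_identical(map_full(motif, idx)$status, "suppressed")
})

test_that("soft-clip rescue recovers tailed reads within the 3 nt budget", {
  g <- make_genome(3000, seed = 4)
  idx <- build_index(g)
  core <- substr(g[["chr1"]], 1001, 1024)
  nongen <- function(at) setdiff(c("A", "C", "G", "T"),
                                 substr(g[["chr1"]], at, at))[1]
  tail2 <- paste0(nongen(1025), nongen(1026))
  ## 2 non-genomic 3' bases: one clip suffices (the residual tail base is the
  ## one tolerated mismatch); clipped bases preserved for NTA calling
  r1 <- rescue_clip(paste0(core, tail2), idx)
  expect_identical(r1$status, "mapped")
  expect_equal(r1$hits$clip3[1], 1L)
  expect_equal(r1$hits$mm[1], 1L)
  expect_identical(r1$clipped3, substr(tail2, 2, 2))
  ## with an internal mismatch the 1-nt clip is exhausted and 2 nt are clipped
  core_mut <- mutate_at(core, 12)
  r2 <- rescue_clip(paste0(core_mut, tail2), idx)
  expect_identical(r2$status, "mapped")
  expect_equal(r2$hits$clip3[1], 2L)
  expect_equal(r2$hits$maplen[1], 24L)
  expect_identical(r2$clipped3, tail2)
  expect_true(any(r2$hits$start == 1000L))
  ## 5' rescue engages after 3' clipping fails
  head2 <- paste0(nongen(999), nongen(1000))
  r5 <- rescue_clip(paste0(head2, core), idx)
  expect_identical(r5$status, "mapped")
  expect_equal(r5$hits$clip5[1], 1L)
  expect_equal(r5$hits$mm[1], 1L)
  expect_identical(r5$clipped5, substr(head2, 1, 1))
  ## a 5-nt non-genomic tail exceeds the 3 nt budget even with the tolerated
  ## mismatch: unmapped
  tail5 <- paste0(tail2, nongen(1027), nongen(1028), nongen(1029))
  expect_identical(rescue_clip(paste0(core, tail5), idx)$status, "unmapped")
  ## 19 nt read: the 3-nt clip would leave a 16 nt mapping, below the floor
  core16 <- mutate_at(substr(g[["chr1"]], 1001, 1016), 8)
  junk3 <- paste0(nongen(1017), nongen(1018), nongen(1019))
  expect_identical(rescue_clip(paste0(core16, junk3), idx)$status, "unmapped")
})

test_that("placements mirror under joint reverse complement of genome and read", {
  g <- make_genome(2000, seed = 5)
  grc <- setNames(oracle_revcomp(g[["chr1"]]), "chr1")
  idx <- build_index(g); idxrc <- build_index(grc)
  N <- nchar(g[["chr1"]])
  set.seed(6)
  for (i in 1:20) {
    L <- sample(18:40, 1)
    s <- sample.int(N - L, 1)
    read <- substr(g[["chr1"]], s + 1, s + L)
    if (runif(1) < 0.5) read <- mutate_at(read, sample.int(L, 1))
    a <- map_full(read, idx)
    b <- map_full(read, idxrc)
    expect_identical(a$status, b$status)
    if (a$status == "mapped") {
      mirrored <- data.frame(start = N - (b$hits$start + b$hits$maplen),
                             strand = ifelse(b$hits$strand == "+", "-", "+"),
                             mm = b$hits$mm)
      o1 <- order(a$hits$start, a$hits$strand)
      o2 <- order(mirrored$start, mirrored$strand)
      expect_equal(a$hits$start[o1], mirrored$start[o2])
      expect_identical(a$hits$strand[o1], mirrored$strand[o2])
      expect_equal(a$hits$mm[o1], mirrored$mm[o2])
    }
  }
})

test_that("batch alignment tallies are conserved and SAM output round-trips", {
  g <- make_genome(1500, seed = 7)
  idx <- build_index(g)
  set.seed(8)
  seqs <- c(substr(g[["chr1"]], 101, 125),
            substr(g[["chr1"]], 401, 430),
            random_dna_str(25),
            oracle_revcomp(substr(g[["chr1"]], 801, 822)))
  reads <- data.frame(read_id = paste0("r", 1:4, "_", strrep("A", 8)),
                      umi = strrep("A", 8), cell = "c1", seq = seqs,
                      stringsAsFactors = FALSE)
  sam <- file.path(tempdir(), "batch.sam")
  out <- align_batch(reads, idx, sam_path = sam)
  expect_equal(sum(out$tally$n), nrow(reads))
  expect_setequal(unique(out$reads$status), c("mapped", "unmapped"))
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(out$placements))
  expect_identical(sort(unique(back$umi)), strrep("A", 8))
  p1 <- back[back$read_id == "r1_AAAAAAAA", ]
  expect_equal(p1$start, 100L)
  ## empty input yields a header-only SAM
  sam0 <- file.path(tempdir(), "empty.sam")
  align_batch(reads[0, ], idx, sam_path = sam0)
  expect_equal(nrow(read_sam(sam0)), 0L)
  expect_true(any(startsWith(readLines(sam0), "@SQ")))
})

test_that("the placement procedure matches the brute-force oracle on random reads", {
  g <- make_genome(2000, seed = 9)
  idx <- build_index(g)
  set.seed(10)
  N <- nchar(g[["chr1"]])
  for (i in 1:60) {
    L <- sample(18:45, 1)
    s <- sample.int(N - L - 5, 1)
    read <- substr(g[["chr1"]], s + 1, s + L)
    nmut <- sample(0:3, 1)
    if (nmut > 0) for (p in sample.int(L, nmut)) read <- mutate_at(read, p)
    if (runif(1) < 0.3) read <- oracle_revcomp(read)
    a <- sncatlas:::place_read(read, idx)
    b <- oracle_place(read, g)
    expect_identical(a$status, b$status)
    expect_equal(canonical_hits(a$hits), canonical_hits(b$hits))
  }
})
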