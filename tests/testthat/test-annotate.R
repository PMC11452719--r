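## hand-built annotation universe for the hierarchy tests
tiny_annotations <- function() {
  annotation_set(data.frame(
    biotype = c("miRNA", "snoRNA", "tRNA", "protein_coding", "lncRNA",
                "repeat_element"),
    chrom = "chr1",
    start = c(100L, 110L, 300L, 500L, 900L, 1200L),
    end = c(122L, 190L, 374L, 800L, 1100L, 1350L),
    strand = c("+", "+", "+", "+", "+", "+"),
    name = c("mir-x", "SNORD-x", "tRNA-Ala-AGC-1", "GENE1", "LINC1", "LTR-1"),
    stringsAsFactors = FALSE))
}

mol_with_placement <- function(id, len, chrom = "chr1", start = 100L,
                               strand = "+") {
  list(molecules = data.frame(molecule_id = id, cell = "c1",
                              seq = strrep("A", len),
                              stringsAsFactors = FALSE),
       placements = data.frame(molecule_id = id, chrom = chrom,
                               start = start, strand = strand, mm = 0L,
                               clip5 = 0L, clip3 = 0L, maplen = len,
                               read_id = paste0(id, "_r"), cell = "c1",
                               nhits = 1L, stringsAsFactors = FALSE))
}

test_that("file coordinate conventions unify to 0-based half-open intervals", {
  bed <- file.path(tempdir(), "pirna.bed")
  writeLines("chr1\t100\t122\tpiR-x\t0\t+", bed)
  gff <- file.path(tempdir(), "mir.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tmiRNA\t101\t122\t.\t+\t.\tID=mir-x;Name=mir-x"),
             gff)
  ann <- load_annotations(gff3 = gff, bed = c(piRNA = bed))
  r <- ann$records
  expect_equal(r$start, c(100L, 100L))   # identical internal intervals
  expect_equal(r$end, c(122L, 122L))
  expect_setequal(r$biotype, c("miRNA", "piRNA"))
  ## duplicate names across biotypes are tolerated (keyed by biotype + name)
  bed2 <- file.path(tempdir(), "rep.bed")
  writeLines("chr1\t200\t300\tmir-x\t0\t-", bed2)
  ann2 <- load_annotations(gff3 = gff, bed = c(piRNA = bed, repeat_element = bed2))
  expect_equal(nrow(ann2$records), 3L)
  ## unknown biotype labels are rejected with the accepted list
  expect_error(load_annotations(bed = c(junkRNA = bed)), "accepted")
})

test_that("round trip through GFF3/BED preserves the planted annotation", {
  cfg <- sim_config(seed = 12L, n_cells = 2L, molecules_per_cell = 10L)
  dir <- file.path(tempdir(), "roundtrip")
  unlink(dir, recursive = TRUE)
  emit_dataset(cfg, dir)
  ref <- build_reference(cfg)
  ann <- load_annotations(
    gff3 = file.path(dir, "annotations.gff3"),
    bed = c(piRNA = file.path(dir, "piRNA.bed"),
            repeat_element = file.path(dir, "repeat_element.bed")))
  a <- ann$records[order(ann$records$biotype, ann$records$name,
                         ann$records$start), ]
  b <- ref$annotations$records[order(ref$annotations$records$biotype,
                                     ref$annotations$records$name,
                                     ref$annotations$records$start), ]
  for (col in c("biotype", "chrom", "start", "end", "strand", "name"))
    expect_equal(unname(a[[col]]), unname(b[[col]]), label = col)
  expect_identical(a$aa[a$biotype == "tRNA"], b$aa[b$biotype == "tRNA"])
})

test_that("category assignment follows the priority hierarchy and length rules", {
  ann <- tiny_annotations()
  ## 22 nt molecule overlapping both a mature miRNA and a snoRNA: miRNA wins
  m <- mol_with_placement("m1", 22L, start = 105L)
  a <- assign_category(m$molecules, m$placements, ann)
  expect_identical(a$category, "miRNA")
  expect_identical(a$feature, "mir-x")
  ## 45 nt molecule over the mature miRNA: too long for miRNA, snoRNA wins
  m2 <- mol_with_placement("m2", 45L, start = 100L)
  a2 <- assign_category(m2$molecules, m2$placements, ann)
  expect_identical(a2$category, "snoRNA")
  ## antisense to a tRNA: no small-RNA category, falls through
  m3 <- mol_with_placement("m3", 30L, start = 320L, strand = "-")
  a3 <- assign_category(m3$molecules, m3$placements, ann)
  expect_true(is.na(a3$category))
  full3 <- annotate_molecules(m3$molecules, m3$placements, ann)
  expect_identical(full3$category, "unannotated")
})

test_that("catch-all routing distinguishes sense, antisense and unannotated", {
  ann <- tiny_annotations()
  m <- mol_with_placement("m1", 25L, start = 600L)
  expect_identical(annotate_molecules(m$molecules, m$placements, ann)$category,
                   "protein_coding_sense")
  m2 <- mol_with_placement("m2", 25L, start = 1250L, strand = "-")
  expect_identical(annotate_molecules(m2$molecules, m2$placements, ann)$category,
                   "repeat_antisense")
  m3 <- mol_with_placement("m3", 25L, start = 2000L)
  expect_identical(annotate_molecules(m3$molecules, m3$placements, ann)$category,
                   "unannotated")
  ## sense protein-coding beats antisense lncRNA when both overlap
  ann2 <- tiny_annotations()
  ann2$records$start[5] <- 500L; ann2$records$end[5] <- 800L
  ann2$records$strand[5] <- "-"
  m4 <- mol_with_placement("m4", 25L, start = 600L)
  expect_identical(annotate_molecules(m4$molecules, m4$placements, ann2)$category,
                   "protein_coding_sense")
})

test_that("every molecule gets exactly one category and matrices balance", {
  res <- small_pipeline()
  a <- res$assigned
  expect_false(anyNA(a$category))
  mats <- res$matrices
  ## proportions rows sum to one over assigned molecules
  expect_equal(unname(rowSums(mats$proportions)),
               rep(1, nrow(mats$proportions)))
  ## per-biotype matrix totals equal molecule totals
  for (bt in names(mats$counts)) {
    expect_equal(sum(mats$counts[[bt]]), sum(a$category == bt), label = bt)
  }
  ## priority dominance: molecules in lower categories never same-strand
  ## overlap a higher-priority feature (within the length rules)
  prio <- c("miRNA", "rRNA", "snoRNA", "snRNA", "tRNA", "piRNA")
  cand <- assign_category(res$molecules, res$placements,
                          res$reference$annotations)
  mi <- match(a$molecule_id, cand$molecule_id)
  agrees <- is.na(cand$category[mi]) | cand$category[mi] == a$category |
    match(a$category, prio) <= match(cand$category[mi], prio)
  expect_true(all(agrees, na.rm = TRUE))
  ## collision-free error-free run: counts equal the planted truth exactly
  tr <- res$truth
  for (bt in prio) {
    feats <- colnames(mats$counts[[bt]])
    truth_m <- truth_count_matrix(tr[tr$biotype == bt & tr$chrom != "chrM", ],
                                  rownames(mats$counts[[bt]]), feats)
    got <- mats$counts[[bt]]
    ## chrM molecules are annotated too; exclude their features for equality
    mt_feats <- grepl("^MT-", feats)
    expect_equal(unname(got[, !mt_feats]), unname(truth_m[, !mt_feats]),
                 label = bt)
  }
  ## the default miRNA insert-length histogram peaks at 22 nt
  lh <- mats$length_histograms
  mir <- lh[lh$category == "miRNA", ]
  expect_equal(mir$length[which.max(mir$n)], 22L)
})
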