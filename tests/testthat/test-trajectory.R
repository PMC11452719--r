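test_that("pseudotime rescaling follows the closed form", {
  pt <- make_pseudotime(pre = c(0, 2), icm = c(3, 4), te = c(5, 6))
  r <- rescale_pseudotime(pt)
  expect_equal(r$alignment$scale_factor, 2)
  ## Psd_ICM = 3 with pre_max 2, scale 2: rescaled to 4
  expect_equal(r$table$pseudotime_mod[r$table$pseudotime == 3 &
                                        r$table$lineage == "ICM"], 4)
  ## the ICM maximum lands exactly on the TE maximum
  expect_equal(max(r$table$pseudotime_mod[r$table$lineage == "ICM"]), 6)
  ## TE and pre-lineage cells are untouched
  unch <- r$table$lineage != "ICM"
  expect_equal(r$table$pseudotime_mod[unch], r$table$pseudotime[unch])
  ## coinciding branch maxima: the identity transform
  pt2 <- make_pseudotime(pre = c(0, 2), icm = c(3, 6), te = c(5, 6))
  r2 <- rescale_pseudotime(pt2)
  expect_equal(r2$alignment$scale_factor, 1)
  expect_equal(r2$table$pseudotime_mod, r2$table$pseudotime)
  ## degenerate denominator errors out
  pt3 <- make_pseudotime(pre = c(0, 4), icm = c(1, 4), te = c(5, 6))
  expect_error(rescale_pseudotime(pt3), "degenerate")
  ## a missing class errors out
  expect_error(rescale_pseudotime(pt[pt$lineage != "TE", ]), "TE")
})

test_that("rescaling identities hold for randomized configurations", {
  set.seed(41)
  for (i in 1:100) {
    pre <- runif(5, 0, 3)
    icm <- c(runif(4, 2, 8), max(pre) + runif(1, 0.5, 6))
    te <- runif(5, 2, 12)
    r <- rescale_pseudotime(make_pseudotime(pre, icm, te))
    expect_lt(abs(max(r$table$pseudotime_mod[r$table$lineage == "ICM"]) -
                    max(te)), 1e-12)
  }
})

test_that("pseudobulk means are group means, invariant to cell order", {
  set.seed(42)
  norm <- matrix(rnorm(12 * 4), nrow = 12,
                 dimnames = list(paste0("c", 1:12), paste0("f", 1:4)))
  grp <- rep(c("8cell", "morula", "EB", "E5_ICM", "E6_ICM", "E7_ICM"), 2)
  pb <- pseudobulk(norm, grp)
  expect_equal(nrow(pb), 6L)
  expect_equal(pb["EB", "f1"], mean(norm[grp == "EB", "f1"]))
  perm <- sample(nrow(norm))
  expect_equal(pseudobulk(norm[perm, ], grp[perm]), pb)
  ## a single-cell group reproduces that cell
  pb1 <- pseudobulk(norm[1:3, ], c("a", "b", "b"))
  expect_equal(unname(pb1["a", ]), unname(norm[1, ]))
})

test_that("target correlation matches the closed-form t test", {
  ## perfectly anticorrelated pair
  x <- 1:6
  pbm <- cbind(m1 = as.numeric(x)); pbg <- cbind(g1 = as.numeric(6:1))
  rownames(pbm) <- rownames(pbg) <- paste0("grp", 1:6)
  ct <- correlate_targets(pbm, pbg, data.frame(mirna = "m1", gene = "g1"))
  expect_equal(ct$results$r, -1)
  expect_lt(ct$results$p_neg, 1e-10)
  expect_equal(nrow(ct$significant_negative), 1L)
  ## exactly uncorrelated: one-sided p = 1/2 by symmetry
  pbm2 <- cbind(m = c(-1, 1, -1, 1)); pbg2 <- cbind(g = c(-1, -1, 1, 1))
  rownames(pbm2) <- rownames(pbg2) <- paste0("grp", 1:4)
  ct2 <- correlate_targets(pbm2, pbg2, data.frame(mirna = "m", gene = "g"))
  expect_equal(ct2$results$r, 0)
  expect_equal(ct2$results$p_neg, 0.5)
  expect_equal(ct2$results$p_neg + ct2$results$p_pos, 1)
  ## r = -0.9 at n = 6: t = -4.1295, one-sided p = 0.00726
  xs <- scale(1:6)[, 1]
  resid <- scale(c(1, -1, 2, -2, 1, -1) -
                   sum(c(1, -1, 2, -2, 1, -1) * xs) / sum(xs^2) * xs)[, 1]
  y <- -(0.9 * xs + sqrt(1 - 0.81) * resid / sqrt(sum(resid^2) / 5))
  pbm3 <- cbind(m = xs); pbg3 <- cbind(g = y)
  rownames(pbm3) <- rownames(pbg3) <- paste0("grp", 1:6)
  ct3 <- correlate_targets(pbm3, pbg3, data.frame(mirna = "m", gene = "g"))
  expect_equal(ct3$results$r, -0.9, tolerance = 1e-10)
  expect_equal(ct3$results$t, -4.1295, tolerance = 1e-4)
  expect_equal(ct3$results$p_neg, 0.00726, tolerance = 2e-3)
  ## and against direct numerical integration of the t density (4 df)
  tdens4 <- function(u) exp(lgamma(2.5) - lgamma(2)) / sqrt(4 * pi) *
    (1 + u^2 / 4)^(-2.5)
  p_int <- integrate(tdens4, -Inf, ct3$results$t, rel.tol = 1e-12)$value
  expect_equal(ct3$results$p_neg, p_int, tolerance = 1e-9)
  ## zero-variance vectors are skipped with a reason
  pbg4 <- cbind(g = rep(1, 6)); rownames(pbg4) <- rownames(pbm3)
  ct4 <- correlate_targets(pbm3, pbg4, data.frame(mirna = "m", gene = "g"))
  expect_equal(nrow(ct4$results), 0L)
  expect_identical(ct4$skipped$reason, "zero_variance")
})

test_that("trajectory-associated miRNAs are selected by slope FDR and stage DE", {
  set.seed(43)
  n <- 200L
  ps <- sort(runif(n, 0, 10))
  batch <- rep(c("b1", "b2"), length.out = n)
  feats <- c("up", "flat1", "flat2", "flat3")
  norm <- cbind(up = 1 * ps + rnorm(n, sd = 0.5) + ifelse(batch == "b2", 1, 0),
                flat1 = rnorm(n, sd = 0.5), flat2 = rnorm(n, sd = 0.5),
                flat3 = rnorm(n, sd = 0.5))
  rownames(norm) <- sprintf("c%03d", 1:n)
  sel <- select_trajectory_mirnas(norm, ps, batch,
                                  de_features = c("up", "flat1"))
  expect_true(sel$associated[sel$feature == "up"])
  expect_true(sel$selected[sel$feature == "up"])
  expect_false(any(sel$associated[sel$feature %in% c("flat1", "flat2", "flat3")]))
  ## associated but not stage-DE is excluded from the final list
  norm2 <- cbind(norm, up2 = 0.8 * ps + rnorm(n, sd = 0.5))
  sel2 <- select_trajectory_mirnas(norm2, ps, batch, de_features = "up")
  expect_true(sel2$associated[sel2$feature == "up2"])
  expect_false(sel2$selected[sel2$feature == "up2"])
  expect_warning(select_trajectory_mirnas(norm, ps, rep("b1", n),
                                          de_features = "up"),
                 "single batch")
})

test_that("pattern clustering labels monotone and peaked profiles C2/C3/C1", {
  set.seed(44)
  n <- 120L
  ps <- seq(0, 1, length.out = n)
  mk <- function(f) f(ps) + rnorm(n, sd = 0.05)
  norm <- cbind(inc1 = mk(function(t) 2 * t), inc2 = mk(function(t) 3 * t),
                inc3 = mk(function(t) t^2),
                dec1 = mk(function(t) -2 * t), dec2 = mk(function(t) 1 - t),
                dec3 = mk(function(t) -t^1.5),
                peak1 = mk(function(t) sin(pi * t)),
                peak2 = mk(function(t) 1 - (2 * t - 1)^2),
                peak3 = mk(function(t) exp(-((t - 0.5) / 0.2)^2)))
  rownames(norm) <- sprintf("c%03d", 1:n)
  cl <- cluster_patterns(norm, ps, colnames(norm), seed = 7L)
  lab <- setNames(cl$labels$cluster, cl$labels$feature)
  expect_true(all(lab[c("inc1", "inc2", "inc3")] == "C2"))
  expect_true(all(lab[c("dec1", "dec2", "dec3")] == "C3"))
  expect_true(all(lab[c("peak1", "peak2", "peak3")] == "C1"))
  expect_error(cluster_patterns(norm, ps, c("inc1", "dec1"), seed = 1L),
               "at least")
})

test_that("the novel-miRNA filter is the conjunction of its four criteria", {
  lens_ok <- paste(sprintf("c%02d:21,22,23", 1:31), collapse = ";")
  lens_29cells <- paste(sprintf("c%02d:21,22", 1:29), collapse = ";")
  lens_long <- paste(sprintf("c%02d:30,31,32,21", 1:35), collapse = ";")
  cand <- data.frame(
    candidate_id = paste0("n", 1:6),
    significant_randfold = c("yes", "yes", "no", "yes", "yes", "yes"),
    mirdeep_score = c(3.2, -0.5, 3.2, 3.2, 3.2, 3.2),
    contexts = c("b1;b2", "b1;b2", "b1;b2", "b1", "b1;b2", "b1;b2"),
    cell_read_lengths = c(lens_ok, lens_ok, lens_ok, lens_ok,
                          lens_29cells, lens_long),
    stringsAsFactors = FALSE)
  fn <- filter_novel(cand)
  expect_equal(fn$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(fn$reason[2], "nonpositive_score")
  expect_identical(fn$reason[3], "not_significant_randfold")
  expect_identical(fn$reason[4], "single_context")
  expect_identical(fn$reason[5], "insufficient_read_support")
  expect_identical(fn$reason[6], "insufficient_read_support")
  ## a missing field rejects the row outright
  cand$mirdeep_score[1] <- NA
  fn2 <- filter_novel(cand)
  expect_false(fn2$accepted[1])
  expect_identical(fn2$reason[1], "missing_field")
})
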