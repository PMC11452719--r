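# Independent oracles used by the property/acceptance tests.
#
# The placement oracle enumerates candidates with Biostrings::matchPattern
# (an independent C implementation) and applies the placement rules in
# straightforward loop code; the package aligner uses its own integer-vector
# scan, so the two routes share no code. The deduplication oracle evaluates
# the directional rule by repeated transitive closure on an explicit
# adjacency matrix, unlike the package's ordered breadth-first search.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## all fully-contained placements of `query` on one strand with at most
## `max_mm` counted mismatches; `exempt` is a query position whose mismatch
## is not counted (0 = none)
oracle_scan <- function(query, genome, max_mm, exempt) {
  res <- list()
  qch <- strsplit(query, "", fixed = TRUE)[[1]]
  allowance <- max_mm + as.integer(exempt > 0L)
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    if (length(qch) > length(subj)) next
    m <- Biostrings::matchPattern(Biostrings::DNAString(query), subj,
                                  max.mismatch = allowance,
                                  with.indels = FALSE)
    st <- Biostrings::start(m)
    st <- st[st >= 1L & st + length(qch) - 1L <= length(subj)]
    for (s in st) {
      gch <- strsplit(as.character(
        Biostrings::subseq(subj, s, s + length(qch) - 1L)), "",
        fixed = TRUE)[[1]]
      mmpos <- which(gch != qch)
      counted <- sum(mmpos != exempt)
      if (counted <= max_mm)
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start = s - 1L, mm = counted,
          stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

oracle_both_strands <- function(query, genome, max_mm, exempt_terminal) {
  L <- nchar(query)
  hp <- oracle_scan(query, genome, max_mm,
                    exempt = if (exempt_terminal) L else 0L)
  hm <- oracle_scan(oracle_revcomp(query), genome, max_mm,
                    exempt = if (exempt_terminal) 1L else 0L)
  if (!is.null(hp)) hp$strand <- "+"
  if (!is.null(hm)) hm$strand <- "-"
  rbind(hp, hm)
}

oracle_best_stratum <- function(h, clip5, clip3, maplen) {
  best <- min(h$mm)
  h <- h[h$mm == best, , drop = FALSE]
  h$clip5 <- clip5; h$clip3 <- clip3; h$maplen <- maplen
  h <- h[order(h$chrom, h$start, h$strand),
         c("chrom", "start", "strand", "mm", "clip5", "clip3", "maplen")]
  rownames(h) <- NULL
  h
}

## full placement procedure: best-stratum full-length pass with the
## length-dependent mismatch filters, then 3' and 5' soft-clip rescue
oracle_place <- function(read, genome) {
  L <- nchar(read)
  h <- oracle_both_strands(read, genome, 2L, exempt_terminal = TRUE)
  if (!is.null(h)) {
    hb <- oracle_best_stratum(h, 0L, 0L, L)
    if (nrow(hb) > 50L)
      return(list(status = "suppressed", hits = NULL))
    best <- hb$mm[1]
    filtered <- (L < 20L && best >= 1L) ||
      (L >= 20L && L <= 40L && best == 2L)
    if (!filtered)
      return(list(status = "mapped", hits = hb))
  }
  for (c3 in 1:3) {
    core <- L - c3
    if (core < 17L) break
    h <- oracle_both_strands(substr(read, 1L, core), genome, 1L,
                             exempt_terminal = FALSE)
    if (is.null(h)) next
    hb <- oracle_best_stratum(h, 0L, c3, core)
    if (nrow(hb) > 50L) return(list(status = "suppressed", hits = NULL))
    return(list(status = "mapped", hits = hb))
  }
  for (c5 in 1:3) {
    core <- L - c5
    if (core < 17L) break
    h <- oracle_both_strands(substr(read, c5 + 1L, L), genome, 1L,
                             exempt_terminal = TRUE)
    if (is.null(h)) next
    hb <- oracle_best_stratum(h, c5, 0L, core)
    if (nrow(hb) > 50L) return(list(status = "suppressed", hits = NULL))
    return(list(status = "mapped", hits = hb))
  }
  list(status = "unmapped", hits = NULL)
}

canonical_hits <- function(h) {
  if (is.null(h)) return(NULL)
  h <- h[order(h$chrom, h$start, h$strand),
         c("chrom", "start", "strand", "mm", "clip5", "clip3", "maplen")]
  rownames(h) <- NULL
  h
}

## cluster-size multiset under the directional rule, by repeated transitive
## closure on the unassigned-node subgraph
oracle_directional_sizes <- function(umis, counts) {
  n <- length(umis)
  M <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  H <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      H[i, j] <- sum(M[i, ] != M[j, ])
  A <- (H <= 1L) & outer(counts, counts, function(a, b) a >= 2L * b - 1L)
  diag(A) <- FALSE
  unassigned <- rep(TRUE, n)
  ord <- order(-counts, umis)
  sizes <- integer(0)
  while (any(unassigned)) {
    top <- ord[unassigned[ord]][1L]
    sub <- which(unassigned)
    R <- A[sub, sub, drop = FALSE]
    for (k in seq_along(sub))        # boolean Floyd-Warshall closure
      R <- R | outer(R[, k], R[k, ])
    reach <- sub[R[match(top, sub), ]]
    members <- union(top, reach)
    sizes <- c(sizes, length(members))
    unassigned[members] <- FALSE
  }
  sort(sizes, decreasing = TRUE)
}

## literal transcription of the tRF rule text, decision by decision
oracle_trf <- function(length, shift5, shift3) {
  if (length < 50) {
    if (shift3 <= -10 && !(shift5 <= -10)) return("five_prime_half")
    if (shift5 <= -10 && !(shift3 <= -10)) return("three_prime_half")
    return("unclassified")
  }
  if (length > 50) {
    if (!(shift5 <= -10) && !(shift3 <= -10)) return("full_length")
    return("unclassified")
  }
  "unclassified"
}
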