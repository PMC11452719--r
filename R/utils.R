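#' @importFrom stats median p.adjust pt rbinom rnbinom rnorm rpois runif
#'   setNames wilcox.test cor lm coef kmeans quantile sd rexp
#' @importFrom utils read.delim write.table
NULL

## integer encoding used by the aligner: A=1 C=2 G=3 T=4; complement = 5 - code
dna_to_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES)
}

int_to_dna <- function(v) paste(DNA_BASES[v], collapse = "")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGT alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## maximal run of 'base' at the end of a string, in characters
trailing_run <- function(seq, base = "A") {
  n <- nchar(seq)
  if (n == 0L) return(0L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- 0L
  while (k < n && ch[n - k] == base) k <- k + 1L
  k
}

## cap A/T homopolymer runs at 3 by rewriting every 4th base of a run to C;
## operates on a character vector of single bases
break_homopolymers <- function(bases, targets = c("A", "T"), max_run = 3L) {
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values %in% targets & r$lengths > max_run)) {
    hit <- seq(starts[k] + max_run, ends[k], by = max_run + 1L)
    bases[hit] <- "C"
  }
  bases
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
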