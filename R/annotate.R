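## ---------------------------------------------------------------------------
## Hierarchical, strand-aware biotype annotation.
##
## Each molecule is assigned to exactly one category: over all of its
## placements, same-strand overlapping features are collected and the
## category highest in the fixed priority list (miRNA, rRNA, snoRNA, snRNA,
## tRNA, piRNA) wins; molecules overlapping mature miRNA or piRNA must be
## shorter than 40 nt. Whatever remains is routed to catch-all categories
## (protein-coding / lncRNA / repeat, each sense or antisense, pseudogene,
## unannotated).
## ---------------------------------------------------------------------------

ACCEPTED_BIOTYPES <- c(BIOTYPE_PRIORITY, "miRNA_hairpin", CATCHALL_BIOTYPES)

#' Construct an annotation set
#'
#' @param records data.frame with biotype, chrom, start, end (0-based
#'   half-open), strand, name, and optionally parent, aa, anticodon.
#' @return object of class \code{annotation_set} with the fixed biotype
#'   priority list.
#' @export
annotation_set <- function(records) {
  needed <- c("biotype", "chrom", "start", "end", "strand", "name")
  stopifnot(all(needed %in% names(records)))
  bad <- setdiff(unique(records$biotype), ACCEPTED_BIOTYPES)
  if (length(bad))
    stopf("unknown biotype label(s): %s (accepted: %s)",
          paste(bad, collapse = ", "), paste(ACCEPTED_BIOTYPES, collapse = ", "))
  if (any(records$start >= records$end))
    stopf("invalid intervals: start must be < end")
  for (col in c("parent", "aa", "anticodon"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  structure(list(records = records,
                 priority = c(BIOTYPE_PRIORITY, "other")),
            class = "annotation_set")
}

annotation_granges <- function(aset, biotypes = NULL) {
  r <- aset$records
  if (!is.null(biotypes)) r <- r[r$biotype %in% biotypes, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = r$chrom,
    ranges = IRanges::IRanges(start = r$start + 1L, end = r$end),
    strand = r$strand)
  S4Vectors::mcols(gr)$biotype <- r$biotype
  S4Vectors::mcols(gr)$name <- r$name
  S4Vectors::mcols(gr)$aa <- r$aa
  S4Vectors::mcols(gr)$anticodon <- r$anticodon
  gr
}

#' Load annotation tracks from GFF3 and BED files
#'
#' GFF3 (1-based closed) and BED (0-based half-open) coordinates are unified
#' to the internal 0-based half-open convention. The biotype of GFF3 records
#' is the feature type; BED tracks carry their biotype in the argument name.
#'
#' @param gff3 paths to GFF3 files whose \code{type} column is the biotype.
#' @param bed named character vector of BED paths; names are biotype labels.
#' @return an \code{annotation_set}.
#' @export
load_annotations <- function(gff3 = character(), bed = character()) {
  recs <- list()
  for (path in gff3) {
    gr <- rtracklayer::import(path, format = "gff3")
    m <- S4Vectors::mcols(gr)
    parent <- if (!is.null(m$Parent)) {
      vapply(as.list(m$Parent), function(p)
        if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    } else NA_character_
    recs[[length(recs) + 1L]] <- data.frame(
      biotype = as.character(m$type),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      name = if (!is.null(m$Name)) as.character(m$Name) else as.character(m$ID),
      parent = parent,
      aa = if (!is.null(m$aa)) as.character(m$aa) else NA_character_,
      anticodon = if (!is.null(m$anticodon)) as.character(m$anticodon)
                  else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(bed) && is.null(names(bed)))
    stopf("bed paths must be named by biotype")
  for (bt in names(bed)) {
    gr <- rtracklayer::import(bed[[bt]], format = "bed")
    recs[[length(recs) + 1L]] <- data.frame(
      biotype = bt,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      name = S4Vectors::mcols(gr)$name,
      parent = NA_character_, aa = NA_character_, anticodon = NA_character_,
      stringsAsFactors = FALSE)
  }
  annotation_set(do.call(rbind, recs))
}

placement_granges <- function(placements, flip = FALSE) {
  strand <- placements$strand
  if (flip) strand <- ifelse(strand == "+", "-", "+")
  GenomicRanges::GRanges(
    seqnames = placements$chrom,
    ranges = IRanges::IRanges(start = placements$start + 1L,
                              end = placements$start + placements$maplen),
    strand = strand)
}

MIRNA_PIRNA_MAX_LEN <- 40L

#' Assign molecules to small-RNA categories by the annotation hierarchy
#'
#' @param molecules molecule table (needs molecule_id, seq).
#' @param placements molecule placements (molecule_id, chrom, start, strand,
#'   maplen).
#' @param annotations an \code{annotation_set}.
#' @return data.frame molecule_id, category, feature, overlap (NA category for
#'   molecules that fall through to \code{\link{assign_other}}).
#' @export
assign_category <- function(molecules, placements, annotations) {
  small <- annotation_granges(annotations, BIOTYPE_PRIORITY)
  pgr <- placement_granges(placements)
  ov <- GenomicRanges::findOverlaps(pgr, small, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  olap <- GenomicRanges::width(GenomicRanges::pintersect(pgr[q], small[s]))
  cand <- data.frame(
    molecule_id = placements$molecule_id[q],
    biotype = S4Vectors::mcols(small)$biotype[s],
    feature = S4Vectors::mcols(small)$name[s],
    overlap = olap,
    stringsAsFactors = FALSE)
  ## mature miRNA / piRNA assignments require molecules shorter than 40 nt
  mol_len <- nchar(molecules$seq)[match(cand$molecule_id, molecules$molecule_id)]
  cand <- cand[!(cand$biotype %in% c("miRNA", "piRNA") &
                   mol_len >= MIRNA_PIRNA_MAX_LEN), , drop = FALSE]
  out <- data.frame(molecule_id = molecules$molecule_id,
                    category = NA_character_, feature = NA_character_,
                    overlap = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(cand)) {
    cand$prio <- match(cand$biotype, BIOTYPE_PRIORITY)
    cand <- cand[order(cand$molecule_id, cand$prio, -cand$overlap,
                       cand$feature), , drop = FALSE]
    ## a molecule can hit the same feature through several placements
    best <- cand[!duplicated(cand$molecule_id), , drop = FALSE]
    mi <- match(best$molecule_id, out$molecule_id)
    out$category[mi] <- best$biotype
    out$feature[mi] <- best$feature
    out$overlap[mi] <- best$overlap
  }
  out
}

OTHER_PRIORITY <- c("protein_coding", "lncRNA", "repeat_element", "pseudogene")

#' Route unassigned molecules to catch-all genomic categories
#'
#' Priority: protein-coding, lncRNA, repeat, pseudogene, each checked sense
#' before antisense; molecules overlapping nothing become "unannotated".
#'
#' @param molecules molecule table.
#' @param placements molecule placements.
#' @param annotations an \code{annotation_set} holding the catch-all tracks.
#' @param unassigned molecule ids to label (from \code{\link{assign_category}}).
#' @return data.frame molecule_id, category, feature.
#' @export
assign_other <- function(molecules, placements, annotations, unassigned) {
  pl <- placements[placements$molecule_id %in% unassigned, , drop = FALSE]
  out <- data.frame(molecule_id = unassigned, category = "unannotated",
                    feature = NA_character_, stringsAsFactors = FALSE)
  if (nrow(pl) == 0L) return(out)
  tracks <- annotation_granges(annotations, OTHER_PRIORITY)
  cand <- list()
  for (sense in c(TRUE, FALSE)) {
    pgr <- placement_granges(pl, flip = !sense)
    ov <- GenomicRanges::findOverlaps(pgr, tracks, ignore.strand = FALSE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    if (!length(q)) next
    bt <- S4Vectors::mcols(tracks)$biotype[s]
    suffix <- ifelse(bt == "pseudogene", "",
                     if (sense) "_sense" else "_antisense")
    olap <- GenomicRanges::width(GenomicRanges::pintersect(pgr[q], tracks[s]))
    cand[[length(cand) + 1L]] <- data.frame(
      molecule_id = pl$molecule_id[q],
      biotype = bt,
      category = paste0(sub("repeat_element", "repeat", bt), suffix),
      feature = S4Vectors::mcols(tracks)$name[s],
      sense = sense, overlap = olap, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (!is.null(cand) && nrow(cand)) {
    cand$prio <- match(cand$biotype, OTHER_PRIORITY) * 2L + !cand$sense
    cand <- cand[order(cand$molecule_id, cand$prio, -cand$overlap,
                       cand$feature), , drop = FALSE]
    best <- cand[!duplicated(cand$molecule_id), , drop = FALSE]
    mi <- match(best$molecule_id, out$molecule_id)
    out$category[mi] <- best$category
    out$feature[mi] <- best$feature
  }
  out
}

#' Assign every molecule to exactly one category
#'
#' Runs \code{\link{assign_category}} then \code{\link{assign_other}} and
#' merges the two partitions.
#'
#' @param molecules molecule table.
#' @param placements molecule placements.
#' @param annotations an \code{annotation_set}.
#' @return molecules with category/feature/insert-length columns added.
#' @export
annotate_molecules <- function(molecules, placements, annotations) {
  a <- assign_category(molecules, placements, annotations)
  unassigned <- a$molecule_id[is.na(a$category)]
  if (length(unassigned)) {
    b <- assign_other(molecules, placements, annotations, unassigned)
    mi <- match(b$molecule_id, a$molecule_id)
    a$category[mi] <- b$category
    a$feature[mi] <- b$feature
  }
  molecules$category <- a$category[match(molecules$molecule_id, a$molecule_id)]
  molecules$feature <- a$feature[match(molecules$molecule_id, a$molecule_id)]
  molecules$insert_length <- nchar(molecules$seq)
  molecules
}

#' Build per-biotype count matrices, per-cell biotype proportions and length
#' histograms
#'
#' @param assigned output of \code{\link{annotate_molecules}}.
#' @param metadata cell metadata (must cover every cell present).
#' @param annotations an \code{annotation_set} (fixes the feature universe per
#'   biotype).
#' @return list(counts = named list of cells x features integer matrices,
#'   proportions = cells x categories matrix with unit row sums,
#'   length_histograms = data.frame(category, length, n)).
#' @export
build_count_matrices <- function(assigned, metadata, annotations) {
  missing_cells <- setdiff(unique(assigned$cell), metadata$cell)
  if (length(missing_cells))
    stopf("metadata missing cell(s): %s", paste(missing_cells, collapse = ", "))
  cells <- metadata$cell
  counts <- list()
  for (bt in BIOTYPE_PRIORITY) {
    feats <- sort(annotations$records$name[annotations$records$biotype == bt])
    m <- matrix(0L, nrow = length(cells), ncol = length(feats),
                dimnames = list(cells, feats))
    sub <- assigned[assigned$category == bt, , drop = FALSE]
    if (nrow(sub)) {
      tab <- table(factor(sub$cell, levels = cells),
                   factor(sub$feature, levels = feats))
      m <- m + as.integer(tab)
      dim(m) <- c(length(cells), length(feats))
      dimnames(m) <- list(cells, feats)
    }
    counts[[bt]] <- m
  }
  cats <- sort(unique(assigned$category))
  prop <- table(factor(assigned$cell, levels = cells),
                factor(assigned$category, levels = cats))
  prop <- matrix(as.numeric(prop), nrow = length(cells),
                 dimnames = list(cells, cats))
  rs <- rowSums(prop)
  prop <- prop / ifelse(rs == 0, 1, rs)
  lh <- as.data.frame(table(category = assigned$category,
                            length = assigned$insert_length),
                      stringsAsFactors = FALSE)
  names(lh)[3] <- "n"
  lh$length <- as.integer(lh$length)
  lh <- lh[lh$n > 0, , drop = FALSE]
  rownames(lh) <- NULL
  list(counts = counts, proportions = prop, length_histograms = lh)
}
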