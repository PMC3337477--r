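suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## A small two-chromosome gene set used across tests.
tiny_genes <- function() {
  gene_set(id = c("g1", "g2", "mir1", "tg1"),
           chrom = c("chr1", "chr1", "chr2", "chr2"),
           strand = c("+", "-", "+", "-"),
           start = c(101, 2001, 1000, 101),
           end = c(600, 3000, 1300, 600),
           kind = c("coding", "coding", "mir", "coding"),
           is_mirna_target = c(FALSE, FALSE, FALSE, TRUE),
           chrom_lengths = c(chr1 = 10000, chr2 = 10000))
}

## Alignment set from explicit read coordinates.
make_reads <- function(chrom, start, end, strand, genotype = "WT",
                       replicate = 1, total_mapped = 1e6,
                       library_id = paste0(genotype, "_r", replicate)) {
  alignment_set(library_id, genotype, replicate,
                GRanges(chrom, IRanges(start, end), strand = strand),
                total_mapped = total_mapped)
}

## Brute-force per-read window count: the independent oracle for the
## interval-index implementation.
brute_count <- function(reads_df, w_chrom, w_start, w_end, w_strand,
                        same_strand = TRUE) {
  hit <- reads_df$chrom == w_chrom &
    pmax(reads_df$start, w_start) <= pmin(reads_df$end, w_end)
  if (same_strand) hit <- hit & reads_df$strand == w_strand
  else hit <- hit & reads_df$strand != w_strand
  sum(hit)
}

## Quadratic all-pairs interval overlap oracle (strand rule optional).
brute_pairs <- function(a, b, opposite_strand = NA) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    if (max(a$start[i], b$start[j]) > min(a$end[i], b$end[j])) next
    if (!is.na(opposite_strand) &&
        (a$strand[i] != b$strand[j]) != opposite_strand) next
    out <- rbind(out, data.frame(i = i, j = j))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer()) else out
}

## Reflect a gene set through the chromosome midpoint and flip strands.
mirror_genes <- function(genes) {
  lens <- seqlengths(genes)[as.character(seqnames(genes))]
  gene_set(id = genes$id, chrom = as.character(seqnames(genes)),
           strand = ifelse(as.character(strand(genes)) == "+", "-", "+"),
           start = lens - end(genes) + 1, end = lens - start(genes) + 1,
           kind = genes$kind, is_mirna_target = genes$is_mirna_target,
           chrom_lengths = seqlengths(genes))
}

## Expected mirrored image of a window GRanges.
mirror_ranges <- function(gr) {
  lens <- seqlengths(gr)[as.character(seqnames(gr))]
  GRanges(seqnames(gr),
          IRanges(lens - end(gr) + 1, lens - start(gr) + 1),
          strand = ifelse(as.character(strand(gr)) == "+", "-", "+"),
          seqinfo = seqinfo(gr))
}

## Random downstream-window quantification table for filter-property
## tests (WT and mutant, 3 replicates each).
random_quant_table <- function(n_genes = 30, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n_genes))
  rows <- expand.grid(gene_id = ids, genotype = c("WT", "mut"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  rows$role <- "downstream500"
  rows$library_id <- paste0(rows$genotype, "_r", rows$replicate)
  rows$length <- 500
  rows$count <- rnbinom(nrow(rows), mu = 2, size = 0.5)
  rows$rpkm <- rpkm(rows$count, rows$length, 1e6)
  rows
}

## Gene set matching random_quant_table (no MIR loci).
random_quant_genes <- function(n_genes = 30) {
  ids <- sprintf("g%03d", seq_len(n_genes))
  gene_set(id = ids, chrom = "chr1", strand = "+",
           start = seq(1, by = 3000, length.out = n_genes),
           end = seq(1, by = 3000, length.out = n_genes) + 999,
           chrom_lengths = c(chr1 = 3000 * n_genes + 2000))
}

## allc-style methylation sample with a given per-site level vector.
make_allc <- function(pos, level, context = "CG", chrom = "chr1",
                      cov = 20, strand = "+") {
  n <- length(pos)
  data.frame(chrom = chrom, pos = pos,
             strand = rep_len(strand, n),
             context = rep_len(context, n),
             mc = round(rep_len(level, n) * rep_len(cov, n)),
             cov = rep_len(cov, n), stringsAsFactors = FALSE)
}
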