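#' Extension spans overlapping opposite-strand neighbouring genes
#'
#' Finds every (extension span, gene) pair where the span shares at least
#' 1 bp with a gene on the opposite strand other than its own parent
#' gene. The attached summary count tallies spans with at least one such
#' partner once, however many partners they have. These are the loci
#' where a read-through transcript runs into antisense transcription —
#' potential double-stranded-RNA sources.
#'
#' @param spans `GRanges` of extension spans with `gene_id` metadata
#'   (see [extension_spans()]).
#' @param genes the gene set.
#' @return `data.frame` of pairs (`span_gene_id`, `partner_gene_id`,
#'   `overlap_bp`); attribute `n_spans_with_partner`.
#' @export
antisense_overlaps <- function(spans, genes) {
  hits <- findOverlaps(spans, genes, minoverlap = 1L, ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  keep <- as.character(strand(spans))[qi] != as.character(strand(genes))[si] &
    spans$gene_id[qi] != genes$id[si]
  qi <- qi[keep]; si <- si[keep]
  ov <- pintersect(ranges(spans)[qi], ranges(genes)[si])
  out <- data.frame(span_gene_id = spans$gene_id[qi],
                    partner_gene_id = genes$id[si],
                    overlap_bp = width(ov), stringsAsFactors = FALSE)
  attr(out, "n_spans_with_partner") <- length(unique(out$span_gene_id))
  out
}

#' Mutually overlapping extension-span pairs
#'
#' Unordered pairs of extension spans on opposite strands sharing at
#' least 1 bp (convergent read-through into read-through). Abutting spans
#' with no shared base do not pair.
#'
#' @param spans `GRanges` of extension spans with `gene_id`.
#' @return `data.frame` of pairs (`gene_id_a`, `gene_id_b`,
#'   `overlap_bp`), each pair once.
#' @export
mutual_extension_overlaps <- function(spans) {
  hits <- findOverlaps(spans, minoverlap = 1L, ignore.strand = TRUE,
                       drop.self = TRUE, drop.redundant = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  keep <- as.character(strand(spans))[qi] != as.character(strand(spans))[si]
  qi <- qi[keep]; si <- si[keep]
  ov <- pintersect(ranges(spans)[qi], ranges(spans)[si])
  data.frame(gene_id_a = spans$gene_id[qi], gene_id_b = spans$gene_id[si],
             overlap_bp = width(ov), stringsAsFactors = FALSE)
}

#' DMRs intersecting extension spans
#'
#' Strand-agnostic >= 1 bp intersections between called DMRs and
#' extension spans — the test of whether read-through loci acquire
#' differential methylation.
#'
#' @param dmrs output of [call_dmrs()] (rows used: `chrom`, `start`,
#'   `end`; typically pre-filtered to `passed`).
#' @param spans `GRanges` of extension spans with `gene_id`.
#' @return `data.frame` of pairs (`dmr_index`, `chrom`, `dmr_start`,
#'   `dmr_end`, `span_gene_id`, `overlap_bp`).
#' @export
dmr_extension_overlap <- function(dmrs, spans) {
  if (nrow(dmrs) == 0L || length(spans) == 0L)
    return(data.frame(dmr_index = integer(), chrom = character(),
                      dmr_start = integer(), dmr_end = integer(),
                      span_gene_id = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE))
  dgr <- GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
  hits <- suppressWarnings(findOverlaps(dgr, spans, minoverlap = 1L,
                                        ignore.strand = TRUE))
  qi <- queryHits(hits); si <- subjectHits(hits)
  ov <- pintersect(ranges(dgr)[qi], ranges(spans)[si])
  data.frame(dmr_index = qi, chrom = dmrs$chrom[qi],
             dmr_start = dmrs$start[qi], dmr_end = dmrs$end[qi],
             span_gene_id = spans$gene_id[si], overlap_bp = width(ov),
             stringsAsFactors = FALSE)
}
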