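## Window geometry. All windows are GRanges on the gene's strand with
## metadata columns gene_id, role and truncated. Coordinates are 1-based
## inclusive (the GRanges convention); BED export converts at the boundary.

make_windows <- function(genes, start, end, role) {
  chrom <- as.character(seqnames(genes))
  lens <- seqlengths(genes)[chrom]
  cs <- pmax(start, 1)
  ce <- pmin(end, lens)
  truncated <- cs != start | ce != end
  keep <- ce >= cs
  if (!all(keep))
    warning(sum(!keep), " zero-length ", role,
            " window(s) at chromosome edges excluded: ",
            paste(utils::head(genes$id[!keep], 5), collapse = ", "))
  GRanges(chrom[keep], IRanges(cs[keep], ce[keep]),
          strand = strand(genes)[keep],
          gene_id = genes$id[keep],
          role = rep_len(role, sum(keep)),
          truncated = truncated[keep],
          seqinfo = seqinfo(genes))
}

#' Windows downstream of gene 3' ends
#'
#' For each gene, the fixed-length region immediately downstream of its
#' annotated 3' terminus, on the gene's strand: bases `end+1 .. end+length`
#' for `+` genes and `start-length .. start-1` for `-` genes. Windows are
#' truncated at chromosome boundaries (`truncated` flag set); genes with no
#' remaining downstream bases are dropped with a warning. This is the
#' geometry used to detect transcriptional read-through past the
#' termination site.
#'
#' @param genes a gene set ([gene_set()]).
#' @param length window length in nt (default 500).
#' @return `GRanges` with metadata `gene_id`, `role = "downstream500"`,
#'   `truncated`.
#' @export
downstream_windows <- function(genes, length = 500) {
  stopifnot(length > 0)
  plus <- as.character(strand(genes)) == "+"
  ws <- ifelse(plus, end(genes) + 1L, start(genes) - length)
  we <- ifelse(plus, end(genes) + length, start(genes) - 1L)
  make_windows(genes, ws, we, "downstream500")
}

#' Extended pri-miRNA windows
#'
#' The strand-aware union of a MIR locus span and a downstream pad: most
#' pri-miRNA gene models cover the hairpin but not the 3' remnant left
#' after microprocessor cleavage, so quantification runs from the model
#' start to `pad` nt past its end (in transcription order).
#'
#' @param genes a gene set; only `kind == "mir"` loci are used.
#' @param pad downstream pad in nt (default 500). `pad = 0` returns the
#'   gene spans themselves.
#' @return `GRanges` with `role = "primirna_ext"`.
#' @export
primirna_windows <- function(genes, pad = 500) {
  stopifnot(pad >= 0)
  mir <- genes[genes$kind == "mir"]
  if (length(mir) == 0L) {
    warning("no MIR loci in gene set")
    return(make_windows(mir, integer(), integer(), "primirna_ext"))
  }
  plus <- as.character(strand(mir)) == "+"
  ws <- ifelse(plus, start(mir), start(mir) - pad)
  we <- ifelse(plus, end(mir) + pad, end(mir))
  make_windows(mir, ws, we, "primirna_ext")
}

#' Head and tail windows of miRNA-target genes
#'
#' For each flagged miRNA target, the first and last `length` nt of the
#' transcript unit in transcription order, both clipped to the gene span.
#' Comparing head (5' cleavage fragment) against tail (3' cleavage
#' fragment) accumulation distinguishes fragment stabilisation from
#' whole-transcript upregulation.
#'
#' @param genes a gene set; only `is_mirna_target` genes are used.
#' @param length window length in nt (default 200). Genes shorter than
#'   `length` yield whole-span windows with the `truncated` flag set.
#' @return `GRanges` with roles `"target_head200"` and `"target_tail200"`.
#' @export
target_end_windows <- function(genes, length = 200) {
  stopifnot(length > 0)
  tg <- genes[genes$is_mirna_target]
  if (length(tg) == 0L) {
    warning("no miRNA-target genes in gene set")
    return(make_windows(tg, integer(), integer(), "target_head200"))
  }
  plus <- as.character(strand(tg)) == "+"
  short <- width(tg) < length
  ## transcription-order head: 5' end of the transcript
  hs <- ifelse(plus, start(tg), pmax(end(tg) - length + 1L, start(tg)))
  he <- ifelse(plus, pmin(start(tg) + length - 1L, end(tg)), end(tg))
  ts <- ifelse(plus, pmax(end(tg) - length + 1L, start(tg)), start(tg))
  te <- ifelse(plus, end(tg), pmin(start(tg) + length - 1L, end(tg)))
  head <- make_windows(tg, hs, he, "target_head200")
  tail <- make_windows(tg, ts, te, "target_tail200")
  head$truncated <- head$truncated | short
  tail$truncated <- tail$truncated | short
  c(head, tail)
}

#' Write windows (or any gene-tagged ranges) as BED6
#'
#' BED is 0-based half-open; conversion from the internal 1-based ranges is
#' handled by `rtracklayer`. The name field is `gene_id:role`.
#'
#' @param windows `GRanges` with `gene_id` and `role` metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_windows_bed <- function(windows, path) {
  out <- windows
  mcols(out) <- NULL
  out$name <- paste(windows$gene_id, windows$role, sep = ":")
  out$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
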