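#' Bundle one library of uniquely mapped reads
#'
#' An alignment set holds the read intervals of one strand-specific library
#' together with its identity (genotype, replicate) and the library-wide
#' count of uniquely mapped reads used as the RPKM denominator. The stored
#' intervals may be a subset of the library (e.g. reads near loci of
#' interest), so `total_mapped` must be at least their number.
#'
#' @param library_id library identifier.
#' @param genotype genotype label (e.g. `"WT"`, `"fry1"`).
#' @param replicate replicate number.
#' @param reads `GRanges` of read intervals, one per uniquely mapped read,
#'   stranded.
#' @param total_mapped uniquely mapped reads in the whole library; defaults
#'   to `length(reads)`.
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(library_id, genotype, replicate, reads,
                          total_mapped = length(reads)) {
  stopifnot(is(reads, "GRanges"))
  if (total_mapped < length(reads))
    stop("total_mapped (", total_mapped, ") < number of stored reads (",
         length(reads), ")")
  if (any(as.character(strand(reads)) == "*"))
    stop("reads must be stranded")
  structure(list(library_id = as.character(library_id),
                 genotype = as.character(genotype),
                 replicate = as.integer(replicate),
                 reads = reads, total_mapped = total_mapped),
            class = "alignment_set")
}

#' Read a BED6 file of read intervals into an alignment set
#'
#' @inheritParams alignment_set
#' @param path BED6 file, one interval per uniquely mapped read.
#' @export
read_alignments_bed <- function(path, library_id, genotype, replicate,
                                total_mapped = NA) {
  reads <- rtracklayer::import(path, format = "BED")
  if (is.na(total_mapped)) total_mapped <- length(reads)
  alignment_set(library_id, genotype, replicate, reads, total_mapped)
}

#' Count reads overlapping windows, strand-specifically
#'
#' A read is counted if at least 1 bp of it overlaps the window and (by
#' default) it lies on the window's strand; each read is counted at most
#' once per window. Set `same_strand = FALSE` to count opposite-strand
#' reads (the antisense use case).
#'
#' @param aln an [alignment_set()].
#' @param windows `GRanges` of windows.
#' @param same_strand count only reads on the window strand (default) or
#'   only reads on the opposite strand.
#' @return Integer vector of counts, one per window.
#' @export
count_reads <- function(aln, windows, same_strand = TRUE) {
  stopifnot(inherits(aln, "alignment_set"))
  if (length(windows) == 0L) return(integer())
  w <- windows
  if (!same_strand)
    strand(w) <- ifelse(as.character(strand(w)) == "+", "-", "+")
  absent <- setdiff(unique(as.character(seqnames(w))),
                    as.character(unique(seqnames(aln$reads))))
  if (length(absent))
    warning("chromosome(s) absent from library ", aln$library_id, ": ",
            paste(absent, collapse = ", "), " (counts 0)")
  suppressWarnings(countOverlaps(w, aln$reads, minoverlap = 1L,
                                 ignore.strand = FALSE))
}

#' Reads per kilobase per million mapped reads
#'
#' `count / ((window_length / 1e3) * (total_mapped / 1e6))` — the
#' length- and depth-normalised abundance used throughout the package.
#'
#' @param count read count (vectorised).
#' @param window_length window length in nt, > 0.
#' @param total_mapped uniquely mapped reads in the library, > 0.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, window_length, total_mapped) {
  if (any(window_length <= 0)) stop("window_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count / ((window_length / 1e3) * (total_mapped / 1e6))
}

#' Mean RPKM across replicates
#'
#' @param values per-replicate RPKM values (at least one).
#' @return Arithmetic mean.
#' @export
mean_rpkm <- function(values) {
  if (length(values) == 0L) stop("mean_rpkm: no replicate values")
  mean(values)
}

#' Four-category RPKM binning
#'
#' Bins an RPKM value into the four accumulation categories
#' `C1: RPKM <= 0.2`, `C2: 0.2 < RPKM <= 1`, `C3: 1 < RPKM <= 10`,
#' `C4: RPKM > 10`.
#'
#' @param value non-negative RPKM value(s).
#' @return Factor with levels `C1`–`C4`.
#' @export
categorize_rpkm <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("RPKM must be non-negative")
  cut(value, breaks = c(-Inf, 0.2, 1, 10, Inf),
      labels = c("C1", "C2", "C3", "C4"), right = TRUE)
}

#' Quantify windows across libraries
#'
#' Builds the long-format quantification table: one row per window per
#' library with the strand-specific read count and RPKM.
#'
#' @param alignments list of [alignment_set()] objects.
#' @param windows `GRanges` of windows (any mix of roles).
#' @param same_strand passed to [count_reads()].
#' @return `data.frame` with columns `gene_id`, `role`, `genotype`,
#'   `replicate`, `library_id`, `length`, `count`, `rpkm`.
#' @export
quantify_windows <- function(alignments, windows, same_strand = TRUE) {
  stopifnot(length(alignments) > 0)
  per_lib <- lapply(alignments, function(aln) {
    cnt <- count_reads(aln, windows, same_strand = same_strand)
    data.frame(gene_id = windows$gene_id, role = windows$role,
               genotype = aln$genotype, replicate = aln$replicate,
               library_id = aln$library_id, length = width(windows),
               count = cnt,
               rpkm = rpkm(cnt, width(windows), aln$total_mapped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_lib)
  rownames(out) <- NULL
  out
}

#' Write a quantification table as TSV
#' @param quant output of [quantify_windows()].
#' @param path output file.
#' @export
write_quant_tsv <- function(quant, path) {
  write.table(quant, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
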