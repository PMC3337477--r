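#' Build a gene set
#'
#' A gene set is a `GRanges` of annotated transcript units (one range per
#' gene, 1-based inclusive coordinates) carrying three metadata columns:
#' `id` (unique gene identifier), `kind` (one of `"coding"`, `"mir"`,
#' `"transposon"`, `"other"`) and `is_mirna_target` (logical). Chromosome
#' lengths live in the object's `seqlengths`.
#'
#' @param id character vector of unique gene identifiers.
#' @param chrom chromosome name per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end 1-based inclusive span per gene (`start <= end`).
#' @param kind gene class, recycled: `"coding"`, `"mir"`, `"transposon"`
#'   or `"other"`.
#' @param is_mirna_target logical, recycled; marks predicted miRNA targets.
#' @param chrom_lengths named integer vector of chromosome lengths covering
#'   every chromosome used.
#' @return A `GRanges` gene set.
#' @export
gene_set <- function(id, chrom, strand, start, end, kind = "coding",
                     is_mirna_target = FALSE, chrom_lengths) {
  n <- length(id)
  stopifnot(n > 0, length(start) == n, length(end) == n)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  if (anyDuplicated(id))
    stop("duplicate gene IDs: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(start < 1) || any(end < start))
    stop("gene spans must satisfy 1 <= start <= end")
  kind <- rep_len(kind, n)
  stopifnot(all(kind %in% c("coding", "mir", "transposon", "other")))
  is_mirna_target <- rep_len(as.logical(is_mirna_target), n)
  if (is.null(names(chrom_lengths)) || !all(chrom %in% names(chrom_lengths)))
    stop("chrom_lengths must be named and cover all chromosomes used")
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                id = id, kind = kind, is_mirna_target = is_mirna_target,
                seqinfo = Seqinfo(names(chrom_lengths),
                                  seqlengths = as.integer(chrom_lengths)))
  bad <- end(gr) > seqlengths(gr)[as.character(seqnames(gr))]
  if (any(bad))
    stop("gene span exceeds chromosome length: ",
         paste(id[bad], collapse = ", "))
  gr
}

#' Read gene models from a GFF3/GTF annotation
#'
#' Imports top-level gene features and returns a gene set (see
#' [gene_set()]). MIR/pri-miRNA loci are flagged either from their feature
#' type (`miRNA`, `miRNA_gene`, `pri_miRNA`) or from an explicit ID list;
#' miRNA targets are flagged from an ID list. Records without a strand are
#' skipped with a warning; duplicate IDs are an error. Chromosome lengths
#' are taken from `##sequence-region` pragmas unless supplied.
#'
#' @param path GFF3 or GTF file.
#' @param mir_ids optional character vector (or one-ID-per-line file) of
#'   MIR locus IDs.
#' @param target_ids optional character vector (or file) of miRNA-target
#'   gene IDs.
#' @param chrom_lengths optional named vector overriding lengths from the
#'   file header.
#' @param feature_types feature `type` values treated as top-level genes.
#' @return A `GRanges` gene set.
#' @export
read_annotation <- function(path, mir_ids = NULL, target_ids = NULL,
                            chrom_lengths = NULL,
                            feature_types = c("gene",
                                              "transposable_element_gene",
                                              "miRNA_gene", "miRNA",
                                              "pri_miRNA", "pseudogene")) {
  mir_ids <- read_id_list(mir_ids)
  target_ids <- read_id_list(target_ids)
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) stop("no gene features found in ", path)
  ids <- if (!is.null(gr$ID)) gr$ID else gr$gene_id
  if (is.null(ids) || anyNA(ids))
    stop("gene features must carry an ID (GFF3 'ID' or GTF 'gene_id')")
  unstranded <- as.character(strand(gr)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand skipped: ",
            paste(utils::head(ids[unstranded], 5), collapse = ", "))
    gr <- gr[!unstranded]
    ids <- ids[!unstranded]
  }
  if (anyDuplicated(ids))
    stop("duplicate gene IDs in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  type <- as.character(gr$type)
  kind <- ifelse(type %in% c("miRNA_gene", "miRNA", "pri_miRNA"), "mir",
          ifelse(type == "transposable_element_gene", "transposon",
          ifelse(type == "gene", "coding", "other")))
  kind[ids %in% mir_ids] <- "mir"
  lens <- chrom_lengths
  if (is.null(lens)) lens <- sequence_region_lengths(path)
  if (is.null(lens) || !all(as.character(seqnames(gr)) %in% names(lens)))
    stop("chromosome lengths missing: supply chrom_lengths or add ",
         "##sequence-region pragmas to the GFF")
  gene_set(id = ids, chrom = as.character(seqnames(gr)),
           strand = as.character(strand(gr)),
           start = start(gr), end = end(gr), kind = kind,
           is_mirna_target = ids %in% target_ids, chrom_lengths = lens)
}

## Chromosome lengths from ##sequence-region pragmas (name start end).
sequence_region_lengths <- function(path) {
  lines <- grep("^##sequence-region", readLines(path, warn = FALSE),
                value = TRUE)
  if (length(lines) == 0L) return(NULL)
  parts <- strsplit(trimws(lines), "[ \t]+")
  stats::setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
                  vapply(parts, `[`, character(1), 2))
}

read_id_list <- function(x) {
  if (is.null(x)) return(character())
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  x[nzchar(x)]
}
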