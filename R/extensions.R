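#' Filter parameters for calling 3' extensions
#'
#' The four-parameter filter applied to downstream-window quantification:
#' mutant/wild-type fold change, mutant mean RPKM, two-sample t-test
#' p-value, and exclusion of pri-miRNA-associated windows. All
#' comparisons are strict (`fold > min_fold`, `rpkm > min_mut_rpkm`,
#' `p < max_p`).
#'
#' @param min_fold minimum mutant/WT fold change (strict; default 5).
#' @param min_mut_rpkm minimum mutant mean RPKM (strict; default 1).
#' @param max_p maximum t-test p-value (strict; default 0.1). Ignored when
#'   `use_p_filter = FALSE`.
#' @param exclude_mir drop genes that are MIR loci or whose downstream
#'   window overlaps one (default TRUE).
#' @param use_p_filter apply the p-value filter (default TRUE). The
#'   relaxed preset disables it.
#' @return List of class `extension_filter_params`.
#' @export
extension_filter_params <- function(min_fold = 5, min_mut_rpkm = 1,
                                    max_p = 0.1, exclude_mir = TRUE,
                                    use_p_filter = TRUE) {
  stopifnot(min_fold > 0, max_p > 0, max_p <= 1)
  structure(list(min_fold = min_fold, min_mut_rpkm = min_mut_rpkm,
                 max_p = max_p, exclude_mir = exclude_mir,
                 use_p_filter = use_p_filter),
            class = "extension_filter_params")
}

#' Filter presets
#'
#' `"default"` is the stringent filter (fold > 5, mutant RPKM > 1,
#' p < 0.1, non-pri-miRNA); `"relaxed"` lowers the fold cut to 2 and drops
#' the p-value filter (fold > 2, mutant RPKM > 1, non-pri-miRNA).
#'
#' @param preset `"default"` or `"relaxed"`.
#' @export
extension_preset <- function(preset = c("default", "relaxed")) {
  preset <- match.arg(preset)
  if (preset == "default") extension_filter_params()
  else extension_filter_params(min_fold = 2, use_p_filter = FALSE)
}

#' Call candidate 3' extensions
#'
#' For every gene with a downstream window in the quantification table,
#' computes wild-type and mutant mean downstream RPKM across replicates,
#' the mutant/WT fold change (`Inf` when the WT mean is 0 and the mutant
#' mean positive; undefined and failing when both are 0), and a pooled
#' two-sample t-test on per-replicate RPKM; then applies the
#' four-parameter filter. A gene fails the non-pri-miRNA filter if it is
#' itself a MIR locus or its downstream window overlaps one on either
#' strand. With fewer than two replicates in either genotype the p-filter
#' is skipped with a warning.
#'
#' @param quant quantification table from [quantify_windows()].
#' @param genes the gene set used to build the windows.
#' @param wt,mut genotype labels present in `quant`.
#' @param params an [extension_filter_params()] object.
#' @param window_length downstream-window length used for the MIR-overlap
#'   check (default 500).
#' @return `data.frame` with one row per gene: means, `fold`, `p`,
#'   per-filter pass flags (`pass_fold`, `pass_rpkm`, `pass_p`,
#'   `pass_nonmir`) and overall `passed`.
#' @export
call_extensions <- function(quant, genes, wt, mut,
                            params = extension_filter_params(),
                            window_length = 500) {
  q <- quant[quant$role == "downstream500", , drop = FALSE]
  if (!wt %in% q$genotype) stop("genotype not in quant table: ", wt)
  if (!mut %in% q$genotype) stop("genotype not in quant table: ", mut)
  qw <- q[q$genotype == wt, ]
  qm <- q[q$genotype == mut, ]
  ids <- intersect(unique(qw$gene_id), unique(qm$gene_id))
  wt_reps <- split(qw$rpkm, qw$gene_id)[ids]
  mut_reps <- split(qm$rpkm, qm$gene_id)[ids]
  wt_mean <- vapply(wt_reps, mean_rpkm, numeric(1))
  mut_mean <- vapply(mut_reps, mean_rpkm, numeric(1))
  fold <- ifelse(wt_mean > 0, mut_mean / wt_mean,
                 ifelse(mut_mean > 0, Inf, NA_real_))
  use_p <- params$use_p_filter
  if (use_p && (min(lengths(wt_reps)) < 2 || min(lengths(mut_reps)) < 2)) {
    warning("fewer than 2 replicates in a genotype; p-value filter skipped")
    use_p <- FALSE
  }
  p <- if (use_p)
    mapply(function(m, w) student_t(m, w)$p, mut_reps, wt_reps)
  else rep(NA_real_, length(ids))

  ## pri-miRNA association: the gene is a MIR locus, or its downstream
  ## window touches one on either strand
  gsub_ <- genes[match(ids, genes$id)]
  mir_loci <- genes[genes$kind == "mir"]
  dw <- suppressWarnings(downstream_windows(gsub_, length = window_length))
  mir_assoc <- gsub_$kind == "mir"
  if (length(mir_loci) > 0 && length(dw) > 0) {
    hit <- overlapsAny(dw, mir_loci, ignore.strand = TRUE)
    mir_assoc[match(dw$gene_id, ids)] <- mir_assoc[match(dw$gene_id, ids)] | hit
  }

  pass_fold <- !is.na(fold) & fold > params$min_fold
  pass_rpkm <- mut_mean > params$min_mut_rpkm
  pass_p <- if (use_p) p < params$max_p else rep(TRUE, length(ids))
  pass_nonmir <- if (params$exclude_mir) !mir_assoc else rep(TRUE, length(ids))
  out <- data.frame(gene_id = ids, wt_mean_rpkm = unname(wt_mean),
                    mut_mean_rpkm = unname(mut_mean), fold = unname(fold),
                    p = unname(p), pass_fold = unname(pass_fold),
                    pass_rpkm = unname(pass_rpkm), pass_p = unname(pass_p),
                    pass_nonmir = unname(pass_nonmir),
                    stringsAsFactors = FALSE)
  out$passed <- out$pass_fold & out$pass_rpkm & out$pass_p & out$pass_nonmir
  attr(out, "wt") <- wt
  attr(out, "mut") <- mut
  attr(out, "params") <- params
  rownames(out) <- NULL
  out
}

#' Count genes with any downstream signal in a mutant
#'
#' The "raw" candidate count: the number of genes whose mutant mean
#' downstream-window RPKM is positive. With `mode = "new_only"` the count
#' is additionally restricted to genes whose wild-type mean is exactly 0
#' (signal absent from the wild type).
#'
#' @param quant quantification table.
#' @param mut mutant genotype label.
#' @param mode `"rpkm_positive"` (default) or `"new_only"`.
#' @param wt wild-type label, required for `mode = "new_only"`.
#' @return Integer count.
#' @export
raw_extension_count <- function(quant, mut,
                                mode = c("rpkm_positive", "new_only"),
                                wt = NULL) {
  mode <- match.arg(mode)
  q <- quant[quant$role == "downstream500", , drop = FALSE]
  if (!mut %in% q$genotype) stop("genotype not in quant table: ", mut)
  mm <- tapply(q$rpkm[q$genotype == mut], q$gene_id[q$genotype == mut], mean)
  if (mode == "rpkm_positive") return(sum(mm > 0))
  if (is.null(wt)) stop("mode 'new_only' needs the wt label")
  wm <- tapply(q$rpkm[q$genotype == wt], q$gene_id[q$genotype == wt], mean)
  ids <- intersect(names(mm), names(wm))
  sum(mm[ids] > 0 & wm[ids] == 0)
}

#' Overlap between two candidate sets
#'
#' Intersection of the passed gene IDs of two extension-call tables, with
#' fractions relative to each set's passed count (the Venn summary).
#'
#' @param calls_a,calls_b outputs of [call_extensions()].
#' @return List with `shared`, `fraction_a`, `fraction_b`,
#'   `shared_ids`, and `empty_set` flag.
#' @export
candidate_overlap <- function(calls_a, calls_b) {
  pa <- calls_a$gene_id[calls_a$passed]
  pb <- calls_b$gene_id[calls_b$passed]
  shared <- intersect(pa, pb)
  list(shared = length(shared),
       fraction_a = if (length(pa)) length(shared) / length(pa) else 0,
       fraction_b = if (length(pb)) length(shared) / length(pb) else 0,
       shared_ids = shared,
       empty_set = length(pa) == 0 || length(pb) == 0)
}

#' Downstream windows of passed extension calls
#'
#' Converts passed calls back to their (possibly truncated) downstream
#' windows for interval-level integration.
#'
#' @param calls output of [call_extensions()].
#' @param genes the gene set.
#' @param window_length downstream-window length (default 500).
#' @return `GRanges` of extension spans with `gene_id` metadata.
#' @export
extension_spans <- function(calls, genes, window_length = 500) {
  ids <- calls$gene_id[calls$passed]
  gs <- genes[match(ids, genes$id)]
  suppressWarnings(downstream_windows(gs, length = window_length))
}
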