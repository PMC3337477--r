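#' Quantify pri-miRNA extended windows
#'
#' Summarises primirna_ext quantification per MIR locus and genotype:
#' replicate-mean RPKM, its four-category bin, and the fold change
#' relative to the reference genotype. A locus is "expressed" when its
#' mean RPKM is positive in at least one genotype; the count of expressed
#' loci is attached as an attribute.
#'
#' @param quant quantification table containing `primirna_ext` rows.
#' @param wt reference genotype label for fold changes.
#' @param expressed_min_rpkm threshold defining "expressed" (default 0,
#'   i.e. any positive mean).
#' @return `data.frame` with columns `locus_id`, `genotype`, `mean_rpkm`,
#'   `category`, `fold`, `expressed`; attribute `n_expressed`.
#' @export
quantify_primirnas <- function(quant, wt, expressed_min_rpkm = 0) {
  q <- quant[quant$role == "primirna_ext", , drop = FALSE]
  if (nrow(q) == 0L) {
    warning("no primirna_ext rows in quant table")
    out <- data.frame(locus_id = character(), genotype = character(),
                      mean_rpkm = numeric(), category = factor(),
                      fold = numeric(), expressed = logical())
    attr(out, "n_expressed") <- 0L
    return(out)
  }
  if (!wt %in% q$genotype) stop("genotype not in quant table: ", wt)
  agg <- aggregate(rpkm ~ gene_id + genotype, data = q, FUN = mean)
  names(agg) <- c("locus_id", "genotype", "mean_rpkm")
  wt_mean <- agg$mean_rpkm[agg$genotype == wt]
  names(wt_mean) <- agg$locus_id[agg$genotype == wt]
  ref <- wt_mean[agg$locus_id]
  agg$category <- categorize_rpkm(agg$mean_rpkm)
  agg$fold <- ifelse(ref > 0, agg$mean_rpkm / ref,
                     ifelse(agg$mean_rpkm > 0, Inf, NA_real_))
  expressed_ids <- unique(agg$locus_id[agg$mean_rpkm > expressed_min_rpkm])
  agg$expressed <- agg$locus_id %in% expressed_ids
  agg <- agg[order(agg$locus_id, agg$genotype), ]
  rownames(agg) <- NULL
  attr(agg, "n_expressed") <- length(expressed_ids)
  agg
}

#' Quantify miRNA-target head and tail windows
#'
#' Pairs the `target_head200` and `target_tail200` quantifications of each
#' flagged miRNA target: replicate-mean head and tail RPKM per genotype,
#' the within-genotype tail/head ratio (NA when the head mean is 0), and
#' head/tail fold changes relative to the reference genotype. Cleavage-
#' fragment stabilisation shows up as a tail fold far above the head fold.
#' Targets missing one window of the pair are dropped with a warning.
#'
#' @param quant quantification table with head/tail rows.
#' @param wt reference genotype label.
#' @return `data.frame` with columns `target_id`, `genotype`, `head_rpkm`,
#'   `tail_rpkm`, `tail_head_ratio`, `head_fold`, `tail_fold`.
#' @export
quantify_target_ends <- function(quant, wt) {
  qh <- quant[quant$role == "target_head200", , drop = FALSE]
  qt <- quant[quant$role == "target_tail200", , drop = FALSE]
  if (nrow(qh) == 0L || nrow(qt) == 0L) {
    warning("no target head/tail rows in quant table")
    return(data.frame(target_id = character(), genotype = character(),
                      head_rpkm = numeric(), tail_rpkm = numeric(),
                      tail_head_ratio = numeric(), head_fold = numeric(),
                      tail_fold = numeric()))
  }
  if (!wt %in% quant$genotype) stop("genotype not in quant table: ", wt)
  ah <- aggregate(rpkm ~ gene_id + genotype, data = qh, FUN = mean)
  at <- aggregate(rpkm ~ gene_id + genotype, data = qt, FUN = mean)
  ids <- intersect(unique(ah$gene_id), unique(at$gene_id))
  dropped <- setdiff(union(unique(ah$gene_id), unique(at$gene_id)), ids)
  if (length(dropped))
    warning(length(dropped), " target(s) missing a head or tail window ",
            "dropped: ", paste(utils::head(dropped, 5), collapse = ", "))
  m <- merge(ah, at, by = c("gene_id", "genotype"),
             suffixes = c("_head", "_tail"))
  m <- m[m$gene_id %in% ids, ]
  out <- data.frame(target_id = m$gene_id, genotype = m$genotype,
                    head_rpkm = m$rpkm_head, tail_rpkm = m$rpkm_tail,
                    tail_head_ratio = ifelse(m$rpkm_head > 0,
                                             m$rpkm_tail / m$rpkm_head,
                                             NA_real_),
                    stringsAsFactors = FALSE)
  wt_rows <- out[out$genotype == wt, ]
  hw <- wt_rows$head_rpkm[match(out$target_id, wt_rows$target_id)]
  tw <- wt_rows$tail_rpkm[match(out$target_id, wt_rows$target_id)]
  fold_vs <- function(x, ref)
    ifelse(ref > 0, x / ref, ifelse(x > 0, Inf, NA_real_))
  out$head_fold <- fold_vs(out$head_rpkm, hw)
  out$tail_fold <- fold_vs(out$tail_rpkm, tw)
  out <- out[order(out$target_id, out$genotype), ]
  rownames(out) <- NULL
  out
}

#' Category histogram of pri-miRNA profiles per genotype
#'
#' Counts loci per four-category RPKM bin and genotype (the accumulation-
#' profile summary).
#'
#' @param profiles output of [quantify_primirnas()].
#' @param expressed_only restrict to expressed loci (default TRUE).
#' @return `data.frame` with `genotype`, `category`, `n`.
#' @export
primirna_category_histogram <- function(profiles, expressed_only = TRUE) {
  pr <- if (expressed_only) profiles[profiles$expressed, ] else profiles
  tab <- as.data.frame(table(genotype = pr$genotype, category = pr$category))
  names(tab)[3] <- "n"
  tab
}
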