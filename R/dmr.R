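#' Read an allc-style per-cytosine methylation table
#'
#' Expects a header-less TSV with columns chrom, pos (1-based), strand,
#' context (CG/CHG/CHH), mc (methylated reads) and cov (total reads).
#' Malformed rows (unknown strand or context, negative counts, mc > cov)
#' are rejected with a warning giving their number.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc`, `cov`.
#' @export
read_allc <- function(path) {
  cols <- c("chrom", "pos", "strand", "context", "mc", "cov")
  if (file.size(path) == 0L) {
    return(stats::setNames(data.frame(character(), integer(), character(),
                                      character(), integer(), integer(),
                                      stringsAsFactors = FALSE), cols))
  }
  x <- read.delim(path, header = FALSE, col.names = cols,
                  colClasses = c("character", "integer", "character",
                                 "character", "integer", "integer"))
  ok <- x$strand %in% c("+", "-") & x$context %in% c("CG", "CHG", "CHH") &
    !is.na(x$pos) & x$pos >= 1 & !is.na(x$mc) & !is.na(x$cov) &
    x$mc >= 0 & x$mc <= x$cov
  if (!all(ok))
    warning(sum(!ok), " malformed row(s) rejected from ", path)
  x[ok, , drop = FALSE]
}

#' DMR-calling parameters
#'
#' Defaults mirror the windowed procedure: non-overlapping 100-bp windows,
#' at least 10 differing cytosines per window, neighbouring significant
#' windows joined when within 100 bp, Benjamini-Hochberg-adjusted
#' (Fisher-combined) p below 0.01, and an 8-fold difference in
#' methylation density between the least and most methylated sample. The
#' per-site "difference" definition (minimum coverage in every sample and
#' minimum level difference) is parameterised.
#'
#' @param window scan window size in nt (default 100).
#' @param min_diff_sites differing cytosines required per window
#'   (default 10).
#' @param join_gap maximum gap in nt for joining neighbouring windows
#'   (default 100).
#' @param max_adj_p adjusted-p retention threshold (strict; default 0.01).
#' @param min_fold methylation-density fold retention threshold
#'   (inclusive; default 8).
#' @param min_cov minimum per-sample coverage for a site to be assessable
#'   (default 3).
#' @param site_diff_min minimum between-sample methylation-level
#'   difference for a site to count as differing (default 0.1).
#' @return List of class `dmr_params`.
#' @export
dmr_params <- function(window = 100, min_diff_sites = 10, join_gap = 100,
                       max_adj_p = 0.01, min_fold = 8, min_cov = 3,
                       site_diff_min = 0.1) {
  stopifnot(window > 0, min_diff_sites > 0, join_gap >= 0,
            max_adj_p > 0, max_adj_p <= 1, min_fold > 0, min_cov > 0,
            site_diff_min > 0)
  structure(list(window = window, min_diff_sites = min_diff_sites,
                 join_gap = join_gap, max_adj_p = max_adj_p,
                 min_fold = min_fold, min_cov = min_cov,
                 site_diff_min = site_diff_min),
            class = "dmr_params")
}

## Align the samples' calls of one context on the union of sites.
## Returns per-site chrom/pos plus cov and level matrices (one column per
## sample; NA level where uncovered).
merge_context_sites <- function(samples, context) {
  sub <- lapply(samples, function(s) s[s$context == context, , drop = FALSE])
  keys <- unique(do.call(rbind, lapply(sub, function(s)
    data.frame(chrom = s$chrom, pos = s$pos, strand = s$strand,
               stringsAsFactors = FALSE))))
  keys <- keys[order(keys$chrom, keys$pos, keys$strand), , drop = FALSE]
  k <- paste(keys$chrom, keys$pos, keys$strand)
  cov <- mc <- matrix(0, nrow = nrow(keys), ncol = length(samples),
                      dimnames = list(NULL, names(samples)))
  for (i in seq_along(sub)) {
    idx <- match(paste(sub[[i]]$chrom, sub[[i]]$pos, sub[[i]]$strand), k)
    cov[idx, i] <- sub[[i]]$cov
    mc[idx, i] <- sub[[i]]$mc
  }
  level <- ifelse(cov > 0, mc / cov, NA_real_)
  list(chrom = keys$chrom, pos = keys$pos, cov = cov, mc = mc,
       level = level)
}

#' Scan fixed windows for candidate DMRs in one context
#'
#' Tiles each chromosome with non-overlapping windows anchored at
#' coordinate 1 and flags as candidates the windows containing at least
#' `min_diff_sites` differing cytosines: sites covered at
#' `min_cov`+ in every sample whose between-sample methylation-level
#' range is at least `site_diff_min`.
#'
#' @param samples named list (>= 2) of [read_allc()]-style tables.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param params a [dmr_params()] object.
#' @return `data.frame` of candidate windows: `chrom`, `start`, `end`
#'   (1-based inclusive window bounds), `n_diff_sites`.
#' @export
scan_windows <- function(samples, context, params = dmr_params()) {
  stopifnot(length(samples) >= 2)
  ms <- merge_context_sites(samples, context)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_diff_sites = integer(),
                      stringsAsFactors = FALSE)
  if (length(ms$pos) == 0L) return(empty)
  covered <- rowSums(ms$cov >= params$min_cov) == ncol(ms$cov)
  lv <- as.data.frame(ms$level)
  rng <- do.call(pmax, c(lv, na.rm = TRUE)) - do.call(pmin, c(lv, na.rm = TRUE))
  diff_site <- covered & !is.na(rng) & rng >= params$site_diff_min
  if (!any(diff_site)) return(empty)
  tile <- (ms$pos[diff_site] - 1L) %/% params$window
  key <- paste(ms$chrom[diff_site], tile)
  tab <- table(key)
  hit <- names(tab)[tab >= params$min_diff_sites]
  if (length(hit) == 0L) return(empty)
  parts <- strsplit(hit, " ", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  t0 <- as.integer(vapply(parts, `[`, character(1), 2))
  out <- data.frame(chrom = chrom, start = t0 * params$window + 1L,
                    end = (t0 + 1L) * params$window,
                    n_diff_sites = as.integer(tab[hit]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Kruskal-Wallis test of one candidate window
#'
#' Compares the per-site methylation levels (sites covered at `min_cov`+
#' in the given sample) across samples within the window span. Windows
#' where any sample has fewer than two usable sites are reported with
#' `p = NA` (dropped by the pipeline with a warning).
#'
#' @param candidate one row of [scan_windows()] output (list or
#'   single-row data.frame with `chrom`, `start`, `end`).
#' @param samples named list of call tables.
#' @param context methylation context to test.
#' @param params a [dmr_params()] object.
#' @return List with `statistic`, `df`, `p`, `degenerate`.
#' @export
test_window <- function(candidate, samples, context,
                        params = dmr_params()) {
  grp <- lapply(samples, function(s) {
    s <- s[s$context == context & s$chrom == candidate$chrom &
             s$pos >= candidate$start & s$pos <= candidate$end &
             s$cov >= params$min_cov, , drop = FALSE]
    s$mc / s$cov
  })
  if (any(lengths(grp) < 2))
    return(test_result(NA_real_, NA_real_, NA_real_, degenerate = TRUE))
  kruskal_wallis(grp)
}

#' Join neighbouring tested windows and combine their p-values
#'
#' Transitively merges same-context windows whose gap is at most
#' `join_gap`; the merged span runs from the smallest start to the
#' largest end, site counts add, and member p-values are combined with
#' Fisher's method (a singleton keeps its own p exactly).
#'
#' @param tested `data.frame` with `chrom`, `start`, `end`,
#'   `n_diff_sites`, `p` (one row per tested window), sorted or not.
#' @param params a [dmr_params()] object.
#' @return `data.frame` with `chrom`, `start`, `end`, `n_sites`,
#'   `n_windows`, `fisher_p`.
#' @export
join_dmrs <- function(tested, params = dmr_params()) {
  if (nrow(tested) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      n_windows = integer(), fisher_p = numeric(),
                      stringsAsFactors = FALSE))
  tested <- tested[order(tested$chrom, tested$start), , drop = FALSE]
  new_chrom <- c(TRUE, tested$chrom[-1] != tested$chrom[-nrow(tested)])
  gap <- c(Inf, tested$start[-1] - tested$end[-nrow(tested)] - 1L)
  grp <- cumsum(new_chrom | gap > params$join_gap)
  do.call(rbind, lapply(split(tested, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               n_sites = sum(g$n_diff_sites), n_windows = nrow(g),
               fisher_p = fisher_combine(g$p)$p,
               stringsAsFactors = FALSE)
  }))
}

#' Call differentially methylated regions
#'
#' The full windowed procedure, per context: scan for candidate windows,
#' Kruskal-Wallis-test each, join neighbours and Fisher-combine their
#' p-values; then, pooling the joined regions of all contexts, apply
#' Benjamini-Hochberg adjustment and retain regions with adjusted p below
#' `max_adj_p` AND a methylation-density fold (most- over least-methylated
#' sample, all three contexts combined) of at least `min_fold`.
#' Methylation density of a region is sum(mc)/sum(cov) over every covered
#' cytosine of any context in its span.
#'
#' @param samples named list (>= 2) of [read_allc()] tables or file paths.
#' @param params a [dmr_params()] object.
#' @param contexts contexts to scan (default CG, CHG, CHH).
#' @return `data.frame` of joined regions with `chrom`, `start`, `end`
#'   (1-based inclusive), `context`, `n_sites`, `fisher_p`, `adj_p`, one
#'   `density_<sample>` column per sample, `fold` and `passed`.
#' @export
call_dmrs <- function(samples, params = dmr_params(),
                      contexts = c("CG", "CHG", "CHH")) {
  if (length(samples) < 2) stop("call_dmrs needs at least 2 samples")
  samples <- lapply(samples, function(s)
    if (is.character(s)) read_allc(s) else s)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("sample", seq_along(samples))

  per_ctx <- lapply(contexts, function(ctx) {
    cand <- scan_windows(samples, ctx, params)
    if (nrow(cand) == 0L) return(NULL)
    cand$p <- vapply(seq_len(nrow(cand)), function(i)
      test_window(cand[i, ], samples, ctx, params)$p, numeric(1))
    dropped <- is.na(cand$p)
    if (any(dropped))
      warning(sum(dropped), " candidate window(s) dropped in ", ctx,
              ": a sample had fewer than 2 covered sites")
    cand <- cand[!dropped, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    joined <- join_dmrs(cand, params)
    joined$context <- ctx
    joined
  })
  dmrs <- do.call(rbind, per_ctx)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      n_windows = integer(), fisher_p = numeric(),
                      context = character(), adj_p = numeric(),
                      fold = numeric(), passed = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(dmrs) || nrow(dmrs) == 0L) return(empty)

  ## single genome-wide FDR across all contexts pooled
  dmrs$adj_p <- bh_adjust(dmrs$fisher_p)

  dens <- t(vapply(seq_len(nrow(dmrs)), function(i) {
    vapply(samples, function(s) {
      in_span <- s$chrom == dmrs$chrom[i] & s$pos >= dmrs$start[i] &
        s$pos <= dmrs$end[i] & s$cov > 0
      if (!any(in_span)) return(NA_real_)
      sum(s$mc[in_span]) / sum(s$cov[in_span])
    }, numeric(1))
  }, numeric(length(samples))))
  colnames(dens) <- paste0("density_", names(samples))
  dmin <- apply(dens, 1, min)
  dmax <- apply(dens, 1, max)
  dmrs$fold <- ifelse(is.na(dmin) | is.na(dmax), NA_real_,
                      ifelse(dmin > 0, dmax / dmin,
                             ifelse(dmax > 0, Inf, NA_real_)))
  dmrs <- cbind(dmrs, dens)
  dmrs$passed <- !is.na(dmrs$adj_p) & dmrs$adj_p < params$max_adj_p &
    !is.na(dmrs$fold) & dmrs$fold >= params$min_fold
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start, dmrs$context), , drop = FALSE]
  rownames(dmrs) <- NULL
  dmrs
}

#' Write DMRs as a BED-like TSV (0-based half-open coordinates)
#'
#' @param dmrs output of [call_dmrs()].
#' @param path output file.
#' @export
write_dmr_tsv <- function(dmrs, path) {
  out <- dmrs
  out$begin <- out$start - 1L
  first <- c("chrom", "begin", "end")
  out <- out[, c(first, setdiff(names(out), c(first, "start")))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
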