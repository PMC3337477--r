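#' Simulation configuration
#'
#' Bundles every parameter of the synthetic dataset: a two-strand
#' multi-gene annotation, per-replicate strand-specific read libraries
#' with negative-binomial noise and planted downstream read-through in
#' mutant genotypes, pri-miRNA loci with planted 3'-remnant signal,
#' miRNA targets with planted cleavage-fragment (tail) signal, and
#' two-sample methylomes with planted DMRs. The seed fully determines
#' every emitted object and file.
#'
#' @param seed integer seed (< 2^31) controlling all randomness.
#' @param n_chroms,chrom_len number and length (nt) of chromosomes.
#' @param n_genes number of protein-coding genes.
#' @param gene_len,mir_len min/max gene-model lengths (nt).
#' @param spacing min/max intergenic gap (nt).
#' @param frac_minus fraction of genes on the minus strand.
#' @param n_mir number of MIR (pri-miRNA) loci.
#' @param n_targets number of miRNA-target genes.
#' @param n_convergent_pairs convergent opposite-strand coding-gene pairs
#'   whose 3' ends lie < 500 nt apart (their downstream windows overlap);
#'   members are always planted with extensions.
#' @param genotypes named integer vector: replicates per genotype.
#' @param wt_genotype label of the wild type within `genotypes`.
#' @param depth nominal uniquely mapped reads per library (the RPKM
#'   denominator); emitted reads are the subset falling in simulated loci.
#' @param nb_dispersion negative-binomial dispersion of replicate counts
#'   (variance `mu + dispersion * mu^2`); 0 gives Poisson.
#' @param read_length read length in nt.
#' @param body_rpkm_meanlog,body_rpkm_sdlog log-normal parameters of
#'   per-gene expression (RPKM).
#' @param mir_body_rpkm min/max hairpin-span expression of MIR loci.
#' @param leakage_rpkm background downstream-window RPKM in every
#'   genotype (terminator read-through leakage).
#' @param n_extensions genes planted with a mutant-only downstream
#'   extension.
#' @param extension_rpkm min/max planted mutant downstream RPKM.
#' @param remnant_rpkm min/max planted mutant 3'-remnant RPKM at MIR loci.
#' @param target_tail_fold fold increase of target tail-window signal in
#'   mutants.
#' @param downstream_length,primirna_pad,target_window window geometry
#'   passed through to the window builders.
#' @param meth_samples names of the simulated methylomes (>= 2).
#' @param meth_site_spacing named vector: mean nt between background
#'   cytosines per context.
#' @param meth_background named vector: background methylation level per
#'   context (identical across samples).
#' @param meth_cov mean (Poisson) per-site read coverage.
#' @param n_dmrs planted differentially methylated regions.
#' @param dmr_len,dmr_n_sites planted-region length and number of evenly
#'   spaced CG sites inside it.
#' @param dmr_levels methylation level of the hyper- and hypo-methylated
#'   sample inside planted regions (direction alternates per region).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2, chrom_len = 6e5,
                       n_genes = 200, gene_len = c(800, 3000),
                       spacing = c(1000, 3000), frac_minus = 0.5,
                       n_mir = 10, mir_len = c(200, 400),
                       n_targets = 15, n_convergent_pairs = 4,
                       genotypes = c(WT = 3, fry1 = 3, xrn3 = 3),
                       wt_genotype = "WT",
                       depth = 1.1e7, nb_dispersion = 0.1,
                       read_length = 42,
                       body_rpkm_meanlog = log(10), body_rpkm_sdlog = 1,
                       mir_body_rpkm = c(0.5, 5),
                       leakage_rpkm = 0.05,
                       n_extensions = 40, extension_rpkm = c(5, 50),
                       remnant_rpkm = c(2, 20), target_tail_fold = 5,
                       downstream_length = 500, primirna_pad = 500,
                       target_window = 200,
                       meth_samples = c("WT", "fry1"),
                       meth_site_spacing = c(CG = 15, CHG = 20, CHH = 10),
                       meth_background = c(CG = 0.25, CHG = 0.1, CHH = 0.05),
                       meth_cov = 20,
                       n_dmrs = 20, dmr_len = 200, dmr_n_sites = 24,
                       dmr_levels = c(0.9, 0.05)) {
  stopifnot(seed == as.integer(seed), n_chroms >= 1, chrom_len > 0,
            n_genes >= 0, n_mir >= 0, n_targets >= 0,
            2 * n_convergent_pairs <= n_genes,
            n_extensions <= n_genes, length(genotypes) >= 1,
            wt_genotype %in% names(genotypes),
            depth > 0, nb_dispersion >= 0, read_length > 0,
            leakage_rpkm >= 0, all(extension_rpkm > 0),
            length(meth_samples) >= 2, meth_cov > 0, n_dmrs >= 0,
            all(dmr_levels >= 0 & dmr_levels <= 1))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
  else rpois(n, mu)
}

#' Simulate a gene annotation
#'
#' Places coding genes, MIR loci, miRNA targets and (optionally)
#' convergent gene pairs on `n_chroms` chromosomes with random intergenic
#' gaps, deterministically under the seed. Errors if the genes cannot be
#' packed into the chromosomes.
#'
#' @param cfg a [sim_config()].
#' @return A gene set (`GRanges`) with attributes `convergent_ids` (IDs
#'   of convergent-pair members, paired consecutively).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  ncp <- cfg$n_convergent_pairs
  ids_coding <- sprintf("G%04d", seq_len(cfg$n_genes))
  ids_mir <- if (cfg$n_mir) sprintf("MIR%03d", seq_len(cfg$n_mir)) else character()
  ids_tg <- if (cfg$n_targets) sprintf("TG%03d", seq_len(cfg$n_targets)) else character()
  pair_ids <- if (ncp) ids_coding[seq_len(2 * ncp)] else character()
  single_ids <- c(setdiff(ids_coding, pair_ids), ids_mir, ids_tg)
  single_kind <- c(rep("coding", cfg$n_genes - 2 * ncp),
                   rep("mir", cfg$n_mir), rep("coding", cfg$n_targets))
  single_tgt <- c(rep(FALSE, cfg$n_genes - 2 * ncp),
                  rep(FALSE, cfg$n_mir), rep(TRUE, cfg$n_targets))

  rlen <- function(n, r) if (n) round(runif(n, r[1], r[2])) else numeric()
  units <- vector("list", length(single_ids) + ncp)
  for (i in seq_along(single_ids)) {
    len <- if (single_kind[i] == "mir") rlen(1, cfg$mir_len)
           else rlen(1, cfg$gene_len)
    units[[i]] <- list(ids = single_ids[i], kinds = single_kind[i],
                       tgts = single_tgt[i],
                       strands = sample(c("+", "-"), 1,
                                        prob = c(1 - cfg$frac_minus,
                                                 cfg$frac_minus)),
                       lens = len, gap3 = 0)
  }
  if (ncp) for (k in seq_len(ncp)) {
    la <- rlen(1, cfg$gene_len); lb <- rlen(1, cfg$gene_len)
    units[[length(single_ids) + k]] <-
      list(ids = pair_ids[c(2 * k - 1, 2 * k)], kinds = c("coding", "coding"),
           tgts = c(FALSE, FALSE), strands = c("+", "-"), lens = c(la, lb),
           gap3 = sample(50:400, 1))
  }
  units <- units[sample(length(units))]

  rows <- list(); chrom_i <- 1L; pos <- 0
  for (u in units) {
    gap <- round(runif(1, cfg$spacing[1], cfg$spacing[2]))
    ulen <- sum(u$lens) + u$gap3
    while (pos + gap + ulen > cfg$chrom_len) {
      chrom_i <- chrom_i + 1L; pos <- 0
      if (chrom_i > cfg$n_chroms)
        stop("infeasible packing: genes do not fit in ", cfg$n_chroms,
             " chromosome(s) of ", cfg$chrom_len, " nt")
    }
    s <- pos + gap + 1
    if (length(u$ids) == 1L) {
      rows[[length(rows) + 1L]] <-
        data.frame(id = u$ids, chrom = paste0("chr", chrom_i),
                   strand = u$strands, start = s, end = s + u$lens - 1,
                   kind = u$kinds, tgt = u$tgts, stringsAsFactors = FALSE)
      pos <- s + u$lens - 1
    } else {
      ## convergent pair: + gene, short 3'-3' gap, - gene
      sa <- s; ea <- s + u$lens[1] - 1
      sb <- ea + u$gap3 + 1; eb <- sb + u$lens[2] - 1
      rows[[length(rows) + 1L]] <-
        data.frame(id = u$ids, chrom = paste0("chr", chrom_i),
                   strand = c("+", "-"), start = c(sa, sb), end = c(ea, eb),
                   kind = u$kinds, tgt = u$tgts, stringsAsFactors = FALSE)
      pos <- eb
    }
  }
  tab <- do.call(rbind, rows)
  lens <- stats::setNames(rep(cfg$chrom_len, cfg$n_chroms),
                          paste0("chr", seq_len(cfg$n_chroms)))
  genes <- gene_set(tab$id, tab$chrom, tab$strand, tab$start, tab$end,
                    kind = tab$kind, is_mirna_target = tab$tgt,
                    chrom_lengths = lens)
  attr(genes, "convergent_ids") <- pair_ids
  genes
}

#' Truth table of planted 3' extensions
#'
#' Samples the planted gene set (convergent-pair members always included)
#' and the per-gene planted mutant downstream RPKM, deterministically
#' under the seed.
#'
#' @param cfg a [sim_config()].
#' @param genes output of [simulate_annotation()].
#' @return `data.frame` with `gene_id` and `extension_rpkm`.
#' @export
make_extension_truth <- function(cfg, genes) {
  set.seed(cfg$seed + 101L)
  coding <- genes$id[genes$kind == "coding" & !genes$is_mirna_target]
  pair_ids <- intersect(attr(genes, "convergent_ids"), coding)
  pair_ids <- utils::head(pair_ids, cfg$n_extensions)
  n_extra <- cfg$n_extensions - length(pair_ids)
  planted <- c(pair_ids, sample(setdiff(coding, pair_ids), n_extra))
  data.frame(gene_id = planted,
             extension_rpkm = runif(length(planted), cfg$extension_rpkm[1],
                                    cfg$extension_rpkm[2]),
             stringsAsFactors = FALSE)
}

#' Truth table of planted pri-miRNA 3' remnants
#'
#' Every MIR locus gets a planted mutant-only remnant RPKM downstream of
#' its gene model.
#'
#' @param cfg a [sim_config()].
#' @param genes output of [simulate_annotation()].
#' @return `data.frame` with `locus_id` and `remnant_rpkm`.
#' @export
make_remnant_truth <- function(cfg, genes) {
  set.seed(cfg$seed + 102L)
  mir <- genes$id[genes$kind == "mir"]
  data.frame(locus_id = mir,
             remnant_rpkm = if (length(mir))
               runif(length(mir), cfg$remnant_rpkm[1], cfg$remnant_rpkm[2])
             else numeric(),
             stringsAsFactors = FALSE)
}

## Uniformly place n fixed-length reads inside a window (clipped at the
## chromosome end).
place_reads <- function(n, chrom, wstart, wend, strand_, rl, chrom_len) {
  if (n == 0) return(GRanges())
  span <- pmax(1, wend - wstart - rl + 2)
  starts <- wstart + floor(runif(n) * span)
  ends <- pmin(starts + rl - 1, chrom_len)
  GRanges(chrom, IRanges(starts, ends), strand = strand_)
}

#' Simulate strand-specific read libraries
#'
#' For every genotype and replicate: per-gene body reads with
#' negative-binomial count noise around a library-size-scaled expected
#' count; downstream-window reads at the leakage rate in every genotype
#' plus the planted extension (coding genes) or remnant (MIR loci) rate
#' in mutant genotypes; and extra tail-window reads at miRNA targets in
#' mutants. Reads are fixed-length intervals on the gene's strand;
#' `total_mapped` is the nominal library depth (the emitted reads are the
#' subset at simulated loci).
#'
#' @param cfg a [sim_config()].
#' @param genes output of [simulate_annotation()].
#' @param extension_truth,remnant_truth truth tables; generated from the
#'   seed when NULL.
#' @return Named list of [alignment_set()] objects (one per library).
#' @export
simulate_alignments <- function(cfg, genes, extension_truth = NULL,
                                remnant_truth = NULL) {
  if (is.null(extension_truth)) extension_truth <- make_extension_truth(cfg, genes)
  if (is.null(remnant_truth)) remnant_truth <- make_remnant_truth(cfg, genes)
  set.seed(cfg$seed + 1L)
  n <- length(genes)
  expr <- ifelse(genes$kind == "mir",
                 runif(n, cfg$mir_body_rpkm[1], cfg$mir_body_rpkm[2]),
                 rlnorm(n, cfg$body_rpkm_meanlog, cfg$body_rpkm_sdlog))
  dw <- suppressWarnings(downstream_windows(genes, cfg$downstream_length))
  tw <- suppressWarnings(target_end_windows(genes, cfg$target_window))
  tails <- tw[tw$role == "target_tail200"]
  scale <- cfg$depth / 1e9  # rpkm * nt * scale = expected reads
  rl <- cfg$read_length
  chrom <- as.character(seqnames(genes))
  clens <- seqlengths(genes)[chrom]
  strand_g <- as.character(strand(genes))

  planted_ext <- stats::setNames(rep(0, n), genes$id)
  planted_ext[extension_truth$gene_id] <- extension_truth$extension_rpkm
  planted_ext[remnant_truth$locus_id] <- remnant_truth$remnant_rpkm

  libs <- list()
  for (gt in names(cfg$genotypes)) {
    is_mut <- gt != cfg$wt_genotype
    for (r in seq_len(cfg$genotypes[[gt]])) {
      reads <- vector("list", 3L)
      ## gene-body reads
      mu_body <- expr * width(genes) * scale
      cnt <- nb_draw(n, mu_body, cfg$nb_dispersion)
      idx <- rep(seq_len(n), cnt)
      reads[[1]] <- place_reads(length(idx), chrom[idx], start(genes)[idx],
                                end(genes)[idx], strand_g[idx], rl,
                                clens[idx])
      ## downstream windows: leakage everywhere, planted signal in mutants
      di <- match(dw$gene_id, genes$id)
      rate <- cfg$leakage_rpkm + if (is_mut) planted_ext[dw$gene_id] else 0
      mu_dw <- rate * width(dw) * scale
      cnt <- nb_draw(length(dw), mu_dw, cfg$nb_dispersion)
      idx <- rep(seq_along(dw), cnt)
      reads[[2]] <- place_reads(length(idx),
                                as.character(seqnames(dw))[idx],
                                start(dw)[idx], end(dw)[idx],
                                as.character(strand(dw))[idx], rl,
                                clens[di][idx])
      ## target tails: cleavage-fragment accumulation in mutants
      if (is_mut && length(tails)) {
        ti <- match(tails$gene_id, genes$id)
        mu_t <- (cfg$target_tail_fold - 1) * expr[ti] * width(tails) * scale
        cnt <- nb_draw(length(tails), mu_t, cfg$nb_dispersion)
        idx <- rep(seq_along(tails), cnt)
        reads[[3]] <- place_reads(length(idx),
                                  as.character(seqnames(tails))[idx],
                                  start(tails)[idx], end(tails)[idx],
                                  as.character(strand(tails))[idx], rl,
                                  clens[ti][idx])
      } else reads[[3]] <- GRanges()
      all_reads <- sort(suppressWarnings(do.call(c, reads)))
      lib_id <- paste0(gt, "_r", r)
      libs[[lib_id]] <- alignment_set(lib_id, gt, r, all_reads,
                                      total_mapped = cfg$depth)
    }
  }
  libs
}

#' Simulate per-cytosine methylomes with planted DMRs
#'
#' Background cytosines are placed at context-specific densities with
#' identical methylation levels in every sample (binomial sampling noise
#' only); planted regions carry `dmr_n_sites` evenly spaced CG sites
#' whose levels differ between samples (`dmr_levels`, direction
#' alternating per region). Per-site coverage is Poisson; methylated
#' counts are binomial. Planted regions avoid gene spans (+/- 500 nt)
#' when a gene set is supplied.
#'
#' @param cfg a [sim_config()].
#' @param genes optional gene set whose loci planted regions must avoid.
#' @return List with `samples` (named list of allc-style `data.frame`s)
#'   and `truth` (`data.frame` of planted regions).
#' @export
simulate_methylome <- function(cfg, genes = NULL) {
  set.seed(cfg$seed + 2L)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  avoid <- if (!is.null(genes) && length(genes))
    suppressWarnings(GRanges(seqnames(genes),
                             IRanges(pmax(1, start(genes) - 500),
                                     end(genes) + 500)))
  else GRanges()

  ## plant non-overlapping regions away from genes
  truth <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  placed <- GRanges()
  tries <- 0
  while (nrow(truth) < cfg$n_dmrs && tries < 10000 * max(1, cfg$n_dmrs)) {
    tries <- tries + 1
    ch <- sample(chroms, 1)
    s <- sample.int(cfg$chrom_len - cfg$dmr_len, 1)
    s <- as.integer(s)
    cand <- GRanges(ch, IRanges(s, s + cfg$dmr_len - 1))
    if (length(avoid) && any(suppressWarnings(overlapsAny(cand + 200, avoid)))) next
    if (length(placed) && any(suppressWarnings(overlapsAny(cand + 200, placed)))) next
    placed <- suppressWarnings(c(placed, cand))
    truth <- rbind(truth, data.frame(chrom = ch, start = s,
                                     end = s + as.integer(cfg$dmr_len) - 1L,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(truth) < cfg$n_dmrs)
    stop("could not place ", cfg$n_dmrs, " DMR regions")

  ## background sites per context, outside planted regions
  site_tab <- do.call(rbind, lapply(chroms, function(ch) {
    do.call(rbind, lapply(names(cfg$meth_site_spacing), function(ctx) {
      ns <- floor(cfg$chrom_len / cfg$meth_site_spacing[[ctx]])
      pos <- sort(sample.int(cfg$chrom_len, ns))
      data.frame(chrom = ch, pos = pos,
                 strand = sample(c("+", "-"), ns, replace = TRUE),
                 context = ctx, level_hi = cfg$meth_background[[ctx]],
                 level_lo = cfg$meth_background[[ctx]], region = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (length(placed)) {
    sg <- GRanges(site_tab$chrom, IRanges(site_tab$pos, site_tab$pos))
    site_tab <- site_tab[!overlapsAny(sg, placed), , drop = FALSE]
  }
  if (nrow(truth)) {
    planted <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      pos <- as.integer(round(seq(truth$start[i] + 2, truth$end[i] - 2,
                                  length.out = cfg$dmr_n_sites)))
      data.frame(chrom = truth$chrom[i], pos = pos,
                 strand = sample(c("+", "-"), length(pos), replace = TRUE),
                 context = "CG", level_hi = cfg$dmr_levels[1],
                 level_lo = cfg$dmr_levels[2], region = i,
                 stringsAsFactors = FALSE)
    }))
    site_tab <- rbind(site_tab, planted)
  }
  site_tab <- site_tab[order(site_tab$chrom, site_tab$pos), , drop = FALSE]

  samples <- lapply(seq_along(cfg$meth_samples), function(i) {
    ## direction of planted differences alternates per region
    first_high <- (i == 1)
    hi_here <- ifelse(is.na(site_tab$region), TRUE,
                      xor(site_tab$region %% 2 == 0, first_high))
    level <- ifelse(hi_here, site_tab$level_hi, site_tab$level_lo)
    cov <- rpois(nrow(site_tab), cfg$meth_cov)
    mc <- rbinom(nrow(site_tab), cov, level)
    keep <- cov > 0
    data.frame(chrom = site_tab$chrom[keep], pos = site_tab$pos[keep],
               strand = site_tab$strand[keep],
               context = site_tab$context[keep],
               mc = mc[keep], cov = cov[keep], stringsAsFactors = FALSE)
  })
  names(samples) <- cfg$meth_samples
  list(samples = samples, truth = truth)
}

#' Simulate the full dataset, optionally writing all files
#'
#' Runs [simulate_annotation()], the truth-table builders,
#' [simulate_alignments()] and [simulate_methylome()] under the config's
#' seed. With `outdir` set, writes GFF3 annotation, MIR/target ID lists,
#' one BED6 file per library plus a manifest TSV, one allc TSV per
#' methylome, the truth tables, and the config as JSON.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return List with `genes`, `alignments`, `meth`, `extension_truth`,
#'   `remnant_truth`, `config` and `files` (named paths, empty when no
#'   `outdir`).
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  genes <- simulate_annotation(cfg)
  ext_truth <- make_extension_truth(cfg, genes)
  rem_truth <- make_remnant_truth(cfg, genes)
  libs <- simulate_alignments(cfg, genes, ext_truth, rem_truth)
  meth <- simulate_methylome(cfg, genes)
  files <- character()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    export_annotation_gff(genes, fp("genes.gff3"))
    writeLines(genes$id[genes$kind == "mir"], fp("mir_ids.txt"))
    writeLines(genes$id[genes$is_mirna_target], fp("target_ids.txt"))
    files <- c(annotation = fp("genes.gff3"), mir_ids = fp("mir_ids.txt"),
               target_ids = fp("target_ids.txt"))
    man <- do.call(rbind, lapply(libs, function(l) {
      bed <- fp(paste0("reads_", l$library_id, ".bed"))
      rtracklayer::export(l$reads, bed, format = "BED")
      data.frame(library_id = l$library_id, genotype = l$genotype,
                 replicate = l$replicate, path = bed,
                 total_mapped = l$total_mapped, stringsAsFactors = FALSE)
    }))
    write.table(man, fp("manifest.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (s in names(meth$samples)) {
      write.table(meth$samples[[s]], fp(paste0("allc_", s, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    write.table(ext_truth, fp("truth_extensions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(meth$truth, fp("truth_dmrs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(cfg), fp("config.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, manifest = fp("manifest.tsv"),
               truth_extensions = fp("truth_extensions.tsv"),
               truth_dmrs = fp("truth_dmrs.tsv"),
               config = fp("config.json"))
  }
  list(genes = genes, alignments = libs, meth = meth,
       extension_truth = ext_truth, remnant_truth = rem_truth,
       config = cfg, files = files)
}

#' Write a gene set as GFF3
#'
#' One top-level feature per gene (`gene`, `miRNA_gene` or
#' `transposable_element_gene` by kind) with `ID`; chromosome lengths go
#' to `##sequence-region` pragmas.
#'
#' @param genes a gene set.
#' @param path output GFF3 file.
#' @export
export_annotation_gff <- function(genes, path) {
  out <- genes
  mcols(out) <- NULL
  out$source <- "readthrough_sim"
  out$type <- c(coding = "gene", mir = "miRNA_gene",
                transposon = "transposable_element_gene",
                other = "gene")[genes$kind]
  out$ID <- genes$id
  out$Name <- genes$id
  rtracklayer::export(out, path, format = "GFF3")
  ## rtracklayer does not emit ##sequence-region pragmas; add them so the
  ## file is self-contained for read_annotation()
  lines <- readLines(path)
  lens <- seqlengths(genes)
  pragmas <- sprintf("##sequence-region %s 1 %d", names(lens), lens)
  first <- grep("^##gff-version", lines)[1]
  writeLines(c(lines[seq_len(first)], pragmas,
               lines[-seq_len(first)]), path)
  invisible(path)
}
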