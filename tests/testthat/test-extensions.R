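## Build a quant table directly from per-replicate downstream RPKM values.
quant_from_rpkm <- function(values) {
  rows <- do.call(rbind, lapply(names(values), function(id) {
    v <- values[[id]]
    do.call(rbind, lapply(names(v), function(gt)
      data.frame(gene_id = id, role = "downstream500", genotype = gt,
                 replicate = seq_along(v[[gt]]),
                 library_id = paste0(gt, "_r", seq_along(v[[gt]])),
                 length = 500, count = NA_integer_, rpkm = v[[gt]],
                 stringsAsFactors = FALSE)))
  }))
  rownames(rows) <- NULL
  rows
}

simple_genes <- function(ids, kinds = "coding") {
  n <- length(ids)
  gene_set(id = ids, chrom = "chr1", strand = "+",
           start = seq(1, by = 5000, length.out = n),
           end = seq(1, by = 5000, length.out = n) + 999,
           kind = rep_len(kinds, n),
           chrom_lengths = c(chr1 = 5000 * n + 2000))
}

test_that("the four-parameter filter passes a clear planted case", {
  q <- quant_from_rpkm(list(
    g1 = list(WT = c(1.0, 0.9, 1.1), mut = c(6, 5, 7)),
    g2 = list(WT = c(2, 2, 2), mut = c(2, 2, 2))))
  gs <- simple_genes(c("g1", "g2"))
  calls <- call_extensions(q, gs, "WT", "mut")
  c1 <- calls[calls$gene_id == "g1", ]
  expect_equal(c1$fold, 6)
  expect_equal(c1$mut_mean_rpkm, 6)
  expect_lt(c1$p, 0.1)
  expect_true(c1$passed)
  # identical replicates: fold 1, not passed
  c2 <- calls[calls$gene_id == "g2", ]
  expect_equal(c2$fold, 1)
  expect_false(c2$passed)
  expect_false(c2$pass_fold)
})

test_that("fold conventions: Inf for new transcripts, undefined when silent", {
  q <- quant_from_rpkm(list(
    new = list(WT = c(0, 0, 0), mut = c(6, 5, 7)),
    dead = list(WT = c(0, 0, 0), mut = c(0, 0, 0))))
  gs <- simple_genes(c("new", "dead"))
  calls <- call_extensions(q, gs, "WT", "mut")
  expect_equal(calls$fold[calls$gene_id == "new"], Inf)
  expect_true(calls$passed[calls$gene_id == "new"])
  expect_true(is.na(calls$fold[calls$gene_id == "dead"]))
  expect_false(calls$passed[calls$gene_id == "dead"])
})

test_that("MIR loci and MIR-overlapping windows fail the non-pri-miRNA filter", {
  # mir sits 200 bp downstream of g1's 3' end, inside its window
  gs <- gene_set(id = c("g1", "mir1", "far"),
                 chrom = "chr1", strand = "+",
                 start = c(1, 1201, 20001), end = c(1000, 1500, 21000),
                 kind = c("coding", "mir", "coding"),
                 chrom_lengths = c(chr1 = 50000))
  q <- quant_from_rpkm(list(
    g1 = list(WT = c(0.1, 0.1, 0.1), mut = c(6, 5, 7)),
    mir1 = list(WT = c(0.1, 0.1, 0.1), mut = c(6, 5, 7)),
    far = list(WT = c(0.1, 0.1, 0.1), mut = c(6, 5, 7))))
  calls <- call_extensions(q, gs, "WT", "mut")
  expect_false(calls$pass_nonmir[calls$gene_id == "g1"])
  expect_false(calls$pass_nonmir[calls$gene_id == "mir1"])
  expect_true(calls$passed[calls$gene_id == "far"])
  expect_false(calls$passed[calls$gene_id == "g1"])
  # filters other than non-pri-miRNA pass for g1: the trace shows why
  g1 <- calls[calls$gene_id == "g1", ]
  expect_true(g1$pass_fold && g1$pass_rpkm && g1$pass_p)
})

test_that("single-replicate genotypes skip the p filter with a warning", {
  q <- quant_from_rpkm(list(g1 = list(WT = 0.5, mut = 6)))
  gs <- simple_genes("g1")
  expect_warning(calls <- call_extensions(q, gs, "WT", "mut"),
                 "p-value filter skipped")
  expect_true(calls$passed)
  expect_true(is.na(calls$p))
})

test_that("missing genotypes are an error", {
  q <- quant_from_rpkm(list(g1 = list(WT = c(1, 1), mut = c(2, 2))))
  gs <- simple_genes("g1")
  expect_error(call_extensions(q, gs, "WT", "xrn9"), "xrn9")
})

test_that("tightening thresholds never grows the passed set", {
  gs <- random_quant_genes(30)
  for (seed in 1:8) {
    q <- random_quant_table(30, seed = seed)
    loose <- call_extensions(q, gs, "WT", "mut",
                             extension_filter_params(min_fold = 2,
                                                     max_p = 0.5))
    tight_fold <- call_extensions(q, gs, "WT", "mut",
                                  extension_filter_params(min_fold = 5,
                                                          max_p = 0.5))
    tight_p <- call_extensions(q, gs, "WT", "mut",
                               extension_filter_params(min_fold = 2,
                                                       max_p = 0.05))
    expect_true(all(tight_fold$gene_id[tight_fold$passed] %in%
                      loose$gene_id[loose$passed]))
    expect_true(all(tight_p$gene_id[tight_p$passed] %in%
                      loose$gene_id[loose$passed]))
  }
})

test_that("the relaxed preset is a superset of the default preset", {
  gs <- random_quant_genes(30)
  for (seed in 9:14) {
    q <- random_quant_table(30, seed = seed)
    def <- call_extensions(q, gs, "WT", "mut", extension_preset("default"))
    rel <- call_extensions(q, gs, "WT", "mut", extension_preset("relaxed"))
    expect_true(all(def$gene_id[def$passed] %in% rel$gene_id[rel$passed]))
  }
})

test_that("raw counts tally genes with positive mutant downstream RPKM", {
  q <- quant_from_rpkm(list(
    a = list(WT = c(1, 1), mut = c(0, 0)),
    b = list(WT = c(0, 0), mut = c(0.4, 0.4)),
    c = list(WT = c(1, 1), mut = c(2.2, 2.2))))
  expect_equal(raw_extension_count(q, "mut"), 2)
  expect_equal(raw_extension_count(q, "mut", mode = "new_only", wt = "WT"), 1)
  q0 <- quant_from_rpkm(list(a = list(WT = c(0, 0), mut = c(0, 0))))
  expect_equal(raw_extension_count(q0, "mut"), 0)
})

test_that("raw count equals the genes-with-reads count on real windows", {
  cfg <- sim_config(seed = 31, n_genes = 40, n_mir = 2, n_targets = 3,
                    n_convergent_pairs = 0, n_extensions = 8,
                    n_chroms = 1, chrom_len = 3e5,
                    genotypes = c(WT = 2, fry1 = 2))
  genes <- simulate_annotation(cfg)
  libs <- simulate_alignments(cfg, genes)
  w <- suppressWarnings(downstream_windows(genes))
  q <- quantify_windows(libs, w)
  qd <- q[q$role == "downstream500" & q$genotype == "fry1", ]
  by_reads <- sum(tapply(qd$count, qd$gene_id, sum) > 0)
  expect_equal(raw_extension_count(q, "fry1"), by_reads)
})

test_that("candidate set overlaps report shared counts and fractions", {
  mk <- function(passed_ids, all_ids) {
    data.frame(gene_id = all_ids, passed = all_ids %in% passed_ids)
  }
  a <- mk(c("g1", "g2", "g3"), sprintf("g%d", 1:5))
  b <- mk(c("g2", "g3", "g4"), sprintf("g%d", 1:5))
  ov <- candidate_overlap(a, b)
  expect_equal(ov$shared, 2)
  expect_equal(ov$fraction_a, 2 / 3)
  expect_equal(ov$fraction_b, 2 / 3)
  disjoint <- candidate_overlap(mk("g1", "g1"), mk("g2", "g2"))
  expect_equal(unlist(disjoint[c("shared", "fraction_a", "fraction_b")]),
               c(shared = 0, fraction_a = 0, fraction_b = 0))
  sub <- candidate_overlap(mk(c("g1", "g2"), sprintf("g%d", 1:5)),
                           mk(c("g1", "g2", "g3"), sprintf("g%d", 1:5)))
  expect_equal(sub$fraction_a, 1)
  emp <- candidate_overlap(mk(character(), "g1"), mk("g1", "g1"))
  expect_true(emp$empty_set)
})
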