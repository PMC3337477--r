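test_that("GFF3 genes are parsed with coordinates, kinds and flags", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\ttest\tgene\t101\t600\t.\t+\t.\tID=g1",
    "chr1\ttest\tgene\t2001\t3000\t.\t-\t.\tID=g2",
    "chr1\ttest\tgene\t5000\t5400\t.\t+\t.\tID=g3"), gff)
  gs <- read_annotation(gff, mir_ids = "g3")
  expect_equal(length(gs), 3L)
  g1 <- gs[gs$id == "g1"]
  expect_equal(start(g1), 101)
  expect_equal(end(g1), 600)
  expect_equal(as.character(strand(g1)), "+")
  expect_equal(sum(gs$kind == "mir"), 1L)
  expect_equal(gs$id[gs$kind == "mir"], "g3")
  expect_equal(unname(seqlengths(gs)["chr1"]), 10000L)
})

test_that("records without strand are skipped and duplicates rejected", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\ttest\tgene\t101\t600\t.\t+\t.\tID=g1",
    "chr1\ttest\tgene\t701\t900\t.\t.\t.\tID=g2"), gff)
  expect_warning(gs <- read_annotation(gff), "without strand")
  expect_equal(gs$id, "g1")

  dup <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\ttest\tgene\t101\t600\t.\t+\t.\tID=g1",
    "chr1\ttest\tgene\t701\t900\t.\t-\t.\tID=g1"), dup)
  expect_error(read_annotation(dup), "duplicate")
})

test_that("downstream windows follow the stated strand geometry", {
  gs <- gene_set(id = c("p", "m"), chrom = "chr1", strand = c("+", "-"),
                 start = c(1, 2001), end = c(1000, 3000),
                 chrom_lengths = c(chr1 = 10000))
  w <- downstream_windows(gs, length = 500)
  wp <- w[w$gene_id == "p"]; wm <- w[w$gene_id == "m"]
  expect_equal(c(start(wp), end(wp)), c(1001, 1500))
  expect_equal(as.character(strand(wp)), "+")
  expect_equal(c(start(wm), end(wm)), c(1501, 2000))
  expect_equal(as.character(strand(wm)), "-")
  expect_false(any(w$truncated))
})

test_that("downstream windows truncate at chromosome ends and drop empties", {
  gs <- gene_set(id = "far", chrom = "chr1", strand = "+",
                 start = 1, end = 920, chrom_lengths = c(chr1 = 2000))
  w <- downstream_windows(gs, length = 500)
  # gene ends 1080 bp before the chromosome end: full window
  expect_equal(width(w), 500)
  gs2 <- gene_set(id = "e", chrom = "chr1", strand = "+",
                  start = 1, end = 1920, chrom_lengths = c(chr1 = 2000))
  w2 <- downstream_windows(gs2, length = 500)
  expect_equal(width(w2), 80)
  expect_true(w2$truncated)
  gs3 <- gene_set(id = "z", chrom = "chr1", strand = "+",
                  start = 1, end = 2000, chrom_lengths = c(chr1 = 2000))
  expect_warning(w3 <- downstream_windows(gs3, length = 500), "zero-length")
  expect_equal(length(w3), 0L)
})

test_that("pri-miRNA windows unite the gene span with a downstream pad", {
  gs <- gene_set(id = c("mp", "mm"), chrom = "chr1", strand = c("+", "-"),
                 start = c(1000, 1000), end = c(1300, 1300), kind = "mir",
                 chrom_lengths = c(chr1 = 10000))
  w <- primirna_windows(gs, pad = 500)
  expect_equal(c(start(w[1]), end(w[1])), c(1000, 1800))
  expect_equal(c(start(w[2]), end(w[2])), c(500, 1300))
  w0 <- primirna_windows(gs, pad = 0)
  expect_equal(start(w0), start(gs))
  expect_equal(end(w0), end(gs))
})

test_that("target head/tail windows respect transcription order", {
  gs <- gene_set(id = c("tp", "tm"), chrom = "chr1", strand = c("+", "-"),
                 start = c(101, 101), end = c(600, 600),
                 is_mirna_target = TRUE, chrom_lengths = c(chr1 = 10000))
  w <- target_end_windows(gs, length = 200)
  hp <- w[w$gene_id == "tp" & w$role == "target_head200"]
  tp <- w[w$gene_id == "tp" & w$role == "target_tail200"]
  expect_equal(c(start(hp), end(hp)), c(101, 300))
  expect_equal(c(start(tp), end(tp)), c(401, 600))
  hm <- w[w$gene_id == "tm" & w$role == "target_head200"]
  tm <- w[w$gene_id == "tm" & w$role == "target_tail200"]
  expect_equal(c(start(hm), end(hm)), c(401, 600))
  expect_equal(c(start(tm), end(tm)), c(101, 300))
  # head precedes tail on the + strand when the gene is long enough
  expect_true(end(hp) <= start(tp))

  short <- gene_set(id = "s", chrom = "chr1", strand = "+",
                    start = 101, end = 250, is_mirna_target = TRUE,
                    chrom_lengths = c(chr1 = 10000))
  ws <- target_end_windows(short, length = 200)
  expect_true(all(start(ws) == 101 & end(ws) == 250))
  expect_true(all(ws$truncated))
})

test_that("window geometry is invariant under the strand-mirror transform", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 12
    st <- sort(sample.int(40000, n)) + seq(0, by = 4000, length.out = n)
    gs <- gene_set(id = sprintf("g%02d", 1:n), chrom = "chr1",
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   start = st, end = st + sample(200:2000, n, TRUE),
                   kind = sample(c("coding", "mir"), n, TRUE),
                   is_mirna_target = sample(c(TRUE, FALSE), n, TRUE),
                   chrom_lengths = c(chr1 = 200000))
    mg <- mirror_genes(gs)
    for (fn in list(function(g) suppressWarnings(downstream_windows(g)),
                    function(g) suppressWarnings(primirna_windows(g)),
                    function(g) suppressWarnings(target_end_windows(g)))) {
      w <- fn(gs); wm <- fn(mg)
      expect_equal(length(w), length(wm))
      if (length(w) == 0) next
      expected <- mirror_ranges(w)
      ord <- order(w$gene_id, w$role); ordm <- order(wm$gene_id, wm$role)
      expect_equal(start(wm)[ordm], start(expected)[ord])
      expect_equal(end(wm)[ordm], end(expected)[ord])
      expect_equal(as.character(strand(wm))[ordm],
                   as.character(strand(expected))[ord])
    }
  }
})

test_that("untruncated downstream windows never overlap their own gene", {
  set.seed(3)
  for (rep in 1:10) {
    st <- sample.int(50000, 1) + 5000
    gs <- gene_set(id = "g", chrom = "chr1",
                   strand = sample(c("+", "-"), 1),
                   start = st, end = st + sample(100:3000, 1),
                   chrom_lengths = c(chr1 = 100000))
    w <- downstream_windows(gs)
    expect_false(w$truncated)
    expect_equal(suppressWarnings(countOverlaps(w, gs)), 0L,
                 ignore_attr = TRUE)
  }
})
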