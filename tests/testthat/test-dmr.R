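test_that("allc parsing validates rows and logs rejections", {
  f <- tempfile()
  writeLines(c("chr1\t100\t+\tCG\t5\t10",
               "chr1\t120\t-\tCHH\t0\t7",
               "chr1\t140\t+\tCG\t5\t3",    # mc > cov
               "chr1\t160\t+\tXX\t1\t5"),   # bad context
             f)
  expect_warning(x <- read_allc(f), "2 malformed")
  expect_equal(nrow(x), 2)
  expect_equal(x$pos, c(100, 120))

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_allc(empty)), 0)
})

test_that("window scan requires the minimum number of differing sites", {
  mk <- function(n_sites, la, lb) {
    pos <- seq(10, by = 8, length.out = n_sites)
    list(A = make_allc(pos, la), B = make_allc(pos, lb))
  }
  s12 <- mk(12, 0.9, 0.05)
  cand <- scan_windows(s12, "CG")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_diff_sites, 12)
  expect_equal(c(cand$start, cand$end), c(1, 100))

  s9 <- mk(9, 0.9, 0.05)
  expect_equal(nrow(scan_windows(s9, "CG")), 0)

  same <- mk(12, 0.6, 0.6)
  expect_equal(nrow(scan_windows(same, "CG")), 0)
})

test_that("sites below coverage or below the level difference do not count", {
  pos <- seq(10, by = 8, length.out = 12)
  a <- make_allc(pos, 0.9); b <- make_allc(pos, 0.05)
  b$cov[1:3] <- 2; b$mc[1:3] <- 0          # undercovered in B
  p <- dmr_params()
  cand <- scan_windows(list(A = a, B = b), "CG", p)
  expect_equal(nrow(cand), 0)              # only 9 usable difference sites
  b2 <- make_allc(pos, 0.85)               # |0.9 - 0.85| < 0.1
  expect_equal(nrow(scan_windows(list(A = a, B = b2), "CG", p)), 0)
})

test_that("window testing uses Kruskal-Wallis on per-site levels", {
  pos <- seq(10, by = 8, length.out = 12)
  set.seed(2)
  mcA <- rbinom(12, 20, 0.9); mcB <- rbinom(12, 20, 0.05)
  a <- make_allc(pos, mcA / 20); b <- make_allc(pos, mcB / 20)
  cand <- list(chrom = "chr1", start = 1, end = 100)
  r <- test_window(cand, list(A = a, B = b), "CG")
  expect_lt(r$p, 0.01)
  # label swap leaves the p unchanged
  r2 <- test_window(cand, list(A = b, B = a), "CG")
  expect_equal(r$p, r2$p)
  # equal levels: p = 1
  r3 <- test_window(cand, list(A = a, B = a), "CG")
  expect_equal(r3$p, 1)
})

test_that("joining merges windows within the gap and Fisher-combines p", {
  two <- data.frame(chrom = "chr1", start = c(101, 251), end = c(200, 350),
                    n_diff_sites = c(10, 11), p = c(0.5, 0.5))
  j <- join_dmrs(two)  # gap 50 <= 100
  expect_equal(nrow(j), 1)
  expect_equal(c(j$start, j$end), c(101, 350))
  expect_equal(j$n_sites, 21)
  x2 <- -2 * 2 * log(0.5)
  expect_equal(j$fisher_p, exp(-x2 / 2) * (1 + x2 / 2), tolerance = 1e-9)

  apart <- data.frame(chrom = "chr1", start = c(101, 451),
                      end = c(200, 550), n_diff_sites = c(10, 10),
                      p = c(0.5, 0.5))
  expect_equal(nrow(join_dmrs(apart)), 2)  # gap 250 > 100

  single <- data.frame(chrom = "chr1", start = 101, end = 200,
                       n_diff_sites = 10, p = 0.037)
  expect_equal(join_dmrs(single)$fisher_p, 0.037, tolerance = 1e-12)
})

test_that("exact boundary gap of 100 bp still joins", {
  tiles <- data.frame(chrom = "chr1", start = c(1, 201), end = c(100, 300),
                      n_diff_sites = c(10, 10), p = c(0.1, 0.1))
  expect_equal(nrow(join_dmrs(tiles)), 1)   # gap exactly 100
  tiles$start[2] <- 202
  expect_equal(nrow(join_dmrs(tiles)), 2)   # gap 101
})

test_that("the full DMR pipeline recovers a planted region and applies the fold filter", {
  set.seed(8)
  pos <- seq(210, by = 8, length.out = 12)     # inside tile 201..300
  bg <- seq(1000, by = 50, length.out = 40)     # flat background
  a <- rbind(make_allc(pos, 0.9), make_allc(bg, 0.3))
  b <- rbind(make_allc(pos, 0.05), make_allc(bg, 0.3))
  d <- call_dmrs(list(A = a, B = b))
  passed <- d[d$passed, ]
  expect_equal(nrow(passed), 1)
  expect_true(passed$start <= 210 && passed$end >= 298)
  expect_gte(passed$fold, 8)
  expect_equal(passed$context, "CG")

  # identical methylomes: nothing called
  expect_equal(nrow(call_dmrs(list(A = a, B = a))), 0)

  # significant but only 2-fold different: rejected by the density filter
  a2 <- rbind(make_allc(pos, 0.99), make_allc(bg, 0.3))
  b2 <- rbind(make_allc(pos, 0.45), make_allc(bg, 0.3))
  d2 <- call_dmrs(list(A = a2, B = b2))
  expect_true(nrow(d2) >= 1)        # window is found and tested
  expect_equal(sum(d2$passed), 0)   # but the 8-fold requirement fails
  expect_lt(d2$adj_p[1], 0.01)
})

test_that("density combines all three contexts within the span", {
  pos_cg <- seq(10, by = 8, length.out = 12)
  pos_chh <- seq(14, by = 16, length.out = 5)
  a <- rbind(make_allc(pos_cg, 0.9),
             make_allc(pos_chh, 0.5, context = "CHH"))
  b <- rbind(make_allc(pos_cg, 0.05),
             make_allc(pos_chh, 0.5, context = "CHH"))
  d <- call_dmrs(list(A = a, B = b))
  expect_equal(nrow(d), 1)
  # density_A = (12*18 + 5*10) / (17*20): CHH sites dilute the CG signal
  expect_equal(d$density_A, (12 * 18 + 5 * 10) / (17 * 20),
               ignore_attr = TRUE)
})

test_that("joined DMRs are non-overlapping within a context", {
  cfg <- sim_config(seed = 17, n_chroms = 1, chrom_len = 1e5, n_dmrs = 10)
  meth <- simulate_methylome(cfg)
  d <- call_dmrs(meth$samples)
  for (ctx in unique(d$context)) {
    dd <- d[d$context == ctx, ]
    dd <- dd[order(dd$chrom, dd$start), ]
    if (nrow(dd) < 2) next
    same_chrom <- dd$chrom[-1] == dd$chrom[-nrow(dd)]
    expect_true(all(!same_chrom | dd$start[-1] > dd$end[-nrow(dd)]))
  }
})

test_that("fewer than two samples is an error", {
  expect_error(call_dmrs(list(A = make_allc(1:5 * 10, 0.5))), "2 samples")
})
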