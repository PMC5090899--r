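toy_params <- scan_params(bin_size = 10000, step_size = 1000)

test_that("window enumeration follows the closed form", {
  p <- scan_params()
  w <- enumerate_windows(1000000, p)
  expect_equal(length(w), 91L)  # floor((L - bin)/step) + 1
  expect_equal(IRanges::start(w)[1], 1)
  expect_equal(IRanges::end(w)[1], 100000)
  expect_equal(IRanges::start(w)[91], 900001)
  expect_equal(IRanges::end(w)[91], 1000000)
  expect_equal(length(enumerate_windows(99999, p)), 0L)
  expect_equal(length(enumerate_windows(100000, p)), 1L)
})

test_that("non-conserved positions are the union of heterozygous calls", {
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  a <- make_callset("a", het = data.frame(contig = "chr1",
                                          pos = c(10, 20, 30, 40, 50)))
  b <- make_callset("b", het = data.frame(contig = "chr1", pos = c(10, 20)))
  cnt <- suppressWarnings(count_window(win, list(a, b), 1e6))
  expect_equal(unname(cnt["n_nonconserved"]), 5)
  expect_equal(unname(cnt["n_covered"]), 100000)
  expect_equal(unname(cnt["n_conserved"]), 99995)

  # no variants at all: everything conserved
  e1 <- make_callset("a"); e2 <- make_callset("b")
  cnt0 <- suppressWarnings(count_window(win, list(e1, e2), 1e6))
  expect_equal(unname(cnt0), c(100000, 0, 100000))

  expect_error(count_window(win, list(), 1e6), "at least one species")
})

test_that("window counts match a position-by-position oracle", {
  set.seed(101)
  L <- 50000
  for (rep in 1:10) {
    panel <- lapply(1:3, function(i) {
      mask <- random_granges(20, max_pos = L)
      het <- data.frame(contig = "chr1", pos = sample.int(L, 80))
      hom <- data.frame(contig = "chr1", pos = sample.int(L, 40))
      make_callset(paste0("sp", i), het = het, hom = hom, mask = mask)
    })
    s <- sample.int(L - 10000, 1)
    win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + 9999))
    got <- count_window(win, panel, L, toy_params)
    want <- brute_count("chr1", s, s + 9999, panel)
    expect_equal(got, want)
    expect_equal(unname(got["n_conserved"] + got["n_nonconserved"]),
                 unname(got["n_covered"]))
  }
})

test_that("chromosome background equals the whole contig as one window", {
  set.seed(5)
  L <- 30000
  panel <- lapply(1:2, function(i)
    make_callset(paste0("sp", i),
                 het = data.frame(contig = "chr1", pos = sample.int(L, 50)),
                 mask = random_granges(10, max_pos = L)))
  bg <- chrom_background("chr1", panel, L, toy_params)
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, L))
  expect_equal(bg, count_window(win, panel, L, toy_params))
  expect_equal(bg, brute_count("chr1", 1, L, panel))
})

test_that("identity mode breaks conservation on discordant homozygous alleles", {
  # pos 100: both HOM_ALT with the same allele  -> conserved in both modes
  # pos 200: HOM_ALT in one species only        -> identity mode only
  # pos 300: both HOM_ALT, different alleles    -> identity mode only
  a <- make_callset("a", hom = data.frame(contig = "chr1",
                                          pos = c(100, 200, 300)),
                    hom_alt = "T")
  b0 <- data.frame(contig = "chr1", pos = c(100, 300))
  b <- species_callset("b", data.frame(contig = "chr1", pos = c(100, 300),
                                       zygosity = "HOM_ALT",
                                       var_class = "SNV",
                                       alt = c("T", "G")))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  zy <- suppressWarnings(count_window(win, list(a, b), 1000, toy_params))
  expect_equal(unname(zy["n_nonconserved"]), 0)
  idp <- scan_params(bin_size = 10000, step_size = 1000, mode = "identity")
  id <- suppressWarnings(count_window(win, list(a, b), 1000, idp))
  expect_equal(unname(id["n_nonconserved"]), 2)
})

test_that("heterozygous indels count only when requested", {
  a <- species_callset("a", data.frame(
    contig = "chr1", pos = c(10, 20), zygosity = "HET",
    var_class = c("SNV", "INDEL"), alt = c("T", "TA")))
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  snv_only <- suppressWarnings(count_window(win, list(a), 1000, toy_params))
  expect_equal(unname(snv_only["n_nonconserved"]), 1)
  with_ind <- scan_params(bin_size = 10000, step_size = 1000,
                          include_indels = TRUE)
  both <- suppressWarnings(count_window(win, list(a), 1000, with_ind))
  expect_equal(unname(both["n_nonconserved"]), 2)
})

test_that("exact test matches enumeration and handles degenerate margins", {
  expect_equal(fisher_exact_2x2(5, 5, 50, 50), 1.0)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1.0)
  expect_equal(fisher_exact_2x2(3, 0, 5, 0), 1.0)  # zero column margin
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "non-negative")

  set.seed(21)
  for (rep in 1:200) {
    t <- rpois(4, 12)
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 fisher_enum_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
  }
})

test_that("exact test agrees with stats::fisher.test", {
  set.seed(22)
  a <- rpois(300, 25); b <- rpois(300, 8)
  c <- rpois(300, 40); d <- rpois(300, 30)
  mine <- fisher_exact_2x2(a, b, c, d)
  ref <- mapply(function(a, b, c, d)
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
    a, b, c, d)
  expect_equal(mine, unname(ref), tolerance = 1e-10)
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")

  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted-p order
  }
})

test_that("usable windows require strictly more than the coverage fraction", {
  # mask covering exactly 80% of each window -> excluded (strict >)
  L <- 20000
  p <- scan_params(bin_size = 10000, step_size = 10000,
                   coverage_fraction = 0.8)
  mask80 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1, 10001), end = c(8000, 18000)))
  cs <- make_callset("a", het = data.frame(contig = "chr1", pos = 5),
                     mask = mask80)
  contigs <- data.frame(contig = "chr1", length = L, is_autosome = TRUE)
  ws <- scan_family(list(a = cs), contigs, p)
  expect_equal(ws$n_covered, c(8000, 8000))
  expect_false(any(ws$usable))

  mask81 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 8001))
  cs2 <- make_callset("a", het = data.frame(contig = "chr1", pos = 5),
                      mask = mask81)
  ws2 <- scan_family(list(a = cs2), contigs, p)
  expect_equal(ws2$usable, c(TRUE, FALSE))
})

test_that("HCR calling extracts merged middle tiles on the step grid", {
  p <- scan_params()
  base <- data.frame(contig = "chr1", start = c(0, 10000, 500000),
                     end = c(100000, 110000, 600000),
                     n_conserved = 99000, n_nonconserved = 10,
                     n_covered = 99010, usable = TRUE,
                     bg_conserved = 1e6, bg_nonconserved = 1e4,
                     p_raw = 1e-10, p_adj = c(1e-8, 1e-8, 0.5),
                     stringsAsFactors = FALSE)
  hcr <- call_hcrs(base, p)
  # two adjacent called windows -> one merged [45000, 65000); third not called
  expect_equal(length(hcr$intervals), 1L)
  expect_equal(IRanges::start(hcr$intervals), 45001)
  expect_equal(IRanges::end(hcr$intervals), 65000)
  expect_equal(hcr$total_length, 20000)
  expect_equal(hcr$unmerged_length, 20000)
  expect_true(hcr$total_length %% p$step_size == 0)

  # single called window -> exactly the middle 10 kb
  one <- base[1, ]
  h1 <- call_hcrs(one, p)
  expect_equal(IRanges::start(h1$intervals), 45001)
  expect_equal(IRanges::end(h1$intervals), 55000)
  expect_equal(h1$total_length, 10000)

  # order invariance
  shuf <- base[c(3, 1, 2), ]
  expect_equal(call_hcrs(shuf, p)$total_length, hcr$total_length)

  # nothing called -> empty set
  none <- base; none$p_adj <- 0.9
  h0 <- call_hcrs(none, p)
  expect_equal(length(h0$intervals), 0L)
  expect_equal(h0$total_length, 0)
})

test_that("the direction filter blocks windows with elevated variation", {
  p <- scan_params()
  up <- data.frame(contig = "chr1", start = 0, end = 100000,
                   n_conserved = 90000, n_nonconserved = 9010,
                   n_covered = 99010, usable = TRUE,
                   bg_conserved = 1e7, bg_nonconserved = 1e4,
                   p_raw = 1e-30, p_adj = 1e-28, stringsAsFactors = FALSE)
  expect_equal(call_hcrs(up, p)$total_length, 0)
  relaxed <- scan_params(require_reduced = FALSE)
  expect_equal(call_hcrs(up, relaxed)$total_length, 10000)
})

test_that("gene-HCR overlap uses half-open boundaries and partitions by family", {
  mk_hcr <- function(s, e) {
    structure(list(intervals = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(s + 1, e)), total_length = e - s),
      class = "hcr_set")
  }
  mk_genes <- function(keys, starts, ends) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts + 1, ends))
    S4Vectors::mcols(gr)$gene_id <- paste0("id_", keys)
    S4Vectors::mcols(gr)$gene_key <- keys
    gr
  }
  # gene [50000,60000) overlaps HCR [45000,55000); gene [55000,60000) does not
  hcr <- list(fam = mk_hcr(45000, 55000))
  genes <- list(fam = mk_genes(c("A", "B"), c(50000, 55000), c(60000, 60000)))
  res <- genes_in_regions(hcr, genes)
  expect_equal(res$per_family$fam, "A")

  # three families, hand-enumerated Venn partition
  h <- list(f1 = mk_hcr(0, 1000), f2 = mk_hcr(0, 1000), f3 = mk_hcr(0, 1000))
  g <- list(
    f1 = mk_genes(c("u", "v", "w", "x"), c(0, 100, 200, 5000),
                  c(50, 150, 250, 6000)),
    f2 = mk_genes(c("u", "v", "y"), c(0, 100, 300), c(50, 150, 350)),
    f3 = mk_genes(c("u", "z"), c(0, 400), c(50, 450)))
  r <- genes_in_regions(h, g)
  expect_equal(r$shared, "u")
  expect_equal(sort(r$per_family$f1), c("u", "v", "w"))  # x outside HCR
  expect_equal(r$specific$f1, "w")
  expect_equal(r$specific$f2, "y")
  expect_equal(r$specific$f3, "z")

  # genes without a key are excluded with a logged count
  g$f3 <- mk_genes(c("u", NA), c(0, 400), c(50, 450))
  expect_message(r2 <- genes_in_regions(h, g), "without gene_key")
})

test_that("scan_family warns on contigs without joint coverage", {
  cs1 <- make_callset("a", mask = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 100000)))
  cs2 <- make_callset("b", mask = GenomicRanges::GRanges(
    "chr2", IRanges::IRanges(1, 100000)))
  contigs <- data.frame(contig = "chr1", length = 100000, is_autosome = TRUE)
  expect_warning(ws <- scan_family(list(a = cs1, b = cs2), contigs),
                 "no jointly covered")
  expect_false(any(ws$usable))
  expect_true(all(is.na(ws$p_adj)))
})
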