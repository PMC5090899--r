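test_that("the panel generator is a pure function of its seed", {
  p <- sim_panel_params(n_species = 2, contig_lengths = c(chr1 = 2e5),
                        seed = 13)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_panel(p, dir = d1)
  simulate_panel(p, dir = d2)
  for (f in c("sp01.vcf", "sp02.vcf", "sp01.mask.bed", "contigs.fai",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("full suppression silences heterozygosity inside planted intervals", {
  pl <- data.frame(contig = "chr1", start = 50000, end = 100000, f = 0)
  p <- sim_panel_params(n_species = 3, contig_lengths = c(chr1 = 2e5),
                        het_rate = 0.01, planted = pl, seed = 7)
  pan <- simulate_panel(p)
  for (cs in pan$species) {
    v <- cs$variants
    het_in <- v$zygosity == "HET" & v$pos > 50000 & v$pos <= 100000
    expect_equal(sum(het_in), 0L)
    # homozygous calls are not suppressed
    hom_in <- v$zygosity == "HOM_ALT" & v$pos > 50000 & v$pos <= 100000
    expect_gt(sum(hom_in), 0L)
  }
})

test_that("heterozygous call counts follow the binomial model", {
  L <- 2e6; h <- 0.002
  p <- sim_panel_params(n_species = 1, contig_lengths = c(chr1 = L),
                        het_rate = h, hom_rate = 0.005, seed = 19)
  pan <- simulate_panel(p)
  n_het <- sum(pan$species[[1]]$variants$zygosity == "HET")
  expect_lt(abs(n_het - L * h), 4 * sqrt(L * h * (1 - h)))
})

test_that("simulated files parse back through the package readers", {
  pl <- data.frame(contig = "chr1", start = 20000, end = 60000, f = 0.1)
  p <- sim_panel_params(n_species = 2,
                        contig_lengths = c(chr1 = 1e5, chr2 = 5e4),
                        het_rate = 0.01, hom_rate = 0.01, planted = pl,
                        mask_dropout = 0.1, mask_block = 5000, seed = 3)
  d <- file.path(tempdir(), "simRT")
  pan <- simulate_panel(p, dir = d)

  ct <- read_contig_table(pan$files$fai)
  expect_equal(ct$contig, c("chr1", "chr2"))
  expect_equal(ct$length, c(1e5, 5e4))

  for (s in names(pan$species)) {
    back <- read_variants(pan$files$vcf[[s]], s,
                          mask = read_mask(pan$files$mask[[s]]))
    expect_equal(back$variants$pos, pan$species[[s]]$variants$pos)
    expect_equal(back$variants$zygosity, pan$species[[s]]$variants$zygosity)
    expect_equal(back$variants$alt, pan$species[[s]]$variants$alt)
    expect_true(all(back$mask == pan$species[[s]]$mask))
  }
  truth_back <- read_mask(pan$files$truth_bed)
  expect_true(all(truth_back == pan$truth))
  unlink(d, recursive = TRUE)
})

test_that("rate bounds are validated", {
  expect_error(sim_panel_params(het_rate = 0.6, hom_rate = 0.5), "< 1")
  expect_error(sim_panel_params(planted = data.frame(
    contig = "chr1", start = 0, end = 3e7, f = 0.1)), "within")
  expect_error(sim_panel_params(planted = data.frame(
    contig = "chr1", start = 0, end = 100, f = 1)), "f must be")
})

test_that("recovery scoring matches a per-base oracle", {
  gr <- function(s, e) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(s, e))
  expect_equal(score_recovery(gr(1, 100), gr(1, 100)),
               c(sensitivity = 1, precision = 1))
  expect_equal(score_recovery(gr(200, 300), gr(1, 100)),
               c(sensitivity = 0, precision = 0))
  expect_true(is.na(score_recovery(GenomicRanges::GRanges(),
                                   gr(1, 100))["precision"]))

  set.seed(41)
  for (rep in 1:10) {
    called <- random_granges(8, max_pos = 5000)
    truth <- random_granges(8, max_pos = 5000)
    got <- score_recovery(called, truth)
    base_called <- unique(unlist(mapply(seq, IRanges::start(called),
                                        IRanges::end(called),
                                        SIMPLIFY = FALSE)))
    base_truth <- unique(unlist(mapply(seq, IRanges::start(truth),
                                       IRanges::end(truth),
                                       SIMPLIFY = FALSE)))
    inter <- length(intersect(base_called, base_truth))
    expect_equal(unname(got["sensitivity"]), inter / length(base_truth))
    expect_equal(unname(got["precision"]), inter / length(base_called))
  }
})

test_that("protein panels plant exactly the recorded truth", {
  groups <- list(carnivore = paste0("c", 1:4), herbivore = paste0("h", 1:3))
  bg <- paste0("o", 1:5)
  pp <- simulate_protein_panel(groups, bg, n_genes = 20, aln_length = 120,
                               n_specific_per_group = 4, n_convergent = 3,
                               n_fa_genes_per_group = 3, noise = 0,
                               seed = 31)
  # noise-free: classifier output equals planted truth exactly per group
  all_sp <- c(unlist(groups), bg)
  for (grp in names(groups)) {
    got <- do.call(rbind, lapply(pp$alignments, function(a)
      group_specific_aacs(a, groups[[grp]], setdiff(all_sp, groups[[grp]]))))
    # truth$specific includes the columns planted for function-altered
    # genes, which are group-specific by construction; convergent columns
    # span both groups and are group-specific for neither
    want <- pp$truth$specific[pp$truth$specific$group == grp, ]
    expect_setequal(paste(got$gene_id, got$column, got$target_residue),
                    paste(want$gene_id, want$column, want$residue))
  }
  conv <- do.call(rbind, lapply(pp$alignments, function(a)
    convergent_aacs(a, unname(groups), bg)))
  expect_setequal(paste(conv$gene_id, conv$column),
                  paste(pp$truth$convergent$gene_id,
                        pp$truth$convergent$column))
  # function-altered genes recovered exactly from the flag table
  for (grp in names(groups)) {
    got_fa <- function_altered_genes(pp$flags, groups[[grp]],
                                     setdiff(all_sp, groups[[grp]]))
    expect_setequal(got_fa,
                    pp$truth$fa_genes$gene_id[pp$truth$fa_genes$group == grp])
  }
})

test_that("protein panel files round-trip and reruns are identical", {
  groups <- list(g1 = c("a1", "a2"))
  d <- file.path(tempdir(), "prot1")
  pp <- simulate_protein_panel(groups, c("b1", "b2"), n_genes = 5,
                               aln_length = 60, n_specific_per_group = 2,
                               n_convergent = 0, n_fa_genes_per_group = 1,
                               seed = 8, dir = d)
  aln <- read_protein_alignment(pp$files$fasta[["g001"]])
  expect_equal(unname(aln$seqs), unname(pp$alignments$g001$seqs))
  fl <- read_aac_flags(pp$files$flags)
  expect_equal(fl$function_altering,
               pp$flags$function_altering[order(pp$flags$gene_id,
                                                pp$flags$column,
                                                pp$flags$species_id)])
  d2 <- file.path(tempdir(), "prot2")
  simulate_protein_panel(groups, c("b1", "b2"), n_genes = 5,
                         aln_length = 60, n_specific_per_group = 2,
                         n_convergent = 0, n_fa_genes_per_group = 1,
                         seed = 8, dir = d2)
  expect_identical(readLines(file.path(d, "g003.faa")),
                   readLines(file.path(d2, "g003.faa")))
  unlink(c(d, d2), recursive = TRUE)
})
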