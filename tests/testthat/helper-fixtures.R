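# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written with per-position / per-table loops,
# independent of the interval and hypergeometric machinery they check.

write_vcf_fixture <- function(body, samples = "spA",
                              contigs = c(chr1 = 1000000)) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

write_bed_fixture <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# quick in-memory callset: het/hom are data.frames with contig, pos (1-based)
make_callset <- function(id, het = NULL, hom = NULL, mask = NULL,
                         het_alt = "T", hom_alt = "T",
                         het_class = "SNV", hom_class = "SNV") {
  rows <- list()
  if (!is.null(het) && nrow(het))
    rows[[1]] <- data.frame(contig = het$contig, pos = het$pos,
                            zygosity = "HET", var_class = het_class,
                            alt = het_alt, stringsAsFactors = FALSE)
  if (!is.null(hom) && nrow(hom))
    rows[[2]] <- data.frame(contig = hom$contig, pos = hom$pos,
                            zygosity = "HOM_ALT", var_class = hom_class,
                            alt = hom_alt, stringsAsFactors = FALSE)
  v <- if (length(rows)) do.call(rbind, rows)
  else data.frame(contig = character(), pos = numeric(),
                  zygosity = character(), var_class = character(),
                  alt = character(), stringsAsFactors = FALSE)
  species_callset(id, v, mask = mask)
}

# position-by-position window counting oracle (1-based closed window)
brute_count <- function(contig, first, last, panel,
                        include_indels = FALSE) {
  pos <- first:last
  covered <- rep(TRUE, length(pos))
  for (cs in panel) {
    if (is.null(cs$mask)) next
    m <- cs$mask[as.character(GenomicRanges::seqnames(cs$mask)) == contig]
    inm <- rep(FALSE, length(pos))
    for (i in seq_along(m))
      inm <- inm | (pos >= IRanges::start(m)[i] & pos <= IRanges::end(m)[i])
    covered <- covered & inm
  }
  noncons <- rep(FALSE, length(pos))
  for (cs in panel) {
    v <- cs$variants
    keep <- v$contig == contig & v$zygosity == "HET" &
      (include_indels | v$var_class == "SNV")
    noncons <- noncons | (pos %in% v$pos[keep])
  }
  nn <- sum(covered & noncons)
  c(n_conserved = sum(covered) - nn, n_nonconserved = nn,
    n_covered = sum(covered))
}

# direct step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided Fisher oracle: full hypergeometric enumeration via lchoose
fisher_enum_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  as <- max(0, k - n2):min(k, n1)
  pr <- exp(lchoose(n1, as) + lchoose(n2, k - as) - lchoose(n1 + n2, k))
  pobs <- pr[as == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# per-column amino-acid classifier oracle (explicit loops)
aac_column_check <- function(col_res, targets, backgrounds) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  involved <- c(targets, backgrounds)
  for (sp in involved) if (!col_res[[sp]] %in% std) return(NA_character_)
  r <- col_res[[targets[1]]]
  for (sp in targets) if (col_res[[sp]] != r) return(NA_character_)
  for (sp in backgrounds) if (col_res[[sp]] == r) return(NA_character_)
  r
}

random_granges <- function(n, contig = "chr1", max_pos = 100000) {
  s <- sample.int(max_pos - 100, n)
  w <- sample.int(500, n)
  GenomicRanges::reduce(GenomicRanges::sort(
    GenomicRanges::GRanges(contig, IRanges::IRanges(start = s, width = w))))
}
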