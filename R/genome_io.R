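#' Read a contig length table (.fai dialect)
#'
#' Parses a whitespace/tab-separated table whose first two columns are
#' contig name and contig length (the layout of a `samtools faidx` .fai
#' file; extra columns are ignored). Autosome status is assigned from a
#' name pattern so that downstream scans can restrict themselves to
#' autosomes.
#'
#' @param path Path to the table.
#' @param autosome_exclude Perl-compatible regular expression; contigs whose
#'   name matches are flagged as non-autosomes. The default excludes sex
#'   chromosomes and mitochondrial contigs (`X`, `Y`, `M`, `MT`, with or
#'   without a `chr` prefix, case-insensitive).
#' @return A `data.frame` with columns `contig` (character), `length`
#'   (numeric bp), and `is_autosome` (logical).
#' @examples
#' fai <- tempfile(fileext = ".fai")
#' writeLines(c("chr1\t1000000", "chrX\t500000"), fai)
#' read_contig_table(fai)
#' @export
read_contig_table <- function(path, autosome_exclude = "(?i)^(chr)?(x|y|m|mt)$") {
  if (!file.exists(path)) stop("contig table not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "", colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("contig table must have at least two columns (name, length)")
  name <- tab[[1L]]
  len_chr <- tab[[2L]]
  if (!all(grepl("^[0-9]+$", len_chr)))
    stop("contig table format error: non-integer length for contig(s) ",
         paste(name[!grepl("^[0-9]+$", len_chr)], collapse = ", "))
  len <- as.numeric(len_chr)
  if (any(len <= 0)) stop("contig table format error: lengths must be > 0")
  if (anyDuplicated(name))
    stop("contig table format error: duplicate contig name(s) ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  data.frame(contig = name, length = len,
             is_autosome = !grepl(autosome_exclude, name, perl = TRUE),
             stringsAsFactors = FALSE)
}

#' Construct a per-species call set
#'
#' Container for one species' variant calls against the family reference
#' plus its callable-region mask. Usually produced by [read_variants()];
#' exposed so that call sets can also be built programmatically (e.g. by
#' the simulator or in tests).
#'
#' @param species_id Species identifier.
#' @param variants `data.frame` with columns `contig` (character), `pos`
#'   (1-based position, numeric), `zygosity` (`"HET"` or `"HOM_ALT"`),
#'   `var_class` (`"SNV"` or `"INDEL"`), and `alt` (character allele; used
#'   only by the identity conservation mode).
#' @param mask `GRanges` of callable intervals, or `NULL` meaning the whole
#'   genome is callable (a warning is emitted downstream when no mask is
#'   supplied).
#' @param n_skipped Number of input records skipped (e.g. missing genotype).
#' @return An object of class `species_callset`.
#' @export
species_callset <- function(species_id, variants, mask = NULL, n_skipped = 0L) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  need <- c("contig", "pos", "zygosity", "var_class")
  if (!all(need %in% names(variants)))
    stop("variants must have columns ", paste(need, collapse = ", "))
  if (!"alt" %in% names(variants)) variants$alt <- NA_character_
  bad <- setdiff(unique(variants$zygosity), c("HET", "HOM_ALT"))
  if (length(bad)) stop("invalid zygosity value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(variants$var_class), c("SNV", "INDEL"))
  if (length(bad)) stop("invalid var_class value(s): ", paste(bad, collapse = ", "))
  if (nrow(variants) && any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (!is.null(mask)) {
    if (!methods::is(mask, "GRanges")) stop("mask must be a GRanges or NULL")
    mask <- GenomicRanges::reduce(GenomicRanges::sort(mask))
  }
  structure(list(species_id = species_id,
                 variants = variants[order(variants$contig, variants$pos), ,
                                     drop = FALSE],
                 mask = mask,
                 n_skipped = as.integer(n_skipped)),
            class = "species_callset")
}

#' @export
print.species_callset <- function(x, ...) {
  cat("<species_callset> ", x$species_id, "\n", sep = "")
  cat("  variants: ", nrow(x$variants),
      " (", sum(x$variants$zygosity == "HET"), " HET, ",
      sum(x$variants$zygosity == "HOM_ALT"), " HOM_ALT; ",
      sum(x$variants$var_class == "INDEL"), " indel)\n", sep = "")
  if (is.null(x$mask)) cat("  mask: none (whole genome callable)\n")
  else cat("  mask: ", length(x$mask), " intervals, ",
           sum(IRanges::width(x$mask)), " bp\n", sep = "")
  if (x$n_skipped > 0) cat("  skipped records:", x$n_skipped, "\n")
  invisible(x)
}

#' Read variant calls for one sample from a VCF
#'
#' Extracts all non-reference genotypes for `sample` and normalizes them to
#' the internal representation: a genotype with two different called
#' alleles is `HET` (whatever the alleles), two identical non-reference
#' alleles are `HOM_ALT`, and a record is an `INDEL` when any allele
#' involved in the genotype has length other than 1. Homozygous-reference
#' genotypes carry no variant and are dropped; missing genotypes (`./.`)
#' are skipped and counted (coverage is governed by the callable mask, not
#' by the VCF).
#'
#' @param path Path to a VCF (v4.x) file.
#' @param sample Sample name; must be present in the VCF.
#' @param mask Optional `GRanges` callable mask to attach (see
#'   [read_mask()]).
#' @param species_id Species identifier for the returned call set; defaults
#'   to the VCF sample name.
#' @return A [species_callset()] whose `species_id` is `species_id`.
#' @export
read_variants <- function(path, sample, mask = NULL, species_id = sample) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(vcf@fix)
  empty <- data.frame(contig = character(), pos = numeric(),
                      zygosity = character(), var_class = character(),
                      alt = character(), stringsAsFactors = FALSE)
  if (n == 0L) {
    samples <- colnames(vcf@gt)[-1L]
    if (!sample %in% samples && length(samples))
      stop("sample '", sample, "' not found in ", path)
    return(species_callset(species_id, empty, mask = mask))
  }
  samples <- colnames(vcf@gt)[-1L]
  if (!sample %in% samples)
    stop("sample '", sample, "' not found in ", path,
         " (samples: ", paste(samples, collapse = ", "), ")")
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]

  n_skipped <- sum(is.na(gt) | gt %in% c(".", "./.", ".|."))
  keep <- !is.na(gt) & !gt %in% c(".", "./.", ".|.")
  if (!any(keep))
    return(species_callset(species_id, empty, mask = mask,
                           n_skipped = n_skipped))

  chrom <- fix[keep, "CHROM"]
  pos <- as.numeric(fix[keep, "POS"])
  ref <- fix[keep, "REF"]
  alt_field <- fix[keep, "ALT"]
  gtk <- gt[keep]

  parts <- strsplit(gtk, "[/|]", perl = TRUE)
  alt_list <- strsplit(ifelse(is.na(alt_field), "", alt_field), ",", fixed = TRUE)

  res <- vector("list", length(gtk))
  for (i in seq_along(gtk)) {
    idx <- suppressWarnings(as.integer(parts[[i]]))
    idx <- idx[!is.na(idx)]
    if (!length(idx) || all(idx == 0L)) next
    alleles <- c(ref[i], alt_list[[i]])
    if (max(idx) + 1L > length(alleles)) next  # malformed ALT index
    called <- alleles[idx + 1L]
    zyg <- if (length(unique(idx)) > 1L) "HET" else "HOM_ALT"
    cls <- if (any(nchar(called) != 1L)) "INDEL" else "SNV"
    alt_allele <- called[idx > 0L][1L]
    res[[i]] <- c(chrom[i], pos[i], zyg, cls, alt_allele)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(species_callset(species_id, empty, mask = mask,
                           n_skipped = n_skipped))
  m <- do.call(rbind, res)
  variants <- data.frame(contig = m[, 1L], pos = as.numeric(m[, 2L]),
                         zygosity = m[, 3L], var_class = m[, 4L],
                         alt = m[, 5L], stringsAsFactors = FALSE)
  if (n_skipped > 0)
    message(sample, ": skipped ", n_skipped, " record(s) with missing genotype")
  species_callset(species_id, variants, mask = mask, n_skipped = n_skipped)
}

#' Read a callable-region mask (BED3)
#'
#' Reads a 3-column BED file (0-based half-open on disk) and returns the
#' intervals sorted and merged per contig as a 1-based `GRanges`.
#' Normalization is idempotent: re-reading a written mask reproduces it
#' exactly.
#'
#' @param path Path to a BED3 file. An empty file yields an empty mask.
#' @return A `GRanges` of non-overlapping, sorted callable intervals.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    return(GenomicRanges::GRanges())
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED format error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (any(IRanges::width(gr) <= 0L))
    stop("BED format error in ", path, ": interval with start >= end")
  GenomicRanges::reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                        ignore.strand = TRUE)
}

#' Write intervals to a BED3 file
#'
#' Writes a `GRanges` as plain 3-column BED (0-based half-open).
#' `read_mask(write_intervals(x, f))` reproduces `x` for any normalized
#' (sorted, merged) input.
#'
#' @param intervals A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(methods::is(intervals, "GRanges"))
  lines <- sprintf("%s\t%.0f\t%.0f",
                   as.character(GenomicRanges::seqnames(intervals)),
                   IRanges::start(intervals) - 1,
                   IRanges::end(intervals))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Read a gene table
#'
#' Reads a tab-separated gene table with header columns `gene_id`,
#' `contig`, `start`, `end` (coordinates 0-based half-open, BED-like) and
#' an optional `gene_key` column holding a cross-family gene symbol used
#' when intersecting gene sets between families mapped to different
#' references.
#'
#' @param path Path to the TSV.
#' @return A `GRanges` with metadata columns `gene_id` and `gene_key`
#'   (`gene_key` is `NA` when absent from the file).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("gene_id", "contig", "start", "end")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("gene table format error: duplicate gene_id")
  if (nrow(tab) && any(tab$start >= tab$end))
    stop("gene table format error: start >= end")
  gr <- GenomicRanges::GRanges(tab$contig,
                               IRanges::IRanges(start = tab$start + 1,
                                                end = tab$end))
  mcols(gr)$gene_id <- tab$gene_id
  mcols(gr)$gene_key <- if ("gene_key" %in% names(tab)) tab$gene_key
                        else NA_character_
  gr
}
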