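#' Parameters for the multi-species variant panel simulator
#'
#' Defines the generative model behind the conservation scan's test data:
#' at every site of every contig each species independently draws a
#' heterozygous SNV with rate `het_rate` (multiplied by the suppression
#' factor `f` inside planted intervals, jointly for all species) and a
#' homozygous-alternate SNV with rate `hom_rate`; callable masks drop
#' `mask_block`-sized blocks independently per species at rate
#' `mask_dropout`. Sites are independent (no linkage): the scan statistic
#' consumes only per-position zygosity.
#'
#' @param n_species Number of species in the panel.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param het_rate Per-site heterozygous SNV rate (default 0.002, the
#'   order of magnitude seen in within-family resequencing panels).
#' @param hom_rate Per-site homozygous-alternate SNV rate (default 0.005).
#' @param planted `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open) and `f` (suppression factor in `[0, 1)`): inside
#'   these intervals every species' heterozygosity rate is `het_rate * f`.
#'   `NULL` for no planted regions.
#' @param mask_dropout Fraction of mask blocks dropped per species
#'   (default 0.02).
#' @param mask_block Mask block granularity in bp (default 10,000).
#' @param seed Integer seed; the generator is a pure function of seed and
#'   parameters (byte-identical reruns).
#' @return An object of class `sim_panel_params`.
#' @export
sim_panel_params <- function(n_species = 5,
                             contig_lengths = c(chr1 = 2e7),
                             het_rate = 0.002, hom_rate = 0.005,
                             planted = NULL,
                             mask_dropout = 0.02, mask_block = 1e4,
                             seed = 1L) {
  stopifnot(n_species >= 1, all(contig_lengths > 0),
            !is.null(names(contig_lengths)),
            het_rate >= 0, het_rate < 1, hom_rate >= 0, hom_rate < 1,
            mask_dropout >= 0, mask_dropout < 1, mask_block > 0)
  if (het_rate + hom_rate >= 1)
    stop("het_rate + hom_rate must be < 1 (per-site rates)")
  if (!is.null(planted)) {
    need <- c("contig", "start", "end", "f")
    if (!all(need %in% names(planted)))
      stop("planted must have columns ", paste(need, collapse = ", "))
    if (any(!planted$contig %in% names(contig_lengths)))
      stop("planted interval on unknown contig")
    if (any(planted$start < 0) || any(planted$end > contig_lengths[planted$contig]))
      stop("planted intervals must lie within their contig")
    if (any(planted$f < 0 | planted$f >= 1))
      stop("suppression factor f must be in [0, 1)")
  }
  structure(list(n_species = n_species, contig_lengths = contig_lengths,
                 het_rate = het_rate, hom_rate = hom_rate, planted = planted,
                 mask_dropout = mask_dropout, mask_block = mask_block,
                 seed = as.integer(seed)),
            class = "sim_panel_params")
}

# split [1, L] (1-based closed) into segments carrying their own het rate
.segments_for <- function(contig, L, planted, het_rate) {
  if (is.null(planted)) pl <- NULL
  else pl <- planted[planted$contig == contig, , drop = FALSE]
  if (is.null(pl) || !nrow(pl)) {
    return(data.frame(start = 1, end = L, het = het_rate))
  }
  pl <- pl[order(pl$start), , drop = FALSE]
  segs <- list(); cur <- 1
  for (i in seq_len(nrow(pl))) {
    s <- pl$start[i] + 1; e <- pl$end[i]
    if (s > cur) segs[[length(segs) + 1L]] <-
      data.frame(start = cur, end = s - 1, het = het_rate)
    segs[[length(segs) + 1L]] <-
      data.frame(start = s, end = e, het = het_rate * pl$f[i])
    cur <- e + 1
  }
  if (cur <= L) segs[[length(segs) + 1L]] <-
    data.frame(start = cur, end = L, het = het_rate)
  do.call(rbind, segs)
}

.write_sim_vcf <- function(variants, contig_lengths, sample_id, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=famcons_simulate",
           sprintf("##contig=<ID=%s,length=%.0f>", names(contig_lengths),
                   contig_lengths),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  gt <- ifelse(variants$zygosity == "HET", "0/1", "1/1")
  body <- sprintf("%s\t%.0f\t.\tA\t%s\t.\tPASS\t.\tGT\t%s",
                  variants$contig, variants$pos, variants$alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.write_fai <- function(contig_lengths, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f\t60\t61", names(contig_lengths),
                     contig_lengths, cumsum(c(0, contig_lengths[-length(contig_lengths)]))),
             path)
  invisible(path)
}

#' Simulate a multi-species variant panel with planted conserved regions
#'
#' Draws per-species heterozygous and homozygous-alternate SNVs site-wise
#' (see [sim_panel_params()]), suppressing heterozygosity jointly in all
#' species inside planted intervals, and generates per-species callable
#' masks with random block dropout. Optionally writes the panel as one VCF
#' and one BED mask per species plus a contig `.fai`, a truth BED, and a
#' truth JSON, all of which parse back through the package's readers.
#'
#' @param params A [sim_panel_params()] object.
#' @param dir Output directory (created if needed), or `NULL` to keep the
#'   panel in memory only.
#' @return An object of class `sim_panel`: list with `species` (named list
#'   of [species_callset()]), `contigs` (contig table), `truth` (`GRanges`
#'   of planted intervals), `params`, and `files` (named paths, or `NULL`).
#' @export
simulate_panel <- function(params, dir = NULL) {
  stopifnot(inherits(params, "sim_panel_params"))
  set.seed(params$seed)
  cl <- params$contig_lengths
  sp_ids <- sprintf("sp%02d", seq_len(params$n_species))
  species <- vector("list", params$n_species)
  names(species) <- sp_ids

  for (s in seq_along(sp_ids)) {
    vlist <- list()
    mask_list <- list()
    for (ci in seq_along(cl)) {
      contig <- names(cl)[ci]; L <- cl[[ci]]
      segs <- .segments_for(contig, L, params$planted, params$het_rate)
      for (k in seq_len(nrow(segs))) {
        len <- segs$end[k] - segs$start[k] + 1
        tot <- segs$het[k] + params$hom_rate
        if (tot <= 0 || len <= 0) next
        nv <- stats::rbinom(1L, size = len, prob = tot)
        if (nv == 0L) next
        pos <- sort(sample.int(len, nv)) + segs$start[k] - 1
        is_het <- stats::runif(nv) < segs$het[k] / tot
        alt <- sample(c("C", "G", "T"), nv, replace = TRUE)
        vlist[[length(vlist) + 1L]] <- data.frame(
          contig = contig, pos = pos,
          zygosity = ifelse(is_het, "HET", "HOM_ALT"),
          var_class = "SNV", alt = alt, stringsAsFactors = FALSE)
      }
      # mask: drop blocks independently
      starts <- seq(1, L, by = params$mask_block)
      ends <- pmin(starts + params$mask_block - 1, L)
      keep <- stats::runif(length(starts)) >= params$mask_dropout
      if (any(keep))
        mask_list[[length(mask_list) + 1L]] <- data.frame(
          contig = contig, start = starts[keep], end = ends[keep])
    }
    variants <- if (length(vlist)) do.call(rbind, vlist)
      else data.frame(contig = character(), pos = numeric(),
                      zygosity = character(), var_class = character(),
                      alt = character(), stringsAsFactors = FALSE)
    mask <- if (length(mask_list)) {
      md <- do.call(rbind, mask_list)
      GenomicRanges::reduce(GenomicRanges::sort(GenomicRanges::GRanges(
        md$contig, IRanges::IRanges(start = md$start, end = md$end))))
    } else GenomicRanges::GRanges()
    species[[s]] <- species_callset(sp_ids[s], variants, mask = mask)
  }

  contigs <- data.frame(contig = names(cl), length = as.numeric(cl),
                        is_autosome = TRUE, stringsAsFactors = FALSE)
  truth <- if (!is.null(params$planted) && nrow(params$planted))
    GenomicRanges::reduce(GenomicRanges::sort(GenomicRanges::GRanges(
      params$planted$contig,
      IRanges::IRanges(start = params$planted$start + 1,
                       end = params$planted$end))))
  else GenomicRanges::GRanges()

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(fai = file.path(dir, "contigs.fai"),
                  truth_bed = file.path(dir, "truth.bed"),
                  truth_json = file.path(dir, "truth.json"),
                  vcf = setNames(file.path(dir, paste0(sp_ids, ".vcf")), sp_ids),
                  mask = setNames(file.path(dir, paste0(sp_ids, ".mask.bed")),
                                  sp_ids))
    .write_fai(cl, files$fai)
    write_intervals(truth, files$truth_bed)
    jsonlite::write_json(
      list(seed = params$seed, n_species = params$n_species,
           contig_lengths = as.list(cl), het_rate = params$het_rate,
           hom_rate = params$hom_rate, mask_dropout = params$mask_dropout,
           mask_block = params$mask_block,
           planted = if (is.null(params$planted)) list() else params$planted),
      files$truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (s in sp_ids) {
      .write_sim_vcf(species[[s]]$variants, cl, s, files$vcf[[s]])
      write_intervals(species[[s]]$mask, files$mask[[s]])
    }
  }
  structure(list(species = species, contigs = contigs, truth = truth,
                 params = params, files = files),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("<sim_panel> ", length(x$species), " species, ",
      nrow(x$contigs), " contig(s), ",
      format(sum(x$contigs$length), big.mark = ","), " bp; ",
      length(x$truth), " planted interval(s)\n", sep = "")
  invisible(x)
}

#' Simulate protein alignments with planted diagnostic columns
#'
#' Generates per-gene protein alignments in which every species shares an
#' ancestral residue per column, perturbed by independent per-species
#' substitution noise; plants group-specific columns (one residue unanimous
#' in a target group and absent from everyone else), convergent columns
#' (unanimous across several disjoint clades, absent elsewhere), and
#' function-altered genes (every group species flagged at a planted column,
#' no other-diet species flagged in the gene). Planted columns are kept
#' noise-free so the emitted truth is exact. Decoy function-altering flags
#' are scattered over non-planted genes but are prevented from completing
#' a full group pattern.
#'
#' @param target_groups Named list of character vectors: diet groups.
#' @param background_species Character vector of species in no target
#'   group.
#' @param n_genes Number of genes (default 50).
#' @param aln_length Alignment length in residues (default 200).
#' @param n_specific_per_group Planted group-specific columns per group
#'   (default 5), each in a distinct random gene/column.
#' @param clades List of pairwise-disjoint species sets used for planted
#'   convergent columns; default: one clade per target group (convergence
#'   across all target groups).
#' @param n_convergent Planted convergent columns (default 5).
#' @param n_fa_genes_per_group Planted function-altered genes per group
#'   (default 5).
#' @param noise Per-species, per-column substitution rate away from the
#'   ancestral residue (default 0.01).
#' @param decoy_flag_rate Rate of decoy function-altering flags per
#'   (non-planted gene, species) (default 0.05).
#' @param seed Integer seed (pure function of seed + parameters).
#' @param dir Output directory for aligned FASTAs, `flags.tsv` and
#'   `truth.json`, or `NULL` for in-memory only.
#' @return An object of class `sim_protein_panel`: list with `alignments`
#'   (named list of [protein_alignment()]), `flags` (aggregated logical
#'   flag table), `flags_raw` (tool-level table), `truth` (list with
#'   `specific`, `convergent`, `fa_genes`), `species`, `params`, `files`.
#' @export
simulate_protein_panel <- function(target_groups, background_species,
                                   n_genes = 50, aln_length = 200,
                                   n_specific_per_group = 5,
                                   clades = NULL, n_convergent = 5,
                                   n_fa_genes_per_group = 5,
                                   noise = 0.01, decoy_flag_rate = 0.05,
                                   seed = 1L, dir = NULL) {
  stopifnot(length(target_groups) >= 1, !is.null(names(target_groups)),
            length(background_species) >= 1, aln_length >= 1, n_genes >= 1,
            noise >= 0, noise < 1)
  all_sp <- c(unlist(target_groups, use.names = FALSE), background_species)
  if (anyDuplicated(all_sp)) stop("species must belong to exactly one group")
  if (is.null(clades)) clades <- unname(target_groups)
  set.seed(as.integer(seed))
  genes <- sprintf("g%03d", seq_len(n_genes))
  aa <- .STANDARD_AA

  # residue matrices, initialised to the ancestral state
  anc <- replicate(n_genes, sample(aa, aln_length, replace = TRUE),
                   simplify = FALSE)
  mats <- lapply(anc, function(a)
    matrix(rep(a, each = length(all_sp)), nrow = length(all_sp),
           dimnames = list(all_sp, NULL)))
  names(mats) <- names(anc) <- genes

  # reserve planted (gene, column) slots without collisions
  n_groups <- length(target_groups)
  n_slots <- n_groups * n_specific_per_group + n_convergent +
    n_groups * n_fa_genes_per_group
  slot_gene <- sample(genes, n_slots, replace = TRUE)
  slot_col <- integer(n_slots)
  used <- setNames(vector("list", length(genes)), genes)
  for (i in seq_len(n_slots)) {
    g <- slot_gene[i]
    free <- setdiff(seq_len(aln_length), used[[g]])
    if (!length(free)) stop("alignment too short for the requested planting")
    slot_col[i] <- if (length(free) == 1L) free else sample(free, 1L)
    used[[g]] <- c(used[[g]], slot_col[i])
  }
  protected <- used  # planted columns stay noise-free

  plant <- function(gene, col, target_sp) {
    m <- mats[[gene]]
    r <- sample(setdiff(aa, m[, col]), 1L)
    m[target_sp, col] <- r
    mats[[gene]] <<- m
    r
  }

  idx <- 0L
  specific <- list()
  for (gi in seq_along(target_groups)) {
    for (k in seq_len(n_specific_per_group)) {
      idx <- idx + 1L
      r <- plant(slot_gene[idx], slot_col[idx], target_groups[[gi]])
      specific[[length(specific) + 1L]] <- data.frame(
        gene_id = slot_gene[idx], column = slot_col[idx],
        group = names(target_groups)[gi], residue = r,
        stringsAsFactors = FALSE)
    }
  }
  convergent <- list()
  clade_union <- unlist(clades, use.names = FALSE)
  for (k in seq_len(n_convergent)) {
    idx <- idx + 1L
    r <- plant(slot_gene[idx], slot_col[idx], clade_union)
    convergent[[length(convergent) + 1L]] <- data.frame(
      gene_id = slot_gene[idx], column = slot_col[idx], residue = r,
      stringsAsFactors = FALSE)
  }
  fa_genes <- list(); fa_flags <- list()
  for (gi in seq_along(target_groups)) {
    grp <- names(target_groups)[gi]
    for (k in seq_len(n_fa_genes_per_group)) {
      idx <- idx + 1L
      r <- plant(slot_gene[idx], slot_col[idx], target_groups[[gi]])
      specific[[length(specific) + 1L]] <- data.frame(
        gene_id = slot_gene[idx], column = slot_col[idx], group = grp,
        residue = r, stringsAsFactors = FALSE)
      fa_genes[[length(fa_genes) + 1L]] <- data.frame(
        gene_id = slot_gene[idx], group = grp, stringsAsFactors = FALSE)
      fa_flags[[length(fa_flags) + 1L]] <- data.frame(
        gene_id = slot_gene[idx], column = slot_col[idx],
        species_id = target_groups[[gi]],
        tool = "polyphen2", call = "probably_damaging",
        stringsAsFactors = FALSE)
    }
  }
  fa_genes <- unique(do.call(rbind, fa_genes))

  # per-species substitution noise away from the ancestral residue,
  # skipping planted columns
  for (g in genes) {
    m <- mats[[g]]
    cols_ok <- setdiff(seq_len(aln_length), protected[[g]])
    for (sp in all_sp) {
      hit <- cols_ok[stats::runif(length(cols_ok)) < noise]
      if (length(hit))
        m[sp, hit] <- vapply(hit, function(j)
          sample(setdiff(aa, m[sp, j]), 1L), character(1))
    }
    mats[[g]] <- m
  }

  # decoy flags on genes that are not planted function-altered genes
  decoy <- list()
  fa_by_gene <- split(fa_genes$group, fa_genes$gene_id)
  for (g in setdiff(genes, fa_genes$gene_id)) {
    flagged <- all_sp[stats::runif(length(all_sp)) < decoy_flag_rate]
    # never let a decoy complete a full group-specific pattern
    for (gi in seq_along(target_groups)) {
      grp_sp <- target_groups[[gi]]
      if (all(grp_sp %in% flagged) && !any(setdiff(all_sp, grp_sp) %in% flagged))
        flagged <- setdiff(flagged, grp_sp[1L])
    }
    if (length(flagged))
      decoy[[length(decoy) + 1L]] <- data.frame(
        gene_id = g, column = sample(aln_length, length(flagged), replace = TRUE),
        species_id = flagged,
        tool = sample(c("polyphen2", "provean"), length(flagged), replace = TRUE),
        call = "deleterious", stringsAsFactors = FALSE)
  }
  # benign rows exercise the call filter without creating flags
  benign <- data.frame(gene_id = genes[1L], column = 1L,
                       species_id = background_species[1L],
                       tool = "provean", call = "neutral",
                       stringsAsFactors = FALSE)
  flags_raw <- rbind(do.call(rbind, fa_flags),
                     if (length(decoy)) do.call(rbind, decoy), benign)
  flags_raw <- flags_raw[order(flags_raw$gene_id, flags_raw$column,
                               flags_raw$species_id), , drop = FALSE]
  rownames(flags_raw) <- NULL
  flags_raw$fa <- grepl("damag|delet", flags_raw$call, ignore.case = TRUE)
  flags <- stats::aggregate(fa ~ gene_id + column + species_id,
                            data = flags_raw, FUN = any)
  names(flags)[names(flags) == "fa"] <- "function_altering"
  flags_raw$fa <- NULL

  alignments <- lapply(genes, function(g)
    protein_alignment(g, apply(mats[[g]], 1L, paste, collapse = "")))
  names(alignments) <- genes

  truth <- list(
    specific = do.call(rbind, specific),
    convergent = do.call(rbind, convergent),
    fa_genes = fa_genes)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- setNames(file.path(dir, paste0(genes, ".faa")), genes)
    for (g in genes) {
      aset <- Biostrings::AAStringSet(alignments[[g]]$seqs)
      Biostrings::writeXStringSet(aset, fasta[[g]])
    }
    flags_path <- file.path(dir, "flags.tsv")
    utils::write.table(flags_raw, flags_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- list(fasta = fasta, flags = flags_path, truth = truth_path)
  }
  structure(list(alignments = alignments, flags = flags,
                 flags_raw = flags_raw, truth = truth,
                 species = list(groups = target_groups,
                                background = background_species,
                                clades = clades),
                 params = list(n_genes = n_genes, aln_length = aln_length,
                               noise = noise, seed = as.integer(seed)),
                 files = files),
            class = "sim_protein_panel")
}

#' Nucleotide-level recovery of planted intervals
#'
#' Scores a called interval set against planted truth at single-base
#' resolution: sensitivity is the fraction of truth bases called,
#' precision the fraction of called bases that are true.
#'
#' @param called An `hcr_set` (from [call_hcrs()]) or a `GRanges`.
#' @param truth A `GRanges` of planted intervals.
#' @return Named numeric vector `c(sensitivity, precision)`; precision is
#'   `NA` when nothing was called, sensitivity is `NA` when truth is empty.
#' @export
score_recovery <- function(called, truth) {
  if (inherits(called, "hcr_set")) called <- called$intervals
  stopifnot(methods::is(called, "GRanges"), methods::is(truth, "GRanges"))
  called <- GenomicRanges::reduce(GenomicRanges::sort(called))
  truth <- GenomicRanges::reduce(GenomicRanges::sort(truth))
  inter <- suppressWarnings(GenomicRanges::intersect(called, truth))
  bp <- function(gr) sum(as.numeric(IRanges::width(gr)))
  c(sensitivity = if (bp(truth) > 0) bp(inter) / bp(truth) else NA_real_,
    precision = if (bp(called) > 0) bp(inter) / bp(called) else NA_real_)
}
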