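#' Parameters for the conserved-region scan
#'
#' Bundles and validates the tunable parameters of the sliding-window
#' conservation scan.
#'
#' @param bin_size Window size in bp (default 100,000).
#' @param step_size Step between window starts in bp (default 10,000); the
#'   "middle tile" extracted from each significant window also has this
#'   length, centred in the window.
#' @param coverage_fraction A window is usable only when strictly more than
#'   this fraction of its positions is callable in every species
#'   (default 0.8).
#' @param alpha_adj Significance threshold on the Benjamini-Hochberg
#'   adjusted P value, strict `<` (default 1e-4).
#' @param require_reduced If `TRUE` (default) a window is only called when
#'   its non-conserved fraction is below the chromosome background, so that
#'   two-sided significance cannot call windows with *elevated* variation.
#' @param mode Conservation definition. `"zygosity"` (default): a covered
#'   position is non-conserved iff at least one species is heterozygous
#'   there; homozygous-alternate calls do not break conservation.
#'   `"identity"`: additionally, a position is non-conserved when species
#'   disagree in their homozygous allele (including disagreement with the
#'   reference allele).
#' @param include_indels If `TRUE`, a heterozygous indel counts as one
#'   non-conserved position at its anchor base; default `FALSE` (SNV-only).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(bin_size = 100000, step_size = 10000,
                        coverage_fraction = 0.8, alpha_adj = 1e-4,
                        require_reduced = TRUE,
                        mode = c("zygosity", "identity"),
                        include_indels = FALSE) {
  mode <- match.arg(mode)
  stopifnot(step_size > 0, bin_size > 0, step_size <= bin_size,
            coverage_fraction > 0, coverage_fraction < 1,
            alpha_adj > 0, alpha_adj < 1)
  if ((bin_size - step_size) %% 2 != 0)
    stop("bin_size - step_size must be even so the middle tile is centred")
  structure(list(bin_size = bin_size, step_size = step_size,
                 coverage_fraction = coverage_fraction, alpha_adj = alpha_adj,
                 require_reduced = require_reduced, mode = mode,
                 include_indels = include_indels),
            class = "scan_params")
}

#' Enumerate scan windows on one contig
#'
#' Windows start at 0, `step_size`, 2*`step_size`, ... and only windows
#' lying fully inside the contig are emitted, so the count is
#' `floor((L - bin_size) / step_size) + 1` when `L >= bin_size` and 0
#' otherwise.
#'
#' @param contig_length Contig length in bp.
#' @param params A [scan_params()] object.
#' @return An `IRanges` of windows (1-based, width `bin_size`).
#' @export
enumerate_windows <- function(contig_length, params = scan_params()) {
  stopifnot(contig_length > 0)
  if (contig_length < params$bin_size) return(IRanges::IRanges())
  starts0 <- seq(0, contig_length - params$bin_size, by = params$step_size)
  IRanges::IRanges(start = starts0 + 1, width = params$bin_size)
}

# Callable mask for one species restricted to one contig; NULL mask means
# the whole contig is callable.
.species_mask_on <- function(cs, contig, contig_length) {
  if (is.null(cs$mask))
    return(IRanges::IRanges(1, contig_length))
  m <- cs$mask[as.character(GenomicRanges::seqnames(cs$mask)) == contig]
  IRanges::restrict(IRanges::reduce(IRanges::ranges(m)), 1L, contig_length)
}

# Joint callable mask (intersection over all species) on one contig.
.joint_mask <- function(panel, contig, contig_length) {
  Reduce(IRanges::intersect,
         lapply(panel, .species_mask_on, contig = contig,
                contig_length = contig_length))
}

# Sorted unique positions on `contig` that break conservation, before
# intersection with the joint mask.
.nonconserved_pos <- function(panel, contig, params) {
  keep_class <- if (params$include_indels) c("SNV", "INDEL") else "SNV"
  het <- lapply(panel, function(cs) {
    v <- cs$variants
    v$pos[v$contig == contig & v$zygosity == "HET" & v$var_class %in% keep_class]
  })
  pos <- sort(unique(unlist(het, use.names = FALSE)))
  if (params$mode == "identity") {
    hom <- lapply(panel, function(cs) {
      v <- cs$variants
      v <- v[v$contig == contig & v$zygosity == "HOM_ALT" &
               v$var_class %in% keep_class, c("pos", "alt")]
      v
    })
    hom_all <- do.call(rbind, hom)
    if (nrow(hom_all)) {
      n_sp <- length(panel)
      # a position is conserved under identity only if every species is
      # homozygous-alternate there with one and the same allele
      by_pos <- split(hom_all$alt, hom_all$pos)
      bad <- vapply(by_pos, function(a)
        !(length(a) == n_sp && length(unique(a)) == 1L), logical(1))
      pos <- sort(unique(c(pos, as.numeric(names(by_pos))[bad])))
    }
  }
  pos
}

# Core counting: for a set of windows (IRanges) on one contig, return a
# data.frame of (n_conserved, n_nonconserved, n_covered).
.count_in_windows <- function(windows, panel, contig, contig_length, params) {
  joint <- .joint_mask(panel, contig, contig_length)
  pos <- .nonconserved_pos(panel, contig, params)
  if (length(pos)) {
    inmask <- IRanges::overlapsAny(IRanges::IRanges(pos, width = 1L), joint)
    pos <- pos[inmask]
  }
  n <- length(windows)
  n_cov <- integer(n)
  if (length(joint) && n) {
    ov <- IRanges::findOverlaps(windows, joint)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(windows[queryHits(ov)],
                                              joint[subjectHits(ov)]))
      agg <- rowsum(w, group = queryHits(ov))
      n_cov[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  n_non <- if (length(pos) && n)
    IRanges::countOverlaps(windows, IRanges::IRanges(pos, width = 1L))
  else integer(n)
  data.frame(n_conserved = n_cov - n_non, n_nonconserved = n_non,
             n_covered = n_cov)
}

#' Count conserved / non-conserved / covered positions in one window
#'
#' A position is covered iff it is callable in every species of the panel;
#' a covered position is non-conserved iff it breaks conservation under the
#' chosen mode (by default: at least one species heterozygous there), and
#' conserved otherwise, so `n_conserved + n_nonconserved = n_covered`.
#'
#' @param window A length-1 `GRanges` giving the window (1-based).
#' @param panel Non-empty list of [species_callset()] objects on the same
#'   reference.
#' @param contig_length Length of the window's contig in bp.
#' @param params A [scan_params()] object.
#' @return Named numeric vector `c(n_conserved, n_nonconserved, n_covered)`.
#' @export
count_window <- function(window, panel, contig_length, params = scan_params()) {
  if (!length(panel)) stop("panel must contain at least one species")
  stopifnot(methods::is(window, "GRanges"), length(window) == 1L)
  contig <- as.character(GenomicRanges::seqnames(window))
  res <- .count_in_windows(IRanges::ranges(window), panel, contig,
                           contig_length, params)
  c(n_conserved = res$n_conserved, n_nonconserved = res$n_nonconserved,
    n_covered = res$n_covered)
}

#' Chromosome-wide conservation background
#'
#' Position-wise totals of conserved and non-conserved positions over a
#' whole contig -- identical to [count_window()] applied to the full contig
#' as a single window. Used as the comparison margin of the per-window
#' Fisher test; the tested window's own positions are included (not
#' subtracted).
#'
#' @inheritParams count_window
#' @param contig Contig name.
#' @return Named numeric vector `c(n_conserved, n_nonconserved, n_covered)`.
#' @export
chrom_background <- function(contig, panel, contig_length,
                             params = scan_params()) {
  if (!length(panel)) stop("panel must contain at least one species")
  res <- .count_in_windows(IRanges::IRanges(1, contig_length), panel, contig,
                           contig_length, params)
  c(n_conserved = res$n_conserved, n_nonconserved = res$n_nonconserved,
    n_covered = res$n_covered)
}

#' Two-sided Fisher's exact test for 2x2 tables (vectorized)
#'
#' Exact two-sided P value for the table `[a b; c d]`, defined as the sum
#' of all hypergeometric point probabilities not exceeding that of the
#' observed table (with the conventional `1 + 1e-7` relative tolerance
#' against floating-point ties, as in [stats::fisher.test()]). Degenerate
#' tables with a zero margin return 1 so a genome-wide scan never aborts.
#'
#' @param a,b,c,d Non-negative integer count vectors (recycled to common
#'   length): `a`,`b` are the window's conserved / non-conserved counts and
#'   `c`,`d` the chromosome totals.
#' @return Numeric vector of two-sided P values.
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)  # 2 / choose(20, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  chk <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
      stop("'", nm, "' must be non-negative integers")
    as.integer(round(x))
  }
  fisher2x2_pvalue(chk(a, "a"), chk(b, "b"), chk(c, "c"), chk(d, "d"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_(j >= i) min(1, p_(j) * m / j)` mapped back to input order,
#' where `m = length(p)`. One scan applies a single correction across all
#' usable autosomal windows of a family.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @return Adjusted P values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Scan a family panel for conserved windows
#'
#' Runs the full window statistic over every autosomal contig of the
#' family: enumerates windows, counts conserved / non-conserved / covered
#' positions, applies the joint-coverage filter (strictly more than
#' `coverage_fraction` of the window callable in all species), tests each
#' usable window against its chromosome background with a two-sided
#' Fisher's exact test, and applies one genome-wide Benjamini-Hochberg
#' correction across all usable windows.
#'
#' @param panel Named, non-empty list of [species_callset()] objects.
#' @param contigs Contig table from [read_contig_table()]; only contigs
#'   flagged `is_autosome` are scanned.
#' @param params A [scan_params()] object.
#' @return A `data.frame` of window statistics with columns `contig`,
#'   `start`, `end` (0-based half-open, matching the on-disk outputs),
#'   `n_conserved`, `n_nonconserved`, `n_covered`, `usable`, `p_raw`,
#'   `p_adj`, `bg_conserved`, `bg_nonconserved`; scan parameters are
#'   attached as attribute `params`.
#' @export
scan_family <- function(panel, contigs, params = scan_params()) {
  if (!length(panel)) stop("panel must contain at least one species")
  no_mask <- vapply(panel, function(cs) is.null(cs$mask), logical(1))
  if (any(no_mask))
    warning("no callable mask for species ",
            paste(vapply(panel[no_mask], `[[`, "", "species_id"),
                  collapse = ", "),
            "; treating their whole genome as callable")
  auto <- contigs[contigs$is_autosome, , drop = FALSE]
  out <- vector("list", nrow(auto))
  for (i in seq_len(nrow(auto))) {
    contig <- auto$contig[i]
    L <- auto$length[i]
    win <- enumerate_windows(L, params)
    if (!length(win)) next
    cnt <- .count_in_windows(win, panel, contig, L, params)
    bg <- chrom_background(contig, panel, L, params)
    if (bg[["n_covered"]] == 0)
      warning("contig ", contig,
              " has no jointly covered positions; its windows are untestable")
    df <- data.frame(contig = contig,
                     start = IRanges::start(win) - 1,
                     end = IRanges::end(win),
                     cnt,
                     stringsAsFactors = FALSE)
    df$usable <- df$n_covered > params$coverage_fraction * params$bin_size
    df$bg_conserved <- bg[["n_conserved"]]
    df$bg_nonconserved <- bg[["n_nonconserved"]]
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(contig = character(), start = numeric(),
                         end = numeric(), n_conserved = numeric(),
                         n_nonconserved = numeric(), n_covered = numeric(),
                         usable = logical(), bg_conserved = numeric(),
                         bg_nonconserved = numeric())
  res$p_raw <- NA_real_
  res$p_adj <- NA_real_
  if (any(res$usable)) {
    u <- which(res$usable)
    res$p_raw[u] <- fisher_exact_2x2(res$n_conserved[u], res$n_nonconserved[u],
                                     res$bg_conserved[u],
                                     res$bg_nonconserved[u])
    res$p_adj[u] <- bh_adjust(res$p_raw[u])
  }
  rownames(res) <- NULL
  attr(res, "params") <- params
  res
}

#' Call highly conserved regions from window statistics
#'
#' A window is called when it is usable, its adjusted P value is strictly
#' below `alpha_adj`, and (with `require_reduced`, the default) its
#' non-conserved fraction is below the chromosome background fraction.
#' Each called window `[s, s + bin_size)` contributes its middle tile
#' `[s + (bin_size - step_size)/2, s + (bin_size + step_size)/2)`;
#' overlapping or adjacent tiles are merged, so the total length is always
#' a multiple of `step_size` and independent of window processing order.
#'
#' @param window_stats Output of [scan_family()].
#' @param params A [scan_params()]; defaults to the parameters attached to
#'   `window_stats`.
#' @return An object of class `hcr_set`: list with elements `intervals`
#'   (merged `GRanges`), `total_length`, `unmerged_length`
#'   (`n_called * step_size`), `n_windows_called`, `params`, and `metadata`
#'   (test sidedness and direction filter, recorded for auditability).
#' @export
call_hcrs <- function(window_stats, params = attr(window_stats, "params")) {
  if (is.null(params)) params <- scan_params()
  ws <- window_stats
  called <- ws$usable & !is.na(ws$p_adj) & ws$p_adj < params$alpha_adj
  if (params$require_reduced) {
    bg_tot <- ws$bg_conserved + ws$bg_nonconserved
    bg_frac <- ifelse(bg_tot > 0, ws$bg_nonconserved / bg_tot, NA_real_)
    win_frac <- ifelse(ws$n_covered > 0, ws$n_nonconserved / ws$n_covered,
                       NA_real_)
    called <- called & !is.na(bg_frac) & !is.na(win_frac) & win_frac < bg_frac
  }
  off <- (params$bin_size - params$step_size) / 2
  if (any(called)) {
    tiles <- GenomicRanges::GRanges(
      ws$contig[called],
      IRanges::IRanges(start = ws$start[called] + off + 1,
                       width = params$step_size))
    merged <- GenomicRanges::reduce(GenomicRanges::sort(tiles))
  } else {
    merged <- GenomicRanges::GRanges()
  }
  structure(list(intervals = merged,
                 total_length = sum(as.numeric(IRanges::width(merged))),
                 unmerged_length = sum(called) * params$step_size,
                 n_windows_called = sum(called),
                 called_windows = called,
                 params = params,
                 metadata = list(test = "two.sided Fisher exact",
                                 direction_filter = params$require_reduced,
                                 mode = params$mode)),
            class = "hcr_set")
}

#' @export
print.hcr_set <- function(x, ...) {
  cat("<hcr_set> ", length(x$intervals), " merged intervals, ",
      format(x$total_length, big.mark = ","), " bp total (",
      x$n_windows_called, " windows called; unmerged ",
      format(x$unmerged_length, big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

#' Genes overlapping highly conserved regions, across families
#'
#' A gene is "in HCRs" iff its interval overlaps at least one HCR interval
#' by at least 1 bp. Cross-family comparison uses the `gene_key` column
#' (gene symbol shared between references); genes without a key are
#' excluded from the partition with a logged count.
#'
#' @param hcr_sets Named list of [call_hcrs()] results, one per family.
#' @param gene_tables Named list of gene `GRanges` from
#'   [read_gene_table()], with names matching `hcr_sets`.
#' @return A list with `per_family` (character vectors of gene keys in
#'   HCRs), `gene_ids` (per-family gene_id vectors), `shared` (keys in all
#'   families' HCRs), `specific` (per family: keys found only in that
#'   family), and `n_missing_key` (per-family excluded-gene counts).
#' @export
genes_in_regions <- function(hcr_sets, gene_tables) {
  stopifnot(length(hcr_sets) >= 1,
            all(names(hcr_sets) %in% names(gene_tables)))
  fams <- names(hcr_sets)
  per_family <- list(); gene_ids <- list(); n_missing <- integer()
  for (fam in fams) {
    genes <- gene_tables[[fam]]
    hits <- IRanges::overlapsAny(genes, hcr_sets[[fam]]$intervals,
                                 ignore.strand = TRUE)
    ids <- mcols(genes)$gene_id[hits]
    keys <- mcols(genes)$gene_key[hits]
    miss <- is.na(keys) | !nzchar(keys)
    if (any(miss))
      message(fam, ": ", sum(miss), " HCR gene(s) without gene_key excluded ",
              "from the cross-family partition")
    per_family[[fam]] <- unique(keys[!miss])
    gene_ids[[fam]] <- ids
    n_missing[fam] <- sum(miss)
  }
  shared <- Reduce(intersect, per_family)
  specific <- lapply(seq_along(fams), function(i) {
    others <- unique(unlist(per_family[-i], use.names = FALSE))
    setdiff(per_family[[i]], others)
  })
  names(specific) <- fams
  list(per_family = per_family, gene_ids = gene_ids, shared = shared,
       specific = specific, n_missing_key = n_missing)
}
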