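#' Run the full pipeline from a validated configuration
#'
#' Executes the conservation scan for every family, the diversity
#' statistics for every species, and (when configured) the amino-acid
#' change stage, writing per-window TSVs, HCR BEDs, gene-set TSVs, and one
#' JSON report with all results and decision metadata (test sidedness,
#' direction filter, conservation mode, thresholds). A failing stage is
#' recorded in the report and later independent stages still run. Output
#' is deterministic given inputs and seed; wall-clock timestamps go to a
#' sidecar file, never into the report.
#'
#' @param config A `famcons_config` from [validate_config()], or a path to
#'   a YAML configuration.
#' @param out_dir Output directory; defaults to the configuration's
#'   `output_dir`.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "famcons_config"))
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$scan
  report <- list(
    seed = config$seed,
    parameters = list(
      bin_size = params$bin_size, step_size = params$step_size,
      coverage_fraction = params$coverage_fraction,
      alpha_adj = params$alpha_adj,
      require_reduced = params$require_reduced, mode = params$mode,
      include_indels = params$include_indels,
      test = "two.sided Fisher exact",
      background = "per-chromosome, window included",
      correction = "Benjamini-Hochberg, one family-wide pass"),
    families = list(), errors = list())

  hcr_sets <- list(); gene_tables <- list()
  for (f in config$families) {
    fam <- f$name
    res <- tryCatch({
      contigs <- read_contig_table(f$contigs)
      panel <- list()
      for (sp in f$species) {
        mask <- if (!is.null(sp$mask)) read_mask(sp$mask) else NULL
        panel[[sp$id]] <- read_variants(sp$vcf, sp$sample %||% sp$id,
                                        mask = mask, species_id = sp$id)
      }
      message("[", fam, "] ", length(panel), " species, ",
              sum(contigs$is_autosome), " autosomal contig(s)")
      ws <- scan_family(panel, contigs, params)
      message("[", fam, "] ", nrow(ws), " windows, ", sum(ws$usable),
              " usable (", round(100 * mean(ws$usable), 1),
              "%); Fisher tests per contig: ",
              paste(vapply(split(ws$usable, ws$contig), sum, 0),
                    collapse = ", "))
      hcr <- call_hcrs(ws, params)
      utils::write.table(
        cbind(ws, called = hcr$called_windows),
        file.path(out_dir, paste0(fam, ".windows.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_intervals(hcr$intervals, file.path(out_dir, paste0(fam, ".hcr.bed")))

      div <- do.call(rbind, lapply(f$species, function(sp) {
        dv <- sp$divergence_mya %||% f$divergence_mya
        species_diversity(panel[[sp$id]], contigs, divergence_mya = dv,
                          include_indels = params$include_indels)
      }))
      fs <- family_summary(div, fam, f$divergence_mya %||% NA_real_)
      utils::write.table(div, file.path(out_dir, paste0(fam, ".diversity.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(f$genes)) gene_tables[[fam]] <- read_gene_table(f$genes)
      hcr_sets[[fam]] <- hcr
      list(n_windows = nrow(ws), n_usable = sum(ws$usable),
           hcr_total_bp = hcr$total_length,
           hcr_unmerged_bp = hcr$unmerged_length,
           n_windows_called = hcr$n_windows_called,
           mean_diversity = fs$mean_diversity,
           mean_distance = fs$mean_distance,
           species = div)
    }, error = function(e) {
      report$errors[[fam]] <<- conditionMessage(e)
      message("[", fam, "] stage failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) report$families[[fam]] <- res
  }

  if (length(gene_tables) && length(hcr_sets)) {
    gi <- tryCatch(
      genes_in_regions(hcr_sets[names(gene_tables)], gene_tables),
      error = function(e) { report$errors$genes <<- conditionMessage(e); NULL })
    if (!is.null(gi)) {
      for (fam in names(gi$per_family))
        writeLines(sort(gi$per_family[[fam]]),
                   file.path(out_dir, paste0(fam, ".hcr_genes.txt")))
      writeLines(sort(gi$shared), file.path(out_dir, "hcr_genes.shared.txt"))
      report$hcr_genes <- list(
        per_family = lapply(gi$per_family, length),
        shared = length(gi$shared),
        specific = lapply(gi$specific, length))
    }
  }

  if (!is.null(config$aac)) {
    aac_res <- tryCatch(.run_aac_stage(config$aac, out_dir),
                        error = function(e) {
                          report$errors$aac <<- conditionMessage(e); NULL })
    if (!is.null(aac_res)) report$aac <- aac_res
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
             file.path(out_dir, "report.time.txt"))
  invisible(report)
}

.run_aac_stage <- function(aac, out_dir) {
  paths <- unlist(aac$alignments)
  files <- unlist(lapply(paths, function(p)
    if (dir.exists(p)) list.files(p, pattern = "\\.(fa|faa|fasta)$",
                                  full.names = TRUE) else p))
  alns <- lapply(files, read_protein_alignment)
  flags <- read_aac_flags(aac$flags)
  groups <- lapply(aac$groups, unlist)
  all_sp <- unlist(groups, use.names = FALSE)

  specific <- list(); fa <- list()
  for (grp in names(groups)) {
    others <- setdiff(all_sp, groups[[grp]])
    hits <- do.call(rbind, lapply(alns, function(a)
      tryCatch(group_specific_aacs(a, groups[[grp]], others),
               error = function(e) NULL)))
    if (!is.null(hits) && nrow(hits)) {
      hits$group <- grp
      specific[[grp]] <- hits
    }
    fa[[grp]] <- function_altered_genes(flags, groups[[grp]], others)
  }
  conv <- NULL
  if (!is.null(aac$clades) && length(aac$clades) >= 2) {
    clades <- lapply(aac$clades, unlist)
    bg <- setdiff(all_sp, unlist(clades))
    conv <- do.call(rbind, lapply(alns, function(a)
      tryCatch(convergent_aacs(a, clades, bg), error = function(e) NULL)))
  }
  sp_tab <- do.call(rbind, specific)
  if (!is.null(sp_tab))
    utils::write.table(sp_tab, file.path(out_dir, "aac.group_specific.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(conv) && nrow(conv))
    utils::write.table(conv, file.path(out_dir, "aac.convergent.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  fa_tab <- do.call(rbind, lapply(names(fa), function(g)
    if (length(fa[[g]])) data.frame(group = g, gene_id = fa[[g]],
                                    stringsAsFactors = FALSE)))
  if (!is.null(fa_tab))
    utils::write.table(fa_tab, file.path(out_dir, "aac.function_altered.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_genes = length(alns),
       n_group_specific = if (is.null(sp_tab)) 0L else nrow(sp_tab),
       n_convergent = if (is.null(conv)) 0L else nrow(conv),
       n_function_altered = lapply(fa, length))
}
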