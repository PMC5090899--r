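#' Per-species nucleotide diversity and genetic distance
#'
#' Nucleotide diversity is the number of heterozygous SNVs divided by the
#' genome size (per-bp heterozygosity). Genetic distance is the number of
#' homozygous-alternate SNVs to the reference divided by genome size and
#' by the divergence time in million years (per-bp, per-MYA). Counts are
#' restricted to autosomal contigs; indels are excluded by default.
#'
#' @param callset A [species_callset()].
#' @param contigs Contig table from [read_contig_table()]; used to restrict
#'   counting to autosomes and, when `genome_size` is `NULL`, to define the
#'   genome size as the summed autosomal contig length.
#' @param divergence_mya Divergence time in million years (> 0), typically
#'   the family crown age or the species-to-reference split time.
#' @param genome_size Genome size in bp (> 0); defaults to the summed
#'   autosomal length of `contigs`.
#' @param include_indels Count heterozygous/homozygous indels too
#'   (default `FALSE`).
#' @return One-row `data.frame` with columns `species_id`, `n_hom_snv`,
#'   `n_het_snv`, `genome_size`, `divergence_mya`, `nucleotide_diversity`,
#'   `genetic_distance`.
#' @examples
#' cs <- species_callset("sp", data.frame(
#'   contig = "chr1", pos = c(10, 20, 30), zygosity = c("HET", "HET", "HOM_ALT"),
#'   var_class = "SNV", alt = "T"))
#' ct <- data.frame(contig = "chr1", length = 10000, is_autosome = TRUE)
#' species_diversity(cs, ct, divergence_mya = 2)
#' @export
species_diversity <- function(callset, contigs, divergence_mya,
                              genome_size = NULL, include_indels = FALSE) {
  stopifnot(inherits(callset, "species_callset"),
            is.numeric(divergence_mya), divergence_mya > 0)
  auto <- contigs$contig[contigs$is_autosome]
  if (is.null(genome_size))
    genome_size <- sum(contigs$length[contigs$is_autosome])
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("genome_size must be > 0")
  v <- callset$variants
  v <- v[v$contig %in% auto, , drop = FALSE]
  if (!include_indels) v <- v[v$var_class == "SNV", , drop = FALSE]
  n_het <- sum(v$zygosity == "HET")
  n_hom <- sum(v$zygosity == "HOM_ALT")
  data.frame(species_id = callset$species_id,
             n_hom_snv = n_hom, n_het_snv = n_het,
             genome_size = genome_size, divergence_mya = divergence_mya,
             nucleotide_diversity = n_het / genome_size,
             genetic_distance = n_hom / genome_size / divergence_mya,
             stringsAsFactors = FALSE)
}

#' Family-level diversity summary
#'
#' Arithmetic means of the per-species nucleotide diversity and genetic
#' distance, keeping the per-species table.
#'
#' @param species_table `data.frame` with one [species_diversity()] row per
#'   member species (at least one).
#' @param family_id Family label.
#' @param divergence_mya Optional family crown age (MYA) carried through to
#'   the summary for reporting.
#' @return A list of class `family_diversity` with elements `family_id`,
#'   `mean_diversity`, `mean_distance`, `divergence_mya`, and `species`.
#' @export
family_summary <- function(species_table, family_id = "family",
                           divergence_mya = NA_real_) {
  if (!nrow(species_table)) stop("species_table must contain at least one species")
  structure(list(family_id = family_id,
                 mean_diversity = mean(species_table$nucleotide_diversity),
                 mean_distance = mean(species_table$genetic_distance),
                 divergence_mya = divergence_mya,
                 species = species_table),
            class = "family_diversity")
}

#' @export
print.family_diversity <- function(x, ...) {
  cat("<family_diversity> ", x$family_id, " (", nrow(x$species),
      " species)\n", sep = "")
  cat("  mean nucleotide diversity: ", signif(x$mean_diversity, 5), "\n",
      sep = "")
  cat("  mean genetic distance:     ", signif(x$mean_distance, 5), "\n",
      sep = "")
  invisible(x)
}
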