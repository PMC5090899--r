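#' Protein alignment for one gene
#'
#' Container for one gene's protein multiple alignment, one sequence per
#' species (consensus per species; within-species polymorphism is assumed
#' resolved upstream). All sequences must have equal (aligned) length and
#' unique species names.
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector of aligned sequences, or a
#'   `Biostrings::AAStringSet` with names.
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(gene_id, seqs) {
  if (methods::is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by species id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate species id in alignment for gene ", gene_id)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length (gene ", gene_id, ")")
  structure(list(gene_id = gene_id, seqs = toupper(seqs),
                 width = nchar(seqs[[1L]])),
            class = "protein_alignment")
}

#' Read one gene's aligned protein FASTA
#'
#' Reads an aligned FASTA via `Biostrings::readAAStringSet`; sequence
#' headers are taken as species ids.
#'
#' @param path Path to the aligned FASTA file.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return A [protein_alignment()].
#' @export
read_protein_alignment <- function(path,
                                   gene_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("alignment not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  protein_alignment(gene_id, seqs)
}

.STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# species-by-column residue matrix for the listed species
.aln_matrix <- function(aln, species) {
  missing <- setdiff(species, names(aln$seqs))
  if (length(missing))
    stop("species missing from alignment of gene ", aln$gene_id, ": ",
         paste(missing, collapse = ", "))
  m <- do.call(rbind, strsplit(aln$seqs[species], ""))
  rownames(m) <- species
  m
}

.empty_aac <- function() {
  data.frame(gene_id = character(), column = integer(),
             target_residue = character(), background_residues = character(),
             is_convergent = logical(), stringsAsFactors = FALSE)
}

#' Group-specific amino-acid changes
#'
#' Reports every alignment column where all target species carry one and
#' the same residue, no background species carries that residue, and no
#' involved species has a gap or ambiguity symbol at the column (columns
#' with gaps/ambiguity in any involved species are skipped: the definition
#' presumes an aligned residue in every species). Reported positions are
#' 1-based.
#'
#' @param aln A [protein_alignment()].
#' @param targets Character vector of target species (non-empty).
#' @param backgrounds Character vector of background species (non-empty,
#'   disjoint from `targets`).
#' @return `data.frame` with columns `gene_id`, `column` (1-based),
#'   `target_residue`, `background_residues` (comma-separated, background
#'   species order), `is_convergent` (all `FALSE` here).
#' @export
group_specific_aacs <- function(aln, targets, backgrounds) {
  stopifnot(length(targets) >= 1, length(backgrounds) >= 1)
  if (length(intersect(targets, backgrounds)))
    stop("targets and backgrounds must be disjoint")
  m <- .aln_matrix(aln, c(targets, backgrounds))
  tm <- m[targets, , drop = FALSE]
  bm <- m[backgrounds, , drop = FALSE]
  valid <- colSums(!matrix(m %in% .STANDARD_AA, nrow = nrow(m))) == 0L
  unanimous <- apply(tm, 2L, function(x) length(unique(x)) == 1L)
  hit <- which(valid & unanimous)
  hit <- hit[vapply(hit, function(j) !any(bm[, j] == tm[1L, j]), logical(1))]
  if (!length(hit)) return(.empty_aac())
  data.frame(gene_id = aln$gene_id, column = as.integer(hit),
             target_residue = tm[1L, hit],
             background_residues = apply(bm[, hit, drop = FALSE], 2L,
                                         paste, collapse = ","),
             is_convergent = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Convergent amino-acid changes across independent clades
#'
#' A column is convergent when every species in every target clade carries
#' one and the same residue. By default the stricter definition is applied:
#' the shared residue must additionally be absent from all background
#' species (`require_background_absent = FALSE` relaxes this to unanimity
#' among the clades only). Columns with a gap or ambiguity symbol in any
#' involved species are skipped.
#'
#' @param aln A [protein_alignment()].
#' @param clades List (length >= 2) of pairwise-disjoint character vectors
#'   of species, one per independent target clade.
#' @param backgrounds Character vector of background species.
#' @param require_background_absent Require the convergent residue to be
#'   absent from every background species (default `TRUE`).
#' @return `data.frame` as in [group_specific_aacs()], with
#'   `is_convergent = TRUE`.
#' @export
convergent_aacs <- function(aln, clades, backgrounds,
                            require_background_absent = TRUE) {
  stopifnot(length(clades) >= 2)
  all_targets <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(all_targets))
    stop("clades must be pairwise disjoint")
  res <- if (require_background_absent) {
    group_specific_aacs(aln, all_targets, backgrounds)
  } else {
    m <- .aln_matrix(aln, c(all_targets, backgrounds))
    tm <- m[all_targets, , drop = FALSE]
    bm <- m[backgrounds, , drop = FALSE]
    valid <- colSums(!matrix(m %in% .STANDARD_AA, nrow = nrow(m))) == 0L
    unanimous <- apply(tm, 2L, function(x) length(unique(x)) == 1L)
    hit <- which(valid & unanimous)
    if (!length(hit)) .empty_aac()
    else data.frame(gene_id = aln$gene_id, column = as.integer(hit),
                    target_residue = tm[1L, hit],
                    background_residues = apply(bm[, hit, drop = FALSE], 2L,
                                                paste, collapse = ","),
                    is_convergent = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  }
  res$is_convergent <- rep(TRUE, nrow(res))
  res
}

#' Read a function-altering annotation table
#'
#' Reads the TSV of upstream effect-predictor calls (columns `gene_id`,
#' `column` (1-based), `species_id`, `tool`, `call`). A (gene, column,
#' species) triple is flagged function-altering when any tool reports a
#' deleterious/damaging call; predictions themselves are consumed, never
#' computed here.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `gene_id`, `column`, `species_id`,
#'   `function_altering` (logical), one row per (gene, column, species).
#' @export
read_aac_flags <- function(path) {
  if (!file.exists(path)) stop("flag table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("gene_id", "column", "species_id", "call")
  if (!all(need %in% names(tab)))
    stop("flag table must have columns ", paste(need, collapse = ", "))
  tab$fa <- grepl("damag|delet", tab$call, ignore.case = TRUE)
  agg <- stats::aggregate(fa ~ gene_id + column + species_id, data = tab,
                          FUN = any)
  names(agg)[names(agg) == "fa"] <- "function_altering"
  agg[order(agg$gene_id, agg$column, agg$species_id), , drop = FALSE]
}

#' Diet-group-specific function-altered genes
#'
#' A gene is group-specific function-altered when every species of the
#' group has at least one function-altering AAC anywhere in the gene and
#' every species of the other diet groups has none.
#'
#' @param flags Flag table as from [read_aac_flags()] (columns `gene_id`,
#'   `species_id`, `function_altering`; a `column` column is allowed and
#'   ignored).
#' @param group Character vector: species of the target diet group.
#' @param other_diet_species Character vector: all species of the other
#'   diet groups.
#' @return Sorted character vector of qualifying gene ids.
#' @export
function_altered_genes <- function(flags, group, other_diet_species) {
  stopifnot(length(group) >= 1)
  fa <- flags[flags$function_altering, , drop = FALSE]
  if (!nrow(fa)) return(character())
  genes <- unique(fa$gene_id)
  keep <- vapply(genes, function(g) {
    sp <- unique(fa$species_id[fa$gene_id == g])
    all(group %in% sp) && !any(other_diet_species %in% sp)
  }, logical(1))
  sort(genes[keep])
}
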