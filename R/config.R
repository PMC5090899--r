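#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration and validates it exhaustively: every
#' problem found is collected and reported in one error rather than
#' failing fast. The configuration names the families (each with a contig
#' table, member species with VCF and optional mask paths, and a
#' divergence time), the scan parameters, optional gene tables, and an
#' optional amino-acid-change section (alignments, flag table, diet
#' groups).
#'
#' @param path Path to a YAML configuration file.
#' @return The resolved configuration (class `famcons_config`), with a
#'   built [scan_params()] under `$scan`. Throws one error listing all
#'   validation failures otherwise.
#' @export
validate_config <- function(path) {
  probs <- character()
  note <- function(...) probs <<- c(probs, paste0(...))
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) { note("YAML parse error: ",
                                             conditionMessage(e)); NULL })
  if (is.null(cfg)) stop(paste(probs, collapse = "\n"))

  known <- c("seed", "output_dir", "scan", "families", "aac")
  for (k in setdiff(names(cfg), known)) note("unknown top-level key: ", k)

  scan <- tryCatch(do.call(scan_params, as.list(cfg$scan %||% list())),
                   error = function(e) { note("scan parameters invalid: ",
                                              conditionMessage(e)); NULL })

  fams <- cfg$families
  if (is.null(fams) || !length(fams)) note("no families defined")
  seen_species <- character()
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    lab <- if (!is.null(f$name)) f$name else paste0("families[", i, "]")
    if (is.null(f$name)) note(lab, ": missing name")
    if (is.null(f$contigs)) note(lab, ": missing contigs path")
    else if (!file.exists(f$contigs)) note(lab, ": contigs file not found: ",
                                           f$contigs)
    if (!is.null(f$genes) && !file.exists(f$genes))
      note(lab, ": gene table not found: ", f$genes)
    dv <- f$divergence_mya
    if (!is.null(dv) && (!is.numeric(dv) || dv <= 0))
      note(lab, ": divergence_mya must be a positive number")
    if (is.null(f$species) || !length(f$species)) note(lab, ": no species")
    for (sp in f$species) {
      slab <- paste0(lab, "/", if (!is.null(sp$id)) sp$id else "?")
      if (is.null(sp$id)) note(lab, ": species without id")
      else {
        if (sp$id %in% seen_species)
          note("species '", sp$id, "' appears in more than one family")
        seen_species <- c(seen_species, sp$id)
      }
      if (is.null(sp$vcf)) note(slab, ": missing vcf path")
      else if (!file.exists(sp$vcf)) note(slab, ": vcf not found: ", sp$vcf)
      if (!is.null(sp$mask) && !file.exists(sp$mask))
        note(slab, ": mask not found: ", sp$mask)
      if (is.null(sp$divergence_mya) && is.null(dv))
        note(slab, ": no divergence_mya (species or family level)")
    }
  }

  if (!is.null(cfg$aac)) {
    a <- cfg$aac
    if (is.null(a$alignments)) note("aac: missing alignments (dir or files)")
    else {
      ok <- vapply(a$alignments, function(p) file.exists(p) || dir.exists(p),
                   logical(1))
      if (!all(ok)) note("aac: alignment path(s) not found: ",
                         paste(unlist(a$alignments)[!ok], collapse = ", "))
    }
    if (is.null(a$flags)) note("aac: missing flags table path")
    else if (!file.exists(a$flags)) note("aac: flags table not found: ", a$flags)
    if (is.null(a$groups) || !length(a$groups) || is.null(names(a$groups)))
      note("aac: groups must be a named mapping of group -> species")
    else if (anyDuplicated(unlist(a$groups)))
      note("aac: groups must be disjoint")
  }

  if (length(probs))
    stop("invalid configuration:\n  - ", paste(probs, collapse = "\n  - "),
         call. = FALSE)
  cfg$scan <- scan
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "famcons_out"
  class(cfg) <- "famcons_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
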