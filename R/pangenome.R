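# Pan-genome container, family classification and the per-gene ortholog
# score.  The ortholog score of a gene of a focal strain is the number of
# OTHER strains with at least one member in that gene's family, so its
# maximum is n_strains - 1.

#' Construct a pan-genome object
#'
#' @param strains ordered character vector of strain identifiers.
#' @param members named list (one element per family) of named lists mapping
#'   strain -> character vector of gene IDs.  A strain with two or more gene
#'   IDs in one family carries paralogs.
#' @param connectivity named numeric vector in `[0,1]`, one value per family
#'   (Proteinortho algebraic connectivity).
#' @return An object of class `pangenome`: list with `strains`, `families`
#'   (data.frame: family_id, n_species, n_genes, connectivity), `members`
#'   and `gene_index` (data.frame: gene_id, strain, family).
#' @export
new_pangenome <- function(strains, members, connectivity) {
  stop_if_not(length(members) > 0, "pan-genome must contain at least one family")
  fam_ids <- names(members)
  stop_if_not(!is.null(fam_ids) && all(nzchar(fam_ids)),
              "members must be a named list of families")
  connectivity <- connectivity[fam_ids]
  stop_if_not(all(is.finite(connectivity) & connectivity >= 0 & connectivity <= 1),
              "connectivity values must lie in [0, 1]")
  bad <- unlist(lapply(members, function(m) setdiff(names(m), strains)))
  if (length(bad)) stop("family members reference unknown strains: ",
                        paste(unique(bad), collapse = ", "))
  n_species <- vapply(members, function(m) sum(lengths(m) > 0), integer(1))
  n_genes <- vapply(members, function(m) sum(lengths(m)), integer(1))
  gene_index <- data.frame(
    gene_id = unlist(lapply(members, unlist), use.names = FALSE),
    strain = unlist(lapply(members, function(m) rep(names(m), lengths(m))),
                    use.names = FALSE),
    family = rep(fam_ids, n_genes),
    stringsAsFactors = FALSE)
  dup <- duplicated(gene_index$gene_id)
  if (any(dup)) stop("duplicate gene ID across families: ",
                     paste(head(unique(gene_index$gene_id[dup]), 5), collapse = ", "))
  structure(list(strains = strains,
                 families = data.frame(family_id = fam_ids,
                                       n_species = n_species,
                                       n_genes = n_genes,
                                       connectivity = as.numeric(connectivity),
                                       row.names = NULL,
                                       stringsAsFactors = FALSE),
                 members = members,
                 gene_index = gene_index),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("Pan-genome: %d strains, %d families, %d genes\n",
              length(x$strains), nrow(x$families), nrow(x$gene_index)))
  invisible(x)
}

#' Classify pan-genome families as core, soft-core or accessory
#'
#' A family is *core* when it has members in every strain and *soft-core*
#' when it reaches at least `ceiling(soft_core_fraction * n_strains)` strains
#' (the ceiling is the only rounding consistent with the 95 % rule giving
#' 104 of 109 strains).  Families also get `has_paralogs` (some strain with
#' two or more members) and `high_connectivity` (connectivity >=
#' `connectivity_min`) flags, which drive the usual core-genome filters.
#'
#' @param pan a [pangenome] object.
#' @param soft_core_fraction fraction of strains defining the soft core
#'   (default 0.95); must lie in (0, 1].
#' @param connectivity_min minimum algebraic connectivity for the
#'   high-connectivity flag (default 0.9; families below are the usual
#'   exclusion set).
#' @return Object of class `family_classification`: the per-family table
#'   plus attributes `soft_core_threshold` (strain count), `n_strains`, and a
#'   `summary` row with the five headline counts (families, core incl.
#'   paralogs, soft-core incl. paralogs, core without paralogs, core without
#'   paralogs at high connectivity).
#' @export
classify_families <- function(pan, soft_core_fraction = 0.95,
                              connectivity_min = 0.9) {
  stopifnot(inherits(pan, "pangenome"))
  if (!(soft_core_fraction > 0 && soft_core_fraction <= 1))
    stop("soft_core_fraction must lie in (0, 1]")
  ns <- length(pan$strains)
  threshold <- as.integer(ceiling(soft_core_fraction * ns))
  df <- pan$families
  df$has_paralogs <- vapply(pan$members, function(m) any(lengths(m) >= 2),
                            logical(1))[df$family_id]
  df$high_connectivity <- df$connectivity >= connectivity_min
  df$label <- ifelse(df$n_species == ns, "core",
                     ifelse(df$n_species >= threshold, "soft_core", "accessory"))
  summary_row <- data.frame(
    n_families = nrow(df),
    core_incl_paralogs = sum(df$label == "core"),
    soft_core_incl_paralogs = sum(df$n_species >= threshold),
    core_no_paralogs = sum(df$label == "core" & !df$has_paralogs),
    core_no_paralogs_high_connectivity =
      sum(df$label == "core" & !df$has_paralogs & df$high_connectivity))
  structure(df, class = c("family_classification", "data.frame"),
            soft_core_threshold = threshold, n_strains = ns,
            soft_core_fraction = soft_core_fraction,
            connectivity_min = connectivity_min, summary = summary_row)
}

#' @export
print.family_classification <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Family classification for %d strains (soft-core threshold: %d strains)\n",
              attr(x, "n_strains"), attr(x, "soft_core_threshold")))
  cat(sprintf("  families: %d | core: %d | soft-core: %d | core, no paralogs: %d | + connectivity >= %.2g: %d\n",
              s$n_families, s$core_incl_paralogs, s$soft_core_incl_paralogs,
              s$core_no_paralogs, attr(x, "connectivity_min"),
              s$core_no_paralogs_high_connectivity))
  invisible(x)
}

#' Pan-genome headline counts
#'
#' @param classification a [classify_families()] result.
#' @return One-row data.frame with the five headline counts.
#' @export
pangenome_summary <- function(classification) {
  stopifnot(inherits(classification, "family_classification"))
  attr(classification, "summary")
}

#' Per-gene ortholog scores for a focal strain
#'
#' The ortholog score of a gene is the number of other strains having at
#' least one member in the gene's family.  Genes present in `annotation` but
#' absent from the orthology table are scored 0 and flagged (with a warning)
#' rather than dropped, so window indexing stays aligned with the chromosome.
#'
#' @param pan a [pangenome] object.
#' @param focal_strain strain identifier, must be in `pan$strains`.
#' @param annotation optional gene data.frame (columns `gene_id`, and
#'   typically `midpoint`) to align scores with; defaults to the genes of the
#'   focal strain found in the table.
#' @return data.frame with `gene_id`, `family`, `score`, `in_table`.
#' @export
ortholog_scores <- function(pan, focal_strain, annotation = NULL) {
  stopifnot(inherits(pan, "pangenome"))
  if (!focal_strain %in% pan$strains)
    stop("unknown strain: ", focal_strain)
  gi <- pan$gene_index[pan$gene_index$strain == focal_strain, , drop = FALSE]
  fam_species <- setNames(pan$families$n_species, pan$families$family_id)
  scores <- data.frame(gene_id = gi$gene_id, family = gi$family,
                       score = as.integer(fam_species[gi$family] - 1L),
                       in_table = TRUE, stringsAsFactors = FALSE)
  if (is.null(annotation)) return(scores)
  m <- match(annotation$gene_id, scores$gene_id)
  out <- annotation
  out$family <- scores$family[m]
  out$score <- scores$score[m]
  out$in_table <- !is.na(m)
  if (any(!out$in_table)) {
    warning(sprintf("%d gene(s) of %s absent from the orthology table scored 0",
                    sum(!out$in_table), focal_strain))
    out$score[!out$in_table] <- 0L
  }
  out
}

#' Reduce a pan-genome to one strain per genus
#'
#' Keeps one randomly selected (seeded, deterministic) strain per genus and
#' re-tallies every family over the kept strains; families left without
#' members are dropped.  Used as a robustness re-analysis when some genera
#' are overrepresented in a cohort.
#'
#' @param pan a [pangenome] object.
#' @param genus_map named character vector mapping every strain to a genus.
#' @param seed integer seed for the per-genus choice.
#' @return A new [pangenome] restricted to the kept strains.
#' @export
reduce_one_per_genus <- function(pan, genus_map, seed = 1L) {
  stopifnot(inherits(pan, "pangenome"))
  missing <- setdiff(pan$strains, names(genus_map))
  if (length(missing)) stop("genus_map does not cover strains: ",
                            paste(missing, collapse = ", "))
  set.seed(seed)
  keep <- unlist(lapply(split(pan$strains, genus_map[pan$strains]),
                        function(s) if (length(s) == 1) s else sample(s, 1)))
  keep <- pan$strains[pan$strains %in% keep]   # preserve original order
  members <- lapply(pan$members, function(m) m[intersect(names(m), keep)])
  members <- members[vapply(members, function(m) sum(lengths(m)) > 0, logical(1))]
  conn <- setNames(pan$families$connectivity, pan$families$family_id)
  new_pangenome(keep, members, conn[names(members)])
}
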