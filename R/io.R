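# Readers and writers for the pipeline's file formats: Proteinortho-dialect
# orthology tables (hand-parsed: tool-specific dialect), FASTA (Biostrings),
# GFF3 and BED (rtracklayer), and a JSON truth file for simulations.

#' Read a Proteinortho-dialect orthology table
#'
#' The dialect is tab-separated with a header line
#' `# Species<TAB>Genes<TAB>Alg.-Conn.<TAB><strain1>...`; each subsequent row
#' is one family: species count, gene count, algebraic connectivity, then one
#' cell per strain holding comma-separated gene IDs or `*` for absence.
#'
#' @param path file path.
#' @return A [pangenome] object.
#' @export
read_proteinortho <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty orthology table: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 4 || hdr[1] != "# Species" || hdr[2] != "Genes" ||
      hdr[3] != "Alg.-Conn.")
    stop("not a Proteinortho table: header must start with ",
         "'# Species\\tGenes\\tAlg.-Conn.\\t<strains>'")
  strains <- hdr[-(1:3)]
  body <- lines[-1]
  body <- body[nzchar(body)]
  members <- vector("list", length(body))
  connectivity <- numeric(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop(sprintf("row %d has %d columns, expected %d (strain-column mismatch)",
                   i, length(f), length(hdr)))
    cells <- f[-(1:3)]
    mem <- lapply(cells, function(x)
      if (x == "*" || !nzchar(x)) character(0)
      else strsplit(x, ",", fixed = TRUE)[[1]])
    names(mem) <- strains
    mem <- mem[lengths(mem) > 0]
    members[[i]] <- mem
    connectivity[i] <- as.numeric(f[3])
    n_sp <- as.integer(f[1]); n_ge <- as.integer(f[2])
    if (!is.na(n_sp) && n_sp != length(mem))
      warning(sprintf("row %d: stated species count %d != %d observed", i,
                      n_sp, length(mem)))
    if (!is.na(n_ge) && n_ge != sum(lengths(mem)))
      warning(sprintf("row %d: stated gene count %d != %d observed", i,
                      n_ge, sum(lengths(mem))))
  }
  names(members) <- sprintf("F%05d", seq_along(members))
  names(connectivity) <- names(members)
  new_pangenome(strains, members, connectivity)
}

#' Write a pan-genome as a Proteinortho-dialect table
#'
#' @param pan a [pangenome] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proteinortho <- function(pan, path) {
  stopifnot(inherits(pan, "pangenome"))
  hdr <- paste(c("# Species", "Genes", "Alg.-Conn.", pan$strains),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(pan$families)), function(i) {
    fam <- pan$families$family_id[i]
    m <- pan$members[[fam]]
    cells <- vapply(pan$strains, function(s)
      if (is.null(m[[s]]) || !length(m[[s]])) "*"
      else paste(m[[s]], collapse = ","), character(1))
    paste(c(pan$families$n_species[i], pan$families$n_genes[i],
            format(pan$families$connectivity[i], trim = TRUE), cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' @param path GFF3 file (coordinates 1-based inclusive; `ID` attribute must
#'   match the gene IDs used in the orthology table; `Name` carries gene
#'   names such as parA/parB when present).
#' @return data.frame with `gene_id`, `strain` (seqnames), `start`, `end`,
#'   `strand`, `midpoint`, `name`, ordered by position.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  df <- data.frame(
    gene_id = as.character(gr$ID),
    strain = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$midpoint <- (df$start - 1 + df$end) / 2
  df$name <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  df[order(df$start), , drop = FALSE]
}

write_genes_gff3 <- function(catalog, path, genome_length) {
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$strain,
    ranges = IRanges::IRanges(start = catalog$start, end = catalog$end),
    strand = catalog$strand,
    type = "gene", source = "panoric_sim",
    ID = catalog$gene_id, Name = catalog$name)
  GenomeInfoDb::seqlengths(gr) <- setNames(genome_length, catalog$strain[1])
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read prophage / genomic-island region calls from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on input.  Field 4 carries the source tool
#' label (`phaster`, `alienhunter` or `islandviewer`).
#'
#' @param path BED file.
#' @param source source label used when field 4 is absent.
#' @return data.frame with `strain`, `start`, `end`, `type`, `source`.
#' @export
read_regions_bed <- function(path, source = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  src <- if (!is.null(gr$name) && all(nzchar(gr$name))) as.character(gr$name)
         else rep(source %||% stop("BED lacks a source field and no `source` given"),
                  length(gr))
  data.frame(strain = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             type = ifelse(src == "phaster", "phage", "GI"),
             source = src, stringsAsFactors = FALSE)
}

write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$strain,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    name = regions$source)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits one FASTA and one GFF3 per strain, the Proteinortho-dialect
#' orthology table, one BED file per region source, and a JSON truth file.
#' Regenerating with the same seed is bit-identical, and every file
#' round-trips through the package's own readers.
#'
#' @param cohort a [simulate_cohort()] result with sequences.
#' @param dir output directory (created if needed).
#' @return data.frame manifest (`file`, `kind`, `strain`).
#' @export
write_fixture_set <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pangenome_sim"))
  if (is.null(cohort$sequences))
    stop("cohort has no sequences; run simulate_cohort(config, sequences = TRUE)")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to directory: ", dir)
  manifest <- list()
  for (s in cohort$strains) {
    fa <- file.path(dir, paste0(s, ".fasta"))
    dna <- Biostrings::DNAStringSet(setNames(cohort$sequences[[s]], s))
    Biostrings::writeXStringSet(dna, fa, width = 80)
    gff <- file.path(dir, paste0(s, ".gff3"))
    write_genes_gff3(cohort$catalogs[[s]], gff, cohort$config$genome_length)
    manifest[[length(manifest) + 1]] <-
      data.frame(file = basename(c(fa, gff)), kind = c("fasta", "gff3"),
                 strain = s, stringsAsFactors = FALSE)
  }
  po <- file.path(dir, "pangenome.poff.tsv")
  write_proteinortho(cohort$pangenome, po)
  manifest[[length(manifest) + 1]] <-
    data.frame(file = basename(po), kind = "proteinortho", strain = NA,
               stringsAsFactors = FALSE)
  reg <- cohort$truth$regions
  for (src in unique(reg$source)) {
    bed <- file.path(dir, paste0("regions_", src, ".bed"))
    write_regions_bed(reg[reg$source == src, , drop = FALSE], bed)
    manifest[[length(manifest) + 1]] <-
      data.frame(file = basename(bed), kind = "bed", strain = NA,
                 stringsAsFactors = FALSE)
  }
  tr <- file.path(dir, "truth.json")
  truth <- cohort$truth
  jsonlite::write_json(
    list(true_oric = as.list(truth$true_oric),
         true_beta = truth$true_beta,
         genome_length = truth$genome_length,
         family_occupancy = as.list(truth$family_occupancy),
         regions = truth$regions,
         dnaa_boxes = cohort$dnaa_boxes),
    tr, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest[[length(manifest) + 1]] <-
    data.frame(file = basename(tr), kind = "truth", strain = NA,
               stringsAsFactors = FALSE)
  do.call(rbind, manifest)
}

#' Read a simulation truth file
#'
#' @param path JSON truth file written by [write_fixture_set()].
#' @return list of class `simulation_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- list(true_oric = unlist(x$true_oric),
                true_beta = x$true_beta,
                genome_length = x$genome_length,
                family_occupancy = unlist(x$family_occupancy),
                regions = x$regions)
  class(truth) <- "simulation_truth"
  truth
}
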