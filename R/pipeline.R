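# End-to-end orchestration: configuration, the pipeline driver, table
# writers and the cohort summary.

#' Build a pipeline run configuration
#'
#' Exactly one input mode must be given: either `simulate` (a [sim_config()])
#' or the real-input paths (`fasta_dir` + `gff_dir` + `orthology`, with
#' optional `region_beds`).
#'
#' @param simulate a [sim_config()] for synthetic runs, or `NULL`.
#' @param fasta_dir,gff_dir directories of per-strain FASTA / GFF3 files
#'   (basename before the extension = strain ID).
#' @param orthology Proteinortho-dialect TSV path.
#' @param region_beds character vector of BED paths (field 4 = source tool).
#' @param outdir output directory for tables and the run log.
#' @param seed integer seed for the run.
#' @param window_size,step sliding-window parameters.
#' @param alpha significance level.
#' @param soft_core_fraction,connectivity_min family classification knobs.
#' @param n_segments segment count for the enrichment analysis.
#' @param oric_params named list of overrides passed to [call_oric()].
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, fasta_dir = NULL, gff_dir = NULL,
                       orthology = NULL, region_beds = NULL,
                       outdir = tempfile("panoric_run_"), seed = 1L,
                       window_size = 20, step = 1, alpha = 0.05,
                       soft_core_fraction = 0.95, connectivity_min = 0.9,
                       n_segments = 8, oric_params = list()) {
  real <- !is.null(fasta_dir) || !is.null(gff_dir) || !is.null(orthology)
  if (!is.null(simulate) && real)
    stop("configuration error: give either `simulate` or real input paths, not both")
  if (is.null(simulate) && !real)
    stop("configuration error: no inputs (need `simulate` or real input paths)")
  if (real && (is.null(fasta_dir) || is.null(gff_dir) || is.null(orthology)))
    stop("real inputs need fasta_dir, gff_dir and orthology")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(simulate = simulate, fasta_dir = fasta_dir,
                 gff_dir = gff_dir, orthology = orthology,
                 region_beds = region_beds, outdir = outdir,
                 seed = as.integer(seed), window_size = window_size,
                 step = step, alpha = alpha,
                 soft_core_fraction = soft_core_fraction,
                 connectivity_min = connectivity_min,
                 n_segments = n_segments, oric_params = oric_params),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate` block
#' is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$conservation_mixture))
      y$simulate$conservation_mixture <-
        as.data.frame(y$simulate$conservation_mixture)
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(run_config, y)
}

write_tsv_with_header <- function(df, path, config, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# panoric %s | %s | seed=%d window_size=%d alpha=%g soft_core_fraction=%g connectivity_min=%g n_segments=%d",
                     as.character(utils::packageVersion("panoric")), what,
                     config$seed, config$window_size, config$alpha,
                     config$soft_core_fraction, config$connectivity_min,
                     config$n_segments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read panoric output tables (comment-headed TSV)
#' @param path TSV written by [run_pipeline()].
#' @return data.frame.
#' @export
read_result_tsv <- function(path)
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)

#' Run the full positional pan-genome pipeline
#'
#' Executes, in order: input acquisition (simulation or file reading), family
#' classification, per-strain oriC calling (strains with ambiguous origins
#' are excluded from the positional statistics but stay in the pan-genome
#' counts), ortholog scoring, sliding-window gradient fits, slope-population
#' analysis, segment enrichment, and — when region annotations are present —
#' the chromosome-thirds analysis.  All tables are written to
#' `config$outdir` with a parameter-provenance header line.
#'
#' @param config a [run_config()].
#' @return Object of class `pipeline_report` with all stage results and a
#'   file `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c(sprintf("panoric %s | seed %d | started %s",
                         as.character(utils::packageVersion("panoric")),
                         config$seed, format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  stage <- function(name, strain = NA, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s'%s failed: %s", name,
                   if (is.na(strain)) "" else paste0(" (strain ", strain, ")"),
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", expr = simulate_cohort(config$simulate))
    pan <- sim$pangenome
    catalogs <- sim$catalogs
    sequences <- sim$sequences
    regions <- sim$truth$regions
    lengths <- setNames(rep(config$simulate$genome_length,
                            length(sim$strains)), sim$strains)
    truth <- sim$truth
  } else {
    pan <- stage("read_orthology", expr = read_proteinortho(config$orthology))
    fa_files <- list.files(config$fasta_dir, "\\.(fa|fasta|fna)$",
                           full.names = TRUE)
    sequences <- list(); lengths <- c()
    for (f in fa_files) {
      dna <- stage("read_fasta", basename(f),
                   Biostrings::readDNAStringSet(f))
      s <- sub("\\s.*", "", names(dna)[1])
      sequences[[s]] <- as.character(dna[[1]])
      lengths[s] <- nchar(sequences[[s]])
    }
    gff_files <- list.files(config$gff_dir, "\\.gff3?$", full.names = TRUE)
    catalogs <- list()
    for (f in gff_files) {
      g <- stage("read_gff", basename(f), read_genes_gff3(f))
      catalogs[[g$strain[1]]] <- g
    }
    regions <- if (length(config$region_beds))
      do.call(rbind, lapply(config$region_beds, read_regions_bed)) else NULL
  }
  strains <- intersect(pan$strains, names(catalogs))

  classification <- stage("classify_families", expr =
    classify_families(pan, config$soft_core_fraction, config$connectivity_min))

  oric_calls <- list()
  for (s in strains) {
    if (is.null(sequences[[s]])) next
    oric_calls[[s]] <- stage("call_oric", s, do.call(call_oric, c(
      list(sequence = sequences[[s]], genes = catalogs[[s]]),
      config$oric_params)))
  }
  called <- names(oric_calls)[vapply(oric_calls, function(x)
    x$status == "called", logical(1))]
  ambiguous <- setdiff(names(oric_calls), called)
  log_lines <- c(log_lines,
                 sprintf("oriC called for %d strains, ambiguous for %d (excluded downstream)",
                         length(called), length(ambiguous)))

  frames <- list(); fits <- list()
  for (s in called) {
    genes <- stage("ortholog_scores", s,
                   ortholog_scores(pan, s, annotation = catalogs[[s]]))
    reg_s <- if (!is.null(regions))
      regions[regions$strain == s, , drop = FALSE] else NULL
    frames[[s]] <- stage("chromosome_frame", s,
      chromosome_frame(s, lengths[[s]], oric_calls[[s]]$oric, genes, reg_s))
    ws <- stage("window_series", s,
                window_series(frames[[s]], config$window_size, config$step))
    fits[[s]] <- stage("fit", s,
                       fit_conservation_gradient(ws, config$alpha))
  }

  fit_table <- if (length(fits))
    do.call(rbind, lapply(fits, summary)) else data.frame()
  rownames(fit_table) <- NULL
  slope_pop <- if (length(fits) >= 2)
    stage("slope_population", expr = slope_population(fits, config$alpha))
    else NULL
  segments <- if (length(frames) >= 2)
    stage("segment_analysis", expr =
      segment_analysis(frames, config$n_segments)) else NULL
  thirds <- if (length(frames) >= 2 && !is.null(regions) &&
                any(vapply(frames, function(fr)
                  !is.null(fr$regions) && nrow(fr$regions) > 0, logical(1))))
    stage("thirds_region_analysis", expr = thirds_region_analysis(frames))
    else NULL

  # ---- write tables -------------------------------------------------------
  manifest <- character(0)
  emit <- function(df, name, what) {
    p <- file.path(config$outdir, name)
    write_tsv_with_header(df, p, config, what)
    manifest <<- c(manifest, p)
  }
  emit(as.data.frame(classification), "family_classification.tsv",
       "per-family classification")
  emit(pangenome_summary(classification), "pangenome_summary.tsv",
       "pan-genome headline counts")
  oric_table <- data.frame(
    strain = names(oric_calls),
    status = vapply(oric_calls, `[[`, character(1), "status"),
    oric = vapply(oric_calls, `[[`, numeric(1), "oric"),
    stringsAsFactors = FALSE)
  if (nrow(oric_table)) emit(oric_table, "oric_calls.tsv", "oriC calls")
  if (nrow(fit_table)) emit(fit_table, "gradient_fits.tsv",
                            "per-strain window-gradient fits")
  if (!is.null(slope_pop)) {
    emit(slope_pop$qq, "slope_qq.tsv", "slope QQ table")
  }
  if (!is.null(segments)) {
    emit(segments$summary, "segment_summary.tsv", "segment summary")
    emit(segments$tukey, "segment_tukey.tsv", "segment Tukey HSD")
  }
  if (!is.null(thirds)) {
    for (src in names(thirds)) {
      emit(thirds[[src]]$per_strain, paste0("thirds_", src, ".tsv"),
           paste("thirds analysis,", src))
      emit(thirds[[src]]$tukey_count, paste0("thirds_tukey_", src, ".tsv"),
           paste("thirds Tukey HSD (counts),", src))
    }
  }
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))

  structure(list(config = config, pangenome = pan,
                 classification = classification,
                 oric_calls = oric_calls, frames = frames, fits = fits,
                 fit_table = fit_table, slope_population = slope_pop,
                 segments = segments, thirds = thirds, truth = truth,
                 called = called, ambiguous = ambiguous,
                 manifest = manifest, outdir = config$outdir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("panoric pipeline report\n")
  print(summarize_cohort(x))
  cat(sprintf("  %d output table(s) in %s\n", length(x$manifest), x$outdir))
  invisible(x)
}

#' Headline cohort counts from a pipeline report
#'
#' @param report a [run_pipeline()] result.
#' @return One-row data.frame: strains analyzed, oriC called / ambiguous,
#'   strains with significant negative / positive gradient slopes, and total
#'   negative / positive slopes.
#' @export
summarize_cohort <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  sp <- report$slope_population
  data.frame(n_strains = length(report$pangenome$strains),
             oric_called = length(report$called),
             oric_ambiguous = length(report$ambiguous),
             sig_negative = if (is.null(sp)) 0L else sp$sig_negative,
             sig_positive = if (is.null(sp)) 0L else sp$sig_positive,
             n_negative = if (is.null(sp)) 0L else sp$n_negative,
             n_positive = if (is.null(sp)) 0L else sp$n_positive)
}
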