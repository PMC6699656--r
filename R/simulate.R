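# Synthetic cohort generator: multi-strain pan-genome with a planted
# conservation gradient along the replication axis, circular sequences with a
# planted GC-disparity extremum and DnaA boxes at the true oriC, and planted
# phage / genomic-island regions.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic cohort generator.
#'
#' @param n_strains number of strains in the cohort.
#' @param n_families number of ortholog families before per-strain padding.
#' @param genes_per_strain exact number of genes on every chromosome.
#' @param genome_length chromosome length in bp.
#' @param conservation_mixture data.frame with columns `occupancy` (fraction
#'   of strains carrying a family, in `[0,1]`) and `weight` (mixture weights,
#'   summing to 1).  Controls how many strains carry each family.
#' @param positional_bias_beta expected change in mean ortholog score per unit
#'   normalized distance from oriC.  Negative values cluster conserved genes
#'   near oriC, positive near terC, 0 places genes at random.
#' @param skew_amplitude strand-compositional asymmetry in `[0,1]`: the
#'   leading strand has G fraction `gc/2*(1+skew)` and C `gc/2*(1-skew)`,
#'   so the cumulative G-C disparity attains its minimum at the true oriC.
#' @param n_dnaa_boxes exact copies of the canonical DnaA box planted in the
#'   intergenic region at the true oriC.
#' @param phage_placement,gi_placement distribution of planted regions over
#'   normalized distance from oriC: `"uniform"`, `"near_ter"` or `"near_ori"`.
#' @param n_phage_regions,n_gi_regions planted regions per strain (genomic
#'   islands are emitted once per island caller, see [simulate_pangenome()]).
#' @param region_length_range bp range for planted region lengths.
#' @param paralog_fraction fraction of families receiving a second in-strain
#'   member (creates paralogs, exercising the paralog filter).
#' @param mean_gene_length gene length in bp.
#' @param gc_content genome-wide GC fraction (Rhodobacteraceae-like default).
#' @param oric_gc GC fraction of the AT-rich intergenic region at oriC.
#' @param par_genes plant parA/parB genes flanking the true oriC.
#' @param seed integer seed; the same seed regenerates bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 20,
                       n_families = 1700,
                       genes_per_strain = 1000,
                       genome_length = 2e6,
                       conservation_mixture = data.frame(
                         occupancy = c(1.0, 0.95, 0.5, 0.15),
                         weight = c(0.35, 0.10, 0.15, 0.40)),
                       positional_bias_beta = 0,
                       skew_amplitude = 0.3,
                       n_dnaa_boxes = 6,
                       phage_placement = c("near_ter", "uniform", "near_ori"),
                       gi_placement = c("uniform", "near_ter", "near_ori"),
                       n_phage_regions = 6,
                       n_gi_regions = 6,
                       region_length_range = c(15000, 40000),
                       paralog_fraction = 0.05,
                       mean_gene_length = 900,
                       gc_content = 0.60,
                       oric_gc = 0.35,
                       par_genes = TRUE,
                       seed = 1L) {
  phage_placement <- match.arg(phage_placement)
  gi_placement <- match.arg(gi_placement)
  mx <- conservation_mixture
  stop_if_not(is.data.frame(mx) && all(c("occupancy", "weight") %in% names(mx)),
              "conservation_mixture must have columns `occupancy` and `weight`")
  stop_if_not(all(mx$occupancy >= 0 & mx$occupancy <= 1),
              "all occupancy fractions must lie in [0, 1]")
  stop_if_not(isTRUE(all.equal(sum(mx$weight), 1)),
              "conservation_mixture weights must sum to 1")
  stop_if_not(skew_amplitude >= 0 && skew_amplitude <= 1,
              "skew_amplitude must lie in [0, 1]")
  stop_if_not(n_strains >= 2, "need at least 2 strains")
  stop_if_not(genes_per_strain >= 1 && n_families >= 1,
              "gene and family counts must be positive")
  # room for every gene plus intergenic spacing on the circle
  stop_if_not(genome_length >= genes_per_strain * (mean_gene_length + 100),
              paste("genome_length too small: need at least genes_per_strain *",
                    "(mean_gene_length + 100) bp"))
  stop_if_not(paralog_fraction >= 0 && paralog_fraction < 1,
              "paralog_fraction must lie in [0, 1)")
  cfg <- list(n_strains = as.integer(n_strains),
              n_families = as.integer(n_families),
              genes_per_strain = as.integer(genes_per_strain),
              genome_length = as.integer(genome_length),
              conservation_mixture = mx,
              positional_bias_beta = positional_bias_beta,
              skew_amplitude = skew_amplitude,
              n_dnaa_boxes = as.integer(n_dnaa_boxes),
              phage_placement = phage_placement,
              gi_placement = gi_placement,
              n_phage_regions = as.integer(n_phage_regions),
              n_gi_regions = as.integer(n_gi_regions),
              region_length_range = region_length_range,
              paralog_fraction = paralog_fraction,
              mean_gene_length = as.integer(mean_gene_length),
              gc_content = gc_content,
              oric_gc = oric_gc,
              par_genes = isTRUE(par_genes),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# per-strain RNG stream derived from the master seed (kept under 2^31)
strain_seed <- function(seed, idx) as.integer((as.double(seed) + 7919 * idx) %% 2147483647)

# normalized-distance sampler for planted regions
sample_placement <- function(n, placement) {
  switch(placement,
         uniform  = runif(n),
         near_ter = rbeta(n, 3, 1),
         near_ori = rbeta(n, 1, 3))
}

#' Simulate a multi-strain pan-genome with a positional conservation gradient
#'
#' Draws each family's carrier-strain count from the conservation mixture,
#' then places genes on each circular chromosome so that the expected
#' ortholog score at normalized distance `d` from the true oriC is
#' approximately `a + beta * d`.  Placement uses rank-matching of the gene
#' scores against a noisy linear score over positions; the noise level is
#' calibrated (Gaussian-copula argument) so that the realized gradient slope
#' matches `positional_bias_beta`.  Every strain ends up with exactly
#' `genes_per_strain` genes: strains over budget shed random accessory
#' memberships, strains under budget gain strain-specific singleton families.
#'
#' @param config a [sim_config()].
#' @return An object of class `pangenome_sim`: a list with `config`,
#'   `catalogs` (one gene data.frame per strain, with true positions and
#'   family assignments), `pangenome` (a [pangenome] object) and `truth`
#'   (true oriC per strain, true beta, planted regions, family occupancy).
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_strains
  strains <- sprintf("strain%02d", seq_len(ns))
  mx <- config$conservation_mixture

  occ <- sample(mx$occupancy, config$n_families, replace = TRUE, prob = mx$weight)
  carriers_n <- pmax(1L, as.integer(round(occ * ns)))
  n_core_demanded <- sum(carriers_n == ns)
  if (n_core_demanded > config$genes_per_strain)
    stop(sprintf(paste("infeasible config: %d core families demanded but only",
                       "%d genes per strain (core families cannot exceed",
                       "genes_per_strain)"),
                 n_core_demanded, config$genes_per_strain))

  fam_ids <- sprintf("F%05d", seq_len(config$n_families))
  memb <- data.frame(
    family = rep(fam_ids, carriers_n),
    strain = unlist(lapply(carriers_n, function(m) sample(strains, m))),
    stringsAsFactors = FALSE)

  # paralogs: duplicate one member in a random carrier strain
  n_paralog <- round(config$paralog_fraction * config$n_families)
  if (n_paralog > 0) {
    pfams <- sample(fam_ids, n_paralog)
    dup <- do.call(rbind, lapply(pfams, function(f) {
      carr <- memb$strain[memb$family == f]
      data.frame(family = f, strain = sample(carr, 1), stringsAsFactors = FALSE)
    }))
    memb <- rbind(memb, dup)
  }

  # exact per-strain gene budget
  target <- config$genes_per_strain
  singleton_k <- 0L
  for (s in strains) {
    idx <- which(memb$strain == s)
    excess <- length(idx) - target
    if (excess > 0) {
      # unique-carrier count per family; rows beyond the first per
      # (family, strain) pair are paralog duplicates
      fam_occ <- vapply(split(memb$strain, memb$family),
                        function(x) length(unique(x)), integer(1))
      dup_row <- duplicated(paste(memb$family, memb$strain))
      # removable: any non-core membership (families may vanish entirely),
      # or a paralog duplicate inside a core family
      removable <- idx[fam_occ[memb$family[idx]] < ns | dup_row[idx]]
      pick <- if (length(removable) >= excess)
                removable[sample.int(length(removable), excess)]
              else stop("infeasible config: cannot trim strain to genes_per_strain without breaking a core family")
      memb <- memb[-pick, ]
    } else if (excess < 0) {
      k <- -excess
      new_ids <- sprintf("S%05d", singleton_k + seq_len(k))
      singleton_k <- singleton_k + k
      memb <- rbind(memb, data.frame(family = new_ids, strain = rep(s, k),
                                     stringsAsFactors = FALSE))
    }
  }

  all_fams <- sort(unique(memb$family))
  connectivity <- setNames(round(rbeta(length(all_fams), 8, 1), 4), all_fams)
  occupancy <- vapply(split(memb$strain, memb$family),
                      function(x) length(unique(x)), integer(1))[all_fams]

  L <- config$genome_length
  glen <- config$mean_gene_length
  spacing <- L %/% config$genes_per_strain
  gap <- spacing - glen
  beta <- config$positional_bias_beta

  catalogs <- vector("list", ns)
  names(catalogs) <- strains
  true_oric <- setNames(numeric(ns), strains)
  regions <- list()

  for (si in seq_len(ns)) {
    s <- strains[si]
    n <- target
    j <- sample.int(n, 1) - 1L            # oriC sits in the gap at slot j
    o <- (j * spacing) %% L
    true_oric[s] <- o
    start0 <- (gap %/% 2 + (seq_len(n) - 1L) * spacing)  # 0-based, no wrap
    mids <- start0 + glen / 2
    d <- circ_dist(mids, o, L) / (L / 2)

    fams <- memb$family[memb$strain == s]
    score <- occupancy[fams] - 1L          # ortholog score of each gene
    # rank-match scores to a noisy linear score over positions; rho calibrated
    # so the realized E[score | d] slope ~= beta.  The calibration constant is
    # the normal-scores covariance of the score distribution (equals sd(score)
    # for normal scores, smaller for the discrete occupancy mixture).
    lambda <- mean(sort(score) * qnorm(ppoints(n)))
    if (lambda > 0 && beta != 0) {
      rho <- max(-0.99, min(0.99, beta * sd(d) / lambda))
    } else rho <- 0
    tgt <- rho * as.numeric(scale(d)) + sqrt(1 - rho^2) * rnorm(n)
    fams_sorted <- fams[order(score + runif(n) * 1e-6)]   # random tie-break
    slot_of <- order(tgt)                 # slots ordered by target ascending
    fam_at_slot <- character(n)
    fam_at_slot[slot_of] <- fams_sorted
    gene_ids <- sprintf("%s_%05d", s, seq_len(n))
    name <- rep(NA_character_, n)
    if (config$par_genes) {
      # first gene clockwise after oriC and the gene just before it
      name[((j) %% n) + 1L] <- "parA"
      name[((j - 1L) %% n) + 1L] <- "parB"
    }
    catalogs[[s]] <- data.frame(
      gene_id = gene_ids, strain = s,
      start = as.integer(start0 + 1L), end = as.integer(start0 + glen),
      strand = sample(c("+", "-"), n, replace = TRUE),
      midpoint = mids, family = fam_at_slot, name = name,
      stringsAsFactors = FALSE)

    regions[[s]] <- plant_regions(config, s, o)
  }

  # gene ids per family: from catalogs (positional ids), grouped by strain
  gene_tbl <- do.call(rbind, catalogs)
  members <- lapply(split(gene_tbl[c("gene_id", "strain")], gene_tbl$family),
                    function(df) split(df$gene_id, df$strain))
  members <- members[all_fams]

  pan <- new_pangenome(strains, members, connectivity)
  region_truth <- do.call(rbind, regions)
  rownames(region_truth) <- NULL

  truth <- list(true_oric = true_oric,
                true_beta = beta,
                genome_length = L,
                family_occupancy = occupancy,
                regions = region_truth)
  class(truth) <- "simulation_truth"

  out <- list(config = config, strains = strains, catalogs = catalogs,
              pangenome = pan, truth = truth)
  class(out) <- "pangenome_sim"
  out
}

# planted phage / genomic-island intervals for one strain (1-based inclusive,
# kept off the assembly boundary so downstream BED files need no wrap).
plant_regions <- function(config, strain, oric) {
  L <- config$genome_length
  one_set <- function(n, placement, type, source) {
    if (n == 0) return(NULL)
    start <- integer(n); end <- integer(n)
    for (i in seq_len(n)) {
      for (try in 1:50) {
        nd <- sample_placement(1, placement)
        side <- sample(c(-1, 1), 1)
        len <- round(runif(1, config$region_length_range[1],
                           config$region_length_range[2]))
        mid <- (oric + side * nd * L / 2) %% L
        st <- round(mid - len / 2)
        if (st >= 0 && st + len - 1 < L) break
      }
      st <- max(0, min(st, L - len))
      start[i] <- st + 1; end[i] <- st + len
    }
    data.frame(strain = strain, start = start, end = end, type = type,
               source = source, stringsAsFactors = FALSE)
  }
  phage <- one_set(config$n_phage_regions, config$phage_placement,
                   "phage", "phaster")
  gi1 <- one_set(config$n_gi_regions, config$gi_placement, "GI", "alienhunter")
  gi2 <- one_set(config$n_gi_regions, config$gi_placement, "GI", "islandviewer")
  rbind(phage, gi1, gi2)
}

#' Simulate a circular chromosome sequence with planted oriC signals
#'
#' Generates the nucleotide sequence for one strain of a [simulate_pangenome()]
#' catalog.  The leading strand of each replichore is G-enriched by
#' `skew_amplitude`, so the cumulative G-C disparity curve has its minimum at
#' the true oriC and its maximum at terC.  The intergenic region at oriC is
#' AT-rich and carries `n_dnaa_boxes` exact copies of the canonical DnaA box
#' (TTATCCACA); planted phage/GI regions get a GC-depressed composition.
#'
#' @param catalog one strain's gene data.frame from [simulate_pangenome()].
#' @param config the [sim_config()] used to generate the catalog.
#' @param oric true origin position (bp, 0-based); defaults to the value
#'   recorded in `truth`.
#' @param regions planted regions for this strain (data.frame, may be NULL).
#' @param seed integer seed for this strain's sequence.
#' @return list with `sequence` (character), `dnaa_boxes` (data.frame of
#'   planted box coordinates, 1-based starts) and `oric`.
#' @export
simulate_sequence <- function(catalog, config, oric, regions = NULL,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$skew_amplitude < 0 || config$skew_amplitude > 1)
    stop("skew_amplitude must lie in [0, 1]")
  set.seed(seed)
  L <- config$genome_length
  gc <- config$gc_content
  at <- 1 - gc
  sk <- config$skew_amplitude
  o <- as.integer(oric)

  # circular-order composition: first half (oriC -> terC clockwise) G/T rich
  half1 <- L %/% 2
  p_right <- c(A = at / 2 * (1 - sk / 2), C = gc / 2 * (1 - sk),
               G = gc / 2 * (1 + sk),     T = at / 2 * (1 + sk / 2))
  p_left <- p_right[c("T", "G", "C", "A")]
  names(p_left) <- c("A", "C", "G", "T")
  bases <- c("A", "C", "G", "T")
  circ <- c(sample(bases, half1, replace = TRUE, prob = p_right),
            sample(bases, L - half1, replace = TRUE, prob = p_left))
  # rotate into assembly coordinates: assembly[p] = circ[(p - o) mod L]
  seqv <- circ[((seq_len(L) - 1L - o) %% L) + 1L]

  # AT-rich oriC gap, centered on o (may wrap the assembly boundary)
  spacing <- L %/% config$genes_per_strain
  gap <- spacing - config$mean_gene_length
  gidx <- ((o - gap %/% 2 + seq_len(gap) - 1L) %% L) + 1L
  p_ori <- c(A = (1 - config$oric_gc) / 2, C = config$oric_gc / 2,
             G = config$oric_gc / 2, T = (1 - config$oric_gc) / 2)
  seqv[gidx] <- sample(bases, gap, replace = TRUE, prob = p_ori)

  # planted regions: GC-depressed composition (keeps replichore skew out)
  if (!is.null(regions) && nrow(regions)) {
    rgc <- max(0.05, gc - 0.08)
    p_reg <- c(A = (1 - rgc) / 2, C = rgc / 2, G = rgc / 2, T = (1 - rgc) / 2)
    for (i in seq_len(nrow(regions))) {
      ii <- regions$start[i]:regions$end[i]
      seqv[ii] <- sample(bases, length(ii), replace = TRUE, prob = p_reg)
    }
  }

  # exact DnaA boxes in the oriC gap
  boxes <- NULL
  nb <- config$n_dnaa_boxes
  if (nb > 0) {
    motif <- strsplit(dnaa_motifs()[1], "")[[1]]
    space <- max(10L, min(25L, as.integer(floor(gap * 0.8 / nb))))
    if (space < 10L) stop("oriC intergenic gap too small for requested DnaA boxes")
    span <- nb * space
    first <- o - span %/% 2
    starts0 <- first + (seq_len(nb) - 1L) * space
    for (st in starts0) {
      ii <- ((st + seq_len(9) - 1L) %% L) + 1L
      seqv[ii] <- motif
    }
    boxes <- data.frame(strain = catalog$strain[1],
                        position = as.integer((starts0 %% L) + 1L),
                        motif = dnaa_motifs()[1], stringsAsFactors = FALSE)
  }

  list(sequence = paste(seqv, collapse = ""), dnaa_boxes = boxes, oric = o)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_pangenome()] and, optionally, [simulate_sequence()] for
#' every strain, giving a self-consistent set of inputs for the full
#' pipeline.
#'
#' @param config a [sim_config()].
#' @param sequences generate nucleotide sequences (set `FALSE` for
#'   statistics-only cohorts, which is much faster).
#' @return An object of class `cohort_sim` extending the
#'   [simulate_pangenome()] result with `sequences` (named character list)
#'   and `dnaa_boxes`.
#' @export
simulate_cohort <- function(config, sequences = TRUE) {
  sim <- simulate_pangenome(config)
  sim$sequences <- NULL
  sim$dnaa_boxes <- NULL
  if (sequences) {
    seqs <- vector("list", length(sim$strains))
    names(seqs) <- sim$strains
    boxes <- list()
    for (i in seq_along(sim$strains)) {
      s <- sim$strains[i]
      reg <- sim$truth$regions[sim$truth$regions$strain == s, , drop = FALSE]
      sq <- simulate_sequence(sim$catalogs[[s]], config,
                              oric = sim$truth$true_oric[s], regions = reg,
                              seed = strain_seed(config$seed, i))
      seqs[[s]] <- sq$sequence
      boxes[[s]] <- sq$dnaa_boxes
    }
    sim$sequences <- seqs
    sim$dnaa_boxes <- do.call(rbind, boxes)
  }
  class(sim) <- c("cohort_sim", "pangenome_sim")
  sim
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat("Synthetic pan-genome cohort\n")
  cat(sprintf("  strains: %d, families: %d, genes/strain: %d, genome: %d bp\n",
              length(x$strains), length(x$pangenome$families$family_id),
              x$config$genes_per_strain, x$config$genome_length))
  cat(sprintf("  true beta: %g, skew: %g, DnaA boxes: %d\n",
              x$truth$true_beta, x$config$skew_amplitude, x$config$n_dnaa_boxes))
  if (!is.null(x$sequences)) cat("  sequences: generated\n")
  invisible(x)
}
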