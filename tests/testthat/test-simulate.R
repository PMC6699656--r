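# Synthetic-cohort generator: config validation, exact structure, planted
# signals and file round-trips.

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(conservation_mixture =
    data.frame(occupancy = c(1, 0.5), weight = c(0.6, 0.6))), "sum to 1")
  expect_error(sim_config(conservation_mixture =
    data.frame(occupancy = c(1.4), weight = 1)), "occupancy")
  expect_error(sim_config(skew_amplitude = 1.5), "skew_amplitude")
  expect_error(sim_config(genes_per_strain = 1000, genome_length = 5e5),
               "genome_length too small")
  expect_error(sim_config(paralog_fraction = 1), "paralog_fraction")
})

test_that("a config demanding more core families than the gene budget errors", {
  cfg <- tiny_cfg(n_families = 300, genes_per_strain = 120,
                  conservation_mixture = data.frame(occupancy = 1, weight = 1))
  expect_error(simulate_pangenome(cfg), "infeasible")
})

test_that("every strain gets exactly genes_per_strain genes", {
  for (beta in c(-5, 0)) {
    sim <- simulate_pangenome(tiny_cfg(positional_bias_beta = beta, seed = 21))
    counts <- vapply(sim$catalogs, nrow, integer(1))
    expect_true(all(counts == sim$config$genes_per_strain))
    # and the orthology table agrees gene-for-gene
    per_strain <- table(sim$pangenome$gene_index$strain)
    expect_true(all(per_strain == sim$config$genes_per_strain))
  }
})

test_that("gene placement correlates with occupancy in the direction of true beta", {
  for (beta in c(-5, 5)) {
    sim <- simulate_pangenome(tiny_cfg(positional_bias_beta = beta, seed = 31))
    s <- sim$strains[1]
    cat <- sim$catalogs[[s]]
    occ <- sim$truth$family_occupancy[cat$family]
    d <- circular_distance(cat$midpoint, sim$truth$true_oric[s],
                           sim$config$genome_length)$normalized
    expect_equal(sign(cor(occ, d, method = "spearman")), sign(beta))
  }
})

test_that("sequences have the configured length and planted, findable DnaA boxes", {
  cfg <- tiny_cfg(seed = 41)
  sim <- simulate_cohort(cfg)
  s <- sim$strains[1]
  expect_equal(nchar(sim$sequences[[s]]), cfg$genome_length)
  planted <- sim$dnaa_boxes[sim$dnaa_boxes$strain == s, ]
  expect_equal(nrow(planted), cfg$n_dnaa_boxes)
  for (i in seq_len(nrow(planted)))
    expect_equal(substr(sim$sequences[[s]], planted$position[i],
                        planted$position[i] + 8), planted$motif[i])
})

test_that("out-of-range skew is rejected at sequence generation", {
  cfg <- tiny_cfg(seed = 1)
  sim <- simulate_pangenome(cfg)
  bad <- cfg; bad$skew_amplitude <- 2
  expect_error(simulate_sequence(sim$catalogs[[1]], bad,
                                 oric = sim$truth$true_oric[1]),
               "skew_amplitude")
})

test_that("the cumulative GC disparity extremum lands at the true oriC", {
  cfg <- tiny_cfg(seed = 51)
  sim <- simulate_cohort(cfg)
  for (s in sim$strains[1:2]) {
    dc <- disparity_curves(sim$sequences[[s]], step = 100)
    err <- min(abs(dc$min_pos - sim$truth$true_oric[s]),
               cfg$genome_length - abs(dc$min_pos - sim$truth$true_oric[s]))
    expect_lt(err, 0.01 * cfg$genome_length)
    expect_false(dc$flat)
  }
})

test_that("fixture sets round-trip through the package readers", {
  cfg <- tiny_cfg(n_strains = 4, n_families = 180, seed = 61)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(sim, dir)
  # one FASTA + one GFF3 per strain
  expect_equal(sum(manifest$kind == "fasta"), 4)
  expect_equal(sum(manifest$kind == "gff3"), 4)

  pan2 <- read_proteinortho(file.path(dir, "pangenome.poff.tsv"))
  expect_equal(pan2$strains, sim$pangenome$strains)
  m1 <- lapply(sim$pangenome$members, function(m) lapply(m, sort))
  m2 <- lapply(pan2$members, function(m) lapply(m, sort))
  expect_equal(unname(m1), unname(m2))

  s <- sim$strains[1]
  genes <- read_genes_gff3(file.path(dir, paste0(s, ".gff3")))
  expect_equal(genes$gene_id, sim$catalogs[[s]]$gene_id)
  expect_equal(genes$start, sim$catalogs[[s]]$start)
  expect_equal(genes$end, sim$catalogs[[s]]$end)
  expect_true("parA" %in% genes$name && "parB" %in% genes$name)

  fa <- Biostrings::readDNAStringSet(file.path(dir, paste0(s, ".fasta")))
  expect_equal(as.character(fa[[1]]), sim$sequences[[s]])

  beds <- list.files(dir, "^regions_.*\\.bed$", full.names = TRUE)
  reread <- do.call(rbind, lapply(beds, read_regions_bed))
  truth <- sim$truth$regions
  key <- function(df) df[order(df$source, df$strain, df$start),
                         c("strain", "start", "end", "source")]
  expect_equal(key(reread), key(truth), ignore_attr = TRUE)

  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$true_oric, sim$truth$true_oric)
  expect_equal(tr$true_beta, sim$truth$true_beta)
})

test_that("regeneration with the same seed is bit-identical on disk", {
  cfg <- tiny_cfg(n_strains = 3, n_families = 150, seed = 71)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_set(simulate_cohort(cfg), d1)
  write_fixture_set(simulate_cohort(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  md5 <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  expect_equal(md5(d1, f1), md5(d2, f2))
  # a different seed must differ
  d3 <- withr::local_tempdir()
  cfg3 <- tiny_cfg(n_strains = 3, n_families = 150, seed = 72)
  write_fixture_set(simulate_cohort(cfg3), d3)
  expect_false(all(md5(d1, f1) == md5(d3, sort(list.files(d3)))))
})
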