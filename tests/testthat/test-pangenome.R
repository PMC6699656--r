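# Orthology-table parsing, family classification and ortholog scores.

test_that("Proteinortho dialect is parsed, including paralogs and absences", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Species\tGenes\tAlg.-Conn.\tA\tB",
               "2\t3\t0.5\ta1,a2\tb1",
               "1\t1\t1\t*\tb2"), path)
  pan <- read_proteinortho(path)
  expect_equal(pan$strains, c("A", "B"))
  expect_equal(pan$families$n_species, c(2L, 1L))
  expect_equal(pan$families$n_genes, c(3L, 1L))
  expect_equal(pan$families$connectivity, c(0.5, 1))
  expect_setequal(pan$members[[1]]$A, c("a1", "a2"))
  cl <- classify_families(pan)
  expect_true(cl$has_paralogs[1])
  expect_false(cl$has_paralogs[2])
  expect_equal(cl$label, c("core", "accessory"))
})

test_that("malformed orthology tables give descriptive errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Species\tGenes\tConn\tA", "1\t1\t1\ta1"), path)
  expect_error(read_proteinortho(path), "header")
  writeLines(c("# Species\tGenes\tAlg.-Conn.\tA\tB", "1\t1\t1\ta1"), path)
  expect_error(read_proteinortho(path), "mismatch")
  # same gene ID in two families
  writeLines(c("# Species\tGenes\tAlg.-Conn.\tA\tB",
               "1\t1\t1\ta1\t*", "1\t1\t1\ta1\t*"), path)
  expect_error(read_proteinortho(path), "duplicate gene ID")
})

test_that("soft-core threshold uses the ceiling rule", {
  mk <- function(ns) {
    strains <- sprintf("s%03d", seq_len(ns))
    toy_pangenome(strains,
                  list(F1 = setNames(lapply(strains, function(s) paste0(s, "_g")),
                                     strains)))
  }
  expect_equal(attr(classify_families(mk(109), 0.95), "soft_core_threshold"), 104L)
  expect_equal(attr(classify_families(mk(20), 0.95), "soft_core_threshold"), 19L)
  expect_error(classify_families(mk(20), 0), "soft_core_fraction")
  expect_error(classify_families(mk(20), 1.2), "soft_core_fraction")
})

test_that("paralogous core families are flagged and excluded from the filtered count", {
  strains <- c("A", "B", "C")
  pan <- toy_pangenome(strains, list(
    F1 = list(A = c("a1", "a2"), B = "b1", C = "c1"),   # core with paralogs
    F2 = list(A = "a3", B = "b2", C = "c2"),            # clean core
    F3 = list(A = "a4")),                               # strain-specific
    connectivity = c(F1 = 0.95, F2 = 0.8, F3 = 1))
  cl <- classify_families(pan)
  s <- pangenome_summary(cl)
  expect_equal(cl$label, c("core", "core", "accessory"))
  expect_true(cl$has_paralogs[1])
  expect_equal(s$core_incl_paralogs, 2)
  expect_equal(s$core_no_paralogs, 1)
  # F2 is paralog-free core but fails the connectivity filter
  expect_equal(s$core_no_paralogs_high_connectivity, 0)
})

test_that("filtered core count is monotonically non-increasing in the connectivity threshold", {
  sim <- simulate_pangenome(tiny_cfg(seed = 7))
  counts <- vapply(c(0, 0.5, 0.8, 0.9, 0.95, 1), function(t) {
    pangenome_summary(classify_families(sim$pangenome,
                                        connectivity_min = t))$core_no_paralogs_high_connectivity
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ortholog score counts the other strains carrying the family", {
  strains <- c("A", "B", "C", "D")
  pan <- toy_pangenome(strains, list(
    F1 = list(A = "a1", B = "b1", C = "c1"),  # focal + 2 others
    F2 = list(A = "a2"),                       # strain-specific
    F3 = list(B = "b2", C = "c2", D = "d1")))
  sc <- ortholog_scores(pan, "A")
  expect_equal(sc$score[sc$gene_id == "a1"], 2L)
  expect_equal(sc$score[sc$gene_id == "a2"], 0L)
  expect_error(ortholog_scores(pan, "Z"), "unknown strain")
  # annotation with a gene missing from the table: scored 0 and flagged
  ann <- data.frame(gene_id = c("a1", "a2", "a_extra"), midpoint = c(10, 20, 30))
  expect_warning(sc2 <- ortholog_scores(pan, "A", annotation = ann),
                 "absent from the orthology table")
  expect_equal(sc2$score, c(2L, 0L, 0L))
  expect_equal(sc2$in_table, c(TRUE, TRUE, FALSE))
})

test_that("an all-core pan-genome scores every gene n_strains - 1", {
  cfg <- tiny_cfg(n_families = 120, genes_per_strain = 120,
                  conservation_mixture = data.frame(occupancy = 1, weight = 1),
                  paralog_fraction = 0)
  sim <- simulate_pangenome(cfg)
  for (s in sim$strains) {
    sc <- ortholog_scores(sim$pangenome, s)
    expect_true(all(sc$score == cfg$n_strains - 1L))
  }
})

test_that("one-strain-per-genus reduction re-tallies families deterministically", {
  strains <- c("A", "B", "C")
  pan <- toy_pangenome(strains, list(
    F1 = list(A = "a1", B = "b1", C = "c1"),
    F2 = list(B = "b2")))
  # all distinct genera: identity
  same <- reduce_one_per_genus(pan, c(A = "g1", B = "g2", C = "g3"))
  expect_equal(same$strains, strains)
  expect_equal(same$families, pan$families)
  # two strains share a genus: family carried by both drops to n_species 1
  red <- reduce_one_per_genus(pan, c(A = "g1", B = "g1", C = "g2"), seed = 4)
  expect_length(red$strains, 2)
  expect_equal(red$families$n_species[red$families$family_id == "F1"], 2L)
  expect_true(all(red$families$n_species <=
                  pan$families$n_species[match(red$families$family_id,
                                               pan$families$family_id)]))
  # 3 genera x 2 strains: exactly 3 retained; same seed, same choice
  strains6 <- sprintf("s%d", 1:6)
  pan6 <- toy_pangenome(strains6, list(
    F1 = setNames(lapply(strains6, function(s) paste0(s, "_g")), strains6)))
  gmap <- setNames(rep(c("gA", "gB", "gC"), each = 2), strains6)
  r1 <- reduce_one_per_genus(pan6, gmap, seed = 11)
  r2 <- reduce_one_per_genus(pan6, gmap, seed = 11)
  expect_length(r1$strains, 3)
  expect_identical(r1$strains, r2$strains)
  expect_error(reduce_one_per_genus(pan6, gmap[-1], seed = 1), "cover")
})

test_that("gene conservation and count-ordering invariants hold on simulated data", {
  for (seed in c(2, 13)) {
    sim <- simulate_pangenome(tiny_cfg(seed = seed))
    pan <- sim$pangenome
    # conservation of genes: family tallies match the gene index
    expect_equal(sum(pan$families$n_genes), nrow(pan$gene_index))
    expect_equal(nrow(pan$gene_index),
                 sum(vapply(sim$catalogs, nrow, integer(1))))
    s <- pangenome_summary(classify_families(pan))
    expect_lte(s$core_incl_paralogs, s$soft_core_incl_paralogs)
    expect_lte(s$soft_core_incl_paralogs, s$n_families)
    # classification recovers the generator's family occupancy exactly
    cl <- classify_families(pan)
    expect_equal(setNames(cl$n_species, cl$family_id),
                 sim$truth$family_occupancy[cl$family_id])
  }
})
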