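# Circular geometry, window series, gradient fits, segment and thirds
# analyses.

test_that("circular distances wrap and normalize correctly", {
  expect_equal(circular_distance(0, 0, 1000)$distance, 0)
  expect_equal(circular_distance(0, 0, 1000)$normalized, 0)
  r <- circular_distance(3e6, 0, 4e6)
  expect_equal(r$distance, 1e6)
  expect_equal(r$normalized, 0.5)
  expect_equal(r$replichore, "left")
  r2 <- circular_distance(100, 900, 1000)
  expect_equal(r2$distance, 200)
  expect_equal(r2$normalized, 0.4)
  expect_error(circular_distance(1, 0, 0), "positive")
})

test_that("circular distance is reflection-symmetric and bounded by L/2", {
  set.seed(5)
  L <- 1e6; o <- 123456
  p <- runif(200, 0, L - 1)
  d1 <- circular_distance(p, o, L)$distance
  p_reflected <- (2 * o - p) %% L
  d2 <- circular_distance(p_reflected, o, L)$distance
  expect_equal(d1, d2)
  expect_true(all(d1 <= L / 2))
})

test_that("window means match a naive circular oracle", {
  set.seed(6)
  n <- 25
  genes <- data.frame(midpoint = sort(runif(n, 0, 49999)),
                      score = sample(0:10, n, replace = TRUE))
  fr <- chromosome_frame("toy", 50000, 20000, genes)
  ws <- window_series(fr, window_size = 7, step = 1)
  expect_equal(ws$mean_score, naive_window_means(fr$genes$score, 7))
})

test_that("window counts, constant series and error cases behave", {
  genes <- data.frame(midpoint = seq(0, 39999, by = 1000), score = 3)
  fr <- chromosome_frame("toy", 40000, 0, genes)
  ws <- window_series(fr, window_size = 20, step = 1)
  expect_equal(nrow(ws), 40)              # circular: one window per gene
  expect_true(all(ws$mean_score == 3))
  expect_error(window_series(fr, window_size = 0), "window_size")
  expect_error(window_series(fr, window_size = 41), "window_size genes")
})

test_that("window mean set is invariant to rotating the gene indexing origin", {
  set.seed(7)
  n <- 30
  genes <- data.frame(midpoint = sort(runif(n, 0, 59999)),
                      score = sample(0:8, n, replace = TRUE))
  f1 <- chromosome_frame("a", 60000, 10000, genes)
  # same circle described from a rotated coordinate origin
  genes2 <- genes
  genes2$midpoint <- (genes$midpoint - 25000) %% 60000
  f2 <- chromosome_frame("a", 60000, (10000 - 25000) %% 60000, genes2)
  w1 <- window_series(f1, 5)
  w2 <- window_series(f2, 5)
  expect_equal(sort(round(w1$mean_score, 9)), sort(round(w2$mean_score, 9)))
})

test_that("gradient fits recover exact lines and closed-form OLS", {
  d <- seq(0, 1, length.out = 50)
  exact <- data.frame(mid_distance = d, mean_score = 5 - 2 * d)
  fit <- fit_conservation_gradient(exact)
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 5)
  expect_lt(fit$p_value, 1e-10)
  expect_false(fit$quadratic_better)

  three <- data.frame(mid_distance = c(0, 0.5, 1), mean_score = c(1, 2, 3))
  fit3 <- fit_conservation_gradient(three)
  want <- ols_closed_form(three$mid_distance, three$mean_score)
  expect_equal(coef(fit3), c(intercept = 1, slope = 2))
  expect_equal(unname(coef(fit3)), unname(want[c("intercept", "slope")]))

  const <- data.frame(mid_distance = d, mean_score = rep(4, 50))
  fitc <- fit_conservation_gradient(const)
  expect_equal(fitc$slope, 0)
  expect_false(fitc$significant)
  expect_true(fitc$p_value >= 0 && fitc$p_value <= 1)

  expect_error(fit_conservation_gradient(exact[1:2, ]), "at least 3")
  flat_d <- data.frame(mid_distance = rep(0.5, 10), mean_score = rnorm(10))
  expect_error(fit_conservation_gradient(flat_d), "zero variance")
})

test_that("slope population counts signs and flags degeneracy", {
  fits <- data.frame(strain = sprintf("s%02d", 1:12),
                     slope = c(rep(-4, 10), rep(4, 2)),
                     p_value = rep(0.001, 12))
  fits$slope <- fits$slope + seq(-0.05, 0.06, length.out = 12)  # break ties
  sp <- slope_population(fits)
  expect_equal(sp$sig_negative, 10)
  expect_equal(sp$sig_positive, 2)
  expect_equal(sp$n, 12)
  deg <- slope_population(data.frame(slope = rep(1, 5), p_value = rep(1, 5)))
  expect_true(deg$degenerate)
  expect_error(slope_population(data.frame(slope = 1, p_value = 1)), "at least 2")
})

test_that("normally distributed slopes stay within the simultaneous KS band", {
  set.seed(9)
  ok <- vapply(1:25, function(i) {
    sp <- slope_population(data.frame(slope = rnorm(100, -1, 0.5),
                                      p_value = runif(100)))
    all(sp$qq$within_band)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("segment indexing centers segment 1 on oriC", {
  L <- 8000; o <- 1000; k <- 8
  genes <- data.frame(midpoint = c(o, (o + L / 16 - 1) %% L, (o + L / 16 + 1) %% L,
                                   (o - L / 16 + 1) %% L, (o + L / 2) %% L),
                      score = 1)
  fr <- chromosome_frame("toy", L, o, genes)
  idx <- panoric:::segment_index(genes$midpoint, o, L, k)
  expect_equal(idx, c(1, 1, 2, 1, 5))   # oriC -> 1; terC -> 5; clockwise
})

test_that("segments partition the genes and detect planted oriC clustering", {
  sim <- simulate_pangenome(tiny_cfg(n_strains = 8, positional_bias_beta = -6,
                                     seed = 101))
  frames <- lapply(sim$strains, function(s) {
    sc <- ortholog_scores(sim$pangenome, s, annotation = sim$catalogs[[s]])
    chromosome_frame(s, sim$config$genome_length, sim$truth$true_oric[s], sc)
  })
  seg <- segment_analysis(frames)
  expect_equal(sum(seg$per_strain$n_genes),
               8 * sim$config$genes_per_strain)            # partition
  expect_equal(seg$summary$segment[which.max(seg$summary$mean_score)], 1)
  expect_lt(seg$anova_p, 0.05)
  expect_error(segment_analysis(frames, n_segments = 1), "at least 2")
})

test_that("uniformly placed scores show no segment enrichment", {
  sim <- simulate_pangenome(tiny_cfg(n_strains = 8, positional_bias_beta = 0,
                                     seed = 103))
  frames <- lapply(sim$strains, function(s) {
    sc <- ortholog_scores(sim$pangenome, s, annotation = sim$catalogs[[s]])
    chromosome_frame(s, sim$config$genome_length, sim$truth$true_oric[s], sc)
  })
  expect_gt(segment_analysis(frames)$anova_p, 0.05)
})

test_that("regions are assigned to thirds by circular midpoint", {
  L <- 9000
  genes <- data.frame(midpoint = seq(0, 8999, by = 300), score = 1)
  regions <- data.frame(strain = "toy",
                        start = c(2950, 7450), end = c(3050, 7550),
                        type = c("phage", "phage"),
                        source = c("phaster", "phaster"))
  # oriC at 3000: first region spans oriC -> third 1; the second sits at the
  # antipode (circular distance 4500 = L/2) -> third 3
  fr <- chromosome_frame("toy", L, 3000, genes, regions)
  fr2 <- chromosome_frame("toy2", L, 3000, genes, regions)
  th <- thirds_region_analysis(list(fr, fr2))
  per <- th$phaster$per_strain
  expect_equal(per$n[per$strain == "toy" & per$third == 1], 1L)
  expect_equal(per$n[per$strain == "toy" & per$third == 3], 1L)
  expect_equal(sum(per$n), 4L)           # conservation across the partition
  bad <- regions; bad$source <- "mystery"
  fr_bad <- chromosome_frame("toy", L, 3000, genes, bad)
  expect_error(thirds_region_analysis(list(fr_bad, fr2)), "unknown region source")
})

test_that("terC-planted phages enrich the distal third", {
  cfg <- tiny_cfg(n_strains = 10, n_phage_regions = 6,
                  phage_placement = "near_ter", seed = 105)
  sim <- simulate_pangenome(cfg)
  frames <- lapply(sim$strains, function(s) {
    sc <- ortholog_scores(sim$pangenome, s, annotation = sim$catalogs[[s]])
    chromosome_frame(s, cfg$genome_length, sim$truth$true_oric[s], sc,
                     sim$truth$regions[sim$truth$regions$strain == s, ])
  })
  th <- thirds_region_analysis(frames)
  ph <- th$phaster
  expect_equal(ph$summary$third[which.max(ph$summary$mean_count)], 3)
  expect_lt(ph$anova_p_count, 0.05)
  cmp <- ph$tukey_count
  expect_lt(cmp$p_adj[cmp$comparison == "3-1"], 0.05)
})

test_that("Tukey HSD adjusted p-values agree with a permutation oracle", {
  set.seed(12)
  vals <- c(rnorm(15, 0), rnorm(15, 0.55), rnorm(15, 0.9))
  grp <- rep(c("g1", "g2", "g3"), each = 15)
  fit <- aov(vals ~ factor(grp))
  tk <- TukeyHSD(fit)$`factor(grp)`
  perm <- tukey_permutation_oracle(vals, grp, n_perm = 4000)
  got <- tk[, "p adj"]
  expect_equal(unname(got[names(perm)]), unname(perm), tolerance = 0.25,
               ignore_attr = TRUE)
  expect_true(all(abs(got[names(perm)] - perm) < 0.05))
})
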