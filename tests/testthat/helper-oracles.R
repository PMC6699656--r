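# Independent oracles and small builders used across the test files.

# toy pan-genome from an explicit member list
toy_pangenome <- function(strains, members, connectivity = NULL) {
  if (is.null(connectivity))
    connectivity <- setNames(rep(1, length(members)), names(members))
  new_pangenome(strains, members, connectivity)
}

# brute-force circular DnaA-box scanner: O(L * |motifs|), both strands
brute_force_boxes <- function(seq, motifs, max_mismatch) {
  L <- nchar(seq)
  ext <- paste0(seq, substr(seq, 1, 8))
  chars <- strsplit(ext, "")[[1]]
  revcomp <- function(m) {
    map <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(map[strsplit(m, "")[[1]]]), collapse = "")
  }
  hits <- list()
  for (pos in seq_len(L)) {
    win <- chars[pos:(pos + 8)]
    for (m in motifs) {
      mm_f <- sum(win != strsplit(m, "")[[1]])
      mm_r <- sum(win != strsplit(revcomp(m), "")[[1]])
      if (mm_f <= max_mismatch)
        hits[[length(hits) + 1]] <- data.frame(position = pos, strand = "+",
                                               motif = m, mismatches = mm_f)
      if (mm_r <= max_mismatch)
        hits[[length(hits) + 1]] <- data.frame(position = pos, strand = "-",
                                               motif = m, mismatches = mm_r)
    }
  }
  if (!length(hits))
    return(data.frame(position = integer(0), strand = character(0),
                      motif = character(0), mismatches = integer(0)))
  df <- do.call(rbind, hits)
  df <- df[order(df$position, df$strand, df$mismatches, df$motif), ]
  df <- df[!duplicated(df[c("position", "strand")]), ]
  rownames(df) <- NULL
  df
}

# naive circular window means: explicit index arithmetic, no cumsum tricks
naive_window_means <- function(scores, w) {
  n <- length(scores)
  vapply(seq_len(n), function(i) {
    idx <- ((i - 1 + 0:(w - 1)) %% n) + 1
    mean(scores[idx])
  }, numeric(1))
}

# closed-form simple OLS
ols_closed_form <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# permutation oracle for Tukey HSD adjusted p-values: the null distribution
# of the maximum studentized pairwise |difference| under label exchange
tukey_permutation_oracle <- function(values, groups, n_perm = 4000, seed = 99) {
  set.seed(seed)
  groups <- factor(groups)
  stat_all <- function(v) {
    m <- tapply(v, groups, mean)
    n <- tapply(v, groups, length)
    df <- length(v) - nlevels(groups)
    s2 <- sum((v - ave(v, groups))^2) / df
    pairs <- combn(levels(groups), 2)
    q <- apply(pairs, 2, function(p) {
      se <- sqrt(s2 / 2 * (1 / n[p[1]] + 1 / n[p[2]]))
      abs(m[p[1]] - m[p[2]]) / se
    })
    names(q) <- apply(pairs, 2, function(p) paste(p[2], p[1], sep = "-"))
    q
  }
  obs <- stat_all(values)
  null_max <- replicate(n_perm, max(stat_all(sample(values))))
  vapply(obs, function(q) mean(null_max >= q), numeric(1))
}

# small fast cohorts for pipeline-level tests
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_strains = 6, n_families = 260, genes_per_strain = 160,
                   genome_length = 3.2e5, n_phage_regions = 3,
                   n_gi_regions = 3,
                   region_length_range = c(3000, 8000), seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}
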