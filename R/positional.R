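# Positional statistics along the oriC -> terC axis: sliding-window ortholog
# score series, gradient fits, slope-population analysis, eight-segment
# enrichment and chromosome-thirds region analysis.

#' Assemble a chromosome frame
#'
#' Binds one strain's gene annotation (with ortholog scores), chromosome
#' length, called oriC and optional region annotations into the unit object
#' consumed by the positional statistics.
#'
#' @param strain strain identifier.
#' @param length chromosome length (bp).
#' @param oric origin position (bp, in `[0, length)`).
#' @param genes data.frame with at least `midpoint` and `score`
#'   (ortholog scores); re-sorted by midpoint.
#' @param regions optional region data.frame (`start`, `end`, `type`,
#'   `source`).
#' @return Object of class `chrom_frame`.
#' @export
chromosome_frame <- function(strain, length, oric, genes, regions = NULL) {
  stop_if_not(length > 0, "chromosome length must be positive")
  stop_if_not(oric >= 0 && oric < length, "oric must lie in [0, length)")
  stop_if_not(all(c("midpoint", "score") %in% names(genes)),
              "genes need `midpoint` and `score` columns")
  stop_if_not(all(genes$midpoint >= 0 & genes$midpoint < length),
              "gene midpoints must lie in [0, length)")
  genes <- genes[order(genes$midpoint), , drop = FALSE]
  cd <- circular_distance(genes$midpoint, oric, length)
  genes$distance <- cd$distance
  genes$normalized <- cd$normalized
  genes$replichore <- cd$replichore
  structure(list(strain = strain, length = length, oric = oric,
                 genes = genes, regions = regions),
            class = "chrom_frame")
}

#' @export
print.chrom_frame <- function(x, ...) {
  cat(sprintf("Chromosome frame %s: %d genes, %d bp, oriC at %.0f%s\n",
              x$strain, nrow(x$genes), x$length, x$oric,
              if (!is.null(x$regions)) sprintf(", %d regions", nrow(x$regions))
              else ""))
  invisible(x)
}

#' Sliding-window mean ortholog score against distance from oriC
#'
#' Windows of `window_size` consecutive genes advance by `step` genes around
#' the circular chromosome (wrapping), so with `step = 1` there are as many
#' windows as genes.  Each window contributes its arithmetic mean ortholog
#' score and the normalized circular distance from oriC of its middle gene's
#' midpoint.
#'
#' @param frame a [chromosome_frame()].
#' @param window_size genes per window (default 20).
#' @param step window advance in genes (default 1).
#' @return Object of class `window_series`: data.frame with `window`,
#'   `mid_distance`, `mean_score`; attributes `window_size`, `step`,
#'   `n_genes`, `strain`.
#' @export
window_series <- function(frame, window_size = 20, step = 1) {
  stopifnot(inherits(frame, "chrom_frame"))
  if (window_size < 1) stop("window_size must be at least 1")
  if (step < 1) stop("step must be at least 1")
  n <- nrow(frame$genes)
  if (n < window_size) stop("need at least window_size genes")
  sc <- frame$genes$score
  padded <- c(sc, sc[seq_len(window_size - 1)])
  cs <- c(0, cumsum(padded))
  starts <- seq.int(1L, n, by = step)
  means <- (cs[starts + window_size] - cs[starts]) / window_size
  midx <- ((starts - 1L + window_size %/% 2) %% n) + 1L
  out <- data.frame(window = seq_along(starts),
                    mid_distance = frame$genes$normalized[midx],
                    mean_score = means)
  structure(out, class = c("window_series", "data.frame"),
            window_size = window_size, step = step, n_genes = n,
            strain = frame$strain)
}

#' Fit linear and quadratic conservation-gradient models
#'
#' Ordinary least squares of window mean ortholog score on normalized
#' distance from oriC.  Because consecutive windows share `window_size - 1`
#' genes, residuals are strongly serially dependent and the naive OLS
#' p-value is badly anticonservative; the reported `p_value` therefore uses
#' a heteroskedasticity-and-autocorrelation-consistent (Newey-West,
#' prewhitened) variance for the slope.  The naive p-value is kept as
#' `p_naive` for reference.  A quadratic model (adding squared distance) is
#' fitted alongside and compared by AIC.
#'
#' @param series a [window_series()] (any data.frame with `mid_distance` and
#'   `mean_score` works).
#' @param alpha two-sided significance level for the slope (default 0.05).
#' @return Object of class `conservation_fit` with elements `slope`,
#'   `intercept`, `p_value`, `p_naive`, `r_squared`, `quadratic`
#'   (coefficients), `aic`, `quadratic_better`, `significant`, `alpha`,
#'   `n_windows`, plus the underlying `lm` fits.
#' @export
fit_conservation_gradient <- function(series, alpha = 0.05) {
  d <- series$mid_distance
  y <- series$mean_score
  if (length(d) < 3) stop("need at least 3 windows to fit")
  if (!isTRUE(sd(d) > 0)) stop("zero variance in distance: cannot fit a gradient")
  fit <- lm(y ~ d)
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  scale_tol <- 1e-9 * max(1, mean(abs(y)))
  degenerate <- sm$sigma < scale_tol       # residuals at machine precision
  p_naive <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  if (degenerate) {
    p_naive <- p_hac <- if (abs(slope) < scale_tol) 1 else 0
  } else {
    p_hac <- tryCatch({
      V <- sandwich::NeweyWest(fit, prewhite = TRUE, adjust = TRUE)
      lmtest::coeftest(fit, vcov. = V)[2, 4]
    }, error = function(e) tryCatch({
      V <- sandwich::NeweyWest(fit, lag = attr(series, "window_size") %||% 20,
                               prewhite = FALSE, adjust = TRUE)
      lmtest::coeftest(fit, vcov. = V)[2, 4]
    }, error = function(e2) p_naive))
    if (is.na(p_hac)) p_hac <- p_naive
  }
  qfit <- lm(y ~ d + I(d^2))
  aic <- c(linear = AIC(fit), quadratic = AIC(qfit))
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 p_value = unname(p_hac),
                 p_naive = unname(p_naive),
                 r_squared = sm$r.squared,
                 quadratic = coef(qfit),
                 aic = aic,
                 quadratic_better = !degenerate &&
                   is.finite(aic["quadratic"]) &&
                   aic["quadratic"] < aic["linear"] - 2,
                 significant = isTRUE(p_hac < alpha),
                 alpha = alpha,
                 n_windows = length(d),
                 window_size = attr(series, "window_size"),
                 strain = attr(series, "strain"),
                 lm_linear = fit, lm_quadratic = qfit,
                 series = series),
            class = "conservation_fit")
}

#' @export
print.conservation_fit <- function(x, ...) {
  cat(sprintf("Conservation gradient%s: slope %.3f (HAC p = %.3g%s), intercept %.2f, R^2 %.3f\n",
              if (!is.null(x$strain)) paste0(" [", x$strain, "]") else "",
              x$slope, x$p_value,
              if (x$significant) sprintf(", significant at %.2g", x$alpha) else "",
              x$intercept, x$r_squared))
  if (isTRUE(x$quadratic_better))
    cat("  quadratic model fits better by AIC\n")
  invisible(x)
}

#' @method coef conservation_fit
#' @export
coef.conservation_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @method summary conservation_fit
#' @export
summary.conservation_fit <- function(object, ...) {
  data.frame(strain = object$strain %||% NA_character_,
             slope = object$slope, intercept = object$intercept,
             p_value = object$p_value, p_naive = object$p_naive,
             r_squared = object$r_squared,
             quadratic_better = object$quadratic_better,
             significant = object$significant,
             n_windows = object$n_windows, stringsAsFactors = FALSE)
}

#' @method predict conservation_fit
#' @export
predict.conservation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$lm_linear))
  if (is.numeric(newdata)) newdata <- data.frame(d = newdata)
  predict(object$lm_linear, newdata = newdata)
}

#' @method residuals conservation_fit
#' @export
residuals.conservation_fit <- function(object, ...) residuals(object$lm_linear)

#' Population analysis of per-strain gradient slopes
#'
#' Compares the observed slope distribution across strains to a normal
#' distribution with the observed mean and SD (quantile-quantile table with a
#' simultaneous Kolmogorov-Smirnov band) and counts strains with
#' significantly negative / positive slopes.
#'
#' @param fits list of [fit_conservation_gradient()] objects (or a data.frame
#'   with `slope` and `p_value` columns).
#' @param alpha significance level for the sign counts.
#' @param band_alpha level of the simultaneous KS band.
#' @return Object of class `slope_population`: `qq` (data.frame with sorted
#'   observed slopes, theoretical quantiles and a `within_band` flag),
#'   `n_negative`, `n_positive`, `sig_negative`, `sig_positive`,
#'   `degenerate` (all slopes identical), `mean`, `sd`, `n`.
#' @export
slope_population <- function(fits, alpha = 0.05, band_alpha = 0.05) {
  if (is.data.frame(fits)) {
    slopes <- fits$slope; pvals <- fits$p_value
    strains <- fits$strain %||% rep(NA_character_, nrow(fits))
  } else {
    slopes <- vapply(fits, function(f) f$slope, numeric(1))
    pvals <- vapply(fits, function(f) f$p_value, numeric(1))
    strains <- vapply(fits, function(f) f$strain %||% NA_character_, character(1))
  }
  n <- length(slopes)
  if (n < 2) stop("need slopes from at least 2 strains")
  m <- mean(slopes); s <- sd(slopes)
  degenerate <- !isTRUE(s > 0)
  ord <- order(slopes)
  sorted <- slopes[ord]
  if (degenerate) {
    theo <- rep(NA_real_, n); within <- rep(NA, n)
  } else {
    theo <- qnorm(ppoints(n), mean = m, sd = s)
    # simultaneous KS band at band_alpha on the fitted normal CDF
    D <- sqrt(-log(band_alpha / 2) / (2 * n))
    u <- stats::pnorm(sorted, m, s)
    within <- pmax(abs(seq_len(n) / n - u), abs((seq_len(n) - 1) / n - u)) <= D
  }
  structure(list(qq = data.frame(strain = strains[ord], observed = sorted,
                                 theoretical = theo, within_band = within,
                                 stringsAsFactors = FALSE),
                 n = n, mean = m, sd = s, degenerate = degenerate,
                 n_negative = sum(slopes < 0), n_positive = sum(slopes > 0),
                 sig_negative = sum(slopes < 0 & pvals < alpha, na.rm = TRUE),
                 sig_positive = sum(slopes > 0 & pvals < alpha, na.rm = TRUE),
                 alpha = alpha, band_alpha = band_alpha),
            class = "slope_population")
}

#' @export
print.slope_population <- function(x, ...) {
  cat(sprintf("Slope population: %d strains, %d negative (%d significant), %d positive (%d significant)\n",
              x$n, x$n_negative, x$sig_negative, x$n_positive, x$sig_positive))
  if (x$degenerate) cat("  degenerate: all slopes identical\n")
  else cat(sprintf("  mean %.3f, sd %.3f; %d/%d QQ points within the %g KS band\n",
                   x$mean, x$sd, sum(x$qq$within_band), x$n, x$band_alpha))
  invisible(x)
}

# segment index of positions on a circle; segment 1 is centered on oriC
# (boundaries at oric +/- L/(2k)) by default, or starts at oriC when
# center_on_oric = FALSE; numbering increases clockwise.
segment_index <- function(position, oric, L, n_segments, center_on_oric = TRUE) {
  x <- (position - oric) %% L
  if (center_on_oric) x <- (x + L / (2 * n_segments)) %% L
  pmin(floor(x / (L / n_segments)) + 1, n_segments)
}

#' Eight-segment enrichment analysis of ortholog scores
#'
#' Splits every chromosome into `n_segments` equal arcs (segment 1 centered
#' on oriC, numbering clockwise), computes per-strain segment means and SDs
#' of the gene ortholog scores, then tests for differences between segments
#' with an ANOVA using the per-strain segment means as replicates and strain
#' as a blocking factor (per-strain summaries share a strain baseline, so
#' the strain-by-segment interaction is the appropriate error term),
#' followed by Tukey HSD pairwise comparisons.
#'
#' @param frames list of [chromosome_frame()]s with called oriCs.
#' @param n_segments number of segments (default 8, minimum 2).
#' @param center_on_oric center segment 1 on oriC (default) rather than
#'   starting it there.
#' @return Object of class `segment_analysis`: `per_strain` (strain, segment,
#'   mean, sd, n_genes), `summary` (per-segment mean of strain means, sd
#'   across strains, total genes), `anova_p`, `tukey` (data.frame of pairwise
#'   comparisons with adjusted p-values), `n_segments`.
#' @export
segment_analysis <- function(frames, n_segments = 8, center_on_oric = TRUE) {
  if (n_segments < 2) stop("need at least 2 segments")
  per <- do.call(rbind, lapply(frames, function(fr) {
    seg <- segment_index(fr$genes$midpoint, fr$oric, fr$length, n_segments,
                         center_on_oric)
    agg <- lapply(split(fr$genes$score, factor(seg, levels = seq_len(n_segments))),
                  function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
    data.frame(strain = fr$strain, segment = seq_len(n_segments),
               mean_score = vapply(agg, `[[`, numeric(1), "mean"),
               sd_score = vapply(agg, `[[`, numeric(1), "sd"),
               n_genes = vapply(agg, `[[`, numeric(1), "n"),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  ok <- complete.cases(per[c("mean_score")])
  dat <- per[ok, ]
  dat$segment_f <- factor(dat$segment, levels = seq_len(n_segments))
  dat$strain_f <- factor(dat$strain)
  # strain is a blocking factor: per-strain summaries share a strain baseline
  # (and, for partitions of a fixed gene set, are negatively correlated), so
  # the strain x segment interaction is the correct error term
  fit <- aov(mean_score ~ strain_f + segment_f, data = dat)
  smry <- summary(fit)[[1]]
  anova_p <- smry[trimws(rownames(smry)) == "segment_f", "Pr(>F)"]
  tk <- TukeyHSD(fit, which = "segment_f")$segment_f
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(dat, dat$segment_f), function(g)
    data.frame(segment = g$segment[1], mean_score = mean(g$mean_score),
               sd_score = sd(g$mean_score), n_genes = sum(g$n_genes),
               n_strains = nrow(g))))
  rownames(summ) <- NULL
  structure(list(per_strain = per, summary = summ, anova_p = anova_p,
                 tukey = tukey, n_segments = n_segments,
                 center_on_oric = center_on_oric, aov = fit),
            class = "segment_analysis")
}

#' @export
print.segment_analysis <- function(x, ...) {
  cat(sprintf("Segment analysis (%d segments, segment 1 %s oriC): ANOVA p = %.3g\n",
              x$n_segments,
              if (x$center_on_oric) "centered on" else "starting at",
              x$anova_p))
  top <- x$summary$segment[which.max(x$summary$mean_score)]
  cat(sprintf("  highest mean ortholog score in segment %d\n", top))
  invisible(x)
}

# third of the chromosome by normalized distance from oriC:
# [0,1/3] -> 1, (1/3,2/3] -> 2, (2/3,1] -> 3
third_index <- function(normalized) {
  as.integer(cut(normalized, breaks = c(0, 1/3, 2/3, 1), labels = FALSE,
                 include.lowest = TRUE))
}

#' Chromosome-thirds analysis of prophage and genomic-island placement
#'
#' Assigns every annotated region (by its circular midpoint) to one of three
#' chromosome parts of increasing distance from oriC — each part is the pair
#' of arcs at normalized distance `[0,1/3]`, `(1/3,2/3]` or `(2/3,1]`,
#' jointly covering one third of the chromosome — and, separately for every
#' source tool, compares per-strain region counts and DNA proportions across
#' thirds with a strain-blocked ANOVA and Tukey HSD.  Blocking on strain
#' matters: each strain's counts across thirds sum to its fixed region
#' total, so the thirds are negatively correlated within a strain and an
#' unblocked one-way ANOVA would be anticonservative.
#'
#' @param frames list of [chromosome_frame()]s whose `regions` carry
#'   `start`, `end`, `type` and `source` columns.
#' @param sources allowed source labels; a region with any other label is an
#'   error.
#' @return Object of class `thirds_analysis`: per source, a list with
#'   `per_strain` (strain, third, n, bp, proportion), `summary`,
#'   `anova_p_count`, `tukey_count`, `anova_p_prop`, `tukey_prop`.
#' @export
thirds_region_analysis <- function(frames,
                                   sources = c("phaster", "alienhunter",
                                               "islandviewer")) {
  regs <- do.call(rbind, lapply(frames, function(fr) {
    r <- fr$regions
    if (is.null(r) || !nrow(r)) return(NULL)
    bad <- setdiff(unique(r$source), sources)
    if (length(bad)) stop("unknown region source label: ",
                          paste(bad, collapse = ", "))
    mid <- circ_midpoint(r$start, r$end, fr$length)
    nd <- circ_dist(mid, fr$oric, fr$length) / (fr$length / 2)
    len <- ifelse(r$end >= r$start, r$end - r$start + 1,
                  fr$length - r$start + r$end + 1)
    data.frame(strain = fr$strain, source = r$source, type = r$type,
               third = third_index(nd), bp = len, L = fr$length,
               stringsAsFactors = FALSE)
  }))
  if (is.null(regs) || !nrow(regs)) stop("no regions to analyze")
  strains <- vapply(frames, function(fr) fr$strain, character(1))
  out <- list()
  for (src in intersect(sources, unique(regs$source))) {
    rr <- regs[regs$source == src, , drop = FALSE]
    grid <- expand.grid(strain = strains, third = 1:3,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(rr$strain, rr$third)
    gkey <- paste(grid$strain, grid$third)
    grid$n <- as.integer(table(factor(key, levels = gkey))[gkey])
    grid$bp <- vapply(gkey, function(k) sum(rr$bp[key == k]), numeric(1))
    Lmap <- setNames(vapply(frames, function(fr) fr$length, numeric(1)), strains)
    grid$proportion <- grid$bp / (Lmap[grid$strain] / 3)
    grid$third_f <- factor(grid$third, levels = 1:3)
    grid$strain_f <- factor(grid$strain)
    # per-strain totals are fixed, so thirds within a strain are negatively
    # correlated; blocking on strain restores nominal ANOVA calibration
    fit_n <- aov(n ~ strain_f + third_f, data = grid)
    fit_p <- aov(proportion ~ strain_f + third_f, data = grid)
    tkify <- function(fit) {
      tk <- TukeyHSD(fit, which = "third_f")$third_f
      data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                 lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
                 row.names = NULL, stringsAsFactors = FALSE)
    }
    summ <- do.call(rbind, lapply(split(grid, grid$third_f), function(g)
      data.frame(third = g$third[1], mean_count = mean(g$n),
                 sd_count = sd(g$n), mean_proportion = mean(g$proportion),
                 total = sum(g$n))))
    rownames(summ) <- NULL
    pval <- function(fit) {
      smry <- summary(fit)[[1]]
      smry[trimws(rownames(smry)) == "third_f", "Pr(>F)"]
    }
    out[[src]] <- list(
      per_strain = grid[c("strain", "third", "n", "bp", "proportion")],
      summary = summ,
      anova_p_count = pval(fit_n),
      tukey_count = tkify(fit_n),
      anova_p_prop = pval(fit_p),
      tukey_prop = tkify(fit_p))
  }
  structure(out, class = "thirds_analysis")
}

#' @export
print.thirds_analysis <- function(x, ...) {
  for (src in names(x)) {
    s <- x[[src]]
    top <- s$summary$third[which.max(s$summary$mean_count)]
    cat(sprintf("%s: ANOVA p (counts) = %.3g, p (DNA proportion) = %.3g; most regions in third %d\n",
                src, s$anova_p_count, s$anova_p_prop, top))
  }
  invisible(x)
}
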