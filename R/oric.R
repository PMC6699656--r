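# Origin-of-replication calling for circular bacterial chromosomes.  The
# caller formalizes the usual manual curation of composition-based origin
# predictions: candidate intergenic regions must carry a cluster of DnaA
# boxes and are ranked by a weighted combination of (1) proximity to the
# cumulative GC-disparity extremum, (2) location within a local GC minimum
# and (3) proximity to the parAB partitioning genes.

#' Canonical DnaA box motifs
#'
#' The three 9-mers used for DnaA-box searches: the E. coli perfect box
#' TTATCCACA plus the two common variants TGTTTCACG and TGTGGATAT.
#'
#' @return character vector of three 9-mers.
#' @export
dnaa_motifs <- function() c("TTATCCACA", "TGTTTCACG", "TGTGGATAT")

as_seq_char <- function(sequence) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)[1]
  toupper(sequence)
}

#' Cumulative GC/AT disparity and windowed GC content of a circular sequence
#'
#' Computes the running sums of (G - C) and (A - T) sampled every `step` bp,
#' both raw and linearly detrended (the detrended curve is invariant, up to a
#' constant, to rotation of the circular assembly, so its extrema are
#' well-defined origin/terminus markers even when total G != total C), plus
#' the GC fraction in circular sliding windows of `window` bp.  On a genome
#' with replication-associated strand asymmetry the detrended (G - C) curve
#' attains one extremum at oriC and the opposite one at terC.
#'
#' The curve is flagged `flat` when its detrended amplitude does not exceed
#' `flat_factor * sqrt(L)`: a skew-free sequence behaves like a random-walk
#' bridge whose amplitude scales with `sqrt(L)`, while a replichore skew of
#' `s` produces an amplitude of order `s * gc * L / 2`, orders of magnitude
#' larger for any realistic skew.
#'
#' @param sequence character, `DNAString` or single-sequence `DNAStringSet`
#'   over A/C/G/T/N (N counts as 0 in the sums).
#' @param step sampling interval in bp.
#' @param window GC window width in bp (must not exceed the sequence length).
#' @param flat_factor flatness threshold multiplier on `sqrt(L)`.
#' @return Object of class `disparity_curves`: list with `positions`,
#'   `cumulative_gc`, `cumulative_at` (raw running sums), `disparity_gc`,
#'   `disparity_at` (detrended), `window_gc`, `min_pos`, `max_pos` (positions
#'   of the detrended G-C extrema), `amplitude`, `flat`, `mean_gc`, `length`.
#' @examples
#' dc <- disparity_curves("GGGGCCCC", step = 1, window = 4)
#' dc$cumulative_gc   # rises to 4 then returns to 0
#' @export
disparity_curves <- function(sequence, step = 100, window = 1000,
                             flat_factor = 10) {
  s <- as_seq_char(sequence)
  L <- nchar(s)
  if (window > L) stop("window exceeds sequence length")
  if (step < 1 || step > L) stop("step must lie in [1, sequence length]")
  r <- charToRaw(s)
  isG <- r == charToRaw("G"); isC <- r == charToRaw("C")
  isA <- r == charToRaw("A"); isT <- r == charToRaw("T")
  gc_diff <- cumsum(as.integer(isG) - as.integer(isC))
  at_diff <- cumsum(as.integer(isA) - as.integer(isT))
  grid <- seq.int(step, L, by = step)
  cum_gc <- gc_diff[grid]
  cum_at <- at_diff[grid]
  # remove the linear trend from any global G/C imbalance (rotation-stable)
  disp_gc <- cum_gc - grid * gc_diff[L] / L
  disp_at <- cum_at - grid * at_diff[L] / L

  gc_ind <- as.integer(isG | isC)
  half <- window %/% 2
  padded <- c(gc_ind, gc_ind[seq_len(window)])
  cs <- c(0, cumsum(padded))
  start0 <- (grid - half - 1L) %% L            # 0-based window starts
  win_gc <- (cs[start0 + window + 1L] - cs[start0 + 1L]) / window

  amp <- max(disp_gc) - min(disp_gc)
  structure(list(positions = grid,
                 cumulative_gc = cum_gc, cumulative_at = cum_at,
                 disparity_gc = disp_gc, disparity_at = disp_at,
                 window_gc = win_gc,
                 min_pos = grid[which.min(disp_gc)],
                 max_pos = grid[which.max(disp_gc)],
                 amplitude = amp,
                 flat = amp <= flat_factor * sqrt(L),
                 mean_gc = mean(gc_ind),
                 step = step, window = window, length = L),
            class = "disparity_curves")
}

#' @export
print.disparity_curves <- function(x, ...) {
  cat(sprintf("Disparity curves: %d bp, step %d, GC window %d\n",
              x$length, x$step, x$window))
  cat(sprintf("  detrended G-C extrema: min at %d, max at %d (amplitude %.0f%s)\n",
              x$min_pos, x$max_pos, x$amplitude,
              if (x$flat) ", FLAT: no compositional signal" else ""))
  invisible(x)
}

#' Find DnaA boxes on a circular sequence
#'
#' Scans both strands of the (circular) sequence for all positions within
#' Hamming distance `max_mismatch` of any motif.  Each hit reports its best
#' motif (fewest mismatches) and the mismatch count; positions are 1-based
#' starts on the forward strand.  N bases count as mismatches.
#'
#' @param sequence character/`DNAString` over A/C/G/T/N.
#' @param motifs character vector of 9-mers over A/C/G/T.
#' @param max_mismatch maximum Hamming distance, 0, 1 or 2.
#' @return data.frame with `position`, `strand`, `motif`, `mismatches`.
#' @export
find_dnaa_boxes <- function(sequence, motifs = dnaa_motifs(), max_mismatch = 1) {
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2")
  if (any(nchar(motifs) != 9) || any(grepl("[^ACGT]", motifs)))
    stop("motifs must be 9-mers over A, C, G, T")
  s <- as_seq_char(sequence)
  L <- nchar(s)
  subj <- Biostrings::DNAString(paste0(s, substr(s, 1, min(8, L))))
  hits <- list()
  for (m in motifs) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") Biostrings::DNAString(m)
             else Biostrings::reverseComplement(Biostrings::DNAString(m))
      mp <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                     fixed = TRUE)
      st <- BiocGenerics::start(mp)
      st <- st[st <= L]
      if (!length(st)) next
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                        fixed = TRUE)
      hits[[length(hits) + 1]] <- data.frame(
        position = st, strand = str, motif = m, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(position = integer(0), strand = character(0),
                      motif = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, hits)
  # best motif per (position, strand)
  df <- df[order(df$position, df$strand, df$mismatches, df$motif), ]
  df <- df[!duplicated(df[c("position", "strand")]), ]
  rownames(df) <- NULL
  df
}

# circular intergenic gaps of an annotated chromosome; a gap wrapping the
# assembly boundary is represented with start > end
intergenic_gaps <- function(genes, L) {
  ir <- IRanges::reduce(IRanges::IRanges(start = genes$start, end = genes$end))
  st <- BiocGenerics::start(ir); en <- BiocGenerics::end(ir)
  n <- length(st)
  if (n == 0) return(data.frame(start = 1, end = L))
  gaps <- data.frame(start = en[-n] + 1, end = st[-1] - 1)
  wrap_start <- (en[n] %% L) + 1
  wrap_end <- st[1] - 1
  if (en[n] < L || st[1] > 1) {
    # the gap across the boundary (possibly degenerate)
    if (en[n] < L && st[1] > 1)
      gaps <- rbind(gaps, data.frame(start = en[n] + 1, end = L + st[1] - 1))
    else if (en[n] < L)
      gaps <- rbind(gaps, data.frame(start = en[n] + 1, end = L))
    else gaps <- rbind(gaps, data.frame(start = 1, end = st[1] - 1))
  }
  gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
  # normalize wrap representation: end > L means the gap wraps
  gaps$wraps <- gaps$end > L
  gaps$end_mod <- ifelse(gaps$wraps, gaps$end - L, gaps$end)
  if (!nrow(gaps)) stop("no intergenic regions on this chromosome")
  rownames(gaps) <- NULL
  gaps
}

#' Call the origin of replication of a circular chromosome
#'
#' Candidates are intergenic regions containing at least `min_boxes` DnaA-box
#' hits (first pass with one mismatch allowed; if that yields no candidate
#' the scan is retried with two).  Each candidate is scored by a weighted sum
#' of normalized criteria: DnaA-box count (higher better), circular distance
#' to the detrended GC-disparity extremum (closer better; the extremum type —
#' minimum or maximum — is chosen as the one nearer the candidate with most
#' boxes, making the call invariant to assembly orientation), local GC
#' deficit (more AT-rich better) and distance to the parA/parB genes (closer
#' better; if no parA gene is annotated the criterion is dropped and the
#' remaining weights renormalized).
#'
#' The call is returned as `"ambiguous"` — mirroring strains that must be
#' excluded from positional analyses — when the disparity curve is flat (no
#' compositional signal), when no DnaA-box cluster exists, or when the
#' runner-up's composite score lies within `ambiguity_margin` of the top
#' candidate's.
#'
#' @param sequence chromosome sequence (character or `DNAString`).
#' @param genes gene annotation data.frame (`start`, `end`, `name`).
#' @param motifs DnaA motifs, see [dnaa_motifs()].
#' @param step,window,flat_factor passed to [disparity_curves()].
#' @param min_boxes minimum DnaA hits for a candidate intergenic region.
#' @param ambiguity_margin relative composite-score margin below the top
#'   candidate within which the call is declared ambiguous.
#' @param weights named weights for the four criteria
#'   (`boxes`, `disparity`, `local_gc`, `parab`).
#' @param max_mismatch_stages mismatch allowances tried in order.
#' @return Object of class `oric_call`: list with `status` (`"called"` or
#'   `"ambiguous"`), `oric` (called position in bp, `NA` if ambiguous),
#'   `candidates` (data.frame with per-criterion scores and per-candidate
#'   status), `extremum`, `flat`, `stage`, `parab_used`, `length`.
#' @export
call_oric <- function(sequence, genes, motifs = dnaa_motifs(),
                      step = 100, window = 1000, min_boxes = 3,
                      ambiguity_margin = 0.1,
                      weights = c(boxes = 0.4, disparity = 0.3,
                                  local_gc = 0.15, parab = 0.15),
                      flat_factor = 10, max_mismatch_stages = c(1, 2)) {
  s <- as_seq_char(sequence)
  L <- nchar(s)
  gaps <- intergenic_gaps(genes, L)
  dc <- disparity_curves(s, step = step, window = window,
                         flat_factor = flat_factor)

  empty <- function(stage, reason) {
    structure(list(status = "ambiguous", oric = NA_real_,
                   candidates = data.frame(), extremum = NULL,
                   flat = dc$flat, stage = stage, parab_used = NA,
                   reason = reason, length = L, curves = dc),
              class = "oric_call")
  }

  boxes <- NULL; stage <- NA_integer_
  for (mm in max_mismatch_stages) {
    hits <- find_dnaa_boxes(s, motifs, max_mismatch = mm)
    if (!nrow(hits)) next
    # assign hits to gaps (gaps may wrap)
    cnt <- vapply(seq_len(nrow(gaps)), function(i) {
      g <- gaps[i, ]
      if (!g$wraps) sum(hits$position >= g$start & hits$position <= g$end)
      else sum(hits$position >= g$start | hits$position <= g$end_mod)
    }, numeric(1))
    if (any(cnt >= min_boxes)) { boxes <- cnt; stage <- mm; break }
  }
  if (is.null(boxes)) return(empty(tail(max_mismatch_stages, 1),
                                   "no DnaA-box cluster found"))

  cand <- gaps[boxes >= min_boxes, , drop = FALSE]
  cand$boxes <- boxes[boxes >= min_boxes]
  cand$mid <- circ_midpoint(cand$start, ifelse(cand$wraps, cand$end_mod, cand$end), L)

  # extremum type: whichever is closer to the candidate with the most boxes
  best_mid <- cand$mid[which.max(cand$boxes)]
  ext_type <- if (circ_dist(best_mid, dc$min_pos, L) <=
                  circ_dist(best_mid, dc$max_pos, L)) "min" else "max"
  ext_pos <- if (ext_type == "min") dc$min_pos else dc$max_pos

  cand$dist_extremum <- circ_dist(cand$mid, ext_pos, L)
  near_grid <- vapply(cand$mid, function(m)
    which.min(circ_dist(dc$positions, m, L)), integer(1))
  cand$local_gc_excess <- dc$window_gc[near_grid] - dc$mean_gc

  par_rows <- !is.na(genes$name) & grepl("^par[ab]$", genes$name, ignore.case = TRUE)
  par_a <- !is.na(genes$name) & grepl("^para$", genes$name, ignore.case = TRUE)
  parab_used <- any(par_a)          # parA is required, parB alone is not enough
  if (parab_used) {
    pmids <- (genes$start[par_rows] + genes$end[par_rows]) / 2
    cand$dist_parab <- vapply(cand$mid, function(m)
      min(circ_dist(pmids, m, L)), numeric(1))
  } else cand$dist_parab <- NA_real_

  # normalized criteria in [0, 1], larger = more origin-like
  sc_boxes <- cand$boxes / max(cand$boxes)
  sc_disp <- 1 - cand$dist_extremum / (L / 2)
  rng <- diff(range(cand$local_gc_excess))
  sc_gc <- if (rng > 0) (max(cand$local_gc_excess) - cand$local_gc_excess) / rng
           else rep(0.5, nrow(cand))
  w <- weights[c("boxes", "disparity", "local_gc", "parab")]
  if (parab_used) {
    sc_par <- 1 - cand$dist_parab / (L / 2)
    cand$composite <- (w["boxes"] * sc_boxes + w["disparity"] * sc_disp +
                       w["local_gc"] * sc_gc + w["parab"] * sc_par) / sum(w)
  } else {
    w <- w[c("boxes", "disparity", "local_gc")]
    cand$composite <- (w["boxes"] * sc_boxes + w["disparity"] * sc_disp +
                       w["local_gc"] * sc_gc) / sum(w)
  }

  ord <- order(-cand$composite, cand$start)
  cand <- cand[ord, , drop = FALSE]
  ambiguous <- dc$flat ||
    (nrow(cand) >= 2 &&
     cand$composite[2] >= cand$composite[1] * (1 - ambiguity_margin))
  cand$status <- if (ambiguous) "ambiguous"
                 else c("called", rep("alternative", nrow(cand) - 1))
  rownames(cand) <- NULL
  out_cols <- c("start", "end", "wraps", "mid", "boxes", "dist_extremum",
                "local_gc_excess", "dist_parab", "composite", "status")
  structure(list(status = if (ambiguous) "ambiguous" else "called",
                 oric = if (ambiguous) NA_real_ else cand$mid[1] %% L,
                 candidates = cand[out_cols],
                 extremum = list(type = ext_type, position = ext_pos),
                 flat = dc$flat, stage = stage, parab_used = parab_used,
                 reason = if (dc$flat) "flat disparity curve"
                          else if (ambiguous) "runner-up within ambiguity margin"
                          else NA_character_,
                 length = L, curves = dc),
            class = "oric_call")
}

#' @export
print.oric_call <- function(x, ...) {
  if (x$status == "called")
    cat(sprintf("oriC called at %.0f bp (of %d): %d DnaA boxes, %.0f bp from disparity %s\n",
                x$oric, x$length, x$candidates$boxes[1],
                x$candidates$dist_extremum[1], x$extremum$type))
  else cat(sprintf("oriC ambiguous (%s); %d candidate(s)\n",
                   x$reason, nrow(x$candidates)))
  invisible(x)
}
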