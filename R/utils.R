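# Circular-coordinate helpers shared across modules.  All public coordinates
# are 1-based inclusive (GFF convention); BED I/O converts at the boundary.

#' Circular distance from a position to the origin of replication
#'
#' Distance is measured along the shorter arc of a circular chromosome, so it
#' is bounded by `length / 2`.  The normalized distance divides by `length/2`
#' and therefore spans `[0, 1]` from oriC to terC.  The replichore is the arc
#' containing `position`: `"right"` if the clockwise (increasing-coordinate)
#' offset from oriC is the shorter one, `"left"` otherwise.
#'
#' @param position numeric vector of positions (bp, `[0, length)`).
#' @param oric origin position (bp).
#' @param length chromosome length (bp), `> 0`.
#' @return A data.frame with columns `distance` (bp), `normalized` (in
#'   `[0,1]`) and `replichore` (`"right"`/`"left"`; `NA` at oriC and terC).
#' @examples
#' circular_distance(1e5, 0, 4e6)
#' circular_distance(3e6, 0, 4e6)   # wraps: distance 1e6, normalized 0.5
#' @export
circular_distance <- function(position, oric, length) {
  if (length(length) != 1L || !is.finite(length) || length <= 0)
    stop("chromosome `length` must be a single positive number")
  if (any(position < 0 | position >= length) || any(oric < 0 | oric >= length))
    stop("positions and oric must lie in [0, length)")
  cw <- (position - oric) %% length          # clockwise offset from oriC
  dist <- pmin(cw, length - cw)
  repl <- ifelse(cw == 0 | cw == length / 2, NA_character_,
                 ifelse(cw < length / 2, "right", "left"))
  data.frame(distance = dist, normalized = dist / (length / 2),
             replichore = repl, stringsAsFactors = FALSE)
}

# shortest circular gap between two positions (vectorised)
circ_dist <- function(a, b, L) {
  x <- (a - b) %% L
  pmin(x, L - x)
}

# circular midpoint of an interval [start, end] that may wrap (start > end)
circ_midpoint <- function(start, end, L) {
  len <- ifelse(end >= start, end - start, L - start + end)
  (start + len / 2) %% L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
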