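# SNIP baseline estimation and the darkness-profile envelope used to split
# pattern-element pixels from background pixels.

#' Darkness series along a transect
#'
#' A darkness series is the sequence of normalized darkness values at each
#' position along a transect, together with a per-position mask flag (TRUE =
#' excluded from all trait computations, e.g. membranous tissue between
#' abdominal segments).
#'
#' @param values Numeric vector of finite darkness values, length >= 1.
#' @param mask Logical vector, recycled from FALSE; TRUE marks excluded
#'   positions.
#' @param params The [darkness_params()] the values were computed under
#'   (kept for provenance; may be NULL).
#' @return An object of class `"darkness_series"`.
#' @seealso [series_darkness()], [compute_envelope()]
#' @export
darkness_series <- function(values, mask = NULL, params = NULL) {
  if (!is.numeric(values) || length(values) < 1L ||
      anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be a non-empty finite numeric vector", call. = FALSE)
  }
  n <- length(values)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (!is.logical(mask) || length(mask) != n || anyNA(mask)) {
    stop("`mask` must be a logical vector matching `values` in length",
         call. = FALSE)
  }
  structure(list(values = as.double(values), mask = mask, params = params),
            class = "darkness_series")
}

#' @export
print.darkness_series <- function(x, ...) {
  cat("<darkness_series> ", length(x$values), " positions (",
      sum(x$mask), " masked)\n", sep = "")
  invisible(x)
}

#' Darkness series of a color series
#'
#' @param series A [color_series()].
#' @param params A [darkness_params()].
#' @return A [darkness_series()] with the same mask.
#' @export
series_darkness <- function(series, params = darkness_params()) {
  stopifnot(inherits(series, "color_series"))
  darkness_series(darkness(series$colors, params), mask = series$mask,
                  params = params)
}

#' SNIP baseline of a sequence
#'
#' Statistics-sensitive Non-linear Iterative Peak-clipping: for window sizes
#' `p = 1, ..., max_window` in increasing order, every value is replaced by
#' `min(y[i], (y[i - p] + y[i + p]) / 2)`, computed simultaneously within a
#' pass from the previous pass's output.  Out-of-range neighbors are
#' supplied by a fixed padding of the *input* sequence: the odd
#' (point-symmetric) extension through the boundary value,
#' `v[1 - k] = 2 v[1] - v[1 + k]`, floored at the boundary value itself.
#' This keeps flat and linear sequences exact fixed points (the midpoint of
#' equidistant neighbors on a straight line equals the value itself),
#' while the floor prevents an interior peak close to a boundary from
#' being mirrored into a spurious low phantom that would drag the baseline
#' down.  Peaks narrower than about twice the maximum window are clipped
#' into the baseline; the result never exceeds the input anywhere.
#'
#' @param values Finite numeric vector (an unmasked contiguous segment;
#'   masked series are split into segments by [compute_envelope()]).
#' @param max_window Largest clipping half-window, an integer in
#'   `[1, length(values) - 1]`.
#' @return Numeric baseline vector, `baseline <= values` elementwise.
#' @examples
#' snip_baseline(c(0, 0, 1, 0, 0), 1)  # the 1-wide peak is clipped to 0
#' @export
snip_baseline <- function(values, max_window) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite numeric", call. = FALSE)
  }
  n <- length(values)
  if (length(max_window) != 1L || !is.finite(max_window) ||
      max_window != as.integer(max_window) || max_window < 1L ||
      max_window >= n) {
    stop("`max_window` must be an integer in [1, length(values) - 1]",
         call. = FALSE)
  }
  v <- as.double(values)
  y <- v
  idx <- seq_len(n)
  for (p in seq_len(as.integer(max_window))) {
    il <- idx - p
    ir <- idx + p
    left <- ifelse(il >= 1L, y[pmax(il, 1L)],
                   pmax(2 * v[1L] - v[pmin(pmax(2L - il, 1L), n)], v[1L]))
    right <- ifelse(ir <= n, y[pmin(ir, n)],
                    pmax(2 * v[n] - v[pmax(pmin(2L * n - ir, n), 1L)], v[n]))
    y <- pmin(y, (left + right) / 2)
  }
  y
}

#' Envelope and pattern/background labels of a darkness series
#'
#' Estimates the two enveloping lines of a darkness profile: the lower
#' envelope is the SNIP baseline of the values, the upper envelope is the
#' negated baseline of the negated values.  Their median line (the midpoint)
#' separates the transect positions into two clusters: positions strictly
#' above the median line are the darker pattern element (thoracic trident,
#' abdominal bands), positions at or below it are background.  Ties label as
#' background, so a perfectly flat profile contains no pattern.
#'
#' Masked intervals split the series into independent unmasked segments: the
#' envelope of each segment is estimated separately and no information flows
#' across a gap.  Segments shorter than 3 positions carry a trivial envelope
#' (equal to the values, hence background labels).
#'
#' @param series A [darkness_series()] (a plain numeric vector is accepted
#'   and treated as fully unmasked).
#' @param max_window SNIP half-window.  `NULL` (default) chooses
#'   `floor(segment_length / 4)` per segment, which clips pattern elements
#'   up to about half the segment long; an explicit value is capped at
#'   `segment_length - 1`.
#' @return An object of class `"envelope_result"`: lists `lower`, `upper`,
#'   `median_line` (NA at masked positions), `labels` (`"pattern"` /
#'   `"background"`, NA at masked positions), `mask`, and the per-segment
#'   `windows` actually used.
#' @examples
#' v <- c(rep(0.2, 70), rep(0.8, 60), rep(0.2, 70))
#' env <- compute_envelope(darkness_series(v))
#' table(env$labels)
#' @export
compute_envelope <- function(series, max_window = NULL) {
  if (is.numeric(series)) series <- darkness_series(series)
  stopifnot(inherits(series, "darkness_series"))
  values <- series$values
  mask <- series$mask
  n <- length(values)
  if (all(mask)) {
    stop("all positions are masked; no envelope can be estimated",
         call. = FALSE)
  }
  if (!is.null(max_window)) {
    if (length(max_window) != 1L || !is.finite(max_window) ||
        max_window != as.integer(max_window) || max_window < 1L) {
      stop("`max_window` must be a positive integer or NULL", call. = FALSE)
    }
  }

  lower <- rep(NA_real_, n)
  upper <- rep(NA_real_, n)
  segs <- unmasked_segments(mask)
  windows <- integer(0)
  for (seg in segs) {
    v <- values[seg]
    len <- length(v)
    if (len < 3L) {
      lower[seg] <- v
      upper[seg] <- v
      windows <- c(windows, 0L)
      next
    }
    w <- if (is.null(max_window)) max(1L, len %/% 4L) else
      min(as.integer(max_window), len - 1L)
    lower[seg] <- snip_baseline(v, w)
    upper[seg] <- -snip_baseline(-v, w)
    windows <- c(windows, w)
  }
  median_line <- (lower + upper) / 2
  labels <- rep(NA_character_, n)
  labels[!mask] <- ifelse(values[!mask] > median_line[!mask],
                          "pattern", "background")
  structure(list(lower = lower, upper = upper, median_line = median_line,
                 labels = labels, mask = mask, windows = windows),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("pattern", "background")))
  cat("<envelope_result> ", length(x$labels), " positions: ",
      tab[["pattern"]], " pattern, ", tab[["background"]],
      " background, ", sum(x$mask), " masked\n", sep = "")
  invisible(x)
}

# Contiguous runs of unmasked positions, as a list of index vectors in
# position order.
unmasked_segments <- function(mask) {
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in seq_along(r$values)) {
    if (r$values[j]) out[[length(out) + 1L]] <- starts[j]:ends[j]
  }
  out
}
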