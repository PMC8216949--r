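# The five pigmentation component traits computed from a masked color
# series: overall darkness (Odk), pattern fraction (Pat), color range
# (Ran), and the background / pattern-element color angles (Cbk, Cpa).

#' Overall darkness of a transect
#'
#' Mean normalized darkness over the unmasked positions.
#'
#' @param series A [darkness_series()].
#' @return Odk, a dimensionless mean darkness.
#' @export
compute_odk <- function(series) {
  stopifnot(inherits(series, "darkness_series"))
  keep <- !series$mask
  if (!any(keep)) stop("all positions are masked", call. = FALSE)
  mean(series$values[keep])
}

#' Pattern fraction of a transect
#'
#' Proportion of unmasked positions labeled as the darker pattern element
#' by the envelope median line.
#'
#' @param envelope An [compute_envelope()] result.
#' @return Pat in `[0, 1]`.
#' @export
compute_pat <- function(envelope) {
  stopifnot(inherits(envelope, "envelope_result"))
  lab <- envelope$labels[!envelope$mask]
  mean(lab == "pattern")
}

#' Split transect pixels into trimmed pattern and background clusters
#'
#' Assigns unmasked pixels to the two clusters given by the envelope labels,
#' then, within each cluster, retains the `keep_fraction` (ceiling) of
#' pixels nearest (Euclidean, RGB) to the cluster's componentwise centroid.
#' The trim discards boundary and outlier pixels before the color-line
#' fits; ties in distance are broken by position index so the result is
#' deterministic.
#'
#' @param series A [color_series()].
#' @param envelope The matching [compute_envelope()] result.
#' @param keep_fraction Fraction of each cluster retained (default 0.95, so
#'   each cluster keeps 95% of its dark or light pixels).
#' @return A list with `pattern` and `background` (retained `m x 3` RGB
#'   matrices, possibly 0-row) and `pattern_idx` / `background_idx`
#'   (retained 1-based positions, sorted).
#' @export
split_color_clusters <- function(series, envelope, keep_fraction = 0.95) {
  stopifnot(inherits(series, "color_series"),
            inherits(envelope, "envelope_result"))
  if (length(keep_fraction) != 1L || !is.finite(keep_fraction) ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must be in (0, 1]", call. = FALSE)
  }
  trim_class <- function(label) {
    idx <- which(!series$mask & envelope$labels == label)
    if (length(idx) == 0L) {
      return(list(colors = series$colors[0L, , drop = FALSE],
                  idx = integer(0)))
    }
    pts <- series$colors[idx, , drop = FALSE]
    centroid <- colMeans(pts)
    d2 <- rowSums(sweep(pts, 2L, centroid)^2)
    m <- ceiling(keep_fraction * length(idx))
    sel <- sort(idx[order(d2, seq_along(d2))[seq_len(m)]])
    list(colors = series$colors[sel, , drop = FALSE], idx = sel)
  }
  pat <- trim_class("pattern")
  bkg <- trim_class("background")
  list(pattern = pat$colors, background = bkg$colors,
       pattern_idx = pat$idx, background_idx = bkg$idx)
}

#' Color angles of the pattern and background clusters
#'
#' Cpa (resp. Cbk) is the angle, in degrees, between the best-fitted line
#' through the pattern (resp. background) pixel colors and the gray vector
#' (the black-to-white diagonal of RGB space); see [fit_color_axis()] and
#' [angle_to_gray()].  An empty cluster yields a missing angle (`NA`), never
#' zero: zeros would silently bias group means toward gray.
#'
#' @param pattern_pixels,background_pixels Retained RGB matrices from
#'   [split_color_clusters()].
#' @param ... Passed to [fit_color_axis()].
#' @return A list with `cpa`, `cbk` (degrees or `NA`) and logical
#'   `cpa_degenerate`, `cbk_degenerate` fit flags.
#' @export
compute_color_angles <- function(pattern_pixels, background_pixels, ...) {
  class_angle <- function(px) {
    if (is.null(px) || nrow(px) == 0L) {
      return(list(angle = NA_real_, degenerate = NA))
    }
    fit <- fit_color_axis(px, ...)
    list(angle = angle_to_gray(fit$direction), degenerate = fit$degenerate)
  }
  if ((is.null(pattern_pixels) || nrow(pattern_pixels) == 0L) &&
      (is.null(background_pixels) || nrow(background_pixels) == 0L)) {
    stop("both pixel clusters are empty", call. = FALSE)
  }
  pa <- class_angle(pattern_pixels)
  bk <- class_angle(background_pixels)
  list(cpa = pa$angle, cbk = bk$angle,
       cpa_degenerate = pa$degenerate, cbk_degenerate = bk$degenerate)
}

#' Color range of a transect
#'
#' Euclidean distance in RGB space between the componentwise median colors
#' of the `k` darkest and the `k` lightest unmasked pixels (darkness rank;
#' ties broken by position index for a deterministic result).
#'
#' @param series A [color_series()].
#' @param dseries The matching [darkness_series()].
#' @param k Number of extreme pixels per side (default 20).
#' @param allow_short If TRUE, a series with fewer than `2 * k` unmasked
#'   positions falls back to `k = floor(n / 2)` with a warning instead of
#'   an error.
#' @return Ran, a nonnegative RGB distance.
#' @export
compute_ran <- function(series, dseries, k = 20L, allow_short = FALSE) {
  stopifnot(inherits(series, "color_series"),
            inherits(dseries, "darkness_series"))
  keep <- which(!series$mask)
  n <- length(keep)
  if (n < 2L) {
    stop("at least 2 unmasked positions are needed for Ran", call. = FALSE)
  }
  if (length(k) != 1L || k < 1L || k != as.integer(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (n < 2L * k) {
    if (!allow_short) {
      stop("Ran needs at least ", 2L * k, " unmasked positions (found ", n,
           "); set allow_short = TRUE to fall back to k = floor(n/2)",
           call. = FALSE)
    }
    k <- n %/% 2L
    warning("short transect: Ran computed with k = ", k, call. = FALSE)
  }
  d <- dseries$values[keep]
  ord_dark <- keep[order(-d, seq_along(d))]
  ord_light <- keep[order(d, seq_along(d))]
  med_dark <- apply(series$colors[ord_dark[seq_len(k)], , drop = FALSE],
                    2L, stats::median)
  med_light <- apply(series$colors[ord_light[seq_len(k)], , drop = FALSE],
                     2L, stats::median)
  sqrt(sum((med_dark - med_light)^2))
}

#' Compute the five pigmentation components of one transect
#'
#' Runs the full per-transect decomposition: darkness profile, SNIP
#' envelope and median-line labels, pattern fraction, trimmed color
#' clusters, color angles, and color range.  The result is deterministic
#' for a fixed series and configuration.
#'
#' @param series A [color_series()] (already masked if needed, and accepted
#'   by [flag_debris()] when that screen is in use).
#' @param params [darkness_params()].
#' @param snip_window SNIP half-window (`NULL` = `floor(segment/4)` per
#'   segment).
#' @param keep_fraction Cluster trim retention, see [split_color_clusters()].
#' @param ran_k Extreme-pixel count for [compute_ran()].
#' @param allow_short_ran Passed to [compute_ran()].
#' @param metadata Named list of grouping fields merged into the record
#'   (e.g. `strain`, `sex`, `temperature`); `fly_id` / `body_part` default
#'   to the series' own identifiers.
#' @return A one-row data.frame: identifiers, `odk`, `pat`, `ran`, `cbk`,
#'   `cpa`, cluster sizes `n_pattern` / `n_background` (envelope label
#'   counts), and the degenerate-fit flags.
#' @export
compute_traits <- function(series, params = darkness_params(),
                           snip_window = NULL, keep_fraction = 0.95,
                           ran_k = 20L, allow_short_ran = FALSE,
                           metadata = list()) {
  stopifnot(inherits(series, "color_series"))
  if (all(series$mask)) {
    stop("all positions are masked; no traits can be computed",
         call. = FALSE)
  }
  dser <- series_darkness(series, params)
  env <- compute_envelope(dser, snip_window)
  split <- split_color_clusters(series, env, keep_fraction)
  ang <- compute_color_angles(split$pattern, split$background)
  lab <- env$labels[!env$mask]

  rec <- data.frame(
    fly_id = series$fly_id,
    body_part = series$body_part,
    strain = NA_character_,
    sex = NA_character_,
    temperature = NA,
    odk = compute_odk(dser),
    pat = compute_pat(env),
    ran = compute_ran(series, dser, k = ran_k, allow_short = allow_short_ran),
    cbk = ang$cbk,
    cpa = ang$cpa,
    n_pattern = sum(lab == "pattern"),
    n_background = sum(lab == "background"),
    cbk_degenerate = ang$cbk_degenerate,
    cpa_degenerate = ang$cpa_degenerate,
    stringsAsFactors = FALSE
  )
  for (nm in names(metadata)) rec[[nm]] <- metadata[[nm]]
  rec
}

#' Mean pattern and background color per group
#'
#' Pools the retained pattern (resp. background) pixels of all transects in
#' a group and returns the componentwise mean RGB, the colors used to
#' render group pigmentation schemes (one color block per group for the
#' pattern element, one for the background).  A group in which no transect
#' detected any pattern yields missing pattern channels.
#'
#' @param splits A list of [split_color_clusters()] results.
#' @param groups A character vector (or factor) of group keys, one per
#'   element of `splits`.
#' @return A data.frame with one row per group x cluster: `group`,
#'   `cluster`, `r`, `g`, `b`, `n_pixels`.
#' @export
group_mean_color <- function(splits, groups) {
  if (length(splits) == 0L) stop("no transects supplied", call. = FALSE)
  if (length(groups) != length(splits)) {
    stop("`groups` must have one key per split", call. = FALSE)
  }
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    members <- splits[groups == g]
    for (cl in c("pattern", "background")) {
      px <- do.call(rbind, lapply(members, `[[`, cl))
      if (is.null(px) || nrow(px) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, cluster = cl, r = NA_real_, g_ = NA_real_,
          b = NA_real_, n_pixels = 0L, stringsAsFactors = FALSE)
      } else {
        m <- colMeans(px)
        out[[length(out) + 1L]] <- data.frame(
          group = g, cluster = cl, r = m[[1L]], g_ = m[[2L]], b = m[[3L]],
          n_pixels = nrow(px), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "g_"] <- "g"
  rownames(res) <- NULL
  res
}
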