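# Transect extraction from RGB images: landmark-defined line profiles with
# perpendicular 5-pixel averaging, membrane masking, and debris rejection.

#' Color series along a transect
#'
#' The sequence of (perpendicular-averaged) RGB pixel values at each
#' position along a transect, with a per-position exclusion mask.
#'
#' @param colors An `n x 3` matrix of RGB values in `[0, 1]`.
#' @param mask Logical vector (TRUE = excluded); defaults to all FALSE.
#' @param fly_id,body_part Source identifiers carried into trait tables.
#' @return An object of class `"color_series"`.
#' @export
color_series <- function(colors, mask = NULL, fly_id = NA_character_,
                         body_part = NA_character_) {
  colors <- as_rgb_matrix(colors)
  n <- nrow(colors)
  if (n < 1L) stop("a color series must have at least one position",
                   call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (!is.logical(mask) || length(mask) != n || anyNA(mask)) {
    stop("`mask` must be a logical vector with one flag per position",
         call. = FALSE)
  }
  structure(list(colors = colors, mask = mask,
                 fly_id = as.character(fly_id),
                 body_part = as.character(body_part)),
            class = "color_series")
}

#' @export
print.color_series <- function(x, ...) {
  cat("<color_series> ", nrow(x$colors), " positions (", sum(x$mask),
      " masked), source ", x$fly_id, "/", x$body_part, "\n", sep = "")
  invisible(x)
}

#' @export
length.color_series <- function(x) nrow(x$colors)

#' Read an RGB image as a [0, 1] float array
#'
#' Reads PNG or TIFF (8- or 16-bit) into an `height x width x 3` array of
#' intensities in `[0, 1]`.  An alpha channel is dropped with a warning;
#' grayscale images are rejected because the pipeline is defined on RGB.
#'
#' @param path Path to a `.png`, `.tif`, or `.tiff` file.
#' @return Numeric array `h x w x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF): ", path,
         call. = FALSE)
  )
  if (length(dim(img)) == 2L) {
    stop("grayscale image; an RGB image is required: ", path, call. = FALSE)
  }
  if (dim(img)[3L] == 4L) {
    warning("alpha channel ignored in ", basename(path), call. = FALSE)
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3L] != 3L) {
    stop("expected 3 color channels, found ", dim(img)[3L], ": ", path,
         call. = FALSE)
  }
  img
}

# Bilinear interpolation of an h x w x 3 image at continuous 0-based
# coordinates (x rightward = column, y downward = row). Callers guarantee
# 0 <= x <= w-1 and 0 <= y <= h-1.
bilinear_sample <- function(image, x, y) {
  h <- dim(image)[1L]
  w <- dim(image)[2L]
  x0 <- pmin(floor(x), w - 2)
  y0 <- pmin(floor(y), h - 2)
  x0 <- pmax(x0, 0)
  y0 <- pmax(y0, 0)
  fx <- x - x0
  fy <- y - y0
  i0 <- y0 + 1L
  j0 <- x0 + 1L
  out <- matrix(0, nrow = length(x), ncol = 3L)
  for (ch in 1:3) {
    plane <- image[, , ch]
    out[, ch] <-
      plane[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      plane[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
      plane[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
      plane[cbind(i0 + 1L, j0 + 1L)] * fx * fy
  }
  out
}

#' Extract a perpendicular-averaged color profile between two landmarks
#'
#' Samples the segment from `a` to `b` at unit-pixel arc-length spacing
#' (`floor(|b - a|) + 1` positions).  At each position, `2 * half_width + 1`
#' samples are taken at integer offsets along the unit perpendicular,
#' bilinearly interpolated, and averaged componentwise; the default
#' `half_width = 2` averages the five closest pixels on a small
#' perpendicular line centered on the transect, the acquisition-noise
#' reduction used throughout the pipeline.
#'
#' Coordinates are continuous, 0-based pixel centers (`x` rightward, `y`
#' downward).  The whole perpendicular stencil must stay inside the image;
#' a stencil falling outside raises an error naming the offending position.
#'
#' @param image `h x w x 3` array from [read_image()] (values in `[0, 1]`).
#' @param a,b Numeric `(x, y)` landmark endpoints, `a != b`.
#' @param half_width Number of perpendicular samples on each side.
#' @param fly_id,body_part Identifiers stored in the result.
#' @return A [color_series()] of length `floor(|b - a|) + 1`.
#' @export
extract_transect <- function(image, a, b, half_width = 2L,
                             fly_id = NA_character_,
                             body_part = NA_character_) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  a <- as.double(a); b <- as.double(b)
  if (length(a) != 2L || length(b) != 2L || anyNA(c(a, b))) {
    stop("landmarks must be numeric (x, y) pairs", call. = FALSE)
  }
  if (length(half_width) != 1L || half_width < 0L ||
      half_width != as.integer(half_width)) {
    stop("`half_width` must be a non-negative integer", call. = FALSE)
  }
  h <- dim(image)[1L]; w <- dim(image)[2L]
  len <- sqrt(sum((b - a)^2))
  if (len < 1e-9) stop("transect endpoints coincide", call. = FALSE)
  for (pt in list(a, b)) {
    if (pt[1L] < 0 || pt[1L] > w - 1 || pt[2L] < 0 || pt[2L] > h - 1) {
      stop("landmark (", pt[1L], ", ", pt[2L], ") outside image bounds",
           call. = FALSE)
    }
  }
  n <- floor(len) + 1L
  t <- seq_len(n) - 1
  u <- (b - a) / len
  v <- c(-u[2L], u[1L])          # unit perpendicular
  offsets <- seq.int(-half_width, half_width)

  cx <- a[1L] + t * u[1L]
  cy <- a[2L] + t * u[2L]
  acc <- matrix(0, nrow = n, ncol = 3L)
  for (off in offsets) {
    sx <- cx + off * v[1L]
    sy <- cy + off * v[2L]
    bad <- sx < -1e-9 | sx > w - 1 + 1e-9 | sy < -1e-9 | sy > h - 1 + 1e-9
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("perpendicular stencil leaves the image at transect position ",
           i - 1L, " (offset ", off, ")", call. = FALSE)
    }
    acc <- acc + bilinear_sample(image, pmin(pmax(sx, 0), w - 1),
                                 pmin(pmax(sy, 0), h - 1))
  }
  colors <- acc / length(offsets)
  # guard against interpolation rounding a hair outside the cube
  colors <- pmin(pmax(colors, 0), 1)
  color_series(colors, fly_id = fly_id, body_part = body_part)
}

#' Mask intervals of a color series
#'
#' Marks the union of half-open, 0-based `[start, end)` position intervals
#' as excluded (e.g. membranous tissue between abdominal segments).
#' Positions are never renumbered: masking excludes, it does not delete, so
#' the envelope can split the series into independent segments at the gap.
#'
#' @param series A [color_series()].
#' @param intervals A list of `c(start, end)` pairs, or a 2-column
#'   matrix/data.frame; overlapping intervals are merged (union semantics).
#'   An empty list leaves the mask unchanged.
#' @return The series with an updated mask.
#' @export
apply_mask <- function(series, intervals) {
  stopifnot(inherits(series, "color_series"))
  n <- nrow(series$colors)
  if (is.matrix(intervals) || is.data.frame(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)),
                        function(i) as.numeric(intervals[i, 1:2]))
  }
  if (length(intervals) == 0L) return(series)
  mask <- series$mask
  for (iv in intervals) {
    iv <- as.numeric(iv)
    if (length(iv) != 2L || anyNA(iv) || iv[1L] != floor(iv[1L]) ||
        iv[2L] != floor(iv[2L])) {
      stop("mask intervals must be integer [start, end) pairs", call. = FALSE)
    }
    if (iv[1L] < 0 || iv[2L] > n || iv[1L] >= iv[2L]) {
      stop("mask interval [", iv[1L], ", ", iv[2L],
           ") out of range for a series of length ", n, call. = FALSE)
    }
    mask[(iv[1L] + 1L):iv[2L]] <- TRUE
  }
  series$mask <- mask
  series
}

#' Screen a transect for debris
#'
#' Transects drawn over debris particles cannot yield accurate pigmentation
#' measurements and are excluded.  The screen looks for a short run of
#' extreme darkness outliers: positions whose darkness deviates from the
#' segment median by more than `k` robust standard deviations (MAD-based,
#' floored at `scale_floor` so a noise-free series still has a finite
#' scale), in a run of `min_run` to `max_run` consecutive unmasked
#' positions.  The run-length upper bound separates debris specks from
#' legitimate pattern elements (trident, abdominal bands), which are wide;
#' the rule is conservative, its decision is always recorded, and it can be
#' disabled in [run_config()].
#'
#' @param series A [color_series()].
#' @param params [darkness_params()] used for the darkness profile.
#' @param k Robust z-score threshold.
#' @param min_run,max_run Outlier run-length window flagged as debris.
#' @param scale_floor Lower bound on the robust scale.
#' @return A list with `decision` (`"accept"` or `"reject"`) and `reason`.
#' @export
flag_debris <- function(series, params = darkness_params(), k = 6,
                        min_run = 3L, max_run = 10L, scale_floor = 1e-3) {
  stopifnot(inherits(series, "color_series"))
  keep <- !series$mask
  if (!any(keep)) {
    return(list(decision = "reject", reason = "no data"))
  }
  d <- darkness(series$colors[keep, , drop = FALSE], params)
  s <- max(stats::mad(d), scale_floor)
  out <- abs(d - stats::median(d)) > k * s
  r <- rle(out)
  bad <- r$values & r$lengths >= min_run & r$lengths <= max_run
  if (any(bad)) {
    len <- r$lengths[which(bad)[1L]]
    return(list(decision = "reject",
                reason = paste0("debris-like outlier run of ", len,
                                " positions (>", k, " robust SD)")))
  }
  list(decision = "accept", reason = NA_character_)
}

#' Read a landmark table
#'
#' Landmarks give the two transect endpoints per body part per fly, in
#' continuous 0-based pixel coordinates.  Required columns: `fly_id`,
#' `body_part`, `x1`, `y1`, `x2`, `y2` (CSV with header, or a JSON array of
#' equivalent records).  An optional `image` column names the image file
#' for each row; extra columns (e.g. `strain`, `sex`, `temperature`) are
#' carried through into the trait table.
#'
#' @param path CSV or JSON file.
#' @return A data.frame, one row per transect.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path,
                               call. = FALSE)
  df <- if (tolower(tools::file_ext(path)) == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("fly_id", "body_part", "x1", "y1", "x2", "y2")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("landmark file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("x1", "y1", "x2", "y2")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      bad <- if (anyNA(df[[col]])) which(is.na(df[[col]]))[1L] else 1L
      stop("non-numeric or missing '", col, "' in landmark row ", bad,
           call. = FALSE)
    }
  }
  df
}

#' Read mask intervals
#'
#' Optional membrane/exclusion intervals: CSV with columns `fly_id`,
#' `body_part`, `start`, `end` (half-open, 0-based transect positions).
#'
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_mask_intervals <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("fly_id", "body_part", "start", "end")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("mask file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
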