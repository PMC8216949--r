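# Elementary color-space computations shared by the trait pipeline:
# normalized darkness, angle of a color direction to the gray diagonal,
# and principal-axis fitting of an RGB point cloud.

#' Darkness normalization parameters
#'
#' Pigmentation darkness is measured per pixel as `dmax - Dbk`, where `Dbk`
#' is the distance of the pixel's RGB coordinates (each channel in `[0, 1]`)
#' to black `(0, 0, 0)`, and `dmax` is a normalization constant at least as
#' large as the maximum attainable `Dbk`.
#'
#' Two distance conventions are supported.  The default is the plain
#' Euclidean distance with `dmax = sqrt(3)` (its maximum on the unit cube),
#' so darkness lies in `[0, sqrt(3)]` with black mapping exactly to
#' `sqrt(3)` and white to 0.  A squared-Euclidean convention
#' (`metric = "squared_euclidean"`, `dmax = 3`) is also available, as is any
#' larger `dmax` (e.g. `darkness_params("euclidean", dmax = 3)`), which
#' offsets all darkness values by a constant without changing any ordering,
#' envelope, or classification downstream.
#'
#' @param metric Distance to black: `"euclidean"` (default) or
#'   `"squared_euclidean"`.
#' @param dmax Normalization constant; defaults to the maximum attainable
#'   distance under `metric` (`sqrt(3)` or 3).  Must be at least that
#'   maximum so darkness is never negative.
#' @return An object of class `"darkness_params"`.
#' @seealso [darkness()]
#' @examples
#' darkness_params()
#' darkness_params("euclidean", dmax = 3)  # offset-only variant
#' @export
darkness_params <- function(metric = c("euclidean", "squared_euclidean"),
                            dmax = NULL) {
  metric <- match.arg(metric)
  max_dbk <- if (metric == "euclidean") sqrt(3) else 3
  if (is.null(dmax)) dmax <- max_dbk
  if (!is.numeric(dmax) || length(dmax) != 1L || !is.finite(dmax) ||
      dmax <= 0) {
    stop("`dmax` must be a single positive number", call. = FALSE)
  }
  if (dmax < max_dbk - 1e-12) {
    stop("`dmax` (", format(dmax), ") is below the maximum attainable ",
         "distance to black under the ", metric, " metric (", format(max_dbk),
         ")", call. = FALSE)
  }
  structure(list(metric = metric, dmax = dmax, max_dbk = max_dbk),
            class = "darkness_params")
}

#' @export
print.darkness_params <- function(x, ...) {
  cat("<darkness_params> metric =", x$metric, ", dmax =", format(x$dmax), "\n")
  invisible(x)
}

# Coerce a length-3 vector or an n x 3 matrix/data.frame of RGB values to an
# n x 3 numeric matrix; validates the unit-cube constraint.
as_rgb_matrix <- function(x, check_range = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop("an RGB color must have exactly 3 channels", call. = FALSE)
    }
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) stop("RGB matrix must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop("RGB values must be finite and non-missing", call. = FALSE)
  }
  if (check_range && (any(x < 0) || any(x > 1))) {
    stop("RGB channels must lie in [0, 1]", call. = FALSE)
  }
  colnames(x) <- c("r", "g", "b")
  x
}

#' Normalized darkness of RGB colors
#'
#' Computes `dmax - Dbk` for each color, where `Dbk` is the distance to
#' black under the configured metric.  Darkness is maximal (`dmax`) at black
#' and strictly decreasing in each channel.
#'
#' @param rgb A length-3 RGB vector or an `n x 3` matrix with channels in
#'   `[0, 1]`.
#' @param params A [darkness_params()] object.
#' @return Numeric vector of darkness values, one per color.
#' @examples
#' darkness(c(0, 0, 0))              # sqrt(3): black
#' darkness(c(1, 1, 1))              # 0: white
#' darkness(c(0.5, 0.5, 0.5))        # sqrt(3)/2
#' @export
darkness <- function(rgb, params = darkness_params()) {
  stopifnot(inherits(params, "darkness_params"))
  m <- as_rgb_matrix(rgb)
  ss <- rowSums(m * m)
  dbk <- if (params$metric == "euclidean") sqrt(ss) else ss
  unname(params$dmax - dbk)
}

#' Angle between a color direction and the gray diagonal
#'
#' Returns the angle, in degrees, between a direction in RGB space and the
#' gray vector (the black-to-white diagonal `(1, 1, 1)/sqrt(3)`).  A fitted
#' color line has no orientation, so the angle is folded to `[0, 90]`
#' degrees: it is invariant to rescaling and to sign flips of `direction`.
#'
#' @param direction Numeric 3-vector with nonzero norm.
#' @return Angle in degrees in `[0, 90]`.
#' @examples
#' angle_to_gray(c(1, 1, 1))   # 0: parallel to gray
#' angle_to_gray(c(1, 0, 0))   # 54.7356: a pure-channel axis
#' angle_to_gray(c(1, -1, 0))  # 90: orthogonal to gray
#' @export
angle_to_gray <- function(direction) {
  if (!is.numeric(direction) || length(direction) != 3L ||
      anyNA(direction) || any(!is.finite(direction))) {
    stop("`direction` must be a finite numeric 3-vector", call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-300) {
    stop("`direction` is the zero vector; its angle to gray is undefined",
         call. = FALSE)
  }
  cosang <- abs(sum(direction)) / (nrm * sqrt(3))
  cosang <- min(max(cosang, 0), 1)
  acos(cosang) * 180 / pi
}

#' Total-least-squares line through an RGB point cloud
#'
#' Fits the best line through a cloud of pixel colors: the line through the
#' componentwise centroid along the first principal axis of the centered
#' cloud, which minimizes the sum of squared orthogonal distances.
#'
#' Two degenerate situations are handled by falling back to the direction
#' from black to the centroid, which for cuticle colors approximates the
#' brightness axis along which pixel colors of a homogeneous region vary:
#'
#' * the cloud has (numerically) zero total variance (`var_tol`), e.g. all
#'   pixels identical;
#' * the cloud has no dominant axis: the leading eigenvalue accounts for
#'   less than `dominance_min` of the total variance, so the principal
#'   direction would be determined by sampling noise rather than by color
#'   structure.
#'
#' In both cases the `degenerate` flag is set (with a `reason`), so
#' downstream trait tables can report which fits were direction-stable.
#'
#' @param points RGB colors: length-3 vector or `n x 3` matrix, `n >= 1`.
#' @param var_tol Total-variance threshold below which the cloud is treated
#'   as a single point (relative to the unit cube).
#' @param dominance_min Minimum share of total variance on the leading
#'   principal axis for the axis to be trusted.
#' @return A list with `centroid` (length-3), `direction` (unit 3-vector,
#'   largest-magnitude component made positive for determinism),
#'   `degenerate` (logical), and `reason` (`NA`, `"point"`, or
#'   `"isotropic"`).
#' @examples
#' t <- seq(0, 1, by = 0.1)
#' fit_color_axis(cbind(t, t, t))$direction  # parallel to (1,1,1)
#' @export
fit_color_axis <- function(points, var_tol = 1e-12, dominance_min = 0.6) {
  pts <- as_rgb_matrix(points)
  n <- nrow(pts)
  if (n < 1L) stop("`points` must contain at least one color", call. = FALSE)
  centroid <- colMeans(pts)

  fallback <- function(reason) {
    dir <- centroid
    if (sqrt(sum(dir^2)) < 1e-12) {
      # all-black cloud: any direction through black fits; use gray
      dir <- c(1, 1, 1)
    }
    dir <- dir / sqrt(sum(dir^2))
    list(centroid = centroid, direction = orient_direction(dir),
         degenerate = TRUE, reason = reason)
  }

  if (n == 1L) return(fallback("point"))
  centered <- sweep(pts, 2L, centroid)
  cov <- crossprod(centered) / n
  total <- sum(diag(cov))
  if (total < var_tol) return(fallback("point"))
  eig <- eigen(cov, symmetric = TRUE)
  if (eig$values[1L] / total < dominance_min) return(fallback("isotropic"))
  dir <- eig$vectors[, 1L]
  dir <- dir / sqrt(sum(dir^2))
  list(centroid = centroid, direction = orient_direction(dir),
       degenerate = FALSE, reason = NA_character_)
}

# Deterministic sign convention: the component of largest magnitude is
# positive (a line has no orientation).
orient_direction <- function(dir) {
  k <- which.max(abs(dir))
  if (dir[k] < 0) dir <- -dir
  unname(dir)
}
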