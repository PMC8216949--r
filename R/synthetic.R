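# Synthetic transects and fly-like images with recorded ground truth, for
# validation and parameter-recovery tests.  The generator emulates a
# lighter background cuticle decorated with darker pattern elements (a
# thoracic trident, abdominal bands) as intervals along an antero-posterior
# transect, with additive pixel noise and an optional smooth illumination
# gradient.

#' Ground truth for a synthetic transect
#'
#' Records the generating parameters of a synthetic transect so recovery
#' tests can compare measured traits against truth.
#'
#' Defaults describe a light tan cuticle (`background_color`) with a dark
#' brown pattern element (`pattern_color`) covering 30% of a 200-position
#' transect, with per-channel Gaussian pixel noise of SD 0.02 and no
#' illumination gradient.
#'
#' @param background_color,pattern_color RGB triples in `[0, 1]`.
#' @param bands List of half-open `[start, end)` position intervals (0-based)
#'   carrying the pattern color.
#' @param noise_sd Per-channel additive Gaussian noise SD (clipped to the
#'   unit cube after addition).
#' @param illumination_slope Additive brightness gradient: position `i` of
#'   an `n`-long transect receives `illumination_slope * i / n` on every
#'   channel.
#' @param edge_width Logistic band-edge width in positions; 0 = hard edges.
#' @param seed RNG seed recorded with the truth; `NULL` leaves the RNG
#'   stream untouched.
#' @return An object of class `"synthetic_truth"`.  `pat_true` and `n` are
#'   filled in by [generate_transect()].
#' @export
synthetic_truth <- function(background_color = c(0.72, 0.55, 0.38),
                            pattern_color = c(0.35, 0.22, 0.12),
                            bands = list(c(70, 130)),
                            noise_sd = 0.02,
                            illumination_slope = 0,
                            edge_width = 0,
                            seed = NULL) {
  bk <- as_rgb_matrix(background_color)[1L, ]
  pa <- as_rgb_matrix(pattern_color)[1L, ]
  stopifnot(is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(illumination_slope),
            is.numeric(edge_width), edge_width >= 0)
  bands <- lapply(bands, as.numeric)
  for (bd in bands) {
    if (length(bd) != 2L || bd[1L] < 0 || bd[2L] <= bd[1L]) {
      stop("each band must be a [start, end) pair with start < end",
           call. = FALSE)
    }
  }
  structure(list(background_color = bk, pattern_color = pa, bands = bands,
                 noise_sd = noise_sd,
                 illumination_slope = illumination_slope,
                 edge_width = edge_width, seed = seed,
                 pat_true = NA_real_, n = NA_integer_),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$bands), " band(s), noise_sd = ",
      x$noise_sd, ", pat_true = ", format(x$pat_true), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic transect with known truth
#'
#' Position `i` (0-based) receives the pattern color inside a band and the
#' background color outside (logistic blending at band edges when
#' `edge_width > 0`), plus the illumination gradient and i.i.d. Gaussian
#' channel noise, clipped to the unit cube.  Deterministic for a fixed
#' seed.
#'
#' @param n Transect length (>= 40 so Ran's default `k = 20` is defined).
#' @param truth A [synthetic_truth()]; all bands must lie within `[0, n)`.
#' @param seed Overrides `truth$seed` when given.
#' @param fly_id,body_part Identifiers stored in the series.
#' @return A list with `series` (a [color_series()]) and `truth` (the input
#'   truth with `pat_true`, `n`, and the seed used filled in).
#' @export
generate_transect <- function(n = 200L, truth = synthetic_truth(),
                              seed = NULL, fly_id = NA_character_,
                              body_part = NA_character_) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(n) != 1L || n < 40L || n != as.integer(n)) {
    stop("`n` must be an integer >= 40", call. = FALSE)
  }
  n <- as.integer(n)
  for (bd in truth$bands) {
    if (bd[2L] > n) {
      stop("band [", bd[1L], ", ", bd[2L], ") exceeds the transect length ",
           n, call. = FALSE)
    }
  }
  if (is.null(seed)) seed <- truth$seed
  if (!is.null(seed)) set.seed(seed)

  pos <- seq_len(n) - 1
  wt <- band_weight(pos, truth$bands, truth$edge_width)
  colors <- outer(1 - wt, truth$background_color) +
    outer(wt, truth$pattern_color)
  colors <- colors + truth$illumination_slope * (pos / n)
  if (truth$noise_sd > 0) {
    colors <- colors + matrix(stats::rnorm(3L * n, sd = truth$noise_sd),
                              nrow = n)
  }
  colors <- pmin(pmax(colors, 0), 1)

  truth$pat_true <- sum(vapply(truth$bands, function(b) b[2L] - b[1L],
                               numeric(1))) / n
  truth$n <- n
  truth$seed <- seed
  list(series = color_series(colors, fly_id = fly_id,
                             body_part = body_part),
       truth = truth)
}

# Pattern membership weight in [0, 1] per 0-based position: indicator for
# hard edges, logistic ramps of the given width otherwise.
band_weight <- function(pos, bands, edge_width) {
  wt <- numeric(length(pos))
  for (bd in bands) {
    if (edge_width <= 0) {
      wt <- wt + as.numeric(pos >= bd[1L] & pos < bd[2L])
    } else {
      wt <- wt + stats::plogis((pos - bd[1L]) / edge_width) -
        stats::plogis((pos - bd[2L]) / edge_width)
    }
  }
  pmin(wt, 1)
}

# Fixed body-plan geometry for rendered flies (0-based pixel coordinates).
fly_geometry <- function() {
  list(width = 170L, height = 320L,
       dish_color = c(0.85, 0.85, 0.85),
       thorax = list(rows = c(20L, 130L), cols = c(35L, 135L),
                     x = 85, y1 = 25, y2 = 125),
       abdomen = list(rows = c(140L, 305L), cols = c(40L, 130L),
                      x = 85, y1 = 145, y2 = 285),
       membrane_color = c(0.90, 0.88, 0.84))
}

#' Render a synthetic fly image with landmarks and ground truth
#'
#' Draws a dorsal fly-like body on a dish-colored canvas: a thorax and an
#' abdomen region filled with the background cuticle color, crossed by
#' darker pattern stripes (a central trident band on the thorax, per-segment
#' bands on the abdomen) that intersect the predefined antero-posterior
#' transect lines.  Band intervals are expressed in transect positions, so
#' the emitted landmarks cross known truth.  Pixel noise is added to the
#' whole canvas, and intensities are snapped to the 8-bit grid (`k/255`, as
#' a camera would), which makes a written-and-reread PNG identical to the
#' in-memory image.  Deterministic per seed.
#'
#' @param fly_id Identifier used in landmark rows and file names.
#' @param background_color,pattern_color Cuticle colors.
#' @param thorax_bands,abdomen_bands Band `[start, end)` intervals in
#'   transect positions (thorax transect has 101 positions, abdomen 141).
#' @param membrane Optional `[start, end)` abdominal transect interval
#'   rendered as membranous tissue and emitted as a mask interval.
#' @param noise_sd Per-channel Gaussian pixel noise SD.
#' @param illumination_slope Additive head-to-tail brightness gradient
#'   applied along each transect's extent of the body.
#' @param seed RNG seed.
#' @param out_dir If non-NULL, writes `<fly_id>.png`,
#'   `<fly_id>_landmarks.csv`, `<fly_id>_masks.csv` (when a membrane is
#'   drawn), and `<fly_id>_truth.json` into this directory.
#' @return (Invisibly) a list with `image` (array), `landmarks`
#'   (data.frame), `masks` (data.frame or NULL), and `truth` (list with
#'   `thorax` and `abdomen` [synthetic_truth()] objects).
#' @export
generate_fly_image <- function(fly_id = "fly1",
                               background_color = c(0.72, 0.55, 0.38),
                               pattern_color = c(0.35, 0.22, 0.12),
                               thorax_bands = list(c(35, 65)),
                               abdomen_bands = list(c(20, 34), c(60, 74),
                                                    c(100, 114)),
                               membrane = NULL,
                               noise_sd = 0.01,
                               illumination_slope = 0,
                               seed = NULL,
                               out_dir = NULL) {
  geo <- fly_geometry()
  if (!is.null(seed)) set.seed(seed)
  img <- array(rep(geo$dish_color, each = geo$height * geo$width),
               dim = c(geo$height, geo$width, 3L))

  paint <- function(img, rows, cols, color) {
    for (ch in 1:3) img[rows, cols, ch] <- color[ch]
    img
  }
  # 0-based coordinate ranges -> 1-based matrix indices
  rows_of <- function(r) (r[1L] + 1L):(r[2L] + 1L)

  truths <- list()
  for (part in c("thorax", "abdomen")) {
    g <- geo[[part]]
    bands <- if (part == "thorax") thorax_bands else abdomen_bands
    img <- paint(img, rows_of(g$rows), rows_of(g$cols), background_color)
    for (bd in bands) {
      band_rows <- (g$y1 + bd[1L]):(g$y1 + bd[2L] - 1L) + 1L
      img <- paint(img, band_rows, rows_of(g$cols), pattern_color)
    }
    truths[[part]] <- synthetic_truth(
      background_color = background_color, pattern_color = pattern_color,
      bands = bands, noise_sd = noise_sd,
      illumination_slope = illumination_slope, seed = seed)
    n_pos <- floor(g$y2 - g$y1) + 1L
    truths[[part]]$n <- as.integer(n_pos)
    truths[[part]]$pat_true <-
      sum(vapply(bands, function(b) b[2L] - b[1L], numeric(1))) / n_pos
  }

  masks <- NULL
  if (!is.null(membrane)) {
    membrane <- as.numeric(membrane)
    g <- geo$abdomen
    mem_rows <- (g$y1 + membrane[1L]):(g$y1 + membrane[2L] - 1L) + 1L
    img <- paint(img, mem_rows, rows_of(g$cols), geo$membrane_color)
    masks <- data.frame(fly_id = fly_id, body_part = "abdomen",
                        start = membrane[1L], end = membrane[2L],
                        stringsAsFactors = FALSE)
  }

  if (illumination_slope != 0) {
    grad <- illumination_slope * (seq_len(geo$height) - 1) / geo$height
    img <- img + array(rep(grad, times = geo$width * 3L),
                       dim = dim(img))
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = noise_sd),
                       dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255   # 8-bit grid: exact PNG round-trip

  landmarks <- data.frame(
    fly_id = fly_id,
    body_part = c("thorax", "abdomen"),
    x1 = c(geo$thorax$x, geo$abdomen$x),
    y1 = c(geo$thorax$y1, geo$abdomen$y1),
    x2 = c(geo$thorax$x, geo$abdomen$x),
    y2 = c(geo$thorax$y2, geo$abdomen$y2),
    image = paste0(fly_id, ".png"),
    stringsAsFactors = FALSE
  )

  out <- list(image = img, landmarks = landmarks, masks = masks,
              truth = truths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(img, file.path(out_dir, paste0(fly_id, ".png")))
    utils::write.csv(landmarks,
                     file.path(out_dir, paste0(fly_id, "_landmarks.csv")),
                     row.names = FALSE)
    if (!is.null(masks)) {
      utils::write.csv(masks,
                       file.path(out_dir, paste0(fly_id, "_masks.csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(out$truth, unclass),
      file.path(out_dir, paste0(fly_id, "_truth.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out)
}

#' Generate a synthetic population across a group design
#'
#' Draws per-fly synthetic transects for a strain x sex x temperature
#' design, so the trait-table summaries can be exercised on group-labeled
#' data.  Flies reared at the colder temperature get a darker pattern color
#' (additive `temp_effect` per channel at `min(temperatures)`), males get a
#' darker pattern by `sex_effect`, and every fly receives an independent
#' Gaussian perturbation (`fly_sd`) of both colors, emulating genetic and
#' micro-environmental variation.  Deterministic per seed.
#'
#' @param n_per_group Replicate flies per design cell.
#' @param strains,sexes,temperatures Factor levels of the design (at least
#'   two design cells in total).
#' @param n Transect length per fly.
#' @param base A [synthetic_truth()] supplying the reference colors, bands,
#'   and noise.
#' @param temp_effect Per-channel shift of the pattern color at the lower
#'   temperature (negative = darker; default -0.12).
#' @param sex_effect Per-channel shift of the pattern color in males
#'   (default -0.04).
#' @param fly_sd SD of the per-fly color perturbation.
#' @param seed RNG seed.
#' @return A list with `series` (list of [color_series()]), `meta`
#'   (data.frame: `fly_id`, `body_part`, `strain`, `sex`, `temperature`),
#'   and `truths` (list of per-fly [synthetic_truth()]).
#' @seealso [population_traits()]
#' @export
generate_population <- function(n_per_group = 8L,
                                strains = c("CanS", "OreR"),
                                sexes = c("F", "M"),
                                temperatures = c(17, 28),
                                n = 200L,
                                base = synthetic_truth(),
                                temp_effect = -0.12,
                                sex_effect = -0.04,
                                fly_sd = 0.02,
                                seed = NULL) {
  design <- expand.grid(strain = strains, sex = sexes,
                        temperature = temperatures,
                        stringsAsFactors = FALSE)
  if (nrow(design) < 2L) stop("the design needs at least two groups",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cold <- min(temperatures)
  series <- list()
  truths <- list()
  meta <- list()
  id <- 0L
  for (gi in seq_len(nrow(design))) {
    for (rep_i in seq_len(n_per_group)) {
      id <- id + 1L
      fly <- sprintf("fly%03d", id)
      shift <- temp_effect * (design$temperature[gi] == cold) +
        sex_effect * (design$sex[gi] == "M")
      tr <- base
      tr$pattern_color <- clip01(base$pattern_color + shift +
                                   stats::rnorm(3L, sd = fly_sd))
      tr$background_color <- clip01(base$background_color +
                                      stats::rnorm(3L, sd = fly_sd))
      tr$seed <- NULL  # stream already seeded; per-fly reseeding would
                       # make all replicates identical
      gen <- generate_transect(n, tr, fly_id = fly, body_part = "abdomen")
      series[[id]] <- gen$series
      truths[[id]] <- gen$truth
      meta[[id]] <- data.frame(fly_id = fly, body_part = "abdomen",
                               strain = design$strain[gi],
                               sex = design$sex[gi],
                               temperature = design$temperature[gi],
                               stringsAsFactors = FALSE)
    }
  }
  list(series = series, meta = do.call(rbind, meta), truths = truths)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Trait table of a synthetic population
#'
#' Applies [compute_traits()] to every transect of a
#' [generate_population()] result, attaching the group labels.
#'
#' @param pop A [generate_population()] result.
#' @param ... Passed to [compute_traits()].
#' @return A data.frame with one row per fly.
#' @export
population_traits <- function(pop, ...) {
  rows <- lapply(seq_along(pop$series), function(i) {
    compute_traits(pop$series[[i]],
                   metadata = as.list(pop$meta[i,
                     c("strain", "sex", "temperature")]), ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
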