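# Pipeline plumbing: run configuration, the batch measurement driver, and
# tabular output with provenance sidecars.

#' Pipeline run configuration
#'
#' Bundles every tunable of the measurement pipeline so one object fully
#' determines a run; the configuration is serialized next to every output
#' file for provenance.
#'
#' @param metric,dmax Darkness convention, see [darkness_params()].
#' @param snip_window SNIP half-window (`NULL` = `floor(segment/4)`).
#' @param keep_fraction Cluster trim retention in (0, 1].
#' @param ran_k Extreme-pixel count for Ran.
#' @param allow_short_ran Permit short transects in [compute_ran()].
#' @param debris_enabled Run the [flag_debris()] screen.
#' @param debris_k,debris_min_run,debris_max_run Debris screen parameters.
#' @param half_width Perpendicular averaging half-width (2 = five pixels).
#' @param seed Seed recorded for any randomized step (the measurement
#'   pipeline itself is deterministic).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(metric = "euclidean", dmax = NULL,
                       snip_window = NULL, keep_fraction = 0.95,
                       ran_k = 20L, allow_short_ran = FALSE,
                       debris_enabled = TRUE, debris_k = 6,
                       debris_min_run = 3L, debris_max_run = 10L,
                       half_width = 2L, seed = NULL) {
  params <- darkness_params(metric, dmax)  # validates metric/dmax
  stopifnot(keep_fraction > 0, keep_fraction <= 1, ran_k >= 1,
            debris_k > 0, debris_min_run >= 1,
            debris_max_run >= debris_min_run, half_width >= 0)
  structure(list(metric = params$metric, dmax = params$dmax,
                 snip_window = snip_window, keep_fraction = keep_fraction,
                 ran_k = as.integer(ran_k),
                 allow_short_ran = isTRUE(allow_short_ran),
                 debris_enabled = isTRUE(debris_enabled),
                 debris_k = debris_k,
                 debris_min_run = as.integer(debris_min_run),
                 debris_max_run = as.integer(debris_max_run),
                 half_width = as.integer(half_width), seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", if (is.null(x[[nm]])) "auto" else format(x[[nm]]),
        "\n", sep = "")
  }
  invisible(x)
}

config_params <- function(config) darkness_params(config$metric, config$dmax)

#' Measure pigmentation traits from images and landmarks
#'
#' The end-to-end batch pipeline: for every landmark row, read the image,
#' extract the perpendicular-averaged transect, apply any mask intervals
#' for that fly and body part, screen for debris, and compute the five
#' pigmentation components.  Rejected or failed transects are never
#' silently dropped: each appears in the QC log with its reason.
#'
#' @param images Where to find images: a directory (landmark rows must then
#'   carry an `image` column), a single image file used for all rows, or a
#'   named character vector mapping `image` values to paths.
#' @param landmarks Landmark table or path ([read_landmarks()]).
#' @param masks Optional mask-interval table or path
#'   ([read_mask_intervals()]).
#' @param config A [run_config()].
#' @return A list with `traits` (one row per accepted transect, including
#'   any extra landmark columns), `qc` (one row per attempted transect:
#'   `fly_id`, `body_part`, `status`, `reason`), and `config`.
#' @export
measure_pigmentation <- function(images, landmarks, masks = NULL,
                                 config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (is.character(masks) && length(masks) == 1L) {
    masks <- read_mask_intervals(masks)
  }
  params <- config_params(config)
  extra_cols <- setdiff(names(landmarks),
                        c("fly_id", "body_part", "x1", "y1", "x2", "y2",
                          "image"))

  resolve_image <- function(row) {
    if (length(images) == 1L && is.null(names(images)) &&
        !dir.exists(images)) {
      return(images)
    }
    if (!"image" %in% names(landmarks) || is.na(row$image)) {
      stop("landmark row for ", row$fly_id,
           " names no image and `images` is not a single file",
           call. = FALSE)
    }
    path <- if (length(images) == 1L && dir.exists(images)) {
      file.path(images, row$image)
    } else if (row$image %in% names(images)) {
      images[[row$image]]
    } else {
      row$image
    }
    if (!file.exists(path)) {
      stop("image not found: ", path, " (landmark row for ", row$fly_id,
           ")", call. = FALSE)
    }
    path
  }

  cache <- new.env(parent = emptyenv())
  traits <- list()
  qc <- list()
  for (i in seq_len(nrow(landmarks))) {
    row <- landmarks[i, , drop = FALSE]
    status <- "accepted"; reason <- NA_character_
    rec <- tryCatch({
      path <- resolve_image(row)
      key <- normalizePath(path)
      if (is.null(cache[[key]])) cache[[key]] <- read_image(path)
      series <- extract_transect(cache[[key]],
                                 a = c(row$x1, row$y1), b = c(row$x2, row$y2),
                                 half_width = config$half_width,
                                 fly_id = row$fly_id,
                                 body_part = row$body_part)
      if (!is.null(masks)) {
        iv <- masks[masks$fly_id == row$fly_id &
                      masks$body_part == row$body_part, c("start", "end"),
                    drop = FALSE]
        if (nrow(iv)) series <- apply_mask(series, iv)
      }
      verdict <- if (config$debris_enabled) {
        flag_debris(series, params, k = config$debris_k,
                    min_run = config$debris_min_run,
                    max_run = config$debris_max_run)
      } else {
        list(decision = "accept")
      }
      if (verdict$decision == "reject") {
        status <- "rejected"
        reason <- verdict$reason
        NULL
      } else {
        compute_traits(series, params,
                       snip_window = config$snip_window,
                       keep_fraction = config$keep_fraction,
                       ran_k = config$ran_k,
                       allow_short_ran = config$allow_short_ran,
                       metadata = as.list(row[extra_cols]))
      }
    }, error = function(e) {
      status <<- "error"; reason <<- conditionMessage(e)
      NULL
    })
    if (!is.null(rec)) traits[[length(traits) + 1L]] <- rec
    qc[[i]] <- data.frame(fly_id = row$fly_id, body_part = row$body_part,
                          status = status, reason = reason,
                          stringsAsFactors = FALSE)
  }
  traits_df <- if (length(traits)) do.call(rbind, traits) else NULL
  if (!is.null(traits_df)) rownames(traits_df) <- NULL
  list(traits = traits_df, qc = do.call(rbind, qc), config = config)
}

#' Write a table as TSV with a provenance sidecar
#'
#' Writes tab-separated values plus `<path>.config.json` recording the
#' serialized run configuration and the package version, so every output
#' is reproducible from its sidecar.
#'
#' @param x Data.frame to write.
#' @param path Output TSV path.
#' @param config Optional [run_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path, config = NULL) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(tool = "pigmentr",
                  version = as.character(utils::packageVersion("pigmentr")),
                  config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(sidecar, paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate a batch of fly images
#'
#' Renders `n_flies` synthetic flies ([generate_fly_image()]) into a
#' directory, with one combined landmark table, combined mask table (when
#' membranes are drawn), and per-fly ground-truth JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_flies Number of flies.
#' @param seed Base RNG seed; fly `i` uses `seed + i`.
#' @param ... Passed to [generate_fly_image()].
#' @return (Invisibly) a list with `landmarks_file`, `masks_file` (or
#'   NULL), and the per-fly results.
#' @export
simulate_flies <- function(out_dir, n_flies = 3L, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flies <- list()
  landmarks <- list()
  masks <- list()
  for (i in seq_len(n_flies)) {
    id <- sprintf("fly%03d", i)
    res <- generate_fly_image(fly_id = id, seed = seed + i,
                              out_dir = out_dir, ...)
    flies[[id]] <- res
    landmarks[[i]] <- res$landmarks
    if (!is.null(res$masks)) masks[[length(masks) + 1L]] <- res$masks
  }
  lm_file <- file.path(out_dir, "landmarks.csv")
  utils::write.csv(do.call(rbind, landmarks), lm_file, row.names = FALSE)
  mask_file <- NULL
  if (length(masks)) {
    mask_file <- file.path(out_dir, "masks.csv")
    utils::write.csv(do.call(rbind, masks), mask_file, row.names = FALSE)
  }
  invisible(list(landmarks_file = lm_file, masks_file = mask_file,
                 flies = flies))
}
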