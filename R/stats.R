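# Trait-table summaries: per-group means, and Pearson correlation matrices
# among the pigmentation components with Holm adjustment.

TRAIT_COLS <- c("odk", "pat", "ran", "cbk", "cpa")

#' Holm step-down adjustment of a p-value family
#'
#' Thin, named wrapper around `stats::p.adjust(method = "holm")`: the
#' adjustment applied across every unique cell of a correlation family.
#' Monotone in the raw p-values and never smaller than them; `NA` cells are
#' excluded from the family size.
#'
#' @param p Numeric vector of raw p-values (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03, 0.04))  # 0.04 0.06 0.06 0.06
#' @export
holm_adjust <- function(p) {
  stats::p.adjust(p, method = "holm")
}

#' Pairwise Pearson correlations among pigmentation traits
#'
#' Computes, within each group, the Pearson correlation for every unique
#' unordered pair of trait columns, the two-sided p-value from the t
#' transform, and Holm-adjusted p-values across the group's family of
#' cells.  Missing trait values are excluded pairwise; cells with fewer
#' than `min_n` complete pairs are reported with missing `r`/`p` and do not
#' enter the Holm family.
#'
#' To reproduce cross-body-part correlation matrices, first reshape the
#' table with [widen_body_parts()] so each body part's traits become
#' separate columns, and correlate those; all unique off-diagonal cells of
#' the displayed matrix are treated as one Holm family.
#'
#' @param table Data.frame of trait records (e.g. from
#'   [population_traits()] or [measure_pigmentation()]).
#' @param traits Character vector of trait columns to correlate.
#' @param group_by Character vector of grouping columns (`NULL` = one
#'   family over the whole table).
#' @param min_n Minimum complete pairs per cell (default 3).
#' @param alpha Familywise significance level for the `significant` flag.
#' @return A long-format data.frame: group columns, `trait_a`, `trait_b`,
#'   `n`, `r`, `p`, `p_holm`, `significant`.
#' @export
correlation_matrix <- function(table, traits = TRAIT_COLS, group_by = NULL,
                               min_n = 3L, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(traits, group_by), names(table))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(traits) < 2L) stop("need at least two traits", call. = FALSE)

  if (is.null(group_by)) {
    groups <- list(table)
    keys <- list(NULL)
  } else {
    split_key <- interaction(table[group_by], drop = TRUE, sep = "\r")
    groups <- split(table, split_key)
    keys <- lapply(groups, function(g) g[1L, group_by, drop = FALSE])
  }

  pairs <- utils::combn(traits, 2L)
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    cells <- data.frame(trait_a = pairs[1L, ], trait_b = pairs[2L, ],
                        n = NA_integer_, r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    for (ci in seq_len(nrow(cells))) {
      x <- g[[cells$trait_a[ci]]]
      y <- g[[cells$trait_b[ci]]]
      ok <- stats::complete.cases(x, y)
      cells$n[ci] <- sum(ok)
      if (sum(ok) >= min_n && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        cells$r[ci] <- unname(ct$estimate)
        cells$p[ci] <- ct$p.value
      }
    }
    cells$p_holm <- holm_adjust(cells$p)
    cells$significant <- !is.na(cells$p_holm) & cells$p_holm < alpha
    if (!is.null(keys[[gi]])) {
      cells <- cbind(keys[[gi]], cells, row.names = NULL)
    }
    out[[gi]] <- cells
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-group trait summaries
#'
#' Mean, standard deviation (n - 1 denominator), sample size, and missing
#' count for every trait within every group.
#'
#' @param table Data.frame of trait records.
#' @param keys Grouping columns.
#' @param traits Trait columns to summarize.
#' @return Long-format data.frame: group columns, `trait`, `mean`, `sd`,
#'   `n`, `n_missing`.  A single-observation group has a missing `sd`; an
#'   all-missing trait has missing `mean` and `n = 0`.
#' @export
group_summary <- function(table, keys = c("strain", "sex", "temperature",
                                          "body_part"),
                          traits = TRAIT_COLS) {
  stopifnot(is.data.frame(table))
  keys <- intersect(keys, names(table))
  missing_cols <- setdiff(traits, names(table))
  if (length(missing_cols)) {
    stop("trait table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(keys) == 0L) {
    groups <- list(table)
    key_rows <- list(NULL)
  } else {
    split_key <- interaction(table[keys], drop = TRUE, sep = "\r")
    groups <- split(table, split_key)
    key_rows <- lapply(groups, function(g) g[1L, keys, drop = FALSE])
  }
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (tr in traits) {
      x <- g[[tr]]
      ok <- !is.na(x)
      row <- data.frame(trait = tr,
                        mean = if (any(ok)) mean(x[ok]) else NA_real_,
                        sd = if (sum(ok) >= 2L) stats::sd(x[ok]) else NA_real_,
                        n = sum(ok), n_missing = sum(!ok),
                        stringsAsFactors = FALSE)
      if (!is.null(key_rows[[gi]])) {
        row <- cbind(key_rows[[gi]], row, row.names = NULL)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spread body-part traits into fly-level columns
#'
#' Reshapes a trait table with one row per fly x body part into one row per
#' fly with columns like `odk_thorax`, `odk_abdomen`, ..., so within- and
#' cross-body-part trait pairs can enter a single correlation family.
#'
#' @param table Trait table with `fly_id` and `body_part` columns.
#' @param traits Trait columns to spread.
#' @param carry Extra per-fly columns (group labels) to keep.
#' @return A data.frame with one row per `fly_id`.
#' @export
widen_body_parts <- function(table, traits = TRAIT_COLS,
                             carry = c("strain", "sex", "temperature")) {
  stopifnot(is.data.frame(table),
            all(c("fly_id", "body_part") %in% names(table)))
  carry <- intersect(carry, names(table))
  flies <- unique(table$fly_id)
  parts <- unique(table$body_part)
  rows <- lapply(flies, function(f) {
    sub <- table[table$fly_id == f, , drop = FALSE]
    row <- data.frame(fly_id = f, stringsAsFactors = FALSE)
    for (cc in carry) row[[cc]] <- sub[[cc]][1L]
    for (p in parts) {
      psub <- sub[sub$body_part == p, , drop = FALSE]
      for (tr in traits) {
        row[[paste(tr, p, sep = "_")]] <-
          if (nrow(psub)) psub[[tr]][1L] else NA_real_
      }
    }
    row
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
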