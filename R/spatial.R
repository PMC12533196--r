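# Tissue-section quantification: nucleus filters, positivity calls, and the
# tagged-neighbor clonality statistic.

#' Filter nuclei by area
#'
#' Retains nuclei with `min_area <= area <= max_area` (boundaries inclusive:
#' the exclusion rule is strictly smaller / strictly larger).
#'
#' @param cells Tibble with a `nucleus_area_um2` column.
#' @param min_area,max_area Area bounds in square microns (defaults 15, 200).
#' @return The filtered tibble.
#' @export
filter_nuclei <- function(cells, min_area = 15, max_area = 200) {
  assert_columns(cells, "nucleus_area_um2", "cells")
  dplyr::filter(cells, .data$nucleus_area_um2 >= min_area,
                .data$nucleus_area_um2 <= max_area)
}

#' Call marker positivity from an intensity channel
#'
#' A cell is positive when its intensity is strictly greater than the fixed
#' threshold. If a logical flag column for the channel already exists it is
#' used as-is; supplying both an intensity column and a flag is an error.
#'
#' @param cells Tibble.
#' @param channel Column name holding the intensity (e.g.
#'   `"tdtomato_intensity"`).
#' @param threshold Fixed intensity threshold.
#' @param flag_name Name of the output logical column (default: channel name
#'   with `_intensity` replaced by `_pos`).
#' @return The tibble with the flag column added.
#' @export
call_positive <- function(cells, channel, threshold,
                          flag_name = sub("_intensity$", "_pos", channel)) {
  if (flag_name %in% names(cells) && channel %in% names(cells)) {
    stop_hifsort("both flag '%s' and intensity '%s' present; supply one",
                 flag_name, channel)
  }
  if (flag_name %in% names(cells)) return(cells)
  assert_columns(cells, channel, "cells")
  cells[[flag_name]] <- cells[[channel]] > threshold
  cells
}

#' Positive-cell fraction per mouse and region
#'
#' @param cells Tibble with `mouse`, `region` and a logical flag column.
#' @param flag Flag column name (default `"tdtomato_pos"`).
#' @return Tibble `mouse`, `region`, `n_cells`, `n_positive`, `fraction`;
#'   regions with zero nuclei are absent by construction.
#' @export
positive_fraction <- function(cells, flag = "tdtomato_pos") {
  assert_columns(cells, c("mouse", "region", flag), "cells")
  cells |>
    dplyr::group_by(.data$mouse, .data$region) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_positive = sum(.data[[flag]]),
                     fraction = mean(.data[[flag]]), .groups = "drop")
}

# Grid-bucketed neighbor counting; must agree exactly with the all-pairs
# scan (asserted in tests). Points are assigned to r-sized grid cells and
# only the 3x3 cell neighborhood is scanned.
count_within_radius <- function(x, y, r) {
  n <- length(x)
  if (n == 0) return(integer(0))
  gx <- floor(x / r); gy <- floor(y / r)
  key <- paste(gx, gy)
  idx_by_cell <- split(seq_len(n), key)
  counts <- integer(n)
  r2 <- r * r
  for (i in seq_len(n)) {
    acc <- 0L
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(gx[i] + dx, gy[i] + dy)
      js <- idx_by_cell[[k]]
      if (is.null(js)) next
      dd <- (x[js] - x[i])^2 + (y[js] - y[i])^2
      acc <- acc + sum(dd <= r2)
    }
    counts[i] <- acc - 1L  # remove the focal cell
  }
  counts
}

#' Tagged-neighbor counts within a radius
#'
#' For every tagged (e.g. tdTomato-positive) cell, counts the other tagged
#' cells whose nucleus centroid lies within Euclidean distance `r_um`
#' (boundary inclusive), excluding the focal cell. Per mouse, the counts are
#' summarized as a frequency vector over `bins` (last bin open-ended) and a
#' mean. The per-tagged-cell coverage diagnostic -- the fraction of tagged
#' cells with at least one neighbor of any type within `r_um` -- is also
#' reported.
#'
#' @param cells Tibble with `x_um`, `y_um`, `mouse` and a logical tag flag.
#' @param r_um Neighborhood radius in microns (default 16).
#' @param flag Tag flag column (default `"tdtomato_pos"`).
#' @param bins Lower bin edges for the frequency vector (default
#'   `0:4`, i.e. bins 0,1,2,3,4,>=5).
#' @return A `neighbor_stats` list: `per_cell` (tibble `cell_id`, `mouse`,
#'   `n_tagged_neighbors`), `per_mouse` (tibble with `freq_<bin>` columns
#'   and `mean_count`), `coverage` (tibble `mouse`, `fraction_with_any_neighbor`),
#'   `r_um`, `bins`.
#' @export
neighbor_counts <- function(cells, r_um = 16, flag = "tdtomato_pos",
                            bins = 0:4) {
  if (r_um <= 0) stop_hifsort("r_um must be > 0")
  assert_columns(cells, c("x_um", "y_um", "mouse", flag), "cells")
  if (!"cell_id" %in% names(cells)) cells$cell_id <- as.character(seq_len(nrow(cells)))
  per_cell <- list(); per_mouse <- list(); cover <- list()
  bin_labels <- c(as.character(bins), paste0("ge", max(bins) + 1))
  for (mo in unique(cells$mouse)) {
    sub <- cells[cells$mouse == mo, , drop = FALSE]
    tag <- sub[[flag]]
    tsub <- sub[tag, , drop = FALSE]
    if (nrow(tsub) > 0) {
      cnt <- count_within_radius(tsub$x_um, tsub$y_um, r_um)
    } else {
      cnt <- integer(0)
    }
    # coverage: any-type neighbors of tagged cells
    if (nrow(tsub) > 0) {
      all_cnt <- integer(nrow(tsub))
      gx <- floor(sub$x_um / r_um); gy <- floor(sub$y_um / r_um)
      idx_by_cell <- split(seq_len(nrow(sub)), paste(gx, gy))
      ti <- which(tag)
      r2 <- r_um^2
      for (k in seq_along(ti)) {
        i <- ti[k]; acc <- 0L
        for (dx in -1:1) for (dy in -1:1) {
          js <- idx_by_cell[[paste(gx[i] + dx, gy[i] + dy)]]
          if (is.null(js)) next
          dd <- (sub$x_um[js] - sub$x_um[i])^2 + (sub$y_um[js] - sub$y_um[i])^2
          acc <- acc + sum(dd <= r2)
        }
        all_cnt[k] <- acc - 1L
      }
      cover[[mo]] <- tibble::tibble(mouse = mo,
                                    fraction_with_any_neighbor = mean(all_cnt >= 1))
    }
    per_cell[[mo]] <- tibble::tibble(cell_id = tsub$cell_id, mouse = mo,
                                     n_tagged_neighbors = cnt)
    binned <- c(vapply(bins, function(b) sum(cnt == b), integer(1)),
                sum(cnt > max(bins)))
    pm <- tibble::as_tibble(as.list(setNames(binned, paste0("freq_", bin_labels))))
    pm$mouse <- mo
    pm$n_tagged <- length(cnt)
    pm$mean_count <- if (length(cnt) > 0) mean(cnt) else NA_real_
    per_mouse[[mo]] <- pm
  }
  structure(list(per_cell = dplyr::bind_rows(per_cell),
                 per_mouse = dplyr::bind_rows(per_mouse) |>
                   dplyr::relocate("mouse"),
                 coverage = dplyr::bind_rows(cover),
                 r_um = r_um, bins = bins),
            class = "neighbor_stats")
}

#' @export
print.neighbor_stats <- function(x, ...) {
  cat(sprintf("<neighbor_stats> r = %g um, %d mice, %d tagged cells\n",
              x$r_um, nrow(x$per_mouse), nrow(x$per_cell)))
  print(x$per_mouse)
  invisible(x)
}
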