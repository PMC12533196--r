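# Synthetic tissue point patterns with clonal expansion and elimination.

#' Spatial simulation configuration
#'
#' Emulates a slide-scanner per-nucleus export for one tissue region:
#' uniform positions with a minimum internuclear spacing, a tagged
#' (recombined) subpopulation, clonal expansion (daughters placed in a disc
#' around parents, default radius 16 um -- the immediate-neighborhood
#' distance), and genotype-dependent elimination of tagged cells in the
#' papilla at the late timepoint. Expansion and elimination magnitudes are
#' free parameters of the generator.
#'
#' @param region `"papilla"` or `"cortex_om"`.
#' @param field_size_um Width/height of the field, microns (default 1000).
#' @param n_cells Founder cells placed (default 2000).
#' @param tag_fraction Fraction initially tagged (default 0.3).
#' @param clone_expansion_rate Expected daughters per tagged cell at the
#'   late timepoint; scalar or named by genotype (default
#'   `c(ConKO = 0, VKO = 1, VHKO = 0.5, VEKO = 0, VHEKO = 0)`).
#' @param daughter_placement_radius_um Disc radius for daughter placement
#'   (default 16).
#' @param elimination_fraction Fraction of tagged cells removed in the
#'   papilla at late; scalar or named by genotype (default
#'   `c(ConKO = 0, VKO = 0.5, VHKO = 0, VEKO = 0.5, VHEKO = 0)`:
#'   elimination requires intact HIF1A).
#' @param min_spacing_um Minimum internuclear distance for founders
#'   (default 5).
#' @param nucleus_area_range_um2 Range of simulated nucleus areas
#'   (default c(20, 150)).
#' @param seed Integer seed.
#' @return List of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(region = c("cortex_om", "papilla"),
                               field_size_um = c(1000, 1000),
                               n_cells = 2000,
                               tag_fraction = 0.3,
                               clone_expansion_rate = c(ConKO = 0, VKO = 1,
                                                        VHKO = 0.5, VEKO = 0,
                                                        VHEKO = 0),
                               daughter_placement_radius_um = 16,
                               elimination_fraction = c(ConKO = 0, VKO = 0.5,
                                                        VHKO = 0, VEKO = 0.5,
                                                        VHEKO = 0),
                               min_spacing_um = 5,
                               nucleus_area_range_um2 = c(20, 150),
                               seed = 1L) {
  region <- match.arg(region)
  if (tag_fraction <= 0 || tag_fraction >= 1) {
    stop_hifsort("tag_fraction must be in (0, 1)")
  }
  structure(list(region = region, field_size_um = field_size_um,
                 n_cells = n_cells, tag_fraction = tag_fraction,
                 clone_expansion_rate = clone_expansion_rate,
                 daughter_placement_radius_um = daughter_placement_radius_um,
                 elimination_fraction = elimination_fraction,
                 min_spacing_um = min_spacing_um,
                 nucleus_area_range_um2 = nucleus_area_range_um2,
                 seed = as.integer(seed)),
            class = "spatial_sim_config")
}

rate_for <- function(x, genotype) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (genotype %in% names(x)) return(unname(x[[genotype]]))
  0
}

#' Simulate a spatial per-nucleus table for one mouse
#'
#' Founders are placed by rejection sampling with the configured minimum
#' spacing; at the late timepoint each tagged founder produces a Poisson
#' number of daughters placed uniformly in a disc of the placement radius,
#' and (papilla only) tagged cells are eliminated at the configured
#' per-genotype fraction before output. tdTomato and Ki67 intensities are
#' drawn from separated log-normal distributions so thresholded positivity
#' calls recover the truth.
#'
#' @param config A [spatial_sim_config()].
#' @param genotype,timepoint,mouse Sample annotations; dynamics apply at
#'   `timepoint = "late"`.
#' @return List with `cells` (tibble: `cell_id`, `x_um`, `y_um`, `region`,
#'   `nucleus_area_um2`, `tdtomato_intensity`, `ki67_intensity`, `mouse`,
#'   `genotype`, `timepoint`) and `truth` (list: `tagged` flag vector
#'   aligned with `cells`, `parent_map` tibble).
#' @export
simulate_spatial <- function(config = spatial_sim_config(),
                             genotype = "VKO", timepoint = "late",
                             mouse = "m1") {
  stopifnot(inherits(config, "spatial_sim_config"))
  set.seed(derive_seed(config$seed, paste(genotype, timepoint, mouse)))
  W <- config$field_size_um[1]; H <- config$field_size_um[2]
  n <- config$n_cells
  smin <- config$min_spacing_um
  # rejection sampling with a grid occupancy check
  xs <- numeric(n); ys <- numeric(n)
  gx <- integer(0); gy <- integer(0)
  grid <- new.env(parent = emptyenv())
  placed <- 0L; attempts <- 0L
  max_attempts <- 60L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_hifsort("field too small for %d cells at %g um spacing", n, smin)
    }
    px <- runif(1, 0, W); py <- runif(1, 0, H)
    cx <- floor(px / smin); cy <- floor(py / smin)
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        js <- grid[[paste(cx + dx, cy + dy)]]
        if (!is.null(js) &&
            any((xs[js] - px)^2 + (ys[js] - py)^2 < smin^2)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    xs[placed] <- px; ys[placed] <- py
    key <- paste(cx, cy)
    grid[[key]] <- c(grid[[key]], placed)
  }
  tagged <- runif(n) < config$tag_fraction
  parent <- rep(NA_integer_, n)

  if (timepoint == "late") {
    rate <- rate_for(config$clone_expansion_rate, genotype)
    if (rate > 0) {
      n_d <- rpois(sum(tagged), rate)
      pidx <- which(tagged)
      for (k in seq_along(pidx)) {
        if (n_d[k] == 0) next
        theta <- runif(n_d[k], 0, 2 * pi)
        rad <- config$daughter_placement_radius_um * sqrt(runif(n_d[k]))
        nx <- pmin(pmax(xs[pidx[k]] + rad * cos(theta), 0), W)
        ny <- pmin(pmax(ys[pidx[k]] + rad * sin(theta), 0), H)
        xs <- c(xs, nx); ys <- c(ys, ny)
        tagged <- c(tagged, rep(TRUE, n_d[k]))
        parent <- c(parent, rep(pidx[k], n_d[k]))
      }
    }
    if (config$region == "papilla") {
      ef <- rate_for(config$elimination_fraction, genotype)
      if (ef > 0) {
        kill <- tagged & (runif(length(tagged)) < ef)
        keep <- !kill
        old_idx <- which(keep)
        remap <- match(parent, old_idx)
        xs <- xs[keep]; ys <- ys[keep]; tagged <- tagged[keep]
        parent <- remap[keep]
      }
    }
  }
  ncell <- length(xs)
  area <- runif(ncell, config$nucleus_area_range_um2[1],
                config$nucleus_area_range_um2[2])
  td <- ifelse(tagged, rlnorm(ncell, log(100), 0.3), rlnorm(ncell, log(5), 0.4))
  is_prolif <- !is.na(parent) | seq_len(ncell) %in% parent[!is.na(parent)]
  ki_pos <- runif(ncell) < ifelse(is_prolif, 0.5, 0.05)
  ki <- ifelse(ki_pos, rlnorm(ncell, log(80), 0.3), rlnorm(ncell, log(4), 0.4))

  cells <- tibble::tibble(
    cell_id = sprintf("%s_%s_n%05d", mouse, config$region, seq_len(ncell)),
    x_um = xs, y_um = ys, region = config$region,
    nucleus_area_um2 = area, tdtomato_intensity = td, ki67_intensity = ki,
    mouse = mouse, genotype = genotype, timepoint = timepoint
  )
  parent_map <- tibble::tibble(
    parent_id = cells$cell_id[parent[!is.na(parent)]],
    daughter_id = cells$cell_id[!is.na(parent)]
  )
  list(cells = cells, truth = list(tagged = tagged, parent_map = parent_map))
}
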