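# Density profiles along a box axis or radially, and the half-maximum
# bilayer-thickness measurement.

#' Per-species density profile along a box axis
#'
#' Bins every bead by its wrapped coordinate along the chosen axis and
#' normalises counts by bin volume, giving beads/rc^3 per species per bin.
#' Binning is exact, so summing `density * bin_volume` over bins recovers
#' each species' bead count.
#'
#' @param state A [dpd_state()], or a list of states whose profiles are
#'   averaged (e.g. stable-stage frames).
#' @param axis `"z"` (default), `"x"` or `"y"`.
#' @param bin_width Bin width in rc (default 0.5).
#' @param species Optional character vector of species labels to keep.
#' @return Tibble with `axis`, `bin`, `coord` (bin midpoint), `species`,
#'   `density` and `bin_volume`; class `dpd_profile`.
#' @export
density_profile <- function(state, axis = c("z", "x", "y"),
                            bin_width = 0.5, species = NULL) {
  axis <- match.arg(axis)
  states <- if (inherits(state, "dpd_state")) list(state) else state
  d <- match(axis, c("x", "y", "z"))
  box <- states[[1]]$box
  n_bins <- max(2L, round(box[d] / bin_width))
  h <- box[d] / n_bins
  bin_volume <- prod(box[-d]) * h
  sp_labels <- dpd_species()
  keep <- if (is.null(species)) sp_labels else species

  counts <- matrix(0, n_bins, length(sp_labels),
                   dimnames = list(NULL, sp_labels))
  for (st in states) {
    b <- pmin(floor((st$positions[, d] %% box[d]) / h), n_bins - 1) + 1
    tab <- table(factor(b, levels = seq_len(n_bins)),
                 factor(sp_labels[st$species], levels = sp_labels))
    counts <- counts + as.matrix(tab)
  }
  counts <- counts / length(states)

  out <- tibble(axis = axis,
                bin = rep(seq_len(n_bins), times = length(sp_labels)),
                coord = rep((seq_len(n_bins) - 0.5) * h,
                            times = length(sp_labels)),
                species = rep(sp_labels, each = n_bins),
                density = as.vector(counts) / bin_volume,
                bin_volume = bin_volume)
  out <- out[out$species %in% keep, ]
  class(out) <- c("dpd_profile", class(out))
  out
}

#' Radial density profile around a centre
#'
#' Bins beads into spherical shells around `center` (minimum-image
#' distances) and normalises by the shell volume `4/3 pi (r1^3 - r0^3)`.
#'
#' @param state A [dpd_state()] or list of states (averaged).
#' @param center Length-3 centre point; default the box centre.
#' @param bin_width Shell width in rc.
#' @param r_max Maximum radius (default half the smallest box edge).
#' @param species Optional species filter.
#' @return Tibble with `bin`, `r` (shell midpoint), `species`, `density`,
#'   `bin_volume`; class `dpd_profile`.
#' @export
radial_density_profile <- function(state, center = NULL, bin_width = 0.5,
                                   r_max = NULL, species = NULL) {
  states <- if (inherits(state, "dpd_state")) list(state) else state
  box <- states[[1]]$box
  if (is.null(center)) center <- box / 2
  if (any(center < 0) || any(center > box)) {
    abort("center must lie inside the box")
  }
  if (is.null(r_max)) r_max <- min(box) / 2
  n_bins <- max(2L, round(r_max / bin_width))
  h <- r_max / n_bins
  sp_labels <- dpd_species()
  keep <- if (is.null(species)) sp_labels else species

  counts <- matrix(0, n_bins, length(sp_labels),
                   dimnames = list(NULL, sp_labels))
  for (st in states) {
    dp <- sweep(st$positions, 2, center)
    for (k in 1:3) {
      dp[, k] <- dp[, k] - box[k] * round(dp[, k] / box[k])
    }
    r <- sqrt(rowSums(dp^2))
    inside <- r < r_max
    b <- pmin(floor(r[inside] / h), n_bins - 1) + 1
    tab <- table(factor(b, levels = seq_len(n_bins)),
                 factor(sp_labels[st$species[inside]], levels = sp_labels))
    counts <- counts + as.matrix(tab)
  }
  counts <- counts / length(states)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  out <- tibble(bin = rep(seq_len(n_bins), times = length(sp_labels)),
                r = rep((edges[-1] + edges[-(n_bins + 1)]) / 2,
                        times = length(sp_labels)),
                species = rep(sp_labels, each = n_bins),
                density = as.vector(counts) / rep(shell_vol,
                                                  length(sp_labels)),
                bin_volume = rep(shell_vol, length(sp_labels)))
  out <- out[out$species %in% keep, ]
  class(out) <- c("dpd_profile", class(out))
  out
}

# positions of local maxima of y (strictly above both neighbours on at
# least one side, >= on the other) at or above `floor_`
profile_peaks <- function(y, floor_) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  idx[y[idx] >= floor_]
}

#' Per-frame bilayer thickness over a trajectory window
#'
#' [membrane_thickness()] applied frame by frame. Membranes drift and
#' undulate, so a profile averaged over many frames smears and can lose
#' its two-peak shape; measuring each frame and averaging the
#' thicknesses is robust to that and is the convention used by the
#' stable-stage summaries.
#'
#' @param frames List of [dpd_state()] frames (e.g. [run_frames()]).
#' @param bin_width Profile bin width in rc.
#' @return Tibble with `time` and `thickness` (NA where the per-frame
#'   profile does not show two head peaks).
#' @export
thickness_timeseries <- function(frames, bin_width = 0.5) {
  if (inherits(frames, "dpd_state")) frames <- list(frames)
  rows <- lapply(frames, function(st) {
    prof <- density_profile(st, bin_width = bin_width,
                            species = c("H1", "H2"))
    tibble(time = st$time,
           thickness = as.numeric(membrane_thickness(prof)))
  })
  bind_rows(rows)
}

#' Bilayer thickness from a head-bead density profile
#'
#' Thickness is the distance between the outermost half-maximum crossings
#' of the total head-bead density along the membrane normal: the profile
#' is scanned inwards from both ends for the first crossing of half its
#' maximum, with linear interpolation between bins. Returns `NA` when the
#' profile does not show the two head peaks of a bilayer.
#'
#' @param profile A [density_profile()] tibble (any species columns; head
#'   species `H1`/`H2` are summed), or a two-column data frame / tibble
#'   with coordinates and densities.
#' @param coord,density Column names when a plain table is passed.
#' @return Thickness in rc (scalar), with attributes `z_left`, `z_right`
#'   and `center`; `NA` if undefined.
#' @export
membrane_thickness <- function(profile, coord = "coord",
                               density = "density") {
  if ("species" %in% names(profile)) {
    heads <- profile[profile$species %in% c("H1", "H2"), ]
    if (nrow(heads) == 0) abort("profile contains no head species")
    agg <- heads %>% group_by(.data[[coord]]) %>%
      summarise(density = sum(.data[[density]]), .groups = "drop")
    z <- agg[[coord]]; y <- agg$density
  } else {
    z <- profile[[coord]]; y <- profile[[density]]
  }
  ord <- order(z); z <- z[ord]; y <- y[ord]
  if (all(y == 0)) return(NA_real_)
  ymax <- max(y)
  half <- ymax / 2
  # light 3-point smoothing for the peak count only (keeps crossings exact)
  ys <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  if (length(profile_peaks(ys, half)) < 2) return(NA_real_)

  cross_in <- function(zz, yy) {
    # first upward crossing of `half` scanning from the start
    for (i in seq_len(length(yy) - 1)) {
      if (yy[i] < half && yy[i + 1] >= half) {
        return(zz[i] + (half - yy[i]) / (yy[i + 1] - yy[i]) *
                 (zz[i + 1] - zz[i]))
      }
    }
    NA_real_
  }
  z_left <- cross_in(z, y)
  z_right_rev <- cross_in(rev(z), rev(y))
  if (is.na(z_left) || is.na(z_right_rev)) return(NA_real_)
  thickness <- z_right_rev - z_left
  if (!is.finite(thickness) || thickness <= 0) return(NA_real_)
  structure(thickness, z_left = z_left, z_right = z_right_rev,
            center = (z_left + z_right_rev) / 2)
}
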