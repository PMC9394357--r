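# Structure-level analytics: leaflet mixing counts, pore detection,
# membrane/vesicle classification, and the three-stage segmentation of
# dynamics time series.

# Connected components of an occupancy grid (2-d matrix or 3-d array) with
# periodic 4-/6-connectivity. Tracks unwrapped offsets during the flood
# fill, so a component that closes on itself through a periodic boundary
# is flagged as wrapping in that dimension.
grid_components <- function(occ) {
  dims <- dim(occ)
  nd <- length(dims)
  ncell <- prod(dims)
  comp <- integer(ncell)
  offset <- matrix(NA_integer_, ncell, nd)
  sizes <- integer(0)
  wraps <- list()
  occv <- as.logical(occ)
  strides <- cumprod(c(1, dims[-nd]))

  idx_coords <- function(i) {
    co <- integer(nd)
    r <- i - 1L
    for (d in seq_len(nd)) {
      co[d] <- r %% dims[d]
      r <- r %/% dims[d]
    }
    co
  }
  coords_idx <- function(co) sum(co * strides) + 1L

  cid <- 0L
  for (start in which(occv)) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    wrap_d <- rep(FALSE, nd)
    comp[start] <- cid
    offset[start, ] <- 0L
    queue <- integer(ncell)
    queue[1L] <- start
    q_head <- 1L; q_tail <- 1L
    size <- 0L
    while (q_head <= q_tail) {
      i <- queue[q_head]
      q_head <- q_head + 1L
      size <- size + 1L
      co <- idx_coords(i)
      for (d in seq_len(nd)) for (s in c(-1L, 1L)) {
        co2 <- co
        co2[d] <- co2[d] + s
        shift <- 0L
        if (co2[d] < 0L) { co2[d] <- dims[d] - 1L; shift <- -1L }
        if (co2[d] >= dims[d]) { co2[d] <- 0L; shift <- 1L }
        j <- coords_idx(co2)
        if (!occv[j]) next
        off_j <- offset[i, ]
        off_j[d] <- off_j[d] + shift
        if (comp[j] == 0L) {
          comp[j] <- cid
          offset[j, ] <- off_j
          q_tail <- q_tail + 1L
          queue[q_tail] <- j
        } else if (any(offset[j, ] != off_j)) {
          wrap_d <- wrap_d | (offset[j, ] != off_j)
        }
      }
    }
    sizes[cid] <- size
    wraps[[cid]] <- wrap_d
  }
  dim(comp) <- dims
  list(comp = comp, sizes = sizes, wraps = wraps)
}

# occupancy grid of selected beads projected on the x-y plane
xy_occupancy <- function(state, beads, grid_spacing) {
  box <- state$box
  nx <- max(3L, round(box[1] / grid_spacing))
  ny <- max(3L, round(box[2] / grid_spacing))
  hx <- box[1] / nx; hy <- box[2] / ny
  occ <- matrix(FALSE, nx, ny)
  if (any(beads)) {
    ix <- pmin(floor((state$positions[beads, 1] %% box[1]) / hx), nx - 1) + 1
    iy <- pmin(floor((state$positions[beads, 2] %% box[2]) / hy), ny - 1) + 1
    occ[cbind(ix, iy)] <- TRUE
  }
  list(occ = occ, hx = hx, hy = hy, nx = nx, ny = ny)
}

#' Leaflet occupancy counts of the two lipid types
#'
#' Assigns each chain to the upper or lower leaflet of a bilayer by its
#' orientation: the chain belongs to the upper leaflet when its mean head
#' z lies above its mean tail z (after unwrapping), i.e. heads point away
#' from the midplane. Chains lying nearly flat (|head z - tail z| below
#' `min_tilt`, typically pore-rim chains) are reported as unassigned
#' rather than forced into a leaflet.
#'
#' @param state A [dpd_state()].
#' @param min_tilt Minimum |head z - tail z| (rc) for an assignment.
#' @param check_topology If `TRUE`, refuse to run on a vesicle (use
#'   radial analyses for closed shells).
#' @return Tibble with one row per lipid type: `time`, `lipid_type`,
#'   `upper`, `lower`, `unassigned`.
#' @export
leaflet_mixing_counts <- function(state, min_tilt = 0.35,
                                  check_topology = FALSE) {
  if (check_topology && classify_structure(state) == "vesicle") {
    abort(paste("leaflet counts are undefined for a vesicle;",
                "use radial_density_profile()"))
  }
  comp <- state$composition
  ct <- composition_chain_table(comp)
  pos <- unwrap_chains(state)
  head_z <- tail_z <- numeric(nrow(ct))
  for (k in seq_len(nrow(ct))) {
    idx <- ct$first_bead[k] + seq_len(ct$n_beads[k]) - 1L
    nh <- ct$n_head[k]
    head_z[k] <- mean(pos[idx[seq_len(nh)], 3])
    tail_z[k] <- mean(pos[idx[(nh + 1):length(idx)], 3])
  }
  dz <- head_z - tail_z
  ct$leaflet <- ifelse(dz > min_tilt, "upper",
                       ifelse(dz < -min_tilt, "lower", "unassigned"))
  ct %>%
    group_by(lipid_type) %>%
    summarise(upper = sum(.data$leaflet == "upper"),
              lower = sum(.data$leaflet == "lower"),
              unassigned = sum(.data$leaflet == "unassigned"),
              .groups = "drop") %>%
    mutate(time = state$time, .before = 1)
}

#' Detect a pore in a membrane-spanning lipid slab
#'
#' Projects the tail beads onto an x-y grid and flood-fills the empty
#' cells under periodic connectivity. The largest empty connected
#' component above a noise floor (small thermal voids are ignored) is
#' reported as a pore with effective diameter `2 sqrt(area / pi)`.
#'
#' @param state A [dpd_state()].
#' @param grid_spacing Grid cell edge in rc (default 1).
#' @param noise_floor Minimum empty-cell count that counts as a pore.
#' @return List with `has_pore`, `diameter`, `area`, `centroid` (x, y)
#'   and `n_cells`.
#' @export
pore_detect <- function(state, grid_spacing = 1, noise_floor = 4) {
  tails <- state$species %in% species_code(c("T1", "T2"))
  g <- xy_occupancy(state, tails, grid_spacing)
  empty <- !g$occ
  if (!any(empty)) {
    return(list(has_pore = FALSE, diameter = 0, area = 0,
                centroid = c(NA_real_, NA_real_), n_cells = 0L))
  }
  cc <- grid_components(empty)
  big <- which.max(cc$sizes)
  n_cells <- cc$sizes[big]
  if (n_cells < noise_floor) {
    return(list(has_pore = FALSE, diameter = 0, area = 0,
                centroid = c(NA_real_, NA_real_), n_cells = n_cells))
  }
  area <- n_cells * g$hx * g$hy
  cells <- which(cc$comp == big, arr.ind = TRUE)
  # periodic (circular) mean of the member cell centres
  circ_mean <- function(i, n, h) {
    ang <- (i - 0.5) / n * 2 * pi
    m <- atan2(mean(sin(ang)), mean(cos(ang)))
    ((m / (2 * pi)) %% 1) * n * h
  }
  centroid <- c(circ_mean(cells[, 1], g$nx, g$hx),
                circ_mean(cells[, 2], g$ny, g$hy))
  list(has_pore = TRUE, diameter = 2 * sqrt(area / pi), area = area,
       centroid = centroid, n_cells = n_cells)
}

#' Classify the self-assembled structure of a frame
#'
#' Decision procedure over the lipid aggregate:
#' a tail-bead aggregate that percolates the periodic x-y plane is a
#' membrane (a `perforated_membrane` when [pore_detect()] finds a hole in
#' it); a non-spanning aggregate enclosing a water pocket disconnected
#' from the bulk solvent (checked on a coarse 3-d water-occupancy grid)
#' is a `vesicle`; anything else is `other`.
#'
#' @param state A [dpd_state()].
#' @param grid_spacing x-y grid for the percolation/pore test, in rc.
#' @param noise_floor Passed to [pore_detect()].
#' @param water_grid Cell edge of the 3-d water-connectivity grid, in rc.
#' @param min_water_pocket Minimum cell count of an enclosed water pocket.
#' @return One of `"membrane"`, `"perforated_membrane"`, `"vesicle"`,
#'   `"other"`.
#' @export
classify_structure <- function(state, grid_spacing = 1, noise_floor = 4,
                               water_grid = 1.5, min_water_pocket = 8) {
  tails <- state$species %in% species_code(c("T1", "T2"))
  if (!any(tails)) return("other")
  g <- xy_occupancy(state, tails, grid_spacing)
  cc <- grid_components(g$occ)
  spanning <- any(vapply(cc$wraps, function(w) w[1] && w[2], logical(1)))
  if (spanning) {
    pore <- pore_detect(state, grid_spacing, noise_floor)
    return(if (pore$has_pore) "perforated_membrane" else "membrane")
  }
  # non-spanning: look for an enclosed water pocket
  box <- state$box
  nn <- pmax(3L, round(box / water_grid))
  hh <- box / nn
  wtr <- which(state$species == species_code("W"))
  if (length(wtr) == 0) return("other")
  ijk <- cbind(
    pmin(floor((state$positions[wtr, 1] %% box[1]) / hh[1]), nn[1] - 1) + 1,
    pmin(floor((state$positions[wtr, 2] %% box[2]) / hh[2]), nn[2] - 1) + 1,
    pmin(floor((state$positions[wtr, 3] %% box[3]) / hh[3]), nn[3] - 1) + 1)
  occ3 <- array(FALSE, nn)
  occ3[ijk] <- TRUE
  cc3 <- grid_components(occ3)
  pockets <- sum(cc3$sizes >= min_water_pocket)
  if (pockets >= 2) "vesicle" else "other"
}

#' Segment a dynamics time series into initial / adjustment / stable stages
#'
#' Self-assembly runs show three regimes in the energy (and related)
#' series: a short violent relaxation, a slower adjustment, and a stable
#' stage. The two stage boundaries are found by an exact least-squares
#' two-change-point fit (piecewise-constant model) on a running-mean
#' smoothed series. A series with no detectable structure is flagged
#' `degenerate` and split at thirds.
#'
#' @param x Numeric series (e.g. per-bead total energy per record), or a
#'   `dpd_run` (its `energy$total` series is used).
#' @param time Optional time stamps matching `x` (defaults to the run's
#'   energy times, or the sample index).
#' @param smooth_window Running-mean window in samples (default 50,
#'   clamped to a third of the series).
#' @param min_seg Minimum segment length in samples.
#' @return A `stage_segmentation`: list with boundary times
#'   `t_initial_end`, `t_adjust_end`, boundary indices, a `stages` tibble
#'   (stage, t_start, t_end, mean of the raw series) and a `degenerate`
#'   flag.
#' @export
stage_segmentation <- function(x, time = NULL, smooth_window = 50,
                               min_seg = NULL) {
  if (inherits(x, "dpd_run")) {
    if (is.null(time)) time <- x$energy$time
    x <- x$energy$total
  }
  n <- length(x)
  if (n < 9) abort("series too short to segment into three stages")
  if (is.null(time)) time <- seq_len(n)
  w <- max(1L, min(as.integer(smooth_window), n %/% 3))
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  # pad the filter edges with the nearest smoothed value
  first_ok <- which(!is.na(y))[1]; last_ok <- max(which(!is.na(y)))
  y[seq_len(first_ok - 1)] <- y[first_ok]
  if (last_ok < n) y[(last_ok + 1):n] <- y[last_ok]

  if (is.null(min_seg)) min_seg <- max(3L, n %/% 20)
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  seg_cost <- function(i, j) {
    # sum of squares of y[i..j] about its mean (vectorised over j)
    s <- s1[j] - ifelse(i > 1, s1[i - 1], 0)
    q <- s2[j] - ifelse(i > 1, s2[i - 1], 0)
    q - s^2 / (j - i + 1)
  }
  best <- Inf; b1_best <- NA_integer_; b2_best <- NA_integer_
  for (b1 in min_seg:(n - 2 * min_seg)) {
    c1 <- seg_cost(1L, b1)
    b2s <- (b1 + min_seg):(n - min_seg)
    tot <- c1 + seg_cost(b1 + 1L, b2s) + seg_cost(b2s + 1L, n)
    k <- which.min(tot)
    if (tot[k] < best) {
      best <- tot[k]; b1_best <- b1; b2_best <- b2s[k]
    }
  }
  sse0 <- seg_cost(1L, n)
  degenerate <- !is.finite(best) || sse0 < 1e-12 ||
    (sse0 - best) / sse0 < 0.01
  if (degenerate) {
    b1_best <- n %/% 3L
    b2_best <- 2L * (n %/% 3L)
  }
  stages <- tibble(
    stage = c("initial", "adjustment", "stable"),
    t_start = time[c(1L, b1_best + 1L, b2_best + 1L)],
    t_end = time[c(b1_best, b2_best, n)],
    mean = c(mean(x[1:b1_best]),
             mean(x[(b1_best + 1):b2_best]),
             mean(x[(b2_best + 1):n])))
  structure(list(t_initial_end = time[b1_best],
                 t_adjust_end = time[b2_best],
                 idx_initial_end = b1_best, idx_adjust_end = b2_best,
                 stages = stages, degenerate = degenerate),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("<stage_segmentation> boundaries at t = ",
      signif(x$t_initial_end, 5), " and ", signif(x$t_adjust_end, 5),
      if (x$degenerate) "  [degenerate: flat series, split at thirds]",
      "\n", sep = "")
  print(x$stages)
  invisible(x)
}

# stage label for arbitrary times given a segmentation
stage_of <- function(times, seg) {
  ifelse(times <= seg$t_initial_end, "initial",
         ifelse(times <= seg$t_adjust_end, "adjustment", "stable"))
}

#' Phase-diagram summary of a completed run
#'
#' Classifies the final structure and bundles the stable-stage metrics
#' used to build phase diagrams: bilayer thickness, pore diameter, mean
#' chain shape factor and stable-stage energy.
#'
#' @param run A `dpd_run`.
#' @return One-row tibble with `nt1`, `nt2`, `label`, `thickness`,
#'   `pore_diameter`, `delta`, `e_stable` and the stage boundaries.
#' @export
phase_point <- function(run) {
  comp <- run$composition
  seg <- stage_segmentation(run)
  frames <- run_frames(run)
  f_times <- vapply(frames, function(s) s$time, numeric(1))
  stable <- frames[stage_of(f_times, seg) == "stable"]
  if (length(stable) == 0) stable <- list(run$final_state)

  label <- classify_structure(run$final_state)
  thick <- mean(thickness_timeseries(stable)$thickness, na.rm = TRUE)
  if (!is.finite(thick)) thick <- NA_real_
  pore <- pore_detect(run$final_state)
  delta <- mean_shape_factor(gyration_chains(stable))
  e_stable <- seg$stages$mean[seg$stages$stage == "stable"]
  tibble(nt1 = comp$topology1$n_tail, nt2 = comp$topology2$n_tail,
         label = label,
         thickness = as.numeric(thick),
         pore_diameter = if (pore$has_pore) pore$diameter else 0,
         delta = delta, e_stable = e_stable,
         t_initial_end = seg$t_initial_end,
         t_adjust_end = seg$t_adjust_end,
         degenerate_stages = seg$degenerate)
}
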