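# Irving-Kirkwood pressure tensor and interfacial tension, whole-box,
# slab-resolved along z, optionally restricted to a y-window, and averaged
# over frames and dynamics stages.

#' Irving-Kirkwood pressure tensor of a frame
#'
#' Diagonal pressure-tensor components
#' `p_aa = (1/V) [ sum_i m v_ia^2 + sum_(i<j) F_ij,a r_ij,a ]`,
#' whole-box and resolved over z-slabs. Each pair's virial contribution is
#' spread over the slabs crossed by the straight minimum-image segment
#' between the two beads, in proportion to the segment length inside each
#' slab (Irving-Kirkwood contour), so the slab decomposition sums exactly
#' to the whole-box virial.
#'
#' By default the virial contains the non-bonded pair (conservative
#' repulsion) forces only - the force set whose interfacial profile shows
#' the bilayer signature of near-zero tension inside the membrane with
#' extrema at the two head-water interfaces. The intramolecular bond and
#' angle forces can be added (`include_bonded = TRUE`; the three-body
#' angle term is decomposed into its two bond legs before localization),
#' which adds the large axial chain-elasticity stress inside the
#' membrane. The dissipative and random forces average to the
#' thermostat's momentum flux and only add noise at equilibrium; they too
#' can be switched on for diagnostics.
#'
#' @param state A [dpd_state()] with velocities.
#' @param interaction An [interaction_model()].
#' @param bonded A [bonded_params()] (used when `include_bonded = TRUE`).
#' @param n_slabs Number of z-slabs (1 gives whole-box resolution only).
#' @param y_window Optional `c(ymin, ymax)` in rc: virial path fractions
#'   and kinetic terms are restricted to this y-range (used for near-pore
#'   profiles).
#' @param include_bonded Include bond and angle forces in the virial.
#' @param include_thermostat Also include dissipative and random forces
#'   in the virial (diagnostics only).
#' @param dt,seed Time step and seed for the random force when
#'   `include_thermostat = TRUE`.
#' @return A `stress_record`: list with `whole` (named pxx/pyy/pzz),
#'   `sigma_z` (whole-box `pzz - (pxx + pyy)/2`), `slabs` tibble
#'   (`z`, `pxx`, `pyy`, `pzz`, `sigma_z`), `time` and `slab_volume`.
#' @export
pressure_tensor <- function(state,
                            interaction = default_interaction_matrix(),
                            bonded = bonded_params(),
                            n_slabs = 1, y_window = NULL,
                            include_bonded = FALSE,
                            include_thermostat = FALSE,
                            dt = 0.01, seed = 1) {
  stopifnot(n_slabs >= 1)
  if (!is.null(y_window)) {
    stopifnot(length(y_window) == 2)
    if (diff(y_window) <= 0) abort("y_window must have positive width")
  }
  comp <- state$composition
  bonds <- if (include_bonded && !is.null(comp)) {
    composition_bonds(comp)
  } else empty_bonds
  angles <- if (include_bonded && !is.null(comp)) {
    composition_angles(comp)
  } else empty_angles
  yw <- if (is.null(y_window)) c(0, -1) else y_window
  res <- cpp_pressure(state$positions, state$velocities, state$species,
                      state$box, interaction$a, interaction$rc,
                      bonds, bonded$ks, bonded$rs,
                      angles, bonded$k_theta, bonded$theta0,
                      as.integer(n_slabs), yw[1], yw[2],
                      include_thermostat, interaction$gamma,
                      include_thermostat, interaction$sigma, dt, seed)
  slabs <- as_tibble(as.data.frame(res$slabs))
  slabs$z <- res$z_mid
  slabs$sigma_z <- slabs$pzz - (slabs$pxx + slabs$pyy) / 2
  slabs <- slabs[, c("z", "pxx", "pyy", "pzz", "sigma_z")]
  structure(list(whole = res$whole,
                 sigma_z = unname(res$whole["pzz"] -
                                    (res$whole["pxx"] + res$whole["pyy"]) / 2),
                 slabs = slabs, time = state$time,
                 slab_volume = res$slab_volume),
            class = "stress_record")
}

#' @export
print.stress_record <- function(x, ...) {
  cat("<stress_record> t = ", signif(x$time, 6), ": pxx = ",
      signif(x$whole["pxx"], 5), ", pyy = ", signif(x$whole["pyy"], 5),
      ", pzz = ", signif(x$whole["pzz"], 5), ", sigma_z = ",
      signif(x$sigma_z, 5), "\n", sep = "")
  invisible(x)
}

#' Interfacial tension of a stress record
#'
#' `sigma_z = pzz - (pxx + pyy)/2` (normal minus mean tangential
#' component): positive where the normal pressure exceeds the lateral
#' pressure, zero in an isotropic fluid.
#'
#' @param record A `stress_record` from [pressure_tensor()], or a named
#'   vector/list with `pxx`, `pyy`, `pzz`.
#' @return Scalar tension in kBT/rc^3.
#' @export
tension_z <- function(record) {
  p <- if (inherits(record, "stress_record")) record$whole else record
  unname(p[["pzz"]] - (p[["pxx"]] + p[["pyy"]]) / 2)
}

#' Interfacial-tension profile along z
#'
#' Per-slab Irving-Kirkwood tensor averaged over frames: the profile is
#' flat and statistically zero in a bulk fluid, and for a bilayer shows
#' its extrema at the two head-water interfaces.
#'
#' @param frames List of [dpd_state()] frames (e.g. [run_frames()]).
#' @param interaction,bonded Force-field parameters of the run.
#' @param n_slabs Number of z-slabs (default 60).
#' @param y_window Optional y-restriction, see [pressure_tensor()].
#' @param include_bonded Include bond/angle forces in the virial (see
#'   [pressure_tensor()]).
#' @return Tibble with `z`, `pxx`, `pyy`, `pzz`, `sigma_z`, averaged over
#'   frames; class `dpd_profile`.
#' @export
tension_profile <- function(frames,
                            interaction = default_interaction_matrix(),
                            bonded = bonded_params(),
                            n_slabs = 60, y_window = NULL,
                            include_bonded = FALSE) {
  if (inherits(frames, "dpd_state")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  acc <- NULL
  for (st in frames) {
    rec <- pressure_tensor(st, interaction, bonded, n_slabs = n_slabs,
                           y_window = y_window,
                           include_bonded = include_bonded)
    m <- as.matrix(rec$slabs[, c("pxx", "pyy", "pzz")])
    acc <- if (is.null(acc)) m else acc + m
    z <- rec$slabs$z
  }
  acc <- acc / length(frames)
  out <- tibble(z = z, pxx = acc[, 1], pyy = acc[, 2], pzz = acc[, 3],
                sigma_z = acc[, 3] - (acc[, 1] + acc[, 2]) / 2)
  class(out) <- c("dpd_profile", class(out))
  out
}

#' Near-pore interfacial-tension profile
#'
#' [tension_profile()] restricted to a lateral window around the pore
#' (default `7 <= y <= 17` rc), averaging over the x-direction only.
#'
#' @inheritParams tension_profile
#' @param y_window Lateral window `c(ymin, ymax)` in rc.
#' @return As [tension_profile()].
#' @export
tension_near_pore <- function(frames,
                              interaction = default_interaction_matrix(),
                              bonded = bonded_params(),
                              y_window = c(7, 17), n_slabs = 60,
                              include_bonded = FALSE) {
  tension_profile(frames, interaction, bonded, n_slabs = n_slabs,
                  y_window = y_window, include_bonded = include_bonded)
}

# slabs whose lipid density exceeds half its plateau: the "membrane
# domain" over which stage tensions are averaged
membrane_domain_slabs <- function(frames, n_slabs) {
  prof <- density_profile(frames, bin_width = frames[[1]]$box[3] / n_slabs,
                          species = c("H1", "T1", "H2", "T2"))
  tot <- prof %>% group_by(bin) %>%
    summarise(density = sum(.data$density), .groups = "drop") %>%
    arrange(bin)
  thr <- 0.5 * max(tot$density)
  which(tot$density > thr)
}

#' Stage-averaged interfacial tension over the membrane domain
#'
#' For each stored frame the slab-resolved tension is averaged over the
#' membrane-domain slabs (z-slabs where the total lipid density exceeds
#' half its plateau, determined from the stable-stage frames); frames are
#' then grouped by dynamics stage and the per-stage mean reported.
#'
#' @param run A `dpd_run` with stored frames and velocities.
#' @param stages Optional [stage_segmentation()] (defaults to segmenting
#'   the run's energy series).
#' @param n_slabs Number of z-slabs.
#' @return Tibble with `stage`, `sigma_z` (mean over frames), `n_frames`,
#'   plus the `membrane_domain` z-range as an attribute.
#' @export
tension_timeseries <- function(run, stages = NULL, n_slabs = 60,
                               include_bonded = FALSE) {
  if (is.null(stages)) stages <- stage_segmentation(run)
  frames <- run_frames(run)
  if (length(frames) == 0) abort("run has no stored frames")
  f_times <- vapply(frames, function(s) s$time, numeric(1))
  f_stage <- stage_of(f_times, stages)
  stable <- frames[f_stage == "stable"]
  if (length(stable) == 0) stable <- frames[length(frames)]
  domain <- membrane_domain_slabs(stable, n_slabs)
  per_frame <- vapply(frames, function(st) {
    rec <- pressure_tensor(st, run$interaction, run$bonded,
                           n_slabs = n_slabs,
                           include_bonded = include_bonded)
    mean(rec$slabs$sigma_z[domain])
  }, numeric(1))
  out <- tibble(time = f_times, stage = f_stage, sigma_z = per_frame) %>%
    group_by(stage) %>%
    summarise(sigma_z = mean(.data$sigma_z), n_frames = n(),
              .groups = "drop")
  out <- out[match(c("initial", "adjustment", "stable"), out$stage), ]
  out <- out[!is.na(out$stage), ]
  z_all <- (domain - 0.5) * frames[[1]]$box[3] / n_slabs
  attr(out, "membrane_domain") <- range(z_all)
  out
}
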