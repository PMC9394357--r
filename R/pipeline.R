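# Configuration-driven orchestration: config objects and plain-text
# serialization, simulate / analyze, and the NT1 x NT2 phase sweep.

#' Build a simulation configuration
#'
#' A flat, serializable description of one simulation: composition,
#' initial condition, integrator settings and recording strides. The
#' defaults reproduce the full-scale study conditions: a 30^3 rc box at
#' bead density 3 (N = 81,000), 900 + 900 chains with 3 head beads each,
#' layered unmixed start, dt = 0.01 tau.
#'
#' @param nt1,nt2 Tail bead counts of the two lipid types.
#' @param nh1,nh2 Head bead counts (default 3).
#' @param n1,n2 Chain counts (default 900 each).
#' @param box Box edges in rc (default `c(30, 30, 30)`).
#' @param density Bead density (default 3).
#' @param n_steps Integration steps (default 300,000).
#' @param dt Time step (default 0.01 tau).
#' @param lambda Velocity-prediction factor (default 0.5).
#' @param initial `"layered"`, `"random"`, `"perforated"` or `"vesicle"`.
#' @param energy_every,frame_every Recording strides in steps.
#' @param a_like,a_unlike,gamma,sigma Interaction parameters
#'   (see [default_interaction_matrix()]).
#' @param ks,rs,k_theta,theta0 Bonded parameters (see [bonded_params()]).
#' @param pore_radius,vesicle_radius Geometry of the fixture initials.
#' @return A `dpd_config` (named list).
#' @export
dpd_config <- function(nt1 = 9, nt2 = 9, nh1 = 3, nh2 = 3,
                       n1 = 900, n2 = 900,
                       box = c(30, 30, 30), density = 3,
                       n_steps = 300000, dt = 0.01, lambda = 0.5,
                       initial = "layered",
                       energy_every = 100, frame_every = 1000,
                       a_like = 25, a_unlike = 100,
                       gamma = 4.5, sigma = 3.0,
                       ks = 120, rs = 0.7, k_theta = 6, theta0 = pi,
                       pore_radius = 8, vesicle_radius = 8) {
  cfg <- as.list(environment())
  structure(cfg, class = "dpd_config")
}

#' Reduced desk-scale preset
#'
#' The scaled-down counterpart of the full-scale box used for routine
#' runs: 15 x 15 x 30 rc (N = 20,250) with the chain count scaled by the
#' area ratio (225 + 225 chains, preserving one chain per rc^2 of leaflet
#' area) and 60,000 steps.
#'
#' @inheritParams dpd_config
#' @param ... Further overrides passed to [dpd_config()].
#' @return A `dpd_config`.
#' @export
reduced_preset <- function(nt1 = 9, nt2 = 9, n_steps = 60000,
                           n1 = 225, n2 = 225, box = c(15, 15, 30), ...) {
  dpd_config(nt1 = nt1, nt2 = nt2, n1 = n1, n2 = n2,
             box = box, n_steps = n_steps, ...)
}

#' Full-scale preset of the study conditions
#'
#' @inheritParams dpd_config
#' @param ... Further overrides passed to [dpd_config()].
#' @return A `dpd_config` with the 30^3 rc box, N = 81,000 beads,
#'   900 + 900 chains and 300,000 steps.
#' @export
full_preset <- function(nt1 = 9, nt2 = 9, ...) {
  dpd_config(nt1 = nt1, nt2 = nt2, ...)
}

#' @export
print.dpd_config <- function(x, ...) {
  cat("<dpd_config> NT1 = ", x$nt1, ", NT2 = ", x$nt2, ", box ",
      paste(x$box, collapse = "x"), " rc, ", x$n1, "+", x$n2,
      " chains, ", format(x$n_steps, big.mark = ","), " steps, initial ",
      x$initial, "\n", sep = "")
  invisible(x)
}

#' Write / read a configuration as plain-text YAML
#'
#' @param config A `dpd_config`.
#' @param path File path.
#' @return `path` (write) or the `dpd_config` (read).
#' @export
write_dpd_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_dpd_config
#' @export
read_dpd_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- dpd_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  defaults[names(cfg)] <- cfg
  defaults$box <- as.numeric(defaults$box)
  structure(defaults, class = "dpd_config")
}

config_composition <- function(config) {
  system_composition(config$n1, config$n2,
                     nh1 = config$nh1, nt1 = config$nt1,
                     nh2 = config$nh2, nt2 = config$nt2,
                     box = config$box, density = config$density)
}

config_interaction <- function(config) {
  default_interaction_matrix(a_like = config$a_like,
                             a_unlike = config$a_unlike,
                             gamma = config$gamma, sigma = config$sigma)
}

config_bonded <- function(config) {
  bonded_params(ks = config$ks, rs = config$rs,
                k_theta = config$k_theta, theta0 = config$theta0)
}

config_initial_state <- function(config, seed) {
  comp <- config_composition(config)
  switch(config$initial,
         layered = layered_bilayer_init(comp, seed = seed, rs = config$rs),
         random = random_init(comp, seed = seed, rs = config$rs),
         perforated = perforated_fixture(comp, config$pore_radius,
                                         seed = seed, rs = config$rs),
         vesicle = vesicle_fixture(comp, config$vesicle_radius,
                                   seed = seed, rs = config$rs),
         abort(paste("unknown initial condition:", config$initial)))
}

#' Run one configured simulation
#'
#' Builds the seeded initial configuration, integrates for the configured
#' number of steps and returns the run together with a manifest (config,
#' config hash, seed) that makes the output exactly reproducible. If
#' `output_dir` is given, the trajectory (LAMMPS-style dump), the energy
#' log (CSV) and the manifest (JSON) are also written there.
#'
#' This is a method for the [stats::simulate()] generic, so plain
#' `simulate(config, seed = 1)` works once the package is attached.
#'
#' @param object A [dpd_config()].
#' @param nsim Unused (one trajectory per call); present for generic
#'   compatibility.
#' @param seed Integer seed covering both the initial configuration and
#'   the thermostat stream.
#' @param output_dir Optional directory for on-disk outputs.
#' @param ... Unused.
#' @return A `dpd_run` with a `manifest` element.
#' @importFrom stats simulate
#' @export
#' @export simulate.dpd_config
simulate.dpd_config <- function(object, nsim = 1, seed = 1,
                                output_dir = NULL, ...) {
  config <- object
  st <- config_initial_state(config, seed)
  run <- dpd_run(st, n_steps = config$n_steps, dt = config$dt,
                 lambda = config$lambda, seed = seed,
                 interaction = config_interaction(config),
                 bonded = config_bonded(config),
                 energy_every = config$energy_every,
                 frame_every = config$frame_every)
  run$manifest <- list(config = unclass(config),
                       config_hash = rlang::hash(unclass(config)),
                       seed = seed,
                       package_version =
                         as.character(utils::packageVersion("dpdmix")))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_lammps_dump(run_frames(run), file.path(output_dir, "traj.dump"))
    utils::write.csv(run$energy, file.path(output_dir, "energy.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run$manifest, file.path(output_dir,
                                                 "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' Run the analysis battery on a completed run
#'
#' Dispatches the requested observables, applying the three-stage
#' segmentation once and sharing it. With an `output_dir`, every table is
#' written as CSV and the classification summary as JSON.
#'
#' @param run A `dpd_run`.
#' @param which Subset of `c("classification", "stages", "density",
#'   "order", "gyration", "mixing", "tension_profile", "tension_stages")`.
#' @param output_dir Optional output directory.
#' @return Named list of result tables / objects.
#' @export
analyze <- function(run,
                    which = c("classification", "stages", "density",
                              "order", "gyration", "mixing"),
                    output_dir = NULL) {
  seg <- stage_segmentation(run)
  frames <- run_frames(run)
  f_times <- vapply(frames, function(s) s$time, numeric(1))
  stable <- frames[stage_of(f_times, seg) == "stable"]
  if (length(stable) == 0) stable <- list(run$final_state)

  out <- list(manifest = run$manifest)
  if ("stages" %in% which) out$stages <- seg$stages
  if ("classification" %in% which) {
    pore <- pore_detect(run$final_state)
    thick <- mean(thickness_timeseries(stable)$thickness, na.rm = TRUE)
    out$classification <- tibble(
      label = classify_structure(run$final_state),
      pore_diameter = if (pore$has_pore) pore$diameter else 0,
      thickness = if (is.finite(thick)) thick else NA_real_)
  }
  if ("density" %in% which) out$density <- density_profile(stable)
  if ("order" %in% which) {
    out$order <- bind_rows(
      mutate(order_parameter(stable, "head"), sub_chain = "head"),
      mutate(order_parameter(stable, "tail"), sub_chain = "tail"))
  }
  if ("gyration" %in% which) out$gyration <- gyration_chains(stable)
  if ("mixing" %in% which) {
    out$mixing <- bind_rows(lapply(frames, leaflet_mixing_counts))
  }
  if ("tension_profile" %in% which) {
    out$tension_profile <- tension_profile(stable, run$interaction,
                                           run$bonded)
  }
  if ("tension_stages" %in% which) {
    out$tension_stages <- tension_timeseries(run, seg)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(out), "manifest")) {
      if (is.data.frame(out[[nm]])) {
        utils::write.csv(out[[nm]],
                         file.path(output_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    if (!is.null(out$classification)) {
      jsonlite::write_json(as.list(out$classification[1, ]),
                           file.path(output_dir, "classification.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}

#' Sweep the NT1 x NT2 phase grid
#'
#' Runs one simulation per grid point (optionally several seeds per
#' point, keeping the outcome with the lowest stable-stage energy per
#' bead) and assembles the phase table used to draw phase diagrams.
#' Individual run failures are recorded and the sweep continues.
#'
#' @param nt1_values,nt2_values Integer vectors of tail bead counts.
#' @param base_config A [dpd_config()] supplying everything but `nt1`,
#'   `nt2`.
#' @param seeds Integer vector of seeds per grid point.
#' @return Tibble: one row per grid point with the [phase_point()]
#'   metrics (all-`NA` metrics and a `failed` label when a run errored).
#' @export
sweep_phase_grid <- function(nt1_values, nt2_values,
                             base_config = reduced_preset(),
                             seeds = 1L) {
  grid <- expand.grid(nt1 = nt1_values, nt2 = nt2_values)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- base_config
    cfg$nt1 <- grid$nt1[k]; cfg$nt2 <- grid$nt2[k]
    best <- NULL
    for (sd in seeds) {
      res <- tryCatch({
        run <- simulate(cfg, seed = sd)
        pp <- phase_point(run)
        pp$seed <- sd
        pp
      }, error = function(e) {
        warn(paste0("sweep point NT1=", cfg$nt1, " NT2=", cfg$nt2,
                    " seed=", sd, " failed: ", conditionMessage(e)))
        NULL
      })
      if (!is.null(res) &&
          (is.null(best) || res$e_stable < best$e_stable)) {
        best <- res
      }
    }
    if (is.null(best)) {
      best <- tibble(nt1 = cfg$nt1, nt2 = cfg$nt2, label = "failed",
                     thickness = NA_real_, pore_diameter = NA_real_,
                     delta = NA_real_, e_stable = NA_real_,
                     t_initial_end = NA_real_, t_adjust_end = NA_real_,
                     degenerate_stages = NA, seed = NA_integer_)
    }
    best
  })
  bind_rows(rows)
}
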