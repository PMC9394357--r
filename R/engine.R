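# R-level interface to the compiled DPD engine.

empty_bonds <- matrix(integer(0), 0, 2)
empty_angles <- matrix(integer(0), 0, 3)

#' DPD pair weight function
#'
#' The dimensionless weight `w(r) = 1 - r/rc` inside the cutoff and 0
#' beyond it, shared by the conservative force (`a w`), the dissipative
#' force (`gamma w^2`) and the random force (`sigma w`).
#'
#' @param r Distance(s), >= 0.
#' @param rc Cutoff length (default 1, the unit of length).
#' @return Weight(s) in `[0, 1]`.
#' @export
#' @examples
#' pair_weight(c(0, 0.3, 1, 2))  # 1, 0.7, 0, 0
pair_weight <- function(r, rc = 1) {
  stopifnot(all(r >= 0), rc > 0)
  pmax(0, 1 - r / rc)
}

#' Evaluate DPD forces on a state
#'
#' Computes the forces on every bead: the soft conservative repulsion
#' `a_ij (1 - r/rc) rhat`, the pairwise dissipative force
#' `-gamma w^2 (rhat . v_ij) rhat`, the pairwise random force
#' `sigma w zeta dt^(-1/2) rhat` (one Gaussian draw per interacting pair,
#' applied antisymmetrically so momentum is conserved), and the bonded
#' bond/angle terms. Intended for diagnostics and testing; the integrator
#' evaluates forces internally.
#'
#' @param state A [dpd_state()].
#' @param interaction An [interaction_model()].
#' @param bonded A [bonded_params()].
#' @param include Character subset of
#'   `c("conservative", "dissipative", "random")`.
#' @param dt Time step (sets the `dt^(-1/2)` random-force scaling).
#' @param seed RNG seed for the random force.
#' @param method `"cell"` (cell-list neighbour search) or `"allpairs"`
#'   (brute-force reference path).
#' @return List with `forces` (N x 3), per-system potential energies
#'   `pair_energy`, `bond_energy`, `angle_energy`, and `n_overlap` (count
#'   of zero-separation pairs handled by the capped-force rule).
#' @export
dpd_forces <- function(state,
                       interaction = default_interaction_matrix(),
                       bonded = bonded_params(),
                       include = c("conservative", "dissipative", "random"),
                       dt = 0.01, seed = 1,
                       method = c("cell", "allpairs")) {
  method <- match.arg(method)
  include <- match.arg(include, several.ok = TRUE)
  comp <- state$composition
  bonds <- if (!is.null(comp)) composition_bonds(comp) else empty_bonds
  angles <- if (!is.null(comp)) composition_angles(comp) else empty_angles
  cpp_forces(state$positions, state$velocities, state$species, state$box,
             interaction$a, interaction$rc, interaction$gamma,
             interaction$sigma, dt,
             bonds, bonded$ks, bonded$rs,
             angles, bonded$k_theta, bonded$theta0,
             method == "cell",
             "conservative" %in% include,
             "dissipative" %in% include,
             "random" %in% include,
             seed)
}

#' Potential and kinetic energy breakdown of a state
#'
#' Pair energy is the integral of the conservative force,
#' `(a rc / 2)(1 - r/rc)^2` per pair within the cutoff; bond energy
#' `(ks rs / 2)(1 - r/rs)^2`; angle energy `k_theta (theta - theta0)^2`;
#' kinetic energy `m v^2 / 2`. All reported per bead in kBT.
#'
#' @inheritParams dpd_forces
#' @return One-row tibble with `kinetic`, `pair`, `bond`, `angle`, `total`
#'   (per-bead energies) and `temperature`.
#' @export
energy_breakdown <- function(state,
                             interaction = default_interaction_matrix(),
                             bonded = bonded_params()) {
  f <- dpd_forces(state, interaction, bonded, include = "conservative")
  n <- nrow(state$positions)
  kin <- 0.5 * sum(state$velocities^2)
  tibble(kinetic = kin / n,
         pair = f$pair_energy / n,
         bond = f$bond_energy / n,
         angle = f$angle_energy / n,
         total = (kin + f$pair_energy + f$bond_energy + f$angle_energy) / n,
         temperature = temperature(state))
}

#' Run the DPD integrator
#'
#' Advances a state with the Groot-Warren modified velocity-Verlet scheme:
#' positions are updated with the current forces, a predicted velocity
#' `v + lambda dt f` enters the force recomputation (the dissipative force
#' sees it and the random force is redrawn), and the velocity is corrected
#' with the mean of old and new forces. Periodic boundaries in x, y, z;
#' neighbour search by a cell list rebuilt every step.
#'
#' The trajectory is exactly reproducible: the same state, parameters and
#' `seed` give a bitwise-identical run.
#'
#' @param state Starting [dpd_state()].
#' @param n_steps Number of time steps.
#' @param dt Time step in tau (default 0.01).
#' @param lambda Velocity-prediction factor in the modified Verlet scheme
#'   (default 0.5, the standard choice).
#' @param seed Integer seed for the random-force stream.
#' @param interaction An [interaction_model()].
#' @param bonded A [bonded_params()].
#' @param energy_every Record the energy breakdown every this many steps
#'   (0 disables).
#' @param frame_every Store a trajectory frame every this many steps
#'   (0 stores none; the final state is always available).
#' @param save_velocities Keep per-frame velocities (needed for the
#'   kinetic part of the pressure tensor).
#' @return A `dpd_run` object: list with `final_state`, `energy`
#'   (tibble: step, time, kinetic, pair, bond, angle, total, temperature;
#'   energies per bead in kBT), `frames` (list of frames with `positions`,
#'   optionally `velocities`, and `time`), the run parameters and seed.
#' @export
#' @examples
#' comp <- system_composition(8, 8, nt1 = 2, nt2 = 2, box = c(4, 4, 8))
#' st <- layered_bilayer_init(comp, seed = 1)
#' run <- dpd_run(st, n_steps = 50, energy_every = 10, seed = 1)
#' run$energy
dpd_run <- function(state, n_steps, dt = 0.01, lambda = 0.5, seed = 1,
                    interaction = default_interaction_matrix(),
                    bonded = bonded_params(),
                    energy_every = 100, frame_every = 1000,
                    save_velocities = TRUE) {
  stopifnot(n_steps >= 1, dt > 0, lambda >= 0, lambda <= 1)
  comp <- state$composition
  bonds <- if (!is.null(comp)) composition_bonds(comp) else empty_bonds
  angles <- if (!is.null(comp)) composition_angles(comp) else empty_angles
  res <- cpp_run(state$positions, state$velocities, state$species,
                 state$box, interaction$a, interaction$rc,
                 interaction$gamma, interaction$sigma,
                 bonds, bonded$ks, bonded$rs,
                 angles, bonded$k_theta, bonded$theta0,
                 as.integer(n_steps), dt, lambda, state$time,
                 as.integer(energy_every), as.integer(frame_every),
                 seed, save_velocities)
  final <- state
  final$positions <- res$positions
  final$velocities <- res$velocities
  final$time <- res$time
  energy <- as_tibble(as.data.frame(res$energy_log))
  structure(list(final_state = final,
                 energy = energy,
                 frames = res$frames,
                 composition = comp,
                 interaction = interaction,
                 bonded = bonded,
                 dt = dt, lambda = lambda, n_steps = n_steps,
                 seed = seed, n_overlap = res$n_overlap),
            class = "dpd_run")
}

#' Advance a state by a single velocity-Verlet step
#'
#' Convenience wrapper around [dpd_run()] for step-level tests and custom
#' loops.
#'
#' @inheritParams dpd_run
#' @return The updated [dpd_state()].
#' @export
dpd_step <- function(state, dt = 0.01, lambda = 0.5, seed = 1,
                     interaction = default_interaction_matrix(),
                     bonded = bonded_params()) {
  dpd_run(state, n_steps = 1, dt = dt, lambda = lambda, seed = seed,
          interaction = interaction, bonded = bonded,
          energy_every = 0, frame_every = 0,
          save_velocities = FALSE)$final_state
}

#' @export
print.dpd_run <- function(x, ...) {
  cat("<dpd_run> ", x$n_steps, " steps of dt = ", x$dt, " tau (",
      nrow(x$final_state$positions), " beads), t = ",
      signif(x$final_state$time, 6), " tau, ",
      length(x$frames), " stored frames\n", sep = "")
  if (nrow(x$energy) > 0) {
    last <- x$energy[nrow(x$energy), ]
    cat("  final per-bead energy ", signif(last$total, 4),
        " kBT, temperature ", signif(last$temperature, 4), "\n", sep = "")
  }
  invisible(x)
}

# convert a stored frame into a dpd_state (for analysis functions)
frame_state <- function(run, frame) {
  st <- run$final_state
  st$positions <- frame$positions
  if (!is.null(frame$velocities)) st$velocities <- frame$velocities
  st$time <- frame$time
  st
}

#' Extract stored frames of a run as states
#'
#' @param run A `dpd_run`.
#' @param which Indices of frames (default all).
#' @return List of [dpd_state()] objects.
#' @export
run_frames <- function(run, which = NULL) {
  idx <- if (is.null(which)) seq_along(run$frames) else which
  lapply(run$frames[idx], function(fr) frame_state(run, fr))
}
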