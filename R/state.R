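# Simulation state container and trajectory I/O.

#' Construct a simulation state
#'
#' A `dpd_state` holds wrapped positions, velocities, per-bead species and
#' molecule ids, the periodic box and the current time, plus the
#' [system_composition()] that generated it (the composition fixes the
#' bead ordering and hence the chain structure).
#'
#' @param positions,velocities N x 3 numeric matrices (rc and rc/tau units).
#' @param composition A [system_composition()].
#' @param time Time in tau.
#' @return A `dpd_state` object.
#' @export
dpd_state <- function(positions, velocities, composition, time = 0) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  n <- composition$N
  if (nrow(positions) != n || nrow(velocities) != n ||
      ncol(positions) != 3 || ncol(velocities) != 3) {
    abort("positions/velocities must be N x 3 with N matching the composition")
  }
  box <- composition$box
  for (d in 1:3) {
    positions[, d] <- positions[, d] %% box[d]
  }
  structure(list(positions = positions, velocities = velocities,
                 species = composition_species(composition),
                 molecule = composition_molecule(composition),
                 box = box, time = time, composition = composition),
            class = "dpd_state")
}

#' @export
print.dpd_state <- function(x, ...) {
  cat("<dpd_state> ", nrow(x$positions), " beads, box ",
      paste(signif(x$box, 4), collapse = " x "), " rc, t = ",
      signif(x$time, 6), " tau\n", sep = "")
  invisible(x)
}

#' Per-bead table view of a state
#'
#' @param x A `dpd_state`.
#' @param ... Unused.
#' @return Tibble with bead id, species label, molecule id, positions and
#'   velocities.
#' @export
as_tibble.dpd_state <- function(x, ...) {
  tibble(bead = seq_len(nrow(x$positions)),
         species = dpd_species()[x$species],
         molecule = x$molecule,
         x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3],
         vx = x$velocities[, 1], vy = x$velocities[, 2],
         vz = x$velocities[, 3])
}

#' Kinetic temperature of a state
#'
#' Mean kinetic energy per degree of freedom after removing the
#' centre-of-mass velocity (the conserved total momentum carries no
#' thermal energy).
#'
#' @param state A `dpd_state`.
#' @return Temperature estimate in kBT.
#' @export
temperature <- function(state) {
  v <- state$velocities
  n <- nrow(v)
  if (n < 2) return(0)
  v <- sweep(v, 2, colMeans(v))
  sum(v^2) / (3 * (n - 1))
}

#' Write a LAMMPS-style text dump
#'
#' One `ITEM:`-delimited frame per state: bead id, integer species type and
#' wrapped coordinates, optionally velocities.
#'
#' @param states A `dpd_state` or list of them.
#' @param path Output file.
#' @param velocities Include velocity columns.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(states, path, velocities = FALSE) {
  if (inherits(states, "dpd_state")) states <- list(states)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$positions)
    step <- if (!is.null(st$step)) st$step else round(st$time / 0.01)
    writeLines(c("ITEM: TIMESTEP", format(step, scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS", format(n, scientific = FALSE),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste(0, st$box[1]), paste(0, st$box[2]),
                 paste(0, st$box[3]),
                 paste("ITEM: ATOMS id type x y z",
                       if (velocities) "vx vy vz" else "")), con)
    m <- cbind(seq_len(n), st$species, st$positions,
               if (velocities) st$velocities)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read frames from a LAMMPS-style text dump
#'
#' Reads dumps written by [write_lammps_dump()] (columns id, type, x, y, z
#' and optionally vx, vy, vz).
#'
#' @param path Dump file.
#' @return List of frames; each a list with `positions`, `species`, `box`,
#'   `step` and (if present) `velocities`.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", lines)
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    step <- as.numeric(lines[i + 1])
    n <- as.integer(lines[i + 3])
    box_hi <- vapply(1:3, function(d) {
      as.numeric(strsplit(trimws(lines[i + 4 + d]), "\\s+")[[1]])[2]
    }, numeric(1))
    hdr <- strsplit(trimws(sub("ITEM: ATOMS", "", lines[i + 8])), "\\s+")[[1]]
    body <- lines[(i + 9):(i + 8 + n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                nrow = n, byrow = TRUE)
    colnames(m) <- hdr
    ord <- order(m[, "id"])
    m <- m[ord, , drop = FALSE]
    fr <- list(positions = unname(m[, c("x", "y", "z")]),
               species = as.integer(m[, "type"]),
               box = box_hi, step = step)
    if (all(c("vx", "vy", "vz") %in% hdr)) {
      fr$velocities <- unname(m[, c("vx", "vy", "vz")])
    }
    frames[[k]] <- fr
  }
  frames
}

#' Checkpoint and restart a simulation state
#'
#' Serializes the full state (positions, velocities, species, box, time
#' and composition) to a portable binary container together with a hash
#' of the provided configuration, so a restart can verify it continues
#' the run it thinks it does.
#'
#' @param state A [dpd_state()].
#' @param path Checkpoint file.
#' @param config Optional configuration object whose hash is stored and
#'   checked on restart.
#' @return `path` (write) or the restored [dpd_state()] (read).
#' @export
write_checkpoint <- function(state, path, config = NULL) {
  payload <- list(state = state,
                  config_hash = if (!is.null(config)) {
                    rlang::hash(unclass(config))
                  },
                  package_version =
                    as.character(utils::packageVersion("dpdmix")))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path, config = NULL) {
  payload <- readRDS(path)
  if (!is.null(config) && !is.null(payload$config_hash) &&
      payload$config_hash != rlang::hash(unclass(config))) {
    abort("checkpoint was written under a different configuration")
  }
  payload$state
}

#' Write an XYZ file for molecular viewers
#'
#' @param state A `dpd_state`.
#' @param path Output file.
#' @param drop_water Omit water beads (the usual choice when inspecting
#'   self-assembled structures).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, drop_water = TRUE) {
  keep <- if (drop_water) state$species != species_code("W") else
    rep(TRUE, length(state$species))
  lab <- dpd_species()[state$species[keep]]
  pos <- state$positions[keep, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(format(sum(keep)), paste0("t = ", state$time)), con)
  utils::write.table(data.frame(lab, pos), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
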