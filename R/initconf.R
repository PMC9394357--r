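# Seeded builders for the study's starting configurations: unmixed layered
# bilayers, random dispersions, and pre-assembled perforated / vesicle
# fixtures. All builders fill the remaining volume with water to the target
# density, draw Maxwellian velocities at kBT = 1 and remove the
# centre-of-mass momentum.

maxwell_velocities <- function(n, kBT = 1) {
  v <- matrix(rnorm(3L * n, sd = sqrt(kBT)), n, 3)
  sweep(v, 2, colMeans(v))
}

# square-ish lattice of n sites over Lx x Ly, with jitter <= frac * spacing
leaflet_sites <- function(n, lx, ly, jitter_frac = 0.2) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  nx <- max(1L, ceiling(sqrt(n * lx / ly)))
  ny <- ceiling(n / nx)
  sx <- lx / nx; sy <- ly / ny
  g <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  g <- g[seq_len(n), , drop = FALSE]
  cbind((g$ix + runif(n, -jitter_frac, jitter_frac)) * sx,
        (g$iy + runif(n, -jitter_frac, jitter_frac)) * sy)
}

# straight vertical chain z-coordinates; bead 1 is the outermost head,
# the last tail bead sits `gap` from the midplane
chain_z <- function(n_beads, rs, z_mid, gap, upper) {
  off <- gap + (n_beads - seq_len(n_beads)) * rs
  if (upper) z_mid + off else z_mid - off
}

# sample n water positions uniformly in the box but outside the exclusion
# predicate; deterministic under the current RNG state
fill_water <- function(n, box, exclude = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  out <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(1000L, ceiling((n - nrow(out)) * 1.6))
    cand <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]),
                  runif(m, 0, box[3]))
    if (!is.null(exclude)) cand <- cand[!exclude(cand), , drop = FALSE]
    out <- rbind(out, cand)
    tries <- tries + 1L
    if (tries > 200L) {
      abort("cannot place water: the excluded region fills the box")
    }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Unmixed layered bilayer starting configuration
#'
#' Builds the study's layer-like initial state: all type-I chains stand in
#' the upper leaflet (heads up, tails pointing down to the midplane at
#' `Lz/2`) and all type-II chains mirrored in the lower leaflet. Chains are
#' straight (bond length `rs`, angles at their equilibrium), placed on a
#' jittered square lattice; water fills the volume outside the lipid slab.
#'
#' @param composition A [system_composition()].
#' @param seed Integer RNG seed; the same seed reproduces the state.
#' @param rs Bond length used for construction (default 0.7 rc).
#' @param jitter_frac Lateral jitter as a fraction of the lattice spacing.
#' @return A [dpd_state()].
#' @export
#' @examples
#' comp <- system_composition(16, 16, nt1 = 2, nt2 = 2, box = c(5, 5, 10))
#' st <- layered_bilayer_init(comp, seed = 1)
#' leaflet_mixing_counts(st)
layered_bilayer_init <- function(composition, seed = 1, rs = 0.7,
                                 jitter_frac = 0.2) {
  comp <- composition
  box <- comp$box
  area_per_chain <- box[1] * box[2] / max(comp$n1, comp$n2, 1)
  if (area_per_chain < 0.25) {
    abort("leaflet area insufficient for the requested chain count")
  }
  nb_max <- max(length(comp$topology1$bead_species),
                length(comp$topology2$bead_species))
  if (comp$NW > 0 && 2 * (rs + (nb_max - 1) * rs + 0.35) >= box[3]) {
    abort("box too short along z for the chain length: no room for water")
  }
  set.seed(seed)
  z_mid <- box[3] / 2
  gap <- rs / 2
  nb1 <- length(comp$topology1$bead_species)
  nb2 <- length(comp$topology2$bead_species)

  xy1 <- leaflet_sites(comp$n1, box[1], box[2], jitter_frac)
  xy2 <- leaflet_sites(comp$n2, box[1], box[2], jitter_frac)
  pos1 <- if (comp$n1 > 0) cbind(
    rep(xy1[, 1], each = nb1), rep(xy1[, 2], each = nb1),
    rep(chain_z(nb1, rs, z_mid, gap, upper = TRUE), comp$n1)) else
      matrix(numeric(0), 0, 3)
  pos2 <- if (comp$n2 > 0) cbind(
    rep(xy2[, 1], each = nb2), rep(xy2[, 2], each = nb2),
    rep(chain_z(nb2, rs, z_mid, gap, upper = FALSE), comp$n2)) else
      matrix(numeric(0), 0, 3)

  # keep water out of the lipid slab so the unmixed start has no trapped
  # solvent; half-thickness covers the taller leaflet plus a small buffer
  half <- gap + (max(nb1, nb2) - 1) * rs + 0.35
  exclude <- function(p) abs(p[, 3] - z_mid) < half
  posw <- fill_water(comp$NW, box, exclude)

  dpd_state(rbind(pos1, pos2, posw),
            maxwell_velocities(comp$N), comp, time = 0)
}

#' Random dispersion starting configuration
#'
#' Chains are laid down as randomly oriented persistent random walks with
#' bond length `rs`; water fills the rest of the box uniformly.
#'
#' @inheritParams layered_bilayer_init
#' @param persistence Directional persistence of the walk in (0, 1]; 1 is a
#'   straight rod, smaller values wiggle more.
#' @return A [dpd_state()].
#' @export
random_init <- function(composition, seed = 1, rs = 0.7, persistence = 0.7) {
  comp <- composition
  box <- comp$box
  set.seed(seed)
  build_chain <- function(nb) {
    p <- matrix(0, nb, 3)
    p[1, ] <- runif(3) * box
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    for (b in seq_len(nb - 1L)) {
      dir <- persistence * dir + (1 - persistence) * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      p[b + 1L, ] <- p[b, ] + rs * dir
    }
    p
  }
  nb1 <- length(comp$topology1$bead_species)
  nb2 <- length(comp$topology2$bead_species)
  pos_chains <- do.call(rbind, c(
    lapply(seq_len(comp$n1), function(i) build_chain(nb1)),
    lapply(seq_len(comp$n2), function(i) build_chain(nb2))))
  if (is.null(pos_chains)) pos_chains <- matrix(numeric(0), 0, 3)
  posw <- fill_water(comp$NW, box)
  dpd_state(rbind(pos_chains, posw),
            maxwell_velocities(comp$N), comp, time = 0)
}

#' Pre-assembled perforated-membrane fixture
#'
#' A layered bilayer with a solvent-filled cylindrical pore of the given
#' radius through the centre: no lipid is placed within the pore cylinder
#' (the displaced chains are redistributed over the remaining leaflet
#' area) and water additionally fills the pore. Used as a geometric test
#' bed for the pore analytics, not as an equilibrated structure.
#'
#' @inheritParams layered_bilayer_init
#' @param pore_radius Pore radius in rc; must be smaller than half the
#'   smallest lateral box edge.
#' @return A [dpd_state()].
#' @export
perforated_fixture <- function(composition, pore_radius, seed = 1,
                               rs = 0.7, jitter_frac = 0.2) {
  comp <- composition
  box <- comp$box
  if (pore_radius >= min(box[1], box[2]) / 2) {
    abort("pore_radius must be below half the lateral box size")
  }
  set.seed(seed)
  z_mid <- box[3] / 2
  gap <- rs / 2
  cx <- box[1] / 2; cy <- box[2] / 2
  outside_pore <- function(xy) {
    dx <- abs(xy[, 1] - cx); dx <- pmin(dx, box[1] - dx)
    dy <- abs(xy[, 2] - cy); dy <- pmin(dy, box[2] - dy)
    dx * dx + dy * dy >= pore_radius^2
  }
  sites_outside <- function(n) {
    if (n == 0) return(matrix(numeric(0), 0, 2))
    n_try <- n
    for (k in 1:8) {
      xy <- leaflet_sites(n_try, box[1], box[2], jitter_frac)
      xy <- xy[outside_pore(xy), , drop = FALSE]
      if (nrow(xy) >= n) {
        # evenly thin the surviving sites so the rim region stays covered
        return(xy[round(seq(1, nrow(xy), length.out = n)), ,
                  drop = FALSE])
      }
      n_try <- ceiling(n_try * 1.3)
    }
    abort("cannot place chains outside the pore: pore too large")
  }
  nb1 <- length(comp$topology1$bead_species)
  nb2 <- length(comp$topology2$bead_species)
  xy1 <- sites_outside(comp$n1)
  xy2 <- sites_outside(comp$n2)
  pos1 <- if (comp$n1 > 0) cbind(
    rep(xy1[, 1], each = nb1), rep(xy1[, 2], each = nb1),
    rep(chain_z(nb1, rs, z_mid, gap, upper = TRUE), comp$n1)) else
      matrix(numeric(0), 0, 3)
  pos2 <- if (comp$n2 > 0) cbind(
    rep(xy2[, 1], each = nb2), rep(xy2[, 2], each = nb2),
    rep(chain_z(nb2, rs, z_mid, gap, upper = FALSE), comp$n2)) else
      matrix(numeric(0), 0, 3)
  half <- gap + (max(nb1, nb2) - 1) * rs + 0.35
  exclude <- function(p) {
    abs(p[, 3] - z_mid) < half & outside_pore(p[, 1:2, drop = FALSE])
  }
  posw <- fill_water(comp$NW, box, exclude)
  dpd_state(rbind(pos1, pos2, posw),
            maxwell_velocities(comp$N), comp, time = 0)
}

# roughly even directions on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  cz <- 1 - 2 * i / n
  sz <- sqrt(pmax(0, 1 - cz^2))
  m <- cbind(sz * cos(phi), sz * sin(phi), cz)
  dimnames(m) <- NULL
  m
}

#' Pre-assembled vesicle fixture
#'
#' A closed spherical bilayer centred in the box: the outer leaflet has
#' heads outermost and tails pointing inwards to the mid-surface at
#' `radius`; the inner leaflet is mirrored with heads facing the enclosed
#' water cavity. Chains of both types are interleaved over each leaflet.
#'
#' @inheritParams layered_bilayer_init
#' @param radius Bilayer mid-surface radius in rc.
#' @return A [dpd_state()].
#' @export
vesicle_fixture <- function(composition, radius, seed = 1, rs = 0.7) {
  comp <- composition
  box <- comp$box
  nb1 <- length(comp$topology1$bead_species)
  nb2 <- length(comp$topology2$bead_species)
  nb_max <- max(nb1, nb2)
  gap <- rs / 2
  chain_ext <- gap + (nb_max - 1) * rs
  if (radius + chain_ext >= min(box) / 2) {
    abort("vesicle does not fit: radius + chain length must be < L/2")
  }
  if (radius - chain_ext <= 1) {
    abort("vesicle radius too small for the chain length")
  }
  set.seed(seed)
  centre <- box / 2
  r_out_head <- radius + chain_ext
  r_in_head <- radius - chain_ext
  # leaflet split proportional to leaflet area at the head surfaces
  frac_out <- r_out_head^2 / (r_out_head^2 + r_in_head^2)
  n_tot <- comp$n1 + comp$n2
  n_out <- round(n_tot * frac_out)
  # interleave the two types over the direction lattice so both leaflets
  # are mixed
  type_of_chain <- rep(c(1L, 2L), length.out = n_tot)
  type_of_chain <- type_of_chain[order(runif(n_tot))]
  # but respect the exact per-type counts
  type_of_chain <- c(rep(1L, comp$n1), rep(2L, comp$n2))[order(runif(n_tot))]
  dirs_out <- fibonacci_sphere(n_out)
  dirs_in <- fibonacci_sphere(n_tot - n_out)
  chain_radii <- function(nb, outer) {
    off <- gap + (nb - seq_len(nb)) * rs  # bead 1 = head end, outermost
    if (outer) radius + off else radius - off
  }
  # build positions per chain in composition order (type-I chains first);
  # assign each chain a leaflet + direction slot
  leaflet <- c(rep(TRUE, n_out), rep(FALSE, n_tot - n_out))
  slot_dir <- rbind(dirs_out, dirs_in)
  # chains of each type take slots in order of the shuffled type vector
  slot_of_type <- split(seq_len(n_tot), type_of_chain)
  pos_list <- vector("list", n_tot)
  for (tp in 1:2) {
    nb <- if (tp == 1) nb1 else nb2
    slots <- slot_of_type[[as.character(tp)]]
    for (k in seq_along(slots)) {
      s <- slots[k]
      rr <- chain_radii(nb, leaflet[s])
      p <- outer(rr, slot_dir[s, ]) +
        matrix(centre, nb, 3, byrow = TRUE)
      idx <- if (tp == 1) k else comp$n1 + k
      pos_list[[idx]] <- p
    }
  }
  pos_chains <- do.call(rbind, pos_list)
  exclude <- function(p) {
    d <- sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2 +
                (p[, 3] - centre[3])^2)
    d > r_in_head - 0.35 & d < r_out_head + 0.35
  }
  posw <- fill_water(comp$NW, box, exclude)
  dpd_state(rbind(pos_chains, posw),
            maxwell_velocities(comp$N), comp, time = 0)
}
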