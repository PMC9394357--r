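# Shared fixtures and independent oracles for the test suite.

# minimal state without molecular topology (unbonded beads)
bare_state <- function(positions, velocities = NULL, species = "W",
                       box = c(5, 5, 5), time = 0) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  sp <- match(rep_len(species, n), dpd_species())
  structure(list(positions = positions, velocities = rbind(velocities),
                 species = sp, molecule = rep(0L, n),
                 box = box, time = time, composition = NULL),
            class = "dpd_state")
}

# pure-water state at density 3 (uniform positions, Maxwell velocities)
water_state <- function(box, seed = 1) {
  comp <- system_composition(0, 0, nt1 = 1, nt2 = 1, box = box)
  random_init(comp, seed = seed)
}

# small two-lipid composition with one chain per rc^2 of leaflet area
small_membrane_comp <- function(nt1, nt2, box = c(8, 8, 16), nh = 3) {
  n <- round(box[1] * box[2])
  system_composition(n, n, nh1 = nh, nt1 = nt1, nh2 = nh, nt2 = nt2,
                     box = box)
}

# Independent all-pairs force oracle in plain R: conservative + dissipative
# (deterministic terms), minimum image, no cutoff tricks.
r_reference_forces <- function(state, interaction, gamma = NULL) {
  pos <- state$positions; vel <- state$velocities
  n <- nrow(pos); box <- state$box
  a <- interaction$a; rc <- interaction$rc
  g <- if (is.null(gamma)) interaction$gamma else gamma
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r >= rc || r < 1e-12) next
    e <- d / r
    w <- 1 - r / rc
    aij <- a[dpd_species()[state$species[i]], dpd_species()[state$species[j]]]
    fc <- aij * w
    fd <- -g * w^2 * sum(e * (vel[i, ] - vel[j, ]))
    ftot <- (fc + fd) * e
    f[i, ] <- f[i, ] + ftot
    f[j, ] <- f[j, ] - ftot
  }
  f
}

# total potential energy of a state in plain R (pair + bond + angle),
# used for finite-difference force checks
r_reference_energy <- function(positions, state, interaction, bonded) {
  pos <- rbind(positions); box <- state$box
  a <- interaction$a; rc <- interaction$rc
  n <- nrow(pos)
  mi <- function(d) d - box * round(d / box)
  e_pair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum(mi(pos[i, ] - pos[j, ])^2))
    if (r < rc) {
      aij <- a[dpd_species()[state$species[i]],
               dpd_species()[state$species[j]]]
      e_pair <- e_pair + aij * rc / 2 * (1 - r / rc)^2
    }
  }
  comp <- state$composition
  e_bond <- 0; e_angle <- 0
  if (!is.null(comp)) {
    bonds <- dpdmix:::composition_bonds(comp)
    for (b in seq_len(nrow(bonds))) {
      r <- sqrt(sum(mi(pos[bonds[b, 1], ] - pos[bonds[b, 2], ])^2))
      e_bond <- e_bond + bonded$ks * bonded$rs / 2 * (1 - r / bonded$rs)^2
    }
    angles <- dpdmix:::composition_angles(comp)
    for (t in seq_len(nrow(angles))) {
      u <- mi(pos[angles[t, 1], ] - pos[angles[t, 2], ])
      w <- mi(pos[angles[t, 3], ] - pos[angles[t, 2], ])
      ct <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
      th <- acos(max(-1, min(1, ct)))
      e_angle <- e_angle + bonded$k_theta * (th - bonded$theta0)^2
    }
  }
  e_pair + e_bond + e_angle
}

# double-loop gyration-tensor oracle:
# Rg2_ab = (1/2N^2) sum_ij (ri_a - rj_a)(ri_b - rj_b)
r_reference_gyration <- function(p) {
  n <- nrow(p)
  g <- matrix(0, 3, 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- p[i, ] - p[j, ]
    g <- g + outer(d, d)
  }
  g / (2 * n^2)
}

# interaction model without conservative repulsion (ideal DPD gas)
ideal_gas_interaction <- function() {
  interaction_model(matrix(0, 5, 5), gamma = 4.5, sigma = 3.0)
}
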