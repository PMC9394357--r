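# Species, molecule topologies, composition bookkeeping, interaction matrix
# and the Flory-Huggins mapping.

#' Bead species of the two-lipid DPD model
#'
#' Five coarse-grained species: hydrophilic heads `H1`/`H2` and hydrophobic
#' tails `T1`/`T2` of the type-I and type-II lipids, plus water `W`. The
#' order defines the integer species codes used throughout the package.
#'
#' @return Character vector of the five species labels.
#' @export
#' @examples
#' dpd_species()
dpd_species <- function() {
  c("H1", "T1", "W", "H2", "T2")
}

species_code <- function(label) {
  m <- match(label, dpd_species())
  if (anyNA(m)) abort(paste0("unknown bead species: ",
                             paste(label[is.na(m)], collapse = ", ")))
  m
}

#' Build the linear topology of a single lipid chain
#'
#' A lipid is a linear chain of `n_head` hydrophilic head beads followed by
#' `n_tail` hydrophobic tail beads. Consecutive beads are bonded; every
#' consecutive triple (including the triple spanning the head-tail junction)
#' carries an angle term, so a chain of `n` beads has `n - 1` bonds and
#' `n - 2` angles.
#'
#' @param lipid_type `"type-I"` or `"type-II"` (controls the head/tail
#'   species labels `H1`/`T1` vs `H2`/`T2`).
#' @param n_head Number of head beads (>= 1).
#' @param n_tail Number of tail beads (>= 1).
#' @return A `lipid_topology` object: list with `lipid_type`, `n_head`,
#'   `n_tail`, `bead_species` (ordered labels, heads first), `bonds`
#'   (two-column index matrix) and `angles` (three-column index matrix).
#' @export
#' @examples
#' top <- build_topology("type-I", 3, 9)
#' length(top$bead_species)  # 12
#' nrow(top$bonds)           # 11
#' nrow(top$angles)          # 10
build_topology <- function(lipid_type = c("type-I", "type-II"),
                           n_head, n_tail) {
  lipid_type <- match.arg(lipid_type)
  if (length(n_head) != 1L || length(n_tail) != 1L ||
      !is.finite(n_head) || !is.finite(n_tail) ||
      n_head < 1 || n_tail < 1 ||
      n_head != round(n_head) || n_tail != round(n_tail)) {
    abort("n_head and n_tail must be positive integers")
  }
  n_head <- as.integer(n_head); n_tail <- as.integer(n_tail)
  nb <- n_head + n_tail
  sp <- if (lipid_type == "type-I") {
    c(rep("H1", n_head), rep("T1", n_tail))
  } else {
    c(rep("H2", n_head), rep("T2", n_tail))
  }
  bonds <- if (nb >= 2) cbind(seq_len(nb - 1), seq_len(nb - 1) + 1L) else
    matrix(integer(0), 0, 2)
  angles <- if (nb >= 3) cbind(seq_len(nb - 2), seq_len(nb - 2) + 1L,
                               seq_len(nb - 2) + 2L) else
    matrix(integer(0), 0, 3)
  structure(list(lipid_type = lipid_type, n_head = n_head, n_tail = n_tail,
                 bead_species = sp, bonds = bonds, angles = angles),
            class = "lipid_topology")
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat("<lipid_topology> ", x$lipid_type, ": ", x$n_head, " head + ",
      x$n_tail, " tail beads, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles\n", sep = "")
  invisible(x)
}

#' Number of beads in a set of identical lipid chains
#'
#' @param n Chain count.
#' @param n_head,n_tail Head and tail bead counts per chain.
#' @return `n * (n_head + n_tail)`.
#' @export
#' @examples
#' lipid_bead_count(900, 3, 2)  # 4500
lipid_bead_count <- function(n, n_head, n_tail) {
  stopifnot(all(n >= 0), all(n_head >= 0), all(n_tail >= 0))
  n * (n_head + n_tail)
}

#' Water beads needed to close a composition at fixed total bead number
#'
#' The total bead number satisfies
#' `N = n1 (NH1 + NT1) + n2 (NH2 + NT2) + NW`, so the water bead count is
#' whatever remains after the lipid beads are accounted for.
#'
#' @param n_total Total bead number `N`.
#' @param n1,n2 Chain counts of the two lipid types.
#' @param nh1,nt1,nh2,nt2 Head/tail bead numbers per chain for each type.
#' @return Water bead count `NW`.
#' @export
#' @examples
#' water_bead_count(81000, 900, 900, 3, 2, 3, 2)  # 72000
water_bead_count <- function(n_total, n1, n2, nh1, nt1, nh2, nt2) {
  nw <- n_total - lipid_bead_count(n1, nh1, nt1) -
    lipid_bead_count(n2, nh2, nt2)
  if (any(nw < 0)) {
    abort("composition infeasible: lipid beads exceed the total bead number")
  }
  nw
}

#' Flory-Huggins parameter from DPD repulsion parameters
#'
#' The linear mapping `chi = 0.286 (a_ij - a_ii)` relating the excess
#' repulsion between unlike beads to the Flory-Huggins segregation
#' parameter at bead density 3.
#'
#' @param a_ij Repulsion between unlike beads (kBT/rc).
#' @param a_ii Repulsion between like beads (kBT/rc).
#' @return Dimensionless `chi`.
#' @export
#' @examples
#' flory_chi(100, 25)  # 21.45: strong segregation
flory_chi <- function(a_ij, a_ii) {
  0.286 * (a_ij - a_ii)
}

#' DPD interaction model (repulsion matrix + thermostat parameters)
#'
#' Bundles the symmetric bead-bead maximum-repulsion matrix `a` with the
#' thermostat pair (`gamma`, `sigma`), cutoff `rc` and thermal energy `kBT`.
#' The dissipative and random amplitudes are tied by the
#' fluctuation-dissipation relation `sigma^2 = 2 gamma kBT`; a model that
#' violates it will not thermostat to `kBT` and triggers a warning.
#'
#' @param a Symmetric numeric matrix (species x species), dimnames in
#'   [dpd_species()] order.
#' @param gamma Dissipative (friction) coefficient.
#' @param sigma Random-force amplitude.
#' @param rc Cutoff length (the unit of length).
#' @param kBT Thermal energy (the unit of energy).
#' @return An `interaction_model` object.
#' @seealso [default_interaction_matrix()]
#' @export
interaction_model <- function(a, gamma = 4.5, sigma = 3.0, rc = 1, kBT = 1) {
  a <- as.matrix(a)
  if (nrow(a) != length(dpd_species()) || ncol(a) != nrow(a)) {
    abort("a must be a square matrix over the five bead species")
  }
  if (!isTRUE(all.equal(a, t(a)))) abort("repulsion matrix must be symmetric")
  if (abs(sigma^2 - 2 * gamma * kBT) > 1e-8) {
    warn("sigma^2 != 2 gamma kBT: the thermostat will not equilibrate to kBT")
  }
  dimnames(a) <- list(dpd_species(), dpd_species())
  structure(list(a = a, gamma = gamma, sigma = sigma, rc = rc, kBT = kBT),
            class = "interaction_model")
}

#' Default repulsion matrix of the two-lipid model
#'
#' Like beads repel with `a = 25 kBT/rc`; unlike beads with `a = 100`,
#' except that heads are hydrophilic (`a(H, W) = 25`) and the two head
#' species are compatible (`a(H1, H2) = 25`). With the `chi` mapping this
#' puts unlike pairs at `chi ~ 21.45`, deep in the strongly segregated
#' regime, which is what drives tail aggregation into bilayers.
#'
#' @param a_like Repulsion between compatible beads (default 25).
#' @param a_unlike Repulsion between incompatible beads (default 100).
#' @param gamma,sigma,rc,kBT Passed to [interaction_model()].
#' @return An `interaction_model` object.
#' @export
#' @examples
#' im <- default_interaction_matrix()
#' im$a["H1", "W"]   # 25: heads are hydrophilic
#' im$a["T2", "W"]   # 100: tails are hydrophobic
default_interaction_matrix <- function(a_like = 25, a_unlike = 100,
                                       gamma = 4.5, sigma = 3.0,
                                       rc = 1, kBT = 1) {
  sp <- dpd_species()
  a <- matrix(a_unlike, 5, 5, dimnames = list(sp, sp))
  diag(a) <- a_like
  compatible <- rbind(c("H1", "W"), c("H2", "W"), c("H1", "H2"))
  for (k in seq_len(nrow(compatible))) {
    a[compatible[k, 1], compatible[k, 2]] <- a_like
    a[compatible[k, 2], compatible[k, 1]] <- a_like
  }
  interaction_model(a, gamma = gamma, sigma = sigma, rc = rc, kBT = kBT)
}

#' Bonded interaction parameters
#'
#' Harmonic bond `F = ks (1 - r/rs) rhat` between consecutive beads and
#' harmonic angle potential `U = k_theta (theta - theta0)^2` on consecutive
#' triples. The defaults (`ks = 120`, `rs = 0.7 rc`, `k_theta = 6`,
#' `theta0 = pi`) give semi-flexible, locally straight chains.
#'
#' @param ks Bond spring constant (> 0).
#' @param rs Equilibrium bond length in rc (0 < rs).
#' @param k_theta Bending constant.
#' @param theta0 Equilibrium angle in radians, in (0, pi].
#' @return A `bonded_params` object.
#' @export
bonded_params <- function(ks = 120, rs = 0.7, k_theta = 6.0, theta0 = pi) {
  stopifnot(ks > 0, rs > 0, theta0 > 0, theta0 <= pi + 1e-12)
  structure(list(ks = ks, rs = rs, k_theta = k_theta, theta0 = theta0),
            class = "bonded_params")
}

#' System composition: chain counts, water fill, box and density
#'
#' Bookkeeping for a two-lipid + water system in a periodic box. The total
#' bead number is fixed by the target density (`N = round(density * V)`),
#' and the water count closes the composition:
#' `N = n1 (NH1 + NT1) + n2 (NH2 + NT2) + NW`.
#'
#' @param n1,n2 Chain counts for type-I and type-II lipids.
#' @param topology1,topology2 [build_topology()] objects for the two types;
#'   alternatively pass `nh1`/`nt1`/`nh2`/`nt2`.
#' @param nh1,nt1,nh2,nt2 Head/tail bead numbers (used when topologies are
#'   not supplied; heads default to 3).
#' @param box Box edge lengths, length-3 numeric, in rc.
#' @param density Bead number density in beads/rc^3 (default 3).
#' @return A `system_composition` object with fields `n1`, `n2`,
#'   `topology1`, `topology2`, `NW`, `N`, `box`, `density`.
#' @export
#' @examples
#' comp <- system_composition(900, 900, nt1 = 2, nt2 = 2,
#'                            box = c(30, 30, 30))
#' comp$NW  # 72000
system_composition <- function(n1, n2, topology1 = NULL, topology2 = NULL,
                               nh1 = 3, nt1 = NULL, nh2 = 3, nt2 = NULL,
                               box = c(30, 30, 30), density = 3) {
  if (is.null(topology1)) {
    if (is.null(nt1)) abort("supply topology1 or nt1")
    topology1 <- build_topology("type-I", nh1, nt1)
  }
  if (is.null(topology2)) {
    if (is.null(nt2)) abort("supply topology2 or nt2")
    topology2 <- build_topology("type-II", nh2, nt2)
  }
  stopifnot(length(box) == 3, all(box > 0), density > 0,
            n1 >= 0, n2 >= 0)
  n_total <- as.integer(round(density * prod(box)))
  nw <- water_bead_count(n_total, n1, n2,
                         topology1$n_head, topology1$n_tail,
                         topology2$n_head, topology2$n_tail)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 topology1 = topology1, topology2 = topology2,
                 NW = as.integer(nw), N = n_total,
                 box = as.numeric(box), density = density),
            class = "system_composition")
}

#' @export
print.system_composition <- function(x, ...) {
  cat("<system_composition>\n",
      "  box      ", paste(x$box, collapse = " x "), " rc, density ",
      x$density, " (N = ", x$N, ")\n",
      "  type-I   ", x$n1, " chains of ", x$topology1$n_head, "H + ",
      x$topology1$n_tail, "T\n",
      "  type-II  ", x$n2, " chains of ", x$topology2$n_head, "H + ",
      x$topology2$n_tail, "T\n",
      "  water    ", x$NW, " beads\n", sep = "")
  invisible(x)
}

# Per-bead metadata implied by the canonical bead ordering: all type-I
# chains (chain-major, heads first within each chain), then all type-II
# chains, then water.
composition_species <- function(comp) {
  c(rep(species_code(comp$topology1$bead_species), comp$n1),
    rep(species_code(comp$topology2$bead_species), comp$n2),
    rep(species_code("W"), comp$NW))
}

composition_molecule <- function(comp) {
  nb1 <- length(comp$topology1$bead_species)
  nb2 <- length(comp$topology2$bead_species)
  c(rep(seq_len(comp$n1), each = nb1),
    if (comp$n2 > 0) rep(comp$n1 + seq_len(comp$n2), each = nb2),
    rep(0L, comp$NW))
}

# Global (1-based) bond and angle index matrices for the whole system.
composition_bonds <- function(comp) {
  one_type <- function(top, n, offset0) {
    nb <- length(top$bead_species)
    if (n == 0 || nrow(top$bonds) == 0) return(matrix(integer(0), 0, 2))
    offs <- offset0 + (seq_len(n) - 1L) * nb
    do.call(rbind, lapply(offs, function(o) top$bonds + o))
  }
  nb1 <- length(comp$topology1$bead_species)
  rbind(one_type(comp$topology1, comp$n1, 0L),
        one_type(comp$topology2, comp$n2, comp$n1 * nb1))
}

composition_angles <- function(comp) {
  one_type <- function(top, n, offset0) {
    nb <- length(top$bead_species)
    if (n == 0 || nrow(top$angles) == 0) return(matrix(integer(0), 0, 3))
    offs <- offset0 + (seq_len(n) - 1L) * nb
    do.call(rbind, lapply(offs, function(o) top$angles + o))
  }
  nb1 <- length(comp$topology1$bead_species)
  rbind(one_type(comp$topology1, comp$n1, 0L),
        one_type(comp$topology2, comp$n2, comp$n1 * nb1))
}

# chain_id -> bead index range, lipid type, head/tail mask
composition_chain_table <- function(comp) {
  nb1 <- length(comp$topology1$bead_species)
  nb2 <- length(comp$topology2$bead_species)
  n_chain <- comp$n1 + comp$n2
  first <- integer(n_chain); len <- integer(n_chain)
  if (comp$n1 > 0) {
    first[seq_len(comp$n1)] <- (seq_len(comp$n1) - 1L) * nb1 + 1L
    len[seq_len(comp$n1)] <- nb1
  }
  if (comp$n2 > 0) {
    idx <- comp$n1 + seq_len(comp$n2)
    first[idx] <- comp$n1 * nb1 + (seq_len(comp$n2) - 1L) * nb2 + 1L
    len[idx] <- nb2
  }
  tibble(chain_id = seq_len(n_chain),
         lipid_type = rep(c("type-I", "type-II"), c(comp$n1, comp$n2)),
         first_bead = first, n_beads = len,
         n_head = rep(c(comp$topology1$n_head, comp$topology2$n_head),
                      c(comp$n1, comp$n2)))
}
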