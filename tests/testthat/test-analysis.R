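test_that("axial density profiles conserve bead counts and shapes", {
  st <- water_state(c(6, 6, 12), seed = 1)
  prof <- density_profile(st, bin_width = 0.5)
  # exact conservation per species
  tot <- prof |> dplyr::group_by(species) |>
    dplyr::summarise(n = sum(density * bin_volume), .groups = "drop")
  expect_equal(tot$n[tot$species == "W"], st$composition$NW)
  # uniform box: flat within Poisson noise (5 sigma on per-bin counts)
  w <- prof[prof$species == "W", ]
  per_bin <- w$density * w$bin_volume
  expect_lt(max(abs(per_bin - mean(per_bin))), 5 * sqrt(mean(per_bin)))

  # layered start: two head peaks flanking the tail core
  comp <- small_membrane_comp(4, 4, box = c(8, 8, 16))
  stm <- layered_bilayer_init(comp, seed = 2)
  hp <- density_profile(stm, species = c("H1", "H2"))
  heads <- hp |> dplyr::group_by(coord) |>
    dplyr::summarise(density = sum(density), .groups = "drop")
  pk <- dpdmix:::profile_peaks(heads$density, max(heads$density) / 2)
  expect_gte(length(pk), 2)
  tp <- density_profile(stm, species = c("T1", "T2")) |>
    dplyr::group_by(coord) |>
    dplyr::summarise(density = sum(density), .groups = "drop")
  # tail core lies between the two outer head peaks
  expect_true(heads$coord[pk[1]] < tp$coord[which.max(tp$density)])
  expect_true(heads$coord[pk[length(pk)]] > tp$coord[which.max(tp$density)])
})

test_that("radial profiles use exact shell volumes", {
  st <- water_state(c(8, 8, 8), seed = 3)
  prof <- radial_density_profile(st, bin_width = 0.4)
  # shell volumes sum to the probed sphere volume
  v <- unique(prof[, c("bin", "bin_volume")])
  expect_equal(sum(v$bin_volume), 4 / 3 * pi * 4^3, tolerance = 1e-10)
  # uniform fluid: flat at density 3 (loose, shells near 0 are tiny)
  w <- prof[prof$species == "W" & prof$r > 1.5, ]
  expect_equal(mean(w$density), 3, tolerance = 0.1)
  expect_error(radial_density_profile(st, center = c(20, 0, 0)), "inside")
})

test_that("P2 order parameter hits its analytic limits", {
  expect_equal(p2_orientation(c(0, 0, 5)), 1)
  expect_equal(p2_orientation(c(0.3, -0.4, 0)), -0.5)
  expect_equal(p2_orientation(rbind(c(1, 0, 1)), axis = c(1, 0, 1)), 1)
  # isotropic Monte-Carlo oracle: mean -> 0
  set.seed(11)
  v <- matrix(rnorm(3 * 20000), ncol = 3)
  p2 <- p2_orientation(v)
  expect_lt(abs(mean(p2)), 3 * sd(p2) / sqrt(length(p2)))
  # zero-length vectors are flagged, not silently dropped
  expect_true(is.na(p2_orientation(c(0, 0, 0))))
})

test_that("order-parameter profile of a layered start is near 1 and skips
           degenerate chains", {
  comp <- small_membrane_comp(4, 4, box = c(8, 8, 16))
  st <- layered_bilayer_init(comp, seed = 4)
  prof <- order_parameter(st, sub_chain = "head")
  got <- prof[!is.na(prof$p2) & prof$n_chains > 0, ]
  # straight vertical chains: every populated bin has P2 = 1
  expect_equal(got$p2, rep(1, nrow(got)), tolerance = 1e-10)
  expect_equal(sum(prof$n_chains), comp$n1 + comp$n2)
  expect_equal(prof$n_skipped[1], 0)
  # whole-chain and tail variants agree for straight chains
  expect_equal(max(order_parameter(st, "whole")$p2, na.rm = TRUE), 1,
               tolerance = 1e-10)
})

test_that("gyration tensor matches the double-loop oracle and shape limits", {
  # two beads at +-d/2 on x: Rgxx2 = d^2/4, everything else 0
  g <- gyration_tensor(rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))
  expect_equal(g$tensor, diag(c(0.25, 0, 0)), tolerance = 1e-12)
  expect_equal(g$eigenvalues, c(0.25, 0, 0))
  # single bead: zero tensor, undefined shape
  g1 <- gyration_tensor(c(1, 2, 3))
  expect_equal(g1$rg2, 0)
  expect_true(is.na(shape_factor(g1$eigenvalues)))
  # random chains against the independent pairwise-sum oracle
  set.seed(13)
  for (k in 1:5) {
    p <- matrix(rnorm(3 * sample(3:20, 1)), ncol = 3)
    g <- gyration_tensor(p)
    expect_equal(g$tensor, r_reference_gyration(p), tolerance = 1e-10)
    expect_equal(g$rg2, sum(diag(r_reference_gyration(p))))
    # shape factor bounds
    d <- shape_factor(g$eigenvalues)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  # quoted limits and the hand-evaluated case
  expect_equal(shape_factor(c(1, 0, 0)), 1)
  expect_equal(shape_factor(c(2, 2, 2)), 0)
  expect_equal(shape_factor(c(2, 1, 1)), 1 / 16)
})

test_that("chain unwrapping reconnects chains across the boundaries", {
  comp <- small_membrane_comp(3, 3, box = c(6, 6, 12))
  st <- layered_bilayer_init(comp, seed = 5)
  # shift everything so many chains straddle the z boundary
  st2 <- st
  st2$positions[, 3] <- (st2$positions[, 3] + 6) %% 12
  pos <- unwrap_chains(st2)
  bonds <- dpdmix:::composition_bonds(comp)
  blen <- sqrt(rowSums((pos[bonds[, 1], ] - pos[bonds[, 2], ])^2))
  expect_equal(blen, rep(0.7, length(blen)), tolerance = 1e-9)
  # gyration is invariant under the shift once unwrapped
  expect_equal(gyration_chains(st2)$rg2, gyration_chains(st)$rg2,
               tolerance = 1e-9)
})

test_that("leaflet counts respond to flips and mirror symmetry", {
  comp <- small_membrane_comp(3, 3, box = c(8, 8, 16))
  st <- layered_bilayer_init(comp, seed = 6)
  n <- comp$n1
  # flip 10 type-I chains through the midplane: they join the lower leaflet
  ct <- dpdmix:::composition_chain_table(comp)
  flip <- ct$first_bead[1:10]
  for (fb in flip) {
    idx <- fb + seq_len(ct$n_beads[1]) - 1L
    st$positions[idx, 3] <- 16 - st$positions[idx, 3]
  }
  mix <- leaflet_mixing_counts(st)
  expect_equal(mix$upper[mix$lipid_type == "type-I"], n - 10)
  expect_equal(mix$lower[mix$lipid_type == "type-I"], 10)
  expect_equal(mix$lower[mix$lipid_type == "type-II"], n)
  # mirror-flip of the whole box swaps the leaflet labels
  stm <- st
  stm$positions[, 3] <- 16 - stm$positions[, 3]
  mixm <- leaflet_mixing_counts(stm)
  expect_equal(mixm$upper, mix$lower)
  expect_equal(mixm$lower, mix$upper)
  # counts are invariant to chain ordering by construction of the table
  expect_equal(sum(mix$upper + mix$lower + mix$unassigned), 2 * n)
})

test_that("membrane thickness matches a closed-form two-Gaussian oracle", {
  # analytic profile: unit-height Gaussians (sigma = 1) centred 10 rc apart
  z1 <- 10; z2 <- 20
  f <- function(z) exp(-(z - z1)^2 / 2) + exp(-(z - z2)^2 / 2)
  # independent oracle: root-find the outer half-maximum crossings
  ymax <- max(f(seq(5, 25, by = 1e-4)))
  left <- uniroot(function(z) f(z) - ymax / 2, c(0, z1))$root
  right <- uniroot(function(z) f(z) - ymax / 2, c(z2, 30))$root
  oracle <- right - left
  z <- seq(0.05, 29.95, by = 0.1)
  got <- membrane_thickness(tibble::tibble(coord = z, density = f(z)))
  expect_equal(as.numeric(got), oracle, tolerance = 0.01)
  # symmetric under z-reflection
  got_rev <- membrane_thickness(tibble::tibble(coord = z,
                                               density = rev(f(z))))
  expect_equal(as.numeric(got_rev), as.numeric(got), tolerance = 1e-6)
  # single peak: undefined
  expect_true(is.na(membrane_thickness(
    tibble::tibble(coord = z, density = exp(-(z - 15)^2 / 2)))))
})

test_that("classifier separates membrane, perforated membrane and vesicle", {
  comp <- small_membrane_comp(3, 3, box = c(8, 8, 16))
  st <- layered_bilayer_init(comp, seed = 7)
  expect_equal(classify_structure(st), "membrane")
  expect_false(pore_detect(st)$has_pore)

  pcomp <- system_composition(900, 900, nt1 = 2, nt2 = 2,
                              box = c(30, 30, 10))
  stp <- perforated_fixture(pcomp, pore_radius = 8, seed = 2)
  expect_equal(classify_structure(stp), "perforated_membrane")
  # deterministic given the frame
  expect_equal(pore_detect(stp)$diameter, pore_detect(stp)$diameter)

  vcomp <- system_composition(150, 150, nh1 = 2, nt1 = 2, nh2 = 2,
                              nt2 = 2, box = c(17, 17, 17))
  stv <- vesicle_fixture(vcomp, radius = 5, seed = 8)
  expect_equal(classify_structure(stv), "vesicle")
  expect_error(leaflet_mixing_counts(stv, check_topology = TRUE), "radial")

  # dilute dispersion: no aggregate at all
  dcomp <- system_composition(4, 4, nt1 = 2, nt2 = 2, box = c(8, 8, 8))
  expect_equal(classify_structure(random_init(dcomp, seed = 1)), "other")
})

test_that("stage segmentation recovers synthetic change points", {
  set.seed(17)
  y <- c(rnorm(100, 6.12, 0.005), rnorm(150, 6.08, 0.005),
         rnorm(200, 6.05, 0.005))
  seg <- stage_segmentation(y, smooth_window = 9)
  expect_false(seg$degenerate)
  expect_lt(abs(seg$idx_initial_end - 100), 10)
  expect_lt(abs(seg$idx_adjust_end - 250), 10)
  expect_equal(seg$stages$mean, c(6.12, 6.08, 6.05), tolerance = 0.01)
  # stage means of a decaying series are non-increasing
  expect_true(all(diff(seg$stages$mean) <= 0))
  # time stamps are honoured
  seg_t <- stage_segmentation(y, time = seq_along(y) * 2,
                              smooth_window = 9)
  expect_equal(seg_t$t_initial_end, seg$idx_initial_end * 2)
  # flat series: flagged degenerate, split at thirds
  flat <- stage_segmentation(rep(5, 60))
  expect_true(flat$degenerate)
  expect_equal(flat$idx_initial_end, 20)
})
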