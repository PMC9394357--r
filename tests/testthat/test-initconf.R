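test_that("layered builder starts completely unmixed at the target density", {
  comp <- small_membrane_comp(3, 3, box = c(8, 8, 16))
  st <- layered_bilayer_init(comp, seed = 3)
  expect_equal(nrow(st$positions), comp$N)
  # species histogram exact
  counts <- table(factor(dpd_species()[st$species], levels = dpd_species()))
  expect_equal(unname(counts[["W"]]), comp$NW)
  # global density is the composition's contract
  expect_equal(comp$N / prod(st$box), 3, tolerance = 1e-3)
  # zero total momentum by construction
  expect_equal(colSums(st$velocities), c(0, 0, 0), tolerance = 1e-10)
  # all type-I in the upper leaflet, all type-II in the lower
  mix <- leaflet_mixing_counts(st)
  expect_equal(mix$upper[mix$lipid_type == "type-I"], comp$n1)
  expect_equal(mix$lower[mix$lipid_type == "type-II"], comp$n2)
  expect_equal(sum(mix$unassigned), 0)
  # coordinates wrapped
  expect_true(all(st$positions >= 0))
  expect_true(all(sweep(st$positions, 2, st$box, "/") < 1))
  # reproducible under seed, different under another seed
  expect_identical(st$positions,
                   layered_bilayer_init(comp, seed = 3)$positions)
  expect_false(identical(st$positions,
                         layered_bilayer_init(comp, seed = 4)$positions))
  # infeasible chain density is rejected
  tiny <- system_composition(200, 200, nt1 = 2, nt2 = 2, box = c(4, 4, 45))
  expect_error(layered_bilayer_init(tiny), "insufficient")
})

test_that("random builder places intact chains with bounded bonds", {
  comp <- small_membrane_comp(4, 2, box = c(6, 6, 8))
  st <- random_init(comp, seed = 5)
  counts <- table(factor(dpd_species()[st$species], levels = dpd_species()))
  expect_equal(unname(counts[["H1"]]), comp$n1 * 3)
  expect_equal(unname(counts[["T1"]]), comp$n1 * 4)
  expect_equal(unname(counts[["T2"]]), comp$n2 * 2)
  # no bond stretched beyond 2 rs at t = 0
  pos <- unwrap_chains(st)
  bonds <- dpdmix:::composition_bonds(comp)
  blen <- sqrt(rowSums((pos[bonds[, 1], ] - pos[bonds[, 2], ])^2))
  expect_lt(max(blen), 2 * 0.7)
  # seeds change positions, not counts
  st2 <- random_init(comp, seed = 6)
  expect_false(identical(st$positions, st2$positions))
  expect_identical(st$species, st2$species)
})

test_that("perforated fixture carves a cylindrical hole of the right area", {
  comp <- system_composition(900, 900, nt1 = 2, nt2 = 2,
                             box = c(30, 30, 10))
  st <- perforated_fixture(comp, pore_radius = 8, seed = 2)
  # no tail bead inside the pore cylinder
  cx <- 15; cy <- 15
  tails <- st$species %in% dpdmix:::species_code(c("T1", "T2"))
  dx <- abs(st$positions[tails, 1] - cx); dx <- pmin(dx, 30 - dx)
  dy <- abs(st$positions[tails, 2] - cy); dy <- pmin(dy, 30 - dy)
  # sites are filtered after jitter, so no tail can sit inside the radius
  expect_gte(min(sqrt(dx^2 + dy^2)), 8 - 1e-9)
  # detected pore area matches pi r^2 within grid error
  # rim cells are ambiguous at one-cell resolution: allow a one-cell band
  pore <- pore_detect(st, grid_spacing = 1)
  expect_true(pore$has_pore)
  expect_gt(pore$area, pi * 7^2)
  expect_lt(pore$area, pi * 9^2)
  expect_equal(pore$diameter, 16, tolerance = 1 / 16)
  # degenerate radius: intact membrane
  st0 <- perforated_fixture(comp, pore_radius = 0.01, seed = 2)
  expect_equal(classify_structure(st0), "membrane")
  expect_error(perforated_fixture(comp, pore_radius = 15.5), "half")
})

test_that("vesicle fixture is a closed shell with two radial head peaks", {
  comp <- system_composition(150, 150, nh1 = 2, nt1 = 2, nh2 = 2, nt2 = 2,
                             box = c(17, 17, 17))
  st <- vesicle_fixture(comp, radius = 5, seed = 8)
  prof <- radial_density_profile(st, species = c("H1", "H2"),
                                 bin_width = 0.4)
  heads <- prof |> dplyr::group_by(bin, r) |>
    dplyr::summarise(density = sum(density), .groups = "drop")
  pk <- dpdmix:::profile_peaks(heads$density, max(heads$density) / 2)
  expect_gte(length(pk), 2)
  # centre of mass of the lipid shell sits at the box centre
  lip <- st$species != dpdmix:::species_code("W")
  expect_equal(colMeans(st$positions[lip, , drop = FALSE]),
               st$box / 2, tolerance = 0.3)
  expect_equal(classify_structure(st), "vesicle")
  expect_error(vesicle_fixture(comp, radius = 12), "fit")
})
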