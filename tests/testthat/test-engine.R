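test_that("pair weight and conservative force follow the soft repulsion", {
  im <- default_interaction_matrix()
  # two water beads at distance 0.3: |F| = 25 * (1 - 0.3) on each, opposite
  st <- bare_state(rbind(c(1, 1, 1), c(1.3, 1, 1)), box = c(5, 5, 5))
  f <- dpd_forces(st, im, include = "conservative")$forces
  expect_equal(f[1, ], c(-25 * 0.7, 0, 0))
  expect_equal(f[2, ], c(25 * 0.7, 0, 0))
  # T1-W pair at r = 0.5: magnitude 100 * 0.5; at r = 0.3: 70
  st2 <- bare_state(rbind(c(1, 1, 1), c(1, 1, 1.5)), species = c("T1", "W"))
  f2 <- dpd_forces(st2, im, include = "conservative")$forces
  expect_equal(f2[2, 3], 50)
  st3 <- bare_state(rbind(c(1, 1, 1), c(1, 1, 1.3)), species = c("T1", "W"))
  expect_equal(dpd_forces(st3, im,
                          include = "conservative")$forces[2, 3], 70)
  # outside the cutoff: zero force, zero energy
  st4 <- bare_state(rbind(c(1, 1, 1), c(1, 1, 2.2)))
  f4 <- dpd_forces(st4, im, include = "conservative")
  expect_equal(f4$forces, matrix(0, 2, 3))
  expect_equal(f4$pair_energy, 0)
  # pair energy at contact: a/2 per overlapping pair
  st5 <- bare_state(rbind(c(1, 1, 1), c(1, 1, 1 + 1e-13)))
  expect_equal(dpd_forces(st5, im,
                          include = "conservative")$pair_energy, 12.5)
})

test_that("dissipative force damps the radial relative velocity only", {
  im <- default_interaction_matrix()
  # relative velocity perpendicular to the separation: no dissipative force
  st <- bare_state(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                   velocities = rbind(c(0, 1, 0), c(0, -1, 0)))
  f <- dpd_forces(st, im, include = "dissipative")$forces
  expect_equal(f, matrix(0, 2, 3))
  # head-on approach at w = 1/2: |F| = gamma w^2 (e . v12)
  st2 <- bare_state(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                    velocities = rbind(c(1, 0, 0), c(-1, 0, 0)))
  f2 <- dpd_forces(st2, im, include = "dissipative")$forces
  expect_equal(f2[1, 1], -4.5 * 0.25 * 2)
  expect_equal(f2[2, 1], 4.5 * 0.25 * 2)
  # beads at rest: nothing to damp
  st3 <- bare_state(rbind(c(1, 1, 1), c(1.5, 1, 1)))
  expect_equal(dpd_forces(st3, im, include = "dissipative")$forces,
               matrix(0, 2, 3))
})

test_that("random force is pairwise antisymmetric with variance sigma^2 w^2 / dt", {
  im <- default_interaction_matrix()
  st <- bare_state(rbind(c(1, 1, 1), c(1.5, 1, 1)))
  draws <- vapply(1:4000, function(s) {
    f <- dpd_forces(st, im, include = "random", dt = 0.01,
                    seed = s)$forces
    expect_equal(f[1, ], -f[2, ])
    f[1, 1]
  }, numeric(1))
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
  # along the pair axis: variance sigma^2 w^2 / dt = 9 * 0.25 / 0.01
  expect_equal(var(draws), 9 * 0.25 / 0.01, tolerance = 0.1)
})

test_that("bond force is harmonic about rs with the documented sign", {
  bp <- bonded_params()
  comp <- system_composition(1, 0, nh1 = 1, nt1 = 1, nt2 = 1,
                             box = c(4, 4, 4))
  place <- function(r) {
    pos <- rbind(c(0.5, 0.5, 0.5), c(0.5 + r, 0.5, 0.5))
    dpd_state(rbind(pos, matrix(runif(3 * comp$NW, 0.1, 3.9),
                                comp$NW, 3)),
              matrix(0, comp$N, 3), comp)
  }
  im0 <- suppressWarnings(interaction_model(matrix(0, 5, 5), gamma = 0,
                                            sigma = 0))
  f_at <- function(r) {
    dpd_forces(place(r), im0, bp, include = "conservative")$forces[1:2, ]
  }
  expect_equal(f_at(0.7), matrix(0, 2, 3))       # equilibrium
  f_half <- f_at(0.35)                           # compressed: repulsive
  expect_equal(f_half[1, 1], -60)
  expect_equal(f_half[2, 1], 60)
  f_double <- f_at(1.4)                          # stretched: attractive
  expect_equal(f_double[1, 1], 120)
  expect_equal(f_double[2, 1], -120)
})

test_that("angle force vanishes at the minimum and conserves momentum", {
  bp <- bonded_params()
  comp <- system_composition(1, 0, nh1 = 1, nt1 = 2, nt2 = 1,
                             box = c(3, 3, 3))
  im0 <- suppressWarnings(interaction_model(matrix(0, 5, 5), gamma = 0,
                                            sigma = 0))
  make <- function(p3) {
    pos <- rbind(c(1.0, 1.5, 1.5), c(1.7, 1.5, 1.5), p3)
    dpd_state(rbind(pos, matrix(runif(3 * comp$NW, 0.1, 2.9),
                                comp$NW, 3)),
              matrix(0, comp$N, 3), comp)
  }
  # straight chain at bond length rs: both bond and angle terms at minimum
  f_straight <- dpd_forces(make(c(2.4, 1.5, 1.5)), im0, bp,
                           include = "conservative")$forces[1:3, ]
  expect_equal(f_straight, matrix(0, 3, 3), tolerance = 1e-12)
  # bent chain: forces nonzero but sum to zero (translation invariance)
  f_bent <- dpd_forces(make(c(1.7, 2.2, 1.5)), im0, bp,
                       include = "conservative")$forces[1:3, ]
  expect_gt(max(abs(f_bent)), 0.1)
  expect_equal(colSums(f_bent), c(0, 0, 0), tolerance = 1e-12)
})

test_that("analytic forces match central differences of the potential", {
  set.seed(42)
  comp <- system_composition(2, 2, nt1 = 3, nt2 = 2, box = c(4, 4, 4))
  st <- random_init(comp, seed = 3)
  im <- default_interaction_matrix()
  bp <- bonded_params()
  f <- dpd_forces(st, im, bp, include = "conservative")$forces
  h <- 1e-6
  # probe a handful of beads (lipid and water) in every direction
  probes <- c(1, 5, 12, 21, comp$N - 1)
  for (i in probes) for (d in 1:3) {
    pp <- st$positions; pp[i, d] <- pp[i, d] + h
    pm <- st$positions; pm[i, d] <- pm[i, d] - h
    num <- -(r_reference_energy(pp, st, im, bp) -
               r_reference_energy(pm, st, im, bp)) / (2 * h)
    expect_equal(f[i, d], num, tolerance = 1e-5)
  }
})

test_that("cell-list forces equal the all-pairs oracle on random boxes", {
  im <- default_interaction_matrix()
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(100:200, 1)
    box <- c(4, 5, 6)
    st <- bare_state(cbind(runif(n, 0, 4), runif(n, 0, 5), runif(n, 0, 6)),
                     velocities = matrix(rnorm(3 * n), n, 3),
                     species = sample(dpd_species(), n, replace = TRUE),
                     box = box)
    f_cell <- dpd_forces(st, im, include = c("conservative", "dissipative"),
                         method = "cell")$forces
    f_all <- dpd_forces(st, im, include = c("conservative", "dissipative"),
                        method = "allpairs")$forces
    expect_lt(max(abs(f_cell - f_all)), 1e-10)
    # and both agree with an independent plain-R implementation
    f_r <- r_reference_forces(st, im)
    expect_lt(max(abs(f_cell - f_r)), 1e-8)
  }
})

test_that("free motion and momentum conservation hold under integration", {
  im0 <- suppressWarnings(interaction_model(matrix(0, 5, 5), gamma = 0,
                                            sigma = 0))
  # no forces: uniform straight-line motion, wrapped
  st <- bare_state(rbind(c(1, 1, 1), c(3, 3, 3)),
                   velocities = rbind(c(0.3, -0.2, 0.5), c(0, 0.1, -0.4)),
                   box = c(5, 5, 5))
  run <- dpd_run(st, n_steps = 200, dt = 0.01, seed = 9,
                 interaction = im0, energy_every = 0, frame_every = 0)
  expect_equal(run$final_state$positions,
               (st$positions + 2 * st$velocities) %% 5, tolerance = 1e-12)
  expect_equal(run$final_state$velocities, st$velocities)

  # interacting fluid: total momentum stays at zero to accumulated rounding
  stw <- water_state(c(5.5, 5.5, 5.5), seed = 2)
  p0 <- colSums(stw$velocities)
  expect_equal(p0, c(0, 0, 0), tolerance = 1e-10)
  run2 <- dpd_run(stw, n_steps = 10000, dt = 0.01, seed = 11,
                  energy_every = 0, frame_every = 0)
  expect_lt(max(abs(colSums(run2$final_state$velocities))), 1e-8)
})

test_that("thermostat equilibrates a water box to kBT = 1 within 5%", {
  st <- water_state(c(5.5, 5.5, 5.5), seed = 4)   # ~500 beads
  run <- dpd_run(st, n_steps = 2000, dt = 0.01, seed = 5,
                 energy_every = 50, frame_every = 0)
  late <- run$energy$temperature[run$energy$step >= 1000]
  expect_gt(mean(late), 0.95)
  expect_lt(mean(late), 1.05)
})

test_that("trajectories are bitwise reproducible under a seed", {
  comp <- small_membrane_comp(3, 3, box = c(6, 6, 10))
  st <- layered_bilayer_init(comp, seed = 7)
  r1 <- dpd_run(st, n_steps = 300, seed = 21, energy_every = 100,
                frame_every = 150)
  r2 <- dpd_run(st, n_steps = 300, seed = 21, energy_every = 100,
                frame_every = 150)
  expect_identical(r1$final_state$positions, r2$final_state$positions)
  expect_identical(r1$final_state$velocities, r2$final_state$velocities)
  expect_identical(r1$energy, r2$energy)
  r3 <- dpd_run(st, n_steps = 300, seed = 22)
  expect_false(identical(r1$final_state$positions,
                         r3$final_state$positions))
})

test_that("energy breakdown totals its parts and responds to structure", {
  comp <- small_membrane_comp(3, 3, box = c(6, 6, 10))
  st <- layered_bilayer_init(comp, seed = 1)
  eb <- energy_breakdown(st)
  expect_equal(eb$total, eb$kinetic + eb$pair + eb$bond + eb$angle)
  expect_gte(eb$kinetic, 0)
  # construction puts bonds at rs and angles at theta0: no bonded energy
  expect_equal(eb$bond, 0, tolerance = 1e-20)
  expect_equal(eb$angle, 0, tolerance = 1e-12)
})

test_that("pair weight is linear inside the cutoff and zero beyond", {
  expect_equal(pair_weight(c(0, 0.3, 1, 2.5)), c(1, 0.7, 0, 0))
  expect_equal(pair_weight(0.5, rc = 2), 0.75)
  r <- runif(50, 0, 2)
  expect_true(all(pair_weight(r) >= 0 & pair_weight(r) <= 1))
})

test_that("checkpoints restart the exact state and catch config drift", {
  comp <- small_membrane_comp(3, 3, box = c(6, 6, 12))
  st <- layered_bilayer_init(comp, seed = 2)
  st2 <- dpd_run(st, n_steps = 50, seed = 3, energy_every = 0,
                 frame_every = 0)$final_state
  cfg <- reduced_preset(nt1 = 3, nt2 = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(st2, path, config = cfg)
  back <- read_checkpoint(path, config = cfg)
  expect_identical(back$positions, st2$positions)
  expect_identical(back$velocities, st2$velocities)
  expect_identical(back$time, st2$time)
  # continuing from the checkpoint matches continuing the original
  c1 <- dpd_run(back, n_steps = 20, seed = 4, energy_every = 0,
                frame_every = 0)$final_state
  c2 <- dpd_run(st2, n_steps = 20, seed = 4, energy_every = 0,
                frame_every = 0)$final_state
  expect_identical(c1$positions, c2$positions)
  expect_error(read_checkpoint(path, config = reduced_preset(nt1 = 4)),
               "different configuration")
})
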