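test_that("ideal DPD gas reproduces p = rho kBT on every diagonal", {
  st <- water_state(c(8, 8, 8), seed = 21)   # 1536 beads, Maxwell at kBT=1
  im0 <- ideal_gas_interaction()
  # a short run keeps the velocities thermostatted while a = 0
  run <- dpd_run(st, n_steps = 200, seed = 3, interaction = im0,
                 energy_every = 0, frame_every = 50)
  p <- vapply(run_frames(run), function(fr) {
    pressure_tensor(fr, im0)$whole
  }, numeric(3))
  rho <- st$composition$N / prod(st$box)
  # MC error on the mean of ~N v^2 terms over 4 frames
  expect_equal(unname(rowMeans(p)), rep(rho, 3), tolerance = 0.05)
})

test_that("a single repulsive pair gives pzz - pxx = f d / V", {
  im <- default_interaction_matrix()
  d <- 0.5
  st <- bare_state(rbind(c(2, 2, 2), c(2, 2, 2 + d)), box = c(4, 4, 4))
  rec <- pressure_tensor(st, im)
  f <- 25 * (1 - d)            # conservative magnitude at separation d
  V <- 64
  expect_equal(unname(rec$whole["pzz"] - rec$whole["pxx"]), f * d / V)
  expect_equal(unname(rec$whole["pxx"]), 0)
  expect_equal(tension_z(rec), f * d / V)
})

test_that("tension_z is the normal minus mean tangential component", {
  expect_equal(tension_z(c(pxx = 2, pyy = 2, pzz = 3)), 1)
  expect_equal(tension_z(c(pxx = 1, pyy = 1, pzz = 1)), 0)
  # linear in the components: mean over records = tension of mean record
  recs <- replicate(5, setNames(runif(3), c("pxx", "pyy", "pzz")),
                    simplify = FALSE)
  expect_equal(mean(vapply(recs, tension_z, numeric(1))),
               tension_z(Reduce(`+`, recs) / 5))
})

test_that("slab decomposition sums exactly to the whole-box tensor", {
  comp <- small_membrane_comp(3, 3, box = c(6, 6, 10))
  st <- layered_bilayer_init(comp, seed = 9)
  st <- dpd_run(st, n_steps = 50, seed = 2, energy_every = 0,
                frame_every = 0)$final_state
  for (with_bonded in c(FALSE, TRUE)) {
    rec <- pressure_tensor(st, n_slabs = 25, include_bonded = with_bonded)
    V <- prod(st$box)
    for (cmp in c("pxx", "pyy", "pzz")) {
      expect_equal(sum(rec$slabs[[cmp]] * rec$slab_volume) / V,
                   unname(rec$whole[cmp]), tolerance = 1e-10)
    }
  }
  # the bonded (chain-elasticity) virial is a real, separate contribution
  expect_false(isTRUE(all.equal(
    pressure_tensor(st, include_bonded = TRUE)$whole,
    pressure_tensor(st)$whole)))
  # degenerate windows are rejected
  expect_error(pressure_tensor(st, y_window = c(3, 3)), "width")
})

test_that("full-box y-window reproduces the unrestricted profile", {
  comp <- small_membrane_comp(3, 3, box = c(6, 6, 10))
  st <- layered_bilayer_init(comp, seed = 10)
  st <- dpd_run(st, n_steps = 50, seed = 4, energy_every = 0,
                frame_every = 0)$final_state
  p_full <- tension_profile(list(st), n_slabs = 20)
  p_win <- tension_near_pore(list(st), y_window = c(0, 6), n_slabs = 20)
  expect_equal(p_win$sigma_z, p_full$sigma_z, tolerance = 1e-9)
  # a genuine half-box window differs
  p_half <- tension_near_pore(list(st), y_window = c(0, 3), n_slabs = 20)
  expect_false(isTRUE(all.equal(p_half$sigma_z, p_full$sigma_z)))
})

test_that("bulk water is statistically tensionless", {
  st <- water_state(c(6, 6, 12), seed = 22)
  run <- dpd_run(st, n_steps = 5000, seed = 7, energy_every = 0,
                 frame_every = 50)
  sz <- vapply(run_frames(run), function(fr) {
    tension_z(pressure_tensor(fr))
  }, numeric(1))
  expect_gte(length(sz), 100)
  se <- sd(sz) / sqrt(length(sz))
  expect_lt(abs(mean(sz)), 3 * se)
  # and its sigma_z(z) profile is flat about zero
  prof <- tension_profile(run_frames(run)[seq(1, 100, by = 4)],
                          n_slabs = 12)
  expect_lt(max(abs(prof$sigma_z)), 0.5)
})

test_that("stage-averaged membrane tension is reported per dynamics stage", {
  cfg <- reduced_preset(nt1 = 6, nt2 = 6, n1 = 36, n2 = 36,
                        box = c(6, 6, 16), n_steps = 600,
                        energy_every = 50, frame_every = 100)
  run <- simulate(cfg, seed = 11)
  ts <- tension_timeseries(run, n_slabs = 16)
  expect_true(all(ts$stage %in% c("initial", "adjustment", "stable")))
  expect_true(all(is.finite(ts$sigma_z)))
  expect_equal(sum(ts$n_frames), length(run$frames))
  expect_length(attr(ts, "membrane_domain"), 2)
})
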