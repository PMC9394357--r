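test_that("chain topologies are linear with complete bond/angle coverage", {
  cases <- list(list(3, 2, 5, 4, 3), list(3, 9, 12, 11, 10),
                list(1, 1, 2, 1, 0))
  for (cs in cases) {
    top <- build_topology("type-I", cs[[1]], cs[[2]])
    expect_length(top$bead_species, cs[[3]])
    expect_equal(nrow(top$bonds), cs[[4]])
    expect_equal(nrow(top$angles), cs[[5]])
    if (nrow(top$bonds) > 0) {
      expect_equal(top$bonds[, 2] - top$bonds[, 1],
                   rep(1L, nrow(top$bonds)))
    }
  }
  top2 <- build_topology("type-II", 3, 4)
  expect_equal(top2$bead_species, c(rep("H2", 3), rep("T2", 4)))
  expect_error(build_topology("type-I", 0, 5), "positive")
  expect_error(build_topology("type-I", 2, -1), "positive")
})

test_that("bead bookkeeping reproduces the study compositions", {
  expect_equal(lipid_bead_count(900, 3, 2), 4500)
  expect_equal(lipid_bead_count(0, 3, 9), 0)
  expect_equal(lipid_bead_count(900, 3, 9), 10800)
  expect_equal(water_bead_count(81000, 900, 900, 3, 2, 3, 2), 72000)
  expect_equal(water_bead_count(81000, 900, 900, 3, 9, 3, 9), 59400)
  expect_equal(water_bead_count(10, 1, 1, 3, 2, 3, 2), 0)
  expect_error(water_bead_count(10, 2, 2, 3, 2, 3, 2), "infeasible")
})

test_that("composition closure holds and species counts re-sum to N", {
  set.seed(7)
  for (k in 1:8) {
    nt1 <- sample(2:10, 1); nt2 <- sample(2:10, 1)
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    box <- c(6, 6, sample(8:14, 1))
    comp <- system_composition(n1, n2, nt1 = nt1, nt2 = nt2, box = box)
    sp <- dpdmix:::composition_species(comp)
    expect_length(sp, comp$N)
    counts <- table(factor(dpd_species()[sp], levels = dpd_species()))
    expect_equal(unname(counts[["H1"]]), n1 * 3)
    expect_equal(unname(counts[["T1"]]), n1 * nt1)
    expect_equal(unname(counts[["T2"]]), n2 * nt2)
    expect_equal(unname(counts[["W"]]), comp$NW)
    expect_equal(sum(counts), comp$N)
    expect_equal(comp$N, round(3 * prod(box)))
  }
})

test_that("Flory-Huggins mapping is linear and matches the quoted value", {
  expect_equal(flory_chi(100, 25), 21.45)
  expect_equal(flory_chi(25, 25), 0)
  expect_equal(flory_chi(50, 25), 7.15)
  # linear in the repulsion difference, zero for identical beads
  d <- seq(-50, 120, by = 17)
  expect_equal(flory_chi(25 + d, 25), 0.286 * d)
  expect_equal(flory_chi(2 * d, d), flory_chi(d, 0))
})

test_that("default interaction matrix reproduces the parameter table", {
  im <- default_interaction_matrix()
  a <- im$a
  expect_true(isSymmetric(a))
  expect_equal(unname(diag(a)), rep(25, 5))
  expect_equal(a["H1", "W"], 25)
  expect_equal(a["H2", "W"], 25)
  expect_equal(a["H1", "H2"], 25)
  expect_equal(a["T1", "W"], 100)
  expect_equal(a["T2", "W"], 100)
  expect_equal(a["T2", "T1"], 100)
  expect_equal(a["H1", "T1"], 100)
  expect_equal(a["H2", "T1"], 100)
  expect_equal(a["T2", "T2"], 25)
  expect_equal(im$gamma, 4.5)
  expect_equal(im$sigma, 3.0)
  # fluctuation-dissipation contract
  expect_equal(im$sigma^2, 2 * im$gamma * im$kBT)
  expect_warning(interaction_model(a, gamma = 4.5, sigma = 1),
                 "thermostat")
  expect_error(interaction_model(matrix(runif(25), 5, 5)), "symmetric")
})

test_that("configs round-trip through the plain-text format", {
  cfg <- reduced_preset(nt1 = 5, nt2 = 6, n_steps = 1234)
  path <- tempfile(fileext = ".yml")
  write_dpd_config(cfg, path)
  cfg2 <- read_dpd_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  # unknown fields are rejected, not silently dropped
  writeLines(c("nt1: 3", "bogus_field: 1"), path)
  expect_error(read_dpd_config(path), "unknown config")
})
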