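test_that("contact energies reproduce the calibrated well depths", {
  p <- energy_params()
  kT <- p$kT
  expect_equal(-pair_energy(4, sticky_pair = TRUE, params = p)$total / kT,
               3.0, tolerance = 0.02)
  expect_equal(-pair_energy(4, params = p)$total / kT, 0.6,
               tolerance = 0.02)
  # overlap is infinitely penalised
  expect_identical(pair_energy(3.9, params = p)$total, Inf)
  expect_identical(pair_energy(3.9, params = p)$hard_sphere, Inf)
})

test_that("unscreened electrostatics recover the Coulomb/Bjerrum scale", {
  p0 <- energy_params(kappa = 0)
  # Bjerrum length ~7.15 A at 298 K in water: u(10 A) ~ 0.715 kT
  expect_equal(pair_energy(10, 1, 1, params = p0)$electrostatic / p0$kT,
               0.715, tolerance = 0.002)
  # opposite charges attract symmetrically
  expect_equal(pair_energy(10, 1, -1, params = p0)$electrostatic,
               -pair_energy(10, 1, 1, params = p0)$electrostatic)
  # screened potential decays faster and is monotone in kappa at fixed r
  kappas <- c(0, 0.05, 0.1, 0.2, 0.4)
  vals <- vapply(kappas, function(k) {
    pair_energy(12, 1, 1, params = energy_params(kappa = k))$electrostatic
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # faster than 1/r for kappa > 0
  ps <- energy_params(kappa = 0.2)
  u8 <- pair_energy(8, 1, 1, params = ps)$electrostatic
  u16 <- pair_energy(16, 1, 1, params = ps)$electrostatic
  expect_lt(u16 / u8, 8 / 16)
  expect_error(pair_energy(0, params = p0), "r must be")
  expect_error(pair_energy(-1, params = p0), "r must be")
})

test_that("bond energy is the calibrated harmonic", {
  p <- energy_params()
  expect_identical(bond_energy(4.1, p), 0)
  # 0.4 N/m converts to ~2.409 kJ/mol/A^2; half of that at 1 A stretch
  expect_equal(bond_energy(5.1, p), 1.2044, tolerance = 1e-3)
  expect_equal(bond_energy(3.1, p), bond_energy(5.1, p))
  expect_equal(p$k_bond, 2.409, tolerance = 1e-3)
})

test_that("debye screening length is ~7.9 A at 150 mM", {
  expect_equal(1 / debye_kappa(150), 7.85, tolerance = 0.01)
  expect_identical(debye_kappa(0), 0)
  # kappa ~ sqrt(I)
  expect_equal(debye_kappa(300) / debye_kappa(75), 2, tolerance = 1e-10)
})

test_that("minimal systems match single-term hand evaluations", {
  p <- energy_params()
  pl <- histazinc:::.params_cpp(p)
  # two uncharged single-bead chains 4.1 A apart: one generic 1/r^6 term
  coords <- rbind(c(10, 10, 10), c(14.1, 10, 10))
  u <- histazinc:::total_energy_cpp(coords, 2L, 1L, 0, FALSE, 200, pl)
  expect_equal(u, -0.6e4 / 4.1^6, tolerance = 1e-9)
  expect_equal(u, -1.263, tolerance = 1e-3)
  # a bonded two-bead chain at r0: bond at equilibrium, bonded pair
  # excluded from the non-bonded terms, so zero total energy
  u2 <- histazinc:::total_energy_cpp(coords, 1L, 2L, c(0, 0), c(FALSE, FALSE),
                                     200, pl)
  expect_equal(u2, 0, tolerance = 1e-12)
  # stretched bond: pure harmonic
  coords2 <- rbind(c(10, 10, 10), c(15.1, 10, 10))
  u3 <- histazinc:::total_energy_cpp(coords2, 1L, 2L, c(0, 0),
                                     c(FALSE, FALSE), 200, pl)
  expect_equal(u3, bond_energy(5.1, p), tolerance = 1e-12)
})

test_that("total energy equals the brute-force double loop", {
  for (seed in 1:4) {
    n <- sample(2:5, 1)
    sys <- make_small_system(n_chains = n, box = 70 + 10 * seed, seed = seed)
    p <- energy_params()
    expect_equal(total_energy(sys, p), oracle_total_energy(sys, p),
                 tolerance = 1e-9)
    # with zinc-mode mixing strengths as well
    pm <- energy_params(eps_cross = "mixing")
    expect_equal(total_energy(sys, pm), oracle_total_energy(sys, pm),
                 tolerance = 1e-9)
  }
})

test_that("energy is invariant under lattice translations (periodicity)", {
  sys <- make_small_system(n_chains = 3, box = 90, seed = 2)
  p <- energy_params()
  u0 <- total_energy(sys, p)
  shifted <- sys
  shifted$coords <- sweep(sys$coords, 2, c(90, -180, 90), `+`)
  expect_equal(total_energy(shifted, p), u0, tolerance = 1e-9)
  # and under a uniform non-lattice shift too (pair distances unchanged)
  shifted$coords <- sweep(sys$coords, 2, c(1.23, -4.56, 7.89), `+`)
  expect_equal(total_energy(shifted, p), u0, tolerance = 1e-9)
})

test_that("overlapping configurations have infinite energy", {
  wt <- build_peptide("WT")
  sys <- build_system(wt, 100, n_chains = 2, seed = 3)
  sys$coords[27, ] <- sys$coords[1, ] + c(3.0, 0, 0)  # bead of chain 2 onto chain 1
  expect_identical(total_energy(sys, energy_params()), Inf)
})

test_that("parameter validation rejects nonsense", {
  expect_error(energy_params(eps_generic = -1))
  expect_error(energy_params(temperature = 0))
  expect_error(energy_params(cutoff = -5), "cutoff")
  expect_error(energy_params(kappa = -0.1), "kappa")
})
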