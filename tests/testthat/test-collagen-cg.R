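ff <- collagen_ff()

test_that("molecule builder counts beads, bonds and angles correctly", {
  m <- build_molecule(10, 5)
  expect_equal(m$n_beads, 3)
  expect_equal(nrow(m$bonds), 2)
  expect_equal(nrow(m$angles), 1)
  # default molecule reproduces the ~300 nm contour length
  md <- build_molecule()
  expect_lt(abs(md$contour_length_nm - 300), md$spacing / 10)
  expect_error(build_molecule(5, 10))
})

test_that("bond potential is continuous, force-consistent and breakable", {
  # spring minimum: zero force, energy c1
  b0 <- bond_energy_force(ff$r0, ff)
  expect_equal(b0$force, 0)
  expect_equal(b0$energy, ff$c1)
  # energy and force continuity at r1 (c1, c2 from continuity; default
  # r1_bar centres the stiff branch so the force is continuous too)
  bl <- bond_energy_force(ff$r1 - 1e-9, ff)
  br <- bond_energy_force(ff$r1 + 1e-9, ff)
  expect_lt(abs(bl$energy - br$energy), 1e-6)
  expect_lt(abs(bl$force - br$force), 1e-6)
  # energy goes to zero continuously at rb, then the bond is broken
  expect_lt(abs(bond_energy_force(ff$rb - 1e-9, ff)$energy), 1e-5)
  bb <- bond_energy_force(ff$rb + 0.1, ff)
  expect_equal(bb$energy, 0)
  expect_equal(bb$force, 0)
  expect_true(bb$broken)
  # force = -dE/dr by central difference on both branches
  for (r in c(0.9 * ff$r1, 0.5 * (ff$r1 + ff$rb))) {
    h <- 1e-6
    fd <- -(bond_energy_force(r + h, ff)$energy -
              bond_energy_force(r - h, ff)$energy) / (2 * h)
    expect_equal(bond_energy_force(r, ff)$force, fd, tolerance = 1e-5)
  }
})

test_that("Lennard-Jones term has its minimum and zero where it should", {
  rmin <- 2^(1 / 6) * ff$sigma_lj
  lj <- lj_energy_force(rmin, ff)
  expect_lt(abs(lj$force), 1e-10)
  # truncated-shifted potential: minimum is -eps minus the cutoff shift
  s6c <- (ff$sigma_lj / ff$lj_cutoff)^6
  shift <- 4 * ff$eps_lj * (s6c^2 - s6c)
  expect_equal(lj$energy, -ff$eps_lj - shift, tolerance = 1e-10)
  # zero crossing at sigma, up to the same shift
  expect_equal(lj_energy_force(ff$sigma_lj, ff)$energy, -shift,
               tolerance = 1e-10)
  h <- 1e-6
  r <- 1.1 * ff$sigma_lj
  fd <- -(lj_energy_force(r + h, ff)$energy -
            lj_energy_force(r - h, ff)$energy) / (2 * h)
  expect_equal(lj_energy_force(r, ff)$force, fd, tolerance = 1e-5)
})

test_that("angle energy is symmetric about theta0 and zero there", {
  expect_equal(angle_energy(ff$theta0, ff), 0)
  expect_equal(angle_energy(ff$theta0 - 0.2, ff),
               angle_energy(ff$theta0 - 0.2, ff))
  expect_gt(angle_energy(ff$theta0 - 0.3, ff), 0)
})

test_that("fibril packing reproduces the stated cross-section counts", {
  f <- build_fibril(diameter_nm = 21.5, beta = 0)
  expect_equal(f$n_molecules, 151)
  # microfibril grouping of 5 recorded
  expect_true(all(table(f$microfibril) <= 5))
  expect_error(build_fibril(beta = 1.5), "beta")
})

test_that("crosslink density beta controls connected ends per molecule", {
  f0 <- build_fibril(8.7, beta = 0, length_nm = 28)
  expect_equal(nrow(f0$crosslinks), 0)
  expect_equal(connected_ends_per_molecule(f0), 0)
  f1 <- build_fibril(8.7, beta = 1, length_nm = 28)
  expect_equal(connected_ends_per_molecule(f1), 2)
  fh <- build_fibril(8.7, beta = 0.5, length_nm = 28, seed = 3)
  expect_equal(connected_ends_per_molecule(fh), 1, tolerance = 0.11)
  # crosslinks bond an end bead to a bead of a different molecule
  expect_true(all(f1$molecule_id[f1$crosslinks[, 1]] !=
                    f1$molecule_id[f1$crosslinks[, 2]]))
})

test_that("compiled forces equal the energy gradient on random configurations", {
  set.seed(4)
  mol <- build_molecule(8.4, 1.4)
  st <- simulation_state(mol, ff)
  st$positions <- st$positions + matrix(rnorm(length(st$positions), 0, 0.6),
                                        ncol = 3)
  ef <- energy_forces(st, ff)
  h <- 1e-5
  for (i in seq_len(nrow(st$positions))) {
    for (j in 1:3) {
      sp <- st
      sp$positions[i, j] <- sp$positions[i, j] + h
      sm <- st
      sm$positions[i, j] <- sm$positions[i, j] - h
      fd <- -(energy_forces(sp, ff)$potential -
                energy_forces(sm, ff)$potential) / (2 * h)
      expect_equal(ef$forces[i, j], fd,
                   tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("kernel pair energy matches the brute-force double loop", {
  # a few short parallel molecules, close enough for LJ to act
  f <- build_fibril(4.8, beta = 0, length_nm = 8.4, stagger_nm = 1,
                    pitch_nm = 1.55)
  expect_gt(f$n_molecules, 1)
  expect_lte(f$n_beads, 50)
  st <- simulation_state(f, ff)
  set.seed(8)
  st$positions <- st$positions + matrix(rnorm(length(st$positions), 0, 0.4),
                                        ncol = 3)
  ef <- energy_forces(st, ff)
  chain_index <- sequence(rep(f$beads_per_molecule, f$n_molecules))
  lj_brute <- brute_lj_energy(st$positions, f$molecule_id, chain_index, ff)
  # subtract bonded + angle energy computed from the R-level terms
  r_b <- sqrt(rowSums((st$positions[st$bonds[, 1], , drop = FALSE] -
                         st$positions[st$bonds[, 2], , drop = FALSE])^2))
  e_bond <- sum(bond_energy_force(r_b, ff)$energy)
  ang <- st$angles
  e_ang <- 0
  for (a in seq_len(nrow(ang))) {
    v1 <- st$positions[ang[a, 1], ] - st$positions[ang[a, 2], ]
    v2 <- st$positions[ang[a, 3], ] - st$positions[ang[a, 2], ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    e_ang <- e_ang + angle_energy(th, ff)
  }
  expect_equal(ef$potential, lj_brute + e_bond + e_ang,
               tolerance = 1e-8 * max(1, abs(ef$potential)))
})

test_that("NVE integration conserves energy and leaves equilibria alone", {
  # two beads at rest length: stationary
  st <- simulation_state(build_molecule(2.8, 1.4), ff)
  out <- integrate_md(st, ff, n_steps = 300, thermostat = "none",
                      sample_every = 300)
  expect_equal(out$positions, st$positions)
  # perturbed 20-bead chain: drift < 0.1% over 1000 steps
  m20 <- build_molecule(26.7, 1.4)
  expect_equal(m20$n_beads, 20)
  st <- simulation_state(m20, ff)
  set.seed(1)
  st$positions <- st$positions + matrix(rnorm(60, 0, 0.3), ncol = 3)
  out <- integrate_md(st, ff, n_steps = 1000, thermostat = "none",
                      sample_every = 10)
  E <- out$trace$epot + out$trace$ekin
  expect_lt(abs(E[length(E)] - E[1]) / abs(E[1]), 1e-3)
})

test_that("Langevin trajectories are reproducible under a seed", {
  st <- simulation_state(build_molecule(8.4, 1.4), ff)
  o1 <- integrate_md(st, ff, n_steps = 200, thermostat = "langevin",
                     seed = 7, sample_every = 50)
  o2 <- integrate_md(st, ff, n_steps = 200, thermostat = "langevin",
                     seed = 7, sample_every = 50)
  o3 <- integrate_md(st, ff, n_steps = 200, thermostat = "langevin",
                     seed = 8, sample_every = 50)
  expect_identical(o1$positions, o2$positions)
  expect_false(identical(o1$positions, o3$positions))
})

test_that("bond breaking is permanent", {
  # stretch a dimer beyond rb, then release: no force pulls it back
  mol <- build_molecule(1.5, 1.4)
  st <- simulation_state(mol, ff)
  st$positions[2, 3] <- st$positions[1, 3] + ff$rb + 1
  ef <- energy_forces(st, ff)
  expect_equal(ef$broken, 1L)
  st$broken <- ef$broken
  # move beads back inside rb: a broken bond still contributes nothing
  st$positions[2, 3] <- st$positions[1, 3] + ff$r0
  ef2 <- energy_forces(st, ff)
  expect_equal(ef2$broken, 1L)
  # bonded pairs stay LJ-excluded, so nothing acts on the dimer any more
  expect_lt(max(abs(ef2$forces[, 3])), 1e-10)
})

test_that("tensile tests produce increasing pre-peak stress from near zero", {
  fib <- build_fibril(6, beta = 1, length_nm = 14, stagger_nm = 7, seed = 2)
  cv <- tensile_test(fib, ff, strain_rate = 4e-4, max_strain = 0.05,
                     seed = 2, n_samples = 10)
  expect_s3_class(cv, "stress_strain_curve")
  expect_true(all(diff(cv$strain) > 0))
  # stress starts small relative to the 5% strain level (the first sample
  # includes the post-equilibration transient)
  expect_lt(abs(cv$stress[1]), 0.5 * max(cv$stress))
  # broadly increasing in the elastic regime
  expect_gt(stats::cor(cv$strain, cv$stress), 0.9)
})
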