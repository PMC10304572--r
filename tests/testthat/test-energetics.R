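one_atom <- function(x = 0, y = 0, z = 0, charge = 0, epsilon = 0,
                     rmin_half = 1, scaled_subset = FALSE) {
  nonbonded_params(tibble::tibble(x = x, y = y, z = z, charge = charge,
                                  epsilon = epsilon, rmin_half = rmin_half,
                                  scaled_subset = scaled_subset))
}

test_that("Coulomb and Lennard-Jones closed forms hold", {
  # two unit charges at 1 A: energy is exactly the Coulomb constant
  expect_equal(pair_energy(one_atom(charge = 1), one_atom(x = 1, charge = 1)),
               332.0636)
  # neutral LJ pair at its minimum distance: energy is -eps_ij
  a <- one_atom(epsilon = 0.3, rmin_half = 1.6)
  b <- one_atom(x = 3.2, epsilon = 0.12, rmin_half = 1.6)
  expect_equal(pair_energy(a, b), -sqrt(0.3 * 0.12), tolerance = 1e-12)
  # subset pair with doubled epsilon: -2 eps_ij
  a$scaled_subset <- TRUE; b$scaled_subset <- TRUE
  expect_equal(pair_energy(a, b, scale_factor = 2), -2 * sqrt(0.3 * 0.12),
               tolerance = 1e-12)
  # coincident atoms are rejected
  expect_error(pair_energy(one_atom(), one_atom()), "zero interatomic")
})

test_that("epsilon scaling touches only subset-subset pairs and is linear in s", {
  set.seed(61)
  molA <- random_molecule(12)
  molB <- random_molecule(12, origin = c(8, 0, 0))
  molA$charge <- 0; molB$charge <- 0
  # all-subset molecules: pure LJ energy scales exactly linearly with s
  subA <- molA; subA$scaled_subset <- TRUE
  subB <- molB; subB$scaled_subset <- TRUE
  e1 <- pair_energy(subA, subB, scale_factor = 1)
  e3 <- pair_energy(subA, subB, scale_factor = 3)
  expect_equal(e3 / e1, 3, tolerance = 1e-12)
  # cross subset/non-subset pairs are untouched
  nonA <- molA; nonA$scaled_subset <- FALSE
  expect_equal(pair_energy(nonA, subB, scale_factor = 3),
               pair_energy(nonA, subB, scale_factor = 1), tolerance = 1e-12)
  # per-atom convention applies sqrt(s) per subset atom
  expect_equal(pair_energy(nonA, subB, scale_factor = 4, scaling = "atom"),
               2 * pair_energy(nonA, subB, scale_factor = 1), tolerance = 1e-12)
})

test_that("pair energy is symmetric, additive over partitions and matches brute force", {
  set.seed(62)
  for (k in 1:10) {
    molA <- random_molecule(20)
    molB <- random_molecule(20, origin = c(7 + k, 1, -2))
    s <- runif(1, 0.5, 3)
    e <- pair_energy(molA, molB, scale_factor = s)
    expect_equal(e, pair_energy(molB, molA, scale_factor = s), tolerance = 1e-12)
    expect_equal(e, bf_pair_energy(molA, molB, s), tolerance = 1e-10)
    # additivity over a partition of molecule B
    e_split <- pair_energy(molA, molB[1:7, ], scale_factor = s) +
      pair_energy(molA, molB[8:20, ], scale_factor = s)
    expect_equal(e, e_split, tolerance = 1e-10)
  }
})

test_that("sigma-convention tables convert to Rmin on input", {
  tab <- nonbonded_params(
    tibble::tibble(x = 0, y = 0, z = 0, charge = 0, epsilon = 0.2,
                   sigma = 3.4, scaled_subset = FALSE),
    convention = "sigma")
  expect_equal(tab$rmin_half, 2^(1 / 6) * 3.4 / 2)
  # LJ minimum sits at Rmin_ij after conversion
  b <- tab; b$x <- 2 * tab$rmin_half
  expect_equal(pair_energy(tab, b), -0.2, tolerance = 1e-12)
})

test_that("PES scans anchor at the reference distance and find wells and barriers", {
  # pure Coulomb repulsion: monotonically decreasing delta_e, no well
  qa <- one_atom(charge = 1)
  qb <- one_atom(charge = 1)
  sc <- scan_pes(qa, qb, c(1, 0, 0), seq(2, 39, 1), reference_distance = 40)
  expect_true(all(diff(sc$delta_e) < 0))
  expect_equal(attr(sc, "well_depth"), min(sc$delta_e))
  expect_gte(attr(sc, "barrier_height"), attr(sc, "well_depth"))

  # neutral single-site LJ: minimum at Rmin_ij with depth -eps_ij
  a <- one_atom(epsilon = 0.25, rmin_half = 1.75)
  b <- one_atom(epsilon = 0.25, rmin_half = 1.75)
  sc <- scan_pes(a, b, c(0, 0, 1), seq(3, 40, 0.5), reference_distance = 40)
  expect_equal(attr(sc, "r_min_location"), 3.5)
  expect_equal(attr(sc, "well_depth"), -0.25, tolerance = 1e-6)
  # delta_e at the reference distance is exactly zero
  expect_identical(sc$delta_e[sc$distance == 40], 0)

  # charged 3-site toy: with charges zeroed, doubling the subset epsilon
  # doubles the well depth (checked against the brute-force pair sum)
  tri <- nonbonded_params(tibble::tibble(
    x = c(-1.5, 0, 1.5), y = 0, z = 0, charge = 0,
    epsilon = c(0.1, 0.2, 0.1), rmin_half = 1.9, scaled_subset = TRUE))
  s1 <- scan_pes(tri, tri, c(0, 0, 1), seq(3, 40, 0.05), scale_factor = 1)
  s2 <- scan_pes(tri, tri, c(0, 0, 1), seq(3, 40, 0.05), scale_factor = 2)
  expect_equal(attr(s2, "well_depth") / attr(s1, "well_depth"), 2,
               tolerance = 0.01)
  d_at <- function(d, s) {
    shifted <- tri; shifted$z <- shifted$z + d
    bf_pair_energy(tri, shifted, s) - {
      ref <- tri; ref$z <- ref$z + 40; bf_pair_energy(tri, ref, s)
    }
  }
  expect_equal(attr(s2, "well_depth"),
               d_at(attr(s2, "r_min_location"), 2), tolerance = 1e-9)

  # steric overlap points are reported as NA with a warning
  expect_warning(
    sc_overlap <- scan_pes(a, b, c(0, 0, 1), c(0.05, 3.5, 40)),
    "steric overlap")
  expect_true(is.na(sc_overlap$delta_e[1]))
})

test_that("the epsilon scale factor is recoverable from a reference scan", {
  mol <- dye_nonbonded_table(charge_scale = 0.25)
  dists <- seq(3.2, 40, 0.4)
  ref2 <- scan_pes(mol, mol, c(0, 0, 1), dists, scale_factor = 2)
  expect_equal(fit_scale_factor(ref2, mol, mol, c(0, 0, 1)), 2,
               tolerance = 1e-3)
  ref1 <- scan_pes(mol, mol, c(0, 0, 1), dists, scale_factor = 1)
  expect_equal(fit_scale_factor(ref1, mol, mol, c(0, 0, 1)), 1,
               tolerance = 1e-3)
  # noisy reference still recovers the truth to ~0.1
  set.seed(63)
  noisy <- ref2
  noisy$delta_e <- noisy$delta_e + rnorm(nrow(noisy), sd = 0.1)
  attr(noisy, "well_depth") <- min(noisy$delta_e)
  expect_equal(fit_scale_factor(noisy, mol, mol, c(0, 0, 1)), 2,
               tolerance = 0.1)
  # a purely repulsive reference has no well to fit
  rep_ref <- scan_pes(one_atom(charge = 1), one_atom(charge = 1),
                      c(1, 0, 0), seq(2, 39, 1))
  expect_error(fit_scale_factor(rep_ref, mol, mol, c(0, 0, 1)), "no well")
})
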