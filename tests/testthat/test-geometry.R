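test_that("molecular frame of a planar molecule recovers plane normal and long axis", {
  mol <- make_dye_frame(c(0, 0, 0))
  fr <- compute_frame(mol, TOPO)
  expect_equal(abs(fr$z_axis), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(abs(fr$x_axis), c(1, 0, 0), tolerance = 1e-10)
  # orthonormal right-handed triad
  expect_equal(sum(fr$x_axis * fr$y_axis), 0, tolerance = 1e-10)
  expect_equal(dyeaggr:::cross3(fr$x_axis, fr$y_axis), fr$z_axis,
               tolerance = 1e-8)
  expect_equal(fr$center, c(0, 0, 0), tolerance = 1e-10)
})

test_that("frame axes are equivariant under rigid rotation (up to sign)", {
  set.seed(41)
  for (k in 1:5) {
    R <- random_rot()
    fr0 <- compute_frame(make_dye_frame(c(0, 0, 0)), TOPO)
    fr1 <- compute_frame(make_dye_frame(c(0, 0, 0), list(R)), TOPO)
    for (ax in c("x_axis", "y_axis", "z_axis")) {
      expect_equal(abs(sum((R %*% fr0[[ax]]) * fr1[[ax]])), 1, tolerance = 1e-8)
    }
  }
})

test_that("collinear xanthene atoms are rejected", {
  mol <- make_dye_frame(c(0, 0, 0))
  mol$y <- 0
  mol$z <- 0
  expect_error(compute_frame(mol, TOPO), "collinear")
})

test_that("cofacial parallel dimer displaced along the normal has the textbook geometry", {
  # plane separation of 3.6 A, the DFT-predicted xanthene-xanthene distance
  d <- make_planted_dimer(theta = 0, alpha = 90, rcc = 3.6)
  mols <- split(d, d$molecule_id)
  g <- dimer_geometry(compute_frame(mols[[1]], TOPO),
                      compute_frame(mols[[2]], TOPO))
  expect_equal(g$theta, 0, tolerance = 1e-8)
  expect_equal(g$alpha, 90, tolerance = 1e-8)
  expect_equal(unname(g$rx), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(g$ry), c(0, 0), tolerance = 1e-8)
  expect_equal(as.numeric(g$probe_plane_dists), rep(3.6, 8), tolerance = 1e-8)
})

test_that("planted dimers reproduce requested theta/alpha/rcc to 1e-6", {
  grid <- expand.grid(theta = c(0, 5, 12, 40, 88),
                      alpha = c(3, 30, 54.7, 75, 90),
                      rcc = c(3.6, 5, 8))
  for (k in seq_len(nrow(grid))) {
    d <- make_planted_dimer(grid$theta[k], grid$alpha[k], grid$rcc[k])
    mols <- split(d, d$molecule_id)
    g <- dimer_geometry(compute_frame(mols[[1]], TOPO),
                        compute_frame(mols[[2]], TOPO))
    expect_equal(g$theta, grid$theta[k], tolerance = 1e-6)
    expect_equal(g$alpha, grid$alpha[k], tolerance = 1e-6)
    expect_equal(g$rcc, grid$rcc[k], tolerance = 1e-9)
  }
  # infeasible: out-of-plane component larger than the center distance
  expect_error(make_planted_dimer(0, 90, 3, plane_sep = 4), "infeasible")
})

test_that("dimer geometry scalars are symmetric, rigid-motion and image invariant", {
  d <- make_planted_dimer(theta = 33, alpha = 47, rcc = 5.5, plane_sep = 3.2)
  mols <- split(d, d$molecule_id)
  fA <- compute_frame(mols[[1]], TOPO)
  fB <- compute_frame(mols[[2]], TOPO)
  g1 <- dimer_geometry(fA, fB)
  g2 <- dimer_geometry(fB, fA)
  expect_equal(g1$rcc, g2$rcc, tolerance = 1e-10)
  expect_equal(g1$theta, g2$theta, tolerance = 1e-8)
  expect_equal(g1$alpha, g2$alpha, tolerance = 1e-8)
  expect_equal(g1$rx[["A"]], g2$rx[["B"]], tolerance = 1e-10)
  expect_equal(g1$probe_plane_dists["A", ], g2$probe_plane_dists["B", ],
               tolerance = 1e-10)
  expect_equal(g1$rx[["A"]]^2 + g1$ry[["A"]]^2 + g1$rz[["A"]]^2, g1$rcc^2,
               tolerance = 1e-6)

  set.seed(42)
  R <- random_rot()
  t0 <- runif(3, -20, 20)
  move <- function(mol) {
    xyz <- as.matrix(mol[, c("x", "y", "z")]) %*% t(R)
    mol$x <- xyz[, 1] + t0[1]; mol$y <- xyz[, 2] + t0[2]; mol$z <- xyz[, 3] + t0[3]
    mol
  }
  g3 <- dimer_geometry(compute_frame(move(mols[[1]]), TOPO),
                       compute_frame(move(mols[[2]]), TOPO))
  expect_equal(g3$rcc, g1$rcc, tolerance = 1e-8)
  expect_equal(g3$theta, g1$theta, tolerance = 1e-6)
  expect_equal(g3$alpha, g1$alpha, tolerance = 1e-6)
  expect_equal(sort(as.numeric(g3$probe_plane_dists)),
               sort(as.numeric(g1$probe_plane_dists)), tolerance = 1e-6)

  # translating B by lattice vectors changes nothing under minimum image
  box <- c(30, 30, 30)
  for (shift in list(c(1, 0, 0), c(0, -2, 1), c(3, 3, -3))) {
    molB <- mols[[2]]
    molB$x <- molB$x + shift[1] * box[1]
    molB$y <- molB$y + shift[2] * box[2]
    molB$z <- molB$z + shift[3] * box[3]
    g4 <- dimer_geometry(fA, compute_frame(molB, TOPO), box = box)
    expect_equal(g4$rcc, g1$rcc, tolerance = 1e-8)
    expect_equal(g4$alpha, g1$alpha, tolerance = 1e-6)
    expect_equal(g4$probe_plane_dists, g1$probe_plane_dists, tolerance = 1e-6)
  }
})

test_that("antiparallel long axes fold to theta = 0 and coincident centers error", {
  mol <- make_dye_frame(c(0, 0, 0))
  molB <- make_dye_frame(c(0, 0, 4), list(rot_z(180)))
  g <- dimer_geometry(compute_frame(mol, TOPO), compute_frame(molB, TOPO))
  expect_equal(g$theta, 0, tolerance = 1e-8)

  molC <- make_dye_frame(c(0, 0, 0), list(rot_z(40)))
  expect_error(dimer_geometry(compute_frame(mol, TOPO),
                              compute_frame(molC, TOPO)),
               "coincident")
  g40 <- dimer_geometry(compute_frame(mol, TOPO),
                        compute_frame(make_dye_frame(c(0, 0, 5),
                                                     list(rot_z(40))), TOPO))
  expect_equal(g40$theta, 40, tolerance = 1e-8)
})
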