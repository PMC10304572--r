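# classify_dimer consumes a dimer_geometry; for boundary tie-break checks we
# fabricate geometries with exact threshold values rather than relying on the
# floating-point recovery of a planted construction.
fake_geometry <- function(rcc, theta, alpha, rx = 0, ry = 0, probe = 3.5) {
  structure(list(
    rcc_vec = c(0, 0, rcc), rcc = rcc, theta = theta, alpha = alpha,
    rx = c(A = rx, B = rx), ry = c(A = ry, B = ry),
    rz = c(A = sqrt(max(0, rcc^2 - rx^2 - ry^2)),
           B = sqrt(max(0, rcc^2 - rx^2 - ry^2))),
    probe_plane_dists = rbind(A = rep(probe, 4), B = rep(probe, 4))),
    class = "dimer_geometry")
}

test_that("interacting dimers split into H, J and crossed-J at the published cutoffs", {
  thr <- classification_thresholds()
  # H: parallel, center line near the plane normal
  lab <- classify_dimer(fake_geometry(4.0, 5, 75), thr)
  expect_true(lab$interacting)
  expect_equal(as.character(lab$geometry_class), "H")
  # J: parallel, center line closer to the long axis than the magic angle
  lab <- classify_dimer(fake_geometry(4.0, 5, 30), thr)
  expect_equal(as.character(lab$geometry_class), "J")
  # crossed-J: long axes rotated by more than 12 degrees
  lab <- classify_dimer(fake_geometry(5.5, 40, 70), thr)
  expect_equal(as.character(lab$geometry_class), "crossed_J")
  # beyond the 6 A cutoff: not interacting at all
  lab <- classify_dimer(fake_geometry(6.5, 5, 75), thr)
  expect_false(lab$interacting)
  expect_equal(as.character(lab$geometry_class), "none")
  expect_false(lab$stacked)
})

test_that("boundary values resolve to the closed-on-the-lower-side convention", {
  thr <- classification_thresholds()
  expect_equal(as.character(classify_dimer(fake_geometry(4, 12, 70), thr)$geometry_class),
               "crossed_J")
  expect_equal(as.character(classify_dimer(fake_geometry(4, 5, 54.7), thr)$geometry_class),
               "J")
  expect_false(classify_dimer(fake_geometry(6, 5, 70), thr)$interacting)
})

test_that("pi-stacking requires small lateral offsets and four close probe atoms", {
  thr <- classification_thresholds()
  # cofacial at the DFT stacking distance
  d <- make_planted_dimer(0, 90, 3.6)
  mols <- split(d, d$molecule_id)
  g <- dimer_geometry(compute_frame(mols[[1]], TOPO), compute_frame(mols[[2]], TOPO))
  expect_true(is_stacked(g, thr))

  # same plane separation but lateral slip of 2.5 A along the short axis
  slip <- make_planted_dimer(0, 90, sqrt(3.5^2 + 2.5^2), plane_sep = 3.5)
  mols <- split(slip, slip$molecule_id)
  g <- dimer_geometry(compute_frame(mols[[1]], TOPO), compute_frame(mols[[2]], TOPO))
  expect_equal(min(g$ry), 2.5, tolerance = 1e-6)
  expect_false(is_stacked(g, thr))

  # T-shaped dimer: planes perpendicular at rcc = 5 A; the edge-on partner's
  # probes sit far from the flat partner's plane and vice versa
  molA <- make_dye_frame(c(0, 0, 0))
  molB <- make_dye_frame(c(0, 0, 5), list(rot_x(90)))
  gT <- dimer_geometry(compute_frame(molA, TOPO), compute_frame(molB, TOPO))
  # explicit construction: B's probes are at z = 5 +/- 0.7 so their distance
  # to A's z = 0 plane exceeds the 4.5 A cutoff
  expect_true(all(gT$probe_plane_dists["B", ] > 4.2))
  expect_false(is_stacked(gT, thr))
})

test_that("classify_frame labels every unordered dye pair, dispersed systems have none", {
  fr <- make_dispersed_frame(synthetic_config(seed = 21, n_steps = 0))
  labs <- classify_frame(fr, TOPO)
  expect_equal(nrow(labs), choose(10, 2))
  expect_equal(sum(labs$interacting), 0)
  expect_true(all(labs$mol_a < labs$mol_b))

  planted <- make_planted_dimer(0, 80, 4.0)
  labs <- classify_frame(planted, TOPO)
  expect_equal(nrow(labs), 1)
  expect_true(labs$interacting)
  expect_equal(as.character(labs$geometry_class), "H")
  expect_true(labs$stacked)

  single <- make_dye_frame(c(0, 0, 0))
  expect_equal(nrow(classify_frame(single, TOPO)), 0)
})

test_that("each interacting pair receives exactly one class and counts are monotone in rcc_cut", {
  fr <- make_dye_frame(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 3, 2), c(20, 0, 0)),
                       list(diag(3), rot_z(30), rot_z(80), diag(3)))
  labs <- classify_frame(fr, TOPO)
  expect_equal(nrow(labs), 6)
  inter <- labs[labs$interacting, ]
  expect_true(all(inter$geometry_class %in% c("H", "J", "crossed_J")))
  expect_true(all(labs$geometry_class[!labs$interacting] == "none"))

  counts <- vapply(c(2, 4, 6, 10, 30), function(cut) {
    sum(classify_frame(fr, TOPO, classification_thresholds(rcc_cut = cut))$interacting)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classification agrees with an independent brute-force oracle on random frames", {
  thr <- classification_thresholds()
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    centers <- matrix(runif(3 * n, 0, 14), ncol = 3)
    rots <- replicate(n, random_rot(), simplify = FALSE)
    box <- if (rep %% 2 == 0) c(40, 40, 40) else NULL
    fr <- make_dye_frame(centers, rots, box = box)
    got <- classify_frame(fr, TOPO, thr, box = box)
    want <- bf_classify_frame(fr, TOPO, thr, box = box)
    expect_equal(got$interacting, want$interacting)
    expect_equal(as.character(got$geometry_class), want$geometry_class)
    expect_equal(got$stacked, want$stacked)
  }
})

test_that("planted dimers inside class regions are recovered with full accuracy", {
  thr <- classification_thresholds()
  cases <- rbind(
    # theta, alpha, rcc, expected class, expected stacked
    expand.grid(theta = c(0, 5, 10.9), alpha = c(55.8, 75, 89), rcc = c(3.6, 4.5),
                class = "H"),
    expand.grid(theta = c(0, 5, 10.9), alpha = c(20, 40, 53.6), rcc = c(3.6, 4.5),
                class = "J"),
    expand.grid(theta = c(13.1, 45, 89), alpha = c(30, 70), rcc = c(3.6, 5.8),
                class = "crossed_J")
  )
  for (k in seq_len(nrow(cases))) {
    d <- make_planted_dimer(cases$theta[k], cases$alpha[k], cases$rcc[k])
    lab <- classify_frame(d, TOPO, thr)
    expect_equal(as.character(lab$geometry_class), as.character(cases$class[k]),
                 info = sprintf("theta=%g alpha=%g rcc=%g", cases$theta[k],
                                cases$alpha[k], cases$rcc[k]))
    expect_true(lab$interacting)
  }
})
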