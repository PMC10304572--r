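test_that("sum of dye-dye center distances is a plain pairwise sum", {
  # 3-4-5 right triangle of xanthene centroids
  fr <- make_dye_frame(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)),
                       list(diag(3), rot_z(30), rot_z(60)))
  st <- frame_stats(classify_frame(fr, TOPO), fr, TOPO)
  expect_equal(st$sum_rcc, 12, tolerance = 1e-9)

  # invariance under rigid motion and relabeling
  R <- rot_z(71)
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% t(R)
  fr2 <- fr
  fr2$x <- xyz[, 1] + 5; fr2$y <- xyz[, 2] - 2; fr2$z <- xyz[, 3] + 1
  st2 <- frame_stats(classify_frame(fr2, TOPO), fr2, TOPO)
  expect_equal(st2$sum_rcc, st$sum_rcc, tolerance = 1e-8)

  # compacting all centers toward their centroid strictly lowers the sum
  ctr <- colMeans(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  compact <- sweep(sweep(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)), 2, ctr), 1, 0.5, `*`)
  fr3 <- make_dye_frame(sweep(compact, 2, ctr, `+`),
                        list(diag(3), rot_z(30), rot_z(60)))
  st3 <- frame_stats(classify_frame(fr3, TOPO), fr3, TOPO)
  expect_lt(st3$sum_rcc, st$sum_rcc)
})

test_that("stacked counts decompose by geometry class", {
  # one stacked H dimer + one stacked crossed-J dimer, far apart
  h <- make_planted_dimer(0, 90, 3.6)
  cj <- make_planted_dimer(45, 90, 3.6)
  cj$x <- cj$x + 40; cj$residue_id <- cj$residue_id + 2
  fr <- dplyr::bind_rows(h, cj)
  fr$molecule_id <- dyeaggr:::assign_molecule_ids(fr$residue_name, fr$residue_id)
  labs <- classify_frame(fr, TOPO)
  st <- frame_stats(labs, fr, TOPO)
  expect_equal(st$n_interacting, 2)
  expect_equal(st$n_H, 1)
  expect_equal(st$n_crossedJ, 1)
  expect_equal(st$n_J, 0)
  expect_equal(st$n_stacked, st$n_H + st$n_J + st$n_crossedJ)

  disp <- make_dispersed_frame(synthetic_config(seed = 31, n_steps = 0))
  std <- frame_stats(classify_frame(disp, TOPO), disp, TOPO)
  expect_equal(std$n_interacting, 0)
  expect_equal(std$n_stacked, 0)
})

test_that("block averages use non-overlapping windows and flag the trailing partial", {
  const <- tibble::tibble(time = seq(0, 0.99, 0.01), value = 5)
  bl <- block_average(const, window = 0.1)
  expect_true(all(bl$value == 5))
  expect_equal(nrow(bl), 10)

  ten <- tibble::tibble(time = seq(0, 0.09, 0.01), value = 1:10)
  bl <- block_average(ten, window = 0.05)
  expect_equal(bl$value, c(3, 8))
  expect_equal(bl$time, c(0.025, 0.075))
  expect_true(bl$partial[2])   # data span 0.09 ns < 2 full windows

  one <- tibble::tibble(time = 0.3, value = 7)
  bl <- block_average(one, window = 0.1)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$value, 7)

  expect_equal(nrow(block_average(tibble::tibble(time = numeric(0),
                                                 value = numeric(0)))), 0)
})

test_that("contact clusters are transitive, exhaustive and match brute force", {
  far <- make_dye_frame(as.matrix(expand.grid(x = c(0, 25, 50, 75),
                                              y = c(0, 25, 50, 75, 100),
                                              z = 0)))
  cl <- find_clusters(far, TOPO)
  expect_equal(nrow(cl), 20)
  expect_equal(length(unique(cl$cluster)), 20)  # all singletons when dispersed
  expect_setequal(cl$molecule_id, unique(far$molecule_id))

  # chain A-B, B-C in contact -> one cluster by transitivity
  chain <- make_dye_frame(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 0, 8)))
  cl <- find_clusters(chain, TOPO, contact_cut = 4.5)
  expect_equal(length(unique(cl$cluster)), 1)

  # two planted 5-dye aggregates; verify sizes against brute-force distances
  g1 <- cbind(0, 0, seq(0, 16, 4))
  g2 <- cbind(40, 0, seq(0, 16, 4))
  fr <- make_dye_frame(rbind(g1, g2), box = c(85, 85, 85))
  cl <- find_clusters(fr, TOPO, contact_cut = 4.5)
  expect_equal(sort(as.integer(table(cl$cluster))), c(5, 5))
  bf_close <- function(i, j) {
    a <- fr[fr$molecule_id == i & fr$element != "H", c("x", "y", "z")]
    b <- fr[fr$molecule_id == j & fr$element != "H", c("x", "y", "z")]
    min(as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))]) < 4.5
  }
  same_cluster <- outer(1:10, 1:10, Vectorize(function(i, j)
    cl$cluster[cl$molecule_id == i] == cl$cluster[cl$molecule_id == j]))
  direct <- outer(1:10, 1:10, Vectorize(bf_close))
  expect_true(all(same_cluster[direct]))  # every contact pair shares a cluster
})

test_that("RDF of an ideal-gas system is flat at 1 with the correct normalization", {
  # minimal square "dye" (the RDF uses only xanthene centroids)
  sq <- tibble::tibble(
    atom_name = c("P1", "P2", "P3", "P4"), element = "C",
    x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  topo4 <- system_topology(c(SQR = "dye"),
                           xanthene_atoms = c("P1", "P2", "P3", "P4"),
                           long_axis_atoms = c("P1", "P3"),
                           stack_probe_atoms = c("P1", "P2", "P3", "P4"))
  L <- 30
  set.seed(55)
  frames <- lapply(1:80, function(f) {
    centers <- matrix(runif(3 * 25, 0, L), ncol = 3)
    rows <- lapply(1:25, function(i) {
      tibble::tibble(frame = f, time = f * 0.01, molecule_id = i,
                     residue_name = "SQR", residue_id = i,
                     atom_name = sq$atom_name, element = sq$element,
                     x = sq$x + centers[i, 1], y = sq$y + centers[i, 2],
                     z = sq$z + centers[i, 3])
    })
    dplyr::bind_rows(rows)
  })
  traj <- dyeaggr:::new_trajectory(dplyr::bind_rows(frames), rep(L, 3))
  rdf <- compute_rdf(traj, topo4, "dye_dye", r_max = 15, bin_width = 0.5,
                     tail = 1e9)
  expect_equal(attr(rdf, "n_frames_averaged"), 80)
  mid <- rdf$r > 3 & rdf$r < 15
  expect_lt(mean(abs(rdf$g[mid] - 1)), 0.1)
  # normalization: the g-weighted ideal shell integral recovers the expected
  # neighbour count inside r_max (within 5% at this sample size)
  dr <- 0.5
  n_pairs <- 25 * 24 / 2
  integral <- sum(4 * pi * rdf$r^2 * dr * rdf$g) * n_pairs / L^3
  analytic <- n_pairs * 4 / 3 * pi * 15^3 / L^3
  expect_equal(integral, analytic, tolerance = 0.05)
})

test_that("RDF puts two fixed molecules in the single occupied bin and validates inputs", {
  frames <- lapply(1:10, function(f) {
    fr <- make_dye_frame(rbind(c(10, 10, 10), c(10, 10, 15)))
    fr$frame <- f; fr$time <- f * 0.01
    fr
  })
  traj <- dyeaggr:::new_trajectory(dplyr::bind_rows(frames), rep(40, 3))
  rdf <- compute_rdf(traj, TOPO, "dye_dye", r_max = 18, bin_width = 0.2,
                     tail = 1e9)
  expect_equal(sum(rdf$g > 0), 1)
  expect_equal(rdf$r[rdf$g > 0], 5.1, tolerance = 0.11)

  no_box <- dyeaggr:::new_trajectory(dplyr::bind_rows(frames), NULL)
  expect_error(compute_rdf(no_box, TOPO, "dye_dye"), "periodic box")
  expect_error(compute_rdf(traj, TOPO, "dye_dye", r_max = 25), "half the smallest")
})
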