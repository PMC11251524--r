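test_that("superposition recovers identity and pure rotations", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  sp2 <- kabsch_superpose(x %*% t(rot90) + 5, x)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)
})

test_that("superposition matches the quaternion-grid oracle", {
  set.seed(22)
  for (i in 1:5) {
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, rmsd_oracle(a, b),
                 tolerance = 1e-3)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(kabsch_superpose(matrix(1:6, 2, 3), matrix(1:6, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSD is invariant under rigid transforms of the frame", {
  sc <- gen_toy_scaffold(14, seed = 4)
  spec <- fluctuation_spec(sc$structure, sc$region_map,
                           sigma_default = 0.5, n_frames = 4, seed = 2)
  tr <- gen_fluctuation_trajectory(spec)$trajectory
  r0 <- rmsd_series(tr)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- lapply(seq_len(4), function(f)
    frame_coords(tr, f) %*% R + matrix(c(3, -2, 8), n_atoms(sc$structure),
                                       3, byrow = TRUE))
  r1 <- rmsd_series(traj_from_frames(sc$structure, moved))
  expect_equal(r1, r0, tolerance = 1e-8)
})

test_that("single displaced atom gives RMSD d/sqrt(N) with frozen fit", {
  # symmetric construction: fit selection excludes the displaced atom and
  # is already perfectly aligned, so the fit is the identity
  n <- 10; d <- 2.5
  xyz <- rbind(cbind(cos(2 * pi * (1:(n - 1)) / (n - 1)),
                     sin(2 * pi * (1:(n - 1)) / (n - 1)), 0),
               c(0, 0, 0))
  s <- mini_structure(rep("P", n), "G", 1:n, xyz)
  frame <- xyz
  frame[n, ] <- c(0, 0, d)
  tr <- traj_from_frames(s, list(frame))
  out <- rmsd_series(tr, s, fit_selection = 1:(n - 1),
                     measure_selection = 1:n)
  # fit is identity (fit atoms unmoved): displaced atom contributes d^2/N
  expect_equal(out, d / sqrt(n), tolerance = 1e-10)
})

test_that("regional RMSD with measure = fit equals the fit residual", {
  sc <- gen_toy_scaffold(14, seed = 4)
  spec <- fluctuation_spec(sc$structure, sc$region_map,
                           sigma_default = 0.4, n_frames = 6, seed = 3)
  tr <- gen_fluctuation_trajectory(spec)$trajectory
  sel <- select_atoms(sc$structure, "region:P3", sc$region_map)
  via_series <- rmsd_series(tr, sc$structure, sel, sel)
  direct <- vapply(seq_len(6), function(f)
    kabsch_superpose(frame_coords(tr, f)[sel, ],
                     coords(sc$structure)[sel, ])$rmsd, numeric(1))
  expect_equal(via_series, direct, tolerance = 1e-10)
})

test_that("RMSF recovers isotropic noise and scales linearly", {
  sc <- gen_toy_scaffold(14, seed = 9)
  mk <- function(sig, seed) gen_fluctuation_trajectory(
    fluctuation_spec(sc$structure, sc$region_map, sigma_default = sig,
                     n_frames = 2000, seed = seed))$trajectory
  r1 <- rmsf_per_residue(mk(0.5, 31))
  expect_equal(mean(r1$rmsf), 0.5 * sqrt(3), tolerance = 0.05)
  r2 <- rmsf_per_residue(mk(1.0, 32))
  expect_equal(mean(r2$rmsf) / mean(r1$rmsf), 2, tolerance = 0.05)
  expect_error(rmsf_per_residue(const_traj(sc$structure, 1)), "single frame")
  expect_equal(max(rmsf_per_residue(const_traj(sc$structure, 5))$rmsf), 0,
               tolerance = 1e-10)
})

test_that("radius of gyration matches closed forms and invariances", {
  expect_equal(radius_of_gyration(matrix(c(5, 1, -2), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(1, 0, 0), c(-1, 0, 0))), 1)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(cube), sqrt(3), tolerance = 1e-12)
  # rotation/translation invariance; linear scaling
  set.seed(5)
  x <- matrix(rnorm(60), 20, 3)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(radius_of_gyration(x %*% R + 10), radius_of_gyration(x),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(3 * x), 3 * radius_of_gyration(x),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(x, integer(0)), "empty selection")
})

test_that("contact distances follow the atom and centroid conventions", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0),     # res1: N1, C4'
               c(3, 0, 0), c(0, 4, 0))     # res2: N3, C2
  s <- mini_structure(c("N1", "C4'", "N3", "C2"), c("G", "G", "C", "C"),
                      c(1, 1, 2, 2), xyz)
  tr <- const_traj(s, 3)
  bp <- contact_spec("basepair", 1, 2, "N1", "N3", threshold = 4)
  cs <- contact_series(tr, list(bp))
  expect_equal(unname(cs$distances[, 1]), rep(3, 3))
  expect_equal(unname(cs$fraction), 1)
  # identical base-atom sets give zero stack distance
  st <- contact_spec("stack", 1, 1, c("N1", "C4'"), c("N1", "C4'"))
  expect_equal(unname(contact_series(tr, list(st))$distances[, 1]),
               rep(0, 3))
  expect_error(contact_series(tr, list(
    contact_spec("basepair", 1, 2, "N9", "N3"))), "not found")
})

test_that("contact formed fraction equals a naive per-frame loop", {
  sc <- gen_toy_scaffold(16, seed = 6)
  spec <- fluctuation_spec(sc$structure, sc$region_map,
                           sigma_default = 1.2, n_frames = 60, seed = 13)
  tr <- gen_fluctuation_trajectory(spec)$trajectory
  at <- sc$structure$atoms
  ct <- contact_spec("basepair", 3, 10, "P", "P", threshold = 21)
  cs <- contact_series(tr, list(ct))
  i <- which(at$residue_index == 3 & at$atom_name == "P")
  j <- which(at$residue_index == 10 & at$atom_name == "P")
  naive <- mean(vapply(seq_len(60), function(f) {
    m <- frame_coords(tr, f)
    sqrt(sum((m[i, ] - m[j, ])^2)) <= 21
  }, logical(1)))
  expect_identical(unname(cs$fraction), naive)
})

test_that("hydrogen bonds form by distance and count per region", {
  # G donor N1/N2 opposite C acceptors N3/O2 at 3.0 A; one far pair
  xyz <- rbind(c(0, 0, 0), c(0, 2, 0), c(10, 0, 0),   # G: N1 N2 P
               c(3, 0, 0), c(3, 2, 0), c(14, 0, 0))   # C: N3 O2 P
  s <- mini_structure(c("N1", "N2", "P", "N3", "O2", "P"),
                      c("G", "G", "G", "C", "C", "C"),
                      c(1, 1, 1, 2, 2, 2), xyz)
  rm <- region_map(list(P2 = 1L, P3 = 2L))
  native <- list(contact_spec("hbond", 1, 2, "N1", "N3"),
                 contact_spec("hbond", 1, 2, "N2", "O2"))
  hb <- hydrogen_bonds(coords(s), s, native, rm)
  p2 <- hb[hb$region == "P2", ]
  expect_equal(p2$n_native, 2)
  expect_equal(p2$native_formed, 2)
  expect_equal(p2$scaled_native, 1)      # reference frame: all native formed
  expect_gte(p2$total_formed, 2)
  # a 4.0 A pair does not count
  far <- mini_structure(c("N1", "N3"), c("G", "C"), c(1, 2),
                        rbind(c(0, 0, 0), c(4, 0, 0)))
  hb2 <- hydrogen_bonds(coords(far), far,
                        list(contact_spec("hbond", 1, 2, "N1", "N3")),
                        region_map(list(P2 = 1L)))
  expect_equal(hb2$native_formed[hb2$region == "P2"], 0)
  # region without native bonds is flagged, not invented
  expect_true(hb[hb$region == "P3", "undefined_scale"])
})

test_that("P-P distance CDF is a step function for constant input", {
  sc <- gen_toy_scaffold(16, seed = 3)
  tr <- const_traj(sc$structure, 4)
  out <- p2p3_distance_cdf(tr, pairs = list(c(2, 9)))
  d <- out$distances[1, 1]
  expect_true(all(out$cdf[out$grid < d - 0.2, 1] == 0))
  expect_true(all(out$cdf[out$grid >= d, 1] == 1))
})

test_that("two-state P-P distances give a CDF plateau at the mixing weight", {
  # explicit construction: distances d1 in p of frames, d2 otherwise
  s <- mini_structure(rep("P", 2), "G", 1:2,
                      rbind(c(0, 0, 0), c(5, 0, 0)))
  n1 <- 30; n2 <- 70
  frames <- c(replicate(n1, rbind(c(0, 0, 0), c(5, 0, 0)),
                        simplify = FALSE),
              replicate(n2, rbind(c(0, 0, 0), c(12, 0, 0)),
                        simplify = FALSE))
  tr <- traj_from_frames(s, frames)
  out <- p2p3_distance_cdf(tr, pairs = list(c(1, 2)),
                           grid = seq(0, 15, 0.5))
  mid <- out$grid > 5.5 & out$grid < 11.5
  expect_true(all(abs(out$cdf[mid, 1] - n1 / (n1 + n2)) < 1e-12))
  # monotone from 0 to 1
  expect_true(all(diff(out$cdf[, 1]) >= 0))
  expect_equal(range(out$cdf[, 1]), c(0, 1))
  # naive oracle: CDF at grid g equals fraction of distances <= g
  naive <- vapply(out$grid, function(g) mean(out$distances[, 1] <= g),
                  numeric(1))
  expect_equal(unname(out$cdf[, 1]), naive)
})
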