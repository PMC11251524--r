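test_that("windowed MSD defaults and degenerate cases", {
  tr <- ion_track(1, matrix(0, 20, 3), dt = 125)
  msd <- windowed_msd(tr, 0, 1000)
  expect_equal(msd$lag_ps, c(125, 250, 375))
  expect_equal(msd$msd_A2, c(0, 0, 0))
  expect_error(windowed_msd(tr, 0, 200), "shorter than")
  expect_error(windowed_msd(tr, 2000, 1000), "past track end")
  expect_error(windowed_msd(tr, 0, 1000, lags = c(100)), "multiples")
})

test_that("oscillating track MSD matches pair enumeration", {
  a <- 1.7
  x <- cbind(rep(c(0, a), 10), 0, 0)
  tr <- ion_track(1, x, dt = 125)
  msd <- windowed_msd(tr, 0, 1000)
  expect_equal(msd$msd_A2, c(a^2, 0, a^2), tolerance = 1e-12)
  # closed-form fit through the origin: D = a^2 / (21 dt)
  fit <- fit_diffusion(msd)
  expect_equal(fit$D_A2_ps, a^2 / (21 * 125), tolerance = 1e-12)
  expect_equal(fit$D_um2_s, a^2 / (21 * 125) * 1e4, tolerance = 1e-12)
})

test_that("diffusion fit equals a generic weighted LS-through-origin oracle", {
  msd <- data.frame(lag_ps = c(125, 250, 375),
                    msd_A2 = c(2.2, 4.1, 6.9))
  fit <- fit_diffusion(msd)
  oracle <- unname(coef(lm(msd_A2 ~ 0 + lag_ps, msd))) / 6
  expect_equal(fit$D_A2_ps, oracle, tolerance = 1e-12)
})

test_that("windowed D recovers free Brownian diffusion", {
  spec <- ion_sim_spec(box = 300, d_free = 100, n_ions = 10,
                       n_frames = 809, dt = 125, seed = 42)
  sim <- gen_ion_tracks(spec)
  Ds <- unlist(lapply(sim$tracks, function(tr)
    diffusion_series(tr)$D_um2_s))
  expect_gte(length(Ds), 1000)
  expect_equal(median(Ds), 100, tolerance = 0.3)
  # frozen ion: every window reads zero
  frozen <- ion_track(1, matrix(5, 40, 3), dt = 125)
  expect_true(all(diffusion_series(frozen)$D_um2_s == 0))
})

test_that("hysteresis detector follows the stated state machine", {
  prof <- data.frame(t0_ps = c(0, 1000, 2000, 3000),
                     D_um2_s = c(200, 5, 5, 150), clipped = FALSE)
  class(prof) <- c("rs_diffusion_profile", "data.frame")
  tr <- ion_track(7, matrix(rep(c(1, 2, 3), each = 33), 33, 3), dt = 125)
  ev <- detect_association_events(prof, tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_ps, 1000)
  expect_equal(ev$end_ps, 3000)
  expect_equal(ev$residence_ps, 2000)
  expect_false(ev$censored)
  # never dropping below d_on: no events
  prof$D_um2_s <- c(200, 150, 300, 120)
  expect_equal(nrow(detect_association_events(prof, tr)), 0L)
  # dropping without recovery: one censored event
  prof$D_um2_s <- c(200, 5, 5, 50)
  ev2 <- detect_association_events(prof, tr)
  expect_true(ev2$censored)
  expect_error(detect_association_events(prof, tr, d_on = 100, d_off = 10),
               "d_on < d_off")
})

test_that("raising d_off cannot shorten any event", {
  set.seed(4)
  prof <- data.frame(t0_ps = seq(0, 40000, 1000),
                     D_um2_s = exp(rnorm(41, log(40), 1.5)),
                     clipped = FALSE)
  class(prof) <- c("rs_diffusion_profile", "data.frame")
  tr <- ion_track(1, matrix(rnorm(3 * 400), 400, 3), dt = 125)
  e1 <- detect_association_events(prof, tr, 10, 60)
  e2 <- detect_association_events(prof, tr, 10, 120)
  if (nrow(e1) && nrow(e2)) {
    for (k in seq_len(nrow(e1))) {
      covering <- e2[e2$start_ps <= e1$start_ps[k] &
                       e2$end_ps >= e1$end_ps[k], ]
      expect_gte(nrow(covering), 1)
    }
  }
  expect_gte(sum(e2$residence_ps), sum(e1$residence_ps))
})

test_that("site clustering uses single linkage, order-independently", {
  mk_ev <- function(xyz, id = seq_len(nrow(xyz))) {
    data.frame(ion_id = id, species = "Mg2+", start_ps = 0,
               end_ps = 1000, residence_ps = 1000,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], censored = FALSE)
  }
  near <- mk_ev(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(nrow(cluster_sites(near, 3)), 1L)
  expect_equal(cluster_sites(near, 3)$n_events, 2L)
  far <- mk_ev(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(cluster_sites(far, 3)), 2L)
  # chain A-B-C at 2 A links merges under single linkage
  chain <- mk_ev(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  expect_equal(nrow(cluster_sites(chain, 3)), 1L)
  # permuting event order leaves the site table unchanged
  perm <- chain[c(3, 1, 2), ]
  expect_equal(cluster_sites(perm, 3)[, -1],
               cluster_sites(chain, 3)[, -1])
})

test_that("bulk volume is exact without RNA and matches sphere exclusion", {
  v0 <- bulk_region_volume(NULL, box = 100, cutoff = 15)
  expect_equal(v0$volume_nm3, 1000)
  expect_equal(v0$se_nm3, 0)
  # single atom at the centre: excluded volume is a sphere
  v1 <- bulk_region_volume(matrix(50, 1, 3), box = 100, cutoff = 12,
                           n_mc = 4e4, seed = 2)
  sphere_nm3 <- (4 / 3) * pi * 12^3 / 1000
  expect_equal(v1$volume_nm3, 1000 - sphere_nm3,
               tolerance = 4 * v1$se_nm3 / (1000 - sphere_nm3))
  expect_identical(v1$volume_nm3,
                   bulk_region_volume(matrix(50, 1, 3), box = 100,
                                      cutoff = 12, n_mc = 4e4,
                                      seed = 2)$volume_nm3)
  expect_error(bulk_region_volume(NULL, box = 0), "zero box volume")
})

test_that("uniform ions in an empty box give N/(NA V) and scale linearly", {
  set.seed(31)
  mk_tracks <- function(n) lapply(seq_len(n), function(i)
    ion_track(i, matrix(runif(3 * 10, 0, 100), 10, 3), 125, "Mg2+"))
  be37 <- bulk_concentration(mk_tracks(37), box = 100)
  expect_equal(be37$conc_mM, 37 / (6.02214076e23 * 1e-21) * 1000,
               tolerance = 1e-12)
  expect_equal(be37$conc_mM, 61.44, tolerance = 0.001)
  expect_false(be37$correction_applied)
  be74 <- bulk_concentration(mk_tracks(74), box = 100)
  expect_equal(be74$conc_mM / be37$conc_mM, 2, tolerance = 1e-12)
  # no ions of a species: zero concentration handled upstream (empty set)
  be0 <- bulk_concentration(list(ion_track(1, matrix(50, 10, 3), 125,
                                           "K+")), box = 100)
  expect_equal(be0$n_total, 1)
})

test_that("bulk and shell counts conserve the species totals", {
  set.seed(32)
  sc <- gen_toy_scaffold(12, seed = 5)
  st <- sc$structure
  st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] + 30
  tr <- const_traj(st, 8)
  tracks <- c(
    lapply(1:20, function(i)
      ion_track(i, matrix(runif(24, 0, 80), 8, 3), 125, "Mg2+")),
    lapply(21:30, function(i)
      ion_track(i, matrix(runif(24, 0, 80), 8, 3), 125, "K+")))
  cnt <- ion_region_counts(tracks, tr, cutoff = 15)
  expect_true(all(cnt$bulk + cnt$shell == cnt$total))
  expect_equal(unique(cnt$total[cnt$species == "Mg2+"]), 20)
  # frame mismatch is an alignment error
  bad <- c(tracks, list(ion_track(99, matrix(0, 5, 3), 125, "K+")))
  expect_error(ion_region_counts(bad, tr), "alignment error")
})

test_that("preferential interaction coefficient handles the null and
          all-shell constructions", {
  sc <- gen_toy_scaffold(12, seed = 6)
  st <- sc$structure
  st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] + 35
  tr <- const_traj(st, 30)
  # null: ions uniform over the whole box, no attraction
  set.seed(33)
  unif <- lapply(1:50, function(i)
    ion_track(i, matrix(runif(90, 0, 90), 30, 3), 125, "K+"))
  be <- bulk_concentration(unif, tr, box = 90)
  g <- preferential_interaction_coefficient(unif, tr, be)
  se <- g$gamma_sd / sqrt(30)
  expect_lt(abs(g$gamma), 3 * max(se, 1))
  # all ions in the shell: c_bulk = 0, Gamma = N exactly
  at <- coords(st)
  shell <- lapply(1:12, function(i)
    ion_track(i, matrix(rep(at[i, ], each = 30), 30, 3) +
                matrix(rnorm(90, sd = 1), 30, 3), 125, "Mg2+"))
  be2 <- bulk_concentration(shell, tr, box = 90)
  g2 <- preferential_interaction_coefficient(shell, tr, be2)
  expect_equal(g2$gamma, 12)
  expect_equal(g2$gamma_sd, 0)
})

test_that("a constructed bulk/shell mixture recovers the shell count", {
  sc <- gen_toy_scaffold(12, seed = 7)
  st <- sc$structure
  st$atoms[, c("x", "y", "z")] <- st$atoms[, c("x", "y", "z")] + 35
  tr <- const_traj(st, 40)
  set.seed(34)
  n_b <- 40; n_s <- 8
  at <- coords(st)
  tracks <- c(
    lapply(seq_len(n_b), function(i)
      ion_track(i, matrix(runif(120, 0, 90), 40, 3), 125, "Mg2+")),
    lapply(seq_len(n_s), function(i)
      ion_track(n_b + i, matrix(rep(at[3 * i, ], each = 40), 40, 3) +
                  matrix(rnorm(120, sd = 1.5), 40, 3), 125, "Mg2+")))
  be <- bulk_concentration(tracks, tr, box = 90)
  g <- preferential_interaction_coefficient(tracks, tr, be)
  se <- g$gamma_sd / sqrt(40)
  expect_lt(abs(g$gamma - n_s), 3 * max(se, 1))
})
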