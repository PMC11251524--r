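test_that("alignment recovers applied shifts and keeps the tie rule", {
  set.seed(51)
  ref <- dnorm(1:200, 60, 4) * 100 + dnorm(1:200, 130, 4) * 60
  expect_equal(align_traces(ref, ref)$shift, 0)
  shifted <- c(rep(0, 7), ref[1:193])   # trace delayed by +7
  al <- align_traces(shifted, ref, max_shift = 20)
  expect_equal(al$shift, 7)
  expect_equal(al$aligned[20:180], ref[20:180], tolerance = 1e-10)
  expect_error(align_traces(rep(1, 50), ref[1:50]), "flat")
  # symmetric two-impulse reference: shifts -5 and +5 tie exactly; the
  # minimal-magnitude rule picks one of them deterministically
  ref2 <- rep(0, 99); ref2[c(45, 55)] <- 1
  tr2 <- rep(0, 99); tr2[50] <- 1
  tie <- align_traces(tr2, ref2, max_shift = 30)
  expect_equal(abs(tie$shift), 5)
  expect_identical(tie$shift, align_traces(tr2, ref2, max_shift = 30)$shift)
})

test_that("noiseless Gaussians integrate to amplitude * sigma * sqrt(2 pi)", {
  grid <- 1:100
  sig <- 2; A <- 100
  y <- 5 + A * exp(-(grid - 50)^2 / (2 * sig^2))
  fit <- fit_peaks(y, 50)
  expect_equal(fit$area, A * sig * sqrt(2 * pi), tolerance = 1e-6)
  expect_equal(attr(fit, "baseline"), 5, tolerance = 1e-6)
  # two peaks at 6 sigma separation recover within 1 percent
  y2 <- 5 + A * exp(-(grid - 40)^2 / 8) + 40 * exp(-(grid - 52)^2 / 8)
  fit2 <- fit_peaks(y2, c(40, 52))
  expect_equal(fit2$area, c(A, 40) * 2 * sqrt(2 * pi), tolerance = 0.01)
  # an all-zero trace yields zero areas
  fit0 <- fit_peaks(rep(0, 100), c(30, 60))
  expect_equal(fit0$area, c(0, 0), tolerance = 1e-8)
})

test_that("nucleotide assignment follows nearest-ladder with tie to lower", {
  ladder <- data.frame(peak = 1:5, center = c(10, 20, 30, 40, 50),
                       sigma = 2, amplitude = 1, area = 1,
                       converged = TRUE)
  peaks <- ladder
  out <- assign_nucleotides(peaks, ladder, "GAUCG")
  expect_equal(out$nucleotide, 1:5)
  expect_equal(out$base, c("G", "A", "U", "C", "G"))
  # midway between ladder peaks 2 and 3: lower index wins
  mid <- ladder[1, ]; mid$center <- 25
  expect_equal(assign_nucleotides(mid, ladder)$nucleotide, 2L)
  # beyond two median spacings: unassigned
  lost <- ladder[1, ]; lost$center <- 95
  expect_true(is.na(assign_nucleotides(lost, ladder)$nucleotide))
  expect_error(assign_nucleotides(peaks, ladder[0, ]), "empty ladder")
})

test_that("blank subtraction is elementwise and keeps negatives flagged", {
  rx <- c(5, 3, 1); bl <- c(5, 1, 2)
  out <- subtract_blank(rx, bl)
  expect_equal(out$values, c(0, 2, -1))
  expect_equal(out$negative, c(FALSE, FALSE, TRUE))
  expect_equal(subtract_blank(rx, rep(0, 3))$values, rx)
  sig <- c(0.3, 0.8, 1.2)
  expect_equal(subtract_blank(bl + sig, bl)$values, sig, tolerance = 1e-12)
  expect_error(subtract_blank(rx, 1:2), "differ in length")
})

test_that("normalization follows the outlier-excluding 10 percent rule", {
  # hand enumeration: nine 1.0 and one 10.0 -> the 10.0 is the outlier,
  # one remaining value is averaged, factor 1.0
  v <- c(rep(1, 9), 10)
  out <- normalize_reactivity(v)
  expect_equal(out$factor, 1.0)
  expect_equal(out$n_out, 1L)
  expect_equal(out$n_avg, 1L)
  expect_equal(out$normalized, v)
  expect_equal(out$outliers, 10L)
  # constant profiles normalize to 1
  out2 <- normalize_reactivity(rep(4.2, 12))
  expect_equal(out2$factor, 4.2)
  expect_equal(out2$normalized, rep(1, 12))
  # scale invariance
  set.seed(52)
  w <- runif(25, 0.1, 3)
  expect_equal(normalize_reactivity(5.7 * w)$normalized,
               normalize_reactivity(w)$normalized, tolerance = 1e-12)
  expect_error(normalize_reactivity(rep(1, 5)), "at least 10")
  expect_error(normalize_reactivity(rep(0, 12)), "not positive")
})

test_that("double normalization equals one pass divided by the 2nd factor", {
  set.seed(53)
  v <- rexp(30) + 0.05
  n1 <- normalize_reactivity(v)
  n2 <- normalize_reactivity(n1$normalized)
  expect_equal(n2$normalized, n1$normalized / n2$factor, tolerance = 1e-12)
})

test_that("classification respects thresholds and a binning oracle", {
  expect_equal(classify_reactivity(0), "low")
  expect_equal(classify_reactivity(0.85), "moderate")  # boundary rule
  expect_equal(classify_reactivity(0.851), "high")
  expect_equal(classify_reactivity(NA_real_), "unanalyzable")
  set.seed(54)
  v <- runif(200, 0, 2)
  cls <- classify_reactivity(v)
  # brute-force binning oracle on each rule
  expect_equal(sum(cls == "low"), sum(v < 0.4))
  expect_equal(sum(cls == "moderate"), sum(v >= 0.4 & v <= 0.85))
  expect_equal(sum(cls == "high"), sum(v > 0.85))
  expect_error(classify_reactivity(1, thresholds = c(0.9, 0.4)),
               "t_low < t_high")
})

test_that("the pipeline recovers a known reactivity profile", {
  set.seed(55)
  n <- 30
  truth <- runif(n, 0, 2)
  areas_rx <- 250 * truth + 120
  areas_bl <- rep(120, n)
  spec <- trace_spec(n, peak_sigma = 2, spacing = 12,
                     true_areas_rx = areas_rx,
                     true_areas_blank = areas_bl, baseline = 20,
                     noise_sigma = mean(areas_rx / (2 * sqrt(2 * pi))) / 50,
                     seed = 56)
  eg <- gen_electropherogram(spec)
  seqs <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
  prof <- run_shape_pipeline(eg$traces, sequence = seqs,
                             ladder_centers = spec$peak_centers)
  expect_gte(cor(prof$reactivity, truth), 0.99)
  meta <- attr(prof, "meta")
  expect_equal(meta$shift_rx, 0)
  expect_gt(meta$factor, 0)
  # deterministic under the generator seed
  prof2 <- run_shape_pipeline(gen_electropherogram(spec)$traces,
                              sequence = seqs,
                              ladder_centers = spec$peak_centers)
  expect_identical(prof$reactivity, prof2$reactivity)
})

test_that("blank identical to rx is a degenerate profile", {
  set.seed(57)
  n <- 15
  areas <- runif(n, 100, 300)
  spec <- trace_spec(n, true_areas_rx = areas, true_areas_blank = areas,
                     baseline = 10, noise_sigma = 0, seed = 58)
  eg <- gen_electropherogram(spec)
  expect_error(run_shape_pipeline(eg$traces,
                                  ladder_centers = spec$peak_centers),
               "not positive|at least 10")
})

test_that("the profile is invariant to a global gain on rx and blank", {
  set.seed(59)
  n <- 20
  truth <- runif(n, 0.1, 2)
  spec <- trace_spec(n, peak_sigma = 2, spacing = 12,
                     true_areas_rx = 300 * truth, baseline = 10,
                     noise_sigma = 1, seed = 60)
  eg <- gen_electropherogram(spec)
  p1 <- run_shape_pipeline(eg$traces, ladder_centers = spec$peak_centers)
  gained <- eg$traces
  gained$rx <- 3.7 * gained$rx
  gained$blank <- 3.7 * gained$blank
  p2 <- run_shape_pipeline(gained, ladder_centers = spec$peak_centers)
  expect_equal(p2$reactivity, p1$reactivity, tolerance = 1e-4)
})

test_that("map output and smoothing utilities behave", {
  set.seed(61)
  n <- 12
  spec <- trace_spec(n, true_areas_rx = runif(n, 100, 400), baseline = 5,
                     noise_sigma = 0.5, seed = 62)
  eg <- gen_electropherogram(spec)
  prof <- run_shape_pipeline(eg$traces,
                             sequence = paste(rep("G", n), collapse = ""),
                             ladder_centers = spec$peak_centers)
  f <- withr::local_tempfile(fileext = ".map")
  write_shape_map(prof, f)
  m <- read.delim(f, header = FALSE)
  expect_equal(nrow(m), n)
  expect_equal(m$V2[prof$class != "unanalyzable"],
               prof$reactivity[prof$class != "unanalyzable"],
               tolerance = 1e-6)
  expect_equal(smooth_profile(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  expect_error(smooth_profile(1:5, 2), "odd")
})
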