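# Processing of capillary-electrophoresis SHAPE traces: alignment,
# simultaneous multi-Gaussian peak fitting, integration, nucleotide
# assignment against the sequencing ladder, blank subtraction, outlier
# normalization and reactivity classification.

# ---- Alignment ---------------------------------------------------------

#' Align a trace channel against a reference channel
#'
#' Integer shift maximising the cross-correlation of the mean-centred
#' signals within `max_shift`; ties go to the smaller `|shift|`.  The
#' aligned channel is the input advanced by the recovered shift (edges
#' padded with the channel ends).
#'
#' @param trace numeric signal vector.
#' @param reference numeric reference signal of equal length.
#' @param max_shift maximum shift magnitude, indices.
#' @return list `aligned`, `shift`.
#' @export
align_traces <- function(trace, reference, max_shift = 50) {
  if (length(trace) != length(reference))
    stop("channels must share one grid")
  if (sd(trace) == 0 || sd(reference) == 0)
    stop("flat trace: alignment undefined")
  n <- length(trace)
  tc <- trace - mean(trace)
  rc <- reference - mean(reference)
  shifts <- -max_shift:max_shift
  score <- vapply(shifts, function(s) {
    # positive s: the trace lags the reference by s indices
    if (s >= 0) sum(tc[(1 + s):n] * rc[seq_len(n - s)])
    else sum(tc[seq_len(n + s)] * rc[(1 - s):n])
  }, numeric(1))
  best <- max(score)
  cand <- shifts[score >= best - 1e-12 * abs(best)]
  shift <- cand[which.min(abs(cand))]
  aligned <- if (shift >= 0)
    c(trace[(1 + shift):n], rep(trace[n], shift))
  else
    c(rep(trace[1], -shift), trace[seq_len(n + shift)])
  list(aligned = aligned, shift = shift)
}

# ---- Peak fitting ------------------------------------------------------

#' Detect local maxima of a trace
#'
#' Simple prominence-filtered local-maxima detector for initial peak
#' centres when no ladder is available.
#'
#' @param signal numeric trace.
#' @param min_prominence minimum height above the trace median.
#' @return integer vector of centre indices.
#' @export
detect_peaks <- function(signal, min_prominence = NULL) {
  if (is.null(min_prominence))
    min_prominence <- 0.1 * (max(signal) - median(signal))
  n <- length(signal)
  i <- which(signal[2:(n - 1)] > signal[1:(n - 2)] &
               signal[2:(n - 1)] >= signal[3:n]) + 1L
  i[signal[i] - median(signal) >= min_prominence]
}

# residuals and analytic Jacobian of baseline + sum-of-Gaussians
gauss_model <- function(par, grid, n_peaks) {
  amp <- par[seq_len(n_peaks)]
  ctr <- par[n_peaks + seq_len(n_peaks)]
  sig <- par[2 * n_peaks + seq_len(n_peaks)]
  base <- par[3 * n_peaks + 1]
  y <- rep(base, length(grid))
  for (k in seq_len(n_peaks))
    y <- y + amp[k] * exp(-(grid - ctr[k])^2 / (2 * sig[k]^2))
  y
}

gauss_jac <- function(par, grid, n_peaks) {
  amp <- par[seq_len(n_peaks)]
  ctr <- par[n_peaks + seq_len(n_peaks)]
  sig <- par[2 * n_peaks + seq_len(n_peaks)]
  J <- matrix(0, length(grid), length(par))
  for (k in seq_len(n_peaks)) {
    u <- (grid - ctr[k]) / sig[k]
    g <- exp(-u^2 / 2)
    J[, k] <- g
    J[, n_peaks + k] <- amp[k] * g * u / sig[k]
    J[, 2 * n_peaks + k] <- amp[k] * g * u^2 / sig[k]
  }
  J[, 3 * n_peaks + 1] <- 1
  J
}

#' Simultaneous multi-Gaussian peak fitting
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm()])
#' of a constant (or linear) baseline plus one Gaussian per initial
#' centre.  Parameters are bounded: sigma within `[0.05, 2]` times the
#' median centre spacing (a width below a twentieth of the spacing is
#' noise, one beyond two spacings is baseline) and centres within two
#' spacings of their initial values.  The peak area is
#' `amplitude * sigma * sqrt(2 pi)`.
#'
#' @param signal numeric trace.
#' @param init_centers initial peak centres (indices), e.g. from the
#'   ladder channel or [detect_peaks()].
#' @param grid index grid (default `seq_along(signal)`).
#' @param init_sigma initial width; default half the median spacing.
#' @param baseline_mode `"constant"` or `"linear"` (linear adds a drift
#'   term).
#' @return object of class `rs_peak_table`: data frame `peak`, `center`,
#'   `sigma`, `amplitude`, `area`, `converged`.
#' @export
fit_peaks <- function(signal, init_centers, grid = seq_along(signal),
                      init_sigma = NULL,
                      baseline_mode = c("constant", "linear")) {
  baseline_mode <- match.arg(baseline_mode)
  np <- length(init_centers)
  if (np < 1L) stop("need at least one initial centre")
  if (np > 1L) {
    spacing <- median(diff(sort(init_centers)))
    if (is.null(init_sigma)) init_sigma <- spacing / 4
    sig_lo <- 0.05 * spacing
    sig_hi <- 2 * spacing
  } else {
    # single peak: no spacing; bound sigma around the initial guess
    spacing <- diff(range(grid)) / 2
    if (is.null(init_sigma)) init_sigma <- diff(range(grid)) / 10
    sig_lo <- init_sigma / 10
    sig_hi <- init_sigma * 10
  }
  base0 <- min(signal)
  amp0 <- pmax(signal[pmin(pmax(round(init_centers), 1), length(signal))] -
                 base0, 1e-3 * max(abs(signal - base0), 1))
  par0 <- c(amp0, init_centers, rep(init_sigma, np), base0)
  lower <- c(rep(0, np), init_centers - 2 * spacing,
             rep(sig_lo, np), -Inf)
  upper <- c(rep(Inf, np), init_centers + 2 * spacing,
             rep(sig_hi, np), Inf)
  drift <- baseline_mode == "linear"
  if (drift) {
    par0 <- c(par0, 0)
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }
  gmid <- mean(grid)
  resid_fn <- function(p) {
    y <- gauss_model(p[seq_len(3 * np + 1)], grid, np)
    if (drift) y <- y + p[3 * np + 2] * (grid - gmid)
    y - signal
  }
  jac_fn <- function(p) {
    J <- gauss_jac(p[seq_len(3 * np + 1)], grid, np)
    if (drift) J <- cbind(J, grid - gmid)
    J
  }
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info %in% c(0, 5, 9)) {
    if (inherits(fit, "try-error")) {
      warning("peak fit failed to run; returning initial parameters")
      p <- par0
    } else {
      warning("peak fit did not converge; parameters retained as-is")
      p <- fit$par
    }
    converged <- FALSE
  } else {
    p <- fit$par
    converged <- TRUE
  }
  amp <- p[seq_len(np)]
  ctr <- p[np + seq_len(np)]
  sig <- p[2 * np + seq_len(np)]
  ord <- order(ctr)
  out <- data.frame(peak = seq_len(np), center = ctr[ord],
                    sigma = sig[ord], amplitude = amp[ord],
                    area = amp[ord] * sig[ord] * sqrt(2 * pi),
                    converged = converged)
  attr(out, "baseline") <- p[3 * np + 1]
  attr(out, "drift") <- if (drift) p[3 * np + 2] else 0
  class(out) <- c("rs_peak_table", "data.frame")
  out
}

# ---- Nucleotide assignment ---------------------------------------------

#' Assign fitted peaks to nucleotides via the sequencing ladder
#'
#' Each peak takes the nucleotide index of the nearest ladder peak by
#' centre distance; when two ladder peaks are equidistant the lower index
#' wins, and peaks farther than two median ladder spacings from any
#' ladder peak stay unassigned.
#'
#' @param peaks an [fit_peaks()] table for the rx or blank channel.
#' @param ladder an [fit_peaks()] table for the ladder channel, ordered
#'   along the sequence (ladder peak i marks nucleotide i).
#' @param sequence optional nucleotide sequence; used to annotate bases.
#' @return `peaks` with columns `nucleotide` (integer or NA) and `base`.
#' @export
assign_nucleotides <- function(peaks, ladder, sequence = NULL) {
  if (!nrow(ladder)) stop("empty ladder: cannot assign nucleotides")
  lc <- ladder$center
  spacing <- if (length(lc) > 1L) median(diff(sort(lc))) else Inf
  nuc <- vapply(peaks$center, function(x) {
    d <- abs(lc - x)
    j <- which(d <= min(d) + 1e-9)[1]      # tie -> lower index
    if (min(d) > 2 * spacing) NA_integer_ else j
  }, integer(1))
  peaks$nucleotide <- nuc
  peaks$base <- if (!is.null(sequence)) {
    s <- strsplit(sequence, "")[[1]]
    ifelse(is.na(nuc) | nuc > length(s), NA_character_, s[nuc])
  } else NA_character_
  peaks
}

# ---- Subtraction, normalization, classification ------------------------

#' Subtract blank areas from reagent-treated areas
#'
#' Elementwise `rx - blank`; negative results are retained (not floored)
#' and flagged.
#'
#' @param rx,blank equal-length per-nucleotide area vectors.
#' @return list `values`, `negative` (logical flags).
#' @export
subtract_blank <- function(rx, blank) {
  if (length(rx) != length(blank))
    stop("rx and blank vectors differ in length")
  v <- rx - blank
  list(values = v, negative = v < 0)
}

#' Outlier-excluding 10 percent normalization of SHAPE areas
#'
#' The highest 10 percent of the values are considered outliers and
#' temporarily excluded; of the remaining values the top 10 percent are
#' averaged to give the normalization factor; the entire profile,
#' including the excluded outliers, is divided by that factor.  Both 10
#' percent counts use the ceiling (`n_out = ceiling(0.1 n)`,
#' `n_avg = ceiling(0.1 (n - n_out))`).  `NA` and flagged (e.g.
#' negative-after-subtraction) values are excluded from the factor
#' computation but still divided.
#'
#' @param areas per-nucleotide area vector (>= 10 analyzable values).
#' @param exclude logical mask of values to keep out of the factor
#'   computation.
#' @return list `normalized`, `factor`, `n_out`, `n_avg`, `outliers`
#'   (indices excluded as outliers).
#' @export
normalize_reactivity <- function(areas, exclude = NULL) {
  if (is.null(exclude)) exclude <- rep(FALSE, length(areas))
  usable <- which(!is.na(areas) & !exclude)
  n <- length(usable)
  if (n < 10L)
    stop("need at least 10 analyzable values to normalize (got ", n, ")")
  ord <- usable[order(areas[usable], decreasing = TRUE)]
  n_out <- ceiling(0.1 * n)
  outliers <- ord[seq_len(n_out)]
  remaining <- ord[-seq_len(n_out)]
  n_avg <- ceiling(0.1 * (n - n_out))
  factor <- mean(areas[remaining[seq_len(n_avg)]])
  if (!is.finite(factor) || factor <= 0)
    stop("degenerate profile: normalization factor not positive")
  list(normalized = areas / factor, factor = factor, n_out = n_out,
       n_avg = n_avg, outliers = sort(outliers))
}

#' Classify normalized SHAPE reactivities
#'
#' `value < t_low` is low, up to and including `t_high` moderate, above
#' `t_high` high; missing or flagged values are unanalyzable.
#'
#' @param values normalized reactivities.
#' @param thresholds `c(t_low, t_high)` with `t_low < t_high`
#'   (defaults 0.4, 0.85).
#' @param unanalyzable logical mask of unanalyzable positions.
#' @return character vector of classes.
#' @export
classify_reactivity <- function(values, thresholds = c(0.4, 0.85),
                                unanalyzable = NULL) {
  if (thresholds[1] >= thresholds[2]) stop("need t_low < t_high")
  if (is.null(unanalyzable)) unanalyzable <- rep(FALSE, length(values))
  cls <- ifelse(values < thresholds[1], "low",
                ifelse(values <= thresholds[2], "moderate", "high"))
  cls[is.na(values) | unanalyzable] <- "unanalyzable"
  cls
}

# ---- End-to-end pipeline -----------------------------------------------

#' SHAPE electropherogram processing pipeline
#'
#' Align the rx and blank channels to the ladder, fit the ladder and then
#' the rx/blank peaks (initialised at the aligned ladder centres),
#' integrate, assign nucleotides, subtract the blank, normalize by the
#' outlier-excluding 10 percent rule and classify.  Full provenance
#' (shifts, factor, flags) is kept in the result.
#'
#' @param traces an `rs_electropherogram` (channels `rx`, `blank`,
#'   `ladder` on one grid; see [gen_electropherogram()]).
#' @param sequence nucleotide sequence (one letter per ladder peak), or
#'   NULL.
#' @param max_shift alignment search range, indices.
#' @param thresholds classification thresholds, see
#'   [classify_reactivity()].
#' @param ladder_centers optional known ladder peak centres; detected
#'   from the ladder channel when NULL.
#' @return object of class `rs_reactivity_profile`: data frame
#'   `nucleotide`, `base`, `area_rx`, `area_blank`, `subtracted`,
#'   `reactivity`, `class`, with provenance in attribute `meta`.
#' @export
run_shape_pipeline <- function(traces, sequence = NULL, max_shift = 50,
                               thresholds = c(0.4, 0.85),
                               ladder_centers = NULL) {
  stopifnot(all(c("rx", "blank", "ladder") %in% names(traces)))
  grid <- traces$index
  al_rx <- align_traces(traces$rx, traces$ladder, max_shift)
  al_bl <- align_traces(traces$blank, traces$ladder, max_shift)
  if (is.null(ladder_centers))
    ladder_centers <- grid[detect_peaks(traces$ladder)]
  if (!length(ladder_centers)) stop("stage ladder: no ladder peaks found")
  ladder <- fit_peaks(traces$ladder, ladder_centers, grid)
  fit_rx <- fit_peaks(al_rx$aligned, ladder$center, grid)
  fit_bl <- fit_peaks(al_bl$aligned, ladder$center, grid)
  fit_rx <- assign_nucleotides(fit_rx, ladder, sequence)
  fit_bl <- assign_nucleotides(fit_bl, ladder, sequence)

  n_nuc <- nrow(ladder)
  area_rx <- area_bl <- rep(NA_real_, n_nuc)
  a_rx <- tapply(fit_rx$area, fit_rx$nucleotide, sum)
  a_bl <- tapply(fit_bl$area, fit_bl$nucleotide, sum)
  area_rx[as.integer(names(a_rx))] <- a_rx
  area_bl[as.integer(names(a_bl))] <- a_bl

  sub <- subtract_blank(area_rx, area_bl)
  norm <- normalize_reactivity(sub$values, exclude = sub$negative)
  cls <- classify_reactivity(norm$normalized, thresholds,
                             unanalyzable = sub$negative)
  base <- if (!is.null(sequence)) {
    s <- strsplit(sequence, "")[[1]]
    ifelse(seq_len(n_nuc) > length(s), NA_character_,
           s[seq_len(n_nuc)])
  } else rep(NA_character_, n_nuc)
  out <- data.frame(nucleotide = seq_len(n_nuc), base = base,
                    area_rx = area_rx, area_blank = area_bl,
                    subtracted = sub$values, reactivity = norm$normalized,
                    class = cls)
  attr(out, "meta") <- list(shift_rx = al_rx$shift, shift_bl = al_bl$shift,
                            factor = norm$factor, n_out = norm$n_out,
                            n_avg = norm$n_avg, outliers = norm$outliers,
                            negative_flags = which(sub$negative),
                            converged = c(ladder = ladder$converged[1],
                                          rx = fit_rx$converged[1],
                                          blank = fit_bl$converged[1]))
  class(out) <- c("rs_reactivity_profile", "data.frame")
  out
}

#' @export
print.rs_reactivity_profile <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("riboscape SHAPE reactivity profile:", nrow(x), "nucleotides,",
      sprintf("normalization factor %.3f;", meta$factor),
      "classes:", paste(names(table(x$class)), table(x$class),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Moving-average smoothing of a reactivity profile
#'
#' Optional utility; the pipeline output itself is unsmoothed.
#'
#' @param values numeric vector.
#' @param k odd window size.
#' @return smoothed vector (edges use the available window).
#' @export
smooth_profile <- function(values, k = 3) {
  if (k %% 2 != 1) stop("k must be odd")
  h <- (k - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i)
    mean(values[max(1, i - h):min(n, i + h)], na.rm = TRUE), numeric(1))
}

#' Write a reactivity profile in SHAPE .map format
#'
#' Tab-separated `nucleotide  reactivity  error  base`; unanalyzable
#' positions get reactivity -999 by .map convention.
#'
#' @param profile an [run_shape_pipeline()] result.
#' @param path output file.
#' @param error per-nucleotide errors (default 0).
#' @return `path`, invisibly.
#' @export
write_shape_map <- function(profile, path, error = 0) {
  v <- profile$reactivity
  v[profile$class == "unanalyzable" | is.na(v)] <- -999
  err <- rep(error, length.out = nrow(profile))
  base <- ifelse(is.na(profile$base), "N", profile$base)
  writeLines(sprintf("%d\t%.6f\t%.6f\t%s", profile$nucleotide, v, err,
                     base), path)
  invisible(path)
}
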