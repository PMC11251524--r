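# Ion-atmosphere analytics: windowed mean-squared displacement and
# diffusion coefficients (<x^2> = 6 D t fit through the origin),
# hysteresis detection of association events and residence times,
# single-linkage site clustering, Monte-Carlo bulk-region volume, bulk
# concentrations, and preferential interaction coefficients.

AVOGADRO <- 6.02214076e23

#' Windowed mean-squared displacement of an ion
#'
#' For a window starting at `t0`, MSD(tau) is the mean of
#' `|r(t + tau) - r(t)|^2` over all ordered frame pairs with both ends
#' inside `[t0, t0 + window]`.  Default lags are 1, 2 and 3 frame
#' spacings.
#'
#' @param track an [ion_track()].
#' @param t0 window start time, ps.
#' @param window window length, ps (default 1000, i.e. 1 ns).
#' @param lags lag times, ps; must be multiples of the track `dt`.
#' @return data frame `lag_ps`, `msd_A2`, `n_pairs`.
#' @export
windowed_msd <- function(track, t0 = 0, window = 1000, lags = NULL) {
  dt <- track$dt
  if (is.null(lags)) lags <- c(1, 2, 3) * dt
  kl <- lags / dt
  if (any(abs(kl - round(kl)) > 1e-6))
    stop("lags must be multiples of dt (", dt, " ps)")
  kl <- as.integer(round(kl))
  if (window < max(lags)) stop("window shorter than the largest lag")
  tmax <- track$times[length(track$times)]
  if (t0 + window > tmax + 1e-9)
    stop("window [", t0, ", ", t0 + window, "] ps extends past track end")
  idx <- which(track$times >= t0 - 1e-9 & track$times <= t0 + window + 1e-9)
  x <- track$coords[idx, , drop = FALSE]
  out <- lapply(kl, function(k) {
    n <- nrow(x) - k
    if (n < 2L)
      stop("fewer than 2 pairs at lag ", k * dt, " ps (window error)")
    d <- x[(k + 1):nrow(x), , drop = FALSE] - x[seq_len(n), , drop = FALSE]
    data.frame(lag_ps = k * dt, msd_A2 = mean(rowSums(d^2)), n_pairs = n)
  })
  do.call(rbind, out)
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares line through the origin on the (lag, MSD) points,
#' following <x^2> = 6 D t:  D = sum(tau * MSD) / (6 * sum(tau^2)).
#' Negative fits (finite-sample artifacts) are clipped to 0 and flagged.
#'
#' @param msd data frame from [windowed_msd()].
#' @return list `D_um2_s`, `D_A2_ps`, `clipped`.
#' @export
fit_diffusion <- function(msd) {
  d_a2ps <- sum(msd$lag_ps * msd$msd_A2) / (6 * sum(msd$lag_ps^2))
  clipped <- d_a2ps < 0
  if (clipped) d_a2ps <- 0
  list(D_um2_s = A2ps_to_um2s(d_a2ps), D_A2_ps = d_a2ps, clipped = clipped)
}

#' Windowed diffusion-coefficient series for an ion
#'
#' @param track an [ion_track()].
#' @param window window length, ps (default 1000).
#' @param stride window start spacing, ps; default one window
#'   (non-overlapping).
#' @param lags lag times, ps (default 1, 2, 3 frame spacings).
#' @return object of class `rs_diffusion_profile`: data frame `t0_ps`,
#'   `D_um2_s`, `clipped` with attributes `window`, `stride`, `ion_id`,
#'   `species`, `dt`.
#' @export
diffusion_series <- function(track, window = 1000, stride = window,
                             lags = NULL) {
  tmax <- track$times[length(track$times)]
  if (tmax < window) stop("track shorter than one window")
  t0s <- seq(0, tmax - window, by = stride)
  rows <- lapply(t0s, function(t0) {
    fit <- fit_diffusion(windowed_msd(track, t0, window, lags))
    data.frame(t0_ps = t0, D_um2_s = fit$D_um2_s, clipped = fit$clipped)
  })
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "stride") <- stride
  attr(out, "ion_id") <- track$ion_id
  attr(out, "species") <- track$species
  attr(out, "dt") <- track$dt
  class(out) <- c("rs_diffusion_profile", "data.frame")
  out
}

#' Detect ion association events by diffusion hysteresis
#'
#' A hysteresis state machine over the windowed diffusion series: an
#' event opens at the first window whose D drops below `d_on` and closes
#' at the first subsequent window whose D rises above `d_off`
#' (`d_on < d_off`; defaults 10 and 100 um^2/s).  The residence time is
#' the difference of the two window start times; the association site is
#' the mean ion coordinate over the event's frames.  An event still open
#' at the end of the series is censored.
#'
#' @param profile an [diffusion_series()] result.
#' @param track the matching [ion_track()].
#' @param d_on,d_off association/dissociation thresholds, um^2/s.
#' @return data frame `ion_id`, `species`, `start_ps`, `end_ps`,
#'   `residence_ps`, `x`, `y`, `z`, `censored`.
#' @export
detect_association_events <- function(profile, track, d_on = 10,
                                      d_off = 100) {
  if (d_on >= d_off) stop("need d_on < d_off")
  open_t <- NA_real_
  ev <- list()
  close_event <- function(t_end, censored) {
    sel <- track$times >= open_t - 1e-9 & track$times <= t_end + 1e-9
    cm <- colMeans(track$coords[sel, , drop = FALSE])
    data.frame(ion_id = track$ion_id, species = track$species,
               start_ps = open_t, end_ps = t_end,
               residence_ps = t_end - open_t,
               x = cm[1], y = cm[2], z = cm[3], censored = censored)
  }
  for (k in seq_len(nrow(profile))) {
    D <- profile$D_um2_s[k]
    if (is.na(open_t) && D < d_on) open_t <- profile$t0_ps[k]
    else if (!is.na(open_t) && D > d_off) {
      ev[[length(ev) + 1L]] <- close_event(profile$t0_ps[k], FALSE)
      open_t <- NA_real_
    }
  }
  if (!is.na(open_t))
    ev[[length(ev) + 1L]] <- close_event(profile$t0_ps[nrow(profile)], TRUE)
  if (!length(ev))
    return(data.frame(ion_id = integer(), species = character(),
                      start_ps = numeric(), end_ps = numeric(),
                      residence_ps = numeric(), x = numeric(),
                      y = numeric(), z = numeric(), censored = logical()))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Cluster association events into sites
#'
#' Single-linkage clustering of event mean coordinates at `link_radius`;
#' the result is independent of the input order (sites are labelled by
#' their centre coordinates).
#'
#' @param events event table (see [detect_association_events()]).
#' @param link_radius linkage distance, angstrom (default 3).
#' @return data frame per site: `site`, `x`, `y`, `z`, `n_events`,
#'   `total_residence_ps`, `mean_residence_ps`, `species`.
#' @export
cluster_sites <- function(events, link_radius = 3) {
  if (link_radius <= 0) stop("link_radius must be > 0")
  n <- nrow(events)
  if (n == 0L)
    return(data.frame(site = integer(), x = numeric(), y = numeric(),
                      z = numeric(), n_events = integer(),
                      total_residence_ps = numeric(),
                      mean_residence_ps = numeric(), species = character()))
  cl <- if (n == 1L) 1L else {
    hc <- hclust(dist(events[, c("x", "y", "z")]), method = "single")
    cutree(hc, h = link_radius)
  }
  out <- lapply(sort(unique(cl)), function(g) {
    e <- events[cl == g, , drop = FALSE]
    data.frame(x = mean(e$x), y = mean(e$y), z = mean(e$z),
               n_events = nrow(e),
               total_residence_ps = sum(e$residence_ps),
               mean_residence_ps = mean(e$residence_ps),
               species = paste(sort(unique(e$species)), collapse = "+"))
  })
  out <- do.call(rbind, out)
  # order-independent site labels: sort by centre coordinates
  out <- out[order(out$x, out$y, out$z), ]
  out <- cbind(site = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# ---- Bulk region and concentrations ------------------------------------

min_dist_to_atoms <- function(points, atoms) {
  # points n x 3, atoms a x 3 -> per-point min distance
  n <- nrow(points)
  dmin <- rep(Inf, n)
  for (chunk in split(seq_len(nrow(atoms)),
                      ceiling(seq_len(nrow(atoms)) / 256))) {
    a <- atoms[chunk, , drop = FALSE]
    d2 <- outer(rowSums(points^2), rep(1, nrow(a))) +
      outer(rep(1, n), rowSums(a^2)) - 2 * points %*% t(a)
    dmin <- pmin(dmin, sqrt(pmax(apply(d2, 1, min), 0)))
  }
  dmin
}

#' Monte-Carlo volume of the bulk region
#'
#' The bulk region is the part of the box at least `cutoff` (default
#' 15 A) away from every RNA atom.  Its volume is the box volume times
#' the fraction of uniform sample points beyond the cutoff, with a
#' binomial standard error.
#'
#' @param rna_coords `A x 3` RNA atom coordinates (angstrom), or NULL for
#'   an empty box (exact result).
#' @param box length-3 box edges, angstrom.
#' @param cutoff bulk distance cutoff, angstrom.
#' @param n_mc number of Monte-Carlo points (>= 1e4).
#' @param seed RNG seed.
#' @return list `volume_nm3`, `se_nm3`, `fraction`.
#' @export
bulk_region_volume <- function(rna_coords, box, cutoff = 15, n_mc = 1e4,
                               seed = 1) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3)
  vbox <- prod(box)
  if (vbox <= 0) stop("zero box volume")
  if (is.null(rna_coords) || !nrow(as.matrix(rna_coords)))
    return(list(volume_nm3 = vbox / 1000, se_nm3 = 0, fraction = 1))
  rna_coords <- as.matrix(rna_coords)
  with_seed(seed, {
    pts <- cbind(runif(n_mc, 0, box[1]), runif(n_mc, 0, box[2]),
                 runif(n_mc, 0, box[3]))
    frac <- mean(min_dist_to_atoms(pts, rna_coords) > cutoff)
    se <- sqrt(frac * (1 - frac) / n_mc)
    list(volume_nm3 = frac * vbox / 1000, se_nm3 = se * vbox / 1000,
         fraction = frac)
  })
}

#' Per-frame bulk/shell ion bookkeeping
#'
#' Counts, for every species and frame, the ions beyond (`bulk`) and
#' within (`shell`) `cutoff` of the RNA.  The two always sum to the
#' species total.
#'
#' @param tracks list of [ion_track()] with equal frame counts.
#' @param traj RNA [rs_trajectory()] time-aligned with the tracks, or
#'   NULL for an empty box (all ions bulk).
#' @param cutoff shell distance cutoff, angstrom.
#' @return data frame `frame`, `species`, `bulk`, `shell`, `total`.
#' @export
ion_region_counts <- function(tracks, traj = NULL, cutoff = 15) {
  nf <- nrow(tracks[[1]]$coords)
  for (tr in tracks)
    if (nrow(tr$coords) != nf)
      stop("tracks have mismatched frame counts (alignment error)")
  if (!is.null(traj) && n_frames(traj) != nf)
    stop("trajectory and tracks have mismatched frame counts (alignment error)")
  species <- vapply(tracks, `[[`, "", "species")
  out <- list()
  for (f in seq_len(nf)) {
    pos <- t(vapply(tracks, function(tr) tr$coords[f, ], numeric(3)))
    in_bulk <- if (is.null(traj)) rep(TRUE, nrow(pos)) else
      min_dist_to_atoms(pos, frame_coords(traj, f)) > cutoff
    for (sp in unique(species)) {
      sel <- species == sp
      out[[length(out) + 1L]] <- data.frame(
        frame = f, species = sp, bulk = sum(in_bulk[sel]),
        shell = sum(!in_bulk[sel]), total = sum(sel))
    }
  }
  do.call(rbind, out)
}

#' Bulk ion concentration
#'
#' Ions beyond `cutoff` from every RNA atom are counted per frame; the
#' concentration is the mean count over the Monte-Carlo bulk volume, with
#' the standard deviation over frames.  A registered correction function
#' (for ion--ion interaction effects) is applied to the raw
#' concentration; the default is the identity and is flagged as such.
#'
#' @param tracks list of [ion_track()].
#' @param traj RNA [rs_trajectory()] or NULL (empty box).
#' @param box length-3 box edges, angstrom (default: the trajectory
#'   structure's box).
#' @param cutoff bulk cutoff, angstrom (default 15).
#' @param n_mc Monte-Carlo points for the bulk volume.
#' @param seed RNG seed for the volume estimate.
#' @param correction NULL, or `function(conc_mM, species)` returning the
#'   corrected concentration.
#' @return object of class `rs_bulk_estimate`: data frame `species`,
#'   `n_total`, `bulk_mean`, `volume_nm3`, `conc_mM`, `conc_sd_mM`,
#'   `correction_applied`, with per-frame counts in attribute `counts`.
#' @export
bulk_concentration <- function(tracks, traj = NULL, box = NULL,
                               cutoff = 15, n_mc = 2e4, seed = 1,
                               correction = NULL) {
  if (is.null(box)) {
    if (!is.null(traj) && !is.null(traj$structure$box))
      box <- traj$structure$box
    else stop("box required when the trajectory carries none")
  }
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3)
  counts <- ion_region_counts(tracks, traj, cutoff)
  rna <- if (is.null(traj)) NULL else frame_coords(traj, 1)
  vol <- bulk_region_volume(rna, box, cutoff, n_mc, seed)
  v_litre <- vol$volume_nm3 * 1e-24
  out <- lapply(unique(counts$species), function(sp) {
    cs <- counts[counts$species == sp, ]
    conc <- cs$bulk / (AVOGADRO * v_litre) * 1000   # mM
    raw <- mean(conc)
    corrected <- if (is.null(correction)) raw else correction(raw, sp)
    data.frame(species = sp, n_total = cs$total[1],
               bulk_mean = mean(cs$bulk), volume_nm3 = vol$volume_nm3,
               conc_mM = corrected, conc_sd_mM = sd(conc),
               correction_applied = !is.null(correction))
  })
  out <- do.call(rbind, out)
  attr(out, "counts") <- counts
  attr(out, "cutoff") <- cutoff
  attr(out, "box") <- box
  class(out) <- c("rs_bulk_estimate", "data.frame")
  out
}

#' Preferential interaction coefficient
#'
#' Gamma = N_total - c_bulk * V_ref per frame, averaged over frames: the
#' excess number of ions relative to what the bulk concentration would
#' place in the reference volume.  `V_ref` is the full box volume
#' (default) or the box minus the RNA-excluded volume (Monte-Carlo volume
#' within `excluded_cutoff` of any RNA atom).
#'
#' @param tracks list of [ion_track()].
#' @param traj RNA [rs_trajectory()] or NULL.
#' @param bulk an [bulk_concentration()] result for the same system.
#' @param v_ref_mode `"box"` or `"box_minus_excluded"`.
#' @param excluded_cutoff excluded-volume distance, angstrom.
#' @param n_mc,seed Monte-Carlo controls for the excluded volume.
#' @return data frame `species`, `gamma`, `gamma_sd`, `v_ref_mode`,
#'   `v_ref_nm3`.
#' @export
preferential_interaction_coefficient <- function(tracks, traj, bulk,
    v_ref_mode = c("box", "box_minus_excluded"), excluded_cutoff = 3.5,
    n_mc = 2e4, seed = 1) {
  v_ref_mode <- match.arg(v_ref_mode)
  counts <- attr(bulk, "counts")
  box <- attr(bulk, "box")
  vbox_nm3 <- prod(box) / 1000
  v_ref_nm3 <- vbox_nm3
  if (v_ref_mode == "box_minus_excluded" && !is.null(traj)) {
    out_vol <- bulk_region_volume(frame_coords(traj, 1), box,
                                  cutoff = excluded_cutoff,
                                  n_mc = n_mc, seed = seed)
    v_ref_nm3 <- out_vol$volume_nm3   # volume farther than excluded_cutoff
  }
  v_bulk_nm3 <- bulk$volume_nm3[1]
  out <- lapply(unique(counts$species), function(sp) {
    cs <- counts[counts$species == sp, ]
    rho <- cs$bulk / v_bulk_nm3               # per nm^3, per frame
    g <- cs$total - rho * v_ref_nm3
    data.frame(species = sp, gamma = mean(g), gamma_sd = sd(g),
               v_ref_mode = v_ref_mode, v_ref_nm3 = v_ref_nm3)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
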