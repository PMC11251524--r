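# Synthetic data with known ground truth: toy aptamer scaffolds, two-state
# fluctuation trajectories, Brownian ion tracks with trap sites, and
# multi-Gaussian electropherograms.  Every generator is deterministic under
# a fixed seed and returns the truth needed to score downstream estimators.

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# unit conversion: D in um^2/s -> A^2/ps  (1 A^2/ns = 10 um^2/s)
um2s_to_A2ps <- function(d) d * 1e-4
A2ps_to_um2s <- function(d) d * 1e4

# ---- Toy scaffold ------------------------------------------------------

#' Generate a toy aptamer scaffold with labelled regions
#'
#' Builds a deterministic helical phosphate/base trace mimicking a
#' three-helix junction fold, with residues partitioned in sequence order
#' into P1A, J12, P2 (two strands), L2, J23, P3 (two strands), L3, J31 and
#' P1B.  Every residue carries a phosphorus (`P`), a sugar carbon (`C4'`)
#' and a full set of base atoms including `N1` and `N3`, so all selection
#' queries and contact definitions used elsewhere resolve.
#'
#' @param n_residues number of residues (>= 12).
#' @param seed RNG seed (small jitter on atom positions).
#' @return list with elements `structure` ([rs_structure()]) and
#'   `region_map` ([region_map()]).
#' @export
gen_toy_scaffold <- function(n_residues, seed = 1) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 12L)
    stop("n_residues must be >= 12 to partition all regions")
  chunk_names <- c("P1A", "J12", "P2", "L2", "P2", "J23",
                   "P3", "L3", "P3", "J31", "P1B")
  # proportional chunk widths, every chunk at least one residue
  w <- c(2, 1, 2, 1.5, 2, 1, 2, 1.5, 2, 1, 2)
  sizes <- pmax(1L, floor(n_residues * w / sum(w)))
  while (sum(sizes) < n_residues) {
    i <- which.max(n_residues * w / sum(w) - sizes)
    sizes[i] <- sizes[i] + 1L
  }
  while (sum(sizes) > n_residues) {
    i <- which(sizes > 1L)[which.max(sizes[sizes > 1L])]
    sizes[i] <- sizes[i] - 1L
  }
  bounds <- cumsum(sizes)
  starts <- c(1L, head(bounds, -1) + 1L)
  regions <- list()
  for (k in seq_along(chunk_names)) {
    nm <- chunk_names[k]
    regions[[nm]] <- c(regions[[nm]], seq(starts[k], bounds[k]))
  }
  map <- region_map(regions)

  bases <- c("A", "G", "C", "U")
  pur_atoms <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  pyr_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6")
  with_seed(seed, {
    resnames <- sample(bases, n_residues, replace = TRUE)
    rows <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      # helical backbone trace: ~11 residues/turn, 2.8 A rise, 9 A radius
      th <- 2 * pi * i / 11
      p <- c(9 * cos(th), 9 * sin(th), 2.8 * i) + rnorm(3, sd = 0.05)
      sugar <- p + 4.5 * c(-sin(th), cos(th), 0) + rnorm(3, sd = 0.05)
      base_ctr <- p + 7 * c(-cos(th), -sin(th), 0.1) + rnorm(3, sd = 0.05)
      bnames <- if (resnames[i] %in% c("A", "G")) pur_atoms else pyr_atoms
      ring_th <- 2 * pi * seq_along(bnames) / length(bnames)
      base <- cbind(base_ctr[1] + 1.3 * cos(ring_th),
                    base_ctr[2] + 1.3 * sin(ring_th),
                    base_ctr[3])
      rows[[i]] <- data.frame(
        atom_name = c("P", "C4'", bnames),
        residue_name = resnames[i],
        residue_index = i,
        element = c("P", "C", substr(bnames, 1, 1)),
        x = c(p[1], sugar[1], base[, 1]),
        y = c(p[2], sugar[2], base[, 2]),
        z = c(p[3], sugar[3], base[, 3]),
        stringsAsFactors = FALSE)
    }
    st <- rs_structure(do.call(rbind, rows),
                       box = rep(max(3 * n_residues, 60), 3))
    list(structure = st, region_map = map)
  })
}

# ---- Fluctuation trajectories ------------------------------------------

#' Specify a synthetic fluctuation trajectory
#'
#' Frames are the reference structure plus a per-region state offset plus
#' isotropic per-atom Gaussian noise; the hidden state follows a Markov
#' chain switching at `switching_rate`.  This emulates the statistical
#' structure of metastable conformational states (a two-state mixture),
#' not real RNA mechanics.
#'
#' @param reference an [rs_structure()].
#' @param region_map an [region_map()] labelling the reference residues.
#' @param per_region_sigma named numeric, per-atom per-axis noise standard
#'   deviation in angstrom per region; unlisted regions get `sigma_default`.
#' @param sigma_default fallback sigma (angstrom).
#' @param n_states number of metastable states (>= 1).
#' @param state_displacements list of length `n_states`; each element a
#'   named list mapping region name to a 3-vector offset (angstrom).
#' @param switching_rate state switching rate, per nanosecond.
#' @param n_frames,dt number of frames and spacing (ps).
#' @param seed RNG seed.
#' @return object of class `rs_fluctuation_spec`.
#' @export
fluctuation_spec <- function(reference, region_map, per_region_sigma = NULL,
                             sigma_default = 0, n_states = 1,
                             state_displacements = NULL,
                             switching_rate = 0, n_frames = 100, dt = 125,
                             seed = 1) {
  sig <- unlist(per_region_sigma)
  if (any(sig < 0) || sigma_default < 0) stop("sigma must be >= 0")
  if (switching_rate < 0) stop("switching_rate must be >= 0")
  n_states <- as.integer(n_states)
  if (n_states < 1L) stop("n_states must be >= 1")
  if (is.null(state_displacements))
    state_displacements <- rep(list(list()), n_states)
  if (length(state_displacements) != n_states)
    stop("state_displacements must have one entry per state")
  if (dt <= 0) stop("dt must be > 0 (ps)")
  structure(list(reference = reference, region_map = region_map,
                 per_region_sigma = sig, sigma_default = sigma_default,
                 n_states = n_states,
                 state_displacements = state_displacements,
                 switching_rate = switching_rate,
                 n_frames = as.integer(n_frames), dt = dt, seed = seed),
            class = "rs_fluctuation_spec")
}

#' Generate a fluctuation trajectory with known hidden states
#'
#' @param spec an [fluctuation_spec()].
#' @return list with `trajectory` ([rs_trajectory()]) and `states`
#'   (integer vector of per-frame hidden states, the ground truth).
#' @export
gen_fluctuation_trajectory <- function(spec) {
  stopifnot(inherits(spec, "rs_fluctuation_spec"))
  ref <- coords(spec$reference)
  a <- nrow(ref)
  res <- spec$reference$atoms$residue_index
  reg <- resolve_region(spec$region_map, res)
  sig_atom <- spec$sigma_default +
    numeric(a)                      # per-atom sigma vector
  for (nm in names(spec$per_region_sigma))
    sig_atom[reg == nm] <- spec$per_region_sigma[[nm]]

  # per-state offset matrices (A x 3)
  offs <- lapply(spec$state_displacements, function(sd1) {
    o <- matrix(0, a, 3)
    for (nm in names(sd1))
      o[reg == nm, ] <- matrix(sd1[[nm]], sum(reg == nm), 3, byrow = TRUE)
    o
  })

  p_switch <- 1 - exp(-spec$switching_rate * spec$dt / 1000)
  with_seed(spec$seed, {
    states <- integer(spec$n_frames)
    states[1] <- 1L
    if (spec$n_states > 1L && spec$n_frames > 1L) {
      for (f in 2:spec$n_frames) {
        states[f] <- states[f - 1L]
        if (runif(1) < p_switch)
          states[f] <- sample(setdiff(seq_len(spec$n_states), states[f]), 1)
      }
    } else states[] <- 1L
    frames <- array(0, c(spec$n_frames, a, 3))
    for (f in seq_len(spec$n_frames)) {
      noise <- matrix(rnorm(3 * a, sd = rep(sig_atom, 3)), a, 3)
      frames[f, , ] <- ref + offs[[states[f]]] + noise
    }
    list(trajectory = rs_trajectory(frames, spec$dt, spec$reference),
         states = states)
  })
}

# ---- Brownian ion tracks with trap sites -------------------------------

#' Specify a Brownian ion simulation with trap sites
#'
#' Ions take overdamped Brownian steps (per-axis standard deviation
#' sqrt(2 D dt)) with `d_free` outside traps and `d_trapped` inside,
#' reflecting box walls.  A free ion entering the radius of an unoccupied
#' trap is captured (one ion per trap); trapped motion is confined to the
#' trap sphere and escape is a Poisson process with mean dwell
#' `1/escape_rate`.  On escape the ion detaches to `escape_jump` trap
#' radii from the centre.
#'
#' @param box length-3 box edges, angstrom.
#' @param d_free,d_trapped diffusion coefficients, um^2/s
#'   (`d_free > d_trapped >= 0`).
#' @param trap_centers matrix `k x 3` of trap centres (angstrom), or NULL.
#' @param trap_radius trap capture radius, angstrom.
#' @param escape_rate Poisson escape rate, per nanosecond.
#' @param escape_jump detachment distance on escape, in trap radii.
#' @param n_ions,n_frames,dt ensemble size, frames and spacing (ps).
#' @param species ion species label.
#' @param seed RNG seed.
#' @return object of class `rs_ion_sim_spec`.
#' @export
ion_sim_spec <- function(box, d_free, trap_centers = NULL, trap_radius = 4,
                         d_trapped = 0, escape_rate = 0.1,
                         escape_jump = 1.5, n_ions = 10, n_frames = 100,
                         dt = 125, species = "Mg2+", seed = 1) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3)
  if (!(d_free >= d_trapped && d_trapped >= 0))
    stop("need d_free >= d_trapped >= 0 (um^2/s)")
  if (trap_radius <= 0) stop("trap_radius must be > 0")
  if (!is.null(trap_centers)) {
    trap_centers <- matrix(trap_centers, ncol = 3)
    inside <- trap_centers >= 0 & trap_centers <= matrix(box,
      nrow(trap_centers), 3, byrow = TRUE)
    if (!all(inside)) stop("trap centres must lie inside the box")
  }
  step_sd <- sqrt(2 * um2s_to_A2ps(d_free) * dt)
  if (step_sd > trap_radius)
    warning(sprintf(paste("free step sd (%.2f A) exceeds trap radius",
                          "(%.2f A); trap detection validity is reduced"),
                    step_sd, trap_radius))
  structure(list(box = box, d_free = d_free, d_trapped = d_trapped,
                 trap_centers = trap_centers, trap_radius = trap_radius,
                 escape_rate = escape_rate, escape_jump = escape_jump,
                 n_ions = as.integer(n_ions),
                 n_frames = as.integer(n_frames), dt = dt,
                 species = species, seed = seed),
            class = "rs_ion_sim_spec")
}

#' Construct an ion coordinate track
#'
#' @param ion_id integer or character ion identifier.
#' @param coords numeric `F x 3` matrix, angstrom.
#' @param dt frame spacing, ps.
#' @param species species label (`"Mg2+"`, `"K+"`, `"Cl-"`, ...).
#' @return object of class `rs_ion_track`.
#' @export
ion_track <- function(ion_id, coords, dt, species = "other") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || !all(is.finite(coords)))
    stop("coords must be a finite F x 3 matrix")
  if (dt <= 0) stop("dt must be > 0 (ps)")
  structure(list(ion_id = ion_id, species = species, coords = coords,
                 dt = dt, times = (seq_len(nrow(coords)) - 1) * dt),
            class = "rs_ion_track")
}

#' Generate Brownian ion tracks with a true association-event log
#'
#' @param spec an [ion_sim_spec()].
#' @return list with `tracks` (list of [ion_track()]) and `events`
#'   (data frame `ion_id`, `trap`, `start_ps`, `end_ps`, `residence_ps`,
#'   `censored` — the ground truth).
#' @export
gen_ion_tracks <- function(spec) {
  stopifnot(inherits(spec, "rs_ion_sim_spec"))
  nf <- spec$n_frames
  ni <- spec$n_ions
  dt <- spec$dt
  box <- spec$box
  traps <- spec$trap_centers
  nt <- if (is.null(traps)) 0L else nrow(traps)
  sd_free <- sqrt(2 * um2s_to_A2ps(spec$d_free) * dt)
  sd_trap <- sqrt(2 * um2s_to_A2ps(spec$d_trapped) * dt)
  p_esc <- 1 - exp(-spec$escape_rate * dt / 1000)

  reflect <- function(x, lim) {
    # reflecting boundaries on [0, lim], handles multiple bounces
    x <- x %% (2 * lim)
    ifelse(x > lim, 2 * lim - x, x)
  }

  with_seed(spec$seed, {
    pos <- cbind(runif(ni, 0, box[1]), runif(ni, 0, box[2]),
                 runif(ni, 0, box[3]))
    tracks <- array(NA_real_, c(nf, ni, 3))
    ion_trap <- rep(0L, ni)       # 0 = free, else trap index
    trap_busy <- rep(FALSE, nt)
    ev_open <- rep(NA_integer_, ni)
    events <- list()

    capture <- function(i, f) {
      if (nt == 0L || ion_trap[i] != 0L) return()
      d2 <- colSums((t(traps) - pos[i, ])^2)
      free_traps <- which(!trap_busy & d2 <= spec$trap_radius^2)
      if (length(free_traps)) {
        tr <- free_traps[which.min(d2[free_traps])]
        ion_trap[i] <<- tr
        trap_busy[tr] <<- TRUE
        ev_open[i] <<- f
      }
    }

    for (i in seq_len(ni)) capture(i, 1L)
    tracks[1, , ] <- pos

    for (f in 2:max(nf, 2L)) {
      if (f > nf) break
      for (i in seq_len(ni)) {
        tr <- ion_trap[i]
        if (tr != 0L) {
          if (runif(1) < p_esc) {
            # escape: log event, detach outside the capture radius
            events[[length(events) + 1L]] <- data.frame(
              ion_id = i, trap = tr,
              start_ps = (ev_open[i] - 1) * dt, end_ps = (f - 1) * dt,
              censored = FALSE)
            trap_busy[tr] <- FALSE
            ion_trap[i] <- 0L
            ev_open[i] <- NA_integer_
            u <- rnorm(3)
            u <- u / sqrt(sum(u^2))
            pos[i, ] <- reflect(traps[tr, ] +
                                  spec$escape_jump * spec$trap_radius * u,
                                box)
          } else {
            step <- rnorm(3, sd = sd_trap)
            cand <- pos[i, ] + step
            # radial reflection keeps the trapped ion inside its sphere
            dvec <- cand - traps[tr, ]
            dn <- sqrt(sum(dvec^2))
            if (dn > spec$trap_radius)
              cand <- traps[tr, ] + dvec / dn *
                max(2 * spec$trap_radius - dn, 0.01 * spec$trap_radius)
            pos[i, ] <- cand
          }
        } else {
          pos[i, ] <- reflect(pos[i, ] + rnorm(3, sd = sd_free), box)
          capture(i, f)
        }
      }
      tracks[f, , ] <- pos
    }
    for (i in seq_len(ni))
      if (ion_trap[i] != 0L)
        events[[length(events) + 1L]] <- data.frame(
          ion_id = i, trap = ion_trap[i],
          start_ps = (ev_open[i] - 1) * dt, end_ps = (nf - 1) * dt,
          censored = TRUE)
    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(ion_id = integer(), trap = integer(),
                 start_ps = numeric(), end_ps = numeric(),
                 censored = logical())
    ev$residence_ps <- ev$end_ps - ev$start_ps
    ev <- ev[order(ev$ion_id, ev$start_ps), ]
    rownames(ev) <- NULL
    track_list <- lapply(seq_len(ni), function(i)
      ion_track(i, tracks[, i, ], dt, species = spec$species))
    list(tracks = track_list, events = ev)
  })
}

# ---- Electropherograms -------------------------------------------------

#' Specify a synthetic capillary-electrophoresis trace set
#'
#' Each channel (reagent-treated `rx`, `blank`, sequencing `ladder`) is a
#' constant baseline plus a sum of Gaussian peaks plus white noise.  Peak
#' areas are the ground truth; amplitudes are `area / (sigma sqrt(2 pi))`.
#'
#' @param n_nucleotides number of nucleotide peaks.
#' @param peak_centers strictly increasing migration indices (one per
#'   nucleotide); default evenly spaced at `spacing`.
#' @param spacing default center spacing in index units.
#' @param peak_sigma Gaussian width, index units.
#' @param true_areas_rx,true_areas_blank per-nucleotide areas (>= 0).
#' @param ladder_area area of the calibration ladder peaks.
#' @param baseline constant baseline level.
#' @param noise_sigma white-noise standard deviation.
#' @param seed RNG seed.
#' @return object of class `rs_trace_spec`.
#' @export
trace_spec <- function(n_nucleotides, peak_centers = NULL, spacing = 12,
                       peak_sigma = 2, true_areas_rx,
                       true_areas_blank = NULL, ladder_area = NULL,
                       baseline = 10, noise_sigma = 0, seed = 1) {
  n <- as.integer(n_nucleotides)
  if (is.null(peak_centers))
    peak_centers <- 3 * peak_sigma + spacing * (seq_len(n) - 1) + 10
  if (length(peak_centers) != n || any(diff(peak_centers) <= 0))
    stop("peak_centers must be strictly increasing, one per nucleotide")
  if (length(true_areas_rx) == 1L) true_areas_rx <- rep(true_areas_rx, n)
  if (is.null(true_areas_blank)) true_areas_blank <- rep(0, n)
  if (length(true_areas_blank) == 1L)
    true_areas_blank <- rep(true_areas_blank, n)
  if (any(true_areas_rx < 0) || any(true_areas_blank < 0))
    stop("areas must be >= 0")
  if (any(diff(peak_centers) < 0.5 * peak_sigma))
    warning("peak centers closer than 0.5 sigma: fits may not be identifiable")
  if (is.null(ladder_area)) ladder_area <- max(median(true_areas_rx), 1)
  structure(list(n_nucleotides = n, peak_centers = peak_centers,
                 peak_sigma = peak_sigma, true_areas_rx = true_areas_rx,
                 true_areas_blank = true_areas_blank,
                 ladder_area = ladder_area, baseline = baseline,
                 noise_sigma = noise_sigma, seed = seed),
            class = "rs_trace_spec")
}

gaussian_sum <- function(grid, centers, sigmas, areas) {
  amps <- areas / (sigmas * sqrt(2 * pi))
  y <- numeric(length(grid))
  for (k in seq_along(centers))
    y <- y + amps[k] * exp(-(grid - centers[k])^2 / (2 * sigmas[k]^2))
  y
}

#' Generate a synthetic electropherogram with known peak areas
#'
#' @param spec an [trace_spec()].
#' @return list with `traces` (class `rs_electropherogram`: `index` grid
#'   plus channels `rx`, `blank`, `ladder`) and `truth` (list of the true
#'   areas and peak centers).
#' @export
gen_electropherogram <- function(spec) {
  stopifnot(inherits(spec, "rs_trace_spec"))
  grid <- seq(1, ceiling(max(spec$peak_centers) + 5 * spec$peak_sigma))
  sig <- rep(spec$peak_sigma, spec$n_nucleotides)
  with_seed(spec$seed, {
    mk <- function(areas) spec$baseline +
      gaussian_sum(grid, spec$peak_centers, sig, areas) +
      rnorm(length(grid), sd = spec$noise_sigma)
    traces <- structure(list(
      index = grid,
      rx = mk(spec$true_areas_rx),
      blank = mk(spec$true_areas_blank),
      ladder = mk(rep(spec$ladder_area, spec$n_nucleotides))),
      class = "rs_electropherogram")
    list(traces = traces,
         truth = list(areas_rx = spec$true_areas_rx,
                      areas_blank = spec$true_areas_blank,
                      centers = spec$peak_centers,
                      sigma = spec$peak_sigma,
                      baseline = spec$baseline))
  })
}

#' @export
print.rs_electropherogram <- function(x, ...) {
  cat("riboscape electropherogram:", length(x$index),
      "points, channels rx/blank/ladder\n")
  invisible(x)
}
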