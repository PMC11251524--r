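# Cartesian principal-component analysis of heavy-atom coordinates,
# free-energy surfaces on PC1-PC2 by Boltzmann inversion of the occupancy
# histogram, covariance traces, and basin counting on the gridded surface.

# frames x 3A coordinate matrix over a selection, optionally superposed
# onto the iterative mean (2 passes)
traj_matrix <- function(traj, selection, superpose = TRUE) {
  nf <- n_frames(traj)
  a <- length(selection)
  X <- matrix(NA_real_, nf, 3 * a)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)[selection, , drop = FALSE]
    X[f, ] <- as.vector(m)
  }
  if (superpose && nf > 1L) {
    ref <- matrix(X[1, ], a, 3)
    for (pass in 1:2) {
      for (f in seq_len(nf)) {
        m <- matrix(X[f, ], a, 3)
        sp <- kabsch_superpose(m, ref)
        X[f, ] <- as.vector(apply_superposition(sp, m))
      }
      ref <- matrix(colMeans(X), a, 3)
    }
  }
  X
}

#' Principal-component analysis of trajectory coordinates
#'
#' The Cartesian coordinates of the selected (heavy) atoms form the
#' variable set; their covariance matrix is calculated and diagonalised
#' to obtain the principal components.  Frames are first superposed onto
#' the iterative mean structure (two passes) unless `superpose = FALSE`.
#' Eigenvector signs follow a deterministic convention: the
#' largest-magnitude component of each eigenvector is positive.
#'
#' @param traj an [rs_trajectory()] with more than one frame.
#' @param selection atom indices (default: heavy atoms).
#' @param superpose remove rigid-body motion before the covariance.
#' @return object of class `rs_pc_model`: `mean` (3A vector), `vectors`
#'   (3A x 3A orthonormal), `values` (angstrom^2, descending), `trace_A2`,
#'   `trace_nm2`, `selection`, `superpose`.
#' @export
fit_pca <- function(traj, selection = select_atoms(traj$structure, "heavy"),
                    superpose = TRUE) {
  if (n_frames(traj) <= 1L) stop("PCA needs more than one frame")
  if (!length(selection)) stop("empty selection")
  X <- traj_matrix(traj, selection, superpose)
  if (!all(is.finite(X))) stop("non-finite coordinates")
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(mean = mu, vectors = vecs, values = vals,
                 trace_A2 = sum(diag(C)), trace_nm2 = sum(diag(C)) / 100,
                 selection = selection, superpose = superpose),
            class = "rs_pc_model")
}

#' @export
print.rs_pc_model <- function(x, ...) {
  cat("riboscape PC model:", length(x$mean) / 3, "atoms,",
      sprintf("trace %.2f A^2 (%.3f nm^2);", x$trace_A2, x$trace_nm2),
      "leading eigenvalues (A^2):",
      paste(sprintf("%.2f", head(x$values, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' Project trajectory frames onto principal components
#'
#' Centred coordinates are dotted with the first `k` eigenvectors; the
#' mean structure projects to the zero vector.
#'
#' @param traj an [rs_trajectory()] compatible with the model's selection.
#' @param model an [fit_pca()] result.
#' @param k number of components (>= 1).
#' @return `F x k` matrix of PC scores (angstrom).
#' @export
project_frames <- function(traj, model, k = 2) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(model$vectors)) stop("k exceeds available components")
  X <- traj_matrix(traj, model$selection, model$superpose)
  scores <- sweep(X, 2, model$mean) %*% model$vectors[, seq_len(k),
                                                      drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Covariance trace of a PC model
#'
#' The trace of the coordinate covariance matrix (sum of eigenvalues), a
#' scalar disorder metric, in both angstrom^2 and nm^2.
#'
#' @param model an [fit_pca()] result.
#' @return named numeric `c(A2 = ..., nm2 = ...)`.
#' @export
covariance_trace <- function(model) {
  c(A2 = model$trace_A2, nm2 = model$trace_A2 / 100)
}

#' Covariance trace per replica and pooled
#'
#' Convenience for multi-replica studies: the trace computed on each
#' replica separately and on the pooled (concatenated) frames.
#'
#' @param trajs list of [rs_trajectory()] sharing one structure.
#' @param selection atom indices.
#' @param superpose passed to [fit_pca()].
#' @return list with `per_replica` (numeric, angstrom^2), `mean_replica`
#'   and `pooled`.
#' @export
replica_trace <- function(trajs,
                          selection =
                            select_atoms(trajs[[1]]$structure, "heavy"),
                          superpose = TRUE) {
  per <- vapply(trajs, function(tr)
    fit_pca(tr, selection, superpose)$trace_A2, numeric(1))
  all_frames <- do.call(abind_frames, trajs)
  pooled <- fit_pca(all_frames, selection, superpose)$trace_A2
  list(per_replica = per, mean_replica = mean(per), pooled = pooled)
}

# concatenate trajectories sharing one structure
abind_frames <- function(...) {
  trajs <- list(...)
  frames <- do.call(rbind, lapply(trajs, function(tr) {
    d <- dim(tr$frames)
    matrix(tr$frames, d[1], d[2] * 3)
  }))
  a <- dim(trajs[[1]]$frames)[2]
  arr <- array(frames, c(nrow(frames), a, 3))
  rs_trajectory(arr, trajs[[1]]$dt, trajs[[1]]$structure)
}

# ---- Free-energy surface -----------------------------------------------

#' Free-energy surface on PC1-PC2
#'
#' Boltzmann inversion of the 2D occupancy histogram:
#' F = -ln(count / count_max) in kT units, so the global minimum is 0 and
#' empty bins are undefined (`NA`, not infinite).
#'
#' @param scores `F x 2` matrix of PC scores (see [project_frames()]).
#' @param bins number of bins per axis, or a list of two edge vectors.
#' @param temperature label for the kT scale, kelvin (does not change the
#'   surface, which is in kT units).
#' @param pad fractional range padding when `bins` is a count.
#' @return object of class `rs_fe_surface`: `edges1`, `edges2`, `counts`,
#'   `F` (kT, `NA` where empty), `prob`, `temperature`.
#' @export
free_energy_surface <- function(scores, bins = 50, temperature = 300,
                                pad = 0.05) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("scores must have two columns (PC1, PC2)")
  if (!nrow(scores)) stop("no frames")
  if (is.list(bins)) {
    e1 <- bins[[1]]; e2 <- bins[[2]]
  } else {
    r1 <- range(scores[, 1]); r2 <- range(scores[, 2])
    w1 <- max(diff(r1), 1e-8) * pad; w2 <- max(diff(r2), 1e-8) * pad
    e1 <- seq(r1[1] - w1, r1[2] + w1, length.out = bins + 1L)
    e2 <- seq(r2[1] - w2, r2[2] + w2, length.out = bins + 1L)
  }
  i1 <- findInterval(scores[, 1], e1, rightmost.closed = TRUE,
                     all.inside = TRUE)
  i2 <- findInterval(scores[, 2], e2, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, length(e1) - 1L, length(e2) - 1L)
  for (f in seq_along(i1))
    counts[i1[f], i2[f]] <- counts[i1[f], i2[f]] + 1L
  Fmat <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0L
  Fmat[occ] <- -log(counts[occ] / max(counts))
  structure(list(edges1 = e1, edges2 = e2, counts = counts, F = Fmat,
                 prob = counts / sum(counts), temperature = temperature),
            class = "rs_fe_surface")
}

#' @export
print.rs_fe_surface <- function(x, ...) {
  cat("riboscape free-energy surface:", nrow(x$counts), "x", ncol(x$counts),
      "bins,", sum(x$counts > 0), "occupied, max F",
      sprintf("%.2f kT\n", max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Export a free-energy surface as a long table
#'
#' @param surface an [free_energy_surface()] result.
#' @return data frame `pc1_bin`, `pc2_bin`, `pc1`, `pc2` (bin centres),
#'   `count`, `F_kT`.
#' @export
fes_table <- function(surface) {
  c1 <- (head(surface$edges1, -1) + tail(surface$edges1, -1)) / 2
  c2 <- (head(surface$edges2, -1) + tail(surface$edges2, -1)) / 2
  g <- expand.grid(pc1_bin = seq_along(c1), pc2_bin = seq_along(c2))
  g$pc1 <- c1[g$pc1_bin]
  g$pc2 <- c2[g$pc2_bin]
  g$count <- surface$counts[cbind(g$pc1_bin, g$pc2_bin)]
  g$F_kT <- surface$F[cbind(g$pc1_bin, g$pc2_bin)]
  g
}

# ---- Basin counting ----------------------------------------------------

# mean filter on the count histogram (empty bins included), the standard
# regularisation before Boltzmann inversion: log-space Poisson noise in
# sparse bins would otherwise read as kT-deep spurious minima
smooth_counts <- function(counts, r) {
  if (r <= 0) return(counts)
  n1 <- nrow(counts); n2 <- ncol(counts)
  out <- counts * 0
  for (i in seq_len(n1)) for (j in seq_len(n2))
    out[i, j] <- mean(counts[max(1, i - r):min(n1, i + r),
                             max(1, j - r):min(n2, j + r)])
  out
}

#' Count basins of a free-energy surface
#'
#' The count histogram is mean-filtered over a `smoothing`-bin radius
#' (empty bins included) and re-inverted to a free-energy grid; local
#' minima are then found by a persistence (watershed) sweep: occupied
#' bins are added in order of increasing free energy, and when two
#' catchments meet, the shallower minimum's depth is its persistence
#' (merge level minus minimum).  Minima with persistence below
#' `depth_cutoff` are absorbed.  Basins in disconnected occupied
#' components never merge (infinite persistence).  Ties are broken
#' lexicographically by bin index, making the count deterministic.
#'
#' @param surface an [free_energy_surface()] result.
#' @param depth_cutoff minimum basin depth (kT) relative to the saddle.
#' @param smoothing count mean-filter radius in bins (0 = none).
#' @param min_count occupancy floor on the raw counts; bins below it are
#'   treated as empty before smoothing.  Default 1 (keep all occupied
#'   bins).
#' @param min_mass minimum fraction of the total population a catchment
#'   must hold for its minimum to count as a basin (default 0.01): a
#'   "metastable state" visited by less than 1 percent of the frames is
#'   read as sampling noise, not a basin.
#' @return object of class `rs_basin_report`: `n_basins`, `basins` (data
#'   frame with bin indices, PC coordinates and minimum F) and
#'   `barrier_kT`, the barrier between the two deepest basins (saddle
#'   level minus the shallower minimum; `Inf` when disconnected, `NA`
#'   with a single basin).
#' @export
count_basins <- function(surface, depth_cutoff = 0, smoothing = 1,
                         min_count = 1, min_mass = 0.01) {
  counts <- surface$counts
  counts[counts < min_count] <- 0
  cs <- smooth_counts(counts, smoothing)
  Fmat <- matrix(NA_real_, nrow(cs), ncol(cs))
  pos <- cs > 0
  Fmat[pos] <- -log(cs[pos] / max(cs))
  occ <- which(!is.na(Fmat), arr.ind = TRUE)
  if (!nrow(occ)) stop("surface has no occupied bins")
  fv <- Fmat[occ]
  ord <- order(fv, occ[, 1], occ[, 2])
  occ <- occ[ord, , drop = FALSE]
  fv <- fv[ord]
  n1 <- nrow(Fmat)
  cellid <- function(i, j) (j - 1L) * n1 + i
  id <- cellid(occ[, 1], occ[, 2])
  pos <- integer(n1 * ncol(Fmat))   # 0 = not yet added
  parent <- seq_len(nrow(occ))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  set_min <- seq_len(nrow(occ))     # index (into occ order) of set minimum
  set_mass <- cs[cbind(occ[, 1], occ[, 2])]  # accumulated catchment mass
  mass_floor <- min_mass * sum(cs)
  surviving <- list()               # minima kept (persistence >= cutoff)
  for (k in seq_len(nrow(occ))) {
    i <- occ[k, 1]; j <- occ[k, 2]
    nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
    nb <- nb[nb[, 1] >= 1L & nb[, 1] <= n1 &
               nb[, 2] >= 1L & nb[, 2] <= ncol(Fmat), , drop = FALSE]
    nbk <- pos[cellid(nb[, 1], nb[, 2])]
    nbk <- nbk[nbk > 0L]
    roots <- unique(vapply(nbk, find, integer(1)))
    if (!length(roots)) {
      # no added neighbour: k founds a new catchment (local-min candidate)
      pos[id[k]] <- k
      next
    }
    # attach k to the catchment with the deepest minimum; merge the rest
    roots <- roots[order(set_min[roots])]
    main <- roots[1]
    parent[k] <- main
    set_mass[main] <- set_mass[main] + cs[occ[k, 1], occ[k, 2]]
    for (r in roots[-1]) {
      persist <- fv[k] - fv[set_min[r]]
      if (persist >= depth_cutoff && set_mass[r] >= mass_floor)
        surviving[[length(surviving) + 1L]] <-
          list(idx = set_min[r], persistence = persist,
               merge_level = fv[k])
      parent[r] <- main
      set_min[main] <- min(set_min[main], set_min[r])
      set_mass[main] <- set_mass[main] + set_mass[r]
    }
    pos[id[k]] <- k
  }
  roots <- unique(vapply(seq_len(nrow(occ)), find, integer(1)))
  roots <- roots[set_mass[roots] >= mass_floor]
  min_idx <- sort(unique(c(set_min[roots],
                           vapply(surviving, `[[`, integer(1), "idx"))))
  if (!length(min_idx)) min_idx <- set_min[which.max(set_mass)]
  c1 <- (head(surface$edges1, -1) + tail(surface$edges1, -1)) / 2
  c2 <- (head(surface$edges2, -1) + tail(surface$edges2, -1)) / 2
  bdf <- data.frame(bin1 = occ[min_idx, 1], bin2 = occ[min_idx, 2],
                    pc1 = c1[occ[min_idx, 1]], pc2 = c2[occ[min_idx, 2]],
                    F_kT = fv[min_idx])
  bdf <- bdf[order(bdf$F_kT, bdf$bin1, bdf$bin2), ]
  rownames(bdf) <- NULL
  barrier <- NA_real_
  if (nrow(bdf) >= 2L) {
    barrier <- basin_barrier(Fmat, bdf[1, c("bin1", "bin2")],
                             bdf[2, c("bin1", "bin2")])
    barrier <- barrier - bdf$F_kT[2]
  }
  structure(list(n_basins = nrow(bdf), basins = bdf, barrier_kT = barrier),
            class = "rs_basin_report")
}

# saddle level between two bins: minimal (over paths) maximal F along a
# 4-connected path through occupied bins; Inf when disconnected
basin_barrier <- function(Fmat, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  occ <- which(!is.na(Fmat), arr.ind = TRUE)
  fv <- Fmat[occ]
  ord <- order(fv, occ[, 1], occ[, 2])
  occ <- occ[ord, , drop = FALSE]
  fv <- fv[ord]
  n1 <- nrow(Fmat)
  id <- (occ[, 2] - 1L) * n1 + occ[, 1]
  ka <- which(occ[, 1] == a[1] & occ[, 2] == a[2])
  kb <- which(occ[, 1] == b[1] & occ[, 2] == b[2])
  pos <- integer(n1 * ncol(Fmat))
  parent <- seq_len(nrow(occ))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(occ))) {
    i <- occ[k, 1]; j <- occ[k, 2]
    nb <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
    nb <- nb[nb[, 1] >= 1L & nb[, 1] <= n1 &
               nb[, 2] >= 1L & nb[, 2] <= ncol(Fmat), , drop = FALSE]
    nbk <- pos[(nb[, 2] - 1L) * n1 + nb[, 1]]
    for (k2 in nbk[nbk > 0L])
      parent[find(k)] <- find(k2)
    pos[id[k]] <- k
    if (find(ka) == find(kb)) return(fv[k])
  }
  Inf
}

#' @export
print.rs_basin_report <- function(x, ...) {
  cat("riboscape basin report:", x$n_basins, "basin(s)")
  if (!is.na(x$barrier_kT))
    cat(sprintf(", barrier between two deepest %.2f kT", x$barrier_kT))
  cat("\n")
  invisible(x)
}
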