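# Global and regional structural fluctuation and contact metrics:
# Kabsch superposition, RMSD/RMSF/Rg series, native base-pair, stack and
# hydrogen-bond contacts, and the P2-P3 helix-distance cumulative
# distribution used to monitor riboswitch-core breathing.

# ---- Superposition -----------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `target`; reflections are excluded so chirality is preserved.
#'
#' @param mobile,target numeric `N x 3` coordinate matrices (N >= 3,
#'   non-collinear).
#' @param weights optional non-negative per-atom weights.
#' @return object of class `rs_superposition` with fields `rotation`
#'   (proper 3x3 matrix applied on the right of centred row vectors),
#'   `translation` (3-vector) and `rmsd` (angstrom, after the fit).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  if (n != nrow(target)) stop("mobile and target atom counts differ")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("bad weights")
  w <- weights / sum(weights)
  cm_m <- colSums(mobile * w)
  cm_t <- colSums(target * w)
  M <- sweep(mobile, 2, cm_m)
  T_ <- sweep(target, 2, cm_t)
  # collinear (rank < 2) point sets leave the rotation underdetermined
  sv_m <- svd(M * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1))
    stop("degenerate (collinear) geometry: superposition underdetermined")
  H <- t(M * w) %*% T_
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  fitted <- M %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - T_)^2)))
  structure(list(rotation = R, translation = cm_t,
                 center_mobile = cm_m, rmsd = rmsd),
            class = "rs_superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp an [kabsch_superpose()] result.
#' @param x numeric `N x 3` coordinates.
#' @return transformed coordinates.
#' @export
apply_superposition <- function(sp, x) {
  sweep(sweep(as.matrix(x), 2, sp$center_mobile) %*% sp$rotation,
        2, sp$translation, `+`)
}

#' @export
print.rs_superposition <- function(x, ...) {
  cat(sprintf("riboscape superposition: rmsd after fit %.4f A\n", x$rmsd))
  invisible(x)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# ---- RMSD / RMSF / Rg --------------------------------------------------

#' Per-frame RMSD against a reference
#'
#' Each frame is superposed onto the reference over `fit_selection`, then
#' the RMSD is measured over `measure_selection` without re-fitting.  This
#' reproduces the global-fit / regional-measure protocol: fit the whole
#' structure, then read off the deviation of one region.
#'
#' @param traj an [rs_trajectory()].
#' @param reference an [rs_structure()] (defaults to the trajectory's).
#' @param fit_selection,measure_selection atom index vectors (see
#'   [select_atoms()]); `measure_selection` defaults to `fit_selection`.
#' @return numeric vector of per-frame RMSD (angstrom).
#' @export
rmsd_series <- function(traj, reference = traj$structure,
                        fit_selection = seq_len(n_atoms(reference)),
                        measure_selection = fit_selection) {
  if (!length(fit_selection) || !length(measure_selection))
    stop("empty selection")
  ref <- coords(reference)
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    sp <- kabsch_superpose(m[fit_selection, , drop = FALSE],
                           ref[fit_selection, , drop = FALSE])
    rmsd_between(apply_superposition(sp, m[measure_selection, , drop = FALSE]),
                 ref[measure_selection, , drop = FALSE])
  }, numeric(1))
}

#' Per-region RMSD summary
#'
#' Global fit (over `fit_selection`, default all heavy atoms) followed by
#' per-region measurement, summarised as mean and standard deviation over
#' frames.
#'
#' @param traj an [rs_trajectory()].
#' @param region_map an [region_map()].
#' @param reference reference [rs_structure()].
#' @param fit_selection atom indices used for the global fit.
#' @return data frame with `region`, `mean_rmsd`, `sd_rmsd` (angstrom).
#' @export
regional_rmsd <- function(traj, region_map, reference = traj$structure,
                          fit_selection = select_atoms(reference, "heavy")) {
  res <- reference$atoms$residue_index
  reg <- resolve_region(region_map, res)
  out <- lapply(names(region_map$regions), function(nm) {
    sel <- which(reg == nm & toupper(reference$atoms$element) != "H")
    if (!length(sel)) return(NULL)
    r <- rmsd_series(traj, reference, fit_selection, sel)
    data.frame(region = nm, mean_rmsd = mean(r), sd_rmsd = sd(r))
  })
  do.call(rbind, out)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed over `fit_selection` (one pass onto the
#' reference, one refinement pass onto the resulting mean structure);
#' RMSF_i = sqrt(<|r_i - <r_i>|^2>) per atom, averaged over each
#' residue's heavy atoms.
#'
#' @param traj an [rs_trajectory()] with >= 2 frames.
#' @param fit_selection atom indices for the superposition.
#' @return data frame with `residue_index`, `residue_name`, `rmsf`
#'   (angstrom).
#' @export
rmsf_per_residue <- function(traj,
                             fit_selection =
                               select_atoms(traj$structure, "heavy")) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF undefined for a single frame")
  ref <- coords(traj$structure)
  a <- nrow(ref)
  aligned <- array(NA_real_, c(nf, a, 3))
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    sp <- kabsch_superpose(m[fit_selection, , drop = FALSE],
                           ref[fit_selection, , drop = FALSE])
    aligned[f, , ] <- apply_superposition(sp, m)
  }
  for (pass in 1:1) {  # refinement pass onto the mean structure
    mu <- apply(aligned, c(2, 3), mean)
    for (f in seq_len(nf)) {
      m <- aligned[f, , ]
      sp <- kabsch_superpose(m[fit_selection, , drop = FALSE],
                             mu[fit_selection, , drop = FALSE])
      aligned[f, , ] <- apply_superposition(sp, m)
    }
  }
  mu <- apply(aligned, c(2, 3), mean)
  dev2 <- matrix(0, nf, a)
  for (f in seq_len(nf))
    dev2[f, ] <- rowSums((aligned[f, , ] - mu)^2)
  rmsf_atom <- sqrt(colMeans(dev2))
  at <- traj$structure$atoms
  heavy <- toupper(at$element) != "H"
  agg <- aggregate(rmsf_atom[heavy],
                   by = list(residue_index = at$residue_index[heavy]),
                   FUN = mean)
  names(agg)[2] <- "rmsf"
  agg$residue_name <- at$residue_name[match(agg$residue_index,
                                            at$residue_index)]
  agg[, c("residue_index", "residue_name", "rmsf")]
}

#' Radius of gyration of a coordinate set
#'
#' Unweighted: Rg = sqrt(sum |r_i - r_com|^2 / N).
#'
#' @param x numeric `N x 3` coordinate matrix.
#' @param selection optional row indices.
#' @return Rg in angstrom.
#' @export
radius_of_gyration <- function(x, selection = NULL) {
  x <- as.matrix(x)
  if (!is.null(selection)) x <- x[selection, , drop = FALSE]
  if (!nrow(x)) stop("empty selection")
  com <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, com)^2)))
}

#' Per-frame radius of gyration
#'
#' @param traj an [rs_trajectory()].
#' @param selection atom indices (default all).
#' @return numeric vector, angstrom.
#' @export
rg_series <- function(traj, selection = seq_len(dim(traj$frames)[2])) {
  vapply(seq_len(n_frames(traj)),
         function(f) radius_of_gyration(frame_coords(traj, f), selection),
         numeric(1))
}

# ---- Native contacts ---------------------------------------------------

resolve_contact_indices <- function(contact, structure) {
  at <- structure$atoms
  pick <- function(res, atom) {
    if (contact$kind == "stack") {
      idx <- which(at$residue_index == res & at$atom_name %in% atom)
      if (!length(idx))
        stop("contact ", contact$label, ": no base atoms of residue ", res,
             " found")
    } else {
      idx <- which(at$residue_index == res & at$atom_name == atom)
      if (!length(idx))
        stop("contact ", contact$label, ": atom ", atom, " of residue ",
             res, " not found")
    }
    idx
  }
  list(a = pick(contact$residue_a, contact$atom_a),
       b = pick(contact$residue_b, contact$atom_b))
}

contact_distance <- function(m, idx) {
  ca <- colMeans(m[idx$a, , drop = FALSE])
  cb <- colMeans(m[idx$b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Track native contacts along a trajectory
#'
#' Base-pair and hydrogen-bond distances are atom--atom Euclidean
#' distances; stack distances are between the unweighted centroids of the
#' two base-atom sets.  A contact is formed when its distance is at or
#' below its threshold.
#'
#' @param traj an [rs_trajectory()].
#' @param contacts list of [contact_spec()] objects.
#' @return object of class `rs_contact_series` with `distances` and
#'   `formed` (frames x contacts matrices) and `fraction` (named vector of
#'   formed fractions).
#' @export
contact_series <- function(traj, contacts) {
  if (inherits(contacts, "rs_contact")) contacts <- list(contacts)
  idxs <- lapply(contacts, resolve_contact_indices, traj$structure)
  nf <- n_frames(traj)
  dmat <- matrix(NA_real_, nf, length(contacts))
  colnames(dmat) <- vapply(contacts, `[[`, "", "label")
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    dmat[f, ] <- vapply(idxs, function(ix) contact_distance(m, ix),
                        numeric(1))
  }
  thr <- vapply(contacts, `[[`, numeric(1), "threshold")
  formed <- sweep(dmat, 2, thr, `<=`)
  structure(list(distances = dmat, formed = formed,
                 fraction = colMeans(formed), contacts = contacts),
            class = "rs_contact_series")
}

#' @export
print.rs_contact_series <- function(x, ...) {
  cat("riboscape contact series over", nrow(x$distances), "frames:\n")
  for (nm in colnames(x$distances))
    cat(sprintf("  %-14s formed %.1f%%\n", nm, 100 * x$fraction[nm]))
  invisible(x)
}

# ---- Hydrogen bonds ----------------------------------------------------

#' Standard nucleic-acid hydrogen-bond donor/acceptor table
#'
#' Heavy-atom donors and acceptors of the four ribonucleotides plus the
#' backbone/sugar oxygens (2'-OH is both donor and acceptor).
#'
#' @return list with data frames `donors` and `acceptors`
#'   (`residue_name`, `atom_name`; `residue_name == "*"` means any).
#' @export
nucleic_donor_acceptor <- function() {
  donors <- rbind(
    data.frame(residue_name = "A", atom_name = "N6"),
    data.frame(residue_name = "G", atom_name = c("N1", "N2")),
    data.frame(residue_name = "C", atom_name = "N4"),
    data.frame(residue_name = "U", atom_name = "N3"),
    data.frame(residue_name = "*", atom_name = "O2'"))
  acceptors <- rbind(
    data.frame(residue_name = "A", atom_name = c("N1", "N3", "N7")),
    data.frame(residue_name = "G", atom_name = c("O6", "N3", "N7")),
    data.frame(residue_name = "C", atom_name = c("O2", "N3")),
    data.frame(residue_name = "U", atom_name = c("O2", "O4")),
    data.frame(residue_name = "*",
               atom_name = c("OP1", "OP2", "O2'", "O3'", "O4'", "O5'")))
  list(donors = donors, acceptors = acceptors)
}

match_da <- function(at, table) {
  hit <- rep(FALSE, nrow(at))
  for (k in seq_len(nrow(table))) {
    rn <- table$residue_name[k]
    hit <- hit | (at$atom_name == table$atom_name[k] &
                    (rn == "*" | at$residue_name == rn))
  }
  which(hit)
}

#' Per-region hydrogen-bond counts for one frame
#'
#' A bond is formed when a donor--acceptor heavy-atom pair (different
#' residues) is within `dist_cutoff`; when the structure carries
#' hydrogens, the D-H...A angle must additionally be at least
#' `angle_cutoff` degrees (distance-only mode otherwise).  Native bonds
#' are counted against `native_list`; regions are assigned by the donor
#' residue and both counts are scaled by the region's native-bond count.
#'
#' @param m numeric `A x 3` frame coordinates.
#' @param structure the [rs_structure()] describing the atoms.
#' @param native_list list of [contact_spec()] (kind `"hbond"`) defining
#'   the native bonds.
#' @param region_map an [region_map()].
#' @param dist_cutoff donor-acceptor distance cutoff, angstrom.
#' @param angle_cutoff D-H...A angle cutoff, degrees.
#' @param da donor/acceptor table, as [nucleic_donor_acceptor()].
#' @return data frame per region: `region`, `n_native`, `native_formed`,
#'   `total_formed`, `scaled_native`, `scaled_total` (`NA` and a flag
#'   where a region has no native bonds).
#' @export
hydrogen_bonds <- function(m, structure, native_list, region_map,
                           dist_cutoff = 3.5, angle_cutoff = 150,
                           da = nucleic_donor_acceptor()) {
  at <- structure$atoms
  m <- as.matrix(m)
  don <- match_da(at, da$donors)
  acc <- match_da(at, da$acceptors)
  has_h <- any(toupper(at$element) == "H")
  hyd <- which(toupper(at$element) == "H")

  formed_pair <- function(i, j) {
    if (at$residue_index[i] == at$residue_index[j]) return(FALSE)
    d <- sqrt(sum((m[i, ] - m[j, ])^2))
    if (d > dist_cutoff) return(FALSE)
    if (!has_h) return(TRUE)
    # hydrogens of the donor residue covalently close to the donor atom
    hs <- hyd[at$residue_index[hyd] == at$residue_index[i]]
    hs <- hs[sqrt(rowSums((m[hs, , drop = FALSE] -
                             matrix(m[i, ], length(hs), 3,
                                    byrow = TRUE))^2)) < 1.2]
    if (!length(hs)) return(TRUE)   # unprotonated donor: distance mode
    for (h in hs) {
      v1 <- m[i, ] - m[h, ]
      v2 <- m[j, ] - m[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_cutoff) return(TRUE)
    }
    FALSE
  }

  # total formed bonds, assigned to the donor residue's region
  total_by_region <- setNames(numeric(length(region_map$regions)),
                              names(region_map$regions))
  if (length(don) && length(acc)) {
    dcut2 <- dist_cutoff^2
    for (i in don) {
      d2 <- rowSums(sweep(m[acc, , drop = FALSE], 2, m[i, ])^2)
      for (j in acc[d2 <= dcut2]) {
        if (formed_pair(i, j)) {
          rg <- resolve_region(region_map, at$residue_index[i])
          if (rg %in% names(total_by_region))
            total_by_region[rg] <- total_by_region[rg] + 1
        }
      }
    }
  }

  native_region <- vapply(native_list, function(ct)
    resolve_region(region_map, ct$residue_a), "")
  native_formed <- vapply(native_list, function(ct) {
    ix <- resolve_contact_indices(ct, structure)
    sqrt(sum((colMeans(m[ix$a, , drop = FALSE]) -
                colMeans(m[ix$b, , drop = FALSE]))^2)) <= dist_cutoff
  }, logical(1))

  out <- lapply(names(region_map$regions), function(nm) {
    n_nat <- sum(native_region == nm)
    nf <- sum(native_formed[native_region == nm])
    tot <- total_by_region[[nm]]
    data.frame(region = nm, n_native = n_nat, native_formed = nf,
               total_formed = tot,
               scaled_native = if (n_nat > 0) nf / n_nat else NA_real_,
               scaled_total = if (n_nat > 0) tot / n_nat else NA_real_,
               undefined_scale = n_nat == 0)
  })
  do.call(rbind, out)
}

#' Hydrogen-bond counts along a trajectory
#'
#' @param traj an [rs_trajectory()].
#' @inheritParams hydrogen_bonds
#' @return data frame: one [hydrogen_bonds()] row set per frame, with a
#'   `frame` column.
#' @export
hbond_series <- function(traj, native_list, region_map,
                         dist_cutoff = 3.5, angle_cutoff = 150) {
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    r <- hydrogen_bonds(frame_coords(traj, f), traj$structure,
                        native_list, region_map, dist_cutoff, angle_cutoff)
    cbind(frame = f, r)
  })
  do.call(rbind, out)
}

# ---- P2-P3 distance distribution ---------------------------------------

#' Cumulative distribution of P2-P3 phosphorus distances
#'
#' Per-frame phosphorus--phosphorus distances between residue pairs
#' spanning the riboswitch core (defaults G34-U74 and G35-U74), returned
#' as empirical CDFs on a common grid.
#'
#' @param traj an [rs_trajectory()].
#' @param pairs list of length-2 residue-index vectors.
#' @param grid distance grid (angstrom); default covers the observed
#'   range at 0.1 A resolution.
#' @return object of class `rs_distance_cdf`: list with `distances`
#'   (frames x pairs), `grid`, `cdf` (grid x pairs) and `table` (long
#'   data frame `pair`, `distance`, `cdf`).
#' @export
p2p3_distance_cdf <- function(traj, pairs = list(c(34, 74), c(35, 74)),
                              grid = NULL) {
  at <- traj$structure$atoms
  p_index <- function(res) {
    i <- which(at$residue_index == res & at$atom_name == "P")
    if (!length(i)) stop("residue ", res, " has no P atom")
    i[1]
  }
  ia <- vapply(pairs, function(p) p_index(p[1]), integer(1))
  ib <- vapply(pairs, function(p) p_index(p[2]), integer(1))
  nf <- n_frames(traj)
  dmat <- matrix(NA_real_, nf, length(pairs))
  colnames(dmat) <- vapply(pairs, function(p)
    sprintf("P%d-P%d", p[1], p[2]), "")
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    dmat[f, ] <- sqrt(rowSums((m[ia, , drop = FALSE] -
                                 m[ib, , drop = FALSE])^2))
  }
  if (is.null(grid))
    grid <- seq(floor(min(dmat)) - 1, ceiling(max(dmat)) + 1, by = 0.1)
  cdf <- vapply(seq_len(ncol(dmat)),
                function(k) ecdf(dmat[, k])(grid),
                numeric(length(grid)))
  colnames(cdf) <- colnames(dmat)
  tab <- data.frame(
    pair = rep(colnames(dmat), each = length(grid)),
    distance = rep(grid, ncol(dmat)),
    cdf = as.vector(cdf))
  structure(list(distances = dmat, grid = grid, cdf = cdf, table = tab),
            class = "rs_distance_cdf")
}
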