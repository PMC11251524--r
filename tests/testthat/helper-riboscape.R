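# shared fixtures and independent oracles, built in code

# constant trajectory replicating the structure's coordinates
const_traj <- function(structure, n_frames = 5, dt = 125) {
  a <- n_atoms(structure)
  m <- coords(structure)
  frames <- array(0, c(n_frames, a, 3))
  for (f in seq_len(n_frames)) frames[f, , ] <- m
  rs_trajectory(frames, dt, structure)
}

# trajectory from a list of coordinate matrices
traj_from_frames <- function(structure, frame_list, dt = 125) {
  a <- n_atoms(structure)
  frames <- array(0, c(length(frame_list), a, 3))
  for (f in seq_along(frame_list)) frames[f, , ] <- frame_list[[f]]
  rs_trajectory(frames, dt, structure)
}

# minimal hand-built structure from an atom table
mini_structure <- function(atom_name, residue_name, residue_index, xyz,
                           element = NULL, box = NULL) {
  if (is.null(element)) element <- substr(atom_name, 1, 1)
  rs_structure(data.frame(atom_name = atom_name,
                          residue_name = residue_name,
                          residue_index = residue_index,
                          element = element,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE), box = box)
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force superposition oracle: quaternion grid search plus
# Nelder-Mead refinement on the best grid point; independent of the
# SVD-based implementation
rmsd_oracle <- function(mobile, target, n_grid = 1500) {
  M <- sweep(mobile, 2, colMeans(mobile))
  T_ <- sweep(target, 2, colMeans(target))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((M %*% t(R) - T_)^2)))
  }
  qs <- matrix(rnorm(4 * n_grid), n_grid, 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  opt2$value
}

# interval Jaccard of one true event against the best-matching detected
# event of the same ion
best_jaccard <- function(true_event, detected) {
  d <- detected[detected$ion_id == true_event$ion_id, , drop = FALSE]
  if (!nrow(d)) return(0)
  inter <- pmax(0, pmin(d$end_ps, true_event$end_ps) -
                  pmax(d$start_ps, true_event$start_ps))
  uni <- pmax(d$end_ps, true_event$end_ps) -
    pmin(d$start_ps, true_event$start_ps)
  max(inter / uni)
}
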