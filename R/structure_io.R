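#' @importFrom stats aggregate cor cov cutree dist ecdf median quantile
#'   rnorm runif sd setNames var
#' @importFrom utils head tail read.csv write.csv
NULL

# ---- Structure container -----------------------------------------------

#' Construct a molecular structure
#'
#' A `riboscape` structure holds an ordered atom table and an optional
#' periodic box.  The atom order defines the canonical atom index used by
#' every trajectory referencing this structure.
#'
#' @param atoms data frame with columns `atom_name`, `residue_name`,
#'   `residue_index` (1-based), `element`, `x`, `y`, `z` (angstrom).
#' @param box optional length-3 numeric, box edge lengths in angstrom.
#' @return object of class `rs_structure`.
#' @export
rs_structure <- function(atoms, box = NULL) {
  need <- c("atom_name", "residue_name", "residue_index", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$residue_index <- as.integer(atoms$residue_index)
  if (any(atoms$residue_index < 1L))
    stop("residue_index must be >= 1")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive finite edge lengths (angstrom)")
  }
  structure(list(atoms = atoms, box = box), class = "rs_structure")
}

#' Number of atoms in a structure
#' @param structure an `rs_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Extract the coordinate matrix of a structure
#' @param structure an `rs_structure`.
#' @return numeric matrix, atoms x 3 (angstrom).
#' @export
coords <- function(structure) {
  m <- as.matrix(structure$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @export
print.rs_structure <- function(x, ...) {
  cat("riboscape structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$residue_index)), "residues")
  if (!is.null(x$box))
    cat(sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

# element inferred as first alphabetic character of the atom name
infer_element <- function(atom_name) {
  el <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name)
  toupper(el)
}

# ---- PDB / XYZ reading -------------------------------------------------

#' Read a structure from PDB or XYZ
#'
#' Parses the fixed-column ATOM/HETATM subset of the PDB format (no altloc
#' or insertion-code handling) or a plain XYZ block.  When the element
#' column is absent the element is inferred from the first alphabetic
#' character of the atom name (so "N1" is nitrogen, "P" phosphorus).
#'
#' @param path file path.
#' @param format `"auto"`, `"pdb"` or `"xyz"`; `"auto"` decides from the
#'   file extension.
#' @return an [rs_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") parse_pdb(lines) else parse_xyz(lines)
}

parse_pdb <- function(lines) {
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) stop("no ATOM/HETATM records found (format error)")
  field <- function(a, b) trimws(substr(rec, a, b))
  atom_name <- field(13, 16)
  element <- field(77, 78)
  no_el <- element == ""
  element[no_el] <- infer_element(atom_name[no_el])
  atoms <- data.frame(
    atom_name = atom_name,
    residue_name = field(18, 20),
    residue_index = as.integer(field(23, 26)),
    element = element,
    x = as.numeric(field(31, 38)),
    y = as.numeric(field(39, 46)),
    z = as.numeric(field(47, 54)),
    stringsAsFactors = FALSE)
  box <- NULL
  cry <- lines[grepl("^CRYST1", lines)]
  if (length(cry)) {
    box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33)))
    if (any(!is.finite(box)) || any(box <= 0)) box <- NULL
  }
  rs_structure(atoms, box)
}

parse_xyz <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("bad XYZ header (format error)")
  body <- lines[seq(3, length.out = n)]
  if (length(body) < n || anyNA(body)) stop("truncated XYZ block")
  tok <- strsplit(trimws(body), "[[:space:]]+")
  el <- vapply(tok, `[`, "", 1L)
  xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  rs_structure(data.frame(
    atom_name = el, residue_name = "UNK",
    residue_index = seq_len(n), element = toupper(el),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

#' Write a structure to PDB or XYZ
#'
#' @param structure an [rs_structure()].
#' @param path output file path.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path,
                            format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  a <- structure$atoms
  if (format == "pdb") {
    out <- character(0)
    if (!is.null(structure$box))
      out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     structure$box[1], structure$box[2], structure$box[3],
                     90, 90, 90)
    nm <- ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name),
                 a$atom_name)
    out <- c(out, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)) %% 100000L, nm, a$residue_name, a$residue_index,
      a$x, a$y, a$z, a$element), "END")
  } else {
    out <- c(as.character(nrow(a)), "generated by riboscape",
             sprintf("%-4s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- Trajectory container and plain-frame format -----------------------

#' Construct a trajectory
#'
#' @param frames numeric array `F x A x 3` of coordinates in angstrom.
#' @param dt frame spacing in picoseconds.
#' @param structure the [rs_structure()] the atom order refers to.
#' @param box optional `F x 3` matrix of per-frame box edges (angstrom).
#' @param times optional per-frame times (ps); defaults to `(0:(F-1))*dt`.
#' @return object of class `rs_trajectory`.
#' @export
rs_trajectory <- function(frames, dt, structure, box = NULL, times = NULL) {
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stop("frames must be an F x A x 3 array")
  if (dim(frames)[2] != n_atoms(structure))
    stop("frame atom count (", dim(frames)[2],
         ") does not match structure (", n_atoms(structure), ")")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0 (ps)")
  nf <- dim(frames)[1]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  structure(list(frames = frames, dt = dt, times = times,
                 structure = structure, box = box),
            class = "rs_trajectory")
}

#' @export
print.rs_trajectory <- function(x, ...) {
  cat("riboscape trajectory:", dim(x$frames)[1], "frames x",
      dim(x$frames)[2], "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `rs_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as a coordinate matrix
#' @param traj an `rs_trajectory`.
#' @param i frame index (1-based).
#' @return numeric `A x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$frames[i, , , drop = TRUE]
  dim(m) <- c(dim(traj$frames)[2], 3L)
  m
}

#' Read a trajectory in the plain frame format
#'
#' The portable frame format is a text file of repeated blocks
#' `frame <index> time_ps <t>` followed by one `x y z` triplet per atom.
#' The atom count must be constant and equal the structure's; the frame
#' spacing is inferred from consecutive time stamps and must be uniform
#' (relative tolerance 1e-6).
#'
#' @param path file path.
#' @param structure the [rs_structure()] the frames refer to.
#' @param default_dt dt (ps) used when the file holds a single frame.
#' @return an [rs_trajectory()].
#' @export
read_trajectory <- function(path, structure, default_dt = 125) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^frame ", lines)
  if (!length(hdr)) stop("no frame headers found (format error)")
  a <- n_atoms(structure)
  ends <- c(hdr[-1] - 1L, length(lines))
  sizes <- ends - hdr
  if (any(sizes != a))
    stop("inconsistent atom count in trajectory: expected ", a,
         ", found ", paste(unique(sizes), collapse = "/"), " (format error)")
  times <- as.numeric(sub("^frame\\s+\\S+\\s+time_ps\\s+(\\S+).*$", "\\1",
                          lines[hdr]))
  if (anyNA(times)) stop("unparseable frame header (format error)")
  nf <- length(hdr)
  body <- lines[-hdr]
  xyz <- matrix(scan(text = body, quiet = TRUE), ncol = 3, byrow = TRUE)
  if (nrow(xyz) != nf * a) stop("truncated coordinate block (format error)")
  frames <- array(NA_real_, c(nf, a, 3))
  for (f in seq_len(nf))
    frames[f, , ] <- xyz[(f - 1L) * a + seq_len(a), , drop = FALSE]
  if (nf > 1L) {
    dts <- diff(times)
    if (any(abs(dts - dts[1]) > 1e-6 * max(abs(dts[1]), 1)))
      stop("non-uniform frame spacing (format error)")
    dt <- dts[1]
  } else dt <- default_dt
  rs_trajectory(frames, dt, structure, times = times)
}

#' Write a trajectory in the plain frame format
#'
#' @param traj an [rs_trajectory()].
#' @param path output file path.
#' @param digits coordinate decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  nf <- n_frames(traj)
  a <- dim(traj$frames)[2]
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %d time_ps %.6f", f - 1L, traj$times[f]), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf(fmt, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

# ---- Region maps -------------------------------------------------------

REGION_NAMES <- c("P1A", "P1B", "P2", "P3", "L2", "L3",
                  "J12", "J23", "J31", "other")

#' Construct a region map
#'
#' Maps secondary-structure region names (helices P1A/P1B/P2/P3, loops
#' L2/L3, junctions J12/J23/J31) to disjoint sets of residue indices.
#'
#' @param regions named list of integer vectors of residue indices.
#' @param offset integer added to these (crystal-convention) residue
#'   numbers to obtain the experimental numbering (e.g. -4 maps C80 to
#'   C76); metadata only.
#' @return object of class `rs_region_map`.
#' @export
region_map <- function(regions, offset = 0L) {
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list")
  bad <- setdiff(names(regions), REGION_NAMES)
  if (length(bad))
    stop("unknown region name(s): ", paste(bad, collapse = ", "))
  regions <- lapply(regions, function(r) sort(unique(as.integer(r))))
  all_res <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_res)) {
    dup <- unique(all_res[duplicated(all_res)])
    stop("residue(s) assigned to more than one region: ",
         paste(dup, collapse = ", "))
  }
  structure(list(regions = regions, offset = as.integer(offset)),
            class = "rs_region_map")
}

#' @export
print.rs_region_map <- function(x, ...) {
  cat("riboscape region map (offset", x$offset, "to experimental numbering):\n")
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat(sprintf("  %-5s %s\n", nm, paste(range(r), collapse = "-")))
  }
  invisible(x)
}

#' Load a region map from a YAML config
#'
#' The config maps region names to residue ranges, e.g.
#' `P2: [29-36, 48-55]` or explicit residue lists.  An optional top-level
#' `offset` key records the crystal-to-experimental numbering shift.
#'
#' @param path YAML file path.
#' @return an [region_map()].
#' @export
load_region_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  offset <- 0L
  if (!is.null(cfg$offset)) {
    offset <- as.integer(cfg$offset)
    cfg$offset <- NULL
  }
  regions <- lapply(cfg, parse_residue_spec)
  region_map(regions, offset = offset)
}

parse_residue_spec <- function(x) {
  items <- unlist(lapply(x, as.character), use.names = FALSE)
  out <- integer(0)
  for (it in items) {
    it <- trimws(it)
    if (grepl("^-?\\d+\\s*-\\s*-?\\d+$", it) && grepl("\\d-", it)) {
      ab <- as.integer(strsplit(it, "\\s*-\\s*")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(it))
  }
  out
}

#' Default region map for the 2'-dG (mfl) aptamer
#'
#' Residue numbering follows the crystal-structure convention.  Anchor
#' residues are fixed (G34/G35 in P2, A42/G45/G46 in L2, C68/C69/A71 in
#' L3, U74 in P3, C80 in J31); the remaining range boundaries interpolate
#' the secondary-structure cartoon and should be overridden when an exact
#' partition is known.  `offset = -4` maps to the experimental numbering
#' (C80 -> C76).
#'
#' @return an [region_map()].
#' @export
default_region_map <- function() {
  load_region_map(system.file("extdata", "mfl_regions.yaml",
                              package = "riboscape", mustWork = TRUE))
}

#' Resolve the region of a residue
#'
#' @param map an [region_map()].
#' @param residue integer residue index (crystal numbering).
#' @return region name, or `"other"` when unassigned.
#' @export
resolve_region <- function(map, residue) {
  vapply(as.integer(residue), function(r) {
    for (nm in names(map$regions))
      if (r %in% map$regions[[nm]]) return(nm)
    "other"
  }, "")
}

# ---- Contact specifications --------------------------------------------

#' Define a native contact
#'
#' Base pairs and hydrogen bonds are atom--atom contacts (for pairs the
#' convention is the N1 atom of the purine against the N3 atom of the
#' pyrimidine); stacks are measured between the unweighted centroids of
#' the two base-atom sets.
#'
#' @param kind `"basepair"`, `"hbond"` or `"stack"`.
#' @param residue_a,residue_b residue indices.
#' @param atom_a,atom_b atom name (basepair/hbond) or character vector of
#'   base-atom names (stack).
#' @param threshold formed-state distance cutoff in angstrom.  Defaults:
#'   4.0 for base pairs, 3.5 for hydrogen bonds, 5.0 for stacks.
#' @param native_distance optional reference-state distance (angstrom).
#' @param label contact label; auto-generated when missing.
#' @return object of class `rs_contact`.
#' @export
contact_spec <- function(kind = c("basepair", "stack", "hbond"),
                         residue_a, residue_b, atom_a, atom_b,
                         threshold = NULL, native_distance = NA_real_,
                         label = NULL) {
  kind <- match.arg(kind)
  if (is.null(threshold))
    threshold <- switch(kind, basepair = 4.0, hbond = 3.5, stack = 5.0)
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(label))
    label <- sprintf("%s:%d-%d", kind, residue_a, residue_b)
  structure(list(kind = kind,
                 residue_a = as.integer(residue_a),
                 residue_b = as.integer(residue_b),
                 atom_a = atom_a, atom_b = atom_b,
                 threshold = threshold,
                 native_distance = native_distance,
                 label = label),
            class = "rs_contact")
}

#' Load contact specifications from a YAML config
#'
#' @param path YAML file; a list of entries with keys `kind`, `residue_a`,
#'   `residue_b`, `atom_a`, `atom_b` and optional `threshold`, `label`.
#' @return list of [contact_spec()] objects.
#' @export
load_contacts <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(e)
    contact_spec(kind = e$kind, residue_a = e$residue_a,
                 residue_b = e$residue_b,
                 atom_a = unlist(e$atom_a), atom_b = unlist(e$atom_b),
                 threshold = if (is.null(e$threshold)) NULL else e$threshold,
                 label = e$label))
}

#' Default pseudoknot contacts of the 2'-dG aptamer
#'
#' The kissing-loop (HHH pseudoknot) contacts tracked along trajectories:
#' base pairs G45-C69 and G46-C68 and the A42-A71 stack.
#'
#' @return list of [contact_spec()] objects.
#' @export
default_contacts <- function() {
  load_contacts(system.file("extdata", "pk_contacts.yaml",
                            package = "riboscape", mustWork = TRUE))
}

# ---- Atom selection ----------------------------------------------------

#' Select atoms by region, name and element
#'
#' Query terms are combined with `" and "`; each term is one of `all`,
#' `heavy` (element not H), `region:<NAME>`, `atom:<NAME[,NAME...]>`,
#' `element:<EL[,EL...]>`, `residue:<N[,N...]>`, optionally negated with a
#' leading `not ` (so `not element:H` is equivalent to `heavy`).
#'
#' @param structure an [rs_structure()].
#' @param query selection expression.
#' @param region_map an [region_map()]; required for `region:` terms.
#' @return sorted integer vector of canonical atom indices.
#' @export
select_atoms <- function(structure, query = "all", region_map = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  for (term in strsplit(trimws(query), "\\s+and\\s+")[[1]]) {
    term <- trimws(term)
    neg <- FALSE
    if (grepl("^not\\s+", term)) {
      neg <- TRUE
      term <- sub("^not\\s+", "", term)
    }
    m <- if (term == "all") {
      rep(TRUE, nrow(a))
    } else if (term == "heavy") {
      toupper(a$element) != "H"
    } else if (term == "H") {         # allows bare "not H"
      toupper(a$element) == "H"
    } else if (grepl("^region:", term)) {
      if (is.null(region_map)) stop("region query requires a region_map")
      rn <- sub("^region:", "", term)
      if (!rn %in% names(region_map$regions))
        stop("unknown region name: ", rn)
      a$residue_index %in% region_map$regions[[rn]]
    } else if (grepl("^atom:", term)) {
      a$atom_name %in% strsplit(sub("^atom:", "", term), ",")[[1]]
    } else if (grepl("^element:", term)) {
      toupper(a$element) %in%
        toupper(strsplit(sub("^element:", "", term), ",")[[1]])
    } else if (grepl("^residue:", term)) {
      a$residue_index %in%
        as.integer(strsplit(sub("^residue:", "", term), ",")[[1]])
    } else stop("unparseable selection term: '", term, "'")
    if (neg) m <- !m
    keep <- keep & m
  }
  sort(which(keep))
}
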