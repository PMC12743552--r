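#' Built-in van der Waals radii (Angstrom), by element
#'
#' Bondi-style radii used to expand atomic spheres for surface-area
#' calculations. Values: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80.
#' The table can be overridden per call via the `radii` argument of
#' [sasa()] and friends; unknown elements fall back to 1.70 A with a warning.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

#' Construct a molecular structure
#'
#' A structure is an atom table with author residue numbering and Cartesian
#' coordinates in Angstrom. This is the container every analysis in the
#' package operates on; [read_structure()] builds one from a PDB file and
#' the synthetic generators build them directly.
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom
#'   name, e.g. "CA", "OD1"), `element` (element symbol), `res_name`
#'   (3-letter residue code), `res_seq` (author residue number, integer),
#'   `chain_id` (single character), `x`, `y`, `z` (Angstrom). An optional
#'   `vdw_radius` column overrides the built-in element table.
#' @param radii named vector of van der Waals radii used to fill missing
#'   `vdw_radius` values; defaults to [vdw_radii()].
#' @return An object of class `ifd_structure`: the validated atom
#'   data.frame with radii assigned.
#' @export
structure_new <- function(atoms, radii = vdw_radii()) {
  req <- c("serial", "name", "element", "res_name", "res_seq",
           "chain_id", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1)
    stop("structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain_id, res_seq, name) atom identity: ",
         key[duplicated(key)][1])
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  need <- is.na(atoms$vdw_radius)
  if (any(need)) {
    r <- unname(radii[atoms$element[need]])
    if (anyNA(r)) {
      unk <- unique(atoms$element[need][is.na(r)])
      warning("unknown element(s) ", paste(unk, collapse = ", "),
              "; using 1.70 A radius")
      r[is.na(r)] <- 1.70
    }
    atoms$vdw_radius[need] <- r
  }
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive")
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  rownames(atoms) <- NULL
  class(atoms) <- c("ifd_structure", "data.frame")
  atoms
}

#' @export
print.ifd_structure <- function(x, ...) {
  ch <- table(x$chain_id)
  cat("ifd_structure: ", nrow(x), " atoms, ", length(ch), " chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure an `ifd_structure`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Construct a trajectory
#'
#' A trajectory pairs a topology (an [structure_new()] object) with a stack
#' of per-frame coordinates congruent with it.
#'
#' @param topology `ifd_structure` giving atom identities.
#' @param frames numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices.
#' @param frame_interval_ns time between consecutive frames, nanoseconds.
#' @return Object of class `ifd_trajectory`: list with elements
#'   `topology`, `coords` (3-d array), `frame_interval_ns`, `n_frames`.
#' @export
trajectory_new <- function(topology, frames, frame_interval_ns = 0.1) {
  stopifnot(inherits(topology, "ifd_structure"))
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  if (length(dim(frames)) != 3 || dim(frames)[1] != nrow(topology) ||
      dim(frames)[2] != 3)
    stop("frames must be an n_atoms x 3 x n_frames array congruent with topology")
  if (dim(frames)[3] < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0)
    stop("frame_interval_ns must be positive")
  out <- list(topology = topology, coords = frames,
              frame_interval_ns = frame_interval_ns,
              n_frames = dim(frames)[3])
  class(out) <- "ifd_trajectory"
  out
}

#' @export
print.ifd_trajectory <- function(x, ...) {
  cat("ifd_trajectory: ", x$n_frames, " frames x ", nrow(x$topology),
      " atoms, dt = ", x$frame_interval_ns, " ns\n", sep = "")
  invisible(x)
}

#' Extract one frame of a trajectory as a coordinate matrix
#'
#' @param traj `ifd_trajectory`.
#' @param i frame index (1-based).
#' @return n x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "ifd_trajectory"))
  if (i < 1 || i > traj$n_frames) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

# guess an element symbol from a PDB atom name when the element column is
# blank; digits and leading hydrogen-position digits are stripped
guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  ifelse(nchar(nm) == 0, "C", substr(nm, 1, 1))
}
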