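#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (PDB v3.3 fixed-width layout, via bio3d) into
#' one or more [structure_new()] objects. Author residue numbering and chain
#' identifiers are kept verbatim. Insertion codes are rejected (the analyses
#' here key residues on `(chain, res_seq)` alone); alternate locations are
#' resolved by keeping the highest-occupancy altloc, ties broken by file
#' order.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` (default) returns a single structure from
#'   the first MODEL; `"all"` returns a list of structures, one per MODEL.
#' @param radii van der Waals radius table, see [vdw_radii()].
#' @return An `ifd_structure`, or a list of them when `model_policy = "all"`.
#' @seealso [read_trajectory()] to assemble congruent models into a
#'   trajectory, [write_structure()] for the inverse.
#' @export
read_structure <- function(path, model_policy = c("first", "all"),
                           radii = vdw_radii()) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = (model_policy == "all"), rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes present in ", path,
         "; renumber residues before analysis")
  # altloc policy: keep highest occupancy per (chain, resno, elety), tie ->
  # first occurrence in file order
  keep <- rep(TRUE, nrow(at))
  has_alt <- !is.na(at$alt) & nzchar(at$alt)
  if (any(has_alt)) {
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, seq_len(nrow(at)))
    keep <- !duplicated(key[ord])[order(ord)]
  }
  build <- function(xyz_row) {
    m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
    if (any(!is.finite(m)))
      stop("malformed/missing coordinate values in ", path)
    el <- at$elesy
    bad <- is.na(el) | !nzchar(trimws(el))
    el[bad] <- guess_element(at$elety[bad])
    atoms <- data.frame(
      serial = at$eleno, name = at$elety, element = trimws(el),
      res_name = at$resid, res_seq = at$resno,
      chain_id = ifelse(is.na(at$chain), " ", at$chain),
      x = m[, 1], y = m[, 2], z = m[, 3],
      stringsAsFactors = FALSE)
    structure_new(atoms[keep, , drop = FALSE], radii = radii)
  }
  xyz <- pdb$xyz
  if (model_policy == "first")
    return(build(as.numeric(xyz[1, ])))
  lapply(seq_len(nrow(xyz)), function(i) build(as.numeric(xyz[i, ])))
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Each MODEL becomes one frame; all models must be congruent with the
#' first (same atoms in the same order).
#'
#' @inheritParams read_structure
#' @param frame_interval_ns time between consecutive models, nanoseconds.
#' @return An `ifd_trajectory`.
#' @export
read_trajectory <- function(path, frame_interval_ns = 0.1,
                            radii = vdw_radii()) {
  models <- read_structure(path, model_policy = "all", radii = radii)
  if (!is.list(models)) models <- list(models)
  topo <- models[[1]]
  n <- nrow(topo)
  arr <- array(NA_real_, dim = c(n, 3, length(models)))
  for (i in seq_along(models)) {
    if (nrow(models[[i]]) != n)
      stop("MODEL ", i, " has ", nrow(models[[i]]),
           " atoms; expected ", n)
    arr[, , i] <- coords(models[[i]])
  }
  trajectory_new(topo, arr, frame_interval_ns)
}

#' Write a structure (or trajectory) to a PDB file
#'
#' @param x an `ifd_structure` or `ifd_trajectory`; trajectories are
#'   written as multi-MODEL files.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "ifd_trajectory")) {
    topo <- x$topology
    xyz <- t(apply(x$coords, 3, function(m) as.numeric(t(m))))
  } else if (inherits(x, "ifd_structure")) {
    topo <- x
    xyz <- matrix(as.numeric(t(coords(x))), nrow = 1)
  } else stop("x must be an ifd_structure or ifd_trajectory")
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(topo)),
    eleno = topo$serial, elety = topo$name, resid = topo$res_name,
    chain = topo$chain_id, resno = topo$res_seq,
    elesy = topo$element)
  invisible(path)
}
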