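#' Hydrogen-bond geometric criteria
#'
#' A hydrogen bond is scored when the donor-acceptor distance is below
#' `d_max` and the angular deviation is below `angle_max`. Two angle
#' conventions are provided because trajectory-analysis tools differ:
#' `"donor"` (default) measures the angle at the donor between the D-H
#' bond vector and the D->A vector (0 degrees = ideally aligned);
#' `"hydrogen"` measures the deviation from linearity at the hydrogen,
#' `180 - angle(D-H-A)`. Both gates use strict `<`.
#'
#' @param d_max maximum donor-acceptor distance, Angstrom.
#' @param angle_max maximum angular deviation, degrees (0 < angle_max < 90).
#' @param require_hydrogen if `TRUE`, explicit hydrogens must be present
#'   and the angle gate applies; if `FALSE`, detection is distance-only
#'   (for hydrogen-free crystal structures).
#' @param angle_convention `"donor"` or `"hydrogen"`, see above.
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_max = 30,
                           require_hydrogen = TRUE,
                           angle_convention = c("donor", "hydrogen")) {
  if (d_max <= 0) stop("d_max must be positive")
  if (angle_max <= 0 || angle_max >= 90)
    stop("angle_max must be in (0, 90) degrees")
  out <- list(d_max = d_max, angle_max = angle_max,
              require_hydrogen = isTRUE(require_hydrogen),
              angle_convention = match.arg(angle_convention))
  class(out) <- "hbond_criteria"
  out
}

#' Salt-bridge geometric criteria
#'
#' A salt bridge is scored when any side-chain oxygen of an acidic residue
#' (ASP OD1/OD2, GLU OE1/OE2) lies within `d_max` of any side-chain
#' nitrogen of a basic residue (ARG NE/NH1/NH2, LYS NZ; histidine ND1/NE2
#' optionally).
#'
#' @param d_max maximum O-N distance, Angstrom (strict `<`).
#' @param include_his whether protonated histidine counts as basic.
#' @return List of class `salt_bridge_criteria`.
#' @export
salt_bridge_criteria <- function(d_max = 4.0, include_his = FALSE) {
  if (d_max <= 0) stop("d_max must be positive")
  out <- list(d_max = d_max, include_his = isTRUE(include_his))
  class(out) <- "salt_bridge_criteria"
  out
}

# donor/acceptor tables: backbone N (donor) and O/OXT (acceptor) plus
# standard N/O side-chain groups; sulfur deliberately excluded
.donor_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1")
.acceptor_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH")
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_atoms  <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")

is_donor <- function(topo) {
  (topo$name == "N" & topo$res_name != "PRO") |
    mapply(function(rn, an) an %in% (.donor_atoms[[rn]] %||% character()),
           topo$res_name, topo$name)
}
is_acceptor <- function(topo) {
  topo$name %in% c("O", "OXT") |
    mapply(function(rn, an) an %in% (.acceptor_atoms[[rn]] %||% character()),
           topo$res_name, topo$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hydrogens covalently attached to heavy atom i: element H within bond_max
attached_hydrogens <- function(topo, xyz, i, bond_max = 1.2) {
  h <- which(topo$element == "H")
  if (length(h) == 0) return(integer())
  d2 <- rowSums(sweep(xyz[h, , drop = FALSE], 2, xyz[i, ])^2)
  h[d2 <= bond_max^2]
}

empty_contacts <- function() {
  data.frame(kind = character(), chain_a = character(), res_a = integer(),
             resname_a = character(), chain_b = character(), res_b = integer(),
             resname_b = character(), min_distance_A = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect interdomain hydrogen bonds in one frame
#'
#' Scans every donor on one partner against every acceptor on the other
#' (both directions) and reports residue pairs with at least one
#' qualifying atom-level contact (union rule: Table-style summaries key on
#' residue pairs, not atom pairs). Side A of each reported pair always
#' belongs to `partner_a`.
#'
#' @param structure an `ifd_structure` topology.
#' @param partner_a,partner_b disjoint chain-ID sets.
#' @param criteria an [hbond_criteria()] object.
#' @param xyz optional coordinate matrix overriding the structure's own
#'   coordinates (per-frame evaluation).
#' @return data.frame with columns `kind`, `chain_a`, `res_a`,
#'   `resname_a`, `chain_b`, `res_b`, `resname_b`, `min_distance_A`.
#' @export
detect_hbonds <- function(structure, partner_a, partner_b,
                          criteria = hbond_criteria(), xyz = NULL) {
  if (length(intersect(partner_a, partner_b)) > 0)
    stop("partner chain sets must be disjoint")
  topo <- structure
  if (is.null(xyz)) xyz <- coords(structure)
  xyz <- as.matrix(xyz)
  if (criteria$require_hydrogen && !any(topo$element == "H"))
    stop("require_hydrogen is TRUE but the structure has no hydrogens; ",
         "use hbond_criteria(require_hydrogen = FALSE) for distance-only ",
         "detection")
  don <- which(is_donor(topo))
  acc <- which(is_acceptor(topo))
  in_a <- topo$chain_id %in% partner_a
  in_b <- topo$chain_id %in% partner_b
  rows <- list()
  for (dir in 1:2) {
    dn <- if (dir == 1) don[in_a[don]] else don[in_b[don]]
    ac <- if (dir == 1) acc[in_b[acc]] else acc[in_a[acc]]
    if (length(dn) == 0 || length(ac) == 0) next
    for (d in dn) {
      dvec <- xyz[d, ]
      dist <- sqrt(rowSums(sweep(xyz[ac, , drop = FALSE], 2, dvec)^2))
      cand <- which(dist < criteria$d_max)
      if (length(cand) == 0) next
      hyd <- if (criteria$require_hydrogen)
        attached_hydrogens(topo, xyz, d) else integer()
      if (criteria$require_hydrogen && length(hyd) == 0) next
      for (ci in cand) {
        a <- ac[ci]
        ok <- !criteria$require_hydrogen
        if (!ok) {
          da <- xyz[a, ] - dvec
          for (h in hyd) {
            if (criteria$angle_convention == "donor") {
              dh <- xyz[h, ] - dvec
              ang <- angle_deg(dh, da)
            } else {
              hd <- dvec - xyz[h, ]
              ha <- xyz[a, ] - xyz[h, ]
              ang <- 180 - angle_deg(hd, ha)
            }
            if (ang < criteria$angle_max) { ok <- TRUE; break }
          }
        }
        if (ok) {
          ia <- if (dir == 1) d else a   # atom on partner A
          ib <- if (dir == 1) a else d
          rows[[length(rows) + 1]] <- data.frame(
            kind = "hbond",
            chain_a = topo$chain_id[ia], res_a = topo$res_seq[ia],
            resname_a = topo$res_name[ia],
            chain_b = topo$chain_id[ib], res_b = topo$res_seq[ib],
            resname_b = topo$res_name[ib],
            min_distance_A = dist[ci], stringsAsFactors = FALSE)
        }
      }
    }
  }
  aggregate_residue_pairs(rows)
}

angle_deg <- function(u, v) {
  cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cth))) * 180 / pi
}

# union rule: collapse atom-level hits to unique residue pairs, keeping the
# minimum contact distance
aggregate_residue_pairs <- function(rows) {
  if (length(rows) == 0) return(empty_contacts())
  df <- do.call(rbind, rows)
  key <- paste(df$kind, df$chain_a, df$res_a, df$chain_b, df$res_b, sep = "|")
  keep <- !duplicated(key)
  out <- df[keep, , drop = FALSE]
  out$min_distance_A <- as.numeric(
    tapply(df$min_distance_A, key, min)[key[keep]])
  ord <- order(out$chain_a, out$res_a, out$chain_b, out$res_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect interdomain salt bridges in one frame
#'
#' @inheritParams detect_hbonds
#' @param criteria a [salt_bridge_criteria()] object.
#' @return data.frame as in [detect_hbonds()] with `kind = "saltbridge"`.
#'   Side A of each pair belongs to `partner_a` regardless of which side
#'   carries the acid.
#' @export
detect_salt_bridges <- function(structure, partner_a, partner_b,
                                criteria = salt_bridge_criteria(),
                                xyz = NULL) {
  if (length(intersect(partner_a, partner_b)) > 0)
    stop("partner chain sets must be disjoint")
  topo <- structure
  if (is.null(xyz)) xyz <- coords(structure)
  xyz <- as.matrix(xyz)
  acid_tab <- .acidic_atoms
  base_tab <- .basic_atoms
  if (criteria$include_his) base_tab$HIS <- c("ND1", "NE2")
  is_acid <- mapply(function(rn, an) an %in% (acid_tab[[rn]] %||% character()),
                    topo$res_name, topo$name)
  is_base <- mapply(function(rn, an) an %in% (base_tab[[rn]] %||% character()),
                    topo$res_name, topo$name)
  in_a <- topo$chain_id %in% partner_a
  in_b <- topo$chain_id %in% partner_b
  rows <- list()
  for (dir in 1:2) {
    ox <- which(is_acid & (if (dir == 1) in_a else in_b))
    nt <- which(is_base & (if (dir == 1) in_b else in_a))
    if (length(ox) == 0 || length(nt) == 0) next
    for (o in ox) {
      dist <- sqrt(rowSums(sweep(xyz[nt, , drop = FALSE], 2, xyz[o, ])^2))
      hit <- which(dist < criteria$d_max)
      for (ci in hit) {
        n <- nt[ci]
        ia <- if (dir == 1) o else n
        ib <- if (dir == 1) n else o
        rows[[length(rows) + 1]] <- data.frame(
          kind = "saltbridge",
          chain_a = topo$chain_id[ia], res_a = topo$res_seq[ia],
          resname_a = topo$res_name[ia],
          chain_b = topo$chain_id[ib], res_b = topo$res_seq[ib],
          resname_b = topo$res_name[ib],
          min_distance_A = dist[ci], stringsAsFactors = FALSE)
      }
    }
  }
  aggregate_residue_pairs(rows)
}

#' Per-frame interface contacts along a trajectory
#'
#' Runs [detect_hbonds()] and/or [detect_salt_bridges()] on every frame
#' and assembles the results into an occupancy matrix (interaction keys x
#' frames), the input to survival-rate statistics.
#'
#' @param traj an `ifd_trajectory`.
#' @param partner_a,partner_b disjoint chain sets.
#' @param hbond an [hbond_criteria()] object, or `NULL` to skip.
#' @param saltbridge a [salt_bridge_criteria()] object, or `NULL` to skip.
#' @return An `ifd_occupancy` object, see [occupancy_matrix()].
#' @export
trajectory_contacts <- function(traj, partner_a, partner_b,
                                hbond = hbond_criteria(),
                                saltbridge = salt_bridge_criteria()) {
  stopifnot(inherits(traj, "ifd_trajectory"))
  per_frame <- lapply(seq_len(traj$n_frames), function(i) {
    xyz <- frame_coords(traj, i)
    out <- list()
    if (!is.null(hbond))
      out$hb <- detect_hbonds(traj$topology, partner_a, partner_b,
                              hbond, xyz = xyz)
    if (!is.null(saltbridge))
      out$sb <- detect_salt_bridges(traj$topology, partner_a, partner_b,
                                    saltbridge, xyz = xyz)
    do.call(rbind, out)
  })
  occupancy_matrix(per_frame, traj$frame_interval_ns)
}

#' Write per-frame contact detections to CSV
#'
#' Columns: `frame`, `kind`, `chain_a`, `res_a`, `chain_b`, `res_b`,
#' `min_distance_A`.
#'
#' @param detections list of per-frame detection data.frames.
#' @param path output CSV path.
#' @export
write_contacts_csv <- function(detections, path) {
  rows <- lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    cbind(frame = i, d[, c("kind", "chain_a", "res_a", "chain_b", "res_b",
                           "min_distance_A")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(), kind = character(),
                      chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      min_distance_A = numeric())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
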