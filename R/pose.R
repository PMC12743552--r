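#' Binding footprint of a ligand on its receptor
#'
#' The set of receptor residues with any heavy atom within
#' `contact_cutoff` of any ligand heavy atom — e.g. the GPIbalpha-binding
#' site on the A1 domain, read off a reference receptor/ligand complex.
#' Heavy atoms only, so hydrogen-free crystal structures work.
#'
#' @param structure an `ifd_structure` holding both partners.
#' @param receptor_chains,ligand_chains disjoint chain-ID sets.
#' @param contact_cutoff Angstrom (default 4.5).
#' @return data.frame of footprint residues: `chain_id`, `res_seq`.
#' @export
binding_footprint <- function(structure, receptor_chains, ligand_chains,
                              contact_cutoff = 4.5) {
  if (length(intersect(receptor_chains, ligand_chains)) > 0)
    stop("receptor and ligand chain sets must be disjoint")
  heavy <- structure$element != "H"
  rec <- which(heavy & structure$chain_id %in% receptor_chains)
  lig <- which(heavy & structure$chain_id %in% ligand_chains)
  if (length(rec) == 0 || length(lig) == 0)
    stop("empty receptor or ligand selection")
  xyz <- coords(structure)
  lx <- xyz[lig, , drop = FALSE]
  near <- vapply(rec, function(i) {
    min(rowSums(sweep(lx, 2, xyz[i, ])^2)) < contact_cutoff^2
  }, logical(1))
  hits <- structure[rec[near], c("chain_id", "res_seq")]
  out <- unique(hits)
  out <- out[order(out$chain_id, out$res_seq), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("empty binding footprint; contact_cutoff may be too small")
  out
}

#' Occlusion of a reference binding site by a candidate pose
#'
#' Quantifies how completely the blocker partner of a docked pose covers
#' a reference ligand's binding footprint on the shared receptor: the
#' pose receptor is superposed onto the reference receptor by matched CA
#' atoms, the transform is applied to the blocker, and the covered
#' fraction is the share of footprint residues with a heavy atom within
#' `contact_cutoff` of the transformed blocker.
#'
#' @param pose an `ifd_structure`: receptor plus blocker chains.
#' @param pose_receptor,pose_blocker chain sets inside `pose`.
#' @param ref an `ifd_structure`: reference receptor/ligand complex.
#' @param ref_receptor,ref_ligand chain sets inside `ref`.
#' @param contact_cutoff Angstrom (default 4.5) used for blocker coverage.
#' @param footprint_cutoff Angstrom used to define the reference
#'   footprint; defaults to `contact_cutoff`. Fixing it while varying
#'   `contact_cutoff` makes the covered fraction monotone in the latter.
#' @return List of class `occlusion_report`: `footprint` (data.frame),
#'   `covered_fraction` in [0,1], `n_covered`, `min_distance_A` (closest
#'   blocker-footprint approach), `ca_rmsd` of the receptor superposition.
#' @export
occlusion_score <- function(pose, pose_receptor, pose_blocker,
                            ref, ref_receptor, ref_ligand,
                            contact_cutoff = 4.5,
                            footprint_cutoff = contact_cutoff) {
  fp <- binding_footprint(ref, ref_receptor, ref_ligand, footprint_cutoff)
  # receptor superposition on shared CA atoms, matched by residue number
  pca <- pose[pose$name == "CA" & pose$chain_id %in% pose_receptor, ]
  rca <- ref[ref$name == "CA" & ref$chain_id %in% ref_receptor, ]
  shared <- intersect(pca$res_seq, rca$res_seq)
  if (length(shared) < 3)
    stop("fewer than 3 shared receptor CA atoms between pose and reference")
  pm <- as.matrix(pca[match(shared, pca$res_seq), c("x", "y", "z")])
  rm_ <- as.matrix(rca[match(shared, rca$res_seq), c("x", "y", "z")])
  fit <- superpose(pm, rm_)
  blk <- pose[pose$element != "H" & pose$chain_id %in% pose_blocker, ]
  if (nrow(blk) == 0) stop("empty blocker selection")
  bx <- apply_transform(as.matrix(blk[, c("x", "y", "z")]), fit)
  rx <- coords(ref)
  heavy <- ref$element != "H"
  fp_key <- paste(fp$chain_id, fp$res_seq)
  covered <- logical(nrow(fp))
  min_d2 <- Inf
  for (k in seq_len(nrow(fp))) {
    idx <- which(heavy & paste(ref$chain_id, ref$res_seq) == fp_key[k] &
                   ref$chain_id %in% ref_receptor)
    d2 <- vapply(idx, function(i)
      min(rowSums(sweep(bx, 2, rx[i, ])^2)), numeric(1))
    covered[k] <- min(d2) < contact_cutoff^2
    min_d2 <- min(min_d2, min(d2))
  }
  out <- list(footprint = fp,
              covered_fraction = if (nrow(fp) > 0) mean(covered) else NA_real_,
              n_covered = sum(covered),
              min_distance_A = sqrt(min_d2),
              ca_rmsd = fit$rmsd)
  class(out) <- "occlusion_report"
  out
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf(
    "occlusion_report: %d/%d footprint residues covered (%.1f%%), min distance %.2f A\n",
    x$n_covered, nrow(x$footprint), 100 * x$covered_fraction,
    x$min_distance_A))
  invisible(x)
}

#' Rank candidate docking poses by binding-site occlusion
#'
#' Poses whose covered fraction falls below `min_covered` are excluded.
#' Survivors are ordered by external docking score ascending when scores
#' are supplied (lower = more favorable), otherwise by covered fraction
#' descending; ties break deterministically by pose ID.
#'
#' @param poses named list of `ifd_structure` poses (names = pose IDs).
#' @param pose_receptor,pose_blocker chain sets (shared by all poses).
#' @inheritParams occlusion_score
#' @param external_scores optional named numeric vector of docking scores
#'   keyed by pose ID.
#' @param min_covered minimum covered fraction to retain (default 0.5).
#' @return data.frame: `pose_id`, `covered_fraction`, `external_score`,
#'   `rank`, sorted best-first.
#' @export
rank_poses <- function(poses, pose_receptor, pose_blocker,
                       ref, ref_receptor, ref_ligand,
                       external_scores = NULL, min_covered = 0.5,
                       contact_cutoff = 4.5) {
  if (length(poses) < 1) stop("at least one pose required")
  ids <- names(poses)
  if (is.null(ids)) ids <- sprintf("pose_%03d", seq_along(poses))
  cov <- vapply(poses, function(p)
    occlusion_score(p, pose_receptor, pose_blocker, ref, ref_receptor,
                    ref_ligand, contact_cutoff)$covered_fraction,
    numeric(1))
  sc <- if (is.null(external_scores)) rep(NA_real_, length(poses))
        else unname(external_scores[ids])
  out <- data.frame(pose_id = ids, covered_fraction = unname(cov),
                    external_score = sc, stringsAsFactors = FALSE)
  out <- out[out$covered_fraction >= min_covered, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no pose reaches min_covered = ", min_covered)
    out$rank <- integer()
    return(out)
  }
  ord <- if (all(!is.na(out$external_score)))
    order(out$external_score, out$pose_id)
  else
    order(-out$covered_fraction, out$pose_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
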