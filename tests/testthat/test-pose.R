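# reference complex: 6-residue receptor (chain A) with a ligand (chain L)
# hovering over residues 2-4
ref_complex <- function() {
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- atomrow("CA", "C", "ALA", i, "A",
                                        c(3.8 * i, 0, 0))
    rows[[length(rows) + 1]] <- atomrow("CB", "C", "ALA", i, "A",
                                        c(3.8 * i, 1.5, 0))
  }
  for (i in 2:4)
    rows[[length(rows) + 1]] <- atomrow("C1", "C", "LIG", 100 + i, "L",
                                        c(3.8 * i, 5, 0))
  do.call(toy_structure, rows)
}

# candidate pose: same receptor, blocker chain B at given offsets
pose_with_blocker <- function(blocker_pos, rigid = NULL) {
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- atomrow("CA", "C", "ALA", i, "A",
                                        c(3.8 * i, 0, 0))
    rows[[length(rows) + 1]] <- atomrow("CB", "C", "ALA", i, "A",
                                        c(3.8 * i, 1.5, 0))
  }
  for (j in seq_len(nrow(blocker_pos)))
    rows[[length(rows) + 1]] <- atomrow("C1", "C", "BLK", 200 + j, "B",
                                        blocker_pos[j, ])
  st <- do.call(toy_structure, rows)
  if (!is.null(rigid)) {
    xyz <- sweep(coords(st) %*% rigid$R, 2, rigid$t, "+")
    st$x <- xyz[, 1]; st$y <- xyz[, 2]; st$z <- xyz[, 3]
  }
  st
}

test_that("binding footprint matches an all-pairs distance oracle", {
  ref <- ref_complex()
  fp <- binding_footprint(ref, "A", "L")
  expect_equal(fp$res_seq, 2:4)

  # exhaustive oracle
  xyz <- coords(ref)
  rec <- which(ref$chain_id == "A")
  lig <- which(ref$chain_id == "L")
  inside <- unique(ref$res_seq[rec[vapply(rec, function(i)
    any(vapply(lig, function(j) vlen(xyz[i, ] - xyz[j, ]) < 4.5,
               logical(1))), logical(1))]])
  expect_setequal(fp$res_seq, inside)

  # far ligand -> empty footprint with warning
  far <- ref
  far$y[far$chain_id == "L"] <- far$y[far$chain_id == "L"] + 100
  expect_warning(fp2 <- binding_footprint(far, "A", "L"), "footprint")
  expect_equal(nrow(fp2), 0)
})

test_that("occlusion is 1 for a perfect mimic and 0 for a distant blocker", {
  ref <- ref_complex()
  lig_xyz <- coords(ref)[ref$chain_id == "L", , drop = FALSE]
  mimic <- pose_with_blocker(lig_xyz)
  rep1 <- occlusion_score(mimic, "A", "B", ref, "A", "L")
  expect_equal(rep1$covered_fraction, 1.0)

  away <- pose_with_blocker(sweep(lig_xyz, 2, c(0, -40, 0), "+"))
  rep0 <- occlusion_score(away, "A", "B", ref, "A", "L")
  expect_equal(rep0$covered_fraction, 0.0)
})

test_that("partial coverage equals brute-force residue counting", {
  ref <- ref_complex()
  # blocker only over residue 2 of the 3-residue footprint
  blk <- matrix(c(3.8 * 2, 5, 0), 1, 3)
  rep_half <- occlusion_score(pose_with_blocker(blk), "A", "B",
                              ref, "A", "L")
  expect_equal(rep_half$covered_fraction, 1 / 3)
  expect_equal(rep_half$n_covered, 1)
})

test_that("occlusion is invariant to rigid motion of the whole pose", {
  ref <- ref_complex()
  lig_xyz <- coords(ref)[ref$chain_id == "L", , drop = FALSE]
  base <- occlusion_score(pose_with_blocker(lig_xyz), "A", "B",
                          ref, "A", "L")
  moved <- pose_with_blocker(lig_xyz,
                             rigid = list(R = euler_rot(0.4, 1.0, 2.2),
                                          t = c(11, -3, 7)))
  got <- occlusion_score(moved, "A", "B", ref, "A", "L")
  expect_equal(got$covered_fraction, base$covered_fraction)
  expect_lt(got$ca_rmsd, 1e-6)
})

test_that("coverage is monotone in the contact cutoff", {
  ref <- ref_complex()
  blk <- matrix(c(3.8 * 2, 7, 0, 3.8 * 3, 8, 0), 2, 3, byrow = TRUE)
  pose <- pose_with_blocker(blk)
  cuts <- c(3, 4.5, 6, 8)
  fr <- vapply(cuts, function(cc)
    occlusion_score(pose, "A", "B", ref, "A", "L", contact_cutoff = cc,
                    footprint_cutoff = 4.5)$covered_fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("pose ranking filters by coverage and orders by score", {
  ref <- ref_complex()
  lig_xyz <- coords(ref)[ref$chain_id == "L", , drop = FALSE]
  poses <- list(
    good_a = pose_with_blocker(lig_xyz),
    good_b = pose_with_blocker(lig_xyz),
    off = pose_with_blocker(sweep(lig_xyz, 2, c(0, -40, 0), "+")))
  out <- rank_poses(poses, "A", "B", ref, "A", "L",
                    external_scores = c(good_a = -90, good_b = -120,
                                        off = -200))
  expect_equal(out$pose_id, c("good_b", "good_a"))  # off fails min_covered
  expect_equal(out$rank, 1:2)

  # without scores: coverage descending, deterministic tie-break by id
  out2 <- rank_poses(poses, "A", "B", ref, "A", "L")
  expect_equal(out2$pose_id, c("good_a", "good_b"))

  expect_warning(
    empty <- rank_poses(poses["off"], "A", "B", ref, "A", "L"),
    "min_covered")
  expect_equal(nrow(empty), 0)
})
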