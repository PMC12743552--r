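#' Build a two-chain toy complex with planted interface interactions
#'
#' Constructs a minimal structure in which every interfacial contact is
#' planted with known geometry: each hydrogen-bond site is a donor
#' (backbone-style N with its H, chain A) facing an acceptor (backbone O,
#' chain B) at a requested distance and D-H/D->A angle; each salt-bridge
#' site pairs an aspartate carboxylate oxygen (chain A) with a lysine
#' ammonium nitrogen (chain B) at a requested separation. Sites are
#' spaced far apart so they cannot cross-talk, and the accompanying
#' manifest records, per site, whether it satisfies the default
#' detection criteria — the ground truth detector tests compare against.
#'
#' @param hb_distance donor-acceptor distances, Angstrom (one H-bond site
#'   per element).
#' @param hb_angle D-H vs D->A angles at the donor, degrees (recycled).
#' @param sb_distance acid-O to base-N distances, Angstrom (one
#'   salt-bridge site per element).
#' @param spacing separation between planted sites, Angstrom.
#' @param hbond,saltbridge criteria used to annotate the manifest.
#' @return List of class `ifd_toy_complex`: `structure`
#'   (an `ifd_structure`, chains "A" and "B"), `manifest` (data.frame
#'   with site geometry, atom indices and a `qualifies` flag).
#' @export
make_toy_complex <- function(hb_distance = numeric(), hb_angle = 0,
                             sb_distance = numeric(), spacing = 20,
                             hbond = hbond_criteria(),
                             saltbridge = salt_bridge_criteria()) {
  n_hb <- length(hb_distance)
  n_sb <- length(sb_distance)
  hb_angle <- rep_len(hb_angle, max(n_hb, 1L))
  atoms <- list()
  manifest <- list()
  serial <- 0L
  add_atom <- function(name, element, res_name, res_seq, chain, pos) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(
      serial = serial, name = name, element = element, res_name = res_name,
      res_seq = res_seq, chain_id = chain,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
    serial
  }
  row <- 0L
  for (i in seq_len(n_hb)) {
    row <- row + 1L
    base <- c(0, (row - 1) * spacing, 0)
    th <- hb_angle[i] * pi / 180
    i_d <- add_atom("N", "N", "GLY", i, "A", base)
    i_h <- add_atom("H", "H", "GLY", i, "A", base + c(1.0, 0, 0))
    acc <- base + hb_distance[i] * c(cos(th), 0, sin(th))
    i_a <- add_atom("O", "O", "GLY", 100L + i, "B", acc)
    q <- hb_distance[i] < hbond$d_max & hb_angle[i] < hbond$angle_max
    manifest[[row]] <- data.frame(
      kind = "hbond", chain_a = "A", res_a = i, resname_a = "GLY",
      chain_b = "B", res_b = 100L + i, resname_b = "GLY",
      distance_A = hb_distance[i], angle_deg = hb_angle[i],
      donor_idx = i_d, hydrogen_idx = i_h, partner_idx = i_a,
      qualifies = q, stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_sb)) {
    row <- row + 1L
    base <- c(0, (row - 1) * spacing, 0)
    i_o <- add_atom("OD1", "O", "ASP", 50L + j, "A", base)
    i_n <- add_atom("NZ", "N", "LYS", 150L + j, "B",
                    base + c(sb_distance[j], 0, 0))
    manifest[[row]] <- data.frame(
      kind = "saltbridge", chain_a = "A", res_a = 50L + j,
      resname_a = "ASP", chain_b = "B", res_b = 150L + j,
      resname_b = "LYS", distance_A = sb_distance[j], angle_deg = NA_real_,
      donor_idx = i_o, hydrogen_idx = NA_integer_, partner_idx = i_n,
      qualifies = sb_distance[j] < saltbridge$d_max,
      stringsAsFactors = FALSE)
  }
  if (length(atoms) == 0) {
    # empty planting still yields a valid two-chain structure
    add_atom("CA", "C", "GLY", 1L, "A", c(0, 0, 0))
    add_atom("CA", "C", "GLY", 101L, "B", c(spacing, 0, 0))
  }
  st <- structure_new(do.call(rbind, atoms))
  xyz <- coords(st)
  if (nrow(xyz) > 1) {
    dm <- as.matrix(stats::dist(xyz))
    diag(dm) <- Inf
    # planted donor-H pairs sit at 1.0 A (covalent); only non-bonded
    # clashes below 0.8 A are infeasible
    if (min(dm) < 0.8)
      stop("infeasible geometry: atom clash below 0.8 A")
  }
  mf <- if (row > 0) do.call(rbind, manifest) else data.frame()
  out <- list(structure = st, manifest = mf)
  class(out) <- "ifd_toy_complex"
  out
}

#' Generate a trajectory with planted per-frame bond occupancies
#'
#' Starting from a [make_toy_complex()] topology, each planted
#' interaction is toggled frame-by-frame: in "off" frames the chain-B
#' partner atom is displaced 6 Angstrom along the pair axis (safely
#' beyond every detection cutoff), in "on" frames it sits at its planted
#' bonded position. Occupancy follows either an independent Bernoulli
#' per frame or a two-state Markov chain (started from its stationary
#' distribution). The true presence matrix is returned alongside, so
#' survival-rate recovery can be checked against ground truth rather
#' than re-derived numbers.
#'
#' @param toy an `ifd_toy_complex`.
#' @param occupancy one element per manifest row: a bare probability
#'   (Bernoulli) or a list `list(p_on = , p_off = )` (Markov on/off
#'   switching probabilities per frame step).
#' @param n_frames number of frames (>= 1).
#' @param frame_interval_ns frame spacing, ns.
#' @param seed integer seed (local RNG).
#' @param displacement off-state displacement, Angstrom.
#' @return List: `trajectory` (`ifd_trajectory`), `truth` (pairs x
#'   frames logical matrix, rownames = pair labels), `manifest`.
#' @export
make_trajectory <- function(toy, occupancy, n_frames, frame_interval_ns = 0.1,
                            seed = 1, displacement = 6) {
  stopifnot(inherits(toy, "ifd_toy_complex"))
  mf <- toy$manifest
  if (nrow(mf) == 0) stop("toy complex has no planted interactions")
  if (length(occupancy) != nrow(mf))
    stop("occupancy spec must have one entry per planted interaction")
  if (n_frames < 1) stop("n_frames must be >= 1")
  base <- coords(toy$structure)
  truth <- with_local_seed(seed, {
    t(vapply(seq_len(nrow(mf)), function(i) {
      sp <- occupancy[[i]]
      if (is.numeric(sp) && length(sp) == 1) {
        if (sp < 0 || sp > 1) stop("Bernoulli p must lie in [0, 1]")
        stats::runif(n_frames) < sp
      } else if (is.list(sp)) {
        p_on <- sp$p_on; p_off <- sp$p_off
        if (is.null(p_on) || is.null(p_off))
          stop("Markov spec needs p_on and p_off")
        s <- logical(n_frames)
        s[1] <- stats::runif(1) < p_on / (p_on + p_off)   # stationary start
        if (n_frames > 1) for (f in 2:n_frames)
          s[f] <- if (s[f - 1]) stats::runif(1) >= p_off
                  else stats::runif(1) < p_on
        s
      } else stop("occupancy entries must be probabilities or Markov specs")
    }, logical(n_frames)))
  })
  truth <- matrix(truth, nrow = nrow(mf))
  rownames(truth) <- pair_label(mf$resname_a, mf$res_a,
                                mf$resname_b, mf$res_b)
  arr <- array(rep(base, n_frames), dim = c(nrow(base), 3, n_frames))
  for (i in seq_len(nrow(mf))) {
    axis <- base[mf$partner_idx[i], ] - base[mf$donor_idx[i], ]
    axis <- axis / sqrt(sum(axis^2))
    off <- base[mf$partner_idx[i], ] + displacement * axis
    for (f in which(!truth[i, ]))
      arr[mf$partner_idx[i], , f] <- off
  }
  list(trajectory = trajectory_new(toy$structure, arr, frame_interval_ns),
       truth = truth, manifest = mf)
}

#' Generate a steered-pulling force curve with planted rupture
#'
#' Emulates a constant-velocity pulling trace: spring-loaded force ramps
#' to a planted rupture force (reaching its exact maximum at the planted
#' rupture time, preceded by a near-flat shoulder), collapses sharply
#' after rupture, and the accompanying contact annotations (hydrogen-bond
#' count, buried interface area) decay to zero exactly at the planted
#' dissociation time. Gaussian noise is added to the force only, so
#' contact-based dissociation recovery stays exact.
#'
#' @param rupture_force_pN planted peak force.
#' @param rupture_time_ns planted peak time.
#' @param dissociation_time_ns planted loss-of-contact time
#'   (>= rupture time; must lie on the sampling grid for exact recovery).
#' @param duration_ns curve length.
#' @param dt_ns sampling interval.
#' @param v,k pulling velocity (Angstrom/ns) and spring constant
#'   (pN/Angstrom), recorded as metadata.
#' @param n_hbonds0 initial interfacial bond count.
#' @param sasa0_A2 initial buried interface area.
#' @param shoulder_ns width of the near-flat pre-peak shoulder.
#' @param noise_sd force noise SD, pN.
#' @param seed integer seed (local RNG).
#' @return List: `curve` (an [force_curve()]), `truth` (list with the
#'   planted rupture force/time and dissociation time).
#' @export
make_smd_curve <- function(rupture_force_pN = 358.7, rupture_time_ns = 20,
                           dissociation_time_ns = 21.6, duration_ns = 25,
                           dt_ns = 0.02, v = 5, k = 69.48, n_hbonds0 = 7,
                           sasa0_A2 = 900, shoulder_ns = 0.5,
                           noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (rupture_time_ns <= 0 || rupture_time_ns > duration_ns)
    stop("rupture time must lie within the curve span")
  if (dissociation_time_ns < rupture_time_ns ||
      dissociation_time_ns > duration_ns)
    stop("dissociation time must lie between rupture time and curve end")
  t <- seq(0, duration_ns, by = dt_ns)
  f <- numeric(length(t))
  t_sh <- max(rupture_time_ns - shoulder_ns, 0)
  if (t_sh > 0) {
    ramp <- t <= t_sh
    # main ramp to 98% of peak, then a slow shoulder reaching the exact
    # peak at the planted time; 2% tilt keeps the argmax unique
    f[ramp] <- 0.98 * rupture_force_pN * t[ramp] / t_sh
  }
  sh <- t > t_sh & t <= rupture_time_ns
  f[sh] <- rupture_force_pN *
    (0.98 + 0.02 * (t[sh] - t_sh) / max(rupture_time_ns - t_sh, dt_ns))
  post <- t > rupture_time_ns
  collapse_end <- max(min(rupture_time_ns + 0.5, dissociation_time_ns),
                      rupture_time_ns + dt_ns)
  f[post] <- pmax(0, rupture_force_pN *
                    (1 - (t[post] - rupture_time_ns) /
                       (collapse_end - rupture_time_ns)))
  if (noise_sd > 0)
    f <- f + with_local_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  bound <- t < dissociation_time_ns - 1e-9   # grid-exact loss of contact
  frac_left <- pmax(0, 1 - t / dissociation_time_ns)
  hb <- ifelse(bound, pmax(1, ceiling(n_hbonds0 * frac_left)), 0L)
  sasa <- ifelse(bound, sasa0_A2 * frac_left, 0)
  curve <- force_curve(t, f, hbond_count = as.integer(hb),
                       buried_sasa_A2 = sasa, pull_velocity = v,
                       spring_k = k)
  list(curve = curve,
       truth = list(rupture_force_pN = rupture_force_pN,
                    rupture_time_ns = rupture_time_ns,
                    dissociation_time_ns = dissociation_time_ns,
                    noise_sd = noise_sd))
}

#' Generate a serial-dilution BLI sensorgram set with known kinetics
#'
#' Defaults mirror a standard serial-dilution design: six analyte
#' concentrations from 125 to 4000 nM, 60 s association, 120 s
#' dissociation.
#'
#' @inheritParams simulate_sensorgram
#' @param concentrations analyte concentrations, M (distinct).
#' @return List: `curves` (list of `ifd_sensorgram`), `truth` (list with
#'   `kon`, `koff`, `Rmax`, `KD`, `concentrations`, `noise_sd`, `seed`).
#' @export
make_sensorgram_set <- function(kon = 1.7e4, koff = 3.7e-2, Rmax = 1,
                                concentrations = c(125, 250, 500, 1000,
                                                   2000, 4000) * 1e-9,
                                t_assoc_end = 60, t_dissoc_end = 180,
                                dt = 0.5, noise_sd = 0, seed = 1) {
  if (anyDuplicated(concentrations))
    stop("concentrations must be distinct")
  curves <- lapply(seq_along(concentrations), function(i)
    simulate_sensorgram(kon, koff, Rmax, concentrations[i],
                        t_assoc_start = 0, t_assoc_end = t_assoc_end,
                        t_dissoc_end = t_dissoc_end, dt = dt,
                        noise_sd = noise_sd,
                        seed = if (noise_sd > 0) seed * 1000L + i else NULL))
  list(curves = curves,
       truth = list(kon = kon, koff = koff, Rmax = Rmax,
                    KD = kd_from_rates(kon, koff),
                    concentrations = concentrations,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate AFM contact cycles with Bernoulli adhesion
#'
#' Defaults follow the standard sampling design: 3 independent
#' substrates, 5 measurement points per substrate, 100 approach-retract
#' cycles per point. Each cycle adheres with probability `p_adhesion`
#' (scalar, or one value per substrate) and, when it does, draws its
#' rupture force from `N(force_mean, force_sd^2)`.
#'
#' @param p_adhesion adhesion probability per cycle.
#' @param force_mean,force_sd rupture-force law, pN.
#' @param n_substrates,points_per_substrate,cycles_per_point design sizes.
#' @param seed integer seed (local RNG).
#' @return List: `cycles` (an [afm_cycles()] table), `truth` (list of the
#'   generating parameters).
#' @export
make_afm_cycles <- function(p_adhesion = 0.191, force_mean = 42.2,
                            force_sd = 8, n_substrates = 3,
                            points_per_substrate = 5,
                            cycles_per_point = 100, seed = 1) {
  p <- rep_len(p_adhesion, n_substrates)
  if (any(p < 0 | p > 1)) stop("p_adhesion must lie in [0, 1]")
  rows <- with_local_seed(seed, {
    out <- list()
    for (s in seq_len(n_substrates)) {
      for (pt in seq_len(points_per_substrate)) {
        adhered <- stats::runif(cycles_per_point) < p[s]
        force <- rep(NA_real_, cycles_per_point)
        force[adhered] <- stats::rnorm(sum(adhered), force_mean, force_sd)
        out[[length(out) + 1]] <- data.frame(
          substrate_id = sprintf("S%d", s), point_id = sprintf("P%d", pt),
          cycle_id = seq_len(cycles_per_point), adhered = adhered,
          rupture_force_pN = force, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  list(cycles = afm_cycles(rows),
       truth = list(p_adhesion = p, force_mean = force_mean,
                    force_sd = force_sd, n_substrates = n_substrates,
                    points_per_substrate = points_per_substrate,
                    cycles_per_point = cycles_per_point, seed = seed))
}
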