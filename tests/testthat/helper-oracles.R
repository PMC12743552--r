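# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (plain loops, closed forms) and shares no geometry code
# with the package internals it checks.

# minimal structure from a coordinate table
toy_structure <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, element = r$element,
               res_name = r$res_name, res_seq = r$res_seq,
               chain_id = r$chain, x = r$pos[1], y = r$pos[2], z = r$pos[3],
               stringsAsFactors = FALSE)
  }))
  structure_new(df)
}

atomrow <- function(name, element, res_name, res_seq, chain, pos) {
  list(name = name, element = element, res_name = res_name,
       res_seq = res_seq, chain = chain, pos = pos)
}

# exposed area of two intersecting probe-expanded spheres (spherical caps)
two_sphere_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  # cap heights from the radical plane
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

vlen <- function(v) sqrt(sum(v^2))

angle_between_deg <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / (vlen(u) * vlen(v))))) * 180 / pi
}

# exhaustive triple-loop hydrogen-bond enumeration (donor-centered angle)
oracle_hbonds <- function(st, partner_a, partner_b, d_max = 3.5,
                          angle_max = 30) {
  xyz <- coords(st)
  donor_tab <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2",
                    GLN = "NE2", HIS = c("ND1", "NE2"), SER = "OG",
                    THR = "OG1", TYR = "OH", TRP = "NE1")
  acc_tab <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
                  GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG",
                  THR = "OG1", TYR = "OH")
  is_don <- function(i) {
    (st$name[i] == "N" && st$res_name[i] != "PRO") ||
      st$name[i] %in% donor_tab[[st$res_name[i]]]
  }
  is_acc <- function(i) {
    st$name[i] %in% c("O", "OXT") ||
      st$name[i] %in% acc_tab[[st$res_name[i]]]
  }
  hyd <- which(st$element == "H")
  found <- character()
  for (d in seq_len(nrow(st))) {
    if (!is_don(d)) next
    hs <- hyd[vapply(hyd, function(h) vlen(xyz[h, ] - xyz[d, ]) <= 1.2,
                     logical(1))]
    if (length(hs) == 0) next
    for (a in seq_len(nrow(st))) {
      if (!is_acc(a)) next
      on_a <- st$chain_id[d] %in% partner_a && st$chain_id[a] %in% partner_b
      on_b <- st$chain_id[d] %in% partner_b && st$chain_id[a] %in% partner_a
      if (!on_a && !on_b) next
      if (vlen(xyz[a, ] - xyz[d, ]) >= d_max) next
      ok <- FALSE
      for (h in hs) {
        if (angle_between_deg(xyz[h, ] - xyz[d, ],
                              xyz[a, ] - xyz[d, ]) < angle_max) ok <- TRUE
      }
      if (!ok) next
      ia <- if (on_a) d else a; ib <- if (on_a) a else d
      found <- c(found, paste(st$chain_id[ia], st$res_seq[ia],
                              st$chain_id[ib], st$res_seq[ib]))
    }
  }
  sort(unique(found))
}

# exhaustive O x N loop for salt bridges
oracle_salt_bridges <- function(st, partner_a, partner_b, d_max = 4.0) {
  xyz <- coords(st)
  acid <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  found <- character()
  for (o in seq_len(nrow(st))) {
    if (!(st$name[o] %in% acid[[st$res_name[o]]])) next
    for (n in seq_len(nrow(st))) {
      if (!(st$name[n] %in% base[[st$res_name[n]]])) next
      on_a <- st$chain_id[o] %in% partner_a && st$chain_id[n] %in% partner_b
      on_b <- st$chain_id[o] %in% partner_b && st$chain_id[n] %in% partner_a
      if (!on_a && !on_b) next
      if (vlen(xyz[o, ] - xyz[n, ]) >= d_max) next
      ia <- if (on_a) o else n; ib <- if (on_a) n else o
      found <- c(found, paste(st$chain_id[ia], st$res_seq[ia],
                              st$chain_id[ib], st$res_seq[ib]))
    }
  }
  sort(unique(found))
}

contact_keys <- function(det) {
  sort(unique(paste(det$chain_a, det$res_a, det$chain_b, det$res_b)))
}

# random two-chain micro-complex of donors/acceptors/charged tips
random_contact_structure <- function(n_a = 8, n_b = 8, box = 12) {
  rows <- list(); serial <- 0
  add <- function(name, el, rn, rs, ch, pos) {
    serial <<- serial + 1
    rows[[serial]] <<- atomrow(name, el, rn, rs, ch, pos)
  }
  rnd <- function() stats::runif(3, 0, box)
  for (i in seq_len(n_a)) {
    kind <- if (i == 1) 1 else sample(3, 1)  # guarantee one donor with H
    p <- rnd()
    if (kind == 1) {           # donor N with H at random orientation
      add("N", "N", "GLY", i, "A", p)
      u <- stats::rnorm(3); u <- u / vlen(u)
      add("H", "H", "GLY", i, "A", p + u)
    } else if (kind == 2) add("OD1", "O", "ASP", i, "A", p)
    else add("NZ", "N", "LYS", i, "A", p)
  }
  for (i in seq_len(n_b)) {
    kind <- sample(3, 1)
    p <- rnd()
    if (kind == 1) add("O", "O", "GLY", 100 + i, "B", p)
    else if (kind == 2) add("OE1", "O", "GLU", 100 + i, "B", p)
    else add("NH1", "N", "ARG", 100 + i, "B", p)
  }
  do.call(toy_structure, rows)
}

# rotation matrix from z-y-z Euler angles
euler_rot <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

# dense-grid (plus local polish) search for the minimal RMSD over proper
# rotations; independent of the SVD route
oracle_min_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% R - B)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 25),
                      b = seq(0, pi, length.out = 13),
                      g = seq(0, 2 * pi, length.out = 25))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  polished <- stats::optim(best, obj, method = "Nelder-Mead",
                           control = list(reltol = 1e-14, maxit = 5000))
  polished$value
}
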