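#' Assemble per-frame contact detections into an occupancy matrix
#'
#' @param per_frame list with one detection data.frame per frame (as
#'   returned by [detect_hbonds()] / [detect_salt_bridges()], possibly
#'   rbind-ed); `NULL`/empty entries mean no contacts that frame.
#' @param frame_interval_ns time between frames, nanoseconds.
#' @return Object of class `ifd_occupancy`: list with `keys` (data.frame
#'   of unique interaction identities with a human-readable `label` such
#'   as "R1334-E1598"), `presence` (keys x frames logical matrix) and
#'   `frame_interval_ns`.
#' @export
occupancy_matrix <- function(per_frame, frame_interval_ns = 0.1) {
  n_frames <- length(per_frame)
  if (n_frames < 1) stop("at least one frame required")
  all_rows <- do.call(rbind, Filter(function(d) !is.null(d) && nrow(d) > 0,
                                    per_frame))
  if (is.null(all_rows)) {
    keys <- cbind(empty_contacts()[0, 1:7], label = character())
    presence <- matrix(FALSE, 0, n_frames)
    return(new_occupancy(keys, presence, frame_interval_ns))
  }
  kf <- function(d) paste(d$kind, d$chain_a, d$res_a, d$chain_b, d$res_b,
                          sep = "|")
  keys <- all_rows[!duplicated(kf(all_rows)),
                   c("kind", "chain_a", "res_a", "resname_a",
                     "chain_b", "res_b", "resname_b"), drop = FALSE]
  keys <- keys[order(keys$kind, keys$chain_a, keys$res_a, keys$res_b), ,
               drop = FALSE]
  rownames(keys) <- NULL
  keys$label <- pair_label(keys$resname_a, keys$res_a,
                           keys$resname_b, keys$res_b)
  id <- kf(keys)
  presence <- matrix(FALSE, nrow(keys), n_frames)
  for (i in seq_len(n_frames)) {
    d <- per_frame[[i]]
    if (is.null(d) || nrow(d) == 0) next
    presence[match(kf(d), id), i] <- TRUE
  }
  new_occupancy(keys, presence, frame_interval_ns)
}

new_occupancy <- function(keys, presence, frame_interval_ns) {
  out <- list(keys = keys, presence = presence,
              frame_interval_ns = frame_interval_ns)
  class(out) <- "ifd_occupancy"
  out
}

#' @export
print.ifd_occupancy <- function(x, ...) {
  cat("ifd_occupancy: ", nrow(x$keys), " interaction key(s) x ",
      ncol(x$presence), " frames\n", sep = "")
  invisible(x)
}

# "ARG" 1334, "GLU" 1598 -> "R1334-E1598"
pair_label <- function(resname_a, res_a, resname_b, res_b) {
  one <- function(rn) {
    o <- suppressWarnings(bio3d::aa321(rn))
    ifelse(is.na(o) | o == "X", rn, o)
  }
  paste0(one(resname_a), res_a, "-", one(resname_b), res_b)
}

#' Survival rate of each interfacial interaction
#'
#' The survival rate (occupancy) of a bond is the percentage of trajectory
#' frames in which it satisfies its geometric criteria.
#'
#' @param occ an `ifd_occupancy` object.
#' @return Named numeric vector (percent, 0-100), names = key labels.
#' @export
survival_rates <- function(occ) {
  stopifnot(inherits(occ, "ifd_occupancy"))
  if (ncol(occ$presence) < 1) stop("occupancy matrix has no frames")
  v <- 100 * rowMeans(occ$presence)
  names(v) <- occ$keys$label
  v
}

#' Aggregate per-run survival rates across replicate trajectories
#'
#' Replicate equilibrium runs rarely show identical interfaces: a bond
#' absent from one run contributes an explicit 0.0% for that run. The
#' mean is the arithmetic mean over runs and the SEM uses the sample
#' (n-1) standard deviation divided by sqrt(n_runs).
#'
#' @param runs list (length >= 2) of named numeric vectors: per-run
#'   survival percentages keyed by interaction label.
#' @param kind optional kind tag ("hbond"/"saltbridge") recorded in the
#'   output.
#' @return A survival table: data.frame with columns `kind`, `pair`,
#'   `res_a`, `res_b`, `run1..runN`, `mean`, `sem`, sorted by mean
#'   descending.
#' @export
aggregate_runs <- function(runs, kind = NA_character_) {
  if (!is.list(runs) || length(runs) < 2)
    stop("need at least 2 runs; SEM is undefined for a single run")
  keys <- Reduce(union, lapply(runs, names))
  if (length(keys) == 0)
    return(survival_table_empty(length(runs), kind))
  m <- vapply(runs, function(r) {
    v <- unname(r[keys]); v[is.na(v)] <- 0; v
  }, numeric(length(keys)))
  m <- matrix(m, nrow = length(keys))
  mean_v <- rowMeans(m)
  sem_v <- apply(m, 1, stats::sd) / sqrt(length(runs))
  nums <- parse_pair_residues(keys)
  out <- data.frame(kind = kind, pair = keys,
                    res_a = nums$res_a, res_b = nums$res_b,
                    stringsAsFactors = FALSE)
  colnames(m) <- paste0("run", seq_along(runs))
  out <- cbind(out, as.data.frame(m))
  out$mean <- mean_v
  out$sem <- sem_v
  sort_survival_table(out)
}

survival_table_empty <- function(n_runs, kind) {
  out <- data.frame(kind = character(), pair = character(),
                    res_a = integer(), res_b = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_runs)) out[[paste0("run", i)]] <- numeric()
  out$mean <- numeric(); out$sem <- numeric()
  out
}

# residue numbers from labels like "R1334-E1598"; NA when unparseable
parse_pair_residues <- function(labels) {
  m <- regmatches(labels, regexec("^[A-Za-z]+([0-9]+)-[A-Za-z]+([0-9]+)$",
                                  labels))
  res_a <- vapply(m, function(g) if (length(g) == 3)
    as.integer(g[2]) else NA_integer_, integer(1))
  res_b <- vapply(m, function(g) if (length(g) == 3)
    as.integer(g[3]) else NA_integer_, integer(1))
  list(res_a = res_a, res_b = res_b)
}

# mean descending; ties by first-run survival descending, then residue
# numbers ascending (stable)
sort_survival_table <- function(tab) {
  ord <- order(-tab$mean, -tab$run1, tab$res_a, tab$res_b)
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a survival table by mean survival threshold
#'
#' Retains rows whose mean survival strictly exceeds `threshold` percent
#' (the convention used for interface summaries and heat maps), sorted by
#' mean descending.
#'
#' @param table a survival table from [aggregate_runs()].
#' @param threshold percent; strict `>`.
#' @return Filtered, sorted survival table.
#' @export
filter_table <- function(table, threshold = 10) {
  sort_survival_table(table[table$mean > threshold, , drop = FALSE])
}

#' Residue-pair heat-map matrix of mean survival
#'
#' @param table a (typically filtered) survival table.
#' @return Numeric matrix, rows = partner-A residues ascending, columns =
#'   partner-B residues ascending, entries = mean survival percent (0
#'   where the pair is absent).
#' @export
heatmap_matrix <- function(table) {
  if (nrow(table) == 0) return(matrix(numeric(), 0, 0))
  if (anyNA(table$res_a) || anyNA(table$res_b))
    stop("heatmap_matrix needs numeric residue ids for every pair")
  ra <- sort(unique(table$res_a)); rb <- sort(unique(table$res_b))
  m <- matrix(0, length(ra), length(rb), dimnames = list(ra, rb))
  for (i in seq_len(nrow(table)))
    m[as.character(table$res_a[i]), as.character(table$res_b[i])] <-
      table$mean[i]
  m
}

#' Per-frame count of present interactions
#'
#' @param occ an `ifd_occupancy`.
#' @param kind optional filter ("hbond"/"saltbridge").
#' @return Integer vector, one count per frame.
#' @export
hbond_count_series <- function(occ, kind = "hbond") {
  stopifnot(inherits(occ, "ifd_occupancy"))
  sel <- if (is.null(kind)) rep(TRUE, nrow(occ$keys)) else occ$keys$kind == kind
  as.integer(colSums(occ$presence[sel, , drop = FALSE]))
}

#' Fit a Gaussian to a binned frequency distribution
#'
#' Nonlinear least squares of `A * exp(-(x - mu)^2 / (2 sigma^2))` against
#' bin counts, used for bond-count distributions and rupture-force
#' histograms (the fitted center is the most probable value, Xc).
#'
#' @param x bin centers.
#' @param counts bin frequencies (same length).
#' @return Object of class `gaussian_fit`: list with `mu`, `sigma`,
#'   `amplitude`, `rss`, `fitted`.
#' @export
fit_gaussian <- function(x, counts) {
  if (length(x) != length(counts)) stop("x and counts must match in length")
  if (sum(counts) <= 0) stop("empty histogram")
  w <- counts / sum(counts)
  mu0 <- sum(w * x)
  s0 <- sqrt(sum(w * (x - mu0)^2))
  if (!is.finite(s0) || s0 < 1e-8)
    stop("degenerate distribution (all mass in one bin); ",
         "sigma has no lower support for a Gaussian fit")
  a0 <- max(counts)
  fit <- minpack.lm::nlsLM(
    counts ~ A * exp(-(x - mu)^2 / (2 * s^2)),
    start = list(A = a0, mu = mu0, s = s0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  out <- list(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
              amplitude = unname(cf["A"]),
              rss = sum(stats::resid(fit)^2),
              fitted = stats::fitted(fit))
  class(out) <- "gaussian_fit"
  out
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: mu = %.4g, sigma = %.4g, amplitude = %.4g, rss = %.4g\n",
              x$mu, x$sigma, x$amplitude, x$rss))
  invisible(x)
}

#' Histogram of integer counts with unit-width bins
#'
#' @param counts integer vector (e.g. per-frame bond counts).
#' @return data.frame with `x` (bin centers = integers spanning the data
#'   range) and `n` (frequencies).
#' @export
count_histogram <- function(counts) {
  rng <- range(counts)
  x <- seq(rng[1], rng[2])
  data.frame(x = x, n = as.integer(table(factor(counts, levels = x))))
}

#' Fit a Gaussian to the distribution of per-frame bond counts
#'
#' @param counts integer vector, length >= 10.
#' @return A `gaussian_fit`.
#' @export
fit_count_distribution <- function(counts) {
  if (length(counts) < 10) stop("need at least 10 frames for a fit")
  h <- count_histogram(counts)
  fit_gaussian(h$x, h$n)
}

#' Write a survival table to CSV
#'
#' Layout mirrors the interface summary tables: `kind`, `res_a`, `res_b`,
#' `pair`, `run1..runN`, `mean`, `sem`.
#'
#' @param table a survival table.
#' @param path output path.
#' @export
write_survival_csv <- function(table, path) {
  runcols <- grep("^run[0-9]+$", names(table), value = TRUE)
  utils::write.csv(table[, c("kind", "res_a", "res_b", "pair",
                             runcols, "mean", "sem")],
                   path, row.names = FALSE)
  invisible(path)
}
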