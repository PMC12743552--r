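#' Virtual-spring pulling force
#'
#' Constant-velocity steered pulling: a dummy atom moves at velocity `v`
#' and is linked to the steered atom through a harmonic spring of
#' stiffness `k`, so the instantaneous force is
#' `F = k * (v * t - x_steered)`, with `x_steered` the steered atom's
#' displacement projected on the pulling axis.
#'
#' @param t time, ns (scalar or vector).
#' @param x_steered displacement of the steered atom along the pulling
#'   axis, Angstrom.
#' @param v pulling velocity, Angstrom/ns (default 5).
#' @param k spring constant, pN/Angstrom (default 69.48).
#' @return Force, pN.
#' @export
spring_force <- function(t, x_steered, v = 5, k = 69.48) {
  if (k <= 0 || v <= 0) stop("k and v must be positive")
  k * (v * t - x_steered)
}

#' Construct a force curve
#'
#' @param time_ns strictly increasing time, ns.
#' @param force_pN force series, pN.
#' @param hbond_count optional per-sample interfacial bond counts.
#' @param buried_sasa_A2 optional per-sample buried interface area.
#' @param pull_velocity,spring_k metadata (Angstrom/ns, pN/Angstrom).
#' @return data.frame of class `ifd_force_curve` with the series as
#'   columns and pulling metadata as attributes.
#' @export
force_curve <- function(time_ns, force_pN, hbond_count = NULL,
                        buried_sasa_A2 = NULL, pull_velocity = 5,
                        spring_k = 69.48) {
  n <- length(time_ns)
  if (length(force_pN) != n) stop("time and force lengths differ")
  if (any(diff(time_ns) <= 0)) stop("time must be strictly increasing")
  df <- data.frame(time_ns = time_ns, force_pN = force_pN)
  if (!is.null(hbond_count)) {
    if (length(hbond_count) != n) stop("hbond_count length mismatch")
    df$hbond_count <- hbond_count
  }
  if (!is.null(buried_sasa_A2)) {
    if (length(buried_sasa_A2) != n) stop("buried_sasa_A2 length mismatch")
    df$buried_sasa_A2 <- buried_sasa_A2
  }
  attr(df, "pull_velocity") <- pull_velocity
  attr(df, "spring_k") <- spring_k
  class(df) <- c("ifd_force_curve", "data.frame")
  df
}

#' Dissociation time of a pulled complex
#'
#' The complex is dissociated once the interfacial hydrogen-bond count
#' and the buried interface area have both dropped to zero; to be robust
#' to transient zero crossings, the rule is sustained: the reported time
#' is the earliest sample from which `hbond_count == 0` and
#' `buried_sasa < sasa_eps` hold through the end of the curve.
#'
#' @param curve an [force_curve()] carrying `hbond_count` and
#'   `buried_sasa_A2`.
#' @param sasa_eps area threshold treated as zero, Angstrom^2.
#' @return Dissociation time, ns; `NA` if contacts never vanish (with a
#'   warning).
#' @export
dissociation_time <- function(curve, sasa_eps = 1.0) {
  if (is.null(curve$hbond_count) || is.null(curve$buried_sasa_A2))
    stop("curve must carry hbond_count and buried_sasa_A2 series")
  zero <- curve$hbond_count == 0 & curve$buried_sasa_A2 < sasa_eps
  n <- length(zero)
  # earliest index i with all(zero[i:n])
  run <- rev(cumprod(rev(zero)))   # 1 where zero holds to the end
  i <- which(run == 1)[1]
  if (is.na(i)) {
    warning("contacts never vanish; no dissociation within the curve")
    return(NA_real_)
  }
  curve$time_ns[i]
}

#' Rupture force of a pulling curve
#'
#' The rupture force is the peak of the force-time curve prior to
#' dissociation. When the curve carries contact annotations the search is
#' restricted to `t <= dissociation_time`; an optional centered moving
#' average can be applied first (default off — raw traces). Ties report
#' the earliest peak.
#'
#' @param curve an [force_curve()].
#' @param smooth_window moving-average width in samples (odd; 1 = none).
#' @return List of class `pulling_result`: `rupture_force` (pN),
#'   `rupture_time` (ns), `dissociation_time` (ns or NA).
#' @export
rupture_force <- function(curve, smooth_window = 1) {
  if (nrow(curve) < 2) stop("need at least 2 samples")
  if (smooth_window < 1) stop("smooth_window must be >= 1")
  f <- curve$force_pN
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
    f <- as.numeric(stats::filter(f, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
    # shrink edge windows rather than dropping them
    half <- (smooth_window - 1) / 2
    n <- length(f)
    for (i in which(is.na(f))) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      f[i] <- mean(curve$force_pN[lo:hi])
    }
  }
  dt <- if (!is.null(curve$hbond_count) && !is.null(curve$buried_sasa_A2))
    suppressWarnings(dissociation_time(curve)) else NA_real_
  idx <- if (!is.na(dt)) which(curve$time_ns <= dt) else seq_along(f)
  if (length(idx) == 0) stop("empty search window before dissociation")
  peak <- idx[which.max(f[idx])]      # which.max -> first occurrence on ties
  out <- list(rupture_force = f[peak], rupture_time = curve$time_ns[peak],
              dissociation_time = dt)
  class(out) <- "pulling_result"
  out
}

#' @export
print.pulling_result <- function(x, ...) {
  cat(sprintf(
    "pulling_result: rupture %.1f pN at %.2f ns; dissociation at %s ns\n",
    x$rupture_force, x$rupture_time,
    if (is.na(x$dissociation_time)) "NA" else
      sprintf("%.2f", x$dissociation_time)))
  invisible(x)
}

#' Construct an AFM contact-cycle set
#'
#' @param cycles data.frame with columns `substrate_id`, `point_id`,
#'   `cycle_id`, `adhered` (0/1 or logical), `rupture_force_pN` (NA for
#'   non-adhered cycles).
#' @return data.frame of class `ifd_afm_cycles` (validated).
#' @export
afm_cycles <- function(cycles) {
  req <- c("substrate_id", "point_id", "cycle_id", "adhered",
           "rupture_force_pN")
  miss <- setdiff(req, names(cycles))
  if (length(miss) > 0)
    stop("cycle table missing columns: ", paste(miss, collapse = ", "))
  cycles$adhered <- as.logical(cycles$adhered)
  if (any(cycles$adhered & is.na(cycles$rupture_force_pN)))
    stop("adhered cycles must carry a rupture force")
  if (any(!cycles$adhered & !is.na(cycles$rupture_force_pN)))
    stop("non-adhered cycles must not carry a rupture force")
  class(cycles) <- c("ifd_afm_cycles", "data.frame")
  cycles
}

#' Adhesion frequency of AFM contact cycles
#'
#' Per substrate, the adhesion frequency is the percentage of contact
#' cycles (pooled over that substrate's measurement points) showing a
#' specific unbinding event. The summary mean +/- SEM is taken across
#' substrates (biological replicates), with the n-1 sample SD.
#'
#' @param cycles an [afm_cycles()] table.
#' @return List of class `adhesion_summary`: `per_substrate` (data.frame
#'   `substrate_id`, `n_cycles`, `n_events`, `frequency_pct`),
#'   `mean_pct`, `sem_pct` (NA for a single substrate), `n_substrates`.
#' @export
adhesion_frequency <- function(cycles) {
  if (nrow(cycles) == 0) stop("no contact cycles")
  sp <- split(cycles, cycles$substrate_id)
  per <- data.frame(
    substrate_id = names(sp),
    n_cycles = vapply(sp, nrow, integer(1)),
    n_events = vapply(sp, function(d) sum(d$adhered), integer(1)),
    stringsAsFactors = FALSE)
  per$frequency_pct <- 100 * per$n_events / per$n_cycles
  out <- list(per_substrate = per,
              mean_pct = mean(per$frequency_pct),
              sem_pct = if (nrow(per) >= 2)
                stats::sd(per$frequency_pct) / sqrt(nrow(per)) else NA_real_,
              n_substrates = nrow(per))
  class(out) <- "adhesion_summary"
  out
}

#' @export
print.adhesion_summary <- function(x, ...) {
  cat(sprintf("adhesion_summary: %.1f%% +/- %.1f%% (SEM, n = %d substrates)\n",
              x$mean_pct, x$sem_pct, x$n_substrates))
  invisible(x)
}

#' Rupture-force distribution of adhered AFM cycles
#'
#' Pools the rupture forces of all adhered cycles, bins them, and fits a
#' Gaussian to the frequency distribution; the fitted center Xc is the
#' most probable rupture force (robust to outliers, unlike the plain
#' mean, which is also reported).
#'
#' @param cycles an [afm_cycles()] table with >= 20 adhered cycles.
#' @param bin_width histogram bin width, pN (default 5).
#' @return List of class `rupture_distribution`: `histogram` (data.frame
#'   `x`, `n`), `fit` (a `gaussian_fit`), `xc_pN` (fitted center),
#'   `mean_force_pN`, `n_events`.
#' @export
rupture_distribution <- function(cycles, bin_width = 5) {
  forces <- cycles$rupture_force_pN[cycles$adhered]
  if (length(forces) < 20)
    stop("need at least 20 adhered cycles for a distribution fit; have ",
         length(forces))
  lo <- floor(min(forces) / bin_width) * bin_width
  brk <- seq(lo, max(forces) + bin_width, by = bin_width)
  h <- graphics::hist(forces, breaks = brk, plot = FALSE)
  fit <- fit_gaussian(h$mids, h$counts)
  out <- list(histogram = data.frame(x = h$mids, n = h$counts),
              fit = fit, xc_pN = fit$mu,
              mean_force_pN = mean(forces), n_events = length(forces))
  class(out) <- "rupture_distribution"
  out
}

#' @export
print.rupture_distribution <- function(x, ...) {
  cat(sprintf(
    "rupture_distribution: Xc = %.1f pN, mean = %.1f pN (n = %d events)\n",
    x$xc_pN, x$mean_force_pN, x$n_events))
  invisible(x)
}

#' Read/write force-curve CSV
#'
#' Columns: `time_ns`, `force_pN` and optionally `hbond_count`,
#' `buried_sasa_A2`.
#'
#' @param path CSV path.
#' @return An `ifd_force_curve`.
#' @export
read_force_curve <- function(path) {
  df <- utils::read.csv(path)
  force_curve(df$time_ns, df$force_pN, hbond_count = df$hbond_count,
              buried_sasa_A2 = df$buried_sasa_A2)
}

#' @rdname read_force_curve
#' @param curve an `ifd_force_curve` to write.
#' @export
write_force_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read/write AFM cycle CSV
#'
#' Columns: `substrate_id`, `point_id`, `cycle_id`, `adhered` (0/1),
#' `rupture_force_pN`.
#'
#' @param path CSV path.
#' @return An `ifd_afm_cycles` table.
#' @export
read_afm_cycles <- function(path) {
  afm_cycles(utils::read.csv(path))
}

#' @rdname read_afm_cycles
#' @param cycles table to write.
#' @export
write_afm_cycles <- function(cycles, path) {
  out <- as.data.frame(cycles)
  out$adhered <- as.integer(out$adhered)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
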