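#' Affinity from rate constants
#'
#' @param kon association rate constant, 1/(M s); must be positive.
#' @param koff dissociation rate constant, 1/s.
#' @return KD = koff / kon, molar.
#' @export
kd_from_rates <- function(kon, koff) {
  if (any(kon <= 0)) stop("kon must be positive")
  koff / kon
}

#' Closed-form 1:1 Langmuir sensorgram response
#'
#' Association: `R(t) = Req * (1 - exp(-kobs * (t - t0)))` with
#' `kobs = kon * C + koff` and `Req = Rmax * C / (C + koff/kon)`.
#' Dissociation: mono-exponential decay from the response at the end of
#' association, rate `koff`.
#'
#' @param t time, s.
#' @param kon,koff rate constants (1/(M s), 1/s).
#' @param Rmax saturating response, nm.
#' @param conc analyte concentration, M.
#' @param t_assoc_start,t_assoc_end phase boundaries, s.
#' @return Response, nm (0 before association start).
#' @export
langmuir_response <- function(t, kon, koff, Rmax, conc,
                              t_assoc_start = 0, t_assoc_end = 60) {
  kobs <- kon * conc + koff
  req <- Rmax * conc / (conc + koff / kon)
  r_end <- req * (1 - exp(-kobs * (t_assoc_end - t_assoc_start)))
  out <- numeric(length(t))
  a <- t >= t_assoc_start & t <= t_assoc_end
  d <- t > t_assoc_end
  out[a] <- req * (1 - exp(-kobs * (t[a] - t_assoc_start)))
  out[d] <- r_end * exp(-koff * (t[d] - t_assoc_end))
  out
}

#' Simulate a BLI sensorgram under 1:1 Langmuir kinetics
#'
#' @inheritParams langmuir_response
#' @param t_dissoc_end end of the dissociation phase, s.
#' @param dt sampling interval, s.
#' @param noise_sd additive Gaussian noise, nm (0 = noiseless).
#' @param seed optional integer seed (local RNG; the global stream is
#'   untouched).
#' @return data.frame of class `ifd_sensorgram` with columns `time_s`,
#'   `response_nm`; concentration and phase boundaries as attributes.
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, conc,
                                t_assoc_start = 0, t_assoc_end = 60,
                                t_dissoc_end = 180, dt = 0.5,
                                noise_sd = 0, seed = NULL) {
  if (kon <= 0 || koff <= 0 || Rmax <= 0 || conc <= 0)
    stop("kon, koff, Rmax and conc must all be positive")
  if (!(t_assoc_start < t_assoc_end && t_assoc_end < t_dissoc_end))
    stop("phase boundaries must satisfy t_assoc_start < t_assoc_end < t_dissoc_end")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  t <- seq(t_assoc_start, t_dissoc_end, by = dt)
  r <- langmuir_response(t, kon, koff, Rmax, conc, t_assoc_start, t_assoc_end)
  if (noise_sd > 0) {
    r <- r + with_local_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  }
  out <- data.frame(time_s = t, response_nm = r)
  attr(out, "concentration_M") <- conc
  attr(out, "t_assoc_start") <- t_assoc_start
  attr(out, "t_assoc_end") <- t_assoc_end
  attr(out, "t_dissoc_end") <- t_dissoc_end
  class(out) <- c("ifd_sensorgram", "data.frame")
  out
}

# run expr under a temporary RNG state; NULL seed uses the current stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Global 1:1 Langmuir fit of a sensorgram set
#'
#' Fits one shared (kon, koff, Rmax) to all curves jointly by nonlinear
#' least squares over both phases (Levenberg-Marquardt), with a
#' multi-start grid over kon in {1e3, 1e4, 1e5} 1/(M s) and koff in
#' {1e-3, 1e-2, 1e-1} 1/s (Rmax started from the maximum observed
#' response); the start with the lowest residual sum of squares wins.
#' Parameters are fitted on a log scale to enforce positivity.
#'
#' @param curves list of `ifd_sensorgram` objects at distinct analyte
#'   concentrations (>= 3 recommended; fewer triggers a warning).
#' @param per_curve_rmax fit a separate Rmax per curve (off by default:
#'   uniform sensor loading).
#' @return List of class `langmuir_fit`: `kon`, `koff`, `Rmax`
#'   (vector when per-curve), `KD` (= koff/kon exactly), `rss`,
#'   `residuals` (per curve), `n_points`.
#' @export
fit_langmuir_global <- function(curves, per_curve_rmax = FALSE) {
  if (length(curves) < 1) stop("no curves supplied")
  concs <- vapply(curves, function(s) attr(s, "concentration_M"), numeric(1))
  if (anyDuplicated(concs)) stop("analyte concentrations must be distinct")
  if (length(curves) < 3)
    warning("fewer than 3 concentrations; the global fit is weakly ",
            "constrained")
  nrmax <- if (per_curve_rmax) length(curves) else 1
  model_resid <- function(par) {
    kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3:(2 + nrmax)])
    unlist(lapply(seq_along(curves), function(i) {
      s <- curves[[i]]
      pred <- langmuir_response(
        s$time_s, kon, koff, if (per_curve_rmax) rmax[i] else rmax,
        concs[i], attr(s, "t_assoc_start"), attr(s, "t_assoc_end"))
      s$response_nm - pred
    }))
  }
  r0 <- max(vapply(curves, function(s) max(s$response_nm), numeric(1)))
  r0 <- max(r0, 1e-6)
  starts <- expand.grid(kon = c(1e3, 1e4, 1e5), koff = c(1e-3, 1e-2, 1e-1))
  best <- NULL
  tried <- list()
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts$kon[i]), log(starts$koff[i]), rep(log(r0), nrmax))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = model_resid,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    tried[[i]] <- c(starts$kon[i], starts$koff[i], rss)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("global Langmuir fit failed to converge from every start; grid: ",
         paste(vapply(tried, function(v) sprintf("(%g,%g)->%g", v[1], v[2],
                                                 v[3]), character(1)),
               collapse = "; "))
  par <- best$fit$par
  kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3:(2 + nrmax)])
  res <- lapply(seq_along(curves), function(i) {
    s <- curves[[i]]
    s$response_nm - langmuir_response(
      s$time_s, kon, koff, if (per_curve_rmax) rmax[i] else rmax,
      concs[i], attr(s, "t_assoc_start"), attr(s, "t_assoc_end"))
  })
  out <- list(kon = kon, koff = koff,
              Rmax = if (per_curve_rmax) rmax else unname(rmax),
              KD = kd_from_rates(kon, koff),
              rss = best$rss, residuals = res,
              n_points = sum(lengths(res)))
  class(out) <- "langmuir_fit"
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf(
    "langmuir_fit: kon = %.3g /M/s, koff = %.3g /s, KD = %.3g M (%.2f uM), rss = %.3g\n",
    x$kon, x$koff, x$KD, x$KD * 1e6, x$rss))
  invisible(x)
}

#' Write/read a sensorgram set as CSV files plus a JSON manifest
#'
#' One `sensorgram_<i>.csv` (`time_s`, `response_nm`) per concentration
#' and a `manifest.json` recording concentrations and phase boundaries.
#'
#' @param curves list of `ifd_sensorgram`.
#' @param dir output directory (created if needed).
#' @export
write_sensorgram_set <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(curves))
  for (i in seq_along(curves)) {
    files[i] <- sprintf("sensorgram_%02d.csv", i)
    utils::write.csv(as.data.frame(curves[[i]]),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- list(
    files = files,
    concentration_M = vapply(curves, function(s)
      attr(s, "concentration_M"), numeric(1)),
    t_assoc_start = attr(curves[[1]], "t_assoc_start"),
    t_assoc_end = attr(curves[[1]], "t_assoc_end"),
    t_dissoc_end = attr(curves[[1]], "t_dissoc_end"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sensorgram_set
#' @return `read_sensorgram_set()`: list of `ifd_sensorgram`.
#' @export
read_sensorgram_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_along(manifest$files), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$files[i]))
    out <- data.frame(time_s = df$time_s, response_nm = df$response_nm)
    attr(out, "concentration_M") <- manifest$concentration_M[i]
    attr(out, "t_assoc_start") <- manifest$t_assoc_start
    attr(out, "t_assoc_end") <- manifest$t_assoc_end
    attr(out, "t_dissoc_end") <- manifest$t_dissoc_end
    class(out) <- c("ifd_sensorgram", "data.frame")
    out
  })
}
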