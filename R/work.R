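#' Strain trace container
#'
#' One subject's global longitudinal strain over a single cardiac cycle,
#' sampled on a strictly increasing time grid. Strain is in percent with
#' negative values denoting shortening.
#'
#' @param time Strictly increasing sample times, ms from cycle start.
#' @param strain Strain values in percent, same length as `time`.
#' @param id Optional source identifier.
#' @param cycle_length Cycle length in ms (defaults to one median grid step
#'   past the last sample).
#' @return An object of class `strain_trace`.
#' @export
strain_trace <- function(time, strain, id = NULL, cycle_length = NULL) {
  if (length(time) != length(strain))
    stopf("'time' and 'strain' must have equal length")
  if (length(time) < 2L) stopf("a strain trace needs at least two samples")
  check_strictly_increasing(time, "time")
  if (any(!is.finite(strain))) stopf("'strain' must be finite")
  if (is.null(cycle_length))
    cycle_length <- max(time) + stats::median(diff(time))
  structure(list(time = time, strain = strain, id = id),
            class = "strain_trace", cycle_length = cycle_length)
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf("Strain trace%s: %d samples over %.0f ms, peak %.1f%%\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              length(x$time), attr(x, "cycle_length"), min(x$strain)))
  invisible(x)
}

#' Cardiac phase segmentation from valve events
#'
#' Defines the analysis window and phases used by the work indices: systole
#' from mitral valve closure to aortic valve closure (including isovolumic
#' contraction), isovolumic relaxation (IVR) from aortic valve closure to
#' mitral valve opening, and the analysis window MVC to MVO.
#'
#' @param events A [valve_events()] object.
#' @return An object of class `phase_segmentation` with elements `systole`,
#'   `ivr` and `analysis_window`, each a length-2 interval in ms.
#' @export
phase_segmentation <- function(events) {
  if (!inherits(events, "valve_events")) events <- do.call(valve_events, as.list(events))
  structure(list(systole = c(events$mvc, events$avc),
                 ivr = c(events$avc, events$mvo),
                 analysis_window = c(events$mvc, events$mvo)),
            class = "phase_segmentation")
}

# Merged time grid of both signals clipped to [lo, hi], with the exact
# breakpoints inserted; validates that both supports cover the window.
merged_window_grid <- function(strain, pressure, lo, hi, breakpoints = numeric()) {
  tol <- 1e-9
  if (min(strain$time) > lo + tol || max(strain$time) < hi - tol)
    stopf("analysis window [%g, %g] ms not covered by the strain trace", lo, hi)
  if (min(pressure$time) > lo + tol || max(pressure$time) < hi - tol)
    stopf("analysis window [%g, %g] ms not covered by the pressure curve", lo, hi)
  g <- sort(unique(c(strain$time, pressure$time, lo, hi, breakpoints)))
  g[g >= lo - tol & g <= hi + tol]
}

central_diff <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  if (n >= 3L)
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  d
}

#' Instantaneous myocardial work rate
#'
#' Resamples strain and pressure onto their merged time grid (linear
#' interpolation over the overlap of the two supports) and returns the
#' pointwise power signal P(t) * d(strain)/dt, with the strain rate computed
#' by central differences (one-sided at the edges).
#'
#' @param strain A [strain_trace()].
#' @param pressure A [pressure_curve()].
#' @return A data.frame with columns `time` (ms), `strain` (%), `pressure`
#'   (mmHg), `power` (mmHg %/ms).
#' @export
work_rate <- function(strain, pressure) {
  stopifnot(inherits(strain, "strain_trace"), inherits(pressure, "pressure_curve"))
  lo <- max(min(strain$time), min(pressure$time))
  hi <- min(max(strain$time), max(pressure$time))
  if (lo >= hi) stopf("strain and pressure time supports do not overlap")
  g <- sort(unique(c(strain$time, pressure$time)))
  g <- g[g >= lo & g <= hi]
  eps <- interp_linear(strain$time, strain$strain, g)
  p <- interp_linear(pressure$time, pressure$pressure, g)
  data.frame(time = g, strain = eps, pressure = p,
             power = p * central_diff(g, eps))
}

# Per-interval trapezoidal work increments over the analysis window:
# dW_i = mean(P) * d(strain) on each consecutive grid interval, together with
# a systole/IVR phase flag at the interval midpoint. GWI, GCW and GWW are all
# derived from these increments so their algebraic identities are exact.
work_increments <- function(strain, pressure, seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  w <- seg$analysis_window
  g <- merged_window_grid(strain, pressure, w[1L], w[2L],
                          breakpoints = seg$systole[2L])
  eps <- interp_linear(strain$time, strain$strain, g)
  p <- interp_linear(pressure$time, pressure$pressure, g)
  n <- length(g)
  dW <- (p[-1L] + p[-n]) / 2 * diff(eps)
  mid <- (g[-1L] + g[-n]) / 2
  list(dW = dW, systole = mid <= seg$systole[2L])
}

#' Global work index (GWI)
#'
#' Signed area of the pressure-strain loop over the analysis window from
#' mitral valve closure to mitral valve opening, computed as the trapezoidal
#' path integral of P d(strain) and orientation-normalized so that a
#' physiologic loop (shortening at high pressure, re-lengthening at low
#' pressure) yields a positive area. Units mmHg %.
#'
#' @param strain A [strain_trace()].
#' @param pressure A [pressure_curve()].
#' @param seg A [phase_segmentation()].
#' @return GWI in mmHg %.
#' @export
compute_gwi <- function(strain, pressure, seg) {
  inc <- work_increments(strain, pressure, seg)
  -sum(inc$dW)
}

#' Global constructive and wasted work (GCW, GWW)
#'
#' Splits the absolute work increments over the MVC to MVO window by whether
#' the wall motion is effective for ejection: shortening during systole and
#' lengthening during isovolumic relaxation count as constructive work,
#' lengthening during systole and shortening during isovolumic relaxation as
#' wasted work. Both are non-negative and `|GWI| <= GCW + GWW` holds as an
#' exact identity of the shared work increments.
#'
#' @inheritParams compute_gwi
#' @return Named numeric vector `c(gcw = , gww = )` in mmHg %.
#' @export
compute_gcw_gww <- function(strain, pressure, seg) {
  inc <- work_increments(strain, pressure, seg)
  dW <- inc$dW
  sys <- inc$systole
  gcw <- sum(pmax(-dW[sys], 0)) + sum(pmax(dW[!sys], 0))
  gww <- sum(pmax(dW[sys], 0)) + sum(pmax(-dW[!sys], 0))
  c(gcw = gcw, gww = gww)
}

#' Global work efficiency (GWE)
#'
#' The percentage of total work that is constructive:
#' `100 * gcw / (gcw + gww)`. When both components are zero the efficiency is
#' undefined and `NA` is returned with a warning (never a silent 0 or 100).
#'
#' @param gcw,gww Non-negative constructive and wasted work, mmHg %.
#' @return Efficiency in percent, or `NA_real_` if `gcw + gww == 0`.
#' @export
compute_gwe <- function(gcw, gww) {
  check_number(gcw, "gcw", lower = 0)
  check_number(gww, "gww", lower = 0)
  if (gcw + gww == 0) {
    warnf("total work is zero; work efficiency is undefined")
    return(NA_real_)
  }
  100 * gcw / (gcw + gww)
}

#' All four myocardial work indices for one subject
#'
#' @param strain A [strain_trace()].
#' @param pressure A [pressure_curve()].
#' @param events A [valve_events()] object.
#' @return An object of class `work_indices`: list with `gwi`, `gcw`, `gww`
#'   (mmHg %) and `gwe` (%).
#' @examples
#' ev <- valve_events(25, 80, 369, 465)
#' p <- estimate_pressure(124, ev, 909)
#' s <- synth_strain_trace(-19.5, ev, 909, 71, noise_sd = 0)
#' work_indices(s, p, ev)
#' @export
work_indices <- function(strain, pressure, events) {
  seg <- phase_segmentation(events)
  cw <- compute_gcw_gww(strain, pressure, seg)
  structure(list(gwi = compute_gwi(strain, pressure, seg),
                 gcw = unname(cw["gcw"]), gww = unname(cw["gww"]),
                 gwe = compute_gwe(unname(cw["gcw"]), unname(cw["gww"]))),
            class = "work_indices")
}

#' @export
print.work_indices <- function(x, ...) {
  cat(sprintf("GWI %.0f | GCW %.0f | GWW %.0f mmHg%% | GWE %.1f%%\n",
              x$gwi, x$gcw, x$gww, x$gwe))
  invisible(x)
}
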