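#' @title Inlet and ventricular pressure waveforms
#'
#' @description The inlet boundary condition is a template aortic pressure
#' shape rescaled in amplitude and time to the patient's measured
#' systolic/diastolic pressures and heart rate, represented both directly
#' and as a truncated Fourier series (the form the voltage source of the
#' circuit consumes, and whose time derivative is analytic). A synthesized
#' left-ventricular pressure wave drives the intramyocardial capacitors;
#' the right-sided intramyocardial pressure is 20% of it.
#'
#' Time origin convention: t = 0 at the diastolic minimum, i.e. the start
#' of the systolic upstroke.
#'
#' @name waveform
NULL

.default_template_knots <- function() {
  # normalized aortic shape: systolic upstroke to the peak, decline into a
  # dicrotic notch (depth ~0.1 of pulse pressure) with a small secondary
  # wave, then a decay reaching the diastolic minimum at the period end
  list(t = c(0, 0.06, 0.12, 0.18, 0.25, 0.31, 0.35, 0.38, 0.42,
             0.50, 0.60, 0.72, 0.86, 1.0),
       v = c(0, 0.45, 0.85, 1.00, 0.88, 0.68, 0.50, 0.40, 0.48,
             0.38, 0.27, 0.16, 0.07, 0))
}

#' Normalized periodic pressure waveform template
#'
#' Builds a C1 periodic interpolant (monotone Hermite between knots, with
#' the slope made periodic by extending the knot set one period to each
#' side) through normalized (time, pressure) knots on the unit square, then
#' normalizes it to min 0 / max 1 exactly.
#'
#' @param knots_t,knots_v knot coordinates; `knots_t` must start at 0 and
#'   end at 1, `knots_v` must have equal first and last values
#' @param systolic_fraction fraction of the period in systole (default
#'   0.35)
#' @return object of class `waveform_template`: a list with `fun`
#'   (vectorized over normalized time, periodic), `systolic_fraction`,
#'   `mean` (time average of the normalized shape), and the knots
#' @export
waveform_template <- function(knots_t = .default_template_knots()$t,
                              knots_v = .default_template_knots()$v,
                              systolic_fraction = 0.35) {
  stopifnot(length(knots_t) == length(knots_v), knots_t[1] == 0,
            knots_t[length(knots_t)] == 1,
            all(diff(knots_t) > 0),
            systolic_fraction > 0, systolic_fraction < 1)
  if (abs(knots_v[1] - knots_v[length(knots_v)]) > 1e-12) {
    stop("template must be periodic: first and last knot values must match")
  }
  n <- length(knots_t)
  t_ext <- c(knots_t[-n] - 1, knots_t, knots_t[-1] + 1)
  v_ext <- c(knots_v[-n], knots_v, knots_v[-1])
  # monotone C1 Hermite with Fritsch-Carlson/Brodlie slopes: zero slope at
  # local extrema (no under/overshoot), harmonic-mean slope elsewhere;
  # the one-period extension to each side makes the slope periodic
  s <- diff(v_ext) / diff(t_ext)
  m <- numeric(length(t_ext))
  m[1] <- s[1]
  m[length(m)] <- s[length(s)]
  for (k in 2:(length(m) - 1)) {
    m[k] <- if (s[k - 1] * s[k] <= 0) 0 else
      2 * s[k - 1] * s[k] / (s[k - 1] + s[k])
  }
  sf <- stats::splinefunH(t_ext, v_ext, m)
  grid <- seq(0, 1, length.out = 4097)[-4097]
  vals <- sf(grid)
  h <- grid[2]
  refine <- function(i, maximum) {
    stats::optimize(sf, c(grid[i] - h, grid[i] + h), maximum = maximum,
                    tol = 1e-12)[[2]]
  }
  lo <- min(vals[1], refine(which.min(vals), FALSE))
  hi <- refine(which.max(vals), TRUE)
  fun <- function(that) (sf(that %% 1) - lo) / (hi - lo)
  structure(list(fun = fun, systolic_fraction = systolic_fraction,
                 mean = mean((vals - lo) / (hi - lo)),
                 knots_t = knots_t, knots_v = knots_v),
            class = "waveform_template")
}

#' Read a waveform template from a two-column CSV
#'
#' Expects columns `time_s` and `pressure_mmHg` covering exactly one
#' period with strictly increasing time; the sampled wave is shifted so
#' that t = 0 sits at the diastolic minimum and normalized to the unit
#' square before periodic interpolation.
#'
#' @param path CSV file path
#' @param systolic_fraction see [waveform_template()]
#' @return a `waveform_template`
#' @export
read_waveform_template <- function(path, systolic_fraction = 0.35) {
  df <- utils::read.csv(path)
  .require_fields(df, c("time_s", "pressure_mmHg"), "waveform CSV")
  stopifnot(all(diff(df$time_s) > 0), nrow(df) >= 8)
  tt <- df$time_s
  pp <- df$pressure_mmHg
  period <- tt[length(tt)] - tt[1]
  # rotate so the minimum is the time origin; drop duplicate endpoint
  if (abs(pp[1] - pp[length(pp)]) < 1e-9 * max(abs(pp))) {
    tt <- tt[-length(tt)]
    pp <- pp[-length(pp)]
  }
  i0 <- which.min(pp)
  ord <- c(i0:length(pp), seq_len(i0 - 1))
  that <- ((tt[ord] - tt[i0]) %% period) / period
  v <- (pp[ord] - min(pp)) / (max(pp) - min(pp))
  waveform_template(c(that, 1), c(v, v[1]),
                    systolic_fraction = systolic_fraction)
}

# ---- Fourier series -----------------------------------------------------

#' Fit a truncated Fourier series to one period of a pressure source
#'
#' Coefficients come from uniform sampling over one period and the FFT
#' (equivalent to trapezoidal quadrature of the Fourier integrals, which
#' is spectrally accurate for a periodic integrand).
#'
#' @param source a `pressure_source` (or any list with elements `fun` and
#'   `period`)
#' @param n_harmonics number of harmonics to retain (>= 1)
#' @param n_samples sampling resolution (default 2048)
#' @return object of class `fourier_series`: `a0`, `an`, `bn` (dyn/cm^2),
#'   `omega0` (rad/s), `f0` (Hz)
#' @export
fourier_fit <- function(source, n_harmonics = 10, n_samples = 2048) {
  stopifnot(n_harmonics >= 1, n_samples > 2 * n_harmonics)
  T <- source$period
  ts <- seq(0, T, length.out = n_samples + 1)[-(n_samples + 1)]
  y <- source$fun(ts)
  cf <- stats::fft(y) / n_samples
  k <- seq_len(n_harmonics)
  structure(list(a0 = Re(cf[1]),
                 an = 2 * Re(cf[k + 1]),
                 bn = -2 * Im(cf[k + 1]),
                 omega0 = 2 * pi / T, f0 = 1 / T),
            class = "fourier_series")
}

#' Evaluate a Fourier series (or its time derivative)
#'
#' @param fs a `fourier_series`
#' @param t times, s (vectorized)
#' @param deriv 0 for the value, 1 for the first time derivative
#' @return numeric vector
#' @export
eval_fourier <- function(fs, t, deriv = 0) {
  k <- seq_along(fs$an)
  ang <- outer(t, k * fs$omega0)
  if (deriv == 0) {
    drop(fs$a0 + cos(ang) %*% fs$an + sin(ang) %*% fs$bn)
  } else if (deriv == 1) {
    w <- k * fs$omega0
    drop(-sin(ang) %*% (fs$an * w) + cos(ang) %*% (fs$bn * w))
  } else stop("deriv must be 0 or 1")
}

.make_source <- function(fun, period, sbp = NULL, dbp = NULL,
                         n_harmonics = 10, label = "source") {
  src <- structure(list(period = period, fun = fun, sbp = sbp, dbp = dbp,
                        fourier = NULL, label = label),
                   class = "pressure_source")
  src$fourier <- fourier_fit(src, n_harmonics = n_harmonics)
  src
}

#' Evaluate a pressure source
#'
#' @param src a `pressure_source`
#' @param t times, s
#' @param method `"direct"` (the rescaled template itself) or `"fourier"`
#'   (the truncated series the circuit solver uses)
#' @return pressure in dyn/cm^2
#' @export
source_pressure <- function(src, t, method = c("direct", "fourier")) {
  method <- match.arg(method)
  if (method == "direct") src$fun(t) else eval_fourier(src$fourier, t)
}

#' Time derivative of a pressure source (via its Fourier series)
#' @param src a `pressure_source`
#' @param t times, s
#' @return dP/dt in dyn/(cm^2 s)
#' @export
source_derivative <- function(src, t) eval_fourier(src$fourier, t, deriv = 1)

#' @export
print.pressure_source <- function(x, ...) {
  cat(sprintf("Pressure source \"%s\": period %.3f s, %d harmonics",
              x$label, x$period, length(x$fourier$an)))
  if (!is.null(x$sbp)) cat(sprintf(", %g/%g mmHg", x$sbp, x$dbp))
  cat("\n")
  invisible(x)
}

#' Rescale the template waveform to patient pressures and heart rate
#'
#' `p(t) = dbp + (sbp - dbp) * template((t mod T)/T)` converted to
#' dyn/cm^2, with period `T = 60/hr` seconds; the extrema of the result
#' equal the targets exactly.
#'
#' @param template a [waveform_template()]
#' @param sbp,dbp systolic and diastolic targets, mmHg (`sbp > dbp`)
#' @param hr heart rate, beats/min
#' @param n_harmonics harmonics retained in the Fourier representation
#' @return a `pressure_source` (pressures in cgs units)
#' @export
rescale_template <- function(template, sbp, dbp, hr, n_harmonics = 16) {
  stopifnot(inherits(template, "waveform_template"))
  .check_positive(hr, "hr")
  .check_positive(dbp, "dbp")
  if (sbp <= dbp) stop("`sbp` must exceed `dbp`", call. = FALSE)
  T <- 60 / hr
  lo <- pressure_mmhg_to_cgs(dbp)
  amp <- pressure_mmhg_to_cgs(sbp - dbp)
  fun <- function(t) lo + amp * template$fun((t / T) %% 1)
  .make_source(fun, T, sbp = sbp, dbp = dbp, n_harmonics = n_harmonics,
               label = "aorta_inlet")
}

#' Synthesize a left-ventricular pressure wave from the aortic source
#'
#' Systole: a squared-sine bump rising from the end-diastolic ventricular
#' pressure to the aortic systolic peak over a fixed fraction of the
#' period (slightly longer than the aortic systolic fraction, so the LVP
#' crosses the aortic wave shortly after the systolic upstroke and again
#' near end systole). Diastole: constant at the end-diastolic pressure.
#' The wave is C1 periodic and non-negative.
#'
#' @param source the aortic `pressure_source` (must carry `sbp`)
#' @param edp end-diastolic ventricular pressure, mmHg (default 10)
#' @param systolic_fraction fraction of the period spent above baseline
#'   (default 0.45)
#' @return a `pressure_source`
#' @export
build_lvp <- function(source, edp = 10, systolic_fraction = 0.45) {
  stopifnot(inherits(source, "pressure_source"), !is.null(source$sbp))
  .check_positive(edp, "edp")
  if (edp >= source$dbp) {
    stop("`edp` must be below the aortic diastolic pressure", call. = FALSE)
  }
  T <- source$period
  lo <- pressure_mmhg_to_cgs(edp)
  amp <- pressure_mmhg_to_cgs(source$sbp - edp)
  fs <- systolic_fraction
  fun <- function(t) {
    that <- (t / T) %% 1
    lo + amp * ifelse(that < fs, sin(pi * that / fs)^2, 0)
  }
  .make_source(fun, T, sbp = source$sbp, dbp = edp,
               n_harmonics = length(source$fourier$an), label = "lvp")
}

#' Intramyocardial pressure source for one side
#'
#' The left intramyocardial pressure is the left-ventricular wave itself;
#' the right is approximated as 20% of it, pointwise.
#'
#' @param lvp the left-ventricular `pressure_source`
#' @param side `"left"` or `"right"`
#' @param right_fraction scale applied for the right side (default 0.20)
#' @return a `pressure_source`
#' @export
build_pim <- function(lvp, side = c("left", "right"), right_fraction = 0.20) {
  side <- match.arg(side)
  stopifnot(inherits(lvp, "pressure_source"))
  if (side == "left") {
    lvp$label <- "pim_left"
    return(lvp)
  }
  k <- right_fraction
  src <- lvp
  src$label <- "pim_right"
  parent_fun <- lvp$fun
  src$fun <- function(t) k * parent_fun(t)
  src$fourier$a0 <- k * src$fourier$a0
  src$fourier$an <- k * src$fourier$an
  src$fourier$bn <- k * src$fourier$bn
  src$sbp <- k * src$sbp
  src$dbp <- k * src$dbp
  src
}

# time-compress a source by `factor` (used by frequency scaling)
.scale_source_time <- function(src, factor) {
  parent_fun <- src$fun
  out <- src
  out$period <- src$period / factor
  out$fun <- function(t) parent_fun(t * factor)
  out$fourier$omega0 <- src$fourier$omega0 * factor
  out$fourier$f0 <- src$fourier$f0 * factor
  out
}
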