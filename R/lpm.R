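#' @title Patient-specific coronary lumped-parameter model
#'
#' @description `coronary_lpm()` is the front door of the package: it
#' calibrates the full electrical-analog network for one patient — vessel
#' RLC compartments from geometry, inlet waveform rescaled to measured
#' pressures and heart rate, three-element Windkessel aortic outlet from
#' cardiac output and mean arterial pressure, six-element coronary outlets
#' from the in-vivo total resistances — for both hemodynamic conditions,
#' and returns a model object with the usual methods.
#'
#' @name coronary_lpm-model
NULL

#' Model constants and configuration
#'
#' Collects every tunable constant of the model. Defaults: blood density
#' 1.06 g/cm^3 and viscosity 0.04 P, wall Young's modulus 1.5 MPa,
#' Windkessel compliance 0.001 cm^5/dyn, coronary outlet compliances
#' `c_a = 1e-5` and `c_im = 1e-4` cm^5/dyn (order-of-magnitude values for
#' coronary outlet circuits; both should be reviewed against any available
#' calibration data — sensitivity to them is part of the uncertainty
#' surface), equal split of the venous 16% resistance share, 16 Fourier
#' harmonics, end-diastolic ventricular pressure 10 mmHg, and the
#' one-third pulse-pressure mean-arterial-pressure estimate.
#'
#' @param blood a [blood_properties()]
#' @param wall a [wall_properties()]
#' @param c_a,c_im coronary outlet compliances, cm^5/dyn
#' @param wk3_c aortic Windkessel compliance, cm^5/dyn
#' @param venous_split fraction of the venous resistance share on `R_v`
#' @param n_harmonics Fourier harmonics for all pressure sources
#' @param template the inlet [waveform_template()]
#' @param lvp_edp end-diastolic ventricular pressure, mmHg
#' @param map_method `"third"` or `"waveform"`, see
#'   [mean_arterial_pressure()]
#' @param solver a [solver_settings()]
#' @return list of class `lpm_control`
#' @export
lpm_control <- function(blood = blood_properties(), wall = wall_properties(),
                        c_a = 1e-5, c_im = 1e-4, wk3_c = 0.001,
                        venous_split = 0.5, n_harmonics = 16,
                        template = waveform_template(), lvp_edp = 10,
                        map_method = c("third", "waveform"),
                        solver = solver_settings()) {
  structure(list(blood = blood, wall = wall, c_a = c_a, c_im = c_im,
                 wk3_c = wk3_c, venous_split = venous_split,
                 n_harmonics = n_harmonics, template = template,
                 lvp_edp = lvp_edp, map_method = match.arg(map_method),
                 solver = solver),
            class = "lpm_control")
}

#' Read model configuration from a JSON file
#'
#' Recognized top-level keys mirror the arguments of [lpm_control()]:
#' `blood` (`density`, `dynamic_viscosity`), `wall` (`youngs_modulus`),
#' `outlet_defaults` (`c_a`, `c_im`, `venous_split`, `wk3_c`), `waveform`
#' (`n_harmonics`, `lvp_edp`, `map_method`) and `solver` (any
#' [solver_settings()] argument). Missing keys keep their defaults.
#'
#' @param path path to a JSON configuration file
#' @return an `lpm_control`
#' @export
read_lpm_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- lpm_control()
  if (!is.null(cfg$blood)) {
    ctl$blood <- blood_properties(
      cfg$blood$density %||% 1.06,
      cfg$blood$dynamic_viscosity %||% 0.04)
  }
  if (!is.null(cfg$wall)) {
    ctl$wall <- wall_properties(cfg$wall$youngs_modulus %||% 1.5e7)
  }
  od <- cfg$outlet_defaults
  if (!is.null(od)) {
    ctl$c_a <- od$c_a %||% ctl$c_a
    ctl$c_im <- od$c_im %||% ctl$c_im
    ctl$venous_split <- od$venous_split %||% ctl$venous_split
    ctl$wk3_c <- od$wk3_c %||% ctl$wk3_c
  }
  wf <- cfg$waveform
  if (!is.null(wf)) {
    ctl$n_harmonics <- wf$n_harmonics %||% ctl$n_harmonics
    ctl$lvp_edp <- wf$lvp_edp %||% ctl$lvp_edp
    if (!is.null(wf$map_method)) ctl$map_method <- wf$map_method
  }
  if (!is.null(cfg$solver)) {
    ctl$solver <- do.call(solver_settings, cfg$solver)
  }
  ctl
}

#' Fit (calibrate) the patient-specific lumped-parameter model
#'
#' @param patient a [patient_record()], or path to a patient JSON file
#' @param conditions which hemodynamic conditions to set up (default both)
#' @param control an [lpm_control()]
#' @return object of class `coronary_lpm` with one assembled network and
#'   state-space system per condition
#' @seealso [predict.coronary_lpm()], [simulate.coronary_lpm()],
#'   [residuals.coronary_lpm()]
#' @export
coronary_lpm <- function(patient, conditions = c("rest", "hyperemia"),
                         control = lpm_control()) {
  if (is.character(patient)) patient <- read_patient(patient)
  validate_patient(patient)
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  fits <- lapply(conditions, function(cond) {
    net <- assemble_network(patient, cond, control)
    list(network = net, system = to_state_space(net))
  })
  names(fits) <- conditions
  structure(list(patient = patient, control = control, fits = fits,
                 cache = new.env(parent = emptyenv()),
                 call = match.call()),
            class = "coronary_lpm")
}

#' @export
print.coronary_lpm <- function(x, ...) {
  cat("Coronary lumped-parameter model\n")
  print(x$patient)
  for (cond in names(x$fits)) {
    sys <- x$fits[[cond]]$system
    cat(sprintf("  %s network: %d states\n", cond, length(sys$state_names)))
  }
  invisible(x)
}

#' Circuit parameters of a fitted model
#'
#' @param object a `coronary_lpm`
#' @param condition which condition's parameters (outlet resistances differ
#'   between conditions; segment RLC values do not)
#' @param ... unused
#' @return named numeric vector of all R (dyn s/cm^5), L (dyn s^2/cm^5)
#'   and C (cm^5/dyn) values of that condition's network
#' @export
coef.coronary_lpm <- function(object, condition = "rest", ...) {
  net <- object$fits[[condition]]$network
  if (is.null(net)) stop("condition not fitted: ", condition)
  br <- net$branches
  nd <- net$nodes
  out <- c(stats::setNames(br$R, paste0("R_", br$label)),
           stats::setNames(br$L[br$L > 0],
                           paste0("L_", br$label[br$L > 0])),
           stats::setNames(nd$C[nd$C > 0],
                           paste0("C_", nd$label[nd$C > 0])))
  out
}

.sim_cached <- function(object, condition) {
  key <- condition
  if (!is.null(object$cache[[key]])) return(object$cache[[key]])
  fit <- object$fits[[condition]]
  if (is.null(fit)) stop("condition not fitted: ", condition)
  sim <- simulate_network(fit$network, object$control$solver, fit$system)
  object$cache[[key]] <- sim
  sim
}

#' Run the time-domain simulation of a fitted model
#'
#' @param object a `coronary_lpm`
#' @param nsim unused (one deterministic trajectory per condition)
#' @param seed unused (the model is deterministic)
#' @param condition condition to simulate (default: first fitted)
#' @param ... unused
#' @return an `lpm_simulation` (see [simulate_network()])
#' @export
simulate.coronary_lpm <- function(object, nsim = 1, seed = NULL,
                                  condition = names(object$fits)[1], ...) {
  .sim_cached(object, condition)
}

#' Predicted coronary blood flow
#'
#' Runs (or reuses) the 30-beat simulation for each requested condition
#' and reports the mean flow entering each coronary outlet circuit over
#' the final beat.
#'
#' @param object a `coronary_lpm`
#' @param conditions conditions to predict (default: all fitted)
#' @param ... unused
#' @return data.frame with columns `patient_id`, `condition`, `ca`
#'   ("left"/"right"), `cbf_insilico` (ml/s), `cbf_invivo` (ml/s, NA when
#'   not measured), `converged`
#' @export
predict.coronary_lpm <- function(object, conditions = names(object$fits),
                                 ...) {
  rows <- lapply(conditions, function(cond) {
    sim <- .sim_cached(object, cond)
    st <- object$patient$states[[cond]]
    iv <- c(left = st$cbf_invivo_left %||% NA_real_,
            right = st$cbf_invivo_right %||% NA_real_)
    iv_mls <- ifelse(is.na(iv), NA_real_, iv * 1000 / 60)
    data.frame(patient_id = object$patient$patient_id, condition = cond,
               ca = c("left", "right"),
               cbf_insilico = unname(sim$cbf[c("left", "right")]),
               cbf_invivo = unname(iv_mls),
               converged = sim$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residuals of the model against the in-vivo measurements
#'
#' @param object a `coronary_lpm`
#' @param ... passed to [predict.coronary_lpm()]
#' @return named vector of in-silico minus in-vivo CBF (ml/s) for every
#'   (condition, coronary) with a measurement
#' @export
residuals.coronary_lpm <- function(object, ...) {
  pr <- predict(object, ...)
  ok <- !is.na(pr$cbf_invivo)
  stats::setNames(pr$cbf_insilico[ok] - pr$cbf_invivo[ok],
                  paste(pr$condition[ok], pr$ca[ok], sep = "."))
}

#' @export
summary.coronary_lpm <- function(object, ...) {
  pr <- predict(object)
  pr$reldiff <- ifelse(is.na(pr$cbf_invivo), NA_real_,
                       relative_difference(pr$cbf_insilico, pr$cbf_invivo))
  structure(list(patient = object$patient, prediction = pr),
            class = "summary.coronary_lpm")
}

#' @export
print.summary.coronary_lpm <- function(x, ...) {
  print(x$patient)
  cat("\nPredicted coronary blood flow (final beat, ml/s):\n")
  print(x$prediction, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot pressure and flow traces of a fitted model
#'
#' Shows the inlet aortic pressure against the distal aortic-root node
#' pressure, and the two coronary inflow waveforms, over the final beats
#' of the simulation.
#'
#' @param x a `coronary_lpm`
#' @param condition condition to plot
#' @param beats how many final beats to display (default 2)
#' @param ... unused
#' @return `x`, invisibly
#' @export
plot.coronary_lpm <- function(x, condition = names(x$fits)[1], beats = 2,
                              ...) {
  sim <- .sim_cached(x, condition)
  nb <- sim$settings$n_beats
  T <- diff(range(sim$time)) / nb
  keep <- sim$time >= (nb - beats) * T
  tt <- sim$time[keep]
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  p_in <- source_pressure(sim$network$sources$aorta_inlet, tt,
                          method = "fourier")
  graphics::plot(tt, pressure_cgs_to_mmhg(p_in), type = "l",
                 xlab = "time (s)", ylab = "pressure (mmHg)",
                 main = paste("aortic pressure,", condition))
  graphics::lines(tt, pressure_cgs_to_mmhg(sim$pressures[keep, "ao_sinus_d"]),
                  lty = 2)
  graphics::legend("topright", c("inlet", "sinus node"), lty = 1:2,
                   bty = "n", cex = 0.8)
  graphics::matplot(tt, sim$flows[keep, c("lca_ra", "rca_ra")], type = "l",
                    lty = 1, col = c("firebrick", "navy"),
                    xlab = "time (s)", ylab = "coronary flow (ml/s)",
                    main = "flow into coronary outlets")
  graphics::legend("topright", c("left", "right"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n", cex = 0.8)
  invisible(x)
}
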