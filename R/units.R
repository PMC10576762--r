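#' @title Unit conversions between clinical and cgs units
#'
#' @description Hemodynamic measurements arrive in clinical units (mmHg,
#' L/min, ml, beats/min) while the circuit model works in cgs units
#' (dyn/cm^2, cm^3/s, dyn s/cm^5). These helpers are exact linear maps using
#' the fixed constants 1 mmHg = 1333.22 dyn/cm^2, 1 L = 1000 cm^3,
#' 1 min = 60 s.
#'
#' @name units
NULL

#' Conversion constant: dyn/cm^2 per mmHg
#' @keywords internal
MMHG_PER_DYN_CM2 <- 1333.22

.check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", what), call. = FALSE)
  }
  invisible(x)
}

#' Convert pressure from mmHg to dyn/cm^2
#' @param p pressure in mmHg
#' @return pressure in dyn/cm^2
#' @export
pressure_mmhg_to_cgs <- function(p) p * MMHG_PER_DYN_CM2

#' Convert pressure from dyn/cm^2 to mmHg
#' @param p pressure in dyn/cm^2
#' @return pressure in mmHg
#' @export
pressure_cgs_to_mmhg <- function(p) p / MMHG_PER_DYN_CM2

#' Convert a vascular resistance from clinical to cgs units
#'
#' Clinical total resistances from thermodilution are reported in
#' mmHg/(L/min); the circuit uses dyn s/cm^5. The factor is
#' 1333.22 / (1000/60) = 79.9932.
#'
#' @param r resistance in mmHg/(L/min); must be > 0
#' @return resistance in dyn s/cm^5
#' @export
resistance_clinical_to_cgs <- function(r) {
  .check_positive(r, "r")
  r * MMHG_PER_DYN_CM2 / (1000 / 60)
}

#' Convert a vascular resistance from cgs to clinical units
#' @param r resistance in dyn s/cm^5; must be > 0
#' @return resistance in mmHg/(L/min)
#' @export
resistance_cgs_to_clinical <- function(r) {
  .check_positive(r, "r")
  r * (1000 / 60) / MMHG_PER_DYN_CM2
}

#' Convert a flow from L/min to ml/s
#' @param q flow in L/min
#' @return flow in ml/s (= cm^3/s)
#' @export
flow_lpm_to_mls <- function(q) {
  stopifnot(is.numeric(q), all(is.finite(q)))
  q * 1000 / 60
}

#' Convert a flow from ml/s to L/min
#' @param q flow in ml/s
#' @return flow in L/min
#' @export
flow_mls_to_lpm <- function(q) {
  stopifnot(is.numeric(q), all(is.finite(q)))
  q * 60 / 1000
}

#' Cardiac output from stroke volume and heart rate
#'
#' @param sv stroke volume, ml; > 0
#' @param hr heart rate, beats/min; > 0
#' @return cardiac output in cm^3/s
#' @export
cardiac_output <- function(sv, hr) {
  .check_positive(sv, "sv")
  .check_positive(hr, "hr")
  sv * hr / 60
}

#' Mean arterial pressure estimate
#'
#' The standard one-third pulse-pressure clinical estimate,
#' MAP = DBP + (SBP - DBP)/3. Alternatively `method = "waveform"` returns
#' the time average of a supplied pressure source (see
#' [rescale_template()]), which is the mean pressure the circuit actually
#' sees at its inlet.
#'
#' @param sbp systolic pressure, mmHg
#' @param dbp diastolic pressure, mmHg; must satisfy `sbp > dbp > 0`
#' @param method `"third"` (default) or `"waveform"`
#' @param source a `pressure_source`, required when `method = "waveform"`
#' @return mean arterial pressure in mmHg
#' @export
mean_arterial_pressure <- function(sbp, dbp, method = c("third", "waveform"),
                                   source = NULL) {
  method <- match.arg(method)
  if (method == "waveform") {
    if (!inherits(source, "pressure_source")) {
      stop("`source` must be a pressure_source when method = \"waveform\"",
           call. = FALSE)
    }
    return(pressure_cgs_to_mmhg(source$fourier$a0))
  }
  .check_positive(dbp, "dbp")
  if (any(sbp <= dbp)) stop("`sbp` must exceed `dbp`", call. = FALSE)
  dbp + (sbp - dbp) / 3
}
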