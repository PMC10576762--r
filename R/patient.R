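#' @title Patient records
#'
#' @description Constructors and validators for the per-patient inputs of
#' the lumped-parameter model: aortic root geometry at three anatomical
#' sites, elliptical coronary cross-sections from intravascular ultrasound,
#' cardiac function, and the two measured hemodynamic states (rest and
#' hyperemia) including the in-vivo total coronary resistances. All lengths
#' are in cm; clinical quantities keep their clinical units and are
#' converted on circuit assembly.
#'
#' @name patient
NULL

AORTIC_SITES <- c("annulus", "sinus_sinotubular", "proximal_ascending")
CORONARY_POSITIONS <- c("ostial_intramural", "proximal", "distal")
CONDITIONS <- c("rest", "hyperemia")

#' Aortic segment geometry
#'
#' @param site one of `"annulus"`, `"sinus_sinotubular"`,
#'   `"proximal_ascending"`
#' @param mean_diameter mean lumen diameter, cm
#' @param length distance between consecutive section centroids, cm
#' @param wall_thickness wall thickness, cm (default 0.3 cm, i.e. 3 mm)
#' @return an object of class `aortic_segment`
#' @export
aortic_segment <- function(site, mean_diameter, length, wall_thickness = 0.3) {
  site <- match.arg(site, AORTIC_SITES)
  .check_positive(mean_diameter, "mean_diameter")
  .check_positive(length, "length")
  .check_positive(wall_thickness, "wall_thickness")
  structure(list(site = site, mean_diameter = mean_diameter,
                 length = length, wall_thickness = wall_thickness),
            class = "aortic_segment")
}

#' Coronary segment geometry (elliptical cross-section)
#'
#' @param position one of `"ostial_intramural"`, `"proximal"`, `"distal"`
#' @param semi_axis_max,semi_axis_min semi-axes of the elliptical lumen, cm;
#'   `semi_axis_max >= semi_axis_min > 0`
#' @param length segment length, cm
#' @param wall_thickness wall thickness, cm (default 0.03 cm, i.e. 0.3 mm)
#' @return an object of class `coronary_segment`
#' @export
coronary_segment <- function(position, semi_axis_max, semi_axis_min, length,
                             wall_thickness = 0.03) {
  position <- match.arg(position, CORONARY_POSITIONS)
  .check_positive(semi_axis_min, "semi_axis_min")
  .check_positive(length, "length")
  .check_positive(wall_thickness, "wall_thickness")
  if (semi_axis_max < semi_axis_min) {
    stop("`semi_axis_max` must be >= `semi_axis_min`", call. = FALSE)
  }
  structure(list(position = position, semi_axis_max = semi_axis_max,
                 semi_axis_min = semi_axis_min, length = length,
                 wall_thickness = wall_thickness),
            class = "coronary_segment")
}

#' Coronary branch geometry
#'
#' A normal coronary is described by two compartments (proximal, distal);
#' an anomalous coronary carries a third, most-proximal ostial/intramural
#' compartment.
#'
#' @param side `"left"` or `"right"`
#' @param anomalous logical; does this branch have the anomalous origin?
#' @param segments list of [coronary_segment()] objects, ordered
#'   proximal-to-distal; 3 segments if anomalous, 2 otherwise
#' @return an object of class `coronary_branch`
#' @export
coronary_branch <- function(side, anomalous, segments) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(is.logical(anomalous), length(anomalous) == 1L)
  if (!all(vapply(segments, inherits, logical(1), "coronary_segment"))) {
    stop("`segments` must be a list of coronary_segment objects",
         call. = FALSE)
  }
  n_expected <- if (anomalous) 3L else 2L
  if (length(segments) != n_expected) {
    stop(sprintf("%s branch (anomalous = %s) must have %d segments, got %d",
                 side, anomalous, n_expected, length(segments)),
         call. = FALSE)
  }
  structure(list(side = side, anomalous = anomalous, segments = segments),
            class = "coronary_branch")
}

#' Cardiac function
#'
#' @param stroke_volume ml; > 0
#' @param end_diastolic_volume,end_systolic_volume ml, optional; when both
#'   are given `stroke_volume` must equal their difference
#' @param ejection_fraction fraction in (0, 1), optional
#' @return an object of class `cardiac_function`
#' @export
cardiac_function <- function(stroke_volume, end_diastolic_volume = NULL,
                             end_systolic_volume = NULL,
                             ejection_fraction = NULL) {
  .check_positive(stroke_volume, "stroke_volume")
  if (!is.null(end_diastolic_volume) && !is.null(end_systolic_volume)) {
    if (abs(stroke_volume - (end_diastolic_volume - end_systolic_volume)) >
        1e-6 * stroke_volume) {
      stop("`stroke_volume` must equal EDV - ESV when both volumes are given",
           call. = FALSE)
    }
  }
  structure(list(stroke_volume = stroke_volume,
                 end_diastolic_volume = end_diastolic_volume,
                 end_systolic_volume = end_systolic_volume,
                 ejection_fraction = ejection_fraction),
            class = "cardiac_function")
}

#' Measured hemodynamic state for one condition
#'
#' @param condition `"rest"` or `"hyperemia"`
#' @param heart_rate beats/min
#' @param systolic_pressure,diastolic_pressure aortic pressures, mmHg;
#'   `systolic_pressure > diastolic_pressure > 0`
#' @param R_total_left,R_total_right in-vivo total coronary resistances,
#'   mmHg/(L/min)
#' @param cbf_invivo_left,cbf_invivo_right optional measured coronary blood
#'   flow, L/min
#' @return an object of class `hemodynamic_state`
#' @export
hemodynamic_state <- function(condition, heart_rate, systolic_pressure,
                              diastolic_pressure, R_total_left, R_total_right,
                              cbf_invivo_left = NULL, cbf_invivo_right = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  .check_positive(heart_rate, "heart_rate")
  .check_positive(diastolic_pressure, "diastolic_pressure")
  if (systolic_pressure <= diastolic_pressure) {
    stop("`systolic_pressure` must exceed `diastolic_pressure`",
         call. = FALSE)
  }
  .check_positive(R_total_left, "R_total_left")
  .check_positive(R_total_right, "R_total_right")
  structure(list(condition = condition, heart_rate = heart_rate,
                 systolic_pressure = systolic_pressure,
                 diastolic_pressure = diastolic_pressure,
                 R_total_left = R_total_left, R_total_right = R_total_right,
                 cbf_invivo_left = cbf_invivo_left,
                 cbf_invivo_right = cbf_invivo_right),
            class = "hemodynamic_state")
}

#' Full per-patient record
#'
#' @param patient_id character identifier
#' @param anomaly_side `"left"` or `"right"`: which coronary has the
#'   anomalous aortic origin
#' @param aorta list of exactly three [aortic_segment()] objects, ordered
#'   annulus, sinus/sinotubular, proximal ascending
#' @param left_ca,right_ca [coronary_branch()] objects; the branch on
#'   `anomaly_side` must be flagged anomalous (3 compartments)
#' @param cardiac a [cardiac_function()]
#' @param states named list of [hemodynamic_state()], with both `rest` and
#'   `hyperemia` present
#' @return an object of class `patient_record`
#' @export
patient_record <- function(patient_id, anomaly_side, aorta, left_ca, right_ca,
                           cardiac, states) {
  rec <- structure(list(patient_id = as.character(patient_id),
                        anomaly_side = match.arg(anomaly_side,
                                                 c("left", "right")),
                        aorta = aorta, left_ca = left_ca, right_ca = right_ca,
                        cardiac = cardiac, states = states),
                   class = "patient_record")
  validate_patient(rec)
}

#' Validate a patient record against all structural invariants
#'
#' @param rec a `patient_record`
#' @return `rec`, invisibly usable, after validation; errors name the
#'   offending field
#' @export
validate_patient <- function(rec) {
  if (!inherits(rec, "patient_record")) stop("not a patient_record")
  if (length(rec$aorta) != 3L ||
      !all(vapply(rec$aorta, inherits, logical(1), "aortic_segment"))) {
    stop("`aorta` must contain exactly three aortic_segment objects",
         call. = FALSE)
  }
  sites <- vapply(rec$aorta, `[[`, character(1), "site")
  if (!identical(sites, AORTIC_SITES)) {
    stop("`aorta` segments must be ordered annulus, sinus_sinotubular, ",
         "proximal_ascending", call. = FALSE)
  }
  for (s in c("left", "right")) {
    br <- rec[[paste0(s, "_ca")]]
    if (!inherits(br, "coronary_branch") || br$side != s) {
      stop(sprintf("`%s_ca` must be a coronary_branch with side \"%s\"", s, s),
           call. = FALSE)
    }
    want <- identical(rec$anomaly_side, s)
    if (!identical(br$anomalous, want)) {
      stop(sprintf("`%s_ca$anomalous` must be %s for anomaly_side \"%s\"",
                   s, want, rec$anomaly_side), call. = FALSE)
    }
    n_expected <- if (want) 3L else 2L
    if (length(br$segments) != n_expected) {
      stop(sprintf("`%s_ca` must have %d segments", s, n_expected),
           call. = FALSE)
    }
  }
  if (!inherits(rec$cardiac, "cardiac_function")) {
    stop("`cardiac` must be a cardiac_function", call. = FALSE)
  }
  if (!all(CONDITIONS %in% names(rec$states))) {
    stop("`states` must contain both \"rest\" and \"hyperemia\"",
         call. = FALSE)
  }
  for (cond in names(rec$states)) {
    st <- rec$states[[cond]]
    if (!inherits(st, "hemodynamic_state") || st$condition != cond) {
      stop(sprintf("states[[\"%s\"]] must be a hemodynamic_state for that ",
                   "condition", cond), call. = FALSE)
    }
  }
  rec
}

#' @export
print.patient_record <- function(x, ...) {
  cat("Patient record:", x$patient_id, "\n")
  cat("  anomalous origin:", x$anomaly_side, "coronary\n")
  cat("  stroke volume:", x$cardiac$stroke_volume, "ml\n")
  for (cond in names(x$states)) {
    st <- x$states[[cond]]
    cat(sprintf("  %-9s HR %.0f bpm, %g/%g mmHg, R(L/R) %.0f/%.0f mmHg/(L/min)\n",
                cond, st$heart_rate, st$systolic_pressure,
                st$diastolic_pressure, st$R_total_left, st$R_total_right))
  }
  invisible(x)
}

# ---- JSON input/output --------------------------------------------------

.seg_to_list <- function(s) unclass(s)

.require_fields <- function(lst, fields, where) {
  miss <- setdiff(fields, names(lst))
  if (length(miss)) {
    stop(sprintf("%s: missing required field(s) %s", where,
                 paste0("\"", miss, "\"", collapse = ", ")), call. = FALSE)
  }
}

#' Write a patient record to a JSON file
#'
#' One JSON document per patient; the schema shipped at
#' `system.file("extdata", "patient-schema.json", package = "coroflow")`
#' documents the layout. The round trip through [read_patient()] is
#' lossless.
#'
#' @param rec a validated `patient_record`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_patient <- function(rec, path) {
  validate_patient(rec)
  out <- list(
    patient_id = rec$patient_id,
    anomaly_side = rec$anomaly_side,
    aorta = lapply(rec$aorta, .seg_to_list),
    left_ca = list(side = "left", anomalous = rec$left_ca$anomalous,
                   segments = lapply(rec$left_ca$segments, .seg_to_list)),
    right_ca = list(side = "right", anomalous = rec$right_ca$anomalous,
                    segments = lapply(rec$right_ca$segments, .seg_to_list)),
    cardiac = Filter(Negate(is.null), unclass(rec$cardiac)),
    states = lapply(rec$states,
                    function(st) Filter(Negate(is.null), unclass(st)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a patient record from a JSON file
#'
#' All structural invariants are validated on load; violations raise an
#' error naming the offending field.
#'
#' @param path path to a patient JSON file written by [write_patient()] or
#'   following the shipped schema
#' @return a validated `patient_record`
#' @export
read_patient <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  .require_fields(raw, c("patient_id", "anomaly_side", "aorta", "left_ca",
                         "right_ca", "cardiac", "states"), "patient record")
  parse_aseg <- function(s) {
    .require_fields(s, c("site", "mean_diameter", "length"), "aortic segment")
    aortic_segment(s$site, s$mean_diameter, s$length,
                   s$wall_thickness %||% 0.3)
  }
  parse_cseg <- function(s) {
    .require_fields(s, c("position", "semi_axis_max", "semi_axis_min",
                         "length"), "coronary segment")
    coronary_segment(s$position, s$semi_axis_max, s$semi_axis_min, s$length,
                     s$wall_thickness %||% 0.03)
  }
  parse_branch <- function(b, side) {
    .require_fields(b, c("anomalous", "segments"), paste0(side, "_ca"))
    coronary_branch(side, isTRUE(b$anomalous),
                    lapply(b$segments, parse_cseg))
  }
  parse_state <- function(st, cond) {
    .require_fields(st, c("heart_rate", "systolic_pressure",
                          "diastolic_pressure", "R_total_left",
                          "R_total_right"),
                    sprintf("states[\"%s\"]", cond))
    hemodynamic_state(cond, st$heart_rate, st$systolic_pressure,
                      st$diastolic_pressure, st$R_total_left,
                      st$R_total_right, st$cbf_invivo_left,
                      st$cbf_invivo_right)
  }
  .require_fields(raw$cardiac, "stroke_volume", "cardiac")
  states <- lapply(CONDITIONS, function(cond) {
    if (is.null(raw$states[[cond]])) {
      stop(sprintf("states: missing required condition \"%s\"", cond),
           call. = FALSE)
    }
    parse_state(raw$states[[cond]], cond)
  })
  names(states) <- CONDITIONS
  patient_record(raw$patient_id, raw$anomaly_side,
                 lapply(raw$aorta, parse_aseg),
                 parse_branch(raw$left_ca, "left"),
                 parse_branch(raw$right_ca, "right"),
                 cardiac_function(raw$cardiac$stroke_volume,
                                  raw$cardiac$end_diastolic_volume,
                                  raw$cardiac$end_systolic_volume,
                                  raw$cardiac$ejection_fraction),
                 states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
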