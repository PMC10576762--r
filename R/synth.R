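#' @title Synthetic cohort generation
#'
#' @description Generates synthetic patient records with the statistical
#' structure of an AAOCA catheterization cohort, so that the whole
#' pipeline (I/O, circuit assembly, simulation, validation statistics) is
#' exercisable without access to clinical tables. Geometry is drawn
#' uniformly within physiological ranges; total coronary resistances are
#' chosen so that the resistive-limit flow (mean inlet pressure over total
#' path resistance) lands in the span of published AAOCA measurements,
#' with right-skewed (log-normal) flow targets; hyperemic resistances are
#' strictly below rest resistances. Each record is stored together with
#' its analytic resistive-limit flow (the "synthetic truth") for recovery
#' testing.
#'
#' @name synth_cohort
NULL

.default_ranges <- function() {
  list(
    aortic_diameter = list(annulus = c(2.0, 2.8),
                           sinus_sinotubular = c(2.6, 3.8),
                           proximal_ascending = c(2.4, 3.4)),
    aortic_length = c(1.0, 2.5),
    coronary_semi_axis_max = c(0.15, 0.30),
    coronary_axis_ratio = c(0.70, 1.00),       # b/a, proximal & distal
    intramural_axis_ratio = c(0.40, 0.70),     # flattened intramural tract
    distal_taper = c(0.55, 0.85),
    coronary_length = c(0.5, 3.0),
    intramural_length = c(0.5, 1.5),
    stroke_volume = c(50, 110),
    heart_rate_rest = c(55, 95),
    hyperemia_hr_gain = c(1.00, 1.15),
    dbp = c(60, 95),
    pulse_pressure = c(30, 70),
    cbf_rest_span = c(0.4, 10),                # ml/s, resistive-limit target
    cbf_hyperemia_span = c(2, 14),
    cbf_rest_meanlog = c(left = log(1.6), right = log(1.1)),
    cbf_rest_sdlog = 0.55,
    hyperemia_flow_gain = c(2.0, 4.0),
    invivo_noise_sd = 0.05
  )
}

#' Specification of a synthetic cohort
#'
#' @param n_patients number of patients (default 19)
#' @param anomalous_right_fraction fraction with an anomalous right
#'   coronary (default 15/19)
#' @param seed integer seed making the cohort reproducible
#' @param ranges optional named list overriding entries of the default
#'   parameter ranges (see the source of `coroflow:::.default_ranges`)
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_patients = 19, anomalous_right_fraction = 15 / 19,
                        seed = 1, ranges = list()) {
  stopifnot(n_patients >= 1, anomalous_right_fraction >= 0,
            anomalous_right_fraction <= 1)
  rg <- utils::modifyList(.default_ranges(), ranges)
  bad <- vapply(rg[c("aortic_length", "coronary_semi_axis_max",
                     "coronary_length", "stroke_volume", "dbp",
                     "pulse_pressure")],
                function(v) v[1] <= 0 || v[2] < v[1], logical(1))
  if (any(bad)) stop("spec error: impossible range(s): ",
                     paste(names(bad)[bad], collapse = ", "))
  structure(list(n_patients = as.integer(n_patients),
                 anomalous_right_fraction = anomalous_right_fraction,
                 seed = as.integer(seed), ranges = rg),
            class = "cohort_spec")
}

.runif1 <- function(range) stats::runif(1, range[1], range[2])

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Generate one synthetic patient with its analytic truth
#'
#' Deterministic given `(spec, index)`: the per-patient RNG stream is
#' seeded from the spec seed and the patient index. Patients with index up
#' to `round(n_patients * anomalous_right_fraction)` carry the anomalous
#' right coronary, the rest the anomalous left.
#'
#' @param spec a [cohort_spec()]
#' @param index patient index in `1:n_patients`
#' @param control an [lpm_control()] (supplies the waveform template whose
#'   time average defines the mean inlet pressure of the resistive limit)
#' @return list with elements `patient` (a [patient_record()]) and `truth`
#'   (per condition, the resistive-limit CBF per side in ml/s and the mean
#'   inlet pressure in mmHg)
#' @export
generate_patient <- function(spec, index, control = lpm_control()) {
  stopifnot(inherits(spec, "cohort_spec"), index >= 1,
            index <= spec$n_patients)
  rg <- spec$ranges
  n_right <- round(spec$n_patients * spec$anomalous_right_fraction)
  side <- if (index <= n_right) "right" else "left"
  seed_i <- (abs(spec$seed) * 1009L + as.integer(index) * 9973L) %%
    .Machine$integer.max

  .with_seed(seed_i, {
    aorta <- lapply(AORTIC_SITES, function(site) {
      aortic_segment(site, .runif1(rg$aortic_diameter[[site]]),
                     .runif1(rg$aortic_length))
    })

    make_branch <- function(br_side) {
      anomalous <- identical(br_side, side)
      a_prox <- .runif1(rg$coronary_semi_axis_max)
      segs <- list()
      if (anomalous) {
        a_im <- .runif1(rg$coronary_semi_axis_max)
        segs <- c(segs, list(coronary_segment(
          "ostial_intramural", a_im,
          a_im * .runif1(rg$intramural_axis_ratio),
          .runif1(rg$intramural_length))))
      }
      a_dist <- a_prox * .runif1(rg$distal_taper)
      segs <- c(segs, list(
        coronary_segment("proximal", a_prox,
                         a_prox * .runif1(rg$coronary_axis_ratio),
                         .runif1(rg$coronary_length)),
        coronary_segment("distal", a_dist,
                         a_dist * .runif1(rg$coronary_axis_ratio),
                         .runif1(rg$coronary_length))))
      coronary_branch(br_side, anomalous, segs)
    }
    left_ca <- make_branch("left")
    right_ca <- make_branch("right")

    sv <- .runif1(rg$stroke_volume)
    hr_rest <- .runif1(rg$heart_rate_rest)
    hr_hyp <- hr_rest * .runif1(rg$hyperemia_hr_gain)
    dbp <- .runif1(rg$dbp)
    sbp <- min(dbp + .runif1(rg$pulse_pressure), 160)
    p_mean_mmhg <- dbp + control$template$mean * (sbp - dbp)
    p_mean_cgs <- pressure_mmhg_to_cgs(p_mean_mmhg)

    seg_r <- function(branch) {
      sum(vapply(branch$segments, function(s) {
        rlc_elliptical(s$semi_axis_max, s$semi_axis_min, s$length,
                       s$wall_thickness, control$blood, control$wall)$R
      }, numeric(1)))
    }
    chain_r <- c(left = seg_r(left_ca), right = seg_r(right_ca))

    # flow targets (ml/s): right-skewed at rest, amplified in hyperemia,
    # clipped to the configured spans; hyperemic target always exceeds the
    # rest target so hyperemic resistance is strictly lower
    span_r <- rg$cbf_rest_span
    margin <- 0.05 * diff(span_r)
    target <- list()
    target$rest <- vapply(c("left", "right"), function(s) {
      min(max(stats::rlnorm(1, rg$cbf_rest_meanlog[[s]], rg$cbf_rest_sdlog),
              span_r[1] + margin), span_r[2] - margin)
    }, numeric(1))
    span_h <- rg$cbf_hyperemia_span
    target$hyperemia <- vapply(c("left", "right"), function(s) {
      min(max(target$rest[[s]] * .runif1(rg$hyperemia_flow_gain),
              span_h[1] + 0.05), span_h[2] - 0.05)
    }, numeric(1))

    states <- list()
    truth_cbf <- list()
    for (cond in CONDITIONS) {
      r_out_cgs <- p_mean_cgs / target[[cond]]      # named left/right
      truth_cbf[[cond]] <- p_mean_cgs / (r_out_cgs + chain_r)
      noise <- 1 + stats::rnorm(2, 0, rg$invivo_noise_sd)
      invivo <- flow_mls_to_lpm(truth_cbf[[cond]] * pmax(noise, 0.5))
      states[[cond]] <- hemodynamic_state(
        cond, if (cond == "rest") hr_rest else hr_hyp, sbp, dbp,
        R_total_left = resistance_cgs_to_clinical(r_out_cgs[["left"]]),
        R_total_right = resistance_cgs_to_clinical(r_out_cgs[["right"]]),
        cbf_invivo_left = invivo[["left"]],
        cbf_invivo_right = invivo[["right"]])
    }

    patient <- patient_record(sprintf("synth-%03d", index), side, aorta,
                              left_ca, right_ca, cardiac_function(sv),
                              states)
    truth <- list(patient_id = patient$patient_id,
                  cbf_resistive = truth_cbf,
                  mean_pressure_mmhg = p_mean_mmhg, seed = seed_i)
    list(patient = patient, truth = truth)
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()]
#' @param dir optional directory; when given, per-patient JSON files, a
#'   cohort CSV (one row per patient per condition) and a truths JSON are
#'   written there
#' @param control an [lpm_control()]
#' @return list with `patients` (list of records), `truths`, and `spec`
#' @export
generate_cohort <- function(spec, dir = NULL, control = lpm_control()) {
  stopifnot(inherits(spec, "cohort_spec"))
  gen <- lapply(seq_len(spec$n_patients), generate_patient, spec = spec,
                control = control)
  patients <- lapply(gen, `[[`, "patient")
  truths <- lapply(gen, `[[`, "truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in patients) {
      write_patient(p, file.path(dir, paste0(p$patient_id, ".json")))
    }
    rows <- do.call(rbind, lapply(patients, function(p) {
      do.call(rbind, lapply(CONDITIONS, function(cond) {
        st <- p$states[[cond]]
        data.frame(patient_id = p$patient_id, anomaly_side = p$anomaly_side,
                   condition = cond, stroke_volume = p$cardiac$stroke_volume,
                   heart_rate = st$heart_rate,
                   systolic_pressure = st$systolic_pressure,
                   diastolic_pressure = st$diastolic_pressure,
                   R_total_left = st$R_total_left,
                   R_total_right = st$R_total_right,
                   cbf_invivo_left = st$cbf_invivo_left,
                   cbf_invivo_right = st$cbf_invivo_right,
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(rows, file.path(dir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(truths, file.path(dir, "truths.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(patients = patients, truths = truths, spec = spec)
}

#' Read a generated cohort directory back
#'
#' @param dir directory written by [generate_cohort()]
#' @return list of validated [patient_record()] objects
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^synth-.*\\.json$",
                           full.names = TRUE))
  if (!length(files)) stop("no patient JSON files found in ", dir)
  lapply(files, read_patient)
}
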