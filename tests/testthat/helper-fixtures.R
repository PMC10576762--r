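# deterministic builders used across test files

# hand-written small patient: anomalous right coronary (3 compartments)
toy_patient <- function(anomaly_side = "right") {
  aorta <- list(
    aortic_segment("annulus", 2.4, 1.2),
    aortic_segment("sinus_sinotubular", 3.2, 1.8),
    aortic_segment("proximal_ascending", 3.0, 2.0)
  )
  normal_segs <- list(
    coronary_segment("proximal", 0.22, 0.18, 1.5),
    coronary_segment("distal", 0.16, 0.14, 2.0)
  )
  anomalous_segs <- list(
    coronary_segment("ostial_intramural", 0.24, 0.11, 1.0),
    coronary_segment("proximal", 0.20, 0.16, 1.4),
    coronary_segment("distal", 0.15, 0.12, 1.8)
  )
  left_segs <- if (anomaly_side == "left") anomalous_segs else normal_segs
  right_segs <- if (anomaly_side == "right") anomalous_segs else normal_segs
  states <- list(
    rest = hemodynamic_state("rest", 70, 125, 78,
                             R_total_left = 820, R_total_right = 1100,
                             cbf_invivo_left = 0.108,
                             cbf_invivo_right = 0.080),
    hyperemia = hemodynamic_state("hyperemia", 78, 125, 78,
                                  R_total_left = 240, R_total_right = 310,
                                  cbf_invivo_left = 0.36,
                                  cbf_invivo_right = 0.28)
  )
  patient_record("toy-01", anomaly_side, aorta,
                 coronary_branch("left", anomaly_side == "left", left_segs),
                 coronary_branch("right", anomaly_side == "right",
                                 right_segs),
                 cardiac_function(72), states)
}

# arbitrary periodic source from a plain function (cgs pressures)
make_test_source <- function(fun, period, n_harmonics = 10, dbp = NULL,
                             sbp = NULL, label = "test") {
  src <- structure(list(period = period, fun = fun, sbp = sbp, dbp = dbp,
                        fourier = NULL, label = label),
                   class = "pressure_source")
  src$fourier <- fourier_fit(src, n_harmonics = n_harmonics)
  src
}

constant_source <- function(P0, period = 1) {
  make_test_source(function(t) rep_len(P0, length(t)), period,
                   n_harmonics = 1)
}

# P0 + amp * cos(2 pi t / period)
cosine_source <- function(P0, amp, period = 1) {
  make_test_source(function(t) P0 + amp * cos(2 * pi * t / period), period,
                   n_harmonics = 3)
}

# minimal network: pinned inlet feeding a three-element Windkessel
wk3_network <- function(source, R_p = 100, R_d = 1000, C = 1e-3) {
  nodes <- data.frame(
    node = 1:2, label = c("inlet", "wk"), C = c(0, C),
    c_ref = NA_character_, pin = c("inlet_src", NA_character_),
    stringsAsFactors = FALSE)
  branches <- data.frame(
    from = c(1L, 2L), to = c(2L, 0L), R = c(R_p, R_d), L = 0,
    label = c("wk_prox", "wk_dist"), stringsAsFactors = FALSE)
  lpm_network(nodes, branches, list(inlet_src = source))
}

# single RC low-pass: pinned source - R - node with C to ground
rc_network <- function(source, R = 50, C = 2e-4) {
  nodes <- data.frame(
    node = 1:2, label = c("in", "out"), C = c(0, C),
    c_ref = NA_character_, pin = c("src", NA_character_),
    stringsAsFactors = FALSE)
  branches <- data.frame(
    from = 1L, to = 2L, R = R, L = 0,
    label = "rin", stringsAsFactors = FALSE)
  lpm_network(nodes, branches, list(src = source))
}
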