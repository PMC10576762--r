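#' Monte-Carlo uncertainty quantification over coronary resistances
#'
#' The measured total coronary resistances are the inputs the model is
#' most sensitive to. This experiment perturbs them: for each relative
#' standard-deviation level, `n` pairs `(R_left, R_right)` are drawn from
#' normal distributions centred on the in-vivo measurements with SD equal
#' to `level * measurement` (negative draws are rejected and redrawn), the
#' rest-condition simulation is rerun for every draw, and the dispersion
#' of the resulting mean CBF is summarized per level.
#'
#' @param patient a [patient_record()]
#' @param sd_levels increasing positive relative-SD levels (default 5%,
#'   10%, 20%)
#' @param n samples per level (default 100)
#' @param seed integer seed; results are reproducible given
#'   `(seed, sd_levels, n)`
#' @param condition condition simulated (default `"rest"`)
#' @param control an [lpm_control()]
#' @return object of class `uq_result`: per level a data.frame of draws
#'   (`R_left`, `R_right` in mmHg/(L/min), `cbf_left`, `cbf_right` in
#'   ml/s) plus `dispersion` (SD and IQR of CBF per side and level) and
#'   the baseline (unperturbed) CBF
#' @export
uq_resistance_sampling <- function(patient, sd_levels = c(0.05, 0.10, 0.20),
                                   n = 100, seed = 1, condition = "rest",
                                   control = lpm_control()) {
  validate_patient(patient)
  stopifnot(length(sd_levels) >= 1, all(sd_levels > 0),
            !is.unsorted(sd_levels, strictly = TRUE), n >= 2)
  st <- patient$states[[condition]]
  base_fit <- coronary_lpm(patient, conditions = condition,
                           control = control)
  base <- predict(base_fit)
  baseline <- stats::setNames(base$cbf_insilico, base$ca)

  draw_pos <- function(mean, sd, k) {
    out <- numeric(k)
    need <- seq_len(k)
    while (length(need)) {
      out[need] <- stats::rnorm(length(need), mean, sd)
      need <- which(out <= 0)
    }
    out
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  levels_out <- lapply(sd_levels, function(lvl) {
    RL <- draw_pos(st$R_total_left, lvl * st$R_total_left, n)
    RR <- draw_pos(st$R_total_right, lvl * st$R_total_right, n)
    cbf <- t(vapply(seq_len(n), function(i) {
      p <- patient
      p$states[[condition]]$R_total_left <- RL[i]
      p$states[[condition]]$R_total_right <- RR[i]
      net <- assemble_network(p, condition, control)
      sim <- simulate_network(net, control$solver)
      sim$cbf[c("left", "right")]
    }, numeric(2)))
    data.frame(sample = seq_len(n), R_left = RL, R_right = RR,
               cbf_left = cbf[, 1], cbf_right = cbf[, 2])
  })
  names(levels_out) <- paste0("sd_", sd_levels)

  dispersion <- do.call(rbind, lapply(seq_along(sd_levels), function(i) {
    d <- levels_out[[i]]
    data.frame(sd_level = sd_levels[i],
               sd_cbf_left = stats::sd(d$cbf_left),
               sd_cbf_right = stats::sd(d$cbf_right),
               iqr_cbf_left = cohort_summary(d$cbf_left)$iqr,
               iqr_cbf_right = cohort_summary(d$cbf_right)$iqr)
  }))

  structure(list(sd_levels = sd_levels, n = n, seed = seed,
                 condition = condition, samples = levels_out,
                 dispersion = dispersion, baseline = baseline),
            class = "uq_result")
}

#' @export
print.uq_result <- function(x, ...) {
  cat(sprintf("Resistance UQ (%s, %d samples/level, seed %d)\n",
              x$condition, x$n, x$seed))
  cat(sprintf("  baseline CBF: left %.3f, right %.3f ml/s\n",
              x$baseline[["left"]], x$baseline[["right"]]))
  print(x$dispersion, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.uq_result <- function(x, ...) {
  d <- do.call(rbind, lapply(seq_along(x$sd_levels), function(i) {
    data.frame(lvl = x$sd_levels[i], cbf = x$samples[[i]]$cbf_left)
  }))
  graphics::boxplot(cbf ~ lvl, data = d, xlab = "relative SD of resistance",
                    ylab = "left CBF (ml/s)", ...)
  graphics::abline(h = x$baseline[["left"]], lty = 2, col = "grey40")
  invisible(x)
}
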