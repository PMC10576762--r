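#' Published AAOCA validation cohort: in-silico and in-vivo CBF
#'
#' Loads the packaged 19-patient validation cohort: per patient, the
#' anomalous side and, for each coronary (LCA, RCA) and each hemodynamic
#' condition (rest, hyperemia), the model-computed (in-silico) coronary
#' blood flow, the thermodilution-measured (in-vivo) flow, both in ml/s,
#' and the relative difference as published. One row per patient, wide
#' layout.
#'
#' Two typographic quirks of the published table are preserved as printed:
#' patient 9's RCA-rest in-silico value is stored as 0.87, and patient 2's
#' LCA-hyperemia relative difference is stored as -0.41 even though the
#' flow columns give +0.04 (recomputation paths always use the flow
#' columns, see [relative_difference()]).
#'
#' @return a `data.frame` of class `cohort_cbf` with 19 rows and columns
#'   `patient_id`, `anomalous_side`, and
#'   `{lca,rca}_{rest,hyperemia}_{insilico,invivo,reldiff}`
#' @export
cohort_cbf <- function() {
  path <- system.file("extdata", "aaoca_cohort_cbf.csv", package = "coroflow")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 19L,
            all(c("patient_id", "anomalous_side") %in% names(df)))
  for (ca in c("lca", "rca")) for (cond in CONDITIONS) {
    for (kind in c("insilico", "invivo", "reldiff")) {
      col <- paste(ca, cond, kind, sep = "_")
      if (!col %in% names(df)) stop("fixture missing column ", col)
      stopifnot(is.numeric(df[[col]]))
    }
  }
  class(df) <- c("cohort_cbf", "data.frame")
  df
}

#' Reshape the validation cohort to long format
#'
#' @param df a `cohort_cbf` data frame (default: the packaged cohort)
#' @return a long `data.frame` with columns `patient_id`, `anomalous_side`,
#'   `ca` ("left"/"right"), `condition`, `cbf_insilico`, `cbf_invivo`,
#'   `reldiff_published`
#' @export
cohort_cbf_long <- function(df = cohort_cbf()) {
  out <- do.call(rbind, lapply(c(lca = "left", rca = "right"), function(side) {
    ca <- if (side == "left") "lca" else "rca"
    do.call(rbind, lapply(CONDITIONS, function(cond) {
      data.frame(patient_id = df$patient_id,
                 anomalous_side = df$anomalous_side,
                 ca = side, condition = cond,
                 cbf_insilico = df[[paste(ca, cond, "insilico", sep = "_")]],
                 cbf_invivo = df[[paste(ca, cond, "invivo", sep = "_")]],
                 reldiff_published = df[[paste(ca, cond, "reldiff",
                                               sep = "_")]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
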