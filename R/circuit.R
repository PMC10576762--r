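#' @title Electrical-analog circuit building blocks
#'
#' @description Each short vessel tract is reduced to one RLC compartment
#' of a transmission line (a simplified Westerhof segment): Poiseuille
#' resistance for viscous loss, inertance for blood inertia, and a
#' thin-wall compliance for wall distensibility. The aorta terminates in a
#' three-element Windkessel; each coronary terminates in a six-element
#' outlet circuit whose total resistance is the in-vivo measured value and
#' whose intramyocardial capacitor is driven by a ventricular pressure
#' source.
#'
#' @name circuit
NULL

#' Blood properties
#' @param density g/cm^3 (default 1.06)
#' @param dynamic_viscosity poise (default 0.04)
#' @return an object of class `blood_properties`
#' @export
blood_properties <- function(density = 1.06, dynamic_viscosity = 0.04) {
  .check_positive(density, "density")
  .check_positive(dynamic_viscosity, "dynamic_viscosity")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "blood_properties")
}

#' Arterial wall properties (linear elastic)
#' @param youngs_modulus dyn/cm^2 (default 1.5 MPa = 1.5e7 dyn/cm^2)
#' @return an object of class `wall_properties`
#' @export
wall_properties <- function(youngs_modulus = 1.5e7) {
  .check_positive(youngs_modulus, "youngs_modulus")
  structure(list(youngs_modulus = youngs_modulus), class = "wall_properties")
}

#' RLC compartment for a cylindrical segment (circular cross-section)
#'
#' With lumen radius `r` (half the mean diameter), length `l`, wall thickness `h`,
#' blood viscosity `mu` and density `rho`, and wall Young's modulus `E`:
#' `R = 8 mu l / (pi r^4)` (Poiseuille), `L = rho l / (pi r^2)` (inertance),
#' `C = 3 pi r^3 l / (2 E h)` (thin-wall compliance).
#'
#' @param mean_diameter lumen diameter, cm
#' @param length segment length, cm
#' @param wall_thickness wall thickness, cm
#' @param blood a [blood_properties()]
#' @param wall a [wall_properties()]
#' @return list of class `segment_rlc` with elements `R` (dyn s/cm^5),
#'   `L` (dyn s^2/cm^5), `C` (cm^5/dyn)
#' @export
rlc_circular <- function(mean_diameter, length, wall_thickness,
                         blood = blood_properties(),
                         wall = wall_properties()) {
  .check_positive(mean_diameter, "mean_diameter")
  .check_positive(length, "length")
  .check_positive(wall_thickness, "wall_thickness")
  r <- mean_diameter / 2
  mu <- blood$dynamic_viscosity
  rho <- blood$density
  E <- wall$youngs_modulus
  structure(list(
    R = 8 * mu * length / (pi * r^4),
    L = rho * length / (pi * r^2),
    C = 3 * pi * r^3 * length / (2 * E * wall_thickness)
  ), class = "segment_rlc")
}

#' RLC compartment for an elliptical segment
#'
#' Resistance uses the exact fully developed flow solution for an
#' elliptical duct, `R = 4 mu l (a^2 + b^2) / (pi a^3 b^3)`; inertance uses
#' the elliptical area `A = pi a b`; compliance uses the area-equivalent
#' circular radius `r_eq = sqrt(a b)`. For `a = b` all three reduce to the
#' circular formulas.
#'
#' @param semi_axis_max,semi_axis_min semi-axes `a >= b > 0`, cm
#' @param length segment length, cm
#' @param wall_thickness wall thickness, cm
#' @param blood a [blood_properties()]
#' @param wall a [wall_properties()]
#' @return list of class `segment_rlc` with elements `R`, `L`, `C`
#' @export
rlc_elliptical <- function(semi_axis_max, semi_axis_min, length,
                           wall_thickness, blood = blood_properties(),
                           wall = wall_properties()) {
  a <- semi_axis_max
  b <- semi_axis_min
  .check_positive(b, "semi_axis_min")
  .check_positive(length, "length")
  .check_positive(wall_thickness, "wall_thickness")
  if (a < b) stop("`semi_axis_max` must be >= `semi_axis_min`", call. = FALSE)
  mu <- blood$dynamic_viscosity
  rho <- blood$density
  E <- wall$youngs_modulus
  area <- pi * a * b
  r_eq <- sqrt(a * b)
  structure(list(
    R = 4 * mu * length * (a^2 + b^2) / (pi * a^3 * b^3),
    L = rho * length / area,
    C = 3 * pi * r_eq^3 * length / (2 * E * wall_thickness)
  ), class = "segment_rlc")
}

#' Split a total coronary resistance among the outlet components
#'
#' The in-vivo measured total resistance of a coronary outlet is divided
#' 32% / 52% / 16% among the proximal arterial resistance `R_a`, the
#' arterial microcirculation `R_a_micro`, and the series of the venous
#' resistances `R_v + R_v_micro`. The internal venous split is an equal
#' halves default (configurable); only the series sum is constrained.
#'
#' @param R_total_cgs total outlet resistance, dyn s/cm^5
#' @param venous_split fraction of the venous 16% share assigned to `R_v`
#'   (default 0.5)
#' @return named list with `R_a`, `R_a_micro`, `R_v`, `R_v_micro`; the four
#'   sum back to `R_total_cgs`
#' @export
split_coronary_resistance <- function(R_total_cgs, venous_split = 0.5) {
  .check_positive(R_total_cgs, "R_total_cgs")
  stopifnot(venous_split > 0, venous_split < 1)
  list(R_a = 0.32 * R_total_cgs,
       R_a_micro = 0.52 * R_total_cgs,
       R_v = 0.16 * venous_split * R_total_cgs,
       R_v_micro = 0.16 * (1 - venous_split) * R_total_cgs)
}

#' Three-element Windkessel for the aortic outlet
#'
#' The total systemic resistance is mean arterial pressure over cardiac
#' output; it is allocated 91% to the distal resistance `R_d` and 9% to
#' the proximal `R_p`. The compliance defaults to 0.001 cm^5/dyn.
#'
#' @param co cardiac output, cm^3/s
#' @param map_cgs mean arterial pressure, dyn/cm^2
#' @param C Windkessel compliance, cm^5/dyn
#' @return list of class `aortic_outlet_wk3` with `R_p`, `R_d`, `C`,
#'   `R_total`
#' @export
build_aortic_outlet <- function(co, map_cgs, C = 0.001) {
  .check_positive(co, "co")
  .check_positive(map_cgs, "map_cgs")
  .check_positive(C, "C")
  R_total <- map_cgs / co
  structure(list(R_p = 0.09 * R_total, R_d = 0.91 * R_total, C = C,
                 R_total = R_total),
            class = "aortic_outlet_wk3")
}

#' Six-element coronary outlet boundary circuit
#'
#' Four resistors (arterial, arterial-microcirculation, venous,
#' venous-microcirculation) splitting the measured total resistance, an
#' arterial compliance `C_a` to ground, and an intramyocardial compliance
#' `C_im` whose far plate is driven by the intramyocardial pressure source
#' (the left-ventricular pressure for the left coronary, 20% of it for the
#' right).
#'
#' @param R_total_cgs measured total outlet resistance, dyn s/cm^5
#' @param c_a arterial compliance, cm^5/dyn
#' @param c_im intramyocardial compliance, cm^5/dyn
#' @param pim_source id of the pressure source driving `C_im`
#' @param venous_split see [split_coronary_resistance()]
#' @return list of class `coronary_outlet_bc`
#' @export
coronary_outlet_bc <- function(R_total_cgs, c_a = 1e-5, c_im = 1e-4,
                               pim_source = "pim_left", venous_split = 0.5) {
  rs <- split_coronary_resistance(R_total_cgs, venous_split)
  .check_positive(c_a, "c_a")
  .check_positive(c_im, "c_im")
  structure(c(rs, list(C_a = c_a, C_im = c_im, P_im = pim_source,
                       R_total = R_total_cgs)),
            class = "coronary_outlet_bc")
}

# ---- network assembly ---------------------------------------------------

#' Low-level network constructor
#'
#' A network is a grounded linear circuit: `nodes` with optional shunt
#' capacitance (to ground, or to a pressure source for the intramyocardial
#' capacitor) and optional pinning to a pressure source (the inlet);
#' `branches` carrying series resistance and inertance between nodes. Node
#' 0 is ground (zero venous pressure).
#'
#' @param nodes data.frame with columns `node` (integer id, ground = 0 is
#'   implicit and must not appear), `label`, `C` (cm^5/dyn, 0 for none),
#'   `c_ref` (source id the capacitor is tied to, NA = ground), `pin`
#'   (source id pinning the node pressure, NA = free)
#' @param branches data.frame with columns `from`, `to`, `R`, `L`, `label`
#' @param sources named list of `pressure_source` objects; all must share
#'   one period
#' @return object of class `lpm_network`
#' @export
lpm_network <- function(nodes, branches, sources) {
  stopifnot(all(c("node", "label", "C", "c_ref", "pin") %in% names(nodes)),
            all(c("from", "to", "R", "L", "label") %in% names(branches)))
  if (any(nodes$node == 0L)) stop("node 0 is the implicit ground")
  if (anyDuplicated(nodes$node)) stop("duplicate node ids")
  ids <- c(0L, nodes$node)
  if (!all(branches$from %in% ids) || !all(branches$to %in% ids)) {
    stop("branch endpoints must reference declared nodes or ground")
  }
  if (any(branches$R < 0) || any(branches$L < 0) || any(nodes$C < 0)) {
    stop("R, L, C must be non-negative")
  }
  if (any(branches$R == 0 & branches$L == 0)) {
    stop("branch with R = 0 and L = 0 (short circuit) not allowed")
  }
  need <- unique(c(stats::na.omit(nodes$pin), stats::na.omit(nodes$c_ref)))
  miss <- setdiff(need, names(sources))
  if (length(miss)) stop("missing source(s): ", paste(miss, collapse = ", "))
  pins <- stats::na.omit(nodes$pin)
  if (length(pins) != 1L) {
    stop("network must have exactly one pressure-pinned inlet node")
  }
  # connectivity to ground over branches
  adj <- rbind(branches[, c("from", "to")],
               stats::setNames(branches[, c("to", "from")], c("from", "to")))
  reach <- 0L
  repeat {
    nxt <- unique(c(reach, adj$to[adj$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  # capacitors to ground and pinned nodes also anchor connectivity
  anchored <- unique(c(reach, nodes$node[!is.na(nodes$pin)],
                       nodes$node[nodes$C > 0]))
  if (!all(nodes$node %in% anchored)) {
    stop("floating node(s): ",
         paste(nodes$label[!nodes$node %in% anchored], collapse = ", "))
  }
  structure(list(nodes = nodes, branches = branches, sources = sources),
            class = "lpm_network")
}

#' @export
print.lpm_network <- function(x, ...) {
  cat("Lumped-parameter network:", nrow(x$nodes), "nodes,",
      nrow(x$branches), "branches,", length(x$sources), "sources\n")
  cat("  states on assembly:", sum(x$branches$L > 0), "inductor flows +",
      sum(x$nodes$C > 0 & is.na(x$nodes$pin)), "capacitor pressures\n")
  invisible(x)
}

#' Assemble the full patient-specific network for one condition
#'
#' Three aortic RLC compartments in series from the pressure inlet to the
#' three-element Windkessel; both coronary chains branch from the distal
#' node of the sinus-of-Valsalva segment, each terminating in its
#' six-element outlet using that condition's measured total resistance.
#' The anomalous branch has three compartments, the other two. The
#' intramyocardial source is the left-ventricular pressure waveform for
#' the left coronary and 20% of it for the right.
#'
#' @param patient a validated [patient_record()]
#' @param condition `"rest"` or `"hyperemia"`
#' @param control a [lpm_control()] list of model constants
#' @return an `lpm_network`
#' @export
assemble_network <- function(patient, condition = c("rest", "hyperemia"),
                             control = lpm_control()) {
  condition <- match.arg(condition)
  validate_patient(patient)
  st <- patient$states[[condition]]
  if (is.null(st)) stop("condition not present in patient states")

  blood <- control$blood
  wall <- control$wall

  # sources: rescaled aortic inlet, LVP-derived intramyocardial pressures
  aorta_src <- rescale_template(control$template, st$systolic_pressure,
                                st$diastolic_pressure, st$heart_rate,
                                n_harmonics = control$n_harmonics)
  lvp <- build_lvp(aorta_src, edp = control$lvp_edp)
  sources <- list(aorta_inlet = aorta_src,
                  pim_left = build_pim(lvp, "left"),
                  pim_right = build_pim(lvp, "right"))

  a_rlc <- lapply(patient$aorta, function(s) {
    rlc_circular(s$mean_diameter, s$length, s$wall_thickness, blood, wall)
  })
  c_rlc <- lapply(c(left = "left", right = "right"), function(side) {
    lapply(patient[[paste0(side, "_ca")]]$segments, function(s) {
      rlc_elliptical(s$semi_axis_max, s$semi_axis_min, s$length,
                     s$wall_thickness, blood, wall)
    })
  })

  co <- cardiac_output(patient$cardiac$stroke_volume, st$heart_rate)
  map_mmhg <- mean_arterial_pressure(st$systolic_pressure,
                                     st$diastolic_pressure,
                                     method = control$map_method,
                                     source = aorta_src)
  wk3 <- build_aortic_outlet(co, pressure_mmhg_to_cgs(map_mmhg),
                             C = control$wk3_c)
  outlets <- lapply(c(left = "left", right = "right"), function(side) {
    coronary_outlet_bc(
      resistance_clinical_to_cgs(st[[paste0("R_total_", side)]]),
      c_a = control$c_a, c_im = control$c_im,
      pim_source = paste0("pim_", side),
      venous_split = control$venous_split)
  })

  nodes <- data.frame(node = integer(), label = character(), C = numeric(),
                      c_ref = character(), pin = character(),
                      stringsAsFactors = FALSE)
  branches <- data.frame(from = integer(), to = integer(), R = numeric(),
                         L = numeric(), label = character(),
                         stringsAsFactors = FALSE)
  add_node <- function(label, C = 0, c_ref = NA_character_,
                       pin = NA_character_) {
    id <- nrow(nodes) + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(id, label, C, c_ref, pin)
    id
  }
  add_branch <- function(from, to, R, L, label) {
    branches[nrow(branches) + 1L, ] <<- list(from, to, R, L, label)
  }

  inlet <- add_node("inlet", pin = "aorta_inlet")
  prev <- inlet
  ao_labels <- c("ao_annulus", "ao_sinus", "ao_ascending")
  for (i in seq_along(a_rlc)) {
    nd <- add_node(paste0(ao_labels[i], "_d"), C = a_rlc[[i]]$C)
    add_branch(prev, nd, a_rlc[[i]]$R, a_rlc[[i]]$L, ao_labels[i])
    prev <- nd
  }
  ao_terminal <- prev
  sinus_node <- nodes$node[nodes$label == "ao_sinus_d"]

  wk_node <- add_node("wk", C = wk3$C)
  add_branch(ao_terminal, wk_node, wk3$R_p, 0, "wk_prox")
  add_branch(wk_node, 0L, wk3$R_d, 0, "wk_dist")

  for (side in c("left", "right")) {
    tag <- if (side == "left") "lca" else "rca"
    prev <- sinus_node
    segs <- c_rlc[[side]]
    for (i in seq_along(segs)) {
      nd <- add_node(sprintf("%s_seg%d_d", tag, i), C = segs[[i]]$C)
      add_branch(prev, nd, segs[[i]]$R, segs[[i]]$L,
                 sprintf("%s_seg%d", tag, i))
      prev <- nd
    }
    ob <- outlets[[side]]
    nd_a <- add_node(paste0(tag, "_ca"), C = ob$C_a)
    nd_b <- add_node(paste0(tag, "_cim"), C = ob$C_im, c_ref = ob$P_im)
    add_branch(prev, nd_a, ob$R_a, 0, paste0(tag, "_ra"))
    add_branch(nd_a, nd_b, ob$R_a_micro, 0, paste0(tag, "_ramicro"))
    add_branch(nd_b, 0L, ob$R_v + ob$R_v_micro, 0, paste0(tag, "_rv"))
  }

  net <- lpm_network(nodes, branches, sources)
  net$meta <- list(patient_id = patient$patient_id, condition = condition,
                   anomaly_side = patient$anomaly_side, wk3 = wk3,
                   outlets = outlets, co = co, map_mmhg = map_mmhg,
                   cbf_branches = c(left = "lca_ra", right = "rca_ra"),
                   inlet_branch = "ao_annulus")
  net
}

#' Scale all reactive elements of a network
#'
#' Multiplies every capacitance and inductance by `factor`, leaving
#' resistances and sources untouched. Shrinking the reactances pushes the
#' network toward its purely resistive (DC) limit, which has a closed-form
#' nodal solution useful for verification.
#'
#' @param network an `lpm_network`
#' @param factor positive scale factor
#' @return the modified network
#' @export
scale_reactances <- function(network, factor) {
  .check_positive(factor, "factor")
  network$nodes$C <- network$nodes$C * factor
  network$branches$L <- network$branches$L * factor
  network
}
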