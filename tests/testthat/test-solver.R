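test_that("state dimension equals the capacitor + inductor count", {
  wk <- wk3_network(constant_source(1e5))
  sys <- to_state_space(wk)
  expect_equal(length(sys$state_names), 1L)
  expect_equal(sys$n_capacitors, 1L)

  p <- toy_patient("right")
  net <- assemble_network(p, "rest")
  sys <- to_state_space(net)
  n_C <- sum(net$nodes$C > 0 & is.na(net$nodes$pin))
  n_L <- sum(net$branches$L > 0)
  expect_equal(length(sys$state_names), n_C + n_L)
  expect_equal(n_L, 8L)   # 3 aortic + 3 + 2 coronary segments
  expect_equal(n_C, 13L)  # 8 segment nodes + wk + 2x(C_a, C_im)
})

test_that("RC low-pass reduces to the closed form A = -1/(RC)", {
  R <- 50
  C <- 2e-4
  net <- rc_network(constant_source(1e5), R = R, C = C)
  sys <- to_state_space(net)
  expect_equal(dim(sys$A), c(1L, 1L))
  expect_equal(sys$A[1, 1], -1 / (R * C), tolerance = 1e-12)
  expect_equal(sys$B[1, 1], 1 / (R * C), tolerance = 1e-12)
})

test_that("the assembled system matrix is passive (no unstable modes)", {
  for (side in c("left", "right")) {
    net <- assemble_network(toy_patient(side), "rest")
    ev <- eigen(to_state_space(net)$A, only.values = TRUE)$values
    expect_true(all(Re(ev) < 0))
  }
})

test_that("constant drive on a Windkessel settles to Ohm's law", {
  P0 <- 1.2e5
  R_p <- 100
  R_d <- 1000
  net <- wk3_network(constant_source(P0), R_p = R_p, R_d = R_d)
  for (method in c("matexp", "lsoda")) {
    sim <- simulate_network(net, solver_settings(n_beats = 10,
                                                 method = method))
    q <- final_beat_mean(sim, "wk_prox")
    expect_equal(q, P0 / (R_p + R_d), tolerance = 1e-3)
  }
})

test_that("sinusoidal drive matches the Windkessel impedance closed form", {
  P0 <- 1.2e5
  amp <- 3e4
  T <- 0.8
  R_p <- 150
  R_d <- 1200
  C <- 8e-4
  net <- wk3_network(cosine_source(P0, amp, T), R_p = R_p, R_d = R_d, C = C)
  w <- 2 * pi / T
  Z <- wk3_impedance(R_p, R_d, C, w)
  for (method in c("matexp", "lsoda")) {
    sim <- simulate_network(net, solver_settings(n_beats = 20,
                                                 samples_per_beat = 400,
                                                 method = method))
    q_dc <- final_beat_mean(sim, "wk_prox")
    q <- sim$flows[, "wk_prox"]
    last <- seq(length(q) - 400, length(q))   # final beat's grid points
    q_ac <- q[last] - q_dc
    expect_equal(max(abs(q_ac)), amp / Mod(Z), tolerance = 5e-3)
    # and the DC component obeys the DC resistance
    expect_equal(q_dc, P0 / (R_p + R_d), tolerance = 1e-3)
  }
})

test_that("with the source off, charged states decay to zero", {
  # zero drive, but capacitors start charged at 50 mmHg
  src <- make_test_source(function(t) rep_len(0, length(t)), 1, dbp = 50)
  net <- wk3_network(src)
  for (method in c("matexp", "lsoda")) {
    sim <- simulate_network(net, solver_settings(n_beats = 10,
                                                 method = method))
    expect_equal(sim$states[1, 1], pressure_mmhg_to_cgs(50),
                 tolerance = 1e-9)
    expect_lt(max(abs(sim$states[nrow(sim$states), ])), 1e-6)
  }
})

test_that("matexp and the ODE integrator agree on the full network", {
  net <- assemble_network(toy_patient("right"), "rest")
  sys <- to_state_space(net)
  s1 <- simulate_network(net, solver_settings(), sys)
  s2 <- simulate_network(net, solver_settings(method = "lsoda"), sys)
  expect_equal(s1$cbf, s2$cbf, tolerance = 1e-4)
  nb <- nrow(s1$beat_flow_means)
  expect_equal(s1$beat_flow_means[nb, ], s2$beat_flow_means[nb, ],
               tolerance = 1e-4)
})

test_that("mean flows balance over the final converged beat", {
  p <- toy_patient("right")
  for (cond in c("rest", "hyperemia")) {
    sim <- simulate_network(assemble_network(p, cond))
    expect_true(sim$converged)
    bm <- sim$beat_flow_means[nrow(sim$beat_flow_means), ]
    inflow <- bm[["ao_annulus"]]
    outflow <- bm[["wk_prox"]] + bm[["lca_ra"]] + bm[["rca_ra"]]
    expect_equal(outflow, inflow, tolerance = 5e-3)
    # intramyocardial capacitors pass no net flow once periodic
    expect_equal(bm[["lca_ra"]], bm[["lca_rv"]], tolerance = 5e-3)
  }
})

test_that("raising one coronary's outlet resistance lowers its mean flow", {
  p <- toy_patient("right")
  base_R <- p$states$rest$R_total_left
  cbf <- vapply(seq(0.5, 3, length.out = 6), function(k) {
    q <- p
    q$states$rest$R_total_left <- base_R * k
    simulate_network(assemble_network(q, "rest"))$cbf[["left"]]
  }, numeric(1))
  expect_true(all(diff(cbf) < 0))
})

test_that("near the resistive limit the flow matches DC nodal analysis", {
  for (side in c("left", "right")) {
    net <- assemble_network(toy_patient(side), "rest")
    lim <- scale_reactances(net, 1e-3)
    sim <- simulate_network(lim)
    oracle <- dc_nodal_flow(lim)
    expect_equal(sim$cbf[["left"]], oracle[["lca_ra"]], tolerance = 0.01)
    expect_equal(sim$cbf[["right"]], oracle[["rca_ra"]], tolerance = 0.01)
  }
})

test_that("frequency scaling by 1000 reproduces the unscaled run", {
  net <- assemble_network(toy_patient("right"), "rest")
  direct <- simulate_network(net, solver_settings())
  scaled <- simulate_network(net,
                             solver_settings(frequency_scale = 1000))
  # identical physical time grid after un-scaling
  expect_equal(scaled$time, direct$time, tolerance = 1e-9)
  expect_equal(scaled$cbf, direct$cbf, tolerance = 5e-3)
  nb <- nrow(direct$beat_flow_means)
  expect_equal(scaled$beat_flow_means[nb, ], direct$beat_flow_means[nb, ],
               tolerance = 5e-3)
  # identity at factor 1
  expect_identical(apply_frequency_scaling(net, 1), net)
  expect_error(apply_frequency_scaling(net, -2), "> 0")
})

test_that("halving integrator tolerances leaves mean CBF unchanged", {
  net <- assemble_network(toy_patient("right"), "rest")
  sys <- to_state_space(net)
  s1 <- simulate_network(net, solver_settings(method = "lsoda",
                                              n_beats = 8), sys)
  s2 <- simulate_network(net, solver_settings(method = "lsoda",
                                              n_beats = 8, rtol = 5e-7),
                         sys)
  nb <- 8
  expect_equal(s1$beat_flow_means[nb, "lca_ra"],
               s2$beat_flow_means[nb, "lca_ra"], tolerance = 1e-3)
})

test_that("a zero-compliance internal node is eliminated algebraically", {
  # source - R - (C=0 node) - R - C node: still solvable, one state less
  src <- constant_source(1e5)
  nodes <- data.frame(node = 1:3, label = c("in", "mid", "out"),
                      C = c(0, 0, 1e-4), c_ref = NA_character_,
                      pin = c("s", NA, NA), stringsAsFactors = FALSE)
  branches <- data.frame(from = c(1L, 2L, 3L), to = c(2L, 3L, 0L),
                         R = c(40, 60, 500), L = 0,
                         label = c("r1", "r2", "r3"),
                         stringsAsFactors = FALSE)
  net <- lpm_network(nodes, branches, list(s = src))
  sys <- to_state_space(net)
  expect_equal(length(sys$state_names), 1L)
  sim <- simulate_network(net, solver_settings(n_beats = 10))
  expect_equal(final_beat_mean(sim, "r3"), 1e5 / 600, tolerance = 1e-3)

  # a zero-compliance junction between two pure inductors is rejected
  nodes2 <- data.frame(node = 1:3, label = c("in", "j", "out"),
                       C = c(0, 0, 1e-4), c_ref = NA_character_,
                       pin = c("s", NA, NA), stringsAsFactors = FALSE)
  branches2 <- data.frame(from = c(1L, 2L, 3L), to = c(2L, 3L, 0L),
                          R = c(0, 0, 500), L = c(0.5, 0.5, 0),
                          label = c("l1", "l2", "r3"),
                          stringsAsFactors = FALSE)
  net2 <- lpm_network(nodes2, branches2, list(s = src))
  expect_error(to_state_space(net2), "assembly error")
})
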