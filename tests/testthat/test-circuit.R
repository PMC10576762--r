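test_that("circular RLC follows the Poiseuille / inertance / compliance laws", {
  seg <- rlc_circular(2, 1, 0.3)       # r = 1 cm, mu = 0.04 P
  expect_equal(seg$R, 8 * 0.04 / pi, tolerance = 1e-6)   # 0.10186
  expect_equal(seg$L, 1.06 / pi, tolerance = 1e-12)
  expect_equal(seg$C, 3 * pi / (2 * 1.5e7 * 0.3), tolerance = 1e-12)

  # linearity in length, r^-4 resistance scaling
  s1 <- rlc_circular(1.3, 1.7, 0.1)
  s2 <- rlc_circular(1.3, 3.4, 0.1)
  expect_equal(unclass(s2)[c("R", "L", "C")],
               lapply(unclass(s1)[c("R", "L", "C")], `*`, 2),
               tolerance = 1e-12)
  expect_equal(rlc_circular(0.65, 1.7, 0.1)$R, 16 * s1$R, tolerance = 1e-10)
  expect_error(rlc_circular(-1, 1, 0.1), "> 0")
})

test_that("elliptical RLC uses the exact elliptical duct resistance", {
  seg <- rlc_elliptical(0.2, 0.1, 1, 0.03)
  # 4 mu l (a^2+b^2) / (pi a^3 b^3) by hand: 0.008 / (pi * 8e-6)
  expect_equal(seg$R, 4 * 0.04 * 0.05 / (pi * 0.008 * 0.001),
               tolerance = 1e-10)
  expect_equal(seg$R, 318.31, tolerance = 1e-4)
  expect_equal(seg$L, 1.06 / (pi * 0.2 * 0.1), tolerance = 1e-12)
  expect_error(rlc_elliptical(0.1, 0.2, 1, 0.03), "semi_axis_max")
})

test_that("a circle is a degenerate ellipse for all RLC values", {
  set.seed(42)
  for (i in 1:1000) {
    r <- runif(1, 0.05, 0.5)
    l <- runif(1, 0.2, 4)
    h <- runif(1, 0.01, 0.1)
    e <- rlc_elliptical(r, r, l, h)
    c <- rlc_circular(2 * r, l, h)
    expect_equal(e$R, c$R, tolerance = 1e-14)
    expect_equal(e$L, c$L, tolerance = 1e-14)
    expect_equal(e$C, c$C, tolerance = 1e-14)
  }
})

test_that("at fixed area, eccentricity strictly increases resistance", {
  area <- pi * 0.04
  ratios <- seq(1, 5, length.out = 41)
  R <- vapply(ratios, function(k) {
    b <- sqrt(area / (pi * k))
    rlc_elliptical(k * b, b, 1, 0.03)$R
  }, numeric(1))
  expect_true(all(diff(R) > 0))
})

test_that("coronary resistance split is 32/52/16 and conserves the total", {
  s <- split_coronary_resistance(100)
  expect_equal(s$R_a, 32)
  expect_equal(s$R_a_micro, 52)
  expect_equal(s$R_v + s$R_v_micro, 16)
  s1 <- split_coronary_resistance(1)
  expect_equal(s1$R_a + s1$R_a_micro + s1$R_v + s1$R_v_micro, 1,
               tolerance = 1e-12)
  s2 <- split_coronary_resistance(resistance_clinical_to_cgs(1))
  expect_equal(s2$R_a, 25.598, tolerance = 1e-4)
  expect_error(split_coronary_resistance(-1), "> 0")
})

test_that("aortic Windkessel allocates 91/9 and scales inversely with CO", {
  wk <- build_aortic_outlet(87.5, pressure_mmhg_to_cgs(93.333))
  expect_equal(wk$R_total, 93.333 * 1333.22 / 87.5, tolerance = 1e-6)
  expect_equal(wk$R_total, 1422.2, tolerance = 1e-4)
  expect_equal(wk$R_d, 1294.2, tolerance = 1e-4)
  expect_equal(wk$R_p + wk$R_d, wk$R_total, tolerance = 1e-12)
  expect_equal(wk$C, 0.001)
  wk2 <- build_aortic_outlet(2 * 87.5, pressure_mmhg_to_cgs(93.333))
  expect_equal(wk2$R_total, wk$R_total / 2, tolerance = 1e-12)
})

test_that("assembled network has the documented topology", {
  p <- toy_patient("right")
  net <- assemble_network(p, "rest")
  expect_s3_class(net, "lpm_network")
  # chains: anomalous right has 3 segments, left 2
  expect_equal(sum(grepl("^rca_seg", net$branches$label)), 3L)
  expect_equal(sum(grepl("^lca_seg", net$branches$label)), 2L)
  p2 <- toy_patient("left")
  net2 <- assemble_network(p2, "rest")
  expect_equal(sum(grepl("^lca_seg", net2$branches$label)), 3L)
  expect_equal(sum(grepl("^rca_seg", net2$branches$label)), 2L)

  # both coronaries branch from the sinus node
  sinus <- net$nodes$node[net$nodes$label == "ao_sinus_d"]
  first_cor <- net$branches[net$branches$label %in%
                              c("lca_seg1", "rca_seg1"), ]
  expect_true(all(first_cor$from == sinus))

  # terminal outlet resistances sum to the converted in-vivo totals
  st <- p$states$rest
  for (side in c("left", "right")) {
    tag <- if (side == "left") "lca" else "rca"
    rt <- sum(net$branches$R[net$branches$label %in%
                               paste0(tag, c("_ra", "_ramicro", "_rv"))])
    expect_equal(rt,
                 resistance_clinical_to_cgs(st[[paste0("R_total_", side)]]),
                 tolerance = 1e-9)
  }

  # rest vs hyperemia differ only in outlet resistances and source timing
  neth <- assemble_network(p, "hyperemia")
  seg_labels <- grepl("_seg|^ao_", net$branches$label)
  expect_equal(net$branches[seg_labels, c("R", "L")],
               neth$branches[seg_labels, c("R", "L")])
  expect_error(assemble_network(p, "exercise"), "arg")

  # intramyocardial sources: right is 20% of left
  expect_equal(net$sources$pim_right$fourier$a0,
               0.2 * net$sources$pim_left$fourier$a0, tolerance = 1e-12)
})

test_that("network constructor rejects malformed topologies", {
  src <- constant_source(1e5)
  nodes <- data.frame(node = 1:2, label = c("a", "b"), C = c(0, 1e-4),
                      c_ref = NA_character_,
                      pin = c("s", NA_character_), stringsAsFactors = FALSE)
  branches <- data.frame(from = 1L, to = 2L, R = 0, L = 0, label = "sc",
                         stringsAsFactors = FALSE)
  expect_error(lpm_network(nodes, branches, list(s = src)), "short circuit")
  # floating node
  nodes3 <- rbind(nodes, data.frame(node = 3L, label = "float", C = 0,
                                    c_ref = NA_character_,
                                    pin = NA_character_))
  branches_ok <- data.frame(from = 1L, to = 2L, R = 10, L = 0, label = "r1",
                            stringsAsFactors = FALSE)
  expect_error(lpm_network(nodes3, branches_ok, list(s = src)), "floating")
  # no inlet
  nodes_np <- nodes
  nodes_np$pin <- NA_character_
  expect_error(lpm_network(nodes_np, branches_ok, list(s = src)),
               "exactly one")
})
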