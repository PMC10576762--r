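test_that("template is periodic, normalized, and has its minimum at t = 0", {
  tpl <- waveform_template()
  grid <- seq(0, 1, length.out = 2001)[-2001]
  v <- tpl$fun(grid)
  expect_equal(min(v), 0, tolerance = 1e-9)
  expect_equal(max(v), 1, tolerance = 1e-9)
  expect_equal(tpl$fun(0), 0, tolerance = 1e-9)
  expect_equal(tpl$fun(0.3 + 2), tpl$fun(0.3), tolerance = 1e-12)
  expect_gt(tpl$mean, 0.2)
  expect_lt(tpl$mean, 0.5)
})

test_that("rescaling hits the pressure targets and compresses time exactly", {
  tpl <- waveform_template()
  src <- rescale_template(tpl, 120, 80, 60)
  expect_equal(src$period, 1.0)
  grid <- seq(0, 1, length.out = 4001)[-4001]
  p <- src$fun(grid)
  expect_equal(max(p), pressure_mmhg_to_cgs(120), tolerance = 0.005)
  expect_equal(min(p), pressure_mmhg_to_cgs(80), tolerance = 0.005)

  src75 <- rescale_template(tpl, 120, 80, 75)
  expect_equal(src75$period, 0.8)
  expect_equal(src75$fun(grid * 60 / 75), src$fun(grid), tolerance = 1e-12)

  expect_error(rescale_template(tpl, 80, 80, 60), "exceed")
  expect_error(rescale_template(tpl, 120, 80, 0), "> 0")
})

test_that("Fourier fit recovers a pure sinusoid exactly", {
  src <- cosine_source(1e5, 2e4, period = 0.8)
  fs <- fourier_fit(src, n_harmonics = 5)
  expect_equal(fs$a0, 1e5, tolerance = 1e-8)
  expect_equal(fs$an[1], 2e4, tolerance = 1e-6)
  expect_lt(max(abs(fs$bn)), 1e-7)
  expect_lt(max(abs(fs$an[2:5])), 1e-7)
})

test_that("Fourier reconstruction error is small and monotone in harmonics", {
  src <- rescale_template(waveform_template(), 130, 70, 72)
  grid <- seq(0, src$period, length.out = 1501)[-1501]
  pp <- pressure_mmhg_to_cgs(130 - 70)
  direct <- src$fun(grid)

  err <- vapply(1:30, function(H) {
    fs <- fourier_fit(src, n_harmonics = H)
    sqrt(mean((eval_fourier(fs, grid) - direct)^2))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))     # L2 error non-increasing

  # default harmonic count: max error within 1% of pulse pressure
  max_err <- max(abs(source_pressure(src, grid, "fourier") - direct))
  expect_lt(max_err, 0.01 * pp)
  # a0 is the time-mean
  expect_equal(src$fourier$a0, mean(direct), tolerance = 1e-3 * pp)
})

test_that("Fourier derivative matches a finite difference", {
  src <- rescale_template(waveform_template(), 120, 80, 60)
  t0 <- seq(0.05, 0.95, by = 0.1)
  h <- 1e-6
  fd <- (eval_fourier(src$fourier, t0 + h) -
           eval_fourier(src$fourier, t0 - h)) / (2 * h)
  expect_equal(source_derivative(src, t0), fd, tolerance = 1e-4)
})

test_that("synthesized LVP tracks systole and rests at low diastole", {
  src <- rescale_template(waveform_template(), 120, 80, 60)
  lvp <- build_lvp(src, edp = 10)
  grid <- seq(0, 1, length.out = 4001)[-4001]
  pl <- lvp$fun(grid)
  pa <- src$fun(grid)
  expect_equal(max(pl), pressure_mmhg_to_cgs(120), tolerance = 0.005)
  expect_lt(min(pl), min(pa))                     # ventricular diastole
  expect_true(all(pl >= 0))
  # crossings with the aortic wave come in pairs over a period
  crossings <- sum(diff(sign(pl - pa)) != 0)
  expect_equal(crossings %% 2, 0)
  expect_gte(crossings, 2)
  expect_error(build_lvp(src, edp = 90), "below")
})

test_that("intramyocardial source is identity on the left, 20% on the right", {
  src <- rescale_template(waveform_template(), 120, 80, 60)
  lvp <- build_lvp(src)
  left <- build_pim(lvp, "left")
  right <- build_pim(lvp, "right")
  tt <- seq(0, 1, length.out = 101)
  expect_equal(left$fun(tt), lvp$fun(tt))
  expect_equal(right$fun(tt), 0.2 * lvp$fun(tt), tolerance = 1e-12)
  expect_equal(max(right$fun(tt)), 0.2 * max(left$fun(tt)),
               tolerance = 1e-12)
  expect_equal(right$fourier$an, 0.2 * lvp$fourier$an, tolerance = 1e-12)
})

test_that("a sampled waveform CSV round-trips into a usable template", {
  tt <- seq(0, 0.8, length.out = 161)
  p <- 80 + 40 * pmax(sin(2 * pi * tt / 0.8), 0)^1.5
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = tt, pressure_mmHg = p), path,
            row.names = FALSE)
  tpl <- read_waveform_template(path)
  grid <- seq(0, 1, length.out = 801)[-801]
  v <- tpl$fun(grid)
  expect_equal(min(v), 0, tolerance = 1e-9)
  expect_equal(max(v), 1, tolerance = 1e-9)
  src <- rescale_template(tpl, 120, 80, 60)
  expect_equal(max(src$fun(grid)), pressure_mmhg_to_cgs(120),
               tolerance = 0.005)
})
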