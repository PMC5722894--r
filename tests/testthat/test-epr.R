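test_that("mobility parameter is the inverse central peak-to-peak width", {
  sp2 <- gen_cw_spectrum(2.0, noise_sd = 0)
  expect_equal(mobility_parameter(sp2), 0.5, tolerance = 0.03)
  sp4 <- gen_cw_spectrum(4.0, noise_sd = 0)
  expect_equal(mobility_parameter(sp4), 0.25, tolerance = 0.03)
  expect_lt(mobility_parameter(sp4), mobility_parameter(sp2))
})

test_that("mobility recovery within 2% across widths 1..8 G (noiseless)", {
  ## single-line spectra: the definitional round trip, free of the
  ## hyperfine-satellite tails that bias the width of very broad lines
  for (w in c(1, 2, 3.5, 5, 6.5, 8)) {
    sp <- gen_cw_spectrum(w, noise_sd = 0, step = 0.02, outer_amplitude = 0)
    expect_equal(mobility_parameter(sp, window_G = 10), 1 / w,
                 tolerance = 0.02)
  }
})

test_that("mobility parameter is invariant to scaling and field offset", {
  sp <- gen_cw_spectrum(3.0, noise_sd = 0)
  v0 <- mobility_parameter(sp)
  sp_scaled <- sp; sp_scaled$amplitude <- 17 * sp$amplitude
  expect_equal(mobility_parameter(sp_scaled), v0)
  sp_shift <- sp; sp_shift$field <- sp$field + 120
  expect_equal(mobility_parameter(sp_shift), v0)
  flat <- sp; flat$amplitude <- rep(0, length(sp$field))
  expect_error(mobility_parameter(flat), "central line")
})

test_that("power-saturation fitting recovers generator parameters", {
  ## noiseless recovery across the parameter box
  for (ph in c(0.5, 5, 50)) for (ep in c(0.5, 1.5, 3)) {
    cv <- gen_power_sat_curve(p_half = ph, eps_inhomogeneity = ep,
                              noise_sd = 0)
    fit <- fit_power_saturation(cv)
    expect_equal(fit$p_half, ph, tolerance = 1e-3)
    expect_equal(fit$eps, ep, tolerance = 0.02)
  }
  ## amplitude scaling doubles 'scale' but leaves p_half unchanged
  cv <- gen_power_sat_curve(p_half = 5, noise_sd = 0)
  cv2 <- cv; cv2$amplitude <- 2 * cv$amplitude
  f1 <- fit_power_saturation(cv); f2 <- fit_power_saturation(cv2)
  expect_equal(f2$p_half, f1$p_half, tolerance = 1e-6)
  expect_equal(f2$scale, 2 * f1$scale, tolerance = 1e-6)
  expect_error(fit_power_saturation(list(power = 1:3, amplitude = 1:3)),
               ">= 6")
})

test_that("P1/2 recovery: median relative error < 5% at 5% noise", {
  amp_max <- max(gen_power_sat_curve(p_half = 5, eps_inhomogeneity = 1.5,
                                     noise_sd = 0)$amplitude)
  errs <- vapply(1:100, function(seed) {
    cv <- gen_power_sat_curve(p_half = 5, eps_inhomogeneity = 1.5,
                              noise_sd = 0.05 * amp_max, seed = seed)
    abs(fit_power_saturation(cv)$p_half - 5) / 5
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("accessibility parameter behaves linearly", {
  expect_equal(accessibility_pi(4, 4, 2), 0)
  expect_equal(accessibility_pi(8, 4, 2), 2 * accessibility_pi(6, 4, 2))
  ## generator round trip at a 10:1 P1/2 contrast
  hi <- fit_power_saturation(gen_power_sat_curve(p_half = 24, noise_sd = 0))
  lo <- fit_power_saturation(gen_power_sat_curve(p_half = 6, noise_sd = 0))
  n2 <- fit_power_saturation(gen_power_sat_curve(p_half = 4, noise_sd = 0))
  pi_hi <- accessibility_pi(hi$p_half, n2$p_half, 2.2)
  pi_lo <- accessibility_pi(lo$p_half, n2$p_half, 2.2)
  expect_equal(pi_hi / pi_lo, 10, tolerance = 0.02)
  expect_warning(accessibility_pi(3, 4, 2), "negative")
  expect_error(accessibility_pi(3, 4, 0), "> 0")
})

test_that("helical periodicity statistic separates signal from flat input", {
  res <- 110:136
  pure <- mobility_profile(res, 0.3 + 0.05 * cos(2 * pi * res / 3.6), "closed")
  expect_gt(helical_periodicity(pure), 0.9)
  flat <- mobility_profile(res, rep(0.3, length(res)), "closed")
  expect_lt(helical_periodicity(flat), 0.05)
  expect_error(helical_periodicity(pure, window = c(116, 121)), ">= 8")
  ## white-noise null: median band fraction, frozen from simulation
  set.seed(42)
  null <- replicate(200, {
    p <- mobility_profile(res, abs(rnorm(27, 0.3, 0.05)) + 0.01, "closed")
    helical_periodicity(p)
  })
  expect_gt(median(null), 0.05)
  expect_lt(median(null), 0.3)    # simulated null median ~0.16
})

test_that("delta-mobility segment calling applies shift and run filters", {
  pr <- gen_mobility_profiles(epr_profile_spec(noise_sd = 0))
  expect_equal(delta_mobility_segments(pr$closed, pr$closed), list())
  expect_equal(delta_mobility_segments(pr$closed, pr$open),
               list(c(110L, 119L)))
  ## single-residue shift is suppressed by min_run = 3
  open1 <- pr$closed
  open1$value[5] <- open1$value[5] + 0.2
  open1 <- mobility_profile(open1$residue, open1$value, "open")
  expect_equal(delta_mobility_segments(pr$closed, open1), list())
  ## mismatched residue sets are an error
  sub <- mobility_profile(pr$open$residue[-1], pr$open$value[-1], "open")
  expect_error(delta_mobility_segments(pr$closed, sub), "residue")
  ## called segments never include residues where open == closed (noise-free)
  segs <- delta_mobility_segments(pr$closed, pr$open)
  eqres <- pr$closed$residue[pr$open$value == pr$closed$value]
  for (s in segs) expect_false(any(eqres >= s[1] & eqres <= s[2]))
})

test_that("EPR artefacts round-trip through their CSV formats", {
  tmp <- tempfile(fileext = ".csv")
  sp <- gen_cw_spectrum(2.5, noise_sd = 0)
  write_spectrum_csv(sp, tmp)
  sp2 <- read_spectrum_csv(tmp)
  expect_equal(mobility_parameter(sp2), mobility_parameter(sp))
  cv <- gen_power_sat_curve(p_half = 7, noise_sd = 0)
  write_powersat_csv(cv, tmp)
  cv2 <- read_powersat_csv(tmp)
  expect_equal(fit_power_saturation(cv2)$p_half, 7, tolerance = 1e-3)
  pr <- gen_mobility_profiles(epr_profile_spec(noise_sd = 0))
  write_profiles_csv(pr, tmp)
  pr2 <- read_profiles_csv(tmp)
  expect_equal(pr2$closed$value, pr$closed$value)
  expect_equal(pr2$open$residue, pr$open$residue)
  unlink(tmp)
})
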