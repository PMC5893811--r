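test_that("healthy waveform peaks at 0.32 m/s and is periodic", {
  wf <- mitral_waveform("healthy")
  t <- seq(0, wf$T, by = 1e-4)
  expect_equal(max(mitral_velocity(t, wf)), 0.32, tolerance = 1e-6)
  expect_true(all(mitral_velocity(t, wf) >= 0))
  # zero while the mitral valve is closed (atrial diastole)
  closed <- seq(0, wf$diastole_fraction * wf$T - 1e-6, by = 1e-3)
  expect_true(all(mitral_velocity(closed, wf) == 0))
  # periodicity: t and t + T give identical values
  expect_equal(mitral_velocity(t + wf$T, wf), mitral_velocity(t, wf))
  expect_equal(mitral_velocity(-0.1, wf), mitral_velocity(wf$T - 0.1, wf))
})

test_that("atrial fibrillation removes the A-wave and only the A-wave", {
  wh <- mitral_waveform("healthy")
  wa <- mitral_waveform("af")
  expect_identical(wa$A_peak, 0)
  expect_identical(wa$E_peak, wh$E_peak)
  # at the healthy A-wave peak instant the AF value is the E tail alone
  ta <- unname(wh$A_timing["center"])
  e_tail <- mitral_velocity(ta, wh) - wh$A_peak # A pulse = A_peak at its peak
  expect_equal(mitral_velocity(ta, wa), e_tail)
  # identical outside the A-wave support
  outside <- seq(0, ta - wh$A_timing["width"] / 2 - 1e-6, by = 1e-3)
  expect_equal(mitral_velocity(outside, wa), mitral_velocity(outside, wh))
  # the removed A-wave volume: AF cycle integral is strictly smaller
  t <- seq(0, wh$T, length.out = 8001)
  int <- function(w) mean(mitral_velocity(t, w)) * w$T
  expect_lt(int(wa), int(wh))
})

test_that("waveforms are continuous at the phase boundaries", {
  for (cond in c("healthy", "af")) {
    wf <- mitral_waveform(cond)
    t <- seq(0, wf$T, by = 1e-5)
    v <- mitral_velocity(t, wf)
    expect_lt(max(abs(diff(v))), 0.32 * pi * 1e-5 / wf$A_timing["width"] * 2)
  }
  expect_error(mitral_waveform("healthy", e_center = 0.2), "argument error")
})

test_that("Reynolds number follows rho v D / mu and stays laminar", {
  props <- fluid_properties()
  expect_equal(reynolds_number(0.32, 0.025, props),
               1060 * 0.32 * 0.025 / 0.0035)
  expect_equal(reynolds_number(0, 0.025, props), 0)
  expect_equal(reynolds_number(0.64, 0.025, props),
               2 * reynolds_number(0.32, 0.025, props))
  expect_equal(reynolds_number(0.32, 0.05, props),
               2 * reynolds_number(0.32, 0.025, props))
  expect_equal(reynolds_number(0.32, 0.025, fluid_properties(mu = 0.007)),
               reynolds_number(0.32, 0.025, props) / 2)
  expect_error(reynolds_number(0.32, 0), "argument error")
  expect_error(reynolds_number(-1, 0.025), "argument error")
  # all four default anatomies at the healthy peak stay below 3000
  for (sp in default_anatomy_specs())
    expect_lt(reynolds_number(0.32, sp$mitral_diameter, props), 3000)
})
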