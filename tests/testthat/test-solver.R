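test_that("the rest state is an exact solution", {
  msh <- structured_rect_mesh(8, 8, 1, 1)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 0.1)
  bcs <- assemble_bcs(msh, "healthy")
  st <- flow_initialize(msh, cfg)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(st$t, 0)
  expect_equal(range(st$c), c(1, 1))
  expect_equal(residual_contrast(st$c, msh), 100)
  for (i in 1:5) st <- momentum_step(st, bcs, fluid_properties(), cfg)
  expect_identical(max(abs(c(st$u, st$v))), 0)
  st <- contrast_step(st, bcs, fluid_properties(), cfg)
  expect_equal(range(st$c), c(1, 1))
})

test_that("steady Poiseuille flow is recovered within 2 percent", {
  res <- poiseuille_error()
  expect_lt(res$err, 0.02)
  # post-projection face-flux divergence is at machine precision every step
  expect_lt(max(res$div_flux), 1e-8)
})

test_that("step counts follow the configuration arithmetic", {
  cfg <- flow_solver_config()
  expect_equal(cfg$n_cycles * round(cfg$T / cfg$dt), 6400L)
  expect_error(flow_solver_config(dt = 3e-4), "argument error")
  expect_error(flow_solver_config(dt = -1), "argument error")
  expect_error(flow_solver_config(n_cycles = 0), "argument error")
})

test_that("runs are bit-identical for identical inputs", {
  msh <- open_channel_mesh(20, 6, 2, 0.5)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 2, T = 0.1,
                            cfl_limit = 3,
                            snapshot_phases = c(0.5, 1))
  wf <- mitral_waveform("healthy", T = 0.1, diastole_fraction = 0.2,
                        e_center = 0.05, e_width = 0.05,
                        a_center = 0.09, a_width = 0.01)
  # reuse the channel: left inlet as "mitral" is not available, so drive by
  # body force through the open ends instead
  bcs <- assemble_bcs(msh, "healthy", waveform = wf)
  forcing <- function(x, y, t) list(fx = rep(0.5, length(x)),
                                    fy = rep(0, length(x)))
  r1 <- run_flow(msh, bcs, fluid_properties(1, 0.01), cfg, forcing = forcing)
  r2 <- run_flow(msh, bcs, fluid_properties(1, 0.01), cfg, forcing = forcing)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$state$u, r2$state$u)
  expect_identical(r1$state$c, r2$state$c)
  # global mass balance: contrast change matches the boundary bookkeeping
  V <- sum(msh$area)
  removed <- 1 - r1$metrics$total_contrast[nrow(r1$metrics)]
  expect_equal(removed * V, r1$state$mass_out - r1$state$mass_in,
               tolerance = 1e-8)
})

test_that("a CFL violation is reported per the configured action", {
  msh <- structured_rect_mesh(8, 8, 1, 1)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 0.1,
                            cfl_limit = 0.5, cfl_action = "error")
  bcs <- assemble_bcs(msh, "healthy")
  st <- flow_initialize(msh, cfg)
  st$u <- rep(10, nrow(msh$vertices)) # CFL = 10*0.01/h >> 0.5
  expect_error(momentum_step(st, bcs, fluid_properties(1, 0.01), cfg),
               "stability error")
  cfg2 <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 0.1,
                             cfl_limit = 0.5, cfl_action = "warn")
  expect_warning(momentum_step(st, bcs, fluid_properties(1, 0.01), cfg2),
                 "stability error")
})
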