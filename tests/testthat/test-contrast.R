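test_that("zero velocity leaves the contrast field unchanged", {
  msh <- structured_rect_mesh(10, 10, 1, 1)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 0.1)
  bcs <- assemble_bcs(msh, "healthy")
  st <- with_velocity(msh, numeric(nrow(msh$vertices)),
                      numeric(nrow(msh$vertices)), cfg, bcs)
  st$c <- runif(nrow(msh$triangles))
  c0 <- st$c
  for (i in 1:10) st <- contrast_step(st, bcs, fluid_properties(), cfg)
  expect_identical(st$c, c0)
})

test_that("a translated blob follows the characteristics", {
  msh <- open_channel_mesh(60, 15, 4, 1)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 2, cfl_limit = 3)
  bcs <- assemble_bcs(msh, "healthy")
  one <- rep(1, nrow(msh$vertices))
  st <- with_velocity(msh, one, 0 * one, cfg, bcs)
  st$c <- as.numeric(msh$centroid[, 1L] > 0.8 & msh$centroid[, 1L] < 1.6 &
                     msh$centroid[, 2L] > 0.3 & msh$centroid[, 2L] < 0.7)
  m0 <- sum(st$c * msh$area)
  cx0 <- sum(st$c * msh$area * msh$centroid[, 1L]) / m0
  nst <- 120 # advance t = 1.2, blob stays interior
  for (i in seq_len(nst)) st <- contrast_step(st, bcs, fluid_properties(), cfg)
  m1 <- sum(st$c * msh$area)
  cx1 <- sum(st$c * msh$area * msh$centroid[, 1L]) / m1
  expect_lt(abs((cx1 - cx0) - 1.2), msh$h) # displacement = v t within a cell
  expect_lt(abs(m1 - m0) / m0, 0.01)       # total contrast conserved
  expect_gte(min(st$c), 0)
  expect_lte(max(st$c), 1)
})

test_that("a closed cavity conserves contrast under rotation", {
  msh <- structured_rect_mesh(24, 24, 1, 1)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 1, cfl_limit = 3)
  bcs <- assemble_bcs(msh, "healthy")
  st <- with_velocity(msh, -(msh$vertices[, 2L] - 0.5),
                      msh$vertices[, 1L] - 0.5, cfg, bcs)
  st$c <- exp(-((msh$centroid[, 1L] - 0.6)^2 +
                (msh$centroid[, 2L] - 0.5)^2) / 0.02)
  m0 <- sum(st$c * msh$area)
  for (i in 1:100) st <- contrast_step(st, bcs, fluid_properties(), cfg)
  expect_lt(abs(sum(st$c * msh$area) - m0) / m0, 0.01)
  expect_gte(min(st$c), 0)
  expect_lte(max(st$c), 1)
})

test_that("with clean inflow the total contrast never increases", {
  msh <- open_channel_mesh(40, 10, 2, 0.5)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 1, T = 1, cfl_limit = 3)
  bcs <- assemble_bcs(msh, "healthy")
  one <- rep(1, nrow(msh$vertices))
  st <- with_velocity(msh, 0.8 * one, 0 * one, cfg, bcs)
  tot <- sum(st$c * msh$area)
  for (i in 1:80) {
    st <- contrast_step(st, bcs, fluid_properties(), cfg)
    tot_new <- sum(st$c * msh$area)
    expect_lte(tot_new, tot + 1e-12)
    tot <- tot_new
  }
  expect_lt(tot, sum(msh$area)) # some washout happened
  expect_gte(min(st$c), 0)
})
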