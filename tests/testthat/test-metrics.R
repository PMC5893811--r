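test_that("SSR reproduces the closed forms for canonical flows", {
  msh <- structured_rect_mesh(8, 8, 1, 1)
  x <- msh$vertices[, 1L]; y <- msh$vertices[, 2L]
  # uniform flow: zero gradient, zero SSR
  expect_equal(max(ssr_field(list(u = rep(2, length(x)),
                                  v = rep(-1, length(x))), msh)), 0)
  # simple shear u = (g y, 0): SSR = g everywhere
  g <- 3.7
  expect_equal(ssr_field(list(u = g * y, v = 0 * y), msh),
               rep(g, nrow(msh$triangles)), tolerance = 1e-12)
  # rigid rotation: antisymmetric gradient, zero strain
  expect_lt(max(ssr_field(list(u = -2 * (y - 0.5), v = 2 * (x - 0.5)), msh)),
            1e-12)
  # invariance under superposed uniform velocity
  s1 <- ssr_field(list(u = g * y, v = 0 * y), msh)
  s2 <- ssr_field(list(u = g * y + 5, v = 0 * y - 2), msh)
  expect_equal(s1, s2)
  expect_true(all(ssr_field(list(u = sin(3 * x) * y, v = cos(x) * y^2),
                            msh) >= 0))
})

test_that("centerline profiles interpolate the field at the stations", {
  msh <- rect_laa_mesh()
  cl <- extract_centerline(msh, 12)
  k <- 4.2
  pr <- centerline_profile(rep(k, nrow(msh$vertices)), cl, msh)
  expect_equal(pr$value, rep(k, nrow(pr)))
  expect_identical(pr$s, cl$s)
  # field equal to the x coordinate: profile = station x
  prx <- centerline_profile(msh$vertices[, 1L], cl, msh)
  expect_equal(prx$value, cl$x, tolerance = 1e-9)
  # station outside the mesh is an interpolation error
  cl_bad <- cl
  cl_bad$x[3L] <- 10
  expect_error(centerline_profile(msh$vertices[, 1L], cl_bad, msh),
               "interpolation error")
})

test_that("normalized volume integrals are exact for affine fields", {
  # single unit right triangle: mean of a linear field = vertex average
  msh <- laa_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(c(1L, 2L, 3L)))
  f <- function(x, y) 2 + 3 * x - 5 * y
  vals <- f(msh$vertices[, 1L], msh$vertices[, 2L])
  exact <- (f(0, 0) + f(1, 0) + f(0, 1)) / 3 # exact mean over the simplex
  expect_equal(normalized_volume_integral(vals, msh, "LA"), exact)
  expect_equal(normalized_volume_integral(vals, msh, "domain"), exact)
  # constant field on any region
  msh2 <- rect_laa_mesh()
  expect_equal(normalized_volume_integral(rep(7, nrow(msh2$triangles)),
                                          msh2, "LAA"), 7)
  # linearity and min/max bounds
  fc <- runif(nrow(msh2$triangles))
  a <- normalized_volume_integral(fc, msh2, "LAA")
  b <- normalized_volume_integral(2 * fc, msh2, "LAA")
  expect_equal(b, 2 * a)
  expect_gte(a, min(fc)); expect_lte(a, max(fc))
  expect_error(normalized_volume_integral(fc, structured_rect_mesh(4, 4),
                                          "LAA"), "region error")
})

test_that("residual contrast matches analytic piecewise-constant cases", {
  msh <- rect_laa_mesh()
  m <- nrow(msh$triangles)
  expect_equal(residual_contrast(rep(1, m), msh, "domain"), 100)
  expect_equal(residual_contrast(rep(0, m), msh, "domain"), 0)
  c_laa <- as.numeric(msh$region == "LAA")
  rv <- region_volumes(msh)
  expect_equal(residual_contrast(c_laa, msh, "domain"),
               100 * rv$V_LAA / rv$V_domain)
  expect_equal(residual_contrast(c_laa, msh, "laa"), 100)
  expect_error(residual_contrast(rep(1.5, m), msh), "field error")
})

test_that("dye localization reads the arclength of the dye centroid", {
  msh <- rect_laa_mesh()
  cl <- extract_centerline(msh, 16)
  m <- nrow(msh$triangles)
  # uniform dye along a straight uniform-width appendage: symmetric, 0.5
  expect_equal(dye_localization(as.numeric(msh$region == "LAA"), cl, msh),
               0.5, tolerance = 0.06)
  # dye only in the most distal cells
  cdist <- as.numeric(msh$centroid[, 1L] > 0.058)
  expect_gt(dye_localization(cdist, cl, msh), 0.93)
  # invariant under uniform scaling of c
  expect_equal(dye_localization(0.3 * cdist, cl, msh),
               dye_localization(cdist, cl, msh))
  expect_error(dye_localization(rep(0, m), cl, msh),
               "undefined-localization")
})

test_that("the periodicity metric has its closed-form values", {
  msh <- structured_rect_mesh(4, 4, 1, 1)
  n <- nrow(msh$vertices)
  snap <- function(u) list(u = u, v = 0 * u, t = 0)
  u1 <- runif(n)
  run <- list(snapshots = list(list(snap(u1), snap(2 * u1)),
                               list(snap(u1), snap(2 * u1)),
                               list(snap(2 * u1), snap(4 * u1))),
              mesh = msh)
  expect_equal(periodicity_metric(run, 1, 2), 0)
  expect_equal(periodicity_metric(run, 1, 3), 1)
  expect_error(periodicity_metric(run, 1, 9), "argument error")
  run$snapshots[[2]] <- list(NULL, NULL)
  expect_error(periodicity_metric(run, 1, 2), "argument error")
})

test_that("a quiescent run summarizes to full residual and zero velocity", {
  msh <- rect_laa_mesh(24, 6)
  cfg <- flow_solver_config(dt = 0.01, n_cycles = 2, T = 0.05,
                            snapshot_phases = c(0.5, 1))
  bcs <- assemble_bcs(msh, "healthy") # all walls: nothing moves
  run <- run_flow(msh, bcs, fluid_properties(), cfg)
  cl <- extract_centerline(msh, 12)
  s <- summarize_run(run, cl)
  expect_equal(s$mean_velocity_LAA, 0)
  expect_equal(s$mean_ssr_LAA, 0)
  expect_equal(s$residual_contrast_domain, 100)
  expect_equal(s$periodicity_metric, 0)
  run2 <- run_flow(msh, bcs, fluid_properties(), cfg)
  s2 <- summarize_run(run2, cl)
  expect_identical(s$centerline_velocity, s2$centerline_velocity)
  expect_identical(s$residual_contrast_laa, s2$residual_contrast_laa)
})
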