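test_that("a unit-square test domain meshes with fully tagged boundary", {
  sq <- polygon_anatomy(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  msh <- generate_mesh(sq, h = 0.1)
  expect_gt(nrow(msh$triangles), 0L)
  b <- msh$faces$right == 0L
  expect_true(all(msh$faces$tag[b] == "wall"))
  expect_false(anyNA(msh$faces$tag[b]))
  # every cell tagged, area adds up to the square
  expect_equal(region_volumes(msh)$V_domain, 1, tolerance = 1e-9)
})

test_that("halving h quadruples the cell count, roughly", {
  sq <- polygon_anatomy(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  n1 <- nrow(generate_mesh(sq, h = 0.1)$triangles)
  n2 <- nrow(generate_mesh(sq, h = 0.05)$triangles)
  expect_gt(n2 / n1, 3.0)
  expect_lt(n2 / n1, 5.0)
  # count oracle: domain area over the expected equilateral cell area
  expect_equal(n2, 1 / (sqrt(3) / 4 * 0.05^2), tolerance = 0.35)
})

test_that("an open outline is rejected", {
  open <- polygon_anatomy(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                          closed = FALSE)
  expect_error(generate_mesh(open, h = 0.1), "geometry error")
})

test_that("h coarser than the ostium is rejected", {
  fix <- cw_mesh()
  expect_error(generate_mesh(fix$anatomy, h = 0.02), "resolution error")
  expect_error(generate_mesh(fix$anatomy, h = -1), "resolution error")
})

test_that("region volumes are exact sums of cell measures", {
  verts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tris <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  msh <- laa_mesh(verts, tris, region = c("LA", "LAA"))
  rv <- region_volumes(msh)
  expect_equal(rv$V_LA, 0.5)
  expect_equal(rv$V_LAA, 0.5)
  expect_equal(rv$V_domain, 1)
  msh2 <- laa_mesh(verts, tris, region = c("LA", "LA"))
  expect_equal(region_volumes(msh2)$V_LAA, 0)
})

test_that("mesh volumes converge to the exact polygon area", {
  fix <- cw_mesh()
  exact <- abs(pracma::polyarea(fix$anatomy$polygon[, 1L],
                                fix$anatomy$polygon[, 2L]))
  got <- region_volumes(fix$mesh)$V_domain
  expect_equal(got, exact, tolerance = 0.01)
  # partition of the domain measure is exact
  rv <- region_volumes(fix$mesh)
  expect_equal(rv$V_LA + rv$V_LAA, rv$V_domain, tolerance = 1e-12)
})

test_that("meshing an anatomy is deterministic and tags the appendage", {
  fix <- cw_mesh()
  m2 <- generate_mesh(fix$anatomy, h = 1.4e-3)
  expect_identical(fix$mesh$vertices, m2$vertices)
  expect_identical(fix$mesh$triangles, m2$triangles)
  expect_identical(fix$mesh$region, m2$region)
  expect_gt(sum(fix$mesh$region == "LAA"), 0L)
  expect_gt(min(fix$mesh$quality), 0.12)
  labs <- unique(fix$mesh$faces$tag[fix$mesh$faces$right == 0L])
  expect_setequal(labs, c("wall", "mitral", paste0("pv_", 1:4)))
})
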