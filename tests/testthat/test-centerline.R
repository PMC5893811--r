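test_that("a straight uniform appendage gives a mid-axis centerline", {
  msh <- rect_laa_mesh() # left strip LA, rest LAA; symmetric about y = H/2
  cl <- extract_centerline(msh, 16)
  expect_s3_class(cl, "laa_centerline")
  expect_gte(nrow(cl), 8L)
  expect_true(all(diff(cl$s) > 0))
  expect_equal(cl$s[1L], 0)
  expect_equal(cl$s[nrow(cl)], 1)
  # stations on the rectangle mid-axis within h/2 (symmetry of the bands)
  expect_lt(max(abs(cl$y - 0.005)), msh$h / 2)
  # first station within h of the ostium-curve centroid
  oc <- laastasis:::.interface_centroid(msh)
  expect_lt(sqrt(sum((c(cl$x[1L], cl$y[1L]) - oc)^2)), msh$h)
})

test_that("a bent appendage keeps a monotone, interior centerline", {
  fix <- cw_mesh()
  cl <- extract_centerline(fix$mesh, 20)
  expect_true(all(diff(cl$s) > 0))
  loc <- laastasis:::.cpp_locate_points(cl$x, cl$y, fix$mesh$triangles,
                                        fix$mesh$vertices[, 1L],
                                        fix$mesh$vertices[, 2L], 0.05)
  expect_true(all(loc$triangle > 0L))
  # station 1 sits on the ostium curve (the LA/LAA interface); all others
  # must lie strictly inside the appendage
  expect_true(all(fix$mesh$region[loc$triangle[-1L]] == "LAA"))
})

test_that("degenerate inputs are rejected", {
  msh <- rect_laa_mesh()
  expect_error(extract_centerline(msh, 4), "argument error")
  all_la <- structured_rect_mesh(10, 4, 1, 0.2)
  expect_error(extract_centerline(all_la, 12), "region error")
})
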