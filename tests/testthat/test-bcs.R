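test_that("boundary facets partition into wall, PV and mitral sets", {
  fix <- cw_mesh()
  bcs <- assemble_bcs(fix$mesh, "healthy")
  expect_length(bcs$pv_facets, 4L) # chicken wing has 4 pulmonary veins
  expect_gt(length(bcs$mitral_facets), 0L)
  all_facets <- c(bcs$wall_facets, unlist(bcs$pv_facets), bcs$mitral_facets)
  boundary <- which(fix$mesh$faces$right == 0L)
  expect_setequal(all_facets, boundary)
  expect_equal(anyDuplicated(all_facets), 0L)
  expect_identical(bcs$p_pv, 0)
  # plug direction is a unit vector pointing out of the domain
  expect_equal(sum(bcs$plug_direction^2), 1, tolerance = 1e-12)
})

test_that("conditions share facet sets and differ only in the waveform", {
  fix <- cw_mesh()
  bh <- assemble_bcs(fix$mesh, "healthy")
  ba <- assemble_bcs(fix$mesh, "af")
  expect_identical(bh$wall_facets, ba$wall_facets)
  expect_identical(bh$pv_facets, ba$pv_facets)
  expect_identical(bh$mitral_facets, ba$mitral_facets)
  expect_identical(ba$waveform$A_peak, 0)
  expect_gt(bh$waveform$A_peak, 0)
})

test_that("unknown facet labels are a tagging error", {
  msh <- structured_rect_mesh(4, 4, 1, 1,
                              facet_tags = function(mx, my)
                                if (my < 0.3) "outflow" else "wall")
  expect_error(assemble_bcs(msh, "healthy"), "tagging error")
})
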