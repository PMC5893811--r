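test_that("specs validate their invariants", {
  expect_error(anatomy_spec("chicken_wing", ostium_diameter = 0),
               "invalid-spec")
  expect_error(anatomy_spec("chicken_wing", laa_length = -0.01),
               "invalid-spec")
  expect_error(anatomy_spec("windsock", ostium_diameter = 0.06),
               "invalid-spec")
  expect_error(anatomy_spec("cactus", n_pv_inlets = 7), "invalid-spec")
  expect_error(anatomy_spec("cauliflower", n_lobes = 2), "invalid-spec")
  expect_error(anatomy_spec("banana"), "invalid-spec")
})

test_that("class defaults encode the clinical shape contrasts", {
  sp <- default_anatomy_specs()
  expect_lt(sp$cauliflower$laa_length, sp$windsock$laa_length)
  expect_equal(vapply(sp, `[[`, integer(1), "n_pv_inlets"),
               c(chicken_wing = 4L, cactus = 5L, windsock = 6L,
                 cauliflower = 4L))
  # pairwise different (lobes, bend, taper, length) signatures
  sig <- lapply(sp, function(s) c(s$n_lobes,
                                  if (s$morphology_class == "chicken_wing")
                                    s$bend_angle else 0,
                                  if (s$morphology_class == "windsock")
                                    s$taper_ratio else 1,
                                  s$laa_length))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(isTRUE(all.equal(sig[[i]], sig[[j]])))
})

test_that("geometry is a deterministic function of the spec", {
  sp <- anatomy_spec("cauliflower", n_lobes = 4, seed = 7)
  a1 <- generate_anatomy(sp)
  a2 <- generate_anatomy(sp)
  expect_identical(a1, a2)
  a3 <- generate_anatomy(anatomy_spec("cauliflower", n_lobes = 4, seed = 8))
  expect_false(identical(a1$polygon, a3$polygon))
})

test_that("boundary outlines are closed and labeled", {
  for (sp in default_anatomy_specs(seed = 3)) {
    an <- generate_anatomy(sp)
    labs <- vapply(an$segments, `[[`, "", "label")
    expect_true("mitral" %in% labs)
    expect_equal(sum(grepl("^pv_", labs)), sp$n_pv_inlets)
    ends <- t(vapply(an$segments, function(s) s$pts[nrow(s$pts), ],
                     numeric(2)))
    starts <- t(vapply(an$segments, function(s) s$pts[1L, ], numeric(2)))
    expect_lt(max(abs(ends - starts[c(seq_len(nrow(starts))[-1L], 1L), ])),
              1e-9)
    expect_equal(nrow(an$ostium), 2L)
  }
})

test_that("the chicken-wing spine bends by the prescribed angle", {
  an <- generate_anatomy(anatomy_spec("chicken_wing", bend_angle = 100,
                                      seed = 1))
  sp <- an$spine
  n <- nrow(sp)
  dir_of <- function(rows) {
    d <- colMeans(diff(sp[rows, 1:2, drop = FALSE]))
    atan2(d[2], d[1]) * 180 / pi
  }
  prox <- dir_of(1:floor(n / 3))
  dist <- dir_of(ceiling(2 * n / 3):n)
  delta <- abs(((dist - prox + 180) %% 360) - 180)
  expect_lt(abs(delta - 100), 5)
})
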