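# parametric hook generator and its ground truth

test_that("ground-truth AD and HNL follow from the construction", {
  p <- hook_shape_params() # identity pose, shaft along +x, base at origin
  f <- build_hook_outline(p)
  expect_equal(unname(f$truth["AD"]),
               sqrt(sum((f$outline$tip - f$outline$articulation_base)^2)),
               tolerance = 1e-10)
  expect_equal(unname(f$truth["HNL"]), p$handle_length)
})

test_that("rigid pose changes coordinates but not structure or truth", {
  base <- build_hook_outline(hook_shape_params())
  posed <- build_hook_outline(hook_shape_params(rotation = 123,
                                                translation = c(-30, 12)))
  expect_equal(nrow(posed$outline$inner_edge), nrow(base$outline$inner_edge))
  expect_equal(nrow(posed$outline$outer_edge), nrow(base$outline$outer_edge))
  expect_equal(posed$outline$straight_range, base$outline$straight_range)
  expect_equal(posed$truth, base$truth, tolerance = 1e-6)
})

test_that("ground truth is stable under resolution doubling", {
  f1 <- build_hook_outline(hook_shape_params(resolution = 100))
  f2 <- build_hook_outline(hook_shape_params(resolution = 200))
  rel <- abs(f2$truth - f1$truth) / pmax(abs(f1$truth), 1e-9)
  expect_lt(max(rel), 0.002)
})

test_that("invalid shape parameters are rejected", {
  expect_error(hook_shape_params(shaft_length = -1), "lengths")
  expect_error(hook_shape_params(blade_arc_degrees = 300), "blade_arc")
  expect_error(hook_shape_params(point_taper_fraction = 0), "taper")
  expect_error(hook_shape_params(resolution = 10), "resolution")
})

test_that("self-intersection detection catches a bowtie ring", {
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_false(hookmorph:::ring_is_simple(bowtie))
  square <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_true(hookmorph:::ring_is_simple(square))
  f <- build_hook_outline(hook_shape_params())
  expect_true(hookmorph:::ring_is_simple(hookmorph:::outline_ring(f$outline)))
})
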