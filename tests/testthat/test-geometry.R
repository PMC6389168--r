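# measurement engine: shaft axis, zenith search, landmarks, measurements

test_that("shaft axis recovers a collinear section exactly and equivariantly", {
  inner <- cbind(rep(0, 20), seq(10, 0, length.out = 20)) # along -y, tip first
  outer <- cbind(c(0, rep(-1, 19)), seq(10, 0, length.out = 20))
  o <- hook_outline(inner, outer, articulation_base = c(-0.5, 0),
                    straight_range = 1:20)
  ax <- fit_shaft_axis(o)
  expect_equal(abs(ax$direction), c(0, 1), tolerance = 1e-12)
  expect_gt(sum(ax$direction * c(0, 1)), 0) # oriented base -> tip

  o2 <- transform_outline(o, rotation = 37)
  ax2 <- fit_shaft_axis(o2)
  expect_equal(ax2$direction, drop(hookmorph:::rotmat(37) %*% ax$direction),
               tolerance = 1e-12)
})

test_that("noisy shaft axis equals the principal component of the scatter", {
  set.seed(1)
  for (i in 1:5) {
    ang <- runif(1, 0, pi)
    t <- seq(0, 8, length.out = 40)
    pts <- cbind(t * cos(ang), t * sin(ang)) + matrix(rnorm(80, 0, 0.1), 40)
    o <- hook_outline(pts, rbind(pts[1, ], pts[1, ] + c(1, 1)),
                      articulation_base = pts[40, ], straight_range = 1:40)
    ax <- fit_shaft_axis(o)
    pc <- prcomp(pts)$rotation[, 1] # independent oracle
    expect_equal(abs(sum(ax$direction * pc)), 1, tolerance = 1e-8)
  }
})

test_that("zenith of a semicircular arc is its apex at distance r", {
  r <- 5
  th <- seq(0, pi, length.out = 400)
  arc <- cbind(r * cos(th), r * sin(th))
  z <- find_zenith(arc, line_point = c(-r, 0), line_direction = c(1, 0))
  expect_equal(unname(z$distance), r, tolerance = 1e-4)
  # apex located to within the polyline's own vertex spacing
  expect_lt(max(abs(z$point - c(0, r))), 0.05)
})

test_that("collinear edge gives zero distance and the tie-break picks the tip end", {
  edge <- cbind(seq(0, 10, length.out = 50), 0)
  z <- find_zenith(edge, line_point = c(0, 0), line_direction = c(1, 0))
  expect_equal(unname(z$distance), 0)
  expect_equal(unname(z$arc_length), 0) # smallest arc length from the tip
})

test_that("zenith search matches a brute-force densified argmax", {
  set.seed(2)
  for (i in 1:10) {
    pts <- cbind(cumsum(runif(30, 0.2, 1)), rnorm(30))
    a <- c(0, -2); u <- c(1, 0.2) / sqrt(1.04)
    z <- find_zenith(pts, a, u, region = c(0.1, 0.9), step = 0.01)
    # oracle: exhaustive over a heavily densified vertex set
    s <- hookmorph:::arc_lengths(pts)
    si <- seq(0, max(s), length.out = 2e5)
    dd <- cbind(approx(s, pts[, 1], si)$y, approx(s, pts[, 2], si)$y)
    tv <- hookmorph:::proj_component(pts, a, u)
    lo <- min(tv) + 0.1 * diff(range(tv)); hi <- min(tv) + 0.9 * diff(range(tv))
    tt <- hookmorph:::proj_component(dd, a, u)
    sel <- tt >= lo & tt <= hi
    dmax <- max(abs(hookmorph:::perp_component(dd[sel, ], a, u)))
    expect_equal(unname(z$distance), dmax, tolerance = 1e-3)
  }
})

test_that("landmarks agree with dense ground truth and move rigidly", {
  set.seed(3)
  f <- build_hook_outline(random_shape_params(posed = FALSE))
  lm <- derive_landmarks(f$outline)
  m <- measure_hook(f$outline)
  lv <- setdiff(names(m), angle_variables())
  expect_lt(max(abs(m - f$truth[names(m)])[lv] /
                  pmax(abs(f$truth[lv]), 1e-9)), 0.005)

  mv <- transform_outline(f$outline, rotation = 77, translation = c(5, -9))
  lm2 <- derive_landmarks(mv)
  R <- hookmorph:::rotmat(77)
  for (nm in c("Z_out", "F_AD", "P_in", "H_heel", "Z_inner_blade",
               "Z_outer_blade")) {
    expect_equal(lm2[[nm]], drop(R %*% lm[[nm]]) + c(5, -9),
                 tolerance = 1e-6, label = nm)
  }
})

test_that("a straight strip with no blade curvature is a geometry error", {
  inner <- cbind(seq(10, 0, length.out = 30), 0)
  outer <- rbind(c(10, 0), cbind(seq(10, 0, length.out = 29), -1))
  o <- hook_outline(inner, outer, articulation_base = c(0, -0.5))
  expect_error(derive_landmarks(o), "degenerate")
})

test_that("axis-aligned distances come out exactly", {
  # AD is a pure point-to-point distance; build a hook whose tip/base are known
  f <- build_hook_outline(hook_shape_params())
  m <- measure_hook(f$outline)
  expect_equal(unname(m["AD"]),
               hookmorph:::vnorm(f$outline$tip - f$outline$articulation_base),
               tolerance = 1e-12)
  expect_equal(measure_handle(c(0, 0), c(0, 41.45)), 41.45)
  expect_warning(z <- measure_handle(c(1, 1), c(1, 1)), "coincide")
  expect_equal(z, 0)
})

test_that("measurements are rigid-motion invariant and scale equivariant", {
  set.seed(4)
  f <- build_hook_outline(random_shape_params(posed = FALSE))
  m <- measure_specimen(f$outline)
  lv <- setdiff(hook_variables(), angle_variables())

  posed <- transform_outline(f$outline, rotation = 211,
                             translation = c(-40, 17), reflect = TRUE)
  mp <- measure_specimen(posed)
  expect_equal(mp[lv] / m[lv], setNames(rep(1, length(lv)), lv),
               tolerance = 2e-3)
  expect_lt(max(abs(mp - m)[angle_variables()]), 0.1)

  scaled <- transform_outline(f$outline, scale = 2)
  ms <- measure_specimen(scaled)
  expect_equal(ms[lv] / m[lv], setNames(rep(2, length(lv)), lv),
               tolerance = 2e-3)
  expect_lt(max(abs(ms - m)[angle_variables()]), 0.1)
})

test_that("measurements are stable under densification-step halving", {
  f <- build_hook_outline(hook_shape_params())
  m1 <- measure_hook(f$outline, geometry_control(step = 0.02))
  m2 <- measure_hook(f$outline, geometry_control(step = 0.01))
  expect_lt(max(abs(m2 - m1) / pmax(abs(m1), 1e-9)), 0.002)
})

test_that("ordering and polygon bounds hold across a random parameter sweep", {
  set.seed(5)
  for (i in 1:20) {
    f <- build_hook_outline(random_shape_params())
    o <- f$outline
    lm <- derive_landmarks(o)
    m <- measure_specimen(o)
    u <- (o$tip - o$articulation_base) /
      hookmorph:::vnorm(o$tip - o$articulation_base)
    ph <- sum((lm$H_heel - o$articulation_base) * u)
    pz <- sum((lm$Z_out - o$articulation_base) * u)
    expect_lt(ph, pz) # heel is proximal of the outer zenith
    expect_true(all(m[setdiff(hook_variables(), angle_variables())] >= 0))
    expect_true(all(m[angle_variables()] > 0 & m[angle_variables()] < 180))
    expect_lte(m[["ISL"]], m[["OSL"]] + m[["PSW"]] + m[["DSW"]] + 1e-9)
  }
})
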