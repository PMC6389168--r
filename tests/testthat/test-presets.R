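# published per-species summary presets

test_that("presets carry the published summary values", {
  p <- diplozoid_presets()
  expect_named(p, c("P. vaalense", "D. paradoxum", "P. ichthyoxanthon"))
  expect_equal(p[["D. paradoxum"]]$variables[["HL"]]$mean, 30.67)
  expect_equal(p[["D. paradoxum"]]$variables[["HL"]]$sd, 0.65)
  expect_equal(p[["P. vaalense"]]$variables[["HL"]]$mean, 18.53)
  expect_equal(p[["P. vaalense"]]$variables[["HL"]]$range_low, 17.77)
  expect_equal(p[["P. vaalense"]]$variables[["HL"]]$range_high, 19.35)
  expect_equal(p[["P. ichthyoxanthon"]]$variables[["HNL"]]$mean, 55.25)
  # discriminant-analysis group sizes
  expect_equal(vapply(p, function(s) s$n_default, integer(1)),
               c("P. vaalense" = 8L, "D. paradoxum" = 4L,
                 "P. ichthyoxanthon" = 5L))
})

test_that("every species carries the 14 variables with consistent ranges", {
  for (sp in diplozoid_presets()) {
    expect_length(sp$variables, 14)
    expect_setequal(names(sp$variables), hook_variables())
    for (v in sp$variables) {
      expect_true(v$sd >= 0)
      expect_true(v$range_low <= v$mean && v$mean <= v$range_high)
    }
  }
})

test_that("parameter constructors validate their invariants", {
  expect_error(variable_params("HL", mean = 10, sd = 1,
                               range_low = 11, range_high = 12),
               "bracket")
  expect_error(variable_params("HL", mean = 10, sd = -1,
                               range_low = 9, range_high = 11))
  vp <- lapply(hook_variables(), variable_params,
               mean = 10, sd = 1, range_low = 8, range_high = 12)
  expect_error(species_params("x", 3, vp[1:13]), "14")
  expect_s3_class(species_params("x", 3, vp), "species_params")
})
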