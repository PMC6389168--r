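# measurement-table simulator

test_that("seeded generation is reproducible bit for bit", {
  a <- generate_measurements(diplozoid_presets(), seed = 11)
  b <- generate_measurements(diplozoid_presets(), seed = 11)
  expect_identical(a, b)
  c <- generate_measurements(diplozoid_presets(), seed = 12)
  expect_false(identical(a, c))
})

test_that("empirical moments converge to the preset distributions", {
  n <- 1e5
  d <- generate_measurements(diplozoid_presets(),
                             n = c("P. vaalense" = n, "D. paradoxum" = 0,
                                   "P. ichthyoxanthon" = 0),
                             seed = 3)
  p <- diplozoid_presets()[["P. vaalense"]]$variables
  for (v in c("HL", "HNL", "PCA", "DSW")) {
    se_mean <- p[[v]]$sd / sqrt(n)
    expect_lt(abs(mean(d[[v]]) - p[[v]]$mean), 4 * se_mean)
    se_sd <- p[[v]]$sd / sqrt(2 * (n - 1))
    expect_lt(abs(sd(d[[v]]) - p[[v]]$sd), 4 * se_sd)
  }
})

test_that("empty request yields an empty table with all variable columns", {
  d <- generate_measurements(diplozoid_presets(),
                             n = c("P. vaalense" = 0, "D. paradoxum" = 0,
                                   "P. ichthyoxanthon" = 0),
                             seed = 1)
  expect_equal(nrow(d), 0)
  expect_true(all(hook_variables() %in% names(d)))
})

test_that("unknown species and missing seed are input errors", {
  expect_error(generate_measurements(diplozoid_presets(),
                                     n = c(Nessie = 3), seed = 1),
               "unknown species")
  expect_error(generate_measurements(diplozoid_presets()), "seed")
})

test_that("truncation keeps every draw inside the published range", {
  d <- generate_measurements(diplozoid_presets(),
                             n = c("P. vaalense" = 500, "D. paradoxum" = 0,
                                   "P. ichthyoxanthon" = 0),
                             seed = 5, truncate = TRUE)
  p <- diplozoid_presets()[["P. vaalense"]]$variables
  for (v in hook_variables()) {
    expect_true(all(d[[v]] >= p[[v]]$range_low & d[[v]] <= p[[v]]$range_high))
  }
})
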