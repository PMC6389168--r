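# summaries, Kruskal-Wallis post hoc, equality of group means

test_that("summaries match hand and formula oracles, with published formatting", {
  d <- data.frame(specimen_id = 1:3, species = "A", HL = c(1, 2, 3))
  s <- summarize_measurements(d, "HL")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$min, 1); expect_equal(s$max, 3)
  expect_equal(s$label, "2.00 ± 1.00 (1.00–3.00)")

  set.seed(6)
  d2 <- generate_measurements(diplozoid_presets(), seed = 6)
  s2 <- summarize_measurements(d2)
  for (i in sample(nrow(s2), 10)) {
    x <- d2[[s2$variable[i]]][d2$species == s2$species[i]]
    expect_equal(s2$mean[i], sum(x) / length(x))
    expect_equal(s2$sd[i], sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  }
  # the published layout round-trips
  expect_equal(format_summary(18.53, 0.39, 17.77, 19.35),
               "18.53 ± 0.39 (17.77–19.35)")
})

test_that("Kruskal-Wallis H matches the rank-formula value on a hand case", {
  d <- data.frame(species = rep(c("a", "b", "c"), each = 2),
                  HL = c(1, 2, 3, 4, 5, 6))
  k <- kw_posthoc(d, "HL")
  expect_equal(k$H, 32 / 7, tolerance = 1e-12)
})

test_that("exact permutation p agrees with an independent Monte-Carlo oracle", {
  set.seed(8)
  for (i in 1:3) {
    d <- data.frame(species = rep(c("a", "b", "c"), times = c(3, 3, 2)),
                    HL = rnorm(8))
    k <- kw_posthoc(d, "HL", exact = TRUE)
    p_mc <- mc_kw_p(d$HL, factor(d$species))
    se <- sqrt(p_mc * (1 - p_mc) / 20000)
    expect_lt(abs(k$p_global - p_mc), 4 * se + 1e-6)
  }
})

test_that("identical observations give H = 0 and no significant pairs", {
  d <- data.frame(species = rep(c("a", "b", "c"), each = 3), HL = 5)
  k <- kw_posthoc(d, "HL")
  expect_equal(k$H, 0)
  expect_false(any(k$pairwise$significant))
})

test_that("complete separation at sizes 8 and 4 is significant post hoc", {
  d <- data.frame(species = rep(c("a", "b"), times = c(8, 4)),
                  HL = c(rnorm(8), rnorm(4) + 1000))
  for (method in c("dunn", "pairwise")) {
    k <- kw_posthoc(d, "HL", method = method)
    expect_true(k$pairwise$significant[1], label = method)
  }
})

test_that("empty groups are rejected", {
  d <- data.frame(species = factor(rep("a", 3), levels = c("a", "b")),
                  HL = 1:3)
  expect_error(kw_posthoc(d, "HL"), "0 observations")
  d2 <- data.frame(species = c("a", "a", "b"), HL = c(1, 2, NA))
  expect_error(kw_posthoc(d2, "HL"), "0 observations")
})

test_that("equality of group means: degenerate and published-shape cases", {
  # identical group means, nonzero within variance -> Lambda = 1, F = 0
  d <- data.frame(species = rep(c("a", "b", "c"), each = 4),
                  HL = rep(c(-1, 1), 6))
  r <- equality_of_group_means(d, "HL")
  expect_equal(r$wilks_lambda, 1)
  expect_equal(r$F, 0)

  # group sizes 8/4/5 -> df1 = 2, df2 = 14 on every row
  d2 <- generate_measurements(diplozoid_presets(), seed = 9)
  r2 <- equality_of_group_means(d2)
  expect_equal(nrow(r2), 14)
  expect_true(all(r2$df1 == 2))
  expect_true(all(r2$df2 == 14))
})

test_that("univariate F equals a one-way ANOVA F and the Lambda identity holds", {
  set.seed(10)
  d <- data.frame(species = rep(c("a", "b", "c"), times = c(6, 5, 7)),
                  HL = rnorm(18), AD = rnorm(18, sd = 3))
  r <- equality_of_group_means(d, c("HL", "AD"))
  for (v in c("HL", "AD")) {
    fo <- anova(aov(d[[v]] ~ d$species))$`F value`[1] # independent oracle
    expect_equal(r$F[r$variable == v], fo, tolerance = 1e-10)
    lam <- r$wilks_lambda[r$variable == v]
    N <- 18; k <- 3
    expect_equal(r$F[r$variable == v],
                 (1 - lam) / lam * ((N - k) / (k - 1)), tolerance = 1e-12)
  }
})

test_that("zero-variance variables are flagged, not silently dropped", {
  d <- data.frame(species = rep(c("a", "b"), each = 3), HL = 2)
  expect_warning(r <- equality_of_group_means(d, "HL"), "zero total variance")
  expect_true(is.na(r$wilks_lambda))
})
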