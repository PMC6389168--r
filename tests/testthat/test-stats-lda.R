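# stepwise selection, canonical functions, classification

test_that("a dominant variable enters first; noise variables stay out", {
  set.seed(11)
  d <- data.frame(species = rep(c("a", "b", "c"), times = c(8, 4, 5)))
  d$signal <- c(rnorm(8), rnorm(4) + 50, rnorm(5) + 100)
  d$noise1 <- rnorm(17)
  d$noise2 <- rnorm(17)
  sel <- stepwise_select(d, c("noise1", "signal", "noise2"))
  expect_equal(sel$selected[1], "signal")
})

test_that("all-noise candidates typically select nothing at N = 17", {
  empty <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    d <- data.frame(species = rep(c("a", "b", "c"), times = c(8, 4, 5)))
    for (v in hook_variables()) d[[v]] <- rnorm(17)
    length(stepwise_select(d, hook_variables())$selected) == 0
  }, logical(1))
  # empty selection is the modal outcome under the null
  sizes <- table(vapply(1:40, function(s) {
    set.seed(1000 + s)
    d <- data.frame(species = rep(c("a", "b", "c"), times = c(8, 4, 5)))
    for (v in hook_variables()) d[[v]] <- rnorm(17)
    length(stepwise_select(d, hook_variables())$selected)
  }, numeric(1)))
  expect_equal(names(which.max(sizes)), "0")
  expect_gt(sum(empty), 10)
})

test_that("the first entered variable has the largest univariate F", {
  for (s in 1:5) {
    d <- generate_measurements(diplozoid_presets(), seed = 100 + s)
    sel <- stepwise_select(d)
    eq <- equality_of_group_means(d)
    expect_equal(sel$selected[1], eq$variable[which.max(eq$F)])
    expect_equal(sel$log$F[1], max(eq$F), tolerance = 1e-10)
  }
})

test_that("three groups give two canonical functions with unit pooled variance", {
  d <- generate_measurements(diplozoid_presets(), seed = 13)
  m <- fit_canonical(d, c("HL", "HNL", "DSW"))
  expect_equal(m$n_functions, 2)
  expect_true(all(abs(m$structure_matrix) <= 1 + 1e-12))
  # pooled within-group variance of scores = 1 per function
  X <- as.matrix(d[, m$variables])
  sc <- sweep(X, 2, m$grand_mean) %*% m$coefficients
  g <- factor(d$species)
  for (j in 1:2) {
    ssw <- sum(tapply(sc[, j], g, function(x) sum((x - mean(x))^2)))
    expect_equal(ssw / (nrow(d) - nlevels(g)), 1, tolerance = 1e-10)
  }
})

test_that("two-group canonical direction matches the Fisher closed form", {
  set.seed(14)
  d <- data.frame(species = rep(c("a", "b"), each = 10),
                  v1 = rnorm(20), v2 = rnorm(20), v3 = rnorm(20))
  d$v1[d$species == "b"] <- d$v1[d$species == "b"] + 3
  d$v2[d$species == "b"] <- d$v2[d$species == "b"] + 1
  m <- fit_canonical(d, c("v1", "v2", "v3"), candidates = c("v1", "v2", "v3"))
  X <- as.matrix(d[, c("v1", "v2", "v3")])
  g <- factor(d$species)
  mu <- rowsum(X, g) / as.vector(table(g))
  Sw <- (crossprod(sweep(X[g == "a", ], 2, mu["a", ])) +
         crossprod(sweep(X[g == "b", ], 2, mu["b", ]))) / (20 - 2)
  fisher <- solve(Sw, mu["b", ] - mu["a", ]) # independent closed form
  v <- m$coefficients[, 1]
  expect_equal(abs(sum(v * fisher) / sqrt(sum(v^2) * sum(fisher^2))), 1,
               tolerance = 1e-8)
  expect_equal(m$n_functions, 1)
})

test_that("widely separated clouds classify perfectly, matching MASS::lda", {
  skip_if_not_installed("MASS")
  d <- two_cloud_data()
  cls <- classify_loo(d, c("v1", "v2"))
  expect_equal(cls$overall$original, 100)
  expect_equal(cls$overall$cv, 100)
  fit <- MASS::lda(species ~ v1 + v2, data = d,
                   prior = c(0.5, 0.5)) # independent implementation
  expect_equal(as.character(cls$original),
               as.character(predict(fit)$class))
})

test_that("each LOO assignment equals a manual refit without that specimen", {
  d <- generate_measurements(diplozoid_presets(), seed = 15)
  sel <- c("HL", "DSW")
  cls <- classify_loo(d, sel)
  for (i in c(1, 5, 9, 13, 17)) {
    m_i <- fit_canonical(d[-i, ], sel, candidates = sel)
    expect_equal(as.character(cls$cv[i]),
                 as.character(predict_discriminant(m_i, d[i, ])))
  }
})

test_that("classification is invariant under affine rescaling of a variable", {
  d <- generate_measurements(diplozoid_presets(), seed = 16)
  cls <- classify_loo(d, c("HL", "HNL"))
  d2 <- d
  d2$HL <- d2$HL * 1000 + 7 # unit change cancels in Mahalanobis distance
  cls2 <- classify_loo(d2, c("HL", "HNL"))
  expect_identical(as.character(cls$original), as.character(cls2$original))
  expect_identical(as.character(cls$cv), as.character(cls2$cv))
})

test_that("classification tables have consistent margins and percentages", {
  d <- generate_measurements(diplozoid_presets(), seed = 17)
  res <- discriminant_analysis(d)
  cls <- res$classification
  expect_equal(unname(rowSums(cls$counts$original)),
               unname(as.vector(table(d$species)[rownames(cls$counts$original)])))
  expect_equal(unname(rowSums(cls$percent$original)), rep(100, 3))
  expect_equal(dim(cls$counts$cv), c(3, 3))
  expect_named(res$scores <- cls$scores,
               c("specimen_id", "species", "function1", "function2"))
})

test_that("singular selections fail with an informative error", {
  d <- generate_measurements(diplozoid_presets(), seed = 18)
  d$dup <- d$HL
  expect_error(fit_canonical(d, c("HL", "dup"), candidates = c("HL", "dup")),
               "singular")
})
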