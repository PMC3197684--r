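test_that("neighbor interpolation reproduces constant, single-source and symmetric fields", {
  g <- flat_grid(-1:1, -1:1, temp = 12)
  g$temp[g$lat == 0 & g$lon == 0] <- NA
  expect_equal(interpolate_cell(g, 0, 0, 0), 12)

  g2 <- flat_grid(-1:1, -1:1, temp = NA_real_)
  g2$temp[g2$lat == 1 & g2$lon == 0] <- 9.5  # only the north neighbor
  expect_equal(interpolate_cell(g2, 0, 0, 0), 9.5)

  # east and west neighbors sit at equal angular distance
  g3 <- flat_grid(-1:1, -1:1, temp = NA_real_)
  g3$temp[g3$lat == 0 & g3$lon == -1] <- 10
  g3$temp[g3$lat == 0 & g3$lon == 1] <- 20
  expect_equal(interpolate_cell(g3, 0, 0, 0), 15)
  expect_equal(interpolate_cell(g3, 0, 0, 0, method = "flat"), 15)

  # all neighbors missing: stays missing
  g4 <- flat_grid(-1:1, -1:1, temp = NA_real_)
  expect_true(is.na(interpolate_cell(g4, 0, 0, 0)))
})

test_that("interpolation is a convex combination of the neighbors it uses", {
  set.seed(61)
  for (rep in 1:50) {
    g <- flat_grid(59:61, 0:2, temp = NA_real_)
    obs <- runif(nrow(g)) < 0.6
    g$temp[obs] <- runif(sum(obs), -2, 30)
    v <- interpolate_cell(g, 60, 1, 0)
    nb <- g$temp[!(g$lat == 60 & g$lon == 1) & !is.na(g$temp)]
    if (length(nb) == 0) {
      expect_true(is.na(v))
    } else {
      expect_gte(v, min(nb))
      expect_lte(v, max(nb))
    }
  }
})

test_that("single-pass filling never cascades through interpolated cells", {
  g <- flat_grid(0:4, 0:0, temp = NA_real_)
  g$temp[g$lat == 0] <- 10
  filled <- fill_missing_temperatures(g)
  # lat 1 has an observed neighbor (lat 0); lat 2 has only missing ones
  expect_equal(filled$temp[filled$lat == 1], 10)
  expect_true(filled$interpolated[filled$lat == 1])
  expect_true(filled$still_missing[filled$lat == 2])
})

test_that("longitude wraps across the antimeridian", {
  g <- flat_grid(0:2, c(-180, -179, 179), temp = NA_real_)
  g$temp[g$lat == 1 & g$lon == 179] <- 7
  expect_equal(interpolate_cell(g, 1, -180, 0), 7)
})

test_that("correlation PCA satisfies its algebraic identities", {
  set.seed(62)
  n <- 60
  base <- runif(n, 0, 25)
  temps <- sapply(water_column_depths(), function(z) {
    2 + (base - 2) * exp(-z / 100) + rnorm(n, 0, 0.3)
  })
  colnames(temps) <- paste0("t", water_column_depths())
  res <- thermal_pca(temps)
  expect_equal(sum(res$eigenvalues), 13, tolerance = 1e-9)
  expect_equal(sum(res$variance_explained), 100, tolerance = 1e-6)
  expect_lt(max(abs(colMeans(res$scores))), 1e-9)
  cc <- crossprod(res$scores) / (n - 1)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-9)
  # PC1 is the mean thermal state
  expect_gt(cor(res$scores[, 1], rowMeans(temps)), 0.99)

  # perfectly collinear variables: PC1 explains everything
  coll <- outer(base, seq(1, 2, length.out = 13))
  colnames(coll) <- paste0("t", water_column_depths())
  res2 <- thermal_pca(coll)
  expect_equal(res2$variance_explained[[1]], 100, tolerance = 1e-6)

  const <- temps
  const[, "t500"] <- 5
  expect_error(thermal_pca(const), "t500")
})

test_that("the synthetic field's PC2 contrasts surface against subsurface depths", {
  grid <- generate_coretop_grid(sim_config(seed = 63, grid_extent = 30))
  tcols <- paste0("t", water_column_depths())
  temps <- as.matrix(grid$coretops[tcols])
  temps <- temps[stats::complete.cases(temps), ]
  res <- thermal_pca(temps)
  l2 <- res$loadings[, 2]
  # depths near the thermocline crossover (75-125 m) sit close to the
  # PC2 node, so only unambiguous surface and deep layers are asserted
  shallow <- l2[paste0("t", c(0, 10, 20, 30, 50))]
  deep <- l2[paste0("t", c(150, 250, 300, 400, 500))]
  expect_true(all(shallow * mean(shallow) > 0))
  expect_true(all(deep * mean(deep) > 0))
  expect_true(sign(mean(shallow)) != sign(mean(deep)))
})

test_that("binned PC1-SST regression recovers exact and noisy linear fields", {
  # noiseless field with SSTs at bin centers: exact recovery
  sst <- rep(seq(0.5, 24.5, by = 1), each = 4)
  pc1 <- 0.3 * sst + 1
  fit <- pc1_sst_regression(pc1, sst)
  expect_equal(fit$slope, 0.3, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$slope_binmean, 0.3, tolerance = 1e-9)

  # noisy field: slope within 3 standard errors
  set.seed(64)
  sst2 <- runif(1000, 0, 25)
  pc12 <- 0.3 * sst2 + 1 + rnorm(1000, 0, 0.5)
  fit2 <- pc1_sst_regression(pc12, sst2)
  bins <- fit2$bins
  se <- summary(lm(pc1_mean ~ center, data = bins))$coefficients["center", 2]
  expect_lt(abs(fit2$slope - 0.3), 3 * se)

  # an empty bin is simply absent and does not break the fit
  sst3 <- c(rep(0.5, 5), rep(1.5, 5), rep(3.5, 5), rep(4.5, 5))
  pc13 <- 0.3 * sst3
  fit3 <- pc1_sst_regression(pc13, sst3)
  expect_false(2.5 %in% fit3$bins$center)
  expect_equal(fit3$slope, 0.3, tolerance = 1e-9)

  expect_error(pc1_sst_regression(1:5, rep(0.5, 5)), "3 non-empty")
})

test_that("occurrence statistics match hand arithmetic and scaling invariance", {
  counts <- rbind(c(50, 50), c(0, 100), c(10, 90), c(30, 70))
  colnames(counts) <- c("focal", "other")
  res <- occurrence_stats(counts, "focal")
  expect_identical(res$n_present, 3L)
  expect_equal(res$pct_present, 75)
  expect_equal(res$mean_rel_abundance, mean(c(0.5, 0.1, 0.3)))
  expect_equal(res$ci_low, unname(quantile(c(0.5, 0.1, 0.3), 0.025, type = 7)))

  # present everywhere at 50%
  c2 <- rbind(c(5, 5), c(20, 20))
  colnames(c2) <- c("focal", "other")
  r2 <- occurrence_stats(c2, "focal")
  expect_equal(c(r2$pct_present, r2$mean_rel_abundance, r2$ci_low, r2$ci_high),
               c(100, 0.5, 0.5, 0.5))

  # uniform per-locality scaling leaves percentages unchanged
  r3 <- occurrence_stats(counts * 7L, "focal")
  expect_equal(r3[c("pct_present", "mean_rel_abundance", "ci_low", "ci_high")],
               res[c("pct_present", "mean_rel_abundance", "ci_low", "ci_high")])

  c4 <- rbind(counts, c(0, 0))
  colnames(c4) <- c("focal", "other")
  expect_warning(r4 <- occurrence_stats(c4, "focal"), "zero total")
  expect_identical(r4$n_localities, 4L)
  expect_error(occurrence_stats(counts, "absent_sp"), "not in count table")
})

test_that("boundary temperatures bracket the front and flag sympatry", {
  st <- data.frame(sst = c(5, 15), n_type1 = c(0L, 3L), n_type2 = c(4L, 0L))
  b <- boundary_temperature(st)
  expect_equal(c(b$warm_edge_type2, b$cold_edge_type1), c(5, 15))
  expect_false(b$overlap)

  st2 <- rbind(st, data.frame(sst = 20, n_type1 = 0L, n_type2 = 2L))
  expect_true(boundary_temperature(st2)$overlap)

  st3 <- data.frame(sst = 10, n_type1 = 1L, n_type2 = 0L)
  expect_error(boundary_temperature(st3), "Type II")
})
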