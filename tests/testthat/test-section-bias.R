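test_that("sampling experiment holds its type-I error under the null", {
  set.seed(1)
  pool <- rnorm(2000, 50, 10)
  res <- sampling_experiment(pool, pool, n = 50, n_reps = 600, seed = 3)
  # null: proportion significant within a wide binomial band around alpha
  ci <- qbinom(c(0.005, 0.995), 600, 0.05) / 600
  expect_gte(res$proportion_significant, ci[1])
  expect_lte(res$proportion_significant, ci[2])
  expect_true(all(res$mean_range[, 1] <= res$mean_range[, 2]))

  one <- sampling_experiment(pool, pool, n = 10, n_reps = 1, seed = 5)
  expect_true(one$proportion_significant %in% c(0, 1))

  expect_error(sampling_experiment(data.frame(radius_um = 1:10,
                                              excluded = FALSE),
                                   1:10, n = 5, metric = "nope"),
               "not a column")
})

test_that("power against a true difference matches the analytic oracle", {
  set.seed(2)
  a <- rnorm(5000, 40, 10)
  b <- rnorm(5000, 50, 10)
  res <- sampling_experiment(a, b, n = 100, n_reps = 400, seed = 7)
  # closed-form two-sample power at delta = 10, sd = 10, n = 100:
  oracle <- power.t.test(n = 100, delta = 10, sd = 10,
                         sig.level = 0.05)$power  # ~ 1 anyway
  expect_equal(res$proportion_significant, oracle, tolerance = 0.02)
  # a regime where power is intermediate
  res2 <- sampling_experiment(a, b, n = 10, n_reps = 400, seed = 8)
  oracle2 <- power.t.test(n = 10, delta = 10, sd = 10,
                          sig.level = 0.05)$power
  # bootstrap resampling inflates the variance slightly; allow MC + design slack
  expect_equal(res2$proportion_significant, oracle2, tolerance = 0.15)
})

test_that("power rises and mean ranges shrink with sample size", {
  set.seed(3)
  a <- rnorm(3000, 45, 10)
  b <- rnorm(3000, 49.5, 10)   # a true ~10% difference in means
  ns <- c(10, 30, 50, 100, 150)
  res <- lapply(ns, function(n)
    sampling_experiment(a, b, n = n, n_reps = 150, seed = 100 + n))
  prop <- vapply(res, function(r) r$proportion_significant, numeric(1))
  width <- vapply(res, function(r) diff(r$mean_range["popA", ]), numeric(1))
  # allow small Monte-Carlo wiggle on monotonicity
  expect_true(all(diff(prop) >= -0.05))
  expect_gt(prop[length(prop)], prop[1])
  expect_true(all(diff(width) <= 1))
  expect_lt(width[length(width)], width[1])
})

test_that("virtual sections reproduce the every-third-of-1mm geometry", {
  # 1 mm volume at 5 um z-step, 40 um sections, every third -> 8 sections,
  # count scale factor 3
  v <- channel_volume(array(runif(6 * 6 * 200), c(6, 6, 200)), c(5, 5, 5))
  vs <- virtual_sections(v, 40, spacing = "every_third", n_sections = 8)
  expect_length(vs$sections, 8)
  expect_equal(vs$count_scale_factor, 25 / 8)  # ~3, the every-third scaling
  expect_identical(vs$z_ranges[, 1], seq(1L, 169L, by = 24L))

  # thickness = full depth: one section equal to the whole-volume MIP
  whole <- virtual_sections(v, 1000, spacing = "all")
  expect_length(whole$sections, 1)
  expect_identical(whole$sections[[1]], apply(v$intensities, c(1, 2), max))
  expect_equal(whole$count_scale_factor, 1)

  # each slab equals the direct max over its z-range
  vs2 <- virtual_sections(v, 75, spacing = "all")
  for (k in seq_along(vs2$sections))
    expect_identical(vs2$sections[[k]],
                     apply(v$intensities[, , vs2$z_ranges[k, 1]:
                                           vs2$z_ranges[k, 2], drop = FALSE],
                           c(1, 2), max))

  expect_error(virtual_sections(v, 2000), "too thin")
})

test_that("radius-pair classification is an exhaustive partition", {
  classes <- c("excluded_small", "false_negative", "false_positive",
               "within_tolerance", "underestimate_gt_10pct",
               "overestimate_gt_10pct")
  # boundary cases, threshold 10 um and tolerance exactly 10%
  expect_identical(classify_radius_pair(8, 15), "false_negative")
  expect_identical(classify_radius_pair(48, 50), "within_tolerance")
  expect_identical(classify_radius_pair(9.99, 9.99), "excluded_small")
  expect_identical(classify_radius_pair(10, 9.99), "false_positive")
  expect_identical(classify_radius_pair(45, 50), "within_tolerance") # = 10%
  expect_identical(classify_radius_pair(44.9, 50), "underestimate_gt_10pct")
  expect_identical(classify_radius_pair(56, 50), "overestimate_gt_10pct")
  expect_identical(classify_radius_pair(10, 10), "within_tolerance")
  expect_equal(underestimation_factor(40, 50), 0.2)
  expect_equal(underestimation_factor(50, 50), 0)

  set.seed(11)
  r2 <- runif(10000, 0, 120); r3 <- runif(10000, 0.1, 120)
  cl <- classify_radius_pair(r2, r3)
  expect_true(all(cl %in% classes))        # exactly one class per pair
  expect_false(any(cl == ""))
})

test_that("thin-slab Monte Carlo attains the pi/4 chord limit", {
  mc <- simulate_section_bias(0, radii_um = 50, n_draws = 1e5, seed = 9)
  expect_equal(mc$mean_ratio, pi / 4, tolerance = 0.01)
  expect_equal(mc$mean_underestimation, 1 - pi / 4, tolerance = 0.04)

  sweep <- simulate_section_bias(c(5, 10, 20, 40, 80, 110, 1000),
                                 radii_um = runif(500, 15, 55),
                                 n_draws = 4e4, seed = 10)
  expect_true(all(diff(sweep$mean_underestimation) <= 0.005))
  expect_lt(sweep$mean_underestimation[7], 0.05)  # -> 0 near full depth
})

test_that("the image-based 2D/3D comparison shows thin-section bias", {
  out <- separated_spheres(n_islets = 12, seed = 19, dims = c(200, 200, 120),
                           r_min = 20, r_max = 50)
  cmp <- suppressMessages(
    compare_2d_3d(out$islet, thicknesses = c(10, 40, 110), spacing = "all"))
  expect_true(all(cmp$records$classification %in%
                    c("excluded_small", "false_negative", "false_positive",
                      "within_tolerance", "underestimate_gt_10pct",
                      "overestimate_gt_10pct")))
  expect_identical(
    cmp$records$underestimation_factor,
    (cmp$records$r3d_um - cmp$records$r2d_um) / cmp$records$r3d_um)
  s <- cmp$summary
  # thin sections underestimate more, and more often, than thick ones
  expect_gt(s$mean_underestimation[s$thickness_um == 10],
            s$mean_underestimation[s$thickness_um == 110])
  expect_gt(s$mean_underestimation[s$thickness_um == 10], 0.05)
  expect_gt(s$within_tolerance[s$thickness_um == 110],
            s$within_tolerance[s$thickness_um == 10])
})

test_that("top-k comparison averages what exists and sees the 2D shortfall", {
  # fewer than k islets: average of all of them
  res <- top_k_comparison(list(c(5, 7, 9, 11, 13)), c(20, 30), k = 20)
  expect_equal(res$section_means[[1]], mean(c(5, 7, 9, 11, 13)))
  expect_equal(res$mean_3d, 25)

  # identical 2D and 3D radii: mean difference 0, p near 1
  same <- c(10, 20, 30, 40)
  res2 <- top_k_comparison(list(same), same, k = 4)
  expect_equal(res2$mean_2d, res2$mean_3d)
  expect_gt(res2$p_value, 0.9)

  # chord-oracle sign check: thin-sliced sphere radii fall below 3D radii
  set.seed(12)
  r3 <- runif(400, 20, 60)
  r2 <- r3 * sqrt(1 - runif(400)^2)   # infinitesimal-plane chord draw
  sections <- split(r2, rep(1:8, each = 50))
  res3 <- top_k_comparison(sections, r3, k = 20)
  expect_lt(res3$mean_2d, res3$mean_3d)
  expect_lt(res3$p_value, 0.05)
})

test_that("two-sample test wrappers match their base distributions", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  mw <- stat_tests(x, y, "mannwhitney")
  expect_equal(mw$statistic, 0)   # complete separation: U = 0 for sample x

  ks <- stat_tests(c(1, 2, 3, 4), c(1, 2, 3, 4), "ks")
  expect_equal(ks$statistic, 0)

  expect_message(zt <- stat_tests(c(2, 2, 2), c(2, 2, 2), "t"),
                 "zero-variance")
  expect_equal(zt$p_value, 1)
  expect_equal(suppressMessages(stat_tests(c(2, 2, 2), c(3, 3, 3),
                                           "t"))$p_value, 0)

  # t wrapper agrees with stats::t.test
  set.seed(13)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  expect_equal(stat_tests(a, b, "t")$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(stat_tests(a, b, "t", var_equal = FALSE)$p_value,
               t.test(a, b)$p.value)

  # under the null, p-values are uniform (KS check on simulated p-values)
  set.seed(14)
  ps <- replicate(2000, stat_tests(rnorm(12), rnorm(12), "t")$p_value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})
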