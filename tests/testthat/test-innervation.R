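test_that("neighborhood mask is the hull offset by a Euclidean distance", {
  hull <- make_disk(40, 20, 20, 10) > 0
  expect_identical(neighborhood_mask(hull, 0L), hull)

  # offset 2: brute-force distance-transform oracle
  nb <- neighborhood_mask(hull, 2L)
  pts <- which(hull, arr.ind = TRUE)
  oracle <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40)
    oracle[i, j] <- min((pts[, 1] - i)^2 + (pts[, 2] - j)^2) <= 4
  expect_identical(nb, oracle)
  # and it is close to a disk of radius 12
  expect_equal(sum(nb), sum(make_disk(40, 20, 20, 12)), tolerance = 0.06)

  # hull touching the border: clipped, no wraparound
  edge <- make_disk(30, 2, 15, 6) > 0
  nbe <- neighborhood_mask(edge, 3L)
  expect_identical(dim(nbe), c(30L, 30L))
  expect_false(any(nbe[28:30, ]))  # nothing wraps to the far side
})

scored_fixture <- function(seed = 23, innervation = c(0.2, 0.8),
                           noise = 0) {
  out <- generate_islet_volume(synth_config(
    volume_shape = c(200, 200, 24), n_islets = 5,
    radius_distribution = list(name = "uniform", min_um = 20, max_um = 45),
    min_center_separation = 40, innervation_range = innervation,
    n_filaments = 0, background_noise_sd = noise, z_contain = FALSE,
    xy_separation = TRUE, seed = seed))
  pop <- detect_islets(out$islet)
  list(out = out, pop = pop)
}

test_that("interaction score is the positive count over the islet area", {
  fx <- scored_fixture()
  pop <- score_population(fx$pop, fx$out$nerve)
  expect_true(all(pop$interaction_score >= 0))
  expect_identical(pop$interaction_score,
                   pop$neighborhood_positive_px / pop$area_px)
  expect_identical(pop$nerve_positive_fraction,
                   pop$neighborhood_positive_px / pop$neighborhood_px)

  # pixel-counting oracle: recompute each record's count directly from the
  # positive mask and the neighborhood mask
  params <- neighborhood_params()
  stack <- project_sections(fx$out$nerve, 150)
  masks <- attr(pop, "masks")
  for (i in seq_len(nrow(pop))) {
    s <- pop$section_index[i]
    positives <- nerve_positive_mask(stack$sections[[s]], params)
    full <- matrix(FALSE, 200, 200)
    off <- masks[[i]]$offset
    h <- masks[[i]]$hull
    full[off[1] + seq_len(nrow(h)) - 1L, off[2] + seq_len(ncol(h)) - 1L] <- h
    nb <- neighborhood_mask(full, params$offset_px)
    expect_identical(pop$neighborhood_positive_px[i], sum(positives & nb))
  }

  # null nerve channel: score identically zero
  null_nerve <- channel_volume(array(0, c(200, 200, 24)), c(5, 5, 5), "nerve")
  pop0 <- score_population(fx$pop, null_nerve)
  expect_true(all(pop0$interaction_score == 0))
  expect_true(all(pop0$neighborhood_positive_px == 0))
})

test_that("score follows the defining formula and is monotone in signal", {
  # direct formula: 100 px islet area, 25 surviving positive px -> 0.25
  rec <- islet_population(
    within(voxislet:::islet_record_row(1L, "s", 1L, c(1L, 4L)), {
      area_px <- 100L; neighborhood_positive_px <- 25L
      interaction_score <- neighborhood_positive_px / area_px
    }), pixel_size = 5)
  expect_equal(rec$interaction_score, 0.25)

  # adding positive nerve pixels inside the neighborhood never lowers the
  # score: compare a weak and a strong innervation draw of the same islets
  weak <- scored_fixture(seed = 29, innervation = c(0.15, 0.15))
  pop_w <- score_population(weak$pop, weak$out$nerve)
  strong_cfg <- synth_config(
    volume_shape = c(200, 200, 24), n_islets = 5,
    radius_distribution = list(name = "uniform", min_um = 20, max_um = 45),
    min_center_separation = 40, innervation_range = c(0.85, 0.85),
    n_filaments = 0, background_noise_sd = 0, z_contain = FALSE,
    xy_separation = TRUE, seed = 29)
  strong <- generate_islet_volume(strong_cfg)
  pop_s <- score_population(weak$pop, strong$nerve)
  expect_true(all(pop_s$interaction_score >= pop_w$interaction_score))
})

test_that("scores are invariant to joint translation of both channels", {
  fx <- scored_fixture(seed = 41)
  sh <- c(7L, 4L)
  # embed both channels at two offsets deep inside a zero canvas: local-mean
  # windows and refinement crops then see identical surroundings
  viA <- embed_volume(fx$out$islet, 280L, c(30L, 30L))
  vnA <- embed_volume(fx$out$nerve, 280L, c(30L, 30L))
  viB <- embed_volume(fx$out$islet, 280L, c(30L, 30L) + sh)
  vnB <- embed_volume(fx$out$nerve, 280L, c(30L, 30L) + sh)
  popA <- score_population(detect_islets(viA), vnA)
  popB <- score_population(detect_islets(viB), vnB)
  o1 <- order(popA$cx_um, popA$cy_um); o2 <- order(popB$cx_um, popB$cy_um)
  expect_equal(popB$interaction_score[o2], popA$interaction_score[o1],
               tolerance = 1e-12)
  expect_equal(popB$entropy_score[o2], popA$entropy_score[o1],
               tolerance = 1e-12)
})

test_that("3-SD exclusion follows the rule and its degenerate cases", {
  # all records identical: sd 0, strict '>' excludes none
  same <- gaussian_population(10, seed = 1, f_sd = 0, e_sd = 0)
  ex <- exclude_artifacts(same)
  expect_identical(sum(ex$excluded), 0L)

  # reference mean 0.10 sd 0.02 -> a record at 0.20 exceeds 0.16
  ref <- gaussian_population(5000, seed = 2)
  one <- gaussian_population(1, seed = 3)
  one$nerve_positive_fraction <- 0.20
  one$entropy_score <- 3
  ex1 <- exclude_artifacts(one, reference = ref)
  expect_true(ex1$excluded[1])
  expect_match(ex1$exclusion_reason[1], "positive-fraction")

  expect_error(exclude_artifacts(gaussian_population(1, seed = 4)),
               "at least two")

  # Monte-Carlo: Gaussian scores on both criteria are excluded at about
  # 2 * pnorm(-3) per criterion
  mc <- gaussian_population(2e5, seed = 5)
  exm <- exclude_artifacts(mc)
  rate <- mean(exm$excluded)
  # one-sided 3-sd exceedance per criterion, two near-independent criteria
  expected <- 2 * pnorm(-3)
  expect_equal(rate, expected, tolerance = 0.15)
})

test_that("exclusion thresholds ignore record order and self-duplication", {
  pop <- gaussian_population(500, seed = 6)
  t1 <- attr(exclude_artifacts(pop), "exclusion_thresholds")
  shuffled <- islet_population(pop[sample(nrow(pop)), ], pixel_size = 5)
  shuffled$islet_id <- seq_len(nrow(shuffled))
  t2 <- attr(exclude_artifacts(shuffled), "exclusion_thresholds")
  expect_equal(t1, t2)
  doubled_df <- rbind(as.data.frame(pop), as.data.frame(pop))
  doubled_df$islet_id <- seq_len(nrow(doubled_df))
  doubled <- islet_population(doubled_df, pixel_size = 5)
  t3 <- attr(exclude_artifacts(doubled), "exclusion_thresholds")
  expect_equal(t1, t3)
})
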