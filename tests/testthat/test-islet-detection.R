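test_that("section segmentation enforces the 5-pixel minimum region size", {
  expect_length(suppressMessages(segment_section(matrix(0, 30, 30))), 0)

  # one 4-px and one 9-px bright square: only the 9-px region survives.
  # erosion with the 3x3 element removes both blocks entirely, so the
  # cleanup pass is disabled here to test the size rule in isolation
  img <- matrix(0, 40, 40)
  img[5:6, 5:6] <- 1          # 4 px
  img[20:22, 20:22] <- 1      # 9 px
  cfg <- detect_config(brush_size = 1L)  # 1x1 brush: cleanup is the identity
  cands <- segment_section(img, min_region_px = 5, config = cfg)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$area_px, 9L)
  expect_equal(cands[[1]]$centroid, c(21, 21), ignore_attr = TRUE)
})

test_that("ten noiseless disks are found with centroids within one pixel", {
  img <- matrix(0, 120, 120)
  centers <- expand.grid(x = c(20, 45, 70, 95, 108), y = c(30, 90))[1:10, ]
  for (i in 1:10)
    img <- pmax(img, make_disk(120, centers$x[i], centers$y[i], 4))
  cands <- segment_section(img)
  expect_length(cands, 10)
  got <- t(vapply(cands, function(c) c$centroid, numeric(2)))
  ord <- order(got[, 2], got[, 1])
  want <- as.matrix(centers[order(centers$y, centers$x), ])
  expect_true(all(abs(got[ord, ] - want) <= 1))
})

test_that("refinement measures a solid disk consistently with a circle", {
  arr <- array(0, c(60, 60, 4))
  for (k in 1:4) arr[, , k] <- make_disk(60, 30, 30, 10)
  v <- channel_volume(arr, c(5, 5, 5))
  cand <- segment_section(arr[, , 1])[[1]]
  rec <- refine_islet(v, cand, c(1, 4))$record
  expect_false(rec$excluded)
  expect_equal(rec$hull_area_px, pi * 100, tolerance = 0.08)
  expect_equal(rec$ellipse_major_um / 5, 10, tolerance = 0.1)
  expect_equal(rec$ellipse_minor_um / 5, 10, tolerance = 0.1)
  expect_equal(rec$radius_um, sqrt(rec$hull_area_px / pi) * 5)
  expect_equal(c(rec$cx_um, rec$cy_um), c(29.5 * 5, 29.5 * 5),
               tolerance = 0.02)

  # candidate at the volume edge: crop clipped to bounds, no error
  arr2 <- array(0, c(40, 40, 2))
  arr2[, , 1] <- make_disk(40, 3, 3, 5)
  arr2[, , 2] <- arr2[, , 1]
  v2 <- channel_volume(arr2, c(5, 5, 5))
  cand2 <- segment_section(arr2[, , 1])[[1]]
  expect_no_error(rec2 <- refine_islet(v2, cand2, c(1, 2))$record)
  expect_false(rec2$excluded)
})

test_that("refinement keeps the component of the original candidate only", {
  # two disks whose union is a single bright blob at section scale but
  # separate components after refinement
  img <- pmax(make_disk(80, 25, 40, 8), make_disk(80, 55, 40, 8))
  arr <- array(rep(img, 2), c(80, 80, 2))
  v <- channel_volume(arr, c(5, 5, 5))
  cands <- segment_section(img)
  expect_length(cands, 2)
  for (cand in cands) {
    out <- refine_islet(v, cand, c(1, 2))
    # oracle: connected-component labeling on the crop must give the same
    # pixel set as the refined mask restricted to the candidate's component
    expect_equal(out$record$area_px, cand$area_px, tolerance = 0.15)
    ctr_local <- cand$centroid - out$masks$offset + 1L
    expect_true(out$masks$region[ctr_local[1], ctr_local[2]])
    # the other disk is 30 px away: the refined region must not reach it
    pts <- which(out$masks$region, arr.ind = TRUE)
    span <- diff(range(pts[, 1]))
    expect_lt(span, 20)
  }
})

test_that("radius estimation matches the closed form and a shoelace oracle", {
  expect_equal(estimate_radius(pi * 100, 5), 50)
  expect_equal(estimate_radius(1, 1), 1 / sqrt(pi))
  expect_error(estimate_radius(0, 5), "positive")
  # random convex polygons: shoelace area -> radius formula
  set.seed(77)
  for (i in 1:5) {
    ang <- sort(runif(12, 0, 2 * pi))
    r <- runif(1, 5, 40)
    x <- r * cos(ang); y <- r * sin(ang)
    a <- abs(sum(x * y[c(2:12, 1)] - x[c(2:12, 1)] * y)) / 2
    expect_equal(estimate_radius(a, 3), sqrt(a / pi) * 3)
  }
})

test_that("detection recovers counts and radii on well-separated spheres", {
  out <- separated_spheres(n_islets = 8, seed = 13)
  pop <- detect_islets(out$islet)
  expect_s3_class(pop, "islet_population")
  expect_identical(nrow(pop), 8L)               # count recovery, exact
  m <- match_to_truth(pop, out$truth)
  expect_true(all(abs(m$detected_um - m$true_um) / m$true_um <= 0.10))
  expect_true(all(pop$area_px >= 5))            # retained-region minimum
  expect_true(all(pop$hull_area_px >= pop$area_px))  # hull dominance
  expect_false(any(duplicated(pop$islet_id)))

  # determinism: same input twice gives identical populations
  pop2 <- detect_islets(out$islet)
  expect_identical(as.data.frame(pop), as.data.frame(pop2))

  # empty volume -> empty population
  empty <- channel_volume(array(0, c(30, 30, 6)), c(5, 5, 5))
  expect_identical(nrow(suppressMessages(detect_islets(empty))), 0L)
})

test_that("whole-voxel translation shifts centroids and preserves radii", {
  out <- separated_spheres(n_islets = 4, seed = 17, dims = c(160, 160, 20),
                           r_min = 15, r_max = 40)
  # embed the same content at two offsets in a large zero canvas so every
  # refinement crop stays clear of the image border
  shift <- c(6L, 9L)
  vA <- embed_volume(out$islet, 240L, c(25L, 25L))
  vB <- embed_volume(out$islet, 240L, c(25L, 25L) + shift)
  popA <- detect_islets(vA)
  popB <- detect_islets(vB)
  expect_identical(nrow(popA), nrow(popB))
  oA <- order(popA$cx_um, popA$cy_um)
  oB <- order(popB$cx_um, popB$cy_um)
  expect_equal(popB$cx_um[oB] - popA$cx_um[oA], rep(shift[1] * 5, nrow(popA)),
               tolerance = 1e-8)
  expect_equal(popB$cy_um[oB] - popA$cy_um[oA], rep(shift[2] * 5, nrow(popA)),
               tolerance = 1e-8)
  # interior translation changes no radius by more than one pixel-equivalent
  expect_true(all(abs(popB$radius_um[oB] - popA$radius_um[oA]) <= 5))
})

test_that("adjacent-section duplicates can be merged post hoc", {
  # one sphere spanning the boundary between two 150 um sections
  arr <- array(0, c(60, 60, 60))
  xs <- (1:60 - 0.5) * 5
  d2 <- outer(outer((xs - 150)^2, (xs - 150)^2, `+`), (xs - 150)^2, `+`)
  arr[d2 <= 60^2] <- 1
  v <- channel_volume(arr, c(5, 5, 5))
  pop <- detect_islets(v)   # 300 um deep: two 150 um sections, islet in both
  expect_identical(nrow(pop), 2L)
  dd <- deduplicate_islets(pop)
  expect_identical(sum(!dd$excluded), 1L)
  expect_identical(dd$exclusion_reason[dd$excluded],
                   "duplicate-adjacent-section")
})
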