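# Tract binarization, partition, dilation, shells, nearby-WMH rules.

test_that("binarize_tract uses a strict threshold", {
  g <- volume_grid(c(5, 1, 1) * c(1, 5, 5))
  a <- array(0, c(5, 5, 5))
  a[1:5] <- c(0, 0.005, 0.01, 0.011, 0.9)
  m <- binarize_tract(scalar_volume(a, g), 0.01)
  expect_equal(mask_count(m), 2)          # only 0.011 and 0.9 pass
  expect_equal(mask_count(binarize_tract(scalar_volume(array(0, c(5, 5, 5)),
                                                       g))), 0)
  b <- array(0, c(5, 5, 5)); b[1:3] <- 1
  expect_identical(binarize_tract(scalar_volume(b, g), 0.5)$data, b == 1)
  expect_error(binarize_tract(scalar_volume(a, g), 1.5), "threshold")
})

test_that("partition_tract computes the WMH/NAWM split and %WMHvol", {
  shape <- c(10, 10, 10)
  g <- volume_grid(shape)
  tract <- array(FALSE, shape); tract[1:100] <- TRUE
  wmh <- array(FALSE, shape); wmh[1:10] <- TRUE
  nawm <- array(FALSE, shape); nawm[11:100] <- TRUE
  p <- partition_tract(mask_volume(tract, g), mask_volume(wmh, g),
                       mask_volume(nawm, g))
  expect_equal(p$pct_wmh_vol, 10)
  expect_equal(mask_count(p$tract_wmh), 10)
  expect_equal(mask_count(p$tract_nawm), 90)
  # WMH disjoint from tract -> 0%
  wmh2 <- array(FALSE, shape); wmh2[200:205] <- TRUE
  p2 <- partition_tract(mask_volume(tract, g), mask_volume(wmh2, g),
                        mask_volume(nawm, g))
  expect_equal(mask_count(p2$tract_wmh), 0)
  expect_equal(p2$pct_wmh_vol, 0)
  # voxels in neither mask belong to neither part
  nawm3 <- array(FALSE, shape); nawm3[11:50] <- TRUE
  p3 <- partition_tract(mask_volume(tract, g), mask_volume(wmh, g),
                        mask_volume(nawm3, g))
  expect_equal(mask_count(p3$tract_wmh) + mask_count(p3$tract_nawm), 50)
  expect_lt(mask_count(p3$tract_wmh) + mask_count(p3$tract_nawm),
            mask_count(p3$tract_mask))
  # tract meeting neither mask -> pct is missing
  empty <- mask_volume(array(FALSE, shape), g)
  p4 <- partition_tract(mask_volume(tract, g), empty, empty)
  expect_true(is.na(p4$pct_wmh_vol))
})

test_that("dilate_step matches the structuring-element definitions", {
  shape <- c(9, 9, 9)
  g <- volume_grid(shape)
  a <- array(FALSE, shape); a[5, 5, 5] <- TRUE
  m <- mask_volume(a, g)
  expect_equal(mask_count(dilate_step(m, 26)), 27)
  expect_equal(mask_count(dilate_step(m, 6)), 7)
  expect_equal(mask_count(dilate_step(m, 18)), 19)
  expect_true(all(dilate_step(m, 6)$data[a]))   # output contains input
  g_aniso <- volume_grid(shape, c(2, 2, 4))
  m2 <- mask_volume(a, g_aniso)
  expect_error(dilate_step(m2), "anisotropic")
  expect_warning(d2 <- dilate_step(m2, allow_anisotropic = TRUE),
                 "anisotropic")
  expect_equal(mask_count(d2), 27)
})

test_that("k dilations equal Chebyshev distance <= k (brute-force oracle)", {
  set.seed(101)
  for (rep in 1:8) {
    shape <- sample(12:21, 3, replace = TRUE)
    a <- random_blob(shape, n_seeds = 2, max_grow = 1)
    oracle <- brute_chebyshev(a)
    cur <- a
    for (k in 1:4) {
      cur <- penumbra:::dilate_binary(cur, 26)
      expect_identical(cur, oracle <= k)
    }
  }
})

test_that("single-voxel seed yields the closed-form shell counts", {
  shape <- c(15, 15, 15)
  lesion <- array(FALSE, shape); lesion[8, 8, 8] <- TRUE
  part <- world_around(lesion)
  ss <- build_tract_wmh_shells(part)
  counts <- vapply(ss$shells, function(s) mask_count(s$mask), numeric(1))
  k <- 1:5
  expect_equal(counts, (2 * k + 1)^3 - (2 * k - 1)^3)  # 26, 98, 218, 386, 602
  expect_equal(vapply(ss$shells, function(s) s$distance_mm, numeric(1)),
               c(2, 4, 6, 8, 10))
})

test_that("shell sets satisfy disjointness, containment and the distance-band property", {
  set.seed(202)
  for (rep in 1:6) {
    shape <- sample(16:24, 3, replace = TRUE)
    lesion <- random_blob(shape, n_seeds = 2, max_grow = 1)
    part <- world_around(lesion)
    ss <- build_tract_wmh_shells(part)
    oracle <- brute_chebyshev(lesion)
    masks <- lapply(ss$shells, function(s) s$mask$data)
    # pairwise disjoint, inside tract-NAWM, never touching the seed
    for (i in seq_along(masks)) {
      expect_false(any(masks[[i]] & lesion))
      expect_true(all(masks[[i]] <= part$tract_nawm$data))
      for (j in seq_along(masks)) if (i < j)
        expect_false(any(masks[[i]] & masks[[j]]))
    }
    # union of shells 1..k = Chebyshev band (0, k]
    u <- array(FALSE, shape)
    for (k in seq_along(masks)) {
      u <- u | masks[[k]]
      expect_identical(u, oracle > 0 & oracle <= k)
    }
  }
})

test_that("empty tract-NAWM or empty seed give empty, flagged shells", {
  shape <- c(12, 12, 12)
  g <- volume_grid(shape)
  lesion <- array(FALSE, shape); lesion[6, 6, 6] <- TRUE
  tract <- mask_volume(array(TRUE, shape), g)
  nawm_empty <- mask_volume(array(FALSE, shape), g)
  p <- partition_tract(tract, mask_volume(lesion, g), nawm_empty)
  ss <- build_tract_wmh_shells(p)
  expect_true(all(vapply(ss$shells,
                         function(s) mask_count(s$mask) == 0, logical(1))))
  p2 <- world_around(array(FALSE, shape))
  ss2 <- build_tract_wmh_shells(p2)
  expect_true(ss2$no_lesion)
  expect_true(all(vapply(ss2$shells,
                         function(s) mask_count(s$mask) == 0, logical(1))))
})

test_that("find_nearby_wmh classifies lesions by distance and intersection", {
  shape <- c(20, 20, 20)
  g <- volume_grid(shape)
  tract <- array(FALSE, shape); tract[3:8, 3:18, 3:18] <- TRUE
  nawm <- array(TRUE, shape)
  make_world <- function(wmh_arr) {
    wmh <- mask_volume(wmh_arr, g)
    part <- partition_tract(mask_volume(tract, g), wmh,
                            mask_volume(nawm & !wmh_arr, g))
    find_nearby_wmh(wmh, part)
  }
  # shares a voxel with the tract -> intersecting, not nearby
  w1 <- array(FALSE, shape); w1[8:10, 10, 10] <- TRUE
  expect_length(make_world(w1), 0)
  # Chebyshev distance 3 (6 mm) -> nearby  (tract ends at x=8)
  w2 <- array(FALSE, shape); w2[11, 10, 10] <- TRUE
  expect_equal(brute_chebyshev(tract)[11, 10, 10], 3)
  expect_length(make_world(w2), 1)
  # Chebyshev distance 6 (12 mm) -> too far
  w3 <- array(FALSE, shape); w3[14, 10, 10] <- TRUE
  expect_equal(brute_chebyshev(tract)[14, 10, 10], 6)
  expect_length(make_world(w3), 0)
  # two eligible components come back separately, in centroid order
  w4 <- array(FALSE, shape); w4[11, 5, 5] <- TRUE; w4[10, 15, 15] <- TRUE
  comps <- make_world(w4)
  expect_length(comps, 2)
  expect_equal(which(comps[[1]]$data, arr.ind = TRUE)[1, ],
               c(dim1 = 10, dim2 = 15, dim3 = 15))
})

test_that("nearby shells honour the tract-WMH contour exclusion", {
  shape <- c(15, 15, 15)
  g <- volume_grid(shape)
  # tract plane of NAWM 1 voxel wide at x=5; nearby component at gap 2
  tract <- array(FALSE, shape); tract[5, , ] <- TRUE
  comp <- array(FALSE, shape); comp[7, 8, 8] <- TRUE  # gap 2 voxels
  wmh <- mask_volume(comp, g)
  part <- partition_tract(mask_volume(tract, g), wmh,
                          mask_volume(!comp, g))
  ns <- build_nearby_shells(mask_volume(comp, g), part, NULL)
  counts <- vapply(ns$shells, function(s) mask_count(s$mask), numeric(1))
  expect_equal(counts[1], 0)              # 2 mm shell cannot reach the plane
  expect_gt(counts[2], 0)                 # first nonempty shell at 4 mm
  # a 2 mm shell wholly inside the tract-WMH contour union is emptied
  excl <- mask_volume(penumbra:::dilate_binary(comp) & !comp &
                        array(TRUE, shape), g)
  tract_all <- world_around(comp)
  ns2 <- build_nearby_shells(mask_volume(comp, g), tract_all, excl)
  expect_equal(mask_count(ns2$shells[[1]]$mask), 0)
  # with an empty exclusion set, shells equal the plain restricted shells
  ns3 <- build_nearby_shells(mask_volume(comp, g), tract_all, NULL)
  ss <- build_tract_wmh_shells(tract_all)
  for (k in 1:5)
    expect_identical(ns3$shells[[k]]$mask$data, ss$shells[[k]]$mask$data)
})

test_that("geometry is deterministic including component ordering", {
  set.seed(77)
  shape <- c(18, 18, 18)
  lesion <- random_blob(shape, n_seeds = 3, max_grow = 1)
  part <- world_around(lesion)
  s1 <- build_tract_wmh_shells(part)
  s2 <- build_tract_wmh_shells(part)
  for (k in 1:5)
    expect_identical(s1$shells[[k]]$mask$data, s2$shells[[k]]$mask$data)
  labs1 <- penumbra:::label_components(lesion)
  labs2 <- penumbra:::label_components(lesion)
  expect_identical(labs1, labs2)
})
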