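test_that("haversine distance is a metric with the fixed Earth radius", {
  expect_equal(haversine_ft(35, -80, 35, -80), 0)
  # one degree of latitude along a meridian is R * pi/180
  expect_equal(haversine_ft(0, 0, 1, 0), 20902231 * pi / 180, tolerance = 1e-10)
  set.seed(2)
  p <- matrix(c(runif(20, -90, 90), runif(20, -180, 180)), ncol = 4)
  d12 <- haversine_ft(p[, 1], p[, 3], p[, 2], p[, 4])
  d21 <- haversine_ft(p[, 2], p[, 4], p[, 1], p[, 3])
  expect_equal(d12, d21)
  expect_true(all(d12 >= 0))
  expect_error(haversine_ft(91, 0, 0, 0), "latitude")
  expect_error(haversine_ft(0, 181, 0, 0), "longitude")
})

test_that("haversine agrees with an independent geodesic implementation", {
  skip_if_not_installed("geosphere")
  set.seed(3)
  n <- 40
  a <- cbind(runif(n, -180, 180), runif(n, -85, 85))
  b <- cbind(runif(n, -180, 180), runif(n, -85, 85))
  ref_m <- geosphere::distHaversine(a, b, r = 6378137)
  mine <- haversine_ft(a[, 2], a[, 1], b[, 2], b[, 1])
  expect_equal(mine, ref_m * 20902231 / 6378137, tolerance = 1e-9)
})

test_that("a coincident control is the nearest neighbour at distance zero", {
  cases <- data.frame(crash_id = "A1", latitude = 40, longitude = -75)
  pool <- data.frame(crash_id = c("B1", "B2", "B3"),
                     latitude = c(41, 40, 39), longitude = c(-75, -75, -74))
  m <- knn_controls(cases, pool, k = 1)
  expect_equal(m$control_id, "B2")
  expect_equal(m$distance_ft, 0)
})

test_that("matching agrees with the exhaustive all-pairs oracle", {
  cases <- rand_points(20, seed = 4, prefix = "A")
  pool <- rand_points(60, seed = 5, prefix = "B")
  for (k in c(1, 3)) {
    m <- knn_controls(cases, pool, k = k)
    o <- knn_oracle(cases, pool, k)
    expect_equal(m$control_id, o$control_id)
    expect_equal(m$distance_ft, o$distance_ft)
    # distances nondecreasing in rank, distinct controls per case
    for (cid in unique(m$case_id)) {
      sub <- m[m$case_id == cid, ]
      expect_true(!is.unsorted(sub$distance_ft))
      expect_false(anyDuplicated(sub$control_id) > 0)
    }
  }
})

test_that("k equal to the pool size returns the whole pool in distance order", {
  cases <- rand_points(3, seed = 6, prefix = "A")
  pool <- rand_points(5, seed = 7, prefix = "B")
  m <- knn_controls(cases, pool, k = 5)
  expect_equal(sort(unique(m$control_id)), sort(pool$crash_id))
  expect_error(knn_controls(cases, pool, k = 6), "smaller than k")
})

test_that("ties break deterministically by identifier order", {
  cases <- data.frame(crash_id = "A1", latitude = 0, longitude = 0)
  pool <- data.frame(crash_id = c("B2", "B1", "B3"),
                     latitude = c(1, 1, -1), longitude = 0)
  m1 <- knn_controls(cases, pool, k = 2)
  m2 <- knn_controls(cases, pool[c(2, 1, 3), ], k = 2)
  expect_equal(m1$control_id, c("B1", "B2"))
  expect_identical(m1$control_id, m2$control_id)
})

test_that("maximum k-th distance summarizes matches and grows with k", {
  m <- data.frame(case_id = "A1", rank = 1:3, control_id = paste0("B", 1:3),
                  distance_ft = c(10, 20, 30))
  expect_equal(max_kth_distance(m, 3), 30)
  expect_error(max_kth_distance(m, 4), "not present")
  cases <- rand_points(10, seed = 8, prefix = "A")
  pool <- rand_points(40, seed = 9, prefix = "B")
  prof <- knn_profile(cases, pool, k_max = 8)
  expect_false(is.unsorted(prof$max_kth_distance_ft))
  # degenerate: all controls coincident with cases
  cases2 <- rand_points(4, seed = 10, prefix = "A")
  pool2 <- cases2
  pool2$crash_id <- sub("A", "B", pool2$crash_id)
  m2 <- knn_controls(cases2, pool2, k = 1)
  expect_equal(max_kth_distance(m2, 1), 0)
})

test_that("the matched sample deduplicates shared controls", {
  cases <- data.frame(crash_id = c("A1", "A2"), latitude = c(40, 40.001),
                      longitude = -75, stringsAsFactors = FALSE)
  pool <- data.frame(crash_id = paste0("B", 1:3), latitude = c(40, 40, 40),
                     longitude = c(-75, -75.001, -74.999),
                     stringsAsFactors = FALSE)
  m <- knn_controls(cases, pool, k = 3)
  s <- build_matched_sample(cases, pool, m)
  expect_equal(nrow(s), 5)  # 2 cases + 3 shared controls
  expect_equal(sum(s$matched_role == "case"), 2)
  # disjoint controls: size n_cases * (1 + k)
  cases2 <- rand_points(4, seed = 12, prefix = "A")
  pool2 <- rand_points(100, seed = 13, prefix = "B")
  m2 <- knn_controls(cases2, pool2, k = 3)
  s2 <- build_matched_sample(cases2, pool2, m2)
  expect_equal(nrow(s2), length(unique(m2$control_id)) + 4)
})
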