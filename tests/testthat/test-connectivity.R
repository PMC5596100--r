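test_that("unit_normalize demeans and scales rows to unit norm", {
  ts <- time_series_volume(matrix(c(1, 2, 3), 1, 3, byrow = TRUE))
  u <- unit_normalize(ts)
  expect_equal(unname(u$values[1, ]), c(-1, 0, 1) / sqrt(2), tolerance = 1e-15)
  # idempotent on an already normalized volume
  expect_equal(unit_normalize(u)$values, u$values, tolerance = 1e-14)
  set.seed(7)
  big <- unit_normalize(time_series_volume(matrix(rnorm(200), 10, 20)))
  expect_true(all(abs(sqrt(rowSums(big$values^2)) - 1) < 1e-12))
  expect_true(all(abs(rowMeans(big$values)) < 1e-14))
  const <- time_series_volume(rbind(rnorm(5), rep(2, 5)),
                              voxel_ids = c("ok", "flat"))
  expect_error(unit_normalize(const), "flat")
})

test_that("voxelwise global connectivity matches the brute-force correlation oracle", {
  # degenerate cases with known answers
  shared <- matrix(rep(sin(1:12), 6), 6, 12, byrow = TRUE)
  expect_equal(unname(voxelwise_global_connectivity(
    time_series_volume(shared))$values), rep(1, 6), tolerance = 1e-12)
  s <- rnorm(10)
  split <- matrix(c(s, s, -s, -s), 4, 10, byrow = TRUE)
  expect_equal(unname(voxelwise_global_connectivity(
    time_series_volume(split))$values), rep(0, 4), tolerance = 1e-12)
  # random instance vs explicit M x M correlation matrix
  set.seed(11)
  ts <- time_series_volume(matrix(rnorm(50 * 40), 50, 40))
  map <- voxelwise_global_connectivity(ts)
  oracle <- rowMeans(stats::cor(t(ts$values)))
  expect_lt(max(abs(map$values - oracle)), 1e-10)
  expect_identical(map$scale, "r")
})

test_that("Fisher z transforms and clips correlation maps", {
  map <- connectivity_map(c(a = 0, b = 0.5, c = 1, d = -1), scale = "r")
  z <- fisher_z(map)
  expect_identical(z$scale, "z")
  expect_equal(unname(z$values[1]), 0)
  expect_equal(unname(z$values[2]), atanh(0.5))
  expect_equal(unname(z$values[3]), atanh(1 - 1e-7))
  expect_equal(unname(z$values[4]), -atanh(1 - 1e-7))
  expect_true(all(is.finite(z$values)))
  expect_error(fisher_z(z), "r-scale")
})

test_that("ROI averaging reduces maps by explicit grouping", {
  set.seed(3)
  vals <- rnorm(9) / 2
  map <- connectivity_map(setNames(vals, paste0("v", 1:9)), scale = "r")
  lab <- roi_labeling(setNames(rep(c("R1", "R2", "R3"), each = 3),
                               paste0("v", 1:9)))
  out <- roi_average(map, lab)
  oracle <- tapply(vals, rep(c("R1", "R2", "R3"), each = 3), mean)
  expect_equal(unname(out), as.numeric(oracle[names(out)]), tolerance = 1e-14)
  # one ROI over everything is the overall mean; singleton ROIs pass through
  all_one <- roi_labeling(setNames(rep("all", 9), paste0("v", 1:9)))
  expect_equal(unname(roi_average(map, all_one)), mean(vals))
  single <- roi_labeling(setNames(paste0("r", 1:9), paste0("v", 1:9)))
  expect_equal(unname(roi_average(map, single)), unname(vals))
  empty <- roi_labeling(setNames("R1", "v1"), roi_ids = c("R1", "R9"))
  expect_error(roi_average(map, empty), "R9")
})

test_that("gcor equals the mean pairwise correlation and the map mean", {
  shared <- matrix(rep(cos(1:15), 5), 5, 15, byrow = TRUE)
  expect_equal(gcor(time_series_volume(shared)), 1, tolerance = 1e-12)
  s <- rnorm(12)
  anti <- rbind(s, -s)
  expect_equal(gcor(time_series_volume(anti)), 0, tolerance = 1e-12)
  set.seed(21)
  ts <- time_series_volume(matrix(rnorm(30 * 25), 30, 25))
  full_corr <- stats::cor(t(ts$values))
  expect_lt(abs(gcor(ts) - mean(full_corr)), 1e-10)
  # identity with the connectivity map (both include self-correlation)
  expect_equal(gcor(ts), mean(voxelwise_global_connectivity(ts)$values),
               tolerance = 1e-12)
  expect_equal(gcor(ts, squared = FALSE), sqrt(gcor(ts)), tolerance = 1e-12)
})

test_that("gcor is invariant to voxel order and per-voxel affine rescaling", {
  set.seed(5)
  vals <- matrix(rnorm(20 * 18), 20, 18)
  g0 <- gcor(time_series_volume(vals))
  expect_gte(g0, 0); expect_lte(g0, 1)
  perm <- sample.int(20)
  expect_equal(gcor(time_series_volume(vals[perm, ])), g0, tolerance = 1e-12)
  scaled <- vals * runif(20, 0.5, 4) + rnorm(20)
  expect_equal(gcor(time_series_volume(scaled)), g0, tolerance = 1e-10)
})

test_that("component connectivity vectorizes the strict upper triangle row-major", {
  set.seed(9)
  # 19 components -> 171 features, the gICA feature-count of the design
  tc19 <- component_timecourses(matrix(rnorm(60 * 19), 60, 19))
  expect_length(component_connectivity(tc19), 19 * 18 / 2)
  # K = 2: single value equal to the plain correlation
  x <- rnorm(30); y2 <- 0.6 * x + rnorm(30)
  tc2 <- component_timecourses(cbind(c1 = x, c2 = y2))
  expect_equal(unname(component_connectivity(tc2)), cor(x, y2),
               tolerance = 1e-14)
  # three series: element-wise oracle + row-major ordering
  a <- rnorm(40); b <- a + rnorm(40); c <- rnorm(40)
  tc3 <- component_timecourses(cbind(A = a, B = b, C = c))
  v <- component_connectivity(tc3)
  expect_equal(names(v), c("A-B", "A-C", "B-C"))
  expect_equal(unname(v), c(cor(a, b), cor(a, c), cor(b, c)),
               tolerance = 1e-12)
  expect_error(component_timecourses(cbind(a, rep(1, 40))), "constant")
})
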