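test_that("kernel density matches hand evaluation of the Gaussian kernel", {
  # two points distance 2 apart, t = 1: f at either point
  pts <- rbind(c(0, 0), c(2, 0))
  d <- estimate_density(pts, t = 1, grid_n = 0)
  expect_equal(d$f_points[1], 0.5 * (1 / (2 * pi)) * (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(d$f_points[1], d$f_points[2], tolerance = 1e-12)
})

test_that("density integrates to one over a generous lattice", {
  pts <- withr::with_seed(31, matrix(rnorm(400), 200, 2))
  d <- estimate_density(pts, grid_n = 200, pad = 5)
  cell <- diff(d$grid_x[1:2]) * diff(d$grid_y[1:2])
  expect_equal(sum(d$grid$f) * cell, 1, tolerance = 1e-3)
})

test_that("bandwidth must be positive and inputs two-dimensional", {
  pts <- matrix(rnorm(20), 10, 2)
  expect_error(estimate_density(pts, t = 0), "positive")
  expect_error(estimate_density(pts, t = -1), "positive")
  expect_error(estimate_density(matrix(rnorm(30), 10, 3)), "two columns")
  expect_error(estimate_density(pts[1, , drop = FALSE]), "two points")
})

test_that("decile levels rank-read-off on strictly decreasing density", {
  lv <- trilocus:::decile_levels(10:1)
  expect_equal(lv, 1:10)
  # ties broken by stable input order
  lv2 <- trilocus:::decile_levels(rep(1, 10))
  expect_equal(lv2, 1:10)
})

test_that("decile regions are nested and mass-calibrated on arbitrary fixtures", {
  cases <- list(c(41, 57), c(42, 230), c(43, 501))
  for (cs in cases) {
    seed <- cs[1]; n <- cs[2]
    f <- withr::with_seed(seed, runif(n))
    lv <- trilocus:::decile_levels(f)
    card <- vapply(1:10, function(k) sum(lv <= k), integer(1))
    expect_true(all(diff(card) >= 0))
    expect_equal(card[10], n)
    expect_true(all(abs(card / n - (1:10) / 10) <= 1 / n))
    # U_k is exactly the k*n/10 densest points
    expect_true(min(f[lv == 1]) >= max(f[lv > 1]))
  }
})

test_that("U_5 of a uniform square covers about half the area", {
  pts <- withr::with_seed(43, matrix(runif(10000), 5000, 2))
  z <- scale(pts)
  d <- estimate_density(z, grid_n = 0)
  lv <- trilocus:::decile_levels(d$f_points)
  thr <- min(d$f_points[lv <= 5])
  # Monte-Carlo coverage: fraction of the square where f >= threshold
  grid <- as.matrix(expand.grid(seq(min(z[, 1]), max(z[, 1]), length.out = 60),
                                seq(min(z[, 2]), max(z[, 2]), length.out = 60)))
  fg <- trilocus:::gauss_kde_eval(grid, z, d$t)
  expect_lt(abs(mean(fg >= thr) - 0.5), 0.05)
})

test_that("U_5 of a standard bivariate normal has the closed-form boundary radius", {
  x <- withr::with_seed(5, matrix(rnorm(10000), 5000, 2))
  d <- estimate_density(x, grid_n = 0)
  rk <- order(order(-d$f_points))
  boundary <- which(rk == ceiling(5 * 5000 / 10))
  expect_lt(abs(sum(x[boundary, ]^2) - 2 * log(2)), 0.1)
})

test_that("level statistics match direct arithmetic and degenerate cases", {
  # four identical points: mu is the point, sigma zero, at every level
  m0 <- fake_map(rep(1.5, 4), rep(0.2, 4), trilocus:::decile_levels(rep(1, 4)))
  st <- level_statistics(m0)
  expect_equal(st$mu_x, rep(1.5, 10))
  expect_equal(st$sigma_x, rep(0, 10))
  expect_equal(st$card[10], 4L)

  # four distinct points, k = 10: population mean/SD by hand
  v1 <- c(1, 2, 3, 6); v2 <- c(0, 1, 0, 1)
  m1 <- fake_map(v1, v2, c(1, 4, 7, 10))
  st1 <- level_statistics(m1)
  expect_equal(st1$mu_x[10], 3)
  expect_equal(st1$sigma_x[10], sqrt(mean((v1 - 3)^2)))
  expect_equal(st1$sigma_y[10], 0.5)
  expect_equal(st1$card, c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L))
})

test_that("build_map composes the pipeline and destandardises correctly", {
  ds <- make_cube_ds(n = 60, seed = 47)
  map <- build_map(ds, "d_rg", "theta_r", grid_n = 16)
  expect_s3_class(map, "trilocus_map")
  expect_equal(map$stats$card[10], 60L)
  geom <- dataset_geometry(ds)
  # standardisation round-trip: mu_10 equals the raw sample mean
  expect_equal(map$stats$mu_x[10], mean(geom$d_rg), tolerance = 1e-9)
  expect_equal(map$stats$mu_y[10], mean(geom$theta_r), tolerance = 1e-9)
  # determinism
  map2 <- build_map(ds, "d_rg", "theta_r", grid_n = 16)
  expect_identical(map$points$level, map2$points$level)
})

test_that("build_map refuses undersized datasets and bad axis ids", {
  ds <- make_cube_ds(n = 9, seed = 48)
  expect_error(build_map(ds), "at least 10")
  ds2 <- make_cube_ds(n = 12, seed = 48)
  expect_error(build_map(ds2, distance = "theta_r"), "must be one of")
})

test_that("the battery yields exactly nine distinct projections", {
  ds <- make_cube_ds(n = 30, seed = 49)
  battery <- build_all_maps(ds, grid_n = 0)
  expect_equal(nrow(battery), 9L)
  expect_equal(nrow(dplyr::distinct(battery[c("distance", "angle")])), 9L)
  expect_true(all(purrr::map_int(battery$map, ~ .x$stats$card[10]) == 30L))
})

test_that("tidy, glance, autoplot and write_map work on a density map", {
  ds <- make_cube_ds(n = 25, seed = 50)
  map <- build_map(ds, "d_gb", "theta_b", grid_n = 12)
  td <- tidy(map)
  expect_equal(nrow(td), 10)
  expect_named(glance(map), c("distance", "angle", "M", "t", "grid_n"))
  expect_s3_class(autoplot(map), "ggplot")
  prefix <- file.path(withr::local_tempdir(), "map")
  write_map(map, prefix)
  expect_true(file.exists(paste0(prefix, "_field.tsv")))
  expect_true(file.exists(paste0(prefix, "_levels.tsv")))
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(side$M, 25L)
})
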