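test_that("normalised PCA recovers exact rank-1 and independent structure", {
  x <- withr::with_seed(81, {
    base <- rnorm(50)
    cbind(a = base, b = 2 * base + 3, c = -base)
  })
  p <- pca_norm(x)
  expect_equal(abs(p$C), matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(p$eigenvalues, c(3, 0, 0), tolerance = 1e-12)

  y <- withr::with_seed(82, matrix(rnorm(30000), 10000, 3))
  q <- pca_norm(y)
  expect_lt(max(abs(q$C[upper.tri(q$C)])), 0.05)
  expect_equal(q$eigenvalues, rep(1, 3), tolerance = 0.05)
  expect_equal(sum(diag(q$C)), 3)
  expect_equal(sum(q$eigenvalues), 3, tolerance = 1e-9)
})

test_that("normalised PCA rejects degenerate input naming the column", {
  x <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_error(pca_norm(x), "b")
  expect_error(pca_norm(x[1:2, ]), "at least 3")
})

test_that("zone centres from mean distances solve the two-circle intersection", {
  eq <- fix_centers(1, 1, 1)
  expect_equal(eq$zones[[2]]$center, c(2.5, 5 * sqrt(3) / 2))
  expect_equal(eq$provenance$r0, 5)

  m345 <- fix_centers(3, 4, 5)
  expect_equal(m345$provenance$r0, 3)
  expect_equal(m345$provenance$r1, 4)
  expect_equal(m345$zones[[2]]$center, c(1.8, 2.4))
  expect_equal(m345$zones[[1]]$center, c(0, 0))
  expect_equal(m345$zones[[3]]$center, c(5, 0))

  # tangent circles: a single intersection point on the axis, no warning
  tang <- fix_centers(1, 1, 2)
  expect_equal(tang$zones[[2]]$center, c(2.5, 0))
  # disjoint circles: collinear fallback with a warning
  expect_warning(deg <- fix_centers(1, 1, 3), "collinear")
  expect_equal(deg$zones[[2]]$center[2], 0)

  expect_error(fix_centers(-1, 1, 1), "positive")
})

test_that("configuration sampling is uniform in the rectangles and reproducible", {
  model <- s4_regimes()$moderate
  cs <- sample_configurations(model, 10000, seed = 83)
  ctr <- trilocus:::model_centers(model)
  eps <- trilocus:::model_eps(model)
  for (j in 1:6) {
    node <- ceiling(j / 2)
    cmid <- ctr[node, 2 - j %% 2]
    expect_true(all(abs(cs$points[, j] - cmid) <= eps[j] + 1e-12))
    # uniform variance eps^2 / 3 within 5%
    expect_equal(stats::var(cs$points[, j]), eps[j]^2 / 3, tolerance = 0.05)
  }
  cs2 <- sample_configurations(model, 10000, seed = 83)
  expect_identical(cs$points, cs2$points)

  # zero half-widths collapse every configuration onto the centres
  degen <- survival_zone_model(list(survival_zone(c(0, 0), 0, 0),
                                    survival_zone(c(2, 2), 0, 0),
                                    survival_zone(c(5, 0), 0, 0)))
  cd <- sample_configurations(degen, 5, seed = 84)
  expect_equal(unique(cd$points[, "x2"]), 2)
  expect_equal(unique(cd$points[, "y3"]), 0)
})

test_that("the objective is zero at identity and tracks single-entry perturbations", {
  model <- s4_regimes()$moderate
  cs <- sample_configurations(model, 500, seed = 85)
  nv <- trilocus:::config_node_variables(cs$points)
  expC <- lapply(nv, function(x) suppressWarnings(stats::cor(x)))
  expect_equal(as.numeric(model_objective(expC, cs)), 0)

  delta <- 0.07
  pert <- expC
  pert[[2]][1, 2] <- pert[[2]][1, 2] + delta
  pert[[2]][2, 1] <- pert[[2]][2, 1] + delta
  expect_equal(as.numeric(model_objective(pert, cs)), sqrt(2) * delta,
               tolerance = 1e-12)
  expect_gte(as.numeric(model_objective(pert, cs)), 0)
})

test_that("grid cardinality multiplies per-parameter counts", {
  expect_equal(grid_size(eps_grid(2)), 1)
  expect_equal(grid_size(eps_grid(list(1:3, 1:3, 1, 1, 1, 1))), 9)
  expect_error(eps_grid(list(1, 2)), "six")
  expect_error(eps_grid(list(1, 1, 1, 1, 1, numeric(0))), "Empty")
})

test_that("the solver returns the single candidate of a one-point grid", {
  ds <- simulate_from_zones(simulation_spec(s4_regimes()$constrained,
                                            n = 80, seed = 86))
  fit <- solve_zones(ds, grid = eps_grid(2.5), m_configs = 500, seed = 87)
  expect_equal(fit$best_eps, rep(2.5, 6))
  expect_equal(fit$evaluations, 1)
  expect_gte(fit$best_objective, 0)
})

test_that("the solver is deterministic and worker-count invariant", {
  ds <- simulate_from_zones(simulation_spec(s4_regimes()$moderate,
                                            n = 120, seed = 88))
  grid <- eps_grid(list(c(1, 3), c(1, 3), c(2, 4), c(2, 4), c(1, 5), 3))
  f1 <- solve_zones(ds, grid = grid, m_configs = 400, seed = 89, workers = 1)
  f2 <- solve_zones(ds, grid = grid, m_configs = 400, seed = 89, workers = 2)
  expect_identical(f1$best_eps, f2$best_eps)
  expect_identical(f1$best_objective, f2$best_objective)
  expect_equal(f1$evaluations, 32)
  f3 <- solve_zones(ds, grid = grid, m_configs = 400, seed = 89,
                    keep_surface = TRUE)
  expect_identical(f3$best_objective, f1$best_objective)
  expect_equal(nrow(f3$surface), 32)
  expect_equal(min(f3$surface$objective), f3$best_objective)
})

test_that("the objective is invariant to rigid transforms of the data", {
  ds <- simulate_from_zones(simulation_spec(s4_regimes()$moderate,
                                            n = 100, seed = 90))
  moved <- apply_random_frames(ds, seed = 91)
  f1 <- solve_zones(ds, grid = eps_grid(list(1, 1, 3, 3, 2, 2)),
                    m_configs = 300, seed = 92)
  f2 <- solve_zones(moved, grid = eps_grid(list(1, 1, 3, 3, 2, 2)),
                    m_configs = 300, seed = 92)
  expect_equal(f1$best_objective, f2$best_objective, tolerance = 1e-9)
})

test_that("refinement tightens the grid around the incumbent", {
  ds <- simulate_from_zones(simulation_spec(s4_regimes()$moderate,
                                            n = 150, seed = 93))
  f0 <- solve_zones(ds, grid = eps_grid(c(1, 3, 5)), m_configs = 300, seed = 94)
  f1 <- solve_zones(ds, grid = eps_grid(c(1, 3, 5)), m_configs = 300, seed = 94,
                    refine = 1)
  expect_lte(f1$best_objective, f0$best_objective)
  expect_gt(f1$evaluations, f0$evaluations)
})

test_that("zone-fit tidiers, plot and JSON export are coherent", {
  ds <- simulate_from_zones(simulation_spec(s4_regimes()$constrained,
                                            n = 60, seed = 95))
  fit <- solve_zones(ds, grid = eps_grid(c(1, 2)), m_configs = 200, seed = 96)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(td$area, 4 * td$eps1 * td$eps2)
  expect_equal(glance(fit)$evaluations, 64)
  expect_s3_class(autoplot(fit), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_zone_fit(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(unlist(js$best_eps), fit$best_eps)
  expect_equal(js$evaluations, 64L)
})
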