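#' Normalised principal component analysis of per-node variables
#'
#' Standardises each column of an M x 3 table of per-node variables
#' (d_i1, d_i2, theta_i), and returns the resulting correlation matrix
#' together with its eigenvalues in descending order.  The correlation
#' matrix is what the survival-zone solver matches; the eigenvalues
#' summarise how the variation around a node distributes over principal
#' axes but do not enter the fitting objective.
#'
#' @param samples An M x 3 numeric matrix or data frame (M >= 3).
#' @return A `pca_norm` object: list with `C` (3 x 3 correlation matrix),
#'   `eigenvalues` (descending, summing to 3) and `n`.
#' @export
pca_norm <- function(samples) {
  x <- as.matrix(samples)
  if (nrow(x) < 3) cli::cli_abort("Need at least 3 samples.")
  if (ncol(x) != 3) cli::cli_abort("samples must have exactly 3 columns.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad) || all(!nzchar(bad))) bad <- which(sds == 0)
    cli::cli_abort("Degenerate input: column {.val {bad}} has zero variance.")
  }
  C <- stats::cor(x)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  structure(list(C = C, eigenvalues = sort(ev, decreasing = TRUE), n = nrow(x)),
            class = "pca_norm")
}

#' @export
print.pca_norm <- function(x, ...) {
  cli::cli_inform("Normalised PCA of {x$n} samples; eigenvalues {paste(signif(x$eigenvalues, 4), collapse = ', ')}")
  print(x$C)
  invisible(x)
}

#' Experimental per-node correlation matrices of a dataset
#'
#' Runs [dataset_geometry()], forms each node's (d_i1, d_i2, theta_i) table
#' via [node_variables()] and applies [pca_norm()].
#'
#' @param ds A `triplet_df` or a geometry table.
#' @return A list of three `pca_norm` objects (nodes 1, 2, 3).
#' @export
node_correlations <- function(ds) {
  geom <- if (inherits(ds, "triplet_df")) dataset_geometry(ds) else tibble::as_tibble(ds)
  lapply(1:3, function(i) {
    nv <- node_variables(geom, i)
    pca_norm(as.matrix(nv[c("d_i1", "d_i2", "theta_i")]))
  })
}

#' Survival zones and the survival-zone model
#'
#' A survival zone is the rectangle `[cx - eps1, cx + eps1] x
#' [cy - eps2, cy + eps2]` (model units) in which one locus roams uniformly.
#' A model is exactly three zones, one per node (1 = r, 2 = g, 3 = b).
#'
#' @param center Numeric length-2 zone centre.
#' @param eps1,eps2 Non-negative half-widths.
#' @return `survival_zone()`: a `survival_zone` list; `survival_zone_model()`:
#'   a `survival_zone_model` (list of 3 zones plus optional provenance).
#' @export
survival_zone <- function(center, eps1, eps2) {
  stopifnot(length(center) == 2, eps1 >= 0, eps2 >= 0)
  structure(list(center = as.numeric(center), eps1 = eps1, eps2 = eps2),
            class = "survival_zone")
}

#' @rdname survival_zone
#' @param zones A list of exactly three `survival_zone`s.
#' @param provenance Optional list (e.g. the `r0`, `r1` of data-fixed
#'   centres).
#' @export
survival_zone_model <- function(zones, provenance = NULL) {
  stopifnot(length(zones) == 3)
  structure(list(zones = zones, provenance = provenance),
            class = "survival_zone_model")
}

#' @rdname survival_zone
#' @param model A `survival_zone_model`.
#' @export
zone_areas <- function(model) {
  vapply(model$zones, function(z) 4 * z$eps1 * z$eps2, numeric(1))
}

#' @export
print.survival_zone_model <- function(x, ...) {
  for (i in 1:3) {
    z <- x$zones[[i]]
    cli::cli_inform("zone {i}: center ({signif(z$center[1], 4)}, {signif(z$center[2], 4)}), eps = ({z$eps1}, {z$eps2})")
  }
  invisible(x)
}

#' Fix zone centres from mean experimental distances
#'
#' Maps the dataset's mean inter-locus distances onto the fixed model scale:
#' node 1 is pinned at (0, 0), node 3 at (5, 0), and node 2 is placed at the
#' intersection (with non-negative y) of the circle of radius
#' `r0 = 5 * mean_d12 / mean_d13` around node 1 and the circle of radius
#' `r1 = 5 * mean_d23 / mean_d13` around node 3.  If the mean distances
#' violate the triangle inequality the circles do not intersect and node 2
#' is placed collinearly at (clamped x, 0) with a warning.
#'
#' @param mean_d12,mean_d23,mean_d13 Mean distances (um) between nodes
#'   1-2, 2-3 and 1-3.
#' @return A `survival_zone_model` with zero half-widths and provenance
#'   `r0`, `r1`.
#' @export
fix_centers <- function(mean_d12, mean_d23, mean_d13) {
  if (any(c(mean_d12, mean_d23, mean_d13) <= 0)) {
    cli::cli_abort("Mean distances must be positive.")
  }
  r0 <- 5 * mean_d12 / mean_d13
  r1 <- 5 * mean_d23 / mean_d13
  x <- (r0^2 - r1^2 + 25) / 10
  y2 <- r0^2 - x^2
  if (y2 < 0) {
    cli::cli_warn("Mean distances violate the triangle inequality; node 2 placed collinearly.")
    x <- min(max(x, 0), 5)
    y <- 0
  } else {
    y <- sqrt(y2)
  }
  survival_zone_model(
    list(survival_zone(c(0, 0), 0, 0),
         survival_zone(c(x, y), 0, 0),
         survival_zone(c(5, 0), 0, 0)),
    provenance = list(r0 = r0, r1 = r1)
  )
}

#' Sample abstract polymer configurations from a zone model
#'
#' Draws `n_configs` placements of the three nodes, each node independently
#' uniform in its rectangle; a zero-area zone puts every sample at its
#' centre.  Reproducible given `seed`.
#'
#' @param model A `survival_zone_model`.
#' @param n_configs Number of configurations (>= 1).
#' @param seed Integer seed.
#' @return A `config_set`: list with `points` (an `n_configs` x 6 matrix,
#'   columns x1, y1, x2, y2, x3, y3), `seed`, `model`.
#' @export
sample_configurations <- function(model, n_configs, seed = 1L) {
  stopifnot(inherits(model, "survival_zone_model"), n_configs >= 1)
  u <- withr::with_seed(seed, matrix(stats::runif(n_configs * 6), n_configs, 6))
  pts <- configs_from_uniforms(u, model_centers(model), model_eps(model))
  structure(list(points = pts, seed = seed, model = model),
            class = "config_set")
}

model_centers <- function(model) {
  do.call(rbind, lapply(model$zones, `[[`, "center"))
}

model_eps <- function(model) {
  unlist(lapply(model$zones, function(z) c(z$eps1, z$eps2)))
}

# map an n x 6 matrix of standard uniforms onto zone rectangles
# (common-random-numbers workhorse of the solver)
configs_from_uniforms <- function(u, centers, eps) {
  ctr <- c(t(centers))  # cx1, cy1, cx2, cy2, cx3, cy3
  pts <- sweep(sweep(u * 2, 2, rep(1, 6)) , 2, eps, `*`)  # eps*(2u-1)
  pts <- sweep(pts, 2, ctr, `+`)
  colnames(pts) <- c("x1", "y1", "x2", "y2", "x3", "y3")
  pts
}

# planar triangle variables of a configuration matrix: per-node
# (d_i1, d_i2, theta_i) following the same node convention as the data
config_node_variables <- function(pts) {
  dx12 <- pts[, 3] - pts[, 1]; dy12 <- pts[, 4] - pts[, 2]
  dx13 <- pts[, 5] - pts[, 1]; dy13 <- pts[, 6] - pts[, 2]
  dx23 <- pts[, 5] - pts[, 3]; dy23 <- pts[, 6] - pts[, 4]
  d12 <- sqrt(dx12^2 + dy12^2)
  d13 <- sqrt(dx13^2 + dy13^2)
  d23 <- sqrt(dx23^2 + dy23^2)
  clamp <- function(x) pmin(1, pmax(-1, x))
  th1 <- acos(clamp((d12^2 + d13^2 - d23^2) / (2 * d12 * d13)))
  th2 <- acos(clamp((d12^2 + d23^2 - d13^2) / (2 * d12 * d23)))
  th3 <- acos(clamp((d13^2 + d23^2 - d12^2) / (2 * d13 * d23)))
  list(cbind(d12, d13, th1),   # node 1: (d_12, d_31, theta_1)
       cbind(d23, d12, th2),   # node 2: (d_23, d_12, theta_2)
       cbind(d13, d23, th3))   # node 3: (d_31, d_23, theta_3)
}

#' Frobenius objective between experimental and abstract correlations
#'
#' For each node, computes the abstract correlation matrix from the
#' configurations' (D_i1, D_i2, Theta_i) and sums, over the three nodes,
#' the Frobenius norm of the difference with the experimental correlation
#' matrix.  A candidate whose abstract geometry is degenerate (a zero-
#' variance node variable, e.g. an exactly collinear zero-spread layout)
#' yields `Inf` and is thereby rejected by the solver.
#'
#' @param exp_corr List of three experimental correlations: `pca_norm`
#'   objects or bare 3 x 3 matrices (nodes 1..3).
#' @param configs A `config_set` from [sample_configurations()].
#' @return The non-negative objective (scalar), with per-node contributions
#'   in attribute `"node_contributions"`.
#' @export
model_objective <- function(exp_corr, configs) {
  stopifnot(inherits(configs, "config_set"))
  Cexp <- lapply(exp_corr, function(x) if (inherits(x, "pca_norm")) x$C else as.matrix(x))
  obj <- objective_from_points(Cexp, configs$points)
  obj
}

objective_from_points <- function(Cexp, pts) {
  nv <- config_node_variables(pts)
  contrib <- numeric(3)
  for (i in 1:3) {
    Ca <- suppressWarnings(stats::cor(nv[[i]]))
    if (any(!is.finite(Ca))) {  # zero-variance column: degenerate candidate
      out <- Inf
      attr(out, "node_contributions") <- rep(NA_real_, 3)
      return(out)
    }
    contrib[i] <- sqrt(sum((Cexp[[i]] - Ca)^2))
  }
  out <- sum(contrib)
  attr(out, "node_contributions") <- contrib
  out
}

#' Cartesian grid of half-width candidates
#'
#' @param values Numeric vector of candidate half-widths, or a list of six
#'   such vectors (one per parameter eps_1^1, eps_2^1, ..., eps_2^3).  The
#'   field default is the 0.2-step subdivision of (0; 5], 25 values per
#'   parameter (zero excluded so every zone has positive extent), yielding
#'   25^6 = 5^12 candidates.
#' @return A list of six numeric vectors (class `eps_grid`).
#' @export
eps_grid <- function(values = seq(0.2, 5, by = 0.2)) {
  if (!is.list(values)) values <- rep(list(as.numeric(values)), 6)
  if (length(values) != 6 || !all(vapply(values, is.numeric, logical(1)))) {
    cli::cli_abort("values must be a numeric vector or a list of six numeric vectors.")
  }
  if (any(vapply(values, length, integer(1)) == 0)) {
    cli::cli_abort("Empty grid.")
  }
  structure(values, class = "eps_grid")
}

#' Number of candidates in a grid
#'
#' @param grid An `eps_grid` (or anything [eps_grid()] accepts).
#' @return The product of per-parameter point counts.
#' @export
#' @examples
#' grid_size(eps_grid())  # 5^12
grid_size <- function(grid) {
  if (!inherits(grid, "eps_grid")) grid <- eps_grid(grid)
  prod(vapply(grid, length, integer(1)))
}

#' Fit the survival-zone model to a dataset by exhaustive grid search
#'
#' Centres are fixed from the dataset's mean inter-locus distances via
#' [fix_centers()]; the experimental per-node correlation matrices come from
#' [node_correlations()].  Every candidate half-width vector on the
#' Cartesian grid is scored with [model_objective()] using common random
#' numbers (one uniform draw shared by all candidates, so the objective
#' surface is smooth in the half-widths), and the arg-min is returned with
#' ties broken lexicographically on the half-width vector (smallest zones
#' win).  Candidates are independent work items distributed over a local
#' worker pool; any scheduling gives a bit-identical result because the
#' reduction is a deterministic global arg-min.
#'
#' An optional coarse-to-fine refinement re-solves `refine` times on a
#' 5-value grid spanning one former step around the incumbent (clipped to
#' (0; 5]), reusing the same uniforms.
#'
#' @param ds A `triplet_df` (pass it through [qc_filter()] first).
#' @param grid An `eps_grid` (default: 5-value coarse grid 1..5 per
#'   parameter; use `eps_grid()` for the full 0.2-step grid, whose 5^12
#'   candidates are a cluster-scale computation).
#' @param m_configs Configurations per candidate (default 10000).
#' @param seed Integer seed for the common random numbers.
#' @param workers Local worker processes (default 1).
#' @param refine Number of refinement rounds (default 0).
#' @param keep_surface Keep the per-candidate objective table (tibble of
#'   half-widths + objective) for diagnostics.
#' @return A `zone_fit`: list with `model` (fitted `survival_zone_model`),
#'   `best_eps`, `best_objective`, `evaluations`, `grid`, `m_configs`,
#'   `seed`, `exp_corr`, and optionally `surface`.
#' @export
solve_zones <- function(ds, grid = eps_grid(1:5), m_configs = 10000,
                        seed = 1L, workers = 1L, refine = 0L,
                        keep_surface = FALSE) {
  if (!inherits(grid, "eps_grid")) grid <- eps_grid(grid)
  geom <- if (inherits(ds, "triplet_df")) dataset_geometry(ds) else tibble::as_tibble(ds)
  centers_model <- fix_centers(mean(geom$d_rg), mean(geom$d_gb), mean(geom$d_rb))
  exp_corr <- node_correlations(geom)
  u <- withr::with_seed(seed, matrix(stats::runif(m_configs * 6), m_configs, 6))
  fit <- solve_grid(exp_corr, centers_model, grid, u, workers, keep_surface)
  total_evals <- fit$evaluations
  step <- vapply(grid, function(v) if (length(v) > 1) min(diff(sort(v))) else 1, numeric(1))
  r <- 0L
  while (r < refine) {
    r <- r + 1L
    step <- step / 2
    grid <- eps_grid(lapply(1:6, function(j) {
      v <- unique(pmin(5, pmax(step[j], fit$best_eps[j] + step[j] * (-2:2))))
      sort(v)
    }))
    fit <- solve_grid(exp_corr, centers_model, grid, u, workers, keep_surface)
    total_evals <- total_evals + fit$evaluations
  }
  zones <- lapply(1:3, function(i) {
    survival_zone(centers_model$zones[[i]]$center,
                  fit$best_eps[2 * i - 1], fit$best_eps[2 * i])
  })
  structure(list(
    model = survival_zone_model(zones, provenance = centers_model$provenance),
    best_eps = fit$best_eps,
    best_objective = fit$best_objective,
    evaluations = total_evals,
    grid = grid, m_configs = m_configs, seed = seed, workers = workers,
    exp_corr = exp_corr,
    surface = fit$surface
  ), class = "zone_fit")
}

solve_grid <- function(exp_corr, centers_model, grid, u, workers, keep_surface) {
  Cexp <- lapply(exp_corr, function(x) if (inherits(x, "pca_norm")) x$C else as.matrix(x))
  centers <- model_centers(centers_model)
  lens <- vapply(grid, length, integer(1))
  n_cand <- prod(lens)
  # decode candidate index (1-based) to the 6 half-widths; index varies the
  # last parameter fastest so enumeration is lexicographic in the eps vector
  decode <- function(idx) {
    idx0 <- idx - 1
    e <- numeric(6)
    for (j in 6:1) {
      e[j] <- grid[[j]][idx0 %% lens[j] + 1]
      idx0 <- idx0 %/% lens[j]
    }
    e
  }
  eval_one <- function(idx) {
    e <- decode(idx)
    pts <- configs_from_uniforms(u, centers, e)
    as.numeric(objective_from_points(Cexp, pts))
  }
  idx_all <- seq_len(n_cand)
  if (workers > 1 && .Platform$OS.type == "unix") {
    chunks <- parallel::splitIndices(n_cand, min(workers * 4L, n_cand))
    obj <- unlist(parallel::mclapply(chunks, function(ix) {
      vapply(ix, eval_one, numeric(1))
    }, mc.cores = workers), use.names = FALSE)
  } else {
    obj <- vapply(idx_all, eval_one, numeric(1))
  }
  best <- min(obj)
  if (!is.finite(best)) cli::cli_abort("Every candidate was degenerate.")
  # lexicographic tie-break: enumeration order is lexicographic, take first
  best_idx <- which(obj == best)[1]
  surface <- NULL
  if (keep_surface) {
    eps_mat <- t(vapply(idx_all, decode, numeric(6)))
    colnames(eps_mat) <- c("eps1_1", "eps2_1", "eps1_2", "eps2_2", "eps1_3", "eps2_3")
    surface <- dplyr::bind_cols(tibble::as_tibble(eps_mat),
                                tibble::tibble(objective = obj))
  }
  list(best_eps = decode(best_idx), best_objective = best,
       evaluations = n_cand, surface = surface)
}

#' @export
print.zone_fit <- function(x, ...) {
  cli::cli_inform(c(
    "i" = "Survival-zone fit: objective {signif(x$best_objective, 5)} over {x$evaluations} candidates (M' = {x$m_configs}, seed {x$seed})"
  ))
  print(x$model)
  invisible(x)
}

#' Tidy a zone fit: one row per node
#' @param x A `zone_fit`.
#' @param ... Unused.
#' @export
tidy.zone_fit <- function(x, ...) {
  purrr::map_dfr(1:3, function(i) {
    z <- x$model$zones[[i]]
    tibble::tibble(node = i, center_x = z$center[1], center_y = z$center[2],
                   eps1 = z$eps1, eps2 = z$eps2, area = 4 * z$eps1 * z$eps2)
  })
}

#' One-row summary of a zone fit
#' @param x A `zone_fit`.
#' @param ... Unused.
#' @export
glance.zone_fit <- function(x, ...) {
  tibble::tibble(objective = x$best_objective, evaluations = x$evaluations,
                 m_configs = x$m_configs, seed = x$seed,
                 total_area = sum(zone_areas(x$model)))
}

#' Plot fitted survival zones
#' @param object A `zone_fit` or `survival_zone_model`.
#' @param ... Unused.
#' @export
autoplot.zone_fit <- function(object, ...) autoplot(object$model, ...)

#' @rdname autoplot.zone_fit
#' @export
autoplot.survival_zone_model <- function(object, ...) {
  df <- purrr::map_dfr(1:3, function(i) {
    z <- object$zones[[i]]
    tibble::tibble(node = factor(i),
                   xmin = z$center[1] - z$eps1, xmax = z$center[1] + z$eps1,
                   ymin = z$center[2] - z$eps2, ymax = z$center[2] + z$eps2,
                   cx = z$center[1], cy = z$center[2])
  })
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$node), alpha = 0.3) +
    ggplot2::geom_point(ggplot2::aes(.data$cx, .data$cy, colour = .data$node)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (model units)", y = "y (model units)") +
    ggplot2::theme_minimal()
}

#' Export a zone fit as JSON
#'
#' @param fit A `zone_fit`.
#' @param path Output path; per-candidate surface (if kept) goes to
#'   `<path>.surface.tsv`.
#' @return `path`, invisibly.
#' @export
write_zone_fit <- function(fit, path) {
  stopifnot(inherits(fit, "zone_fit"))
  out <- list(
    best_eps = fit$best_eps,
    best_objective = fit$best_objective,
    evaluations = fit$evaluations,
    m_configs = fit$m_configs,
    seed = fit$seed,
    grid = lapply(fit$grid, identity),
    zones = lapply(fit$model$zones, function(z) {
      list(center = z$center, eps1 = z$eps1, eps2 = z$eps2)
    }),
    r0 = fit$model$provenance$r0, r1 = fit$model$provenance$r1
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12)
  if (!is.null(fit$surface)) {
    readr::write_tsv(fit$surface, paste0(path, ".surface.tsv"), progress = FALSE)
  }
  invisible(path)
}
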