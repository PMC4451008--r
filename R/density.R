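#' Gaussian kernel density estimate on a 2D point set
#'
#' Parzen-Rosenblatt estimate with the isotropic Gaussian kernel
#' `K(x, y, t) = exp(-||x - y||^2 / (2 t)) / (2 pi t)`, so
#' `f(x) = mean_m K(x, y_m, t)`.  The bandwidth `t` is the kernel variance in
#' the (usually standardised) units of the input.  When `t = NULL` it is set
#' by Scott's rule on the sample, `t = (M^(-1/6) * s)^2` with `s` the mean of
#' the two axis standard deviations (equal to 1 after standardisation).
#'
#' @param points A two-column matrix or data frame of observations.
#' @param t Kernel variance (> 0), or `NULL` for Scott's rule.
#' @param grid_n Lattice resolution per axis for the rendered field; `0`
#'   skips the lattice (point-level densities only).
#' @param pad Lattice margin beyond the data range, in multiples of
#'   `sqrt(t)` (default 3).
#' @return A list with `f_points` (density at each observation, input
#'   order), `t`, and (if `grid_n > 0`) tibble `grid` with columns `x`, `y`,
#'   `f`, plus `grid_x`, `grid_y` axis vectors.
#' @export
estimate_density <- function(points, t = NULL, grid_n = 128, pad = 3) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) cli::cli_abort("points must have exactly two columns.")
  if (nrow(pts) < 2) cli::cli_abort("Need at least two points.")
  if (is.null(t)) {
    s <- mean(apply(pts, 2, stats::sd))
    t <- (nrow(pts)^(-1 / 6) * s)^2
  }
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t <= 0) {
    cli::cli_abort("Bandwidth t must be a positive scalar.")
  }
  out <- list(f_points = gauss_kde_eval(pts, pts, t), t = t)
  if (grid_n > 0) {
    h <- pad * sqrt(t)
    gx <- seq(min(pts[, 1]) - h, max(pts[, 1]) + h, length.out = grid_n)
    gy <- seq(min(pts[, 2]) - h, max(pts[, 2]) + h, length.out = grid_n)
    eval_pts <- as.matrix(expand.grid(x = gx, y = gy))
    f <- gauss_kde_eval(eval_pts, pts, t)
    out$grid_x <- gx
    out$grid_y <- gy
    out$grid <- tibble::tibble(x = eval_pts[, 1], y = eval_pts[, 2], f = f)
  }
  out
}

# density of the Gaussian-kernel mixture at arbitrary d-dim eval points,
# chunked so the distance matrix never exceeds ~8e6 doubles
gauss_kde_eval <- function(eval_pts, data_pts, t) {
  d <- ncol(data_pts)
  M <- nrow(data_pts)
  norm_const <- (2 * pi * t)^(d / 2)
  chunk <- max(1L, floor(8e6 / M))
  f <- numeric(nrow(eval_pts))
  sq_data <- rowSums(data_pts^2)
  i <- 1L
  while (i <= nrow(eval_pts)) {
    j <- min(i + chunk - 1L, nrow(eval_pts))
    E <- eval_pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(E^2), sq_data, `+`) - 2 * tcrossprod(E, data_pts)
    d2[d2 < 0] <- 0
    f[i:j] <- rowMeans(exp(-d2 / (2 * t))) / norm_const
    i <- j + 1L
  }
  f
}

# decile level of each point: rank by density descending (ties broken by
# stable input order), level k holds the top ceiling(k*M/10) points
decile_levels <- function(f_points) {
  M <- length(f_points)
  rk <- order(order(-f_points))  # stable: order() breaks ties by position
  level <- rep(10L, M)
  for (k in 9:1) level[rk <= ceiling(k * M / 10)] <- k
  n_tied <- M - length(unique(f_points))
  if (n_tied > 0.01 * M) {
    cli::cli_inform("{n_tied} tied density value{?s} broken by input order.")
  }
  level
}

#' Assign decile occupancy levels on a density map
#'
#' Realises the nested level sets U_1 c U_2 c ... c U_10 as highest-density
#' regions: points are ranked by their kernel density descending, and U_k is
#' the top `ceiling(k*M/10)` points; a point's level is the smallest k whose
#' region contains it.  Ties in density are broken by stable input order.
#'
#' @param map A `trilocus_map` from [build_map()].
#' @return The map with its `points$level` column (re)computed.
#' @export
decile_regions <- function(map) {
  stopifnot(inherits(map, "trilocus_map"))
  map$points$level <- decile_levels(map$points$f)
  map
}

#' Per-level means and standard deviations of a density map
#'
#' For each cumulative region U_k (k = 1..10) computes the point count, the
#' mean vector and the population standard-deviation vector (divisor
#' `card_k`) of the points it contains, de-standardised back to the original
#' units (um for the distance axis, radians for the angle axis).
#'
#' @param map A `trilocus_map`.
#' @return A tibble: `level`, `card`, `mu_x`, `mu_y`, `sigma_x`, `sigma_y`.
#' @export
level_statistics <- function(map) {
  stopifnot(inherits(map, "trilocus_map"))
  pts <- map$points
  purrr::map_dfr(1:10, function(k) {
    inside <- pts$level <= k
    n <- sum(inside)
    if (n == 0) {
      return(tibble::tibble(level = k, card = 0L, mu_x = NA_real_,
                            mu_y = NA_real_, sigma_x = NA_real_,
                            sigma_y = NA_real_))
    }
    x <- pts$v1[inside]
    y <- pts$v2[inside]
    tibble::tibble(
      level = k, card = n,
      mu_x = mean(x), mu_y = mean(y),
      sigma_x = sqrt(sum((x - mean(x))^2) / n),
      sigma_y = sqrt(sum((y - mean(y))^2) / n)
    )
  })
}

#' Build one (distance, angle) kernel density map
#'
#' Projects the per-nucleus triangle variables onto one distance/angle plane,
#' standardises each axis (z-scores, so the micrometre and radian axes become
#' commensurate for the isotropic kernel), estimates the Gaussian kernel
#' density, assigns decile occupancy levels and computes per-level
#' statistics.
#'
#' @param ds A `triplet_df` (or a precomputed geometry table).
#' @param distance One of `"d_rg"`, `"d_rb"`, `"d_gb"`.
#' @param angle One of `"theta_r"`, `"theta_g"`, `"theta_b"`.
#' @param t Kernel variance in standardised units, `NULL` for Scott's rule.
#' @param grid_n Lattice resolution (0 to skip the rendered field).
#' @param std Optional shared standardisation, a list with numeric length-2
#'   elements `center` and `scale` (distance axis first); used by
#'   [compare_experiments()] to put two experiments in a common frame.
#' @return A `trilocus_map` object: fields `distance`, `angle`, `points`
#'   (tibble `nucleus_id`, `v1`, `v2` in original units, `z1`, `z2`
#'   standardised, `f`, `level`), `std`, `t`, `grid` (or `NULL`), `stats`,
#'   `M`.
#' @export
build_map <- function(ds, distance = "d_rg", angle = "theta_r",
                      t = NULL, grid_n = 128, std = NULL) {
  geom <- if (inherits(ds, "triplet_df")) dataset_geometry(ds) else tibble::as_tibble(ds)
  distance <- rlang::arg_match(distance, c("d_rg", "d_rb", "d_gb"))
  angle <- rlang::arg_match(angle, c("theta_r", "theta_g", "theta_b"))
  if (nrow(geom) < 10) {
    cli::cli_abort("Need at least 10 nuclei to define decile regions (have {nrow(geom)}).")
  }
  v1 <- geom[[distance]]
  v2 <- geom[[angle]]
  if (is.null(std)) {
    std <- list(center = c(mean(v1), mean(v2)),
                scale = c(stats::sd(v1), stats::sd(v2)))
  }
  if (any(std$scale <= 0)) cli::cli_abort("Degenerate axis: zero variance.")
  z1 <- (v1 - std$center[1]) / std$scale[1]
  z2 <- (v2 - std$center[2]) / std$scale[2]
  dens <- estimate_density(cbind(z1, z2), t = t, grid_n = grid_n)
  map <- structure(list(
    distance = distance, angle = angle,
    points = tibble::tibble(nucleus_id = geom$nucleus_id,
                            v1 = v1, v2 = v2, z1 = z1, z2 = z2,
                            f = dens$f_points, level = NA_integer_),
    std = std, t = dens$t,
    grid = dens$grid, grid_x = dens$grid_x, grid_y = dens$grid_y,
    M = nrow(geom)
  ), class = "trilocus_map")
  map <- decile_regions(map)
  map$stats <- level_statistics(map)
  map
}

#' All nine (distance, angle) maps of one dataset
#'
#' The full battery of projections: each of the three distances against each
#' of the three angles.
#'
#' @inheritParams build_map
#' @param ... Passed to [build_map()].
#' @return A tibble with columns `distance`, `angle` and a `map` list-column
#'   of nine `trilocus_map` objects.
#' @export
build_all_maps <- function(ds, ...) {
  geom <- if (inherits(ds, "triplet_df")) dataset_geometry(ds) else tibble::as_tibble(ds)
  combos <- tidyr::expand_grid(distance = c("d_rg", "d_rb", "d_gb"),
                               angle = c("theta_r", "theta_g", "theta_b"))
  combos$map <- purrr::pmap(combos, function(distance, angle) {
    build_map(geom, distance = distance, angle = angle, ...)
  })
  combos
}

#' @export
print.trilocus_map <- function(x, ...) {
  cli::cli_inform(c(
    "i" = "Density map {x$distance} vs {x$angle}: M = {x$M}, t = {signif(x$t, 4)}",
    "i" = "Level cards: {paste(x$stats$card, collapse = ', ')}"
  ))
  invisible(x)
}

#' Tidy a density map: its per-level statistics
#' @param x A `trilocus_map`.
#' @param ... Unused.
#' @export
tidy.trilocus_map <- function(x, ...) {
  dplyr::mutate(x$stats, distance = x$distance, angle = x$angle,
                .before = "level")
}

#' One-row summary of a density map
#' @param x A `trilocus_map`.
#' @param ... Unused.
#' @export
glance.trilocus_map <- function(x, ...) {
  tibble::tibble(distance = x$distance, angle = x$angle, M = x$M,
                 t = x$t, grid_n = if (is.null(x$grid)) 0L else length(x$grid_x))
}

#' Plot a density map
#'
#' Filled density field (if a lattice was computed) with the observation
#' points coloured by decile occupancy level (warm = dense).  Angles are
#' shown in degrees.
#'
#' @param object A `trilocus_map`.
#' @param ... Unused.
#' @export
autoplot.trilocus_map <- function(object, ...) {
  pts <- object$points
  pts$v2_deg <- pts$v2 * 180 / pi
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$v1, .data$v2_deg))
  if (!is.null(object$grid)) {
    g <- object$grid
    g$v1 <- g$x * object$std$scale[1] + object$std$center[1]
    g$v2_deg <- (g$y * object$std$scale[2] + object$std$center[2]) * 180 / pi
    p <- p + ggplot2::geom_raster(data = g, ggplot2::aes(.data$v1, .data$v2_deg, fill = .data$f)) +
      ggplot2::scale_fill_viridis_c(option = "magma")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$level)), size = 0.8) +
    ggplot2::scale_colour_viridis_d(option = "plasma", direction = -1,
                                    name = "decile level") +
    ggplot2::labs(x = paste0(object$distance, " (µm)"),
                  y = paste0(object$angle, " (deg)"),
                  fill = "density") +
    ggplot2::theme_minimal()
}

#' Export a density map (lattice + sidecar + point levels)
#'
#' Writes the lattice density as a dense TSV matrix, a JSON sidecar with the
#' axes, standardisation, bandwidth and level cardinalities, and the
#' per-point levels as TSV.
#'
#' @param map A `trilocus_map` built with `grid_n > 0`.
#' @param prefix Output path prefix; writes `<prefix>_field.tsv`,
#'   `<prefix>_levels.tsv`, `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_map <- function(map, prefix) {
  stopifnot(inherits(map, "trilocus_map"))
  if (!is.null(map$grid)) {
    fmat <- matrix(map$grid$f, nrow = length(map$grid_x))
    readr::write_tsv(tibble::as_tibble(fmat, .name_repair = "minimal"),
                     paste0(prefix, "_field.tsv"), col_names = FALSE,
                     progress = FALSE)
  }
  readr::write_tsv(map$points[c("nucleus_id", "level")],
                   paste0(prefix, "_levels.tsv"), progress = FALSE)
  sidecar <- list(distance = map$distance, angle = map$angle, M = map$M,
                  t = map$t,
                  standardization = list(center = map$std$center,
                                         scale = map$std$scale),
                  level_card = map$stats$card)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(prefix)
}
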