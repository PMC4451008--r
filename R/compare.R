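#' Level correlation between two density maps
#'
#' Ratio-of-level-statistics similarity between level `k1` of experiment A
#' and level `k2` of experiment B.  The first approximation multiplies, over
#' the two axes, the ratios `min(|mu_A|, |mu_B|) / max(|mu_A|, |mu_B|)` of
#' the level means; the second approximation additionally multiplies the
#' analogous ratios of the level standard deviations.  Both lie in \[0, 1\],
#' equal 1 iff the level statistics coincide, and satisfy `rho2 <= rho1`.
#'
#' @param stats_a,stats_b Level-statistics tibbles from [level_statistics()]
#'   (columns `level`, `card`, `mu_x`, `mu_y`, `sigma_x`, `sigma_y`), in
#'   identical units.
#' @param k1,k2 Level indices in 1..10 (A's level and B's level).
#' @return A one-row tibble: `k1`, `k2`, `rho1`, `rho2`.
#' @export
level_correlation <- function(stats_a, stats_b, k1, k2 = k1) {
  ra <- stats_a[stats_a$level == k1, ]
  rb <- stats_b[stats_b$level == k2, ]
  if (nrow(ra) != 1 || nrow(rb) != 1 || ra$card == 0 || rb$card == 0) {
    cli::cli_abort("Both levels must be defined (card > 0).")
  }
  mu_ratio <- function(a, b) {
    if (a == 0 || b == 0) {
      cli::cli_abort("Level mean of exactly 0: ratio statistic undefined.")
    }
    min(abs(a), abs(b)) / max(abs(a), abs(b))
  }
  sd_ratio <- function(a, b) {
    if (a == b) return(1)  # covers the degenerate 0/0 case
    min(a, b) / max(a, b)
  }
  rho1 <- mu_ratio(ra$mu_x, rb$mu_x) * mu_ratio(ra$mu_y, rb$mu_y)
  rho2 <- rho1 * sd_ratio(ra$sigma_x, rb$sigma_x) * sd_ratio(ra$sigma_y, rb$sigma_y)
  tibble::tibble(k1 = k1, k2 = k2, rho1 = rho1, rho2 = rho2)
}

#' Compare two experiments' density-map batteries
#'
#' Builds the nine (distance, angle) density maps of each experiment in a
#' common frame — pooled per-axis standardisation and a shared bandwidth
#' (Scott's rule on the pooled standardised sample unless `t` is given) —
#' then reports the diagonal level correlations (k1 = k2 = k, k = 1..10) for
#' every map, and the headline correlation factor `c` of each map at the 30%
#' level (k = 3).  `c` is the stricter second-approximation `rho2`; `rho1`
#' is reported alongside.
#'
#' @param ds_a,ds_b `triplet_df` datasets with identical `label_map`s.
#' @param t Shared kernel variance, `NULL` for Scott's rule on the pooled
#'   sample (per projection).
#' @param grid_n Lattice resolution for the stored maps (level statistics
#'   are grid-free; default 0 skips the lattice).
#' @return A `trilocus_comparison`: list with `levels` (tibble `distance`,
#'   `angle`, `level`, `rho1`, `rho2`), `headline` (per-map `c` at k = 3),
#'   and `t_used`.  `tidy()` returns `levels`, `glance()` a one-row summary
#'   with the median headline `c`.
#' @export
compare_experiments <- function(ds_a, ds_b, t = NULL, grid_n = 0) {
  assert_triplet_df(ds_a); assert_triplet_df(ds_b)
  if (!identical(label_map(ds_a), label_map(ds_b))) {
    cli::cli_abort("label_maps differ: the two experiments' loci do not correspond.")
  }
  geom_a <- dataset_geometry(ds_a)
  geom_b <- dataset_geometry(ds_b)
  if (nrow(geom_a) < 10 || nrow(geom_b) < 10) {
    cli::cli_abort("Both experiments need at least 10 usable nuclei.")
  }
  combos <- tidyr::expand_grid(distance = c("d_rg", "d_rb", "d_gb"),
                               angle = c("theta_r", "theta_g", "theta_b"))
  res <- purrr::pmap(combos, function(distance, angle) {
    pooled1 <- c(geom_a[[distance]], geom_b[[distance]])
    pooled2 <- c(geom_a[[angle]], geom_b[[angle]])
    std <- list(center = c(mean(pooled1), mean(pooled2)),
                scale = c(stats::sd(pooled1), stats::sd(pooled2)))
    t_use <- t
    if (is.null(t_use)) t_use <- length(pooled1)^(-1 / 3)
    map_a <- build_map(geom_a, distance, angle, t = t_use, grid_n = grid_n, std = std)
    map_b <- build_map(geom_b, distance, angle, t = t_use, grid_n = grid_n, std = std)
    lv <- purrr::map_dfr(1:10, function(k) {
      level_correlation(map_a$stats, map_b$stats, k, k)
    })
    list(levels = dplyr::mutate(lv, distance = distance, angle = angle,
                                level = .data$k1, .before = "k1"),
         t_used = t_use)
  })
  levels <- dplyr::select(purrr::list_rbind(purrr::map(res, "levels")),
                          -"k1", -"k2")
  headline <- dplyr::rename(
    dplyr::filter(levels, .data$level == 3), c = "rho2")
  structure(list(levels = levels, headline = headline,
                 t_used = purrr::map_dbl(res, "t_used"),
                 M = c(A = nrow(geom_a), B = nrow(geom_b))),
            class = "trilocus_comparison")
}

#' @export
print.trilocus_comparison <- function(x, ...) {
  cli::cli_inform(c(
    "i" = "Map comparison over 9 projections (M = {x$M[['A']]} vs {x$M[['B']]})",
    "i" = "Headline c (30% level): median {signif(stats::median(x$headline$c), 3)}"
  ))
  print(x$headline)
  invisible(x)
}

#' @rdname compare_experiments
#' @param x A `trilocus_comparison`.
#' @param ... Unused.
#' @export
tidy.trilocus_comparison <- function(x, ...) x$levels

#' @rdname compare_experiments
#' @export
glance.trilocus_comparison <- function(x, ...) {
  tibble::tibble(
    n_maps = nrow(x$headline),
    c_median = stats::median(x$headline$c),
    c_min = min(x$headline$c),
    c_max = max(x$headline$c),
    M_a = x$M[["A"]], M_b = x$M[["B"]]
  )
}

#' Plot per-level correlations of a comparison
#'
#' @param object A `trilocus_comparison`.
#' @param ... Unused.
#' @export
autoplot.trilocus_comparison <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(.data$level, .data$rho2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.6, 0.7),
                        linetype = "dotted", colour = "red") +
    ggplot2::facet_grid(ggplot2::vars(.data$distance), ggplot2::vars(.data$angle)) +
    ggplot2::scale_x_continuous(breaks = c(1, 3, 5, 7, 9)) +
    ggplot2::labs(x = "occupancy level k (k/10 of sample)",
                  y = expression(rho[2])) +
    ggplot2::theme_minimal()
}

#' 3D highest-density-region overlap of two experiments
#'
#' Kernel density on the standardised distance triple (d_rg, d_rb, d_gb)
#' of each experiment (pooled standardisation, shared Scott bandwidth).
#' The HDR of each sample is the set of its points above the density
#' threshold that captures fraction `mass` of the sample.  Reports, for each
#' dataset, the fraction of its HDR points that also clear the other
#' dataset's threshold, plus the Jaccard overlap of the lattice cells above
#' the two thresholds.
#'
#' @param ds_a,ds_b `triplet_df` datasets.
#' @param mass HDR mass fraction, in (0, 1).
#' @param grid_n Lattice resolution per axis for the Jaccard overlap.
#' @param t Kernel variance, `NULL` for the 3D Scott's rule on the pooled
#'   sample.
#' @return A one-row tibble: `mass`, `cross_a_in_b`, `cross_b_in_a`,
#'   `jaccard`, `t`.
#' @export
hdr3d_overlap <- function(ds_a, ds_b, mass = 0.5, grid_n = 24, t = NULL) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    cli::cli_abort("mass must lie strictly between 0 and 1.")
  }
  geom_a <- dataset_geometry(ds_a)
  geom_b <- dataset_geometry(ds_b)
  vars <- c("d_rg", "d_rb", "d_gb")
  pooled <- rbind(as.matrix(geom_a[vars]), as.matrix(geom_b[vars]))
  center <- colMeans(pooled)
  scale <- apply(pooled, 2, stats::sd)
  za <- sweep(sweep(as.matrix(geom_a[vars]), 2, center), 2, scale, `/`)
  zb <- sweep(sweep(as.matrix(geom_b[vars]), 2, center), 2, scale, `/`)
  if (is.null(t)) t <- (nrow(pooled)^(-1 / 7))^2
  fa <- gauss_kde_eval(za, za, t)
  fb <- gauss_kde_eval(zb, zb, t)
  thr <- function(f, mass) sort(f, decreasing = TRUE)[ceiling(mass * length(f))]
  ta_ <- thr(fa, mass); tb_ <- thr(fb, mass)
  in_a <- fa >= ta_
  in_b <- fb >= tb_
  cross_a_in_b <- mean(gauss_kde_eval(za[in_a, , drop = FALSE], zb, t) >= tb_)
  cross_b_in_a <- mean(gauss_kde_eval(zb[in_b, , drop = FALSE], za, t) >= ta_)
  rng <- apply(rbind(za, zb), 2, range)
  pad <- 3 * sqrt(t)
  axes <- lapply(1:3, function(j) {
    seq(rng[1, j] - pad, rng[2, j] + pad, length.out = grid_n)
  })
  lattice <- as.matrix(expand.grid(axes))
  la <- gauss_kde_eval(lattice, za, t) >= ta_
  lb <- gauss_kde_eval(lattice, zb, t) >= tb_
  jac <- if (any(la | lb)) sum(la & lb) / sum(la | lb) else 0
  tibble::tibble(mass = mass, cross_a_in_b = cross_a_in_b,
                 cross_b_in_a = cross_b_in_a, jaccard = jac, t = t)
}

#' Distance and angle Wilcoxon battery
#'
#' For each of the three inter-locus distances and three interior angles:
#' the two samples' medians and interquartile ranges, and the two-sided
#' Wilcoxon rank-sum p-value comparing the experiments.  The exact test is
#' used when both groups have fewer than 25 observations (falling back to
#' the tie-corrected normal approximation when ties are present); otherwise
#' the normal approximation with continuity correction.  P-values are raw —
#' no multiple-testing correction is applied across the battery.
#'
#' @param ds_a,ds_b `triplet_df` datasets.
#' @return A tibble: `variable`, `median_a`, `median_b`, `iqr_a`, `iqr_b`,
#'   `p_value`.
#' @export
pairwise_tests <- function(ds_a, ds_b) {
  geom_a <- dataset_geometry(ds_a)
  geom_b <- dataset_geometry(ds_b)
  vars <- c("d_rg", "d_rb", "d_gb", "theta_r", "theta_g", "theta_b")
  purrr::map_dfr(vars, function(v) {
    a <- geom_a[[v]]; b <- geom_b[[v]]
    exact <- length(a) < 25 && length(b) < 25
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value
    )
    tibble::tibble(
      variable = v,
      median_a = stats::median(a), median_b = stats::median(b),
      iqr_a = stats::IQR(a), iqr_b = stats::IQR(b),
      p_value = p
    )
  })
}
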