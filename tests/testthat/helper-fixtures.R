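# fixtures are generated in code; nothing is read from disk

# a small valid dataset with coordinates uniform in a 2 um cube
make_cube_ds <- function(n = 20, seed = 1) {
  coords <- withr::with_seed(seed, matrix(stats::runif(n * 9, 0, 2), n, 9))
  colnames(coords) <- c("x_r", "y_r", "z_r", "x_g", "y_g", "z_g",
                        "x_b", "y_b", "z_b")
  df <- tibble::as_tibble(coords)
  df$nucleus_id <- sprintf("nuc%03d", seq_len(n))
  triplet_dataset(df, strain_id = "cube_fixture")
}

# right triangle: d_rg = 5, d_rb = 5, theta_r = pi/2
ortho_triplet <- list(r = c(0, 0, 0), g = c(3, 4, 0), b = c(0, 0, 5))

# unit equilateral triangle in the xy-plane
equi_triplet <- list(r = c(0, 0, 0), g = c(1, 0, 0), b = c(0.5, sqrt(3) / 2, 0))

ds_from_triplets <- function(...) {
  tps <- list(...)
  df <- purrr::imap_dfr(tps, function(tp, i) {
    tibble::tibble(nucleus_id = paste0("n", i),
                   x_r = tp$r[1], y_r = tp$r[2], z_r = tp$r[3],
                   x_g = tp$g[1], y_g = tp$g[2], z_g = tp$g[3],
                   x_b = tp$b[1], y_b = tp$b[2], z_b = tp$b[3])
  })
  triplet_dataset(df)
}

# independent scalar oracle for the triangle variables of one nucleus
scalar_triangle_oracle <- function(r, g, b) {
  d <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
  ang <- function(v, p, q) {
    num <- sum((p - v) * (q - v))
    den <- d(v, p) * d(v, q)
    acos(max(-1, min(1, num / den)))
  }
  c(d_rg = d(r, g), d_rb = d(r, b), d_gb = d(g, b),
    theta_r = ang(r, g, b), theta_g = ang(g, r, b), theta_b = ang(b, r, g))
}

# minimal density-map object for direct level_statistics checks
fake_map <- function(v1, v2, level) {
  structure(list(
    distance = "d_rg", angle = "theta_r",
    points = tibble::tibble(nucleus_id = as.character(seq_along(v1)),
                            v1 = v1, v2 = v2, z1 = v1, z2 = v2,
                            f = rev(seq_along(v1)), level = level),
    std = list(center = c(0, 0), scale = c(1, 1)),
    t = 1, grid = NULL, M = length(v1)
  ), class = "trilocus_map")
}
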