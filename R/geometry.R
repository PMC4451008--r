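#' Triangle variables of one nucleus
#'
#' Converts the microscope-frame coordinates of one nucleus's three spots
#' into the frame-invariant triangle variables: the three inter-locus
#' distances and the three interior angles.  Distances are Euclidean norms of
#' the difference vectors; each angle is the arccos of the normalised scalar
#' product of the two edge vectors meeting at that vertex, with the argument
#' clamped to \[-1, 1\] to absorb floating-point overshoot on near-collinear
#' triangles.  Collinear triangles (an angle of 0 or pi) are valid.
#'
#' @param r,g,b Numeric length-3 vectors: the (x, y, z) positions (um) of the
#'   red, green and blue spots.
#' @return A one-row tibble with `d_rg`, `d_rb`, `d_gb` (um) and `theta_r`,
#'   `theta_g`, `theta_b` (radians).
#' @export
#' @examples
#' triangle_geometry(c(0, 0, 0), c(3, 4, 0), c(0, 0, 5))
triangle_geometry <- function(r, g, b) {
  stopifnot(length(r) == 3, length(g) == 3, length(b) == 3)
  v_rg <- g - r
  v_rb <- b - r
  v_gb <- b - g
  d_rg <- sqrt(sum(v_rg^2))
  d_rb <- sqrt(sum(v_rb^2))
  d_gb <- sqrt(sum(v_gb^2))
  pairs <- c(`r-g` = d_rg, `r-b` = d_rb, `g-b` = d_gb)
  if (any(pairs == 0)) {
    bad <- names(pairs)[pairs == 0][1]
    cli::cli_abort("Degenerate geometry: spots {bad} are coincident.")
  }
  clamp <- function(x) pmin(1, pmax(-1, x))
  theta_r <- acos(clamp(sum(v_rg * v_rb) / (d_rg * d_rb)))
  theta_g <- acos(clamp(sum(-v_rg * v_gb) / (d_rg * d_gb)))
  theta_b <- acos(clamp(sum(v_rb * v_gb) / (d_rb * d_gb)))
  tibble::tibble(d_rg = d_rg, d_rb = d_rb, d_gb = d_gb,
                 theta_r = theta_r, theta_g = theta_g, theta_b = theta_b)
}

#' Triangle variables for every nucleus of a dataset
#'
#' Vectorised conversion of a whole triplet dataset to its geometry table.
#' Nuclei with coincident spots are skipped with a message; the skip count is
#' attached as the `"skipped_degenerate"` attribute.
#'
#' @param ds A `triplet_df`.
#' @return A tibble with one row per non-degenerate nucleus: `nucleus_id`,
#'   the three distances (um) and the three angles (radians), in input order.
#' @export
dataset_geometry <- function(ds) {
  assert_triplet_df(ds)
  if (nrow(ds) == 0) cli::cli_abort("Dataset is empty.")
  R <- channel_matrix(ds, "r")
  G <- channel_matrix(ds, "g")
  B <- channel_matrix(ds, "b")
  v_rg <- G - R; v_rb <- B - R; v_gb <- B - G
  d_rg <- sqrt(rowSums(v_rg^2))
  d_rb <- sqrt(rowSums(v_rb^2))
  d_gb <- sqrt(rowSums(v_gb^2))
  ok <- is.finite(d_rg) & is.finite(d_rb) & is.finite(d_gb) &
    d_rg > 0 & d_rb > 0 & d_gb > 0
  clamp <- function(x) pmin(1, pmax(-1, x))
  theta_r <- acos(clamp(rowSums(v_rg * v_rb) / (d_rg * d_rb)))
  theta_g <- acos(clamp(rowSums(-v_rg * v_gb) / (d_rg * d_gb)))
  theta_b <- acos(clamp(rowSums(v_rb * v_gb) / (d_rb * d_gb)))
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    cli::cli_inform("Skipped {n_skip} degenerate nucle{?us/i}.")
  }
  out <- tibble::tibble(
    nucleus_id = ds$nucleus_id,
    d_rg = d_rg, d_rb = d_rb, d_gb = d_gb,
    theta_r = theta_r, theta_g = theta_g, theta_b = theta_b
  )[ok, , drop = FALSE]
  attr(out, "skipped_degenerate") <- n_skip
  out
}

#' Per-node distance/angle variables
#'
#' For local analysis around one vertex (node) of the closed three-node
#' polygon, each node i carries the two adjacent side lengths and its
#' interior angle.  Nodes map to channels 1=r, 2=g, 3=b; with sides named by
#' their endpoints, node 1 gets (d_rg, d_rb), node 2 gets (d_gb, d_rg) and
#' node 3 gets (d_rb, d_gb), so across the three nodes each side appears
#' exactly twice.
#'
#' @param geom A geometry table from [dataset_geometry()] (or any tibble with
#'   the six variable columns).
#' @param node Node index 1, 2 or 3.
#' @return A tibble `nucleus_id` (if present), `node`, `d_i1`, `d_i2` (um),
#'   `theta_i` (radians).
#' @export
node_variables <- function(geom, node) {
  if (!is.numeric(node) || length(node) != 1 || !node %in% 1:3) {
    cli::cli_abort("node must be 1, 2 or 3.")
  }
  cols <- switch(node,
                 list(d1 = "d_rg", d2 = "d_rb", th = "theta_r"),
                 list(d1 = "d_gb", d2 = "d_rg", th = "theta_g"),
                 list(d1 = "d_rb", d2 = "d_gb", th = "theta_b"))
  out <- tibble::tibble(
    node = as.integer(node),
    d_i1 = geom[[cols$d1]],
    d_i2 = geom[[cols$d2]],
    theta_i = geom[[cols$th]]
  )
  if ("nucleus_id" %in% names(geom)) {
    out <- dplyr::bind_cols(tibble::tibble(nucleus_id = geom$nucleus_id), out)
  }
  out
}

#' Export a geometry table as TSV (angles in degrees)
#'
#' @param geom A geometry table from [dataset_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry_table <- function(geom, path) {
  out <- tibble::tibble(
    nucleus_id = geom$nucleus_id,
    d_rg = geom$d_rg, d_rb = geom$d_rb, d_gb = geom$d_gb,
    theta_r_deg = geom$theta_r * 180 / pi,
    theta_g_deg = geom$theta_g * 180 / pi,
    theta_b_deg = geom$theta_b * 180 / pi
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
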