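#' Simulation specification for survival-zone datasets
#'
#' Bundles everything [simulate_from_zones()] needs: the generating zone
#' model, the number of nuclei, the localisation-noise level, the
#' model-unit-to-micrometre scale and the seed.  The default scale of
#' 0.18 um per model unit places the 0-5 model span (~0.9 um) comfortably
#' inside a ~2 um nucleus.
#'
#' @param model A `survival_zone_model`.
#' @param n Number of nuclei (>= 1).
#' @param noise_sd Gaussian localisation noise SD in model units (lateral
#'   axes); 0 disables noise.
#' @param noise_z_factor Multiplier on `noise_sd` for the axial (z)
#'   component; 2 mimics the coarser focal stepping of 3D stack
#'   acquisition.
#' @param scale Micrometres per model unit (> 0).
#' @param translation_box Half-width (um) of the uniform per-nucleus
#'   translation cube.
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(model, n = 500, noise_sd = 0, noise_z_factor = 1,
                            scale = 0.18, translation_box = 2, seed = 1L) {
  stopifnot(inherits(model, "survival_zone_model"), n >= 1,
            noise_sd >= 0, scale > 0)
  structure(list(model = model, n = as.integer(n), noise_sd = noise_sd,
                 noise_z_factor = noise_z_factor, scale = scale,
                 translation_box = translation_box, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a triplet dataset from survival zones
#'
#' Per nucleus: draw one abstract configuration (each node uniform in its
#' rectangle), lift the planar points to 3D (z = 0), scale to micrometres,
#' apply an independent uniformly random rigid motion (rotation from the
#' full rotation group plus a uniform translation), and add Gaussian
#' localisation noise in the microscope frame.  Because the analysis
#' variables are frame-invariant, with zero noise the simulated dataset's
#' geometry equals the planar configurations' geometry exactly.
#'
#' @param spec A [simulation_spec()].
#' @return A `triplet_df` with the spec recorded in attribute
#'   `"simulation_spec"`.
#' @export
simulate_from_zones <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n
  withr::with_seed(spec$seed, {
    u <- matrix(stats::runif(n * 6), n, 6)
    pts <- configs_from_uniforms(u, model_centers(spec$model),
                                 model_eps(spec$model)) * spec$scale
    rot <- random_rotations(n)
    trans <- matrix(stats::runif(n * 3, 0, spec$translation_box), n, 3)
    coords <- matrix(NA_real_, n, 9)
    for (ch in 1:3) {
      p <- cbind(pts[, 2 * ch - 1], pts[, 2 * ch], 0)
      coords[, (3 * ch - 2):(3 * ch)] <- rotate_rows(p, rot) + trans
    }
    if (spec$noise_sd > 0) {
      sd_um <- spec$noise_sd * spec$scale
      noise <- matrix(stats::rnorm(n * 9), n, 9)
      sds <- rep(c(sd_um, sd_um, sd_um * spec$noise_z_factor), 3)
      coords <- coords + sweep(noise, 2, sds, `*`)
    }
  })
  colnames(coords) <- coord_cols()  # x_r, y_r, z_r, x_g, ..., z_b
  df <- tibble::as_tibble(coords)
  df <- dplyr::bind_cols(
    tibble::tibble(nucleus_id = sprintf("sim_%05d", seq_len(n))), df)
  ds <- triplet_dataset(df, strain_id = "synthetic_zones")
  attr(ds, "simulation_spec") <- spec
  ds
}

#' The three constraint regimes used in fiber-flexibility simulations
#'
#' Three generating zone models for a flexible, a moderately constrained and
#' a constrained fiber.  The moderately constrained regime uses the
#' rectangles Z1 = \[-1;1\] x \[-1;1\], Z2 = \[-1;5\] x \[-1;5\],
#' Z3 = \[3.5;6.5\] x \[-1.5;1.5\].  The flexible and constrained regimes
#' keep the same zone centres and scale the half-widths up (x2) or down
#' (x0.5) respectively, so total zone area orders
#' flexible > moderate > constrained.
#'
#' @return A named list of three `survival_zone_model`s.
#' @export
s4_regimes <- function() {
  centers <- list(c(0, 0), c(2, 2), c(5, 0))
  eps_moderate <- list(c(1, 1), c(3, 3), c(1.5, 1.5))
  make <- function(f) {
    survival_zone_model(purrr::map2(centers, eps_moderate, function(ctr, e) {
      survival_zone(ctr, min(5, e[1] * f), min(5, e[2] * f))
    }))
  }
  list(flexible = make(2), moderate = make(1), constrained = make(0.5))
}

#' Null control: three loci uniform in a sphere
#'
#' Draws, for each nucleus, the three loci independently and uniformly
#' inside a sphere (default 2 um diameter) — the random-positioning control
#' against which experimental density maps are compared.
#'
#' @param n Number of nuclei.
#' @param diameter Sphere diameter in micrometres.
#' @param seed Integer seed.
#' @return A `triplet_df`.
#' @export
random_sphere_dataset <- function(n, diameter = 2, seed = 1L) {
  stopifnot(n >= 1, diameter > 0)
  R <- diameter / 2
  coords <- withr::with_seed(seed, {
    dir <- matrix(stats::rnorm(n * 9), n * 3, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- R * stats::runif(n * 3)^(1 / 3)
    matrix(t(dir * r), n, 9, byrow = TRUE)
  })
  # layout per nucleus: (x,y,z) of r, then g, then b
  df <- tibble::tibble(
    nucleus_id = sprintf("sph_%05d", seq_len(n)),
    x_r = coords[, 1], y_r = coords[, 2], z_r = coords[, 3],
    x_g = coords[, 4], y_g = coords[, 5], z_g = coords[, 6],
    x_b = coords[, 7], y_b = coords[, 8], z_b = coords[, 9]
  )
  triplet_dataset(df, strain_id = "random_sphere")
}

#' Re-embed every nucleus in a random rigid frame
#'
#' Applies one shared uniformly random rotation and translation to each
#' nucleus's three spots, emulating the arbitrary per-nucleus orientation of
#' the acquisition frame.  The triangle geometry is preserved exactly.
#'
#' @param ds A `triplet_df`.
#' @param seed Integer seed.
#' @param translation_box Half-width (um) of the uniform translation cube.
#' @return A `triplet_df` with transformed coordinates.
#' @export
apply_random_frames <- function(ds, seed = 1L, translation_box = 2) {
  assert_triplet_df(ds)
  n <- nrow(ds)
  out <- tibble::as_tibble(ds)
  withr::with_seed(seed, {
    rot <- random_rotations(n)
    trans <- matrix(stats::runif(n * 3, 0, translation_box), n, 3)
  })
  for (ch in c("r", "g", "b")) {
    p <- channel_matrix(ds, ch)
    q <- rotate_rows(p, rot) + trans
    out[paste(c("x", "y", "z"), ch, sep = "_")] <- q
  }
  res <- triplet_dataset(out, label_map = label_map(ds), strain_id = strain_id(ds))
  res
}

# n rotation matrices drawn uniformly from SO(3) via unit quaternions,
# returned as an n x 9 matrix (row-major 3x3)
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(n * 4), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  )
}

# apply per-row rotation matrices (n x 9) to per-row points (n x 3)
rotate_rows <- function(p, rot) {
  cbind(
    rot[, 1] * p[, 1] + rot[, 2] * p[, 2] + rot[, 3] * p[, 3],
    rot[, 4] * p[, 1] + rot[, 5] * p[, 2] + rot[, 6] * p[, 3],
    rot[, 7] * p[, 1] + rot[, 8] * p[, 2] + rot[, 9] * p[, 3]
  )
}

#' Write a simulated dataset plus its ground-truth sidecar
#'
#' Emits the canonical simple TSV and a JSON sidecar recording the full
#' simulation specification (the ground truth for recovery tests).
#'
#' @param ds A simulated `triplet_df` (from [simulate_from_zones()]).
#' @param path TSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(ds, path) {
  write_triplet_table(ds, path)
  spec <- attr(ds, "simulation_spec")
  if (!is.null(spec)) {
    side <- list(
      n = spec$n, noise_sd = spec$noise_sd,
      noise_z_factor = spec$noise_z_factor, scale = spec$scale,
      translation_box = spec$translation_box, seed = spec$seed,
      zones = lapply(spec$model$zones, function(z) {
        list(center = z$center, eps1 = z$eps1, eps2 = z$eps2)
      })
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = 12)
  }
  invisible(path)
}
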