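#' Build a three-locus triplet dataset
#'
#' A triplet dataset holds, for each scored nucleus, the 3D microscope-frame
#' coordinates (micrometres) of three fluorescently tagged loci, one per
#' colour channel `r`, `g`, `b`.  It is an ordinary tibble (one row per
#' nucleus, columns `nucleus_id`, `x_r` ... `z_b`) carrying a channel-to-locus
#' `label_map` and a `strain_id` as attributes, so it pipes through dplyr
#' verbs like any other data frame.
#'
#' @param coords A data frame with columns `nucleus_id` and the nine
#'   coordinate columns `x_r, y_r, z_r, x_g, y_g, z_g, x_b, y_b, z_b`
#'   (micrometres).  An optional `cell_cycle_tag` column is kept.
#' @param label_map Named character vector mapping the channels `r`, `g`, `b`
#'   to locus names, e.g. `c(r = "HML", g = "MAT", b = "HMR")`.
#' @param strain_id Free-text strain or condition identifier.
#'
#' @return A `triplet_df` tibble.
#' @seealso [read_triplet_table()], [qc_filter()], [dataset_geometry()]
#' @export
#' @examples
#' ds <- triplet_dataset(tibble::tibble(
#'   nucleus_id = "n1",
#'   x_r = 0, y_r = 0, z_r = 0,
#'   x_g = 0.5, y_g = 0, z_g = 0,
#'   x_b = 0.2, y_b = 0.4, z_b = 0
#' ))
#' n_nuclei(ds)
triplet_dataset <- function(coords,
                            label_map = c(r = "HML", g = "MAT", b = "HMR"),
                            strain_id = "unspecified") {
  coords <- tibble::as_tibble(coords)
  missing_cols <- setdiff(c("nucleus_id", coord_cols()), names(coords))
  if (length(missing_cols) > 0) {
    cli::cli_abort("coords is missing column{?s} {.field {missing_cols}}.")
  }
  if (anyDuplicated(coords$nucleus_id)) {
    cli::cli_abort("nucleus_id values must be unique.")
  }
  if (!setequal(names(label_map), c("r", "g", "b"))) {
    cli::cli_abort("label_map must name exactly the channels r, g and b.")
  }
  coords$nucleus_id <- as.character(coords$nucleus_id)
  keep <- intersect(c("nucleus_id", coord_cols(), "cell_cycle_tag"), names(coords))
  new_triplet_df(coords[keep], label_map = label_map[c("r", "g", "b")],
                 strain_id = strain_id)
}

new_triplet_df <- function(x, label_map, strain_id) {
  structure(x,
            label_map = label_map,
            strain_id = strain_id,
            class = c("triplet_df", class(tibble::tibble())))
}

coord_cols <- function() {
  as.vector(outer(c("x", "y", "z"), c("r", "g", "b"), paste, sep = "_"))
}

#' @rdname triplet_dataset
#' @param ds A `triplet_df`.
#' @export
n_nuclei <- function(ds) nrow(ds)

#' @rdname triplet_dataset
#' @export
label_map <- function(ds) attr(ds, "label_map")

#' @rdname triplet_dataset
#' @export
strain_id <- function(ds) attr(ds, "strain_id")

#' @export
print.triplet_df <- function(x, ...) {
  lm <- label_map(x)
  cli::cli_inform(c(
    "i" = "Triplet dataset: {nrow(x)} nucle{?us/i}, strain {.val {strain_id(x)}}",
    "i" = "Channels: r={lm[['r']]}, g={lm[['g']]}, b={lm[['b']]}"
  ))
  NextMethod()
}

# keep attributes through dplyr-style subsetting
#' @export
`[.triplet_df` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("nucleus_id", coord_cols()) %in% names(out))) {
    out <- new_triplet_df(out, label_map(x), strain_id(x))
  }
  out
}

# extract the n x 3 coordinate matrix of one channel
channel_matrix <- function(ds, channel) {
  as.matrix(ds[paste(c("x", "y", "z"), channel, sep = "_")])
}

assert_triplet_df <- function(ds, arg = rlang::caller_arg(ds)) {
  if (!inherits(ds, "triplet_df")) {
    cli::cli_abort("{.arg {arg}} must be a triplet_df (see {.fn triplet_dataset}).")
  }
  invisible(ds)
}
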