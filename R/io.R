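#' Read a per-nucleus three-channel spot-coordinate table
#'
#' Reads the canonical tab-separated format for three-colour spot
#' localisation: one row per nucleus per channel, columns `nucleus_id`,
#' `channel` (one of `r`, `g`, `b`), `x`, `y`, `z` in micrometres
#' (`dialect = "simple"`), or one row per nucleus with per-channel coordinate
#' blocks `x_r, y_r, z_r, ..., z_b` (`dialect = "spotdistance"`, the layout
#' produced by spot-distance style measurement tools).
#'
#' Nuclei missing one or more channels cannot enter the triangle analysis and
#' are dropped with a message; their ids are recorded in the
#' `"dropped_incomplete"` attribute of the result.  Row order (first
#' appearance of each nucleus) is preserved.
#'
#' @param path Path to a TSV file.
#' @param dialect `"simple"` (long, default) or `"spotdistance"` (wide).
#' @param label_map,strain_id Passed to [triplet_dataset()].
#' @return A `triplet_df`.
#' @export
read_triplet_table <- function(path, dialect = c("simple", "spotdistance"),
                               label_map = c(r = "HML", g = "MAT", b = "HMR"),
                               strain_id = "unspecified") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cli::cli_abort("File {.path {path}} does not exist.")
  if (dialect == "spotdistance") {
    return(read_spotdistance(path, label_map, strain_id))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("nucleus_id", "channel", "x", "y", "z")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    cli::cli_abort("Malformed table: missing column{?s} {.field {missing_cols}}.")
  }
  bad_channel <- which(!raw$channel %in% c("r", "g", "b"))
  if (length(bad_channel) > 0) {
    cli::cli_abort("Malformed table: channel must be r, g or b (row{?s} {bad_channel}).")
  }
  dup <- duplicated(raw[c("nucleus_id", "channel")])
  if (any(dup)) {
    cli::cli_abort("Malformed table: duplicate (nucleus_id, channel) at row{?s} {which(dup)}.")
  }
  for (cc in c("x", "y", "z")) {
    num <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(num) & !is.na(raw[[cc]]))
    if (length(bad) > 0) {
      cli::cli_abort("Malformed table: non-numeric {.field {cc}} at row{?s} {bad}.")
    }
    raw[[cc]] <- num
  }
  wide <- tidyr::pivot_wider(raw,
                             id_cols = "nucleus_id",
                             names_from = "channel",
                             values_from = c("x", "y", "z"),
                             names_sep = "_")
  complete <- stats::complete.cases(wide[intersect(coord_cols(), names(wide))]) &
    all(coord_cols() %in% names(wide))
  incomplete_ids <- wide$nucleus_id[!complete]
  if (!all(coord_cols() %in% names(wide))) {
    # an entire channel absent from the file: every nucleus is incomplete
    incomplete_ids <- wide$nucleus_id
    complete <- rep(FALSE, nrow(wide))
  }
  if (length(incomplete_ids) > 0) {
    cli::cli_inform("Dropped {length(incomplete_ids)} nucle{?us/i} with missing channel{?s}.")
  }
  wide <- wide[complete, , drop = FALSE]
  for (col in coord_cols()) if (!col %in% names(wide)) wide[[col]] <- numeric(0)
  ds <- triplet_dataset(wide, label_map = label_map, strain_id = strain_id)
  attr(ds, "dropped_incomplete") <- incomplete_ids
  ds
}

read_spotdistance <- function(path, label_map, strain_id) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  nm <- names(raw)
  # permissive: accept x_r or r_x (any case)
  canon <- tolower(nm)
  flip <- sub("^([rgb])_([xyz])$", "\\2_\\1", canon)
  names(raw) <- flip
  if (!"nucleus_id" %in% names(raw)) {
    cli::cli_abort("Malformed table: missing column {.field nucleus_id}.")
  }
  missing_cols <- setdiff(coord_cols(), names(raw))
  if (length(missing_cols) > 0) {
    cli::cli_abort("Malformed table: missing column{?s} {.field {missing_cols}}.")
  }
  triplet_dataset(raw, label_map = label_map, strain_id = strain_id)
}

#' Write a triplet dataset to the canonical simple TSV
#'
#' Writes the long-format (`nucleus_id`, `channel`, `x`, `y`, `z`) table.
#' Doubles are written with shortest round-trip precision, so
#' [read_triplet_table()] inverts the write bit-exactly.
#'
#' @param ds A `triplet_df`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triplet_table <- function(ds, path) {
  assert_triplet_df(ds)
  if (nrow(ds) == 0) cli::cli_abort("Refusing to write an empty dataset.")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(ds)[c("nucleus_id", coord_cols())],
    cols = -"nucleus_id",
    names_to = c(".value", "channel"),
    names_sep = "_"
  )
  long$channel <- factor(long$channel, levels = c("r", "g", "b"))
  long <- dplyr::arrange(long, match(.data$nucleus_id, ds$nucleus_id), .data$channel)
  long$channel <- as.character(long$channel)
  readr::write_tsv(long[c("nucleus_id", "channel", "x", "y", "z")], path,
                   progress = FALSE)
  invisible(path)
}

#' Quality-control filter for triplet datasets
#'
#' Removes nuclei whose spot triplet cannot support the geometric analysis:
#' a missing (NA) coordinate, a non-finite coordinate, two coincident spots
#' (zero pairwise distance), or an inter-spot distance exceeding
#' `max_pair_distance`.  The default ceiling of 2.5 um generously bounds what
#' fits inside a ~2 um yeast nucleus while tolerating slightly elongated,
#' e.g. budding, nuclei.
#'
#' The removal tally is attached as the `"qc_report"` attribute (a tibble of
#' `reason`, `n`) and retrievable with [qc_report()].  Each nucleus is counted
#' once, under the first failing reason in the order missing-channel,
#' non-finite, coincident spots, distance ceiling.
#'
#' @param ds A `triplet_df`.
#' @param max_pair_distance Largest admissible inter-spot distance (um).
#' @param require_complete Drop nuclei with any NA coordinate (default TRUE).
#' @return The filtered `triplet_df` with a `"qc_report"` attribute.
#' @export
qc_filter <- function(ds, max_pair_distance = 2.5, require_complete = TRUE) {
  assert_triplet_df(ds)
  if (!is.numeric(max_pair_distance) || max_pair_distance <= 0) {
    cli::cli_abort("max_pair_distance must be a positive number of micrometres.")
  }
  cm <- lapply(c("r", "g", "b"), function(ch) channel_matrix(ds, ch))
  has_na <- Reduce(`|`, lapply(cm, function(m) rowSums(is.na(m)) > 0))
  nonfinite <- Reduce(`|`, lapply(cm, function(m) {
    rowSums(!is.finite(m) & !is.na(m)) > 0
  }))
  d_rg <- sqrt(rowSums((cm[[1]] - cm[[2]])^2))
  d_rb <- sqrt(rowSums((cm[[1]] - cm[[3]])^2))
  d_gb <- sqrt(rowSums((cm[[2]] - cm[[3]])^2))
  dmin <- pmin(d_rg, d_rb, d_gb)
  dmax <- pmax(d_rg, d_rb, d_gb)
  reason <- rep(NA_character_, nrow(ds))
  if (require_complete) reason[has_na] <- "missing_channel"
  reason[is.na(reason) & nonfinite] <- "nonfinite_coordinate"
  reason[is.na(reason) & !has_na & dmin == 0] <- "coincident_spots"
  reason[is.na(reason) & !has_na & dmax > max_pair_distance] <- "distance_exceeds_max"
  keep <- is.na(reason)
  reasons <- c("missing_channel", "nonfinite_coordinate",
               "coincident_spots", "distance_exceeds_max")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1))
  report <- tibble::tibble(reason = reasons, n = unname(counts))
  out <- ds[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    cli::cli_warn("QC removed every nucleus; the filtered dataset is empty.")
  }
  total <- sum(report$n)
  if (total > 0) {
    cli::cli_inform("QC removed {total} of {nrow(ds)} nucle{?us/i}.")
  }
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_filter
#' @export
qc_report <- function(ds) attr(ds, "qc_report")
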