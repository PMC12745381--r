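#' Plate layout geometry
#'
#' Describes how a multi-well plate maps onto the camera image: the well grid,
#' the pixel rectangle ("tile") imaged for each well, which edge wells are
#' empty (dry wells used for background thresholds), the physical pixel pitch,
#' and the compound-addition time if a drug was dispensed during acquisition.
#'
#' Tiles are half-open 0-based pixel rectangles `[y0, y1) x [x0, x1)` laid out
#' on a regular grid; they may cover a slightly larger area than the physical
#' growth surface of the well, which is why zone masks
#' ([build_zone_mask()]) are derived from the image itself.
#'
#' @param plate_format 96 or 384; sets the well grid (8 x 12 or 16 x 24).
#' @param tile_shape integer `c(y, x)` pixels per well tile. Defaults:
#'   `c(24, 24)` for 96-well (about 400 growth pixels per well) and
#'   `c(15, 16)` for 384-well (about 130 growth pixels).
#' @param empty_wells character vector of well ids (e.g. `"A01"`) left dry;
#'   used for global detection thresholds.
#' @param pixel_pitch_um physical size of one pixel, micrometers.
#' @param compound_addition_time time (s) at which a compound was dispensed
#'   during the recording, or `NA` if none.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(plate_format = 96,
                         tile_shape = NULL,
                         empty_wells = character(0),
                         pixel_pitch_um = 284,
                         compound_addition_time = NA_real_) {
  if (!plate_format %in% c(96, 384))
    stop("plate_layout(): plate_format must be 96 or 384")
  dims <- if (plate_format == 96) c(8L, 12L) else c(16L, 24L)
  if (is.null(tile_shape))
    tile_shape <- if (plate_format == 96) c(24L, 24L) else c(15L, 16L)
  tile_shape <- as.integer(tile_shape)
  if (length(tile_shape) != 2L || any(tile_shape < 4L))
    stop("plate_layout(): tile_shape must be two integers >= 4")
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("plate_layout(): pixel_pitch_um must be > 0")
  ids <- well_ids(dims[1], dims[2])
  bad <- setdiff(empty_wells, ids)
  if (length(bad))
    stop("plate_layout(): unknown empty wells: ", paste(bad, collapse = ", "))
  structure(list(
    plate_format = plate_format,
    n_rows = dims[1], n_cols = dims[2],
    tile_shape = tile_shape,
    empty_wells = empty_wells,
    pixel_pitch_um = pixel_pitch_um,
    compound_addition_time = compound_addition_time
  ), class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d-well (%d x %d), tile %d x %d px, pitch %g um\n",
              x$plate_format, x$n_rows, x$n_cols,
              x$tile_shape[1], x$tile_shape[2], x$pixel_pitch_um))
  if (length(x$empty_wells))
    cat("  empty wells:", paste(x$empty_wells, collapse = ", "), "\n")
  invisible(x)
}

#' Well identifiers in row-major order ("A01", "A02", ...)
#' @param n_rows,n_cols well grid dimensions.
#' @return character vector of length `n_rows * n_cols`.
#' @export
well_ids <- function(n_rows, n_cols) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)],
                    sprintf("%02d", seq_len(n_cols)), paste0)))
}

# Row/col (1-based) of a well id within the layout grid.
well_rc <- function(layout, well) {
  ids <- well_ids(layout$n_rows, layout$n_cols)
  i <- match(well, ids)
  if (anyNA(i)) stop("unknown well id: ", paste(well[is.na(i)], collapse = ", "))
  cbind(row = (i - 1L) %/% layout$n_cols + 1L,
        col = (i - 1L) %% layout$n_cols + 1L)
}

#' Pixel rectangle of a well tile
#'
#' @param layout a [plate_layout()].
#' @param well well id, e.g. `"B03"`.
#' @return list with 0-based half-open bounds `y0, y1, x0, x1`.
#' @export
tile_bounds <- function(layout, well) {
  rc <- well_rc(layout, well)
  ty <- layout$tile_shape[1]; tx <- layout$tile_shape[2]
  list(y0 = (rc[1, "row"] - 1L) * ty, y1 = rc[1, "row"] * ty,
       x0 = (rc[1, "col"] - 1L) * tx, x1 = rc[1, "col"] * tx)
}

#' Read / write a plate layout as YAML
#' @param path file path.
#' @return `read_layout()` returns a `plate_layout`; `write_layout()` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  plate_layout(plate_format = y$plate_format,
               tile_shape = unlist(y$tile_shape),
               empty_wells = as.character(unlist(y$empty_wells)),
               pixel_pitch_um = y$pixel_pitch_um,
               compound_addition_time =
                 if (is.null(y$compound_addition_time)) NA_real_
                 else y$compound_addition_time)
}

#' @rdname read_layout
#' @param layout a [plate_layout()].
#' @export
write_layout <- function(layout, path) {
  yaml::write_yaml(list(
    plate_format = layout$plate_format,
    tile_shape = as.integer(layout$tile_shape),
    empty_wells = as.list(layout$empty_wells),
    pixel_pitch_um = layout$pixel_pitch_um,
    compound_addition_time =
      if (is.na(layout$compound_addition_time)) NULL
      else layout$compound_addition_time
  ), path)
  invisible(path)
}
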