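# Lightweight S3 containers for the pipeline's data.

#' Multi-channel registered field of view
#'
#' @param channels named list of same-shaped numeric matrices with
#'   non-negative intensities.
#' @param pixel_size_um physical pixel size in microns per pixel.
#' @param well_id,site_id identifiers used by the aggregation layer.
#' @return an object of class `gj_image_set`.
#' @export
image_set <- function(channels, pixel_size_um, well_id = NA_character_,
                      site_id = NA_integer_) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all channels must share the same shape")
  assert_positive(pixel_size_um, "pixel_size_um")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 well_id = well_id, site_id = site_id),
            class = "gj_image_set")
}

#' @export
print.gj_image_set <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<gj_image_set> ", d[1], "x", d[2], " px, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "),
      "; pixel ", x$pixel_size_um, " um\n", sep = "")
  invisible(x)
}

#' 3D intensity volume with physical voxel size
#'
#' @param data 3D numeric array (rows, cols, slices).
#' @param voxel_um length-3 numeric: xy pixel sizes and slice increment in
#'   microns (default z step 0.4).
#' @return an object of class `gj_volume_image`.
#' @export
volume_image <- function(data, voxel_um = c(0.2, 0.2, 0.4)) {
  stopifnot(length(dim(data)) == 3L, length(voxel_um) == 3L)
  assert_positive(voxel_um, "voxel_um")
  structure(list(data = data, voxel_um = as.numeric(voxel_um)),
            class = "gj_volume_image")
}

#' @export
print.gj_volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<gj_volume_image> ", d[1], "x", d[2], "x", d[3], " voxels @ ",
      paste(signif(x$voxel_um, 3), collapse = " x "), " um\n", sep = "")
  invisible(x)
}

# internal constructor for detected object sets that need both a table and
# the label image (pixel-level colocalization requires the labels)
puncta_set <- function(table, labels) {
  structure(list(table = table, labels = labels), class = "gj_puncta_set")
}

#' @export
print.gj_puncta_set <- function(x, ...) {
  cat("<gj_puncta_set> ", nrow(x$table), " objects\n", sep = "")
  invisible(x)
}
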