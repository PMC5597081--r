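# 3D gap-junction plaque quantification from confocal z-stacks.

#' Detect gap-junction plaques in a z-stack
#'
#' Above-threshold voxels are grouped by 3D connected components
#' (26-connectivity by default), each object's volume is its voxel count
#' times the physical voxel volume, and the volume gate (default 5-100
#' cubic microns, inclusive at both bounds) is applied.
#'
#' @param volume a [volume_image()]; voxel size must be known.
#' @param v_min,v_max inclusive volume gate in cubic microns.
#' @param threshold threshold policy or absolute value.
#' @param connectivity 6 or 26.
#' @return a data.frame of class `gj_plaque_set`: label, voxels, volume_um3,
#'   mean_signal, plus the label array in attribute `labels`.
#' @export
detect_plaques <- function(volume, v_min = 5, v_max = 100,
                           threshold = "otsu", connectivity = 26L) {
  if (!inherits(volume, "gj_volume_image"))
    stop("detect_plaques needs a volume_image (voxel size unknown otherwise)")
  vox_vol <- prod(volume$voxel_um)
  a <- volume$data
  if (all(a == a[1])) {
    out <- data.frame(label = integer(), voxels = integer(),
                      volume_um3 = numeric(), mean_signal = numeric())
    attr(out, "labels") <- array(0L, dim = dim(a))
    class(out) <- c("gj_plaque_set", "data.frame")
    return(out)
  }
  thr <- resolve_threshold(a, threshold)
  labels <- label_components_3d(a > thr, connectivity)
  idx <- which(labels > 0L)
  tab <- data.frame(label = integer(), voxels = integer(),
                    volume_um3 = numeric(), mean_signal = numeric())
  if (length(idx) > 0L) {
    l <- labels[idx]
    nvox <- tabulate(l)
    keep0 <- which(nvox > 0L)
    sums <- rowsum(as.numeric(a[idx]), l)[, 1]
    tab <- data.frame(label = keep0, voxels = nvox[keep0],
                      volume_um3 = nvox[keep0] * vox_vol,
                      mean_signal = as.numeric(sums) / nvox[keep0])
    tab <- tab[tab$volume_um3 >= v_min & tab$volume_um3 <= v_max, ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "labels") <- labels
  class(tab) <- c("gj_plaque_set", "data.frame")
  tab
}

#' Flag plaques at the cell-cell interface by pixel-pixel colabeling
#'
#' A plaque is interface-localized iff at least one of its voxels is
#' above threshold in the marker volume (ITGA3 / Glut1 style colabeling).
#'
#' @param plaques [detect_plaques()] output (carries the label array).
#' @param marker_volume a [volume_image()] on the same voxel grid.
#' @param threshold threshold policy or absolute value for the marker.
#' @return the plaque table with a logical `interface` column.
#' @export
interface_localization <- function(plaques, marker_volume,
                                   threshold = "otsu") {
  stopifnot(inherits(plaques, "gj_plaque_set"),
            inherits(marker_volume, "gj_volume_image"))
  labels <- attr(plaques, "labels")
  if (!all(dim(labels) == dim(marker_volume$data)))
    stop("marker volume grid does not match the plaque stack")
  m <- marker_volume$data
  if (all(m == m[1])) {
    plaques$interface <- rep(FALSE, nrow(plaques))
    return(plaques)
  }
  thr <- resolve_threshold(m, threshold)
  hot <- m > thr
  plaques$interface <- vapply(plaques$label, function(l)
    any(hot[labels == l]), logical(1))
  plaques
}
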