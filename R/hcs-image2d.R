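# High-content 2D pipeline: illumination correction, segmentation, puncta
# objects, compartment assignment, hierarchical aggregation, and fly-CNS
# tract densitometry.

#' Estimate a per-channel illumination gain field
#'
#' Median-filters the average of all same-channel fields of a plate with a
#' large window (default 200 x 200 px) and normalizes the result to mean 1 —
#' the classic flat-field estimate for 96-well high-content plates.  The
#' exact window median is evaluated on a regular grid (`grid_step`) and
#' bilinearly interpolated, which is indistinguishable from the dense filter
#' for smooth illumination bias.
#'
#' @param images a single matrix or a list of same-channel matrices.
#' @param window median filter window size in pixels (square).
#' @param grid_step spacing of exact-median evaluation points.
#' @param stat `"median"` (the classic plate median filter) or
#'   `"background"` (median of the window pixels below a global object
#'   cutoff), the robust choice when bright objects cover a large fraction
#'   of the field and would bias the plain window median.
#' @param object_cut fraction of the image's robust dynamic range above
#'   which pixels count as object and are excluded by the background
#'   statistic.
#' @return a mean-normalized, strictly positive gain matrix of class
#'   `gj_gain_field`.
#' @export
compute_gain_field <- function(images, window = 200L, grid_step = 16L,
                               stat = c("median", "background"),
                               object_cut = 0.1) {
  stat <- match.arg(stat)
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1]])
  if (window > min(d))
    stop("median filter window (", window, ") larger than image (",
         paste(d, collapse = "x"), ")")
  avg <- Reduce(`+`, images) / length(images)
  halfwin <- floor(window / 2)
  gi <- unique(c(seq(0L, d[1] - 1L, by = grid_step), d[1] - 1L))
  gj <- unique(c(seq(0L, d[2] - 1L, by = grid_step), d[2] - 1L))
  med <- if (stat == "median") {
    .cpp_grid_median(avg, as.integer(halfwin), as.integer(gi),
                     as.integer(gj))
  } else {
    q <- stats::quantile(avg, c(0.5, 0.999), names = FALSE)
    cutoff <- q[1] + object_cut * (q[2] - q[1])
    .cpp_grid_masked_median(avg, as.integer(halfwin), as.integer(gi),
                            as.integer(gj), cutoff)
  }
  # windows are clamped at the borders, so each grid value estimates the
  # field at the window's effective centre, not at the grid node; attribute
  # it there before interpolating to avoid flattening the border bands
  eff <- function(x, n) (pmax(0, x - halfwin) + pmin(n - 1, x + halfwin)) / 2
  g <- interp_grid(med, eff(gi, d[1]), eff(gj, d[2]), d)
  g <- g / mean(g)
  if (any(g <= 0))
    stop("estimated gain field is not strictly positive; ",
         "check image background levels")
  structure(g, class = c("gj_gain_field", "matrix", "array"))
}

# bilinear interpolation of grid-sampled values back to full resolution
interp_grid <- function(med, gi, gj, d) {
  rows_full <- 0:(d[1] - 1)
  cols_full <- 0:(d[2] - 1)
  tmp <- apply(med, 2, function(col)
    stats::approx(gi, col, xout = rows_full, rule = 2)$y)
  t(apply(tmp, 1, function(row)
    stats::approx(gj, row, xout = cols_full, rule = 2)$y))
}

#' Flat-field correct an image by a gain field
#'
#' @param image intensity matrix.
#' @param gain gain matrix ([compute_gain_field()] output or any strictly
#'   positive matrix of the same shape).
#' @return pointwise quotient `image / gain`.
#' @export
correct_illumination <- function(image, gain) {
  if (!all(dim(image) == dim(gain))) stop("image and gain shapes differ")
  if (any(gain <= 0)) stop("gain field must be strictly positive")
  image / unclass(gain)
}

#' Flat-field correct every channel of a field
#'
#' @param iset a [image_set()].
#' @param gains a single gain matrix (applied to all channels) or a named
#'   list with one gain per channel.
#' @return corrected `gj_image_set`.
#' @export
correct_image_set <- function(iset, gains) {
  stopifnot(inherits(iset, "gj_image_set"))
  for (nm in names(iset$channels)) {
    g <- if (is.list(gains)) gains[[nm]] else gains
    if (is.null(g)) stop("no gain field for channel ", nm)
    iset$channels[[nm]] <- correct_illumination(iset$channels[[nm]], g)
  }
  iset
}

#' Segment nuclei from a DNA channel
#'
#' Thresholds the (corrected) DNA channel, fills holes, splits touching
#' nuclei by a distance-transform watershed, and gates objects on
#' equivalent-circle diameter (default 20-60 px) and solidity
#' (circular-shape filter).  Gate bounds carry a half-pixel quantization
#' allowance, since object diameters are only defined to the pixel.
#'
#' @param dna corrected DNA-channel matrix.
#' @param min_px,max_px equivalent-diameter gate in pixels.
#' @param solidity_min minimum solidity (area / convex area).
#' @param threshold threshold policy (see [otsu_threshold()] family);
#'   numeric for an absolute cutoff.
#' @param split_touching apply the watershed split.
#' @return integer label matrix (0 = background, labels consecutive).
#' @export
segment_nuclei <- function(dna, min_px = 20, max_px = 60, solidity_min = 0.8,
                           threshold = "otsu", split_touching = TRUE) {
  if (all(dna == dna[1])) return(matrix(0L, nrow(dna), ncol(dna)))
  thr <- resolve_threshold(dna, threshold)
  mask <- dna > thr
  if (!any(mask)) return(matrix(0L, nrow(dna), ncol(dna)))
  mask <- fill_holes(mask)
  if (split_touching) {
    dist <- .cpp_chamfer(mask)
    r <- max(3L, as.integer(round(min_px / 2)))
    peaks <- (dist >= .cpp_maxfilter(dist, r) - 1e-9) & (dist > 1)
    markers <- label_components(peaks, 8L)
    labels <- .cpp_watershed(-dist, mask, markers)
    # pixels missed by flooding (none expected) fall back to plain labelling
    if (any(mask & labels == 0L)) {
      rest <- label_components(mask & labels == 0L, 8L)
      rest[rest > 0L] <- rest[rest > 0L] + max(labels)
      labels <- labels + rest
    }
  } else {
    labels <- label_components(mask, 8L)
  }
  props <- region_props(labels)
  sol <- region_solidity(labels)
  keep <- props$label[props$equivalent_diameter_px >= min_px - 0.5 &
                      props$equivalent_diameter_px <= max_px + 0.5 &
                      sol[as.character(props$label)] >= solidity_min]
  relabel_keep(labels, keep)
}

# fill background holes not connected to the image border
fill_holes <- function(mask) {
  bg <- label_components(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | !(bg %in% border | bg == 0L)
}

# keep the given labels and renumber them 1..k preserving order
relabel_keep <- function(labels, keep) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep) == 0L) return(out)
  map <- integer(max(labels))
  map[sort(keep)] <- seq_along(keep)
  pos <- labels > 0L
  mapped <- map[labels[pos]]
  out[pos] <- ifelse(is.na(mapped), 0L, mapped)
  out
}

#' Identify cells by seeded propagation from nuclei
#'
#' Each above-threshold pixel of the cell-body channel is assigned to the
#' geodesically nearest nucleus (multi-source flood), so cells partition the
#' foreground and there is exactly one cell per nucleus.  A nucleus falling
#' outside the foreground keeps its own pixels as a degenerate cell.
#'
#' @param nuclei label matrix from [segment_nuclei()].
#' @param cell_channel corrected intensity matrix used to delimit the
#'   cellular foreground.
#' @param threshold threshold policy or absolute value.
#' @return integer cell label matrix; labels match nucleus labels.
#' @export
segment_cells <- function(nuclei, cell_channel, threshold = "otsu3-lower") {
  if (!all(dim(nuclei) == dim(cell_channel)))
    stop("nuclei mask and cell channel shapes differ")
  if (max(nuclei) == 0L) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  thr <- resolve_threshold(cell_channel, threshold)
  fg <- cell_channel > thr
  orphan <- setdiff(unique(nuclei[nuclei > 0L & !fg]),
                    unique(nuclei[nuclei > 0L & fg]))
  if (length(orphan) > 0L)
    message("segment_cells: ", length(orphan),
            " nucleus(ei) outside foreground; kept as degenerate cells")
  fg <- fg | nuclei > 0L          # every cell contains its seed nucleus
  .cpp_propagate(nuclei, fg)
}

#' Partition cells into transfected / non-transfected by GFP
#'
#' A cell is transfected iff its mean GFP intensity exceeds the threshold;
#' the default derives the threshold by Otsu over the per-cell means, with a
#' guard that declares all cells untransfected when the means show no
#' high-expressing population (max < 2 x min).
#'
#' @param cell_mask integer cell label matrix.
#' @param gfp GFP channel matrix; an error if missing/NULL.
#' @param threshold NULL for the Otsu default or an absolute per-cell-mean
#'   cutoff.
#' @return named logical vector, one entry per cell label.
#' @export
partition_transfected <- function(cell_mask, gfp, threshold = NULL) {
  if (is.null(gfp)) stop("GFP channel required for transfection partitioning")
  if (!all(dim(cell_mask) == dim(gfp))) stop("shape mismatch")
  labs <- sort(unique(cell_mask[cell_mask > 0L]))
  if (length(labs) == 0L) return(setNames(logical(0), character(0)))
  means <- vapply(labs, function(l) mean(gfp[cell_mask == l]), numeric(1))
  if (is.null(threshold)) {
    if (max(means) < 2 * min(means))
      return(setNames(rep(FALSE, length(labs)), labs))
    threshold <- otsu_threshold(means, nbins = 64L)
  }
  setNames(means > threshold, labs)
}

#' Detect punctae within the cellular region
#'
#' Connected above-threshold components inside the cell mask, gated by
#' equivalent-circle diameter (default 8-20 px, with a half-pixel
#' quantization allowance); each puncta is assigned to the cell containing
#' its centroid.  The default `"halfmax"` threshold places the object
#' boundary at half the robust peak amplitude, the standard convention for
#' diffraction-limited spots, so measured diameters track true FWHMs.
#'
#' @param channel corrected puncta channel (e.g. Cx43, EEA1, LAMP1).
#' @param cell_mask integer cell label matrix restricting the search.
#' @param d_min,d_max equivalent-diameter gate in pixels.
#' @param threshold threshold policy or absolute value.
#' @param transfected optional named logical from [partition_transfected()].
#' @return a `gj_puncta_set`: `$table` with one row per retained puncta
#'   (label, centroid, area, equivalent diameter, integrated and mean
#'   intensity, owning cell, transfected flag) and `$labels`, the component
#'   label matrix for pixel-level colocalization.
#' @export
detect_punctae <- function(channel, cell_mask, d_min = 8, d_max = 20,
                           threshold = "halfmax", transfected = NULL) {
  if (!all(dim(channel) == dim(cell_mask))) stop("shape mismatch")
  if (max(cell_mask) == 0L) stop("empty cell mask; segment cells first")
  thr <- resolve_threshold(channel, threshold)
  mask <- (channel > thr) & (cell_mask > 0L)
  labels <- label_components(mask, 8L)
  props <- region_props(labels, intensity = channel)
  keep <- props$equivalent_diameter_px >= d_min - 0.5 &
          props$equivalent_diameter_px <= d_max + 0.5
  props <- props[keep, , drop = FALSE]
  if (nrow(props) > 0) {
    ri <- pmin(nrow(cell_mask), pmax(1L, round(props$centroid_row) + 1L))
    ci <- pmin(ncol(cell_mask), pmax(1L, round(props$centroid_col) + 1L))
    own <- cell_mask[cbind(ri, ci)]
    # non-convex components: fall back to majority label over object pixels
    for (k in which(own == 0L)) {
      px <- cell_mask[labels == props$label[k]]
      px <- px[px > 0L]
      own[k] <- if (length(px)) as.integer(names(which.max(table(px)))) else 0L
    }
    props$cell_label <- own
    props$transfected <- if (is.null(transfected)) NA else
      unname(transfected[as.character(own)])
  } else {
    props$cell_label <- integer(0)
    props$transfected <- logical(0)
  }
  rownames(props) <- NULL
  puncta_set(props, labels)
}

#' Segment the ITGA3-labelled cell surface
#'
#' Binary mask of above-threshold ITGA3 signal; the default two-level Otsu
#' (`"otsu-upper"`) isolates the bright membrane rim from moderate
#' cytoplasmic signal and background.  Reports surface area for the protocol's
#' per-area normalizations.
#'
#' @param itga3 corrected ITGA3 channel.
#' @param threshold threshold policy or absolute value.
#' @param pixel_size_um optional physical pixel size for the um^2 area.
#' @return list(mask, area_px, area_um2).
#' @export
surface_objects <- function(itga3, threshold = "otsu3-upper",
                            pixel_size_um = NULL) {
  if (all(itga3 == itga3[1])) {
    mask <- matrix(FALSE, nrow(itga3), ncol(itga3))
  } else {
    thr <- resolve_threshold(itga3, threshold)
    mask <- itga3 > thr
  }
  area_px <- sum(mask)
  list(mask = mask, area_px = area_px,
       area_um2 = if (is.null(pixel_size_um)) NA_real_ else
         area_px * pixel_size_um^2)
}

#' Assign Cx43 punctae to subcellular compartments
#'
#' A puncta is `surface` if any of its pixels intersect the surface mask,
#' `EE`/`LYS` if its pixels intersect a retained marker puncta
#' (object-object colocalization by shared pixels).  Multi-hit punctae are
#' resolved with priority surface > early endosome > lysosome; punctae
#' hitting nothing are labelled `other` and excluded from the three-way
#' fraction, which is normalized to sum to exactly 100.
#'
#' @param cx43 `gj_puncta_set` of Cx43 punctae.
#' @param surface surface mask (logical matrix) or [surface_objects()]
#'   output.
#' @param markers a single marker `gj_puncta_set` (with `marker_kind`
#'   `"EEA1"` or `"LAMP1"`), or a named list with entries `EEA1` and/or
#'   `LAMP1` when the field carries both markers.
#' @param marker_kind which marker `markers` is, when a single set is given.
#' @param mode `"pixel"` (any shared pixel, the default) or `"centroid"`
#'   (marker object containing the Cx43 centroid).
#' @param n_cells optional cell count for the punctae-per-cell level.
#' @return a `gj_compartment_fractions` list: `pct_surface`,
#'   `pct_early_endosome`, `pct_lysosome` (summing to 100), `n_punctae`,
#'   `n_classified`, `punctae_per_cell`, and `per_puncta` assignments.
#' @export
assign_compartments <- function(cx43, surface, markers = NULL,
                                marker_kind = NULL, mode = c("pixel", "centroid"),
                                n_cells = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cx43, "gj_puncta_set"))
  smask <- if (is.list(surface)) surface$mask else surface
  marker_sets <- list()
  if (inherits(markers, "gj_puncta_set")) {
    if (is.null(marker_kind) || !marker_kind %in% c("EEA1", "LAMP1"))
      stop("marker_kind must be \"EEA1\" or \"LAMP1\"")
    marker_sets[[marker_kind]] <- markers
  } else if (is.list(markers) && length(markers) > 0) {
    if (!all(names(markers) %in% c("EEA1", "LAMP1")))
      stop("marker list names must be EEA1 / LAMP1")
    marker_sets <- markers
  }

  tab <- cx43$table
  n <- nrow(tab)
  comp <- rep("other", n)
  if (n > 0) {
    marker_hit <- function(mset, idx_px, centroid) {
      if (mode == "pixel") {
        l <- mset$labels[idx_px]
        any(l %in% mset$table$label)
      } else {
        l <- mset$labels[centroid[1] + 1L + nrow(mset$labels) * centroid[2]]
        l %in% mset$table$label
      }
    }
    for (i in seq_len(n)) {
      idx_px <- which(cx43$labels == tab$label[i])
      ctr <- c(round(tab$centroid_row[i]), round(tab$centroid_col[i]))
      if (any(smask[idx_px])) {
        comp[i] <- "surface"
      } else if (!is.null(marker_sets$EEA1) &&
                 marker_hit(marker_sets$EEA1, idx_px, ctr)) {
        comp[i] <- "EE"
      } else if (!is.null(marker_sets$LAMP1) &&
                 marker_hit(marker_sets$LAMP1, idx_px, ctr)) {
        comp[i] <- "LYS"
      }
    }
  }
  counts <- c(surface = sum(comp == "surface"),
              EE = sum(comp == "EE"),
              LYS = sum(comp == "LYS"))
  n_classified <- sum(counts)
  pct <- if (n_classified > 0) 100 * counts / n_classified else
    c(surface = NA_real_, EE = NA_real_, LYS = NA_real_)
  structure(list(pct_surface = unname(pct["surface"]),
                 pct_early_endosome = unname(pct["EE"]),
                 pct_lysosome = unname(pct["LYS"]),
                 n_punctae = n, n_classified = n_classified,
                 punctae_per_cell = if (is.null(n_cells)) NA_real_ else
                   n / n_cells,
                 per_puncta = data.frame(label = tab$label,
                                         compartment = comp)),
            class = "gj_compartment_fractions")
}

#' @export
print.gj_compartment_fractions <- function(x, ...) {
  cat(sprintf(
    "<compartment fractions> surface %.1f%% | early endosome %.1f%% | lysosome %.1f%% (n=%d classified of %d)\n",
    x$pct_surface, x$pct_early_endosome, x$pct_lysosome,
    x$n_classified, x$n_punctae))
  invisible(x)
}

#' Run the full 2D quantification pipeline on one field
#'
#' Convenience wrapper chaining illumination estimation and correction,
#' nuclei and cell segmentation, transfection partitioning (when a GFP
#' channel is present), Cx43 and marker puncta detection, surface masking
#' and compartment assignment.  Illumination is estimated per channel with
#' the robust background statistic (see [compute_gain_field()]), since the
#' synthetic fields carry a high object coverage at this scale.
#'
#' @param iset a [image_set()] with channels DNA, CX43, ITGA3 and
#'   optionally EEA1, LAMP1, GFP.
#' @param gain_images optional named list of same-channel image lists from
#'   which to estimate the per-channel gains (defaults to the field
#'   itself); pass `gains` to skip estimation entirely.
#' @param gains optional named list (or single matrix) of gain fields.
#' @param correct apply illumination correction (TRUE by default).
#' @param nucleus_gate,puncta_gate diameter gates in pixels.
#' @return list: corrected channels, `nuclei`, `cells`, `transfected`,
#'   `cx43`, `markers`, `surface`, `fractions`, `n_cells`, `n_punctae`.
#' @export
quantify_field <- function(iset, gain_images = NULL, gains = NULL,
                           correct = TRUE,
                           nucleus_gate = c(20, 60), puncta_gate = c(8, 20)) {
  stopifnot(inherits(iset, "gj_image_set"))
  ch <- iset$channels
  stopifnot(all(c("DNA", "CX43", "ITGA3") %in% names(ch)))
  if (correct) {
    if (is.null(gains)) {
      src <- if (is.null(gain_images))
        lapply(ch, function(m) list(m)) else gain_images
      gains <- lapply(src, compute_gain_field, stat = "background")
    }
    ch <- mapply(function(m, nm) {
      g <- if (is.list(gains)) gains[[nm]] else gains
      correct_illumination(m, g)
    }, ch, names(ch), SIMPLIFY = FALSE)
  }
  nuclei <- segment_nuclei(ch$DNA, min_px = nucleus_gate[1],
                           max_px = nucleus_gate[2])
  cells <- segment_cells(nuclei, ch$ITGA3)
  transfected <- if (!is.null(ch$GFP))
    partition_transfected(cells, ch$GFP) else NULL
  cx43 <- detect_punctae(ch$CX43, cells, d_min = puncta_gate[1],
                         d_max = puncta_gate[2], transfected = transfected)
  markers <- list()
  for (nm in intersect(c("EEA1", "LAMP1"), names(ch)))
    markers[[nm]] <- detect_punctae(ch[[nm]], cells, d_min = puncta_gate[1],
                                    d_max = puncta_gate[2])
  surface <- surface_objects(ch$ITGA3, pixel_size_um = iset$pixel_size_um)
  fractions <- assign_compartments(cx43, surface, markers,
                                   n_cells = max(cells))
  list(channels = ch, nuclei = nuclei, cells = cells,
       transfected = transfected, cx43 = cx43, markers = markers,
       surface = surface, fractions = fractions,
       n_cells = max(cells), n_punctae = nrow(cx43$table))
}

#' Aggregate site records to a single well value
#'
#' Unweighted mean over the sites of one well; mixing wells in one call is
#' an error (aggregation is strictly hierarchical).
#'
#' @param site_df data.frame with a `well_id` column and numeric value
#'   columns.
#' @param value_cols columns to aggregate; default all numeric except ids.
#' @return one-row data.frame with the well means and `n_sites`.
#' @export
aggregate_well <- function(site_df, value_cols = NULL) {
  stopifnot(nrow(site_df) >= 1L, "well_id" %in% names(site_df))
  if (length(unique(site_df$well_id)) != 1L)
    stop("mixed wells in one aggregation call; aggregate per well first")
  if (is.null(value_cols))
    value_cols <- setdiff(names(site_df)[vapply(site_df, is.numeric, TRUE)],
                          c("site_id"))
  out <- as.data.frame(lapply(site_df[value_cols], mean))
  cbind(data.frame(well_id = site_df$well_id[1]), out,
        data.frame(n_sites = nrow(site_df)))
}

#' Hierarchical site -> well -> condition aggregation
#'
#' Means are taken first over the sites within each well, then over the
#' replicate wells of each condition (unweighted at each level), carrying
#' the n at every step.
#'
#' @param site_df data.frame with `condition`, `well_id`, optionally
#'   `site_id`, and numeric value columns.
#' @param value_cols value columns; default all numeric except ids.
#' @return list(wells, conditions) of aggregated data.frames.
#' @export
hcs_aggregate <- function(site_df, value_cols = NULL) {
  stopifnot(all(c("condition", "well_id") %in% names(site_df)))
  if (is.null(value_cols))
    value_cols <- setdiff(names(site_df)[vapply(site_df, is.numeric, TRUE)],
                          c("site_id"))
  pieces <- split(site_df, list(site_df$condition, site_df$well_id),
                  drop = TRUE)
  wells <- do.call(rbind, lapply(pieces, function(p)
    cbind(data.frame(condition = p$condition[1]), aggregate_well(p, value_cols))))
  rownames(wells) <- NULL
  conds <- do.call(rbind, lapply(split(wells, wells$condition), function(w) {
    out <- as.data.frame(lapply(w[value_cols], mean))
    sem <- as.data.frame(lapply(w[value_cols], function(v)
      stats::sd(v) / sqrt(length(v))))
    names(sem) <- paste0(names(sem), "_sem")
    cbind(data.frame(condition = w$condition[1]), out, sem,
          data.frame(n_wells = nrow(w)))
  }))
  rownames(conds) <- NULL
  list(wells = wells, conditions = conds)
}

#' Sum-slices projection of a z-stack
#'
#' @param zstack 3D array or [volume_image()]; at least one slice.
#' @return 2D matrix, the per-pixel sum over all focal planes.
#' @export
sum_slices <- function(zstack) {
  a <- if (inherits(zstack, "gj_volume_image")) zstack$data else zstack
  d <- dim(a)
  if (is.null(d) || length(d) == 2L) return(as.matrix(a))
  stopifnot(length(d) == 3L, d[3] >= 1L)
  apply(a, c(1, 2), sum)
}

#' Densitometry of bilateral ROI tracts on a projection
#'
#' For each ROI polygon: area, mean grey value (MGV), and integrated
#' density = area x MGV (exact).  The combined readout is the area-weighted
#' mean MGV over both tracts and the total integrated density from the
#' weighted MGV and total area.
#'
#' @param projection 2D matrix (e.g. from [sum_slices()]).
#' @param roi_polygons list of exactly 2 vertex matrices, columns
#'   (row, col), 0-based pixel coordinates; pixel centres inside (or on) the
#'   polygon belong to the ROI.
#' @param pixel_size_um optional pixel size for um^2 areas.
#' @return list(per_roi data.frame, weighted_mean_mgv, total_area_px,
#'   total_integrated_density).
#' @export
quantify_tracts <- function(projection, roi_polygons, pixel_size_um = NULL) {
  stopifnot(is.list(roi_polygons), length(roi_polygons) == 2L)
  nr <- nrow(projection)
  per <- lapply(seq_along(roi_polygons), function(k) {
    poly <- roi_polygons[[k]]
    stopifnot(is.matrix(poly), ncol(poly) == 2L)
    rr <- range(poly[, 1]); cr <- range(poly[, 2])
    rs <- max(0, floor(rr[1])):min(nr - 1, ceiling(rr[2]))
    cs <- max(0, floor(cr[1])):min(ncol(projection) - 1, ceiling(cr[2]))
    pr <- rep(rs, times = length(cs))
    pc <- rep(cs, each = length(rs))
    inside <- points_in_polygon(pr, pc, poly)
    if (!any(inside)) stop("empty ROI polygon (no pixel centres inside)")
    vals <- projection[cbind(pr[inside] + 1L, pc[inside] + 1L)]
    area <- sum(inside)
    mgv <- mean(vals)
    data.frame(roi = k, area_px = area,
               area_um2 = if (is.null(pixel_size_um)) NA_real_ else
                 area * pixel_size_um^2,
               mgv = mgv, integrated_density = area * mgv)
  })
  per <- do.call(rbind, per)
  wmgv <- sum(per$area_px * per$mgv) / sum(per$area_px)
  list(per_roi = per, weighted_mean_mgv = wmgv,
       total_area_px = sum(per$area_px),
       total_integrated_density = wmgv * sum(per$area_px))
}
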