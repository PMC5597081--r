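# Flow-cytometry post-processing: geometric means and the transferrin
# recycling / uptake normalization chains.

#' Geometric mean of a cytometry population
#'
#' `exp(mean(log x))`, the standard flow-cytometry population summary.
#' Non-positive events are dropped with a warning count (log undefined);
#' an empty population after filtering is an error.
#'
#' @param x numeric vector of per-event fluorescence, or an event-table
#'   data.frame with a `fluorescence` column.
#' @return geometric mean.
#' @export
geometric_mean <- function(x) {
  if (is.data.frame(x)) x <- x$fluorescence
  bad <- sum(!is.finite(x) | x <= 0)
  if (bad > 0) {
    warning(bad, " non-positive event(s) dropped from geometric mean")
    x <- x[is.finite(x) & x > 0]
  }
  if (length(x) == 0L) stop("no positive events to summarize")
  exp(mean(log(x)))
}

#' Transferrin efflux normalization chain
#'
#' Per condition, the intracellular-label geometric mean at each efflux
#' timepoint is divided by that condition's saturated level at t = 0 (after
#' the 45-minute uptake pre-incubation); all conditions are then divided by
#' the reference condition's value at the 7.5-minute anchor and expressed in
#' percent, so the reference condition maps to exactly 100% at 7.5 min.
#'
#' @param events event-table data.frame (fluorescence, condition,
#'   timepoint).
#' @param reference reference condition name (the anchor, e.g. the resting /
#'   elevated-signaling cells).
#' @param anchor_time anchor timepoint in minutes (default 7.5).
#' @return data.frame of class `gj_efflux_curve` (condition, timepoint,
#'   geometric_mean, saturation_normalized, percent_remaining).
#' @export
efflux_normalize <- function(events, reference, anchor_time = 7.5) {
  stopifnot(all(c("fluorescence", "condition", "timepoint") %in% names(events)))
  if (!reference %in% events$condition)
    stop("reference condition '", reference, "' not present")
  g <- aggregate(fluorescence ~ condition + timepoint, data = events,
                 FUN = function(v) exp(mean(log(v[v > 0]))))
  names(g)[3] <- "geometric_mean"
  conds <- unique(g$condition)
  sat <- setNames(rep(NA_real_, length(conds)), conds)
  for (cn in conds) {
    row0 <- g$condition == cn & g$timepoint == 0
    if (!any(row0))
      stop("missing saturation population (t = 0) for condition '", cn, "'")
    sat[cn] <- g$geometric_mean[row0][1]
  }
  g$saturation_normalized <- g$geometric_mean / sat[g$condition]
  ref_row <- g$condition == reference & g$timepoint == anchor_time
  if (!any(ref_row))
    stop("missing anchor population: reference '", reference,
         "' at t = ", anchor_time, " min")
  anchor <- g$saturation_normalized[ref_row][1]
  g$percent_remaining <- 100 * g$saturation_normalized / anchor
  g <- g[order(g$condition, g$timepoint), ]
  rownames(g) <- NULL
  class(g) <- c("gj_efflux_curve", "data.frame")
  g
}

#' Surface-to-total receptor ratio with isotype background subtraction
#'
#' `(g(surface) - g(isotype_surface)) / (g(total) - g(isotype_total))`
#' using geometric means; isotype controls measure background staining and
#' are subtracted (a documented choice, configurable upstream).
#'
#' @param surface_events,total_events target-stain populations (vectors or
#'   event tables).
#' @param isotype_surface,isotype_total isotype-control populations, or
#'   numeric 0 for no background.
#' @return the ratio (scalar).
#' @export
surface_total_ratio <- function(surface_events, total_events,
                                isotype_surface = 0, isotype_total = 0) {
  gm_or_0 <- function(x) {
    if (is.numeric(x) && length(x) == 1L && x == 0) return(0)
    geometric_mean(x)
  }
  num <- geometric_mean(surface_events) - gm_or_0(isotype_surface)
  den <- geometric_mean(total_events) - gm_or_0(isotype_total)
  if (den <= 0)
    stop("total-receptor signal does not exceed isotype background; ",
         "staining failed")
  if (num < 0)
    warning("surface signal below isotype background; ratio is negative")
  num / den
}

#' Normalize transferrin uptake by the surface/total receptor ratio
#'
#' Uptake geometric mean divided by the sample's surface-to-total receptor
#' ratio, expressed relative to the control sample's ratio-normalized
#' uptake.  Invariant under joint rescaling of instrument gain.
#'
#' @param uptake_events sample uptake population.
#' @param ratio sample [surface_total_ratio()].
#' @param control_uptake_events,control_ratio control population and ratio;
#'   omit both to get the un-referenced normalized uptake.
#' @return normalized uptake (control = 1 when a control is given).
#' @export
uptake_normalize <- function(uptake_events, ratio,
                             control_uptake_events = NULL,
                             control_ratio = NULL) {
  assert_positive(ratio, "surface/total ratio")
  val <- geometric_mean(uptake_events) / ratio
  if (is.null(control_uptake_events)) return(val)
  assert_positive(control_ratio, "control surface/total ratio")
  val / (geometric_mean(control_uptake_events) / control_ratio)
}
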