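# Trace analysis: evoked-response latency, response frequency, and
# fluorogenic enzyme kinetics.

#' Response latency from stimulation artifact to EPSP onset
#'
#' For each stimulus marker: the artifact onset is the first sample whose
#' |dV/dt| exceeds half the window's peak slope inside the artifact window;
#' after blanking, the EPSP onset is coarsely located as the first sample
#' exceeding baseline mean + `k_sd` x SD for `persist` consecutive samples,
#' then refined to sub-sample precision by least-squares fitting of a
#' flat-then-exponential-rise model over a short window (grid over onset
#' time and rise constant, continuous refinement of the onset).  Latency is
#' EPSP onset minus artifact onset; a stimulus with no onset inside the
#' response window is flagged a failure (not an error) and excluded from
#' the mean.
#'
#' @param trace a `gj_trace` (see [make_trace()]) or a list with `time_ms`,
#'   `voltage_mv`, `sampling_rate_hz`, `stim_times_ms`.
#' @param k_sd EPSP onset criterion in baseline SDs.
#' @param persist samples the criterion must hold.
#' @param artifact_window_ms half-width of the artifact search window.
#' @param blank_ms post-artifact blanking.
#' @param response_window_ms maximal latency searched.
#' @param baseline_window_ms baseline interval (default: trace start to 1 ms
#'   before the first stimulus).
#' @param refine logical; disable to keep the coarse threshold onset.
#' @return a `gj_latency_result`: per-stimulus table, `mean_latency_ms`
#'   (over responses only), `sd_latency_ms`, `response_probability`.
#' @export
detect_latency <- function(trace, k_sd = 3, persist = 5,
                           artifact_window_ms = 1, blank_ms = 0.2,
                           response_window_ms = 10,
                           baseline_window_ms = NULL, refine = TRUE) {
  t <- trace$time_ms; v <- trace$voltage_mv
  fs <- trace$sampling_rate_hz
  stims <- trace$stim_times_ms
  if (length(stims) < 1L) stop("at least one stimulus marker required")
  dt <- 1000 / fs
  if (is.null(baseline_window_ms))
    baseline_window_ms <- c(0, max(dt, min(stims) - 1))
  bl <- v[t >= baseline_window_ms[1] & t <= baseline_window_ms[2]]
  if (length(bl) < 10L) stop("baseline window too short")
  sdev <- stats::sd(bl)
  dv <- c(0, diff(v))
  res <- lapply(stims, function(s) {
    # local baseline just before this stimulus (robust to residual decay
    # from a preceding response); falls back to the global window
    bl_s <- v[t >= s - 6 & t <= s - 1]
    b <- if (length(bl_s) >= 10L) mean(bl_s) else mean(bl)
    win <- which(t >= s - artifact_window_ms & t <= s + artifact_window_ms)
    if (length(win) < 2L) stop("stimulus marker outside trace")
    peak_slope <- max(abs(dv[win]))
    if (peak_slope < 8 * stats::sd(diff(bl)) || peak_slope == 0)
      stop("no stimulation artifact found near t = ", s, " ms")
    hot <- win[abs(dv[win]) >= 0.5 * peak_slope]
    art_idx <- min(hot)
    art_end <- max(hot)
    art_time <- t[art_idx]
    search0 <- t[art_end] + blank_ms
    search <- which(t > search0 & t <= s + response_window_ms)
    thr <- b + k_sd * sdev
    above <- v[search] > thr
    coarse <- if (length(above) >= persist) first_run(above, persist) else
      NA_integer_
    if (is.na(coarse))
      return(data.frame(stim_time_ms = s, artifact_time_ms = art_time,
                        onset_time_ms = NA_real_, latency_ms = NA_real_,
                        responded = FALSE))
    onset_idx <- search[coarse]
    onset_time <- t[onset_idx]
    if (refine) {
      onset_time <- refine_onset(t, v, i0 = max(search[1],
                                                onset_idx - round(1.5 / dt)),
                                 i1 = min(length(t),
                                          onset_idx + round(1.0 / dt)),
                                 coarse_idx = onset_idx, dt = dt)
    }
    data.frame(stim_time_ms = s, artifact_time_ms = art_time,
               onset_time_ms = onset_time,
               latency_ms = onset_time - art_time, responded = TRUE)
  })
  per <- do.call(rbind, res)
  lat <- per$latency_ms[per$responded]
  structure(list(per_stimulus = per,
                 mean_latency_ms = if (length(lat)) mean(lat) else NA_real_,
                 sd_latency_ms = if (length(lat) > 1) stats::sd(lat) else
                   if (length(lat) == 1) 0 else NA_real_,
                 n_responses = sum(per$responded),
                 response_probability = mean(per$responded)),
            class = "gj_latency_result")
}

#' @export
print.gj_latency_result <- function(x, ...) {
  cat(sprintf(
    "<latency> mean %.3f ms (sd %.3f) over %d/%d responses\n",
    x$mean_latency_ms, x$sd_latency_ms, x$n_responses,
    nrow(x$per_stimulus)))
  invisible(x)
}

# first index at which `persist` consecutive TRUEs begin, NA if none
first_run <- function(x, persist) {
  if (persist <= 1L) return(if (any(x)) which(x)[1] else NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persist)
  if (length(hit) == 0L) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

# sub-sample EPSP onset: fit v ~ b + A*(1-exp(-(t-t0)/tau)) for t >= t0,
# flat before; grid over (t0, tau), then continuous t0 refinement.
refine_onset <- function(t, v, i0, i1, coarse_idx, dt) {
  idx <- i0:i1
  tt <- t[idx]; vv <- v[idx]
  taus <- c(0.2, 0.35, 0.5, 0.75, 1, 1.5, 2.5)
  cand <- t[max(i0, coarse_idx - round(1.2 / dt)):coarse_idx]
  rss_of <- function(t0, tau) {
    x <- ifelse(tt >= t0, 1 - exp(-(tt - t0) / tau), 0)
    sx <- sum(x); sxx <- sum(x * x); sy <- sum(vv); sxy <- sum(x * vv)
    n <- length(x)
    den <- n * sxx - sx * sx
    if (den <= 0) return(sum((vv - mean(vv))^2))
    slope <- (n * sxy - sx * sy) / den
    if (slope < 0) return(sum((vv - mean(vv))^2))
    inter <- (sy - slope * sx) / n
    sum((vv - inter - slope * x)^2)
  }
  grid <- expand.grid(t0 = cand, tau = taus)
  rss <- mapply(rss_of, grid$t0, grid$tau)
  best <- grid[which.min(rss), ]
  opt <- stats::optimize(function(t0) rss_of(t0, best$tau),
                         interval = c(best$t0 - dt, best$t0 + dt))
  opt$minimum
}

#' Response frequency in a time window
#'
#' Counts suprathreshold depolarization events (upward crossings of a
#' robust baseline + `k_mad` x MAD criterion, with a refractory separation)
#' and divides by the window duration.  With the default relative
#' criterion, the frequency is invariant to rescaling the voltage.
#'
#' @param trace a `gj_trace`.
#' @param window_s analysis window duration in seconds (default 5, the
#'   air-puff protocol readout).
#' @param start_ms window start.
#' @param k_mad event criterion in MADs above the median voltage; or give
#'   `threshold` directly.
#' @param threshold optional absolute voltage threshold (overrides k_mad).
#' @param min_separation_ms refractory separation between counted events.
#' @return frequency in Hz, with attributes `n_events`, `event_times_ms`.
#' @export
response_frequency <- function(trace, window_s = 5, start_ms = 0,
                               k_mad = 8, threshold = NULL,
                               min_separation_ms = 20) {
  t <- trace$time_ms; v <- trace$voltage_mv
  end_ms <- start_ms + window_s * 1000
  if (start_ms < t[1] - 1e-9 || end_ms > t[length(t)] + 1e-9)
    stop("analysis window exceeds trace extent")
  sel <- t >= start_ms & t <= end_ms
  vv <- v[sel]; tt <- t[sel]
  if (is.null(threshold))
    threshold <- stats::median(vv) + k_mad * stats::mad(vv)
  above <- vv > threshold
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  keep <- numeric(0)
  last <- -Inf
  for (i in onsets) {
    if (tt[i] - last >= min_separation_ms) {
      keep <- c(keep, tt[i]); last <- tt[i]
    }
  }
  structure(length(keep) / window_s, n_events = length(keep),
            event_times_ms = keep)
}

#' Proteasome activity as the slope of AMC accumulation
#'
#' Ordinary least-squares fit of fluorescence against time over the full
#' series (or a configurable sub-range); activity is the slope.
#'
#' @param series data.frame(time_min, fluorescence) with >= 3 points (e.g.
#'   [make_kinetic_series()]).
#' @param t_range optional c(min, max) sub-range of times to fit.
#' @return a `gj_kinetic_fit` list: slope (a.u./min), intercept,
#'   r_squared, slope_se, n.
#' @export
proteasome_slope <- function(series, t_range = NULL) {
  stopifnot(all(c("time_min", "fluorescence") %in% names(series)))
  d <- series
  if (!is.null(t_range))
    d <- d[d$time_min >= t_range[1] & d$time_min <= t_range[2], ]
  if (nrow(d) < 3L) stop("at least 3 points required for a kinetic slope")
  if (any(diff(d$time_min) <= 0)) stop("time must be strictly increasing")
  # closed-form OLS (avoids summary.lm's perfect-fit warning on noiseless
  # calibration series)
  t <- d$time_min; y <- d$fluorescence; n <- length(t)
  sxx <- sum((t - mean(t))^2)
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  rss <- sum((y - intercept - slope * t)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = slope,
                 intercept = intercept,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 slope_se = sqrt(rss / (n - 2) / sxx),
                 n = n),
            class = "gj_kinetic_fit")
}

#' @export
print.gj_kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic fit> slope %.4g a.u./min (se %.3g, R^2 %.4f, n=%d)\n",
              x$slope, x$slope_se, x$r_squared, x$n))
  invisible(x)
}
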