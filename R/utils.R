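# Shared helpers: seeded RNG scoping, thresholding policies, geometry.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Otsu threshold of an intensity image
#'
#' Maximizes between-class variance over a 256-bin histogram; the standard
#' reproducible stand-in for the "arbitrary fluorescence intensity" thresholds
#' of manual high-content protocols.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- as.numeric(tabulate(pmin(nbins, 1L + floor((v - r[1]) / (r[2] - r[1]) * nbins)),
                           nbins))
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * (r[2] - r[1])
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- n - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[ok] <- (mt * w0[ok] - n * m0[ok])^2 / (w0[ok] * w1[ok])
  k <- which.max(bcv)
  # boundary between bins k and k+1
  r[1] + k / nbins * (r[2] - r[1])
}

#' Two-threshold (three-class) Otsu
#'
#' Exhaustively maximizes between-class variance over all threshold pairs on
#' a 128-bin histogram; the standard multilevel-Otsu generalization for
#' images with background, moderate, and bright classes (e.g. background /
#' cytoplasm / membrane rim).
#'
#' @param x numeric vector or matrix of intensities.
#' @return c(lower, upper) thresholds.
#' @export
otsu_thresholds3 <- function(x) {
  nbins <- 128L
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2]) return(c(r[1], r[1]))
  h <- as.numeric(tabulate(pmin(nbins, 1L + floor((v - r[1]) / (r[2] - r[1]) * nbins)),
                           nbins))
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * (r[2] - r[1])
  W <- c(0, cumsum(h))
  M <- c(0, cumsum(h * mids))
  cls <- function(a, b) {       # bins (a+1)..b
    w <- W[b + 1] - W[a + 1]
    if (w <= 0) return(0)
    m <- (M[b + 1] - M[a + 1]) / w
    w * m * m
  }
  best <- -Inf; bi <- c(1L, 2L)
  for (t1 in 1:(nbins - 2L)) {
    for (t2 in (t1 + 1L):(nbins - 1L)) {
      s <- cls(0L, t1) + cls(t1, t2) + cls(t2, nbins)
      if (s > best) { best <- s; bi <- c(t1, t2) }
    }
  }
  r[1] + bi / nbins * (r[2] - r[1])
}

# Resolve a threshold policy to a numeric cutoff.
# Policies:
#   numeric            absolute value
#   "otsu"             one-level Otsu on the whole image
#   "otsu-upper"       Otsu within the foreground of a first Otsu pass
#   "otsu3-lower"      lower threshold of a three-class Otsu (foreground =
#                      everything above background when a brighter third
#                      class exists, e.g. cytoplasm + membrane rim)
#   "otsu3-upper"      upper threshold of a three-class Otsu (the brightest
#                      class only, e.g. the membrane rim)
#   "halfmax"          background + half the robust peak-to-background range
#                      (object extent at half maximum, the diffraction-limited
#                      spot convention)
#   "quantile:q"       the q quantile of the image
resolve_threshold <- function(img, policy) {
  if (is.numeric(policy)) return(as.numeric(policy)[1])
  stopifnot(is.character(policy), length(policy) == 1L)
  if (policy == "otsu") return(otsu_threshold(img))
  if (policy == "otsu-upper") {
    t1 <- otsu_threshold(img)
    fg <- img[img > t1]
    if (length(fg) < 2L) return(t1)
    return(otsu_threshold(fg))
  }
  if (policy == "otsu3-lower") return(otsu_thresholds3(img)[1])
  if (policy == "otsu3-upper") return(otsu_thresholds3(img)[2])
  if (policy == "halfmax") {
    bg <- stats::median(img)
    pk <- stats::quantile(img, 0.999, names = FALSE)
    return(bg + 0.5 * (pk - bg))
  }
  if (startsWith(policy, "quantile:")) {
    q <- as.numeric(sub("^quantile:", "", policy))
    return(stats::quantile(img, q, names = FALSE))
  }
  stop("unknown threshold policy: ", policy)
}

# Connected-component labelling wrappers around the C++ kernels.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  .cpp_label2d(mask, as.integer(connectivity))
}

label_components_3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- .cpp_label3d(as.logical(mask), d[1], d[2], d[3],
                      as.integer(connectivity))
  array(lab, dim = d)
}

# Per-label region properties of a 2D label matrix.
# Returns data.frame(label, area_px, centroid_row, centroid_col,
# equivalent_diameter_px, integrated_intensity, mean_intensity).
region_props <- function(labels, intensity = NULL) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      equivalent_diameter_px = numeric(),
                      integrated_intensity = numeric(),
                      mean_intensity = numeric()))
  }
  l <- labels[idx]
  nr <- nrow(labels)
  ri <- (idx - 1L) %% nr           # 0-based row
  ci <- (idx - 1L) %/% nr          # 0-based col
  area <- tabulate(l)
  keep <- which(area > 0L)
  cr <- rowsum(as.numeric(ri), l)[, 1] / area[keep]
  cc <- rowsum(as.numeric(ci), l)[, 1] / area[keep]
  out <- data.frame(
    label = keep,
    area_px = area[keep],
    centroid_row = as.numeric(cr),
    centroid_col = as.numeric(cc),
    equivalent_diameter_px = 2 * sqrt(area[keep] / pi)
  )
  if (!is.null(intensity)) {
    s <- rowsum(as.numeric(intensity[idx]), l)[, 1]
    out$integrated_intensity <- as.numeric(s)
    out$mean_intensity <- out$integrated_intensity / out$area_px
  } else {
    out$integrated_intensity <- NA_real_
    out$mean_intensity <- NA_real_
  }
  rownames(out) <- NULL
  out
}

# Solidity (area / convex hull area) per label, for circular-shape gating.
region_solidity <- function(labels) {
  labs <- sort(unique(labels[labels > 0L]))
  nr <- nrow(labels)
  out <- setNames(numeric(length(labs)), labs)
  for (k in seq_along(labs)) {
    idx <- which(labels == labs[k])
    r <- (idx - 1L) %% nr
    c <- (idx - 1L) %/% nr
    pts <- cbind(r, c)
    if (nrow(pts) < 3L) { out[k] <- 1; next }
    h <- grDevices::chull(pts)
    hull <- pts[h, , drop = FALSE]
    # shoelace area of pixel-centre hull plus ~1 px border correction
    xs <- hull[, 1]; ys <- hull[, 2]
    a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    peri <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ])^2)))
    hull_area <- a + peri / 2 + 1   # Pick-style dilation to pixel area
    out[k] <- min(1, length(idx) / hull_area)
  }
  out
}

# Even-odd point-in-polygon test for pixel centres.  poly: matrix (row, col),
# 0-based vertex coordinates.  Half-open semantics: lower/left edges are
# inside, upper/right edges outside, so adjacent ROIs never double-count.
points_in_polygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & (yj != yi))
    j <- i
  }
  inside
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

assert_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(what, " must be positive and finite", call. = FALSE)
  invisible(x)
}
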