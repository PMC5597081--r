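# Synthetic-data generators with exact ground truth.
#
# The generators emulate the statistical structure of the assays the
# quantification stack consumes: confluent-ish epithelial monolayers imaged in
# up to six channels, confocal z-stacks of bright blobs, log-normal cytometry
# populations, linear enzyme kinetics, and intracellular traces with a
# stimulation artifact followed by an EPSP.

# truncated-normal sampler (rejection; bounds are generous so this is cheap)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(2L * n, 16L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# additive rendering of an isotropic Gaussian spot, FWHM = diameter
add_gaussian_spot <- function(img, row0, col0, amplitude, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- ceiling(1.0 * fwhm)   # truncate far tails (~6% of peak at the rim)
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(0, floor(row0 - w)):min(nr - 1, ceiling(row0 + w))
  cs <- max(0, floor(col0 - w)):min(nc - 1, ceiling(col0 + w))
  if (length(rs) == 0L || length(cs) == 0L) return(img)
  dr2 <- (rs - row0)^2
  dc2 <- (cs - col0)^2
  patch <- amplitude * exp(-(outer(dr2, dc2, "+")) / (2 * sigma^2))
  img[rs + 1, cs + 1] <- img[rs + 1, cs + 1] + patch
  img
}

add_disk <- function(img, row0, col0, diameter, value) {
  r <- diameter / 2
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(0, floor(row0 - r)):min(nr - 1, ceiling(row0 + r))
  cs <- max(0, floor(col0 - r)):min(nc - 1, ceiling(col0 + r))
  inside <- outer((rs - row0)^2, (cs - col0)^2, "+") <= r^2
  sub <- img[rs + 1, cs + 1]
  sub[inside] <- value
  img[rs + 1, cs + 1] <- sub
  img
}

# smooth multiplicative illumination field: random quadratic polynomial over
# [-1,1]^2, scaled so max |deviation| = amplitude, then mean-normalized to 1
make_gain_field <- function(shape, amplitude) {
  if (amplitude <= 0) return(matrix(1, shape[1], shape[2]))
  x <- seq(-1, 1, length.out = shape[2])
  y <- seq(-1, 1, length.out = shape[1])
  cf <- rnorm(5)
  p <- outer(y, x, function(yy, xx)
    cf[1] * xx + cf[2] * yy + cf[3] * xx * yy + cf[4] * xx^2 + cf[5] * yy^2)
  p <- p / max(abs(p))
  g <- 1 + amplitude * p
  g / mean(g)
}

apply_camera_noise <- function(img, poisson_scale, gaussian_sd) {
  out <- img
  if (is.finite(poisson_scale) && poisson_scale > 0)
    out <- matrix(rpois(length(img), pmax(img, 0) * poisson_scale),
                  nrow(img), ncol(img)) / poisson_scale
  if (gaussian_sd > 0)
    out <- out + matrix(rnorm(length(img), 0, gaussian_sd), nrow(img), ncol(img))
  out
}

#' Parameters for a synthetic epithelial monolayer field
#'
#' Describes the stated world the 2D pipeline is validated against: a
#' near-confluent monolayer of `n_cells` cells laid out on a jittered grid,
#' each with a roughly circular nucleus, carrying `punctae_per_cell`
#' diffraction-limited punctae distributed over three subcellular compartments
#' (cell surface, early endosome, lysosome) with the given fractions.
#'
#' Nucleus and puncta diameters are drawn from truncated normal distributions
#' centred in the given ranges (mean at the midpoint, sd = width/8), so the
#' population sits strictly inside the detection gates that default to the
#' same ranges — as in the real assay, where the size filters are set to
#' bracket the observed population.
#'
#' @param field_shape image height and width in pixels.
#' @param n_cells number of cells; the generator errors if they cannot be
#'   packed without forced overlap.
#' @param nucleus_diameter_px admissible nucleus equivalent-diameter range.
#' @param puncta_diameter_px admissible puncta FWHM range.
#' @param punctae_per_cell punctae rendered per cell (rounded to an integer).
#' @param compartment_fractions proportions (surface, early endosome,
#'   lysosome); must sum to 1 within 1e-9.
#' @param transfected_fraction proportion of cells expressing the GFP
#'   construct; 0 suppresses the GFP channel.
#' @param gain_field_amplitude relative amplitude of the smooth multiplicative
#'   illumination bias (0.2 = +/-20 percent).
#' @param noise length-2 vector: Poisson photon scale (photons per intensity
#'   unit; 0 or Inf disables shot noise) and additive Gaussian read-noise sd.
#' @param pixel_size_um physical pixel size.
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @return an object of class `gj_monolayer_params`.
#' @export
monolayer_params <- function(field_shape = c(576L, 576L),
                             n_cells = 20L,
                             nucleus_diameter_px = c(20, 60),
                             puncta_diameter_px = c(8, 20),
                             punctae_per_cell = 10,
                             compartment_fractions = c(surface = 0.60,
                                                       early_endosome = 0.25,
                                                       lysosome = 0.15),
                             transfected_fraction = 0,
                             gain_field_amplitude = 0.2,
                             noise = c(poisson_scale = 200, gaussian_sd = 0.01),
                             pixel_size_um = 0.325,
                             seed = NULL) {
  stopifnot(length(field_shape) == 2L, all(field_shape > 0),
            length(nucleus_diameter_px) == 2L,
            length(puncta_diameter_px) == 2L,
            length(compartment_fractions) == 3L,
            length(noise) == 2L)
  assert_positive(nucleus_diameter_px, "nucleus_diameter_px")
  assert_positive(puncta_diameter_px, "puncta_diameter_px")
  if (abs(sum(compartment_fractions) - 1) > 1e-9)
    stop("compartment_fractions must sum to 1 (within 1e-9)")
  if (any(compartment_fractions < 0))
    stop("compartment_fractions must be non-negative")
  if (n_cells < 0 || punctae_per_cell < 0)
    stop("n_cells and punctae_per_cell must be non-negative")
  if (transfected_fraction < 0 || transfected_fraction > 1)
    stop("transfected_fraction must lie in [0, 1]")
  p <- list(field_shape = as.integer(field_shape), n_cells = as.integer(n_cells),
            nucleus_diameter_px = as.numeric(nucleus_diameter_px),
            puncta_diameter_px = as.numeric(puncta_diameter_px),
            punctae_per_cell = punctae_per_cell,
            compartment_fractions = as.numeric(compartment_fractions),
            transfected_fraction = transfected_fraction,
            gain_field_amplitude = gain_field_amplitude,
            noise = as.numeric(noise), pixel_size_um = pixel_size_um,
            seed = seed)
  class(p) <- "gj_monolayer_params"
  # packing feasibility: every grid slot must hold the largest nucleus with
  # room to spare after jitter
  if (p$n_cells > 0) {
    lay <- monolayer_layout(p)
    if (min(lay$spacing) * 0.8 < max(p$nucleus_diameter_px) + 4)
      stop("packing failure: ", p$n_cells, " cells with nuclei up to ",
           max(p$nucleus_diameter_px), " px do not fit a ",
           p$field_shape[1], "x", p$field_shape[2], " field")
  }
  p
}

# grid layout used for cell placement (also consulted by the packing check)
monolayer_layout <- function(p) {
  H <- p$field_shape[1]; W <- p$field_shape[2]; n <- p$n_cells
  ncol_g <- max(1L, ceiling(sqrt(n * W / H)))
  nrow_g <- ceiling(n / ncol_g)
  list(nrow = nrow_g, ncol = ncol_g,
       spacing = c(H / nrow_g, W / ncol_g))
}

empty_puncta_truth <- function() {
  data.frame(puncta_id = integer(), row = numeric(), col = numeric(),
             diameter_px = numeric(),
             compartment = character(), cell_label = integer(),
             transfected = logical(), amplitude = numeric())
}

#' Simulate a multi-channel monolayer field with exact ground truth
#'
#' Renders channels `DNA`, `CX43`, `ITGA3`, `EEA1`, `LAMP1` (and `GFP` when
#' `transfected_fraction > 0`).  Nuclei are hard disks; punctae are isotropic
#' Gaussians with FWHM equal to their recorded diameter.  Surface-compartment
#' punctae sit on the ITGA3-positive rim at cell-cell interfaces (where gap
#' junctions live) and are co-rendered into the ITGA3 channel;
#' early-endosome/lysosome punctae are co-rendered into EEA1/LAMP1 at the same
#' position so that object-level colocalization is exactly recoverable.  A
#' smooth multiplicative gain field and Poisson-Gaussian camera noise are
#' applied last.
#'
#' @param params a [monolayer_params()] object.
#' @return list with elements `images` (a [image_set()]) and `truth`, a
#'   `gj_ground_truth` list carrying nucleus centroids, the cell label mask,
#'   the puncta records, the transfected cell set, the rim mask and the clean
#'   gain field.
#' @export
make_monolayer <- function(params) {
  stopifnot(inherits(params, "gj_monolayer_params"))
  with_seed(params$seed, make_monolayer_impl(params))
}

make_monolayer_impl <- function(p) {
  H <- p$field_shape[1]; W <- p$field_shape[2]
  bg <- 0.05
  blank <- matrix(bg, H, W)
  chans <- list(DNA = blank, CX43 = blank, ITGA3 = blank,
                EEA1 = blank, LAMP1 = blank)
  if (p$transfected_fraction > 0) chans$GFP <- matrix(0.03, H, W)

  truth <- list(nucleus_centroids = matrix(numeric(0), 0, 2,
                                           dimnames = list(NULL, c("row", "col"))),
                cell_mask = matrix(0L, H, W),
                puncta = empty_puncta_truth(),
                transfected_cells = integer(0),
                rim_mask = matrix(FALSE, H, W),
                gain = matrix(1, H, W))
  class(truth) <- "gj_ground_truth"

  if (p$n_cells > 0) {
    lay <- monolayer_layout(p)
    slots <- seq_len(p$n_cells) - 1L
    gr <- slots %/% lay$ncol
    gc <- slots %% lay$ncol
    jit <- 0.10
    cr <- (gr + 0.5) * lay$spacing[1] +
      runif(p$n_cells, -jit, jit) * lay$spacing[1]
    cc <- (gc + 0.5) * lay$spacing[2] +
      runif(p$n_cells, -jit, jit) * lay$spacing[2]
    # cells cover ~85-90% of the field: near-confluent, but with enough
    # background for a bimodal foreground threshold, as in real monolayers
    r_cell <- 0.55 * max(lay$spacing)

    # nearest / second-nearest centre per pixel (vectorized over cells)
    px_r <- matrix(rep(0:(H - 1), W), H, W)
    px_c <- matrix(rep(0:(W - 1), each = H), H, W)
    d1 <- matrix(Inf, H, W); d2 <- matrix(Inf, H, W)
    n1 <- matrix(0L, H, W)
    for (k in seq_len(p$n_cells)) {
      dk <- sqrt((px_r - cr[k])^2 + (px_c - cc[k])^2)
      closer <- dk < d1
      d2 <- pmin(d2, ifelse(closer, d1, dk))
      d1[closer] <- dk[closer]
      n1[closer] <- k
    }
    cell_mask <- ifelse(d1 <= r_cell, n1, 0L)
    storage.mode(cell_mask) <- "integer"
    # inset the monolayer from the field border so no cell rim touches the
    # image edge: edge-clipped objects would have unrecoverable truth
    inset <- 14L
    cell_mask[c(seq_len(inset), H - seq_len(inset) + 1L), ] <- 0L
    cell_mask[, c(seq_len(inset), W - seq_len(inset) + 1L)] <- 0L

    # distance of each cell pixel to its boundary (different label or bg)
    b_mask <- cell_mask > 0L
    same <- b_mask
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shift_matrix(cell_mask, sh[1], sh[2], fill = -1L)
      same <- same & (nb == cell_mask)
    }
    Db <- .cpp_chamfer(same)          # 0 on boundary pixels, grows inward
    rim <- b_mask & Db <= 3
    interface <- (d2 - d1 < 12) & (d2 <= r_cell)
    rim_if <- rim & interface

    # nuclei
    nd <- rtrunc_norm(p$n_cells,
                      mean(p$nucleus_diameter_px),
                      diff(p$nucleus_diameter_px) / 8,
                      p$nucleus_diameter_px[1], p$nucleus_diameter_px[2])
    nuc_r <- cr + runif(p$n_cells, -4, 4)
    nuc_c <- cc + runif(p$n_cells, -4, 4)
    for (k in seq_len(p$n_cells))
      chans$DNA <- add_disk(chans$DNA, nuc_r[k], nuc_c[k], nd[k], bg + 1)

    # transfected cells: exact count, sampled without replacement
    n_tf <- round(p$transfected_fraction * p$n_cells)
    tf_cells <- sort(sample(seq_len(p$n_cells), n_tf))
    if (!is.null(chans$GFP) && n_tf > 0)
      chans$GFP[cell_mask %in% tf_cells] <- chans$GFP[cell_mask %in% tf_cells] + 0.8

    # ITGA3: moderate cytoplasmic signal, bright rim
    chans$ITGA3 <- chans$ITGA3 + 0.5 * (cell_mask > 0L)
    chans$ITGA3[rim] <- bg + 1.0

    # punctae
    ppc <- round(p$punctae_per_cell)
    n_p <- ppc * p$n_cells
    pt <- empty_puncta_truth()
    if (n_p > 0) {
      comp <- sample(c("surface", "EE", "LYS"), n_p, replace = TRUE,
                     prob = p$compartment_fractions)
      own <- rep(seq_len(p$n_cells), each = ppc)
      # candidate pixel pools per cell: interface rim (preferred for surface
      # punctae, where gap junctions live), whole rim (fallback), interior
      cand_if <- lapply(seq_len(p$n_cells), function(k)
        which(rim_if & cell_mask == k))
      cand_rim <- lapply(seq_len(p$n_cells), function(k)
        which(rim & cell_mask == k))
      place_all <- function(dia) {
        pr <- numeric(n_p); pc <- numeric(n_p)
        placed_r <- numeric(0); placed_c <- numeric(0); placed_d <- numeric(0)
        for (i in sample.int(n_p)) {     # random order eases tight packings
          cidx <- own[i]
          pools <- if (comp[i] == "surface")
            list(cand_if[[cidx]], cand_rim[[cidx]])
          else
            list(which(cell_mask == cidx & Db >= dia[i] / 2 + 4))
          # keep the above-half-max footprint fully inside the field: an
          # edge-clipped spot has no recoverable size by construction
          bm <- ceiling(0.6 * dia[i])
          ok <- FALSE
          for (cand in pools) {
            if (length(cand) == 0L) next
            for (try in seq_len(200L)) {
              pick <- cand[sample.int(length(cand), 1L)]
              rr <- (pick - 1L) %% H
              cc2 <- (pick - 1L) %/% H
              if (rr < bm || rr > H - 1L - bm || cc2 < bm || cc2 > W - 1L - bm)
                next
              # resolvability: at 0.75*(d1+d2) separation the summed tails at
              # the midpoint stay below half-maximum, so spots never merge
              if (length(placed_r) == 0L ||
                  all((placed_r - rr)^2 + (placed_c - cc2)^2 >=
                      (0.75 * (placed_d + dia[i]) + 2)^2)) {
                pr[i] <- rr; pc[i] <- cc2; ok <- TRUE; break
              }
            }
            if (!ok) {
              # rejection sampling exhausted: compute the exact allowed set
              rrs <- (cand - 1L) %% H
              ccs <- (cand - 1L) %/% H
              allowed <- rrs >= bm & rrs <= H - 1L - bm &
                ccs >= bm & ccs <= W - 1L - bm
              for (j in seq_along(placed_r))
                allowed <- allowed &
                  ((rrs - placed_r[j])^2 + (ccs - placed_c[j])^2 >=
                     (0.75 * (placed_d[j] + dia[i]) + 2)^2)
              if (any(allowed)) {
                pick <- which(allowed)[sample.int(sum(allowed), 1L)]
                pr[i] <- rrs[pick]; pc[i] <- ccs[pick]; ok <- TRUE
              }
            }
            if (ok) break
          }
          if (!ok) return(NULL)
          placed_r <- c(placed_r, pr[i]); placed_c <- c(placed_c, pc[i])
          placed_d <- c(placed_d, dia[i])
        }
        list(pr = pr, pc = pc)
      }
      pos <- NULL
      for (attempt in seq_len(30L)) {
        dia <- rtrunc_norm(n_p, mean(p$puncta_diameter_px),
                           diff(p$puncta_diameter_px) / 8,
                           p$puncta_diameter_px[1], p$puncta_diameter_px[2])
        pos <- place_all(dia)
        if (!is.null(pos)) break
      }
      if (is.null(pos))
        stop("packing failure: could not place ", n_p,
             " punctae without overlap; lower punctae_per_cell or ",
             "enlarge the field")
      amp <- pmax(0.5, rnorm(n_p, 1, 0.05))
      pr <- pos$pr; pc <- pos$pc
      for (i in seq_len(n_p)) {
        chans$CX43 <- add_gaussian_spot(chans$CX43, pr[i], pc[i], amp[i], dia[i])
        if (comp[i] == "surface")
          chans$ITGA3 <- add_gaussian_spot(chans$ITGA3, pr[i], pc[i],
                                           0.6 * amp[i], dia[i])
        else if (comp[i] == "EE")
          chans$EEA1 <- add_gaussian_spot(chans$EEA1, pr[i], pc[i], amp[i], dia[i])
        else
          chans$LAMP1 <- add_gaussian_spot(chans$LAMP1, pr[i], pc[i], amp[i], dia[i])
      }
      pt <- data.frame(puncta_id = seq_len(n_p), row = pr, col = pc,
                       diameter_px = dia, compartment = comp, cell_label = own,
                       transfected = own %in% tf_cells, amplitude = amp)
    }

    truth$nucleus_centroids <- cbind(row = nuc_r, col = nuc_c)
    truth$cell_mask <- cell_mask
    truth$puncta <- pt
    truth$transfected_cells <- tf_cells
    truth$rim_mask <- rim
  }

  gain <- make_gain_field(c(H, W), p$gain_field_amplitude)
  truth$gain <- gain
  for (nm in names(chans))
    chans[[nm]] <- apply_camera_noise(chans[[nm]] * gain,
                                      p$noise[1], p$noise[2])

  list(images = image_set(chans, pixel_size_um = p$pixel_size_um,
                          well_id = "synthetic", site_id = 1L),
       truth = truth)
}

#' Simulate a confocal z-stack of gap-junction plaques
#'
#' Renders one spherical blob per requested volume at non-overlapping random
#' positions; the returned truth carries the requested analytic volumes
#' unchanged.  Optionally renders a marker channel (spheres co-centred on the
#' plaques flagged `interface`) for interface-colabeling tests.
#'
#' @param volumes_um3 numeric vector of plaque volumes in cubic microns.
#' @param shape stack dimensions (rows, cols, slices).
#' @param pixel_size_um xy pixel size in microns.
#' @param slice_increment_um z step in microns (default 0.4).
#' @param interface_flags optional logical vector (one per plaque); flagged
#'   plaques are co-rendered into a `marker` volume.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `volume` (a [volume_image()]), `marker` (a
#'   [volume_image()] or NULL) and `truth` data.frame
#'   (volume_um3, interface, row, col, slice).
#' @export
make_zstack <- function(volumes_um3, shape = c(96L, 96L, 36L),
                        pixel_size_um = 0.2, slice_increment_um = 0.4,
                        interface_flags = NULL, noise_sd = 0.01, seed = NULL) {
  assert_positive(c(pixel_size_um, slice_increment_um), "voxel size")
  stopifnot(length(shape) == 3L)
  if (length(volumes_um3) > 0) assert_positive(volumes_um3, "volumes_um3")
  if (is.null(interface_flags)) interface_flags <- rep(FALSE, length(volumes_um3))
  stopifnot(length(interface_flags) == length(volumes_um3))
  with_seed(seed, {
    bg <- 0.02
    vol <- array(bg, dim = shape)
    marker <- if (any(interface_flags)) array(bg, dim = shape) else NULL
    n <- length(volumes_um3)
    radii <- (3 * volumes_um3 / (4 * pi))^(1 / 3)     # um
    ctr <- matrix(NA_real_, n, 3)
    if (n > 0) {
      r_px <- cbind(radii / pixel_size_um, radii / pixel_size_um,
                    radii / slice_increment_um)
      for (i in order(radii, decreasing = TRUE)) {
        ok <- FALSE
        for (try in seq_len(500L)) {
          cand <- c(runif(1, r_px[i, 1] + 2, shape[1] - 1 - r_px[i, 1] - 2),
                    runif(1, r_px[i, 2] + 2, shape[2] - 1 - r_px[i, 2] - 2),
                    runif(1, r_px[i, 3] + 2, shape[3] - 1 - r_px[i, 3] - 2))
          sep_ok <- TRUE
          for (j in seq_len(n)) {
            if (j == i || is.na(ctr[j, 1])) next
            d_um <- sqrt(sum((c(pixel_size_um, pixel_size_um,
                                slice_increment_um) * (cand - ctr[j, ]))^2))
            if (d_um < radii[i] + radii[j] + 2 * pixel_size_um) {
              sep_ok <- FALSE; break
            }
          }
          if (sep_ok) { ctr[i, ] <- cand; ok <- TRUE; break }
        }
        if (!ok) stop("packing failure: plaques do not fit the stack")
      }
      # render spheres: voxel centre within physical radius
      for (i in seq_len(n)) {
        ri <- ceiling(r_px[i, ])
        rs <- max(0, floor(ctr[i, 1] - ri[1])):min(shape[1] - 1, ceiling(ctr[i, 1] + ri[1]))
        cs <- max(0, floor(ctr[i, 2] - ri[2])):min(shape[2] - 1, ceiling(ctr[i, 2] + ri[2]))
        zs <- max(0, floor(ctr[i, 3] - ri[3])):min(shape[3] - 1, ceiling(ctr[i, 3] + ri[3]))
        for (z in zs) {
          dz2 <- ((z - ctr[i, 3]) * slice_increment_um)^2
          d2 <- outer(((rs - ctr[i, 1]) * pixel_size_um)^2,
                      ((cs - ctr[i, 2]) * pixel_size_um)^2, "+") + dz2
          inside <- d2 <= radii[i]^2
          sl <- vol[rs + 1, cs + 1, z + 1]
          sl[inside] <- bg + 1
          vol[rs + 1, cs + 1, z + 1] <- sl
          if (interface_flags[i] && !is.null(marker)) {
            # marker sphere slightly larger so the plaque sits inside the band
            inside_m <- d2 <= (radii[i] + 2 * pixel_size_um)^2
            slm <- marker[rs + 1, cs + 1, z + 1]
            slm[inside_m] <- bg + 1
            marker[rs + 1, cs + 1, z + 1] <- slm
          }
        }
      }
    }
    if (noise_sd > 0) {
      vol <- vol + array(rnorm(length(vol), 0, noise_sd), dim = shape)
      if (!is.null(marker))
        marker <- marker + array(rnorm(length(marker), 0, noise_sd), dim = shape)
    }
    truth <- data.frame(volume_um3 = volumes_um3,
                        interface = interface_flags,
                        row = ctr[, 1], col = ctr[, 2], slice = ctr[, 3])
    list(volume = volume_image(vol, c(pixel_size_um, pixel_size_um,
                                      slice_increment_um)),
         marker = if (is.null(marker)) NULL else
           volume_image(marker, c(pixel_size_um, pixel_size_um,
                                  slice_increment_um)),
         truth = truth)
  })
}

#' Simulate a flow-cytometry event table
#'
#' Draws per-event fluorescence from a log-normal population whose geometric
#' mean is `10^log10_mean`, matching the per-cell summary flow protocols use.
#'
#' @param n_events number of events (>= 1).
#' @param log10_mean,log10_sd mean and sd of log10 fluorescence.
#' @param condition,timepoint,stain labels attached to every event.
#' @param seed integer seed.
#' @return a data.frame event table (event_id, fluorescence, condition,
#'   timepoint, stain).
#' @export
make_cytometry <- function(n_events, log10_mean, log10_sd,
                           condition = "A", timepoint = 0, stain = "target",
                           seed = NULL) {
  stopifnot(n_events >= 1, log10_sd >= 0)
  with_seed(seed, {
    v <- 10^rnorm(n_events, log10_mean, log10_sd)
    data.frame(event_id = seq_len(n_events), fluorescence = v,
               condition = condition, timepoint = timepoint, stain = stain)
  })
}

#' Parameters for a synthetic intracellular trace
#'
#' @param sampling_rate_hz sampling rate (default 40 kHz).
#' @param duration_ms trace length.
#' @param stim_times_ms stimulus times; each gets an artifact and (if
#'   `epsp_amplitude_mv > 0`) an EPSP starting `true_latency_ms` later.
#' @param artifact_amplitude_mv stimulation-artifact amplitude.
#' @param true_latency_ms latency from artifact onset to EPSP onset; must be
#'   at least one sample period.
#' @param epsp_amplitude_mv EPSP amplitude (0 = response failure).
#' @param epsp_rise_tau_ms,epsp_decay_tau_ms EPSP rise / decay time constants.
#' @param baseline_mv resting potential.
#' @param baseline_noise_sd_mv recording noise sd.
#' @param seed integer seed.
#' @return an object of class `gj_trace_params`.
#' @export
trace_params <- function(sampling_rate_hz = 40000,
                         duration_ms = 40,
                         stim_times_ms = 10,
                         artifact_amplitude_mv = 30,
                         true_latency_ms = 1.0,
                         epsp_amplitude_mv = 15,
                         epsp_rise_tau_ms = 0.5,
                         epsp_decay_tau_ms = 20,
                         baseline_mv = -70,
                         baseline_noise_sd_mv = 0.5,
                         seed = NULL) {
  assert_positive(sampling_rate_hz, "sampling_rate_hz")
  assert_positive(true_latency_ms, "true_latency_ms")
  if (true_latency_ms < 1000 / sampling_rate_hz)
    stop("true_latency_ms shorter than one sample period is undetectable")
  p <- list(sampling_rate_hz = sampling_rate_hz, duration_ms = duration_ms,
            stim_times_ms = stim_times_ms,
            artifact_amplitude_mv = artifact_amplitude_mv,
            true_latency_ms = true_latency_ms,
            epsp_amplitude_mv = epsp_amplitude_mv,
            epsp_rise_tau_ms = epsp_rise_tau_ms,
            epsp_decay_tau_ms = epsp_decay_tau_ms,
            baseline_mv = baseline_mv,
            baseline_noise_sd_mv = baseline_noise_sd_mv, seed = seed)
  class(p) <- "gj_trace_params"
  p
}

#' Simulate an intracellular voltage trace with artifact and EPSP
#'
#' The stimulation artifact is a sharp biphasic deflection starting exactly at
#' each stimulus time; the EPSP onset is at stimulus + `true_latency_ms`
#' (a continuous time, not snapped to the sample grid), rising as
#' `1 - exp(-t/tau_rise)` and decaying with `tau_decay`.
#'
#' @param params a [trace_params()] object.
#' @return a `gj_trace`: list(time_ms, voltage_mv, sampling_rate_hz,
#'   stim_times_ms, true_latency_ms).  `true_latency_ms` is NA when
#'   `epsp_amplitude_mv` is 0 (truth latency absent).
#' @export
make_trace <- function(params) {
  stopifnot(inherits(params, "gj_trace_params"))
  p <- params
  with_seed(p$seed, {
    dt <- 1000 / p$sampling_rate_hz
    t <- seq(0, p$duration_ms, by = dt)
    v <- rep(p$baseline_mv, length(t))
    for (s in p$stim_times_ms) {
      if (s < 0 || s > p$duration_ms) stop("stimulus time outside trace")
      art <- (t >= s) & (t < s + 0.1)
      art2 <- (t >= s + 0.1) & (t < s + 0.2)
      v[art] <- v[art] + p$artifact_amplitude_mv
      v[art2] <- v[art2] - 0.6 * p$artifact_amplitude_mv
      if (p$epsp_amplitude_mv > 0) {
        t0 <- s + p$true_latency_ms
        e <- t >= t0
        dtau <- t[e] - t0
        v[e] <- v[e] + p$epsp_amplitude_mv *
          (1 - exp(-dtau / p$epsp_rise_tau_ms)) *
          exp(-dtau / p$epsp_decay_tau_ms)
      }
    }
    if (p$baseline_noise_sd_mv > 0)
      v <- v + rnorm(length(v), 0, p$baseline_noise_sd_mv)
    structure(list(time_ms = t, voltage_mv = v,
                   sampling_rate_hz = p$sampling_rate_hz,
                   stim_times_ms = p$stim_times_ms,
                   true_latency_ms = if (p$epsp_amplitude_mv > 0)
                     p$true_latency_ms else NA_real_),
              class = "gj_trace")
  })
}

#' Simulate a trace of spontaneous/evoked muscle responses
#'
#' Renders one EPSP-like event per entry of `event_times_ms` over a noisy
#' baseline; used to validate response-frequency extraction from air-puff
#' recordings.
#'
#' @param event_times_ms event onset times.
#' @param duration_ms,sampling_rate_hz trace geometry.
#' @param amplitude_mv,rise_tau_ms,decay_tau_ms event kernel.
#' @param baseline_mv,noise_sd_mv baseline and noise.
#' @param seed integer seed.
#' @return a `gj_trace` without stimulus markers.
#' @export
make_event_trace <- function(event_times_ms, duration_ms = 5000,
                             sampling_rate_hz = 10000, amplitude_mv = 30,
                             rise_tau_ms = 1, decay_tau_ms = 8,
                             baseline_mv = -70, noise_sd_mv = 0.5,
                             seed = NULL) {
  with_seed(seed, {
    dt <- 1000 / sampling_rate_hz
    t <- seq(0, duration_ms, by = dt)
    v <- rep(baseline_mv, length(t))
    for (s in event_times_ms) {
      e <- t >= s
      dtau <- t[e] - s
      v[e] <- v[e] + amplitude_mv * (1 - exp(-dtau / rise_tau_ms)) *
        exp(-dtau / decay_tau_ms)
    }
    if (noise_sd_mv > 0) v <- v + rnorm(length(v), 0, noise_sd_mv)
    structure(list(time_ms = t, voltage_mv = v,
                   sampling_rate_hz = sampling_rate_hz,
                   stim_times_ms = numeric(0), true_latency_ms = NA_real_),
              class = "gj_trace")
  })
}

#' Simulate a linear fluorogenic-substrate kinetic series
#'
#' Emulates AMC accumulation read every `t_step_min` minutes for
#' `duration_min` minutes (defaults give the canonical 16 points at
#' 0, 2, ..., 30 min).
#'
#' @param intercept,slope line parameters (a.u., a.u./min).
#' @param t_step_min,duration_min sampling grid.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return data.frame(time_min, fluorescence).
#' @export
make_kinetic_series <- function(intercept, slope, t_step_min = 2,
                                duration_min = 30, noise_sd = 0, seed = NULL) {
  assert_positive(t_step_min, "t_step_min")
  with_seed(seed, {
    t <- seq(0, duration_min, by = t_step_min)
    y <- intercept + slope * t
    if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
    data.frame(time_min = t, fluorescence = y)
  })
}
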