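# 2D high-content pipeline operations.

test_that("gain field from a constant image is identically 1", {
  g <- compute_gain_field(matrix(5, 256, 256))
  expect_lt(max(abs(g - 1)), 1e-12)
  expect_equal(mean(g), 1, tolerance = 1e-6)
})

test_that("gain field recovers a smooth 20% bias at r > 0.99", {
  # plate-scale field: the 200-px window must be small relative to the
  # field for the median filter to act locally
  f <- make_monolayer(monolayer_params(n_cells = 0L, seed = 6,
                                       field_shape = c(1024L, 1024L),
                                       gain_field_amplitude = 0.2,
                                       noise = c(0, 0)))
  img <- f$images$channels$CX43          # constant background x gain
  g <- compute_gain_field(img)
  expect_gt(cor(as.numeric(g), as.numeric(f$truth$gain)), 0.99)
  expect_true(all(g > 0))
})

test_that("gain field is robust to a single hot pixel", {
  base <- matrix(3, 256, 256)
  g0 <- compute_gain_field(base)
  hot <- base; hot[100, 117] <- 1e6
  g1 <- compute_gain_field(hot)
  expect_lt(max(abs(g1 - g0)), 1e-3)
})

test_that("gain field window validation", {
  expect_error(compute_gain_field(matrix(1, 100, 100), window = 200),
               "larger than image")
})

test_that("illumination correction is exact pointwise division", {
  img <- matrix(runif(100, 1, 2), 10, 10)
  expect_equal(correct_illumination(img, matrix(1, 10, 10)), img)
  g <- matrix(runif(100, 0.8, 1.2), 10, 10)
  expect_equal(correct_illumination(img * g, g), img)
  expect_error(correct_illumination(img, matrix(0, 10, 10)), "positive")
  expect_error(correct_illumination(img, matrix(1, 5, 5)), "shapes")
})

test_that("nuclei segmentation: counts, gates, empty input", {
  f <- small_field(seed = 2, gain_field_amplitude = 0, noise = c(0, 0.01))
  nuc <- segment_nuclei(f$images$channels$DNA)
  expect_equal(max(nuc), 6L)
  # object below the diameter gate is excluded
  img <- fixture_disk(matrix(0, 100, 100), 50, 50, 5)    # d = 10 < 20
  expect_equal(max(segment_nuclei(img, threshold = 0.5)), 0L)
  # in-gate object kept
  img2 <- fixture_disk(matrix(0, 100, 100), 50, 50, 15)
  expect_equal(max(segment_nuclei(img2, threshold = 0.5)), 1L)
  # empty image -> empty mask, not an error
  expect_equal(max(segment_nuclei(matrix(0, 50, 50))), 0L)
})

test_that("cell identification: disk case, bijection, truth overlap", {
  # single nucleus centred in a disk of signal -> cell mask = disk
  chan <- fixture_disk(matrix(0, 80, 80), 40, 40, 25)
  nuc <- matrix(0L, 80, 80); nuc <- fixture_disk(nuc, 40, 40, 8, 1L)
  storage.mode(nuc) <- "integer"
  cells <- segment_cells(nuc, chan, threshold = 0.5)
  expect_equal(cells > 0, chan > 0.5)
  # bijection + per-cell Jaccard on a synthetic monolayer; detected labels
  # are in scan order, so map them to truth labels by maximal overlap
  f <- default_field(1)
  q <- default_quant(1)
  expect_equal(max(q$cells), max(q$nuclei))
  tm <- f$truth$cell_mask
  agree <- 0
  mapped <- integer(0)
  for (k in seq_len(max(q$cells))) {
    ov <- table(tm[q$cells == k & tm > 0])
    tk <- as.integer(names(which.max(ov)))
    mapped <- c(mapped, tk)
    inter <- sum(q$cells == k & tm == tk)
    uni <- sum(q$cells == k | tm == tk)
    expect_gt(inter / uni, 0.8)
    agree <- agree + inter
  }
  expect_equal(sort(mapped), seq_len(max(tm)))   # one-to-one mapping
  expect_gt(agree / sum(tm > 0), 0.95)
})

test_that("transfection partitioning: dark, bimodal, override", {
  f <- make_monolayer(monolayer_params(n_cells = 10L,
                                       field_shape = c(420L, 420L),
                                       transfected_fraction = 0.4, seed = 8))
  q <- suppressMessages(quantify_field(f$images))
  # map detected cell labels to truth labels by overlap, then compare flags
  tm <- f$truth$cell_mask
  truth_of <- vapply(seq_len(max(q$cells)), function(k) {
    ov <- table(tm[q$cells == k & tm > 0])
    as.integer(names(which.max(ov)))
  }, integer(1))
  truth_flag <- truth_of %in% f$truth$transfected_cells
  acc <- mean(q$transfected == truth_flag)
  expect_gte(acc, 0.98)
  # all-dark channel -> all FALSE
  dark <- matrix(0.02, 420, 420) + matrix(rnorm(420^2, 0, 1e-4), 420, 420)
  expect_false(any(partition_transfected(f$truth$cell_mask, dark)))
  # absolute override 0 -> all TRUE (positive background)
  expect_true(all(partition_transfected(f$truth$cell_mask, dark + 1,
                                        threshold = 0)))
  expect_error(partition_transfected(f$truth$cell_mask, NULL), "GFP")
})

test_that("puncta detection: counts, gates, mask restriction", {
  f <- small_field(seed = 3, gain_field_amplitude = 0, noise = c(0, 0))
  cx <- detect_punctae(f$images$channels$CX43, f$truth$cell_mask)
  expect_equal(nrow(cx$table), nrow(f$truth$puncta))
  # gates are monotone: shrinking the gate never increases the count
  n_full <- nrow(cx$table)
  n_narrow <- nrow(detect_punctae(f$images$channels$CX43, f$truth$cell_mask,
                                  d_min = 10, d_max = 16)$table)
  expect_lte(n_narrow, n_full)
  # spot below the gate is excluded; spot outside any cell is excluded
  img <- matrix(0.0, 200, 200)
  img <- gjflux:::add_gaussian_spot(img, 60, 60, 1, 4)     # d = 4: too small
  img <- gjflux:::add_gaussian_spot(img, 120, 120, 1, 12)  # in gate
  img <- gjflux:::add_gaussian_spot(img, 30, 170, 1, 12)   # outside mask
  cells <- matrix(0L, 200, 200)
  cells[31:160, 31:160] <- 1L
  got <- detect_punctae(img, cells, threshold = 0.5)
  expect_equal(nrow(got$table), 1L)
  expect_equal(got$table$centroid_row, 120, tolerance = 0.5)
})

test_that("surface objects: blank channel, rim recovery, area additivity", {
  blank <- matrix(0.5, 64, 64)
  s0 <- surface_objects(blank)
  expect_equal(s0$area_px, 0L)
  f <- default_field(1)
  q <- default_quant(1)
  rim <- f$truth$rim_mask
  expect_gt(sum(q$surface$mask & rim) / sum(rim), 0.9)
  # area additive over disjoint fields
  a <- matrix(0.02, 64, 64); a[10:20, 10:20] <- 1
  b <- matrix(0.02, 64, 64); b[30:35, 40:50] <- 1
  s_a <- surface_objects(a, threshold = 0.5)
  s_b <- surface_objects(b, threshold = 0.5)
  ab <- pmax(a, b)
  expect_equal(surface_objects(ab, threshold = 0.5)$area_px,
               s_a$area_px + s_b$area_px)
})

test_that("compartment assignment: trivial all-surface and error cases", {
  labels <- matrix(0L, 40, 40)
  labels[5:8, 5:8] <- 1L; labels[20:23, 20:23] <- 2L
  tab <- gjflux:::region_props(labels)
  ps <- gjflux:::puncta_set(tab, labels)
  allmask <- matrix(TRUE, 40, 40)
  fr <- assign_compartments(ps, allmask)
  expect_equal(fr$pct_surface, 100)
  expect_equal(fr$pct_early_endosome, 0)
  expect_equal(fr$pct_lysosome, 0)
  expect_error(assign_compartments(ps, allmask, ps, marker_kind = "GOLGI"),
               "marker_kind")
})

test_that("multi-hit punctae resolve surface-first; fractions sum to 100", {
  labels <- matrix(0L, 30, 30)
  labels[10:13, 10:13] <- 1L
  ps <- gjflux:::puncta_set(gjflux:::region_props(labels), labels)
  # marker puncta exactly on top of the object
  mk <- gjflux:::puncta_set(gjflux:::region_props(labels), labels)
  surface <- matrix(TRUE, 30, 30)
  fr <- assign_compartments(ps, surface, mk, marker_kind = "EEA1")
  expect_equal(fr$pct_surface, 100)      # surface wins over the marker hit
  nosurf <- matrix(FALSE, 30, 30)
  fr2 <- assign_compartments(ps, nosurf, mk, marker_kind = "EEA1")
  expect_equal(fr2$pct_early_endosome, 100)
  expect_equal(fr$pct_surface + fr$pct_early_endosome + fr$pct_lysosome, 100,
               tolerance = 1e-6)
})

test_that("aggregation is hierarchical and rejects mixed wells", {
  one <- data.frame(well_id = "A1", site_id = 1, value = 7)
  expect_equal(aggregate_well(one)$value, 7)
  sites <- data.frame(well_id = "A1", site_id = 1:3, value = c(10, 20, 30))
  expect_equal(aggregate_well(sites)$value, 20)
  mixed <- data.frame(well_id = c("A1", "A2"), value = c(1, 2))
  expect_error(aggregate_well(mixed), "mixed wells")
  # unbalanced design: hierarchical mean differs from pooled mean;
  # hand-computed oracle
  df <- data.frame(condition = "c",
                   well_id = c("A1", "A1", "A1", "A2"),
                   site_id = c(1, 2, 3, 1),
                   value = c(0, 0, 0, 12))
  agg <- hcs_aggregate(df)
  expect_equal(sort(agg$wells$value), c(0, 12))   # per-well means
  expect_equal(agg$conditions$value, (0 + 12) / 2 / 1)   # mean(0, 12) = 6
  expect_false(isTRUE(all.equal(agg$conditions$value, mean(df$value))))
  expect_equal(agg$conditions$n_wells, 2L)
})

test_that("sum-slices projection and tract densitometry", {
  st <- array(0, dim = c(8, 8, 3))
  st[, , 1] <- 1; st[, , 2] <- 2; st[, , 3] <- 4
  expect_equal(sum_slices(st), matrix(7, 8, 8))
  expect_equal(sum_slices(st[, , 1, drop = FALSE]), matrix(1, 8, 8))
  # ROI of constant value: MGV and integrated density by hand
  proj <- matrix(7, 40, 60)
  r1 <- cbind(row = c(5, 5, 15, 15), col = c(5, 15, 15, 5))     # 100 px
  r2 <- cbind(row = c(20, 20, 35, 35), col = c(20, 40, 40, 20)) # 300 px
  q <- quantify_tracts(proj, list(r1, r2))
  expect_equal(q$per_roi$area_px, c(100, 300))
  expect_equal(q$per_roi$mgv, c(7, 7))
  expect_equal(q$per_roi$integrated_density, c(700, 2100))
  # weighted mean MGV oracle: (100*10 + 300*20) / 400 = 17.5
  proj2 <- matrix(0, 40, 60)
  proj2[6:15, 6:15] <- 10
  proj2[21:35, 21:40] <- 20
  q2 <- quantify_tracts(proj2, list(r1, r2))
  expect_equal(q2$weighted_mean_mgv,
               sum(q2$per_roi$area_px * q2$per_roi$mgv) /
                 sum(q2$per_roi$area_px))
  expect_equal(q2$weighted_mean_mgv, 17.5)
  expect_equal(q2$total_integrated_density, 17.5 * 400)
  # empty ROI errors
  bad <- cbind(row = c(0.2, 0.2, 0.4), col = c(0.2, 0.4, 0.3))
  expect_error(quantify_tracts(proj, list(r1, bad)), "empty ROI")
})
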