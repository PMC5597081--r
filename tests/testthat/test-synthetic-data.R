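# Synthetic-data generators: contracts, determinism, truth consistency.

test_that("monolayer params validate their invariants", {
  expect_error(monolayer_params(compartment_fractions = c(0.5, 0.3, 0.1)),
               "sum to 1")
  expect_error(monolayer_params(nucleus_diameter_px = c(-5, 10)), "positive")
  expect_error(monolayer_params(transfected_fraction = 1.5), "\\[0, 1\\]")
  # impossible packing is rejected up front
  expect_error(monolayer_params(field_shape = c(128L, 128L), n_cells = 50L),
               "packing failure")
})

test_that("empty monolayer gives background-only channels and empty truth", {
  f <- make_monolayer(monolayer_params(n_cells = 0L, seed = 3,
                                       gain_field_amplitude = 0,
                                       noise = c(0, 0)))
  expect_equal(nrow(f$truth$puncta), 0L)
  expect_equal(max(f$truth$cell_mask), 0L)
  for (ch in f$images$channels)
    expect_lt(diff(range(ch)), 1e-12)
})

test_that("puncta records count and compartments are multinomial", {
  f <- default_field(1)
  tp <- f$truth$puncta
  expect_equal(nrow(tp), 20 * 10)
  expect_true(all(tp$compartment %in% c("surface", "EE", "LYS")))
  # multinomial sampling: chi-square on truth compartments pooled over
  # fields (scaled down from the 1e4-puncta scale at which exact multinomial sampling
  # is distinguishable, to keep the suite fast; the sampler is one sample() call
  comp <- c(tp$compartment, default_field(2)$truth$puncta$compartment,
            default_field(3)$truth$puncta$compartment)
  cs <- suppressWarnings(
    chisq.test(table(factor(comp, c("surface", "EE", "LYS"))),
               p = c(0.60, 0.25, 0.15)))
  expect_gt(cs$p.value, 0.001)
})

test_that("identical seeds give bit-identical monolayers", {
  a <- make_monolayer(monolayer_params(n_cells = 4L,
                                       field_shape = c(288L, 288L), seed = 9))
  b <- make_monolayer(monolayer_params(n_cells = 4L,
                                       field_shape = c(288L, 288L), seed = 9))
  expect_identical(a$images$channels, b$images$channels)
  expect_identical(a$truth$puncta, b$truth$puncta)
})

test_that("every puncta lies inside its owning cell's mask; labels consecutive", {
  f <- default_field(1)
  tp <- f$truth$puncta
  own <- f$truth$cell_mask[cbind(round(tp$row) + 1L, round(tp$col) + 1L)]
  expect_equal(own, tp$cell_label)
  labs <- sort(unique(as.integer(f$truth$cell_mask)))
  expect_equal(labs, 0:20)
})

test_that("rendered puncta diameters recover requested FWHM within 1 px", {
  # interior punctae only: rim punctae at the field boundary are clipped by
  # the image edge, so their rendered extent is not recoverable by design
  f <- make_monolayer(monolayer_params(n_cells = 4L,
                                       field_shape = c(288L, 288L),
                                       punctae_per_cell = 4,
                                       compartment_fractions = c(0, 0.5, 0.5),
                                       gain_field_amplitude = 0,
                                       noise = c(0, 0), seed = 5))
  tp <- f$truth$puncta
  bg <- 0.05
  for (i in seq_len(nrow(tp))) {
    # cancel all other spots exactly (negative re-render), then measure the
    # remaining object's extent at half its own amplitude
    img <- f$images$channels$CX43
    for (j in setdiff(seq_len(nrow(tp)), i))
      img <- gjflux:::add_gaussian_spot(img, tp$row[j], tp$col[j],
                                        -tp$amplitude[j], tp$diameter_px[j])
    thr <- bg + 0.5 * tp$amplitude[i]
    w <- 16
    rs <- max(1, round(tp$row[i]) - w + 1):min(288, round(tp$row[i]) + w + 1)
    cs <- max(1, round(tp$col[i]) - w + 1):min(288, round(tp$col[i]) + w + 1)
    area <- sum(img[rs, cs] > thr)
    expect_lt(abs(2 * sqrt(area / pi) - tp$diameter_px[i]), 1)
  }
})

test_that("transfected cells are sampled at the exact requested fraction", {
  f <- make_monolayer(monolayer_params(n_cells = 10L,
                                       field_shape = c(420L, 420L),
                                       transfected_fraction = 0.4, seed = 2))
  expect_length(f$truth$transfected_cells, 4L)
  expect_true("GFP" %in% names(f$images$channels))
  expect_false("GFP" %in% names(default_field(1)$images$channels))
})

test_that("zstack truth passes requested volumes through; empty case works", {
  z <- make_zstack(c(4, 50, 120), seed = 1)
  expect_equal(z$truth$volume_um3, c(4, 50, 120))
  z0 <- make_zstack(numeric(0), seed = 1)
  expect_equal(nrow(z0$truth), 0L)
  expect_error(make_zstack(10, pixel_size_um = 0), "positive")
})

test_that("rendered sphere volume is within one voxel shell of analytic", {
  z <- make_zstack(50, shape = c(96L, 96L, 36L), noise_sd = 0, seed = 4)
  # voxel-count oracle straight from the noiseless rendering
  count <- sum(z$volume$data > 0.5)
  vox <- prod(z$volume$voxel_um)
  r <- (3 * 50 / (4 * pi))^(1 / 3)
  shell <- 4 * pi * r^2 * sqrt(sum(z$volume$voxel_um^2)) / 2
  expect_lt(abs(count * vox - 50), shell)
})

test_that("cytometry generator hits its geometric mean and edge cases", {
  e1 <- make_cytometry(1, log10_mean = 2, log10_sd = 0, seed = 1)
  expect_equal(e1$fluorescence, 100)
  e <- make_cytometry(1e5, 2, 0.3, seed = 7)
  expect_lt(abs(geometric_mean(e) / 100 - 1), 0.01)
  expect_identical(make_cytometry(50, 2, 0.3, seed = 3),
                   make_cytometry(50, 2, 0.3, seed = 3))
  expect_error(make_cytometry(0, 2, 0.3), "n_events")
})

test_that("trace generator places the EPSP onset at the exact sample offset", {
  p <- trace_params(true_latency_ms = 0.8, baseline_noise_sd_mv = 0,
                    epsp_decay_tau_ms = 1e9, stim_times_ms = 10)
  tr <- make_trace(p)
  i_stim <- which(tr$time_ms == 10)          # artifact start sample
  # onset grid point: stim index + 0.8 ms * 40 kHz = +32; the rise is zero
  # exactly at onset, so the first deviating sample is +33
  post <- tr$voltage_mv > -70 + 1e-9 & tr$time_ms > 10.5
  expect_equal(min(which(post)) - i_stim, 33L)
  expect_equal(tr$voltage_mv[i_stim + 32L], -70)
})

test_that("trace generator contracts: latency floor and absent EPSP", {
  expect_error(trace_params(true_latency_ms = 0.00001), "sample period")
  tr <- make_trace(trace_params(epsp_amplitude_mv = 0, seed = 1))
  expect_true(is.na(tr$true_latency_ms))
})

test_that("kinetic series has 16 points and exact noiseless values", {
  s <- make_kinetic_series(5, 3)
  expect_equal(nrow(s), 16L)
  expect_equal(s$time_min, seq(0, 30, 2))
  expect_equal(s$fluorescence[s$time_min == 10], 35)
})
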