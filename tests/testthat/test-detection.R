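# helpers to build synthetic stacks with a flat zero background
flat_stack <- function(nr = 64, nc = 64, channels = c("Hoechst", "CD45")) {
  array(0, dim = c(nr, nc, length(channels)),
        dimnames = list(NULL, NULL, channels))
}

test_that("background estimation is robust and reports MAD noise", {
  cfg <- segmentation_config()
  flat <- matrix(100, 64, 64)
  bg <- estimate_background(flat, cfg)
  expect_equal(bg$background, 100)
  expect_equal(bg$noise_sd, 0)
  set.seed(1)
  noisy <- matrix(100 + rnorm(200 * 200, sd = 5), 200, 200)
  bg <- estimate_background(noisy, cfg)
  expect_lt(abs(bg$noise_sd - 5), 0.5)
  expect_lt(abs(bg$background - 100), 0.5)
  # a bright spot is rejected by the robust estimator
  spot <- noisy
  spot[90:110, 90:110] <- 5000
  bg2 <- estimate_background(spot, cfg)
  expect_lt(abs(bg2$background - 100), 1)
})

test_that("constant frames fall back to a background + 1 threshold", {
  st <- flat_stack(channels = "CD45")
  st[, , 1] <- 100
  st[10:12, 10:12, 1] <- 102   # 9 px, only 2 units above background
  seg <- segment_stack(st)
  expect_equal(max(seg$labels), 1)
  expect_equal(sum(seg$labels > 0), 9)
})

test_that("objects must be strictly larger than four pixels", {
  st <- flat_stack()
  st[5, 5:7, 1] <- 50            # 3 px
  st[20:21, 20:21, 1] <- 50      # 4 px
  st[40, 40:44, 1] <- 50         # 5 px
  st[55:57, 55:57, 2] <- 50      # 9 px
  seg <- segment_stack(st)
  expect_equal(max(seg$labels), 2)
  expect_setequal(tabulate(seg$labels[seg$labels > 0]), c(5, 9))
})

test_that("channels are combined with union semantics", {
  st <- flat_stack()
  st[10:12, 10:12, 1] <- 50
  st[40:42, 40:42, 2] <- 50      # disjoint
  expect_equal(max(segment_stack(st)$labels), 2)
  st2 <- flat_stack()
  st2[10:12, 10:12, 1] <- 50
  st2[12:14, 12:14, 2] <- 50     # overlapping
  expect_equal(max(segment_stack(st2)$labels), 1)
})

test_that("raising the threshold never increases the count of isolated objects", {
  opt <- tiny_optics(frame = c(192L, 192L))
  p <- grid_particles(opt)
  rw <- render_well(p, opt, frames = 1L, seed = 21L)
  st <- rw$images[, , , 1]
  counts <- vapply(c(3, 5, 8, 12, 30), function(k)
    max(segment_stack(st, segmentation_config(threshold_k = k))$labels), 0)
  expect_equal(counts[2], nrow(p))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected-component labelling agrees with an independent oracle", {
  set.seed(9)
  mask <- matrix(runif(120 * 120) < 0.25, 120, 120)
  ours <- evcounter:::cpp_label(mask, 4L)
  ref <- EBImage::bwlabel(matrix(as.integer(mask), 120, 120))
  # same partition: label images must be identical up to renaming
  expect_equal(max(ours), max(ref))
  key <- paste(ours[mask], ref[mask])
  expect_equal(length(unique(key)), max(ref))
})

test_that("8-connectivity joins diagonals, 4-connectivity does not", {
  mask <- matrix(FALSE, 8, 8)
  mask[cbind(c(2, 3), c(2, 3))] <- TRUE
  expect_equal(max(evcounter:::cpp_label(mask, 4L)), 2)
  expect_equal(max(evcounter:::cpp_label(mask, 8L)), 1)
})

test_that("morphology measurements match their closed forms", {
  opt <- optics_config(pixel_pitch = 0.64, frame_shape = c(64L, 64L))
  cfg <- segmentation_config(min_pixels = 0L)
  st <- flat_stack(channels = c("CD45"))
  st[20:24, 20:24, 1] <- 60      # 5x5 square, 25 px
  seg <- segment_stack(st, cfg)
  ft <- extract_features(seg$labels, st, opt, seg$background, cfg)
  expect_equal(ft$area_px, 25)
  expect_equal(ft$size_um2, 25 * 0.64^2)   # 10.24 um^2
  expect_equal(ft$size_um2 / ft$area_px, opt$pixel_pitch^2)
  expect_equal(ft$perimeter_px, 20)
  expect_equal(ft$equivalent_radius_um, sqrt(10.24 / pi))

  # disc of radius 5 px: near-zero eccentricity
  stD <- flat_stack(channels = "CD45")
  stD[, , 1] <- 60 * ((row(stD[, , 1]) - 32)^2 + (col(stD[, , 1]) - 32)^2 <= 25)
  segD <- segment_stack(stD, cfg)
  ftD <- extract_features(segD$labels, stD, opt, segD$background, cfg)
  expect_lt(ftD$eccentricity, 0.2)

  # 2:1 axis-ratio ellipse: eccentricity sqrt(1 - 1/4), above the 0.85 gate
  stE <- flat_stack(channels = "CD45")
  stE[, , 1] <- 60 * (((row(stE[, , 1]) - 32) / 16)^2 +
                        ((col(stE[, , 1]) - 32) / 8)^2 <= 1)
  segE <- segment_stack(stE, cfg)
  ftE <- extract_features(segE$labels, stE, opt, segE$background, cfg)
  expect_lt(abs(ftE$eccentricity - sqrt(1 - 0.25)), 0.01)
  expect_gt(ftE$eccentricity, 0.85)
})

test_that("an object of 9 um^2 has an equivalent radius near 1.7 um", {
  opt <- optics_config(pixel_pitch = 0.6, frame_shape = c(32L, 32L))
  st <- array(0, dim = c(32, 32, 1), dimnames = list(NULL, NULL, "CD45"))
  st[10:14, 10:14, 1] <- 40      # 25 px x 0.36 um^2 = 9 um^2
  seg <- segment_stack(st)
  ft <- extract_features(seg$labels, st, opt, seg$background)
  expect_equal(ft$size_um2, 9)
  expect_equal(ft$equivalent_radius_um, sqrt(9 / pi))
  expect_lt(abs(ft$equivalent_radius_um - 1.7), 0.05)
})

test_that("feature extraction matches a brute-force per-object oracle", {
  opt <- tiny_optics(frame = c(128L, 128L))
  cfg <- sample_config(recovery_populations(platelets = 2e4, rbcs = 4e4),
                       frames_per_well = 2, seed = 31L)
  p <- sample_well(cfg, 1L, opt)
  rw <- render_well(p, opt, frames = 2L, seed = 31L)
  checked <- 0
  for (f in 1:2) {
    st <- rw$images[, , , f]
    seg <- segment_stack(st)
    ft <- extract_features(seg$labels, st, opt, seg$background)
    bf <- brute_features(seg$labels, st, opt, seg$background)
    expect_gt(nrow(ft), 0)
    for (col in names(bf))
      expect_equal(ft[[col]], bf[[col]], tolerance = 1e-9)
    checked <- checked + nrow(ft)
    # intensity ordering invariant per channel
    for (ch in opt$channel_names) {
      expect_true(all(ft[[paste0("max_intensity_", ch)]] >=
                        ft[[paste0("mean_intensity_", ch)]]))
      expect_true(all(ft[[paste0("mean_intensity_", ch)]] >=
                        ft[[paste0("min_intensity_", ch)]]))
      expect_true(all(ft[[paste0("std_intensity_", ch)]] >= 0))
      expect_equal(ft[[paste0("integrated_intensity_", ch)]],
                   ft[[paste0("mean_intensity_", ch)]] * ft$area_px)
    }
  }
  expect_gt(checked, 100)
})

test_that("border objects are kept by default and excludable by policy", {
  st <- flat_stack()
  st[1:3, 10:12, 1] <- 50
  st[30:32, 30:32, 1] <- 50
  expect_equal(max(segment_stack(st)$labels), 2)
  seg <- segment_stack(st, segmentation_config(border_policy = "exclude"))
  expect_equal(max(seg$labels), 1)
})

test_that("blank stacks yield an empty feature table", {
  opt <- tiny_optics()
  rw <- render_well(one_particle()[0, ], opt, frames = 2L, seed = 6L)
  ft <- detect_well(rw$images, opt)
  expect_equal(nrow(ft), 0)
  expect_true(all(c("size_um2", "mean_intensity_CD45", "frame_id") %in%
                    names(ft)))
})
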