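test_that("undiluted volume follows the dilution scheme", {
  expect_equal(undiluted_volume(sample_config(dilution_factor = 500,
                                              loaded_volume = 10)), 0.02)
  expect_equal(undiluted_volume(sample_config(dilution_factor = 1,
                                              loaded_volume = 10)), 10)
  expect_equal(undiluted_volume(sample_config(dilution_factor = 500,
                                              loaded_volume = 25)), 0.05)
  expect_error(sample_config(dilution_factor = 0.5), "dilution_factor")
  expect_error(sample_config(loaded_volume = 0), "loaded_volume")
})

test_that("population and sample configs enforce their invariants", {
  expect_error(population_spec("leukocyte", -1, c(7, 20),
                               c(CD45 = "positive")), "concentration")
  expect_error(population_spec("leukocyte", 10, c(20, 7),
                               c(CD45 = "positive")), "diameter_range")
  expect_error(population_spec("leukocyte", 10, c(7, 20),
                               c(CD45 = "bright")), "expression")
  expect_error(sample_config(list(
    population_spec("leukocyte", 10, c(7, 20), c(CD45 = "positive")),
    population_spec("ldEV", 10, c(1, 6), c(CD61 = "positive")))),
    "panel")
  # whole-blood mode ignores supplied retention
  cfg <- sample_config(retention = c(leukocyte = 0.5))
  expect_true(all(cfg$retention == 1))
  expect_error(optics_config(channel_names = c("Hoechst", "CD45")), "extra")
})

test_that("well loading is Poisson with mean concentration x volume x retention", {
  opt <- tiny_optics()
  pops <- list(population_spec("ldEV", 50000, c(3, 6),
                               c(Hoechst = "negative", CD45 = "positive",
                                 CD61 = "negative", CD235a = "negative"),
                               in_focus = FALSE))
  cfg <- sample_config(pops, frames_per_well = 10, seed = 11L)
  counts <- vapply(1:200, function(w) nrow(sample_well(cfg, w, opt)), 0)
  # mean 50000 * 0.02 = 1000, Monte-Carlo tolerance 3 standard errors
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 200))
  # replicate realism: CV approaches 1/sqrt(mean)
  expect_lt(abs(sd(counts) / mean(counts) - 1 / sqrt(1000)),
            0.2 / sqrt(1000))
})

test_that("zero concentration never yields particles", {
  opt <- tiny_optics()
  pops <- list(population_spec("platelet", 0, c(2, 5),
                               c(Hoechst = "negative", CD45 = "negative",
                                 CD61 = "positive", CD235a = "negative")))
  cfg <- sample_config(pops, seed = 3L)
  for (w in 1:5) expect_equal(nrow(sample_well(cfg, w, opt)), 0)
})

test_that("implausible expected counts are rejected", {
  cfg <- sample_config(default_blood_populations(), max_expected = 1e4)
  expect_error(sample_well(cfg, 1L, tiny_optics()), "max_expected")
})

test_that("ground truth is deterministic and leaves the caller's RNG alone", {
  opt <- tiny_optics()
  cfg <- sample_config(recovery_populations(), seed = 99L)
  set.seed(123)
  a <- sample_well(cfg, 2L, opt)
  x1 <- runif(1)
  set.seed(123)
  b <- sample_well(cfg, 2L, opt)
  x2 <- runif(1)
  expect_identical(a, b)
  expect_identical(x1, x2)
  expect_false(identical(a, sample_well(cfg, 3L, opt)))
})

test_that("particle attributes respect their population definitions", {
  opt <- tiny_optics()
  cfg <- sample_config(recovery_populations(), frames_per_well = 20,
                       seed = 7L)
  p <- sample_well(cfg, 1L, opt)
  expect_true(all(p$frame_id >= 0 & p$frame_id < 20))
  for (pop in cfg$populations) {
    pc <- p[p$class == pop$class_name, ]
    expect_true(all(pc$diameter_um >= pop$diameter_range[1] &
                      pc$diameter_um <= pop$diameter_range[2]))
    for (ch in names(pop$marker_expression)) {
      v <- pc[[paste0("intensity_", ch)]]
      if (pop$marker_expression[[ch]] == "negative")
        expect_true(all(v == 0))
      else expect_true(all(v > 0))
    }
    # settled classes render in focus, suspended ones draw a blur sigma
    if (pop$in_focus) expect_true(all(pc$defocus_sigma == 0))
  }
  expect_true(all(p$intensity_extra == 0))
})

test_that("enrichment retention thins classes and clustering packs leukocytes", {
  opt <- tiny_optics(frame = c(256L, 256L))
  pops <- default_blood_populations(platelets = 1e5, rbcs = 1e6)
  cfg <- sample_config(pops, dilution_factor = 1, loaded_volume = 7500,
                       mode = "epcam_enriched",
                       retention = c(leukocyte = 1e-3, ldEV = 5e-4,
                                     platelet = 0, RBC = 0),
                       cluster_fraction = 0.5, seed = 5L,
                       max_expected = 1e6)
  p <- sample_well(cfg, 1L, opt)
  counts <- table(factor(p$class, levels = c("leukocyte", "ldEV",
                                             "platelet", "RBC")))
  # means: 4500*7500*1e-3 = 33750 and 1500*7500*5e-4 = 5625
  expect_lt(abs(counts[["leukocyte"]] - 33750), 4 * sqrt(33750))
  expect_lt(abs(counts[["ldEV"]] - 5625), 4 * sqrt(5625))
  expect_equal(counts[["platelet"]], 0)
  expect_equal(counts[["RBC"]], 0)
  # clustered leukocytes sit within touching distance of another leukocyte
  lk <- p[p$class == "leukocyte", ]
  near <- 0
  samp <- sample(nrow(lk), 200)
  for (i in samp) {
    same <- lk[lk$frame_id == lk$frame_id[i], ]
    d <- sqrt((same$row - lk$row[i])^2 + (same$col - lk$col[i])^2)
    reach <- (same$diameter_um + lk$diameter_um[i]) / 2 / opt$pixel_pitch
    if (any(d > 0 & d < reach + 1)) near <- near + 1
  }
  expect_gt(near / length(samp), 0.3)
})
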