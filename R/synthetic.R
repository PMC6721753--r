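# Synthetic blood-sample generator: particle populations with known class,
# size and marker expression are Poisson-loaded into counting-chamber wells
# and rendered into multichannel fluorescence frames with a known ground
# truth, so the detection -> gating -> quantification chain can be validated
# without external image data.

#' Describe one particle population
#'
#' A population is one object class (leukocyte, ldEV, platelet or RBC) with a
#' concentration in undiluted blood, a diameter range, and a marker expression
#' pattern over the active antibody panel.
#'
#' @param class_name One of `"leukocyte"`, `"ldEV"`, `"platelet"`, `"RBC"`.
#' @param concentration Objects per microlitre of undiluted blood.
#' @param diameter_range Length-2 numeric, min/max diameter in micrometres.
#' @param marker_expression Named character vector mapping each panel marker
#'   (e.g. `Hoechst`, `CD45`, `CD61`, `CD235a`) to an expression level
#'   `"negative"`, `"low"` or `"positive"`.
#' @param nucleated Logical; must agree with a positive nuclear dye entry.
#' @param in_focus Logical. Settled objects (cells imaged on the chamber
#'   floor) render with zero defocus; suspended small objects (EVs,
#'   platelets) draw a defocus blur sigma from the optics configuration.
#' @return A `population_spec` object.
#' @export
population_spec <- function(class_name, concentration, diameter_range,
                            marker_expression, nucleated = FALSE,
                            in_focus = TRUE) {
  class_name <- match.arg(class_name, CLASS_NAMES)
  stopifnot(is.numeric(concentration), length(concentration) == 1,
            concentration >= 0)
  stopifnot(length(diameter_range) == 2, all(diameter_range > 0),
            diameter_range[1] <= diameter_range[2])
  if (is.null(names(marker_expression)) || any(names(marker_expression) == ""))
    stop("marker_expression must be a named vector")
  bad <- setdiff(marker_expression, EXPRESSION_LEVELS)
  if (length(bad))
    stop("unknown expression level(s): ", paste(bad, collapse = ", "))
  structure(list(class_name = class_name,
                 concentration = concentration,
                 diameter_range = as.numeric(diameter_range),
                 marker_expression = marker_expression,
                 nucleated = isTRUE(nucleated),
                 in_focus = isTRUE(in_focus)),
            class = "population_spec")
}

#' Default whole-blood populations
#'
#' Typical adult hematology values: leukocytes 4,500/uL (7-20 um, nucleated,
#' CD45+), red blood cells 5e6/uL (6-10 um, CD235a+), platelets 2.5e5/uL
#' (2-5 um, CD61+) and large ldEVs 1,500/uL (CD45+, anuclear).  The ldEV
#' diameter range (1-6 um) is a modelling default: their true size
#' distribution is not resolvable at the pixel pitch this pipeline targets.
#'
#' @param leukocytes,ldevs,platelets,rbcs Concentrations per uL of blood.
#' @param ldev_diameter Length-2 numeric, ldEV diameter range in um.
#' @return List of [population_spec()] for the Hoechst/CD45/CD61/CD235a panel.
#' @export
default_blood_populations <- function(leukocytes = 4500, ldevs = 1500,
                                      platelets = 2.5e5, rbcs = 5e6,
                                      ldev_diameter = c(1, 6)) {
  panel <- function(Hoechst, CD45, CD61, CD235a)
    c(Hoechst = Hoechst, CD45 = CD45, CD61 = CD61, CD235a = CD235a)
  list(
    population_spec("leukocyte", leukocytes, c(7, 20),
                    panel("positive", "positive", "negative", "negative"),
                    nucleated = TRUE, in_focus = TRUE),
    population_spec("ldEV", ldevs, ldev_diameter,
                    panel("negative", "positive", "negative", "negative"),
                    nucleated = FALSE, in_focus = FALSE),
    population_spec("platelet", platelets, c(2, 5),
                    panel("negative", "negative", "positive", "negative"),
                    nucleated = FALSE, in_focus = FALSE),
    population_spec("RBC", rbcs, c(6, 10),
                    panel("negative", "negative", "negative", "positive"),
                    nucleated = FALSE, in_focus = TRUE)
  )
}

#' Default populations for the EpCAM-enriched (cartridge) panel
#'
#' Only leukocytes and ldEVs survive EpCAM enrichment in appreciable numbers;
#' the panel is the nuclear dye (DAPI), CD45 and cytokeratin (CK, negative
#' for both classes).  Depletion itself is modelled by the retention
#' probabilities of [sample_config()], not here.
#'
#' @inheritParams default_blood_populations
#' @return List of [population_spec()] for the DAPI/CD45/CK panel.
#' @export
default_epcam_populations <- function(leukocytes = 4500, ldevs = 1500,
                                      ldev_diameter = c(1, 6)) {
  panel <- function(DAPI, CD45, CK) c(DAPI = DAPI, CD45 = CD45, CK = CK)
  list(
    population_spec("leukocyte", leukocytes, c(7, 20),
                    panel("positive", "positive", "negative"),
                    nucleated = TRUE, in_focus = TRUE),
    population_spec("ldEV", ldevs, ldev_diameter,
                    panel("negative", "positive", "negative"),
                    nucleated = FALSE, in_focus = TRUE)
  )
}

#' Configure a simulated sample
#'
#' Captures the dilution scheme of the counting-chamber protocol: blood
#' diluted `dilution_factor` times, `loaded_volume` uL of the dilution loaded
#' per well, imaged as `frames_per_well` frames, with `replicate_wells`
#' technical replicates.  In `epcam_enriched` mode the full processed blood
#' volume flows into one cartridge and per-class `retention` probabilities
#' model the net depletion of EpCAM-negative objects.
#'
#' @param populations List of [population_spec()]; all must share one panel.
#' @param dilution_factor Final dilution of the blood (default 500).
#' @param loaded_volume uL of diluted sample loaded per well (default 10).
#' @param frames_per_well Number of frames imaged per well (default 60).
#' @param replicate_wells Technical replicates per donor (default 5).
#' @param mode `"whole_blood"` or `"epcam_enriched"`.
#' @param retention Named class -> probability in \[0,1\] that an object
#'   survives enrichment.  Forced to 1 in `whole_blood` mode; defaults in
#'   `epcam_enriched` mode to leukocyte 1e-3, ldEV 5e-4, others 0.
#' @param cluster_fraction Fraction of retained leukocytes placed within
#'   touching distance of another leukocyte (`epcam_enriched` mode only);
#'   models the cell clumping seen on enriched cartridges.
#' @param seed Integer seed; together with the well index it fixes the drawn
#'   particle set exactly.
#' @param max_expected Guard: expected objects per well above this value
#'   signal an implausible configuration and raise an error.
#' @return A `sample_config` object.
#' @export
sample_config <- function(populations = default_blood_populations(),
                          dilution_factor = 500, loaded_volume = 10,
                          frames_per_well = 60, replicate_wells = 5,
                          mode = c("whole_blood", "epcam_enriched"),
                          retention = NULL, cluster_fraction = 0,
                          seed = 1L, max_expected = 1e6) {
  mode <- match.arg(mode)
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, TRUE, "population_spec")))
  panels <- lapply(populations, function(p) sort(names(p$marker_expression)))
  if (length(unique(panels)) != 1)
    stop("all populations must share the same marker panel")
  stopifnot(dilution_factor >= 1, loaded_volume > 0,
            frames_per_well >= 1, replicate_wells >= 1,
            cluster_fraction >= 0, cluster_fraction <= 1)
  classes <- vapply(populations, `[[`, "", "class_name")
  if (anyDuplicated(classes)) stop("duplicate population classes")
  if (mode == "whole_blood") {
    retention <- setNames(rep(1, length(classes)), classes)
  } else {
    if (is.null(retention))
      retention <- c(leukocyte = 1e-3, ldEV = 5e-4, platelet = 0, RBC = 0)
    retention <- retention[classes]
    retention[is.na(retention)] <- 0
    names(retention) <- classes
  }
  if (any(retention < 0 | retention > 1)) stop("retention must be in [0,1]")
  structure(list(populations = populations, dilution_factor = dilution_factor,
                 loaded_volume = loaded_volume,
                 frames_per_well = as.integer(frames_per_well),
                 replicate_wells = as.integer(replicate_wells), mode = mode,
                 retention = retention, cluster_fraction = cluster_fraction,
                 seed = as.integer(seed), max_expected = max_expected),
            class = "sample_config")
}

#' Volume of undiluted blood represented by one well
#'
#' `loaded_volume / dilution_factor`: e.g. 10 uL of a 500x dilution
#' corresponds to 0.02 uL of blood.
#'
#' @param config A [sample_config()].
#' @return Volume in uL of undiluted blood.
#' @export
undiluted_volume <- function(config) {
  stopifnot(inherits(config, "sample_config"))
  config$loaded_volume / config$dilution_factor
}

#' Configure the imaging model
#'
#' @param pixel_pitch um per pixel (default 0.64, a 10x/0.45 NA objective on
#'   a standard sCMOS sensor).
#' @param frame_shape Integer (rows, cols) of one frame.
#' @param channel_names Ordered marker names; must include `"extra"`, a
#'   noise-only channel used by the gate libraries as a negativity control.
#' @param background_level Background intensity (a.u.), scalar or per channel.
#' @param noise_sd Additive Gaussian noise SD (a.u.), scalar or per channel.
#' @param defocus_sigma_range Length-2 range (pixels) of the blur sigma drawn
#'   for suspended (out-of-focus) particles.
#' @param intensity_per_expression Named numeric, the rendered peak intensity
#'   (a.u. above background) for `negative`, `low`, `positive` expression.
#'   The defaults are calibrated to the gate thresholds: `positive` objects
#'   clear mean > 30 and max > 50 after background subtraction, `low`
#'   straddles them, `negative` contributes nothing.
#' @param exposure_ms Optional named vector of exposure times, recorded as
#'   metadata only (the renderer works in calibrated arbitrary units).
#' @return An `optics_config` object.
#' @export
optics_config <- function(pixel_pitch = 0.64, frame_shape = c(512L, 512L),
                          channel_names = c("Hoechst", "CD45", "CD61",
                                            "CD235a", "extra"),
                          background_level = 100, noise_sd = 2,
                          defocus_sigma_range = c(0, 2),
                          intensity_per_expression = c(negative = 0, low = 40,
                                                       positive = 120),
                          exposure_ms = NULL) {
  stopifnot(pixel_pitch > 0, length(frame_shape) == 2, all(frame_shape >= 8))
  if (!"extra" %in% channel_names)
    stop("channel_names must include the noise-only 'extra' channel")
  per_channel <- function(x, what) {
    if (length(x) == 1) x <- setNames(rep(x, length(channel_names)),
                                      channel_names)
    if (!all(channel_names %in% names(x)))
      stop(what, " must be scalar or named per channel")
    x[channel_names]
  }
  background_level <- per_channel(background_level, "background_level")
  noise_sd <- per_channel(noise_sd, "noise_sd")
  stopifnot(all(background_level >= 0), all(noise_sd >= 0),
            length(defocus_sigma_range) == 2,
            all(defocus_sigma_range >= 0),
            defocus_sigma_range[1] <= defocus_sigma_range[2])
  stopifnot(all(EXPRESSION_LEVELS %in% names(intensity_per_expression)),
            all(intensity_per_expression >= 0),
            intensity_per_expression["negative"] == 0)
  structure(list(pixel_pitch = pixel_pitch,
                 frame_shape = as.integer(frame_shape),
                 channel_names = channel_names,
                 background_level = background_level, noise_sd = noise_sd,
                 defocus_sigma_range = as.numeric(defocus_sigma_range),
                 intensity_per_expression = intensity_per_expression,
                 exposure_ms = exposure_ms),
            class = "optics_config")
}

# deterministic per-well seed below 2^31
well_seed <- function(seed, well_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(well_index) * 104729) %%
               2147483629)
}

#' Draw the ground-truth particles of one well
#'
#' For each population the number of objects loaded into the well is Poisson
#' with mean `concentration * undiluted_volume(config) * retention[class]`.
#' Particles are placed uniformly over frames and frame area, diameters drawn
#' uniformly in the population's range, and suspended particles receive a
#' defocus sigma uniform in the optics' `defocus_sigma_range`.  Identical
#' `config` (including its seed) and `well_index` reproduce the table
#' exactly.
#'
#' @param config A [sample_config()].
#' @param well_index Integer well number (also used to derive the RNG state).
#' @param optics An [optics_config()]; supplies frame geometry, defocus range
#'   and the expression -> intensity calibration.
#' @return Ground-truth `data.frame`: `particle_id`, `well_id`, `frame_id`
#'   (0-based), `class`, `row`, `col` (pixels, sub-pixel), `diameter_um`,
#'   `defocus_sigma`, `clipped`, and one `intensity_<channel>` column per
#'   channel.
#' @export
sample_well <- function(config, well_index = 1L, optics = optics_config()) {
  stopifnot(inherits(config, "sample_config"), inherits(optics, "optics_config"))
  vol <- undiluted_volume(config)
  mu <- vapply(config$populations, function(p)
    p$concentration * vol * config$retention[[p$class_name]], 0)
  if (any(mu > config$max_expected))
    stop("expected per-well count ", format(max(mu)), " exceeds max_expected (",
         format(config$max_expected), "): implausible configuration")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(well_seed(config$seed, well_index))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  pieces <- vector("list", length(config$populations))
  for (k in seq_along(config$populations)) {
    p <- config$populations[[k]]
    n <- rpois(1, mu[k])
    if (n == 0) { pieces[[k]] <- NULL; next }
    sig <- if (p$in_focus) rep(0, n)
           else runif(n, optics$defocus_sigma_range[1],
                      optics$defocus_sigma_range[2])
    d <- data.frame(
      class = rep(p$class_name, n),
      frame_id = sample.int(config$frames_per_well, n, replace = TRUE) - 1L,
      row = runif(n, -0.5, nr - 0.5),
      col = runif(n, -0.5, nc - 0.5),
      diameter_um = runif(n, p$diameter_range[1], p$diameter_range[2]),
      defocus_sigma = sig,
      stringsAsFactors = FALSE)
    for (ch in optics$channel_names) {
      lev <- if (ch %in% names(p$marker_expression)) p$marker_expression[[ch]]
             else "negative"
      d[[paste0("intensity_", ch)]] <-
        rep(unname(optics$intensity_per_expression[[lev]]), n)
    }
    pieces[[k]] <- d
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(class = character(), frame_id = integer(),
                      row = numeric(), col = numeric(),
                      diameter_um = numeric(), defocus_sigma = numeric())
    for (ch in optics$channel_names) out[[paste0("intensity_", ch)]] <- numeric()
  }
  # leukocyte clustering on enriched cartridges: a fraction of leukocytes is
  # re-placed within touching distance of another leukocyte
  if (config$mode == "epcam_enriched" && config$cluster_fraction > 0) {
    il <- which(out$class == "leukocyte")
    if (length(il) >= 2) {
      nclust <- round(config$cluster_fraction * length(il))
      if (nclust >= 1) {
        moved <- sample(il, nclust)
        for (i in moved) {
          anchor <- sample(setdiff(il, i), 1)
          dist_px <- (out$diameter_um[i] + out$diameter_um[anchor]) / 2 /
            optics$pixel_pitch * runif(1, 0.6, 1.0)
          ang <- runif(1, 0, 2 * pi)
          out$row[i] <- out$row[anchor] + dist_px * sin(ang)
          out$col[i] <- out$col[anchor] + dist_px * cos(ang)
          out$frame_id[i] <- out$frame_id[anchor]
        }
      }
    }
  }
  out$clipped <- out$row < -0.5 | out$row >= nr - 0.5 |
    out$col < -0.5 | out$col >= nc - 0.5
  out <- cbind(particle_id = seq_len(nrow(out)),
               well_id = rep(well_index, nrow(out)), out)
  rownames(out) <- NULL
  out
}

# render the channels of a single frame; returns array (rows, cols, channels)
render_frame <- function(particles, optics, noise_seeds = NULL) {
  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  nch <- length(optics$channel_names)
  if (is.null(noise_seeds))
    noise_seeds <- matrix(sample.int(2147483647L, 2L * nch, replace = TRUE),
                          ncol = 2)
  stack <- array(0, dim = c(nr, nc, nch), dimnames = list(NULL, NULL,
                                                          optics$channel_names))
  rad <- particles$diameter_um / optics$pixel_pitch / 2
  for (k in seq_len(nch)) {
    ch <- optics$channel_names[k]
    fr <- matrix(cpp_gaussian_noise(nr * nc, optics$noise_sd[[ch]],
                                    noise_seeds[k, 1], noise_seeds[k, 2]) +
                   optics$background_level[[ch]], nr, nc)
    if (nrow(particles)) {
      amp <- particles[[paste0("intensity_", ch)]]
      on <- amp > 0
      if (any(on))
        cpp_add_particles(fr, particles$row[on], particles$col[on],
                          rad[on], particles$defocus_sigma[on], amp[on])
    }
    stack[, , k] <- fr
  }
  stack
}

#' Render one well into a multichannel frame stack
#'
#' Every particle contributes, in each channel where its marker intensity is
#' positive, an anti-aliased disc of its diameter convolved with a Gaussian
#' of its defocus sigma and normalised so the post-blur peak equals its
#' marker intensity.  Background plus per-pixel Gaussian noise is added
#' everywhere; the `extra` channel carries background and noise only.
#' Particles whose centre falls outside the frame are rendered clipped and
#' flagged in the truth table.
#'
#' @param particles Ground truth from [sample_well()].
#' @param optics An [optics_config()].
#' @param frames Number of frames; defaults to one past the largest
#'   `frame_id` present.
#' @param seed Optional integer fixing the rendering noise.
#' @return List with `images` (array rows x cols x channels x frames) and
#'   `truth` (the particle table).
#' @export
render_well <- function(particles, optics = optics_config(), frames = NULL,
                        seed = NULL) {
  stopifnot(inherits(optics, "optics_config"))
  if (is.null(frames))
    frames <- if (nrow(particles)) max(particles$frame_id) + 1L else 1L
  if (nrow(particles) && any(particles$frame_id >= frames))
    stop("particle frame_id outside 0..frames-1")
  if (!is.null(seed)) set.seed(seed)
  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  nch <- length(optics$channel_names)
  images <- array(0, dim = c(nr, nc, nch, frames),
                  dimnames = list(NULL, NULL, optics$channel_names, NULL))
  for (f in seq_len(frames) - 1L)
    images[, , , f + 1L] <- render_frame(particles[particles$frame_id == f, ,
                                                   drop = FALSE], optics)
  list(images = images, truth = particles)
}
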