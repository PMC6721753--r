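# End-to-end pipeline: sample ground truth, render frames, detect objects,
# gate them and accumulate per-well class counts.  Frames are rendered and
# processed one at a time so arbitrarily large wells stream in constant
# memory.

#' Simulate, image and count one well
#'
#' @param config A [sample_config()].
#' @param well_index Well number (fixes the drawn particles via the config
#'   seed).
#' @param optics An [optics_config()].
#' @param seg_config A [segmentation_config()].
#' @param library Gate library (object or `"A"`/`"B"`).
#' @param donor_id Identifier copied into the result.
#' @param keep_features Return the full feature table (default `FALSE`).
#' @return List with `counts` (named vector), `well` (one-row data frame of
#'   counts plus volume metadata), `truth` (ground-truth particle table) and
#'   optionally `features`.
#' @export
count_well <- function(config, well_index = 1L, optics = optics_config(),
                       seg_config = segmentation_config(), library = "B",
                       donor_id = 1L, keep_features = FALSE) {
  if (is.character(library)) library <- load_gate_library(library)
  particles <- sample_well(config, well_index, optics)
  set.seed(well_seed(config$seed, well_index) %/% 2L + 1L)  # rendering noise
  pieces <- vector("list", config$frames_per_well)
  for (f in seq_len(config$frames_per_well) - 1L) {
    stack <- render_frame(particles[particles$frame_id == f, , drop = FALSE],
                          optics)
    seg <- segment_stack(stack, seg_config)
    ft <- extract_features(seg$labels, stack, optics, seg$background,
                           seg_config)
    if (nrow(ft)) {
      ft$frame_id <- f
      pieces[[f + 1L]] <- ft
    }
  }
  features <- do.call(rbind, pieces)
  if (is.null(features)) {
    features <- empty_feature_table(optics$channel_names)
    features$frame_id <- integer()
  }
  features$well_id <- rep(well_index, nrow(features))
  features$object_id <- seq_len(nrow(features))
  cls <- classify_objects(features, library)
  vol <- undiluted_volume(config)
  well <- data.frame(donor_id = donor_id, well_id = well_index,
                     mode = config$mode, sampled_volume_ul = vol,
                     n_objects = nrow(features))
  for (nm in names(cls$counts)) well[[nm]] <- cls$counts[[nm]]
  out <- list(counts = cls$counts, well = well, truth = particles,
              assignments = cls$assignments)
  if (keep_features) out$features <- features
  out
}

#' Simulate and count a donor cohort
#'
#' Each donor contributes `config$replicate_wells` technical replicate wells;
#' donors differ only through the random draw (each donor gets an independent
#' seed derived from `seed`).
#'
#' @param n_donors Number of donors.
#' @param config A [sample_config()] (its `seed` is overridden per donor).
#' @param optics,seg_config,library As in [count_well()].
#' @param seed Cohort-level seed.
#' @param progress Print one line per donor.
#' @return List with `well_counts` (one row per well) and `truth_counts`
#'   (ground-truth per-class counts per well).
#' @export
run_cohort <- function(n_donors, config, optics = optics_config(),
                       seg_config = segmentation_config(), library = "B",
                       seed = 1L, progress = FALSE) {
  if (is.character(library)) library <- load_gate_library(library)
  wells <- list()
  truths <- list()
  for (d in seq_len(n_donors)) {
    cfg <- config
    cfg$seed <- well_seed(seed, d * 7L + 3L)
    for (w in seq_len(config$replicate_wells)) {
      res <- count_well(cfg, w, optics, seg_config, library, donor_id = d)
      res$well$well_id <- paste0("D", d, "W", w)
      wells[[length(wells) + 1]] <- res$well
      tc <- table(factor(res$truth$class, levels = CLASS_NAMES))
      truths[[length(truths) + 1]] <- data.frame(
        donor_id = d, well_id = paste0("D", d, "W", w),
        as.list(tc), check.names = FALSE)
    }
    if (progress) message("donor ", d, "/", n_donors, " done")
  }
  list(well_counts = do.call(rbind, wells),
       truth_counts = do.call(rbind, truths))
}
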