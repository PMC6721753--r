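# shared fixtures: small optics, sparse populations, brute-force oracles

tiny_optics <- function(frame = c(96L, 96L), defocus = c(0, 2))
  optics_config(frame_shape = frame, defocus_sigma_range = defocus)

# sparse, fully detectable populations for recovery experiments: every class
# well above the 4-pixel detection floor, low density so overlaps are rare
recovery_populations <- function(leukocytes = 4500, ldevs = 1500,
                                 platelets = 5000, rbcs = 10000)
  default_blood_populations(leukocytes = leukocytes, ldevs = ldevs,
                            platelets = platelets, rbcs = rbcs,
                            ldev_diameter = c(3, 6))

# hand-placed single-particle table matching the whole-blood panel
one_particle <- function(class = "leukocyte", row = 48, col = 48,
                         diameter = 12, sigma = 0,
                         hoechst = 120, cd45 = 120, cd61 = 0, cd235a = 0) {
  data.frame(particle_id = 1L, well_id = 1L, class = class, frame_id = 0L,
             row = row, col = col, diameter_um = diameter,
             defocus_sigma = sigma, clipped = FALSE,
             intensity_Hoechst = hoechst, intensity_CD45 = cd45,
             intensity_CD61 = cd61, intensity_CD235a = cd235a,
             intensity_extra = 0)
}

# brute-force feature oracle: per-object loop over the pixel set
brute_features <- function(labels, stack, optics, background) {
  channels <- dimnames(stack)[[3]]
  nlab <- max(labels)
  rows <- lapply(seq_len(nlab), function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    n <- nrow(idx)
    r <- idx[, 1] - 1; c <- idx[, 2] - 1
    mu20 <- mean(r^2) - mean(r)^2
    mu02 <- mean(c^2) - mean(c)^2
    mu11 <- mean(r * c) - mean(r) * mean(c)
    ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2))$values
    ecc <- if (max(ev) > 0) sqrt(max(0, 1 - min(ev) / max(ev))) else 0
    perim <- 0
    inlab <- function(i, j) i >= 1 && i <= nrow(labels) && j >= 1 &&
      j <= ncol(labels) && labels[i, j] == l
    for (k in seq_len(n)) {
      i <- idx[k, 1]; j <- idx[k, 2]
      perim <- perim + (!inlab(i - 1, j)) + (!inlab(i + 1, j)) +
        (!inlab(i, j - 1)) + (!inlab(i, j + 1))
    }
    out <- data.frame(area_px = n, size_um2 = n * optics$pixel_pitch^2,
                      perimeter_px = perim, eccentricity = ecc,
                      roundness = 4 * pi * n / perim^2,
                      equivalent_radius_um = sqrt(n * optics$pixel_pitch^2 / pi))
    for (k in seq_along(channels)) {
      v <- stack[, , k][idx] - background[[k]]$background
      ch <- channels[k]
      out[[paste0("mean_intensity_", ch)]] <- mean(v)
      out[[paste0("max_intensity_", ch)]] <- max(v)
      out[[paste0("min_intensity_", ch)]] <- min(v)
      out[[paste0("std_intensity_", ch)]] <- if (n > 1) sd(v) else 0
      out[[paste0("integrated_intensity_", ch)]] <- sum(v)
    }
    out
  })
  do.call(rbind, rows)
}

# brute-force gate oracle: per-record, per-criterion interpretation
brute_classify <- function(records, library) {
  channel_map <- library$channel_map
  morph <- c("size_um2", "perimeter_px", "eccentricity")
  vapply(seq_len(nrow(records)), function(i) {
    hits <- vapply(library$gates, function(g) {
      all(vapply(g$criteria, function(cr) {
        col <- if (cr$feature %in% morph) cr$feature
               else paste0(cr$feature, "_", channel_map[[cr$channel_role]])
        v <- records[[col]][i]
        if (cr$cmp == ">") v > cr$threshold else v <= cr$threshold
      }, TRUE))
    }, TRUE)
    if (sum(hits) == 1) vapply(library$gates, `[[`, "", "class_name")[hits]
    else if (sum(hits) > 1) "ambiguous" else "unclassified"
  }, "")
}

# random feature records spread across all gate thresholds
random_records <- function(n, channels = c("Hoechst", "CD45", "CD61",
                                           "CD235a", "extra")) {
  out <- data.frame(object_id = seq_len(n),
                    size_um2 = runif(n, 0, 500),
                    perimeter_px = sample(0:60, n, replace = TRUE),
                    eccentricity = runif(n))
  for (ch in channels) {
    m <- runif(n, 0, 80)
    out[[paste0("mean_intensity_", ch)]] <- m
    out[[paste0("max_intensity_", ch)]] <- m + runif(n, 0, 60)
    out[[paste0("std_intensity_", ch)]] <- runif(n, 0, 12)
  }
  out
}

# well-separated particles on a grid (no touching pairs by construction)
grid_particles <- function(optics, spacing = 24, classes = c("leukocyte",
                                                             "ldEV")) {
  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  pos <- expand.grid(row = seq(spacing / 2, nr - spacing / 2, by = spacing),
                     col = seq(spacing / 2, nc - spacing / 2, by = spacing))
  n <- nrow(pos)
  cls <- rep_len(classes, n)
  out <- data.frame(particle_id = seq_len(n), well_id = 1L, class = cls,
                    frame_id = 0L, row = pos$row, col = pos$col,
                    diameter_um = ifelse(cls == "leukocyte", 9, 4),
                    defocus_sigma = 0, clipped = FALSE)
  out$intensity_Hoechst <- ifelse(cls == "leukocyte", 120, 0)
  out$intensity_CD45 <- 120
  out$intensity_CD61 <- 0
  out$intensity_CD235a <- 0
  out$intensity_extra <- 0
  out
}

# ground-truth pairs closer than touching distance (centres within the sum
# of their pixel radii plus one pixel), per class involvement
touching_pairs <- function(truth, optics) {
  n <- nrow(truth)
  involved <- setNames(numeric(length(unique(truth$class))),
                       unique(truth$class))
  total <- 0
  if (n < 2) return(list(total = 0, involved = involved))
  rad <- truth$diameter_um / optics$pixel_pitch / 2
  for (i in seq_len(n - 1)) {
    same <- which(truth$frame_id[(i + 1):n] == truth$frame_id[i]) + i
    for (j in same) {
      d <- sqrt((truth$row[i] - truth$row[j])^2 +
                  (truth$col[i] - truth$col[j])^2)
      # rendered footprints reach beyond the physical radius: defocus blur,
      # the anti-aliased rim, diagonal (8-neighbour) bridging and noise
      reach <- rad[i] + rad[j] + 2.5 * (truth$defocus_sigma[i] +
                                          truth$defocus_sigma[j]) + 3
      if (d < reach) {
        total <- total + 1
        involved[truth$class[i]] <- involved[truth$class[i]] + 1
        involved[truth$class[j]] <- involved[truth$class[j]] + 1
      }
    }
  }
  list(total = total, involved = involved)
}
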