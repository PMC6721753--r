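# Count statistics downstream of gating: volume extrapolation, ldEV:leukocyte
# relative frequencies, technical-replicate variability, box-plot summaries
# and correlation against reference (hematology-analyzer) concentrations.

#' Extrapolate a count to another blood volume
#'
#' `count * target_volume / sampled_volume`, reported as a rate (not
#' rounded).  E.g. 18 objects in a 0.02 uL well correspond to 900 per uL.
#'
#' @param count Object count (non-negative).
#' @param sampled_volume uL of undiluted blood the count was observed in.
#' @param target_volume uL to extrapolate to (7.5 mL = 7500 uL).
#' @return Extrapolated count (numeric rate).
#' @export
extrapolate_count <- function(count, sampled_volume, target_volume) {
  if (any(sampled_volume <= 0)) stop("sampled_volume must be positive")
  count * target_volume / sampled_volume
}

#' Leukocytes-per-ldEV relative frequency
#'
#' The number of leukocytes detected per ldEV ("one ldEV for every N
#' leukocytes").  Undefined (NA) when no ldEVs were counted; never reported
#' as infinity.
#'
#' @param counts Named vector or list with `leukocyte` and `ldEV` entries.
#' @return Ratio leukocyte count / ldEV count, or `NA` when ldEV count is 0.
#' @export
relative_frequency <- function(counts) {
  l <- as.numeric(counts[["leukocyte"]])
  e <- as.numeric(counts[["ldEV"]])
  if (is.na(e) || e == 0) return(NA_real_)
  l / e
}

#' Technical-replicate statistics
#'
#' @param x Per-well counts of one donor and class (`n >= 2`).
#' @return List with `n`, `mean`, `sd` (sample SD, n-1 denominator) and
#'   `se_pct`, the standard error as a percentage of the mean
#'   (`100 * (sd/sqrt(n)) / mean`), `NA` when the mean is 0.
#' @export
replicate_stats <- function(x) {
  n <- length(x)
  if (n < 2) stop("replicate statistics require at least two wells")
  m <- mean(x)
  s <- sd(x)
  list(n = n, mean = m, sd = s,
       se_pct = if (m > 0) 100 * (s / sqrt(n)) / m else NA_real_)
}

#' Box-plot summary of a group
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`); whiskers are the `Q1 - 1.5*IQR` / `Q3 + 1.5*IQR`
#' fences.
#'
#' @param x Numeric values (non-empty).
#' @param type Quantile convention, recorded in the output.
#' @return List with `n`, `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `quantile_type`.
#' @export
boxplot_stats <- function(x, type = 7) {
  if (length(x) == 0) stop("empty group")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = type))
  iqr <- q[3] - q[1]
  list(n = length(x), q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr,
       quantile_type = type)
}

#' Correlate imaging-derived and reference concentrations
#'
#' Ordinary least-squares fit of the reference concentration on the
#' imaging-derived concentration per class (one point per donor, replicate
#' wells averaged beforehand), plus the per-class underestimation factor
#' `mean(imaging) / mean(reference)`.
#'
#' @param imaging,reference Data frames with columns `donor_id`, `class`,
#'   `per_ul`; donors are matched by `donor_id` within each class.
#' @return Data frame, one row per class: `n`, `slope`, `intercept`,
#'   `r_squared`, `underestimation_factor`.
#' @export
correlate_counts <- function(imaging, reference) {
  need <- c("donor_id", "class", "per_ul")
  stopifnot(all(need %in% names(imaging)), all(need %in% names(reference)))
  classes <- intersect(unique(imaging$class), unique(reference$class))
  rows <- lapply(classes, function(cl) {
    a <- imaging[imaging$class == cl, ]
    b <- reference[reference$class == cl, ]
    m <- merge(a, b, by = "donor_id", suffixes = c("_img", "_ref"))
    if (nrow(m) < 3) stop("fewer than 3 paired observations for class ", cl)
    if (var(m$per_ul_ref) == 0 || var(m$per_ul_img) == 0)
      stop("zero variance in class ", cl, ": fit undefined")
    fit <- lm(per_ul_ref ~ per_ul_img, data = m)
    ss_res <- sum(residuals(fit)^2)
    ss_tot <- sum((m$per_ul_ref - mean(m$per_ul_ref))^2)
    data.frame(class = cl, n = nrow(m),
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = 1 - ss_res / ss_tot,
               underestimation_factor = mean(m$per_ul_img) / mean(m$per_ul_ref))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a donor's technical replicates
#'
#' @param well_counts Data frame of per-well counts (columns `donor_id`,
#'   `well_id`, `sampled_volume_ul`, one column per class).
#' @param classes Class columns to summarise; defaults to the four blood
#'   classes present.
#' @param target_volume_ul Second extrapolation volume (default 7.5 mL).
#' @return Data frame, one row per donor x class: replicate `n`, `mean`,
#'   `sd`, `se_pct`, extrapolated `per_ul` and `per_target`, plus the
#'   donor-level `leukocytes_per_ldev` ratio (from mean counts).
#' @export
donor_summary <- function(well_counts, classes = NULL,
                          target_volume_ul = 7500) {
  if (is.null(classes))
    classes <- intersect(CLASS_NAMES, names(well_counts))
  stopifnot(length(classes) >= 1, "donor_id" %in% names(well_counts),
            "sampled_volume_ul" %in% names(well_counts))
  rows <- list()
  for (d in unique(well_counts$donor_id)) {
    w <- well_counts[well_counts$donor_id == d, ]
    vol <- unique(w$sampled_volume_ul)
    stopifnot(length(vol) == 1)
    means <- vapply(classes, function(cl) mean(w[[cl]]), 0)
    ratio <- if ("leukocyte" %in% classes && "ldEV" %in% classes)
      relative_frequency(means) else NA_real_
    for (cl in classes) {
      st <- replicate_stats(w[[cl]])
      rows[[length(rows) + 1]] <- data.frame(
        donor_id = d, class = cl, n = st$n, mean = st$mean, sd = st$sd,
        se_pct = st$se_pct,
        per_ul = extrapolate_count(st$mean, vol, 1),
        per_target = extrapolate_count(st$mean, vol, target_volume_ul),
        leukocytes_per_ldev = ratio)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a cohort group with box-plot statistics
#'
#' @param donor_summaries Output of [donor_summary()], optionally with a
#'   `group` column; the summary value is the per-donor `per_target` count.
#' @param value Column to summarise (default `"per_target"`).
#' @return Data frame, one row per group x class, with quartiles, IQR and
#'   whisker fences, plus the group-level mean leukocytes-per-ldEV ratio.
#' @export
cohort_summary <- function(donor_summaries, value = "per_target") {
  d <- donor_summaries
  if (!"group" %in% names(d)) d$group <- "all"
  rows <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, ]
    ratio <- mean(dg$leukocytes_per_ldev[dg$class == "leukocyte"], na.rm = TRUE)
    for (cl in unique(dg$class)) {
      bs <- boxplot_stats(dg[[value]][dg$class == cl])
      rows[[length(rows) + 1]] <- data.frame(
        group = g, class = cl, n = bs$n, q1 = bs$q1, median = bs$median,
        q3 = bs$q3, iqr = bs$iqr, whisker_low = bs$whisker_low,
        whisker_high = bs$whisker_high, leukocytes_per_ldev = ratio)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
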