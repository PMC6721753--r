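# Linear gating: each object class is a conjunction of per-channel feature
# thresholds (e.g. CD45 mean intensity > 30 AND max > 50 AND size <= 150
# um^2).  Two gate libraries ship with the package: "A" for EpCAM-enriched
# cartridges (nuclear dye DAPI, CD45, CK) and "B" for unenriched whole blood
# (Hoechst, CD45, CD61, CD235a).  Gates reference channel *roles*; a channel
# map ties roles to the channel names of a given data set.

GATE_FEATURES <- c(CHANNEL_FEATURES, MORPHOLOGY_FEATURES)

#' One gate criterion
#'
#' @param channel_role Marker role the criterion refers to (`nuclear`,
#'   `CD45`, `CD61`, `CD235a`, `CK`, `extra`).  Morphology features are
#'   shared across channels; the role is kept for provenance.
#' @param feature One of `mean_intensity`, `max_intensity`, `std_intensity`
#'   (channel-scoped, arbitrary units), `size_um2`, `perimeter_px`,
#'   `eccentricity` (morphology).
#' @param cmp `">"` (strict) or `"<="` (inclusive), exactly as printed in
#'   gate tables.
#' @param threshold Numeric threshold in the feature's units.
#' @return A `gate_criterion` object.
#' @export
gate_criterion <- function(channel_role, feature, cmp, threshold) {
  feature <- match.arg(feature, GATE_FEATURES)
  cmp <- match.arg(cmp, c(">", "<="))
  stopifnot(is.character(channel_role), length(channel_role) == 1,
            is.numeric(threshold), length(threshold) == 1)
  structure(list(channel_role = channel_role, feature = feature, cmp = cmp,
                 threshold = as.numeric(threshold)), class = "gate_criterion")
}

#' One class gate (a conjunction of criteria)
#'
#' @param class_name Object class the gate defines.
#' @param criteria Non-empty list of [gate_criterion()]; all must hold.
#' @param library Optional library identifier.
#' @return A `gate_set` object.
#' @export
gate_set <- function(class_name, criteria, library = NA_character_) {
  stopifnot(is.character(class_name), length(criteria) >= 1,
            all(vapply(criteria, inherits, TRUE, "gate_criterion")))
  structure(list(class_name = class_name, criteria = criteria,
                 library = library), class = "gate_set")
}

bundled_gate_path <- function(name) {
  file <- switch(name,
                 A = "gates_epcam_A.json",
                 B = "gates_whole_blood_B.json",
                 stop("unknown bundled gate library: ", name))
  system.file("extdata", file, package = "evcounter", mustWork = TRUE)
}

#' Load a gate library
#'
#' @param source `"A"` (EpCAM enrichment), `"B"` (whole blood, no
#'   enrichment), or the path to a gate-library JSON file.
#' @return A `gate_library`: list with `library` (identifier), `channel_map`
#'   (role -> channel name) and `gates` (list of [gate_set()]).
#' @export
load_gate_library <- function(source) {
  path <- if (source %in% c("A", "B")) bundled_gate_path(source) else source
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$gates) || length(cfg$gates) == 0)
    stop("gate library contains no gates: ", path)
  gates <- lapply(cfg$gates, function(g) {
    if (is.null(g$criteria) || length(g$criteria) == 0)
      stop("gate for class '", g$class_name, "' has no criteria")
    crit <- lapply(g$criteria, function(cr)
      gate_criterion(cr$channel_role, cr$feature, cr$cmp, cr$threshold))
    gate_set(g$class_name, crit, cfg$library)
  })
  channel_map <- unlist(cfg$channel_map)
  structure(list(library = cfg$library, channel_map = channel_map,
                 gates = gates), class = "gate_library")
}

#' Save a gate library to JSON
#'
#' `load_gate_library(save_gate_library(x, path))` reproduces `x` exactly.
#'
#' @param library A `gate_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_gate_library <- function(library, path) {
  stopifnot(inherits(library, "gate_library"))
  out <- list(
    library = library$library,
    channel_map = as.list(library$channel_map),
    gates = lapply(library$gates, function(g) list(
      class_name = g$class_name,
      criteria = lapply(g$criteria, function(cr)
        list(channel_role = cr$channel_role, feature = cr$feature,
             cmp = cr$cmp, threshold = cr$threshold)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# resolve a criterion to its feature-table column name
criterion_column <- function(criterion, channel_map) {
  if (criterion$feature %in% MORPHOLOGY_FEATURES) return(criterion$feature)
  role <- criterion$channel_role
  ch <- if (role %in% names(channel_map)) channel_map[[role]] else role
  paste0(criterion$feature, "_", ch)
}

#' Evaluate one gate on object records
#'
#' @param records Feature table (one or more rows).
#' @param gate A [gate_set()].
#' @param channel_map Named vector mapping channel roles to channel names.
#' @return Logical vector, `TRUE` where every criterion holds.  A feature
#'   column missing from `records` is an error naming the column, never a
#'   silent `FALSE`.
#' @export
evaluate_gate <- function(records, gate, channel_map) {
  stopifnot(inherits(gate, "gate_set"))
  ok <- rep(TRUE, nrow(records))
  for (cr in gate$criteria) {
    colname <- criterion_column(cr, channel_map)
    if (!colname %in% names(records))
      stop("feature column '", colname, "' required by the ",
           gate$class_name, " gate is missing")
    v <- records[[colname]]
    ok <- ok & if (cr$cmp == ">") v > cr$threshold else v <= cr$threshold
  }
  ok
}

#' Classify a feature table
#'
#' Every record is evaluated against every gate of the library.  Records
#' matching exactly one gate take that class; records matching none are
#' `unclassified`; records matching several are `ambiguous` and are always
#' reported separately, never folded into a class.
#'
#' @param features Feature table from [extract_features()]/[detect_well()]
#'   (may be empty).
#' @param library A `gate_library` or `"A"`/`"B"`.
#' @param channel_map Role -> channel map; defaults to the library's own.
#' @return List with `assignments` (`object_id`, one logical
#'   `matched_<class>` column per gate, `n_matched`, `final_class`) and
#'   `counts` (named integer vector over the library's classes plus
#'   `ambiguous` and `unclassified`).
#' @export
classify_objects <- function(features, library, channel_map = NULL) {
  if (is.character(library)) library <- load_gate_library(library)
  stopifnot(inherits(library, "gate_library"))
  if (is.null(channel_map)) channel_map <- library$channel_map
  classes <- vapply(library$gates, `[[`, "", "class_name")
  n <- nrow(features)
  matched <- matrix(FALSE, n, length(classes),
                    dimnames = list(NULL, classes))
  for (k in seq_along(library$gates))
    matched[, k] <- evaluate_gate(features, library$gates[[k]], channel_map)
  nm <- rowSums(matched)
  final <- rep("unclassified", n)
  final[nm > 1] <- "ambiguous"
  if (any(nm == 1))
    final[nm == 1] <- classes[max.col(matched[nm == 1, , drop = FALSE])]
  counts <- setNames(integer(length(classes) + 2),
                     c(classes, "ambiguous", "unclassified"))
  tab <- table(final)
  counts[names(tab)] <- as.integer(tab)
  assignments <- data.frame(object_id = if (n) features$object_id else integer())
  for (cl in classes) assignments[[paste0("matched_", cl)]] <- matched[, cl]
  assignments$n_matched <- as.integer(nm)
  assignments$final_class <- final
  list(assignments = assignments, counts = counts)
}
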