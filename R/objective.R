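#' Texture property subsets
#'
#' The scalarized objective can be built from two standard property sets:
#' `"without_tensile"` uses the compression and cutting measurements
#' (hardness, springiness, chewiness, transverse/longitudinal cutting force),
#' and `"with_tensile"` adds the transverse/longitudinal tensile strengths.
#' Any other ordered set of property names defines a `"custom"` subset.
#'
#' @param subset either one of the labels above or a character vector of
#'   property names.
#' @return A character vector of property names with attribute `label`.
#' @examples
#' texture_subset("with_tensile")
#' @export
texture_subset <- function(subset = c("with_tensile", "without_tensile")) {
  base <- c("hardness", "springiness", "chewiness",
            "cutting_force_T", "cutting_force_L")
  tens <- c("tensile_T", "tensile_L")
  if (length(subset) >= 1 && all(subset %in% c("with_tensile", "without_tensile"))) {
    label <- match.arg(subset)
    names <- if (label == "with_tensile") c(base, tens) else base
  } else {
    label <- "custom"
    names <- as.character(subset)
    if (anyDuplicated(names))
      stop("duplicate property names in custom subset", call. = FALSE)
  }
  structure(names, label = label)
}

#' Scalarize a texture profile against a reference
#'
#' Collapses a multi-property texture profile into the single dimensionless
#' deviation score
#' \deqn{S = \sum_i w_i \, |x_i - x_{i,\mathrm{ref}}| / x_{i,\mathrm{ref}},}
#' the weighted sum of normalized absolute deviations of each measured
#' property from the reference product (here: ready-to-eat chicken breast).
#' With the default equal weights (all 1), S is 0 exactly when the profile
#' matches the reference on the chosen subset, and each property contributes
#' its relative deviation regardless of units.
#'
#' @param profile named numeric vector (or one-row data frame) of measured
#'   properties, strictly positive.
#' @param reference named numeric vector of reference values, strictly
#'   positive for every subset property.
#' @param subset a [texture_subset()] (or label understood by it).
#' @param weights optional named (or subset-ordered) non-negative weights;
#'   default all 1.
#' @return The scalarized value (non-negative numeric scalar) with attribute
#'   `subset`.
#' @examples
#' ref <- c(hardness = 30, springiness = 0.9, chewiness = 25,
#'          cutting_force_T = 20, cutting_force_L = 18,
#'          tensile_T = 5, tensile_L = 7)
#' scalarize(ref * 1.1, ref)  # every property 10% off -> 0.7
#' @export
scalarize <- function(profile, reference, subset = "with_tensile",
                      weights = NULL) {
  sub <- texture_subset(subset)
  if (is.data.frame(profile)) profile <- unlist(profile[1, , drop = TRUE])
  if (is.data.frame(reference)) reference <- unlist(reference[1, , drop = TRUE])
  miss_p <- sub[!(sub %in% names(profile)) | is.na(profile[sub])]
  if (length(miss_p))
    stop("incomplete profile; missing properties: ",
         paste(miss_p, collapse = ", "), call. = FALSE)
  miss_r <- sub[!(sub %in% names(reference)) | is.na(reference[sub])]
  if (length(miss_r))
    stop("incomplete reference; missing properties: ",
         paste(miss_r, collapse = ", "), call. = FALSE)
  x <- as.numeric(profile[sub])
  r <- as.numeric(reference[sub])
  if (any(r <= 0))
    stop("invalid reference: non-positive value for ",
         paste(sub[r <= 0], collapse = ", "), call. = FALSE)
  if (is.null(weights)) {
    w <- rep(1, length(sub))
  } else if (!is.null(names(weights))) {
    if (!all(sub %in% names(weights)))
      stop("weights must cover every subset property", call. = FALSE)
    w <- as.numeric(weights[sub])
  } else {
    stopifnot(length(weights) == length(sub))
    w <- as.numeric(weights)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  structure(sum(w * abs(x - r) / r), subset = attr(sub, "label"))
}

#' Scalarize a per-run, per-replicate texture table
#'
#' Takes a long table with one row per (run, replicate) and one column per
#' texture property, aggregates replicates within each run, and scalarizes
#' against the reference. By default replicates are averaged first and the
#' mean profile is scalarized (`"mean_then_scalarize"`); the alternative
#' scalarizes each replicate and then aggregates the scores.
#'
#' @param texture data frame with a `run` column and property columns;
#'   an optional `replicate` column is ignored beyond grouping by `run`.
#' @param reference named numeric reference profile.
#' @param subset a [texture_subset()] or label.
#' @param weights optional weights passed to [scalarize()].
#' @param aggregate `"mean"` or `"median"` across replicates.
#' @param order aggregation order, see Details.
#' @return Data frame with columns `run` and `response`, one row per run,
#'   ordered by run.
#' @export
scalarize_runs <- function(texture, reference, subset = "with_tensile",
                           weights = NULL, aggregate = c("mean", "median"),
                           order = c("mean_then_scalarize",
                                     "scalarize_then_mean")) {
  aggregate <- match.arg(aggregate)
  order <- match.arg(order)
  if (!"run" %in% names(texture))
    stop("texture table needs a 'run' column", call. = FALSE)
  sub <- texture_subset(subset)
  missing <- setdiff(sub, names(texture))
  if (length(missing))
    stop("texture table lacks property columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  runs <- sort(unique(texture$run))
  response <- vapply(runs, function(r) {
    rows <- texture[texture$run == r, sub, drop = FALSE]
    if (order == "mean_then_scalarize") {
      prof <- vapply(rows, agg_fun, numeric(1))
      as.numeric(scalarize(prof, reference, subset, weights))
    } else {
      agg_fun(vapply(seq_len(nrow(rows)), function(i)
        as.numeric(scalarize(unlist(rows[i, ]), reference, subset, weights)),
        numeric(1)))
    }
  }, numeric(1))
  data.frame(run = runs, response = response)
}

#' Read a texture measurement table
#'
#' CSV with columns `run`, optionally `replicate`, and one column per
#' texture property.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_texture_csv <- function(path) {
  out <- utils::read.csv(path)
  if (!"run" %in% names(out))
    stop("texture file lacks a 'run' column", call. = FALSE)
  out
}
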