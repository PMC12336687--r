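#' Define the extrusion factor space
#'
#' Constructs the three-factor space used throughout the package: barrel
#' temperature (zones 8--9, degrees C), water content (% of total mass) and
#' cooling-die temperature (section a, degrees C). Each factor carries three
#' actual levels mapped to the coded levels -1, 0, +1, plus closed bounds for
#' optimum searches. The cooling-die factor additionally carries the paired
#' section-b temperature, which is derived metadata: all models treat the
#' cooling die as the single section-a scalar.
#'
#' @param bt_levels,wc_levels,cdt_levels numeric length-3 vectors of actual
#'   values at coded levels (-1, 0, +1); must be strictly increasing.
#' @param bt_bounds,wc_bounds,cdt_bounds closed intervals (length-2) for the
#'   optimum search; must contain the three levels. Default to the level range.
#' @param cdt_section_b named numeric vector mapping each cooling-die
#'   section-a level to its paired section-b temperature.
#' @return An object of class `"factor_space"`: a list with elements
#'   `factors` (list of three factor records with `name`, `levels`, `bounds`)
#'   and `cdt_section_b`.
#' @examples
#' sp <- factor_space()
#' sp$factors$bt$levels
#' @export
factor_space <- function(bt_levels = c(110, 125, 140),
                         wc_levels = c(55, 60, 65),
                         cdt_levels = c(60, 70, 80),
                         bt_bounds = range(bt_levels),
                         wc_bounds = range(wc_levels),
                         cdt_bounds = range(cdt_levels),
                         cdt_section_b = c(`60` = 55, `70` = 60, `80` = 65)) {
  mk <- function(name, levels, bounds) {
    stopifnot(length(levels) == 3L, length(bounds) == 2L)
    if (any(diff(levels) <= 0))
      stop("factor '", name, "': actual levels must be strictly increasing",
           call. = FALSE)
    if (bounds[1] > levels[1] || bounds[2] < levels[3])
      stop("factor '", name, "': bounds must contain all three levels",
           call. = FALSE)
    list(name = name, levels = as.numeric(levels), bounds = as.numeric(bounds))
  }
  fs <- list(
    factors = list(
      bt  = mk("barrel_temperature", bt_levels, bt_bounds),
      wc  = mk("water_content", wc_levels, wc_bounds),
      cdt = mk("cooling_die_temperature", cdt_levels, cdt_bounds)
    ),
    cdt_section_b = cdt_section_b
  )
  sb_levels <- as.numeric(names(cdt_section_b))
  if (!all(fs$factors$cdt$levels %in% sb_levels))
    stop("cdt_section_b must be defined at every cooling-die level", call. = FALSE)
  class(fs) <- "factor_space"
  fs
}

#' @export
print.factor_space <- function(x, ...) {
  cat("Extrusion factor space (coded -1 / 0 / +1):\n")
  for (f in x$factors)
    cat(sprintf("  %-25s %s   bounds [%g, %g]\n", f$name,
                paste(f$levels, collapse = " / "), f$bounds[1], f$bounds[2]))
  invisible(x)
}

factor_names <- c("bt", "wc", "cdt")

as_point_matrix <- function(x, what = "point") {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stop(what, " must have 3 columns (bt, wc, cdt)", call. = FALSE)
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(what, " must have 3 columns (bt, wc, cdt)", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Convert actual factor settings to coded units
#'
#' Applies, per factor, the affine map sending (low, center, high) actual
#' levels to (-1, 0, +1); intermediate values map linearly. For the
#' Box-Behnken levels the map is exact; arbitrary in-bounds settings give
#' fractional coded values.
#'
#' @param space a [factor_space()].
#' @param actual a length-3 vector `(bt, wc, cdt)` or a matrix/data frame
#'   with three columns, one row per point.
#' @return A numeric matrix of coded coordinates (columns `bt`, `wc`, `cdt`).
#' @examples
#' code_point(factor_space(), c(125, 60, 70))  # design center -> (0, 0, 0)
#' @export
code_point <- function(space, actual) {
  stopifnot(inherits(space, "factor_space"))
  a <- as_point_matrix(actual, "actual")
  out <- matrix(NA_real_, nrow(a), 3L, dimnames = list(NULL, factor_names))
  for (j in seq_len(3L)) {
    f <- space$factors[[j]]
    bad <- a[, j] < f$bounds[1] - 1e-9 | a[, j] > f$bounds[2] + 1e-9
    if (any(bad))
      stop("actual value out of bounds for factor '", f$name, "': ",
           paste(a[bad, j], collapse = ", "), call. = FALSE)
    half <- (f$levels[3] - f$levels[1]) / 2
    out[, j] <- (a[, j] - f$levels[2]) / half
  }
  out
}

#' Convert coded coordinates to actual factor settings
#'
#' Inverse of [code_point()]. Attaches the paired cooling-die section-b
#' temperature: at a tabulated section-a level the stored pairing is used,
#' elsewhere section b is linearly interpolated (and extrapolated) through
#' the tabulated pairs. Section b is reporting metadata only.
#'
#' @param space a [factor_space()].
#' @param coded a length-3 coded vector or a matrix/data frame of coded rows.
#' @return A data frame with columns `coded_bt`, `coded_wc`, `coded_cdt`,
#'   `bt_c`, `wc_pct`, `cdt_a_c`, `cdt_b_c`.
#' @examples
#' decode_point(factor_space(), c(0, 0, 0))
#' @export
decode_point <- function(space, coded) {
  stopifnot(inherits(space, "factor_space"))
  cc <- as_point_matrix(coded, "coded")
  act <- matrix(NA_real_, nrow(cc), 3L)
  for (j in seq_len(3L)) {
    f <- space$factors[[j]]
    half <- (f$levels[3] - f$levels[1]) / 2
    act[, j] <- f$levels[2] + half * cc[, j]
  }
  sb_a <- as.numeric(names(space$cdt_section_b))
  sb_b <- as.numeric(space$cdt_section_b)
  fit <- stats::lm.fit(cbind(1, sb_a), sb_b)  # pairs are collinear; exact line
  cdt_b <- fit$coefficients[1] + fit$coefficients[2] * act[, 3]
  exact <- match(round(act[, 3], 9), sb_a)
  cdt_b[!is.na(exact)] <- sb_b[exact[!is.na(exact)]]
  data.frame(coded_bt = cc[, 1], coded_wc = cc[, 2], coded_cdt = cc[, 3],
             bt_c = act[, 1], wc_pct = act[, 2], cdt_a_c = act[, 3],
             cdt_b_c = cdt_b)
}

#' Generate the three-factor Box-Behnken design
#'
#' Returns the fixed 15-run layout: 12 edge midpoints (every pair of factors
#' at +/-1 with the third at 0) followed by 3 center replicates. The design
#' deliberately contains no corner of the factor cube, keeping all runs inside
#' the stable extrusion envelope. Run order is fixed (not randomized) so that
#' downstream fixtures are reproducible.
#'
#' @param space a [factor_space()] with exactly three factors.
#' @return A data frame of class `"bbd_design"` with columns `run`,
#'   `coded_bt`, `coded_wc`, `coded_cdt`, `bt_c`, `wc_pct`, `cdt_a_c`,
#'   `cdt_b_c`.
#' @examples
#' generate_bbd(factor_space())
#' @export
generate_bbd <- function(space) {
  stopifnot(inherits(space, "factor_space"))
  if (length(space$factors) != 3L)
    stop("unsupported design: Box-Behnken construction requires exactly 3 factors",
         call. = FALSE)
  # pairs ordered (-,-), (+,-), (-,+), (+,+) within each block
  edges <- rbind(
    c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0), c(1, 1, 0),
    c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1), c(1, 0, 1),
    c(0, -1, -1), c(0, 1, -1), c(0, -1, 1), c(0, 1, 1)
  )
  coded <- rbind(edges, matrix(0, 3, 3))
  out <- cbind(run = seq_len(15L), decode_point(space, coded))
  class(out) <- c("bbd_design", "data.frame")
  out
}

#' Read or write a design table
#'
#' CSV schema: `run, coded_bt, coded_wc, coded_cdt, bt_c, wc_pct, cdt_a_c,
#' cdt_b_c` (one row per run).
#'
#' @param design a design data frame as returned by [generate_bbd()].
#' @param path file path.
#' @return `read_design()` returns the design data frame; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- utils::read.csv(path)
  need <- c("run", "coded_bt", "coded_wc", "coded_cdt",
            "bt_c", "wc_pct", "cdt_a_c", "cdt_b_c")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("design file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  class(out) <- c("bbd_design", "data.frame")
  out
}

#' Extract the coded coordinate matrix of a design
#'
#' @param design a design data frame with `coded_bt`, `coded_wc`,
#'   `coded_cdt` columns.
#' @return Numeric matrix with one row per run.
#' @export
coded_matrix <- function(design) {
  as.matrix(design[, c("coded_bt", "coded_wc", "coded_cdt")])
}
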