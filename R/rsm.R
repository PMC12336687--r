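#' Bundle a design and its scalarized responses
#'
#' Pairs each design run with its scalarized response and groups replicate
#' runs (identical coded coordinates); the within-group scatter of the center
#' replicates is the pure-error estimate used by the ANOVA and by the
#' Gaussian-process noise level.
#'
#' @param design a design data frame ([generate_bbd()] / [read_design()]).
#' @param response numeric vector of scalarized responses, or a data frame
#'   with columns `run` and `response`.
#' @return An object of class `"response_dataset"`: list with `design`,
#'   `response`, and `replicate_groups` (list of run-index vectors sharing
#'   coded coordinates, singletons included).
#' @export
response_dataset <- function(design, response) {
  if (is.data.frame(response)) {
    ord <- match(design$run, response$run)
    if (anyNA(ord))
      stop("response table does not cover every design run", call. = FALSE)
    response <- response$response[ord]
  }
  stopifnot(length(response) == nrow(design), is.numeric(response))
  key <- apply(round(coded_matrix(design), 9), 1, paste, collapse = "/")
  groups <- split(seq_len(nrow(design)), key)
  names(groups) <- NULL
  structure(list(design = design, response = as.numeric(response),
                 replicate_groups = groups),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  nrep <- sum(lengths(x$replicate_groups) > 1)
  cat(sprintf("Response dataset: %d runs, %d replicate group(s), response range [%.2f, %.2f]\n",
              nrow(x$design), nrep, min(x$response), max(x$response)))
  invisible(x)
}

quad_design_matrix <- function(coded, include_interactions = FALSE) {
  X <- cbind(1, coded, coded^2)
  cn <- c("(Intercept)", "bt", "wc", "cdt", "bt^2", "wc^2", "cdt^2")
  if (include_interactions) {
    X <- cbind(X, coded[, 1] * coded[, 2], coded[, 1] * coded[, 3],
               coded[, 2] * coded[, 3])
    cn <- c(cn, "bt:wc", "bt:cdt", "wc:cdt")
  }
  colnames(X) <- cn
  X
}

#' Fit the second-order response surface
#'
#' Ordinary least squares fit of the quadratic polynomial
#' \deqn{\hat S = \beta_0 + \sum_i \beta_i \theta_i + \sum_i \beta_{ii}
#'   \theta_i^2 \;(+ \sum_{i<j} \beta_{ij}\theta_i\theta_j)}
#' on coded coordinates. Coded-unit regression makes the linear columns of
#' the Box-Behnken design orthogonal and yields the adjusted sums of squares
#' conventionally reported for such designs; coefficients in actual units are
#' derived from the same fit and predictions are identical under either
#' coding. Interaction terms are excluded by default (the usual final-model
#' choice when screening shows them insignificant) but can be included.
#'
#' @param data a [response_dataset()].
#' @param include_interactions logical; fit the three two-way interactions.
#' @param space optional [factor_space()] used to derive actual-unit
#'   coefficients; defaults to the study space.
#' @return An object of class `"rsm_fit"`: list with `coefficients` (coded),
#'   `coefficients_actual`, `include_interactions`, `sigma2` (residual mean
#'   square), `df_residual`, `leverage`, `fitted`, `residuals`, `data`,
#'   `space`.
#' @examples
#' cs <- load_case_study()
#' fit <- fit_quadratic(cs$dataset)
#' round(coef(fit), 3)
#' @export
fit_quadratic <- function(data, include_interactions = FALSE, space = NULL) {
  stopifnot(inherits(data, "response_dataset"))
  if (is.null(space)) space <- factor_space()
  coded <- coded_matrix(data$design)
  X <- quad_design_matrix(coded, include_interactions)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("singular design: ", p, "-parameter quadratic is not estimable ",
         "from these points", call. = FALSE)
  fit <- stats::lm.fit(X, data$response)
  beta <- fit$coefficients
  res <- fit$residuals
  dfe <- length(data$response) - p
  H <- X %*% solve(crossprod(X)) %*% t(X)
  out <- list(coefficients = beta,
              coefficients_actual = recode_coefficients(beta, space,
                                                        include_interactions),
              include_interactions = include_interactions,
              sigma2 = if (dfe > 0) sum(res^2) / dfe else NA_real_,
              df_residual = dfe,
              leverage = diag(H),
              fitted = as.numeric(X %*% beta),
              residuals = as.numeric(res),
              data = data, space = space)
  class(out) <- "rsm_fit"
  out
}

# Re-express coded-unit coefficients in actual units; predictions are
# invariant under this affine reparameterization.
recode_coefficients <- function(beta, space, include_interactions) {
  ctr <- vapply(space$factors, function(f) f$levels[2], numeric(1))
  half <- vapply(space$factors, function(f) (f$levels[3] - f$levels[1]) / 2,
                 numeric(1))
  b0 <- beta[1]; bl <- beta[2:4]; bq <- beta[5:7]
  # coded x = (a - c)/h  =>  bl*x + bq*x^2 expands in a
  lin <- bl / half - 2 * bq * ctr / half^2
  quad <- bq / half^2
  int0 <- b0 - sum(bl * ctr / half) + sum(bq * ctr^2 / half^2)
  out <- c(int0, lin, quad)
  names(out) <- c("(Intercept)", "bt", "wc", "cdt", "bt^2", "wc^2", "cdt^2")
  if (include_interactions && length(beta) == 10L) {
    bij <- beta[8:10]
    hh <- c(half[1] * half[2], half[1] * half[3], half[2] * half[3])
    cc <- rbind(c(1, 2), c(1, 3), c(2, 3))
    for (k in 1:3) {
      i <- cc[k, 1]; j <- cc[k, 2]
      out[1] <- out[1] + bij[k] * ctr[i] * ctr[j] / hh[k]
      out[1 + i] <- out[1 + i] - bij[k] * ctr[j] / hh[k]
      out[1 + j] <- out[1 + j] - bij[k] * ctr[i] / hh[k]
    }
    out <- c(out, bij / hh)
    names(out)[8:10] <- c("bt:wc", "bt:cdt", "wc:cdt")
  }
  out
}

#' @export
coef.rsm_fit <- function(object, coding = c("coded", "actual"), ...) {
  coding <- match.arg(coding)
  if (coding == "coded") object$coefficients else object$coefficients_actual
}

#' Predict from a fitted response surface
#'
#' Evaluates the polynomial at new points given in actual units (default) or
#' coded units. Extrapolation beyond the design region is permitted.
#'
#' @param object an `"rsm_fit"`.
#' @param newdata length-3 vector, matrix, or data frame of points; a design
#'   data frame with `coded_*` columns is also accepted.
#' @param units `"actual"` or `"coded"` interpretation of `newdata`.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_fit <- function(object, newdata, units = c("actual", "coded"), ...) {
  units <- match.arg(units)
  if (is.data.frame(newdata) && all(c("coded_bt", "coded_wc", "coded_cdt") %in%
                                    names(newdata))) {
    coded <- coded_matrix(newdata)
  } else {
    m <- as_point_matrix(newdata, "newdata")
    coded <- if (units == "coded") m else code_point_unbounded(object$space, m)
  }
  X <- quad_design_matrix(coded, object$include_interactions)
  as.numeric(X %*% object$coefficients)
}

# coding map without the bounds check, for extrapolated predictions
code_point_unbounded <- function(space, actual) {
  a <- as_point_matrix(actual, "actual")
  out <- a
  for (j in seq_len(3L)) {
    f <- space$factors[[j]]
    out[, j] <- (a[, j] - f$levels[2]) / ((f$levels[3] - f$levels[1]) / 2)
  }
  colnames(out) <- factor_names
  out
}

#' ANOVA table for a response-surface fit
#'
#' Variance decomposition in the style standard for Box-Behnken analyses:
#' the model row, pooled linear and square rows, per-factor rows with
#' adjusted (drop-one-term, type-III) sums of squares, residual error split
#' into lack-of-fit and pure error (from replicate groups), and the total.
#' The lack-of-fit F compares model-form misfit against pure replicate error;
#' a small F (large p) means the quadratic is adequate at the measurement
#' noise level.
#'
#' @param fit an `"rsm_fit"`.
#' @return An object of class `"rsm_anova"`: data frame with columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`; attributes `r2`, `r2_adj`,
#'   `r2_pred` (percent).
#' @examples
#' cs <- load_case_study()
#' rsm_anova(fit_quadratic(cs$dataset))
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  data <- fit$data
  y <- data$response
  n <- length(y)
  coded <- coded_matrix(data$design)
  X <- quad_design_matrix(coded, fit$include_interactions)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  dfe <- fit$df_residual
  dfm <- ncol(X) - 1L

  drop_ss <- function(cols) {
    Xr <- X[, setdiff(colnames(X), cols), drop = FALSE]
    sum(stats::lm.fit(Xr, y)$residuals^2) - sse
  }
  lin_terms <- c("bt", "wc", "cdt")
  sq_terms <- c("bt^2", "wc^2", "cdt^2")
  mse <- sse / dfe
  row <- function(source, df, ss, with_f = TRUE) {
    f <- if (with_f) (ss / df) / mse else NA_real_
    p <- if (with_f) stats::pf(f, df, dfe, lower.tail = FALSE) else NA_real_
    data.frame(source = source, df = df, ss = ss,
               ms = ss / df, f = f, p = p)
  }
  tab <- rbind(
    row("Model", dfm, ssm),
    row("Linear", 3L, drop_ss(lin_terms)),
    row("  Barrel Temperature", 1L, drop_ss("bt")),
    row("  Water Content", 1L, drop_ss("wc")),
    row("  Cooling Die Temperature", 1L, drop_ss("cdt")),
    row("Square", 3L, drop_ss(sq_terms)),
    row("  Barrel Temperature^2", 1L, drop_ss("bt^2")),
    row("  Water Content^2", 1L, drop_ss("wc^2")),
    row("  Cooling Die Temperature^2", 1L, drop_ss("cdt^2"))
  )
  if (fit$include_interactions) {
    int_terms <- c("bt:wc", "bt:cdt", "wc:cdt")
    tab <- rbind(tab,
                 row("Interaction", 3L, drop_ss(int_terms)),
                 row("  BT x WC", 1L, drop_ss("bt:wc")),
                 row("  BT x CDT", 1L, drop_ss("bt:cdt")),
                 row("  WC x CDT", 1L, drop_ss("wc:cdt")))
  }
  err <- data.frame(source = "Error", df = dfe, ss = sse, ms = mse,
                    f = NA_real_, p = NA_real_)
  reps <- Filter(function(g) length(g) > 1, data$replicate_groups)
  if (length(reps)) {
    ss_pe <- sum(vapply(reps, function(g) sum((y[g] - mean(y[g]))^2),
                        numeric(1)))
    df_pe <- sum(vapply(reps, length, integer(1))) - length(reps)
    ss_lof <- sse - ss_pe
    df_lof <- dfe - df_pe
    ms_pe <- ss_pe / df_pe
    f_lof <- (ss_lof / df_lof) / ms_pe
    p_lof <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    err <- rbind(err,
                 data.frame(source = "  Lack-of-Fit", df = df_lof, ss = ss_lof,
                            ms = ss_lof / df_lof, f = f_lof, p = p_lof),
                 data.frame(source = "  Pure Error", df = df_pe, ss = ss_pe,
                            ms = ms_pe, f = NA_real_, p = NA_real_))
  } else {
    warning("no replicate groups: lack-of-fit split unavailable", call. = FALSE)
  }
  tab <- rbind(tab, err,
               data.frame(source = "Total", df = n - 1L, ss = sst,
                          ms = NA_real_, f = NA_real_, p = NA_real_))
  rownames(tab) <- NULL
  r2 <- r2_metrics(fit)
  structure(tab, class = c("rsm_anova", "data.frame"),
            r2 = r2[["r2"]], r2_adj = r2[["r2_adj"]], r2_pred = r2[["r2_pred"]])
}

#' @export
print.rsm_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$ss <- round(df$ss, 2); df$ms <- round(df$ms, 2)
  df$f <- round(df$f, 2); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE, na.print = "")
  cat(sprintf("R2 = %.2f%%   R2(adj) = %.2f%%   R2(pred) = %.2f%%\n",
              attr(x, "r2"), attr(x, "r2_adj"), attr(x, "r2_pred")))
  invisible(x)
}

#' Coefficient-of-determination diagnostics
#'
#' Computes R-squared, adjusted R-squared, and predictive R-squared (from
#' PRESS, the leave-one-out prediction error sum of squares obtained through
#' the leverage shortcut \eqn{\mathrm{PRESS}=\sum_i (e_i/(1-h_{ii}))^2}),
#' all as percentages.
#'
#' @param fit an `"rsm_fit"`.
#' @return Named numeric vector `r2`, `r2_adj`, `r2_pred` (percent).
#' @export
r2_metrics <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  y <- fit$data$response
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y)
  h <- fit$leverage
  if (any(h >= 1 - 1e-10)) {
    warning("leverage of 1 at point(s) ",
            paste(which(h >= 1 - 1e-10), collapse = ", "),
            ": PRESS undefined", call. = FALSE)
    press <- NA_real_
  } else {
    press <- sum((fit$residuals / (1 - h))^2)
  }
  c(r2 = 100 * (1 - sse / sst),
    r2_adj = 100 * (1 - (sse / fit$df_residual) / (sst / (n - 1))),
    r2_pred = 100 * (1 - press / sst))
}

#' Locate the response-surface optimum over the operational box
#'
#' Minimizes the fitted polynomial over the factor bounds by dense grid
#' search followed by a bound-constrained local polish (L-BFGS-B from the
#' best grid point). The reported settings are then snapped to the
#' operational control grid; the default snap direction is `"down"`
#' (truncation toward the lower bound), the convention consistent with how
#' process setpoints are quoted for this line, with `"nearest"` and `"none"`
#' available.
#'
#' @param model an `"rsm_fit"` (or any object with a `predict(object, m,
#'   units = "actual")` method over the box).
#' @param space a [factor_space()] supplying bounds.
#' @param grid_steps numeric length-3 grid resolution in actual units
#'   (default 1 degree C, 0.5 %, 1 degree C).
#' @param polish logical; run the local refinement after the grid pass.
#' @param snap `"down"`, `"nearest"`, or `"none"` -- how the polished
#'   location is snapped to the operational grid for reporting.
#' @return List with `point` (named reported settings incl. section-b
#'   temperature), `value` (prediction at the reported point),
#'   `point_continuous`, `value_continuous`.
#' @examples
#' cs <- load_case_study()
#' find_optimum(fit_quadratic(cs$dataset), factor_space())
#' @export
find_optimum <- function(model, space = factor_space(),
                         grid_steps = c(1, 0.5, 1), polish = TRUE,
                         snap = c("down", "nearest", "none")) {
  snap <- match.arg(snap)
  lo <- vapply(space$factors, function(f) f$bounds[1], numeric(1))
  hi <- vapply(space$factors, function(f) f$bounds[2], numeric(1))
  grid <- expand.grid(bt = seq(lo[1], hi[1], by = grid_steps[1]),
                      wc = seq(lo[2], hi[2], by = grid_steps[2]),
                      cdt = seq(lo[3], hi[3], by = grid_steps[3]))
  pred <- predict(model, as.matrix(grid), units = "actual")
  best <- as.numeric(grid[which.min(pred), ])
  if (polish) {
    opt <- stats::optim(best,
                        function(x) predict(model, x, units = "actual"),
                        method = "L-BFGS-B", lower = lo, upper = hi)
    cont <- opt$par
    vcont <- opt$value
  } else {
    cont <- best
    vcont <- min(pred)
  }
  rep_pt <- switch(snap,
    none = cont,
    down = lo + floor((cont - lo) / grid_steps + 1e-9) * grid_steps,
    nearest = lo + round((cont - lo) / grid_steps) * grid_steps)
  rep_pt <- pmin(pmax(rep_pt, lo), hi)
  dec <- decode_point(space, code_point_unbounded(space, rep_pt))
  point <- c(bt_c = dec$bt_c, wc_pct = dec$wc_pct, cdt_a_c = dec$cdt_a_c,
             cdt_b_c = dec$cdt_b_c)
  list(point = point,
       value = predict(model, rep_pt, units = "actual"),
       point_continuous = stats::setNames(cont, factor_names),
       value_continuous = vcont)
}

#' Prediction grid over a two-factor slice
#'
#' Evaluates the fitted surface on a regular two-dimensional grid with the
#' third factor held fixed (by default at its center), for contour plotting
#' or export.
#'
#' @param model an `"rsm_fit"` (or GP model with compatible predict).
#' @param space a [factor_space()].
#' @param fixed_factor `"bt"`, `"wc"`, or `"cdt"`.
#' @param fixed_value actual value of the fixed factor; defaults to its
#'   center level.
#' @param n grid points per free axis.
#' @return List with `x`, `y` (axis values of the two free factors, in
#'   design order), `z` (`n` x `n` prediction matrix), `free` (axis names),
#'   suitable for [graphics::contour()].
#' @export
contour_grid <- function(model, space = factor_space(), fixed_factor,
                         fixed_value = NULL, n = 41) {
  if (!fixed_factor %in% factor_names)
    stop("unknown factor '", fixed_factor, "'; use one of ",
         paste(factor_names, collapse = ", "), call. = FALSE)
  k <- match(fixed_factor, factor_names)
  if (is.null(fixed_value)) fixed_value <- space$factors[[k]]$levels[2]
  free <- setdiff(seq_len(3L), k)
  ax <- lapply(free, function(j) {
    f <- space$factors[[j]]
    seq(f$bounds[1], f$bounds[2], length.out = n)
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]])
  m <- matrix(NA_real_, nrow(g), 3L)
  m[, free[1]] <- g$x; m[, free[2]] <- g$y; m[, k] <- fixed_value
  z <- matrix(predict(model, m, units = "actual"), n, n)
  list(x = ax[[1]], y = ax[[2]], z = z, free = factor_names[free],
       fixed = stats::setNames(fixed_value, fixed_factor))
}

#' Export an ANOVA table or fit
#'
#' `write_anova_csv()` writes the ANOVA rows (plus R-squared summary rows).
#' `rsm_fit_to_json()` serializes coefficients in both codings.
#'
#' @param anova an `"rsm_anova"`.
#' @param fit an `"rsm_fit"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anova_csv <- function(anova, path) {
  df <- as.data.frame(anova)
  df <- rbind(df, data.frame(source = c("R2 (%)", "R2 adj (%)", "R2 pred (%)"),
                             df = NA, ss = c(attr(anova, "r2"),
                                             attr(anova, "r2_adj"),
                                             attr(anova, "r2_pred")),
                             ms = NA, f = NA, p = NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_anova_csv
#' @export
rsm_fit_to_json <- function(fit, path) {
  jsonlite::write_json(list(coded = as.list(fit$coefficients),
                            actual = as.list(fit$coefficients_actual),
                            sigma2 = fit$sigma2,
                            df_residual = fit$df_residual),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
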