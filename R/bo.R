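#' Pool-constrained Bayesian optimization over a measured design
#'
#' Replays sequential Bayesian optimization against a pre-measured
#' Box-Behnken dataset. The run starts from the three center replicates
#' (3 experimental trials); unless overridden, the kernel noise `alpha` is
#' set to the sample variance of those replicates. Each iteration then
#' (1) proposes the remaining design point with maximal expected
#' improvement, (2) retrieves its pre-measured response, (3) refits the GP,
#' and (4) records the predicted optimum of the posterior mean over the full
#' operational box (dense-grid argmin) together with the best observed
#' response so far. The incumbent best used by the acquisition is the
#' minimum posterior mean over the points observed so far, which is robust
#' to observation noise at the `alpha` level.
#'
#' @param dataset a [response_dataset()] containing center replicates.
#' @param space a [factor_space()].
#' @param config a [gp_config()]; its `alpha` is used only if
#'   `alpha_auto = FALSE`.
#' @param max_iterations iterations to run (at most the pool size).
#' @param seed integer; drives hyperparameter-restart draws and tie-breaks.
#' @param alpha_auto set `alpha` to the center-replicate variance.
#' @param grid_steps actual-unit resolution of the predicted-optimum grid.
#' @param init `"replicates"` (default) initializes on the three center
#'   observations; `"mean"` initializes on their mean as a single point
#'   (still counted as 3 trials, since all replicates were consumed).
#' @return An object of class `"bo_trace"`: data frame with one row per
#'   iteration (`iteration`, `selected_run`, `observed`, `best_observed`,
#'   `pred_opt_bt`, `pred_opt_wc`, `pred_opt_cdt`, `pred_opt_value`), plus
#'   attributes `trials_used`, `alpha`, `seed`, and `iteration0` (the
#'   post-initialization state).
#' @examples
#' cs <- load_case_study()
#' tr <- run_constrained_bo(cs$dataset, max_iterations = 3, seed = 1)
#' tr
#' @export
run_constrained_bo <- function(dataset, space = factor_space(),
                               config = gp_config(), max_iterations = 12,
                               seed = 0, alpha_auto = TRUE,
                               grid_steps = c(1, 0.5, 1),
                               init = c("replicates", "mean")) {
  stopifnot(inherits(dataset, "response_dataset"))
  init <- match.arg(init)
  design <- dataset$design
  y <- dataset$response
  coded <- coded_matrix(design)
  center <- which(rowSums(abs(coded)) == 0)
  if (length(center) < 2L)
    stop("initialization requires replicated center points in the dataset",
         call. = FALSE)
  if (max_iterations > nrow(design) - length(center))
    stop("max_iterations exceeds the candidate pool size", call. = FALSE)
  if (alpha_auto) config$alpha <- stats::var(y[center])

  # grid over the operational box for the predicted-optimum report
  lo <- vapply(space$factors, function(f) f$bounds[1], numeric(1))
  hi <- vapply(space$factors, function(f) f$bounds[2], numeric(1))
  grid_act <- as.matrix(expand.grid(
    bt = seq(lo[1], hi[1], by = grid_steps[1]),
    wc = seq(lo[2], hi[2], by = grid_steps[2]),
    cdt = seq(lo[3], hi[3], by = grid_steps[3])))
  grid_cod <- code_point_unbounded(space, grid_act)

  if (init == "replicates") {
    obs_idx <- center
    Xo <- coded[center, , drop = FALSE]
    yo <- y[center]
  } else {
    obs_idx <- center
    Xo <- coded[center[1], , drop = FALSE]
    yo <- mean(y[center])
  }
  pool <- design[-center, , drop = FALSE]

  refit <- function(iter) {
    cfg <- config
    cfg$seed <- as.integer(seed * 1000L + iter) %% .Machine$integer.max
    fit_gp(Xo, yo, cfg)
  }
  gp <- refit(0L)
  record <- function(gp) {
    pm <- predict(gp, grid_cod)$mean
    i <- which.min(pm)
    c(grid_act[i, ], value = pm[i])
  }
  rec0 <- record(gp)
  rows <- vector("list", max_iterations)
  best_obs <- min(y[obs_idx])
  for (t in seq_len(max_iterations)) {
    incumbent <- min(predict(gp, Xo)$mean)
    # tie-break jitter is per-iteration but seed-independent, so replicate
    # runs differ only through hyperparameter-restart randomness
    prop <- propose_next(gp, pool, incumbent, seed = t)
    run_sel <- prop$selected$run
    i_sel <- match(run_sel, design$run)
    obs_idx <- c(obs_idx, i_sel)
    Xo <- rbind(Xo, coded[i_sel, , drop = FALSE])
    yo <- c(yo, y[i_sel])
    pool <- pool[pool$run != run_sel, , drop = FALSE]
    gp <- refit(t)
    best_obs <- min(best_obs, y[i_sel])
    rec <- record(gp)
    rows[[t]] <- data.frame(iteration = t, selected_run = run_sel,
                            observed = y[i_sel], best_observed = best_obs,
                            pred_opt_bt = rec[["bt"]], pred_opt_wc = rec[["wc"]],
                            pred_opt_cdt = rec[["cdt"]],
                            pred_opt_value = rec[["value"]])
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("bo_trace", "data.frame"),
            trials_used = length(center) + max_iterations,
            alpha = config$alpha, seed = seed,
            iteration0 = list(best_observed = min(y[center]),
                              pred_opt = rec0),
            final_model = gp)
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf("Pool-constrained BO trace (seed %s, alpha = %.3g, %d trials used)\n",
              attr(x, "seed"), attr(x, "alpha"), attr(x, "trials_used")))
  print(as.data.frame(lapply(as.data.frame(x), function(col)
    if (is.numeric(col)) round(col, 3) else col)), row.names = FALSE)
  invisible(x)
}

#' Multi-seed convergence analysis of pool-constrained BO
#'
#' Repeats [run_constrained_bo()] across seeds and aggregates the
#' best-observed and predicted-minimum curves: per-iteration mean and
#' percentile 95 % confidence band. Convergence is declared at the first
#' iteration after which the mean best-observed curve changes by less than
#' `tolerance` times its total range over all remaining iterations; the
#' trial budget at convergence adds the three initialization trials.
#'
#' @param dataset a [response_dataset()].
#' @param space a [factor_space()].
#' @param config a [gp_config()].
#' @param n_runs number of independent seeded runs (at least 2).
#' @param tolerance convergence tolerance as a fraction of the mean curve's
#'   total range (default 0.01).
#' @param max_iterations iterations per run.
#' @param seeds integer vector of seeds (default `0:(n_runs-1)`).
#' @param ... passed to [run_constrained_bo()].
#' @return An object of class `"bo_convergence"`: list with `curves` (data
#'   frame indexed by iteration, 0 = after initialization: mean/lo/hi of
#'   best-observed and predicted-minimum), `convergence_iteration`,
#'   `trials_at_convergence`, `n_runs`, `tolerance`, `traces`.
#' @export
convergence_analysis <- function(dataset, space = factor_space(),
                                 config = gp_config(), n_runs = 50,
                                 tolerance = 0.01, max_iterations = 12,
                                 seeds = NULL, ...) {
  stopifnot(n_runs >= 2)
  if (is.null(seeds)) seeds <- seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  traces <- lapply(seeds, function(s)
    run_constrained_bo(dataset, space, config, max_iterations, seed = s, ...))
  best <- vapply(traces, function(tr)
    c(attr(tr, "iteration0")$best_observed, tr$best_observed),
    numeric(max_iterations + 1L))
  pred <- vapply(traces, function(tr)
    c(attr(tr, "iteration0")$pred_opt[["value"]], tr$pred_opt_value),
    numeric(max_iterations + 1L))
  qlo <- function(m) apply(m, 1, stats::quantile, probs = 0.025, names = FALSE)
  qhi <- function(m) apply(m, 1, stats::quantile, probs = 0.975, names = FALSE)
  curves <- data.frame(
    iteration = 0:max_iterations,
    best_mean = rowMeans(best), best_lo = qlo(best), best_hi = qhi(best),
    pred_mean = rowMeans(pred), pred_lo = qlo(pred), pred_hi = qhi(pred))
  mb <- curves$best_mean
  rng <- diff(range(mb))
  tol_abs <- if (rng > 0) tolerance * rng else 0
  conv <- max_iterations
  for (j in seq_along(mb)) {
    if (max(abs(mb[j:length(mb)] - mb[j])) <= tol_abs) {
      conv <- j - 1L  # iteration index (0-based curve)
      break
    }
  }
  structure(list(curves = curves, convergence_iteration = conv,
                 trials_at_convergence = 3L + conv,
                 n_runs = n_runs, tolerance = tolerance, seeds = seeds,
                 traces = traces),
            class = "bo_convergence")
}

#' @export
print.bo_convergence <- function(x, ...) {
  cat(sprintf("BO convergence over %d seeded runs: converged at iteration %d (%d trials incl. 3 center replicates)\n",
              x$n_runs, x$convergence_iteration, x$trials_at_convergence))
  print(as.data.frame(lapply(x$curves, function(c) round(c, 3))),
        row.names = FALSE)
  invisible(x)
}

#' Plot BO convergence curves
#'
#' Draws the mean best-observed and mean predicted-minimum curves with their
#' percentile 95 % confidence bands against iteration.
#'
#' @param x a `"bo_convergence"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bo_convergence <- function(x, ...) {
  cv <- x$curves
  ylim <- range(cv$best_lo, cv$best_hi, cv$pred_lo, cv$pred_hi)
  graphics::plot(cv$iteration, cv$best_mean, type = "n", ylim = ylim,
                 xlab = "Iteration", ylab = "Scalarized response", ...)
  band <- function(lo, hi, col)
    graphics::polygon(c(cv$iteration, rev(cv$iteration)), c(lo, rev(hi)),
                      col = col, border = NA)
  band(cv$best_lo, cv$best_hi, grDevices::adjustcolor("red", 0.2))
  band(cv$pred_lo, cv$pred_hi, grDevices::adjustcolor("blue", 0.2))
  graphics::lines(cv$iteration, cv$best_mean, col = "red", lwd = 2)
  graphics::lines(cv$iteration, cv$pred_mean, col = "blue", lwd = 2)
  graphics::abline(v = x$convergence_iteration, lty = 3)
  graphics::legend("topright", c("best observed (mean)", "predicted minimum (mean)"),
                   col = c("red", "blue"), lwd = 2, bty = "n")
  invisible(x)
}

#' Serialize BO results
#'
#' `write_bo_trace_csv()` writes one row per iteration;
#' `convergence_to_json()` stores the aggregated curves and the
#' trials-to-convergence summary.
#'
#' @param trace a `"bo_trace"`.
#' @param conv a `"bo_convergence"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bo_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bo_trace_csv
#' @export
convergence_to_json <- function(conv, path) {
  jsonlite::write_json(list(
    n_runs = conv$n_runs, tolerance = conv$tolerance,
    convergence_iteration = conv$convergence_iteration,
    trials_at_convergence = conv$trials_at_convergence,
    curves = conv$curves), path, auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(path)
}
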