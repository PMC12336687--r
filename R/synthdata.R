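#' Specify a ground-truth response surface
#'
#' Defines the latent scalar landscape used by the simulator: a quadratic in
#' coded units, optionally with two-way interactions and a smooth
#' non-polynomial ripple (a product-of-sines term) to emulate model-form
#' misfit, plus homoscedastic Gaussian observation noise. The defaults mirror
#' the packaged case study: coefficients near the fitted tensile-inclusive
#' surface and a noise SD equal to the square root of its pure-error mean
#' square (sqrt(34.35)), so synthetic and measured pipelines are directly
#' comparable.
#'
#' @param intercept,linear,quadratic,interaction polynomial coefficients in
#'   coded units (`linear`, `quadratic` length 3; `interaction` length 3 for
#'   the bt:wc, bt:cdt, wc:cdt terms, default zero).
#' @param ripple amplitude of the non-polynomial term
#'   `ripple * sin(pi*bt) * sin(pi*wc) * sin(pi*cdt)` (default 0).
#' @param noise_sd observation noise SD (>= 0).
#' @return An object of class `"surface_spec"`.
#' @export
surface_spec <- function(intercept = 27.44,
                         linear = c(7.51, -18.47, -2.22),
                         quadratic = c(5.97, 6.07, -4.78),
                         interaction = c(0, 0, 0),
                         ripple = 0,
                         noise_sd = sqrt(34.35)) {
  stopifnot(length(linear) == 3L, length(quadratic) == 3L,
            length(interaction) == 3L, noise_sd >= 0)
  structure(list(intercept = intercept, linear = as.numeric(linear),
                 quadratic = as.numeric(quadratic),
                 interaction = as.numeric(interaction),
                 ripple = ripple, noise_sd = noise_sd),
            class = "surface_spec")
}

eval_surface <- function(spec, coded) {
  coded <- as_point_matrix(coded, "coded")
  v <- spec$intercept +
    coded %*% spec$linear + (coded^2) %*% spec$quadratic +
    (coded[, 1] * coded[, 2]) * spec$interaction[1] +
    (coded[, 1] * coded[, 3]) * spec$interaction[2] +
    (coded[, 2] * coded[, 3]) * spec$interaction[3]
  if (spec$ripple != 0)
    v <- v + spec$ripple * sin(pi * coded[, 1]) * sin(pi * coded[, 2]) *
      sin(pi * coded[, 3])
  as.numeric(v)
}

#' Simulate scalarized responses over a design
#'
#' Draws `response = surface(coded) + N(0, noise_sd^2)` independently per
#' design row (replicate rows get independent draws), reproducibly for a
#' given seed.
#'
#' @param spec a [surface_spec()].
#' @param design a design data frame ([generate_bbd()]).
#' @param seed integer seed.
#' @param replicates_at_center if larger than the number of center rows in
#'   `design`, extra center replicates are appended (run ids continue).
#' @return A [response_dataset()] with attribute `truth` (noise-free surface
#'   values).
#' @export
simulate_responses <- function(spec, design, seed = 0,
                               replicates_at_center = NULL) {
  stopifnot(inherits(spec, "surface_spec"))
  coded <- coded_matrix(design)
  if (!is.null(replicates_at_center)) {
    nc <- sum(rowSums(abs(coded)) == 0)
    extra <- replicates_at_center - nc
    if (extra > 0) {
      ctr <- design[rowSums(abs(coded)) == 0, , drop = FALSE][1, , drop = FALSE]
      add <- ctr[rep(1, extra), , drop = FALSE]
      add$run <- max(design$run) + seq_len(extra)
      design <- rbind(design, add)
      coded <- coded_matrix(design)
    }
  }
  truth <- eval_surface(spec, coded)
  # draw noise without disturbing the caller's RNG state
  noise <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    z <- stats::rnorm(length(truth), 0, spec$noise_sd)
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    z
  })
  ds <- response_dataset(design, truth + noise)
  attr(ds, "truth") <- truth
  ds
}

#' Specify latent texture-property surfaces
#'
#' Per-property ground truth for the texture simulator. Each of the seven
#' properties follows a positive-valued response surface
#' `scale * exp(latent(coded))`, where `latent` is a small quadratic in coded
#' units, with multiplicative log-normal replicate noise
#' (`exp(N(0, noise_cv^2))`). The exponential keeps every generated value
#' strictly positive (no truncation artifacts), as the scalarization's
#' denominators require. Default scales are order-of-magnitude placeholders
#' for a chicken-breast-like reference (the published study's raw
#' per-property data are not available): hardness 30 N, springiness 0.85,
#' chewiness 25 N, cutting forces 20/18 N, tensile strengths 5/7 N.
#'
#' @param reference named numeric reference profile (also the property
#'   scales).
#' @param latents named list of [surface_spec()]s, one per property, on the
#'   log scale (their `noise_sd` fields are ignored).
#' @param noise_cv coefficient of variation of the multiplicative replicate
#'   noise.
#' @return An object of class `"texture_surface_spec"`.
#' @export
texture_surface_spec <- function(
    reference = c(hardness = 30, springiness = 0.85, chewiness = 25,
                  cutting_force_T = 20, cutting_force_L = 18,
                  tensile_T = 5, tensile_L = 7),
    latents = NULL, noise_cv = 0.05) {
  props <- names(reference)
  if (is.null(latents)) {
    # distinct, gentle log-scale landscapes per property
    base <- list(
      linear = rbind(c(0.25, -0.35, 0.05), c(0.05, 0.10, -0.05),
                     c(0.30, -0.30, 0.05), c(0.20, -0.25, 0.10),
                     c(0.15, -0.20, 0.10), c(0.35, -0.15, 0.20),
                     c(0.30, -0.10, 0.25)),
      quadratic = rbind(c(0.10, 0.10, -0.05), c(-0.05, 0.05, 0.05),
                        c(0.10, 0.15, -0.05), c(0.05, 0.10, 0.00),
                        c(0.05, 0.10, 0.00), c(0.15, 0.05, -0.10),
                        c(0.10, 0.05, -0.10)))
    latents <- lapply(seq_along(props), function(i)
      surface_spec(intercept = 0.3, linear = base$linear[i, ],
                   quadratic = base$quadratic[i, ], noise_sd = 0))
    names(latents) <- props
  }
  stopifnot(all(props %in% names(latents)), all(reference > 0), noise_cv >= 0)
  structure(list(reference = reference, latents = latents,
                 noise_cv = noise_cv),
            class = "texture_surface_spec")
}

#' Simulate a per-run texture measurement table
#'
#' Generates `replicates` texture profiles per design run from the latent
#' property surfaces of a [texture_surface_spec()], with multiplicative
#' log-normal noise. Scalarizing the result against the spec's reference
#' (via [scalarize_runs()]) yields a smooth, noisy scalar landscape, so the
#' full measurement-to-optimization pipeline can be exercised without any
#' external data.
#'
#' @param spec a [texture_surface_spec()].
#' @param design a design data frame.
#' @param replicates replicate profiles per run.
#' @param seed integer seed.
#' @return List with `texture` (data frame: `run`, `replicate`, one column
#'   per property) and `reference` (named numeric profile).
#' @export
simulate_texture_dataset <- function(spec, design, replicates = 3, seed = 0) {
  stopifnot(inherits(spec, "texture_surface_spec"), replicates >= 1)
  coded <- coded_matrix(design)
  props <- names(spec$reference)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rows <- expand.grid(replicate = seq_len(replicates), run = design$run)
  rows <- rows[, c("run", "replicate")]
  idx <- match(rows$run, design$run)
  for (p in props) {
    latent <- eval_surface(spec$latents[[p]], coded)[idx]
    noise <- if (spec$noise_cv > 0)
      stats::rnorm(nrow(rows), 0, spec$noise_cv) else 0
    rows[[p]] <- spec$reference[[p]] * exp(latent + noise)
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  rows <- rows[order(rows$run, rows$replicate), ]
  rownames(rows) <- NULL
  list(texture = rows, reference = spec$reference)
}
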