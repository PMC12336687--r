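#' Gaussian-process surrogate configuration
#'
#' Settings for the anisotropic constant-times-RBF kernel
#' \deqn{k(\theta,\theta') = \sigma^2 \exp\!\big(-\tfrac12 \sum_d
#'   (\theta_d-\theta'_d)^2 / l_d^2\big)}
#' with observation-noise variance `alpha` added to the kernel diagonal.
#' Inputs are in coded units; responses are left on their raw scale so that
#' `alpha` can be set directly from the replicate variance of the center
#' point (the pure-error mean square). Hyperparameters `sigma2` and the
#' per-dimension length scales are optimized by maximum marginal likelihood
#' within the given bounds, restarting from seeded log-uniform draws;
#' `alpha` is fixed, never optimized.
#'
#' @param sigma2 initial signal variance.
#' @param length_scales initial per-dimension length scales (coded units).
#' @param alpha non-negative noise variance on the diagonal.
#' @param sigma2_bounds,length_scale_bounds optimization bounds.
#' @param restarts number of additional random restarts after the start at
#'   the initial values.
#' @param seed integer seed driving the restart draws.
#' @param prior_mean constant prior mean of the process (default 0).
#' @return An object of class `"gp_config"`.
#' @export
gp_config <- function(sigma2 = 1, length_scales = c(1, 1, 1), alpha = 0,
                      sigma2_bounds = c(1e-2, 1e4),
                      length_scale_bounds = c(0.1, 10),
                      restarts = 10, seed = 0, prior_mean = 0) {
  stopifnot(sigma2 > 0, all(length_scales > 0), alpha >= 0,
            sigma2_bounds[1] > 0, length_scale_bounds[1] > 0,
            restarts >= 0)
  structure(list(sigma2 = sigma2, length_scales = length_scales,
                 alpha = alpha, sigma2_bounds = sigma2_bounds,
                 length_scale_bounds = length_scale_bounds,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 prior_mean = prior_mean),
            class = "gp_config")
}

# squared-distance array between rows of A and B per dimension, combined
# into the RBF correlation matrix for length scales l
rbf_cor <- function(A, B, l) {
  n <- nrow(A); m <- nrow(B)
  s <- matrix(0, n, m)
  for (d in seq_len(ncol(A)))
    s <- s + outer(A[, d], B[, d], "-")^2 / l[d]^2
  exp(-0.5 * s)
}

gp_loglik <- function(theta, X, yc, alpha) {
  # theta = log(sigma2), log(l_1..l_d)
  sigma2 <- exp(theta[1]); l <- exp(theta[-1])
  K <- sigma2 * rbf_cor(X, X, l)
  diag(K) <- diag(K) + alpha + 1e-10
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = -Inf, gradient = rep(0, length(theta))))
  a <- backsolve(ch, forwardsolve(t(ch), yc))
  n <- length(yc)
  ll <- -0.5 * sum(yc * a) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  W <- tcrossprod(a) - Kinv           # (alpha alpha' - K^-1)
  grad <- numeric(length(theta))
  Ks <- sigma2 * rbf_cor(X, X, l)
  grad[1] <- 0.5 * sum(W * Ks)        # d/dlog(sigma2)
  for (d in seq_len(ncol(X))) {
    D2 <- outer(X[, d], X[, d], "-")^2
    grad[1 + d] <- 0.5 * sum(W * (Ks * D2 / l[d]^2))  # d/dlog(l_d)
  }
  list(value = ll, gradient = grad)
}

#' Fit the Gaussian-process surrogate
#'
#' Maximizes the log marginal likelihood over `log(sigma2)` and the log
#' length scales with L-BFGS-B, from the configured initial values plus
#' `restarts` seeded log-uniform draws within the bounds, keeping the best
#' optimum. The noise level `alpha` stays fixed.
#'
#' @param X matrix of coded training inputs (rows = observations).
#' @param y numeric response vector (raw scale).
#' @param config a [gp_config()].
#' @return An object of class `"gp_model"`: list with `config` (updated to
#'   the optimized hyperparameters), `X`, `y`, `log_marginal_likelihood`, and
#'   the cached Cholesky factor of the regularized kernel matrix.
#' @examples
#' cs <- load_case_study()
#' gp <- fit_gp(coded_matrix(cs$dataset$design), cs$dataset$response,
#'              gp_config(alpha = 34.35, seed = 1))
#' predict(gp, c(0, 0, 0))
#' @export
fit_gp <- function(X, y, config = gp_config()) {
  stopifnot(inherits(config, "gp_config"))
  X <- as_point_matrix(X, "X")
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 training points", call. = FALSE)
  stopifnot(length(y) == nrow(X))
  yc <- y - config$prior_mean
  d <- ncol(X)
  lower <- c(log(config$sigma2_bounds[1]), rep(log(config$length_scale_bounds[1]), d))
  upper <- c(log(config$sigma2_bounds[2]), rep(log(config$length_scale_bounds[2]), d))
  starts <- list(c(log(config$sigma2), log(config$length_scales)))
  if (config$restarts > 0) {
    rng <- local_rng(config$seed)
    for (i in seq_len(config$restarts))
      starts[[i + 1L]] <- lower + rng(d + 1L) * (upper - lower)
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper),
                   fn = function(t) -gp_loglik(t, X, yc, config$alpha)$value,
                   gr = function(t) -gp_loglik(t, X, yc, config$alpha)$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best))
    stop("kernel matrix not positive definite for any restart; ",
         "increase alpha", call. = FALSE)
  theta <- best$par
  config$sigma2 <- exp(theta[1])
  config$length_scales <- exp(theta[-1])
  K <- config$sigma2 * rbf_cor(X, X, config$length_scales)
  diag(K) <- diag(K) + config$alpha + 1e-10
  ch <- tryCatch(chol(K), error = function(e)
    stop("kernel matrix not positive definite after regularization; ",
         "increase alpha", call. = FALSE))
  structure(list(config = config, X = X, y = y, yc = yc,
                 chol = ch, alpha_vec = backsolve(ch, forwardsolve(t(ch), yc)),
                 log_marginal_likelihood = -best$value),
            class = "gp_model")
}

# deterministic uniform stream independent of the global RNG state
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("GP surrogate: n = %d, sigma2 = %.3g, length scales = (%s), alpha = %.3g\n",
              nrow(x$X), x$config$sigma2,
              paste(signif(x$config$length_scales, 3), collapse = ", "),
              x$config$alpha))
  cat(sprintf("  log marginal likelihood = %.4f\n", x$log_marginal_likelihood))
  invisible(x)
}

#' Posterior prediction from a Gaussian-process surrogate
#'
#' Standard GP posterior under the constant-times-RBF kernel with fixed
#' diagonal noise: mean \eqn{\mu(\theta) = m + k_*^\top (K+\alpha I)^{-1}
#' (y - m)} and standard deviation \eqn{\sigma(\theta) = \sqrt{k(\theta,
#' \theta) - k_*^\top (K+\alpha I)^{-1} k_*}} (noise-free latent SD, not
#' including `alpha`).
#'
#' @param object a `"gp_model"`.
#' @param newdata coded point(s): length-3 vector or 3-column matrix.
#' @param ... unused.
#' @return Data frame with columns `mean` and `sd`.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  Xs <- as_point_matrix(newdata, "newdata")
  ks <- object$config$sigma2 * rbf_cor(Xs, object$X, object$config$length_scales)
  mu <- object$config$prior_mean + as.numeric(ks %*% object$alpha_vec)
  V <- forwardsolve(t(object$chol), t(ks))
  var <- pmax(object$config$sigma2 - colSums(V^2), 0)
  data.frame(mean = mu, sd = sqrt(var))
}

#' @rdname predict.gp_model
#' @param model a `"gp_model"`.
#' @param point coded point(s).
#' @export
gp_predict <- function(model, point) predict(model, point)

#' Expected improvement for minimization
#'
#' Scores a candidate by the expected amount its outcome falls below the
#' incumbent best:
#' \deqn{\mathrm{EI}(\theta) = \mathrm{E}[\max(S_{best} - S(\theta), 0)]
#'   = (S_{best}-\mu)\,\Phi(z) + \sigma\,\phi(z), \quad
#'   z = (S_{best}-\mu)/\sigma,}
#' with the degenerate limit \eqn{\max(S_{best}-\mu, 0)} at \eqn{\sigma = 0}.
#' Always non-negative; the balance of the two terms trades off exploitation
#' (low predicted mean) against exploration (high predictive uncertainty).
#'
#' @param model a `"gp_model"`.
#' @param point coded candidate point(s).
#' @param best incumbent best (finite scalar), on the response scale.
#' @return Numeric vector of expected-improvement values.
#' @export
expected_improvement <- function(model, point, best) {
  stopifnot(is.finite(best))
  p <- predict(model, point)
  ei_value(p$mean, p$sd, best)
}

# closed form of E[max(best - N(mu, sd^2), 0)]
ei_value <- function(mu, sd, best) {
  imp <- best - mu
  ei <- ifelse(sd > 0,
               imp * stats::pnorm(imp / sd) + sd * stats::dnorm(imp / sd),
               pmax(imp, 0))
  pmax(ei, 0)
}

#' Propose the next pool candidate
#'
#' Scores every remaining pool point with [expected_improvement()] and
#' selects the maximizer. A seeded perturbation below 1e-12 breaks exact
#' floating-point ties reproducibly; remaining ties go to the lowest run id.
#'
#' @param model a `"gp_model"`.
#' @param pool design data frame of remaining candidates (with `run` and
#'   `coded_*` columns).
#' @param best incumbent best value.
#' @param seed integer seed for tie-breaking jitter.
#' @return List with `selected` (one-row design data frame), `scores`
#'   (data frame of run id and EI), `best`.
#' @export
propose_next <- function(model, pool, best, seed = 0) {
  if (nrow(pool) == 0L)
    stop("candidate pool exhausted", call. = FALSE)
  ei <- expected_improvement(model, coded_matrix(pool), best)
  jitter <- local_rng(seed)(length(ei)) * 1e-13
  score <- ei + jitter
  top <- which(score == max(score))
  sel <- top[which.min(pool$run[top])]
  list(selected = pool[sel, , drop = FALSE],
       scores = data.frame(run = pool$run, ei = ei),
       best = best)
}
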