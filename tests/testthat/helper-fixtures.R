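# Shared fixtures and independent oracles used across test files.

study_space <- function() factor_space()

study_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_case_study()
    cache
  }
})

# direct dense-linear-algebra GP posterior, independent of the package's
# Cholesky path
gp_oracle <- function(X, y, Xs, sigma2, l, alpha, prior_mean = 0) {
  sq <- function(A, B) {
    s <- matrix(0, nrow(A), nrow(B))
    for (d in seq_len(ncol(A))) s <- s + outer(A[, d], B[, d], "-")^2 / l[d]^2
    s
  }
  K <- sigma2 * exp(-0.5 * sq(X, X)) + diag(alpha + 1e-10, nrow(X))
  Ks <- sigma2 * exp(-0.5 * sq(Xs, X))
  Kinv <- solve(K)
  mu <- prior_mean + Ks %*% Kinv %*% (y - prior_mean)
  var <- sigma2 - rowSums((Ks %*% Kinv) * Ks)
  list(mean = as.numeric(mu), sd = sqrt(pmax(var, 0)))
}

# term-by-term quadratic polynomial evaluation in coded units
quad_oracle <- function(beta, coded) {
  apply(coded, 1, function(x)
    beta[1] + sum(beta[2:4] * x) + sum(beta[5:7] * x^2))
}

# leave-one-out refit PRESS, the slow route the leverage shortcut must match
press_loo_oracle <- function(dataset) {
  coded <- coded_matrix(dataset$design)
  y <- dataset$response
  X <- cbind(1, coded, coded^2)
  sum(vapply(seq_along(y), function(i) {
    b <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    (y[i] - sum(X[i, ] * b))^2
  }, numeric(1)))
}
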