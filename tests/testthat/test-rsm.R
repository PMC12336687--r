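test_that("the quadratic fit reproduces the case study's predicted responses", {
  cs <- study_case()
  fit <- fit_quadratic(cs$dataset)
  pred <- predict(fit, cs$design)
  expect_true(all(abs(pred - cs$responses$predicted_rsm) <= 0.01))
  # center prediction equals the replicate mean for this orthogonal layout
  expect_equal(predict(fit, c(125, 60, 70)), mean(cs$dataset$response[13:15]),
               tolerance = 1e-10)
})

test_that("noise-free quadratic responses are recovered exactly", {
  truth <- c(12, 3, -5, 1.5, 2, -1, 0.5)  # b0, linear, quadratic
  des <- generate_bbd(study_space())
  y <- quad_oracle(truth, coded_matrix(des))
  fit <- fit_quadratic(response_dataset(des, y))
  expect_lt(max(abs(coef(fit) - truth)), 1e-8)
  expect_equal(unname(r2_metrics(fit)[["r2"]]), 100)
})

test_that("prediction agrees with term-by-term evaluation and both codings", {
  cs <- study_case()
  fit <- fit_quadratic(cs$dataset)
  set.seed(11)
  coded <- matrix(stats::runif(150, -1.2, 1.2), ncol = 3)  # incl. mild extrapolation
  expect_lt(max(abs(predict(fit, coded, units = "coded") -
                    quad_oracle(coef(fit), coded))), 1e-8)

  # actual-unit coefficients define the same polynomial
  act <- decode_point(study_space(), coded)
  b <- coef(fit, "actual")
  direct <- b[1] + b[2] * act$bt_c + b[3] * act$wc_pct + b[4] * act$cdt_a_c +
    b[5] * act$bt_c^2 + b[6] * act$wc_pct^2 + b[7] * act$cdt_a_c^2
  expect_lt(max(abs(predict(fit, coded, units = "coded") - direct)), 1e-8)

  # extrapolated point used in the validation experiments
  expect_equal(predict(fit, c(115, 65, 80)), 5.67, tolerance = 0.01)

  # the zero polynomial predicts zero everywhere
  zfit <- fit_quadratic(response_dataset(generate_bbd(study_space()),
                                         rep(0, 15)))
  expect_equal(max(abs(predict(zfit, coded, units = "coded"))), 0)
})

test_that("ANOVA reproduces the variance decomposition and is additive", {
  cs <- study_case()
  fit <- fit_quadratic(cs$dataset)
  an <- rsm_anova(fit)
  g <- function(src, col) an[[col]][an$source == src]

  expect_equal(g("Total", "ss"), 3808.26, tolerance = 0.01)
  expect_equal(g("Total", "df"), 14L)
  expect_equal(g("  Pure Error", "ms"), var(cs$dataset$response[13:15]),
               tolerance = 1e-10)
  expect_equal(g("  Pure Error", "ms"), 34.35, tolerance = 0.01)
  expect_equal(g("  Water Content", "f"), 99.06, tolerance = 0.05)
  expect_equal(g("Model", "df"), 6L)
  expect_equal(g("Error", "df"), 8L)

  # additivity: model + error = total; LOF + pure error = error
  expect_lt(abs(g("Model", "ss") + g("Error", "ss") - g("Total", "ss")), 1e-8)
  expect_lt(abs(g("  Lack-of-Fit", "ss") + g("  Pure Error", "ss") -
                g("Error", "ss")), 1e-8)
  # pooled rows match their per-factor components
  expect_lt(abs(g("Linear", "ss") -
                sum(an$ss[an$source %in% c("  Barrel Temperature",
                                           "  Water Content",
                                           "  Cooling Die Temperature")])),
            1e-8)
})

test_that("ANOVA without replicates degrades gracefully", {
  des <- generate_bbd(study_space())[1:13, ]
  y <- quad_oracle(c(10, 1, -2, 0.5, 1, 1, -1), coded_matrix(des)) +
    stats::rnorm(13, 0, 0.1)
  fit <- fit_quadratic(response_dataset(des, y))
  # the lone center point carries leverage 1, so PRESS is flagged too
  expect_warning(expect_warning(an <- rsm_anova(fit), "lack-of-fit"),
                 "PRESS undefined")
  expect_false(any(grepl("Lack-of-Fit", an$source)))
})

test_that("R-squared diagnostics match the study and the LOO oracle", {
  cs <- study_case()
  fit <- fit_quadratic(cs$dataset)
  r2 <- r2_metrics(fit)
  expect_equal(unname(r2[["r2"]]), 94.20, tolerance = 0.05)
  expect_equal(unname(r2[["r2_adj"]]), 89.90, tolerance = 0.05)
  expect_equal(unname(r2[["r2_pred"]]), 80.00, tolerance = 0.05)

  # PRESS leverage shortcut equals explicit leave-one-out refitting
  sst <- sum((cs$dataset$response - mean(cs$dataset$response))^2)
  r2_pred_loo <- 100 * (1 - press_loo_oracle(cs$dataset) / sst)
  expect_lt(abs(unname(r2[["r2_pred"]]) - r2_pred_loo), 1e-8)
})

test_that("coefficient estimates are unbiased over noisy replications", {
  truth <- c(27.44, 7.51, -18.47, -2.22, 5.97, 6.07, -4.78)
  spec <- surface_spec(truth[1], truth[2:4], truth[5:7],
                       noise_sd = sqrt(34.35))
  des <- generate_bbd(study_space())
  nsim <- 500
  est <- matrix(NA_real_, nsim, 7)
  for (i in seq_len(nsim)) {
    ds <- simulate_responses(spec, des, seed = 20000 + i)
    est[i, ] <- coef(fit_quadratic(ds))
  }
  err <- colMeans(est) - truth
  se <- apply(est, 2, stats::sd) / sqrt(nsim)
  expect_true(all(abs(err) <= 3 * se))
})

test_that("the optimum search finds the box minimum", {
  cs <- study_case()
  fit <- fit_quadratic(cs$dataset)
  opt <- find_optimum(fit, study_space())
  expect_equal(unname(opt$point[c("bt_c", "wc_pct", "cdt_a_c")]),
               c(115, 65, 80))
  expect_equal(unname(opt$point[["cdt_b_c"]]), 65)
  expect_equal(opt$value, 5.67, tolerance = 0.02)

  # agreement with an exhaustive fine-grid oracle within one coarse step
  g <- as.matrix(expand.grid(bt = seq(110, 140, by = 0.1),
                             wc = seq(55, 65, by = 0.1),
                             cdt = seq(60, 80, by = 0.1)))
  fine <- g[which.min(predict(fit, g, units = "actual")), ]
  expect_true(all(abs(opt$point_continuous - fine) <= c(1, 0.5, 1)))

  # interior convex paraboloid: vertex recovered without snapping
  des <- generate_bbd(study_space())
  vert <- c(-0.25, 0.4, -0.5)
  y <- apply(coded_matrix(des), 1, function(x) 5 + sum((x - vert)^2))
  pfit <- fit_quadratic(response_dataset(des, y))
  popt <- find_optimum(pfit, study_space(), snap = "none")
  expect_equal(unname(popt$point_continuous),
               unname(decode_point(study_space(), vert)[1, c("bt_c", "wc_pct",
                                                             "cdt_a_c")]
                      |> unlist()),
               tolerance = 1e-4)
})

test_that("contour slices are consistent with prediction and the optimum", {
  cs <- study_case()
  fit <- fit_quadratic(cs$dataset)

  zfit <- fit_quadratic(response_dataset(generate_bbd(study_space()),
                                         rep(0, 15)))
  expect_equal(max(abs(contour_grid(zfit, study_space(), "wc")$z)), 0)

  cg <- contour_grid(fit, study_space(), "cdt", n = 41)
  # center cell equals the overall center prediction (odd n -> exact center)
  expect_equal(cg$z[21, 21], predict(fit, c(125, 60, 70)), tolerance = 1e-10)

  # slice argmin equals the optimum restricted to the slice
  i <- which(cg$z == min(cg$z), arr.ind = TRUE)
  slice_min <- c(cg$x[i[1]], cg$y[i[2]])
  g <- as.matrix(expand.grid(bt = seq(110, 140, by = 0.25),
                             wc = seq(55, 65, by = 0.25), cdt = 70))
  oracle <- g[which.min(predict(fit, g, units = "actual")), 1:2]
  expect_true(all(abs(slice_min - oracle) <= c(0.75, 0.25)))

  expect_error(contour_grid(fit, study_space(), "screw_speed"),
               "unknown factor")
})

test_that("rank-deficient designs are rejected", {
  des <- generate_bbd(study_space())[c(1:4, 13:15), ]  # cdt column all zero
  expect_error(fit_quadratic(response_dataset(des, rnorm(7))),
               "singular design")
})
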