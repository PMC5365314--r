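# Hill-equation evaluation and nonlinear least-squares fitting.

GRID <- c(7.0, 6.0, 5.8, 5.6, 5.5, 5.4, 5.2, 5.0, 4.5)

make_curve <- function(pca50, n_h, baseline, amplitude, noise_sd = 0,
                       pca = GRID, kind = "force") {
  y <- hill_eval(list(pca50 = pca50, n_h = n_h, baseline = baseline,
                      amplitude = amplitude), pca)
  if (noise_sd > 0) y <- y + stats::rnorm(length(pca), 0, noise_sd)
  titration_curve(pca, y, kind)
}

test_that("hill_eval matches the formula transcription", {
  p <- list(pca50 = 5.37, n_h = 4.03, baseline = 0, amplitude = 1)
  expect_equal(hill_eval(p, 5.37), 0.5)
  # direct transcription: Y = 1 / (1 + 10^(nH (pCa - pCa50)))
  expect_equal(hill_eval(p, 6.0), 1 / (1 + 10^(4.03 * (6.0 - 5.37))))
  expect_lt(hill_eval(p, 6.0), 3.1e-3)  # ~2.9e-3, essentially relaxed
  p0 <- list(pca50 = 5.5, n_h = 3, baseline = 0.2, amplitude = 0)
  expect_equal(hill_eval(p0, c(9, 6, 4.5)), rep(0.2, 3))
})

test_that("noise-free Hill data are recovered essentially exactly", {
  cv <- make_curve(5.50, 4.29, 0, 32.4)
  fit <- fit_hill(cv, fix_baseline = 0)
  expect_equal(fit$pca50, 5.50, tolerance = 1e-6)
  expect_equal(fit$n_h, 4.29, tolerance = 1e-6)
  expect_equal(fit$amplitude, 32.4, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)
  # four-parameter variant with non-zero baseline (a <P2>-style curve)
  cv2 <- make_curve(5.34, 3.59, 0.283, -0.101, kind = "p2")
  fit2 <- fit_hill(cv2)
  expect_equal(fit2$pca50, 5.34, tolerance = 1e-6)
  expect_equal(fit2$n_h, 3.59, tolerance = 1e-6)
  expect_equal(fit2$baseline, 0.283, tolerance = 1e-6)
  expect_equal(fit2$amplitude, -0.101, tolerance = 1e-6)
})

test_that("fits are equivariant under sign flip and translation", {
  set.seed(11)
  y <- hill_eval(list(pca50 = 5.4, n_h = 3.5, baseline = 0.1,
                      amplitude = -0.08), GRID) + rnorm(length(GRID), 0, 0.002)
  f1 <- fit_hill(titration_curve(GRID, y, "p2"))
  f2 <- fit_hill(titration_curve(GRID, -y, "p2"))
  expect_equal(f2$pca50, f1$pca50, tolerance = 1e-8)
  expect_equal(f2$n_h, f1$n_h, tolerance = 1e-8)
  expect_equal(f2$amplitude, -f1$amplitude, tolerance = 1e-8)
  f3 <- fit_hill(titration_curve(GRID, y + 0.5, "p2"))
  expect_equal(f3$baseline, f1$baseline + 0.5, tolerance = 1e-8)
  expect_equal(f3$pca50, f1$pca50, tolerance = 1e-8)
  expect_equal(f3$n_h, f1$n_h, tolerance = 1e-8)
})

test_that("normalization reports force as fraction of fitted maximum", {
  cv <- make_curve(5.37, 4.03, 0, 22.7)
  fit <- fit_hill(cv, normalize = TRUE, fix_baseline = 0)
  expect_equal(fit$amplitude, 1, tolerance = 1e-8)
  expect_equal(fit$pca50, 5.37, tolerance = 1e-6)
})

test_that("flat curves flag as degenerate instead of raising", {
  set.seed(12)
  y <- 0.2 + rnorm(length(GRID), 0, 0.01)
  fit <- fit_hill(titration_curve(GRID, y, "p2"))
  expect_true(fit$degenerate)
  expect_error(titration_curve(c(6, 5.5, 5, 4.5), c(1, 2, 3, 4), "p2"),
               "5 distinct")
})

test_that("parameter recovery is unbiased at 3% noise over 200 replicates", {
  set.seed(13)
  fits <- replicate(200, {
    cv <- make_curve(5.37, 4.03, 0, 1, noise_sd = 0.03)
    f <- fit_hill(cv, fix_baseline = 0)
    c(f$pca50, f$n_h)
  })
  expect_lt(abs(mean(fits[1, ]) - 5.37), 0.01)
  expect_lt(abs(mean(fits[2, ]) / 4.03 - 1), 0.05)
})

test_that("pCa50 is invariant to affine response transforms", {
  set.seed(14)
  y <- hill_eval(list(pca50 = 5.45, n_h = 3.2, baseline = 0.05,
                      amplitude = 0.1), GRID) + rnorm(length(GRID), 0, 0.003)
  f1 <- fit_hill(titration_curve(GRID, y, "p2"))
  f2 <- fit_hill(titration_curve(GRID, 3.7 * y - 1.2, "p2"))
  expect_equal(f2$pca50, f1$pca50, tolerance = 1e-6)
})

test_that("sarcomere-shortening drift lowers fitted pCa50 and nH", {
  clean <- make_curve(5.5, 4.0, 0, 1)
  f0 <- fit_hill(clean, fix_baseline = 0)
  # rightward drift of the high-force points: shift responses at low pCa as
  # if the curve were evaluated at slightly higher pCa (less activation)
  drift <- 0.15 * pmax(0, hill_eval(list(pca50 = 5.5, n_h = 4, baseline = 0,
                                         amplitude = 1), GRID))
  shifted <- hill_eval(list(pca50 = 5.5, n_h = 4, baseline = 0,
                            amplitude = 1), GRID + drift)
  f1 <- fit_hill(titration_curve(GRID, shifted, "force"), fix_baseline = 0)
  expect_lt(f1$pca50, f0$pca50)
  expect_lt(f1$n_h, f0$n_h)
})

test_that("delta_p2 takes the signed pCa 6 -> 4.5 difference", {
  cv <- titration_curve(c(9, 6, 5.5, 5, 4.5),
                        c(0.283, 0.283, 0.24, 0.2, 0.182), "p2")
  expect_equal(delta_p2(cv), -0.101)
  same <- titration_curve(c(9, 6, 5.5, 5, 4.5), rep(0.1, 5), "p2")
  expect_equal(delta_p2(same), 0)
  cv2 <- titration_curve(c(9, 6, 5.5, 5, 4.5),
                         c(0.091, 0.091, 0.05, 0.02, 0.009), "p2")
  expect_equal(delta_p2(cv2), -0.082)
  nomatch <- titration_curve(c(9, 6.6, 5.5, 5, 4.8), rep(0.1, 5), "p2")
  expect_error(delta_p2(nomatch), "pCa 4.50")
})
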