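# Forward/inverse optical model and angle-distribution moments.

test_that("delta-distribution moments and order parameters use closed forms", {
  expect_equal(unclass(moments_from_distribution(angle_dist_delta(0)))[c("m2", "m4")],
               list(m2 = 1, m4 = 1))
  expect_equal(unclass(moments_from_distribution(angle_dist_delta(90)))[c("m2", "m4")],
               list(m2 = 0, m4 = 0), tolerance = 1e-15)
  # magic angle: cos^2 = 1/3
  th <- acos(sqrt(1 / 3)) * 180 / pi
  ops <- order_params_from_moments(moments_from_distribution(angle_dist_delta(th)))
  expect_equal(ops$p2, 0, tolerance = 1e-12)
  expect_equal(ops$p4, -7 / 18, tolerance = 1e-12)
})

test_that("gaussian-on-sphere moments match the dense-grid trapezoid oracle", {
  cases <- list(c(60, 20), c(0, 10), c(90, 35), c(30, 5), c(45, 70))
  for (cs in cases) {
    m <- moments_from_distribution(angle_dist_gaussian(cs[1], cs[2]))
    o <- oracle_gauss_moments(cs[1], cs[2])
    expect_equal(m$m2, o$m2, tolerance = 1e-8)
    expect_equal(m$m4, o$m4, tolerance = 1e-8)
  }
})

test_that("order parameters map linearly from moments with the stated anchors", {
  expect_equal(unclass(order_params_from_moments(moments(1 / 3, 1 / 5)))[c("p2", "p4")],
               list(p2 = 0, p4 = 0), tolerance = 1e-14)
  perp <- order_params_from_moments(moments(0, 0))
  expect_equal(perp$p2, -0.5)
  expect_equal(perp$p4, 0.375)
  expect_error(moments(0.5, 0.6), "m4.*m2")
  expect_error(moments(0.5, 0.1), "Jensen")
})

test_that("forward model reproduces the closed-form signatures", {
  iso <- forward_intensities(order_params(0, 0), scale = 1)
  tot <- iso$i_pp + iso$i_pt + iso$i_tp + iso$i_tt
  expect_equal(c(iso$i_pp, iso$i_pt, iso$i_tp, iso$i_tt) / tot,
               c(0.375, 0.125, 0.125, 0.375), tolerance = 1e-12)
  par <- forward_intensities(order_params(1, 1), scale = 3)
  expect_equal(c(par$i_pp, par$i_pt, par$i_tp, par$i_tt), c(3, 0, 0, 0),
               tolerance = 1e-12)
  prp <- forward_intensities(order_params(-0.5, 0.375), scale = 8)
  expect_equal(c(prp$i_pp, prp$i_pt, prp$i_tp, prp$i_tt), c(0, 0, 0, 3),
               tolerance = 1e-12)
  expect_error(forward_intensities(order_params(0, 0), scale = 0), "scale")
})

test_that("forward -> invert round trip is exact over random feasible sets", {
  set.seed(42)
  for (i in 1:1000) {
    ops <- random_feasible_ops()
    scale <- stats::runif(1, 0.1, 10)
    inv <- invert_intensities(forward_intensities(ops, scale))
    expect_equal(inv$order_params$p2, ops$p2, tolerance = 1e-10)
    expect_equal(inv$order_params$p4, ops$p4, tolerance = 1e-10)
    expect_equal(inv$scale, scale, tolerance = 1e-10)
    expect_false(inv$order_params$feasibility_flag)
  }
})

test_that("distribution moments always satisfy the feasibility bounds", {
  set.seed(43)
  for (i in 1:200) {
    m <- moments_from_distribution(random_angle_dist())
    expect_true(m$m2 >= 0 && m$m2 <= 1)
    expect_true(m$m4 <= m$m2 + 1e-12)
    expect_true(m$m4 >= m$m2^2 - 1e-9)
  }
})

test_that("closed-form intensities equal direct quadrature of the angular factors", {
  set.seed(44)
  cases <- replicate(25, random_angle_dist(), simplify = FALSE)
  for (d in cases) {
    m <- moments_from_distribution(d)
    f <- forward_intensities(order_params_from_moments(m), scale = 1)
    wfun <- switch(d$kind,
      delta = NULL,
      gaussian_on_sphere = function(th) {
        t0 <- d$theta0 * pi / 180; s <- d$sigma * pi / 180
        g <- 0
        for (k in -8:8) {
          g <- g + exp(-((th - t0 - 2 * pi * k)^2) / (2 * s^2)) +
            exp(-((th + t0 - 2 * pi * k)^2) / (2 * s^2))
        }
        g * sin(th)
      },
      mixture = NULL)
    if (is.null(wfun)) next  # quadrature oracle targets the continuous family
    o <- oracle_intensities(wfun)
    expect_equal(f$i_pp, o$i_pp, tolerance = 1e-8)
    expect_equal(f$i_pt, o$i_pt, tolerance = 1e-8)
    expect_equal(f$i_tt, o$i_tt, tolerance = 1e-8)
  }
})

test_that("a very broad gaussian on the sphere is isotropic", {
  ops <- order_params_from_moments(
    moments_from_distribution(angle_dist_gaussian(45, 1e4)))
  expect_lt(abs(ops$p2), 1e-3)
  expect_lt(abs(ops$p4), 1e-3)
})

test_that("observed p2 of summed two-population intensities is the weighted mean", {
  set.seed(45)
  for (i in 1:50) {
    a <- random_feasible_ops(); b <- random_feasible_ops()
    w <- stats::runif(1)
    fa <- forward_intensities(a, scale = w)
    fb <- forward_intensities(b, scale = 1 - w)
    summed <- polarized_intensities(fa$i_pp + fb$i_pp, fa$i_pt + fb$i_pt,
                                    fa$i_tp + fb$i_tp, fa$i_tt + fb$i_tt)
    inv <- invert_intensities(summed)
    expect_equal(inv$order_params$p2,
                 mixture_p2(c(w, 1 - w), c(a$p2, b$p2)), tolerance = 1e-10)
  }
})

test_that("mixture_p2 validates and averages", {
  expect_equal(mixture_p2(c(0.5, 0.5), c(1, -0.5)), 0.25)
  expect_equal(mixture_p2(1, 0.3), 0.3)
  expect_equal(mixture_p2(c(0.2, 0.3, 0.5), c(0, 0.4, -0.2)), 0.02)
  expect_error(mixture_p2(c(0.6, 0.6), c(0, 0)), "sum to 1")
})

test_that("attenuation multiplies order parameters and preserves feasibility", {
  ops <- order_params(1, 1)
  att <- apply_attenuation(ops, 0.8, 0.6)
  expect_equal(c(att$p2, att$p4), c(0.8, 0.6))
  ident <- apply_attenuation(order_params(-0.4, 0.2), 1, 1)
  expect_equal(c(ident$p2, ident$p4), c(-0.4, 0.2))
  zero <- apply_attenuation(order_params(-0.4, 0.2), 0, 0)
  expect_equal(c(zero$p2, zero$p4), c(0, 0))
  expect_error(apply_attenuation(ops, 1.2, 1), "\\[0, 1\\]")
  # (p2, p4) = (0, 1) scaled in p2 only leaves the feasible region
  expect_error(apply_attenuation(order_params(1, 1), 0.1, 1), "infeasible")
})

test_that("noisy inversion projects infeasible moments and flags them", {
  # all intensity in the crossed channels: m4 = 0, m2 = 2b/S, feasible only
  # on the boundary; perturb i_pp slightly negative-wards via large i_tt
  obs <- polarized_intensities(1, 0, 0, 0.0)  # p2 = 1 exactly, feasible
  expect_false(invert_intensities(obs)$order_params$feasibility_flag)
  noisy <- polarized_intensities(1, 0.6, 0.6, 0.01)  # m4 > feasibility?
  inv <- invert_intensities(noisy)
  m <- moments_from_order_params(inv$order_params)
  expect_true(m$m4 >= m$m2^2 - 1e-9 && m$m4 <= m$m2 + 1e-9)
  # direct infeasible construction: i_pp alone with crossed channels zero
  # but i_tt large drives m4/m2 ratio up; craft an infeasible case
  bad <- polarized_intensities(0.5, 0.01, 0.01, 1e-6)
  invb <- invert_intensities(bad)
  expect_true(invb$order_params$feasibility_flag)
  expect_error(invert_intensities(polarized_intensities(0, 0, 0, 0)),
               "zero")
})
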