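# Orientation distributions and their moments.
#
# The polar angle theta is measured between a probe's fluorescence dipole and
# the fiber (trabecular) axis.  User-facing angles are in degrees; all
# internal computation is in radians.

DEG <- pi / 180

#' Angle distributions for dipole populations
#'
#' Constructors for the parametric polar-angle distributions used by the
#' forward optical model and the synthetic-data generator.  A distribution
#' describes the angle `theta` between a fluorescence dipole and the fiber
#' axis, assumed cylindrically symmetric about that axis.
#'
#' * `angle_dist_delta(theta0)` — all dipoles at a single polar angle.
#' * `angle_dist_gaussian(theta0, sigma)` — Gaussian dispersion of width
#'   `sigma` about `theta0`, defined on the sphere: the angular density is
#'   proportional to `exp(-(theta - theta0)^2 / (2 sigma^2)) * sin(theta)`
#'   on `[0, pi]`, with the Gaussian reflected at both boundaries so no
#'   probability leaks off the interval.  As `sigma` grows the distribution
#'   tends to uniform in solid angle (isotropic).
#' * `angle_dist_mixture(components, weights)` — convex combination of
#'   sub-populations; weights must be non-negative and sum to 1.
#'
#' @param theta0 Mean polar angle in degrees, in `[0, 90]`.
#' @param sigma Angular dispersion in degrees, strictly positive.
#' @param components List of `angle_distribution` objects.
#' @param weights Numeric weights, same length as `components`,
#'   non-negative, summing to 1 within `1e-12`.
#' @return An object of class `angle_distribution`.
#' @examples
#' angle_dist_delta(60)
#' angle_dist_gaussian(60, 20)
#' angle_dist_mixture(list(angle_dist_delta(0), angle_dist_delta(90)),
#'                    c(0.5, 0.5))
#' @export
angle_dist_delta <- function(theta0) {
  check_theta0(theta0)
  structure(list(kind = "delta", theta0 = theta0),
            class = "angle_distribution")
}

#' @rdname angle_dist_delta
#' @export
angle_dist_gaussian <- function(theta0, sigma) {
  check_theta0(theta0)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive finite number (degrees)",
         call. = FALSE)
  }
  structure(list(kind = "gaussian_on_sphere", theta0 = theta0, sigma = sigma),
            class = "angle_distribution")
}

#' @rdname angle_dist_delta
#' @export
angle_dist_mixture <- function(components, weights) {
  if (!is.list(components) ||
      !all(vapply(components, inherits, logical(1), "angle_distribution"))) {
    stop("'components' must be a list of angle_distribution objects",
         call. = FALSE)
  }
  if (length(weights) != length(components)) {
    stop("'weights' and 'components' must have the same length",
         call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("mixture weights must be non-negative", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("mixture weights must sum to 1 within 1e-12", call. = FALSE)
  }
  structure(list(kind = "mixture", components = components,
                 weights = as.numeric(weights)),
            class = "angle_distribution")
}

check_theta0 <- function(theta0) {
  if (!is.numeric(theta0) || length(theta0) != 1L || !is.finite(theta0) ||
      theta0 < 0 || theta0 > 90) {
    stop("'theta0' must be a single angle in degrees within [0, 90]",
         call. = FALSE)
  }
  invisible(theta0)
}

#' @export
print.angle_distribution <- function(x, ...) {
  switch(x$kind,
    delta = cat(sprintf("<angle distribution: delta at %.4g deg>\n",
                        x$theta0)),
    gaussian_on_sphere = cat(sprintf(
      "<angle distribution: gaussian on sphere, theta0 = %.4g deg, sigma = %.4g deg>\n",
      x$theta0, x$sigma)),
    mixture = cat(sprintf("<angle distribution: mixture of %d components>\n",
                          length(x$components)))
  )
  invisible(x)
}

#' Moments of cos(theta) for an angle distribution
#'
#' Computes `m2 = <cos^2 theta>` and `m4 = <cos^4 theta>` over the given
#' distribution.  Delta distributions use the closed form; Gaussian-on-sphere
#' distributions are integrated by adaptive quadrature (absolute tolerance
#' `1e-10`); mixtures are weight-averaged.
#'
#' @param dist An [angle_dist_delta()] / [angle_dist_gaussian()] /
#'   [angle_dist_mixture()] object.
#' @return A `moments` object with fields `m2`, `m4` satisfying
#'   `0 <= m2^2 <= m4 <= m2 <= 1`.
#' @examples
#' moments_from_distribution(angle_dist_delta(0))   # m2 = m4 = 1
#' moments_from_distribution(angle_dist_gaussian(60, 20))
#' @export
moments_from_distribution <- function(dist) {
  stopifnot(inherits(dist, "angle_distribution"))
  switch(dist$kind,
    delta = {
      c2 <- cos(dist$theta0 * DEG)^2
      moments(c2, c2^2)
    },
    gaussian_on_sphere = gaussian_sphere_moments(dist$theta0 * DEG,
                                                 dist$sigma * DEG),
    mixture = {
      parts <- lapply(dist$components, moments_from_distribution)
      m2 <- sum(dist$weights * vapply(parts, `[[`, numeric(1), "m2"))
      m4 <- sum(dist$weights * vapply(parts, `[[`, numeric(1), "m4"))
      moments(m2, m4)
    }
  )
}

# Unnormalized angular weight on [0, pi]: Gaussian in theta reflected at 0 and
# pi (images at -theta0 + 2*pi*k and theta0 + 2*pi*k), times the sin(theta)
# solid-angle factor applied by the caller.
gaussian_sphere_weight <- function(theta, theta0, sigma) {
  k_max <- min(ceiling((6 * sigma + pi) / (2 * pi)) + 1L, 2000L)
  ks <- seq.int(-k_max, k_max)
  out <- numeric(length(theta))
  for (k in ks) {
    out <- out +
      exp(-((theta - theta0 - 2 * pi * k)^2) / (2 * sigma^2)) +
      exp(-((theta + theta0 - 2 * pi * k)^2) / (2 * sigma^2))
  }
  out
}

gaussian_sphere_moments <- function(theta0, sigma) {
  # restrict to where the (reflected) Gaussian has mass so the adaptive rule
  # cannot step over a narrow peak; reflected images near 0 stay inside
  lo <- max(0, theta0 - 12 * sigma)
  hi <- min(pi, theta0 + 12 * sigma)
  if (lo >= hi) { lo <- 0; hi <- pi }
  quad <- function(f) {
    stats::integrate(f, lo, hi, abs.tol = 1e-12, rel.tol = 1e-12,
                     subdivisions = 2000L)$value
  }
  w <- function(th) gaussian_sphere_weight(th, theta0, sigma) * sin(th)
  z  <- quad(w)
  m2 <- quad(function(th) cos(th)^2 * w(th)) / z
  m4 <- quad(function(th) cos(th)^4 * w(th)) / z
  moments(m2, m4)
}

#' Construct / validate a pair of cosine moments
#'
#' A feasible pair of moments of `cos^2 theta` and `cos^4 theta` must satisfy
#' `0 <= m2 <= 1`, `m4 <= m2` (since `cos^4 <= cos^2`) and `m4 >= m2^2`
#' (Jensen).  Violations are reported naming the bound.
#'
#' @param m2 `<cos^2 theta>`.
#' @param m4 `<cos^4 theta>`.
#' @param tol Numerical slack allowed on each bound.
#' @return A `moments` object (list with `m2`, `m4`).
#' @export
moments <- function(m2, m4, tol = 1e-9) {
  stopifnot(is.numeric(m2), is.numeric(m4), length(m2) == 1L,
            length(m4) == 1L, is.finite(m2), is.finite(m4))
  if (m2 < -tol || m2 > 1 + tol) {
    stop(sprintf("infeasible moments: m2 = %.6g violates 0 <= m2 <= 1", m2),
         call. = FALSE)
  }
  if (m4 > m2 + tol) {
    stop(sprintf("infeasible moments: m4 = %.6g > m2 = %.6g (requires m4 <= m2)",
                 m4, m2), call. = FALSE)
  }
  if (m4 < m2^2 - tol) {
    stop(sprintf("infeasible moments: m4 = %.6g < m2^2 = %.6g (Jensen bound m4 >= m2^2)",
                 m4, m2^2), call. = FALSE)
  }
  # snap tiny numerical violations back onto the region
  m2 <- min(max(m2, 0), 1)
  m4 <- min(max(m4, m2^2), m2)
  structure(list(m2 = m2, m4 = m4), class = "moments")
}

#' @export
print.moments <- function(x, ...) {
  cat(sprintf("<moments: m2 = %.6g, m4 = %.6g>\n", x$m2, x$m4))
  invisible(x)
}

#' Order parameters from cosine moments (and back)
#'
#' `order_params_from_moments()` maps `(m2, m4)` to the ensemble-average
#' Legendre order parameters `<P2> = (3 m2 - 1)/2` and
#' `<P4> = (35 m4 - 30 m2 + 3)/8`.  `moments_from_order_params()` inverts the
#' linear relations.  `<P2>` is +1 if every dipole is parallel to the fiber
#' axis and -0.5 if all are perpendicular.
#'
#' @param m A [moments()] object.
#' @param ops An [order_params()] object.
#' @return For `order_params_from_moments`, an [order_params()] object with
#'   `p2d` unset; for `moments_from_order_params`, a [moments()] object.
#' @examples
#' order_params_from_moments(moments(1 / 3, 1 / 5))  # isotropic: p2 = p4 = 0
#' @export
order_params_from_moments <- function(m) {
  stopifnot(inherits(m, "moments"))
  order_params(p2 = (3 * m$m2 - 1) / 2,
               p4 = (35 * m$m4 - 30 * m$m2 + 3) / 8)
}

#' @rdname order_params_from_moments
#' @export
moments_from_order_params <- function(ops) {
  stopifnot(inherits(ops, "order_params"))
  m2 <- (2 * ops$p2 + 1) / 3
  m4 <- (8 * ops$p4 + 30 * m2 - 3) / 35
  moments(m2, m4)
}

#' Order-parameter set for a dipole population
#'
#' Bundles the slow-timescale orientation order parameters `<P2>` and `<P4>`
#' with the (optional) fast-wobble order parameter `<P2d>` describing
#' sub-nanosecond probe motion about its mean axis.  `<P2d>` is treated as a
#' supplied constant throughout this package; it is carried as metadata and
#' may be used as an extra attenuation factor by the generator, but the
#' optical model itself is the static uniaxial form.
#'
#' The pair `(p2, p4)` must be feasible, i.e. the implied `(m2, m4)` must be
#' admissible cosine moments; in particular `p2` lies in `[-0.5, 1]` and `p4`
#' in `[-3/7, 1]`.
#'
#' @param p2 `<P2>`, dimensionless in `[-0.5, 1]`.
#' @param p4 `<P4>`, dimensionless in `[-3/7, 1]`.
#' @param p2d Optional fast-wobble order parameter in `[0, 1]`.
#' @param feasibility_flag Logical; set by [invert_intensities()] when noisy
#'   moments had to be projected onto the feasibility boundary.
#' @return An object of class `order_params`.
#' @export
order_params <- function(p2, p4, p2d = NA_real_, feasibility_flag = FALSE) {
  stopifnot(is.numeric(p2), is.numeric(p4), length(p2) == 1L,
            length(p4) == 1L, is.finite(p2), is.finite(p4))
  tol <- 1e-9
  if (p2 < -0.5 - tol || p2 > 1 + tol) {
    stop(sprintf("p2 = %.6g outside [-0.5, 1]", p2), call. = FALSE)
  }
  if (!is.na(p2d) && (p2d < -tol || p2d > 1 + tol)) {
    stop(sprintf("p2d = %.6g outside [0, 1]", p2d), call. = FALSE)
  }
  ops <- structure(list(p2 = p2, p4 = p4, p2d = p2d,
                        feasibility_flag = isTRUE(feasibility_flag)),
                   class = "order_params")
  # feasibility of the implied moment pair (errors name the violated bound)
  m2 <- (2 * p2 + 1) / 3
  m4 <- (8 * p4 + 30 * m2 - 3) / 35
  moments(m2, m4)
  ops
}

#' @export
print.order_params <- function(x, ...) {
  cat(sprintf("<order parameters: p2 = %.6g, p4 = %.6g%s%s>\n",
              x$p2, x$p4,
              if (is.na(x$p2d)) "" else sprintf(", p2d = %.4g", x$p2d),
              if (x$feasibility_flag) " [projected]" else ""))
  invisible(x)
}

#' Attenuate order parameters by axial disorder
#'
#' Nested, statistically independent disorder (e.g. myofibrillar
#' misalignment on top of the probe's own distribution) multiplies order
#' parameters: `p2' = p2 * d2`, `p4' = p4 * d4`.  Better myofibrillar
#' alignment at longer sarcomere length corresponds to `d2`, `d4` closer
#' to 1.
#'
#' @param ops An [order_params()] object.
#' @param d2,d4 Attenuation factors in `[0, 1]`.
#' @return An [order_params()] object; an error is signalled if the
#'   attenuated pair leaves the feasible region.
#' @export
apply_attenuation <- function(ops, d2, d4) {
  stopifnot(inherits(ops, "order_params"))
  if (d2 < 0 || d2 > 1 || d4 < 0 || d4 > 1) {
    stop("attenuation factors d2, d4 must lie in [0, 1]", call. = FALSE)
  }
  order_params(ops$p2 * d2, ops$p4 * d4, p2d = ops$p2d)
}

#' Linear mixing of `<P2>` across dipole populations
#'
#' When several dipole populations with distinct orientations contribute to
#' the signal, the observed `<P2>` is the population-fraction-weighted mean
#' of the component `<P2>` values.
#'
#' @param weights Population fractions, non-negative, summing to 1 within
#'   `1e-12`.
#' @param p2s Component `<P2>` values, each in `[-0.5, 1]`.
#' @return The mixture `<P2>`.
#' @examples
#' mixture_p2(c(0.5, 0.5), c(1, -0.5))  # 0.25
#' @export
mixture_p2 <- function(weights, p2s) {
  if (length(weights) != length(p2s)) {
    stop("'weights' and 'p2s' must have the same length", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be non-negative and sum to 1 within 1e-12",
         call. = FALSE)
  }
  if (any(p2s < -0.5 - 1e-12 | p2s > 1 + 1e-12)) {
    stop("each p2 must lie in [-0.5, 1]", call. = FALSE)
  }
  sum(weights * p2s)
}

# Euclidean projection of (m2, m4) onto the feasible region
# {0 <= x <= 1, x^2 <= y <= x}.  For fixed x the nearest feasible y is the
# clamp of y0 to [x^2, x]; the outer problem is a smooth 1-d minimization.
project_moments <- function(m2, m4) {
  f <- function(x) {
    y <- min(max(m4, x^2), x)
    (x - m2)^2 + (y - m4)^2
  }
  opt <- stats::optimize(f, c(0, 1), tol = 1e-14)
  x <- opt$minimum
  # also consider the corners, optimize() can sit near but not at them
  cand <- c(x, 0, 1, min(max(m2, 0), 1))
  vals <- vapply(cand, f, numeric(1))
  x <- cand[which.min(vals)]
  y <- min(max(m4, x^2), x)
  list(m2 = x, m4 = y)
}
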