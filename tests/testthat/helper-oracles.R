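# Independent oracles used by the test suite.  These deliberately avoid the
# package's own code paths: dense-grid trapezoid quadrature instead of
# adaptive integration, grid-scan root finding instead of bisection, and
# direct transcriptions of textbook formulas.

# dense-grid trapezoid moments for the gaussian-on-sphere family
# (density on [0, pi] proportional to reflected Gaussian times sin(theta))
oracle_gauss_moments <- function(theta0_deg, sigma_deg, n_grid = 400001L) {
  t0 <- theta0_deg * pi / 180
  s <- sigma_deg * pi / 180
  th <- seq(0, pi, length.out = n_grid)
  g <- numeric(n_grid)
  kmax <- min(ceiling((6 * s + pi) / (2 * pi)) + 1L, 2000L)
  for (k in seq.int(-kmax, kmax)) {
    g <- g + exp(-((th - t0 - 2 * pi * k)^2) / (2 * s^2)) +
      exp(-((th + t0 - 2 * pi * k)^2) / (2 * s^2))
  }
  w <- g * sin(th)
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * (pi / (n_grid - 1))
  z <- trapz(w)
  list(m2 = trapz(cos(th)^2 * w) / z, m4 = trapz(cos(th)^4 * w) / z)
}

# polarized intensities by direct numerical integration of the angular
# factors against an arbitrary (unnormalized) angular density w(theta)
# already including the sin(theta) solid-angle factor
oracle_intensities <- function(wfun, scale = 1, n_grid = 400001L) {
  th <- seq(0, pi, length.out = n_grid)
  w <- wfun(th)
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * (pi / (n_grid - 1))
  z <- trapz(w)
  list(i_pp = scale * trapz(cos(th)^4 * w) / z,
       i_pt = scale * trapz(cos(th)^2 * sin(th)^2 * w) / z / 2,
       i_tt = scale * (3 / 8) * trapz(sin(th)^4 * w) / z)
}

# free calcium by residual scan + iterative grid zoom (no bisection)
oracle_free_ca <- function(total_ca, total_egta, total_atp, free_mg, k) {
  resid <- function(x) {
    e <- total_egta / (1 + k$k_ca_egta * x + k$k_mg_egta * free_mg)
    a <- total_atp / (1 + k$k_ca_atp * x + k$k_mg_atp * free_mg)
    x + k$k_ca_egta * x * e + k$k_ca_atp * x * a - total_ca
  }
  lo <- 0
  hi <- total_ca
  for (zoom in 1:40) {
    xs <- seq(lo, hi, length.out = 201L)
    rs <- vapply(xs, resid, numeric(1))
    i <- which(rs >= 0)[1]
    if (is.na(i) || i == 1L) i <- 2L
    lo <- xs[i - 1L]
    hi <- xs[i]
    if ((hi - lo) < 1e-18 * max(total_ca, 1e-12)) break
  }
  (lo + hi) / 2
}

# random feasible order-parameter set: sample the moment region directly
random_feasible_ops <- function() {
  m2 <- stats::runif(1)
  m4 <- stats::runif(1, m2^2, m2)
  order_params((3 * m2 - 1) / 2, (35 * m4 - 30 * m2 + 3) / 8)
}

# random angle distribution (for property loops)
random_angle_dist <- function() {
  kind <- sample(c("delta", "gaussian", "mixture"), 1)
  if (kind == "delta") {
    angle_dist_delta(stats::runif(1, 0, 90))
  } else if (kind == "gaussian") {
    angle_dist_gaussian(stats::runif(1, 0, 90), stats::runif(1, 1, 80))
  } else {
    w <- stats::runif(2)
    w <- w / sum(w)
    angle_dist_mixture(list(angle_dist_delta(stats::runif(1, 0, 90)),
                            angle_dist_gaussian(stats::runif(1, 0, 90),
                                                stats::runif(1, 1, 60))),
                       w)
  }
}

# minimal null fit report for summary-table calibration: n trabeculae,
# one probe, p2 pca50 at both SLs with NO true SL effect
null_fit_report <- function(n, between_sd = 0.05, meas_sd = 0.02) {
  ids <- sprintf("T%02d", seq_len(n))
  base <- 5.37 + stats::rnorm(n, 0, between_sd)
  data.frame(
    trabecula_id = rep(ids, 2),
    probe = "cTnC-C",
    sl_um = rep(c(1.9, 2.3), each = n),
    treatment = "control",
    response_kind = "p2",
    pca50 = c(base + stats::rnorm(n, 0, meas_sd),
              base + stats::rnorm(n, 0, meas_sd)),
    stringsAsFactors = FALSE)
}
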