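# Forward and inverse optical model.
#
# Static uniaxial parallel-dipole model: excitation and emission dipoles are
# taken parallel, the dipole distribution is cylindrically symmetric about
# the fiber axis, and fast wobble is not folded into the absorption-emission
# correlation (p2d travels as metadata).  With m2 = <cos^2>, m4 = <cos^4>:
#
#   I_pp = S * m4                      (excitation and emission parallel)
#   I_pt = I_tp = S * (m2 - m4) / 2    (crossed)
#   I_tt = S * (3/8) * (1 - 2 m2 + m4) (both perpendicular)
#
# which is exactly invertible from the three distinct components.

#' Polarized intensity set
#'
#' Container for the four steady-state fluorescence intensity components,
#' indexed by (excitation, emission) polarization relative to the fiber
#' axis: parallel/parallel (`i_pp`), parallel/perpendicular (`i_pt`),
#' perpendicular/parallel (`i_tp`), perpendicular/perpendicular (`i_tt`).
#' Under the static uniaxial model `i_pt == i_tp`; measured sets may differ
#' by noise, and their discrepancy is reported by [invert_intensities()] as
#' a quality metric.
#'
#' @param i_pp,i_pt,i_tp,i_tt Non-negative intensities (arbitrary units).
#' @return An object of class `polarized_intensities`.
#' @export
polarized_intensities <- function(i_pp, i_pt, i_tp, i_tt) {
  v <- c(i_pp = i_pp, i_pt = i_pt, i_tp = i_tp, i_tt = i_tt)
  if (!all(is.finite(v))) stop("intensities must be finite", call. = FALSE)
  if (any(v < 0)) {
    stop(sprintf("negative intensity component: %s",
                 paste(names(v)[v < 0], collapse = ", ")), call. = FALSE)
  }
  structure(as.list(v), class = "polarized_intensities")
}

#' @export
print.polarized_intensities <- function(x, ...) {
  cat(sprintf("<polarized intensities: i_pp = %.6g, i_pt = %.6g, i_tp = %.6g, i_tt = %.6g>\n",
              x$i_pp, x$i_pt, x$i_tp, x$i_tt))
  invisible(x)
}

#' Forward model: order parameters to polarized intensities
#'
#' Computes the four polarized intensity components predicted by the static
#' uniaxial parallel-dipole model for a dipole population with the given
#' order parameters and overall brightness `scale`.
#'
#' @param ops An [order_params()] object with a feasible `(p2, p4)` pair.
#' @param scale Positive overall brightness factor.
#' @return A [polarized_intensities()] object.
#' @examples
#' forward_intensities(order_params(0, 0), scale = 1)  # isotropic, 3:1:1:3
#' @export
forward_intensities <- function(ops, scale = 1) {
  stopifnot(inherits(ops, "order_params"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive number", call. = FALSE)
  }
  m <- moments_from_order_params(ops)
  i_pp <- scale * m$m4
  i_x  <- scale * (m$m2 - m$m4) / 2
  i_tt <- scale * (3 / 8) * (1 - 2 * m$m2 + m$m4)
  # clip sub-epsilon negatives arising at the region boundary
  polarized_intensities(max(i_pp, 0), max(i_x, 0), max(i_x, 0), max(i_tt, 0))
}

#' Inverse model: polarized intensities to order parameters
#'
#' Solves the static uniaxial model exactly for `(m2, m4, scale)` from the
#' three distinct intensity components (`i_pt` and `i_tp` are averaged
#' first), then converts to `<P2>`, `<P4>`.  If measurement noise drives the
#' solved moments outside the feasible region they are projected onto the
#' nearest feasible point (Euclidean distance in `(m2, m4)`) and the result
#' carries `feasibility_flag = TRUE`; nothing is silently clipped.
#'
#' @param obs A [polarized_intensities()] object (or a list with the four
#'   named components); at least one component must be positive.
#' @return A list with elements
#'   \describe{
#'     \item{order_params}{[order_params()] with `feasibility_flag` set when
#'       projection occurred}
#'     \item{scale}{recovered brightness factor}
#'     \item{ipt_itp_diff}{relative discrepancy
#'       `|i_pt - i_tp| / max(intensity)`, a data-quality metric (the static
#'       model predicts 0)}
#'   }
#' @examples
#' f <- forward_intensities(order_params(0.3, 0.1), scale = 2)
#' invert_intensities(f)
#' @export
invert_intensities <- function(obs) {
  if (!inherits(obs, "polarized_intensities")) {
    obs <- polarized_intensities(obs$i_pp, obs$i_pt, obs$i_tp, obs$i_tt)
  }
  tot <- max(obs$i_pp, obs$i_pt, obs$i_tp, obs$i_tt)
  if (tot <= 0) stop("all intensity components are zero", call. = FALSE)
  a <- obs$i_pp
  b <- (obs$i_pt + obs$i_tp) / 2
  cc <- obs$i_tt
  # S = a + 4 b + (8/3) c;  m4 = a / S;  m2 = (a + 2 b) / S
  scale <- a + 4 * b + (8 / 3) * cc
  m2 <- (a + 2 * b) / scale
  m4 <- a / scale
  flagged <- FALSE
  feas_tol <- 1e-9
  if (m2 < -feas_tol || m2 > 1 + feas_tol || m4 > m2 + feas_tol ||
      m4 < m2^2 - feas_tol) {
    pr <- project_moments(m2, m4)
    m2 <- pr$m2
    m4 <- pr$m4
    flagged <- TRUE
  }
  ops <- order_params_from_moments(moments(m2, m4))
  ops$feasibility_flag <- flagged
  list(order_params = ops,
       scale = scale,
       ipt_itp_diff = abs(obs$i_pt - obs$i_tp) / tot)
}
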