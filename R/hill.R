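# Hill-equation titration fitting.
#
# Model:  Y(pCa) = baseline + amplitude / (1 + 10^(n_h * (pCa - pca50)))
#
# so Y -> baseline at high pCa (relaxed) and baseline + amplitude at
# saturating calcium.  amplitude is signed: negative for probes whose <P2>
# falls on activation (troponin C helices), positive for force and for the
# myosin light-chain probe.

LOG10 <- log(10)

#' Titration curve container
#'
#' One per-preparation (pCa, response) series, for force or `<P2>`, with its
#' condition metadata.  At least 5 distinct pCa points are required so the
#' four-parameter Hill fit is determined.
#'
#' @param pca Numeric pCa values (positive decimals, e.g. 4.5).
#' @param response Numeric responses, same length (force in kPa or
#'   normalized units, or dimensionless `<P2>`).
#' @param response_kind `"force"` or `"p2"`.
#' @param probe Probe label, one of `"cTnC-C"`, `"cTnC-E"`, `"cRLC-BC"`,
#'   `"none"`.
#' @param sl_um Sarcomere length in micrometres.
#' @param treatment `"control"` or `"blebbistatin"`.
#' @param trabecula_id Identifier of the preparation.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(pca, response, response_kind = c("p2", "force"),
                            probe = "none", sl_um = NA_real_,
                            treatment = "control",
                            trabecula_id = NA_character_) {
  response_kind <- match.arg(response_kind)
  stopifnot(is.numeric(pca), is.numeric(response),
            length(pca) == length(response))
  if (!all(is.finite(pca)) || !all(is.finite(response))) {
    stop("pca and response must be finite", call. = FALSE)
  }
  if (length(unique(pca)) < 5L) {
    stop("a titration curve needs at least 5 distinct pCa points",
         call. = FALSE)
  }
  o <- order(pca, decreasing = TRUE)   # relaxed end first
  structure(list(pca = pca[o], response = response[o],
                 response_kind = response_kind, probe = probe,
                 sl_um = sl_um, treatment = treatment,
                 trabecula_id = trabecula_id),
            class = "titration_curve")
}

#' Evaluate the Hill equation
#'
#' `Y = baseline + amplitude / (1 + 10^(n_h * (pca - pca50)))`.  At
#' `pca = pca50` the response is `baseline + amplitude / 2` (half-maximal
#' change by definition).
#'
#' @param params A `hill_parameters` object (from [fit_hill()]) or any list
#'   with fields `pca50`, `n_h`, `baseline`, `amplitude`.
#' @param pca Numeric pCa value(s).
#' @return Numeric response(s).
#' @examples
#' p <- list(pca50 = 5.37, n_h = 4.03, baseline = 0, amplitude = 1)
#' hill_eval(p, 5.37)  # 0.5
#' @export
hill_eval <- function(params, pca) {
  params$baseline +
    params$amplitude / (1 + 10^(params$n_h * (pca - params$pca50)))
}

# residual Jacobian columns for (pca50, n_h, baseline, amplitude)
hill_jacobian <- function(theta, pca) {
  pca50 <- theta[["pca50"]]; n_h <- theta[["n_h"]]
  amp <- theta[["amplitude"]]
  u <- 10^(n_h * (pca - pca50))
  h <- 1 / (1 + u)
  dh_common <- u / (1 + u)^2 * LOG10
  cbind(pca50     = amp * dh_common * n_h,
        n_h       = -amp * dh_common * (pca - pca50),
        baseline  = rep(1, length(pca)),
        amplitude = h)
}

#' Fit the Hill equation to a titration curve
#'
#' Nonlinear least-squares fit of the four-parameter Hill model (baseline,
#' amplitude, pCa50, Hill coefficient) by damped Gauss-Newton
#' (Levenberg-Marquardt) with analytic Jacobian.  Standard errors come from
#' the usual linearized covariance `s^2 (J'J)^-1`.  On noise-free Hill data
#' the generating parameters are recovered essentially exactly; the fit is
#' deterministic given identical input.
#'
#' Initialization: baseline and plateau from the means of the two most
#' relaxed / most activated pCa points, pCa50 from the half-level crossing
#' of a monotone interpolation, `n_h = 3`.  Bounds: `n_h` in `[0.5, 10]`,
#' pCa50 within the data range plus or minus 0.5 pCa units (these prevent
#' divergence on noisy flat curves; reported Hill coefficients for this
#' preparation are about 2.5-4.3).
#'
#' A curve whose fitted amplitude is indistinguishable from zero at two
#' standard errors is returned with `degenerate = TRUE` rather than raising.
#'
#' @param curve A [titration_curve()].
#' @param normalize If `TRUE`, response-scale parameters (baseline,
#'   amplitude and their SEs) are divided by the fitted maximum
#'   `baseline + amplitude` before reporting, so force curves read as
#'   fraction of fitted maximum force.
#' @param fix_baseline Optional numeric: constrain the baseline (use `0` for
#'   force curves, the package convention).
#' @return An object of class `hill_parameters`: fields `pca50`, `n_h`,
#'   `baseline`, `amplitude`, `se_pca50`, `se_nh`, `se_baseline`,
#'   `se_amplitude`, `converged`, `degenerate`, `rss`, `n`.
#' @examples
#' pca <- c(7, 6, 5.8, 5.6, 5.5, 5.4, 5.2, 5, 4.5)
#' y <- hill_eval(list(pca50 = 5.5, n_h = 4.3, baseline = 0,
#'                     amplitude = 32.4), pca)
#' fit_hill(titration_curve(pca, y, "force"), fix_baseline = 0)
#' @export
fit_hill <- function(curve, normalize = FALSE, fix_baseline = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  x <- curve$pca
  y <- curve$response
  n <- length(x)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)

  lower <- c(pca50 = min(x) - 0.5, n_h = 0.5, baseline = -Inf,
             amplitude = -Inf)
  upper <- c(pca50 = max(x) + 0.5, n_h = 10, baseline = Inf,
             amplitude = Inf)

  theta <- hill_init(x, y, fix_baseline)
  free <- c("pca50", "n_h", "baseline", "amplitude")
  if (!is.null(fix_baseline)) {
    theta[["baseline"]] <- fix_baseline
    free <- setdiff(free, "baseline")
  }

  ssr <- function(th) sum((y - hill_eval(as.list(th), x))^2)
  lambda <- 1e-3
  s0 <- ssr(theta)
  converged <- FALSE
  for (it in seq_len(400L)) {
    r <- y - hill_eval(as.list(theta), x)
    J <- hill_jacobian(theta, x)[, free, drop = FALSE]
    A <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (tries in seq_len(30L)) {
      Areg <- A + lambda * diag(pmax(diag(A), 1e-12), nrow(A))
      delta <- tryCatch(drop(solve(Areg, g)), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- theta
      cand[free] <- cand[free] + delta
      cand <- pmin(pmax(cand, lower), upper)
      s1 <- ssr(cand)
      if (is.finite(s1) && s1 <= s0) { step_ok <- TRUE; break }
      lambda <- lambda * 5
    }
    if (!step_ok) break
    moved <- max(abs(cand[free] - theta[free]) /
                   pmax(abs(theta[free]), 1e-8))
    theta <- cand
    improved <- s0 - s1
    s0 <- s1
    lambda <- max(lambda / 3, 1e-12)
    if (s0 < 1e-24 || improved < 1e-15 * (s0 + 1e-15) || moved < 1e-12) {
      converged <- TRUE
      break
    }
  }

  # linearized covariance on the free parameters
  J <- hill_jacobian(theta, x)[, free, drop = FALSE]
  p <- length(free)
  dof <- max(n - p, 1L)
  s2 <- s0 / dof
  se <- stats::setNames(rep(NA_real_, 4L),
                        c("pca50", "n_h", "baseline", "amplitude"))
  cov_ok <- tryCatch({
    cv <- s2 * solve(crossprod(J))
    se[free] <- sqrt(pmax(diag(cv), 0))
    TRUE
  }, error = function(e) FALSE)
  if (!is.null(fix_baseline)) se[["baseline"]] <- 0

  degenerate <- is.na(se[["amplitude"]]) ||
    abs(theta[["amplitude"]]) < 2 * se[["amplitude"]]

  out <- list(pca50 = theta[["pca50"]], n_h = theta[["n_h"]],
              baseline = theta[["baseline"]],
              amplitude = theta[["amplitude"]],
              se_pca50 = se[["pca50"]], se_nh = se[["n_h"]],
              se_baseline = se[["baseline"]],
              se_amplitude = se[["amplitude"]],
              converged = converged || s0 < 1e-20,
              degenerate = degenerate,
              rss = s0, n = n, normalized = isTRUE(normalize))
  if (isTRUE(normalize)) {
    ymax <- out$baseline + out$amplitude
    if (abs(ymax) > .Machine$double.eps) {
      for (f in c("baseline", "amplitude", "se_baseline", "se_amplitude")) {
        out[[f]] <- out[[f]] / abs(ymax)
      }
    }
  }
  structure(out, class = "hill_parameters")
}

hill_init <- function(x, y, fix_baseline = NULL) {
  o <- order(x, decreasing = TRUE)
  xs <- x[o]; ys <- y[o]
  baseline <- if (is.null(fix_baseline)) mean(ys[1:2]) else fix_baseline
  plateau <- mean(ys[(length(ys) - 1):length(ys)])
  amplitude <- plateau - baseline
  if (amplitude == 0) amplitude <- diff(range(y))
  if (amplitude == 0) amplitude <- 1e-6
  half <- baseline + amplitude / 2
  # half-level crossing of the piecewise-linear interpolation
  frac <- (ys - baseline) / amplitude
  idx <- which(diff(sign(frac - 0.5)) != 0)
  pca50 <- if (length(idx) > 0) {
    i <- idx[1]
    x1 <- xs[i]; x2 <- xs[i + 1]
    f1 <- frac[i]; f2 <- frac[i + 1]
    if (f2 == f1) (x1 + x2) / 2 else x1 + (0.5 - f1) / (f2 - f1) * (x2 - x1)
  } else {
    stats::median(xs)
  }
  c(pca50 = pca50, n_h = 3, baseline = baseline, amplitude = amplitude)
}

#' @export
print.hill_parameters <- function(x, ...) {
  cat(sprintf(
    "<Hill fit: pCa50 = %.3f +/- %.3f, nH = %.2f +/- %.2f, baseline = %.4g, amplitude = %.4g%s%s>\n",
    x$pca50, x$se_pca50, x$n_h, x$se_nh, x$baseline, x$amplitude,
    if (!x$converged) " [not converged]" else "",
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Activation-associated change in response between pCa 6 and 4.5
#'
#' `delta = response(pCa 4.5) - response(pCa 6)`: the total change in `<P2>`
#' (or force) associated with calcium activation, negative for troponin C
#' probes and positive for the myosin light-chain probe.  Repeated
#' measurements at an anchor pCa are averaged.  Per-preparation deltas are
#' averaged by the caller (paired design), which is why a cohort-mean delta
#' can differ in the last digit from the difference of the cohort means at
#' the two anchors.
#'
#' @param curve A [titration_curve()] containing measurements at pCa 6.0 and
#'   pCa 4.5 (matched within `tol`).
#' @param tol Matching tolerance on pCa (default `1e-6`).
#' @return Signed change (response units).
#' @examples
#' cv <- titration_curve(c(9, 6, 5.5, 5, 4.5),
#'                       c(0.283, 0.283, 0.23, 0.19, 0.182), "p2")
#' delta_p2(cv)  # -0.101
#' @export
delta_p2 <- function(curve, tol = 1e-6) {
  stopifnot(inherits(curve, "titration_curve"))
  at <- function(target) {
    hit <- abs(curve$pca - target) < tol
    if (!any(hit)) {
      stop(sprintf("curve has no measurement at pCa %.2f", target),
           call. = FALSE)
    }
    mean(curve$response[hit])
  }
  at(4.5) - at(6.0)
}
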