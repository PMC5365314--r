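# Free-calcium solver for mixed Ca/Mg/EGTA/ATP bathing solutions.
#
# Species set: {Ca.EGTA, Mg.EGTA, Ca.ATP, Mg.ATP}, all 1:1, with proton
# microstates folded into user-supplied APPARENT association constants at
# the stated pH / temperature / ionic strength (MaxChelator practice).
# Free Mg2+ is clamped at its target value: total Mg is an output.

#' Apparent binding constants for the standard bathing solution
#'
#' Default apparent 1:1 association constants (per molar) for Ca and Mg
#' binding to EGTA and ATP at pH 7.1, 20 degrees C, ionic strength 0.2 M.
#' These are package defaults in the range of standard MaxChelator-style
#' tabulations for those conditions; they are NOT measured values and should
#' be replaced with instrument- or lab-specific constants when available.
#'
#' @return Named list with `k_ca_egta`, `k_mg_egta`, `k_ca_atp`, `k_mg_atp`
#'   in 1/M.
#' @export
default_binding_constants <- function() {
  list(k_ca_egta = 10^6.57,  # apparent Ca-EGTA at pH 7.1
       k_mg_egta = 10^1.7,   # Mg binds EGTA weakly
       k_ca_atp  = 10^3.7,
       k_mg_atp  = 10^3.9)
}

#' Bathing-solution recipe
#'
#' Describes a Ca/Mg/EGTA/ATP solution by its total ligand concentrations,
#' the clamped free-Mg target, and apparent association constants.  The
#' standard experimental solution contains 10 mM EGTA, 5 mM MgATP, 1 mM free
#' Mg2+ and 0-10 mM total calcium at pH 7.1, 20 degrees C, ionic strength
#' 0.2 M.
#'
#' @param total_ca Total calcium, molar.
#' @param total_egta Total EGTA, molar (default 10 mM).
#' @param total_atp Total ATP, molar (default 5 mM).
#' @param free_mg Clamped free Mg2+ concentration, molar (default 1 mM).
#' @param constants Named list of apparent association constants (1/M); see
#'   [default_binding_constants()].
#' @param ph,temperature_c,ionic_strength Solution conditions recorded as
#'   metadata (the constants are assumed already apparent at these
#'   conditions; no correction engine is applied).
#' @return An object of class `solution_recipe`.
#' @export
solution_recipe <- function(total_ca,
                            total_egta = 0.010,
                            total_atp = 0.005,
                            free_mg = 0.001,
                            constants = default_binding_constants(),
                            ph = 7.1,
                            temperature_c = 20,
                            ionic_strength = 0.2) {
  conc <- c(total_ca = total_ca, total_egta = total_egta,
            total_atp = total_atp, free_mg = free_mg)
  if (!all(is.finite(conc)) || any(conc < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  needed <- c("k_ca_egta", "k_mg_egta", "k_ca_atp", "k_mg_atp")
  if (!all(needed %in% names(constants))) {
    stop("constants must supply ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  kv <- unlist(constants[needed])
  if (!all(is.finite(kv)) || any(kv <= 0)) {
    stop("all binding constants must be finite and > 0", call. = FALSE)
  }
  structure(list(total_ca = total_ca, total_egta = total_egta,
                 total_atp = total_atp, free_mg = free_mg,
                 constants = as.list(kv), ph = ph,
                 temperature_c = temperature_c,
                 ionic_strength = ionic_strength),
            class = "solution_recipe")
}

#' @export
print.solution_recipe <- function(x, ...) {
  cat(sprintf(
    "<solution recipe: %.4g mM total Ca, %.4g mM EGTA, %.4g mM ATP, %.4g mM free Mg, pH %.2f>\n",
    1e3 * x$total_ca, 1e3 * x$total_egta, 1e3 * x$total_atp,
    1e3 * x$free_mg, x$ph))
  invisible(x)
}

#' Convert between pCa and free calcium
#'
#' `pCa = -log10([Ca2+]free / M)`; pCa 9 is 1 nM, pCa 4.5 is 31.6 uM.
#'
#' @param pca pCa value(s).
#' @param free_ca Free calcium concentration(s), molar.
#' @return Molar free calcium, or pCa (`Inf` for zero free calcium).
#' @export
free_ca_from_pca <- function(pca) {
  stopifnot(is.numeric(pca), all(is.finite(pca)))
  10^(-pca)
}

#' @rdname free_ca_from_pca
#' @export
pca_from_free_ca <- function(free_ca) {
  stopifnot(is.numeric(free_ca), all(free_ca >= 0))
  ifelse(free_ca == 0, Inf, -log10(free_ca))
}

# bound calcium at a given free Ca x (free Mg clamped at mg)
bound_ca_at <- function(x, r) {
  k <- r$constants
  e_free <- r$total_egta / (1 + k$k_ca_egta * x + k$k_mg_egta * r$free_mg)
  a_free <- r$total_atp / (1 + k$k_ca_atp * x + k$k_mg_atp * r$free_mg)
  k$k_ca_egta * x * e_free + k$k_ca_atp * x * a_free
}

#' Solve the multi-equilibrium system for free calcium
#'
#' Finds the free Ca2+ concentration satisfying calcium mass balance under
#' the coupled 1:1 equilibria Ca.EGTA, Mg.EGTA, Ca.ATP and Mg.ATP, with free
#' Mg2+ clamped at the recipe value.  The calcium residual
#' `free + bound - total` is strictly monotone in free Ca, so bisection on
#' `[0, total_ca]` converges unconditionally; iteration stops when the
#' residual is below `1e-12` M (at most 200 iterations).
#'
#' @param recipe A [solution_recipe()].
#' @return A list with
#'   \describe{
#'     \item{free_ca}{free Ca2+, molar}
#'     \item{pca}{`-log10(free_ca)`; `Inf` when total calcium is zero}
#'     \item{species}{data frame of every free and bound species (molar)}
#'     \item{residuals}{named conservation residuals for Ca, EGTA, ATP}
#'     \item{total_mg}{implied total magnesium (output, since free Mg is
#'       clamped)}
#'   }
#' @examples
#' r <- solution_recipe(total_ca = 0.005)
#' solve_free_ca(r)$pca
#' @export
solve_free_ca <- function(recipe) {
  stopifnot(inherits(recipe, "solution_recipe"))
  tca <- recipe$total_ca
  if (tca == 0) {
    return(species_report(0, recipe))
  }
  g <- function(x) x + bound_ca_at(x, recipe) - tca
  lo <- 0
  hi <- tca           # free Ca can never exceed total Ca
  x <- tca / 2
  # run the bisection to interval collapse (~1 ulp): the residual then sits
  # far below the 1e-12 M contract for any recipe on the molar scale
  for (it in seq_len(200L)) {
    x <- (lo + hi) / 2
    if (x <= lo || x >= hi) break
    if (g(x) > 0) hi <- x else lo <- x
  }
  if (abs(g(x)) >= 1e-12) {
    stop("free-calcium bisection did not converge in 200 iterations",
         call. = FALSE)
  }
  species_report(x, recipe)
}

species_report <- function(x, r) {
  k <- r$constants
  e_free <- r$total_egta / (1 + k$k_ca_egta * x + k$k_mg_egta * r$free_mg)
  a_free <- r$total_atp / (1 + k$k_ca_atp * x + k$k_mg_atp * r$free_mg)
  ca_egta <- k$k_ca_egta * x * e_free
  mg_egta <- k$k_mg_egta * r$free_mg * e_free
  ca_atp  <- k$k_ca_atp * x * a_free
  mg_atp  <- k$k_mg_atp * r$free_mg * a_free
  species <- data.frame(
    species = c("Ca_free", "Mg_free", "EGTA_free", "ATP_free",
                "CaEGTA", "MgEGTA", "CaATP", "MgATP"),
    concentration_m = c(x, r$free_mg, e_free, a_free,
                        ca_egta, mg_egta, ca_atp, mg_atp),
    stringsAsFactors = FALSE
  )
  if (any(species$concentration_m < 0)) {
    stop("negative species concentration in equilibrium solution",
         call. = FALSE)
  }
  residuals <- c(
    ca   = (x + ca_egta + ca_atp) - r$total_ca,
    egta = (e_free + ca_egta + mg_egta) - r$total_egta,
    atp  = (a_free + ca_atp + mg_atp) - r$total_atp
  )
  list(free_ca = x,
       pca = pca_from_free_ca(x),
       species = species,
       residuals = residuals,
       total_mg = r$free_mg + mg_egta + mg_atp)
}

#' Total calcium required to reach a target pCa
#'
#' Inverse solution-design problem: finds the total calcium (in
#' `[0, 0.1 M]`) for which [solve_free_ca()] returns the target free
#' calcium, by bisection to an absolute free-calcium tolerance of `1e-12` M.
#' Free calcium is strictly increasing in total calcium, so the round trip
#' with [solve_free_ca()] is the identity.
#'
#' @param recipe A [solution_recipe()]; its `total_ca` field is ignored.
#' @param target_pca Desired pCa of the solution.
#' @return Total calcium, molar.
#' @examples
#' r <- solution_recipe(total_ca = 0)
#' tca <- total_ca_for_target_pca(r, 6.0)
#' @export
total_ca_for_target_pca <- function(recipe, target_pca) {
  stopifnot(inherits(recipe, "solution_recipe"))
  target <- free_ca_from_pca(target_pca)
  with_total <- function(tca) {
    r2 <- recipe
    r2$total_ca <- tca
    solve_free_ca(r2)$free_ca
  }
  hi <- 0.1
  if (with_total(hi) < target) {
    stop(sprintf("target pCa %.3f not achievable with total Ca <= 0.1 M",
                 target_pca), call. = FALSE)
  }
  lo <- 0
  mid <- hi / 2
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    err <- with_total(mid) - target
    if (abs(err) < 1e-15 * max(target, 1e-12)) break
    if (err > 0) hi <- mid else lo <- mid
  }
  if (abs(with_total(mid) - target) >= 1e-12) {
    stop("total-calcium bisection did not reach the target free calcium",
         call. = FALSE)
  }
  mid
}
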