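# Synthetic trabecula experiments.
#
# The generator emulates the statistical structure of the length-dependent
# activation study: per-preparation Hill-shaped pCa dependence of force and
# <P2>, probed at two sarcomere lengths (1.9 and 2.3 um) with an optional
# myosin-inhibitor (blebbistatin) condition; troponin C probes (C and E
# helices) lose orientation order on activation (negative delta <P2>),
# the myosin light-chain probe gains it; longer sarcomeres are better
# aligned (weaker disorder attenuation) and produce ~40% more force and a
# ~0.11-0.12 pCa-unit gain in calcium sensitivity.

PCA_GRID <- c(9.0, 6.6, 6.0, 5.8, 5.6, 5.5, 5.4, 5.2, 5.0, 4.5)

#' Default condition-effect table for the generator
#'
#' Returns the generating "truth" of the synthetic world.  Per probe it
#' stores the Hill parameters of the `<P2>` and force titrations OBSERVED at
#' sarcomere length 1.9 um in control (so they can be read directly against
#' published-style summary tables); the generator divides out the 1.9-um
#' alignment attenuation to obtain the underlying dipole curve and
#' re-attenuates per sarcomere length.  Effects:
#'
#' * `sl_pca50_shift_p2` / `sl_pca50_shift_force` — additive pCa50 gain at
#'   SL 2.3 um (+0.11 / +0.12 pCa units).
#' * `sl_force_factor` — multiplicative gain of maximum force at 2.3 um
#'   (1.4).
#' * `bleb_pca50_shift` — pCa50 drop under blebbistatin (-0.08).
#' * `bleb_nh_factor` — Hill-coefficient reduction under blebbistatin
#'   (0.83, e.g. 3.29 to about 2.7).
#' * `bleb_force_fraction` — residual force under blebbistatin (0.015 of
#'   control).
#' * `alignment_d2`, `alignment_d4` — disorder attenuation factors per
#'   sarcomere length, closer to 1 at 2.3 um.
#'
#' The troponin probes use published-style values (pCa50 about 5.34-5.37,
#' Hill coefficient 3.3-4.1, `<P2>` falling from about 0.28 to 0.18 for the
#' E helix and 0.11 to 0.03 for the C helix, maximum force about 23 kPa);
#' the light-chain probe, for which no table values exist, uses a plausible
#' positive-going curve.
#'
#' @return A list of class `condition_effects`.
#' @export
condition_effects <- function() {
  probes <- list(
    "cTnC-C" = list(
      p2 = list(pca50 = 5.37, n_h = 3.28, baseline = 0.108,
                amplitude = -0.080),
      force = list(pca50 = 5.37, n_h = 4.03, fmax = 22.7)
    ),
    "cTnC-E" = list(
      p2 = list(pca50 = 5.34, n_h = 3.59, baseline = 0.283,
                amplitude = -0.101),
      force = list(pca50 = 5.37, n_h = 4.12, fmax = 23.2)
    ),
    "cRLC-BC" = list(
      p2 = list(pca50 = 5.40, n_h = 3.0, baseline = 0.040,
                amplitude = +0.060),
      force = list(pca50 = 5.38, n_h = 4.0, fmax = 23.0)
    )
  )
  structure(list(
    probes = probes,
    sl_pca50_shift_p2 = 0.11,
    sl_pca50_shift_force = 0.12,
    sl_force_factor = 1.4,
    bleb_pca50_shift = -0.08,
    bleb_nh_factor = 0.83,
    bleb_force_fraction = 0.015,
    alignment_d2 = c("1.9" = 0.85, "2.3" = 0.93),
    alignment_d4 = c("1.9" = 0.72, "2.3" = 0.86),
    pca_grid = PCA_GRID
  ), class = "condition_effects")
}

#' Measurement-noise model for the generator
#'
#' Multiplicative Gaussian noise on each intensity component and on force,
#' plus per-preparation random offsets that make the paired design
#' informative: each trabecula carries its own pCa50 offset (shared across
#' its conditions) and its own baseline `<P2>` offset.  Defaults are
#' calibrated so cohort SEMs at n = 5-7 land near published-style tables.
#'
#' @param intensity_cv Coefficient of variation of each intensity (0.02).
#' @param force_cv Coefficient of variation of force (0.03).
#' @param pca50_sd SD of the per-trabecula pCa50 offset (0.05 pCa units).
#' @param baseline_p2_sd SD of the per-trabecula baseline `<P2>` offset
#'   (0.01).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(intensity_cv = 0.02, force_cv = 0.03,
                        pca50_sd = 0.05, baseline_p2_sd = 0.01) {
  v <- c(intensity_cv, force_cv, pca50_sd, baseline_p2_sd)
  if (any(v < 0)) stop("noise parameters must be >= 0", call. = FALSE)
  structure(list(intensity_cv = intensity_cv, force_cv = force_cv,
                 pca50_sd = pca50_sd, baseline_p2_sd = baseline_p2_sd),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_free <- function() noise_model(0, 0, 0, 0)

# condition-specific Hill parameters (observed scale, i.e. post-attenuation
# at that SL) for one trabecula
condition_truth <- function(probe, sl, treatment, effects, off_pca50,
                            off_base) {
  pr <- effects$probes[[probe]]
  if (is.null(pr)) stop("unknown probe: ", probe, call. = FALSE)
  slk <- sprintf("%.1f", sl)
  d2 <- effects$alignment_d2[[slk]]
  d4 <- effects$alignment_d4[[slk]]
  if (is.null(d2) || is.null(d4)) {
    stop("no alignment factors for SL ", slk, call. = FALSE)
  }
  d2_ref <- effects$alignment_d2[["1.9"]]

  p2 <- pr$p2
  p2$pca50 <- p2$pca50 + off_pca50
  p2$baseline <- p2$baseline + off_base
  # underlying (pre-attenuation) dipole curve, then re-attenuate per SL
  under_base <- p2$baseline / d2_ref
  under_amp <- p2$amplitude / d2_ref
  p2_obs <- list(pca50 = p2$pca50, n_h = p2$n_h,
                 baseline = under_base * d2, amplitude = under_amp * d2)

  force <- pr$force
  force$pca50 <- force$pca50 + off_pca50
  fmax <- force$fmax
  if (sl == 2.3) {
    p2_obs$pca50 <- p2_obs$pca50 + effects$sl_pca50_shift_p2
    force$pca50 <- force$pca50 + effects$sl_pca50_shift_force
    fmax <- fmax * effects$sl_force_factor
  }
  if (treatment == "blebbistatin") {
    p2_obs$pca50 <- p2_obs$pca50 + effects$bleb_pca50_shift
    force$pca50 <- force$pca50 + effects$bleb_pca50_shift
    p2_obs$n_h <- p2_obs$n_h * effects$bleb_nh_factor
    force$n_h <- force$n_h * effects$bleb_nh_factor
    fmax <- fmax * effects$bleb_force_fraction
  }
  list(p2 = p2_obs,
       force = list(pca50 = force$pca50, n_h = force$n_h, baseline = 0,
                    amplitude = fmax),
       d2 = d2, d4 = d4, d2_ref = d2_ref)
}

# delta-closure companion: p4 of a delta distribution with the same p2
companion_p4 <- function(p2) {
  m2 <- (2 * p2 + 1) / 3
  m4 <- m2^2
  (35 * m4 - 30 * m2 + 3) / 8
}

#' Simulate one trabecula across the condition grid
#'
#' For every requested (sarcomere length, treatment) condition and every pCa
#' on the grid, the generator evaluates the trabecula's true `<P2>` from its
#' Hill curve, forms the companion `<P4>` by the delta-function-at-mean-angle
#' closure, attenuates both by the sarcomere length's alignment factors
#' relative to the 1.9-um reference, runs the forward optical model, and
#' applies multiplicative intensity noise; force is generated analogously.
#' Fully deterministic given `seed`.
#'
#' @param trabecula_id Identifier string.
#' @param probe `"cTnC-C"`, `"cTnC-E"` or `"cRLC-BC"`.
#' @param effects A [condition_effects()] table.
#' @param noise A [noise_model()].
#' @param seed Integer seed (required; the generator is seeded locally and
#'   restores the caller's RNG state).
#' @param sls Sarcomere lengths to include (default both 1.9 and 2.3 um).
#' @param treatments Treatments to include (default control only; add
#'   `"blebbistatin"` for the inhibitor arm).
#' @param scale Overall fluorescence brightness (arbitrary units).
#' @return List with `records` (data frame, one row per measurement:
#'   `trabecula_id`, `probe`, `sl_um`, `pca`, `treatment`, `i_pp`, `i_pt`,
#'   `i_tp`, `i_tt`, `force`, `seed_provenance`) and `truth` (data frame of
#'   the observed-scale generating Hill parameters and activation deltas
#'   per condition and response kind, including the closure/attenuation
#'   metadata columns `d2`, `d4`).
#' @export
generate_trabecula <- function(trabecula_id, probe, effects = condition_effects(),
                               noise = noise_model(), seed,
                               sls = c(1.9, 2.3), treatments = "control",
                               scale = 100) {
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  stopifnot(inherits(effects, "condition_effects"),
            inherits(noise, "noise_model"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  off_pca50 <- stats::rnorm(1, 0, noise$pca50_sd)
  off_base <- stats::rnorm(1, 0, noise$baseline_p2_sd)

  rec_rows <- list()
  truth_rows <- list()
  for (sl in sls) {
    for (tr in treatments) {
      tt <- condition_truth(probe, sl, tr, effects, off_pca50, off_base)
      for (pca in effects$pca_grid) {
        p2_true <- hill_eval(tt$p2, pca)
        # build the underlying dipole pair, then attenuate to this SL
        p2_under <- p2_true / tt$d2
        ops <- order_params(p2_under, companion_p4(p2_under))
        ops_att <- apply_attenuation(ops, tt$d2, tt$d4)
        ints <- forward_intensities(ops_att, scale = scale)
        jitter <- 1 + stats::rnorm(4, 0, noise$intensity_cv)
        f_true <- hill_eval(tt$force, pca)
        f_obs <- f_true * (1 + stats::rnorm(1, 0, noise$force_cv))
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          trabecula_id = trabecula_id, probe = probe, sl_um = sl,
          pca = pca, treatment = tr,
          i_pp = max(ints$i_pp * jitter[1], 0),
          i_pt = max(ints$i_pt * jitter[2], 0),
          i_tp = max(ints$i_tp * jitter[3], 0),
          i_tt = max(ints$i_tt * jitter[4], 0),
          force = f_obs,
          seed_provenance = as.integer(seed),
          stringsAsFactors = FALSE)
      }
      for (kind in c("p2", "force")) {
        par <- tt[[kind]]
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          trabecula_id = trabecula_id, probe = probe, sl_um = sl,
          treatment = tr, response_kind = kind,
          pca50 = par$pca50, n_h = par$n_h, baseline = par$baseline,
          amplitude = par$amplitude,
          delta = hill_eval(par, 4.5) - hill_eval(par, 6.0),
          d2 = tt$d2, d4 = tt$d4,
          p4_closure = "delta_at_mean_angle",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rec_rows),
       truth = do.call(rbind, truth_rows))
}

#' Simulate a cohort of trabeculae
#'
#' Draws per-trabecula seeds reproducibly from `master_seed` and
#' concatenates the per-trabecula records, emitting a ground-truth sidecar
#' for parameter-recovery scoring.
#'
#' @param n_trabeculae Number of preparations (>= 2); the study used 5-7
#'   per group.
#' @param probe Probe label (one cohort is labelled with one probe, as in
#'   the experiments).
#' @param effects,noise,sls,treatments,scale Passed to
#'   [generate_trabecula()].
#' @param master_seed Integer master seed.
#' @return List with `records` and `truth` data frames spanning the cohort.
#' @export
generate_cohort <- function(n_trabeculae, probe = "cTnC-C",
                            effects = condition_effects(),
                            noise = noise_model(), master_seed,
                            sls = c(1.9, 2.3), treatments = "control",
                            scale = 100) {
  if (missing(master_seed)) stop("an explicit master_seed is required",
                                 call. = FALSE)
  if (n_trabeculae < 2L) stop("a cohort needs n >= 2", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n_trabeculae)
  parts <- lapply(seq_len(n_trabeculae), function(i) {
    generate_trabecula(sprintf("T%02d", i), probe, effects, noise,
                       seed = seeds[i], sls = sls,
                       treatments = treatments, scale = scale)
  })
  list(records = do.call(rbind, lapply(parts, `[[`, "records")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}
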