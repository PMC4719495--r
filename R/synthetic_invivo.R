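# Synthetic stand-in for the in vivo epicardial recordings: hierarchical
# activation-recovery-interval (ARI) samples with rate dependence and
# patient/site spread, calibration envelopes derived from them, and toy
# unipolar electrograms exercising the derivative-rule ARI extractor.
#
# Everything here is a labelled synthetic emulation: the generator reproduces
# the structure of multi-electrode sock recordings (ARIs decreasing with
# cycle length, between-patient and between-site variability, a minority of
# alternans-susceptible sites), not any patient's data.

#' Generator settings for the synthetic ARI study
#'
#' The mean ARI curve is linear in cycle length and anchored so that the
#' baseline epicardial model's APDs fall inside the generated envelopes at
#' every protocol cycle length. Spreads are chosen at the scale typical of
#' epicardial sock recordings.
#'
#' @param ari_intercept,ari_slope Mean ARI (ms) = intercept + slope * CL.
#' @param patient_sd Between-patient SD (ms).
#' @param site_sd Between-site (within patient) SD (ms).
#' @param noise_sd Per-beat measurement noise SD (ms).
#' @param alternans_fraction Fraction of sites with period-2 ARI sequences.
#' @param alternans_amp_range Range (ms) of site alternans magnitudes.
#' @param n_beats Beats recorded per site and cycle length.
#' @param activation_latency Stimulus-to-activation delay (ms).
#' @return Named list of generator parameters.
#' @export
ari_study_params <- function(ari_intercept = 113, ari_slope = 0.22,
                             patient_sd = 18, site_sd = 15, noise_sd = 4,
                             alternans_fraction = 0.1,
                             alternans_amp_range = c(5, 25),
                             n_beats = 8, activation_latency = 20) {
  list(ari_intercept = ari_intercept, ari_slope = ari_slope,
       patient_sd = patient_sd, site_sd = site_sd, noise_sd = noise_sd,
       alternans_fraction = alternans_fraction,
       alternans_amp_range = alternans_amp_range,
       n_beats = n_beats, activation_latency = activation_latency)
}

#' Generate a synthetic in vivo ARI study
#'
#' Hierarchical model: ARI(patient, site, CL, beat) = mean curve + patient
#' effect + site effect + beat noise, with a fraction of sites carrying
#' period-2 (alternating) ARI sequences below a site-specific onset cycle
#' length. Calibration envelopes are the per-CL min/max of the normal-site
#' ARIs.
#'
#' @param cl_list Cycle lengths (ms), descending.
#' @param n_sites Electrode sites per patient.
#' @param n_patients Number of patients.
#' @param params Generator settings from [ari_study_params()].
#' @param seed Integer seed; fixed seed gives a bit-identical study.
#' @return List of class `ari_study`: `samples` (patient, site, cl, beat,
#'   ari, alternans_site), `ranges` (cl, lower, upper; normal sites only),
#'   `params`, `seed`.
#' @export
generate_ari_study <- function(cl_list = c(600, 550, 500, 450, 400, 350),
                               n_sites = 240, n_patients = 41,
                               params = ari_study_params(), seed = 1) {
  stopifnot(all(diff(cl_list) < 0))
  set.seed(seed)
  p <- params
  mean_curve <- p$ari_intercept + p$ari_slope * cl_list
  if (any(diff(mean_curve[order(cl_list)]) <= 0))
    stop("mean ARI must strictly decrease with decreasing cycle length")
  pat_eff <- stats::rnorm(n_patients, 0, p$patient_sd)
  rows <- vector("list", n_patients)
  for (pt in seq_len(n_patients)) {
    site_eff <- stats::rnorm(n_sites, 0, p$site_sd)
    alt_site <- stats::runif(n_sites) < p$alternans_fraction
    alt_amp <- stats::runif(n_sites, p$alternans_amp_range[1],
                            p$alternans_amp_range[2])
    alt_onset <- sample(cl_list[cl_list <= 500], n_sites, replace = TRUE)
    g <- expand.grid(beat = seq_len(p$n_beats), cl = cl_list,
                     site = seq_len(n_sites))
    base <- p$ari_intercept + p$ari_slope * g$cl + pat_eff[pt] +
      site_eff[g$site]
    alt_now <- alt_site[g$site] & g$cl <= alt_onset[g$site]
    phase <- ifelse(g$beat %% 2 == 0, 0.5, -0.5)
    ari <- base + ifelse(alt_now, alt_amp[g$site] * phase, 0) +
      stats::rnorm(nrow(g), 0, p$noise_sd)
    ari <- pmin(ari, g$cl - 5)  # repolarization completes before next beat
    rows[[pt]] <- data.frame(patient = pt, site = g$site, cl = g$cl,
                             beat = g$beat, ari = ari,
                             alternans_site = alt_site[g$site])
  }
  samples <- do.call(rbind, rows)
  norm <- samples[!samples$alternans_site, ]
  ranges <- do.call(rbind, lapply(split(norm, norm$cl), function(x)
    data.frame(cl = x$cl[1], lower = min(x$ari), upper = max(x$ari))))
  ranges <- ranges[order(-ranges$cl), ]
  rownames(ranges) <- NULL
  structure(list(samples = samples, ranges = ranges, params = p, seed = seed),
            class = "ari_study")
}

#' @export
print.ari_study <- function(x, ...) {
  cat(sprintf("synthetic ARI study: %d patients x %d sites, %d CLs\n",
              length(unique(x$samples$patient)),
              length(unique(x$samples$site)),
              length(unique(x$samples$cl))))
  print(round(x$ranges, 1))
  invisible(x)
}

#' Synthesize a toy unipolar electrogram
#'
#' Builds one electrogram as the sum of a biphasic depolarization wavelet
#' (steepest negative slope exactly at the encoded activation time) and a
#' Gaussian T wave whose steepest positive slope falls exactly at activation
#' + ARI. This is a test fixture for the ARI extractor, not a physiological
#' forward model.
#'
#' @param ari_sequence Per-beat ARIs (ms), each < cl.
#' @param cl Pacing cycle length (ms).
#' @param noise_sd Additive white noise SD (signal units; depolarization
#'   amplitude is 1).
#' @param seed Seed for the noise.
#' @param sample_dt Sampling interval (ms), at most 1.
#' @param activation_latency Stimulus-to-activation delay (ms).
#' @return List of class `synthetic_egm`: `signal` (data.frame t, v),
#'   `stim_times`, `truth` (beat, t_act, t_rec, ari), `cl`.
#' @export
synth_electrogram <- function(ari_sequence, cl, noise_sd = 0, seed = 1,
                              sample_dt = 1, activation_latency = 20) {
  stopifnot(all(ari_sequence < cl), sample_dt <= 1)
  set.seed(seed)
  n <- length(ari_sequence)
  t <- seq(0, n * cl, by = sample_dt)
  v <- numeric(length(t))
  sig_d <- 6      # depolarization wavelet envelope width (ms)
  sig_t <- 18     # T-wave width (ms)
  stim <- (seq_len(n) - 1) * cl
  t_act <- stim + activation_latency
  t_rec <- t_act + ari_sequence
  for (b in seq_len(n)) {
    # compact biphasic deflection: steepest negative slope exactly at t_act,
    # envelope confined within the activation latency so that no flank leaks
    # into the preceding beat's repolarization window
    dep <- -tanh((t - t_act[b]) / (sig_d / 2)) *
      exp(-(t - t_act[b])^2 / (2 * sig_d^2))
    tc <- t_rec[b] + sig_t   # Gaussian peak one SD after recovery time
    twave <- 0.35 * exp(-(t - tc)^2 / (2 * sig_t^2))
    v <- v + dep + twave
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  structure(list(signal = data.frame(t = t, v = v), stim_times = stim,
                 truth = data.frame(beat = seq_len(n), t_act = t_act,
                                    t_rec = t_rec, ari = ari_sequence),
                 cl = cl),
            class = "synthetic_egm")
}

#' Extract per-beat ARIs from a unipolar electrogram
#'
#' Derivative rule: activation is the time of minimum dV/dt in the
#' depolarization window after each stimulus, recovery the time of maximum
#' dV/dt in the repolarization window, and ARI their difference.
#'
#' @param egm A `synthetic_egm`, or a data.frame with columns `t` and `v`.
#' @param stimulus_times Stimulus onsets (ms); taken from the object when a
#'   `synthetic_egm` is given.
#' @param depol_window Window after each stimulus searched for the activation
#'   deflection (ms).
#' @param repol_start Start of the repolarization window after the stimulus
#'   (ms); the window ends at the next stimulus.
#' @param min_slope Minimum |dV/dt| (per ms) for a deflection to count;
#'   beats without one are flagged unmeasurable (NA).
#' @param smooth_ms Width (ms) of the symmetric moving-average filter applied
#'   before differentiation; 0 disables. Smoothing is standard practice for
#'   derivative-based fiducial detection on noisy electrograms; a symmetric
#'   window leaves the extremum locations of (anti)symmetric deflections
#'   unchanged.
#' @return data.frame: beat, t_act, t_rec, ari, measurable.
#' @export
ari_extract <- function(egm, stimulus_times = NULL, depol_window = 80,
                        repol_start = 100, min_slope = 1e-3,
                        smooth_ms = 12) {
  if (inherits(egm, "synthetic_egm")) {
    if (is.null(stimulus_times)) stimulus_times <- egm$stim_times
    sig <- egm$signal
  } else sig <- egm
  stopifnot(is.data.frame(sig), all(c("t", "v") %in% names(sig)),
            length(stimulus_times) >= 1)
  dtv <- diff(sig$t)
  if (max(dtv) > 1 + 1e-9) stop("electrogram must be sampled at 1 ms or finer")
  v <- sig$v
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / stats::median(dtv)))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1) {
      vs <- stats::filter(v, rep(1 / w, w), sides = 2)
      v <- ifelse(is.na(vs), v, as.numeric(vs))  # keep raw values at edges
    }
  }
  slope <- diff(v) / dtv
  tm <- (utils::head(sig$t, -1) + sig$t[-1]) / 2
  n <- length(stimulus_times)
  ends <- c(stimulus_times[-1], max(sig$t))
  out <- data.frame(beat = seq_len(n), t_act = NA_real_, t_rec = NA_real_,
                    ari = NA_real_, measurable = FALSE)
  for (b in seq_len(n)) {
    s0 <- stimulus_times[b]
    idep <- which(tm >= s0 & tm <= s0 + depol_window)
    # keep the filter half-width clear of the next activation deflection
    irep <- which(tm >= s0 + repol_start & tm < ends[b] - smooth_ms)
    if (!length(idep) || !length(irep)) next
    iact <- idep[which.min(slope[idep])]
    irec <- irep[which.max(slope[irep])]
    if (-slope[iact] < min_slope || slope[irec] < min_slope) next
    out$t_act[b] <- tm[iact]
    out$t_rec[b] <- tm[irec]
    out$ari[b] <- tm[irec] - tm[iact]
    out$measurable[b] <- TRUE
  }
  out
}
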