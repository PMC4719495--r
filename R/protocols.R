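# Pacing, dynamic restitution and action potential clamp protocols.

#' Steady-state pacing protocol description
#'
#' @param cl_list Ordered cycle lengths in ms, paced in the given order
#'   (default 600 to 350 ms in 50 ms steps, the in vivo protocol range).
#'   A 200 ms extension can be appended to probe whether open (Fork-type)
#'   restitution bifurcations stay open at very fast rates.
#' @param n_prebeats Unrecorded conditioning beats per cycle length; either a
#'   single count or one per cycle length. With carry-over the first cycle
#'   length does most of the conditioning work.
#' @param n_record Recorded steady-state beats per cycle length (>= 4, even,
#'   so odd/even beat averages are balanced during alternans).
#' @param carryover Logical; carry the final state from one cycle length to
#'   the next (mimics the in vivo step protocol) instead of re-initializing.
#' @return List of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cl_list = c(600, 550, 500, 450, 400, 350),
                            n_prebeats = 500, n_record = 8,
                            carryover = TRUE) {
  stopifnot(length(cl_list) >= 1, all(cl_list >= 200),
            n_record >= 4, n_record %% 2 == 0, all(n_prebeats >= 0))
  if (length(n_prebeats) == 1)
    n_prebeats <- rep(n_prebeats, length(cl_list))
  if (length(n_prebeats) != length(cl_list))
    stop("n_prebeats must have length 1 or length(cl_list)")
  structure(list(cl_list = as.numeric(cl_list),
                 n_prebeats = as.integer(n_prebeats),
                 n_record = as.integer(n_record),
                 carryover = isTRUE(carryover)),
            class = "pacing_protocol")
}

.beats_df <- function(mat) {
  df <- as.data.frame(mat)
  df$captured <- df$captured > 0
  # engine integrates balances in mM (cytosol); report umol/L per beat
  for (col in c("srcb", "scb", "jrel_int", "ical_influx"))
    df[[col]] <- 1000 * df[[col]]
  df
}

#' Pace a model at a fixed cycle length
#'
#' Runs `n_prebeats` unrecorded conditioning beats followed by `n_record`
#' recorded beats and returns the recorded traces, per-beat summaries and the
#' final state (for carry-over).
#'
#' @param spec Model specification from [build_model()].
#' @param cl Cycle length in ms (>= 200, multiple of the sampling interval).
#' @param n_prebeats Conditioning beats (>= 0).
#' @param n_record Recorded beats (>= 0; 0 returns the final state only).
#' @param initial_state Starting state (default [ord_initial_state()]).
#' @return A `beat_series`: list with `trace` (data.frame sampled every
#'   `spec$sample_dt` ms; columns include t, v, cai, cass, cajsr, cansr, the
#'   cytosol-referenced SR fluxes jrel/jup and every sarcolemmal current),
#'   `beats` (one row per recorded beat: fiducial stimulus time, RMP, peak
#'   voltage, interpolated APD90/APD40, CaT extrema, per-beat SR and
#'   sarcolemmal Ca balance integrals, capture flag), `state`, `cl`, `spec`.
#' @export
pace <- function(spec, cl, n_prebeats = 500, n_record = 8,
                 initial_state = NULL) {
  stopifnot(inherits(spec, "ord_model_spec"), cl >= 200)
  if (is.null(initial_state)) initial_state <- ord_initial_state()
  n_beats <- n_prebeats + n_record
  if (n_beats == 0)
    return(structure(list(trace = NULL, beats = NULL,
                          state = initial_state, cl = cl, spec = spec),
                     class = "beat_series"))
  r <- pace_cpp(unclass(spec$scaling), unclass(spec$kinetics),
                unname(initial_state), cl, n_beats, n_prebeats,
                spec$stim_amp, spec$stim_dur, spec$dt_fine, spec$dt_coarse,
                spec$sample_dt, spec$fine_win, spec$dvdt_thresh)
  if (isTRUE(r$failed))
    stop(sprintf("integration failed (non-finite state) at beat %d, CL %g ms",
                 r$fail_beat, cl))
  state <- stats::setNames(r$state, ord_state_names())
  beats <- .beats_df(r$beats)
  trace <- if (nrow(r$trace)) as.data.frame(r$trace) else NULL
  structure(list(trace = trace,
                 beats = beats[beats$beat > n_prebeats, , drop = FALSE],
                 all_beats = beats, state = state, cl = cl, spec = spec),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  nb <- if (is.null(x$beats)) 0 else nrow(x$beats)
  cat(sprintf("beat_series: %d recorded beat(s) at CL %g ms\n", nb, x$cl))
  if (nb) {
    cat(sprintf("  APD90: %s ms\n",
                paste(sprintf("%.1f", x$beats$apd90), collapse = ", ")))
  }
  invisible(x)
}

#' Capture check for one beat
#'
#' A beat is captured when the membrane potential exceeds 0 mV within 50 ms
#' of stimulus onset. Beats paced into refractory tissue (2:1 block at very
#' short cycle lengths) fail this check.
#'
#' @param beat Either one row of a `beat_series$beats` table or a single-beat
#'   trace data.frame with columns `t` and `v` (t relative to stimulus onset
#'   or absolute with the beat's own origin at its first sample).
#' @return Logical flag.
#' @export
check_capture <- function(beat) {
  if (is.data.frame(beat) && all(c("t", "v") %in% names(beat))) {
    t0 <- beat$t[1]
    win <- beat$v[beat$t - t0 <= 50]
    return(max(win) > 0)
  }
  if (!is.null(beat$peak_v_early)) return(beat$peak_v_early > 0)
  stop("beat must be a trace data.frame or a per-beat summary row")
}

#' Dynamic (steady-state) restitution of one model
#'
#' Paces the model through the protocol's cycle lengths (long to short, with
#' optional state carry-over), and summarizes each cycle length by its
#' steady-state odd/even APDs, alternans magnitudes, diastolic interval and
#' capture status, together with per-beat calcium-balance integrals.
#'
#' @param spec Model specification from [build_model()].
#' @param protocol A [pacing_protocol()].
#' @param initial_state Starting state (default [ord_initial_state()]).
#' @param keep_traces Keep the recorded voltage/calcium traces of every cycle
#'   length (memory-heavy; off by default).
#' @param biomarkers Compute trace-based AP/CaT biomarkers per cycle length.
#' @return A `restitution_result`: list with `per_cl` (one row per cycle
#'   length: apd_odd, apd_even, dapd, dcat, mean_di, captured), `beats`
#'   (per-beat detail incl. srcb/scb), optionally `biomarkers` and `traces`,
#'   and the final `state`.
#' @export
run_restitution <- function(spec, protocol = pacing_protocol(),
                            initial_state = NULL, keep_traces = FALSE,
                            biomarkers = FALSE) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  state <- if (is.null(initial_state)) ord_initial_state() else initial_state
  per_cl <- vector("list", length(protocol$cl_list))
  beats_all <- vector("list", length(protocol$cl_list))
  traces <- if (keep_traces) vector("list", length(protocol$cl_list)) else NULL
  bios <- if (biomarkers) vector("list", length(protocol$cl_list)) else NULL
  for (i in seq_along(protocol$cl_list)) {
    cl <- protocol$cl_list[i]
    bs <- pace(spec, cl, protocol$n_prebeats[i], protocol$n_record,
               initial_state = state)
    if (protocol$carryover) state <- bs$state
    b <- bs$beats
    b$cl <- cl
    beats_all[[i]] <- b
    per_cl[[i]] <- .summarize_cl(b, cl)
    if (keep_traces) traces[[i]] <- bs$trace
    if (biomarkers) {
      bio <- series_biomarkers(bs)
      bio$cl <- cl
      bios[[i]] <- bio
    }
  }
  out <- list(per_cl = do.call(rbind, per_cl),
              beats = do.call(rbind, beats_all),
              state = state, protocol = protocol, spec = spec)
  if (keep_traces) {
    names(traces) <- protocol$cl_list
    out$traces <- traces
  }
  if (biomarkers) out$biomarkers <- do.call(rbind, bios)
  structure(out, class = "restitution_result")
}

# per-CL summary row from the recorded-beat table
.summarize_cl <- function(b, cl) {
  captured <- all(b$captured) && all(is.finite(b$apd90))
  if (captured) {
    apd <- b$apd90
    camp <- b$cat_max - b$cat_min
    odd <- seq(1, nrow(b), by = 2)
    even <- seq(2, nrow(b), by = 2)
    dapd <- mean(abs(diff(apd)))
    dcat <- mean(abs(diff(camp)))
    mean_di <- mean(cl - apd[-length(apd)])
    data.frame(cl = cl, apd_odd = mean(apd[odd]), apd_even = mean(apd[even]),
               dapd = dapd, dcat = dcat, mean_catamp = mean(camp),
               mean_di = mean_di, captured = TRUE)
  } else {
    data.frame(cl = cl, apd_odd = NA_real_, apd_even = NA_real_,
               dapd = NA_real_, dcat = NA_real_, mean_catamp = NA_real_,
               mean_di = NA_real_, captured = FALSE)
  }
}

#' @export
print.restitution_result <- function(x, ...) {
  cat("restitution_result\n")
  print(round(x$per_cl[, c("cl", "apd_odd", "apd_even", "dapd", "dcat",
                           "mean_di")], 3))
  invisible(x)
}

#' Action potential clamp
#'
#' Forces the membrane potential to a periodic command waveform while all
#' gates and concentrations evolve freely; used to test whether calcium
#' alternans persist when APD alternans are abolished (two identical long or
#' two identical short beats).
#'
#' @param spec Model specification.
#' @param vm_waveform Command waveform: data.frame with columns `t` (ms, from
#'   0 to one cycle length) and `v` (mV), sampled at 1 ms or finer.
#' @param n_beats Number of clamped beats to run.
#' @param initial_state Starting state.
#' @param n_record How many final beats to record (default all).
#' @return A `beat_series` (APD fields are undefined under clamp).
#' @export
ap_clamp <- function(spec, vm_waveform, n_beats, initial_state = NULL,
                     n_record = n_beats) {
  stopifnot(inherits(spec, "ord_model_spec"),
            is.data.frame(vm_waveform), all(c("t", "v") %in% names(vm_waveform)))
  if (is.null(initial_state)) initial_state <- ord_initial_state()
  tw <- vm_waveform$t
  if (max(diff(tw)) > 1 + 1e-9)
    stop("clamp waveform must be sampled at 1 ms or finer")
  cl <- max(tw)
  spb <- round(cl / spec$sample_dt)
  if (abs(spb * spec$sample_dt - cl) > 1e-9)
    stop("waveform period must be a multiple of the sampling interval")
  grid <- (seq_len(spb) - 1) * spec$sample_dt
  wf <- stats::approx(tw, vm_waveform$v, xout = grid, rule = 2)$y
  r <- clamp_cpp(unclass(spec$scaling), unclass(spec$kinetics),
                 unname(initial_state), wf, cl, n_beats,
                 n_beats - n_record, spec$dt_fine, spec$dt_coarse,
                 spec$sample_dt, spec$fine_win, spec$dvdt_thresh)
  if (isTRUE(r$failed))
    stop(sprintf("clamped integration failed at beat %d", r$fail_beat))
  beats <- .beats_df(r$beats)
  structure(list(trace = if (nrow(r$trace)) as.data.frame(r$trace) else NULL,
                 beats = beats[beats$beat > n_beats - n_record, , drop = FALSE],
                 all_beats = beats,
                 state = stats::setNames(r$state, ord_state_names()),
                 cl = cl, spec = spec),
            class = "beat_series")
}

#' Extract one beat's steady-state AP waveform for clamping
#'
#' @param series A `beat_series` with traces.
#' @param beat Which recorded beat to extract.
#' @return data.frame with `t` (0..CL) and `v`, suitable for [ap_clamp()].
#' @export
clamp_waveform <- function(series, beat = nrow(series$beats)) {
  stopifnot(inherits(series, "beat_series"), !is.null(series$trace))
  bno <- series$beats$beat[beat]
  tr <- series$trace[series$trace$beat == bno, ]
  data.frame(t = tr$t - tr$t[1], v = tr$v)
}
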