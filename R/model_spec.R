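# Parameter and kinetics scaling containers, and the model specification
# object consumed by the pacing protocols.

#' Names of the varied conductance/permeability scaling factors
#' @return Character vector of length 11.
#' @export
scaling_names <- function() {
  c("s_GNa", "s_GNaL", "s_Gto", "s_GCaL", "s_GKr", "s_GKs", "s_GK1",
    "s_GNaCa", "s_GNaK", "s_PJrel", "s_PJup")
}

#' Multiplicative scaling of ionic conductances and permeabilities
#'
#' Eleven dimensionless factors applied to the maximal conductances and
#' permeabilities of the epicardial cell model: fast and late Na+ current,
#' transient outward K+ current, L-type Ca2+ channel permeability, rapid and
#' slow delayed rectifiers, inward rectifier, Na+/Ca2+ exchanger, Na+/K+ pump,
#' RyR release permeability and SERCA uptake permeability. A factor of 1 for
#' every parameter reproduces the original model; the population design varies
#' each factor over [0, 2] (plus/minus 100 percent).
#'
#' @param ... Named factors among [scaling_names()]; unnamed defaults are 1.
#' @param .values Optional named numeric vector/list overriding `...`.
#' @return Named numeric vector of class `parameter_scaling`.
#' @examples
#' parameter_scaling()                  # baseline model
#' parameter_scaling(s_PJrel = 1.8, s_PJup = 0.5)
#' @export
parameter_scaling <- function(..., .values = NULL) {
  out <- stats::setNames(rep(1, 11), scaling_names())
  vals <- if (is.null(.values)) list(...) else as.list(.values)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals))))
      stop("scaling factors must be named")
    bad <- setdiff(names(vals), scaling_names())
    if (length(bad))
      stop("unknown scaling factor(s): ", paste(bad, collapse = ", "))
    out[names(vals)] <- unlist(vals)
  }
  if (any(!is.finite(out)) || any(out < 0) || any(out > 2))
    stop("scaling factors must be finite and within [0, 2]")
  structure(out, class = "parameter_scaling")
}

#' Multiplicative scaling of L-type Ca2+ current time constants
#'
#' Three dimensionless multipliers on the I_CaL kinetics: `m_tau_d` scales the
#' activation time constant, `m_tau_f` the voltage-dependent inactivation time
#' constants (fast and slow, and their phosphorylated counterparts), and
#' `m_tau_j` the time constant of recovery from Ca2+-dependent inactivation.
#' Steady-state activation/inactivation curves are left unchanged. The
#' kinetics study varies each multiplier within [0.5, 1.5].
#'
#' @param m_tau_d,m_tau_f,m_tau_j Multipliers in [0.5, 1.5].
#' @return Named numeric vector of class `kinetics_scaling`.
#' @export
kinetics_scaling <- function(m_tau_d = 1, m_tau_f = 1, m_tau_j = 1) {
  out <- c(m_tau_d = m_tau_d, m_tau_f = m_tau_f, m_tau_j = m_tau_j)
  if (any(!is.finite(out)) || any(out < 0.5) || any(out > 1.5))
    stop("kinetics multipliers must be finite and within [0.5, 1.5]")
  structure(out, class = "kinetics_scaling")
}

#' Build an evaluatable cell model specification
#'
#' Combines conductance/permeability scaling and I_CaL kinetics scaling with
#' solver settings into the object every protocol consumes. The epicardial
#' variant of the human ventricular model is the only cell type provided.
#'
#' @param scaling A [parameter_scaling()] object (or named vector coercible).
#' @param kinetics A [kinetics_scaling()] object.
#' @param stim_amp Stimulus amplitude in A/F (negative = depolarizing).
#' @param stim_dur Stimulus duration in ms.
#' @param dt_fine,dt_coarse Integration steps (ms) used by the compiled
#'   fixed-step engine during fast (upstroke/stimulus) and slow phases.
#' @param sample_dt Output sampling interval in ms (must divide evenly into
#'   both stimulus duration and cycle lengths; 0.5 ms default).
#' @param fine_win Length (ms) of the post-stimulus window always integrated
#'   with the fine step; covers the upstroke and the SR release phase, where
#'   the calcium transient is most sensitive to step size.
#' @param dvdt_thresh |dVm/dt| (mV/ms) above which the fine step is used
#'   outside that window (steep repolarization, upstrokes of non-stimulated
#'   activity).
#' @return List of class `ord_model_spec`.
#' @export
build_model <- function(scaling = parameter_scaling(),
                        kinetics = kinetics_scaling(),
                        stim_amp = -80, stim_dur = 0.5,
                        dt_fine = 0.005, dt_coarse = 0.025,
                        sample_dt = 0.5, fine_win = 60, dvdt_thresh = 1) {
  if (!inherits(scaling, "parameter_scaling"))
    scaling <- parameter_scaling(.values = scaling)
  if (!inherits(kinetics, "kinetics_scaling"))
    kinetics <- do.call(kinetics_scaling, as.list(kinetics))
  stopifnot(stim_dur > 0, sample_dt > 0, sample_dt <= 1,
            dt_fine > 0, dt_coarse >= dt_fine)
  if (abs(sample_dt / dt_fine - round(sample_dt / dt_fine)) > 1e-9 ||
      abs(sample_dt / dt_coarse - round(sample_dt / dt_coarse)) > 1e-9)
    stop("dt_fine and dt_coarse must divide evenly into sample_dt")
  structure(list(scaling = scaling, kinetics = kinetics,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 dt_fine = dt_fine, dt_coarse = dt_coarse,
                 sample_dt = sample_dt, fine_win = fine_win,
                 dvdt_thresh = dvdt_thresh),
            class = "ord_model_spec")
}

#' @export
print.ord_model_spec <- function(x, ...) {
  cat("Human ventricular epicardial cell model (ORd equations)\n")
  sc <- unclass(x$scaling)
  varied <- sc[sc != 1]
  if (length(varied)) {
    cat("  scaled parameters:",
        paste(sprintf("%s=%.3g", names(varied), varied), collapse = ", "),
        "\n")
  } else cat("  baseline parameters (all scaling factors = 1)\n")
  kt <- unclass(x$kinetics)
  if (any(kt != 1))
    cat("  ICaL kinetics multipliers:",
        paste(sprintf("%s=%.3g", names(kt), kt), collapse = ", "), "\n")
  cat(sprintf("  stimulus %.3g A/F for %.3g ms; dt %.3g/%.3g ms; sampled every %.3g ms\n",
              x$stim_amp, x$stim_dur, x$dt_fine, x$dt_coarse, x$sample_dt))
  invisible(x)
}
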