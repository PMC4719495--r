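# Per-beat sarcoplasmic-reticulum calcium balance (SRCB) and sarcolemmal
# calcium balance (SCB), and their correlation with APD alternans magnitude.
#
# Unit convention: balances are reported in umol of Ca per litre of cytosol
# per beat. The engine accumulates the same integrals internally at full step
# resolution (columns srcb/scb of beat tables); the trace-based functions
# below compute them by trapezoidal quadrature from sampled traces and exist
# so that balances can be checked and computed on exported traces.

.trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + y[-1]) / 2)

# net sarcolemmal Ca gain rate in mM (cytosol)/ms from trace currents
.scb_rate <- function(tr) {
  k <- ord_constants()
  (-(tr$ical - 2 * tr$inaca_ss) - (tr$ipca + tr$icab - 2 * tr$inaca_i)) *
    k$Acap / (2 * k$F * k$vmyo)
}

#' SR calcium balance of one beat
#'
#' Integral over the beat window of SERCA uptake minus RyR release, expressed
#' per litre of cytosol. Zero at a non-alternating steady state; during
#' alternans, consecutive beats carry balances of similar magnitude and
#' opposite sign.
#'
#' @param trace Trace data.frame (see [pace()]) with cytosol-referenced flux
#'   columns `jrel` and `jup`.
#' @param beat_window Optional length-2 vector of times (ms) delimiting one
#'   beat (stimulus to next stimulus); defaults to the full trace, which must
#'   then hold exactly one beat.
#' @return SRCB in umol/L cytosol per beat.
#' @export
srcb_per_beat <- function(trace, beat_window = NULL) {
  tr <- .window(trace, beat_window)
  1000 * .trapz(tr$t, tr$jup - tr$jrel)
}

#' Sarcolemmal calcium balance of one beat
#'
#' Integral of the net calcium flux carried across the sarcolemma by the
#' L-type Ca current, background Ca current, sarcolemmal Ca pump and both
#' Na/Ca exchanger components (one Ca ion per exchanger cycle), converted
#' from A/F to molar flux via the capacitive membrane area, the Faraday
#' constant and the carried-charge stoichiometry, and referenced to cytosolic
#' volume. Positive values mean net cellular Ca gain.
#'
#' @inheritParams srcb_per_beat
#' @return SCB in umol/L cytosol per beat.
#' @export
scb_per_beat <- function(trace, beat_window = NULL) {
  need <- c("ical", "icab", "ipca", "inaca_i", "inaca_ss")
  if (!all(need %in% names(trace)))
    stop("trace is missing sarcolemmal Ca current column(s): ",
         paste(setdiff(need, names(trace)), collapse = ", "))
  tr <- .window(trace, beat_window)
  1000 * .trapz(tr$t, .scb_rate(tr))
}

.window <- function(trace, beat_window) {
  stopifnot(is.data.frame(trace), "t" %in% names(trace))
  if (is.null(beat_window)) return(trace)
  stopifnot(length(beat_window) == 2)
  if (diff(beat_window) <= 0) stop("beat window must have positive length")
  out <- trace[trace$t >= beat_window[1] & trace$t < beat_window[2], ]
  if (!nrow(out)) stop("beat window shorter than available trace")
  out
}

#' Per-beat balance table of a restitution run
#'
#' Collects the engine-integrated per-beat SRCB and SCB values and labels the
#' beats of each cycle length by parity (short- vs long-APD beat during
#' alternans; the phase itself is arbitrary).
#'
#' @param r A `restitution_result`.
#' @return data.frame: cl, beat, parity ("short"/"long"; "tie" without
#'   alternans), apd90, srcb, scb (umol/L cytosol per beat).
#' @export
balance_table <- function(r) {
  stopifnot(inherits(r, "restitution_result"))
  b <- r$beats
  out <- lapply(split(b, b$cl), function(bb) {
    odd <- seq(1, nrow(bb), 2)
    even <- seq(2, nrow(bb), 2)
    m_odd <- mean(bb$apd90[odd])
    m_even <- mean(bb$apd90[even])
    parity <- rep("tie", nrow(bb))
    if (is.finite(m_odd) && is.finite(m_even) && m_odd != m_even) {
      short_is_odd <- m_odd < m_even
      parity[odd] <- if (short_is_odd) "short" else "long"
      parity[even] <- if (short_is_odd) "long" else "short"
    }
    data.frame(cl = bb$cl, beat = bb$beat, parity = parity,
               apd90 = bb$apd90, srcb = bb$srcb, scb = bb$scb)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-out$cl, out$beat), ]
}

#' Correlation of balance magnitude with APD alternans magnitude
#'
#' Pearson correlation, per cycle length, between the magnitude of the
#' short-APD-beat balance (SRCB or SCB) and the APD alternans magnitude
#' across alternans models.
#'
#' @param tab data.frame with one row per model x cycle length: columns `cl`,
#'   `dapd`, and the balance magnitude named by `measure`.
#' @param measure Column name holding |SRCB| or |SCB| of the short-APD beat.
#' @return data.frame per cycle length: cl, n, r, p (NA with a warning flag
#'   when fewer than 3 alternans models are available at that cycle length).
#' @export
balance_alternans_correlation <- function(tab, measure = "srcb_short") {
  stopifnot(all(c("cl", "dapd", measure) %in% names(tab)))
  out <- lapply(split(tab, tab$cl), function(tt) {
    tt <- tt[is.finite(tt$dapd) & is.finite(tt[[measure]]), ]
    if (nrow(tt) < 3)
      return(data.frame(cl = tt$cl[1], n = nrow(tt), r = NA_real_,
                        p = NA_real_))
    pr <- pearson(abs(tt[[measure]]), tt$dapd)
    data.frame(cl = tt$cl[1], n = nrow(tt), r = pr$r, p = pr$p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-out$cl), ]
}
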