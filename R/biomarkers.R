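# AP and calcium-transient biomarkers, and alternans magnitudes.

# linear-interpolated first downward crossing of `y` through `level` after
# index `from`; returns the interpolated x or NA
.cross_down <- function(x, y, level, from = 1) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- which(y[from:(n - 1)] >= level & y[(from + 1):n] < level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1] + from - 1
  x[i] + (x[i + 1] - x[i]) * (y[i] - level) / (y[i] - y[i + 1])
}

.cross_up <- function(x, y, level, from = 1) {
  n <- length(y)
  if (from >= n) return(NA_real_)
  idx <- which(y[from:(n - 1)] < level & y[(from + 1):n] >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1] + from - 1
  x[i] + (x[i + 1] - x[i]) * (level - y[i]) / (y[i + 1] - y[i])
}

#' Action potential biomarkers of one beat
#'
#' Computes the voltage biomarkers from a single-beat trace: resting membrane
#' potential (RMP, Vm at the pre-stimulus sample), peak upstroke voltage
#' (Vmax), AP amplitude (APA = Vmax - RMP), upstroke duration (UPD, 10 to 90
#' percent of APA on the upstroke), AP duration at 90 and 40 percent
#' repolarization measured from the AP take-off (10 percent of APA), and
#' triangulation (Tri = APD90 - APD40).
#'
#' @param beat Single-beat trace data.frame with columns `t` (ms) and `v`
#'   (mV); the first sample must precede the upstroke.
#' @return One-row data.frame: RMP, Vmax, APA, UPD, APD90, APD40, Tri, and a
#'   `valid` flag (FALSE when the beat is not captured, in which case the
#'   duration biomarkers are NA).
#' @export
ap_biomarkers <- function(beat) {
  stopifnot(is.data.frame(beat), all(c("t", "v") %in% names(beat)))
  t <- beat$t - beat$t[1]
  v <- beat$v
  rmp <- v[1]
  ipk <- which.max(v)
  vmax <- v[ipk]
  apa <- vmax - rmp
  captured <- max(v[t <= 50]) > 0
  if (!captured) {
    return(data.frame(RMP = rmp, Vmax = vmax, APA = apa, UPD = NA_real_,
                      APD90 = NA_real_, APD40 = NA_real_, Tri = NA_real_,
                      valid = FALSE))
  }
  v10 <- rmp + 0.10 * apa
  v90u <- rmp + 0.90 * apa
  t10 <- .cross_up(t, v, v10)
  t90u <- .cross_up(t, v, v90u)
  upd <- t90u - t10
  t_apd90 <- .cross_down(t, v, rmp + 0.10 * apa, from = ipk)
  t_apd40 <- .cross_down(t, v, rmp + 0.60 * apa, from = ipk)
  apd90 <- t_apd90 - t10
  apd40 <- t_apd40 - t10
  data.frame(RMP = rmp, Vmax = vmax, APA = apa, UPD = upd,
             APD90 = apd90, APD40 = apd40, Tri = apd90 - apd40,
             valid = TRUE)
}

#' Calcium transient biomarkers of one beat
#'
#' @param beat Single-beat trace data.frame with columns `t` (ms) and `cai`
#'   (mM).
#' @return One-row data.frame: CaTmax, CaTmin, CaTamp (mM) and CaTD (ms, from
#'   CaT take-off at 10 percent of the amplitude to 90 percent decay), with a
#'   `valid` flag (FALSE for flat transients, range < 1e-6 mM).
#' @export
cat_biomarkers <- function(beat) {
  stopifnot(is.data.frame(beat), all(c("t", "cai") %in% names(beat)))
  t <- beat$t - beat$t[1]
  ca <- beat$cai
  cat_max <- max(ca)
  cat_min <- min(ca)
  amp <- cat_max - cat_min
  if (amp < 1e-6) {
    return(data.frame(CaTmax = cat_max, CaTmin = cat_min, CaTamp = amp,
                      CaTD = NA_real_, valid = FALSE))
  }
  base <- ca[1]
  ipk <- which.max(ca)
  t_on <- .cross_up(t, ca, base + 0.10 * (cat_max - base))
  t_off <- .cross_down(t, ca, cat_max - 0.90 * (cat_max - base), from = ipk)
  data.frame(CaTmax = cat_max, CaTmin = cat_min, CaTamp = amp,
             CaTD = t_off - t_on, valid = TRUE)
}

#' Biomarkers of every recorded beat in a series
#'
#' @param series A `beat_series` with traces (see [pace()]).
#' @return data.frame, one row per recorded beat, AP and CaT biomarkers
#'   side by side.
#' @export
series_biomarkers <- function(series) {
  stopifnot(inherits(series, "beat_series"), !is.null(series$trace))
  out <- lapply(unique(series$trace$beat), function(bn) {
    tr <- series$trace[series$trace$beat == bn, ]
    cbind(beat = bn, ap_biomarkers(tr),
          cat_biomarkers(tr)[, c("CaTmax", "CaTmin", "CaTamp", "CaTD")])
  })
  do.call(rbind, out)
}

#' Alternans magnitudes of a steady-state beat series
#'
#' The APD alternans magnitude is the mean absolute APD difference between
#' consecutive beats; the CaT alternans magnitude is the analogous quantity
#' on CaT amplitude. Undefined (error) without 1:1 capture.
#'
#' @param series A `beat_series` from [pace()] with at least 4 recorded
#'   captured beats, or a per-beat data.frame with columns `apd90`,
#'   `cat_max`, `cat_min`, `captured`.
#' @return List with `dAPD` (ms) and `dCaT` (mM).
#' @export
alternans_magnitude <- function(series) {
  b <- if (inherits(series, "beat_series")) series$beats else series
  stopifnot(is.data.frame(b), nrow(b) >= 4)
  if (!all(b$captured) || any(!is.finite(b$apd90)))
    stop("alternans magnitude undefined without 1:1 capture of all beats")
  camp <- b$cat_max - b$cat_min
  list(dAPD = mean(abs(diff(b$apd90))), dCaT = mean(abs(diff(camp))))
}
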