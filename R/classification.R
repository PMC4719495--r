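# Classification of restitution behaviour into normal, Eye-type, Fork-type,
# or CaT-only alternans, and the alternans-onset cycle length.

#' Classify a restitution result
#'
#' APD-alternans models are split by the state of the restitution bifurcation
#' at the fastest captured cycle length: still alternating there = Fork-type
#' (open bifurcation); alternans present at some intermediate rate but gone
#' at the fastest captured rate = Eye-type (closed bifurcation). Models whose
#' APD alternans stay below threshold but whose calcium-transient amplitude
#' alternates are CaT-only alternans models. Cycle lengths that lose 1:1
#' capture are excluded so that 2:1 block cannot masquerade as alternans
#' disappearance.
#'
#' @param r A `restitution_result` (see [run_restitution()]) or its `per_cl`
#'   data.frame (columns cl, dapd, dcat, mean_catamp, captured).
#' @param apd_thresh APD alternans threshold in ms (default 5, the boundary
#'   below which models count as CaT-only).
#' @param cat_thresh CaT alternans threshold, as a fraction of the mean CaT
#'   amplitude at the same cycle length (default 0.05).
#' @return List of class `alternans_class`: `label` in
#'   c("normal", "eye", "fork", "cat_only"), `onset_cl` (ms; NA unless
#'   eye/fork), and the `per_cl` table used.
#' @export
classify <- function(r, apd_thresh = 5, cat_thresh = 0.05) {
  pc <- if (inherits(r, "restitution_result")) r$per_cl else r
  stopifnot(is.data.frame(pc), all(c("cl", "dapd", "captured") %in% names(pc)))
  cap <- pc[pc$captured & is.finite(pc$dapd), , drop = FALSE]
  if (nrow(cap) < 2) stop("classification requires >= 2 captured cycle lengths")
  fastest <- cap[which.min(cap$cl), ]
  apd_alt <- cap$dapd >= apd_thresh
  label <-
    if (fastest$dapd >= apd_thresh) "fork"
    else if (any(apd_alt)) "eye"
    else if (any(cap$dcat >= cat_thresh * cap$mean_catamp)) "cat_only"
    else "normal"
  onset <- if (label %in% c("eye", "fork")) max(cap$cl[apd_alt]) else NA_real_
  structure(list(label = label, onset_cl = onset, apd_thresh = apd_thresh,
                 cat_thresh = cat_thresh, per_cl = pc),
            class = "alternans_class")
}

#' @export
print.alternans_class <- function(x, ...) {
  cat("alternans class:", x$label)
  if (!is.na(x$onset_cl)) cat(sprintf(" (onset at CL %g ms)", x$onset_cl))
  cat("\n")
  invisible(x)
}

#' Alternans onset cycle length
#'
#' The longest cycle length at which the APD alternans magnitude reaches the
#' threshold. Only defined for Eye- and Fork-type models.
#'
#' @inheritParams classify
#' @return Onset cycle length in ms.
#' @export
onset_cl <- function(r, apd_thresh = 5) {
  pc <- if (inherits(r, "restitution_result")) r$per_cl else r
  cap <- pc[pc$captured & is.finite(pc$dapd), , drop = FALSE]
  qual <- cap$cl[cap$dapd >= apd_thresh]
  if (!length(qual))
    stop("no cycle length reaches the APD alternans threshold")
  max(qual)
}
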