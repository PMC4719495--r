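# Latin Hypercube population generation, evaluation through the restitution
# protocol, and calibration against ARI envelopes.

#' Latin Hypercube sample of scaling factors
#'
#' One sample per equal-width stratum per dimension over [low, high]^11
#' (default 0..2, i.e. +/-100 percent around the published values).
#' Reproducible under a fixed seed.
#'
#' @param n Number of models (>= 1).
#' @param seed Integer seed.
#' @param low,high Range of every scaling factor.
#' @return n x 11 numeric matrix, columns named by [scaling_names()].
#' @export
lhs_sample <- function(n, seed = 1, low = 0, high = 2) {
  stopifnot(n >= 1, low < high)
  set.seed(seed)
  X <- low + (high - low) * lhs::randomLHS(n, length(scaling_names()))
  colnames(X) <- scaling_names()
  X
}

#' Evaluate a population of models through the restitution protocol
#'
#' Runs every parameter set through [run_restitution()] and collects per-model
#' and per-cycle-length summary tables. Failed integrations are recorded with
#' their reason, never dropped. Results are independent of worker count and
#' execution order.
#'
#' @param samples Matrix of scaling factors (rows = models) as from
#'   [lhs_sample()], or a data.frame thereof.
#' @param protocol A [pacing_protocol()].
#' @param model_ids Optional ids (default 1..n).
#' @param biomarker_cls Cycle lengths at which trace-based biomarkers are
#'   computed (averaged over recorded beats).
#' @param workers Parallel workers (forked; 1 = serial).
#' @param ... Additional arguments to [build_model()] (solver settings).
#' @return List of class `population_table`: `models` (id, scalings, status),
#'   `per_cl` (id x cl summaries incl. alternans magnitudes and short-beat
#'   balance magnitudes), `biomarkers` (id x cl biomarker means), `protocol`.
#' @export
evaluate_population <- function(samples, protocol = pacing_protocol(),
                                model_ids = NULL, biomarker_cls = c(600, 350),
                                workers = 1, ...) {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples))) colnames(samples) <- scaling_names()
  n <- nrow(samples)
  if (is.null(model_ids)) model_ids <- seq_len(n)
  stopifnot(length(model_ids) == n || n == 0)
  dots <- list(...)
  biomarker_cls <- intersect(biomarker_cls, protocol$cl_list)

  eval_one <- function(i) {
    sc <- tryCatch(parameter_scaling(.values = samples[i, ]),
                   error = function(e) e)
    if (inherits(sc, "error"))
      return(list(status = "failed", reason = conditionMessage(sc)))
    spec <- do.call(build_model, c(list(scaling = sc), dots))
    r <- tryCatch(
      run_restitution(spec, protocol, keep_traces = length(biomarker_cls) > 0),
      error = function(e) e)
    if (inherits(r, "error"))
      return(list(status = "failed", reason = conditionMessage(r)))
    bal <- balance_table(r)
    short <- bal[bal$parity != "long", ]
    agg <- function(v, g) tapply(v, g, function(x) mean(abs(x)))
    srcb_short <- agg(short$srcb, short$cl)
    scb_short <- agg(short$scb, short$cl)
    pc <- r$per_cl
    pc$srcb_short <- as.numeric(srcb_short[as.character(pc$cl)])
    pc$scb_short <- as.numeric(scb_short[as.character(pc$cl)])
    bio <- NULL
    if (length(biomarker_cls)) {
      bio <- do.call(rbind, lapply(biomarker_cls, function(cl) {
        tr <- r$traces[[as.character(cl)]]
        if (is.null(tr)) return(NULL)
        bb <- lapply(unique(tr$beat), function(bn) {
          one <- tr[tr$beat == bn, ]
          cbind(ap_biomarkers(one),
                cat_biomarkers(one)[, c("CaTmax", "CaTmin", "CaTamp", "CaTD")])
        })
        bb <- do.call(rbind, bb)
        if (!all(bb$valid)) return(NULL)
        data.frame(cl = cl, t(colMeans(bb[, c("RMP", "Vmax", "APA", "UPD",
                                              "APD90", "APD40", "Tri",
                                              "CaTmax", "CaTmin", "CaTamp",
                                              "CaTD")])))
      }))
    }
    list(status = "ok", per_cl = pc, bio = bio)
  }

  res <- if (workers > 1) {
    parallel::mclapply(seq_len(n), eval_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else lapply(seq_len(n), eval_one)

  models <- data.frame(model_id = model_ids,
                       as.data.frame(samples, optional = TRUE))
  models$status <- vapply(res, `[[`, "", "status")
  models$reason <- vapply(res, function(x)
    if (x$status == "failed") x$reason else "", "")
  ok <- which(models$status == "ok")
  per_cl <- do.call(rbind, lapply(ok, function(i)
    cbind(model_id = model_ids[i], res[[i]]$per_cl)))
  bio <- do.call(rbind, lapply(ok, function(i)
    if (!is.null(res[[i]]$bio)) cbind(model_id = model_ids[i], res[[i]]$bio)))
  structure(list(models = models, per_cl = per_cl, biomarkers = bio,
                 protocol = protocol, solver = dots),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("population_table: %d models (%d evaluated ok)\n",
              nrow(x$models), sum(x$models$status == "ok")))
  if (!is.null(x$models$accepted))
    cat(sprintf("  accepted after calibration: %d\n", sum(x$models$accepted)))
  if (!is.null(x$models$label))
    print(table(x$models$label[x$models$accepted]))
  invisible(x)
}

#' Calibration ranges
#'
#' @param ranges data.frame with columns `cl`, `lower`, `upper` (ms), one row
#'   per protocol cycle length, or an `ari_study` whose envelopes are used.
#' @return data.frame of class `calibration_ranges`.
#' @export
calibration_ranges <- function(ranges) {
  if (inherits(ranges, "ari_study")) ranges <- ranges$ranges
  stopifnot(is.data.frame(ranges),
            all(c("cl", "lower", "upper") %in% names(ranges)),
            all(ranges$lower < ranges$upper))
  structure(ranges, class = c("calibration_ranges", "data.frame"))
}

#' Calibrate a population against APD envelopes
#'
#' A model is accepted when, at every protocol cycle length, its mean
#' steady-state APD lies inside the [lower, upper] envelope (min/max style
#' calibration on APD only). Models without 1:1 capture at some cycle length,
#' or that failed to integrate, are rejected with that reason.
#'
#' @param pop A `population_table` from [evaluate_population()].
#' @param ranges A [calibration_ranges()] (or coercible data.frame /
#'   `ari_study`).
#' @return The population with `accepted` and `reject_reason` filled in
#'   `$models`.
#' @export
calibrate <- function(pop, ranges) {
  stopifnot(inherits(pop, "population_table"))
  ranges <- calibration_ranges(ranges)
  cls <- pop$protocol$cl_list
  missing_cl <- setdiff(cls, ranges$cl)
  if (length(missing_cl))
    stop("no calibration range for CL(s): ", paste(missing_cl, collapse = ", "))
  pop$models$accepted <- FALSE
  pop$models$reject_reason <- pop$models$reason
  for (i in seq_len(nrow(pop$models))) {
    if (pop$models$status[i] != "ok") next
    pc <- pop$per_cl[pop$per_cl$model_id == pop$models$model_id[i], ]
    verdict <- "accepted"
    for (cl in sort(cls, decreasing = TRUE)) {
      row <- pc[pc$cl == cl, ]
      rg <- ranges[ranges$cl == cl, ]
      if (!nrow(row) || !row$captured || !is.finite(row$apd_odd)) {
        verdict <- sprintf("no 1:1 capture at CL %g", cl)
        break
      }
      apd <- (row$apd_odd + row$apd_even) / 2
      if (apd < rg$lower || apd > rg$upper) {
        verdict <- sprintf("APD out of range at CL %g", cl)
        break
      }
    }
    pop$models$accepted[i] <- verdict == "accepted"
    pop$models$reject_reason[i] <- if (verdict == "accepted") "" else verdict
  }
  pop
}

#' Classify every accepted model of a calibrated population
#'
#' Optionally applies a screen-and-confirm scheme: models whose screening run
#' shows any hint of alternans are re-run with a longer (steady-state)
#' conditioning protocol before the final classification, because alternans
#' inherited from the carry-over staircase can take hundreds of beats to
#' decay and would otherwise be misread as stable. Confirmed models have
#' their per-CL summaries replaced by the converged values, so downstream
#' balance and onset analyses operate on steady-state numbers.
#'
#' @param pop A calibrated `population_table`.
#' @param apd_thresh,cat_thresh Thresholds passed to [classify()].
#' @param confirm_protocol Optional [pacing_protocol()] with long conditioning
#'   used to re-run alternans candidates.
#' @param candidate_dapd Screening dAPD (ms) above which a model counts as an
#'   alternans candidate for confirmation.
#' @return The population with `label` and `onset_cl` columns in `$models`
#'   (and `confirmed`, when a confirmation protocol was used).
#' @export
classify_population <- function(pop, apd_thresh = 5, cat_thresh = 0.05,
                                confirm_protocol = NULL,
                                candidate_dapd = 2) {
  stopifnot(inherits(pop, "population_table"),
            !is.null(pop$models$accepted))
  if (!is.null(confirm_protocol)) {
    pop$models$confirmed <- FALSE
    for (i in which(pop$models$accepted)) {
      id <- pop$models$model_id[i]
      rows <- pop$per_cl$model_id == id
      pc <- pop$per_cl[rows, ]
      cand <- any(pc$captured & is.finite(pc$dapd) &
                    (pc$dapd >= candidate_dapd |
                       pc$dcat >= 0.5 * cat_thresh * pc$mean_catamp))
      if (!cand) next
      sc <- parameter_scaling(.values = stats::setNames(
        as.numeric(pop$models[i, scaling_names()]), scaling_names()))
      spec <- do.call(build_model, c(list(scaling = sc), pop$solver))
      r <- tryCatch(run_restitution(spec, confirm_protocol),
                    error = function(e) NULL)
      if (is.null(r)) next
      bal <- balance_table(r)
      short <- bal[bal$parity != "long", ]
      srcb_short <- tapply(short$srcb, short$cl, function(x) mean(abs(x)))
      scb_short <- tapply(short$scb, short$cl, function(x) mean(abs(x)))
      new_pc <- r$per_cl
      new_pc$srcb_short <- as.numeric(srcb_short[as.character(new_pc$cl)])
      new_pc$scb_short <- as.numeric(scb_short[as.character(new_pc$cl)])
      ord <- match(pop$per_cl$cl[rows], new_pc$cl)
      pop$per_cl[rows, names(new_pc)] <- new_pc[ord, ]
      pop$models$confirmed[i] <- TRUE
    }
  }
  pop$models$label <- NA_character_
  pop$models$onset_cl <- NA_real_
  for (i in which(pop$models$accepted)) {
    pc <- pop$per_cl[pop$per_cl$model_id == pop$models$model_id[i], ]
    cls <- tryCatch(classify(pc, apd_thresh, cat_thresh),
                    error = function(e) NULL)
    if (is.null(cls)) next
    pop$models$label[i] <- cls$label
    pop$models$onset_cl[i] <- cls$onset_cl
  }
  pop
}
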