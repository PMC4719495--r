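# In silico interventions: Na/Ca exchanger block on alternans models, and
# one-at-a-time variation of the L-type Ca current kinetics time constants.

#' Na/Ca exchanger block study
#'
#' Rescales the exchanger conductance of each alternans model by (1 - f) for
#' every block fraction f, re-runs the restitution protocol and re-classifies.
#' Reports per-model pre/post classes and balance magnitudes, plus the
#' percentage of models per class under each block level.
#'
#' @param models data.frame with a `model_id` column, the 11 scaling-factor
#'   columns and a `label` column (pre-intervention class); typically the
#'   alternans rows of a calibrated, classified `population_table$models`.
#' @param block_fractions Block levels (0 = no block).
#' @param protocol A [pacing_protocol()].
#' @param apd_thresh,cat_thresh Classification thresholds (see [classify()]).
#' @param confirm_protocol Optional long-conditioning [pacing_protocol()];
#'   any (model, fraction) pair still classified as alternans under the
#'   screening protocol is re-run with it before being reported (transient
#'   alternans inherited through the CL staircase decay slowly and would
#'   otherwise inflate the residual-alternans counts).
#' @param ... Solver settings forwarded to [build_model()].
#' @return List of class `inaca_block_result`: `per_model` (model_id,
#'   fraction, label_pre, label_post, max_dapd, srcb, scb at the pre-block
#'   alternans CL), `summary` (fraction x class percentages, with APD
#'   alternans conversion rates over the eye+fork denominator and over all
#'   alternans models).
#' @export
inaca_block_study <- function(models, block_fractions = c(0.2, 0.4, 0.6),
                              protocol = pacing_protocol(),
                              apd_thresh = 5, cat_thresh = 0.05,
                              confirm_protocol = NULL, ...) {
  stopifnot(all(c("model_id", "label") %in% names(models)),
            all(scaling_names() %in% names(models)),
            all(block_fractions >= 0 & block_fractions < 1))
  rows <- list()
  for (i in seq_len(nrow(models))) {
    base_sc <- as.numeric(models[i, scaling_names()])
    names(base_sc) <- scaling_names()
    for (f in block_fractions) {
      sc <- base_sc
      sc["s_GNaCa"] <- sc["s_GNaCa"] * (1 - f)
      spec <- build_model(parameter_scaling(.values = sc), ...)
      r <- tryCatch(run_restitution(spec, protocol), error = function(e) e)
      if (inherits(r, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          model_id = models$model_id[i], fraction = f,
          label_pre = models$label[i], label_post = "failed",
          max_dapd = NA_real_, srcb = NA_real_, scb = NA_real_)
        next
      }
      cls <- tryCatch(classify(r, apd_thresh, cat_thresh),
                      error = function(e) NULL)
      if (!is.null(confirm_protocol) && !is.null(cls) &&
          cls$label != "normal" &&
          !identical(confirm_protocol$n_prebeats, protocol$n_prebeats)) {
        r2 <- tryCatch(run_restitution(spec, confirm_protocol),
                       error = function(e) NULL)
        if (!is.null(r2)) {
          r <- r2
          cls <- tryCatch(classify(r, apd_thresh, cat_thresh),
                          error = function(e) NULL)
        }
      }
      bal <- balance_table(r)
      short <- bal[bal$parity != "long", ]
      mag <- function(v) mean(abs(v))
      # balance magnitudes at the CL of maximal residual alternans
      pc <- r$per_cl[r$per_cl$captured, ]
      cl_at <- pc$cl[which.max(pc$dapd)]
      sb <- short[short$cl == cl_at, ]
      rows[[length(rows) + 1]] <- data.frame(
        model_id = models$model_id[i], fraction = f,
        label_pre = models$label[i],
        label_post = if (is.null(cls)) "unclassifiable" else cls$label,
        max_dapd = max(pc$dapd, na.rm = TRUE),
        srcb = mag(sb$srcb), scb = mag(sb$scb))
    }
  }
  per_model <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_model, per_model$fraction),
                                function(pm) {
    apd_pre <- pm$label_pre %in% c("eye", "fork")
    data.frame(
      fraction = pm$fraction[1],
      pct_normal = 100 * mean(pm$label_post == "normal"),
      pct_eye = 100 * mean(pm$label_post == "eye"),
      pct_fork = 100 * mean(pm$label_post == "fork"),
      pct_cat_only = 100 * mean(pm$label_post == "cat_only"),
      conv_apd_to_normal = if (any(apd_pre))
        100 * mean(pm$label_post[apd_pre] == "normal") else NA_real_,
      conv_all_to_normal = 100 * mean(pm$label_post == "normal"),
      apd_alt_remaining = sum(pm$label_post %in% c("eye", "fork")))
  }))
  rownames(summ) <- NULL
  structure(list(per_model = per_model, summary = summ),
            class = "inaca_block_result")
}

#' @export
print.inaca_block_result <- function(x, ...) {
  cat("I_NaCa block study\n")
  print(round(x$summary, 1))
  invisible(x)
}

#' I_CaL kinetics variation study
#'
#' Varies the activation (tau_d), inactivation (tau_f) and recovery from
#' Ca-dependent inactivation (tau_j) time-constant multipliers one at a time
#' over a grid, re-runs the restitution protocol for each condition, and
#' relates the APD alternans magnitude to the SCB and SRCB magnitudes at the
#' analysis cycle length.
#'
#' @param scaling The model's [parameter_scaling()] (or named vector).
#' @param multipliers Grid applied to each time constant in turn.
#' @param protocol A [pacing_protocol()].
#' @param analysis_cl Cycle length at which alternans and balances are
#'   compared; default the CL of maximal alternans under original kinetics.
#' @param apd_thresh,cat_thresh Classification thresholds.
#' @param confirm_protocol Optional long-conditioning [pacing_protocol()] used
#'   to re-run conditions that the screening protocol classifies as alternans
#'   (guards against slowly decaying staircase transients).
#' @param ... Solver settings for [build_model()].
#' @return List of class `ical_kinetics_result`: `conditions` (one row per
#'   condition: label, tau multipliers, dapd, srcb, scb, class), `fits`
#'   (R squared and slope of dapd ~ |SCB| and dapd ~ |SRCB| across
#'   conditions), `analysis_cl`.
#' @export
ical_kinetics_study <- function(scaling,
                                multipliers = c(0.5, 0.75, 1, 1.25, 1.5),
                                protocol = pacing_protocol(),
                                analysis_cl = NULL,
                                apd_thresh = 5, cat_thresh = 0.05,
                                confirm_protocol = NULL, ...) {
  if (!inherits(scaling, "parameter_scaling"))
    scaling <- parameter_scaling(.values = scaling)
  taus <- c("m_tau_d", "m_tau_f", "m_tau_j")
  conds <- data.frame(tau = "none", mult = 1)
  varied <- setdiff(multipliers, 1)
  if (length(varied))
    for (tn in taus)
      conds <- rbind(conds, data.frame(tau = tn, mult = varied))
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    kt <- kinetics_scaling()
    if (conds$tau[i] != "none") kt[[conds$tau[i]]] <- conds$mult[i]
    kt <- kinetics_scaling(kt[["m_tau_d"]], kt[["m_tau_f"]], kt[["m_tau_j"]])
    spec <- build_model(scaling, kt, ...)
    r <- run_restitution(spec, protocol)
    cls <- tryCatch(classify(r, apd_thresh, cat_thresh)$label,
                    error = function(e) NA_character_)
    if (!is.null(confirm_protocol) && !is.na(cls) && cls != "normal" &&
        !identical(confirm_protocol$n_prebeats, protocol$n_prebeats)) {
      r <- run_restitution(spec, confirm_protocol)
      cls <- tryCatch(classify(r, apd_thresh, cat_thresh)$label,
                      error = function(e) NA_character_)
    }
    pc <- r$per_cl[r$per_cl$captured, ]
    if (i == 1 && is.null(analysis_cl))
      analysis_cl <- pc$cl[which.max(pc$dapd)]
    bal <- balance_table(r)
    sb <- bal[bal$parity != "long" & bal$cl == analysis_cl, ]
    at <- pc[pc$cl == analysis_cl, ]
    label <- if (conds$tau[i] == "none") "original" else
      sprintf("%s_x%.2f", sub("m_", "", conds$tau[i]), conds$mult[i])
    rows[[length(rows) + 1]] <- data.frame(
      condition = label, tau = conds$tau[i], mult = conds$mult[i],
      dapd = if (nrow(at)) at$dapd else NA_real_,
      srcb = mean(abs(sb$srcb)), scb = mean(abs(sb$scb)),
      label = cls)
  }
  conditions <- do.call(rbind, rows)
  fit_r2 <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return(c(NA_real_, NA_real_))
    m <- stats::lm(y[ok] ~ x[ok])
    c(summary(m)$r.squared, unname(stats::coef(m)[2]))
  }
  f1 <- fit_r2(abs(conditions$scb), conditions$dapd)
  f2 <- fit_r2(abs(conditions$srcb), conditions$dapd)
  fits <- data.frame(predictor = c("scb", "srcb"),
                     r_squared = c(f1[1], f2[1]),
                     slope = c(f1[2], f2[2]))
  structure(list(conditions = conditions, fits = fits,
                 analysis_cl = analysis_cl),
            class = "ical_kinetics_result")
}

#' @export
print.ical_kinetics_result <- function(x, ...) {
  cat(sprintf("I_CaL kinetics study at CL %g ms\n", x$analysis_cl))
  print(x$conditions[, c("condition", "dapd", "srcb", "scb", "label")],
        digits = 3)
  cat("linear fits of dAPD vs balance magnitude:\n")
  print(x$fits, digits = 3)
  invisible(x)
}
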