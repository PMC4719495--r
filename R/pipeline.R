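# End-to-end study pipeline: sample -> evaluate -> calibrate -> classify ->
# balance/statistics -> interventions, with CSV table export and a run
# manifest.

#' Study configuration
#'
#' @param n_models Latin Hypercube sample size (the baseline model is always
#'   appended as model_id 0).
#' @param seed Master seed; stage seeds are derived from it.
#' @param cl_list Protocol cycle lengths (ms), descending.
#' @param n_prebeats Conditioning beats per cycle length for the screening
#'   pass (scalar or vector).
#' @param n_prebeats_confirm Conditioning beats for the steady-state
#'   confirmation pass applied to alternans candidates, to post-intervention
#'   runs that still show alternans, and to the kinetics study on the
#'   largest-alternans models. Alternans inherited through the CL staircase
#'   decay over hundreds of beats, so the screening pass alone over-counts
#'   marginal alternans.
#' @param n_record Recorded beats per cycle length.
#' @param apd_thresh,cat_thresh Alternans classification thresholds.
#' @param ranges Calibration envelopes: NULL to generate synthetic in vivo
#'   envelopes, a data.frame (cl, lower, upper), or a CSV path.
#' @param ari_params Generator settings for synthetic envelopes
#'   ([ari_study_params()]).
#' @param run_block,run_kinetics Intervention toggles.
#' @param block_fractions I_NaCa block levels.
#' @param workers Parallel workers for the population stage.
#' @param biomarker_cls Cycle lengths for trace-based biomarkers.
#' @param dt_fine,dt_coarse,fine_win,dvdt_thresh Solver settings (see
#'   [build_model()]); defaults here favour population throughput.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_models = 400, seed = 1,
                         cl_list = c(600, 550, 500, 450, 400, 350),
                         n_prebeats = c(100, rep(50, 5)),
                         n_prebeats_confirm = c(400, rep(300, 5)),
                         n_record = 8,
                         apd_thresh = 5, cat_thresh = 0.05,
                         ranges = NULL, ari_params = ari_study_params(),
                         run_block = TRUE, run_kinetics = TRUE,
                         block_fractions = c(0.2, 0.4, 0.6),
                         workers = 1, biomarker_cls = c(600, 350),
                         dt_fine = 0.01, dt_coarse = 0.1,
                         fine_win = 30, dvdt_thresh = 3) {
  cfg <- list(n_models = n_models, seed = as.integer(seed),
              cl_list = cl_list, n_prebeats = n_prebeats,
              n_prebeats_confirm = n_prebeats_confirm,
              n_record = n_record, apd_thresh = apd_thresh,
              cat_thresh = cat_thresh, ranges = ranges,
              ari_params = ari_params, run_block = run_block,
              run_kinetics = run_kinetics,
              block_fractions = block_fractions, workers = workers,
              biomarker_cls = biomarker_cls, dt_fine = dt_fine,
              dt_coarse = dt_coarse, fine_win = fine_win,
              dvdt_thresh = dvdt_thresh)
  structure(cfg, class = "study_config")
}

#' Read/write a study configuration as YAML
#' @param path YAML file path.
#' @param config A [study_config()].
#' @return `read_study_config` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ranges) && is.character(raw$ranges))
    raw$ranges <- utils::read.csv(raw$ranges)
  if (!is.null(raw$ari_params))
    raw$ari_params <- do.call(ari_study_params, raw$ari_params)
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full alternans population study
#'
#' Executes every stage from sampling to interventions and returns a report
#' holding all result tables. All randomness derives from `config$seed`;
#' repeated runs with the same configuration are identical.
#'
#' @param config A [study_config()].
#' @param progress Print one-line stage updates.
#' @return List of class `study_report` with elements `config`, `ari_study`,
#'   `ranges`, `population` (calibrated, classified `population_table`),
#'   `pcc` (partial-correlation report), `group_comparison` (alternans vs
#'   normal parameter tests), `balance_correlation`, `onset_summary`,
#'   `block` (I_NaCa block study, when enabled), `kinetics` (per reference
#'   model), and `manifest`.
#' @export
run_study <- function(config = study_config(), progress = TRUE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (progress) message(sprintf(...))
  solver <- config[c("dt_fine", "dt_coarse", "fine_win", "dvdt_thresh")]
  protocol <- pacing_protocol(config$cl_list, config$n_prebeats,
                              config$n_record)
  confirm <- pacing_protocol(config$cl_list, config$n_prebeats_confirm,
                             config$n_record)

  # calibration envelopes
  ari <- NULL
  if (is.null(config$ranges)) {
    say("generating synthetic in vivo ARI envelopes")
    ari <- generate_ari_study(cl_list = config$cl_list,
                              params = config$ari_params,
                              seed = config$seed + 1L)
    ranges <- calibration_ranges(ari)
  } else ranges <- calibration_ranges(config$ranges)

  # population
  say("sampling %d models (Latin Hypercube) + baseline", config$n_models)
  X <- lhs_sample(config$n_models, seed = config$seed)
  X <- rbind(stats::setNames(rep(1, 11), scaling_names()), X)
  ids <- c(0L, seq_len(config$n_models))
  say("evaluating population through the restitution protocol")
  pop <- do.call(evaluate_population,
                 c(list(samples = X, protocol = protocol, model_ids = ids,
                        biomarker_cls = config$biomarker_cls,
                        workers = config$workers), solver))
  say("calibrating and classifying (screen + steady-state confirmation)")
  pop <- calibrate(pop, ranges)
  pop <- classify_population(pop, config$apd_thresh, config$cat_thresh,
                             confirm_protocol = confirm)
  m <- pop$models
  acc <- m[m$accepted, ]
  say("accepted %d / %d models; classes: %s", nrow(acc), nrow(m),
      paste(names(table(acc$label)), table(acc$label), collapse = ", "))

  # statistics
  pcc <- NULL
  if (!is.null(pop$biomarkers) && nrow(acc) > 13) {
    bio_cl <- max(config$biomarker_cls)
    b <- pop$biomarkers[pop$biomarkers$cl == bio_cl, ]
    b <- b[b$model_id %in% acc$model_id, ]
    idx <- match(b$model_id, acc$model_id)
    pcc <- correlation_report(acc[idx, scaling_names()],
                              b[, c("APD90", "APA", "Vmax", "RMP", "UPD",
                                    "Tri", "CaTmax", "CaTmin", "CaTD")])
  }
  grp <- NULL
  alt <- acc[acc$label %in% c("eye", "fork", "cat_only"), ]
  nrm <- acc[acc$label == "normal", ]
  if (nrow(alt) >= 2 && nrow(nrm) >= 2) {
    grp <- do.call(rbind, lapply(scaling_names(), function(pn) {
      mw <- mann_whitney(alt[[pn]], nrm[[pn]])
      data.frame(parameter = pn, median_alternans = stats::median(alt[[pn]]),
                 median_normal = stats::median(nrm[[pn]]),
                 U = mw$U, p = mw$p, stars = mw$stars)
    }))
  }

  # balance vs alternans magnitude: across every APD-alternans model at each
  # cycle length where alternans occur in the population (models that do not
  # alternate at a given CL contribute near-zero dAPD and balance, as in the
  # per-CL magnitude plots of the study design)
  balcor <- NULL
  apd_alt_ids <- acc$model_id[acc$label %in% c("eye", "fork")]
  if (length(apd_alt_ids) >= 3) {
    tab <- pop$per_cl[pop$per_cl$model_id %in% apd_alt_ids &
                        pop$per_cl$captured, ]
    tab <- tab[is.finite(tab$dapd), ]
    alt_cls <- unique(tab$cl[tab$dapd >= config$apd_thresh])
    tab <- tab[tab$cl %in% alt_cls, ]
    balcor <- list(
      srcb = balance_alternans_correlation(
        stats::setNames(tab[, c("cl", "dapd", "srcb_short")],
                        c("cl", "dapd", "srcb_short")), "srcb_short"),
      scb = balance_alternans_correlation(
        stats::setNames(tab[, c("cl", "dapd", "scb_short")],
                        c("cl", "dapd", "scb_short")), "scb_short"))
  }

  onset <- NULL
  if (any(acc$label %in% c("eye", "fork"))) {
    oo <- acc[acc$label %in% c("eye", "fork"), c("label", "onset_cl")]
    onset <- do.call(rbind, lapply(split(oo, oo$label), function(x)
      data.frame(label = x$label[1], n = nrow(x),
                 median_onset_cl = stats::median(x$onset_cl))))
    rownames(onset) <- NULL
  }

  # interventions
  block <- NULL
  if (config$run_block && nrow(alt) >= 1) {
    say("I_NaCa block study on %d alternans models", nrow(alt))
    block <- do.call(inaca_block_study,
                     c(list(models = alt,
                            block_fractions = config$block_fractions,
                            protocol = protocol,
                            apd_thresh = config$apd_thresh,
                            cat_thresh = config$cat_thresh,
                            confirm_protocol = confirm), solver))
  }
  kin <- NULL
  if (config$run_kinetics) {
    refs <- .kinetics_reference_models(pop, config)
    if (nrow(refs)) {
      say("I_CaL kinetics study on %d reference models", nrow(refs))
      kin <- lapply(seq_len(nrow(refs)), function(i) {
        # the two largest-alternans reference models need converged balances
        # in every condition (they feed the dAPD-vs-balance fits); the normal
        # reference models only need screening plus confirmation of any
        # apparent alternans
        alt_ref <- grepl("largest_", refs$role[i])
        res <- do.call(ical_kinetics_study,
                       c(list(scaling = as.numeric(refs[i, scaling_names()]) |>
                                stats::setNames(scaling_names()),
                              protocol = if (alt_ref) confirm else protocol,
                              apd_thresh = config$apd_thresh,
                              cat_thresh = config$cat_thresh,
                              confirm_protocol = confirm), solver))
        res$model_id <- refs$model_id[i]
        res$role <- refs$role[i]
        res
      })
      names(kin) <- refs$role
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("alternanspop")),
    seed = config$seed, n_models = config$n_models,
    cl_list = config$cl_list, n_prebeats = config$n_prebeats,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(config = config, ari_study = ari, ranges = ranges,
                 population = pop, pcc = pcc, group_comparison = grp,
                 balance_correlation = balcor, onset_summary = onset,
                 block = block, kinetics = kin, manifest = manifest),
            class = "study_report")
}

# reference models for the kinetics study: largest-alternans eye and fork,
# the baseline model, and the longest- and shortest-APD accepted normal models
.kinetics_reference_models <- function(pop, config) {
  m <- pop$models
  acc <- m[m$accepted, ]
  pc <- pop$per_cl
  maxd <- vapply(acc$model_id, function(id) {
    x <- pc[pc$model_id == id & pc$captured, "dapd"]
    if (length(x)) max(x, na.rm = TRUE) else NA_real_
  }, 1)
  refs <- list()
  for (lab in c("eye", "fork")) {
    cand <- which(acc$label == lab)
    if (length(cand)) {
      best <- cand[which.max(maxd[cand])]
      refs[[length(refs) + 1]] <- cbind(acc[best, ],
                                        role = paste0("largest_", lab))
    }
  }
  if (any(acc$model_id == 0))
    refs[[length(refs) + 1]] <- cbind(acc[acc$model_id == 0, ],
                                      role = "baseline")
  nrm <- acc[acc$label == "normal" & acc$model_id != 0, ]
  if (nrow(nrm) >= 2) {
    apd600 <- vapply(nrm$model_id, function(id) {
      x <- pc[pc$model_id == id & pc$cl == max(config$cl_list), ]
      if (nrow(x)) (x$apd_odd + x$apd_even) / 2 else NA_real_
    }, 1)
    refs[[length(refs) + 1]] <- cbind(nrm[which.max(apd600), ],
                                      role = "longest_apd_normal")
    refs[[length(refs) + 1]] <- cbind(nrm[which.min(apd600), ],
                                      role = "shortest_apd_normal")
  }
  if (!length(refs)) return(data.frame())
  do.call(rbind, refs)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  print(x$population)
  if (!is.null(x$onset_summary)) print(x$onset_summary)
  if (!is.null(x$block)) print(x$block$summary, digits = 3)
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Stable filenames, CSV format, every table keyed by model_id where
#' applicable; the run manifest is written as JSON.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed; must be writable).
#' @return Invisibly, the vector of files written.
#' @export
write_tables <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
  probe <- file.path(dir, ".write_test")
  ok <- tryCatch({ file.create(probe); file.remove(probe); TRUE },
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok) stop("output directory not writable: ", dir)
  files <- character()
  put <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  put(report$population$models, "population.csv")
  put(report$population$per_cl, "restitution_per_cl.csv")
  if (!is.null(report$population$biomarkers))
    put(report$population$biomarkers, "biomarkers.csv")
  put(as.data.frame(report$ranges), "calibration_ranges.csv")
  if (!is.null(report$ari_study))
    put(report$ari_study$samples, "synthetic_ari_samples.csv")
  if (!is.null(report$pcc)) {
    put(data.frame(biomarker = rownames(report$pcc$pcc),
                   report$pcc$pcc, check.names = FALSE), "pcc.csv")
  }
  if (!is.null(report$group_comparison))
    put(report$group_comparison, "group_comparison.csv")
  if (!is.null(report$balance_correlation)) {
    put(report$balance_correlation$srcb, "srcb_dapd_correlation.csv")
    put(report$balance_correlation$scb, "scb_dapd_correlation.csv")
  }
  if (!is.null(report$onset_summary))
    put(report$onset_summary, "onset_summary.csv")
  if (!is.null(report$block)) {
    put(report$block$per_model, "inaca_block_per_model.csv")
    put(report$block$summary, "inaca_block_summary.csv")
  }
  if (!is.null(report$kinetics)) {
    kt <- do.call(rbind, lapply(report$kinetics, function(k)
      cbind(model_id = k$model_id, role = k$role, k$conditions)))
    put(kt, "ical_kinetics_conditions.csv")
    kf <- do.call(rbind, lapply(report$kinetics, function(k)
      cbind(model_id = k$model_id, role = k$role, k$fits)))
    put(kf, "ical_kinetics_fits.csv")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(dir, "manifest.json"))
  invisible(files)
}
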