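# Intervention semantics on a single known alternans model (the population-
# scale intervention results are exercised in the acceptance suite).

test_that("zero block fraction leaves the classification unchanged", {
  r <- alternans_restitution()
  pre <- classify(r)
  models <- data.frame(model_id = 1L,
                       t(as.numeric(unclass(alternans_scaling()))) |>
                         as.data.frame() |>
                         stats::setNames(scaling_names()),
                       label = pre$label)
  out <- do.call(inaca_block_study,
                 c(list(models, block_fractions = 0,
                        protocol = short_protocol()), fast_solver))
  expect_equal(out$per_model$label_post, pre$label)
  expect_equal(out$per_model$max_dapd, max(r$per_cl$dapd, na.rm = TRUE),
               tolerance = 1e-6)
})

test_that("identity kinetics reproduces the untreated condition exactly", {
  res <- do.call(ical_kinetics_study,
                 c(list(alternans_scaling(), multipliers = 1,
                        protocol = short_protocol()), fast_solver))
  expect_equal(nrow(res$conditions), 1)
  r <- alternans_restitution()
  cl_at <- res$analysis_cl
  expect_equal(res$conditions$dapd,
               r$per_cl$dapd[r$per_cl$cl == cl_at], tolerance = 1e-9)
})

test_that("kinetics multipliers outside the +/-50% range are rejected", {
  expect_error(
    do.call(ical_kinetics_study,
            c(list(alternans_scaling(), multipliers = c(0.3, 1),
                   protocol = short_protocol()), fast_solver)),
    "within")
})
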