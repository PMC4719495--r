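# Synthetic in vivo module: ARI study generator, toy electrograms, and the
# derivative-rule ARI extractor.

test_that("encode -> extract round-trip recovers ARI within 1 ms at zero noise", {
  for (cl in c(600, 500, 400, 350)) {
    ari <- cl * 0.55
    egm <- synth_electrogram(rep(ari, 3), cl, noise_sd = 0, sample_dt = 0.5)
    got <- ari_extract(egm)
    expect_true(all(got$measurable))
    expect_true(all(abs(got$ari - ari) <= 1))
  }
})

test_that("alternating encoded ARIs produce an alternating extracted sequence", {
  seqs <- rep(c(260, 220), 4)
  egm <- synth_electrogram(seqs, 500, noise_sd = 0, sample_dt = 0.5)
  got <- ari_extract(egm)
  expect_true(all(got$measurable))
  expect_equal(got$ari, seqs, tolerance = 0.005)
  d <- diff(got$ari)
  expect_true(all(d[-1] * head(d, -1) < 0))
})

test_that("flat signals are unmeasurable and amplitude scaling is irrelevant", {
  flat <- data.frame(t = 0:2000, v = rep(0.3, 2001))
  got <- ari_extract(flat, stimulus_times = c(0, 500, 1000))
  expect_true(all(!got$measurable))

  egm <- synth_electrogram(c(250, 250), 500, noise_sd = 0, sample_dt = 0.5)
  big <- egm
  big$signal$v <- 250 * big$signal$v
  # invariant up to one sample: rescaling can flip floating-point ties at the
  # flat extremum of the smoothed slope
  expect_lt(max(abs(ari_extract(big)$ari - ari_extract(egm)$ari)), 0.51)
})

test_that("moderate noise keeps extraction error < 5 ms in 95% of beats", {
  err <- unlist(lapply(1:25, function(s) {
    egm <- synth_electrogram(rep(250, 8), 500, noise_sd = 0.005, seed = s,
                             sample_dt = 0.5)
    got <- ari_extract(egm)
    abs(got$ari - 250)
  }))
  expect_gt(mean(err < 5, na.rm = TRUE), 0.95)
})

test_that("ARI study is reproducible, rate-dependent, and respects ARI < CL", {
  s1 <- generate_ari_study(n_sites = 40, n_patients = 8, seed = 5)
  s2 <- generate_ari_study(n_sites = 40, n_patients = 8, seed = 5)
  expect_identical(s1$samples, s2$samples)
  m <- tapply(s1$samples$ari, s1$samples$cl, mean)
  cls <- as.numeric(names(m))
  expect_true(all(diff(m[order(cls)]) > 0))  # ARI grows with CL
  expect_true(all(s1$samples$ari < s1$samples$cl))
  expect_true(all(s1$ranges$lower < s1$ranges$upper))
})

test_that("zero variances collapse sites onto the mean curve", {
  p <- ari_study_params(patient_sd = 0, site_sd = 0, noise_sd = 0,
                        alternans_fraction = 0)
  s <- generate_ari_study(n_sites = 10, n_patients = 3, params = p, seed = 2)
  expect_equal(s$ranges$lower, s$ranges$upper, tolerance = 1e-12)
  expect_equal(s$ranges$upper, 113 + 0.22 * s$ranges$cl)
})

test_that("calibration envelopes widen monotonically with the spread parameters", {
  width <- function(site_sd, patient_sd) {
    p <- ari_study_params(site_sd = site_sd, patient_sd = patient_sd,
                          alternans_fraction = 0)
    s <- generate_ari_study(n_sites = 60, n_patients = 10, params = p,
                            seed = 3)
    mean(s$ranges$upper - s$ranges$lower)
  }
  w0 <- width(2, 2)
  w1 <- width(10, 10)
  w2 <- width(25, 25)
  expect_true(w0 < w1 && w1 < w2)
})

test_that("baseline model APDs fall inside the default synthetic envelopes", {
  study <- generate_ari_study(seed = 20160122)
  r <- cached("baseline_restitution", {
    run_restitution(fast_model(), short_protocol())
  })
  apd <- (r$per_cl$apd_odd + r$per_cl$apd_even) / 2
  rg <- study$ranges[match(r$per_cl$cl, study$ranges$cl), ]
  expect_true(all(apd > rg$lower & apd < rg$upper))
})
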