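# Biomarker extraction on synthetic waveforms with closed-form answers, and
# on simulated beats.

# trapezoid AP: instant rise to +40 mV at t = 0, linear fall back to -85 mV
# over 300 ms, then flat
trapezoid_beat <- function(dt = 0.5, t_end = 400) {
  t <- seq(0, t_end, by = dt)
  v <- ifelse(t <= 0, -85, pmax(40 - (125 / 300) * t, -85))
  v[1] <- -85
  data.frame(t = t, v = v)
}

test_that("APD90 of a trapezoid AP matches the ramp geometry", {
  beat <- trapezoid_beat()
  bio <- ap_biomarkers(beat)
  # APA = 125 mV; 90% repolarization level = -85 + 12.5 = -72.5 mV;
  # the ramp reaches it at t = (40 + 72.5) / (125/300) = 270 ms
  expect_equal(bio$APD90, 270, tolerance = 0.01)
  expect_equal(bio$APD40, 120, tolerance = 0.01)   # 40% repol at -10 mV
  expect_equal(bio$Tri, 150, tolerance = 0.02)
  expect_equal(bio$RMP, -85)
  expect_equal(bio$Vmax, 40, tolerance = 0.01)
})

test_that("biomarkers are invariant to time shift and sampling refinement", {
  b1 <- trapezoid_beat(dt = 0.5)
  b2 <- trapezoid_beat(dt = 0.25)
  b3 <- b1
  b3$t <- b3$t + 1234
  expect_lt(abs(ap_biomarkers(b1)$APD90 - ap_biomarkers(b2)$APD90), 0.5)
  expect_equal(ap_biomarkers(b1)$APD90, ap_biomarkers(b3)$APD90)
})

test_that("sampling refinement moves simulated-beat APD90 by < 0.5 ms", {
  spec1 <- build_model(sample_dt = 0.5)
  spec2 <- build_model(sample_dt = 0.25)
  st <- pace(spec1, 1000, n_prebeats = 30, n_record = 0)$state
  b1 <- pace(spec1, 1000, 0, 1, initial_state = st)
  b2 <- pace(spec2, 1000, 0, 1, initial_state = st)
  a1 <- ap_biomarkers(b1$trace)$APD90
  a2 <- ap_biomarkers(b2$trace)$APD90
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("triangular CaT pulse gives the geometric CaTD", {
  t <- seq(0, 500, by = 0.5)
  base <- 1e-4; peak <- 6e-4
  up <- 20; down <- 200  # linear rise to t=20, linear decay to t=220
  ca <- ifelse(t <= up, base + (peak - base) * t / up,
               pmax(peak - (peak - base) * (t - up) / down, base))
  bio <- cat_biomarkers(data.frame(t = t, cai = ca))
  expect_equal(bio$CaTmax, peak)
  expect_equal(bio$CaTmin, base)
  # take-off at 10% of amplitude: t = 2; 90% decay: t = 20 + 0.9*200 = 200
  expect_equal(bio$CaTD, 198, tolerance = 0.02)
})

test_that("flat CaT is flagged invalid", {
  bio <- cat_biomarkers(data.frame(t = 0:100, cai = rep(1e-4, 101)))
  expect_false(bio$valid)
  expect_true(is.na(bio$CaTD))
})

test_that("alternans magnitude arithmetic and phase invariance", {
  mk <- function(apd) data.frame(apd90 = apd, cat_max = 4e-4, cat_min = 1e-4,
                                 captured = TRUE)
  expect_equal(alternans_magnitude(mk(c(300, 300, 300, 300)))$dAPD, 0)
  expect_equal(alternans_magnitude(mk(c(280, 240, 280, 240)))$dAPD, 40)
  # phase swap leaves the magnitude unchanged
  expect_equal(alternans_magnitude(mk(c(240, 280, 240, 280)))$dAPD, 40)
  bad <- mk(c(280, 240, 280, 240))
  bad$captured[2] <- FALSE
  expect_error(alternans_magnitude(bad), "capture")
})

test_that("non-captured beat yields invalid AP biomarkers", {
  t <- seq(0, 300, 0.5)
  bio <- ap_biomarkers(data.frame(t = t, v = rep(-85, length(t))))
  expect_false(bio$valid)
  expect_true(is.na(bio$APD90))
})
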