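# Pacing, restitution and AP-clamp protocol behaviour.

test_that("baseline model shows no alternans and converged APDs at CL 600", {
  spec <- fast_model()
  bs <- pace(spec, 600, n_prebeats = 150, n_record = 8)
  expect_true(all(bs$beats$captured))
  expect_lt(max(abs(diff(bs$beats$apd90))), 1)
  expect_true(all(diff(bs$trace$t) > 0))
})

test_that("n_record = 0 returns the final state only", {
  spec <- fast_model()
  bs <- pace(spec, 600, n_prebeats = 2, n_record = 0)
  expect_null(bs$trace)
  expect_length(bs$state, 41)
})

test_that("steady-state convergence: doubling the default conditioning beats moves APD < 1 ms", {
  spec <- fast_model()
  b1 <- pace(spec, 1000, n_prebeats = 500, n_record = 2)
  b2 <- pace(spec, 1000, n_prebeats = 1000, n_record = 2,
             initial_state = b1$state)
  # b2 continues from b1: compare recorded APDs 500 vs 1500 beats deep
  expect_lt(max(abs(b1$beats$apd90 - b2$beats$apd90)), 1)
})

test_that("alternans model shows a period-2 APD sequence at its alternans CL", {
  r <- alternans_restitution()
  pc <- r$per_cl
  cl_alt <- pc$cl[which.max(pc$dapd)]
  b <- r$beats[r$beats$cl == cl_alt, ]
  apd <- b$apd90
  expect_gte(mean(abs(diff(apd))), 5)
  # period-2 structure: lag-2 autocorrelation of the APD sequence near 1
  expect_gt(cor(apd[-(1:2)], head(apd, -2)), 0.99)
  # alternating signs beat to beat
  dd <- diff(apd)
  expect_true(all(dd[-1] * head(dd, -1) < 0))
})

test_that("restitution carries state long-to-short and flags capture", {
  spec <- fast_model(scaling = parameter_scaling(s_GNa = 0))
  r <- run_restitution(spec, pacing_protocol(n_prebeats = 2, n_record = 4))
  expect_true(all(!r$per_cl$captured))
  expect_true(all(is.na(r$per_cl$dapd)))
})

test_that("self-clamp is a fixed point of the calcium dynamics", {
  spec <- fast_model()
  free <- pace(spec, 600, n_prebeats = 150, n_record = 2)
  wf <- clamp_waveform(free, beat = 2)
  clamped <- ap_clamp(spec, wf, n_beats = 4, initial_state = free$state)
  amp_free <- free$beats$cat_max[2] - free$beats$cat_min[2]
  amp_cl <- clamped$beats$cat_max - clamped$beats$cat_min
  expect_lt(max(abs(amp_cl - amp_free)) / amp_free, 0.02)
})

test_that("clamp rejects waveforms sampled coarser than 1 ms", {
  spec <- fast_model()
  wf <- data.frame(t = seq(0, 600, by = 2), v = -85)
  expect_error(ap_clamp(spec, wf, n_beats = 1), "1 ms or finer")
})
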