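# SRCB/SCB quadrature, conservation at steady state, and alternans closure.

test_that("synthetic flux integrals are exact", {
  t <- seq(0, 500, by = 0.5)
  jup <- ifelse(t < 100, 1e-3, 0)   # mM/ms (cytosol) for 100 ms
  tr <- data.frame(t = t, jup = jup, jrel = 0)
  # 1e-3 mM/ms * 100 ms = 0.1 mM = 100 umol/L; trapezoid clips half a sample
  # at the discontinuity
  expect_equal(srcb_per_beat(tr), 100, tolerance = 0.005)

  zero <- data.frame(t = t, ical = 0, icab = 0, ipca = 0, inaca_i = 0,
                     inaca_ss = 0)
  expect_identical(scb_per_beat(zero), 0)
})

test_that("steady-state balances are below 1% of their per-beat reference integrals", {
  bs <- baseline_cl1000()
  b <- bs$beats[2, ]
  expect_lt(abs(b$srcb), 0.01 * b$jrel_int)
  expect_lt(abs(b$scb), 0.01 * b$ical_influx)
  # trace-based quadrature agrees with the engine accumulator
  tr <- bs$trace[bs$trace$beat == b$beat, ]
  expect_lt(abs(srcb_per_beat(tr) - b$srcb), 0.02 * b$jrel_int)
})

test_that("two-beat closure during alternans: consecutive balances cancel", {
  bs <- alternans_steady()
  bb <- bs$beats[order(bs$beats$beat), ]
  mag_srcb <- mean(abs(bb$srcb))
  mag_scb <- mean(abs(bb$scb))
  pair_sum_srcb <- abs(bb$srcb[-1] + head(bb$srcb, -1))
  pair_sum_scb <- abs(bb$scb[-1] + head(bb$scb, -1))
  expect_lt(max(pair_sum_srcb) / mag_srcb, 0.02)
  expect_lt(max(pair_sum_scb) / mag_scb, 0.02)
  # opposite signs, similar magnitude
  expect_true(all(bb$srcb[-1] * head(bb$srcb, -1) < 0))
})

test_that("SRCB equals the change in total SR calcium content over a beat", {
  spec <- build_model()
  pre <- pace(spec, 1000, n_prebeats = 20, n_record = 0)
  one <- pace(spec, 1000, n_prebeats = 0, n_record = 1,
              initial_state = pre$state)
  k <- ord_constants()
  sr_content <- function(st) {
    csqn <- k$csqnmax * st["cajsr"] / (k$kmcsqn + st["cajsr"])
    (st["cansr"] * k$vnsr + (st["cajsr"] + csqn) * k$vjsr) / k$vmyo
  }
  delta <- unname(sr_content(one$state) - sr_content(pre$state)) * 1000
  # agreement scaled by the per-beat release integral (the natural magnitude)
  expect_lt(abs(delta - one$beats$srcb[1]) / one$beats$jrel_int[1], 0.005)
})

test_that("short window errors and parity labelling are sane", {
  tr <- data.frame(t = 0:10, jup = 1, jrel = 0)
  expect_error(srcb_per_beat(tr, beat_window = c(100, 200)), "window")
  r <- alternans_restitution()
  bal <- balance_table(r)
  cl_alt <- r$per_cl$cl[which.max(r$per_cl$dapd)]
  bb <- bal[bal$cl == cl_alt, ]
  expect_setequal(unique(bb$parity), c("short", "long"))
  # the short-APD beats indeed have the smaller APD
  expect_lt(mean(bb$apd90[bb$parity == "short"]),
            mean(bb$apd90[bb$parity == "long"]))
})

test_that("perfect proportionality gives r = 1 and anti-proportionality -1", {
  tab <- data.frame(cl = 500, dapd = c(5, 10, 20, 40),
                    srcb_short = c(1, 2, 4, 8))
  expect_equal(balance_alternans_correlation(tab)$r, 1)
  tab$srcb_short <- -tab$srcb_short  # magnitudes used, sign-robust
  expect_equal(balance_alternans_correlation(tab)$r, 1)
  tab2 <- data.frame(cl = 500, dapd = c(40, 30, 20, 10),
                     srcb_short = c(2, 4, 6, 8))
  expect_equal(balance_alternans_correlation(tab2)$r, -1)
  few <- data.frame(cl = 500, dapd = c(5, 10), srcb_short = c(1, 2))
  expect_true(is.na(balance_alternans_correlation(few)$r))
})

test_that("quadrature refinement: halving the sampling interval moves SRCB < 0.5%", {
  spec1 <- build_model(sample_dt = 0.5)
  spec2 <- build_model(sample_dt = 0.25)
  st <- pace(spec1, 1000, n_prebeats = 30, n_record = 0)$state
  b1 <- pace(spec1, 1000, 0, 1, initial_state = st)
  b2 <- pace(spec2, 1000, 0, 1, initial_state = st)
  s1 <- srcb_per_beat(b1$trace)
  s2 <- srcb_per_beat(b2$trace)
  ref <- b1$beats$jrel_int[1]   # per-beat release integral as scale
  expect_lt(abs(s1 - s2) / ref, 0.005)
})
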