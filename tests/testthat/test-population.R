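# Latin Hypercube sampling, population evaluation and calibration.

test_that("LHS stratification: one sample per stratum per dimension", {
  X <- lhs_sample(2, seed = 1)
  expect_true(all(colSums(X < 1) == 1 & colSums(X >= 1) == 1))
  X2 <- lhs_sample(100, seed = 2)
  bins <- apply(X2, 2, function(col) table(cut(col, breaks = seq(0, 2, 0.2))))
  expect_true(all(bins == 10))
  expect_true(all(X2 >= 0 & X2 <= 2))
})

test_that("LHS is reproducible under a fixed seed", {
  expect_identical(lhs_sample(50, seed = 123), lhs_sample(50, seed = 123))
  expect_false(identical(lhs_sample(50, seed = 123), lhs_sample(50, seed = 124)))
})

test_that("empty sample list gives an empty table; failures are recorded not dropped", {
  pop <- evaluate_population(matrix(numeric(0), 0, 11,
                                    dimnames = list(NULL, scaling_names())),
                             short_protocol())
  expect_equal(nrow(pop$models), 0)

  X <- rbind(rep(1, 11), c(2.5, rep(1, 10)))  # second row out of range
  colnames(X) <- scaling_names()
  pop <- do.call(evaluate_population,
                 c(list(X, pacing_protocol(n_prebeats = 2, n_record = 4),
                        biomarker_cls = numeric(0)), fast_solver))
  expect_equal(pop$models$status, c("ok", "failed"))
  expect_match(pop$models$reason[2], "within")
})

test_that("baseline sample reproduces the baseline restitution", {
  X <- matrix(1, 1, 11, dimnames = list(NULL, scaling_names()))
  pop <- do.call(evaluate_population,
                 c(list(X, short_protocol(), biomarker_cls = numeric(0)),
                   fast_solver))
  r <- cached("baseline_restitution", {
    run_restitution(fast_model(), short_protocol())
  })
  expect_equal(pop$per_cl$apd_odd, r$per_cl$apd_odd, tolerance = 1e-12)
})

test_that("calibration verdicts follow the envelope definition", {
  # synthetic population table: 2 models, 2 CLs
  pop <- structure(list(
    models = data.frame(model_id = 1:2,
                        matrix(1, 2, 11, dimnames = list(NULL, scaling_names())),
                        status = "ok", reason = ""),
    per_cl = data.frame(model_id = rep(1:2, each = 2),
                        cl = rep(c(600, 350), 2),
                        apd_odd = c(220, 190, 600, 400),
                        apd_even = c(220, 190, 600, 400),
                        dapd = 0, dcat = 0, mean_catamp = 3e-4,
                        mean_di = 200, captured = TRUE,
                        srcb_short = 0, scb_short = 0),
    biomarkers = NULL,
    protocol = pacing_protocol(cl_list = c(600, 350), n_prebeats = 1)),
    class = "population_table")
  wide <- data.frame(cl = c(600, 350), lower = 0, upper = 1e6)
  cal <- calibrate(pop, wide)
  expect_true(all(cal$models$accepted))

  tight <- data.frame(cl = c(600, 350), lower = c(150, 120),
                      upper = c(400, 350))
  cal2 <- calibrate(pop, tight)
  expect_equal(cal2$models$accepted, c(TRUE, FALSE))
  expect_match(cal2$models$reject_reason[2], "600")

  expect_error(calibrate(pop, data.frame(cl = 600, lower = 0, upper = 1)),
               "350")
})

test_that("acceptance is monotone in envelope width", {
  set.seed(4)
  base <- data.frame(cl = c(600, 350), lower = c(180, 150),
                     upper = c(280, 240))
  pop <- structure(list(
    models = data.frame(model_id = 1:30,
                        matrix(1, 30, 11, dimnames = list(NULL, scaling_names())),
                        status = "ok", reason = ""),
    per_cl = data.frame(model_id = rep(1:30, each = 2),
                        cl = rep(c(600, 350), 30),
                        apd_odd = runif(60, 120, 350),
                        dapd = 0, dcat = 0, mean_catamp = 3e-4,
                        mean_di = 200, captured = TRUE,
                        srcb_short = 0, scb_short = 0),
    biomarkers = NULL,
    protocol = pacing_protocol(cl_list = c(600, 350), n_prebeats = 1)),
    class = "population_table")
  pop$per_cl$apd_even <- pop$per_cl$apd_odd
  a1 <- calibrate(pop, base)$models$accepted
  wider <- transform(base, lower = lower - 30, upper = upper + 30)
  a2 <- calibrate(pop, wider)$models$accepted
  expect_true(all(a2[a1]))            # widening never rejects
  expect_gte(sum(a2), sum(a1))        # accepted fraction grows
})
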