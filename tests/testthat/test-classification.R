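# Restitution classification on hand-worked dAPD grids.

grid_result <- function(dapd, cl = c(600, 550, 500, 450, 400, 350),
                        dcat = rep(0, length(cl)),
                        catamp = rep(4e-4, length(cl)),
                        captured = rep(TRUE, length(cl))) {
  data.frame(cl = cl, dapd = dapd, dcat = dcat, mean_catamp = catamp,
             captured = captured)
}

test_that("hand-worked grids classify as normal / eye / fork / cat_only", {
  expect_equal(classify(grid_result(c(0, 0, 0, 0, 0, 0)))$label, "normal")

  eye <- classify(grid_result(c(0, 12, 20, 15, 6, 0)))
  expect_equal(eye$label, "eye")
  expect_equal(eye$onset_cl, 550)

  fork <- classify(grid_result(c(0, 0, 0, 8, 14, 20)))
  expect_equal(fork$label, "fork")
  expect_equal(fork$onset_cl, 450)

  fork2 <- classify(grid_result(c(0, 0, 0, 0, 0, 9)))
  expect_equal(fork2$label, "fork")
  expect_equal(fork2$onset_cl, 350)

  co <- classify(grid_result(c(0, 1, 2, 1, 0, 0),
                             dcat = c(0, 0, 4e-5, 0, 0, 0)))
  expect_equal(co$label, "cat_only")
  expect_true(is.na(co$onset_cl))
})

test_that("onset is the longest CL reaching threshold", {
  expect_equal(onset_cl(grid_result(c(0, 12, 20, 15, 6, 0))), 550)
  expect_equal(onset_cl(grid_result(c(0, 0, 0, 0, 0, 9))), 350)
  expect_error(onset_cl(grid_result(rep(0, 6))), "threshold")
})

test_that("capture-conditional rule: 2:1 block does not close the eye", {
  # alternans at 450-400, capture lost at 350: fastest *captured* CL is 400,
  # still alternating, so the bifurcation is open (fork)
  r <- grid_result(c(0, 0, 0, 8, 14, NA),
                   captured = c(rep(TRUE, 5), FALSE))
  expect_equal(classify(r)$label, "fork")
})

test_that("classification is threshold-monotone", {
  g <- grid_result(c(0, 12, 20, 15, 6, 0))
  labels <- vapply(c(2, 5, 10, 25), function(th)
    classify(g, apd_thresh = th)$label, "")
  expect_equal(labels, c("eye", "eye", "eye", "normal"))
  # raising the threshold never converts normal into an alternans class
  g0 <- grid_result(c(0, 1, 1, 1, 1, 0))
  expect_equal(classify(g0, apd_thresh = 5)$label, "normal")
  expect_equal(classify(g0, apd_thresh = 50)$label, "normal")
})

test_that("eye and fork are disjoint and exhaust APD-alternans grids", {
  set.seed(1)
  for (i in 1:50) {
    dapd <- round(runif(6, 0, 12), 1)
    cls <- classify(grid_result(dapd))
    has_apd_alt <- any(dapd >= 5)
    expect_equal(cls$label %in% c("eye", "fork"), has_apd_alt)
    if (has_apd_alt) {
      expected <- if (dapd[6] >= 5) "fork" else "eye"
      expect_equal(cls$label, expected)
      expect_equal(cls$onset_cl, max(c(600, 550, 500, 450, 400, 350)[dapd >= 5]))
    }
  }
})

test_that("classification needs at least two captured CLs", {
  r <- grid_result(c(0, NA, NA, NA, NA, NA),
                   captured = c(TRUE, rep(FALSE, 5)))
  expect_error(classify(r), "2 captured")
})
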