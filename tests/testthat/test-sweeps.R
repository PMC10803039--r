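test_that("classify_response labels canonical shapes", {
  expect_equal(classify_response(1:5, c(1, 2, 3, 4, 5))$label, "increasing")
  expect_equal(classify_response(1:5, c(5, 4, 3, 2, 1))$label, "decreasing")
  cl <- classify_response(1:5, c(1, 3, 5, 4, 2))
  expect_equal(cl$label, "unimodal_peak")
  expect_equal(cl$argmax, 3)
  expect_equal(classify_response(1:5, rep(2, 5))$label, "flat")
  expect_equal(classify_response(1:6, c(1, 3, 2, 4, 1, 3))$label, "irregular")
  # a peak with a flat-zero tail is still unimodal (oscillation death)
  expect_equal(classify_response(1:7, c(2, 4, 5, 3, 0, 0, 0))$label,
               "unimodal_peak")
  expect_error(classify_response(1:4, 1:4), "length")
})

test_that("log-bilinear interpolation is exact at nodes and matches brute force", {
  pd <- structure(list(k_eng = c(0.05, 0.1, 0.2, 0.4),
                       k_act = c(0.5, 1, 2),
                       frequency = matrix(c(6, 5, 4, 3,
                                            7, 6, 5, 4,
                                            5, 4, 3, 2), 4, 3),
                       f_engaged = matrix(0.5, 4, 3),
                       low_confidence = matrix(FALSE, 4, 3),
                       base_params = NULL, t_end = NA, t_burn = NA),
                  class = "gr_phase_diagram")
  for (i in seq_along(pd$k_eng)) for (j in seq_along(pd$k_act))
    expect_equal(interpolate_frequency(pd, pd$k_eng[i], pd$k_act[j]),
                 pd$frequency[i, j])
  # cell-center query of a {1,1,3,3} cell -> 2 under the bilinear rule
  pd2 <- pd
  pd2$frequency[1:2, 1:2] <- c(1, 1, 3, 3)
  qe <- exp(mean(log(pd$k_eng[1:2]))); qa <- exp(mean(log(pd$k_act[1:2])))
  expect_equal(interpolate_frequency(pd2, qe, qa), 2)
  # random interior points vs an independent bilinear evaluation
  set.seed(5)
  le <- log(pd$k_eng); la <- log(pd$k_act)
  for (k in 1:20) {
    qe <- runif(1, min(le), max(le)); qa <- runif(1, min(la), max(la))
    i <- findInterval(qe, le, rightmost.closed = TRUE)
    j <- findInterval(qa, la, rightmost.closed = TRUE)
    u <- (qe - le[i]) / (le[i + 1] - le[i])
    v <- (qa - la[j]) / (la[j + 1] - la[j])
    want <- (1 - u) * ((1 - v) * pd$frequency[i, j] + v * pd$frequency[i, j + 1]) +
      u * ((1 - v) * pd$frequency[i + 1, j] + v * pd$frequency[i + 1, j + 1])
    expect_equal(interpolate_frequency(pd, exp(qe), exp(qa)), want,
                 tolerance = 1e-12)
  }
  expect_error(interpolate_frequency(pd, 0.01, 1), "hull")
  expect_error(interpolate_frequency(pd, 0.1, 5), "hull")
})

test_that("phase diagram CSV round-trips", {
  pd <- structure(list(k_eng = c(0.1, 0.2), k_act = c(1, 2, 4),
                       frequency = matrix(1:6 + 0.5, 2, 3),
                       f_engaged = matrix(seq(0.1, 0.6, 0.1), 2, 3),
                       low_confidence = matrix(FALSE, 2, 3),
                       base_params = default_params(), t_end = NA, t_burn = NA),
                  class = "gr_phase_diagram")
  tmp <- tempfile(fileext = ".csv")
  write_phase_diagram_csv(pd, tmp)
  pd2 <- read_phase_diagram_csv(tmp)
  expect_equal(pd2$k_eng, pd$k_eng)
  expect_equal(pd2$k_act, pd$k_act)
  expect_equal(pd2$frequency, pd$frequency)
  expect_equal(pd2$f_engaged, pd$f_engaged)
})
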