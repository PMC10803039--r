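test_that("network enumeration yields 18 shared + 6 split = 24 unique ids", {
  nets <- enumerate_networks()
  expect_equal(nrow(nets), 24)
  expect_equal(sum(!nets$split), 18)
  expect_equal(sum(nets$split), 6)
  expect_equal(anyDuplicated(nets$id), 0)
  # split regimes are tied to the activation-effect direction
  sp <- nets[nets$split, ]
  expect_true(all(sp$s_on_activation != "none"))
  expect_true(all(sp$regime[sp$s_on_activation == "promote"] == "split_wt_high"))
  expect_true(all(sp$regime[sp$s_on_activation == "inhibit"] == "split_wt_low"))
  # deterministic ordering
  expect_identical(nets$id, enumerate_networks()$id)
})

test_that("point placement follows the factor rules (rule-replay oracle)", {
  conv <- default_convention()
  nets <- enumerate_networks()
  dir_fac <- function(eff, s) if (eff == "promote") s
    else if (eff == "inhibit") 1 / s else 1
  for (i in seq_len(nrow(nets))) {
    net <- as.list(nets[i, ])
    pts <- place_points(net, conv)
    # mutant: base point and engagement-only displacement on hard agar
    expect_equal(pts["sm_soft", "k_eng"], conv$k_eng0)
    expect_equal(pts["sm_hard", "k_eng"], conv$k_eng0 * conv$rho)
    expect_equal(pts["sm_soft", "k_act"], pts["sm_hard", "k_act"])
    # wild type: replay the rules step by step
    wt_base <- switch(net$regime, shared_low = conv$k_act_low,
                      shared_high = conv$k_act_high,
                      split_wt_high = conv$k_act_high * conv$delta_split,
                      split_wt_low = conv$k_act_low / conv$delta_split)
    expect_equal(pts["wt_soft", "k_eng"],
                 conv$k_eng0 * dir_fac(net$s_on_engagement, conv$sigma_soft))
    expect_equal(pts["wt_hard", "k_eng"],
                 conv$k_eng0 * conv$rho * dir_fac(net$s_on_engagement, conv$sigma_hard))
    expect_equal(pts["wt_soft", "k_act"],
                 wt_base * dir_fac(net$s_on_activation, conv$sigma_soft))
    expect_equal(pts["wt_hard", "k_act"],
                 wt_base * dir_fac(net$s_on_activation, conv$sigma_hard))
  }
})

test_that("no-effect shared networks place wild type on the mutant points", {
  conv <- default_convention()
  nets <- enumerate_networks()
  net <- as.list(nets[nets$s_on_engagement == "none" &
                        nets$s_on_activation == "none" &
                        nets$regime == "shared_low", ][1, ])
  pts <- place_points(net, conv)
  expect_equal(pts["wt_soft", ], pts["sm_soft", ], ignore_attr = TRUE)
  expect_equal(pts["wt_hard", ], pts["sm_hard", ], ignore_attr = TRUE)
})

test_that("engagement promotion separates the soft pair farther than the hard pair", {
  conv <- default_convention()
  nets <- enumerate_networks()
  net <- as.list(nets[nets$s_on_engagement == "promote" &
                        nets$s_on_activation == "none" &
                        nets$regime == "shared_low", ][1, ])
  pts <- place_points(net, conv)
  # same displacement direction, larger distance on soft agar
  d_soft <- log(pts["wt_soft", "k_eng"] / pts["sm_soft", "k_eng"])
  d_hard <- log(pts["wt_hard", "k_eng"] / pts["sm_hard", "k_eng"])
  expect_gt(d_soft, 0)
  expect_gt(d_hard, 0)
  expect_gt(d_soft, d_hard)
})

test_that("screening on a synthetic shaped diagram picks exactly the 3 activation-promoting split networks", {
  # synthetic diagram with the qualitative model shape: frequency decreasing
  # in k_eng; in k_act a gentle rise to a peak, a near-flat shoulder past
  # it, then a steep collapse (oscillation death) at high activation
  ke <- exp(seq(log(0.005), log(3), length.out = 16))
  ka <- exp(seq(log(0.01), log(400), length.out = 20))
  act_shape <- function(x) {
    lx <- log(x)
    ifelse(lx <= log(2), 0.92 + 0.08 * (lx - log(0.01)) / (log(2) - log(0.01)),
      ifelse(lx <= log(12), 1 - 0.03 * (lx - log(2)) / (log(12) - log(2)),
        pmax(0, 0.97 * (1 - (lx - log(12)) / (log(100) - log(12))))))
  }
  fr <- outer(seq_along(ke), seq_along(ka), function(i, j) {
    eng <- 6 - 3.5 * (log(ke[i]) - log(0.005)) / (log(3) - log(0.005))
    pmax(eng, 0.3) * act_shape(ka[j])
  })
  pd <- structure(list(k_eng = ke, k_act = ka, frequency = fr,
                       f_engaged = matrix(0.5, 16, 20),
                       low_confidence = matrix(FALSE, 16, 20),
                       base_params = NULL, t_end = NA, t_burn = NA),
                  class = "gr_phase_diagram")
  conv <- default_convention(k_eng0 = 0.03, rho = 7, sigma_soft = 3,
                             sigma_hard = 1.3, k_act_low = 0.4,
                             k_act_high = 2, delta_split = 10)
  sc <- screen_networks(enumerate_networks(), pd, conv, check_shape = FALSE)
  expect_equal(sum(sc$viable), 3)
  expect_true(all(sc$s_on_activation[sc$viable] == "promote"))
  expect_true(all(sc$split[sc$viable]))
  expect_true(all(!sc$viable[!sc$split]))
  # the mutant prediction is network-independent: soft > hard everywhere
  expect_true(all(sc$f_sm_soft > sc$f_sm_hard))
  # outcome is stable under +/-20% perturbation of the convention factors
  rb <- screen_robustness(enumerate_networks(), pd, conv)
  expect_true(rb$stable)
  expect_equal(length(rb$viable_ids), 3)
})
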