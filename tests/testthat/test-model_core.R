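test_that("default parameters carry the anchored values and round-trip", {
  p <- default_params()
  expect_equal(p$v_a, 2)            # um/s, active-motor speed
  expect_equal(p$v_c_max, 2)        # um/min, maximal cell speed
  expect_equal(p$geometry$L, 5)     # um, cell length
  expect_equal(p$geometry$dx, 5 / p$geometry$n_cells)

  tmp <- tempfile(fileext = ".json")
  save_config(p, tmp)
  p2 <- load_config(tmp)$params
  expect_equal(p2, p)
})

test_that("parameter validation names the offending field", {
  expect_error(default_params(k_eng = -1), "k_eng")
  expect_error(default_params(K_AB = 0), "K_AB")
  expect_error(default_params(theta = 0.7), "theta")
  expect_error(default_params(nonsense = 1), "nonsense")
  expect_error(default_params(n_AB = 0.5), "n_AB")
})

test_that("geometry invariants hold", {
  g <- cell_geometry(L = 5, n_cells = 60, pole_width = 0.3)
  expect_equal(sum(g$wl) * g$dx, 0.3)
  expect_equal(sum(g$wr) * g$dx, 0.3)
  expect_error(cell_geometry(n_cells = 4), "n_cells")
  expect_error(cell_geometry(pole_width = 0.01), "pole_width")
  expect_error(cell_geometry(pole_width = 3), "overlap")
})

test_that("mass_totals matches a brute-force per-cell accumulation", {
  p <- tiny_params()
  g <- p$geometry
  # all-zero state
  st0 <- initial_state(p)
  st0$pools[] <- 0; st0$fields[] <- 0
  expect_equal(unname(mass_totals(st0)), rep(0, 4))
  # only engaged motors: each carries one MglA
  st1 <- st0
  st1$fields[, "M_ep"] <- 0.7
  tt <- mass_totals(st1)
  expect_equal(unname(tt["A_total"]), 0.7 * g$n_cells * g$dx)
  expect_equal(unname(tt["M_total"]), 0.7 * g$n_cells * g$dx)
  # random state vs independent loop
  st <- random_state(p, seed = 42)
  tt <- mass_totals(st)
  acc <- c(A = sum(st$pools[c("A_l", "A_r")]), B = sum(st$pools[c("B_l", "B_r")]),
           R = sum(st$pools[c("R_l", "R_r")]), M = 0)
  for (j in seq_len(g$n_cells)) {
    f <- st$fields[j, ]
    acc["A"] <- acc["A"] + (f[["a"]] + f[["M_ap"]] + f[["M_am"]] +
                              f[["M_ep"]] + f[["M_em"]]) * g$dx
    acc["B"] <- acc["B"] + f[["b"]] * g$dx
    acc["R"] <- acc["R"] + f[["r"]] * g$dx
    acc["M"] <- acc["M"] + (f[["M_i"]] + f[["M_ap"]] + f[["M_am"]] +
                              f[["M_ep"]] + f[["M_em"]]) * g$dx
  }
  expect_equal(unname(tt), unname(acc), tolerance = 1e-12)
})

test_that("bin_profile partitions mass over the 8 subdomains", {
  g <- cell_geometry()
  # uniform field: cytoplasmic bins proportional to width, sum preserved
  total <- 60
  b <- bin_profile(rep(1, g$n_cells), g)
  expect_equal(sum(b), total, tolerance = 1e-9)
  inner <- (g$L - 2 * g$pole_width) / 6          # width of one c-bin
  expect_equal(unname(b[paste0("c", 1:6)]),
               rep(total * inner / g$L, 6), tolerance = 1e-9)
  # delta mass in the leftmost cell lands in bin l
  d <- rep(0, g$n_cells); d[1] <- 5
  bd <- bin_profile(d, g)
  expect_equal(unname(bd["l"]), 5)
  expect_equal(sum(bd[-1]), 0)
  # random fields: partition property against an enumeration oracle
  for (seed in 1:5) {
    set.seed(seed)
    f <- runif(g$n_cells)
    bb <- bin_profile(f, g)
    expect_equal(sum(bb), sum(f), tolerance = 1e-9)
    expect_true(all(bb >= -1e-12))
    # polar bins match direct overlap-weight sums
    expect_equal(unname(bb["l"]), sum(g$wl * f), tolerance = 1e-12)
    expect_equal(unname(bb["r"]), sum(g$wr * f), tolerance = 1e-12)
  }
  expect_error(bin_profile(rep(1, 10), g), "length")
})
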