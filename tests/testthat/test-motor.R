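test_that("traversal_time reproduces the printed timescales", {
  expect_equal(traversal_time(5, 2), 2.5)      # active motor, whole cell
  expect_equal(traversal_time(0, 2), 0)
  expect_equal(traversal_time(5, 2 / 60), 150) # engaged motor at cell speed
  expect_error(traversal_time(5, 0), "v")
})

test_that("cell velocity saturates with engaged motors and follows polar MglA", {
  p <- tiny_params()
  st <- initial_state(p)
  st$fields[, c("M_ep", "M_em")] <- 0
  expect_equal(cell_velocity(st, p), 0)  # E = 0
  # E = K_v -> half-maximal speed; direction toward the larger MglA pool
  st$pools["A_l"] <- 0.4; st$pools["A_r"] <- 0.1
  st$fields[, "M_ep"] <- p$K_v / (p$geometry$n_cells * p$geometry$dx)
  expect_equal(cell_velocity(st, p), -(p$v_c_max / 60) / 2)
  # E -> infinity: magnitude approaches v_c_max = 2 um/min
  st$fields[, "M_ep"] <- 1e6
  expect_equal(abs(cell_velocity(st, p)) * 60, 2, tolerance = 1e-4)
  # exactly equal pools: zero velocity
  st$pools["A_r"] <- st$pools["A_l"]
  expect_equal(cell_velocity(st, p), 0)
})

test_that("motor_rhs limits: uniform diffusion-only and two-state switching", {
  p <- tiny_params(k_act = 0, k_eng = 0)
  st <- initial_state(p)
  st$pools[] <- 0
  rhs <- motor_rhs(st, p, v_cell = 0)
  expect_equal(max(abs(rhs$dfields)), 0)  # uniform M_i, nothing active
  # pure switching: M_ap = c, M_am = 0, v_a = 0
  p2 <- tiny_params(v_a = 0, k_act = 0, k_eng = 0, k_deact = 0)
  st2 <- initial_state(p2)
  st2$pools[] <- 0
  st2$fields[, "M_i"] <- 0
  st2$fields[, "M_ap"] <- 0.3
  rhs2 <- motor_rhs(st2, p2, v_cell = 0)
  expect_equal(rhs2$dfields[, "M_ap"], rep(-p2$k_sw * 0.3, p2$geometry$n_cells))
  expect_equal(rhs2$dfields[, "M_am"], rep(+p2$k_sw * 0.3, p2$geometry$n_cells))
  expect_equal(unname(rhs2$dA_pools), c(0, 0))
})

test_that("upwind advection matches the hand-computed stencil", {
  fx <- make_fixture("step_advection")
  # one explicit Euler step of the first-order upwind scheme on the pulse
  p <- default_params(n_cells = 10, L = 5, pole_width = 0.5, v_a = fx$v, k_sw = 0, k_act = 0,
                      k_eng = 0, k_deact = 0, D_i = 0)
  st <- initial_state(p)
  st$pools[] <- 0
  st$fields[] <- 0
  st$fields[, "M_ap"] <- fx$q0
  rhs <- motor_rhs(st, p, v_cell = 0)
  stepped <- fx$q0 + fx$dt * rhs$dfields[, "M_ap"]
  expect_equal(stepped, fx$q1)
  # mass is conserved by the closed walls
  expect_equal(sum(rhs$dfields[, "M_ap"]), 0, tolerance = 1e-14)
})

test_that("activation consumes polar MglA exactly as the fields gain it", {
  p <- tiny_params()
  for (seed in 1:3) {
    st <- random_state(p, seed)
    rhs <- motor_rhs(st, p)
    dx <- p$geometry$dx
    # MglA gained by active+engaged fields equals the polar pools' loss
    dA_fields <- sum(rhs$dfields[, c("M_ap", "M_am", "M_ep", "M_em")]) * dx
    expect_equal(dA_fields, -sum(rhs$dA_pools), tolerance = 1e-12)
    # total motor number is conserved by the kinetics
    expect_equal(sum(rhs$dfields) * dx, 0, tolerance = 1e-12)
  }
})

test_that("frozen-regulator motor subsystem matches the matrix exponential", {
  fx <- make_fixture("linear_toy_6cell")
  p <- fx$params
  st <- fx$state
  t_end <- 10
  tr <- simulate_cell(p, t_end = t_end, output_dt = t_end, snapshot_dt = 0,
                      state0 = st, freeze_regulators = TRUE,
                      fixed_v_cell = 0, dt_max = 2e-4)
  y <- tr$state_final
  n <- p$geometry$n_cells
  got <- matrix(y[-(1:6)], n, 8)[, 4:8]  # M_i, M_ap, M_am, M_ep, M_em
  y0 <- as.numeric(st$fields[, c("M_i", "M_ap", "M_am", "M_ep", "M_em")])
  want <- matrix(as.numeric(Matrix::expm(fx$A * t_end) %*% y0), n, 5)
  expect_lt(max(abs(got - want)), 1e-8)
  # pools untouched when regulators are frozen
  expect_equal(y[1:6], unname(st$pools))
})
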