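test_that("hill multipliers obey their identities", {
  expect_equal(hill_up(0, 1, 2), 0)
  expect_equal(hill_up(1, 1, 2), 0.5)   # half-saturation
  expect_equal(hill_down(1, 1, 2), 0.5)
  expect_equal(hill_up(3, 1, 2), 9 / 10) # closed form: 9/(1+9)
  expect_equal(hill_down(0, 2, 3), 1)
  set.seed(1)
  x <- runif(20, 0, 5)
  expect_equal(hill_up(x, 1.3, 2) + hill_down(x, 1.3, 2), rep(1, 20))
  expect_error(hill_up(1, 0, 2), "K")
})

test_that("polarity fluxes match an independent term-by-term evaluation", {
  p <- tiny_params()
  st <- random_state(p, seed = 7)
  fl <- polarity_fluxes(st, p)
  g <- p$geometry
  hu <- function(x, K, n) x^n / (K^n + x^n)
  hd <- function(x, K, n) K^n / (K^n + x^n)
  for (pl in c("l", "r")) {
    w <- if (pl == "l") g$wl else g$wr
    a_p <- sum(w * st$fields[, "a"]) * g$dx / g$pole_width
    b_p <- sum(w * st$fields[, "b"]) * g$dx / g$pole_width
    r_p <- sum(w * st$fields[, "r"]) * g$dx / g$pole_width
    A <- st$pools[[paste0("A_", pl)]]
    B <- st$pools[[paste0("B_", pl)]]
    R <- st$pools[[paste0("R_", pl)]]
    pick <- function(sp, col) fl[fl$species == sp & fl$pole == pl, col]
    expect_equal(pick("A", "J_on"),
                 p$k_Aon * a_p * hu(R, p$K_RA, p$n_RA) * hd(B, p$K_BA, p$n_BA))
    expect_equal(pick("A", "J_off"),
                 (p$k_Aoff_basal + p$k_Aoff * hu(B, p$K_BA, p$n_BA)) * A)
    expect_equal(pick("B", "J_on"),
                 p$k_Bon * b_p * hd(A, p$K_AB, p$n_AB) *
                   (1 + p$beta * hu(B, p$K_BB, p$n_BB)))
    expect_equal(pick("B", "J_off"), p$k_Boff * B)
    expect_equal(pick("R", "J_on"),
                 p$k_Ron * r_p * (1 + p$gamma * hu(B, p$K_BB, p$n_BB)))
    expect_equal(pick("R", "J_off"), p$k_Roff * R)
  }
  expect_true(all(fl$J_on >= 0) && all(fl$J_off >= 0))
})

test_that("symmetric states give symmetric fluxes; zero MglB gives basal MglA off-flux", {
  p <- tiny_params()
  st <- initial_state(p, eps = 0)  # exactly symmetric
  st$pools[] <- c(0.2, 0.2, 0.1, 0.1, 0.3, 0.3)
  fl <- polarity_fluxes(st, p)
  for (sp in c("A", "B", "R")) for (col in c("J_on", "J_off"))
    expect_equal(fl[fl$species == sp & fl$pole == "l", col],
                 fl[fl$species == sp & fl$pole == "r", col])
  st$pools["B_l"] <- 0
  fl <- polarity_fluxes(st, p)
  expect_equal(fl[fl$species == "A" & fl$pole == "l", "J_off"],
               p$k_Aoff_basal * 0.2)
})

test_that("regulatory sign structure holds on random states", {
  p <- tiny_params()
  eps <- 1e-6
  for (seed in 1:5) {
    st <- random_state(p, seed)
    get <- function(st, sp, pl, col)
      polarity_fluxes(st, p)[with(polarity_fluxes(st, p),
                                  species == sp & pole == pl), col]
    bump <- function(pool) { s <- st; s$pools[pool] <- s$pools[pool] + eps; s }
    # dJ_on(B,l)/dA_l <= 0 (MglA inhibits MglB recruitment)
    expect_lte(get(bump("A_l"), "B", "l", "J_on"), get(st, "B", "l", "J_on"))
    # dJ_on(A,l)/dR_l >= 0 (RomR promotes MglA recruitment)
    expect_gte(get(bump("R_l"), "A", "l", "J_on"), get(st, "A", "l", "J_on"))
    # dJ_on(R,l)/dB_l >= 0 (MglB promotes RomR recruitment)
    expect_gte(get(bump("B_l"), "R", "l", "J_on"), get(st, "R", "l", "J_on"))
    # dJ_off(A,l)/dB_l >= 0 (MglB expels polar MglA)
    expect_gte(get(bump("B_l"), "A", "l", "J_off"), get(st, "A", "l", "J_off"))
  }
})
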