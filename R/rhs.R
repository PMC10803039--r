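#' Full model right-hand side (reference implementation)
#'
#' Combines [polarity_fluxes()], [motor_rhs()], polar exchange of the free
#' cytoplasmic species and diffusion into the complete time-derivative of a
#' state. This pure-R evaluation is the reference the compiled engine is
#' verified against; it is far too slow for production integration.
#'
#' @param state A `gr_state`.
#' @param params A `gr_params`.
#' @return List: `dpools` (named length-6), `dfields` (n x 8 matrix),
#'   `v_cell` (um/s).
#' @export
full_rhs <- function(state, params) {
  g <- params$geometry
  n <- g$n_cells; dx <- g$dx; W <- g$pole_width
  f <- state$fields
  fl <- polarity_fluxes(state, params)
  v_cell <- cell_velocity(state, params)
  mot <- motor_rhs(state, params, v_cell)

  J <- function(sp, pl, col) fl[fl$species == sp & fl$pole == pl, col]
  dpools <- stats::setNames(numeric(6), POOL_NAMES)
  for (sp in c("A", "B", "R")) for (pl in c("l", "r"))
    dpools[paste0(sp, "_", pl)] <- J(sp, pl, "J_on") - J(sp, pl, "J_off")
  dpools["A_l"] <- dpools["A_l"] + mot$dA_pools["A_l"]
  dpools["A_r"] <- dpools["A_r"] + mot$dA_pools["A_r"]

  lap <- function(q) {
    d <- numeric(n)
    d[1] <- q[2] - q[1]
    d[2:(n - 1)] <- q[1:(n - 2)] - 2 * q[2:(n - 1)] + q[3:n]
    d[n] <- q[n - 1] - q[n]
    d / dx^2
  }
  # polar exchange of a free species: on-flux removes proportional to the
  # local density; off-flux deposits uniformly over the polar region
  exch <- function(q, sp) {
    d <- numeric(n)
    for (pl in c("l", "r")) {
      w <- if (pl == "l") g$wl else g$wr
      S <- sum(w * q) * dx
      Jon <- J(sp, pl, "J_on"); Joff <- J(sp, pl, "J_off")
      rem <- if (S > 0) Jon * w * q / S else 0 * q
      d <- d - rem + Joff * w / W
    }
    d
  }
  dfields <- matrix(0, n, 8, dimnames = list(NULL, FIELD_NAMES))
  dfields[, "a"] <- params$D_A * lap(f[, "a"]) + exch(f[, "a"], "A")
  dfields[, "b"] <- params$D_B * lap(f[, "b"]) + exch(f[, "b"], "B")
  dfields[, "r"] <- params$D_R * lap(f[, "r"]) + exch(f[, "r"], "R")
  dfields[, colnames(mot$dfields)] <- mot$dfields
  list(dpools = dpools, dfields = dfields, v_cell = v_cell)
}

# evaluate the compiled RHS on a gr_state, unpacked to the same shape
# as full_rhs() (internal; used to verify the engine against the reference)
cpp_rhs_wrap <- function(params, state) {
  dy <- cpp_rhs(params_to_clist(params), state_to_vector(state))
  n <- params$geometry$n_cells
  list(dpools = stats::setNames(dy[1:6], POOL_NAMES),
       dfields = matrix(dy[-(1:6)], n, 8, dimnames = list(NULL, FIELD_NAMES)))
}
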