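#' Cell velocity from engaged motors
#'
#' Speed saturates with the total engaged-motor amount E as
#' `v_c_max * E / (E + K_v)` (um/min converted to um/s internally); the
#' direction points toward the pole holding more MglA (the leading pole,
#' where the motility machineries are activated). Zero when the polar MglA
#' amounts are exactly equal.
#'
#' @param state A `gr_state`.
#' @param params A `gr_params`.
#' @return Signed velocity, um/s (positive = rightward).
#' @export
cell_velocity <- function(state, params) {
  stopifnot(inherits(state, "gr_state"), inherits(params, "gr_params"))
  E <- sum(state$fields[, c("M_ep", "M_em")]) * state$geometry$dx
  dirn <- sign(unname(state$pools["A_r"] - state$pools["A_l"]))
  dirn * (params$v_c_max / 60) * E / (E + params$K_v)
}

#' Pole-to-pole traversal time
#'
#' Time for a motor moving at speed `v` to traverse a length `L`; with the
#' typical cell length (5 um) and active-motor speed (2 um/s) this is 2.5 s,
#' against ~150 s for an engaged motor drifting at the cell speed.
#'
#' @param L Length, um.
#' @param v Speed, um/s (> 0).
#' @return Time in seconds, `L / v`.
#' @examples
#' traversal_time(5, 2)      # 2.5 s
#' traversal_time(5, 2 / 60) # 150 s, engaged-motor timescale
#' @export
traversal_time <- function(L, v) {
  if (v <= 0) stop("v must be > 0")
  L / v
}

#' Time-derivatives of the motor fields (reference implementation)
#'
#' Pure-R evaluation of the five motor-field equations: diffusion of
#' inactive motors, polar activation (consuming one polar MglA per motor,
#' split between the two directions according to `act_split`), polar
#' MglB-mediated deactivation (returning the MglA), directional switching,
#' engagement/disengagement (engagement only outside the polar regions,
#' fast disengagement at the poles), first-order upwind advection of active
#' motors at `v_a` and of engaged motors at the cell speed toward the
#' trailing pole. The compiled engine implements the same terms; this
#' function exists for direct inspection and as the reference the engine is
#' tested against.
#'
#' @param state A `gr_state`.
#' @param params A `gr_params`.
#' @param v_cell Signed cell velocity, um/s; engaged motors advect at
#'   `-v_cell` in the cell frame. Defaults to [cell_velocity()].
#' @return List: `dfields` (n x 5 matrix, columns `M_i`, `M_ap`, `M_am`,
#'   `M_ep`, `M_em`, amount/um/s) and `dA_pools` (MglA exchange with the
#'   two polar pools: `-activation + deactivation`, amount/s).
#' @export
motor_rhs <- function(state, params, v_cell = cell_velocity(state, params)) {
  stopifnot(inherits(state, "gr_state"), inherits(params, "gr_params"))
  g <- params$geometry
  n <- g$n_cells; dx <- g$dx
  if (abs(v_cell) > params$v_c_max / 60 + 1e-12)
    stop("|v_cell| exceeds v_c_max")
  f <- state$fields; po <- state$pools
  wl <- g$wl; wr <- g$wr; cj <- 1 - wl - wr
  Mi <- f[, "M_i"]; Map <- f[, "M_ap"]; Mam <- f[, "M_am"]
  Mep <- f[, "M_ep"]; Mem <- f[, "M_em"]

  lap <- function(q) {
    d <- numeric(n)
    d[1] <- q[2] - q[1]
    d[2:(n - 1)] <- q[1:(n - 2)] - 2 * q[2:(n - 1)] + q[3:n]
    d[n] <- q[n - 1] - q[n]
    d / dx^2
  }
  upwind <- function(q, u) {
    d <- numeric(n)
    if (u == 0) return(d)
    if (u > 0) {
      d[1] <- -u * q[1] / dx
      d[2:(n - 1)] <- u * (q[1:(n - 2)] - q[2:(n - 1)]) / dx
      d[n] <- u * q[n - 1] / dx
    } else {
      d[1] <- -u * q[2] / dx
      d[2:(n - 1)] <- -u * (q[3:n] - q[2:(n - 1)]) / dx
      d[n] <- u * q[n] / dx
    }
    d
  }

  actL <- params$k_act * po["A_l"] * wl * Mi
  actR <- params$k_act * po["A_r"] * wr * Mi
  kdeact <- params$k_deact * (po["B_l"] * wl + po["B_r"] * wr)
  kdis <- params$k_dis * cj + params$k_dis_pole * (1 - cj)
  if (params$act_split == "half") {
    toMap <- 0.5 * (actL + actR); toMam <- toMap
  } else {
    toMap <- actL; toMam <- actR
  }
  u_e <- -v_cell

  dMi <- params$D_i * lap(Mi) - (actL + actR) + kdeact * (Map + Mam)
  dMap <- upwind(Map, params$v_a) + toMap - params$k_sw * Map +
    params$k_sw * Mam - params$k_eng * cj * Map + kdis * Mep - kdeact * Map
  dMam <- upwind(Mam, -params$v_a) + toMam + params$k_sw * Map -
    params$k_sw * Mam - params$k_eng * cj * Mam + kdis * Mem - kdeact * Mam
  dMep <- upwind(Mep, u_e) + params$k_eng * cj * Map - kdis * Mep
  dMem <- upwind(Mem, u_e) + params$k_eng * cj * Mam - kdis * Mem

  dfields <- cbind(M_i = dMi, M_ap = dMap, M_am = dMam,
                   M_ep = dMep, M_em = dMem)
  dA_pools <- c(A_l = unname(-sum(actL) * dx +
                               params$k_deact * po["B_l"] *
                               sum(wl * (Map + Mam)) * dx),
                A_r = unname(-sum(actR) * dx +
                               params$k_deact * po["B_r"] *
                               sum(wr * (Map + Mam)) * dx))
  list(dfields = dfields, dA_pools = dA_pools)
}
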