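#' Polar binding/unbinding fluxes of the polarity network
#'
#' Evaluates the on- and off-fluxes (amount/s) of MglA, MglB and RomR at
#' each pole for a given state. The signed regulatory structure is: RomR
#' promotes and MglB opposes polar MglA recruitment; MglB additionally
#' expels polar MglA (GAP action, modeled as enhanced off-flux returning
#' MglA to the diffusive cytoplasmic pool); MglA inhibits polar MglB
#' recruitment while MglB promotes its own; MglB promotes polar RomR
#' recruitment. All multipliers are Hill-type ([hill_up()]/[hill_down()]):
#'
#' \deqn{J_{on}(A,p) = k_{Aon} a_p \, h^+(R_p;K_{RA}) h^-(B_p;K_{BA})}
#' \deqn{J_{off}(A,p) = (k_{Aoff,0} + k_{Aoff} h^+(B_p;K_{BA})) A_p}
#' \deqn{J_{on}(B,p) = k_{Bon} b_p \, h^-(A_p;K_{AB}) (1+\beta h^+(B_p;K_{BB}))}
#' \deqn{J_{off}(B,p) = k_{Boff} B_p}
#' \deqn{J_{on}(R,p) = k_{Ron} r_p \, (1+\gamma h^+(B_p;K_{BB}))}
#' \deqn{J_{off}(R,p) = k_{Roff} R_p}
#'
#' where \eqn{a_p, b_p, r_p} are the mean free densities over the polar
#' region adjacent to pole \eqn{p}. Every on-flux removes from the adjacent
#' cytoplasm exactly what it adds to the pool (local conservation).
#'
#' @param state A `gr_state`.
#' @param params A `gr_params`.
#' @return A data frame with columns `species` (A/B/R), `pole` (l/r),
#'   `J_on`, `J_off` (amount/s).
#' @export
polarity_fluxes <- function(state, params) {
  stopifnot(inherits(state, "gr_state"), inherits(params, "gr_params"))
  g <- params$geometry
  if (nrow(state$fields) != g$n_cells) stop("state does not match params grid")
  if (min(state$fields[, c("a", "b", "r")]) < -1e-9 ||
      min(state$pools) < -1e-9)
    stop("negative state entries beyond tolerance")
  W <- g$pole_width; dx <- g$dx
  po <- state$pools
  avg <- function(col, w) sum(w * state$fields[, col]) * dx / W
  out <- expand.grid(species = c("A", "B", "R"), pole = c("l", "r"),
                     stringsAsFactors = FALSE)
  out$J_on <- NA_real_; out$J_off <- NA_real_
  for (i in seq_len(nrow(out))) {
    pl <- out$pole[i]
    w <- if (pl == "l") g$wl else g$wr
    A <- po[paste0("A_", pl)]; B <- po[paste0("B_", pl)]; R <- po[paste0("R_", pl)]
    if (out$species[i] == "A") {
      out$J_on[i] <- params$k_Aon * avg("a", w) *
        hill_up(R, params$K_RA, params$n_RA) *
        hill_down(B, params$K_BA, params$n_BA)
      out$J_off[i] <- (params$k_Aoff_basal +
                         params$k_Aoff * hill_up(B, params$K_BA, params$n_BA)) * A
    } else if (out$species[i] == "B") {
      out$J_on[i] <- params$k_Bon * avg("b", w) *
        hill_down(A, params$K_AB, params$n_AB) *
        (1 + params$beta * hill_up(B, params$K_BB, params$n_BB))
      out$J_off[i] <- params$k_Boff * B
    } else {
      out$J_on[i] <- params$k_Ron * avg("r", w) *
        (1 + params$gamma * hill_up(B, params$K_BB, params$n_BB))
      out$J_off[i] <- params$k_Roff * R
    }
  }
  out
}
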