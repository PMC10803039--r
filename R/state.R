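#' Model state
#'
#' A `gr_state` holds the six polar pools (`A_l`, `A_r`, `B_l`, `B_r`,
#' `R_l`, `R_r`, amounts), the eight cytoplasmic fields as an
#' `n_cells x 8` matrix of densities (amount/um) with columns
#' `a`, `b`, `r` (free MglA, MglB, RomR) and `M_i`, `M_ap`, `M_am`,
#' `M_ep`, `M_em` (motor states; `+` moves right, `-` moves left), and the
#' geometry. Active and engaged motors each carry one MglA.
#'
#' @name gr_state
NULL

FIELD_NAMES <- c("a", "b", "r", "M_i", "M_ap", "M_am", "M_ep", "M_em")
POOL_NAMES <- c("A_l", "A_r", "B_l", "B_r", "R_l", "R_r")

#' Deterministic seeded-asymmetry initial state
#'
#' All species start uniformly distributed in the cytoplasm and all motors
#' inactive, except that 1% of the MglA total is placed in one polar pool to
#' break the left-right symmetry deterministically (no randomness). The
#' perturbed pool is `A_l` by default; `mirror = TRUE` perturbs `A_r`
#' instead, which must produce the mirrored trajectory.
#'
#' @param params A [default_params()] object.
#' @param mirror Perturb the right instead of the left pole.
#' @param eps Perturbation size as a fraction of `A_tot` (default 0.01).
#' @return A `gr_state`.
#' @export
initial_state <- function(params, mirror = FALSE, eps = 0.01) {
  stopifnot(inherits(params, "gr_params"))
  g <- params$geometry
  n <- g$n_cells
  fields <- matrix(0, n, 8, dimnames = list(NULL, FIELD_NAMES))
  pert <- eps * params$A_tot
  fields[, "a"] <- (params$A_tot - pert) / g$L
  fields[, "b"] <- params$B_tot / g$L
  fields[, "r"] <- params$R_tot / g$L
  fields[, "M_i"] <- params$M_tot / g$L
  pools <- stats::setNames(numeric(6), POOL_NAMES)
  pools[if (mirror) "A_r" else "A_l"] <- pert
  structure(list(pools = pools, fields = fields, s_v = 0L, geometry = g),
            class = "gr_state")
}

#' Conserved totals of a model state
#'
#' Bookkeeping for the conserved quantities. Motor-bound MglA (one molecule
#' per active or engaged motor) counts toward the MglA total:
#' `A_total = A_l + A_r + int a dx + int (M_ap+M_am+M_ep+M_em) dx`. The
#' other totals are the polar pools plus the free field integral (B, R), and
#' the integral over all five motor fields (M).
#'
#' @param state A `gr_state`.
#' @param geom Optional [cell_geometry()] (defaults to the state's own).
#' @return Named numeric: `A_total`, `B_total`, `R_total`, `M_total`.
#' @export
mass_totals <- function(state, geom = state$geometry) {
  stopifnot(inherits(state, "gr_state"))
  f <- state$fields
  if (nrow(f) != geom$n_cells) stop("state fields do not match geometry grid")
  dx <- geom$dx
  motA <- sum(f[, c("M_ap", "M_am", "M_ep", "M_em")]) * dx
  c(A_total = unname(state$pools["A_l"] + state$pools["A_r"]) +
      sum(f[, "a"]) * dx + motA,
    B_total = unname(state$pools["B_l"] + state$pools["B_r"]) +
      sum(f[, "b"]) * dx,
    R_total = unname(state$pools["R_l"] + state$pools["R_r"]) +
      sum(f[, "r"]) * dx,
    M_total = sum(f[, c("M_i", "M_ap", "M_am", "M_ep", "M_em")]) * dx)
}

# ---- packing helpers (engine state vector layout) ----

state_to_vector <- function(state) {
  c(unname(state$pools), as.numeric(state$fields))
}

vector_to_state <- function(y, geom) {
  n <- geom$n_cells
  stopifnot(length(y) == 6 + 8 * n)
  pools <- stats::setNames(y[1:6], POOL_NAMES)
  fields <- matrix(y[-(1:6)], n, 8, dimnames = list(NULL, FIELD_NAMES))
  structure(list(pools = pools, fields = fields,
                 s_v = as.integer(sign(pools["A_r"] - pools["A_l"])),
                 geometry = geom),
            class = "gr_state")
}

#' @export
print.gr_state <- function(x, ...) {
  t <- mass_totals(x)
  cat("<gr_state>", x$geometry$n_cells, "grid cells;",
      sprintf("totals A=%.4f B=%.4f R=%.4f M=%.4f\n",
              t["A_total"], t["B_total"], t["R_total"], t["M_total"]))
  invisible(x)
}
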