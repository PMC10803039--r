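#' One-dimensional cell geometry
#'
#' The cell is a 1D axis of length `L` discretized into `n_cells` uniform
#' grid cells. The outermost `pole_width` micrometres at each end form the
#' polar regions: the polar protein pools are well-mixed zero-dimensional
#' compartments that exchange material with the cytoplasmic grid cells lying
#' inside these regions, and motor activation/deactivation is restricted to
#' them.
#'
#' @param L Cell length, um (default 5, a typical M. xanthus cell).
#' @param n_cells Number of grid cells (>= 6; default 60, fine enough for the
#'   fast active-motor advection).
#' @param pole_width Width of each polar region, um (default 0.3); must be at
#'   least one grid cell and the two regions must not overlap.
#' @return An object of class `gr_geometry`: list with `L`, `n_cells`,
#'   `pole_width`, `dx`, and the per-cell polar overlap weights `wl`, `wr`
#'   (fraction of each cell inside the left/right polar region).
#' @examples
#' g <- cell_geometry()
#' sum(g$wl) * g$dx  # == pole_width
#' @export
cell_geometry <- function(L = 5, n_cells = 60, pole_width = 0.3) {
  stopifnot(L > 0, n_cells >= 6)
  dx <- L / n_cells
  if (pole_width < dx) stop("pole_width must be at least one grid cell (dx)")
  if (2 * pole_width > L) stop("polar regions must not overlap")
  xs <- seq(0, L, length.out = n_cells + 1)
  wl <- pmax(0, pmin(xs[-1], pole_width) - xs[-(n_cells + 1)]) / dx
  wr <- pmax(0, xs[-1] - pmax(xs[-(n_cells + 1)], L - pole_width)) / dx
  structure(list(L = L, n_cells = n_cells, pole_width = pole_width, dx = dx,
                 wl = wl, wr = wr, x_centers = xs[-1] - dx / 2),
            class = "gr_geometry")
}

#' Bin a spatial profile into the standard 8 reporting subdomains
#'
#' Collapses a per-cell profile into the polar bins `l` and `r` (cells inside
#' the polar regions, by overlap weight) plus six contiguous near-equal
#' cytoplasmic bins `c1..c6`, the convention used for reporting spatial
#' distributions. The bin sums exactly preserve the field total.
#'
#' @param field Per-cell amounts (length `n_cells`); interpreted as amounts
#'   per cell, not densities.
#' @param geom A [cell_geometry()] object.
#' @return Named numeric vector of length 8 (`l`, `c1`..`c6`, `r`).
#' @examples
#' g <- cell_geometry()
#' bin_profile(rep(1, g$n_cells), g)
#' @export
bin_profile <- function(field, geom) {
  stopifnot(inherits(geom, "gr_geometry"))
  n <- geom$n_cells
  if (length(field) != n) stop("field length must equal n_cells")
  wl <- geom$wl; wr <- geom$wr
  l <- sum(wl * field); r <- sum(wr * field)
  cyt <- (1 - wl - wr) * field
  # cytoplasmic span [pole_width, L - pole_width] split into 6 equal bins
  edges <- seq(geom$pole_width, geom$L - geom$pole_width, length.out = 7)
  xs0 <- seq(0, geom$L, length.out = n + 1)[-(n + 1)]
  xs1 <- xs0 + geom$dx
  cw <- pmax(0, pmin(xs1, geom$L - geom$pole_width) - pmax(xs0, geom$pole_width))
  cbin <- numeric(6)
  for (k in 1:6) {
    ov <- pmax(0, pmin(xs1, edges[k + 1]) - pmax(xs0, edges[k]))
    frac <- ifelse(cw > 0, ov / cw, 0)
    cbin[k] <- sum(frac * cyt)
  }
  out <- c(l = l, cbin, r = r)
  names(out) <- c("l", paste0("c", 1:6), "r")
  out
}
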