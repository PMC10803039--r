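#' Model parameters with calibrated defaults
#'
#' Builds the full parameter set of the coupled polarity/A-motor model. The
#' shipped defaults are the committed output of [calibrate_baseline()]: they
#' give a reversal period of ~12 min with about half of the MglA outside the
#' polar regions, and an engaged-motor fraction in the mid of its calibrated
#' range.
#'
#' Units: lengths um, time s, amounts normalized so every protein total is
#' 1.0. Exceptions: `v_c_max` is in um/min (the scale on which cell speeds
#' are quoted); reversal frequencies are reported per hour.
#'
#' @param ... Named overrides of any default, e.g. `k_eng = 0.2`. Geometry
#'   fields (`L`, `n_cells`, `pole_width`) may be overridden directly.
#' @return Object of class `gr_params`: a named list with a nested
#'   `geometry` ([cell_geometry()]) element.
#'
#' @section Parameters:
#' \describe{
#'   \item{A_tot, B_tot, R_tot, M_tot}{protein/motor totals (normalized).}
#'   \item{v_a}{active-motor speed along the track, um/s (2).}
#'   \item{v_c_max}{maximal cell speed, um/min (2).}
#'   \item{k_sw}{direction-switch rate of active motors, 1/s.}
#'   \item{k_act, k_deact}{polar motor (de)activation rate constants,
#'     1/(amount s); activation consumes one polar MglA per motor,
#'     deactivation returns it.}
#'   \item{k_eng, k_dis}{engagement/disengagement rates, 1/s; `k_eng` is the
#'     substrate-stiffness proxy. `k_dis_pole` is the fast disengagement of
#'     engaged motors that reach a pole.}
#'   \item{D_i, D_A, D_B, D_R}{diffusivities, um^2/s.}
#'   \item{k_Aon, k_Aoff_basal, k_Aoff, k_Bon, k_Boff, k_Ron, k_Roff}{polar
#'     binding/unbinding rate constants of MglA, MglB, RomR.}
#'   \item{beta, gamma}{strength of MglB self-promotion and of MglB's
#'     promotion of RomR recruitment.}
#'   \item{K_AB, K_BA, K_RA, K_BB, n_AB, n_BA, n_RA, n_BB}{Hill constants
#'     and exponents of the four regulatory interactions.}
#'   \item{theta}{Schmitt-trigger hysteresis for reversal detection,
#'     fraction of the polarity-indicator amplitude.}
#'   \item{K_v}{engaged-motor amount at half-maximal cell speed.}
#'   \item{act_split}{`"half"`: newly activated motors split 50/50 between
#'     the two directions; `"away"`: all leave their pole.}
#' }
#' @examples
#' p <- default_params()
#' p$v_a          # 2 um/s
#' p$geometry$L   # 5 um
#' @export
default_params <- function(...) {
  p <- list(
    # totals
    A_tot = 1, B_tot = 1, R_tot = 1, M_tot = 1,
    # speeds
    v_a = 2,        # um/s
    v_c_max = 2,    # um/min
    # motor kinetics (k_act, k_eng calibrated; see calibrate_baseline)
    k_sw = 0.2,
    k_act = 0.3,
    k_deact = 3,
    k_eng = 0.086,
    k_dis = 0.01,
    k_dis_pole = 0.5,
    K_v = 0.2,
    # diffusion
    D_i = 0.083, D_A = 1, D_B = 1, D_R = 1,
    # polarity network
    k_Aon = 9.69, k_Aoff_basal = 0.526, k_Aoff = 0.387,
    k_Bon = 1.66, k_Boff = 0.154,
    k_Ron = 0.0271, k_Roff = 0.00223,
    beta = 6.9, gamma = 8.77,
    K_AB = 0.07, K_BA = 0.391, K_RA = 0.599, K_BB = 0.0915,
    n_AB = 2, n_BA = 2, n_RA = 2, n_BB = 2,
    # detection / misc
    theta = 0.1,
    act_split = "half"
  )
  geo <- list(L = 5, n_cells = 60, pole_width = 0.3)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named")
    for (nm in names(ov)) {
      if (nm %in% names(geo)) geo[[nm]] <- ov[[nm]]
      else if (nm == "geometry") {
        stopifnot(inherits(ov[[nm]], "gr_geometry"))
        geo <- ov[[nm]][c("L", "n_cells", "pole_width")]
      } else if (nm %in% names(p)) p[[nm]] <- ov[[nm]]
      else stop("unknown parameter: ", nm)
    }
  }
  p$geometry <- cell_geometry(geo$L, geo$n_cells, geo$pole_width)
  class(p) <- "gr_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks nonnegativity of all rates, speeds, totals and diffusivities,
#' positivity of Hill constants, Hill exponents >= 1, and the hysteresis
#' theta in (0, 0.5). Errors name the offending field.
#'
#' @param p A `gr_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "gr_params"))
  nonneg <- c("A_tot", "B_tot", "R_tot", "M_tot", "v_a", "v_c_max", "k_sw",
              "k_act", "k_deact", "k_eng", "k_dis", "k_dis_pole", "K_v",
              "D_i", "D_A", "D_B", "D_R", "k_Aon", "k_Aoff_basal", "k_Aoff",
              "k_Bon", "k_Boff", "k_Ron", "k_Roff", "beta", "gamma")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a nonnegative number")
  }
  for (nm in c("K_AB", "K_BA", "K_RA", "K_BB"))
    if (!(p[[nm]] > 0)) stop("parameter '", nm, "' must be > 0")
  for (nm in c("n_AB", "n_BA", "n_RA", "n_BB"))
    if (!(p[[nm]] >= 1)) stop("parameter '", nm, "' must be >= 1")
  if (!(p$theta > 0 && p$theta < 0.5)) stop("parameter 'theta' must be in (0, 0.5)")
  if (!p$act_split %in% c("half", "away"))
    stop("parameter 'act_split' must be \"half\" or \"away\"")
  invisible(p)
}

#' Modify a parameter set
#'
#' @param p A `gr_params` object.
#' @param ... Named overrides (see [default_params()]).
#' @return A new validated `gr_params`.
#' @export
set_params <- function(p, ...) {
  stopifnot(inherits(p, "gr_params"))
  ov <- list(...)
  geo <- p$geometry[c("L", "n_cells", "pole_width")]
  for (nm in names(ov)) {
    if (nm %in% names(geo)) geo[[nm]] <- ov[[nm]]
    else if (nm %in% names(p)) p[[nm]] <- ov[[nm]]
    else stop("unknown parameter: ", nm)
  }
  p$geometry <- cell_geometry(geo$L, geo$n_cells, geo$pole_width)
  validate_params(p)
  p
}

#' Set a parameter by path name
#'
#' Accepts either a flat kinetic name (`"k_eng"`) or a geometry field
#' (`"L"`, `"n_cells"`, `"pole_width"`); used by the sweep machinery.
#' @param p A `gr_params` object.
#' @param name Parameter name.
#' @param value New value.
#' @return Updated `gr_params`.
#' @export
set_param <- function(p, name, value) {
  args <- stats::setNames(list(value), name)
  do.call(set_params, c(list(p), args))
}

#' @export
print.gr_params <- function(x, ...) {
  cat("<gr_params> coupled polarity/A-motor model parameters\n")
  cat(sprintf("  geometry: L=%g um, n_cells=%d, pole_width=%g um\n",
              x$geometry$L, x$geometry$n_cells, x$geometry$pole_width))
  cat(sprintf("  motors:   k_act=%g k_deact=%g k_eng=%g k_dis=%g k_sw=%g\n",
              x$k_act, x$k_deact, x$k_eng, x$k_dis, x$k_sw))
  cat(sprintf("  speeds:   v_a=%g um/s, v_c_max=%g um/min\n", x$v_a, x$v_c_max))
  invisible(x)
}

# flatten for the C++ engine
params_to_clist <- function(p) {
  out <- p[setdiff(names(p), "geometry")]
  out$L <- p$geometry$L
  out$n_cells <- p$geometry$n_cells
  out$pole_width <- p$geometry$pole_width
  out
}
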